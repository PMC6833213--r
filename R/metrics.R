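## Validation indicators comparing online estimates with offline DCW
## observations, over two accounting windows (since inoculation, since feed
## start).

checkPairs <- function(estimates, observations) {
  if (length(estimates) == 0L || length(estimates) != length(observations))
    stopInvalidInput("estimates (%d) and observations (%d) must be non-empty and of equal length",
                     length(estimates), length(observations))
}

#' Mean absolute error
#'
#' @param estimates estimated values.
#' @param observations observed values (same length).
#' @return mean of absolute differences (g/l when comparing biomass).
#' @examples
#' mae(c(2, 4), c(1, 6))   # 1.5
#' @export
mae <- function(estimates, observations) {
  checkPairs(estimates, observations)
  mean(abs(estimates - observations))
}

#' Mean absolute percentage error
#'
#' @inheritParams mae
#' @return `100/n * sum(|est - obs| / |obs|)`, in percent.  A zero
#'   observation is an error: silently dropping the point would bias
#'   windowed comparisons.
#' @examples
#' mape(c(1, 3), c(2, 2))   # 50
#' @export
mape <- function(estimates, observations) {
  checkPairs(estimates, observations)
  if (any(observations == 0))
    stopInvalidInput("zero observation: MAPE undefined")
  100 * mean(abs((estimates - observations) / observations))
}

#' Root mean square error
#'
#' @inheritParams mae
#' @return square root of the mean squared difference; never smaller than
#'   [mae()] on the same pair.
#' @examples
#' rmse(c(2, 4), c(1, 6))   # sqrt(2.5)
#' @export
rmse <- function(estimates, observations) {
  checkPairs(estimates, observations)
  sqrt(mean((estimates - observations)^2))
}

#' Windowed evaluation of an estimated trajectory against offline samples
#'
#' Matches every offline DCW sample to the nearest trajectory point (within
#' half the median online interval) and reports MAE, MAPE and RMSE over the
#' full window since inoculation and over the window since feed start.
#'
#' @param trajectory a [BiomassTrajectory-class].
#' @param offline an [OfflineDataset-class].
#' @param feedStart feed start time, h (default 0: both windows coincide).
#' @return list with `maeSinceInoculation`, `maeSinceFeedStart` (g/l),
#'   `mapeSinceInoculation`, `mapeSinceFeedStart` (percent),
#'   `rmseSinceInoculation`, `rmseSinceFeedStart` (g/l) and the per-window
#'   point counts `nSinceInoculation`, `nSinceFeedStart`.
#' @export
evaluateEstimation <- function(trajectory, offline, feedStart = 0) {
  tt <- trajectory@times
  tol <- stats::median(diff(tt)) / 2
  idx <- vapply(offline@sampleTimes, function(s) which.min(abs(tt - s)), integer(1))
  off <- abs(tt[idx] - offline@sampleTimes)
  if (any(off > tol + 1e-12))
    stopInvalidInput("offline sample time(s) %s not matched by the trajectory grid (tolerance %.4g h)",
                     paste(signif(offline@sampleTimes[off > tol + 1e-12], 6),
                           collapse = ", "), tol)
  est <- trajectory@xEstimates[idx]
  obs <- offline@biomass
  inFeed <- offline@sampleTimes >= feedStart
  if (!any(inFeed))
    stopInvalidInput("no offline samples at or after feed start (%.4g h)", feedStart)
  list(maeSinceInoculation = mae(est, obs),
       maeSinceFeedStart = mae(est[inFeed], obs[inFeed]),
       mapeSinceInoculation = mape(est, obs),
       mapeSinceFeedStart = mape(est[inFeed], obs[inFeed]),
       rmseSinceInoculation = rmse(est, obs),
       rmseSinceFeedStart = rmse(est[inFeed], obs[inFeed]),
       nSinceInoculation = length(obs),
       nSinceFeedStart = sum(inFeed))
}
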