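## Stage A: offline identification of oxygen-consumption stoichiometry.
##
## The weighted residual criterion S (an entropy maximisation: S <= 0, with
## S = 0 only at a perfect fit) is quadratic in (alpha, k1), so its maximiser
## is the solution of a 2x2 linear system assembled from the offline samples.
## The activation time tI enters non-linearly and is found by exhaustive
## search over a candidate grid.

#' Inverse-variance weight of an offline sample
#'
#' The uncertainty of a cumulative-OUR observation is modelled with a
#' Monod-form dependence on biomass,
#' `var_m ~ X_m^2 / (kExp * X_m^2 + (1 - kExp))`.  This function returns the
#' reciprocal, `(kExp * X_m^2 + (1 - kExp)) / X_m^2`, used as the
#' inverse-variance weight in the fitting criterion.  `kExp = 1` gives
#' uniform weights (ordinary least squares); `kExp = 0` gives variance
#' proportional to `X^2` (squared-percentage-error weighting).
#'
#' @param x biomass concentration(s), g/l, positive (zero allowed only when
#'   `kExp = 1`).
#' @param kExp weight coefficient in \[0, 1\].
#' @return inverse-variance weight(s), same length as `x`.
#' @examples
#' uncertaintyWeight(2, kExp = 0)    # 0.25
#' uncertaintyWeight(5, kExp = 0.4)  # 0.424
#' @export
uncertaintyWeight <- function(x, kExp) {
  if (length(kExp) != 1L || is.na(kExp) || kExp < 0 || kExp > 1)
    stopInvalidInput("kExp must be a single value in [0, 1]")
  x <- as.numeric(x)
  if (kExp == 1) return(rep(1, length(x)))
  if (any(x == 0))
    stopInvalidInput("zero biomass with kExp < 1: weight diverges")
  (kExp * x^2 + (1 - kExp)) / x^2
}

## Discrete maintenance regressor R_m = sum_{l <= m, t_l > tI}
## (t_l - tI) * X_l * dt_{l,l-1} over the offline sample grid, with the first
## interval measured from inoculation (t0 = 0).  Terms with t_l <= tI
## contribute zero (a negative (t_l - tI) factor would produce unphysical
## negative maintenance).
maintenanceRegressor <- function(sampleTimes, biomass, tI, t0 = 0) {
  dt <- diff(c(t0, sampleTimes))
  term <- ifelse(sampleTimes > tI, (sampleTimes - tI) * biomass * dt, 0)
  cumsum(term)
}

#' Entropy criterion for a stoichiometric parameter point
#'
#' Evaluates the (non-positive) fitting criterion
#' `S = -sum_m w_m (cOUR_m - pred_m)^2` over the offline samples, where the
#' model prediction is `alpha * (X_m - X0)` up to the activation time and
#' gains the discrete maintenance term `k1 * R_m` afterwards, and `w_m` is
#' the Monod-form inverse-variance weight ([uncertaintyWeight()]).  `S = 0`
#' exactly when the model reproduces every offline sample.
#'
#' @param dataset an [OfflineDataset-class].
#' @param cour observed cumulative oxygen uptake at the offline sample times,
#'   g O2/l (align with [courAtTimes()]).
#' @param alpha,k1,tI parameter point to evaluate.
#' @param kExp weight coefficient in \[0, 1\].
#' @return a list with `sValue` (<= 0), the evaluated `alpha`, `k1`, `tI`,
#'   `kExp`, and the per-sample weighted residual contributions
#'   `weightedResiduals` (`sqrt(w_m) * residual_m`).
#' @export
entropyCriterion <- function(dataset, cour, alpha, k1, tI, kExp) {
  tt <- dataset@sampleTimes
  if (length(cour) != length(tt))
    stopInvalidInput("cour (%d) not aligned with offline sample times (%d)",
                     length(cour), length(tt))
  x <- dataset@biomass
  w <- uncertaintyWeight(x, kExp)
  r <- maintenanceRegressor(tt, x, tI)
  resid <- cour - alpha * (x - dataset@x0) - k1 * r
  list(sValue = -sum(w * resid^2), alpha = alpha, k1 = k1, tI = tI,
       kExp = kExp, weightedResiduals = sqrt(w) * resid)
}

#' Closed-form stoichiometry solve at a fixed activation time
#'
#' Maximises the entropy criterion over (alpha, k1) at a given activation
#' time tI.  The criterion is an (entropy-weighted) quadratic form, so the
#' maximiser solves the 2x2 linear system
#' `[[B, C], [E, F]] %*% c(alpha, k1) == c(A, D)` with
#' `A = sum w g c`, `B = sum w g^2` (over all samples, g = X_m - X0),
#' `C = E = sum w g R`, `D = sum w c R`, `F = sum w R^2` (over post-tI
#' samples; R is the discrete maintenance regressor).  When no sample falls
#' after tI the system degenerates to the one-parameter solution
#' `alpha = A / B`, `k1 = 0`.
#'
#' @inheritParams entropyCriterion
#' @param tI activation time, h.
#' @return list with `alpha`, `k1`, `gramWeight` (the B coefficient, used as
#'   the pooling weight across experiments), and `nPost` (number of samples
#'   after tI).
#' @export
solveStoichiometry <- function(dataset, cour, tI, kExp) {
  tt <- dataset@sampleTimes
  if (length(cour) != length(tt))
    stopInvalidInput("cour (%d) not aligned with offline sample times (%d)",
                     length(cour), length(tt))
  x <- dataset@biomass
  g <- x - dataset@x0
  w <- uncertaintyWeight(x, kExp)
  r <- maintenanceRegressor(tt, x, tI)
  post <- tt > tI

  A <- sum(w * g * cour)
  B <- sum(w * g^2)
  if (B == 0)
    stopDegenerateFit("all offline samples equal X0: growth regressor vanishes")
  if (!any(post))
    return(list(alpha = A / B, k1 = 0, gramWeight = B, nPost = 0L))

  C <- sum(w * g * r)
  D <- sum(w * cour * r)
  E <- C
  F <- sum(w * r^2)
  det <- B * F - C * E
  if (!is.finite(det) || abs(det) <= 1e-12 * max(abs(B * F), abs(C * E), 1e-300))
    stopDegenerateFit(
      "singular normal equations: growth and maintenance regressors are collinear")
  alpha <- (A * F - C * D) / det
  k1 <- (B * D - E * A) / det
  list(alpha = alpha, k1 = k1, gramWeight = B, nPost = sum(post))
}

#' Search for the maintenance activation time
#'
#' For strains without a known induction time (yeast), the activation time tI
#' is identified by exhaustive search over a candidate grid: at each
#' candidate the closed-form solve ([solveStoichiometry()]) is followed by an
#' evaluation of the entropy criterion at the solution, and the candidate
#' with the largest criterion wins (ties break toward the earliest
#' candidate, which activates maintenance conservatively soon).
#'
#' @inheritParams entropyCriterion
#' @param candidates candidate activation times, h; default: the offline
#'   sample times after the first one.  Candidates outside
#'   `(first sample time, last sample time]` are dropped with a warning.
#' @return list with `tI`, `alpha`, `k1`, `gramWeight`, `trace` (a
#'   data.frame of candidate tI and criterion values, sorted by candidate)
#'   and `flags`.
#' @export
findInductionTime <- function(dataset, cour, kExp, candidates = NULL) {
  tt <- dataset@sampleTimes
  if (is.null(candidates))
    candidates <- tt[tt > tt[1L]]
  candidates <- sort(unique(as.numeric(candidates)))
  keep <- candidates > tt[1L] & candidates <= tt[length(tt)]
  if (!all(keep)) {
    warnDataQuality("%d candidate activation time(s) outside (%.4g, %.4g] dropped",
                    sum(!keep), tt[1L], tt[length(tt)])
    candidates <- candidates[keep]
  }
  if (!length(candidates))
    stopInvalidInput("no usable activation-time candidates")

  fits <- vector("list", length(candidates))
  sVals <- rep(NA_real_, length(candidates))
  for (j in seq_along(candidates)) {
    fit <- tryCatch(solveStoichiometry(dataset, cour, candidates[j], kExp),
                    coursense_degenerate_fit = function(e) NULL)
    if (is.null(fit)) next
    fits[[j]] <- fit
    sVals[j] <- entropyCriterion(dataset, cour, fit$alpha, fit$k1,
                                 candidates[j], kExp)$sValue
  }
  if (all(is.na(sVals)))
    stopDegenerateFit("every activation-time candidate produced a degenerate fit")

  ## ties (within floating-point noise on the criterion's natural scale)
  ## resolve to the earliest candidate: maintenance activates conservatively
  ## soon, and a flat region (perfect single-phase fit) returns its start
  scale <- sum(uncertaintyWeight(dataset@biomass, kExp) * cour^2)
  best <- which(sVals >= max(sVals, na.rm = TRUE) - 1e-10 * max(scale, 1e-300))[1L]
  fit <- fits[[best]]
  flags <- character()
  if (fit$nPost == 0L)
    flags <- c(flags,
               "no offline samples after the activation time: maintenance unidentifiable (k1 = 0)")
  list(tI = candidates[best], alpha = fit$alpha, k1 = fit$k1,
       gramWeight = fit$gramWeight,
       trace = data.frame(candidate_t_i = candidates, s_value = sVals),
       flags = flags)
}

#' Ordinary least-squares polynomial fit of beta against biomass
#'
#' Regresses the maintenance coefficient values recovered in Stage A
#' (`beta(X_m) ~= k1 * (t_m - tI)` for post-activation samples) against
#' biomass concentration with an ordinary least-squares polynomial of the
#' stated degree (1 for yeast-like strains, 2 for E. coli-like strains).
#'
#' @param betaSamples data.frame with columns `x` (biomass g/l) and `beta`
#'   (maintenance coefficient).
#' @param degree polynomial degree, 1 or 2.
#' @return a [MaintenanceModel-class] with `xSpecific` computed by
#'   [computeXSpecific()].
#' @export
fitMaintenancePolynomial <- function(betaSamples, degree = 2L) {
  degree <- as.integer(degree)
  if (!degree %in% c(1L, 2L))
    stopInvalidInput("degree must be 1 or 2")
  if (!is.data.frame(betaSamples) || !all(c("x", "beta") %in% names(betaSamples)))
    stopInvalidInput("betaSamples must be a data.frame with columns 'x' and 'beta'")
  xd <- length(unique(betaSamples$x))
  if (nrow(betaSamples) < degree + 1L || xd < degree + 1L)
    stopInvalidInput("need at least %d samples with distinct biomass values, got %d",
                     degree + 1L, xd)
  fit <- if (degree == 2L)
    stats::lm(beta ~ x + I(x^2), data = betaSamples)
  else
    stats::lm(beta ~ x, data = betaSamples)
  if (fit$rank < degree + 1L)
    stopDegenerateFit("rank-deficient beta(X) regression")
  cf <- stats::coef(fit)
  maintenanceModel(kBeta2 = if (degree == 2L) unname(cf["I(x^2)"]) else 0,
                   kBeta1 = unname(cf["x"]),
                   kBeta0 = unname(cf["(Intercept)"]),
                   degree = degree)
}

#' Strain-specific biomass threshold from the maintenance polynomial
#'
#' Solves beta(X) = 0 for the biomass concentration above which maintenance
#' consumption stops being negligible.  Degree 1: the line's root
#' `-kBeta0 / kBeta1`.  Degree 2: the real root at which beta turns positive
#' with increasing biomass (the larger root of a convex parabola, the
#' smaller root of a concave one); if the discriminant is negative (the
#' parabola never crosses zero, as for the published E. coli coefficients)
#' the stationary point `-kBeta1 / (2 kBeta2)` is used instead and the
#' result is flagged with attribute `stationaryFallback = TRUE`.
#'
#' @param model a [MaintenanceModel-class] (its `xSpecific` slot is ignored).
#' @return the threshold in g/l (positive), with attribute
#'   `stationaryFallback`.
#' @examples
#' computeXSpecific(maintenanceModel(0, 2.3851e-3, -1.5014e-2, xSpecific = 1,
#'                                   degree = 1))   # 6.29 g/l
#' @export
computeXSpecific <- function(model) {
  fallback <- FALSE
  if (model@degree == 1L) {
    if (model@kBeta1 == 0)
      stopInvalidModel("degree-1 maintenance model with zero slope has no root")
    xs <- -model@kBeta0 / model@kBeta1
  } else {
    a <- model@kBeta2; b <- model@kBeta1; cc <- model@kBeta0
    if (a == 0)
      stopInvalidModel("degree-2 maintenance model with zero quadratic coefficient")
    disc <- b^2 - 4 * a * cc
    if (disc >= 0) {
      roots <- (-b + c(-1, 1) * sqrt(disc)) / (2 * a)
      ## the activation threshold is the root where beta turns positive with
      ## increasing X: the larger root for a convex parabola (positive again
      ## above it), the smaller one for a concave parabola (positive between
      ## the roots)
      xs <- if (a > 0) max(roots) else min(roots)
    } else {
      xs <- -b / (2 * a)
      fallback <- TRUE
    }
  }
  if (!is.finite(xs) || xs <= 0)
    stopInvalidModel("non-positive biomass threshold (%.4g g/l) from maintenance model", xs)
  structure(xs, stationaryFallback = fallback)
}

#' Fit strain stoichiometric parameters from one or more experiments (Stage A)
#'
#' Full offline identification: for each experiment the cOUR signal is
#' aligned with the offline sample times, the activation time is either taken
#' from the dataset (known induction, E. coli) or found by criterion search
#' ([findInductionTime()]), and (alpha, k1) are solved in closed form.  The
#' per-experiment growth yields are pooled with Gram-matrix weights (the B
#' coefficient of the normal equations), the recovered (biomass, maintenance)
#' pairs are pooled across experiments, and the biomass-parameterised
#' maintenance polynomial and its threshold X_specific are fitted from the
#' pooled scatter.
#'
#' @param experiments a list of experiments; each entry is either a
#'   [SyntheticExperiment-class] or a list with elements `offline` (an
#'   [OfflineDataset-class]) and `our` (an [OURSeries-class]).
#' @param kExp weight coefficient in \[0, 1\] (default 0.4).
#' @param degree requested degree of the maintenance polynomial (default 2).
#' @param candidates optional candidate grid for the activation-time search.
#' @param autoDegree when TRUE (default) a degree-2 fit whose negative
#'   quadratic coefficient makes beta decreasing over the observed biomass
#'   range is downgraded to degree 1.
#' @param strainLabel label stored in the result.
#' @return a [StageAFit-class]; the fitted parameter set is in its
#'   `strainParameters` slot.
#' @export
fitStrain <- function(experiments, kExp = 0.4, degree = 2L, candidates = NULL,
                      autoDegree = TRUE, strainLabel = "strain") {
  if (is(experiments, "SyntheticExperiment") ||
      (is.list(experiments) && !is.null(names(experiments)) &&
       all(c("offline", "our") %in% names(experiments))))
    experiments <- list(experiments)
  if (!is.list(experiments) || !length(experiments))
    stopInvalidInput("at least one experiment is required")

  perExperiment <- vector("list", length(experiments))
  betaSamples <- data.frame(x = numeric(), beta = numeric(),
                            experiment = character())
  traces <- list()
  flags <- character()

  for (i in seq_along(experiments)) {
    exper <- experiments[[i]]
    if (is(exper, "SyntheticExperiment"))
      exper <- list(offline = exper@offlineDataset, our = exper@observedOurSeries)
    if (!is(exper$offline, "OfflineDataset") || !is(exper$our, "OURSeries"))
      stopInvalidInput("experiment %d must provide an OfflineDataset and an OURSeries", i)
    ds <- exper$offline
    label <- ds@label

    cour <- tryCatch(
      courAtTimes(exper$our, ds@sampleTimes),
      coursense_error = function(e)
        stopInvalidInput("experiment '%s': %s", label, conditionMessage(e)))

    if (is.finite(ds@inductionTime)) {
      fit <- solveStoichiometry(ds, cour, ds@inductionTime, kExp)
      tI <- ds@inductionTime
      trace <- data.frame(candidate_t_i = numeric(), s_value = numeric())
      expFlags <- character()
    } else {
      search <- findInductionTime(ds, cour, kExp, candidates)
      fit <- search[c("alpha", "k1", "gramWeight")]
      tI <- search$tI
      trace <- search$trace
      expFlags <- search$flags
    }
    crit <- entropyCriterion(ds, cour, fit$alpha, fit$k1, tI, kExp)

    post <- ds@sampleTimes > tI
    if (any(post))
      betaSamples <- rbind(betaSamples, data.frame(
        x = ds@biomass[post],
        beta = fit$k1 * (ds@sampleTimes[post] - tI),
        experiment = label))

    if (nrow(trace)) traces[[length(traces) + 1L]] <-
      cbind(experiment = label, trace)
    flags <- c(flags, if (length(expFlags)) paste0(label, ": ", expFlags))
    perExperiment[[i]] <- list(label = label, alpha = fit$alpha, k1 = fit$k1,
                               tI = tI, gramWeight = fit$gramWeight,
                               sValue = crit$sValue,
                               weightedResiduals = crit$weightedResiduals,
                               flags = expFlags)
  }

  wts <- vapply(perExperiment, `[[`, numeric(1), "gramWeight")
  alphas <- vapply(perExperiment, `[[`, numeric(1), "alpha")
  k1s <- vapply(perExperiment, `[[`, numeric(1), "k1")
  tIs <- vapply(perExperiment, `[[`, numeric(1), "tI")
  alpha <- sum(wts * alphas) / sum(wts)
  k1 <- sum(wts * k1s) / sum(wts)
  tI <- sum(wts * tIs) / sum(wts)

  degree <- as.integer(degree)
  if (nrow(betaSamples) >= degree + 1L &&
      length(unique(betaSamples$x)) >= degree + 1L &&
      any(betaSamples$beta != 0)) {
    if (!autoDegree) {
      model <- fitMaintenancePolynomial(betaSamples, degree)
    } else {
      model <- NULL
      if (degree == 2L) {
        ## a concave parabola (kBeta2 < 0) makes beta eventually decrease
        ## with biomass, which is physically implausible for maintenance
        ## consumption; fall back to the linear model
        m2 <- tryCatch(fitMaintenancePolynomial(betaSamples, 2L),
                       coursense_invalid_model = function(e) NULL)
        if (!is.null(m2) && m2@kBeta2 >= 0) model <- m2
        else flags <- c(flags,
          "degree-2 beta(X) fit concave or without positive activation root; downgraded to degree 1")
      }
      if (is.null(model))
        model <- tryCatch(fitMaintenancePolynomial(betaSamples, 1L),
                          coursense_invalid_model = function(e) NULL)
      if (is.null(model)) {
        ## beta positive over the whole observed range: maintenance starts at
        ## (or below) the first post-activation sample
        cf <- stats::coef(stats::lm(beta ~ x, data = betaSamples))
        model <- new("MaintenanceModel", kBeta2 = 0, kBeta1 = cf[["x"]],
                     kBeta0 = cf[["(Intercept)"]],
                     xSpecific = min(betaSamples$x), degree = 1L,
                     stationaryFallback = FALSE)
        flags <- c(flags,
          "fitted beta(X) has no positive root; X_specific set to the smallest post-activation biomass")
      }
    }
  } else {
    flags <- c(flags, "no identifiable maintenance: beta(X) fixed at zero")
    model <- new("MaintenanceModel", kBeta2 = 0, kBeta1 = 0, kBeta0 = 0,
                 xSpecific = Inf, degree = 1L, stationaryFallback = FALSE)
  }
  if (model@stationaryFallback)
    flags <- c(flags,
               "beta(X) parabola has no real root; X_specific taken at its stationary point")

  params <- strainParameters(alpha = alpha, maintenance = model, k1 = k1,
                             tI = tI, kExp = kExp, strainLabel = strainLabel)
  new("StageAFit", strainParameters = params, perExperiment = perExperiment,
      betaSamples = betaSamples,
      criterionTrace = if (length(traces)) do.call(rbind, traces)
                       else data.frame(experiment = character(),
                                       candidate_t_i = numeric(),
                                       s_value = numeric()),
      flags = flags)
}
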