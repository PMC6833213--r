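## CSV and JSON interchange.  A single CSV dialect (header row, comma
## separated, hour-based time, '#' comments and blank lines allowed, LF or
## CRLF endings) and a flat JSON document for strain parameters mirroring
## the published parameter-table field set.

#' Read a time-series CSV
#'
#' Parses a delimited time series with a header row, skipping blank lines
#' and `#` comment lines; CRLF and LF files parse identically.  The first
#' requested column is treated as time in hours and must be strictly
#' increasing; violations are reported with the offending file line number.
#'
#' @param path file path.
#' @param columns character vector of required column names; the first is
#'   the time column.
#' @return data.frame with the requested (numeric) columns.
#' @export
readTimeseriesCsv <- function(path, columns = c("time_h", "our")) {
  if (!file.exists(path)) stopParse("file not found: %s", path)
  raw <- sub("\r$", "", readLines(path, warn = FALSE))
  keep <- which(!grepl("^\\s*(#|$)", raw))
  if (length(keep) < 2L)
    stopParse("%s: need a header row and at least one data row", path)
  header <- trimws(strsplit(raw[keep[1L]], ",", fixed = TRUE)[[1L]])
  miss <- setdiff(columns, header)
  if (length(miss))
    stopParse("%s: missing column(s): %s", path, paste(miss, collapse = ", "))
  dataLineNo <- keep[-1L]
  df <- utils::read.csv(text = paste(raw[keep], collapse = "\n"),
                        colClasses = "character", check.names = FALSE)
  out <- data.frame(row.names = seq_len(nrow(df)))
  for (col in columns) {
    vals <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(vals))
    if (length(bad))
      stopParse("%s: non-numeric value '%s' in column '%s' at line %d",
                path, df[[col]][bad[1L]], col, dataLineNo[bad[1L]])
    out[[col]] <- vals
  }
  tcol <- out[[columns[1L]]]
  nonMono <- which(diff(tcol) <= 0)
  if (length(nonMono))
    stopParse("%s: non-monotone time in column '%s' at line %d",
              path, columns[1L], dataLineNo[nonMono[1L] + 1L])
  out
}

writeTimeseriesCsv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

strainParameterFields <- c("strain_label", "alpha", "k1", "t_i", "k_exp",
                           "k_beta2", "k_beta1", "k_beta0", "x_specific",
                           "degree")

#' Write strain parameters to a flat JSON document
#'
#' Serialises a [StrainParameters-class] to a key/value JSON file (fields
#' `alpha`, `k1`, `t_i`, `k_exp`, `k_beta2`, `k_beta1`, `k_beta0`,
#' `x_specific`, `degree`, `strain_label`, `stationary_fallback`) at full
#' numeric precision, so a write/read round trip reproduces the parameters.
#'
#' @param params a [StrainParameters-class].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeStrainParameters <- function(params, path) {
  m <- params@maintenance
  doc <- list(strain_label = params@strainLabel,
              alpha = params@alpha, k1 = params@k1, t_i = params@tI,
              k_exp = params@kExp, k_beta2 = m@kBeta2, k_beta1 = m@kBeta1,
              k_beta0 = m@kBeta0, x_specific = m@xSpecific,
              degree = m@degree, stationary_fallback = m@stationaryFallback)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Read strain parameters from a JSON document
#'
#' Counterpart of [writeStrainParameters()].  A missing required field is a
#' parse error naming the field; unknown extra fields are ignored with a
#' warning (forward compatibility).
#'
#' @param path file path.
#' @return a [StrainParameters-class].
#' @export
readStrainParameters <- function(path) {
  if (!file.exists(path)) stopParse("file not found: %s", path)
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  miss <- setdiff(strainParameterFields, names(doc))
  if (length(miss))
    stopParse("%s: missing strain-parameter field(s): %s", path,
              paste(miss, collapse = ", "))
  extra <- setdiff(names(doc), c(strainParameterFields, "stationary_fallback"))
  if (length(extra))
    warnDataQuality("%s: ignoring unknown field(s): %s", path,
                    paste(extra, collapse = ", "))
  asNum <- function(x) if (is.null(x)) NA_real_ else as.numeric(x)
  model <- new("MaintenanceModel", kBeta2 = asNum(doc$k_beta2),
               kBeta1 = asNum(doc$k_beta1), kBeta0 = asNum(doc$k_beta0),
               xSpecific = asNum(doc$x_specific),
               degree = as.integer(doc$degree),
               stationaryFallback = isTRUE(doc$stationary_fallback))
  validObject(model)
  strainParameters(alpha = asNum(doc$alpha), maintenance = model,
                   k1 = asNum(doc$k1), tI = asNum(doc$t_i),
                   kExp = asNum(doc$k_exp),
                   strainLabel = as.character(doc$strain_label))
}

#' Write an estimated trajectory to CSV
#'
#' Columns `time_h`, `x_est_g_per_l`, `regime`.
#'
#' @param trajectory a [BiomassTrajectory-class].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeTrajectoryCsv <- function(trajectory, path) {
  writeTimeseriesCsv(data.frame(time_h = trajectory@times,
                                x_est_g_per_l = trajectory@xEstimates,
                                regime = trajectory@regime), path)
}

#' Read an estimated trajectory from CSV
#'
#' @param path file path (as written by [writeTrajectoryCsv()]).
#' @return a [BiomassTrajectory-class].
#' @export
readTrajectoryCsv <- function(path) {
  df <- readTimeseriesCsv(path, columns = c("time_h", "x_est_g_per_l"))
  raw <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  regime <- if ("regime" %in% names(raw)) as.character(raw$regime)
            else rep("growth", nrow(df))
  new("BiomassTrajectory", times = df$time_h, xEstimates = df$x_est_g_per_l,
      regime = regime)
}
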