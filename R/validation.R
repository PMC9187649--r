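#' Limits of detection and quantification from spiked replicates
#'
#' `LOD = 3.3 * SD` and `LOQ = 10 * SD`, where SD is the sample standard
#' deviation (n - 1 denominator) of replicate analyses of a sample spiked
#' at a low concentration; five replicates is the customary design. The
#' LOQ/LOD ratio is 10/3.3 by construction.
#'
#' @param measured Numeric vector of replicate measured concentrations,
#'   mg/kg (length >= 2, all >= 0).
#' @return A list with elements `lod` and `loq` (mg/kg).
#' @examples
#' lod_loq(c(0.095, 0.102, 0.099, 0.101, 0.097))
#' @export
lod_loq <- function(measured) {
  if (length(measured) < 2) stop("need at least 2 replicates")
  if (any(is.na(measured) | measured < 0))
    stop("measured values must be >= 0")
  s <- sd(measured)
  list(lod = 3.3 * s, loq = 10 * s)
}

#' Recovery and precision of spiked replicates
#'
#' Recovery is the mean measured concentration as a percentage of the
#' spike level; precision is the relative standard deviation
#' `RSD = 100 * SD / mean` (sample SD).
#'
#' @param measured Numeric vector of replicate measured concentrations,
#'   mg/kg (length >= 2, all >= 0).
#' @param spike_level Fortification level, mg/kg (> 0).
#' @return A list with elements `recovery` and `rsd`, both in percent.
#' @examples
#' recovery_precision(c(0.08, 0.09, 0.10), spike_level = 0.1)
#' @export
recovery_precision <- function(measured, spike_level) {
  if (length(measured) < 2) stop("need at least 2 replicates")
  if (any(is.na(measured) | measured < 0))
    stop("measured values must be >= 0")
  if (!is.numeric(spike_level) || length(spike_level) != 1 ||
      is.na(spike_level) || spike_level <= 0)
    stop("spike_level must be a single number > 0")
  m <- mean(measured)
  if (m == 0) stop("mean of replicates is 0; RSD undefined")
  list(recovery = 100 * m / spike_level, rsd = 100 * sd(measured) / m)
}

#' Calibration linearity
#'
#' Coefficient of determination of the ordinary least-squares line of
#' instrument response against concentration over all replicate points
#' (the customary design fortifies blank extracts at several levels and
#' injects each in triplicate). A constant response has no explained
#' variance and returns 0.
#'
#' @param concentration Numeric vector of fortification levels (one entry
#'   per replicate point; at least 3 distinct levels).
#' @param response Numeric vector of responses, same length.
#' @return R-squared in \[0, 1\].
#' @examples
#' linearity(rep(c(0.05, 0.1, 0.25, 1, 2), each = 3),
#'           rep(c(0.05, 0.1, 0.25, 1, 2), each = 3) * 2)
#' @export
linearity <- function(concentration, response) {
  if (length(concentration) != length(response))
    stop("concentration and response must have equal length")
  if (length(unique(concentration)) < 3)
    stop("need at least 3 distinct concentration levels")
  if (var(concentration) == 0)
    stop("concentration has zero variance")
  if (var(response) == 0) return(0)
  fit <- lm(response ~ concentration)
  # R^2 from the decomposition directly; summary.lm() warns on an exact line
  1 - sum(fit$residuals^2) / sum((response - mean(response))^2)
}

#' Method acceptance check
#'
#' A pesticide's method passes when its recovery lies inside the
#' acceptance range (inclusive at both ends, 70--120% by default) and its
#' RSD is strictly below the precision limit (10% by default).
#'
#' @param recovery Recovery in percent.
#' @param rsd Relative standard deviation in percent.
#' @param config An [analysis_config()] carrying `recovery_range` and
#'   `rsd_limit`.
#' @return Logical (vectorised).
#' @examples
#' check_acceptance(c(85.3, 65, 120), c(4.3, 5, 9.9))
#' @export
check_acceptance <- function(recovery, rsd, config = analysis_config()) {
  if (any(is.na(recovery) | is.na(rsd))) stop("recovery/rsd must be numeric")
  recovery >= config$recovery_range[1] &
    recovery <= config$recovery_range[2] &
    rsd < config$rsd_limit
}

#' Method validation summary table
#'
#' Computes, per pesticide, recovery and RSD at each fortification level,
#' the pooled (across-level mean) recovery, LOD/LOQ from the replicates at
#' the lowest level, linearity from an optional calibration table, and the
#' pass/fail acceptance verdict.
#'
#' @param replicates Data frame in wide replicate layout: `pesticide`,
#'   `spike_level`, then replicate columns named `rep1`, `rep2`, ...
#' @param calibration Optional data frame: `pesticide`, `level`, then
#'   response columns `resp1`, `resp2`, ... (triplicate is customary).
#' @param config An [analysis_config()].
#' @return A data frame of class `"method_validation"`, one row per
#'   pesticide x level plus one pooled row per pesticide
#'   (`level == "pooled"`): `pesticide`, `level`, `r_squared`, `lod`,
#'   `loq`, `recovery`, `rsd`, `passed`.
#' @export
method_validation <- function(replicates, calibration = NULL,
                              config = analysis_config()) {
  need <- c("pesticide", "spike_level")
  if (!all(need %in% names(replicates)))
    stop("replicates needs columns: ", paste(need, collapse = ", "))
  repcols <- grep("^rep[0-9]+$", names(replicates), value = TRUE)
  if (length(repcols) < 2) stop("need at least 2 replicate columns (rep1..)")

  r2 <- NULL
  if (!is.null(calibration)) {
    respcols <- grep("^resp[0-9]+$", names(calibration), value = TRUE)
    if (length(respcols) == 0) stop("calibration needs resp1.. columns")
    r2 <- vapply(split(calibration, calibration$pesticide), function(d) {
      conc <- rep(d$level, times = length(respcols))
      resp <- unlist(d[respcols], use.names = FALSE)
      keep <- !is.na(resp)
      linearity(conc[keep], resp[keep])
    }, numeric(1))
  }

  rows <- list()
  for (p in unique(replicates$pesticide)) {
    sub <- replicates[replicates$pesticide == p, , drop = FALSE]
    sub <- sub[order(sub$spike_level), , drop = FALSE]
    limits <- NULL
    level_rows <- lapply(seq_len(nrow(sub)), function(i) {
      meas <- as.numeric(sub[i, repcols])
      meas <- meas[!is.na(meas)]
      rp <- recovery_precision(meas, sub$spike_level[i])
      data.frame(pesticide = p,
                 level = format(sub$spike_level[i], trim = TRUE),
                 recovery = rp$recovery, rsd = rp$rsd,
                 stringsAsFactors = FALSE)
    })
    meas_low <- as.numeric(sub[1, repcols])
    limits <- lod_loq(meas_low[!is.na(meas_low)])
    lv <- do.call(rbind, level_rows)
    pooled <- data.frame(pesticide = p, level = "pooled",
                         recovery = mean(lv$recovery), rsd = mean(lv$rsd),
                         stringsAsFactors = FALSE)
    out <- rbind(lv, pooled)
    out$lod <- limits$lod
    out$loq <- limits$loq
    out$r_squared <- if (is.null(r2)) NA_real_ else unname(r2[p])
    rows[[p]] <- out
  }
  res <- do.call(rbind, rows)
  res$passed <- check_acceptance(res$recovery, res$rsd, config)
  res <- res[, c("pesticide", "level", "r_squared", "lod", "loq",
                 "recovery", "rsd", "passed")]
  rownames(res) <- NULL
  class(res) <- c("method_validation", "data.frame")
  res
}

#' @export
print.method_validation <- function(x, ...) {
  cat("Analytical method validation (LOD/LOQ in mg/kg; recovery/RSD in %)\n")
  y <- as.data.frame(x)
  y$lod <- round_half_up(y$lod, 3)
  y$loq <- round_half_up(y$loq, 3)
  y$recovery <- round_half_up(y$recovery, 1)
  y$rsd <- round_half_up(y$rsd, 1)
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}
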