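#' Analysis configuration
#'
#' Bundles the scalar settings shared by the classification, summary and
#' exposure stages. Defaults follow common regulatory practice for Korean
#' produce monitoring: a 60 kg adult body weight, the positive-list-system
#' (PLS) default MRL of 0.01 mg/kg for unregistered pesticide x commodity
#' pairs, percentages reported at one decimal (round-half-up), and
#' method-acceptance bounds of 70--120% recovery with RSD below 10%.
#'
#' @param body_weight Consumer body weight in kg (> 0). Divides both the
#'   short-term (ESTI) and long-term (EDI) intake estimates.
#' @param pls_default_mrl Default MRL in mg/kg applied to any pesticide x
#'   commodity pair without a registered limit.
#' @param percent_decimals Number of decimals for reported percentages.
#' @param rsd_limit Precision acceptance bound in percent; RSD must be
#'   strictly below it.
#' @param recovery_range Length-2 numeric, inclusive recovery acceptance
#'   bounds in percent.
#' @param nondetect_policy How non-detected measurements enter the mean
#'   residue used for EDI: `"exclude"` (default; mean over detected
#'   concentrations only) or `"half_lod"` (non-detects substituted at LOD/2,
#'   for sensitivity analysis).
#' @return An object of class `"analysis_config"` (a validated list).
#' @examples
#' cfg <- analysis_config(body_weight = 55)
#' cfg$pls_default_mrl
#' @export
analysis_config <- function(body_weight = 60,
                            pls_default_mrl = 0.01,
                            percent_decimals = 1,
                            rsd_limit = 10,
                            recovery_range = c(70, 120),
                            nondetect_policy = c("exclude", "half_lod")) {
  nondetect_policy <- match.arg(nondetect_policy)
  stopifnot(
    is.numeric(body_weight), length(body_weight) == 1, body_weight > 0,
    is.numeric(pls_default_mrl), length(pls_default_mrl) == 1,
    pls_default_mrl > 0,
    is.numeric(percent_decimals), length(percent_decimals) == 1,
    percent_decimals >= 0, percent_decimals == round(percent_decimals),
    is.numeric(rsd_limit), length(rsd_limit) == 1, rsd_limit > 0,
    is.numeric(recovery_range), length(recovery_range) == 2
  )
  if (!(recovery_range[1] < recovery_range[2]))
    stop("recovery_range must be increasing: [low, high]")
  structure(
    list(body_weight = body_weight,
         pls_default_mrl = pls_default_mrl,
         percent_decimals = as.integer(percent_decimals),
         rsd_limit = rsd_limit,
         recovery_range = recovery_range,
         nondetect_policy = nondetect_policy),
    class = "analysis_config"
  )
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("Analysis configuration\n")
  cat(sprintf("  body weight:      %g kg\n", x$body_weight))
  cat(sprintf("  PLS default MRL:  %g mg/kg\n", x$pls_default_mrl))
  cat(sprintf("  percentages:      %d decimal(s), round-half-up\n",
              x$percent_decimals))
  cat(sprintf("  recovery bounds:  [%g, %g]%%, RSD < %g%%\n",
              x$recovery_range[1], x$recovery_range[2], x$rsd_limit))
  cat(sprintf("  non-detects:      %s\n", x$nondetect_policy))
  invisible(x)
}

#' Read an analysis configuration from YAML
#'
#' The file may set any subset of the [analysis_config()] fields; unset
#' fields keep their defaults.
#'
#' @param path Path to a YAML file.
#' @return An `"analysis_config"` object.
#' @export
read_config_yaml <- function(path) {
  vals <- yaml::read_yaml(path)
  if (!is.list(vals)) stop("config file must be a YAML mapping")
  known <- names(formals(analysis_config))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0)
    stop("unknown config field(s): ", paste(bad, collapse = ", "))
  if (!is.null(vals$recovery_range))
    vals$recovery_range <- as.numeric(unlist(vals$recovery_range))
  do.call(analysis_config, vals)
}

#' Round half away from zero
#'
#' Decimal rounding with ties going up in absolute value (so 0.5 -> 1,
#' 43.75 -> 43.8 at one decimal), the convention used for all reported
#' percentages. Base R's `round()` rounds ties to even instead.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return `x` rounded to `digits` decimals.
#' @examples
#' round_half_up(c(0.5, 1.5, 43.75), c(0, 0, 1))
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  # small relative nudge so values that are exact halves after a decimal
  # division (e.g. 43.75 stored as 43.74999...) still round up
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}
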