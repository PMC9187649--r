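#' Analyse a residue monitoring campaign
#'
#' The main entry point for the compliance side of the package: resolves
#' MRLs, classifies every measurement and sample, and tabulates occurrence
#' (by commodity) and incidence (by pesticide). The pieces are also
#' available individually ([classify_residues()],
#' [occurrence_by_commodity()], [incidence_by_pesticide()]).
#'
#' @param samples,measurements Data frames as returned by
#'   [read_measurements()], [generate_monitoring_dataset()] or
#'   [build_survey_fixture()].
#' @param mrl_table Registered MRLs, or `NULL` (everything falls to the
#'   PLS default).
#' @param config An [analysis_config()].
#' @param classes Optional data frame `pesticide`, `function_class` used
#'   by the incidence table and [function_class_breakdown()].
#' @return An object of class `"residue_survey"`: a list with the inputs
#'   plus `verdicts`, `categories`, `occurrence` and `incidence`.
#' @examples
#' fx <- build_survey_fixture()
#' sv <- residue_survey(fx$samples, fx$measurements, fx$mrl_table)
#' sv
#' @export
residue_survey <- function(samples, measurements, mrl_table = NULL,
                           config = analysis_config(), classes = NULL) {
  verdicts <- classify_residues(samples, measurements, mrl_table, config)
  structure(
    list(samples = samples, measurements = measurements,
         mrl_table = mrl_table, config = config,
         verdicts = verdicts,
         categories = sample_categories(samples, verdicts),
         occurrence = occurrence_by_commodity(samples, verdicts, config),
         incidence = incidence_by_pesticide(samples, verdicts, config,
                                            classes)),
    class = "residue_survey")
}

#' @export
print.residue_survey <- function(x, ...) {
  tot <- x$occurrence[x$occurrence$product == "Total", ]
  cat("Residue monitoring survey\n")
  cat(sprintf("  %d samples, %d commodities, %d pesticides detected\n",
              tot$n_total, nrow(x$occurrence) - 1, nrow(x$incidence)))
  cat(sprintf("  without residue: %d (%.*f%%)\n", tot$n_without,
              x$config$percent_decimals, tot$pct_without))
  cat(sprintf("  with residue:    %d (%.*f%%), of which above MRL: %d (%.*f%%)\n",
              tot$n_below + tot$n_above, x$config$percent_decimals,
              tot$pct_with, tot$n_above, x$config$percent_decimals,
              tot$pct_above))
  invisible(x)
}

#' @export
summary.residue_survey <- function(object, ...) {
  print(object)
  cat("\n")
  print(object$occurrence)
  cat("\n")
  print(object$incidence)
  if (!anyNA(object$incidence$function_class)) {
    cat("\nDetected pesticides by functional class:\n")
    print.data.frame(function_class_breakdown(object$incidence,
                                              object$config),
                     row.names = FALSE)
  }
  invisible(object)
}

#' @export
plot.residue_survey <- function(x, ...) {
  occ <- x$occurrence[x$occurrence$product != "Total", ]
  op <- par(mar = c(9, 4, 2, 1))
  on.exit(par(op))
  barplot(rbind(occ$pct_with - occ$pct_above, occ$pct_above),
          names.arg = occ$product, las = 2, cex.names = 0.7,
          col = c("grey70", "firebrick"),
          ylab = "% of samples with residues",
          legend.text = c("below MRL", "above MRL"),
          args.legend = list(bty = "n"), ...)
  invisible(x)
}
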