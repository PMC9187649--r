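#' Occurrence of residues by commodity
#'
#' Tabulates, for each commodity, how many samples were residue-free,
#' carried residues at or below the MRL, and carried residues above it,
#' with the percentages used in survey reporting. Following that reporting
#' convention, `pct_with` is the any-residue rate
#' `100 * (n_below + n_above) / n_total`; the unambiguous below-MRL-only
#' percentage is additionally emitted as `pct_below`. A grand-total row is
#' appended. Percentages use round-half-up at `config$percent_decimals`.
#'
#' @param samples Sample table.
#' @param verdicts Measurement verdict table from [classify_residues()].
#' @param config An [analysis_config()].
#' @return A data frame of class `"occurrence_summary"`: `group`,
#'   `product`, `n_total`, `n_without`, `pct_without`, `n_below`,
#'   `pct_with`, `pct_below`, `n_above`, `pct_above`; last row is the
#'   total (`product == "Total"`).
#' @export
occurrence_by_commodity <- function(samples, verdicts,
                                    config = analysis_config()) {
  cats <- sample_categories(samples, verdicts)
  prods <- unique(cats[, c("commodity", "group")])
  prods$group <- factor(prods$group, levels = c("vegetable", "fruit"))
  prods <- prods[order(prods$group, prods$commodity), ]

  tab <- table(cats$commodity, cats$category)
  n_without <- tab[prods$commodity, "without_residue"]
  n_below <- tab[prods$commodity, "below_mrl"]
  n_above <- tab[prods$commodity, "above_mrl"]
  n_total <- n_without + n_below + n_above

  out <- data.frame(
    group = as.character(prods$group),
    product = prods$commodity,
    n_total = as.integer(n_total),
    n_without = as.integer(n_without),
    n_below = as.integer(n_below),
    n_above = as.integer(n_above),
    stringsAsFactors = FALSE
  )
  total <- data.frame(group = NA_character_, product = "Total",
                      n_total = sum(out$n_total),
                      n_without = sum(out$n_without),
                      n_below = sum(out$n_below),
                      n_above = sum(out$n_above),
                      stringsAsFactors = FALSE)
  out <- rbind(out, total)

  pct <- function(x) round_half_up(100 * x / out$n_total,
                                   config$percent_decimals)
  out$pct_without <- pct(out$n_without)
  out$pct_with <- pct(out$n_below + out$n_above)
  out$pct_below <- pct(out$n_below)
  out$pct_above <- pct(out$n_above)
  out <- out[, c("group", "product", "n_total", "n_without", "pct_without",
                 "n_below", "pct_with", "pct_below", "n_above", "pct_above")]
  rownames(out) <- NULL
  class(out) <- c("occurrence_summary", "data.frame")
  out
}

#' Incidence of residues by pesticide
#'
#' For every pesticide with at least one detection: detection and
#' violation counts with percentages of the full sample count, the range
#' of detected concentrations, and the range of MRLs applied across the
#' commodities in which it was found.
#'
#' @param samples Sample table (supplies the denominator).
#' @param verdicts Measurement verdict table from [classify_residues()].
#' @param config An [analysis_config()].
#' @param classes Optional data frame `pesticide`, `function_class`
#'   (codes F fungicide, G growth regulator, H herbicide, I insecticide).
#' @return A data frame of class `"incidence_summary"` with one row per
#'   detected pesticide: `pesticide`, `function_class`, `n_detected`,
#'   `pct_detected`, `n_above`, `pct_above`, `conc_min`, `conc_max`,
#'   `mrl_min`, `mrl_max`.
#' @export
incidence_by_pesticide <- function(samples, verdicts,
                                   config = analysis_config(),
                                   classes = NULL) {
  n_samples <- nrow(samples)
  det <- verdicts[as.character(verdicts$verdict) != "not_detected", ]
  pests <- sort(unique(det$pesticide))
  stat <- function(f, col) {
    vapply(pests, function(p) f(det[[col]][det$pesticide == p]), numeric(1))
  }
  n_detected <- stat(length, "concentration")
  n_above <- vapply(pests, function(p) {
    sum(as.character(det$verdict[det$pesticide == p]) == "above_mrl")
  }, numeric(1))
  out <- data.frame(
    pesticide = pests,
    function_class = NA_character_,
    n_detected = as.integer(n_detected),
    pct_detected = round_half_up(100 * n_detected / n_samples,
                                 config$percent_decimals),
    n_above = as.integer(n_above),
    pct_above = round_half_up(100 * n_above / n_samples,
                              config$percent_decimals),
    conc_min = stat(min, "concentration"),
    conc_max = stat(max, "concentration"),
    mrl_min = stat(min, "mrl"),
    mrl_max = stat(max, "mrl"),
    stringsAsFactors = FALSE
  )
  if (!is.null(classes))
    out$function_class <- classes$function_class[
      match(out$pesticide, classes$pesticide)]
  rownames(out) <- NULL
  class(out) <- c("incidence_summary", "data.frame")
  out
}

#' Breakdown of detected pesticides by functional class
#'
#' Counts distinct detected pesticides per functional class (F fungicide,
#' G growth regulator, H herbicide, I insecticide) and expresses each as a
#' round-half-up percentage of all detected pesticides.
#'
#' @param incidence An [incidence_by_pesticide()] table whose
#'   `function_class` column is filled.
#' @param config An [analysis_config()].
#' @return A data frame `function_class`, `n`, `pct`, ordered by
#'   decreasing count.
#' @export
function_class_breakdown <- function(incidence, config = analysis_config()) {
  cls <- incidence$function_class
  if (any(is.na(cls) | !(cls %in% c("F", "G", "H", "I"))))
    stop("every pesticide needs a function class code in {F, G, H, I}")
  tab <- table(cls)
  out <- data.frame(function_class = names(tab),
                    n = as.integer(tab),
                    stringsAsFactors = FALSE)
  out$pct <- round_half_up(100 * out$n / sum(out$n), config$percent_decimals)
  out <- out[order(-out$n, out$function_class), ]
  rownames(out) <- NULL
  out
}

#' @export
print.occurrence_summary <- function(x, ...) {
  cat("Occurrence of pesticide residues by commodity\n")
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}

#' @export
print.incidence_summary <- function(x, ...) {
  cat("Pesticide residue incidence (", nrow(x), " pesticides detected)\n",
      sep = "")
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}
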