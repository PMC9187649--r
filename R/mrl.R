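#' Resolve the applicable maximum residue limit
#'
#' Looks up the registered MRL for each pesticide x commodity pair; pairs
#' without a registration fall back to the positive-list-system (PLS)
#' default in `config$pls_default_mrl` (0.01 mg/kg unless changed). The
#' fallback is total: resolution never fails.
#'
#' @param pesticide,commodity Character vectors of equal length (or one of
#'   them length 1, recycled).
#' @param mrl_table A data frame with columns `pesticide`, `commodity`,
#'   `mrl` as returned by [read_mrl_table()], or `NULL` for an empty
#'   registry (everything falls to the PLS default).
#' @param config An [analysis_config()].
#' @return A data frame with one row per input pair and columns
#'   `pesticide`, `commodity`, `mrl` (mg/kg) and `source` (`"registered"`
#'   or `"pls_default"`).
#' @examples
#' reg <- data.frame(pesticide = "chlorfenapyr", commodity = "lettuce",
#'                   mrl = 1.0)
#' resolve_mrl(c("chlorfenapyr", "fenobucarb"), c("lettuce", "aster scaber"),
#'             reg)
#' @export
resolve_mrl <- function(pesticide, commodity, mrl_table = NULL,
                        config = analysis_config()) {
  n <- max(length(pesticide), length(commodity))
  pesticide <- rep_len(as.character(pesticide), n)
  commodity <- rep_len(as.character(commodity), n)
  if (any(pesticide == "" | is.na(pesticide)))
    stop("pesticide must be non-empty")
  if (any(commodity == "" | is.na(commodity)))
    stop("commodity must be non-empty")

  out <- data.frame(pesticide = pesticide, commodity = commodity,
                    mrl = rep(config$pls_default_mrl, n),
                    source = rep("pls_default", n),
                    stringsAsFactors = FALSE)
  if (!is.null(mrl_table) && nrow(mrl_table) > 0) {
    key <- paste(mrl_table$pesticide, mrl_table$commodity, sep = "\r")
    if (anyDuplicated(key) > 0)
      stop("duplicated pesticide x commodity entries in MRL table")
    idx <- match(paste(pesticide, commodity, sep = "\r"), key)
    hit <- !is.na(idx)
    out$mrl[hit] <- mrl_table$mrl[idx[hit]]
    out$source[hit] <- "registered"
  }
  out
}
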