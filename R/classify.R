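residue_levels <- c("not_detected", "below_mrl", "above_mrl")
sample_levels <- c("without_residue", "below_mrl", "above_mrl")

#' Classify a residue measurement against its MRL
#'
#' A concentration below the limit of detection counts as not detected;
#' a detected concentration exceeds the MRL only under strict inequality,
#' so a residue exactly at the limit is compliant (the usual regulatory
#' reading of "above the MRL").
#'
#' @param concentration,lod Measured concentration and limit of detection,
#'   mg/kg, vectors recycled to a common length.
#' @param mrl Applicable MRL in mg/kg (> 0), recycled likewise.
#' @return An ordered factor with levels `not_detected < below_mrl <
#'   above_mrl`; the ordering reflects monotonicity in concentration.
#' @examples
#' classify_residue(c(0.0005, 0.05, 0.364), lod = 0.004, mrl = 0.01)
#' @export
classify_residue <- function(concentration, lod, mrl) {
  n <- max(length(concentration), length(lod), length(mrl))
  concentration <- rep_len(concentration, n)
  lod <- rep_len(lod, n)
  mrl <- rep_len(mrl, n)
  if (any(is.na(concentration) | concentration < 0))
    stop("concentration must be >= 0")
  if (any(is.na(lod) | lod < 0)) stop("lod must be >= 0")
  if (any(is.na(mrl) | mrl <= 0)) stop("mrl must be > 0")
  v <- ifelse(concentration < lod, "not_detected",
              ifelse(concentration > mrl, "above_mrl", "below_mrl"))
  factor(v, levels = residue_levels, ordered = TRUE)
}

#' Classify a sample from its residue verdicts
#'
#' One sample is counted once, in its worst category: any residue above
#' the MRL puts the sample above the MRL; otherwise any detected residue
#' puts it in the below-MRL class; a sample with no detected residue
#' (including an empty verdict list) is residue-free.
#'
#' @param verdicts A (possibly empty) vector of residue verdicts as
#'   produced by [classify_residue()].
#' @return One of `"without_residue"`, `"below_mrl"`, `"above_mrl"`.
#' @examples
#' classify_sample(character(0))
#' classify_sample(c("below_mrl", "above_mrl"))
#' @export
classify_sample <- function(verdicts) {
  verdicts <- as.character(verdicts)
  if (!all(verdicts %in% residue_levels))
    stop("verdicts must be not_detected/below_mrl/above_mrl")
  if (any(verdicts == "above_mrl")) return("above_mrl")
  if (any(verdicts == "below_mrl")) return("below_mrl")
  "without_residue"
}

#' Classify every measurement of a monitoring dataset
#'
#' Resolves the MRL for each measurement's pesticide x commodity pair
#' (PLS default where unregistered) and attaches the residue verdict.
#'
#' @param samples,measurements Data frames as returned by
#'   [read_measurements()].
#' @param mrl_table Registered MRLs ([read_mrl_table()]) or `NULL`.
#' @param config An [analysis_config()].
#' @return A data frame with one row per measurement: `sample_id`,
#'   `commodity`, `group`, `pesticide`, `concentration`, `lod`, `loq`,
#'   `mrl`, `mrl_source`, `verdict`.
#' @export
classify_residues <- function(samples, measurements, mrl_table = NULL,
                              config = analysis_config()) {
  stray <- setdiff(measurements$sample_id, samples$sample_id)
  if (length(stray) > 0)
    stop("measurement(s) reference unknown sample_id: ",
         paste(head(stray, 5), collapse = ", "))
  idx <- match(measurements$sample_id, samples$sample_id)
  out <- data.frame(
    sample_id = measurements$sample_id,
    commodity = samples$commodity[idx],
    group = samples$group[idx],
    pesticide = measurements$pesticide,
    concentration = measurements$concentration,
    lod = measurements$lod,
    loq = measurements$loq,
    stringsAsFactors = FALSE
  )
  res <- resolve_mrl(out$pesticide, out$commodity, mrl_table, config)
  out$mrl <- res$mrl
  out$mrl_source <- res$source
  out$verdict <- classify_residue(out$concentration, out$lod, out$mrl)
  out
}

#' Per-sample compliance categories
#'
#' Applies [classify_sample()] to every sample of the dataset, including
#' samples with no measurement rows (residue-free by definition).
#'
#' @param samples Sample table.
#' @param verdicts Measurement verdict table from [classify_residues()].
#' @return A data frame `sample_id`, `commodity`, `group`, `category`.
#' @export
sample_categories <- function(samples, verdicts) {
  worst <- rep("without_residue", nrow(samples))
  if (nrow(verdicts) > 0) {
    per <- tapply(as.character(verdicts$verdict), verdicts$sample_id,
                  classify_sample)
    idx <- match(names(per), samples$sample_id)
    if (anyNA(idx))
      stop("verdict table references unknown sample_id")
    worst[idx] <- unlist(per)
  }
  data.frame(sample_id = samples$sample_id,
             commodity = samples$commodity,
             group = samples$group,
             category = factor(worst, levels = sample_levels),
             stringsAsFactors = FALSE)
}
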