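# Shared builders for small in-memory datasets and an independent
# per-sample tally used as the oracle for the occurrence summary.

make_samples <- function(commodity, n, group = "vegetable") {
  data.frame(
    sample_id = sprintf("%s-%03d", gsub("[^a-z0-9]+", "_",
                                        tolower(commodity)), seq_len(n)),
    commodity = commodity, group = group, stringsAsFactors = FALSE)
}

make_measurement <- function(sample_id, pesticide, concentration,
                             lod = 0.001, loq = 3 * lod) {
  n <- length(sample_id)
  data.frame(sample_id = sample_id, pesticide = pesticide,
             concentration = concentration,
             lod = rep_len(lod, n), loq = rep_len(loq, n),
             stringsAsFactors = FALSE)
}

# random small monitoring dataset (<= 50 samples) with a registered MRL
# for every pesticide x commodity pair
random_dataset <- function(seed) {
  set.seed(seed)
  commodities <- paste0("crop", seq_len(sample(2:4, 1)))
  pesticides <- paste0("pest", seq_len(sample(2:3, 1)))
  samples <- do.call(rbind, lapply(commodities, function(cm) {
    make_samples(cm, sample(3:15, 1),
                 group = sample(c("vegetable", "fruit"), 1))
  }))
  rows <- list()
  for (sid in samples$sample_id) {
    for (p in pesticides) {
      if (runif(1) < 0.3) {
        rows[[length(rows) + 1]] <-
          make_measurement(sid, p, stats::rlnorm(1, log(0.05), 1),
                           lod = 0.01)
      }
    }
  }
  measurements <- if (length(rows) > 0) do.call(rbind, rows) else
    make_measurement(character(0), character(0), numeric(0))
  mrl_table <- expand.grid(pesticide = pesticides, commodity = commodities,
                           stringsAsFactors = FALSE)
  mrl_table$mrl <- stats::runif(nrow(mrl_table), 0.02, 0.3)
  mrl_table$source <- "registered"
  list(samples = samples, measurements = measurements,
       mrl_table = mrl_table)
}

# independent oracle: exhaustive per-sample tally with plain loops
brute_occurrence <- function(samples, verdicts) {
  out <- list()
  for (cm in unique(samples$commodity)) {
    ids <- samples$sample_id[samples$commodity == cm]
    n_without <- n_below <- n_above <- 0
    for (sid in ids) {
      v <- as.character(verdicts$verdict[verdicts$sample_id == sid])
      v <- v[v != "not_detected"]
      if (length(v) == 0) n_without <- n_without + 1
      else if (any(v == "above_mrl")) n_above <- n_above + 1
      else n_below <- n_below + 1
    }
    out[[cm]] <- data.frame(product = cm, n_total = length(ids),
                            n_without = n_without, n_below = n_below,
                            n_above = n_above, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
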