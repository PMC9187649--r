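#' Simulation configuration for a monitoring campaign
#'
#' Describes a stochastic residue monitoring campaign: which commodities
#' are sampled and how often, which pesticides can occur, the per-sample
#' contamination probability, the conditional probability that a detected
#' residue violates its MRL, and the lognormal residue-concentration
#' model. Defaults emulate the reference survey: its 20 commodities with
#' their actual sample counts (1,146 samples), the 15 method-validated
#' pesticides with their reported LODs, a 7.9% contamination rate, an
#' 11/91 conditional violation rate, and a lognormal concentration whose
#' median (0.15 mg/kg) and spread (sdlog 1.2) reproduce detected ranges
#' spanning roughly two orders of magnitude.
#'
#' @param commodities Data frame `name`, `group`, `n_samples`; default:
#'   the reference survey's commodity plan.
#' @param pesticides Data frame `name`, `function_class`, `lod`, `loq`;
#'   default: the 15 validated pesticides.
#' @param detection_prob Probability that a sample carries at least one
#'   residue.
#' @param violation_prob Conditional probability that a drawn residue
#'   exceeds its commodity MRL.
#' @param conc_lognormal Length-2 numeric `(meanlog, sdlog)` of the
#'   residue concentration model, sdlog > 0.
#' @param extra_residue_mean Poisson mean of additional residues per
#'   contaminated sample (0 = strictly single-residue, the reference
#'   survey's situation; > 0 produces multi-residue samples).
#' @param seed Integer seed making the campaign reproducible.
#' @return An object of class `"sim_config"`.
#' @export
sim_config <- function(commodities = NULL, pesticides = NULL,
                       detection_prob = 91 / 1146,
                       violation_prob = 11 / 91,
                       conc_lognormal = c(meanlog = log(0.15), sdlog = 1.2),
                       extra_residue_mean = 0,
                       seed = 1L) {
  if (is.null(commodities)) {
    occ <- read_survey_table("survey_occurrence.csv")
    commodities <- data.frame(name = occ$product, group = occ$group,
                              n_samples = occ$n_total,
                              stringsAsFactors = FALSE)
  }
  if (is.null(pesticides)) {
    val <- read_survey_table("survey_validation.csv")
    inc <- read_survey_table("survey_incidence.csv")
    pesticides <- data.frame(
      name = val$pesticide,
      function_class = inc$function_class[match(val$pesticide,
                                                inc$pesticide)],
      lod = val$lod, loq = val$loq, stringsAsFactors = FALSE)
  }
  stopifnot(
    all(c("name", "group", "n_samples") %in% names(commodities)),
    all(c("name", "lod", "loq") %in% names(pesticides)),
    is.numeric(detection_prob), detection_prob >= 0, detection_prob <= 1,
    is.numeric(violation_prob), violation_prob >= 0, violation_prob <= 1,
    length(conc_lognormal) == 2, conc_lognormal[2] > 0,
    is.numeric(extra_residue_mean), extra_residue_mean >= 0,
    all(commodities$n_samples >= 0),
    all(commodities$n_samples == round(commodities$n_samples))
  )
  structure(
    list(commodities = commodities, pesticides = pesticides,
         detection_prob = detection_prob, violation_prob = violation_prob,
         conc_lognormal = unname(conc_lognormal),
         extra_residue_mean = extra_residue_mean,
         seed = as.integer(seed)),
    class = "sim_config")
}

# draw from a lognormal truncated to (lower, upper); falls back to a
# shifted-exponential tail draw when the requested region carries
# essentially no mass
rtrunc_lnorm <- function(n, meanlog, sdlog, lower = 0, upper = Inf) {
  p_lo <- plnorm(lower, meanlog, sdlog)
  p_hi <- plnorm(upper, meanlog, sdlog)
  if (p_hi - p_lo < 1e-12) {
    if (is.finite(upper)) return(rep((lower + upper) / 2, n))
    return(lower * (1 + rexp(n)))
  }
  qlnorm(runif(n, p_lo, p_hi), meanlog, sdlog)
}

#' Generate a synthetic monitoring dataset
#'
#' Seeded generator for a residue monitoring campaign. Each sample is
#' independently contaminated with probability `detection_prob`; a
#' contaminated sample carries one residue (plus a Poisson number of
#' extras when `extra_residue_mean > 0`) from a uniformly chosen
#' pesticide. Concentrations follow the configured lognormal, truncated
#' below at the pesticide's LOD; with probability `violation_prob` the
#' residue is instead drawn above the commodity's MRL. Registered MRLs
#' are set at the 95th percentile of the concentration model (2
#' significant figures) for every pesticide x commodity pair.
#'
#' @param config A [sim_config()].
#' @return A list with data frames `samples`, `measurements` and
#'   `mrl_table`, in the same layout as [read_measurements()] /
#'   [read_mrl_table()].
#' @export
generate_monitoring_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  mu <- config$conc_lognormal[1]
  sig <- config$conc_lognormal[2]
  pests <- config$pesticides

  mrl_value <- signif(qlnorm(0.95, mu, sig), 2)
  mrl_table <- expand.grid(pesticide = pests$name,
                           commodity = config$commodities$name,
                           stringsAsFactors = FALSE)
  mrl_table$mrl <- mrl_value
  mrl_table$source <- "registered"

  samples <- do.call(rbind, lapply(seq_len(nrow(config$commodities)),
    function(i) {
      cm <- config$commodities[i, ]
      if (cm$n_samples == 0) return(NULL)
      data.frame(
        sample_id = sprintf("%s-%04d",
                            gsub("[^A-Za-z0-9]+", "_", tolower(cm$name)),
                            seq_len(cm$n_samples)),
        commodity = cm$name, group = cm$group, stringsAsFactors = FALSE)
    }))
  if (is.null(samples))
    samples <- data.frame(sample_id = character(), commodity = character(),
                          group = character(), stringsAsFactors = FALSE)

  contaminated <- runif(nrow(samples)) < config$detection_prob
  rows <- list()
  for (i in which(contaminated)) {
    k <- 1 + rpois(1, config$extra_residue_mean)
    k <- min(k, nrow(pests))
    chosen <- sample(nrow(pests), k)
    for (j in chosen) {
      lod <- pests$lod[j]
      violate <- runif(1) < config$violation_prob
      conc <- if (violate) {
        rtrunc_lnorm(1, mu, sig, lower = max(lod, mrl_value))
      } else {
        rtrunc_lnorm(1, mu, sig, lower = lod, upper = mrl_value)
      }
      rows[[length(rows) + 1]] <- data.frame(
        sample_id = samples$sample_id[i], pesticide = pests$name[j],
        concentration = conc, lod = lod, loq = pests$loq[j],
        stringsAsFactors = FALSE)
    }
  }
  measurements <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(sample_id = character(), pesticide = character(),
               concentration = numeric(), lod = numeric(), loq = numeric(),
               stringsAsFactors = FALSE)
  rownames(measurements) <- NULL
  list(samples = samples, measurements = measurements,
       mrl_table = mrl_table)
}

#' Generate spiked validation replicates
#'
#' Seeded generator of replicate measurements of a sample fortified at
#' `spike_level`: normal with mean `spike_level * recovery_mean / 100` and
#' coefficient of variation `cv` percent, truncated at zero.
#'
#' @param spike_level Fortification level, mg/kg (> 0).
#' @param recovery_mean Target mean recovery in percent.
#' @param cv Coefficient of variation in percent (>= 0).
#' @param n Number of replicates (>= 2; 5 is the customary design).
#' @param seed Integer seed.
#' @return Numeric vector of `n` measured concentrations.
#' @export
generate_validation_replicates <- function(spike_level, recovery_mean, cv,
                                           n = 5, seed = 1L) {
  stopifnot(spike_level > 0, recovery_mean >= 0, cv >= 0, n >= 2)
  set.seed(as.integer(seed))
  m <- spike_level * recovery_mean / 100
  pmax(0, rnorm(n, mean = m, sd = cv / 100 * m))
}
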