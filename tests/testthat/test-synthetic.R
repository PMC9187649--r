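test_that("the campaign generator is seed-deterministic", {
  cfg <- sim_config(seed = 77)
  a <- generate_monitoring_dataset(cfg)
  b <- generate_monitoring_dataset(cfg)
  expect_identical(a, b)
  c2 <- generate_monitoring_dataset(sim_config(seed = 78))
  expect_false(identical(a$measurements, c2$measurements))
})

test_that("zero detection probability yields an all-clean campaign", {
  cfg <- sim_config(detection_prob = 0, seed = 3)
  d <- generate_monitoring_dataset(cfg)
  expect_equal(nrow(d$measurements), 0)
  expect_equal(nrow(d$samples), 1146)
  occ <- occurrence_by_commodity(
    d$samples, classify_residues(d$samples, d$measurements, d$mrl_table))
  expect_equal(occ$pct_without[occ$product == "Total"], 100.0)
})

test_that("generator marginals are recovered at campaign scale", {
  commodities <- data.frame(name = "cropX", group = "vegetable",
                            n_samples = 10000)
  cfg <- sim_config(commodities = commodities,
                    detection_prob = 0.079, seed = 123)
  d <- generate_monitoring_dataset(cfg)
  rate <- length(unique(d$measurements$sample_id)) / nrow(d$samples)
  se <- sqrt(0.079 * (1 - 0.079) / 10000)
  expect_lt(abs(rate - 0.079), 3 * se)

  # conditional violation rate among residues
  v <- classify_residues(d$samples, d$measurements, d$mrl_table)
  det <- v[as.character(v$verdict) != "not_detected", ]
  p_v <- cfg$violation_prob
  se_v <- sqrt(p_v * (1 - p_v) / nrow(det))
  expect_lt(abs(mean(det$verdict == "above_mrl") - p_v), 3 * se_v)
})

test_that("log-concentration location is recovered when truncation is off", {
  # with LOD 0 and the violation share equal to the MRL tail mass, the
  # generated concentrations are exactly the configured lognormal
  pest <- data.frame(name = "pestX", function_class = "F", lod = 0, loq = 0)
  cfg <- sim_config(
    commodities = data.frame(name = "cropX", group = "vegetable",
                             n_samples = 5000),
    pesticides = pest, detection_prob = 1, violation_prob = 0.05,
    conc_lognormal = c(log(0.15), 1.2), seed = 31)
  d <- generate_monitoring_dataset(cfg)
  m <- mean(log(d$measurements$concentration))
  expect_lt(abs(m - log(0.15)), 3 * 1.2 / sqrt(5000))
})

test_that("multi-residue samples appear and classify by worst verdict", {
  cfg <- sim_config(detection_prob = 0.3, extra_residue_mean = 1.5,
                    violation_prob = 0.3, seed = 9)
  d <- generate_monitoring_dataset(cfg)
  per_sample <- table(d$measurements$sample_id)
  expect_gt(max(per_sample), 1)
  v <- classify_residues(d$samples, d$measurements, d$mrl_table)
  cats <- sample_categories(d$samples, v)
  mixed <- names(per_sample)[per_sample > 1]
  for (sid in mixed[seq_len(min(5, length(mixed)))]) {
    expect_equal(as.character(cats$category[cats$sample_id == sid]),
                 classify_sample(v$verdict[v$sample_id == sid]))
  }
})

test_that("validation replicate generator hits its targets", {
  a <- generate_validation_replicates(0.1, 95.3, 3.2, n = 5, seed = 4)
  b <- generate_validation_replicates(0.1, 95.3, 3.2, n = 5, seed = 4)
  expect_identical(a, b)

  flat <- generate_validation_replicates(0.1, 95.3, 0, n = 5, seed = 4)
  expect_equal(recovery_precision(flat, 0.1)$rsd, 0)
  expect_equal(recovery_precision(flat, 0.1)$recovery, 95.3)

  big <- generate_validation_replicates(0.1, 95.3, 3.2, n = 200, seed = 8)
  rec <- recovery_precision(big, 0.1)$recovery
  expect_lt(abs(rec - 95.3), 3 * 3.2 / sqrt(200))
})

test_that("the survey reconstruction is deterministic and exact", {
  t0 <- proc.time()[["elapsed"]]
  fx <- build_survey_fixture()
  expect_equal(nrow(fx$samples), 1146)
  expect_equal(nrow(fx$measurements), 91)
  v <- classify_residues(fx$samples, fx$measurements, fx$mrl_table)
  cats <- sample_categories(fx$samples, v)
  expect_equal(sum(cats$category == "above_mrl"), 11)

  fx2 <- build_survey_fixture()
  expect_identical(fx, fx2)  # no seed dependence: a pure function
  expect_lt(proc.time()[["elapsed"]] - t0, 30)
})

test_that("reconstruction accepts small specs and rejects bad marginals", {
  spec <- list(
    occurrence = data.frame(group = "vegetable", product = "lettuce",
                            n_total = 5, n_without = 4, n_below = 1,
                            n_above = 0, stringsAsFactors = FALSE),
    incidence = data.frame(pesticide = "pestA", n_detected = 1, n_above = 0,
                           conc_min = 0.2, conc_max = 0.2, mrl_min = 1,
                           mrl_max = 1, stringsAsFactors = FALSE),
    pairs = data.frame(pesticide = "pestA", commodity = "lettuce",
                       stringsAsFactors = FALSE))
  fx <- build_survey_fixture(spec)
  expect_equal(nrow(fx$samples), 5)
  expect_equal(fx$measurements$concentration, 0.2)
  occ <- occurrence_by_commodity(
    fx$samples, classify_residues(fx$samples, fx$measurements,
                                  fx$mrl_table))
  expect_equal(occ$n_without[occ$product == "lettuce"], 4L)

  bad <- spec
  bad$occurrence$n_below <- 2
  bad$occurrence$n_without <- 3
  expect_error(build_survey_fixture(bad), "inconsistent marginals")

  bad2 <- spec
  bad2$incidence$n_above <- 2
  expect_error(build_survey_fixture(bad2), "n_above")
})

test_that("detections balance between the two survey margins", {
  spec <- survey_fixture_spec()
  expect_equal(sum(spec$occurrence$n_below + spec$occurrence$n_above),
               sum(spec$incidence$n_detected))
  expect_equal(sum(spec$occurrence$n_above), sum(spec$incidence$n_above))
})
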