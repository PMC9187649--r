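test_that("MRL resolution prefers registrations and falls back to PLS", {
  reg <- data.frame(pesticide = "chlorfenapyr", commodity = "lettuce",
                    mrl = 1.0, source = "registered",
                    stringsAsFactors = FALSE)
  hit <- resolve_mrl("chlorfenapyr", "lettuce", reg)
  expect_equal(hit$mrl, 1.0)
  expect_equal(hit$source, "registered")

  miss <- resolve_mrl("fenobucarb", "aster scaber", reg)
  expect_equal(miss$mrl, 0.01)
  expect_equal(miss$source, "pls_default")

  none <- resolve_mrl("anything", "anything", NULL)
  expect_equal(none$mrl, 0.01)
  expect_equal(none$source, "pls_default")

  cfg <- analysis_config(pls_default_mrl = 0.05)
  expect_equal(resolve_mrl("x", "y", NULL, cfg)$mrl, 0.05)
})

test_that("residue verdicts follow LOD and strict-MRL conventions", {
  expect_equal(as.character(classify_residue(0.364, 0.001, 0.01)),
               "above_mrl")
  expect_equal(as.character(classify_residue(0.0005, 0.004, 0.01)),
               "not_detected")
  # equality with the MRL is compliant: "exceeding" is strict
  expect_equal(as.character(classify_residue(0.01, 0.001, 0.01)),
               "below_mrl")
})

test_that("residue classification is monotone in concentration", {
  set.seed(11)
  for (i in 1:50) {
    lod <- runif(1, 0, 0.05)
    mrl <- runif(1, lod + 0.01, 1)
    conc <- sort(runif(8, 0, 2))
    v <- classify_residue(conc, lod, mrl)
    expect_false(is.unsorted(v))
  }
})

test_that("a sample takes its worst residue verdict", {
  expect_equal(classify_sample(character(0)), "without_residue")
  expect_equal(classify_sample(c("below_mrl", "above_mrl")), "above_mrl")
  expect_equal(classify_sample(c("not_detected", "below_mrl")), "below_mrl")
  expect_equal(classify_sample(rep("not_detected", 3)), "without_residue")
  expect_error(classify_sample("weird"), "verdicts")
})

test_that("occurrence rows match an exhaustive per-sample tally", {
  for (seed in c(3, 17, 29, 101)) {
    d <- random_dataset(seed)
    v <- classify_residues(d$samples, d$measurements, d$mrl_table)
    occ <- occurrence_by_commodity(d$samples, v)
    oracle <- brute_occurrence(d$samples, v)
    m <- match(oracle$product, occ$product)
    expect_equal(occ$n_without[m], oracle$n_without)
    expect_equal(occ$n_below[m], oracle$n_below)
    expect_equal(occ$n_above[m], oracle$n_above)
    # counts always sum to the sample total, and the residue-free and
    # any-residue fractions are complementary before rounding
    expect_equal(occ$n_without + occ$n_below + occ$n_above, occ$n_total)
    raw_without <- 100 * occ$n_without / occ$n_total
    raw_with <- 100 * (occ$n_below + occ$n_above) / occ$n_total
    expect_equal(raw_without + raw_with, rep(100, nrow(occ)))
  }
})

test_that("occurrence on clean samples is 100% residue-free", {
  samples <- make_samples("spinach", 10)
  v <- classify_residues(samples,
                         make_measurement(character(0), character(0),
                                          numeric(0)))
  occ <- occurrence_by_commodity(samples, v)
  row <- occ[occ$product == "spinach", ]
  expect_equal(row$pct_without, 100.0)
  expect_equal(row$pct_with, 0.0)
  expect_equal(row$pct_above, 0.0)
})

test_that("incidence reports counts, rates and ranges per pesticide", {
  samples <- make_samples("lettuce", 20)
  meas <- rbind(
    make_measurement("lettuce-001", "chlorfenapyr", 0.2),
    make_measurement("lettuce-002", "chlorfenapyr", 0.5),
    make_measurement("lettuce-003", "fluopyram", 0.08))
  mrl <- data.frame(pesticide = c("chlorfenapyr", "fluopyram"),
                    commodity = "lettuce", mrl = c(1.0, 3.0),
                    source = "registered", stringsAsFactors = FALSE)
  v <- classify_residues(samples, meas, mrl)
  inc <- incidence_by_pesticide(samples, v)
  expect_equal(nrow(inc), 2)
  chl <- inc[inc$pesticide == "chlorfenapyr", ]
  expect_equal(chl$n_detected, 2L)
  expect_equal(chl$pct_detected, 10.0)
  expect_equal(c(chl$conc_min, chl$conc_max), c(0.2, 0.5))
  # a single detection collapses the range to a point
  flu <- inc[inc$pesticide == "fluopyram", ]
  expect_equal(flu$conc_min, flu$conc_max)
})

test_that("function class breakdown uses round-half-up percentages", {
  inc <- data.frame(
    pesticide = paste0("p", 1:32),
    function_class = rep(c("F", "I", "H", "G"), c(15, 14, 2, 1)),
    stringsAsFactors = FALSE)
  br <- function_class_breakdown(inc)
  expect_equal(br$n[br$function_class == "F"], 15L)
  expect_equal(br$pct[br$function_class == "F"], 46.9)
  # 100 * 14/32 = 43.75 rounds up, not to even
  expect_equal(br$pct[br$function_class == "I"], 43.8)
  expect_equal(br$pct[br$function_class == "H"], 6.3)
  expect_equal(br$pct[br$function_class == "G"], 3.1)

  one <- function_class_breakdown(
    data.frame(pesticide = "x", function_class = "F"))
  expect_equal(one$pct, 100.0)

  expect_error(function_class_breakdown(
    data.frame(pesticide = "x", function_class = "Z")), "function class")
})

test_that("sample ids of measurements must exist among samples", {
  samples <- make_samples("apple", 2, group = "fruit")
  meas <- make_measurement("ghost-001", "captan", 0.1)
  expect_error(classify_residues(samples, meas), "unknown sample_id")
})
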