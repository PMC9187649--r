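test_that("intake estimates follow residue x consumption / body weight", {
  expect_equal(esti(0.5, 0.12, 60), 1.0e-3)
  expect_equal(esti(0, 0.5, 70), 0)
  expect_equal(edi(0.1, 0.06, 60), 1.0e-4)
  # homogeneity: linear in consumption, inversely proportional to weight
  expect_equal(esti(1.452, 0.2, 60), 2 * esti(1.452, 0.1, 60))
  expect_equal(edi(0.3, 0.06, 120), edi(0.3, 0.06, 60) / 2)
  expect_error(esti(0.1, 0.1, 0), "body_weight")
  expect_error(esti(-0.1, 0.1, 60), ">= 0")
})

test_that("hazard quotients reproduce the reference arithmetic", {
  expect_equal(acute_hq(2.1e-4, 0.5), 0.042)
  expect_equal(acute_hq(8.0e-5, 0.2), 0.040)
  expect_equal(chronic_hq(6.8e-6, 0.01), 0.068)
  expect_equal(chronic_hq(6.4e-5, 0.2), 0.032)
  expect_equal(chronic_hq(0, 5), 0)
  # no authorised ARfD: the acute index does not exist, it is not zero
  expect_true(is.na(acute_hq(0.5, NA)))
  expect_error(acute_hq(0.5, 0), "arfd")
  expect_error(chronic_hq(1e-5, 0), "adi")
})

test_that("hazard quotients scale with consumption and body weight", {
  set.seed(5)
  for (i in 1:25) {
    resid <- runif(1, 0.01, 5)
    cons <- runif(1, 0.001, 0.5)
    bw <- runif(1, 20, 100)
    ref <- runif(1, 0.001, 1)
    k <- runif(1, 0.5, 4)
    expect_equal(acute_hq(esti(resid, k * cons, bw), ref),
                 k * acute_hq(esti(resid, cons, bw), ref))
    expect_equal(chronic_hq(edi(resid, cons, k * bw), ref),
                 chronic_hq(edi(resid, cons, bw), ref) / k)
    # the short-term estimate dominates the daily one for the same intake
    mean_resid <- resid * runif(1, 0, 1)
    expect_gte(esti(resid, cons, bw), edi(mean_resid, cons, bw))
  }
})

test_that("the cumulative index is an additive sum with a strict-100 cut", {
  expect_equal(cumulative_hi(numeric(0)), 0)
  expect_equal(cumulative_hi(c(0.080, 6.384)), 6.464)
  set.seed(9)
  for (i in 1:10) {
    a <- runif(sample(0:5, 1), 0, 40)
    b <- runif(sample(0:5, 1), 0, 40)
    expect_equal(cumulative_hi(c(a, b)),
                 cumulative_hi(a) + cumulative_hi(b))
  }
  expect_error(cumulative_hi(c(1, -2)), ">= 0")

  expect_equal(interpret_hazard_index(17.714), "acceptable")
  expect_equal(interpret_hazard_index(135), "potential_risk")
  expect_equal(interpret_hazard_index(100), "acceptable")
  # monotone: raising any quotient never clears a flagged index
  set.seed(13)
  for (i in 1:20) {
    hqs <- runif(4, 0, 60)
    bumped <- hqs + c(runif(1, 0, 50), 0, 0, 0)
    if (interpret_hazard_index(cumulative_hi(hqs)) == "potential_risk")
      expect_equal(interpret_hazard_index(cumulative_hi(bumped)),
                   "potential_risk")
  }
})

test_that("risk_table aggregates detections into the exposure records", {
  samples <- make_samples("lettuce", 5)
  meas <- rbind(make_measurement("lettuce-001", "pestA", 0.2),
                make_measurement("lettuce-002", "pestA", 0.4))
  mrl <- data.frame(pesticide = "pestA", commodity = "lettuce", mrl = 1,
                    source = "registered", stringsAsFactors = FALSE)
  v <- classify_residues(samples, meas, mrl)
  tox <- data.frame(pesticide = "pestA", adi = 0.01, arfd = 0.1,
                    stringsAsFactors = FALSE)
  cons <- data.frame(commodity = "lettuce", daily_intake = 0.06,
                     stringsAsFactors = FALSE)
  ra <- risk_table(v, cons, tox, analysis_config(body_weight = 60))
  r <- ra$records
  expect_equal(nrow(r), 1)
  expect_equal(r$esti, 4.0e-4)
  expect_equal(r$ahq, 0.40)
  expect_equal(r$edi, 3.0e-4)
  expect_equal(r$hq, 3.0)
  expect_equal(ra$summary$chi, 3.0)
  expect_equal(ra$summary$verdict, "acceptable")
})

test_that("risk_table handles empty surveys and reports what is missing", {
  samples <- make_samples("lettuce", 3)
  none <- classify_residues(samples,
                            make_measurement(character(0), character(0),
                                             numeric(0)))
  tox <- data.frame(pesticide = "pestA", adi = 0.01, arfd = NA,
                    stringsAsFactors = FALSE)
  cons <- data.frame(commodity = "lettuce", daily_intake = 0.06)
  ra <- risk_table(none, cons, tox)
  expect_equal(nrow(ra$records), 0)
  expect_equal(ra$summary$chi, 0)
  expect_equal(ra$summary$verdict, "acceptable")

  meas <- make_measurement("lettuce-001", "pestB", 0.2)
  v <- classify_residues(samples, meas)
  expect_error(risk_table(v, cons, tox), "pestB")
  tox2 <- rbind(tox, data.frame(pesticide = "pestB", adi = 0.02, arfd = NA))
  expect_error(risk_table(v, cons[0, ], tox2), "lettuce")
})

test_that("absent ARfD propagates as absent through the records", {
  samples <- make_samples("spinach", 4)
  meas <- rbind(make_measurement("spinach-001", "noArfD", 0.1),
                make_measurement("spinach-002", "hasArfD", 0.2))
  mrl <- data.frame(pesticide = c("noArfD", "hasArfD"),
                    commodity = "spinach", mrl = 1, source = "registered")
  v <- classify_residues(samples, meas, mrl)
  tox <- data.frame(pesticide = c("noArfD", "hasArfD"),
                    adi = c(0.01, 0.01), arfd = c(NA, 0.5))
  cons <- data.frame(commodity = "spinach", daily_intake = 0.05)
  ra <- risk_table(v, cons, tox)
  expect_true(is.na(ra$records$ahq[ra$records$pesticide == "noArfD"]))
  expect_false(is.na(ra$records$ahq[ra$records$pesticide == "hasArfD"]))
  # absent acute entries are excluded from the acute maximum
  expect_equal(ra$summary$ahq_max,
               ra$records$ahq[ra$records$pesticide == "hasArfD"])
})

test_that("the LOD/2 substitution policy lowers the mean residue", {
  samples <- make_samples("chard", 4)
  meas <- rbind(make_measurement("chard-001", "pestA", 0.2, lod = 0.05),
                make_measurement("chard-002", "pestA", 0.01, lod = 0.05))
  mrl <- data.frame(pesticide = "pestA", commodity = "chard", mrl = 1,
                    source = "registered")
  v <- classify_residues(samples, meas, mrl)
  tox <- data.frame(pesticide = "pestA", adi = 0.01, arfd = NA)
  cons <- data.frame(commodity = "chard", daily_intake = 0.1)
  excl <- risk_table(v, cons, tox, analysis_config())
  subs <- risk_table(v, cons, tox,
                     analysis_config(nondetect_policy = "half_lod"))
  expect_equal(excl$records$mean_residue, 0.2)
  expect_equal(subs$records$mean_residue, mean(c(0.2, 0.025)))
})
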