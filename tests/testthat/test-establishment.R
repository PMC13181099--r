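test_that("ordinal scores map to nested outcomes; score 4 never establishes", {
  oc <- derive_outcomes(0:5)
  expect_equal(oc$germinated, c(FALSE, TRUE, TRUE, TRUE, TRUE, TRUE))
  expect_equal(oc$cotyledon, c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE))
  expect_equal(oc$established, c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE))
  # arrested growth / fungal damage (4): germinated and cotyledon, not
  # established
  expect_equal(unlist(derive_outcomes(4)), c(germinated = TRUE,
                                             cotyledon = TRUE,
                                             established = FALSE))
  expect_error(derive_outcomes(7), "0..5")
  expect_error(derive_outcomes(-1), "0..5")
})

test_that("Wilson intervals match the closed form and are boundary-safe", {
  # independent evaluation of the closed-form score interval
  z <- qnorm(0.975)
  x <- 4; n <- 5; p <- x / n
  low <- (p + z^2 / (2 * n) - z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))) /
    (1 + z^2 / n)
  high <- (p + z^2 / (2 * n) + z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))) /
    (1 + z^2 / n)
  ci <- wilson_ci(4, 5)
  expect_equal(unname(ci[1, ]), c(low, high), tolerance = 1e-10)
  # cross-check against the score interval of prop.test (no continuity
  # correction)
  pt <- suppressWarnings(stats::prop.test(4, 5, correct = FALSE))$conf.int
  expect_equal(unname(ci[1, ]), as.numeric(pt), tolerance = 1e-10)
  expect_equal(unname(wilson_ci(0, 5)[1, "low"]), 0)
  expect_equal(unname(wilson_ci(5, 5)[1, "high"]), 1)
})

test_that("group rates respect nesting and recombine consistently", {
  cfg <- sim_config(rng_seed = 13, n_accessions = 12, seeds_per_unit = 5)
  o <- simulate_soil_experiment(cfg)
  rates <- aggregate_rates(o, c("species", "soil_code", "treatment"))
  expect_true(all(rates$establishment_rate <= rates$cotyledon_rate + 1e-12))
  expect_true(all(rates$cotyledon_rate <= rates$germination_rate + 1e-12))
  for (nm in c("germination", "cotyledon", "establishment")) {
    expect_true(all(rates[[paste0(nm, "_low")]] <= rates[[paste0(nm, "_rate")]]))
    expect_true(all(rates[[paste0(nm, "_rate")]] <= rates[[paste0(nm, "_high")]]))
  }
  # disjoint-group weighted average equals the pooled rate
  by_soil <- aggregate_rates(o, "soil_code")
  fine <- aggregate_rates(o, c("soil_code", "treatment"))
  for (soil in by_soil$soil_code) {
    sub <- fine[fine$soil_code == soil, ]
    expect_equal(sum(sub$germination_rate * sub$n) / sum(sub$n),
                 by_soil$germination_rate[by_soil$soil_code == soil],
                 tolerance = 1e-12)
  }
  # boundary groups
  r0 <- aggregate_rates(ordinal_records(rep(0, 5)), "soil_code")
  expect_equal(r0$establishment_rate, 0)
  expect_equal(r0$establishment_low, 0)
  r5 <- aggregate_rates(ordinal_records(rep(5, 5)), "soil_code")
  expect_equal(r5$establishment_rate, 1)
  expect_equal(r5$establishment_high, 1)
})

test_that("establishment matrix averages the two treatments per cell", {
  recs <- rbind(ordinal_records(c(5, 5, 0, 0, 0), treatment = "NS"),
                ordinal_records(c(5, 5, 5, 5, 0), treatment = "S"))
  m <- establishment_matrix(recs)
  expect_equal(unname(m["A1", "BV"]), mean(c(40, 80)))
  # same rate in both treatments: cell equals that rate
  recs2 <- rbind(ordinal_records(c(5, 5, 5, 0, 0), treatment = "NS"),
                 ordinal_records(c(5, 5, 5, 0, 0), treatment = "S"))
  expect_equal(unname(establishment_matrix(recs2)["A1", "BV"]), 60)
  # missing cells stay NA
  recs3 <- rbind(ordinal_records(5, accession_id = "A1", soil_code = "BV"),
                 ordinal_records(0, accession_id = "B2", soil_code = "MEC"))
  m3 <- establishment_matrix(recs3)
  expect_true(is.na(m3["A1", "MEC"]) && is.na(m3["B2", "BV"]))
  # row/column means match an independent groupby
  cfg <- sim_config(rng_seed = 17, n_accessions = 9)
  o <- simulate_soil_experiment(cfg)
  m4 <- establishment_matrix(o)
  est <- derive_outcomes(o$score)$established
  for (soil in colnames(m4)) {
    manual <- sapply(rownames(m4), function(acc) {
      sel <- o$accession_id == acc & o$soil_code == soil
      100 * mean(tapply(est[sel], o$treatment[sel], mean))
    })
    expect_equal(unname(m4[, soil]), unname(manual), tolerance = 1e-12)
  }
})

test_that("IRLS logistic reproduces the 2x2 odds ratio and matches glm", {
  a <- 8; b <- 4; c_ <- 3; d <- 9
  recs <- rbind(ordinal_records(rep(c(5, 0), c(a, b)), treatment = "NS"),
                ordinal_records(rep(c(5, 0), c(c_, d)), treatment = "S"))
  fit <- fit_logistic(recs, "established", ~ treatment)
  or <- fit$coefficients$or[fit$coefficients$term == "treatmentS"]
  expect_equal(or, (c_ * b) / (d * a), tolerance = 1e-6)

  cfg <- sim_config(rng_seed = 19, n_accessions = 12, seeds_per_unit = 10)
  o <- simulate_soil_experiment(cfg)
  fit2 <- fit_logistic(o, "germinated", ~ species * soil_code + treatment)
  y <- derive_outcomes(o$score)$germinated
  ref <- stats::glm(y ~ species * soil_code + treatment, data = o,
                    family = stats::binomial(),
                    control = stats::glm.control(epsilon = 1e-14, maxit = 100))
  expect_equal(fit2$coefficients$estimate,
               unname(coef(ref)[fit2$coefficients$term]), tolerance = 1e-6)
  expect_equal(fit2$coefficients$se,
               unname(summary(ref)$coefficients[fit2$coefficients$term,
                                                "Std. Error"]),
               tolerance = 1e-8)
})

test_that("degenerate logistic designs fail loudly", {
  expect_error(fit_logistic(ordinal_records(rep(5, 10)), "established",
                            ~ treatment), "constant")
  # outcome perfectly separated by treatment
  recs <- rbind(ordinal_records(rep(5, 10), treatment = "S"),
                ordinal_records(rep(0, 10), treatment = "NS"))
  expect_error(fit_logistic(recs, "established", ~ treatment), "separation")
  # aliased column: soil perfectly confounded with treatment
  recs2 <- rbind(ordinal_records(c(0, 5, 5), treatment = "NS", soil_code = "BV"),
                 ordinal_records(c(5, 0, 0), treatment = "S", soil_code = "MEC"))
  expect_error(fit_logistic(recs2, "established", ~ treatment + soil_code),
               "rank deficient.*soil_code")
})

test_that("scarification effect estimate covers the truth across replicates", {
  hits <- 0L
  for (r in 1:30) {
    cfg <- sim_config(rng_seed = 100 + r, n_accessions = 12,
                      seeds_per_unit = 8,
                      exp2 = list(beta_scar = 1.0, sigma_accession = 0))
    o <- simulate_soil_experiment(cfg)
    fit <- fit_logistic(o, "established", ~ species * soil_code + treatment)
    row <- fit$coefficients[fit$coefficients$term == "treatmentS", ]
    lo <- row$estimate - qnorm(0.975) * row$se
    hi <- row$estimate + qnorm(0.975) * row$se
    if (lo <= 1.0 && 1.0 <= hi) hits <- hits + 1L
    expect_gt(row$estimate, 0)  # sign always recovered at this n
  }
  expect_gte(hits, 25L)  # ~95% nominal coverage over 30 replicates
})

test_that("dormancy-establishment correlation matches the direct formula", {
  est <- matrix(c(10, 20, 30, 40, 15, 35, 25, 45), 4, 2,
                dimnames = list(c("A", "B", "C", "D"), c("BV", "MEC")))
  dd <- data.frame(accession_id = c("A", "B", "C", "D"),
                   dds50 = c(5, 10, 15, 20), dds50_censored = FALSE)
  res <- correlate_dormancy_establishment(dd, est)
  expect_equal(res$r[res$soil_code == "BV"], 1)
  x <- dd$dds50; y <- est[, "MEC"]
  r_manual <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(res$r[res$soil_code == "MEC"], r_manual, tolerance = 1e-12)
  expect_equal(res$p[res$soil_code == "MEC"],
               cor.test(x, y)$p.value, tolerance = 1e-10)

  # constant establishment: undefined marker, not an error
  est2 <- est; est2[, "MEC"] <- 50
  res2 <- correlate_dormancy_establishment(dd, est2)
  expect_true(is.na(res2$r[res2$soil_code == "MEC"]))
  expect_match(res2$note[res2$soil_code == "MEC"], "zero variance")

  # censored accessions are excluded and counted
  dd3 <- rbind(dd, data.frame(accession_id = "E", dds50 = 365,
                              dds50_censored = TRUE))
  est3 <- rbind(est, E = c(50, 60))
  res3 <- correlate_dormancy_establishment(dd3, est3)
  expect_equal(res3$n, c(4L, 4L))
  expect_equal(res3$n_censored_excluded, c(1L, 1L))
})
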