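test_that("growth traits follow their defining formulas", {
  tr <- derive_growth_traits(growth_records(20, 10))
  expect_equal(tr$total_mm, 30)
  expect_equal(tr$ratio, 20 / 11)
  expect_equal(tr$allocation, 2 / 3)
  expect_true(tr$established)  # threshold inclusive at exactly 30 mm
  expect_false(derive_growth_traits(growth_records(20, 9.99))$established)

  # stabilizer: epicotyl measured but non-elongated
  tr0 <- derive_growth_traits(growth_records(5, 0))
  expect_equal(tr0$ratio, 5)

  # missing organ: retained but invalid, no traits
  trm <- derive_growth_traits(growth_records(NA, 10))
  expect_false(trm$valid)
  expect_true(is.na(trm$total_mm))

  # both allocation and ratio reproducible from the stored organ lengths
  set.seed(8)
  g <- growth_records(runif(20, 1, 40), runif(20, 0, 30),
                      replicate = rep(1:2, 10))
  tt <- derive_growth_traits(g)
  expect_equal(tt$allocation, g$hypocotyl_mm / (g$hypocotyl_mm + g$epicotyl_mm))
  expect_equal(tt$ratio, g$hypocotyl_mm / (g$epicotyl_mm + 1))
})

test_that("exclusion rule retains only fully measured seedlings", {
  g <- rbind(growth_records(c(10, NA, 12, 14), c(5, 6, NA, 7)),
             growth_records(c(NA, 20), c(NA, 10), ph_level = 5.5, das = 7L))
  fv <- filter_valid(derive_growth_traits(g))
  expect_equal(fv$n_excluded, 3L)
  expect_equal(nrow(fv$retained), 3L)
  by_str <- fv$excluded_by_stratum
  expect_equal(by_str$n_excluded[by_str$ph_level == "5.5" & by_str$das == "7"],
               1L)
})

test_that("two-way ANOVA matches the projection oracle and its invariances", {
  set.seed(12)
  d <- expand.grid(ph_level = c(5.5, 7, 8.5), das = c(7L, 14L), rep = 1:4)
  d$y <- 10 + 2 * (d$ph_level == 7) + 5 * (d$das == 14) + rnorm(nrow(d))
  tab <- anova_two_way(d, "y")
  oracle <- anova2_oracle(d$y, d$ph_level, d$das)
  expect_equal(tab$ss, oracle$ss, tolerance = 1e-10)
  expect_equal(tab$df, oracle$df)
  expect_equal(tab$f[1:3], oracle$f[1:3], tolerance = 1e-10)
  expect_equal(sum(tab$df), nrow(d) - 1)

  # location invariance: adding a constant leaves every F unchanged
  d2 <- d; d2$y <- d2$y + 100
  expect_equal(anova_two_way(d2, "y")$f, tab$f, tolerance = 1e-10)
  # affine rescaling of the response too
  d3 <- d; d3$y <- 3.7 * d3$y - 12
  expect_equal(anova_two_way(d3, "y")$f, tab$f, tolerance = 1e-10)

  # unbalanced data: type II still agrees with the projection oracle
  d4 <- d[-c(1, 5, 8), ]
  expect_equal(anova_two_way(d4, "y")$ss,
               anova2_oracle(d4$y, d4$ph_level, d4$das)$ss, tolerance = 1e-10)

  # empty cell is a design error naming the cell
  d5 <- d[!(d$ph_level == 8.5 & d$das == 14), ]
  expect_error(anova_two_way(d5, "y"), "empty design cell.*8.5.*14")
})

test_that("DAS dominates the F ordering on fixtures built that way", {
  cfg <- sim_config(rng_seed = 23, n_accessions = 6)
  tr <- filter_valid(derive_growth_traits(simulate_ph_experiment(cfg)))$retained
  tab <- anova_two_way(tr, "total_mm")
  f_das <- tab$f[tab$source == "das"]
  f_ph <- tab$f[tab$source == "ph_level"]
  expect_gt(f_das, f_ph)
  expect_lt(tab$p[tab$source == "das"], 0.001)
})

test_that("permutation max-|t| contrasts behave like a family-wise test", {
  set.seed(3)
  d <- data.frame(g = rep(c("a", "b"), each = 12),
                  y = c(rnorm(12), rnorm(12, 2)))
  two <- pairwise_contrasts(d, "y", "g", n_perm = 499, rng_seed = 5)
  expect_equal(nrow(two), 1L)
  # with exactly two groups the adjusted p IS the unadjusted permutation p
  # (max over one pair), so it must match a direct permutation of that pair
  pair_t <- function(y, g) {
    ms <- tapply(y, g, mean); vs <- tapply(y, g, var); ns <- table(g)
    sp2 <- ((ns[1] - 1) * vs[1] + (ns[2] - 1) * vs[2]) / (sum(ns) - 2)
    (ms[1] - ms[2]) / sqrt(sp2 * (1 / ns[1] + 1 / ns[2]))
  }
  t_obs <- abs(pair_t(d$y, factor(d$g)))
  set.seed(5)
  exceed <- sum(vapply(1:499, function(b)
    abs(pair_t(d$y, sample(factor(d$g)))) >= t_obs, TRUE))
  expect_equal(two$p_adjusted, (1 + exceed) / 500)

  # constructed ordering 7.0 > 5.5 > 8.5 is reproduced by the significant
  # contrasts
  set.seed(9)
  d3 <- data.frame(g = rep(c("5.5", "7", "8.5"), each = 30),
                   y = c(rnorm(30, 10), rnorm(30, 14), rnorm(30, 6)))
  res <- pairwise_contrasts(d3, "y", "g", n_perm = 499, rng_seed = 2)
  get <- function(g1, g2) res[res$group1 == g1 & res$group2 == g2, ]
  expect_lt(get("5.5", "7")$diff, 0)    # 7.0 above 5.5
  expect_gt(get("5.5", "8.5")$diff, 0)  # 5.5 above 8.5
  expect_true(all(res$p_adjusted < 0.05))
  expect_error(pairwise_contrasts(data.frame(g = "a", y = 1), "y", "g"),
               ">= 2 groups")
})

test_that("polynomial pH response matches the normal-equation oracle", {
  # degree 2 on three level means: saturated, zero residuals
  d <- data.frame(ph_level = rep(c(5.5, 7, 8.5), each = 2),
                  y = rep(c(3, 9, 4), each = 2))
  fit <- suppressWarnings(polynomial_ph_response(d, "y", degree = 2))
  expect_true(fit$saturated)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)

  # symmetric response about 7.0: linear slope is zero
  ds <- data.frame(ph_level = c(5.5, 7, 8.5), y = c(5, 9, 5))
  fit1 <- polynomial_ph_response(ds, "y", degree = 1)
  expect_equal(fit1$coefficients$estimate[2], 0, tolerance = 1e-10)

  # random data: coefficients equal the explicit normal-equation solution
  set.seed(6)
  dr <- data.frame(ph_level = sample(c(5.5, 7, 8.5), 30, replace = TRUE))
  dr$y <- 2 + 0.8 * dr$ph_level + rnorm(30)
  fit2 <- polynomial_ph_response(dr, "y", degree = 2)
  ph_c <- dr$ph_level - mean(c(5.5, 7, 8.5))
  X <- cbind(1, ph_c, ph_c^2)
  beta <- solve(t(X) %*% X, t(X) %*% dr$y)
  expect_equal(fit2$coefficients$estimate, as.numeric(beta), tolerance = 1e-10)
  expect_error(polynomial_ph_response(ds, "y", degree = 3), "distinct pH")
})

test_that("logit allocation regression transforms and clamps correctly", {
  d <- derive_growth_traits(growth_records(rep(10, 8), rep(10, 8),
                                           das = rep(c(7L, 14L), 4)))
  fit <- logit_allocation_regression(d, ~ das)
  expect_equal(fit$coefficients$estimate, c(0, 0), tolerance = 1e-12)

  # allocation of exactly 1 enters at logit(0.995)
  d1 <- derive_growth_traits(growth_records(c(10, 10), c(0, 0)))
  expect_warning(fit1 <- logit_allocation_regression(d1, ~ 1), "degenerate")
  expect_equal(fit1$coefficients$estimate[1], qlogis(0.995), tolerance = 1e-12)

  # linear-in-logit recovery against lm
  set.seed(14)
  n <- 200
  ph <- sample(c(5.5, 7, 8.5), n, replace = TRUE)
  eta <- -0.3 + 0.25 * ph + rnorm(n, 0, 0.3)
  alloc <- plogis(eta)
  tot <- runif(n, 20, 50)
  g <- growth_records(alloc * tot, (1 - alloc) * tot, ph_level = ph)
  tr <- derive_growth_traits(g)
  fit2 <- logit_allocation_regression(tr, ~ ph_level)
  ref <- lm(qlogis(pmin(pmax(tr$allocation, 0.005), 0.995)) ~ tr$ph_level)
  expect_equal(fit2$coefficients$estimate, unname(coef(ref)),
               tolerance = 1e-10)
  expect_equal(fit2$coefficients$p, unname(summary(ref)$coefficients[, 4]),
               tolerance = 1e-10)
})
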