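test_that("balanced one-way REML matches the closed-form ANOVA estimators", {
  d <- one_way_records(40, 4, sigma_f = 3, sigma_e = 5, seed = 42)
  fit <- fit_varcomps(d, random = "family")
  av <- anova(lm(value ~ family, d))
  s2e_ems <- av["Residuals", "Mean Sq"]
  s2f_ems <- (av["family", "Mean Sq"] - s2e_ems) / 4
  expect_lt(abs(fit$components["sigma2_f"] - s2f_ems), 1e-6)
  expect_lt(abs(fit$components["sigma2_e"] - s2e_ems), 1e-6)
  expect_true(fit$converged)
})

test_that("REML log-likelihood agrees with the independent mixed-model fitter", {
  skip_if_not_installed("lme4")
  set.seed(7)
  d <- expand.grid(family = sprintf("F%03d", 1:50), rep = 1:3, harvest = 1:4,
                   stringsAsFactors = FALSE)
  d$year <- ifelse(d$harvest <= 2, 1, 2)
  d$site <- "S"; d$treatment <- "T"; d$row <- 1; d$col <- 1; d$population <- "P"
  fi <- match(d$family, sprintf("F%03d", 1:50))
  f <- rnorm(50, 0, sqrt(10.3)); fy <- matrix(rnorm(100, 0, sqrt(8)), 50, 2)
  d$value <- 32.2 + f[fi] + fy[cbind(fi, d$year)] + rnorm(nrow(d), 0, sqrt(66.1))
  fit <- fit_varcomps(d, random = c("family", "family:year"), se = FALSE)
  lf <- lme4::lmer(value ~ (1 | family) + (1 | family:year),
                   data = transform(d, family = factor(family),
                                    year = factor(year)), REML = TRUE)
  expect_lt(abs(fit$loglik - as.numeric(logLik(lf))), 1e-5)
  ref <- as.data.frame(lme4::VarCorr(lf))
  expect_equal(sort(unname(fit$components)), sort(ref$vcov), tolerance = 1e-4)
})

test_that("the EM/AI iteration never decreases the REML log-likelihood", {
  d <- one_way_records(25, 3, sigma_f = 2, sigma_e = 6, seed = 8)
  fit <- fit_varcomps(d, random = "family", se = FALSE)
  expect_true(all(diff(fit$loglik_trace) > -1e-7))
  # plain EM (no acceleration) is monotone too
  fit_em <- fit_varcomps(d, random = "family", se = FALSE, accelerate = FALSE)
  expect_true(all(diff(fit_em$loglik_trace) > -1e-9))
  expect_equal(fit$components, fit_em$components, tolerance = 1e-3)
})

test_that("BLUPs shrink raw family means toward the grand mean", {
  d <- one_way_records(30, 3, sigma_f = 2, sigma_e = 8, seed = 9)
  fit <- fit_varcomps(d, random = "family", se = FALSE)
  raw <- tapply(d$value, d$family, mean)
  gm <- mean(d$value)
  dev_blup <- abs(fit$blups$u[match(names(raw), fit$blups$family)])
  dev_raw <- abs(raw - gm)
  expect_true(all(dev_blup <= dev_raw + 1e-8))
  expect_lt(abs(mean(fit$blups$u)), 1e-6)   # random effects centre on zero
})

test_that("non-identifiable interaction terms are refused by name", {
  d <- one_way_records(10, 2, 1, 2, seed = 10)   # single year in the data
  expect_error(fit_varcomps(d, random = c("family", "family:year")),
               "family:year")
  expect_error(fit_varcomps(d[0, ], random = "family"), "families")
})

test_that("the boundary-mixture likelihood-ratio test is calibrated", {
  d <- one_way_records(40, 3, sigma_f = 2, sigma_e = 5, seed = 11)
  full <- fit_varcomps(d, random = "family", se = FALSE)
  # p = 0.05 at the textbook 2.706 threshold of the half-half mixture
  fake_red <- full; fake_red$random <- character(0)
  fake_red$loglik <- full$loglik - 2.706 / 2
  # restore nesting fields expected by the checker
  fake_red$random <- setdiff(full$random, "family")
  out <- lrt_varcomp(full, fake_red)
  expect_equal(out$statistic, 2.706)
  expect_equal(out$p_value, 0.05, tolerance = 1e-3)
  # identical fits: statistic 0, p 1
  same <- full; same$random <- character(0)
  expect_equal(lrt_varcomp(full, same)$p_value, 1)
  expect_error(lrt_varcomp(full, full), "nested")
})

test_that("the family-variance test has power and respects the null", {
  null_p <- vapply(1:30, function(s) {
    d <- one_way_records(40, 3, sigma_f = 0, sigma_e = 5, seed = 100 + s)
    full <- fit_varcomps(d, random = "family", se = FALSE)
    red <- fit_varcomps(d, random = "family", se = FALSE)
    # reduced model: family variance forced out (intercept-only REML)
    ll0 <- stats::logLik(stats::lm(value ~ 1, d), REML = TRUE)
    red$loglik <- as.numeric(ll0); red$random <- character(0)
    lrt_varcomp(full, red)$p_value
  }, numeric(1))
  expect_gte(mean(null_p > 0.05), 0.9)

  strong_p <- vapply(1:15, function(s) {
    d <- one_way_records(100, 3, sigma_f = 5, sigma_e = 5, seed = 200 + s)
    full <- fit_varcomps(d, random = "family", se = FALSE)
    red <- full
    red$loglik <- as.numeric(stats::logLik(stats::lm(value ~ 1, d), REML = TRUE))
    red$random <- character(0)
    lrt_varcomp(full, red)$p_value
  }, numeric(1))
  expect_gte(mean(strong_p < 0.001), 0.95)
})

test_that("a zero-variance family effect is estimated at the boundary", {
  hits <- vapply(1:20, function(s) {
    d <- one_way_records(30, 3, sigma_f = 0, sigma_e = 4, seed = 300 + s)
    fit <- fit_varcomps(d, random = "family", se = FALSE)
    fit$components["sigma2_f"] / fit$components["sigma2_e"]
  }, numeric(1))
  # under a zero-variance truth the estimate collapses toward the boundary
  expect_lt(median(hits), 0.1)
})

test_that("repeatability follows its divisor algebra", {
  expect_equal(repeatability(c(sigma2_f = 10, sigma2_e = 30), d_e = 3), 0.5)
  expect_equal(repeatability(c(sigma2_f = 0, sigma2_e = 30), d_e = 3), 0)
  # worked multi-component case: 10.3 / (10.3 + 8/2 + 66.1/48)
  r <- repeatability(c(sigma2_f = 10.3, sigma2_gy = 8.0, sigma2_e = 66.1),
                     interactions = c(sigma2_gy = 2), d_e = 48)
  expect_equal(r, 10.3 / (10.3 + 4 + 66.1 / 48), tolerance = 1e-12)
  expect_equal(round(r, 3), 0.657)
  # strictly increasing in each divisor and in sigma2_g; bounded in [0,1]
  r_lo <- repeatability(c(sigma2_f = 10.3, sigma2_gy = 8, sigma2_e = 66.1),
                        interactions = c(sigma2_gy = 1), d_e = 16)
  expect_lt(r_lo, r)
  r_hi_g <- repeatability(c(sigma2_f = 20, sigma2_gy = 8, sigma2_e = 66.1),
                          interactions = c(sigma2_gy = 2), d_e = 48)
  expect_gt(r_hi_g, r)
  expect_true(r >= 0 && r <= 1)
  expect_error(repeatability(c(sigma2_f = 0, sigma2_e = 0), d_e = 3), "denominator")
  expect_error(repeatability(c(sigma2_f = 1, sigma2_e = 1),
                             interactions = c(sigma2_gy = 2), d_e = 3),
               "absent")
})

test_that("family clustering applies complete linkage and the Hartigan rule", {
  set.seed(12)
  blobs <- rbind(matrix(rnorm(40 * 3, 0, 1), 40, 3),
                 matrix(rnorm(40 * 3, 10, 1), 40, 3))
  out <- cluster_families(blobs)
  expect_equal(out$k_opt, 2)
  # merge heights monotone non-decreasing (complete-linkage property)
  expect_true(all(diff(out$hclust$height) >= -1e-10))
  # all rows identical: one cluster with zero within-SS
  same <- matrix(1, 10, 3)
  out2 <- cluster_families(same)
  expect_equal(out2$k_opt, 1)
  expect_equal(out2$W[1], 0)
  expect_error(cluster_families(matrix(1, 1, 3)), "2 families")
})
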