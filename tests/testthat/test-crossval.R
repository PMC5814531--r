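sim_cv_data <- function(n = 60, m = 300, h2 = 0.5, seed = 1) {
  set.seed(seed)
  M <- matrix(rbinom(n * m, 2, rep(runif(m, .1, .9), each = n)), n, m,
              dimnames = list(sprintf("I%03d", 1:n), NULL))
  b <- rnorm(m)
  g <- drop(scale(M, scale = FALSE) %*% b)
  g <- g / sd(g)
  y <- g + rnorm(n, 0, sqrt((1 - h2) / h2))
  names(y) <- rownames(M)
  list(M = M, y = y, g = stats::setNames(g, rownames(M)))
}

test_that("fold sizes are balanced and partitions reproducible", {
  parts <- cv_partitions(103, folds = 10, n_reps = 5, seed = 3)
  for (p in parts) expect_lte(diff(range(table(p))), 1)
  expect_identical(parts, cv_partitions(103, folds = 10, n_reps = 5, seed = 3))
  expect_false(identical(parts[[1]], parts[[2]]))
  expect_error(make_folds(5, 10, 1), "folds")
})

test_that("an oracle model attains perfect predictive ability", {
  d <- sim_cv_data(seed = 4)
  rep_cv <- run_tenfold(d$y, oracle_factory(d$y), n_reps = 3, seed = 5)
  expect_equal(rep_cv$replicates$pa, rep(1, 3), tolerance = 1e-12)
  expect_equal(rep_cv$replicates$slope, rep(1, 3), tolerance = 1e-12)
})

test_that("a mean predictor yields zero PA with a warning, not NaN", {
  d <- sim_cv_data(n = 40, seed = 6)
  flat <- function(y_train, tr, te) stats::setNames(rep(0, length(te)), te)
  w <- capture_warnings(rep_cv <- run_tenfold(d$y, flat, n_reps = 2, seed = 7))
  expect_match(w, "zero-variance", all = TRUE)
  expect_length(w, 2)
  expect_equal(rep_cv$replicates$pa, c(0, 0))
})

test_that("cross-validation reports are deterministic given the seed", {
  d <- sim_cv_data(seed = 8)
  f <- gblup_factory(standard_grm(d$M))
  r1 <- run_tenfold(d$y, f, n_reps = 2, seed = 9)
  r2 <- run_tenfold(d$y, f, n_reps = 2, seed = 9)
  expect_identical(r1$replicates, r2$replicates)
})

test_that("model failures flag the replicate and are excluded from the mean", {
  d <- sim_cv_data(n = 30, seed = 10)
  n_calls <- 0
  flaky <- function(y_train, tr, te) {
    n_calls <<- n_calls + 1
    if (n_calls > 12) stop("solver blew up")
    d$y[te]
  }
  expect_warning(rep_cv <- run_tenfold(d$y, flaky, folds = 10, n_reps = 2, seed = 11),
                 "flagged")
  expect_equal(sum(rep_cv$replicates$failed), 1)
  expect_equal(rep_cv$mean_pa, 1, tolerance = 1e-12)
})

test_that("balanced-target training matches the published design arithmetic", {
  set.seed(12)
  n_per <- 104
  pop <- rep(paste0("Pop", 1:5), each = n_per)
  ids <- sprintf("I%03d", seq_along(pop))
  y <- rnorm(length(pop)); names(y) <- ids
  seen <- new.env()
  spy <- function(y_train, tr, te) {
    seen$train <- tr; seen$test <- te
    stats::setNames(y[te], te)
  }
  rep_cv <- run_balanced_target(y, pop, "Pop2", spy, n_reps = 2, seed = 13)
  # 5 x 52 = 260 ~ "approximately 258"
  expect_equal(length(seen$train), 5 * (n_per / 2))
  expect_true(all(table(pop[match(seen$train, ids)]) == n_per / 2))
  # validation only from the target population, never in training
  expect_true(all(pop[match(seen$test, ids)] == "Pop2"))
  expect_length(intersect(seen$train, seen$test), 0)
  expect_equal(rep_cv$mean_pa, 1, tolerance = 1e-12)
  expect_error(run_balanced_target(y, pop, "Pop9", spy), "unknown")
  expect_error(run_balanced_target(y[1:104], pop[1:104], "Pop1", spy), "2 populations")
})

test_that("bias slope recovers known linear relations", {
  set.seed(14)
  blup <- rnorm(50, 0, 2)
  expect_equal(bias_slope(blup, blup), 1)
  expect_equal(bias_slope(0.5 * blup, blup), 0.5)
  expect_equal(bias_slope(2 * blup + 3, blup), 2)
  expect_error(bias_slope(1:2, 1:2), "pairs")
  expect_error(bias_slope(rnorm(5), rep(1, 5)), "variance")
})

test_that("the method-by-trait ANOVA has the factorial degrees of freedom", {
  set.seed(15)
  tab <- expand.grid(method = paste0("m", 1:4), trait = paste0("t", 1:8),
                     replicate = 1:5, stringsAsFactors = FALSE)
  tab$pa <- rnorm(nrow(tab), 0.3, 0.05)
  out <- method_trait_anova(tab)
  expect_equal(out$df[out$term == "method"], 3)
  expect_equal(out$df[out$term == "trait"], 7)
  expect_equal(out$df[out$term == "method:trait"], 21)
  expect_equal(out$df[out$term == "Residuals"], 128)
  # degenerate all-equal table: p reported as 1, no NaN propagation
  tab$pa <- 0.3
  out2 <- method_trait_anova(tab)
  expect_true(all(out2$p_value[out2$term != "Residuals"] == 1))
  expect_error(method_trait_anova(tab[-1, ]), "unbalanced")
})
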