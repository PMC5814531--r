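test_that("founder simulation honours the Balding-Nichols divergence level", {
  # no divergence: multi-population Fst indistinguishable from 0
  pops0 <- simulate_founders(n_pops = 3, n_per_pop = 80, n_snps = 2000,
                             fst = 0, seed = 7)
  by_pop <- lapply(levels(pops0$pop), function(k)
    pops0$dosage[pops0$pop == k, , drop = FALSE])
  expect_lt(abs(wc_fst(by_pop)), 0.005)

  # study-scale divergence recovered by the Weir-Cockerham moment oracle
  pops <- simulate_founders(n_pops = 5, n_per_pop = 110, n_snps = 5000,
                            fst = 0.1, seed = 7)
  by_pop <- lapply(levels(pops$pop), function(k)
    pops$dosage[pops$pop == k, , drop = FALSE])
  fst_hat <- wc_fst(by_pop)
  expect_gt(fst_hat, 0.07)
  expect_lt(fst_hat, 0.13)
})

test_that("founder sets match the study scale and structural invariants", {
  pops <- simulate_founders(seed = 1, n_snps = 500)
  expect_gte(length(pops$ids), 517)
  expect_lte(length(pops$ids), 566)
  expect_true(all(pops$dosage %in% 0:2))
  expect_equal(length(pops$pop), length(pops$ids))
  for (sc in unique(pops$snps$scaffold)) {
    pos <- pops$snps$pos[pops$snps$scaffold == sc]
    expect_true(all(diff(pos) > 0))
  }
  expect_error(simulate_founders(n_pops = 0), "n_pops")
  expect_error(simulate_founders(fst = 1), "fst")
  expect_error(simulate_founders(maf_floor = 0.7), "maf_floor")
})

test_that("simulation is bit-reproducible under a fixed seed", {
  a <- simulate_founders(n_pops = 2, n_per_pop = 30, n_snps = 200, seed = 42)
  b <- simulate_founders(n_pops = 2, n_per_pop = 30, n_snps = 200, seed = 42)
  expect_identical(a, b)
  fa <- simulate_polycross(a, seed = 9)
  fb <- simulate_polycross(b, seed = 9)
  expect_identical(fa, fb)
  ra <- simulate_gbs_reads(a$dosage, mean_depth = 3, seed = 5)
  rb <- simulate_gbs_reads(b$dosage, mean_depth = 3, seed = 5)
  expect_identical(ra, rb)
  pa <- simulate_trial(fa, trial_design(n_reps = 2), seed = 3)
  pb <- simulate_trial(fb, trial_design(n_reps = 2), seed = 3)
  expect_identical(pa, pb)
})

test_that("polycross family values obey the quarter-additive-variance relation", {
  pops <- simulate_founders(n_pops = 1, n_per_pop = 500, n_snps = 3000,
                            fst = 0, seed = 11)
  fams <- simulate_polycross(pops, sigma2_A = 41.2, n_pollen = 40, seed = 2)
  expect_equal(nrow(fams), 500)
  # among-family variance ~ sigma2_A / 4 = 10.3
  expect_lt(abs(var(fams$value) - 10.3) / 10.3, 0.15)
})

test_that("polycross excludes selfing and degenerates correctly", {
  x <- matrix(rep(c(0L, 2L, 1L, 1L), each = 10), nrow = 10)
  rownames(x) <- sprintf("M%02d", 1:10)
  pop <- manual_population(x)
  fams <- simulate_polycross(pop, sigma2_A = 5, n_pollen = 3, seed = 1)
  # identical parents: no among-family variance
  expect_equal(var(fams$value), 0)
  pollen <- attr(fams, "pollen")
  for (i in seq_len(nrow(fams)))
    expect_false(fams$mother[i] %in% pollen[[i]])
  # a single-member population cannot be polycrossed
  lone <- manual_population(x, pop = c("A", rep("B", 9)))
  expect_error(simulate_polycross(lone), "polycross")
})

test_that("trial records decompose into the requested effects", {
  # all variances zero: every observation is the grand mean
  ph0 <- simulate_trial(20, trial_design(n_reps = 3, n_harvests = 2),
                        varcomps = list(sigma2_f = 0, sigma2_e = 0),
                        grand_mean = 32.2, seed = 1)
  expect_true(all(abs(ph0$value - 32.2) < 1e-12))
  expect_equal(nrow(ph0), 20 * 3 * 2)

  # layout: each family once per replicate block, grid covers all plots
  suppressMessages(
    ph <- simulate_trial(24, trial_design(n_reps = 3),
                         varcomps = list(sigma2_f = 4, sigma2_e = 9), seed = 2))
  per_rep <- table(ph$family, ph$rep)
  expect_true(all(per_rep == 1))
  expect_false(any(duplicated(ph[c("rep", "row", "col")])))

  # unknown component rejected, missing ones tolerated with a message
  expect_error(simulate_trial(10, varcomps = list(sigma2_bogus = 1)), "unknown")
  expect_message(simulate_trial(10, varcomps = list(sigma2_f = 1)), "treated as 0")
})

test_that("GBS read counts reproduce the requested depth law", {
  x <- hwe_dosages(50, runif(400, 0.2, 0.8), seed = 3)
  # infinite-depth limit: calls equal truth
  deep <- simulate_gbs_reads(x, mean_depth = 1000, seed = 4)
  called <- call_dosages(deep)$dosage
  ok <- !is.na(called)
  expect_gt(mean(called[ok] == x[ok]), 0.999)

  # Poisson depth: empirical mean within 2%, zero-depth mass ~ exp(-3)
  reads <- simulate_gbs_reads(hwe_dosages(100, runif(2000, .2, .8), 5),
                              mean_depth = 3, seed = 6)
  depth <- reads$ref + reads$alt
  expect_lt(abs(mean(depth) - 3) / 3, 0.02)
  expect_lt(abs(mean(depth == 0) - exp(-3)), 0.005)

  # extra dropout reaches a requested missing fraction
  sparse <- simulate_gbs_reads(x, mean_depth = 3, missing_target = 0.5, seed = 7)
  expect_lt(abs(mean(sparse$ref + sparse$alt == 0) - 0.5), 0.02)
  expect_error(simulate_gbs_reads(x, mean_depth = 0), "mean_depth")
})
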