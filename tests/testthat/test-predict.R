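make_instance <- function(n = 50, m = 500, h2 = 0.5, seed = 1) {
  set.seed(seed)
  M <- matrix(rbinom(n * m, 2, rep(runif(m, 0.1, 0.9), each = n)), n, m,
              dimnames = list(sprintf("I%03d", seq_len(n)), NULL))
  b <- rnorm(m, 0, sqrt(h2 / (m * 0.3)))
  g <- drop(scale(M, scale = FALSE) %*% b)
  y <- g + rnorm(n, 0, sd(g) * sqrt((1 - h2) / h2))
  names(y) <- rownames(M)
  list(M = M, y = y, g = g)
}

test_that("an identity GRM transfers no information to unseen individuals", {
  set.seed(2)
  S <- diag(30)
  rownames(S) <- colnames(S) <- sprintf("I%03d", 1:30)
  y <- rnorm(20); names(y) <- rownames(S)[1:20]
  fit <- fit_gblup(y, S)
  expect_equal(unname(predict_gblup(fit, rownames(S)[21:30])), rep(0, 10))
})

test_that("zero phenotypic variance collapses the genetic variance", {
  x <- hwe_dosages(25, runif(400, .2, .8), seed = 3)
  g <- standard_grm(x)
  y <- rep(5, 20); names(y) <- rownames(x)[1:20]
  fit <- fit_gblup(y, g)
  expect_lt(fit$sigma2_u, 1e-6)
  expect_lt(max(abs(predict_gblup(fit, rownames(x)))), 1e-6)
  expect_equal(fit$mu, 5, tolerance = 1e-8)
})

test_that("the symmetric two-train hand example predicts exactly zero", {
  S <- rbind(c(1, 0.5, 0.5), c(0.5, 1, 0.5), c(0.5, 0.5, 1))
  rownames(S) <- colnames(S) <- c("a", "b", "v")
  y <- c(a = 1, b = -1)
  fit <- fit_gblup(y, S)
  expect_lt(abs(predict_gblup(fit, "v")), 1e-10)
  expect_error(predict_gblup(fit, "nope"), "unknown id")
})

test_that("a duplicated training row reproduces the fitted training effect", {
  x <- hwe_dosages(30, runif(600, .2, .8), seed = 4)
  x <- rbind(x, dup = x[1, ])
  inst_y <- rnorm(30, sd = 2); names(inst_y) <- rownames(x)[1:30]
  fit <- fit_gblup(inst_y, standard_grm(x))
  # the duplicate makes the GRM singular, so agreement is bounded by the
  # 1e-6 diagonal stabilisation rather than solver precision
  expect_lt(abs(predict_gblup(fit, "dup") - fit$u_train["I0001"]), 1e-5)
})

test_that("ridge with the GBLUP-equivalent shrinkage reproduces GBLUP exactly", {
  for (s in 1:3) {
    inst <- make_instance(seed = s)
    tr <- rownames(inst$M)[1:40]; te <- rownames(inst$M)[41:50]
    # both routes share the training-frequency reference: the GRM is
    # extended to the candidates with training centring and scaling
    p_tr <- colMeans(inst$M[tr, ]) / 2
    g_ext <- standard_grm(inst$M, allele_freq = p_tr)
    gb <- fit_gblup(inst$y[tr], g_ext, ids = tr)
    rr <- fit_ridge(inst$y[tr], inst$M[tr, ], policy = "reml")
    expect_lt(max(abs(predict_ridge(rr, inst$M[te, ]) -
                        predict_gblup(gb, te))), 1e-6)
  }
})

test_that("extreme shrinkage sends every GEBV to zero", {
  inst <- make_instance(n = 30, m = 100, seed = 5)
  fit <- fit_ridge(inst$y, inst$M, lambda = 1e12, policy = "fixed")
  expect_lt(max(abs(predict_ridge(fit, inst$M))), 1e-4)
})

test_that("unshrunk single-marker ridge is ordinary least squares", {
  set.seed(6)
  M <- matrix(rbinom(40, 2, 0.5), 40, 1, dimnames = list(sprintf("I%02d", 1:40), "s"))
  y <- 0.7 * M[, 1] + rnorm(40, 0, 0.5); names(y) <- rownames(M)
  fit <- fit_ridge(y, M, lambda = 0, policy = "fixed")
  ols <- coef(lm(y ~ I(M[, 1] - mean(M[, 1]))))
  expect_equal(unname(fit$u), unname(ols[2]), tolerance = 1e-10)
  expect_error(fit_ridge(y, M, lambda = -1, policy = "fixed"))
})

test_that("predictions are invariant to SNP order and equivariant in scale", {
  inst <- make_instance(n = 40, m = 200, seed = 7)
  tr <- rownames(inst$M)[1:30]; te <- rownames(inst$M)[31:40]
  perm <- sample(200)
  f1 <- fit_ridge(inst$y[tr], inst$M[tr, ], lambda = 50, policy = "fixed")
  f2 <- fit_ridge(inst$y[tr], inst$M[tr, perm], lambda = 50, policy = "fixed")
  expect_equal(predict_ridge(f1, inst$M[te, ]),
               predict_ridge(f2, inst$M[te, perm]), tolerance = 1e-10)
  # scale equivariance of GBLUP
  g <- standard_grm(inst$M)
  a <- predict_gblup(fit_gblup(inst$y[tr], g, ids = tr), te)
  b <- predict_gblup(fit_gblup(3 * inst$y[tr], g, ids = tr), te)
  expect_equal(3 * a, b, tolerance = 1e-6)
})

test_that("GBLUP predicts positively on heritable simulated family means", {
  hits <- vapply(1:10, function(s) {
    inst <- make_instance(n = 120, m = 400, h2 = 0.5, seed = 40 + s)
    tr <- rownames(inst$M)[1:96]; te <- rownames(inst$M)[97:120]
    fit <- fit_gblup(inst$y[tr], standard_grm(inst$M), ids = tr)
    cor(predict_gblup(fit, te), inst$g[te]) > 0
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("the plug-in adapter honours and polices its contract", {
  inst <- make_instance(n = 30, m = 50, seed = 8)
  # mean predictor: constant output
  mp <- fit_plugin(inst$y, inst$M, mean_plugin())
  expect_equal(unname(predict_plugin(mp, inst$M)), rep(0, 30))
  # a plugin echoing the ridge model matches fit_ridge
  echo <- plugin_regressor(
    fit = function(X, y) fit_ridge(y, X, lambda = 20, policy = "fixed"),
    predict = function(state, X) state$mu + predict_ridge(state, X),
    label = "echo-ridge")
  ef <- fit_plugin(inst$y, inst$M, echo)
  direct <- fit_ridge(inst$y, inst$M, lambda = 20, policy = "fixed")
  expect_equal(predict_plugin(ef, inst$M), predict_ridge(direct, inst$M),
               tolerance = 1e-10)
  # violations surface as adapter errors
  expect_error(plugin_regressor(fit = 1, predict = identity), "contract")
  boom <- plugin_regressor(fit = function(X, y) stop("nope"),
                           predict = function(s, X) 0, label = "boom")
  expect_error(fit_plugin(inst$y, inst$M, boom), "failed during fit")
  short <- plugin_regressor(fit = function(X, y) NULL,
                            predict = function(s, X) 1, label = "short")
  sf <- fit_plugin(inst$y, inst$M, short)
  expect_error(predict_plugin(sf, inst$M), "contract")
})
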