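# Profiled REML for the one-random-effect animal model via a single
# eigendecomposition of the projected GRM (EMMA-style): with
# V = s2u * (G + delta * I), delta = s2e/s2u, the (n - p) rotated
# contrasts give a 1-D likelihood in delta that is optimised on the log
# scale.
.gblup_reml <- function(y, G, X = matrix(1, length(y), 1), tol = 1e-10) {
  n <- length(y)
  p <- ncol(X)
  S <- diag(n) - X %*% solve(crossprod(X), t(X))
  es <- eigen(S %*% G %*% S, symmetric = TRUE)
  keep <- seq_len(n - p)              # the trailing p eigenvalues are the
  xi <- pmax(es$values[keep], 0)      # projection zeros; clamp fp noise
  U <- es$vectors[, keep, drop = FALSE]
  eta2 <- drop(crossprod(U, y))^2
  q <- n - p
  negll <- function(logd) {
    d <- exp(logd)
    r <- sum(eta2 / (xi + d))
    0.5 * (q * log(r) + sum(log(xi + d)))
  }
  # the ratio is profiled on a bounded log grid: below exp(-12) (and above
  # exp(12)) the criterion is flat to machine precision while the linear
  # systems it feeds become numerically singular
  opt <- stats::optimize(negll, c(-12, 12), tol = tol)
  delta <- exp(opt$minimum)
  s2u <- sum(eta2 / (xi + delta)) / q
  list(delta = delta, s2u = s2u, s2e = delta * s2u)
}

#' Fit a GBLUP model
#'
#' The animal model `y = mu + g + e` with `g ~ N(0, s2u * G)` and
#' `e ~ N(0, s2e * I)`, where `G` is a genomic relationship matrix (either
#' the standard frequency-centred one or a depth-adjusted one) restricted
#' to the training individuals. The variance ratio is estimated by REML
#' through one spectral decomposition and a 1-D profiled-likelihood
#' optimisation; training genetic effects are the usual shrunken solutions
#' `G (G + lambda I)^(-1) (y - mu)` with `lambda = s2e / s2u` and `mu` the
#' GLS mean. When the smallest eigenvalue of the training block is below
#' 1e-8 the diagonal is stabilised by adding 1e-6.
#'
#' @param y named numeric vector of training phenotypes (family BLUPs).
#' @param grm a `GRM` (or square matrix) covering at least the training
#'   ids; kept whole so that any individual in it can be predicted.
#' @param ids training ids; default `names(y)`.
#' @return object of class `gblup_fit`: `mu`, `sigma2_u`, `sigma2_e`,
#'   `lambda`, `u_train` (training genetic effects), plus internals used
#'   by [predict_gblup()].
#' @export
fit_gblup <- function(y, grm, ids = names(y)) {
  S <- if (inherits(grm, "GRM")) grm$S else grm
  if (is.null(ids)) stop_invalid("'y' must be named or 'ids' supplied")
  if (!all(ids %in% rownames(S)))
    stop_invalid("training ids absent from GRM: ",
                 paste(utils::head(setdiff(ids, rownames(S)), 5), collapse = ", "))
  y <- as.numeric(y)
  n <- length(y)
  G_tt <- S[ids, ids]
  ev_min <- min(eigen(G_tt, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min < -1e-8) {
    # genuinely non-PSD (e.g. a noisy depth-adjusted matrix): stabilise.
    # PSD-but-singular blocks are left alone -- the shrinkage lambda
    # already regularises them, and perturbing the diagonal would break
    # the exact ridge-GBLUP correspondence.
    G_tt <- G_tt + diag(1e-6, n)
    if (min(eigen(G_tt, symmetric = TRUE, only.values = TRUE)$values) < -1e-4)
      stop_invalid("training GRM block is strongly non-PSD (min eigenvalue ",
                   signif(ev_min, 3), "); check the relatedness input")
  }
  if (stats::var(y) < .Machine$double.eps) {
    fit <- list(delta = exp(12), s2u = 0, s2e = stats::var(y))
  } else {
    fit <- .gblup_reml(y, G_tt)
  }
  delta <- fit$delta
  A <- solve(G_tt + diag(delta, n))
  one <- rep(1, n)
  mu <- drop(crossprod(one, A %*% y) / crossprod(one, A %*% one))
  w <- drop(A %*% (y - mu))                 # (G + lambda I)^(-1) (y - mu)
  u_train <- drop(G_tt %*% w)
  names(u_train) <- ids
  structure(list(method = "gblup", mu = mu, sigma2_u = fit$s2u,
                 sigma2_e = fit$s2e, lambda = delta,
                 u_train = u_train, w = w, ids_train = ids, S = S),
            class = "gblup_fit")
}

#' Predict GEBVs from a fitted GBLUP model
#'
#' Conditional-expectation extension to any individual present in the
#' relationship matrix:
#' `GEBV = G[target, train] (G[train, train] + lambda I)^(-1) (y - mu)`.
#' GEBVs are genetic effects centred on the training mean; add `$mu` for
#' predicted phenotypic scale.
#'
#' @param model a `gblup_fit`.
#' @param target_ids ids to predict (must exist in the GRM used at fit).
#' @return named numeric vector of GEBVs.
#' @export
predict_gblup <- function(model, target_ids) {
  stopifnot(inherits(model, "gblup_fit"))
  missing_ids <- setdiff(target_ids, rownames(model$S))
  if (length(missing_ids))
    stop_invalid("unknown id(s): ", paste(missing_ids, collapse = ", "))
  G_vt <- model$S[target_ids, model$ids_train, drop = FALSE]
  gebv <- drop(G_vt %*% model$w)
  names(gebv) <- target_ids
  gebv
}

#' Fit a ridge-regression marker model
#'
#' `u = (Z'Z + lambda I)^(-1) Z' (y - mu)` on frequency-centred markers
#' `Z = M - 2p` (training allele frequencies). Three shrinkage policies:
#'
#' * `"reml"`: `lambda = 2 sum p q * (s2e / s2u)` taken from a GBLUP fit
#'   on the standard GRM built from the same matrix -- the exact
#'   GBLUP-equivalent value, so predictions reproduce GBLUP.
#' * `"fixed"`: `lambda` supplied by the caller (> 0, or 0 for ordinary
#'   least squares when the system is overdetermined).
#' * `"cv"`: internal k-fold grid search over `lambda`.
#'
#' @param y named numeric training phenotypes.
#' @param M training marker matrix (complete, e.g. mean-imputed dosages),
#'   rows named by individual.
#' @param lambda shrinkage parameter for `policy = "fixed"`.
#' @param policy one of `"reml"`, `"fixed"`, `"cv"`.
#' @param cv_folds,cv_grid internal CV controls for `policy = "cv"`.
#' @param seed seed for the internal CV partition.
#' @return object of class `ridge_fit` with marker effects `u`, `mu`,
#'   `lambda`, and the centring frequencies.
#' @export
fit_ridge <- function(y, M, lambda = NULL,
                      policy = c("reml", "fixed", "cv"),
                      cv_folds = 5, cv_grid = 10^seq(-2, 6, length.out = 25),
                      seed = 1) {
  policy <- match.arg(policy)
  stopifnot(is.matrix(M), nrow(M) == length(y))
  if (anyNA(M)) stop_invalid("marker matrix has missing cells; impute first")
  y <- as.numeric(y)
  ctr <- colMeans(M)                       # = 2 p_j
  Z <- sweep(M, 2, ctr)

  if (policy == "fixed") {
    if (is.null(lambda)) stop_invalid("'lambda' required for policy = 'fixed'")
    check_scalar(lambda, "lambda", 0)
    if (lambda == 0 && nrow(M) <= ncol(M))
      stop_invalid("lambda = 0 needs an overdetermined system")
    mu <- mean(y)
  } else if (policy == "reml") {
    g <- standard_grm(M)
    gf <- fit_gblup(y, g, ids = rownames(M) %||% as.character(seq_len(nrow(M))))
    lambda <- g$denom * gf$lambda
    mu <- gf$mu
  } else {
    folds <- make_folds(length(y), cv_folds, derive_seed(seed, "ridge_cv"))
    press <- vapply(cv_grid, function(l) {
      sum(vapply(seq_len(cv_folds), function(f) {
        tr <- folds != f
        Zt <- Z[tr, , drop = FALSE]
        u <- solve(crossprod(Zt) + diag(l, ncol(Z)),
                   crossprod(Zt, y[tr] - mean(y[tr])))
        sum((y[!tr] - mean(y[tr]) - Z[!tr, , drop = FALSE] %*% u)^2)
      }, numeric(1)))
    }, numeric(1))
    lambda <- cv_grid[which.min(press)]
    mu <- mean(y)
  }
  u <- drop(solve(crossprod(Z) + diag(lambda, ncol(Z)),
                  crossprod(Z, y - mu)))
  structure(list(method = "rr", mu = mu, lambda = lambda, u = u,
                 center = ctr),
            class = "ridge_fit")
}

#' Predict GEBVs from a ridge fit
#'
#' @param model a `ridge_fit`.
#' @param M_new marker matrix for target individuals (same SNPs, same
#'   order as at training). Predictions are invariant to a common
#'   permutation of SNP columns in training and target.
#' @return named numeric vector of GEBVs (centred on training mean).
#' @export
predict_ridge <- function(model, M_new) {
  stopifnot(inherits(model, "ridge_fit"), is.matrix(M_new))
  if (ncol(M_new) != length(model$u))
    stop_invalid("target marker matrix has ", ncol(M_new),
                 " SNPs; model was trained on ", length(model$u))
  gebv <- drop(sweep(M_new, 2, model$center) %*% model$u)
  names(gebv) <- rownames(M_new)
  gebv
}

#' Plug-in regressor adapter
#'
#' Exposes any external regression method to the prediction and
#' cross-validation machinery through a minimal fit/predict contract, so
#' that machine-learning methods (e.g. a random forest with 500 trees and
#' 10% feature sampling) can sit beside GBLUP and ridge without the core
#' package depending on them. `plugin$fit(X, y)` must return a state
#' object; `plugin$predict(state, X)` a numeric vector. Contract
#' violations and plugin failures surface as adapter errors.
#'
#' @param fit function(X, y) -> state.
#' @param predict function(state, X) -> numeric.
#' @param label method label used in reports.
#' @return a `plugin_regressor`.
#' @export
plugin_regressor <- function(fit, predict, label = "plugin") {
  if (!is.function(fit) || !is.function(predict))
    stop_invalid("plugin contract violation: 'fit' and 'predict' must be functions")
  structure(list(fit = fit, predict = predict, label = label),
            class = "plugin_regressor")
}

#' Reference mean-predictor plugin
#'
#' Predicts the training mean for every target: the no-information
#' baseline whose predictive ability is ~0 on any data.
#' @return a `plugin_regressor`.
#' @export
mean_plugin <- function() {
  plugin_regressor(fit = function(X, y) mean(y),
                   predict = function(state, X) rep(state, nrow(X)),
                   label = "mean")
}

#' Fit a plug-in regressor on markers
#'
#' @param y training phenotypes.
#' @param M training marker matrix.
#' @param plugin a [plugin_regressor()].
#' @return object of class `plugin_fit`.
#' @export
fit_plugin <- function(y, M, plugin) {
  stopifnot(inherits(plugin, "plugin_regressor"))
  state <- tryCatch(plugin$fit(M, as.numeric(y)),
                    error = function(e)
                      stop_invalid("plugin '", plugin$label,
                                   "' failed during fit: ", conditionMessage(e)))
  structure(list(method = plugin$label, state = state, plugin = plugin,
                 mu = mean(y)),
            class = "plugin_fit")
}

#' @rdname fit_plugin
#' @param model a `plugin_fit`.
#' @param M_new target marker matrix.
#' @export
predict_plugin <- function(model, M_new) {
  stopifnot(inherits(model, "plugin_fit"))
  out <- tryCatch(model$plugin$predict(model$state, M_new),
                  error = function(e)
                    stop_invalid("plugin '", model$method,
                                 "' failed during predict: ",
                                 conditionMessage(e)))
  if (!is.numeric(out) || length(out) != nrow(M_new))
    stop_invalid("plugin contract violation: predict must return one numeric ",
                 "value per target row")
  gebv <- out - model$mu        # report on the centred GEBV scale
  names(gebv) <- rownames(M_new)
  gebv
}
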