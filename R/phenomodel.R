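# Random-effect terms understood by fit_varcomps, with the variance
# component each one maps onto. rep/row/col are nested within the
# site-treatment environment; interactions with family carry the
# genotype-by-environment components.
.vc_name <- c("family" = "sigma2_f",
              "family:year" = "sigma2_gy",
              "family:harvest" = "sigma2_gh",
              "family:treatment" = "sigma2_gt",
              "family:site" = "sigma2_gl",
              "rep" = "sigma2_rep",
              "row" = "sigma2_row",
              "col" = "sigma2_col")

.term_factor <- function(term, d) {
  f <- switch(term,
    "family" = factor(d$family),
    "rep" = interaction(d$site, d$treatment, d$rep, drop = TRUE),
    "row" = interaction(d$site, d$treatment, d$rep, d$row, drop = TRUE),
    "col" = interaction(d$site, d$treatment, d$rep, d$col, drop = TRUE),
    "family:year" = interaction(d$family, d$year, drop = TRUE),
    "family:harvest" = interaction(d$family, d$harvest, drop = TRUE),
    "family:treatment" = interaction(d$family, d$treatment, drop = TRUE),
    "family:site" = interaction(d$family, d$site, drop = TRUE),
    stop_invalid("unknown random term: ", term))
  if (grepl(":", term)) {
    with_what <- sub("family:", "", term)
    if (length(unique(d[[with_what]])) < 2)
      stop_invalid(sprintf(
        "random term '%s' is not identifiable: '%s' has a single level",
        term, with_what))
  }
  f
}

# -2 * REML log-likelihood (with constant) and EM quantities for given
# variance components, from precomputed crossproducts. C is the
# sigma2_e-scaled mixed-model coefficient matrix.
.reml_eval <- function(s2, s2e, pre) {
  gamma <- s2 / s2e
  C <- pre$C0
  for (k in seq_along(pre$blocks)) {
    idx <- pre$blocks[[k]]
    diag(C)[idx] <- diag(pre$C0)[idx] + 1 / gamma[k]
  }
  R <- chol(C)
  Cinv <- chol2inv(R)
  coef <- drop(Cinv %*% pre$Wty)
  ypy_num <- max(pre$yty - sum(coef * pre$Wty), 0)
  logdetC <- 2 * sum(log(diag(R)))
  np <- pre$n - pre$p
  m2ll <- np * log(s2e) + sum(pre$q * log(gamma)) + logdetC +
    ypy_num / s2e + np * log(2 * pi)
  list(loglik = -0.5 * m2ll, coef = coef, Cinv = Cinv, ypy_num = ypy_num)
}

#' REML variance components and family BLUPs for half-sib trial records
#'
#' Fits a Gaussian linear mixed model with independent random effects by
#' EM-REML: at each iteration the mixed-model equations are solved at the
#' current variance components and the classical EM updates are applied
#' (which keep every component non-negative and never decrease the REML
#' log-likelihood). Iteration stops when the relative log-likelihood
#' change falls below `tol` or after `max_iter` iterations. Standard
#' errors come from the numerically differentiated REML information at the
#' converged estimates; family BLUPs from the mixed-model equations.
#'
#' @param records long-format phenotype data.frame with columns family,
#'   population, site, treatment, rep, row, col, year, harvest, value.
#' @param random character vector of random terms among `"family"`,
#'   `"rep"`, `"row"`, `"col"`, `"family:year"`, `"family:harvest"`,
#'   `"family:treatment"`, `"family:site"`.
#' @param fixed character vector of fixed-effect factors among
#'   `"population"`, `"site"`, `"treatment"`, `"year"`, `"harvest"`
#'   (an intercept is always included).
#' @param tol relative log-likelihood convergence tolerance.
#' @param max_iter maximum EM iterations.
#' @param se compute standard errors (numerical information matrix).
#' @param accelerate after a short EM burn-in, attempt average-information
#'   (quasi-Newton) steps, falling back to the EM update whenever a step
#'   would leave the parameter space or reduce the likelihood.
#' @return object of class `varcomp_fit`: list with `components` (named
#'   vector including `sigma2_e`), `se`, `loglik`, `loglik_trace`,
#'   `converged`, `iterations`, `grand_mean`, `blups` (data.frame family /
#'   blup, the family adjusted means), `u` (all random-effect solutions),
#'   `random`, `fixed`, `n`.
#' @export
fit_varcomps <- function(records, random = "family", fixed = NULL,
                         tol = 1e-8, max_iter = 500, se = TRUE,
                         accelerate = TRUE) {
  stopifnot(is.data.frame(records), "value" %in% names(records))
  if (length(unique(records$family)) < 2)
    stop_invalid("need at least 2 families")
  if (!"family" %in% random)
    stop_invalid("'random' must include the family term")
  d <- records
  y <- d$value
  n <- length(y)

  X <- if (is.null(fixed)) {
    matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  } else {
    stats::model.matrix(
      stats::as.formula(paste("~", paste(fixed, collapse = " + "))),
      data = as.data.frame(lapply(d[fixed], factor)))
  }
  qrX <- qr(X)
  X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
  p <- ncol(X)

  Zs <- lapply(random, function(tm) {
    f <- .term_factor(tm, d)
    stats::model.matrix(~ 0 + f)
  })
  q <- vapply(Zs, ncol, integer(1))
  W <- cbind(X, do.call(cbind, Zs))
  blocks <- split(p + seq_len(sum(q)), rep(seq_along(q), q))
  pre <- list(C0 = crossprod(W), Wty = drop(crossprod(W, y)),
              yty = sum(y^2), n = n, p = p, q = q, blocks = blocks)

  vary <- stats::var(y)
  floor_s2 <- max(vary, 1e-8) * 1e-9
  K <- length(random)
  s2 <- rep(vary / (K + 1), K)
  s2e <- vary / (K + 1)

  ll_trace <- numeric(0)
  ll_prev <- -Inf
  converged <- FALSE
  ev <- NULL
  theta_prev <- c(s2, s2e)
  for (it in seq_len(max_iter)) {
    ev <- .reml_eval(s2, s2e, pre)
    ll_trace <- c(ll_trace, ev$loglik)
    theta <- c(s2, s2e)
    if (is.finite(ll_prev) &&
        abs(ev$loglik - ll_prev) / (abs(ll_prev) + 1) < tol &&
        max(abs(theta - theta_prev) / (theta_prev + floor_s2)) < 1e-7) {
      converged <- TRUE
      break
    }
    ll_prev <- ev$loglik
    theta_prev <- theta

    # EM updates; they are always admissible and never decrease the
    # REML log-likelihood
    s2_em <- vapply(seq_len(K), function(k) {
      idx <- blocks[[k]]
      max((sum(ev$coef[idx]^2) + s2e * sum(diag(ev$Cinv)[idx])) / q[k],
          floor_s2)
    }, numeric(1))
    s2e_em <- max(ev$ypy_num / (n - p), floor_s2)

    accepted <- FALSE
    if (accelerate && it > 2) {
      # REML score from the standard trace identities:
      #   tr(P Z_k Z_k') = (q_k - (s2e/s2_k) tr(Cinv_kk)) / s2_k
      #   y'P Z_k Z_k' P y = u_k'u_k / s2_k^2
      #   s2e tr(P) = n - p - sum_k s2_k tr(P Z_k Z_k')
      u2 <- vapply(seq_len(K), function(k) sum(ev$coef[blocks[[k]]]^2),
                   numeric(1))
      tC <- vapply(seq_len(K), function(k) sum(diag(ev$Cinv)[blocks[[k]]]),
                   numeric(1))
      trPQ <- (q - (s2e / s2) * tC) / s2
      resid <- drop(y - W %*% ev$coef)
      trP <- (n - p - sum(s2 * trPQ)) / s2e
      score <- c(0.5 * (u2 / s2^2 - trPQ),
                 0.5 * (sum(resid^2) / s2e^2 - trP))
      # average-information matrix from the working vectors
      # f_k = Z_k u_k / s2_k, f_e = Py;  AI_ij = f_i' P f_j / 2
      Fm <- vapply(seq_len(K), function(k)
        drop(Zs[[k]] %*% ev$coef[blocks[[k]]]) / s2[k], numeric(n))
      Fm <- cbind(Fm, drop(y - W %*% ev$coef) / s2e)
      PF <- (Fm - W %*% (ev$Cinv %*% crossprod(W, Fm))) / s2e
      AI <- crossprod(Fm, PF) / 2
      step <- try(solve(AI, score), silent = TRUE)
      if (!inherits(step, "try-error")) {
        cand <- c(s2, s2e) + step
        if (all(cand > 0)) {
          ev_cand <- .reml_eval(cand[seq_len(K)], cand[K + 1], pre)
          if (is.finite(ev_cand$loglik) && ev_cand$loglik >= ev$loglik - 1e-10) {
            s2 <- pmax(cand[seq_len(K)], floor_s2)
            s2e <- max(cand[K + 1], floor_s2)
            accepted <- TRUE
          }
        }
      }
    }
    if (!accepted) {
      s2 <- s2_em
      s2e <- s2e_em
    }
  }
  ev <- .reml_eval(s2, s2e, pre)

  comp <- stats::setNames(c(s2, s2e),
                          c(unname(.vc_name[random]), "sigma2_e"))
  comp[comp <= 2 * floor_s2] <- 0

  ses <- rep(NA_real_, K + 1)
  if (se) {
    th0 <- c(s2, s2e)
    f <- function(th) .reml_eval(th[seq_len(K)], th[K + 1], pre)$loglik
    h <- pmax(abs(th0) * 1e-4, 1e-6)
    H <- matrix(NA_real_, K + 1, K + 1)
    for (i in seq_len(K + 1)) for (j in i:(K + 1)) {
      ei <- ej <- rep(0, K + 1); ei[i] <- h[i]; ej[j] <- h[j]
      H[i, j] <- H[j, i] <-
        (f(th0 + ei + ej) - f(th0 + ei - ej) -
           f(th0 - ei + ej) + f(th0 - ei - ej)) / (4 * h[i] * h[j])
    }
    V <- try(solve(-H), silent = TRUE)
    if (!inherits(V, "try-error")) {
      dv <- diag(V)
      ses[dv > 0] <- sqrt(dv[dv > 0])
    }
  }
  names(ses) <- names(comp)

  beta <- ev$coef[seq_len(p)]
  grand_mean <- mean(drop(X %*% beta))
  fam_idx <- blocks[[which(random == "family")]]
  u_f <- ev$coef[fam_idx]
  names(u_f) <- sub("^f", "", colnames(Zs[[which(random == "family")]]))
  u <- lapply(seq_len(K), function(k) {
    uk <- ev$coef[blocks[[k]]]
    names(uk) <- sub("^f", "", colnames(Zs[[k]]))
    uk
  })
  names(u) <- random

  structure(list(components = comp, se = ses, loglik = ev$loglik,
                 loglik_trace = ll_trace, converged = converged,
                 iterations = length(ll_trace), grand_mean = grand_mean,
                 blups = data.frame(family = names(u_f),
                                    blup = grand_mean + u_f,
                                    u = u_f, row.names = NULL,
                                    stringsAsFactors = FALSE),
                 u = u, beta = beta, random = random, fixed = fixed, n = n),
            class = "varcomp_fit")
}

#' @export
print.varcomp_fit <- function(x, ...) {
  cat("EM-REML fit:", x$n, "records,",
      x$iterations, "iterations,",
      if (x$converged) "converged" else "NOT converged", "\n")
  tab <- data.frame(estimate = x$components, se = x$se)
  print(round(tab, 4))
  invisible(x)
}

#' Likelihood-ratio test for one variance component
#'
#' Tests the component dropped between two nested REML fits with the
#' boundary-corrected null distribution: an equal mixture of a point mass
#' at zero and a 1-df chi-square, so `p = 0.5 * P(chisq_1 >= statistic)`
#' for a positive statistic and 1 when the statistic is zero.
#'
#' @param full,reduced `varcomp_fit` objects; `reduced` must drop exactly
#'   one random term of `full`, with the same fixed effects and data size.
#' @return list with `statistic`, `p_value`, `term` (the tested component).
#' @export
lrt_varcomp <- function(full, reduced) {
  stopifnot(inherits(full, "varcomp_fit"), inherits(reduced, "varcomp_fit"))
  dropped <- setdiff(full$random, reduced$random)
  if (length(dropped) != 1L || length(setdiff(reduced$random, full$random)) ||
      !identical(full$fixed, reduced$fixed) || full$n != reduced$n)
    stop_invalid("models are not nested by removal of exactly one random term")
  stat <- max(0, 2 * (full$loglik - reduced$loglik))
  p <- if (stat <= 0) 1 else 0.5 * stats::pchisq(stat, df = 1, lower.tail = FALSE)
  list(statistic = stat, p_value = p, term = unname(.vc_name[dropped]))
}

# shared denominator for the family-mean repeatability and the
# among-family phenotypic variance: sigma2_g + sum_k sigma2_k / n_k +
# sigma2_e / d_e
.family_mean_denom <- function(varcomps, interactions, d_e) {
  vc <- as.list(varcomps)
  if (is.null(vc$sigma2_e)) stop_invalid("'sigma2_e' missing from varcomps")
  g_name <- intersect(c("sigma2_g", "sigma2_f", "sigma2_a"), names(vc))[1]
  if (is.na(g_name)) stop_invalid("among-family component (sigma2_f) missing")
  check_scalar(d_e, "d_e", 1)
  acc <- vc[[g_name]]
  if (length(interactions)) {
    if (is.null(names(interactions)) || any(names(interactions) == ""))
      stop_invalid("'interactions' must be a named vector of divisors")
    miss <- setdiff(names(interactions), names(vc))
    if (length(miss))
      stop_invalid("interaction component(s) absent from varcomps: ",
                   paste(miss, collapse = ", "))
    acc <- acc + sum(unlist(vc[names(interactions)]) / interactions)
  }
  denom <- acc + vc$sigma2_e / d_e
  list(g = vc[[g_name]], denom = denom)
}

#' Family-mean repeatability / narrow-sense heritability
#'
#' `R = sigma2_g / (sigma2_g + sum_k sigma2_k / n_k + sigma2_e / d_e)`:
#' the among-family variance over the variance of a family mean, with each
#' requested genotype-by-environment interaction component divided by its
#' replication count and the residual divided by `d_e`, the product of the
#' relevant replication numbers (replicates x harvests x years ... as
#' dictated by the trial). Which interaction terms enter, and their
#' divisors, are deliberately caller-specified: they depend on the trial
#' structure being summarised. For single-population half-sib analyses the
#' among-family component is one quarter of the additive variance and the
#' same ratio is the family-mean narrow-sense heritability.
#'
#' @param varcomps named list/vector with `sigma2_f` (or `sigma2_g`),
#'   `sigma2_e`, and any interaction components used.
#' @param interactions named numeric vector: names are interaction
#'   component names in `varcomps`, values their divisors (e.g.
#'   `c(sigma2_gy = 2)` for two years).
#' @param d_e divisor for the residual component.
#' @return repeatability in `[0, 1]`.
#' @export
repeatability <- function(varcomps, interactions = numeric(0), d_e) {
  parts <- .family_mean_denom(varcomps, interactions, d_e)
  if (parts$denom <= 0) stop_invalid("zero or negative denominator")
  parts$g / parts$denom
}

#' Hierarchical clustering of family-by-environment BLUP profiles
#'
#' Complete-linkage agglomerative clustering on squared Euclidean
#' distances between family BLUP profiles across environments, with the
#' optimal cluster count chosen by Hartigan's rule: the smallest `k` whose
#' statistic `(W_k / W_(k+1) - 1) * (n - k - 1)` drops to 10 or below,
#' where `W_k` is the total within-cluster sum of squares at `k` clusters.
#'
#' @param blup_matrix complete families x environments numeric matrix.
#' @param max_k largest cluster count examined.
#' @return list with `hclust` (the merge tree), `k_opt`, `W` (within-SS by
#'   k) and `hartigan` (the statistic by k).
#' @export
cluster_families <- function(blup_matrix, max_k = 10) {
  stopifnot(is.matrix(blup_matrix) || is.data.frame(blup_matrix))
  m <- as.matrix(blup_matrix)
  if (anyNA(m)) stop_invalid("BLUP matrix must be complete")
  n <- nrow(m)
  if (n < 2) stop_invalid("need at least 2 families")
  hc <- stats::hclust(stats::dist(m)^2, method = "complete")
  max_k <- min(max_k, n - 1)
  wss <- function(k) {
    cl <- stats::cutree(hc, k)
    sum(vapply(split(seq_len(n), cl), function(i) {
      sum(sweep(m[i, , drop = FALSE], 2,
                colMeans(m[i, , drop = FALSE]))^2)
    }, numeric(1)))
  }
  W <- vapply(seq_len(max_k + 1), wss, numeric(1))
  H <- vapply(seq_len(max_k), function(k) {
    if (W[k] <= .Machine$double.eps) return(0)
    if (W[k + 1] <= .Machine$double.eps) return(Inf)
    (W[k] / W[k + 1] - 1) * (n - k - 1)
  }, numeric(1))
  k_opt <- which(H <= 10)[1]
  if (is.na(k_opt)) k_opt <- max_k + 1
  list(hclust = hc, k_opt = k_opt, W = W[seq_len(max_k)], hartigan = H)
}
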