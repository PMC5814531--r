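#' Pairwise composite LD within scaffolds
#'
#' Computes the composite (Hill-Robertson style) squared correlation
#' `r^2 = cov(x_a, x_b)^2 / (var(x_a) var(x_b))` between dosages of every
#' SNP pair mapping to the same scaffold, over the individuals with
#' non-missing genotypes at both SNPs (whose count is recorded per pair as
#' `n`). Dosages are either hard presence/absence calls or posterior-mean
#' dosages from the binomial read model (`use = "posterior"`), the latter
#' preferred for read-count input because it carries genotype uncertainty
#' into the correlation; the LD filter ruleset keeps only deep SNPs, where
#' the two coincide. Pairs with a monomorphic-in-sample SNP are skipped
#' and counted.
#'
#' @param x a `DosageMatrix` or `ReadCountMatrix`.
#' @param max_pairs cap on the number of pairs; beyond it a seeded random
#'   subsample is taken.
#' @param use `"dosage"` (calls) or `"posterior"` (read-ratio posterior
#'   means; requires read counts).
#' @param min_n minimum complete-case count for a pair to be kept.
#' @param seed seed for the subsampling lottery.
#' @return data.frame of class `LdPairSet` with columns `snp_a`, `snp_b`,
#'   `scaffold`, `d` (bp), `r2`, `n`; skipped-pair count in attribute
#'   `n_skipped`.
#' @export
pairwise_r2 <- function(x, max_pairs = 50000, use = c("dosage", "posterior"),
                        min_n = 2, seed = 1) {
  use <- match.arg(use)
  if (use == "posterior") {
    if (!inherits(x, "ReadCountMatrix"))
      stop_invalid("posterior-mean dosages need read-count input")
    dm <- posterior_mean_dosages(x)
  } else {
    dm <- if (inherits(x, "ReadCountMatrix")) call_dosages(x) else x
  }
  stopifnot(inherits(dm, "DosageMatrix"))
  dos <- dm$dosage
  snps <- dm$snps

  by_scaf <- split(seq_len(nrow(snps)), snps$scaffold)
  pairs <- do.call(rbind, lapply(by_scaf, function(idx) {
    if (length(idx) < 2) return(NULL)
    cmb <- utils::combn(idx, 2)
    cbind(cmb[1, ], cmb[2, ])
  }))
  if (is.null(pairs) || nrow(pairs) == 0)
    stop_invalid("no within-scaffold SNP pairs available")
  if (nrow(pairs) > max_pairs) {
    set.seed(derive_seed(seed, "ldpairs"))
    pairs <- pairs[sample.int(nrow(pairs), max_pairs), , drop = FALSE]
  }

  n_skipped <- 0L
  out <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    a <- pairs[i, 1]; b <- pairs[i, 2]
    xa <- dos[, a]; xb <- dos[, b]
    cc <- !is.na(xa) & !is.na(xb)
    n_cc <- sum(cc)
    if (n_cc < min_n) { n_skipped <- n_skipped + 1L; next }
    va <- stats::var(xa[cc]); vb <- stats::var(xb[cc])
    if (va < .Machine$double.eps || vb < .Machine$double.eps) {
      n_skipped <- n_skipped + 1L; next
    }
    r2 <- stats::cov(xa[cc], xb[cc])^2 / (va * vb)
    out[[i]] <- data.frame(snp_a = snps$snp[a], snp_b = snps$snp[b],
                           scaffold = snps$scaffold[a],
                           d = abs(snps$pos[a] - snps$pos[b]),
                           r2 = r2, n = n_cc, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) stop_invalid("every pair was skipped")
  rownames(res) <- NULL
  attr(res, "n_skipped") <- n_skipped
  class(res) <- c("LdPairSet", "data.frame")
  res
}

#' Fit the LD distance-decay model
#'
#' Nonlinear least squares of `r^2` on distance under
#' `E(r^2) = 1 / (alpha + 4 beta d) + 1/n`, with the per-pair
#' complete-case sample size `n` supplying the sampling-noise floor (for
#' unlinked SNPs `E(r^2)` is approximately `1/n`). Starting values:
#' `alpha0 = 1 / median(r^2 - 1/n)` clipped positive; `beta0` from the
#' contrast of the near- and far-distance halves of the data. Fitting
#' uses bounded Gauss-Newton (`nls`, port algorithm, `alpha > 0`,
#' `beta >= 0`), up to 200 iterations.
#'
#' @param pairs an `LdPairSet` (or data.frame with `d`, `r2`, `n`).
#' @param start optional named list `list(alpha=, beta=)`.
#' @return object of class `LdDecayFit`: `alpha`, `beta`, `se` (named),
#'   the underlying `nls` object, and `curve(d, n_ref)` evaluating the
#'   fitted expectation.
#' @export
fit_decay <- function(pairs, start = NULL) {
  stopifnot(all(c("d", "r2", "n") %in% names(pairs)))
  pairs <- as.data.frame(pairs)
  if (nrow(pairs) < 10 || length(unique(pairs$d)) < 2)
    stop_invalid("need >= 10 pairs spanning >= 2 distinct distances")
  if (is.null(start)) {
    adj <- pairs$r2 - 1 / pairs$n
    a0 <- 1 / max(stats::median(adj), 1e-3)
    half <- pairs$d <= stats::median(pairs$d)
    m1 <- max(mean(adj[half]), 1e-4)
    m2 <- max(mean(adj[!half]), 1e-4)
    d1 <- mean(pairs$d[half]); d2 <- mean(pairs$d[!half])
    b0 <- if (d2 > d1) max((1 / m2 - 1 / m1) / (4 * (d2 - d1)), 0) else 0
    start <- list(alpha = a0, beta = b0)
  }
  fit <- tryCatch(
    stats::nls(r2 ~ 1 / (alpha + 4 * beta * d) + 1 / n, data = pairs,
               start = start, algorithm = "port",
               lower = c(alpha = 1e-9, beta = 0),
               control = stats::nls.control(maxiter = 200, warnOnly = TRUE)),
    error = function(e)
      stop_invalid("decay fit did not converge from start (alpha=",
                   signif(start$alpha, 4), ", beta=", signif(start$beta, 4),
                   "): ", conditionMessage(e)))
  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) stats::setNames(c(NA, NA), names(cf)))
  structure(list(alpha = unname(cf["alpha"]), beta = unname(cf["beta"]),
                 se = se, nls = fit,
                 curve = function(d, n_ref)
                   1 / (cf["alpha"] + 4 * cf["beta"] * d) + 1 / n_ref),
            class = "LdDecayFit")
}

#' @export
print.LdDecayFit <- function(x, ...) {
  cat(sprintf("LD decay fit: alpha = %.4g (SE %.3g), beta = %.4g (SE %.3g)\n",
              x$alpha, x$se[1], x$beta, x$se[2]))
  invisible(x)
}

#' Distance at which expected LD drops to a threshold
#'
#' Closed-form inversion of the decay model at a reference sample size:
#' `d = (1 / (threshold - 1/n_ref) - alpha) / (4 beta)`, clamped at 0
#' when the curve starts below the threshold; `Inf` when `beta = 0`
#' (no decay).
#'
#' @param fit an `LdDecayFit`.
#' @param threshold target `r^2`, in `(1/n_ref, 1 + 1/n_ref)`.
#' @param n_ref reference sample size anchoring the `1/n` noise floor.
#' @return distance in base pairs (possibly `Inf`).
#' @export
distance_at_r2 <- function(fit, threshold = 0.25, n_ref) {
  stopifnot(inherits(fit, "LdDecayFit"))
  n_ref <- check_count(n_ref, "n_ref")
  check_scalar(threshold, "threshold", 1 / n_ref, 1 + 1 / n_ref,
               open_lower = TRUE, open_upper = TRUE)
  if (fit$beta <= 0) return(Inf)
  max((1 / (threshold - 1 / n_ref) - fit$alpha) / (4 * fit$beta), 0)
}
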