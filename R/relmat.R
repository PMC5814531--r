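new_grm <- function(S, method, denom, ids, n_snps) {
  dimnames(S) <- list(ids, ids)
  structure(list(S = S, method = method, denom = denom, ids = ids,
                 n_snps = n_snps), class = "GRM")
}

#' @export
print.GRM <- function(x, ...) {
  cat(sprintf("GRM (%s): %d individuals, %d SNPs, mean diagonal %.3f\n",
              x$method, length(x$ids), x$n_snps,
              mean(diag(x$S), na.rm = TRUE)))
  invisible(x)
}

#' Standard (VanRaden) genomic relationship matrix
#'
#' `G = Z Z' / (2 * sum_j p_j (1 - p_j))` where `Z` has elements
#' `m_ij - 2 p_j`, the dosages centred at twice the allele frequency
#' computed from the data. Requires a complete matrix, normally the
#' mean-imputed training dosages: frequency centring makes the result
#' invariant to which allele is counted, and mean imputation contributes
#' exactly zero to `Z`. For a non-inbred Hardy-Weinberg population the
#' expected diagonal is 1.
#'
#' @param dosages complete `DosageMatrix` or plain matrix (no `NA`s).
#' @param allele_freq optional vector of reference alternate-allele
#'   frequencies used for centring and scaling instead of the frequencies
#'   of `dosages` itself -- e.g. training-set frequencies when extending a
#'   training GRM to selection candidates, so that the training block is
#'   unchanged by the extension.
#' @return a `GRM` with `method = "standard"`; `$denom` holds the scaling
#'   constant `2 sum p q`.
#' @export
standard_grm <- function(dosages, allele_freq = NULL) {
  M <- if (inherits(dosages, "DosageMatrix")) dosages$dosage else dosages
  stopifnot(is.matrix(M))
  if (anyNA(M)) stop_invalid("dosage matrix has missing cells; impute first")
  if (ncol(M) < 2) stop_invalid("need >= 2 SNPs")
  p <- if (is.null(allele_freq)) colMeans(M) / 2 else allele_freq
  stopifnot(length(p) == ncol(M))
  if (any(p <= 0 | p >= 1))
    stop_invalid("monomorphic SNP(s) present (p = 0 or 1); filter them first")
  Z <- sweep(M, 2, 2 * p)
  denom <- 2 * sum(p * (1 - p))
  new_grm(tcrossprod(Z) / denom, "standard", denom,
          ids = rownames(M) %||% sprintf("I%04d", seq_len(nrow(M))),
          n_snps = ncol(M))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Depth-adjusted (KGD-style) genomic relationship matrix
#'
#' Computes relatedness directly from GBS read counts, correcting the bias
#' that low read depth induces in genotype-call-based estimators.
#' Read-ratio dosages `x = 2 * alt / depth` are unbiased for the true
#' dosage, and reads of distinct individuals are independent, so
#' off-diagonals are estimated from the centred read-ratio products over
#' SNPs observed in both individuals, each pair normalised by
#' `2 sum p q` over exactly those SNPs. Self-relatedness needs depth >= 2:
#' the squared centred read ratio is inflated by binomial sampling, and the
#' per-SNP correction `(x - 2p)^2 - x (2 - x) / (d - 1)` removes that
#' inflation exactly in expectation. Allele frequencies are estimated from
#' the pooled read-ratio dosages.
#'
#' @param reads a `ReadCountMatrix`.
#' @param min_diag_depth minimum depth for a SNP to enter the diagonal
#'   (>= 2; the variance correction is undefined at depth 1).
#' @param allele_freq optional vector of known alternate-allele
#'   frequencies (one per SNP). By default frequencies are estimated from
#'   the pooled read-ratio dosages; supplying reference frequencies
#'   removes the finite-sample centring shift that sample-estimated
#'   frequencies induce (relatedness is then measured against the
#'   reference population rather than the sample mean).
#' @return a `GRM` with `method = "kgd"`. Entries with no usable SNP are
#'   `NA`.
#' @export
kgd_grm <- function(reads, min_diag_depth = 2, allele_freq = NULL) {
  stopifnot(inherits(reads, "ReadCountMatrix"))
  min_diag_depth <- check_count(min_diag_depth, "min_diag_depth", min = 2L)
  depth <- reads$ref + reads$alt
  obs <- depth > 0
  x <- matrix(NA_real_, nrow(depth), ncol(depth), dimnames = dimnames(depth))
  x[obs] <- 2 * reads$alt[obs] / depth[obs]

  if (is.null(allele_freq)) {
    p <- colMeans(x, na.rm = TRUE) / 2
  } else {
    stopifnot(length(allele_freq) == ncol(depth))
    p <- allele_freq
  }
  poly <- p > 0 & p < 1
  if (!any(poly)) stop_invalid("no polymorphic SNPs with data")
  x <- x[, poly, drop = FALSE]
  depth <- depth[, poly, drop = FALSE]
  obs <- obs[, poly, drop = FALSE]
  p <- p[poly]
  w <- 2 * p * (1 - p)

  # off-diagonals: numer = sum_j z_ij z_kj over shared SNPs, denom = sum w_j
  z <- sweep(x, 2, 2 * p)
  z0 <- z; z0[!obs] <- 0
  numer <- tcrossprod(z0)
  denom <- tcrossprod(sweep(obs * 1, 2, w, `*`), obs * 1)
  S <- numer / denom
  S[denom <= 0] <- NA_real_

  # diagonals: depth >= min_diag_depth, binomial sampling variance removed
  deep <- depth >= min_diag_depth
  corr <- matrix(0, nrow(z), ncol(z))
  corr[deep] <- x[deep] * (2 - x[deep]) / (depth[deep] - 1)
  zd <- z^2 - corr
  zd[!deep] <- 0
  diag_num <- rowSums(zd)
  diag_den <- drop((deep * 1) %*% w)
  dg <- diag_num / diag_den
  dg[diag_den <= 0] <- NA_real_
  diag(S) <- dg

  new_grm(S, "kgd", denom = NULL, ids = reads$ids, n_snps = sum(poly))
}

#' Classical MDS ordination of a relationship matrix
#'
#' Applies classical (metric) multidimensional scaling to the distance
#' matrix `1 - S`: double-centring of `-D^2 / 2` followed by
#' eigendecomposition, with axes ordered by decreasing eigenvalue.
#' Replicated control samples (identical genotypes) land at near-identical
#' coordinates, which is the standard visual QC for GBS libraries.
#'
#' @param grm a `GRM` or square symmetric matrix.
#' @param dims number of axes to return.
#' @return an `MdsResult`: list with `coords` (individuals x dims),
#'   `eig` (all eigenvalues) and `prop` (proportion of positive dispersion
#'   per returned axis).
#' @export
grm_mds <- function(grm, dims = 2) {
  S <- if (inherits(grm, "GRM")) grm$S else grm
  if (!is.matrix(S) || nrow(S) != ncol(S))
    stop_invalid("'grm' must be a square matrix")
  dims <- check_count(dims, "dims")
  D <- 1 - S
  D <- (D + t(D)) / 2
  diag(D) <- 0
  D[D < 0] <- 0
  fit <- stats::cmdscale(stats::as.dist(D), k = dims, eig = TRUE)
  coords <- fit$points
  rownames(coords) <- rownames(S)
  pos <- sum(pmax(fit$eig, 0))
  structure(list(coords = coords, eig = fit$eig,
                 prop = pmax(fit$eig[seq_len(dims)], 0) / pos),
            class = "MdsResult")
}
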