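#' Construct a GBS read-count matrix
#'
#' The GBS observation layer: per individual x SNP reference and alternate
#' read counts. Depth (`ref + alt`) of zero is the only representation of a
#' missing genotype observation.
#'
#' @param ref,alt non-negative integer matrices of identical dimension.
#' @param ids individual identifiers (unique); defaults to rownames.
#' @param snps data.frame describing the SNPs (columns `snp`, `scaffold`,
#'   `pos`, `ref`, `alt`); a minimal one is synthesised when `NULL`.
#' @return object of class `ReadCountMatrix`.
#' @export
read_count_matrix <- function(ref, alt, ids = rownames(ref), snps = NULL) {
  stopifnot(is.matrix(ref), is.matrix(alt), all(dim(ref) == dim(alt)))
  if (any(ref < 0) || any(alt < 0)) stop_invalid("read counts must be >= 0")
  if (is.null(ids)) ids <- sprintf("I%04d", seq_len(nrow(ref)))
  if (anyDuplicated(ids)) stop_invalid("individual ids must be unique")
  if (is.null(snps)) {
    snp_names <- colnames(ref)
    if (is.null(snp_names)) snp_names <- sprintf("S1_%d", seq_len(ncol(ref)) * 100L)
    snps <- data.frame(snp = snp_names, scaffold = "scaffold_1",
                       pos = seq_len(ncol(ref)) * 100L,
                       ref = "A", alt = "C", stringsAsFactors = FALSE)
  }
  stopifnot(nrow(snps) == ncol(ref))
  dimnames(ref) <- dimnames(alt) <- list(ids, snps$snp)
  structure(list(ref = ref, alt = alt, ids = ids, snps = snps),
            class = "ReadCountMatrix")
}

#' @export
print.ReadCountMatrix <- function(x, ...) {
  cat(sprintf("ReadCountMatrix: %d individuals x %d SNPs, mean depth %.2f, %.1f%% depth-0 cells\n",
              length(x$ids), nrow(x$snps), mean(x$ref + x$alt),
              100 * mean(x$ref + x$alt == 0)))
  invisible(x)
}

#' Call allele dosages from read counts
#'
#' Presence/absence calling appropriate for low-depth GBS: depth 0 is
#' missing; only reference reads gives dosage 0; only alternate reads gives
#' dosage 2; both alleles observed gives the heterozygote dosage 1. Dosage
#' counts the alternate allele. At depth 2 a true heterozygote is called
#' homozygous with probability 0.5 (both reads drawn from one allele).
#'
#' @param reads a `ReadCountMatrix`.
#' @return a `DosageMatrix`: list with `dosage` (matrix in `{0,1,2}` with
#'   `NA` for missing), `ids`, `snps`, allele-frequency vector `p` (from the
#'   data, alternate allele), and `counted = "alt"`.
#' @export
call_dosages <- function(reads) {
  stopifnot(inherits(reads, "ReadCountMatrix"))
  depth <- reads$ref + reads$alt
  d <- matrix(NA_real_, nrow(depth), ncol(depth), dimnames = dimnames(depth))
  d[depth > 0] <- 1
  d[reads$alt == 0 & depth > 0] <- 0
  d[reads$ref == 0 & depth > 0] <- 2
  dosage_matrix(d, ids = reads$ids, snps = reads$snps)
}

#' Construct a dosage matrix
#'
#' @param dosage individuals x SNPs numeric matrix in `[0, 2]`, `NA` for
#'   missing.
#' @param ids,snps as in [read_count_matrix()].
#' @return object of class `DosageMatrix`.
#' @export
dosage_matrix <- function(dosage, ids = rownames(dosage), snps = NULL) {
  stopifnot(is.matrix(dosage))
  rng <- range(dosage, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 2) stop_invalid("dosages must lie in [0, 2]")
  if (is.null(ids)) ids <- sprintf("I%04d", seq_len(nrow(dosage)))
  if (is.null(snps)) {
    snp_names <- colnames(dosage)
    if (is.null(snp_names)) snp_names <- sprintf("S1_%d", seq_len(ncol(dosage)) * 100L)
    snps <- data.frame(snp = snp_names, scaffold = "scaffold_1",
                       pos = seq_len(ncol(dosage)) * 100L,
                       ref = "A", alt = "C", stringsAsFactors = FALSE)
  }
  dimnames(dosage) <- list(ids, snps$snp)
  p <- colMeans(dosage, na.rm = TRUE) / 2
  structure(list(dosage = dosage, ids = ids, snps = snps, p = p,
                 counted = "alt"),
            class = "DosageMatrix")
}

#' @export
print.DosageMatrix <- function(x, ...) {
  cat(sprintf("DosageMatrix: %d individuals x %d SNPs, %.1f%% missing\n",
              length(x$ids), nrow(x$snps), 100 * mean(is.na(x$dosage))))
  invisible(x)
}

#' Per-SNP summary statistics
#'
#' Computes, per SNP: missing-call rate; minor allele frequency
#' `MAF = min(p, 1 - p)` with `p` the mean non-missing dosage over 2; mean
#' read depth over all cells including depth-0 cells (`NA` when called from
#' dosages alone); and the Hardy-Weinberg disequilibrium estimate
#' `D = P(hom alt) - p^2` from the non-missing calls. Positive `D` marks a
#' heterozygote deficit, negative `D` a heterozygote excess. All-missing
#' SNPs get `NA` statistics and automatically fail every filter.
#'
#' @param x a `ReadCountMatrix` or `DosageMatrix`.
#' @return data.frame of class `SnpStats` with columns `snp`, `missing`,
#'   `maf`, `mean_depth`, `hwdiseq`.
#' @export
snp_stats <- function(x) {
  if (inherits(x, "ReadCountMatrix")) {
    depth <- colMeans(x$ref + x$alt)
    dos <- call_dosages(x)$dosage
    snps <- x$snps
  } else if (inherits(x, "DosageMatrix")) {
    depth <- rep(NA_real_, ncol(x$dosage))
    dos <- x$dosage
    snps <- x$snps
  } else stop_invalid("'x' must be a ReadCountMatrix or DosageMatrix")
  if (nrow(dos) < 1) stop_invalid("need at least one individual")
  n_obs <- colSums(!is.na(dos))
  p <- ifelse(n_obs > 0, colMeans(dos, na.rm = TRUE) / 2, NA_real_)
  hom_alt <- ifelse(n_obs > 0, colMeans(dos == 2, na.rm = TRUE), NA_real_)
  out <- data.frame(snp = snps$snp,
                    missing = 1 - n_obs / nrow(dos),
                    maf = pmin(p, 1 - p),
                    mean_depth = depth,
                    hwdiseq = hom_alt - p^2,
                    stringsAsFactors = FALSE)
  class(out) <- c("SnpStats", "data.frame")
  out
}

#' Apply a SNP filter ruleset
#'
#' Two named rulesets reflect the two stages of a GBS training analysis,
#' plus a fully caller-specified one. All rules are conjunctive, so the
#' order of application is irrelevant and filtering is idempotent.
#'
#' * `training`: retain a SNP iff missing <= `max_missing` (0.50), MAF >
#'   `min_maf` (0.05), mean depth > `min_depth` (1) and HW disequilibrium >
#'   `hwdiseq_min` (-0.05).
#' * `ld`: remove a SNP iff MAF < 0.05, or missing >= 0.25, or mean depth
#'   <= 20, or HW disequilibrium < -0.05 or < -0.8 * MAF^2. The stringent
#'   depth rule restricts LD estimation to deeply genotyped SNPs.
#' * `custom`: thresholds taken from the arguments, interpreted as in
#'   `training`.
#'
#' @param stats a `SnpStats` data.frame.
#' @param ruleset one of `"training"`, `"ld"`, `"custom"`.
#' @param max_missing,min_maf,min_depth,hwdiseq_min thresholds for
#'   `custom` (defaults are the training values).
#' @return integer vector of retained SNP indices, with the per-rule
#'   verdicts attached as attribute `report` (a data.frame).
#' @export
filter_snps <- function(stats, ruleset = c("training", "ld", "custom"),
                        max_missing = 0.5, min_maf = 0.05, min_depth = 1,
                        hwdiseq_min = -0.05) {
  stopifnot(inherits(stats, "data.frame"))
  ruleset <- match.arg(ruleset)
  miss <- stats$missing; maf <- stats$maf
  dp <- stats$mean_depth; D <- stats$hwdiseq
  ok <- function(x) !is.na(x) & x   # NA statistic fails the rule
  if (ruleset == "ld") {
    report <- data.frame(
      snp = stats$snp,
      pass_maf = ok(maf >= 0.05),
      pass_missing = ok(miss < 0.25),
      pass_depth = ok(dp > 20),
      pass_hwdiseq = ok(D >= -0.05 & D >= -0.8 * maf^2))
  } else {
    if (ruleset == "training") {
      max_missing <- 0.5; min_maf <- 0.05; min_depth <- 1; hwdiseq_min <- -0.05
    }
    report <- data.frame(
      snp = stats$snp,
      pass_maf = ok(maf > min_maf),
      pass_missing = ok(miss <= max_missing),
      pass_depth = if (all(is.na(dp))) TRUE else ok(dp > min_depth),
      pass_hwdiseq = ok(D > hwdiseq_min))
  }
  report$retained <- report$pass_maf & report$pass_missing &
    report$pass_depth & report$pass_hwdiseq
  idx <- which(report$retained)
  attr(idx, "report") <- report
  idx
}

#' Mean imputation (MNI) of missing dosages
#'
#' Replaces each missing cell by the mean non-missing dosage of its SNP,
#' the simplest of the standard marker-imputation strategies and the one a
#' frequency-centred relationship matrix is insensitive to (column means
#' are invariant under it). Non-missing cells are unchanged.
#'
#' @param dosages a `DosageMatrix` (or plain matrix with `NA`s).
#' @return a complete `DosageMatrix`.
#' @export
mean_impute <- function(dosages) {
  d <- if (inherits(dosages, "DosageMatrix")) dosages$dosage else dosages
  stopifnot(is.matrix(d))
  n_obs <- colSums(!is.na(d))
  if (any(n_obs == 0))
    stop_invalid("all-missing SNP(s) cannot be mean-imputed; filter them first: ",
                 paste(utils::head(which(n_obs == 0), 5), collapse = ", "))
  mu <- colMeans(d, na.rm = TRUE)
  idx <- which(is.na(d), arr.ind = TRUE)
  if (nrow(idx)) d[idx] <- mu[idx[, 2]]
  if (inherits(dosages, "DosageMatrix")) {
    dosage_matrix(d, ids = dosages$ids, snps = dosages$snps)
  } else d
}

#' Subset a read-count or dosage matrix by SNP index
#'
#' @param x a `ReadCountMatrix` or `DosageMatrix`.
#' @param snp_idx integer vector of SNP columns to keep.
#' @return object of the same class restricted to those SNPs.
#' @export
subset_snps <- function(x, snp_idx) {
  if (inherits(x, "ReadCountMatrix")) {
    read_count_matrix(x$ref[, snp_idx, drop = FALSE],
                      x$alt[, snp_idx, drop = FALSE],
                      ids = x$ids, snps = x$snps[snp_idx, , drop = FALSE])
  } else if (inherits(x, "DosageMatrix")) {
    dosage_matrix(x$dosage[, snp_idx, drop = FALSE],
                  ids = x$ids, snps = x$snps[snp_idx, , drop = FALSE])
  } else stop_invalid("'x' must be a ReadCountMatrix or DosageMatrix")
}

#' Posterior-mean dosages from read counts
#'
#' Under the binomial read model with a uniform prior over the three
#' genotypes, the posterior mean alternate-allele dosage given `a`
#' alternate and `r` reference reads is
#' `(0.5^d + 2 * I(r = 0)) / (I(a = 0) + 0.5^d + I(r = 0))` with
#' `d = a + r`; depth 0 stays missing. Used where hard presence/absence
#' calls would overstate certainty, e.g. LD estimation.
#'
#' @param reads a `ReadCountMatrix`.
#' @return a `DosageMatrix` of posterior-mean dosages in `[0, 2]`.
#' @export
posterior_mean_dosages <- function(reads) {
  stopifnot(inherits(reads, "ReadCountMatrix"))
  d <- reads$ref + reads$alt
  lik_het <- 0.5^d
  lik0 <- (reads$alt == 0) * 1
  lik2 <- (reads$ref == 0) * 1
  post <- (lik_het + 2 * lik2) / (lik0 + lik_het + lik2)
  post[d == 0] <- NA_real_
  dosage_matrix(post, ids = reads$ids, snps = reads$snps)
}
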