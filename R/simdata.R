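#' Simulate divergent outbred founder populations
#'
#' Draws per-population allele frequencies around shared ancestral
#' frequencies under a Balding-Nichols model (a single Fst shared by all
#' populations) and samples founder dosages under within-population
#' Hardy-Weinberg equilibrium. The default sizes emulate a multi-population
#' forage-breeding training set: five populations of roughly 102-117
#' maternal parents each.
#'
#' @param n_pops number of populations.
#' @param n_per_pop individuals per population; scalar or vector of length
#'   `n_pops`.
#' @param n_snps number of biallelic SNPs.
#' @param n_scaffolds number of scaffolds the SNPs are spread over.
#' @param fst divergence among populations, in `[0, 1)`. `fst = 0` gives all
#'   populations identical expected allele frequencies.
#' @param maf_floor lower bound on the ancestral minor allele frequency,
#'   in (0, 0.5).
#' @param seed integer seed; fixing it fixes every emitted value.
#'
#' @return an object of class `PopulationSet`: a list with `ids`, `pop`
#'   (factor of population labels), `freq` (populations x SNPs allele
#'   frequency matrix for the alternate allele), `anc_freq`, `dosage`
#'   (individuals x SNPs matrix of true alternate-allele dosages in
#'   `{0,1,2}`) and `snps` (data.frame with scaffold, pos, ref, alt).
#' @export
simulate_founders <- function(n_pops = 5, n_per_pop = c(110, 102, 117, 113, 108),
                              n_snps = 5000, n_scaffolds = 20,
                              fst = 0.1, maf_floor = 0.05, seed = 1) {
  n_pops <- check_count(n_pops, "n_pops")
  n_snps <- check_count(n_snps, "n_snps")
  n_scaffolds <- check_count(n_scaffolds, "n_scaffolds")
  check_scalar(fst, "fst", 0, 1, open_upper = TRUE)
  check_scalar(maf_floor, "maf_floor", 0, 0.5, open_lower = TRUE, open_upper = TRUE)
  if (length(n_per_pop) == 1L) n_per_pop <- rep(n_per_pop, n_pops)
  if (length(n_per_pop) != n_pops)
    stop_invalid("'n_per_pop' must have length 1 or n_pops")
  n_per_pop <- check_count(n_per_pop, "n_per_pop")

  set.seed(derive_seed(seed, "founders"))
  anc <- stats::runif(n_snps, maf_floor, 1 - maf_floor)
  if (fst == 0) {
    freq <- matrix(rep(anc, each = n_pops), nrow = n_pops)
  } else {
    theta <- (1 - fst) / fst
    freq <- matrix(stats::rbeta(n_pops * n_snps,
                                shape1 = rep(anc, each = n_pops) * theta,
                                shape2 = rep(1 - anc, each = n_pops) * theta),
                   nrow = n_pops)
  }

  n_total <- sum(n_per_pop)
  pop <- factor(rep(paste0("Pop", seq_len(n_pops)), n_per_pop))
  dosage <- matrix(0L, n_total, n_snps)
  row0 <- 0L
  for (k in seq_len(n_pops)) {
    nk <- n_per_pop[k]
    dosage[row0 + seq_len(nk), ] <- matrix(
      stats::rbinom(nk * n_snps, 2L, rep(freq[k, ], each = nk)), nk, n_snps)
    row0 <- row0 + nk
  }
  ids <- sprintf("I%04d", seq_len(n_total))
  rownames(dosage) <- ids

  scaf <- sort(rep_len(seq_len(n_scaffolds), n_snps))
  pos <- unlist(lapply(split(seq_len(n_snps), scaf), function(i)
    cumsum(sample(50:3000, length(i), replace = TRUE))), use.names = FALSE)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n_snps, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), character(1))
  snps <- data.frame(snp = sprintf("S%d_%d", scaf, pos),
                     scaffold = paste0("scaffold_", scaf), pos = pos,
                     ref = ref, alt = alt, stringsAsFactors = FALSE)
  colnames(dosage) <- snps$snp

  structure(list(ids = ids, pop = pop, freq = freq, anc_freq = anc,
                 dosage = dosage, snps = snps,
                 fst = fst, seed = seed),
            class = "PopulationSet")
}

#' Simulate a polycross and derive half-sib family genetic values
#'
#' Every individual in the founder set acts as a maternal parent of one
#' half-sib family. SNP effects are drawn so that the expected
#' within-population additive variance equals `sigma2_A`; each parent's
#' breeding value is the sum of its centred dosages weighted by those
#' effects. A family's genetic value is half the maternal breeding value
#' plus half the mean breeding value of `n_pollen` pollen parents sampled
#' uniformly without replacement from the same population, selfing
#' excluded (obligate outcrossing). As the pollen pool grows the
#' among-family genetic variance converges to one quarter of the additive
#' variance.
#'
#' @param pops a `PopulationSet`.
#' @param sigma2_A target within-population additive genetic variance
#'   (trait units squared).
#' @param n_pollen pollen parents contributing to each family.
#' @param seed integer seed.
#'
#' @return an object of class `FamilySet`: data.frame with `family`,
#'   `mother`, `population` and `value` (true family genetic value,
#'   centred), with attributes `mother_bv` (parent breeding values),
#'   `pollen` (list of pollen-parent ids per family), `beta` (SNP effects)
#'   and `sigma2_A`.
#' @export
simulate_polycross <- function(pops, sigma2_A = 41.2, n_pollen = 20, seed = 1) {
  stopifnot(inherits(pops, "PopulationSet"))
  check_scalar(sigma2_A, "sigma2_A", 0)
  n_pollen <- check_count(n_pollen, "n_pollen")
  sizes <- table(pops$pop)
  if (any(sizes < 2))
    stop_invalid("cannot polycross: population(s) with fewer than 2 members: ",
                 paste(names(sizes)[sizes < 2], collapse = ", "))

  set.seed(derive_seed(seed, "polycross"))
  m <- ncol(pops$dosage)
  # expected heterozygosity within populations sets the effect-size scale
  het <- mean(rowSums(2 * pops$freq * (1 - pops$freq)))
  scale2 <- if (het > 0) sigma2_A / het else 0
  beta <- stats::rnorm(m, 0, sqrt(scale2))
  p_bar <- colMeans(pops$dosage) / 2
  bv <- drop((pops$dosage - matrix(2 * p_bar, nrow(pops$dosage), m, byrow = TRUE)) %*% beta)
  names(bv) <- pops$ids

  n <- length(pops$ids)
  pollen <- vector("list", n)
  value <- numeric(n)
  for (i in seq_len(n)) {
    mates <- pops$ids[pops$pop == pops$pop[i] & pops$ids != pops$ids[i]]
    take <- min(n_pollen, length(mates))
    pollen[[i]] <- sample(mates, take)
    value[i] <- 0.5 * bv[i] + 0.5 * mean(bv[pollen[[i]]])
  }

  fam <- data.frame(family = sprintf("F%04d", seq_len(n)),
                    mother = pops$ids,
                    population = as.character(pops$pop),
                    value = value, stringsAsFactors = FALSE)
  structure(fam, mother_bv = bv, pollen = pollen, beta = beta,
            sigma2_A = sigma2_A, class = c("FamilySet", "data.frame"))
}

#' Describe a row-column half-sib family trial
#'
#' @param n_reps replicates per trial (each family appears once per
#'   replicate).
#' @param n_years years of evaluation.
#' @param n_harvests total number of harvests, spread as evenly as possible
#'   across the years.
#' @param sites character vector of site labels.
#' @param treatments character vector of management-treatment labels.
#' @param n_cols columns per replicate block; rows are derived so the
#'   row-column grid covers all families. `NULL` gives a near-square block.
#' @return a `TrialDesign` list.
#' @export
trial_design <- function(n_reps = 3, n_years = 1, n_harvests = 1,
                         sites = "Site1", treatments = "STD", n_cols = NULL) {
  n_reps <- check_count(n_reps, "n_reps")
  n_years <- check_count(n_years, "n_years")
  n_harvests <- check_count(n_harvests, "n_harvests")
  stopifnot(length(sites) >= 1, length(treatments) >= 1)
  structure(list(n_reps = n_reps, n_years = n_years, n_harvests = n_harvests,
                 sites = as.character(sites),
                 treatments = as.character(treatments), n_cols = n_cols),
            class = "TrialDesign")
}

#' Simulate long-format phenotype records from a family trial
#'
#' Each plot-harvest observation is the grand mean plus the family genetic
#' value and Gaussian family-by-year, family-by-harvest, family-by-treatment,
#' family-by-site, replicate, row, column and residual effects with the
#' requested variances. Families are laid out on a fresh randomised
#' row-column grid within every replicate. Missing variance components are
#' treated as zero (with a notice).
#'
#' @param families a `FamilySet`, or an integer number of families. When an
#'   integer is given (or `use_family_values = FALSE`) family genetic values
#'   are drawn as N(0, `sigma2_f`), the family-level variance; a `FamilySet`
#'   contributes its true polycross values instead.
#' @param design a `TrialDesign`.
#' @param varcomps named list of variance components (trait units squared):
#'   `sigma2_f`, `sigma2_gy`, `sigma2_gh`, `sigma2_gt`, `sigma2_gl`,
#'   `sigma2_rep`, `sigma2_row`, `sigma2_col`, `sigma2_e`. Missing entries
#'   default to 0.
#' @param grand_mean trial grand mean (trait units, e.g. g DM per plot).
#' @param seed integer seed.
#' @param use_family_values use the `FamilySet` values as family effects
#'   (default TRUE when a `FamilySet` is supplied).
#'
#' @return a long-format data.frame with columns family, population, site,
#'   treatment, rep, row, col, year, harvest, value; the true simulated
#'   effects are attached as attribute `truth`.
#' @export
simulate_trial <- function(families, design = trial_design(),
                           varcomps = list(sigma2_f = 10.3, sigma2_e = 66.1),
                           grand_mean = 32.2, seed = 1,
                           use_family_values = inherits(families, "FamilySet")) {
  stopifnot(inherits(design, "TrialDesign"))
  known <- c("sigma2_f", "sigma2_gy", "sigma2_gh", "sigma2_gt", "sigma2_gl",
             "sigma2_rep", "sigma2_row", "sigma2_col", "sigma2_e")
  bad <- setdiff(names(varcomps), known)
  if (length(bad)) stop_invalid("unknown variance component(s): ",
                                paste(bad, collapse = ", "))
  missing_vc <- setdiff(known, names(varcomps))
  if (length(missing_vc))
    message("variance component(s) treated as 0: ",
            paste(missing_vc, collapse = ", "))
  vc <- stats::setNames(as.list(rep(0, length(known))), known)
  vc[names(varcomps)] <- varcomps
  if (any(unlist(vc) < 0)) stop_invalid("variance components must be >= 0")

  if (inherits(families, "FamilySet")) {
    fam_id <- families$family
    fam_pop <- families$population
    fam_val <- if (use_family_values) families$value else NULL
  } else {
    nf <- check_count(families, "families", min = 2L)
    fam_id <- sprintf("F%04d", seq_len(nf))
    fam_pop <- rep("Pop1", nf)
    fam_val <- NULL
  }
  nf <- length(fam_id)

  set.seed(derive_seed(seed, "trial"))
  if (is.null(fam_val)) fam_val <- stats::rnorm(nf, 0, sqrt(vc$sigma2_f))
  names(fam_val) <- fam_id

  n_cols <- if (is.null(design$n_cols)) ceiling(sqrt(nf)) else design$n_cols
  n_rows <- ceiling(nf / n_cols)
  harvest_year <- sort(rep_len(seq_len(design$n_years), design$n_harvests))

  env <- expand.grid(site = design$sites, treatment = design$treatments,
                     stringsAsFactors = FALSE)
  out <- vector("list", nrow(env))
  truth <- list(family = fam_val, grand_mean = grand_mean, varcomps = vc)

  for (e in seq_len(nrow(env))) {
    site <- env$site[e]; trt <- env$treatment[e]
    gy <- matrix(stats::rnorm(nf * design$n_years, 0, sqrt(vc$sigma2_gy)),
                 nf, design$n_years, dimnames = list(fam_id, NULL))
    gh <- matrix(stats::rnorm(nf * design$n_harvests, 0, sqrt(vc$sigma2_gh)),
                 nf, design$n_harvests, dimnames = list(fam_id, NULL))
    gt <- stats::rnorm(nf, 0, sqrt(vc$sigma2_gt))
    gl <- stats::rnorm(nf, 0, sqrt(vc$sigma2_gl))
    rep_eff <- stats::rnorm(design$n_reps, 0, sqrt(vc$sigma2_rep))
    row_eff <- matrix(stats::rnorm(n_rows * design$n_reps, 0, sqrt(vc$sigma2_row)),
                      n_rows, design$n_reps)
    col_eff <- matrix(stats::rnorm(n_cols * design$n_reps, 0, sqrt(vc$sigma2_col)),
                      n_cols, design$n_reps)

    plots <- do.call(rbind, lapply(seq_len(design$n_reps), function(r) {
      ord <- sample.int(nf)   # fresh randomisation per replicate block
      data.frame(family = fam_id[ord], population = fam_pop[ord], rep = r,
                 row = rep(seq_len(n_rows), each = n_cols)[seq_len(nf)],
                 col = rep_len(seq_len(n_cols), nf), stringsAsFactors = FALSE)
    }))

    recs <- plots[rep(seq_len(nrow(plots)), each = design$n_harvests), ]
    recs$harvest <- rep(seq_len(design$n_harvests), nrow(plots))
    recs$year <- harvest_year[recs$harvest]
    recs$site <- site
    recs$treatment <- trt
    fidx <- match(recs$family, fam_id)
    recs$value <- grand_mean +
      fam_val[fidx] +
      gy[cbind(fidx, recs$year)] +
      gh[cbind(fidx, recs$harvest)] +
      gt[fidx] * (length(design$treatments) > 1) +
      gl[fidx] * (length(design$sites) > 1) +
      rep_eff[recs$rep] +
      row_eff[cbind(recs$row, recs$rep)] +
      col_eff[cbind(recs$col, recs$rep)] +
      stats::rnorm(nrow(recs), 0, sqrt(vc$sigma2_e))
    out[[e]] <- recs
  }
  records <- do.call(rbind, out)
  rownames(records) <- NULL
  records <- records[, c("family", "population", "site", "treatment",
                         "rep", "row", "col", "year", "harvest", "value")]
  attr(records, "truth") <- truth
  records
}

#' Simulate GBS read counts from true dosages
#'
#' Per-cell sequencing depth is Poisson (`depth_dispersion = 0`) or
#' negative-binomial with the given dispersion; conditional on depth the
#' alternate-allele read count is Binomial(depth, dosage/2). Depth zero is
#' the only representation of missingness. Defaults emulate low-depth GBS
#' genotyping with mean depth about 3.
#'
#' @param true_dosages individuals x SNPs matrix with values in `{0,1,2}`.
#' @param mean_depth mean sequencing depth per cell (> 0).
#' @param depth_dispersion negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2); 0 gives Poisson depths.
#' @param missing_target optional overall fraction of missing (depth-0)
#'   cells; when larger than the depth model already produces, extra cells
#'   are zeroed at random to reach it in expectation.
#' @param seed integer seed.
#' @return a `ReadCountMatrix` (see [read_count_matrix()]).
#' @export
simulate_gbs_reads <- function(true_dosages, mean_depth = 3,
                               depth_dispersion = 0, missing_target = NULL,
                               seed = 1) {
  stopifnot(is.matrix(true_dosages))
  check_scalar(mean_depth, "mean_depth", 0, open_lower = TRUE)
  check_scalar(depth_dispersion, "depth_dispersion", 0)
  set.seed(derive_seed(seed, "gbs"))
  n <- nrow(true_dosages); m <- ncol(true_dosages)
  depth <- if (depth_dispersion > 0) {
    stats::rnbinom(n * m, size = 1 / depth_dispersion, mu = mean_depth)
  } else {
    stats::rpois(n * m, mean_depth)
  }
  if (!is.null(missing_target)) {
    check_scalar(missing_target, "missing_target", 0, 1)
    p0 <- mean(depth == 0)
    if (missing_target > p0) {
      extra <- (missing_target - p0) / (1 - p0)
      depth[depth > 0 & stats::runif(n * m) < extra] <- 0L
    }
  }
  alt <- stats::rbinom(n * m, size = depth, prob = as.vector(true_dosages) / 2)
  alt <- matrix(alt, n, m, dimnames = dimnames(true_dosages))
  depth <- matrix(depth, n, m)
  read_count_matrix(ref = depth - alt, alt = alt,
                    ids = rownames(true_dosages),
                    snps = attr(true_dosages, "snps"))
}
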