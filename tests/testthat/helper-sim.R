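# Shared fixtures and independent oracles, built in code at test time.

# Weir & Cockerham (1984) multi-population theta, ratio-of-averages over
# loci, from per-population dosage matrices. Independent moment-estimator
# oracle for the founder simulator.
wc_fst <- function(dosage_list) {
  r <- length(dosage_list)
  n_i <- vapply(dosage_list, nrow, integer(1))
  m <- ncol(dosage_list[[1]])
  p_mat <- vapply(dosage_list, function(d) colMeans(d) / 2, numeric(m))
  h_mat <- vapply(dosage_list, function(d) colMeans(d == 1), numeric(m))
  n_bar <- mean(n_i)
  n_c <- (r * n_bar - sum(n_i^2) / (r * n_bar)) / (r - 1)
  p_bar <- drop(p_mat %*% n_i) / (r * n_bar)
  s2 <- drop(((p_mat - p_bar)^2) %*% n_i) / ((r - 1) * n_bar)
  h_bar <- drop(h_mat %*% n_i) / (r * n_bar)
  a <- (n_bar / n_c) *
    (s2 - (p_bar * (1 - p_bar) - (r - 1) / r * s2 - h_bar / 4) / (n_bar - 1))
  b <- (n_bar / (n_bar - 1)) *
    (p_bar * (1 - p_bar) - (r - 1) / r * s2 - (2 * n_bar - 1) / (4 * n_bar) * h_bar)
  cc <- h_bar / 2
  sum(a) / sum(a + b + cc)
}

# Hardy-Weinberg population of unrelated individuals at given frequencies.
hwe_dosages <- function(n, p, seed) {
  set.seed(seed)
  m <- length(p)
  x <- matrix(rbinom(n * m, 2, rep(p, each = n)), n, m)
  rownames(x) <- sprintf("I%04d", seq_len(n))
  x
}

# Parent-offspring pairs by Mendelian gamete sampling at given frequencies.
parent_offspring_dosages <- function(n_pairs, p, seed) {
  set.seed(seed)
  m <- length(p)
  par1 <- matrix(rbinom(n_pairs * m, 2, rep(p, each = n_pairs)), n_pairs, m)
  par2 <- matrix(rbinom(n_pairs * m, 2, rep(p, each = n_pairs)), n_pairs, m)
  off <- matrix(rbinom(n_pairs * m, 1, par1 / 2), n_pairs, m) +
    matrix(rbinom(n_pairs * m, 1, par2 / 2), n_pairs, m)
  x <- rbind(par1, off)
  rownames(x) <- c(sprintf("P%04d", seq_len(n_pairs)),
                   sprintf("O%04d", seq_len(n_pairs)))
  x
}

# A tiny PopulationSet built by hand (bypasses the founder simulator).
manual_population <- function(dosage, pop = rep("Pop1", nrow(dosage)),
                              freq = NULL) {
  m <- ncol(dosage)
  ids <- rownames(dosage) %||% sprintf("I%04d", seq_len(nrow(dosage)))
  rownames(dosage) <- ids
  if (is.null(freq)) {
    pops <- unique(pop)
    freq <- t(vapply(pops, function(k)
      colMeans(dosage[pop == k, , drop = FALSE]) / 2, numeric(m)))
  }
  snps <- data.frame(snp = sprintf("S1_%d", seq_len(m) * 100L),
                     scaffold = "scaffold_1", pos = seq_len(m) * 100L,
                     ref = "A", alt = "C", stringsAsFactors = FALSE)
  colnames(dosage) <- snps$snp
  structure(list(ids = ids, pop = factor(pop), freq = freq,
                 anc_freq = colMeans(freq), dosage = dosage, snps = snps,
                 fst = NA, seed = NA),
            class = "PopulationSet")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Balanced one-family-effect trial records without the package simulator.
one_way_records <- function(n_fam, n_rep, sigma_f, sigma_e, mu = 10, seed = 1) {
  set.seed(seed)
  d <- expand.grid(family = sprintf("F%03d", seq_len(n_fam)), rep = seq_len(n_rep),
                   stringsAsFactors = FALSE)
  d$site <- "S"; d$treatment <- "T"; d$row <- 1; d$col <- 1
  d$year <- 1; d$harvest <- 1; d$population <- "P"
  fam <- rnorm(n_fam, 0, sigma_f)
  d$value <- mu + fam[match(d$family, sprintf("F%03d", seq_len(n_fam)))] +
    rnorm(nrow(d), 0, sigma_e)
  d
}
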