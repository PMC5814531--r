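.default_config <- function() {
  list(
    seed = 1,
    stages = c("simulate", "filter", "grm", "blup", "predict", "cv", "ld", "gain"),
    simulate = list(n_pops = 5, n_per_pop = 60, n_snps = 3000, n_scaffolds = 20,
                    fst = 0.1, maf_floor = 0.05, sigma2_A = 41.2, n_pollen = 20,
                    mean_depth = 3, n_reps = 3, n_years = 1, n_harvests = 2,
                    grand_mean = 32.2,
                    varcomps = list(sigma2_f = 10.3, sigma2_gh = 4,
                                    sigma2_e = 66.1)),
    filter = list(ruleset = "training", max_missing = 0.5, min_maf = 0.05,
                  min_depth = 1, hwdiseq_min = -0.05),
    grm = list(method = "standard", min_diag_depth = 2),
    blup = list(random = c("family", "family:harvest"), fixed = "harvest"),
    predict = list(method = "gblup", lambda = NULL, lambda_policy = "reml"),
    cv = list(scheme = "tenfold", folds = 10, reps = 5),
    ld = list(threshold = 0.25, max_pairs = 20000, use = "dosage"),
    gain = list(kf_top = 0.20, kw_top = 0.01, r = 0.27, d_e = NULL,
                interactions = NULL)
  )
}

#' Validate a pipeline configuration
#'
#' Injects defaults, rejects unknown keys and range-checks every
#' parameter, aggregating all problems into one error. An empty config
#' returns the full default set.
#'
#' @param config nested list (e.g. from [yaml::read_yaml()]), or `NULL`.
#' @return the validated config with defaults filled in.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  defaults <- .default_config()
  errors <- character(0)
  unknown_top <- setdiff(names(config), names(defaults))
  if (length(unknown_top))
    errors <- c(errors, paste0("unknown key(s): ",
                               paste(unknown_top, collapse = ", ")))
  merged <- defaults
  for (k in intersect(names(config), names(defaults))) {
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]]))) {
      bad <- setdiff(names(config[[k]]), names(defaults[[k]]))
      if (length(bad))
        errors <- c(errors, paste0("unknown key(s) under '", k, "': ",
                                   paste(bad, collapse = ", ")))
      merged[[k]][names(config[[k]])] <- config[[k]]
    } else {
      merged[[k]] <- config[[k]]
    }
  }
  rng <- function(ok, msg) if (!isTRUE(ok)) errors <<- c(errors, msg)
  rng(merged$simulate$fst >= 0 && merged$simulate$fst < 1,
      "simulate.fst must be in [0, 1)")
  rng(merged$simulate$maf_floor > 0 && merged$simulate$maf_floor < 0.5,
      "simulate.maf_floor must be in (0, 0.5)")
  rng(merged$simulate$mean_depth > 0, "simulate.mean_depth must be > 0")
  rng(merged$filter$min_maf >= 0 && merged$filter$min_maf <= 0.5,
      "filter.min_maf must be in [0, 0.5]")
  rng(merged$filter$max_missing >= 0 && merged$filter$max_missing <= 1,
      "filter.max_missing must be in [0, 1]")
  rng(merged$filter$ruleset %in% c("training", "ld", "custom"),
      "filter.ruleset must be training, ld or custom")
  rng(merged$grm$method %in% c("standard", "kgd"),
      "grm.method must be standard or kgd")
  rng(merged$cv$folds >= 2, "cv.folds must be >= 2")
  n_total <- sum(rep(merged$simulate$n_per_pop,
                     length.out = merged$simulate$n_pops))
  rng(!("cv" %in% merged$stages) || n_total >= merged$cv$folds,
      "cv stage needs at least as many individuals as folds")
  rng(merged$gain$kf_top > 0 && merged$gain$kf_top < 1,
      "gain.kf_top must be in (0, 1)")
  rng(merged$gain$kw_top > 0 && merged$gain$kw_top < 1,
      "gain.kw_top must be in (0, 1)")
  if (length(errors))
    stop_invalid("invalid configuration:\n  - ",
                 paste(errors, collapse = "\n  - "))
  merged
}

.stage_log <- function(stage, msg) {
  message(sprintf("[%s] %s", stage, msg))
}

#' Run the full training-analysis pipeline on simulated data
#'
#' Executes the requested stages in dependency order -- simulate GBS and
#' trial data, filter SNPs, build the relationship matrix, estimate
#' variance components and family BLUPs, fit the genomic prediction
#' model, cross-validate it, model LD decay, and predict genetic gain --
#' handing results between stages as plain files under `out_dir` so each
#' stage is independently inspectable and re-usable on real data. A
#' manifest records outputs, checksums and timing per stage;
#' deterministic stages reproduce identical checksums under an identical
#' config.
#'
#' @param config a config list or YAML path (see [validate_config()]).
#' @param out_dir output directory (created if needed).
#' @return a `RunManifest` data.frame (stage, output, md5, seconds) with
#'   the validated config attached as attribute `config`.
#' @export
run_pipeline <- function(config = list(), out_dir = tempfile("pgs_run_")) {
  cfg <- validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  note <- function(stage, file, secs) {
    manifest[[length(manifest) + 1]] <<- data.frame(
      stage = stage, output = basename(file),
      md5 = unname(tools::md5sum(file)), seconds = round(secs, 2),
      stringsAsFactors = FALSE)
  }
  path <- function(f) file.path(out_dir, f)
  timed <- function(expr) system.time(expr)[["elapsed"]]

  state <- new.env(parent = emptyenv())

  if ("simulate" %in% cfg$stages) {
    s <- cfg$simulate
    secs <- timed({
      pops <- simulate_founders(s$n_pops, s$n_per_pop, s$n_snps, s$n_scaffolds,
                                s$fst, s$maf_floor, seed = cfg$seed)
      fams <- simulate_polycross(pops, s$sigma2_A, s$n_pollen, seed = cfg$seed)
      reads <- simulate_gbs_reads(pops$dosage, s$mean_depth, seed = cfg$seed)
      reads$snps <- pops$snps
      pheno <- simulate_trial(fams,
                              trial_design(s$n_reps, s$n_years, s$n_harvests),
                              s$varcomps, s$grand_mean, seed = cfg$seed)
      write_gbs_vcf(reads, path("genotypes.vcf"))
      write_phenotypes(pheno, path("phenotypes.tsv"))
      utils::write.table(
        data.frame(family = fams$family, mother = fams$mother,
                   population = fams$population, true_value = fams$value),
        path("truth.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
      state$pops <- pops; state$fams <- fams; state$reads <- reads
      state$pheno <- pheno
    })
    .stage_log("simulate", sprintf("%d individuals, %d SNPs, %d phenotype records",
                                   length(state$pops$ids), nrow(state$reads$snps),
                                   nrow(state$pheno)))
    note("simulate", path("genotypes.vcf"), secs)
    note("simulate", path("phenotypes.tsv"), 0)
    note("simulate", path("truth.tsv"), 0)
  }

  if ("filter" %in% cfg$stages) {
    if (is.null(state$reads)) {
      if (!file.exists(path("genotypes.vcf")))
        stop_invalid("filter stage needs genotypes.vcf (run simulate first ",
                     "or place the file in out_dir)")
      state$reads <- read_gbs_vcf(path("genotypes.vcf"))
    }
    f <- cfg$filter
    secs <- timed({
      st <- snp_stats(state$reads)
      keep <- filter_snps(st, f$ruleset, f$max_missing, f$min_maf,
                          f$min_depth, f$hwdiseq_min)
      rep_df <- attr(keep, "report")
      utils::write.table(cbind(st, rep_df[-1]), path("filter_report.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      state$reads_f <- subset_snps(state$reads, keep)
      state$n_before <- nrow(st); state$n_after <- length(keep)
    })
    .stage_log("filter", sprintf("SNPs in %d, retained %d",
                                 state$n_before, state$n_after))
    note("filter", path("filter_report.tsv"), secs)
  }

  if ("grm" %in% cfg$stages) {
    stopifnot(!is.null(state$reads_f))
    secs <- timed({
      grm <- if (cfg$grm$method == "kgd") {
        kgd_grm(state$reads_f, cfg$grm$min_diag_depth)
      } else {
        standard_grm(mean_impute(call_dosages(state$reads_f)))
      }
      write_grm(grm, path("grm.tsv"))
      state$grm <- grm
    })
    .stage_log("grm", sprintf("%s GRM on %d individuals, mean diagonal %.3f",
                              state$grm$method, length(state$grm$ids),
                              mean(diag(state$grm$S), na.rm = TRUE)))
    note("grm", path("grm.tsv"), secs)
  }

  if ("blup" %in% cfg$stages) {
    if (is.null(state$pheno)) {
      if (!file.exists(path("phenotypes.tsv")))
        stop_invalid("blup stage needs phenotypes.tsv")
      state$pheno <- read_phenotypes(path("phenotypes.tsv"))
    }
    b <- cfg$blup
    secs <- timed({
      fit <- fit_varcomps(state$pheno, random = b$random, fixed = b$fixed,
                          se = FALSE)
      utils::write.table(
        data.frame(component = names(fit$components),
                   estimate = fit$components),
        path("varcomps.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(fit$blups[c("family", "blup")], path("blups.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      state$vc_fit <- fit
    })
    .stage_log("blup", sprintf("%d records in, %d family BLUPs out (%d EM iterations)",
                               nrow(state$pheno), nrow(state$vc_fit$blups),
                               state$vc_fit$iterations))
    note("blup", path("varcomps.tsv"), secs)
    note("blup", path("blups.tsv"), 0)
  }

  if ("predict" %in% cfg$stages || "cv" %in% cfg$stages) {
    stopifnot(!is.null(state$vc_fit), !is.null(state$fams))
    # family BLUPs keyed by maternal-parent genotype id
    map <- stats::setNames(state$fams$mother, state$fams$family)
    y <- stats::setNames(state$vc_fit$blups$blup,
                         map[state$vc_fit$blups$family])
    state$y <- y[!is.na(names(y))]
  }

  if ("predict" %in% cfg$stages) {
    secs <- timed({
      fit <- fit_gblup(state$y, state$grm)
      gebv <- predict_gblup(fit, state$grm$ids)
      utils::write.table(data.frame(id = names(gebv), gebv = gebv),
                         path("gebv.tsv"), sep = "\t", quote = FALSE,
                         row.names = FALSE)
      state$gblup <- fit
    })
    .stage_log("predict", sprintf("GBLUP lambda %.3f; %d GEBVs out",
                                  state$gblup$lambda, length(state$grm$ids)))
    note("predict", path("gebv.tsv"), secs)
  }

  if ("cv" %in% cfg$stages) {
    secs <- timed({
      rep_cv <- run_tenfold(state$y, gblup_factory(state$grm),
                            folds = cfg$cv$folds, n_reps = cfg$cv$reps,
                            seed = cfg$seed, method = "gblup")
      utils::write.table(rep_cv$replicates, path("cv_report.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      state$cv <- rep_cv
    })
    .stage_log("cv", sprintf("mean PA %.3f (SE %.3f) over %d replicates",
                             state$cv$mean_pa, state$cv$se_pa, cfg$cv$reps))
    note("cv", path("cv_report.tsv"), secs)
  }

  if ("ld" %in% cfg$stages) {
    stopifnot(!is.null(state$reads))
    secs <- timed({
      st_all <- snp_stats(state$reads)
      keep_ld <- filter_snps(st_all, "ld")
      ld_ok <- length(keep_ld) >= 10
      if (ld_ok) {
        prs <- pairwise_r2(subset_snps(state$reads, keep_ld),
                           max_pairs = cfg$ld$max_pairs, use = cfg$ld$use,
                           seed = cfg$seed)
        utils::write.table(prs, path("ld_pairs.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
        dfit <- try(fit_decay(prs), silent = TRUE)
        if (!inherits(dfit, "try-error")) {
          n_ref <- round(stats::median(prs$n))
          utils::write.table(
            data.frame(alpha = dfit$alpha, beta = dfit$beta,
                       d_at_threshold = distance_at_r2(dfit, cfg$ld$threshold,
                                                       n_ref),
                       n_ref = n_ref),
            path("ld_fit.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
        }
      } else {
        utils::write.table(data.frame(note = "too few SNPs pass the ld ruleset"),
                           path("ld_pairs.tsv"), sep = "\t", quote = FALSE,
                           row.names = FALSE)
      }
    })
    .stage_log("ld", sprintf("%d SNPs pass the ld ruleset", length(keep_ld)))
    note("ld", path("ld_pairs.tsv"), secs)
  }

  if ("gain" %in% cfg$stages) {
    stopifnot(!is.null(state$vc_fit))
    g <- cfg$gain
    secs <- timed({
      vc <- as.list(state$vc_fit$components)
      inter <- if (is.null(g$interactions)) {
        present <- intersect(c("sigma2_gy", "sigma2_gh"), names(vc))
        div <- c(sigma2_gy = cfg$simulate$n_years,
                 sigma2_gh = cfg$simulate$n_harvests)
        stats::setNames(div[present], present)
      } else unlist(g$interactions)
      d_e <- if (is.null(g$d_e))
        cfg$simulate$n_reps * cfg$simulate$n_harvests * cfg$simulate$n_years
      else g$d_e
      spf <- family_phenotypic_sd(vc, inter, d_e)
      sc <- gain_scenario(k_f = selection_intensity(g$kf_top),
                          k_w = selection_intensity(g$kw_top),
                          r = g$r, sigma2_A = 4 * vc$sigma2_f,
                          sigma_PF = spf,
                          mean = state$vc_fit$grand_mean)
      grid <- scenario_grid(sc)
      utils::write.table(grid, path("gain_grid.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      state$gain <- grid
    })
    .stage_log("gain", sprintf("%d scenario cells; baseline %.2f%%",
                               nrow(state$gain),
                               attr(state$gain, "baseline_pct")))
    note("gain", path("gain_grid.tsv"), secs)
  }

  out <- do.call(rbind, manifest)
  attr(out, "config") <- cfg
  class(out) <- c("RunManifest", "data.frame")
  out
}
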