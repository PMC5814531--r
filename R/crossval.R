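#' Balanced random fold assignment
#'
#' @param n number of individuals.
#' @param k number of folds (sizes differ by at most 1).
#' @param seed integer seed; the partition is a pure function of `(n, k, seed)`.
#' @return integer vector of fold labels in `1..k`.
#' @export
make_folds <- function(n, k, seed) {
  k <- check_count(k, "k", min = 2L)
  if (n < k) stop_invalid("cannot make ", k, " folds from ", n, " individuals")
  set.seed(seed)
  sample(rep_len(seq_len(k), n))
}

#' Reusable cross-validation partitions
#'
#' Generates the fold assignments for every replicate up front so that
#' different prediction methods can be compared on exactly the same
#' partitions.
#'
#' @param n individuals.
#' @param folds folds per replicate.
#' @param n_reps replicates.
#' @param seed integer seed.
#' @return list of integer fold vectors, one per replicate.
#' @export
cv_partitions <- function(n, folds = 10, n_reps = 5, seed = 1) {
  lapply(seq_len(n_reps), function(r)
    make_folds(n, folds, derive_seed(seed, "tenfold", r)))
}

.replicate_pa <- function(pred, obs) {
  if (stats::sd(pred) < .Machine$double.eps) {
    warning("zero-variance predictions; predictive ability recorded as 0",
            call. = FALSE)
    return(0)
  }
  stats::cor(pred, obs)
}

#' Tenfold cross-validation of a prediction method
#'
#' Per replicate: a fresh random partition into `folds` near-equal folds;
#' each fold is predicted from a model trained on the remaining folds;
#' predictive ability (PA) is the Pearson correlation between the pooled
#' held-out GEBVs and the observed BLUPs of that replicate, and the bias
#' slope the OLS slope of GEBV on BLUP. A model failure inside a fold
#' flags the whole replicate, which is excluded from the summary with a
#' warning.
#'
#' @param y named numeric vector of observed values (family BLUPs).
#' @param model_factory `function(y_train, train_ids, test_ids)` returning
#'   numeric GEBVs for `test_ids` (see [gblup_factory()] and friends).
#' @param folds folds per replicate.
#' @param n_reps number of replicates.
#' @param seed integer seed.
#' @param partitions optional list of precomputed fold vectors
#'   ([cv_partitions()]) so several methods share identical partitions.
#' @param method,trait labels carried into the report.
#' @return object of class `cv_report`: data.frame `replicates`
#'   (replicate, pa, slope, failed), `mean_pa`, `se_pa`, `mean_slope`.
#' @export
run_tenfold <- function(y, model_factory, folds = 10, n_reps = 5, seed = 1,
                        partitions = NULL, method = "model", trait = "trait") {
  ids <- names(y)
  if (is.null(ids)) stop_invalid("'y' must be a named vector")
  n <- length(y)
  if (is.null(partitions))
    partitions <- cv_partitions(n, folds, n_reps, seed)
  stopifnot(length(partitions) >= n_reps)

  rows <- lapply(seq_len(n_reps), function(r) {
    part <- partitions[[r]]
    pred <- rep(NA_real_, n)
    ok <- TRUE
    for (f in sort(unique(part))) {
      test <- ids[part == f]
      train <- ids[part != f]
      stopifnot(!any(test %in% train))
      gebv <- tryCatch(model_factory(y[train], train, test),
                       error = function(e) {
                         warning(sprintf(
                           "replicate %d flagged: model failed in fold %d (%s)",
                           r, f, conditionMessage(e)), call. = FALSE)
                         NULL
                       })
      if (is.null(gebv)) { ok <- FALSE; break }
      pred[part == f] <- gebv[test]
    }
    if (!ok) return(data.frame(replicate = r, pa = NA_real_,
                               slope = NA_real_, failed = TRUE))
    data.frame(replicate = r,
               pa = .replicate_pa(pred, y),
               slope = if (stats::sd(pred) < .Machine$double.eps) NA_real_
                       else bias_slope(pred, y),
               failed = FALSE)
  })
  reps <- do.call(rbind, rows)
  ok <- !reps$failed
  structure(list(scheme = "tenfold", method = method, trait = trait,
                 replicates = reps,
                 mean_pa = mean(reps$pa[ok]),
                 se_pa = stats::sd(reps$pa[ok]) / sqrt(sum(ok)),
                 mean_slope = mean(reps$slope[ok], na.rm = TRUE)),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("%s CV [%s / %s]: mean PA %.3f (SE %.3f), mean slope %.3f over %d replicates\n",
              x$scheme, x$method, x$trait, x$mean_pa, x$se_pa, x$mean_slope,
              nrow(x$replicates)))
  invisible(x)
}

#' Population-balanced target cross-validation
#'
#' Per replicate: the training set is a random 50% of the target
#' population plus equally sized random draws from every other population
#' (so populations are balanced in training, counts differing by at most
#' one); the validation set is the remaining half of the target
#' population only. PA and bias slope are computed per replicate on the
#' validation set.
#'
#' @param y named numeric observed values.
#' @param pop population label per individual (aligned with `y`).
#' @param target_pop population to predict.
#' @param model_factory as in [run_tenfold()].
#' @param n_reps replicates.
#' @param seed integer seed.
#' @param method,trait labels.
#' @return a `cv_report` (scheme `"balanced-target"`).
#' @export
run_balanced_target <- function(y, pop, target_pop, model_factory,
                                n_reps = 25, seed = 1,
                                method = "model", trait = "trait") {
  ids <- names(y)
  if (is.null(ids)) stop_invalid("'y' must be a named vector")
  pop <- as.character(pop)
  stopifnot(length(pop) == length(y))
  pops <- unique(pop)
  if (length(pops) < 2) stop_invalid("need >= 2 populations")
  if (!target_pop %in% pops) stop_invalid("unknown target population: ", target_pop)
  n_target <- sum(pop == target_pop)
  if (n_target < 4) stop_invalid("target population too small: ", target_pop)
  n_half <- floor(n_target / 2)
  small <- pops[vapply(pops, function(p) sum(pop == p), integer(1)) < n_half &
                  pops != target_pop]
  if (length(small))
    stop_invalid("population(s) too small to balance the training set: ",
                 paste(small, collapse = ", "))

  rows <- lapply(seq_len(n_reps), function(r) {
    set.seed(derive_seed(seed, "balanced", r))
    tgt <- ids[pop == target_pop]
    train_t <- sample(tgt, n_half)
    valid <- setdiff(tgt, train_t)
    train_o <- unlist(lapply(setdiff(pops, target_pop), function(p)
      sample(ids[pop == p], n_half)))
    train <- c(train_t, train_o)
    stopifnot(!any(valid %in% train))
    gebv <- model_factory(y[train], train, valid)
    data.frame(replicate = r,
               pa = .replicate_pa(gebv[valid], y[valid]),
               slope = if (stats::sd(gebv[valid]) < .Machine$double.eps)
                 NA_real_ else bias_slope(gebv[valid], y[valid]),
               failed = FALSE)
  })
  reps <- do.call(rbind, rows)
  structure(list(scheme = "balanced-target", method = method, trait = trait,
                 target_pop = target_pop, replicates = reps,
                 mean_pa = mean(reps$pa), se_pa = stats::sd(reps$pa) / sqrt(n_reps),
                 mean_slope = mean(reps$slope, na.rm = TRUE)),
            class = "cv_report")
}

#' Prediction bias slope
#'
#' OLS slope of GEBV regressed on BLUP. A slope of 1 marks unbiased
#' prediction; below 1 the spread of GEBVs under-represents the observed
#' differences, above 1 it exaggerates them.
#'
#' @param gebv predicted values.
#' @param blup observed values (>= 3 pairs, non-zero variance).
#' @return the slope.
#' @export
bias_slope <- function(gebv, blup) {
  if (length(gebv) != length(blup) || length(gebv) < 3)
    stop_invalid("need >= 3 aligned (gebv, blup) pairs")
  if (stats::var(blup) < .Machine$double.eps)
    stop_invalid("undefined slope: zero BLUP variance")
  stats::cov(gebv, blup) / stats::var(blup)
}

#' Two-way method x trait ANOVA of predictive abilities
#'
#' Fixed-effects two-factor ANOVA with interaction on the per-replicate
#' PA values of a complete, balanced methods x traits x replicates
#' factorial (the design produced by running every method on identical
#' CV partitions). Degrees of freedom: `a - 1`, `b - 1`, `(a-1)(b-1)` and
#' `ab(r - 1)`. When a sum of squares is exactly zero (e.g. all PA values
#' equal) the corresponding p-value is reported as 1.
#'
#' @param pa_table data.frame with columns `method`, `trait`, `replicate`,
#'   `pa`.
#' @return data.frame with Df, Sum Sq, Mean Sq, F value, p.
#' @export
method_trait_anova <- function(pa_table) {
  stopifnot(all(c("method", "trait", "replicate", "pa") %in% names(pa_table)))
  tab <- table(pa_table$method, pa_table$trait)
  if (length(unique(as.vector(tab))) != 1L || any(tab == 0))
    stop_invalid("unbalanced method x trait table; the design must be a ",
                 "complete factorial with equal replicates")
  d <- data.frame(method = factor(pa_table$method),
                  trait = factor(pa_table$trait),
                  pa = pa_table$pa)
  fit <- stats::aov(pa ~ method * trait, data = d)
  a <- summary(fit)[[1]]
  out <- data.frame(term = trimws(rownames(a)), df = a$Df,
                    sum_sq = a$`Sum Sq`, mean_sq = a$`Mean Sq`,
                    f_value = a$`F value`, p_value = a$`Pr(>F)`,
                    row.names = NULL, stringsAsFactors = FALSE)
  zero <- !is.na(out$sum_sq) & out$sum_sq < .Machine$double.eps &
    out$term != "Residuals"
  out$p_value[zero | is.nan(out$f_value)] <- 1
  out
}

#' Model factories for the CV engine
#'
#' Each factory closes over its data (GRM or marker matrix) and returns
#' the `function(y_train, train_ids, test_ids)` contract the CV schemes
#' consume.
#'
#' @param grm a `GRM` covering all individuals.
#' @return a model-factory function.
#' @export
gblup_factory <- function(grm) {
  function(y_train, train_ids, test_ids) {
    fit <- fit_gblup(y_train, grm, ids = train_ids)
    predict_gblup(fit, test_ids)
  }
}

#' @rdname gblup_factory
#' @param M complete marker matrix with rownames for all individuals.
#' @param policy,lambda passed to [fit_ridge()].
#' @export
ridge_factory <- function(M, policy = "reml", lambda = NULL) {
  function(y_train, train_ids, test_ids) {
    fit <- fit_ridge(y_train, M[train_ids, , drop = FALSE],
                     lambda = lambda, policy = policy)
    predict_ridge(fit, M[test_ids, , drop = FALSE])
  }
}

#' @rdname gblup_factory
#' @param plugin a [plugin_regressor()].
#' @export
plugin_factory <- function(M, plugin) {
  function(y_train, train_ids, test_ids) {
    fit <- fit_plugin(y_train, M[train_ids, , drop = FALSE], plugin)
    predict_plugin(fit, M[test_ids, , drop = FALSE])
  }
}

#' @rdname gblup_factory
#' @param truth named numeric vector of true values; the oracle factory
#'   returns them directly (PA = 1 by construction), used as an upper
#'   bound / sanity check on real methods.
#' @export
oracle_factory <- function(truth) {
  function(y_train, train_ids, test_ids) truth[test_ids]
}
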