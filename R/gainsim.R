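#' Standardized selection intensity
#'
#' The mean deviation, in standard-deviation units, of the top proportion
#' `p` of a standard normal distribution: `k = dnorm(qnorm(1 - p)) / p`
#' (infinite-population truncation selection). The working values for
#' half-sib family schemes: top 20% of families gives k = 1.40; top 5, 3
#' and 1% of individuals within family give 2.06, 2.27 and 2.67.
#'
#' @param p selected proportion(s), each in (0, 1).
#' @return selection intensity (vectorised).
#' @export
selection_intensity <- function(p) {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p <= 0) || any(p >= 1))
    stop_invalid("'p' must lie strictly inside (0, 1)")
  stats::dnorm(stats::qnorm(1 - p)) / p
}

#' Among-family phenotypic standard deviation of family means
#'
#' `sigma_PF = sqrt(sigma2_f + sum_k sigma2_k / n_k + sigma2_e / d_e)`:
#' the phenotypic SD of a family mean, sharing its divisor structure with
#' [repeatability()]. This is the denominator of the among-family
#' selection response.
#'
#' @inheritParams repeatability
#' @return `sigma_PF` in trait units.
#' @export
family_phenotypic_sd <- function(varcomps, interactions = numeric(0), d_e) {
  if (any(unlist(varcomps) < 0)) stop_invalid("variance components must be >= 0")
  parts <- .family_mean_denom(varcomps, interactions, d_e)
  sqrt(parts$denom)
}

#' Define a genetic-gain scenario
#'
#' Collects the deterministic inputs of the single-cycle gain equations
#' for half-sib family selection. The among-family variance of a half-sib
#' trial is one quarter of the additive variance, so `sigma2_A` is four
#' times the estimated family component. Parental control is 0.5 for both
#' stages of half-sib selection (only the female parent is selected).
#'
#' @param k_f among-family selection intensity.
#' @param k_w within-family selection intensity.
#' @param c_f,c_w among- and within-family parental control.
#' @param h_x square root of the secondary-trait heritability (1 when the
#'   secondary trait is the GEBV itself).
#' @param r genomic predictive ability (correlation of GEBV with additive
#'   merit), in `[0, 1]`.
#' @param sigma2_A additive genetic variance (trait units squared).
#' @param sigma_PF among-family phenotypic SD of family means.
#' @param mean population mean of the trait (for percentage gain).
#' @return a `GainScenario` list.
#' @export
gain_scenario <- function(k_f = selection_intensity(0.20),
                          k_w = 0, c_f = 0.5, c_w = 0.5, h_x = 1,
                          r = 0, sigma2_A = 4 * 10.3, sigma_PF = NULL,
                          mean = 32.2) {
  check_scalar(k_f, "k_f", 0); check_scalar(k_w, "k_w", 0)
  check_scalar(r, "r", 0, 1)
  check_scalar(h_x, "h_x", 0, 1, open_lower = TRUE)
  check_scalar(sigma2_A, "sigma2_A", 0)
  if (is.null(sigma_PF)) stop_invalid("'sigma_PF' is required")
  check_scalar(sigma_PF, "sigma_PF", 0, open_lower = TRUE)
  structure(list(k_f = k_f, k_w = k_w, c_f = c_f, c_w = c_w, h_x = h_x,
                 r = r, sigma2_A = sigma2_A, sigma_PF = sigma_PF,
                 mean = mean),
            class = "GainScenario")
}

.gain_result <- function(among, within, mean) {
  dG <- among + within
  structure(list(dG = dG,
                 dG_pct = if (mean != 0) 100 * dG / mean else NA_real_,
                 among = among, within = within),
            class = "GainResult")
}

#' @export
print.GainResult <- function(x, ...) {
  cat(sprintf("dG = %.3f trait units (%.2f%% of mean); among-family %.3f, within-family %.3f\n",
              x$dG, x$dG_pct, x$among, x$within))
  invisible(x)
}

#' Expected gain from half-sib family phenotypic selection
#'
#' `dG = k_f c (sigma2_A / 4) / sigma_PF`: the classical among-family
#' response for forage crops, with `c = 0.5` for half-sib families.
#'
#' @param scenario a [gain_scenario()].
#' @param percent require the population mean to be non-zero and report
#'   the gain as a percentage of it.
#' @return a `GainResult` with `dG`, `dG_pct` and the among/within
#'   decomposition (within = 0 here).
#' @export
delta_g_hsf <- function(scenario, percent = TRUE) {
  stopifnot(inherits(scenario, "GainScenario"))
  if (percent && scenario$mean == 0)
    stop_invalid("percentage gain undefined: zero population mean")
  among <- scenario$k_f * scenario$c_f *
    (scenario$sigma2_A / 4) / scenario$sigma_PF
  .gain_result(among, 0, scenario$mean)
}

#' Expected gain from among-family phenotypic plus within-family genomic
#' selection
#'
#' Adds to the among-family response a within-family term driven by
#' genomic prediction:
#' `dG = k_f c_f (sigma2_A/4)/sigma_PF +
#'       k_w c_w h_x r sqrt(3)/2 sigma_A`.
#' The within-family additive SD of a half-sib family is
#' `sqrt(3)/2 sigma_A` (three quarters of the additive variance is
#' within-family), and the realised within-family response scales linearly
#' with the predictive ability `r` of the GEBVs used to rank sibs.
#'
#' @inheritParams delta_g_hsf
#' @return a `GainResult` with the among/within decomposition.
#' @export
delta_g_apwf <- function(scenario, percent = TRUE) {
  stopifnot(inherits(scenario, "GainScenario"))
  if (percent && scenario$mean == 0)
    stop_invalid("percentage gain undefined: zero population mean")
  among <- scenario$k_f * scenario$c_f *
    (scenario$sigma2_A / 4) / scenario$sigma_PF
  within <- scenario$k_w * scenario$c_w * scenario$h_x * scenario$r *
    (sqrt(3) / 2) * sqrt(scenario$sigma2_A)
  .gain_result(among, within, scenario$mean)
}

#' Evaluate a grid of gain scenarios
#'
#' Crosses predictive abilities with within-family selection intensities
#' and reports, per cell, the combined-selection gain and its relative
#' improvement over the family-selection baseline. Two modes:
#'
#' * component mode (`calibration = NULL`): every cell is evaluated from
#'   the scenario's variance components via [delta_g_apwf()].
#' * calibrated mode: published percentage anchors pin the baseline and
#'   the within-family increment scale -- `s = (anchor - baseline) /
#'   (anchor_r * anchor_kw)`, each cell `baseline + s * r * k_w`. This
#'   exists because rounded variance-component tables cannot reproduce
#'   percentage gains computed from unrounded estimates; two printed
#'   anchor points recover the exact linear within-family scale.
#'
#' @param base a [gain_scenario()] carrying `k_f` and the component
#'   inputs (component mode) or only `k_f` (calibrated mode).
#' @param r_values predictive abilities to evaluate.
#' @param kw_values within-family intensities to evaluate.
#' @param calibration `NULL`, or `list(baseline_pct=, anchor_pct=,
#'   anchor_r=, anchor_kw=)`.
#' @return data.frame with `r`, `k_w`, `dG_pct`, `improvement_pct`
#'   (percent above baseline); the baseline percentage is attached as
#'   attribute `baseline_pct`.
#' @export
scenario_grid <- function(base, r_values = seq(0.1, 0.5, by = 0.1),
                          kw_values = c(2.06, 2.27, 2.67),
                          calibration = NULL) {
  stopifnot(inherits(base, "GainScenario"))
  if (!length(r_values) || !length(kw_values))
    stop_invalid("empty scenario grid")
  grid <- expand.grid(r = r_values, k_w = kw_values)
  if (is.null(calibration)) {
    baseline <- delta_g_hsf(base)$dG_pct
    grid$dG_pct <- vapply(seq_len(nrow(grid)), function(i) {
      sc <- base
      sc$r <- grid$r[i]; sc$k_w <- grid$k_w[i]
      delta_g_apwf(sc)$dG_pct
    }, numeric(1))
  } else {
    need <- c("baseline_pct", "anchor_pct", "anchor_r", "anchor_kw")
    if (!is.list(calibration) || !all(need %in% names(calibration)))
      stop_invalid("unknown calibration mode: need ",
                   paste(need, collapse = ", "))
    baseline <- calibration$baseline_pct
    s <- (calibration$anchor_pct - baseline) /
      (calibration$anchor_r * calibration$anchor_kw)
    grid$dG_pct <- baseline + s * grid$r * grid$k_w
  }
  grid$improvement_pct <- 100 * (grid$dG_pct - baseline) / baseline
  attr(grid, "baseline_pct") <- baseline
  grid
}
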