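---
title: "Models and methods behind polycrossGS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind polycrossGS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

polycrossGS implements the full analysis chain used to build and validate
a genomic-selection training set for an outbred, half-sib-family breeding
programme: synthetic data generation, GBS genotype handling, relatedness,
variance components and BLUPs, genomic prediction, cross-validation, LD
decay, and deterministic genetic-gain prediction. This vignette explains
the models, the parameters that matter, the numerical choices, and what
the simulation-based tests do and do not establish.

## What the synthetic data emulate

The generator reproduces the statistical shape of a multi-population
training programme:

* **Founders** (`simulate_founders()`): five outbred populations of
  roughly 102–117 maternal parents each (517–566 total). Divergence
  follows a Balding–Nichols model — per-population allele frequencies are
  Beta-distributed around shared ancestral frequencies with a single
  F~ST~ for all populations (default 0.1). This is the minimal model
  that produces realistic between-population structure in an MDS
  ordination of `1 − S`; it was chosen over per-population drift
  parameters because nothing downstream depends on asymmetric divergence.
  Ancestral frequencies are uniform on (`maf_floor`, 1 − `maf_floor`),
  default floor 0.05, matching a MAF-filtered SNP panel.
* **Polycross families** (`simulate_polycross()`): every founder mothers
  one half-sib family. SNP effects are scaled so the expected
  within-population additive variance is `sigma2_A` (default 41.2 trait
  units², four times a family component of 10.3 g² DM per plot — the
  magnitude of a productive herbage-accumulation trial). The family
  genetic value is ½ × maternal breeding value + ½ × the mean of
  `n_pollen` pollen parents drawn uniformly without replacement from the
  same population, selfing excluded (obligate outcrossing). As the pollen
  pool grows, the among-family variance converges to ¼ of the additive
  variance — the classical half-sib relation the gain equations rely on.
  The default of 20 pollen parents keeps the excess over ¼σ²~A~ at 5%.
  Family genetic values are simulated at the family level because every
  downstream analysis operates on family means; individual progeny
  genotypes are never needed.
* **Trials** (`simulate_trial()`): long-format plot–harvest records,
  `value = grand mean + family + family×year + family×harvest +
  family×treatment + family×site + replicate + row + column + residual`,
  each effect Gaussian with a requested variance; families are freshly
  randomised on a row–column grid within every replicate. Harvests are
  spread as evenly as possible over years. Missing variance components
  default to zero with a notice rather than an error, because most
  scenarios exercise a subset of effects. Default components
  (σ²~f~ = 10.3, σ²~ε~ = 66.1 g² DM per plot, grand mean 32.2) are
  the magnitudes of a well-replicated single-site standard-management
  herbage trial. Harvest counts per trial are a free parameter: they vary
  widely between real trials and there is no single canonical value.
* **GBS reads** (`simulate_gbs_reads()`): per-cell depth is Poisson
  (negative-binomial if `depth_dispersion > 0`) with mean depth default 3;
  alternate read counts are Binomial(depth, dosage/2); depth 0 is the only
  representation of missingness. An optional `missing_target` adds
  dropout beyond what the depth law implies, mimicking restriction-site
  polymorphism.

What the generator does **not** emulate: linkage and recombination (SNPs
are in linkage equilibrium within populations, so simulated LD decay
curves are driven by the injected functional form, not by population
history), non-additive genetic effects, selection over generations,
spatial autocorrelation beyond row/column effects, allele-specific
sequencing bias, and endophyte or other biological covariates. Passing
tests therefore demonstrate that each estimator recovers the quantities
it targets *under its own model assumptions at realistic scale*; they do
not certify performance on real data whose violations of those
assumptions are the interesting part.

## GBS genotypes, filters, imputation

Dosage counts the alternate allele; allele frequencies are always
computed from the data rather than read from the VCF, because the
frequency-centred `Z` matrix makes the orientation cancel but a single
convention must be fixed. Missingness is representable only as depth 0 or
an explicit `NA` — never a sentinel dosage.

The Hardy–Weinberg disequilibrium statistic is
`D = P(hom alt) − p²` from presence/absence calls. At low depth these
calls under-count heterozygotes, biasing `D` upward; the statistic is
nevertheless computed exactly this way and the training threshold
(−0.05) applied as such, because the depth-aware variant used by
specialist GBS software is not publicly specified. The practical
consequence is that the HW filter is slightly conservative at depth ~3
(it removes marginally fewer heterozygote-excess SNPs than a
depth-corrected statistic would).

Two named filter stacks are provided. The `training` rules retain a SNP
iff missing ≤ 0.50, MAF > 0.05, mean depth > 1 and `D` > −0.05. The `ld`
rules additionally require missing < 0.25 and mean depth > 20 and
`D ≥ −0.8·MAF²`; the stringent depth rule is applied exactly as stated
even though it discards most of a depth-3 panel — LD estimation is the
one analysis where per-genotype uncertainty compounds across SNP pairs,
and restricting to deep SNPs is what makes the hard-call approximation
below defensible. All rules are conjunctive, so filtering is idempotent
and order-independent; a SNP with undefined statistics fails every rule.

Mean imputation fills missing cells with the SNP's mean non-missing
dosage. It is the simplest of the standard marker-imputation strategies
and the natural partner of a frequency-centred GRM: imputed cells
contribute exactly zero to `Z`, so imputation never manufactures
relatedness.

## Relatedness

`standard_grm()` is the frequency-centred cross-product
`ZZᵀ/(2Σp(1−p))` on a complete (imputed) matrix; monomorphic SNPs are an
error because they contribute nothing to the numerator but would be
silently wrong in the denominator. An optional `allele_freq` argument
substitutes reference frequencies — used when extending a training GRM to
selection candidates so the training block is unchanged.

`kgd_grm()` estimates relatedness directly from read counts. Read-ratio
dosages `x̂ = 2·alt/depth` are unbiased for the true dosage, and reads of
distinct individuals are independent, so off-diagonals are unbiased with
no correction; each pair is normalised by `2Σpq` over exactly the SNPs
observed in both individuals, which handles zero-depth missingness
without imputation. Diagonals are where low depth bites: `E[(x̂−2p)²]`
exceeds `(x−2p)²` by the binomial sampling variance `x(2−x)/d`. For
depth ≥ 2, `x̂(2−x̂)/(d−1)` is an unbiased estimate of that variance, so
the per-SNP diagonal contribution `(x̂−2p)² − x̂(2−x̂)/(d−1)` is unbiased
for the true squared deviation; depth-1 cells are excluded from the
diagonal (the correction is undefined there). This contract — defined by
unbiasedness under the binomial read model and validated by simulation
(depth-2 HWE data: naive mean diagonal ≈ 1.33, corrected ≈ 1.0) — is
deliberately not tied to matching any external implementation.

Allele frequencies for the depth-adjusted estimator default to the
pooled read-ratio mean. A caveat worth knowing: frequencies estimated
from the sample centre relatedness on the *sample mean*, shifting every
entry by O(1/n). That shift is a property of frequency estimation, not of
the depth adjustment, so the package's pedigree-based validation supplies
the known simulation frequencies via `allele_freq` to isolate the depth
correction; with sample frequencies the same check would need a bias
allowance of a few thousandths at n = 200. Whether pooled or
per-population frequencies are more appropriate for a structured training
set is a genuine modelling choice the caller controls.

`grm_mds()` is classical metric MDS of `1 − S` (double-centred −½D²,
eigendecomposition), axes ordered by decreasing eigenvalue, two axes by
default — sufficient to separate five populations at F~ST~ = 0.1 and the
standard way to spot mislabelled samples (replicated controls must land
on top of each other).

## Variance components, repeatability, clustering

`fit_varcomps()` fits a Gaussian mixed model with independent random
effects by REML. The engine is EM with average-information (AI)
acceleration: after two burn-in iterations it attempts a Newton step
using the analytic REML score (from the standard mixed-model-equation
trace identities) and the AI matrix built from the working vectors
`Z_k û_k/σ²_k` and the residual; whenever the proposed step leaves the
parameter space or would reduce the likelihood it falls back to the
plain EM update, which is always admissible and monotone. Convergence
requires both a relative log-likelihood change below `tol` (default
1e-8) and a relative parameter change below 1e-7; variance floors at
~1e-9 of the phenotypic variance keep the equations finite at the
boundary, and estimates at the floor are reported as 0. The monotone
trace is exposed (`$loglik_trace`) and asserted in the tests. The
log-likelihood includes its constants, so it is directly comparable with
other REML software (the tests check agreement with lme4 to 1e-5).
Standard errors come from a central-difference Hessian of the REML
log-likelihood at the converged estimates.

Interaction terms are refused by name when their environmental factor has
a single level (a `family:year` effect is not identifiable from one
year). Significance of a component uses the likelihood-ratio test with
the boundary-corrected null — an equal mixture of a point mass at zero
and χ²₁ — so p = 0.5·P(χ²₁ ≥ 2ΔlogL).

The two-stage structure (stage 1: family BLUPs per trait; stage 2:
genomic prediction on those BLUPs) mirrors how multi-environment breeding
data are actually analysed; a single-stage genotype-in-mixed-model
variant is deliberately out of scope.

Family-mean repeatability
`R = σ²_g/(σ²_g + Σ σ²_k/n_k + σ²_ε/d_ε)` takes its interaction terms
and divisors from the caller rather than hard-coding them: the correct
divisors depend on each trial's replicate/harvest/year structure, and no
single default is right across trials. The same divisor algebra yields
the among-family phenotypic SD `σ_PF` for the gain equations — one
implementation, used twice, kept consistent by construction.

`cluster_families()` follows the classical recipe for grouping families
by environment response: complete-linkage agglomeration on squared
Euclidean distances between BLUP profiles, with the optimal cluster count
the smallest k whose Hartigan statistic `(W_k/W_{k+1} − 1)(n − k − 1)`
drops to ≤ 10. Zero within-cluster sums of squares are handled explicitly
(identical profiles give k = 1).

## Genomic prediction

GBLUP is implemented as the animal model `y = μ + g + e`,
`g ~ N(0, σ²_u G)` with `G` n×n — the model the standard genomic-BLUP
software actually computes, even where the literature writes the display
in marker-effect notation. The variance ratio `δ = σ²_e/σ²_u` is
profiled by REML through one spectral decomposition of the projected
training GRM and a 1-D optimisation on the log scale (tolerance 1e-10),
bounded to log δ ∈ [−12, 12]: beyond those bounds the criterion is flat
to machine precision while the downstream linear systems become
numerically singular, so the bound changes no estimate that the data can
distinguish and protects the solves. Predictions extend by conditional
expectation, `G₍v,t₎(G₍t,t₎ + δI)⁻¹(y − μ̂)` with the GLS mean; GEBVs are
reported centred (add `$mu` for the phenotypic scale).

A training block whose smallest eigenvalue is below −1e-8 (genuinely
non-PSD, as a noisy depth-adjusted matrix can be) is stabilised by adding
1e-6 to the diagonal. PSD-but-singular blocks — routine whenever the
matrix is frequency-centred or contains duplicates — are left untouched:
`δ > 0` already regularises them, and perturbing the diagonal would break
the exact ridge/GBLUP correspondence that anchors the test suite.

Ridge regression solves `(ZᵀZ + λI)u = Zᵀ(y − μ̂)` on training-centred
markers. Three shrinkage policies: caller-fixed λ; an internal k-fold
grid search; and the REML-equivalent λ = `2Σpq · δ` taken from a GBLUP
fit on the GRM built from the same matrix, which makes ridge and GBLUP
GEBVs identical (the push-through identity) — the module's central
correctness oracle, asserted to 1e-6 on random 50×500 instances. Both λ
policies are provided because published analyses rarely state which one
their software used.

Arbitrary regressors (random forests and the like) enter through a
minimal fit/predict plug-in contract rather than being reimplemented or
imported: the cross-validation engine stays method-agnostic, a trivial
mean-predictor reference implementation ships with the package, and
contract violations surface as adapter errors that flag (not crash) a CV
replicate.

## Cross-validation

Two schemes. *Tenfold*: per replicate a fresh random partition into ten
near-equal folds (sizes differ by at most one); each fold predicted from
the other nine; predictive ability is the Pearson correlation between
the pooled held-out GEBVs of the replicate and the observed BLUPs —
pooled rather than averaged over folds, matching the convention of one
GEBV per genotype per replicate. *Balanced-target*: training is a random
50% of the target population plus equal-sized draws from every other
population; validation is the remaining half of the target only, so the
predicted population is represented equally in both sets.

Partitions are pure functions of (seed, replicate index), generated up
front by `cv_partitions()` so competing methods run on *identical*
partitions — the condition under which the two-way method × trait ANOVA
of per-replicate PAs (fixed effects, interaction, the standard factorial
degrees of freedom) is a fair comparison. Bias is the OLS slope of GEBV
on BLUP (1 = unbiased). Zero-variance predictions yield PA 0 with a
warning rather than NaN; a model failure inside any fold flags the whole
replicate and excludes it from the summary with a warning.

## LD decay

Composite (Hill–Robertson style) `r²` between within-scaffold pairs,
over the individuals non-missing at both SNPs, whose count `n` is stored
per pair. Input dosages are either hard calls or posterior-mean dosages
under the binomial read model with a uniform genotype prior
(`use = "posterior"`). The depth-aware likelihood used by specialist GBS
software is unpublished; posterior-mean dosages are this package's
documented approximation, and it is an acceptable one here precisely
because the `ld` filter stack keeps only SNPs with mean depth above 20,
where hard calls, posterior means and any depth-aware likelihood
coincide for practical purposes. Quadratic pair growth is capped by
seeded subsampling (`max_pairs`).

The decay curve `E(r²) = 1/(α + 4βd) + 1/n` is fitted by bounded
nonlinear least squares (`nls`, port algorithm, α > 0, β ≥ 0, 200
iterations). Starting values: α₀ = 1/median(r² − 1/n) clipped positive;
β₀ from the contrast of the near- and far-distance halves. The `+1/n`
term is the sampling floor — unlinked SNPs have E(r²) ≈ 1/n, a property
the tests verify directly. `distance_at_r2()` inverts the curve in
closed form at a caller-supplied reference `n`; the reference must be
explicit because `n` varies per pair and no single value is canonical.
β = 0 returns an infinite-distance flag rather than an error.

## Genetic gain

Selection intensities use the infinite-population formula
`k = φ(Φ⁻¹(1−p))/p`, which reproduces the working values 1.40 (top 20%),
2.06 (5%), 2.27 (3%) and 2.67 (1%) at two decimals; no finite-sample
correction is applied. Family selection gains
`ΔG = k_f c (¼σ²_A)/σ_PF` with parental control c = 0.5 for half-sib
families; within-family genomic selection adds
`k_w c_w h_X r (√3/2)σ_A`, linear in the predictive ability `r`, because
the within-family additive SD of a half-sib family is `√(¾σ²_A)` (an
identity the tests assert algebraically). Throughout, a published
family-level variance component is interpreted as ¼σ²_A — the
among-half-sib-family share of additive variance — so σ²_A enters the
equations as four times the trial's family component; this is the
interpretation under which the within-family and among-family terms are
mutually consistent.

`scenario_grid()` evaluates the cross of predictive abilities and
within-family intensities against the family-selection baseline. It has
a calibration mode pinning the baseline percentage and the within-family
increment scale to two supplied anchor percentages: variance-component
tables are published rounded, percentage gains are computed from
unrounded estimates, and two anchor points recover the exact linear
within-family scale without access to the original unrounded components.
Component mode and calibrated mode agree in structure; they differ
numerically by exactly the rounding of the published inputs.

## Pipeline

`validate_config()` merges a nested config (list or YAML) over defaults,
rejects unknown keys, range-checks every parameter and aggregates all
problems into one error. `run_pipeline()` executes the stages in
dependency order, handing results between stages as plain TSV/VCF files
so each stage is independently inspectable and re-usable on real data,
and returns a manifest of outputs, MD5 checksums and timings; identical
configs reproduce identical checksums. The demo configuration (five
populations × 60 parents, 3000 SNPs, one environment) runs in well under
a minute.

## Problem sizes and determinism

All randomness flows from one integer seed through deterministic
per-stage substreams, so every simulated byte is reproducible and
partitions can be regenerated independently of execution order. The test
suite runs its stochastic checks at sizes chosen to make their
Monte-Carlo error small relative to the tolerance being asserted while
keeping the suite fast: 10⁴ SNPs × 200 individuals for the depth-bias
checks, 108 families × 3 replicates × 8 harvests × 20 seeds for
variance-component recovery, 5×10⁴ pairs × 20 seeds for noisy LD
recovery. These sizes are the package's own choices for a desk-scale
validation; scaling any of them up sharpens the checks without changing
their logic.

## Known limitations

* The residual-row-column model covers within-replicate spatial trends
  only; no autoregressive spatial correlation.
* Single-trait REML; no multi-trait or factor-analytic variance
  structures.
* The depth-adjusted GRM assumes reads within a cell are conditionally
  iid Binomial given the genotype — allelic sequencing bias or
  PCR-duplicate clustering would violate it.
* LD estimation ignores phase (composite r² only, no D′), and
  inter-scaffold LD is out of scope.
* Gain prediction is single-cycle and deterministic: no drift, no
  reduction of variance under selection, no economic weighting of traits.
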