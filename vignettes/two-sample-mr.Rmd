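---
title: "Two-sample Mendelian randomization with mrkit: models, conventions, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-sample Mendelian randomization with mrkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

Two-sample Mendelian randomization treats genetic variants as instrumental
variables for an exposure. For SNP $j$, let $\gamma_j$ be its true per-allele
effect on the exposure and $\Gamma_j$ its effect on the outcome (log-odds
scale for a binary outcome). If the variant is a valid instrument —
relevant, independent of confounders, and affecting the outcome only
through the exposure — then $\Gamma_j = \theta\,\gamma_j$, where $\theta$
is the causal effect. With summary estimates
$(\hat\beta_{Xj}, \hat\beta_{Yj})$ and standard errors from two
non-overlapping GWAS, each SNP supplies a Wald ratio
$\hat\theta_j = \hat\beta_{Yj}/\hat\beta_{Xj}$, to first order distributed
around $\theta$ with standard error
$\sigma_j = \mathrm{se}(\hat\beta_{Yj})/|\hat\beta_{Xj}|$.

The pooled estimators differ in how they spend the validity assumptions:

* **fe-IVW** pools the ratios with weights $w_j = \sigma_j^{-2}$. It is
  efficient when *all* instruments are valid and is algebraically the
  weighted least-squares slope of $\hat\beta_Y$ on $\hat\beta_X$ through
  the origin with weights $\mathrm{se}(\hat\beta_Y)^{-2}$ (tested as an
  exact equivalence).
* **mre-IVW** keeps the fe-IVW point estimate but inflates its standard
  error by the residual scale $\sqrt{Q/(k-1)}$, a multiplicative
  random-effects model for balanced heterogeneity.
* The **weighted median** is consistent when instruments carrying at least
  half the total weight are valid; its standard error comes from a
  parametric bootstrap.
* **MR-Egger** adds an intercept to the weighted regression. Under the
  InSIDE assumption (instrument strength independent of direct effects),
  the slope remains consistent under directional pleiotropy, and the
  intercept estimates the average direct effect — its test is the
  pleiotropy diagnostic.

## Workflow and parameters

`run_pipeline()` executes the stages in the standard order; each stage is
also exposed as a function. The tunable parameters, their defaults, and the
reasoning:

| parameter | default | meaning |
|---|---|---|
| `p_threshold` | 5e-8 | genome-wide significance screen (strict `<`) |
| `maf_min` | 0.01 | minor-allele-frequency floor (strict `>`) |
| `clump_r2_max` | 0.001 | maximum tolerated LD between retained instruments |
| `clump_window_kb` | 10000 | physical window within which LD is considered |
| `f_min` | 10 | weak-instrument F threshold |
| `ambiguity_window` | 0.08 | palindromic SNPs with EAF in [0.42, 0.58] are unresolvable |
| `n_boot` | 1000 | weighted-median bootstrap replicates |
| `n_sim` | 1000 | MR-PRESSO simulated replicates |

All threshold comparisons are strict inequalities, matching how the
criteria are conventionally stated ("p < 5×10⁻⁸", "MAF over 0.01"); the
edge cases are pinned by tests. Clumping is greedy on ascending p-value
with ties broken by (chromosome, position) so results are deterministic.

Instrument strength uses $R^2 = \hat\beta^2/(\hat\beta^2 + N\,\mathrm{se}^2)$
and $F = R^2(N-2)/(1-R^2)$. The $R^2$ form is the standard reduction: the
allele-frequency factor $2\,\mathrm{EAF}(1-\mathrm{EAF})$ multiplies both
the signal and the noise term and cancels, so $R^2$ does not depend on EAF
(a property the tests assert). A `formula = "verbatim"` switch reproduces a
commonly mis-typeset variant of the expression for auditing only; it is not
used anywhere in the pipeline.

### Harmonization rules

Effect alleles are aligned in a fixed resolution order: direct match;
swapped alleles (negate the outcome beta, reflect its EAF); complementary
strand, then direct or swapped; palindromic SNPs last. For a palindromic
SNP (A/T or C/G) strand cannot be inferred from the alleles, so the pair is
oriented by allele-frequency concordance — but only when both EAFs are
outside the ambiguity window around 0.5; otherwise, and whenever an EAF is
missing, the SNP is dropped as unresolvable. The window half-width of 0.08
is a conventional operating point for "intermediate allele frequency";
it is a config parameter because cohorts with well-matched ancestries can
justify a narrower window. Duplicated SNP ids in either dataset are dropped
(a duplicated id means the extraction returned conflicting records), and
instruments absent from the outcome are reported as such. The status counts
always sum to the number of instruments offered — the conservation is
asserted at run time and property-tested on fuzzed datasets.

### Unknown LD

An LD lookup distinguishes "pair not measured" (`NA`) from "independent"
(r² = 0). During clumping, unknown LD within the window retains the SNP by
default — the practical reading when no reference panel is bundled — while
`strict_ld = TRUE` drops such SNPs instead. Silently mapping unknown to 0
would make clumping claim independence it cannot know.

## Numerical choices

* **Ratio SEs** are first-order delta method (`se_y/|beta_x|`), the common
  two-sample convention; a `second_order` flag adds the
  $\hat\beta_Y^2\mathrm{se}_X^2/\hat\beta_X^4$ term.
* **Residual scales** in mre-IVW, Egger, and multivariable IVW are
  truncated below at 1, so random-effects intervals are never narrower
  than fixed-effects ones under underdispersion (flag `truncate_scale`).
* **Reference distributions**: normal for IVW and the weighted median,
  $t_{k-2}$ for Egger ($t_{J-E}$ for multivariable IVW), reflecting the
  estimated residual scale in the regression-based methods.
* **Orientation**: Egger and the weighted-median bootstrap first orient
  every pair to $\hat\beta_X \ge 0$. For Egger this is required for
  identifiability under allele recoding; for the bootstrap it makes the
  resampled draws — and hence the SE — exactly recoding-invariant. All
  estimators are tested to be invariant to simultaneous sign flips of any
  SNP's effects.
* **Monte-Carlo p-values** (MR-PRESSO) use the add-one form
  $(1 + \#\{T^* \ge T\})/(n_{\mathrm{sim}}+1)$ and can never be zero.
  Per-SNP outlier p-values are Bonferroni-multiplied by $k$, which couples
  the simulation count to the instrument count: the smallest attainable
  adjusted p is $k/(n_{\mathrm{sim}}+1)$, so calling outliers at 0.05
  among 117 instruments needs $n_{\mathrm{sim}} > 117/0.05 = 2340$. The
  validation runs therefore use 5000 replicates for outlier detection and
  1000 for the global test, which needs no per-SNP resolution.
* **Degenerate inputs**: pairs with $\hat\beta_X = 0$ have no defined
  ratio and are excluded with their ids recorded; estimators check their
  minimum instrument counts (1 for fe-IVW, 2 for mre-IVW, 3 for the
  median and Egger, 4 for MR-PRESSO, $J > E$ for multivariable IVW) and
  collinear designs raise errors naming the offending exposures.
* **I² labels** use the four conventional intervals — [0, 25) low,
  [25, 50) moderate, [50, 75) large, [75, 100] extreme.

## Multivariable MR

`mvmr_harmonize()` builds the joint instrument set as the union of each
exposure's genome-wide-significant SNPs, jointly clumped using the minimum
p-value across exposures, restricted to SNPs present in every dataset, and
oriented to the first exposure's alleles. `mvmr_ivw()` then fits weighted
least squares of the outcome effects on the $J \times E$ exposure-effect
matrix without an intercept; each coefficient is that exposure's direct
effect conditional on the others. When adjusting for several covariates the
pipeline fits one two-exposure model per covariate (exposure + covariate),
the reading under which adjusted estimates are usually reported; a joint
model is available by passing all exposures to `mvmr_harmonize()` at once.
Binary covariate GWAS are treated like continuous ones on the beta scale.

## Power

For a binary outcome the package uses the standard normal approximation
implemented by the online MR power calculators:
$\mathrm{power} = \Phi\!\left(\sqrt{N R^2 K(1-K)}\,|\ln \mathrm{OR}| -
z_{1-\alpha/2}\right)$, inverted in closed form for the detectable OR at a
target power, so `or_low * or_high = 1` exactly and the power/detectable-OR
round trip holds to numerical precision (both tested). This is an
approximation: it ignores the attenuation of the observed log-OR under the
two-stage model, so it is mildly optimistic for strong effects.

## The synthetic-data generator

`simulate_two_sample()` emulates the statistical structure that
summary-level MR assumes, not individual-level genetics. Under
standardized-trait scalings, per-SNP instrument effects $\gamma_j$ are
drawn and rescaled so the instruments jointly explain `total_r2` of
exposure variance; sampling noise follows the analytic forms
$\mathrm{se}_X = 1/\sqrt{2p(1-p)N_X}$ and, on the log-odds scale,
$\mathrm{se}_Y = 1/\sqrt{2p(1-p)N_Y K(1-K)}$; the outcome mean is
$\theta\gamma_j + \alpha_j$ with the direct effects $\alpha_j$ drawn as
none, balanced (mean zero), directional (non-zero mean), or correlated
with $\gamma_j$ (an InSIDE violation). A configurable fraction of outcome
records is re-presented with swapped alleles and/or on the complementary
strand, which harmonization must undo; optional LD blocks append tagged
satellite SNPs with a pairwise r² table; a confounder table marks a chosen
subset of instruments.

The defaults are the study conditions the package validates against:
117 instruments, an exposure GWAS of 218,796 individuals, a biobank-scale
binary outcome GWAS (218,792 individuals, case fraction 0.145 — chosen as
realistic for a large case-control ischemic-heart-disease GWAS, whose case
fraction is not part of the summary export), causal effect
$\theta = \ln 0.80$, total instrument $R^2 = 0.04$, MAF uniform on
[0.05, 0.5], 20% palindromic SNPs, 30% scrambled outcome orientation, and
pleiotropy SD 0.01 (the order of the per-SNP outcome standard error at
these sample sizes). Simulator p-values are floored at the smallest
normalized double so extreme associations never underflow to an invalid
p = 0. All randomness flows through one seed; replicate indices are folded
in deterministically via `replicate_seed()`.

What the generator does *not* emulate — and hence what passing tests do not
establish about real data: winner's curse from selecting instruments in the
same sample, sample overlap between the two GWAS, realistic genome-wide LD
structure, population stratification, and effect heterogeneity across
strata. Results on simulated data validate the estimators' algebra and
calibration under their own assumptions, not robustness to these realities.

## Validation at desk scale

The acceptance suite (and `scripts/acceptance.R`) validates, with fixed
problem sizes chosen to make Monte-Carlo bands tight while keeping the
suite quick to run:

* analytic chi-square heterogeneity values at Q = 160.5 on 116 df
  (p ≈ 0.004, I² ≈ 27.7%, "moderate");
* exact agreement (1e-10) of fe-IVW, Egger, and multivariable IVW with
  brute-force weighted-least-squares oracles, and of the weighted median
  with its interpolation definition on hand-traced fixtures;
* type-I error of fe-IVW (θ = 0, no pleiotropy) and of the Egger intercept
  test (balanced pleiotropy) over 500 replicates of 100-instrument
  studies;
* recovery of OR 0.80 and nominal CI coverage over 200 replicates at the
  default study conditions;
* MR-PRESSO detection of a 10-SE injected outlier over 100 runs and global
  null calibration over 200 runs;
* bit-identical estimates when the outcome table's allele orientation is
  scrambled for half the SNPs, and exact palindromic-ambiguity drops;
* the power/detectable-OR identities.

## Known limitations

Beyond the generator's scope above: no Steiger directionality filtering,
no proxy-SNP substitution for instruments missing in the outcome (they are
dropped), no reference-panel LD computation (LD must be supplied as a
table), no MR-PRESSO distortion test, no mode-based or robust-regression
estimators, and no conditional F-statistics for multivariable MR. The
power formula is the unattenuated normal approximation. Harmonization is
defined for biallelic SNPs only; indels and multi-allelic records are
dropped at read time with a tally.
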