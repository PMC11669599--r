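---
title: "Two-step mediation Mendelian randomization with medmr: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-step mediation Mendelian randomization with medmr: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(medmr)
```

## The causal model

medmr implements two-sample Mendelian randomization (MR) from GWAS summary
statistics, extended to two-step mediation. Genetic variants serve as
instrumental variables under the three IV assumptions: *relevance* (the
variant is associated with the exposure), *exclusion* (it affects the
outcome only through the exposure) and *independence* (it is not associated
with confounders of the exposure–outcome relation). Because alleles are
assorted at conception, estimates are protected from classical confounding
and reverse causation — to the extent the assumptions hold, which summary
data can probe but never prove.

For an exposure $X$, a candidate mediator $M$ and an outcome $Y$
(binary, analysed on the log odds-ratio scale), three MR estimates are
combined by the product-of-coefficients rule:

* $\beta_1$: effect of $X$ on $M$ (step 1),
* $\beta_2$: effect of $M$ on $Y$ (step 2),
* total effect of $X$ on $Y$,

with

$$\text{mediated} = \beta_1 \beta_2, \qquad
  \text{direct} = \text{total} - \text{mediated}, \qquad
  \text{proportion} = \frac{\beta_1 \beta_2}{\text{total}}.$$

The mediated effect's standard error is the Sobel delta-method form
$\sqrt{\beta_2^2 \, se_1^2 + \beta_1^2 \, se_2^2}$, and the proportion's
treats the mediated and total effects as independent:
$|\hat p| \sqrt{se_{med}^2/\text{med}^2 + se_{tot}^2/\text{tot}^2}$.
Both derive from overlapping outcome data, so the independence is an
approximation; when the mediated effect is within one standard error of
zero the ratio delta method is unreliable and `two_step_mediation()`
labels the interval unstable and can substitute a seeded parametric
bootstrap over the three coefficients. All arithmetic is done on the
log(-OR) scale; odds ratios are exponentiated for display only.

```{r}
two_step_mediation(list(beta = log(0.960), se = 0.0149),
                   list(beta = log(1.218), se = 0.0552),
                   list(beta = log(0.952), se = 0.0228))
```

## Instrument selection

`select_instruments()` applies three filters in order, logging counts at
each stage:

1. **Association screen**: keep variants with $P$ strictly below a
   threshold. Genome-wide significance ($5\times10^{-8}$) is used where
   instruments are plentiful (e.g. a disease GWAS feeding reverse MR);
   weakly powered molecular traits commonly use $10^{-5}$, which is the
   default here.
2. **LD clumping** (`clump()`): greedy index selection — repeatedly take
   the remaining variant with the smallest p-value, remove all variants
   within 10\,000 kb on the same chromosome with $r^2 > 0.001$ against it.
   P-value ties are broken by (chromosome, position, id) so the output is
   invariant to row order. The LD matrix is an explicit input; variants
   absent from it are treated as unlinked, with a warning, since no
   reference panel is bundled.
3. **Strength filter**: per-variant
   $F = R^2 (n - k - 1) / [k (1 - R^2)]$ with $k = 1$, where $R^2$ is
   $2p(1-p)\beta^2$ for a standardized trait (or
   $\beta^2/(\beta^2 + n\,se^2)$ when the allele frequency is missing);
   variants with $F < 10$ are dropped as weak. The filter is applied
   per variant because weakness is a per-instrument property; the
   overall-set $F$ (with $k$ = number of instruments) is reported for
   information.

Fewer than `min_snps` (default 3) survivors raises a classed
`medmr_underpowered` condition rather than returning silently, so screens
across hundreds of exposures can skip and log.

## Harmonization

`harmonize()` matches variants by id (the data sources this package
targets share rsIDs; positional matching is out of scope), aligns the
outcome effect to the exposure's effect allele (negating the outcome beta
and complementing its allele frequency when the allele pair is swapped),
and drops variants whose allele sets cannot be reconciled. Palindromic
variants (A/T, C/G) carry no strand information in their allele labels and
are removed unconditionally by default — no frequency-based rescue is
attempted, because inferring strand from allele frequency near 0.5 is
error-prone. Harmonization is idempotent and flip-antisymmetric, both
property-tested.

## The five estimators

All estimators start from per-variant Wald ratios
$\hat\theta_j = \hat\beta_{Y,j}/\hat\beta_{X,j}$ with first-order standard
errors $\sigma_j = se_{Y,j}/|\hat\beta_{X,j}|$ (exposure-side uncertainty
ignored — the standard two-sample convention, adequate when instruments
pass the $F \ge 10$ screen) and weights $w_j = \sigma_j^{-2}$.

* **IVW** — $\hat\theta = \sum w_j \hat\theta_j / \sum w_j$, the headline
  estimator. The default error model is multiplicative random effects:
  the fixed-effect SE $(\sum w_j)^{-1/2}$ is inflated by
  $\max(1, \sqrt{Q/(J-1)})$, so the model reduces to fixed effects for
  homogeneous instruments instead of rewarding under-dispersion.
* **MR-Egger** — weighted regression of outcome on exposure effects *with*
  an intercept, after orienting exposure effects non-negative. The
  intercept estimates average directional pleiotropy; the slope remains a
  consistent causal estimate under the InSIDE assumption even when the
  average pleiotropic effect is nonzero.
* **Weighted median** — the 50% point of the weight-ordered ratios with
  linear interpolation of the centred cumulative weights; consistent while
  valid instruments carry a majority of weight. Its SE comes from a
  parametric bootstrap redrawing $\hat\theta_j \sim N(\hat\theta_j,
  \sigma_j)$, 1000 replicates, mandatory seed.
* **Weighted and simple mode** — the argmax of a Gaussian-kernel-smoothed
  density of the ratios (bandwidth $0.9\,\min(sd, IQR/1.349)\,J^{-1/5}$
  times a user factor, maximized over a fixed 512-point grid spanning the
  ratio range $\pm 3$ bandwidths, so the argmax is deterministic);
  consistent when the largest cluster of instruments is valid. When all
  ratios coincide the density is degenerate and the common value is
  returned.

P-values and 95% intervals use the normal approximation (the 1.96
quantile) throughout, including the Egger slope and intercept. This keeps
every interval exactly $\pm 1.96\,se$, at the cost of mild anti-
conservatism for Egger at small $J$ compared with a t reference.

`mr_all()` runs all five and sets a consistency flag when the five point
estimates share one sign — the screening convention for "the auxiliary
methods agree with IVW"; no stricter criterion is imposed because sign
agreement is what a forest plot shows.

## Sensitivity battery

* **Cochran's Q** (`cochran_q()`): $\sum w_j(\hat\theta_j -
  \hat\theta_{IVW})^2$ around the *fixed-effect* center (the standard
  definition, whatever error model the headline estimate uses), referred
  to $\chi^2_{J-1}$.
* **Egger intercept test**: two-sided normal test of zero average
  directional pleiotropy; reported as a p-value, not a binary verdict.
* **MR-PRESSO** (`mr_presso()`): for each variant, the fixed-effect IVW
  estimate computed without it predicts that variant's outcome effect.
  The observed residual sum of squares is compared with a null
  distribution obtained by redrawing every outcome effect from
  $N(\hat\theta_{(-j)}\hat\beta_{X,j}, se_{Y,j})$ and recomputing the
  statistic, `n_sim` times under a fixed seed (global test). Each
  variant's squared residual against its simulated distribution gives the
  outlier test, Bonferroni-corrected across variants. Because the
  empirical p-value cannot fall below $1/(n_{sim}+1)$, outlier detection
  requires $n_{sim} > J/\alpha$; the function warns when the setting
  cannot resolve any outlier. When outliers are found, an
  outlier-corrected IVW estimate is returned together with a distortion
  test: the corrected-minus-full shift is compared against shifts from
  removing random variant subsets of the same size (an empirical
  two-sided p). The default of 1000 simulations keeps desk-scale runs
  fast; raise it for large instrument sets.
* **Leave-one-out** (`leave_one_out()`): IVW with each variant removed; a
  variant is flagged dominant when its removal flips the estimate's sign
  or moves the p-value across 0.05.

`bonferroni_threshold()` and `classify_pvalue()` encode the multiple-
testing rule for screens of $N$ traits: below $0.05/N$ is significant
after correction, between $0.05/N$ and $0.05$ is *suggestive* (to be
interpreted with caution), otherwise null.

## Pipeline decisions

`run_forward()` chains selection → harmonization → estimation → battery
and assigns a verdict. Two points were genuinely open and are resolved as
follows:

* **Outlier correction before the verdict.** When MR-PRESSO flags
  outliers, they are pruned and the estimates and battery recomputed once
  (`presso_correction = TRUE`); `failed_sensitivity` is assigned only if
  pleiotropy evidence persists (global PRESSO p or Egger intercept p
  below $\alpha$ on the final set). Discarding a trait whose pleiotropy
  is fully attributable to removable outliers would waste exactly the
  correction MR-PRESSO provides. Set `presso_correction = FALSE` for the
  stricter uncorrected verdict.
* **Shared instruments in the mediator leg.** In
  `run_mediation_study()`, variants that instrument the exposure are
  excluded from the mediator's instrument set (`exclude_shared = TRUE`).
  An exposure instrument reaches the outcome through the exposure's
  direct path as well as through the mediator, so its mediator-leg Wald
  ratio estimates $\theta_{direct}/\alpha + b$ rather than $b$ — a bias
  that also masquerades as heterogeneity. The exposure's associations
  *with* the mediator are of course retained for step 1.

The mediation report keeps the exact identities
mediated + direct = total and proportion × total = mediated on every row,
ranks pairs by absolute mediated proportion, and annotates each pair with
reverse-MR guards: the pipeline re-runs MR from the outcome (instruments
at genome-wide significance) to the exposure and to the mediator, and
marks the pair unidirectional only when both reverse tests are null. Too
few outcome instruments make a guard *indeterminate*, never a pass.

## The synthetic generator

`simulate_triplet()` generates summary statistics directly — no
individual-level genotypes — for three non-overlapping cohorts, matching
the two-sample design's no-overlap assumption. Defaults emulate the
motivating data sources: a quantitative immune-cell trait GWAS of
$n = 3757$, a quantitative plasma-metabolite GWAS of $n = 8299$, and a
binary disease outcome with 3597 cases and 364\,071 controls analysed on
the log-OR scale.

Per-variant true effects are drawn on the standardized scale,
$u_j \sim N(0, \texttt{effect\_sd}^2)$ with `effect_sd = 0.1` — about 1%
of trait variance per instrument, i.e. instrument $F \approx 38$ at
$n = 3757$, strong enough to clear the $10^{-5}$ screen for roughly half
the draws, which is what makes selection behave realistically. The
mediator has its own instrument set of the same strength (as a metabolite
GWAS does) in addition to the $\alpha u_j$ it inherits from the exposure.
Observed effects add independent noise with standard error $1/\sqrt n$ on
the standardized scale for quantitative traits and
$\sqrt{1/n_{case} + 1/n_{control}}$ for the binary outcome (the rare-ish
disease log-OR approximation); per-allele effects divide by
$\sqrt{2p(1-p)}$, with minor-allele frequencies uniform on the configured
range (default 0.05–0.5). Invalid instruments receive an additional
direct outcome effect $\gamma_j \sim N(\mu, \sigma^2_{pleio})$, balanced
($\mu = 0$) or directional ($\mu \ne 0$, violating the zero-mean
pleiotropy that IVW needs while leaving InSIDE intact).

What the generator does *not* emulate: realistic LD (blocks are
block-constant $r^2$ supplied to the clumping step only; sampling noise
across variants stays independent), sample overlap, winner's curse from
discovery-stage selection in the source GWAS, allele-frequency
differences between cohorts, and strand ambiguity (all variants are
generated A/G). Passing tests therefore certify the statistical machinery
under the stated model, not robustness to those real-data complications.

`fixture_small()` is a deterministic 20+20-variant triplet with a planted
path ($\alpha = -0.3$, $b = 0.25$, direct $= -0.04$, true mediated
proportion $\approx 65\%$) and one directionally pleiotropic instrument,
used throughout the test suite.

## Numerical and testing choices

* All stochastic operations (bootstrap SEs, MR-PRESSO, the generator)
  take explicit seeds; child seeds are derived from one master seed, so
  identical configuration and seed reproduce reports byte-for-byte.
* Summary-statistics files are written with `%.17g` formatting: the
  write–read round trip is exact and rewriting is byte-stable.
* The simulation studies shipped with the package use 200 replicates for
  recovery and coverage checks, 1000 for the type-I error of IVW, 100
  seeds for the weighted-median contamination study and 50 for the
  MR-PRESSO spike-in study, with 50 instruments per leg — sizes at which
  the Monte-Carlo error is comfortably smaller than the acceptance bands
  while a full run stays in the minutes range on one core.
* Known limitations: first-order Wald SEs understate uncertainty for
  weak instruments (mitigated by the $F$ filter); the proportion-mediated
  delta method ignores the mediated–total covariance; the Egger normal
  reference is slightly liberal at very small $J$; palindromic removal
  discards information that allele frequencies could in principle rescue.
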