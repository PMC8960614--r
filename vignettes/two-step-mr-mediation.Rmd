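---
title: "Two-step Mendelian randomisation for mediation: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-step Mendelian randomisation for mediation: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrmediate)
```

## The problem

Type 2 diabetes shares many risk factors with atherosclerotic
cardiovascular disease, and is itself a strong risk factor for coronary
and peripheral artery disease. For a risk factor such as fasting insulin
or hip circumference, the question is how much of its effect on
cardiovascular disease runs *through* liability to diabetes (the
indirect, mediated effect) and how much is *direct* (independent of the
mediator). `mrmediate` implements a two-stage summary-statistics pipeline
for that question: bidirectional univariate Mendelian randomisation (MR)
screening of candidate traits against the mediator, followed by
multivariable MR and a product-of-coefficients mediation decomposition.
All inputs are per-variant GWAS association tables from non-overlapping
samples; no individual-level data are used.

## The model

Genetic variants robustly associated with an exposure $X$ (the
*instrument*, here genome-wide significant variants at $p < 5 \times
10^{-8}$ after LD clumping) proxy the exposure. Writing
$\hat\beta_{x,i}$, $\hat\beta_{m,i}$, $\hat\beta_{y,i}$ for variant $i$'s
associations with the trait, the mediator $M$ and the outcome $Y$, the
structural model is linear with no exposure-mediator interaction:

$$ M = \beta_{XM} X + u, \qquad
   Y = \theta_X X + \theta_M M + v. $$

The total effect of $X$ on $Y$ is $\theta_X + \beta_{XM}\theta_M$; the
indirect effect is $\beta_{XM}\theta_M$ and the proportion mediated is
their ratio. Binary traits (the mediator and both outcomes) stay on the
log-odds scale throughout; no liability-scale conversion is applied, and
the non-collapsibility of odds ratios is addressed by re-running with a
linear-model mediator GWAS swapped in, not by rescaling.

### Stage 1: univariate estimators

* **IVW.** The inverse-variance weighted estimate is the no-intercept
  weighted regression of $\hat\beta_{y}$ on $\hat\beta_{x}$ with weights
  $w_i = 1/\mathrm{se}(\hat\beta_{y,i})^2$. Standard errors use a
  multiplicative random-effects model: the fixed-effects SE is scaled by
  $\max\{1, \sqrt{Q/(k-1)}\}$, so heterogeneity widens intervals but can
  never narrow them below the fixed-effects value.
* **MR-Egger.** The same regression with a free intercept; the intercept
  estimates average directional pleiotropy under the InSIDE assumption.
  Inference uses the $t$ distribution on $k-2$ degrees of freedom — the
  small-$k$ case is exactly where Egger is used, and the normal
  approximation is anticonservative there. The $I^2_{GX}$ statistic
  quantifies regression dilution from measurement error in
  $\hat\beta_x$; $(1 - I^2_{GX}) \times 100$ bounds the relative
  attenuation of the slope towards the null (`egger_attenuation()`:
  $I^2_{GX} = 0.93$ bounds it at 7%).
* **Weighted median and modes.** Robust estimators over the per-variant
  ratios $\theta_i = \hat\beta_{y,i}/\hat\beta_{x,i}$; the median is
  consistent when at least half the weight comes from valid instruments,
  the mode when the largest homogeneous cluster is valid. Standard
  errors come from a seeded parametric bootstrap (1000 draws by
  default). All other estimators use the normal approximation with the
  95% multiplier 1.959964.
* **Diagnostics.** Cochran's $Q$ over the ratio estimates, and
  leave-one-out IVW to expose single variants driving a pooled effect.

Instruments are harmonised so every variant's effect allele increases
the exposure before estimation; the Egger intercept is not invariant to
allele coding, so orientation is applied after alignment, as the last
harmonisation step.

### Screening

Each trait is tested in four analysis families: trait→mediator,
mediator→trait, and trait→outcome for each outcome. Within each family,
Benjamini–Hochberg adjustment is applied across traits and *supportive*
evidence means adjusted $p < 0.05$ (strict). This study design does not
by itself pin down whether correction runs within families or jointly; the
default is within-family (`fdr_scope = "family"`), matching per-analysis
FDR phrasing, with a `"joint"` switch. A trait progresses to stage 2 for
an outcome when it is a supportive cause of the mediator, *not* a
supportive consequence of it (bidirectional traits are excluded because
neither phenotype can be designated the exposure), and a supportive
cause of that outcome. Traits whose clumped instrument has fewer than
ten variants are recorded as ineligible rather than silently dropped.

### Stage 2: multivariable MR and decomposition

For each eligible (trait, outcome) pair the union of both exposures'
genome-wide-significant variants is clumped on the p-values of whichever
exposure has the smaller pre-clump instrument set, harmonised three ways,
and fitted by weighted no-intercept regression of $\hat\beta_y$ on
$[\hat\beta_x, \hat\beta_m]$. The trait coefficient is the direct effect
$\hat\theta_X$; the mediator coefficient $\hat\theta_M$ enters the
indirect effect

$$ \widehat{\text{indirect}} = \hat\beta_{XM}\,\hat\theta_M,
   \qquad
   \mathrm{se} = \sqrt{\hat\theta_M^2\,\mathrm{se}_1^2 +
                       \hat\beta_{XM}^2\,\mathrm{se}_2^2}, $$

the sum-of-squares (delta) form with no covariance term — the two
estimates come from separate fits. The proportion mediated is reported
as a point estimate (a delta-method CI is available behind
`proportion_ci = TRUE` but is not the default); values outside $[0,1]$
are flagged, never truncated, because a negative or super-unity
proportion is itself diagnostic. Instrument strength per exposure uses
the conditional $F$ statistic (weighted residual sum of squares of one
exposure's associations regressed on the other's, divided by $L-K+1$),
and heterogeneity uses the modified Cochran's $Q_A$ on $L-K$ degrees of
freedom against the 5% $\chi^2$ critical value. Cross-trait sampling
covariance is fixed at zero: exposure and outcome samples are
non-overlapping by design, and no covariance input is published for
trait-mediator overlap — a documented limitation. Conventions differ
across software for the $F$ denominator and $Q_A$ degrees of freedom, so
both are recorded in the run manifest.

## Harmonisation rules

Variants are matched by identifier only (positions are used solely for
clump windows, 1-based). Outcome alleles equal to the exposure's are
kept; swapped alleles flip the sign and complement the frequency;
alleles matching after strand complement (A↔T, C↔G) are complemented
first. Palindromic variants (A/T, C/G) cannot be disambiguated by
labels, so they are resolved by effect-allele frequency: kept only when
both frequencies are present and outside $[0.5-w,\ 0.5+w]$, with
frequencies on opposite sides of 0.5 read as a strand flip. The
half-width defaults to $w = 0.08$ — a common two-sample MR convention,
not a value the study design dictates — and is configurable; a
palindromic variant with missing frequency is dropped. Drop counts are
carried on the harmonised set and conserved
(`matched = retained + palindromic + incompatible`).

## LD clumping

Greedy index selection: the remaining variant with the smallest p-value
becomes an index, and every remaining variant on the same chromosome
within the window whose $r^2$ with the index exceeds the threshold
(default 0.001) is removed. The stated 10 Mb window is interpreted as
±10 Mb from the index (the convention of the standard clumping tools),
not a 10 Mb total span; the choice is configurable and recorded in the
manifest. Ties on p-value break by chromosome, position, then
identifier, so results are independent of input row order.
Cross-chromosome pairs and variants absent from the LD matrix count as
independent (the latter with a warning). The LD matrix is an input —
computing LD from a reference panel is out of scope.

## The synthetic-data generator

`simulate_study()` draws per-variant true instrument effects
$\gamma_i$ with magnitudes uniform on $[0.03, 0.08]$ and random signs,
gives the mediator its own instruments $\delta_j$, and propagates
associations through the structural model above. Observed associations
add independent noise per GWAS with
$\mathrm{se}_i = 1/\sqrt{n \cdot 2f_i(1-f_i)}$, the standard
approximation for a standardised trait; frequencies are uniform on
$(0.05, 0.95)$ by default. Summary statistics are simulated directly —
no individual-level genotypes — which is sufficient for two-sample MR
and orders of magnitude faster. Allele pairs are palindromic at rate
0.10, and the mediator and outcome tables re-express variants with
swapped alleles (rate 0.20) or on the complementary strand (rate 0.10)
so that harmonisation is always exercised. LD comes in blocks of
configurable size and within-block correlation; both the marginal
associations and the sampling noise respect the block correlation.
Pleiotropic effects are defined per exposure-increasing allele (they are
multiplied by the sign of the instrument effect), so a directional mean
survives harmonisation instead of being scrambled by orientation.

The default causal system — $\theta_X = 0.2$, $\beta_{XM} = 0.3$,
$\theta_M = 0.5$, hence total 0.35 and proportion mediated
$0.15/0.35 \approx 42.9\%$ — is the reference configuration for all
parameter-recovery checks, and the default sample size of 200,000 per
GWAS matches the scale of modern biobank consortia.

What the generator does **not** emulate: genome-wide polygenicity and
MAF-dependent effect-size spectra, realistic LD beyond exchangeable
blocks, sample overlap between trait GWASs, case-control ascertainment,
or population structure. Passing tests therefore demonstrate
correctness of the estimators and decision logic under the stated
model, not robustness to everything real consortium data contain.

## Validation experiments and their sizes

The test suite and `scripts/acceptance.R` recompute the following, with
problem sizes chosen to keep each experiment's Monte-Carlo error well
inside its decision band:

* **Oracle equivalence.** IVW and multivariable IVW against base R's
  weighted least squares on 200 random instances (relative tolerance
  $10^{-10}$); the weighted median against an exhaustive
  cumulative-weight search on up to 7 variants; greedy clumping against
  full subset enumeration on up to 12 variants; BH against the
  brute-force step-up definition on lists up to length 10.
* **Parameter recovery.** 300–500 replicates of the reference system at
  $n = 4\times 10^6$ per GWAS. The large $n$ puts the experiment in the
  asymptotic regime the recovery claim is about: weak-instrument and
  errors-in-variables biases shrink as $1/n$ while Monte-Carlo error
  shrinks as $1/\sqrt{n \cdot \text{reps}}$, so at biobank-scale $n$
  the $1/n$ terms are still comparable to the Monte-Carlo error of a
  500-replicate mean and would confound the comparison.
* **Calibration.** IVW 95% CI coverage under a true null (1000
  replicates; the random-effects floor makes coverage mildly
  conservative, about 96%); Egger intercept type-I error under balanced
  pleiotropy (2000 replicates). The calibration runs fix allele
  frequencies in $(0.35, 0.65)$: when pleiotropy variance dominates the
  outcome sampling variance, $1/\mathrm{se}_y^2$ weights are badly
  misspecified across a wide frequency range and the multiplicative
  overdispersion model no longer matches the residual structure — the
  narrow band isolates the test's calibration from that weighting
  artefact. Realised false-discovery proportion under an all-null
  ten-trait screen (500–1000 replicates) stays at or below 5% up to
  Monte-Carlo tolerance.
* **Decision fidelity.** An engineered six-trait study — one trait
  eligible for both outcomes, one for the first only (its direct effect
  on the second outcome exactly cancels the mediated path), one
  bidirectional, one with a nine-variant instrument, one null on the
  mediator, one null on both outcomes — must reproduce its truth table
  of stage-2 flags exactly. This experiment runs at $n = 10^5$ per
  GWAS: at much larger $n$ the causal path makes trait instruments
  genome-wide significant *in the mediator GWAS*, the reverse analysis
  inherits them, and genuinely unidirectional traits start classifying
  as bidirectional. That is a real property of bidirectional MR
  screening (the same tension the glycaemic traits show in practice),
  not an artefact, and it bounds the sample sizes at which the
  engineered truth table is recoverable.
* **Determinism.** Re-running the pipeline with an identical
  configuration and seed must reproduce every TSV byte for byte and
  every manifest checksum.

One identity deserves a note: total = direct + indirect holds exactly in
the structural model, but in estimates the first-order sampling noise
cancels in the difference, leaving a second-order remainder whose mean
*and* spread both scale as $1/n$. A criterion of the form "mean gap
within Monte-Carlo error of zero" is therefore unattainable at any $n$;
the suite instead asserts the gap is below 10% of the total effect's own
standard error.

## Numerical choices and degenerate inputs

* P-values are floored at the smallest positive double; biobank-scale
  z-scores underflow the normal tail and a literal zero would violate
  the $(0,1]$ contract.
* Mode estimation uses a Gaussian kernel with bandwidth $\varphi$ times
  Silverman's rule (default $\varphi = 1$) and a fixed 512-point grid
  over $[\min\theta - 3h,\ \max\theta + 3h]$; identical ratios return
  that value exactly.
* Variants with $\hat\beta_x = 0$ after orientation are excluded from
  ratio-based estimators (with a warning) but retained for
  regression-based ones.
* A single-variant instrument reduces IVW to the Wald ratio with the
  first-order SE $\mathrm{se}_y/|\hat\beta_x|$.
* An identically-zero mediator column in the multivariable fit returns
  the univariate fit for the trait with an undefined mediator
  coefficient (warning); *proportional* nonzero columns are a
  collinearity error (condition number above $10^8$).
* Estimation failures inside `run_study()` are caught per trait and
  recorded in the manifest; one degenerate trait cannot abort a study.

## Known limitations

No Steiger filtering, MR-PRESSO or contamination-mixture estimators; no
MVMR-Egger or $Q$-minimisation robust MVMR; no modelling of sample
overlap or cross-trait sampling covariance; no liability-scale
conversion. The bidirectionality screen is itself subject to
causal-path contamination at very large sample sizes, as described
above. These boundaries mirror the pipeline's design scope; the module
surfaces make the estimators individually reusable where a different
study design needs them.
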