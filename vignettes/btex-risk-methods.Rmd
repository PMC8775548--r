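---
title: "Methods: probabilistic BTEX inhalation risk assessment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: probabilistic BTEX inhalation risk assessment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(btexrisk)
```

## The problem

Communities downwind of coking and other coal-conversion industries are
chronically exposed to benzene, toluene, ethylbenzene and xylenes (BTEX) by
inhalation. `btexrisk` implements the standard US EPA-style assessment of
that exposure for a non-occupational adult population: deterministic hazard
quotients against inhalation reference concentrations (RfC) and urinary
biological exposure indices (BEI), lifetime cancer risk for benzene via the
chronic-daily-intake pathway, and a Monte Carlo treatment of the
population variability in concentration, inhalation rate and body weight.
Alongside the risk engine it provides the supporting machinery such an
assessment needs: distribution fitting, biomarker normalisation, emission
source diagnostics, and a synthetic generator of study-shaped data.

## Exposure and risk model

Non-cancer screening uses the hazard quotient

$$HQ = \frac{C}{RfC},$$

with $C$ the exposure concentration and $RfC$ the threshold below which
adverse effects are not expected ($HQ < 1$: unlikely concern). For the
benzene metabolites trans,trans-muconic acid (T,T-MA) and
S-phenylmercapturic acid (S-PMA) the comparison value is the ACGIH BEI on
the creatinine-corrected scale, so the same quotient doubles as an
internal-exposure index. HQs of different chemicals are never summed here:
their toxicity endpoints differ (immune system for benzene, nervous system
for toluene and xylenes), so a sum has no interpretation.

Cancer risk for benzene is

$$LCR = CDI \times SF, \qquad
  CDI = \frac{C \times IR \times EF \times ED}{BW \times AT} \times 10^{-3},$$

with $C$ in µg·m⁻³, inhalation rate $IR$ in m³·day⁻¹, exposure frequency
$EF = 365$ day·year⁻¹, exposure duration $ED = 53$ year (adults aged 18–70),
body weight $BW$ in kg, averaging time $AT = 25{,}550$ day (a 70-year
lifetime), and slope factor $SF = 0.029$ (mg·kg⁻¹·day⁻¹)⁻¹. The µg→mg
factor $10^{-3}$ is applied inside `chronic_daily_intake()`, never at input
parsing, so all tabular inputs stay in the units they were measured in.

## Distributions

Two families cover every variate in the model, represented by `dist_spec`:

* **normal** for body weight and inhalation rate, with mean `a` and SD `b`;
* **lognormal10** for concentrations and corrected biomarkers: the base-10
  logarithm of the variate is $N(a, b)$. Base 10 is the natural reading of
  the parameter table the defaults come from: $10^{2.102} \approx 126$
  µg·(g crt)⁻¹ matches the reported T,T-MA average of ~127, whereas
  $e^{2.102} \approx 8$ does not, and $10^{0.321} \approx 2.1$ µg·m⁻³ is a
  plausible residential benzene level.

`fit_normal_quantiles()` fits a normal to published quantiles (medians and
quartiles of exposure-factor handbooks) by least squares of the quantile
values on standard-normal scores. This Q-Q regression is exact — to machine
precision — whenever the supplied points are true quantiles of a normal,
which is the property the tests assert. Any quantile set with at least two
distinct probabilities is accepted, since handbooks differ in which
quantiles they print. A slightly negative fitted slope (below `1e-8`) is
clamped with a warning; a genuinely negative slope means decreasing
quantiles and is an error.

`fit_lognormal10()` is the moment estimator on the log10 scale (mean, and
SD with the $n-1$ denominator). Exceedance probabilities against RfC/BEI
thresholds are computed analytically through the normal CDF;
`ks_statistic()` provides the classical one-sample two-sided D (both step
edges evaluated at every point) to check distributional adequacy, with the
asymptotic Kolmogorov p-value — platform-specific small-sample corrections
used by commercial statistics packages are deliberately not reproduced.

## Monte Carlo propagation

`simulate_lcr()` draws $(C, IR, BW)$ independently per iteration — no
correlation structure between the three is assumed, because none is
established for this population — and pushes each triple through the LCR
formula. Normal draws for $IR$ and $BW$ are rejection-sampled to
positivity when `truncate_positive` is on (the default); at the default
parameters the truncation probability is below $10^{-6}$ per draw, so the
effect is negligible but the rejection count is still reported. The
default iteration count is 10,000, matching common practice for this kind
of screening assessment; the package's own verification runs use $10^5$ to
$10^6$ iterations so that Monte Carlo error is small against the two
significant figures being checked (at $10^6$ the standard error of the mean
LCR is about $3\times10^{-8}$). These sizes keep any run in seconds on one
core.

Two independent cross-checks guard the simulator:

* `analytic_mean_lcr()` computes
  $SF \cdot k \cdot E[C]\, E[IR]\, E[1/BW]$ with the closed-form log-normal
  mean, the closed-form truncated-normal mean, and $E[1/BW]$ by adaptive
  quadrature over the truncated normal;
* the test suite also compares the serious-risk tail fraction against a
  moment-matched log-normal product approximation and a larger reference
  simulation.

Parameter sensitivity is summarised as the Spearman rank correlation of
each sampled parameter with the per-iteration LCR (ties by average ranks;
constant columns are flagged and reported as 0). With the default
parameters the concentration dominates — its log-scale spread (0.426 in
log10) far exceeds the coefficients of variation of IR and BW — and body
weight correlates negatively, as it must from the denominator.

Risk lines default to the US EPA conventions: $10^{-6}$ acceptable,
$10^{-4}$ serious. Exceedance fractions are non-increasing in the line by
construction.

## Urinary biomarkers

Creatinine excretion is approximately constant per person per day, so
dividing a urinary analyte (µg·L⁻¹) by creatinine (g·L⁻¹) removes urine
dilution: `creatinine_correct()` returns µg·(g crt)⁻¹ and *excludes* (with
indices) samples whose creatinine is non-positive rather than zeroing them.
Site summaries report the geometric mean of the positive corrected values
paired with their **arithmetic** standard deviation. That pairing is a
deliberate reading of the "GM ± SD" convention in cohort tables of this
kind: the magnitude pattern of the defaults (e.g. 213 ± 434, dispersion
double the centre) is only consistent with an arithmetic SD of a skewed
variate; a geometric SD is available via `dispersion = "geometric"`.
Below-detection-limit handling imposes no substitution: values pass through
and exclusion from the GM is counted, since any imputation rule would be a
modelling choice the data owner should make. Group-difference testing
(Kruskal–Wallis and similar) is left to the standard facilities of any
statistics package — the module exposes the group splits; it does not wrap
the tests.

## Source apportionment

Three diagnostics, all deliberately simple:

* **T/B ratio** (`tb_ratio_classify()`): < 1 biomass/biofuel/coal burning,
  1–10 vehicle exhaust, > 10 industrial/solvent. Published bands overlap
  (industrial sources are often quoted as simply "> 1"); the disjoint bins
  make the label deterministic while the raw ratio is always returned so
  users can re-bin. Boundary values go to the middle band by the stated
  `≤` convention.
* **Ternary composition** (`ternary_coords()` + `classify_composition()`):
  benzene/toluene/ethylbenzene fractions placed in the equilateral-triangle
  embedding and tested against source-region polygons with a
  winding-number point-in-polygon test, inclusive on boundaries (an
  on-edge point belongs to every region touching it; overlapping regions
  all match). The shipped polygons in
  `source_regions_synthetic.json` are *synthetic approximations* — real
  source fingerprints are measured quantities not derivable here — and the
  file is user-editable JSON precisely so that measured profiles can be
  dropped in.
* **Co-emission correlation** (`co_emission_correlation()`): Spearman rho
  via Pearson on average ranks, p-value by the t approximation, with
  constant inputs flagged rather than erroring.

## The synthetic-data generator

No raw air or urine measurements are distributable for the study design
this package emulates, so `generate_study()` produces study-shaped data
from the packaged configuration: four residential sites with five canister
samples each, cohorts of 50/49/50/25 participants with the configured sex
splits and male smoking rates (68.0/72.0/62.5/81.8 %), and age groups
drawn with the configured weights. Air concentrations are base-10
log-normal with the pooled dispersions; the benzene location parameter is
shifted per site to the configured site geometric means (5.14/4.41/2.83/
0.91 µg·m⁻³) over the shared dispersion, a site-structured-mean model.
The within-site versus between-site variance split of a five-sample
canister design is not identifiable from summary statistics, so the
generator keeps the pooled dispersion at each site; each site's
distribution is an ordinary `dist_spec`, so a user can tighten or widen it
per site.

Biomarker distributions are interpreted on the **corrected** scale and raw
values back-computed as corrected × creatinine, so creatinine correction
inverts the generator exactly — an identity the tests exploit. Per-site
biomarker generators are parameterised from the configured site GM/SD
pairs by log-normal moment matching
(`lognormal10_from_gm_sd()`: $e^{s^2} = (1+\sqrt{1+4\,SD^2/GM^2})/2$).
Creatinine itself is not characterised by any configured summary, so it
defaults to lognormal10(0, 0.17): median 1 g·L⁻¹ and a geometric SD of
about 1.5, a physiologically ordinary spread for spot urine; it is a
configurable entry like every other distribution.

What the generator does **not** emulate: instrument measurement error and
QA/QC recovery structure, within-day sampling correlation, any dependence
between smoking status and biomarker level, and real between-site
composition differences for species other than benzene. Tests passing on
synthetic data therefore validate the *computational pipeline* — fitting,
correction, risk arithmetic, propagation — under the declared model; they
are not evidence about any real population beyond what the configured
parameters encode.

## Numerical and design choices

* Seeds are explicit everywhere; identical seed + configuration gives
  bit-identical output, including the written CSV/JSON files.
* Degenerate scales (`b = 0`) are handled by direct comparison — no
  division by zero anywhere in the exceedance or sampling paths.
* The deterministic risk path refuses distribution-valued scenarios and
  points the caller to the Monte Carlo module, rather than silently using
  a mean.
* `risk_table()` defaults to geometric-mean site concentrations, the
  statistic under which the default configuration reproduces its reference
  hazard-quotient surface; missing (site, analyte) cells are `NA`, never 0.
  One known cell discrepancy is tolerated at ±0.01: a published S-PMA
  quotient of 0.09 where GM/BEI = 2.06/25 computes to 0.082, most likely
  rounding from unprinted precision upstream.
* The pipeline manifest hashes the configuration with a small FNV-1a
  implementation (no hashing dependency is required), records seeds,
  package version and every output path, and fails if a declared output is
  missing.

## Limitations

Inhalation is the only route (no dermal or oral pathways); ED is not
age-stratified; only normal and base-10 log-normal families are supported;
no variance reduction (Latin hypercube etc.) and no two-dimensional
variability × uncertainty simulation; factory-site species-level risk is
not reproducible from the packaged configuration because only total BTEX
levels are configured there. The shipped ternary source regions are
placeholders, and classifications against them demonstrate the machinery,
not real source attribution.
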