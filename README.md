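# btexrisk

Probabilistic human health-risk assessment for inhalation exposure to
benzene, toluene, ethylbenzene and xylenes (BTEX), aimed at environmental
health scientists assessing non-occupational populations near industrial
emission sources such as coking plants.

## What it computes

**Non-cancer screening.** Hazard quotients

    HQ = C / RfC

against inhalation reference concentrations for air species, and against
ACGIH biological exposure indices (BEI) for the creatinine-corrected urinary
benzene metabolites trans,trans-muconic acid (T,T-MA) and
S-phenylmercapturic acid (S-PMA). `HQ < 1` indicates adverse effects are
unlikely.

**Cancer risk.** Lifetime cancer risk for benzene via chronic daily intake:

    CDI = C × IR × EF × ED / (BW × AT) × 10⁻³    [mg·kg⁻¹·day⁻¹]
    LCR = CDI × SF

with defaults EF = 365 day·yr⁻¹, ED = 53 yr, AT = 25,550 day and
SF = 0.029 (mg·kg⁻¹·day⁻¹)⁻¹. `simulate_lcr()` propagates base-10
log-normal concentration and normal inhalation-rate/body-weight
distributions through the formula by Monte Carlo, reporting the mean,
percentiles, the fractions exceeding the US EPA acceptable (10⁻⁶) and
serious (10⁻⁴) risk lines, and Spearman parameter-sensitivity ranks.

**Supporting machinery.** Quantile-based normal fitting (Q-Q regression,
exact on true quantiles), base-10 log-normal fitting, analytic exceedance
probabilities, a one-sample Kolmogorov–Smirnov check, creatinine correction
and GM ± SD cohort summaries, T/B-ratio and ternary-composition source
diagnostics, a seedable synthetic-data generator reproducing the emulated
study design (4 sites × 5 canister samples; cohorts of 50/49/50/25), and a
`run_pipeline()` front end that writes tables, JSON summaries and a
reproducibility manifest.

## Worked example

```r
library(btexrisk)
cfg <- default_study_config()

# deterministic screening: benzene geometric mean at the nearest site vs RfC
hazard_quotient(5.14, 30)
#> <risk_result> HQ = 0.171333

# probability that residential benzene exceeds its RfC of 30 ug/m3
dist_exceedance(cfg$air$benzene, 30)
#> 0.0033

# Monte Carlo lifetime cancer risk, adult males
male <- simulate_lcr(cfg$air$benzene, cfg$scenarios$male,
                     sf = cfg$thresholds$sf,
                     cfg = mc_config(n_iterations = 1e5, seed = 42))
male
#> <lcr_summary> male: mean LCR = 2.17e-05 (n = 100000, seed = 42)
#>   exceedance: P(>1e-06) = 0.994, P(>1e-04) = 0.0223
round(male$sensitivity, 3)
#> concentration            ir            bw
#>         0.958         0.166        -0.194
```

The mean LCR of 2.17 × 10⁻⁵ sits between the acceptable and serious risk
lines: essentially the whole simulated population exceeds the one-in-a-
million acceptable level, and about 2.2 % of males exceed the serious
10⁻⁴ level. Concentration variability dominates the risk distribution
(rank correlation 0.96); body weight correlates negatively because it sits
in the intake denominator.

A full synthetic-study run:

```r
m <- run_pipeline(cfg, out_dir = "demo_run", seed = 1)
read.csv("demo_run/risk_table.csv")
#>   site    benzene      toluene ethylbenzene     xylenes      ttma       spma
#> 1   R1 0.13438859 0.0001713887 0.0004159666 0.006003930 0.4337263 0.16196987
#> 2   R2 0.13468506 0.0004823862 0.0002614375 0.005473173 0.2442170 0.09634446
#> 3   R3 0.21143702 0.0001833064 0.0001063327 0.004017126 0.1712094 0.09820775
#> 4   R4 0.04950594 0.0005176671 0.0002040291 0.004520833 0.2365455 0.09339722
```

Every HQ is far below 1 — low non-cancer risk at all four synthetic
residential sites (these are hazard quotients of *generated* data; with
only five air samples per site the site geometric means are noisy, which is
why R3 can exceed R1 in a given draw).

## Configuration

All parameters live in `inst/extdata/study_config.json` (distributions,
RfC/BEI thresholds, slope factor, scenario constants, site and cohort
structure); pass an edited copy to `default_study_config(path = ...)`.
Ternary source-region polygons are in
`inst/extdata/source_regions_synthetic.json` — synthetic approximations to
be replaced with measured source profiles for real use.
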