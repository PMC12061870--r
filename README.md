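# faersignal

Pharmacovigilance signal detection and time-to-onset analysis for
FAERS-style spontaneous adverse-event reports, built around the thrombotic
adverse-event profile of the five TNF-α blockers (adalimumab, infliximab,
etanercept, certolizumab pegol, golimumab).

Spontaneous-reporting databases such as the FDA Adverse Event Reporting
System (FAERS) have no denominator, so drug–event associations are screened
by **disproportionality analysis**: for a target drug and a target event,
build the 2×2 table over all reports in the database

|                | target event | other events |
|----------------|-------------:|-------------:|
| target drug    | a            | b            |
| other drugs    | c            | d            |

and ask whether the event is reported disproportionately often with the
drug. The package implements the four standard statistics with their usual
positivity criteria:

- **ROR** = ad/bc, 95% CI `exp(ln ROR ± 1.96·√(1/a+1/b+1/c+1/d))`;
  positive when a ≥ 3 and the CI lower bound exceeds 1.
- **PRR** = [a/(a+b)]/[c/(c+d)] with the Yates-corrected Pearson χ²;
  positive when a ≥ 3, PRR ≥ 2 and χ² ≥ 4.
- **IC** (BCPNN information component) = log₂((a+½)/(E+½)) with
  E = (a+b)(a+c)/n; IC025 is the 2.5% quantile of the
  Gamma(a+½, E+½) posterior; positive when IC025 > 0.
- **EBGM** (multi-item gamma-Poisson shrinker): counts are
  Poisson(λE) with a two-component gamma mixture prior on λ fitted by
  marginal maximum likelihood over every drug–event pair in the database;
  EBGM is the posterior geometric mean of λ and EBGM05 its 5% quantile;
  positive when EBGM05 ≥ 2.

A pair is a signal when **any** of the four methods is positive. Around the
statistics the package provides the full pipeline: FAERS quarterly ASCII
(`$`-delimited) ingestion, FDA-style case-version deduplication, drug-name
normalization against a synonym dictionary, a MedDRA-lite PT→HLT→HLGT→SOC
hierarchy, sex/age stratification, Fisher/Benjamini–Hochberg volcano
payloads, cross-drug heatmaps, and **time-to-onset analysis**: induction
times from therapy start, type-7 quantile summaries, Lilliefors/
Kruskal–Wallis group comparisons, and two-parameter Weibull maximum
likelihood whose shape CI classifies the onset hazard as early-failure
(CI < 1), random, or wear-out (CI > 1).

Because raw FAERS archives are large and MedDRA is licensed, validation
runs on a **synthetic FAERS generator** (`faers_scenario()`,
`generate_faers()`) that writes genuine FAERS-dialect files with planted
ground truth: configurable reporting-rate ratios per drug–event pair,
Weibull onset times, demographics with missingness, and duplicate case
versions. `study_scenario()` plants the published per-drug signal
strengths and onset laws shipped as reference data.

## Worked example

```r
library(faersignal)

sc <- study_scenario(n_reports = 30000)        # planted ground truth
g  <- generate_faers(sc, seed = 20240401, dir = "results/synthetic_faers",
                     quarter_label = "2024Q1")
asm <- assemble_cases(read_generated(g$paths, "2024Q1"))
asm$drugs$canonical <- normalize_drug(asm$drugs$drugname)

univ  <- pair_universe(asm)
e     <- (univ$a + univ$b) * (univ$a + univ$c) / univ$n
prior <- fit_mgps_prior(univ$a, e, seed = 1)

tab <- count_table(asm, "adalimumab", "Postoperative thrombosis")
signal_stats(tab, prior = prior)
```

On this universe the planted adalimumab pair (rate ratio 10.39) comes back
as

```
    a   ror ror_lo ror_hi  prr    chi2 ebgm ebgm05    ic ic025 any_positive
 1541 12.29  11.04  13.69 9.97 3077.58 2.99   2.87 1.619 1.546         TRUE
```

i.e. ROR 12.29 (95% CI 11.04–13.69) with all four methods positive — the
EBGM is smaller than the ROR because the empirical-Bayes prior shrinks
observed/expected ratios toward the database norm. The Weibull step on the
same pair's onset times gives shape 0.708 (0.681–0.736), scale 440 days
against the planted 0.69/428.94, and classifies it "early failure" (shape
CI entirely below 1): the reporting hazard decreases with time on drug.

The numbered drivers under `analysis/` run the whole study end to end and
write their tables under `results/`:

```sh
Rscript analysis/01_simulate.R                # synthetic FAERS quarter
Rscript analysis/02_etl.R                     # load, dedup, normalize
Rscript analysis/03_signals.R                 # 2x2s, four statistics, subgroups
Rscript analysis/04_time_to_onset.R           # inductions, tests, Weibull
Rscript analysis/05_descriptives_and_checks.R # table 1 + reference checks
```

`run_pipeline()` performs the same stages in one call from a config list.

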