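---
title: "Disproportionality and time-to-onset analysis of FAERS-style reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality and time-to-onset analysis of FAERS-style reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faersignal)
```

# The problem

Spontaneous-reporting systems collect adverse-event reports without any
exposure denominator, so the only internal comparison available for a
drug–event pair is *disproportionality*: is this event a larger share of
this drug's reports than of every other drug's reports? The package
implements that analysis end to end for FAERS-style quarterly extracts,
motivated by the thrombotic adverse-event profile of the five TNF-α
blockers, together with the complementary time dimension: how long after
the start of therapy do the events occur, and does that onset hazard rise
or fall with time on drug?

# Data model and ETL

A FAERS quarter is a set of `$`-delimited ASCII tables (DEMO, DRUG, REAC,
plus OUTC/RPSR/THER/INDI) keyed by `primaryid`. Cases (CASEID) are
re-submitted over time with incremented CASEVERSION, so before any counting
the pipeline keeps, per case, only the highest version — ties broken by the
latest receipt date, then the largest `primaryid` — and drops every
drug/reaction/therapy row whose report was superseded. This follows the
FDA-recommended deduplication practice; the rule is deliberately the *only*
exclusion applied by default, since other published exclusions ("recording
errors", "lacking specific data") are not specified precisely enough to
reproduce; they can be layered on by filtering the assembled tables.

Design choices a reader should know:

- **Age units.** FAERS `age_cod` values convert as DEC×10, YR×1, MON÷12,
  WK÷52.18, DY÷365.25, HR÷8766; a blank unit is taken as years (the FAERS
  convention), an unknown unit becomes missing. Converted ages outside
  [0, 130] years are treated as recording errors and set missing.
- **Partial dates.** `YYYY` imputes July 1 and `YYYYMM` day 15 — midpoint
  imputation minimizes directional bias in onset intervals; the rows are
  flagged `imputed` so sensitivity runs can drop them.
- **Drug names.** Free-text names are folded (case, whitespace,
  punctuation) and matched against a synonym dictionary covering generic,
  trade and biosimilar-suffixed names; a leading-canonical prefix rule
  catches unlisted biosimilar suffixes. Recall is preferred over precision
  here because a missed synonym silently moves reports into the comparator.

# The 2×2 and its comparator

A report counts in the drug margin iff at least one of its
*primary-suspect* (PS) drugs normalizes to the target — concomitant and
interacting roles are excluded to keep the exposure definition sharp — and
in the event margin iff any of its PTs is in the target event set. The
comparator is the full remaining database ("all other drugs"), the
convention under which a signal means "more likely to be reported with this
drug than with all other drugs". The counting unit is the report: a report
with three thrombosis PTs is still one event-positive report. Strata
restrict the universe before counting; reports with unknown sex or age are
excluded from non-ALL strata, and the age bands default to <18 /
18–65 / >65 with configurable edges (published TNF-blocker tables are
internally inconsistent about the elderly cutoff — 65 vs 85 — so the edge
is a parameter, not a constant).

The thrombosis event set is built either from a stem search (default stem
`"thrombo"` over the MedDRA-lite table; embolism PTs are *not* included by
default, because published keyword strategies for thrombosis vary on
exactly this point and neither choice can be asserted as canonical) or from
an explicit PT list.

# The four statistics

For a table (a, b, c, d), n = a+b+c+d and E = (a+b)(a+c)/n:

- ROR = ad/bc with Wald CI on the log scale. When any cell is zero, 0.5 is
  added to all four cells (Haldane–Anscombe); otherwise raw counts are
  used, which is what keeps single-report pairs (N = 1) at finite
  estimates with very wide CIs.
- PRR = [a/(a+b)]/[c/(c+d)]; χ² is the Pearson statistic with the Yates
  correction on by default (toggleable — published FAERS analyses rarely
  state the choice; the corrected statistic is the conservative one).
- IC = log₂((a+½)/(E+½)). The posterior of the rate ratio λ is
  Gamma(a+½, rate E+½) and IC025 is log₂ of its 2.5% quantile. Published
  signal tables sometimes print an "IC025" roughly 1.67 bits below IC at
  large N, which matches no standard closed form; this package implements
  the standard posterior quantile and documents the discrepancy rather
  than imitating it. What *is* checked against published tables is the
  internal identity IC = log₂(EBGM) under weak shrinkage, which holds for
  all 35 published thrombosis rows within print rounding
  (`ic_ebgm_consistent()`).
- EBGM: the marginal distribution of a pair's count under a two-component
  gamma mixture prior on λ is a negative-binomial mixture; the five
  hyperparameters (α₁, β₁, α₂, β₂, w) are fitted by bounded L-BFGS-B from
  the conventional start (0.2, 0.1, 2.0, 4.0, ⅓) with box
  [10⁻⁶, 50] (w in [10⁻⁴, 1−10⁻⁴]), five seeded restarts on
  non-convergence. The posterior is the updated two-component mixture;
  EBGM = 2^E[log₂ λ | N] and EBGM05 solves the mixture CDF = 0.05 by
  bisection to 10⁻¹⁰.

One caveat established during validation and reflected in the tests: the
raw mixture coordinates are only weakly identified (two gamma components
can trade weight for shape with almost no likelihood cost), while the
induced prior law — its mean, its tail mass, hence the shrinkage — is
recovered accurately. Parameter-recovery tests therefore compare the
induced distribution, not the coordinates.

Fisher's exact test (two-sided) supplies the volcano p-values — many cells
are small, so the exact test is used rather than χ² — adjusted by
Benjamini–Hochberg within each drug's PT family.

# Time to onset

The induction time of a report is event date minus the *earliest* therapy
start of its PS target drug (one onset per report; repeat therapy episodes
are not expanded, since the analysis counts cases, not episodes). Records
with a missing date, a non-positive interval, or an interval above a
plausibility cap (default 7,300 days = 20 years; the cap is configurable
because no published threshold exists) are excluded and counted by reason.

Summaries use type-7 quantiles — linear interpolation between closest
ranks — the convention that produces fractional quartiles (e.g. 129.75) on
even sample sizes, matching how published onset tables read. Normality is
assessed by a Lilliefors-style Kolmogorov–Smirnov test: the KS distance is
computed against a normal with the *sample's* mean and SD, so the
classical KS null distribution is wrong, and the p-value is obtained by
Monte Carlo (default 2,000 standard-normal replicates, fixed seed).
Group location differences use Kruskal–Wallis with tie correction and
pairwise two-sided Wilcoxon rank-sum tests, Bonferroni-adjusted over the
drug pairs (published analyses report only significant pairs without
naming an adjustment; Bonferroni is the conservative default).

The Weibull fit maximizes the two-parameter likelihood by Newton iteration
on the profile score for the shape (the scale has a closed form at any
shape), started from the Menon-type moment estimate, with a
method-of-moments fallback after 200 iterations and a degeneracy flag for
zero-variance samples. 95% CIs come from the observed information on the
log-parameter scale. The shape CI classifies the hazard: **early failure**
if the upper bound is below 1 (reporting hazard decreases with time on
drug), **wear-out** if the lower bound exceeds 1, **random** otherwise.

# The synthetic generator

`faers_scenario()` / `generate_faers()` produce FAERS-dialect files with
known truth. Each base report draws one PS drug from a drug mix and one PT
from a background pool; planted (drug, PT) pairs multiply the conditional
PT probability by a rate ratio ρ (renormalized over the remaining pool;
infeasible ρ is fatal). Onsets are Weibull(shape, scale) days for planted
pairs and uniform 1–1,000 days otherwise; the event date is the therapy
start plus the onset. A configurable fraction of cases is re-emitted as
CASEVERSION 2 with perturbed demographics so deduplication is exercised,
and the generator keeps complete bookkeeping (realized per-pair 2×2
counts, duplicate case ids) so downstream steps can be checked exactly.
`expected_table()` gives the closed-form expected 2×2 — the reason the
default is one PT per report; a multi-PT mode exists for ETL tests but
breaks the closed form.

`study_scenario()` fixes the study conditions: the five TNF-α blockers
plus a 30% background comparator, sex mix 60/32/8 (F/M/missing), ages
4/80/16% across <18/18–65/>65 with 25% missingness — chosen once to echo
the published descriptive structure of TNF-blocker reporting — and one
planted thrombosis pair per drug whose ρ equals the drug's published ROR
for that PT and whose onset law is the published per-drug Weibull
(shape 0.60–0.79, scale 355–900 days, all "early failure").

What the generator deliberately does **not** emulate: real FAERS marginal
frequencies, co-medication structure, indication confounding, free-text
noise beyond case/whitespace perturbation, or the pre-2012 legacy ISR
format. Passing tests therefore demonstrate that the statistics, the ETL
bookkeeping and the inference behave correctly under a known generative
law — not that any particular real-world signal is causal.

# Numerical and validation choices

- Problem sizes: the analysis drivers use 30,000 synthetic reports; the
  validation suite uses 2,000-report universes across 100 seeds for null
  calibration (coverage of the 95% ROR CI must land in [90%, 99%] and
  mean BH discoveries under the null must stay below α·m), a
  50,000-report universe for strong-signal recovery by all four methods,
  20,000 draws for Weibull parameter recovery (shape within ±0.01 of the
  published 0.69, classified early), and 1,000 random tables for
  brute-force oracle equivalence of ROR/CI, PRR, Yates χ², BH,
  Kruskal–Wallis H and type-7 quantiles.
- Determinism: every stochastic routine takes a seed; the generator
  restores the caller's RNG state, and identical seeds give byte-identical
  output files.
- Degenerate inputs are flagged, not thrown: all-zero tables produce
  `undefined` statistics, zero-variance samples produce degenerate
  Weibull/KS results with floor p-values, empty strata produce zero
  tables.

# Limitations

Disproportionality measures reporting association, not risk: no
causality, no incidence, and masking by a drug's own dominant events can
suppress or inflate signals. The MedDRA-lite table covers only the PTs
these analyses touch plus background fillers; a licensed full MedDRA in
the same 4-column format can be dropped in. The MGPS implementation is
the pairwise (two-dimensional) shrinker; multi-item sets and MCMC-based
BCPNN variants are out of scope, as are per-quarter signal trending and
indication-restricted comparators.
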