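---
title: "Ascertaining small cell lung cancer in primary-care EHRs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ascertaining small cell lung cancer in primary-care EHRs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sclcehr)
```

## The problem

Small cell lung cancer (SCLC) is an aggressive histological subtype of lung
cancer, accounting for roughly 10–15% of cases, with median survival well
under a year. UK primary-care coding dictionaries of the study era carried
codes for lung cancer (unspecified or non-small-cell) and for small cell
cancer of unspecified site, but no dedicated SCLC code. Incident SCLC cases
therefore cannot be read off the coded record: they must be reconstructed by
combining coded entries with string searches of the free-text comments that
practitioners attach to clinical records.

`sclcehr` implements that reconstruction as a reusable, tested pipeline:

1. **Cohort** — eligibility rules, start dates, follow-up, person-time.
2. **Index detection** — the first lung-cancer (group 1) or small-cell
   cancer (group 2) code during follow-up.
3. **Cross-code confirmation** — the complementary code type within ±90
   days of the index code confirms the case without text review.
4. **Text mining** — negation-aware string search of free-text comments in
   a −30/+90-day window around the index code.
5. **Validation** — random-sample chart review (simulated against ground
   truth), per-stratum confirmation rates, positive predictive values.
6. **Extrapolation** — confirmation rates applied to whole strata give the
   expected number of incident cases.
7. **Epidemiology** — incidence per person-time, baseline characterisation,
   one-year mortality and Kaplan–Meier survival from backdated event dates.

Because the source database is access-restricted, a synthetic EHR generator
with configurable ground truth stands in for it; every stage of the
pipeline is exercised against that truth.

## The ascertainment model

Let the cohort contribute $T$ person-years. Group sizes $N_1, N_2$ are the
patients whose first qualifying code is a lung-cancer or SCC code. After
removing cross-code-confirmed patients $x_1, x_2$, the free-text search
splits the remainder into strata: group 1 into *SCLC text only* ($n_s$),
*'non' text only* ($n_n$), *both* ($n_b$), *no text*; group 2 into *lung
cancer text* ($n_\ell$) and *no text*. Manual review of random samples
yields per-stratum confirmation rates $r_s, r_b, r_\ell$, and the expected
number of incident cases is

$$\hat{N} = x_1 + x_2 + [r_s n_s] + [r_b n_b] + [r_\ell n_\ell],$$

with $[\cdot]$ rounding half away from zero. The ambiguous $[r_b n_b]$ term
is reported but excluded from the final case count $\hat{N}_f$, which feeds
the incidence estimate $\hat{N}_f / T$. Because the confirmation rates are
estimated from simple random samples, each term $\hat r\,n$ is an unbiased
estimator of the number of true cases in its stratum; the extrapolation
therefore self-corrects for false positives (including prevalent cases
detected late) that reach the text strata.

## Negation handling in the text search

Matching is deliberately plain, lower-cased substring search — no
stemming, no tokenisation beyond separator handling — because that is how
such searches are actually run against primary-care free text, and because
a transparent matcher is auditable. Three rules refine it:

* **Word-start boundary.** A pattern occurrence counts only when the
  preceding character is not alphanumeric, so `"sclc"` does not fire
  inside `"nsclc"`.
* **Adjacent negation.** An SCLC string is negated when a negation prefix
  (`"non"`) immediately precedes it, allowing at most one space or hyphen:
  `"non small cell lung cancer"` and `"non-small cell ca"` are negated,
  `"non smoker, small cell carcinoma"` is not. Restricting negation to
  adjacency avoids over-negating long comments.
* **Negated tokens.** Abbreviations such as `"nsclc"` are treated as
  negated mentions outright. Whether the original in-house search did this
  is not documented; we decided yes, since the abbreviation unambiguously
  denotes the non-small-cell subtype.

Both search windows are closed intervals: ±90 days for cross-codes and
[−30, +90] days for text, reading "30 days before … to 90 days after" as
inclusive at both ends.

## Cohort conventions

* "2 years" is exactly 730 days; a person-year is 365 days; a person-month
  is 30.4375 days (365.25/12). The source study reports person-years and
  person-months without defining the conversion, so these package-wide
  constants are declared once and used everywhere.
* An "encounter" is any clinical event row, anchored at the candidate start
  date (the alternative anchoring at study entry is not what the eligibility
  sentence most naturally reads as, and the choice is noted here because the
  source is silent).
* Age bounds (18–89) are entry criteria; follow-up is not truncated when a
  patient turns 90 because the bound is stated as an entry condition.
* Follow-up is half-open `[start, end)`: an index code on the start date
  counts, contributing zero person-days.
* Patients whose first lung-cancer/SCC code precedes their candidate start
  date are prevalent and never enter the cohort.
* When both code types appear on the same first day, the SCC code (more
  specific) defines the group.

## The synthetic generator

`generate_bundle()` simulates registration intervals, routine visits,
lifestyle and comorbidity history, prescriptions, disease onset, coding and
free-text behaviour, deaths and record censoring. Its defaults *are* the
study conditions:

| parameter | default | rationale |
|---|---|---|
| `annual_sclc_hazard` | 1.01e-4 /person-year | the reported incidence, 1.01 per 10,000 person-years |
| `nsclc_to_sclc_ratio` | 7 | SCLC is ~10–15% of lung cancer |
| `p_code_lung_given_sclc` / `p_code_scc_given_sclc` | 0.8 / 0.2 | group-1 vs group-2 composition of the reported case set (2382 vs 574 of 2956) |
| `p_cross_code` | 0.15 | 364 cross-coded of ~2400 group-1 true cases |
| `p_text_sclc`, `p_text_lung` | 0.99, 0.98 | free-text recording of a new cancer diagnosis is near-complete |
| `p_text_non` | 0.2 | 4166 'non' texts among ~22,000 non-cross group-1 patients |
| `p_symptom_before` | 0.845 | 84.5% of confirmed cases had a recorded symptom |
| `symptom_lead_days_max` | 72 | uniform lead gives a median backdating of ~36 days |
| `median_survival_months` | 7.37 | the reported median survival |
| `censor_dropout_rate` | 0.033 | the 98/2938 records excluded from mortality follow-up |

Disease onset uses competing exponential clocks (SCLC, NSCLC, other-site
small-cell disease, background death) over each patient's at-risk time, so
the empirical SCLC hazard converges to the configured one. Transfers out of
the practice are independent of disease status, which keeps the incidence
estimator unbiased under the cohort's registration-status exclusion.

What the generator deliberately does **not** emulate: a real Read-code
dictionary (synthetic stand-in codes are used), clinically plausible
comorbidity co-occurrence, practice-level clustering, non-exponential
survival, and calendar trends. Consequently, green tests demonstrate that
the *algorithm* is implemented correctly and recovers known parameters
under the stated recording model — not that the algorithm would achieve the
same PPV on any particular real database.

Survival is exponential with the configured median, with log-hazard shifts
of +0.35 for men and +0.025 per year of age at onset so mortality is higher
in men and the elderly. A consequence of the exponential shape is an
implied one-year case fatality near 64–68%, a little below the reported
70.4%; the package reports what it computes and does not calibrate the
shape to match.

## Numerical choices

* **Rounding of extrapolated terms:** nearest integer, half away from zero
  (0.05 × 353 = 17.65 → 18). Base R's round-half-to-even would disagree on
  exact halves.
* **Proportion intervals:** Clopper–Pearson exact, computed from the beta
  quantile form; exactness matters at the review sample sizes (18, 20, 25).
* **Rate intervals:** log-normal, `exp(log r ± 1.96/√events)`; this
  reproduces the published mortality-rate intervals to within 0.02. With
  zero events the exact Poisson upper bound `3.69/PT` is used.
* **Kaplan–Meier:** the product-limit estimator is implemented directly
  (risk sets at each distinct event time; censored subjects at a tied time
  remain in the risk set). The median is the first time survival drops to
  ≤ 0.5 and is reported as undefined — not infinite — when never reached.
  `survival::survfit` is used in the test suite as an independent oracle,
  never as the implementation.
* **Backdating lookback:** 90 days by default; the source states no window
  for the "first related symptom, procedure or surgery" rule, and 90 days
  comfortably covers the reported median backdating of 36 days.
* **Degenerate inputs:** empty strata raise explicit errors where a rate
  would be undefined (`confirmation_rates`, `ppv_estimate`); zero-event
  rates and empty cohorts return well-defined zeros.

## Problem sizes in the test suite

Property-style checks run on synthetic populations of 20,000–100,000
patients; the parameter-recovery check pools 20 independent populations of
60,000 patients (~1.2 million person-years, ~1,100 incident cases) and
requires the pipeline's incidence estimate to fall within three
Monte-Carlo standard errors of the configured hazard. The acceptance
script pools the same design. These sizes were chosen so the Monte-Carlo
bands are a few per cent wide — tight enough to detect real defects, wide
enough not to flag ordinary sampling noise.

## Known limitations

* The matcher is not a clinical NLP system: no bidirectional negation, no
  misspelling tolerance, no section awareness. This mirrors the simplicity
  of the original string-search design.
* Stage, metastasis and treatment characterisation of confirmed cases
  depends on chart review of real records and is represented here only by
  the truth-label stage field.
* The crude one-year mortality of the synthetic cohort reflects the
  exponential survival model, not the empirical survival curve of real
  SCLC patients.
* Stratified PPV is implemented (`stratified_ppv()`) but has no published
  reference values to compare against.

## A worked example

```{r example, eval = FALSE}
library(sclcehr)

run <- run_pipeline(run_config(
  sim = sim_config(n_patients = 60000, seed = 1),
  seed = 1))
print(run)

# the published flowchart counts through the same extrapolation
sc <- make_step_counts(24508, 733, 364, 137, 2000, 4166, 353, 437)
extrapolate_cases(sc, c(sclc_only = 1, both = 0.05, lung = 1))
```
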