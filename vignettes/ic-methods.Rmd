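---
title: "Methods: information-component screening of spontaneous reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: information-component screening of spontaneous reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icscreen)
```

## The case/non-case design

Spontaneous-report databases have no denominator of exposed patients, so
risk cannot be estimated; what can be estimated is *disproportionality*:
whether an event is reported more often with a drug than the database as a
whole would predict under independence. `icscreen` implements the
case/non-case form of this design. Cases are the reports carrying the
target event (defined as a set of MedDRA preferred terms, matched
case-insensitively after whitespace normalisation); non-cases are every
other report. For each drug the case-level counts
$(N_{obs}, N_{drug}, N_{eff}, N_{tot})$ give the expected count
$E = N_{drug} N_{eff} / N_{tot}$ and the information component

$$IC = \log_2 \frac{N_{obs} + 0.5}{E + 0.5}.$$

Only *suspect* and *interacting* drug mentions are analysed; a drug
recorded as concomitant contributes to neither $N_{obs}$ nor $N_{drug}$.
We use the same role restriction in the numerator and in $N_{drug}$:
whether a database's own IC denominators count concomitant mentions is a
convention that varies between systems, and a mismatched convention would
bias the ratio for heavily co-prescribed drugs. All counts are case-level:
a case mentioning a drug twice counts once.

## The credibility bound

The $+0.5$ terms are the mean shrinkage of a Gamma posterior: with the
observed-to-expected ratio $\lambda$ given a
$\mathrm{Gamma}(N_{obs}+0.5,\; E+0.5)$ (shape, rate) posterior, the IC
point estimate above is exactly $\log_2 E[\lambda]$. The package therefore
takes the credibility interval from the same posterior:

$$IC_{025} = \log_2 Q_{\Gamma}(0.025;\; N_{obs}+0.5,\; E+0.5),$$

and analogously $IC_{975}$. $IC_{025} > 0$ is the signal threshold. The
bound is computed with `stats::qgamma` and is validated in the test suite
against an independent Monte-Carlo oracle (empirical quantiles of $10^6$
Gamma draws) to within 0.01 bits over a grid
$N_{obs} \in \{0,1,5,20,100\} \times E \in \{0.1,1,10,100\}$. Useful exact
properties: an $N_{obs}=0$ drug can never be significant; the bound is
strictly increasing in $N_{obs}$ at fixed $E$; and for large counts at
fixed ratio $R$, $IC_{025} \to \log_2 R$.

A closed-form approximation
($IC - 3.3(N_{obs}+0.5)^{-1/2} - 2(N_{obs}+0.5)^{-3/2}$ for the lower
bound, $IC + 2.4(N_{obs}+0.5)^{-1/2} - 0.5(N_{obs}+0.5)^{-3/2}$ for the
upper) is available behind `method = "approx"` for sensitivity analysis
against results computed with the older interval form; it is not the
default because it is an approximation to the exact quantile the default
already computes.

## The exclusion procedure

`apply_exclusions()` runs three ordered stages and tags each screened drug
with the *first* applicable reason:

1. `not_significant`: $IC_{025} \le 0$;
2. `single_country`: all of the drug's *event* cases share one country
   value. Only event cases are examined — the drug's background reports do
   not enter — because the concern is a signal created by one national
   reporting culture. A drug with exactly one event case is single-country
   by construction and is excluded under the rule; we do not carve out
   $N=1$ because such signals are equally unverifiable across countries.
3. `protopathic`: the drug's normalised name is on the configured
   protopathic list — drugs given *to treat* the event or its causes, whose
   association is reversed causation. The packaged default list for the
   hyperammonaemia event contains the five ammonia-lowering therapies
   (lactulose, rifaximin, sodium phenylbutyrate, benzoic acid, carglumic
   acid). Matching is by exact normalised name since spontaneous reports
   carry names, not stable identifiers.

The stage order is fixed as significance → single-country → protopathic.
Whether single-country filtering precedes significance cannot matter for
*which* drugs are retained (the stages are conjunctive), but it determines
the per-stage tallies; the adopted order reflects the usual narrative of
such studies (statistical screen first, then reporting-pattern and
indication-bias filters) and is what the calibration fixture reproduces.

## Case scoring

* **Informativity (NI0–NI2)**, per (case, drug): NI2 when both the time to
  onset and the discontinuation of the drug are described, NI1 when exactly
  one is, NI0 when neither. "Discontinuation described" is operationalised
  as `action_taken == "withdrawn"`; a dose reduction does not qualify
  (conservative reading: reducing is not discontinuing), and the
  `"unknown"` token counts as not described. When a case mentions the same
  drug twice the best-documented mention is used.
* **Extrinsic imputability (B1–B4)**, per drug, from a user-supplied frozen
  label-knowledge table with precedence B4 (on-label) > B3 (widely
  published in reference sources) > B2 (published case reports) > B1 (not
  published). The table is an input, never scraped at run time: label
  databases drift, and a reproducible analysis needs a dated snapshot.
  Drugs absent from the table grade B1.
* **Clinical presentation**: a case is assigned every category of the
  phenotype map whose preferred-term set intersects its co-reported PTs,
  after removing the event-definition PTs themselves. The packaged map
  (five neurological presentation categories plus liver- and
  kidney-dysfunction term sets) is a documented default with disjoint
  sets; the exact vocabulary is configuration, the classification logic is
  the tested content. Analyses holding a licensed MedDRA dictionary should
  substitute their own table.
* **Seriousness**: at least one of the six regulatory outcome categories.

## Summaries and missing data

All percentages in `summarize_drugs()` and `cohort_summary()` use
available-case denominators: cases with the field missing leave the
denominator, and the `denom_*` columns report the denominators explicitly
so the missing-data accounting is visible. Missing values are never
imputed, and an all-missing field yields a missing summary, not zero.
Available-case analysis is unbiased under missingness completely at random
(MCAR), which is exactly the regime the synthetic generator produces — a
deliberate pairing documented below. `pct_single_suspect` is the share of
the drug's event cases in which it is the only suspect/interacting drug;
`mean_n_suspect` the mean count of suspect/interacting drugs per case;
`pct_interruption` the share of withdrawn among cases whose action is
described. Output CSVs round percentages to one decimal and keep a
full-precision `*_raw` column alongside.

## The synthetic generator

`generate_database()` emulates the statistical structure of a global
spontaneous-reporting stream: a drug catalog with skewed popularity
weights, multi-drug reports with therapeutic-class co-prescription
clustering (`co_class_prob`), rare-event preferred terms, per-drug relative
reporting rates, demographics with a world-wide country mix, right-skewed
log-normal times to onset (default median 13 days), regulatory outcomes,
and MCAR missingness masks. The event mechanism combines per-drug hazards
independently: a case exposed to drugs $d$ has event probability
$1 - \prod_d (1 - \mathrm{clamp}(p_0\, rr_d, 0, 1))$, which makes marginal
relative reporting rates approximately multiplicative at small $p_0$ — the
quantity IC estimates. Every case has a guaranteed suspect drug; further
drugs are suspect/interacting/concomitant with probabilities 0.5/0.1/0.4,
so the concomitant stream exercises the role filter.

What the generator does *not* model, and hence what passing tests do not
establish about real data: reporting trends over time (report years are
uniform), informative missingness (real databases are MNAR — e.g. serious
cases are better documented), duplicate reports, indication channelling
and confounding by underlying disease, and within-class correlation of
event risk. Signal-recovery results on this generator validate the
*statistic and pipeline*, not robustness to those biases.

In the planted-signal validation study (the conditions under which the
package's signal-recovery claims are tested: 20 replicate databases of
50 000 cases, $p_0 = 0.005$, one drug planted at relative rate 8 among 40
nulls, single-drug reports dominant with `mean_extra_drugs = 0.05`), the
planted drug is deliberately given a *small* popularity share (~1.7 % of
reports, via `planted_signal_catalog()`). This is because the case/non-case
comparator includes the planted drug's own excess cases: a popular signal
drug inflates $N_{eff}$ and dilutes its own observed-to-expected ratio
below the planted rate, and the $+0.5$ shrinkage lowers small-count ratios
further. The study asserts the mean of $2^{IC}$ in $[6, 10]$ around the
planted 8, significance of the planted drug in at least 19/20 replicates,
and a false-positive rate at most 4 % among null drugs with $E \ge 5$
(nominal 2.5 % plus Monte-Carlo slack).

## The calibration fixture

`calibration_fixture()` packages a database on which the three exclusion
stages reproduce the reference tallies of a hyperammonaemia screen — 642
event-associated drugs; 555 excluded as not significant, 11 as
single-country, 5 as protopathic; 71 retained. The fixture plants *exact
counts* rather than sampling them: null drugs receive one or two event
cases, counts for which the Gamma bound is negative for every possible
expected value (at $N_{obs} \le 2$,
$Q_\Gamma(0.025; N_{obs}+0.5, 1) < 0.5 \le E + 0.5$), while planted drugs
receive five or more event cases against few background reports, which
puts their $IC_{025}$ safely positive at the fixture's event rate.
Event-case countries cycle a multi-country rota except for the 11
single-country drugs, which are pinned to one country each. Consequently
the stage tallies are invariant to the seed — randomness touches only
nuisance fields (ages, sexes, onset times, outcomes, report years) — and
`check_calibration()` verifies them at build time by actually running the
screening pipeline, naming the failing stage if any. A stochastically
thinned fixture could not make the tallies exact: with 555 null drugs and
a 2.5 % nominal threshold, about 14 would cross it per realisation.

## Numerical and degenerate-input choices

* Screen ordering is descending $N_{obs}$ with ties broken by `drug_id`,
  so output files are reproducible.
* The pipeline itself draws no random numbers; `run_pipeline()` rewrites
  byte-identical outputs on identical inputs, and the run log records
  content hashes instead of timestamps for the same reason.
* Counts are validated against
  $N_{obs} \le \min(N_{drug}, N_{eff}) \le N_{tot}$ before any IC is
  computed; impossible contingencies are typed errors, not NaNs.
* Missing values are empty CSV fields and absent JSONL keys, never
  sentinel numbers; `sex` and `action_taken` use the explicit `"unknown"`
  token as their missing value since it is part of their vocabularies.
* An empty event-PT set is a configuration error raised before any
  computation; an event matching no cases is *not* an error (the screen is
  simply empty).
* Test problem sizes: unit and property tests run on databases of
  200–4 000 cases; the signal-recovery study uses 20 × 50 000 cases and the
  calibration fixture about 15 500 cases — sizes at which the asserted
  statistical bands are comfortably stable while the whole suite stays
  fast.

## Known limitations

Disproportionality is not risk: without exposure denominators neither
incidence nor relative risk can be estimated, and IC significance is a
reporting association. No multiplicity adjustment is applied across the
screened drugs, matching standard signal-detection practice where
$IC_{025} > 0$ is itself the conservative element. The single-country rule
uses the country *value* equality only; it does not detect near-single-
country concentration. Protopathic exclusion depends entirely on the
supplied list. The label-knowledge and phenotype tables are user inputs
whose quality bounds the NI/B and presentation outputs.
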