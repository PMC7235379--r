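---
title: "Methods: cohorts, pathways, and drug-resistance classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cohorts, pathways, and drug-resistance classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epipathways)
```

## The analysis in one paragraph

`epipathways` characterizes how pediatric epilepsy is treated by mining
ordered anti-seizure-medication (ASM) sequences from OMOP-CDM-style
records. A patient enters the cohort at their first-ever ASM prescription
(the *index date*) if they were 18 or younger, remained observed for at
least two years, carry an epilepsy diagnosis, and kept filling ASM
prescriptions in every 120-day *persistence window* after the index. Each
member's *treatment pathway* is the list of distinct drug ingredients in
order of first exposure during the initial two treatment years. The
number of distinct ingredients classifies drug resistance: reaching a
third ASM is the operational surrogate for drug-resistant epilepsy (DRE).
Pathways are then counted, stratified by epilepsy category, onset age and
syndrome, and summarized as an annual monotherapy prescription trend.

## Cohort model and its assumptions

The cohort definition is a new-user design without wash-out: EHR data
cannot show prescriptions issued elsewhere before the record starts, so
the first observed exposure is taken as the first ever. Day arithmetic is
integral: the index day is day 0, and the default persistence windows are
the closed intervals [121, 240], [241, 360], [361, 480], [481, 600],
[601, 730] in days since index. The first 120 days carry no requirement
because the index prescription itself covers them; the window list is a
plain parameter, so requiring [1, 120] as well is a one-line change.
Closed intervals were chosen because interval-boundary membership is
otherwise ambiguous; the boundary tests pin both endpoints.

Age at index is exact fractional years, `days / 365.25`, and the cap
"age ≤ 18" is inclusive on that scale. Note this is subtly stricter than
"before the 19th birthday" and subtly looser than "strictly under 18";
with leap days, a calendar 18th birthday is about 18.0014 fractional
years and therefore falls just outside. A person whose first-ever
exposure fails the cap is excluded outright rather than indexed on a
later exposure, because index events are limited to the earliest per
person. The epilepsy-diagnosis requirement accepts a diagnosis at any
time, before or after index — the permissive reading, which avoids losing
patients whose diagnosis was coded at a later visit.

Each person may have at most one observation period. Multi-period input
is rejected with an explicit error instead of being silently merged:
period-stitching rules (how large a gap may be bridged) are a study
design decision we do not want to make implicitly.

## Sequences and the DRE classifier

Drug exposures are point events (prescription dates), not eras. The
persistence criterion counts prescriptions inside windows, and the
sequencer needs only first-exposure dates, so era construction would add
assumptions without adding information. Sequences de-duplicate to the
first occurrence of each ingredient, capped at 20, within a window of 730
days after index (`window_days = NULL` sequences the full follow-up).
Substitution and addition are deliberately indistinguishable — the data
rarely record why a drug appears — so a pathway "A → B" covers both
"switched from A to B" and "added B to A". Same-day first exposures are
ordered by concept id, a documented, deterministic tie-break.

`classify_dre()` is a threshold on the distinct-ingredient count,
default 3: two ASMs may reflect one substitution, but a third agent
implies failure of two adequate trials, which is the usual operational
reading of the ILAE definition when seizure outcomes are not in the
data. Because the 1 / 2 / 3+ partition is exhaustive and disjoint,
`pct(3+) = 100 − pct(1) − pct(2)` holds up to one-decimal rounding for
any input.

Two share definitions are offered by `asm_frequency()` because "the share
of drug X" is ambiguous in a pathway table. The default *slot share*
divides an ingredient's appearances by the total number of sequence
positions and sums to 1; the *patient share* divides by the cohort size
and does not. Slot share is the default because it weights each
prescription decision equally rather than each patient.

## Stratification and trend definitions

The bundled condition vocabulary holds 20 epilepsy concepts — 10 focal,
9 generalized, 1 unclassified (the unclassified concept id is synthetic,
since unclassified patients have no single source code) — with syndrome
tags for Lennox–Gastaut syndrome (LGS), childhood absence epilepsy (CAE)
and benign epilepsy with centrotemporal spikes (BECTS). When a patient
carries several distinct epilepsy concepts, the *classifying diagnosis*
is the most frequent one, with ties broken by earliest start date and
then lowest concept id. This policy is an explicit choice (source records
do not dictate one); it lives in a single internal function so an
alternative policy is a drop-in replacement.

Onset-age bins implement "under 4 / 4 to 13 / over 13" as the half-closed
partition [0, 4), [4, 13], (13, 18]: the ordinary-language reading puts
both boundary ages in the middle bin. Within every stratification kind
the strata are pairwise disjoint and, together with the remainder stratum
("unclassified" or "none"), cover the cohort — an invariant the test
suite asserts on randomized inputs.

The annual trend counts *monotherapy-in-year*: for calendar year Y and
ingredient D, the number of cohort members with at least one exposure to
D and none to any other ASM ingredient in Y. A patient on two drugs in a
year contributes to neither; a patient can contribute in several years.
Counts, not shares, are emitted, because the appropriate denominator
(active patients? observed patients?) depends on the question being
asked.

## What the synthetic generator emulates — and what it does not

The generator produces the five CDM tables plus per-patient ground truth
(intended cohort membership, true pathway, true syndrome, onset age,
index date, dropout reason). Its defaults are the study conditions the
package targets:

| parameter | default | rationale |
|---|---|---|
| calendar span | 2004-01-01 – 2017-10-31 | the emulated observation era |
| onset age | truncated normal, mean 8.3, sd 5.0, on [0, 18] years | reference cohort's age at diagnosis |
| follow-up | truncated normal, mean 6.5, sd 3.2, on [2.0, 14.2] years | reference cohort's follow-up |
| sex | P(male) = 653/1192 | reference cohort's sex ratio |
| syndrome mixture | proportional to the bundled reference counts (835 focal : 344 generalized : 12 unclassified) | reference diagnostic case mix |
| dropout | p = 0.2, one persistence window emptied | attrition with a known, testable cause |

Members are constructed to satisfy the default cohort definition:
prescriptions follow a roughly 60-day cadence whose jittered anchor days
(±15 days) cannot leave their 120-day window, so persistence holds by
construction; drug *k* of an *L*-drug pathway first appears on day
`round((k−1)·730/L)` and co-continues afterwards (add-on semantics).
Dropouts are identical except that one uniformly chosen window is emptied
of all exposures — a targeted violation, so each excluded patient's
logged reason can be compared with the injected one. An optional
`calendar_trend` table multiplies the selection weight of sequences by
first-line drug per index year, which is enough to inject directional
drift into the monotherapy trend.

The reference-count total is 835 + 344 + 12 = 1,191, one less than the
1,192 patients of the reference demographics; the counts and the total
come from the same source and disagree by one. The generator uses the
proportions and leaves the discrepancy as-is.

The `make_paperlike_config()` preset adds per-subgroup pathway mixtures
whose injected DRE rates reproduce the reference subgroup profile
(back-solved so the subgroup rates pool to 187/835 focal and 91/344
generalized: focal-non-BECTS 0.2357, BECTS 0.09, generalized-other 0.228,
CAE 0.071, LGS 0.79, unclassified 0.238) and whose marginal slot shares
approximate the reference top five (valproic acid ≳ oxcarbazepine >
lamotrigine ≈ levetiracetam > topiramate). These menus were tuned
analytically against the closed-form slot-share implied by the mixture,
once, at design time.

What the generator does **not** emulate — and therefore what green tests
do not certify about real data: dosing and dose forms, visit structure,
comorbidities and co-medication, irregular prescription cadence,
era-style exposures with gaps, multiple observation periods, coding
errors and vocabulary drift, age-dependent drug choice (phenobarbital in
infants, for example, appears only via its mixture weight, not as an
age-coupled preference), and any correlation between onset age and
pathway. Real EHR pipelines must expect all of these.

## Numerical and degenerate-input choices

* Dates are ISO-8601 throughout; CSV files are comma-separated UTF-8 with
  mandatory headers, so fixtures round-trip bit-exactly.
* `n_patients = 0`, empty cohorts, and empty strata are valid everywhere:
  readers return typed empty tables, `count_pathways()` returns an empty
  table with total 0, empty strata report `NA` DRE percentage.
* A cohort member with no in-window exposures is impossible by
  construction, so `build_sequence()` treats it as an internal
  consistency error rather than returning an empty sequence.
* Probability maps must sum to 1 within 1e-9 at config time; failures are
  config errors, not downstream surprises.
* All generation is deterministic given (config, seed); the generator
  saves and restores the caller's RNG state.
* Pathway tables order rows by descending count then sequence string;
  sunburst children by descending count then name — every output is
  byte-stable across runs.

## Problem sizes

The shipped tests run the oracle-equivalence comparison on 200 random
instances (mostly 3–35 patients, with spot checks at 150–500), mixture
recovery on a 2,000-patient paper-like cohort, constructive recovery on
300 patients at 30% dropout, and structural invariants on over a thousand
randomized cases; `scripts/acceptance.R` recomputes the headline
quantities on a fresh 2,000-patient simulation. These sizes give the
binomial checks (3 standard errors) enough resolution for every injected
pathway with probability ≥ 0.02 while keeping a full run in minutes on
one core.

## Known limitations

Ingredient-level vocabulary only: mapping branded or combination products
onto ingredients is supported through an optional
`ingredient_concept_id` column but no mapping table is bundled. Exposure
is prescription-based; actual adherence is invisible. The DRE surrogate
counts drugs, not seizure outcomes, and misclassifies patients who switch
drugs for tolerability. The monotherapy-in-year definition is calendar
based; a patient switching in December counts for neither drug that year.
Single-site semantics: no federation, no de-identification machinery.
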