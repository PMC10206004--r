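---
title: "Scoring treatment response from clinical notes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring treatment response from clinical notes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(notescore)
```

## The problem

Cholinesterase inhibitors (CEIs) are prescribed to dementia outpatients for
cognitive symptoms; SSRIs for the neuropsychiatric symptoms that accompany
dementia. Outside of trials, how many patients actually respond is hard to
measure: structured instruments such as the MMSE are administered too
irregularly to anchor a before/after comparison for most patients, and the
richest evidence of benefit or harm lives in free-text clinical notes
("anxiety better", "memory slightly worse or around the same").

`notescore` operationalizes a note-based scoring procedure for exactly this
setting. Each *medication episode* (a continuous period of same-class drug
use) is scored, per symptom domain, on a three-point ordinal scale —
1 improved, 2 no change, 3 worse — with two side codes: 0 when no evidence
is available (N/A) and 0.5 when the drug was stopped for an adverse event
or added to the allergy list (intolerance). A parallel seven-point global
impression of change (1 markedly improved ... 4 unchanged ... 7 markedly
worse) is assigned from the same evidence whenever an intensity modifier
makes the finer grading possible.

## The annotation model

Annotation is deliberately lexicon-driven, not statistical. The built-in
lexicon enumerates drug names, psychiatric and cognitive symptom cues,
direction-of-change cues, and intensity modifiers. Matching is whole-token
and case-insensitive with no stemming: the inventory explicitly lists
inflected forms ("improve, improvement, improved, improving"), so stemming
would add ambiguity without adding coverage. Negation is handled by the
lexicon itself ("not helpful", "no improvement" are no-change entries) plus
a longest-match rule: when two phrases of the same category group overlap,
only the longer is kept, so "not helpful" suppresses "helpful". Suppression
is confined to a category group (drugs / symptom cues / direction cues /
intensity) on purpose — "no longer depressed" must beat the direction cue
"depressed" would never carry, while still leaving "depressed" visible as
the psychiatric cue that fixes the sentence's domain.

Some direction entries are *templates*: a trigger that only becomes a
direction cue when a slot-filling cue co-occurs within eight tokens. This
is how the asymmetric reading of "stable" is implemented: cognition is
expected to decline, so "dementia stable" is *no change*, while "agitation
now stable" is an *improvement*. The eight-token window, and the
three-token window within which an intensity modifier may attach to its
direction cue, are implementation choices (clinical phrasing is short;
wider windows start capturing unrelated clauses); neither is derived from
a reference value, and both are exposed as arguments.

Sentences that carry a direction cue and a drug mention but no symptom cue
("sertraline working well") are annotated with an *unclassified* domain and
are counted only toward the drug class's own target domain — psychiatric
for SSRIs, cognitive for CEIs — when an episode is scored.

Author role (clinician / caregiver / patient) is read from note metadata,
never inferred from the text: the downstream priority rule needs an
attribution the words themselves do not reliably carry. Roles outside the
known set map to `unknown`, which ranks below `patient` — the conservative
choice for evidence of unknown provenance.

## Episodes and exclusions

Prescription records merge into episodes under a washout rule: same-class
records separated by less than 90 days (of reported disuse, or between a
stop and a switch) continue one episode; 90 days or more start a new one.
A disuse gap within a single drug follows the same rule as a switch. The
calendar-language constants are fixed as days — "3 months" = 90/91 days,
"6 months" = 182 days — so the boundary behavior is exactly testable; all
windows are closed. An episode whose previous record has no stop date is
treated as ongoing use, so a same-class switch during it merges.

Episodes are excluded, with an enumerated reason, when the reported start
is more than 182 days before or 91 days after the first order (index)
date; when an SSRI episode starts within 90 days of a prior SNRI; for
unknown start dates, protected records, never-started prescriptions,
discontinuation due to a changed diagnosis; or when no follow-up
annotation exists after the start. Intolerant episodes are exempt from the
follow-up rule: intolerance *is* their outcome (0.5), and excluding them
for lacking efficacy evidence would remove a category the rate tables are
designed to report.

## Evidence prioritization

When an episode has several domain-relevant comments, one is selected by,
in order: (1) direction precedence improve > worse > no change — a noted
improvement marks the drug effective even if decline is recorded later,
and definite change outranks "about the same" within a sentence too;
(2) author priority clinician > caregiver > patient > unknown, applied
among comments of the winning direction; (3) for the cognitive domain,
comments dated within 14 days of a measured MMSE change; (4) proximity to
the 182-day mark, earlier date breaking ties. The 14-day MMSE-matching
tolerance reuses the same two-week window as the MMSE-change computation
itself, inclusive of day 14. Where improve and worse comments carry the
same date and author, precedence (1) already resolves the tie in favor of
improvement; this is a documented choice, as no reference behavior exists
for that corner.

MMSE change is the score nearest the comment date minus the score nearest
the episode start, both within 14 days, nearest-first and earlier-on-ties.
MoCA scores convert to MMSE equivalents through a bundled monotone
crosswalk table; the file is labelled *synthetic* because it is a
constructed stand-in with the structural guarantees downstream code needs
(identity at both endpoints, monotone non-decreasing, MoCA reading below
MMSE mid-range) rather than a transcription of a published table. Only the
sign of an MMSE change ever feeds back into scoring behavior, so row-level
values of the crosswalk do not affect any reported statistic.

## The validation battery

* **Krippendorff's alpha** (ordinal metric) is computed from the
  coincidence matrix and tolerates missing cells, weighting each unit's
  pairable values by 1/(m−1); codes 0 and 0.5 are recoded to missing. The
  implementation is original to this package and is tested against an
  independent brute-force oracle written directly from the
  pairwise-disagreement definition.
* **ICC(2,k)** — two-way random effects, average measures — comes from the
  ANOVA mean-squares identities after listwise deletion of non-evaluable
  units, with the row-effect F test for significance. A perfectly agreeing
  non-constant matrix gives exactly 1 with p below 0.001.
* **Dice coefficients** are reported per category; a category absent from
  both raters is omitted rather than reported as 0/0.
* **Spearman correlations** use midrank ties and exclude code-0/0.5 pairs;
  ordinal statistics are only meaningful on the 1–3 (and 1–7) part of the
  scales.
* **BCa bootstrap intervals** are hand-implemented (bias correction from
  the bootstrap distribution with a midpoint tie convention, acceleration
  from jackknife influence values). Degenerate resamples are skipped and
  counted; more than half failing is an error, not a silent narrowing. The
  quantile-adjustment step is exposed (`bca_interval()`) so the reduction
  to the plain percentile interval at zero bias and acceleration is
  directly assertable. Defaults follow the analysis constants: 500
  iterations for reliability statistics, 10,000 for correlations.
* The **multinomial baseline-category logit** is fitted by
  `nnet::multinom`; each covariate's p-value is a type-II likelihood-ratio
  test (full model vs. the model with that covariate dropped). The
  significance threshold is 0.05 throughout and no multiple-testing
  correction is applied, matching the analysis the battery mirrors.

## The synthetic corpus

The generator exists so that every stage is testable end to end with known
ground truth. Its defaults *are* the study conditions: 225 SSRI cases
(6 N/A, 17 intolerant, 156 improved, 28 no change, 18 worse) and 115 CEI
cases (7 N/A, 12 intolerant, 31 improved, 40 no change, 25 worse), with
the corresponding diagnosis-group, sex, and age margins. Category counts
are honoured exactly, never sampled. Each case becomes one patient with
one prescription record (hence exactly one included episode), a comment
drawn 120–240 days after the start from sentence templates assembled from
lexicon phrases, an author role drawn from a clinician-heavy mix
(0.7/0.2/0.1), and — for half of evaluable cognitive cases — pre/post MMSE
records whose change sign matches the truth direction. Intolerance is
signalled by the structured adverse-event flag, not by text. N/A cases get
a genuine follow-up comment in the *other* domain, so they pass the
follow-up screen yet stay unavailable on the prioritized domain, as such
cases do in practice. An intensity modifier is attached with probability
0.7; without one, a comment is scorable on the three-point but not the
seven-point scale, which is precisely the relationship between the two
scales the package models.

What the generator does *not* emulate: realistic clinical prose,
misspellings, abbreviation noise, multi-episode patients, conflicting
multi-author narratives, or correlation between covariates and outcome.
Passing round-trip tests therefore demonstrates that the pipeline's rules
are implemented exactly — not that the lexicon would capture every way a
real clinician phrases change. `noise_rate` removes a comment's keyword
(and adds distractor sentences) with the given probability, which
degrades recovery roughly linearly and is the knob robustness tests use.

At `noise_rate = 0` the round trip is exact: annotation recovers every
embedded (domain, direction) pair, scoring recovers every truth category,
and the rate tables reproduce the built-in case mix percentages, e.g.
69.3% SSRI improved and 27.0/34.8/21.7% CEI improved/stable/worse, with
97.3% / 93.9% evaluable. One printed-rounding caveat is deliberate: the
CEI responder share computes to 71/115 = 61.739 → 61.7% under half-up
rounding; a source that prints 61.8% for the same fraction has applied
inconsistent rounding, and this package reports the computed value.

## Problem sizes and determinism

Test and validation runs use the default corpora (225 + 115 cases), a
500-case round-trip corpus, rater matrices of 10–30 units, and bootstrap
runs of 200–500 iterations — sizes chosen because every property they
check is scale-free (exact rule behavior, oracle agreement to 1e-6,
determinism). All randomness flows through explicit integer seeds:
identical seeds give byte-identical corpora, bootstrap intervals, and
output files (each stamped with the seed and a config fingerprint).

## Known limitations

* The lexicon is American-English and inventory-bound; phrasing outside it
  is invisible to the annotator by design (no embeddings, no spelling
  correction).
* Memantine and SNRIs are out of scope as treatment classes; SNRI history
  enters only through the carryover exclusion.
* Domain/direction pairing within a sentence uses token distance, not
  syntax; densely packed multi-clause sentences can mispair in ways the
  bounded windows only mitigate.
* The crosswalk table is a labelled synthetic stand-in (see above).
* The multinomial model reports likelihood-ratio p-values only; no effect
  sizes or corrected inference.
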