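---
title: "Methods: rule-based Gleason extraction, specimen classification and triage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rule-based Gleason extraction, specimen classification and triage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gleasonr)
```

## The extraction model

`gleasonr` treats Gleason-score curation as four composed, fully
deterministic stages operating on raw note text.

**Mention extraction.** A score mention is anchored on a lexicon hit
("Gleason score", "Gleason", "GS"; case-insensitive, whole-token so that
"GS" never fires inside another word). Around each anchor a bounded window
is scanned for the numeric components using surface grammars in fixed
precedence:

| grammar | example | yields |
|---|---|---|
| (a) `P+S=T` | `Gleason 3+4=7` | all three, read |
| (b) `P+S` | `Gleason 4+3` | P, S read; T derived |
| (c) `T (P+S)` | `GS 7 (4+3)` | all three, read |
| (d) lone total | `Gleason 9` | T read; P, S unknown |
| (e) qualified pattern | `Primary GS was 4` | one pattern read |

Two grammar details matter for error detection. First, (b) carries a
negative lookbehind for an opening parenthesis: otherwise `GS 8 (4+3)`
would be consumed as the pair `4+3` and re-derived to a *consistent* 7,
silently erasing the note's written (and wrong) total. Second, a lone
integer next to an unqualified anchor is accepted only in 6–10, and digits
glued to `/`, `-`, `%` or other digits are rejected, so dates
(`9/2019`), ranges (`Gleason 6-7`) and percentages never become totals.
Hyphenated ranges are therefore deliberately unparsed — a documented
limitation, not an accident.

When exactly two components are read, the third is completed via the
identity *P + S = T* and recorded as *derived*. Completion never
overwrites a read digit and is idempotent. Validation then classifies each
mention: `incomplete` (any component still missing), `inaccurate` (a
component out of range — P, S in 3–5, T in 6–10 — or all three read with
*P + S ≠ T*), else `valid`. A derived component skips the sum check (it
holds by construction) but not the range check: from `P = 3, T = 9` the
derived `S = 6` is carried verbatim and flagged inaccurate downstream,
never clamped.

**Specimen classification.** Pathology reports describe a single
accession, so they receive one note-level class before extraction, from
specimen cues anywhere in the text; every mention inherits it. Clinical
notes are extracted first and classified per mention, because one clinic
note can cite scores from several specimens. Cues carry priority tiers
(tier 1 = most specific: "prostatectomy", "RRP", "PNBx", "core biopsy";
tier 2 = generic: "pathologic stage", "biopsy", "cores"); within a search
window the best tier wins and ties break by character proximity of cue
midpoint to anchor midpoint. If the first window holds no cue the search
broadens along the schedule and finally covers the whole note. A residual
exact tie between a surgery and a biopsy cue returns `unclassified`
rather than a guess: mis-assigning a specimen corrupts the database
silently, whereas an unclassified mention is escalated to review.

**Triage.** The triage unit is the (patient, specimen) *task* — exactly
two per patient, which is what makes cohort arithmetic well defined
(2 tasks x n patients). A task is `complicated` when any of four reasons
holds: `inaccurate` (any such mention), `incomplete` (an incomplete
mention with *no* valid mention supplying the task), `conflicting` (two
valid mentions in *different* notes with different scores), or
`unclassified_specimen` (the would-be deciding evidence has no specimen).
Two of these rules were genuinely open design choices:

* *Incomplete is downgraded under redundancy.* A terse "Gleason 7" in a
  clinic note does not escalate a patient whose pathology report spells
  out 3+4=7; only tasks whose evidence is incomplete *everywhere* are
  flagged. The alternative (any incomplete mention flags) would route a
  large share of ordinary patients to review for no information gain.
* *Conflicts compare full triples by default.* 3+4=7 vs 4+3=7 is a real
  clinical disagreement (the dominant pattern differs, and 4+3 carries a
  worse prognosis), so triples are compared component-wise; a config
  switch (`conflict_mode = "totals"`) relaxes this for users who only
  curate totals. Mentions within one note never self-conflict.

The fourth reason, `unclassified_specimen`, exists because the three
classical reasons cannot dispose of an unclassifiable mention: dropping it
would bias the maximum rule, and blindly assigning it would guess. It
fires only when the task has no classified valid mention of its own.

**Aggregation.** Per task, the patient-level result is the maximum valid
score — by total, ties to the higher primary (4+3 over 3+4, the more
aggressive reading), then first-seen; for valid triples equal (T, P)
forces equal S, so aggregation is fully permutation-invariant. Classified
mentions are preferred; purely unclassified valid evidence still produces
a *draft* (the task is complicated anyway and the draft merely seeds the
reviewer). No valid evidence yields `not_found`, which is itself a
reportable outcome, not an error.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| parse window after / before anchor | 60 / 30 | characters | components usually follow the anchor within a clause; the before-window is a fallback for inverted phrasings. Windows stop at sentence boundaries (period + whitespace) and at neighbouring anchors so adjacent mentions cannot steal digits. |
| classification radii | 150, 500, whole note | characters | ~one sentence, ~one paragraph, then everything; strictly increasing, whole note always last. |
| cue tiers | per lexicon file | — | tier 1 for terms that name the procedure; tier 2 for terms that merely imply a context. |
| `conflict_mode` | `"triples"` | — | see above. |
| generator `complication_rate` | 0.0485 | per task | the observed complicated fraction in the cohort the generator emulates. |
| generator note means | 18.2 clinical / 3.6 pathology | notes/patient | observed per-patient note volumes. |
| generator `surgery_prob` | 0.56 | — | share of patients with a documented surgery score (biopsy scores are always documented). |
| generator `upgrade_prob` | 0.35 | — | chance a surgery score is strictly upgraded over the biopsy; surgery totals never fall below biopsy totals (pathologic upgrading, not downgrading). |
| `kind_split` | uniform | — | only the aggregate complication rate is known; the three corruption kinds default to equal shares. |
| human error rates (simulation) | 10/381 uncomplicated, 0 complicated | per task | the observed review error rates; a labelled Bernoulli stand-in for real annotators, not a claim about them. |

All window sizes and tiers are config-exposed through the lexicon YAML;
the bundled lexicon is a reconstruction of an expert-curated list and the
config file is the escape hatch for local dialects.

## The synthetic generator: what it does and does not show

`generate_corpus()` renders each patient's true scores into pathology
reports and clinical notes drawn from a template bank covering grammars
(a)–(d), both specimen types and score-free filler, then injects
corruptions task-by-task: `inaccurate_sum` perturbs a written total by
one, `missing_component` replaces the score expression with a
primary-only statement, `cross_note_conflict` fabricates a second note
with a different valid score. Corruption is sampled per task across all
2n tasks, so the complicated count is exactly Binomial(2n, rate); a
corrupted surgery task that would otherwise have been undocumented gets a
score instantiated first, since every corruption kind needs score text to
corrupt (this inflates surgery documentation by at most
`(1 - surgery_prob) x rate`, under half a percent at defaults). One
master seed drives counter-derived per-patient substreams, so corpora are
byte-identical across runs and edits to one patient's draws cannot
cascade.

Grammar-(d) templates (lone totals) are used only as echoes of a task
that already carries a complete rendering — deliberately, so the
incomplete-downgrade rule is exercised while clean corpora stay fully
recoverable.

What passing tests on this corpus demonstrate: the extraction grammars,
classification logic, triage rules and bookkeeping are internally
consistent, deterministic, and achieve 100% task accuracy and 100%
corruption recall *on in-grammar text*. What they do not demonstrate:
performance on real clinical prose — abbreviation dialects outside the
template bank, OCR noise, copy-forward duplication, negation ("no
Gleason assigned"), tertiary patterns and Grade Groups are all outside
the generator's vocabulary, and real-world accuracy must be established
by chart review, exactly as the assisted workflow assumes.

## Numerical and degenerate-input choices

* **Rounding:** reported accuracies use half-away-from-zero rounding at
  one decimal (95.25 → 95.3), with a 1e-9 guard against binary
  representation artifacts. Accuracy on zero tasks is an error, not NaN.
* **Fisher exact test:** implemented by direct enumeration of the
  hypergeometric support with fixed margins; "as extreme" uses a 1e-7
  relative tolerance when comparing point masses, and when the whole
  support qualifies the p-value is exactly 1 by construction. Agreement
  with `stats::fisher.test` is asserted in the test suite; empty strata
  yield `NA` rather than a fabricated table.
* **Tie-breaks** are all deterministic and documented: longer lexicon
  surface over shorter at one offset, better tier then proximity for
  cues, higher primary for equal totals, `unclassified` for exact
  cue-class ties.
* **Degenerate inputs:** empty corpora run vacuously (zero records, zero
  queue, exit 0); empty note text yields no mentions; a patient with no
  mentions still owns two (uncomplicated, `not_found`) tasks.

## Problem sizes used by the checks

The bundled test suite runs clean round-trips at 30 patients, corruption
recall at 40–60 patients with an elevated 0.3 rate (to observe enough
corrupted tasks), generator calibration at 100 patients over several
seeds, and one full 200-patient end-to-end cohort at a 5% complication
rate whose flagged-task count is required to fall within three binomial
standard deviations of its expectation. These sizes were chosen to give
every rule multiple opportunities to fire while keeping the default
`R CMD check`-style run comfortably fast on one core.

## Known limitations

* The lexicon and template bank are reconstructions; institutional
  dialects will need config additions (that interface is the point).
* No section segmentation or negation handling: a cue in "family history
  of prostatectomy" classifies like any other cue.
* No temporal logic: aggregation is by maximum, never by most recent, and
  same-day duplicate notes are not merged.
* Tertiary patterns, Grade Groups and sub-6 (benign) totals are out of
  scope end to end.
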