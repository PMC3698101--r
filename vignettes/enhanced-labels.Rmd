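---
title: "Linking drug claims to product-label sections: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking drug claims to product-label sections: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(labelweaver)
```

## The problem and the model

Drug product labels are the reference document clinicians consult for a
drug's efficacy, interactions and pharmacokinetics, yet their content can
trail the literature by years. labelweaver prototypes the *dynamic
enhancement* of labels: rather than editing the label, it computes a
mapping graph that attaches machine-readable claims from external drug
information sources to the label sections where a reader would look for
them, and surfaces a cue when a claim appears to be new to that section.

The routing model is deliberately simple and fully determined by claim
kind:

* a published result of a registered clinical trial whose interventions
  include the drug routes to the **Clinical Studies** section;
* an active drug–drug interaction (DDI) claim naming the drug as a
  participant routes to the **Drug Interactions** section, carrying its
  two-valued severity (`Critical` interactions are less modifiable by
  local formularies than `Significant` ones);
* a pharmacokinetic assertion (the drug *is a substrate of* or
  *inhibits* a metabolic enzyme) that has at least one supporting or
  refuting evidence item routes to the **Clinical Pharmacology**
  section.

A mapping exists per (claim, label) pair, and only for labels that carry
the target section: a mapping "to a section" requires the section. This
was a genuinely open design point — one could attach claims to the label
regardless — so the permissive variant is available behind
`attach_missing_section = TRUE`, with the default chosen because every
downstream novelty computation reads the section text. Mapping identity
is `(spl_id, claim_kind, claim_ref)`: evidence items never multiply
mappings, and a PK claim's identity is its (object drug, slot, enzyme)
triple, so the evidence-level and unique-claim views of the knowledge
base are kept distinct (`pk_evidence_records()` vs the graph, reconciled
by `unique_claim_count()`).

## Novelty flagging

A DDI claim is flagged *potentially novel* to a label when

1. the interactor's name does not occur in the label's Drug Interactions
   section under a case-insensitive substring match on normalized text
   (lower-cased, markup stripped, whitespace collapsed); an absent
   section counts as no occurrence, and
2. when a reference interaction set covers the drug, the (object drug,
   interactor) pair is not listed in it after drug-class entries have
   been expanded to their member drugs.

Substring (not token) matching is intentional: the method's interesting
failure modes live at the string level. A section that says "digoxin"
does not cover a claim naming "digitalis", so the claim is flagged even
though a clinician would consider it covered — the flag is *potentially*
novel, an audit cue rather than an adjudication. Word-boundary matching
is available (`word_boundary = TRUE`, default off) for users who prefer
fewer accidental substring hits at the cost of missing hyphenated or
inflected mentions. The two criteria are checked text-first because the
text test is cheapest; the result is order-independent. The flag is
monotone in the reference set: adding entries can only withdraw flags.

The PK cue is the negation of a plain substring search of the Clinical
Pharmacology text for the full enzyme name. A hyphenated shorthand list
("CYP3A4, -1A2, -2C19") therefore does *not* match `CYP2C19`; this is a
known under-count that we preserve rather than repair, because the
search string semantics are part of what is being evaluated.

## Discourse classification

Published-result abstracts are segmented by a deterministic rule-based
splitter (sentence ends at `.`/`!`/`?` followed by whitespace and an
upper-case letter or digit, with an abbreviation and single-initial
guard; structured-abstract headings remain prefixed to their first
sentence, so concatenation reconstructs the input). Any splitter with
these properties would do — what matters for evaluation is that gold and
predictions use the same one.

Conclusion-sentence identification is a pluggable interface: any
function mapping a sentence vector to an equal-length tag vector over
the 11 core scientific discourse tags is accepted, and the evaluation
code is classifier-agnostic. The shipped baseline tags every sentence
from a `CONCLUSION`-bearing heading to the next heading as `Conclusion`
and everything else `Background`. This mirrors the section-based
convention used when reference standards are built by extracting
consecutive conclusions-section sentences — which also means the
baseline is exact (P = R = 1) on heading-structured abstracts and finds
nothing on heading-free ones; the generator can emit a heading-free
fraction precisely to expose that cliff. A trained statistical
classifier is out of scope by design; it would plug in through the same
interface.

## Evaluation quantities

`prf()` computes precision, recall and balanced F over sentence-id sets,
with empty-set conventions P = 0 for an empty prediction set, R = 0 for
an empty gold set, and F = 0 when P + R = 0. `pipeline_precision()`
composes the routing step's precision — relevant routed conclusions over
*interpretable* routed conclusions — with the classifier's precision;
the interpretable denominator (routed minus dropped non-studies, before
removing uninterpretable ones) is an assumption we document because with
the published counts (51/166 × 0.75 = 0.230) it reproduces the printed
two-decimal value. `cohen_kappa()` is the textbook chance-corrected
agreement with kappa defined as 1 when both raters are constant and
identical. `relevance_bookkeeping()` enforces the review-flow identities
(considered = routed − dropped; relevant = considered − uninterpretable
− non-relevant; indication-relevant = relevant − off-label) and fails
loudly, naming the violated identity, instead of silently clamping.

Printed-style outputs round half away from zero (`round_half_up()`), and
medians for even n are the mean of the two middle order statistics; raw
values are retained alongside every rounded figure. Distribution
summaries are computed over drugs with at least one item of the kind
being summarized, matching how ranges are conventionally reported with
zero-count drugs excluded.

## The synthetic-data generator

Nothing in the package downloads data. `generate_corpus()` emulates the
full data environment — SPL-dialect labels, trial registry, DDI
terminology, PK knowledge base, reference set — with *exact* ground
truth: the generator decides per (claim, label) whether the interactor
or enzyme string is embedded in the section text
(`p_mentioned_in_text`), and per claim whether the reference set covers
it (`p_in_ref_set`), so every expected novelty flag, mapping count and
per-drug summary row is known by construction. Drug and interactor
names are synthetic with a fixed `<letters><digits>` shape chosen so
that no name can occur as a substring of a different name and filler
prose contains neither digits nor lexicon words — planted decisions
therefore translate into flags with no accidental matches. Optional
stressors: a `synonym_trap` claim whose interactor is an alias of a name
that *is* in the text (the flag stays true, reproducing the
string-match blind spot), inactive claims, combination products, and a
`p_missing_section` probability.

Default generator conditions (8 drugs, 2–10 labels per drug, up to ~8
Significant and 6 Critical claims, small PK and trial ranges, mention
and coverage probabilities of 0.5) are desk-scale values matching the
order of magnitude of a per-drug pilot; they were fixed when the
generator was written. `pilot_fixture()` is different in kind: it is
deterministic and plants the per-drug counts of a 29-drug psychotropic
pilot — 1,102 labels, 784 DDI claims with planted novelty counts, 112
unique PK claims carrying 161 evidence items (each claim has one item
per evidence direction present; 46 deterministic replicates create the
duplicate-key records), and 409 published results over 22 drugs — so the
summary-arithmetic identities (column sums 409 and 784, medians 9 and
16, means 19 and 13, the 161→112 deduplication) are exercised end to
end.

What passing these tests shows — and does not show. The generator's
prose is templated, names are synthetic, and mentions are planted
verbatim; success demonstrates that the pipeline's mechanics (routing,
matching, counting, rounding) are exact, not that the string-matching
heuristic performs well on real label prose, where synonyms,
abbreviations and formatting make both false flags and missed mentions
common.

## Numerical and degenerate-input choices

* All text I/O is UTF-8; normalization is deterministic, so matching is
  reproducible across platforms.
* Duplicate mapping insertion is idempotent (first wins); graph rows are
  kept in `(spl_id, claim_kind, claim_ref)` order so serializations are
  byte-stable.
* The triple count expands one triple per populated mapping field; the
  novelty predicate is bound-only — counted and emitted only when a
  claim is flagged — so audits can filter on the predicate's presence.
* Severities outside {Critical, Significant} and PK slots outside
  {substrate_of, inhibits} are hard load-time errors; a dangling
  published-result reference yields a placeholder pair plus a warning
  (dropping it silently would understate the routing count).
* Unknown drug ids in corpus lookups return empty results with a
  warning, not an error (mirroring optional-match query semantics).
* DDI participant matching is exact preferred-label equality on trimmed
  labels, case-insensitive by default and configurable — synonym
  resolution is deliberately absent so the digitalis-style failure mode
  remains observable.

## Problem sizes used in the checks

The acceptance-level suites run on: the deterministic 29-drug pilot
corpus (built once per test run); a 3 × 3 grid of mention/coverage
probabilities {0, 0.5, 1}² × 3 seeds of small random corpora (3 drugs,
1–3 labels each) for ground-truth recovery; 1,000 random instances each
for the precision/recall and kappa oracle-equivalence checks; and 25
structured abstracts for classifier exactness. These sizes give full
coverage of the combinatorics (every flag path, every claim kind, even
and odd median cases) while keeping the suite quick to run.

## Known limitations

* Novelty is lexical, not clinical: no synonym, class or ontology
  reasoning at match time (class expansion applies only to the reference
  set), so flags over-trigger on renamed drugs and under-trigger never.
* The baseline classifier is a convention detector, not a model; its
  perfect fixture scores say nothing about free-text performance.
* The SPL dialect is a small subset of the real schema; full HL7
  validation and relational staging are non-goals.
* Corpus-scale figures that depend on historical snapshots of external
  resources (tens of thousands of labels, endpoint triple counts) are
  not reproducible here and are not claimed.
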