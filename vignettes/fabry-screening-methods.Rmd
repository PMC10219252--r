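---
title: "Screening for Fabry disease from clinical text: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening for Fabry disease from clinical text: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fabryscreen)
```

## The screening model

`fabryscreen` implements a factor-based screening statistic rather than a
learned classifier. With around a dozen confirmed cases in a realistic
hospital cohort, fitting and validating a discriminative model is
statistically fragile; an additive, expert-weighted score is fully
controllable and explainable, which is what a screening workflow that ends
in physician review requires. The per-patient risk factor is

$$R = \sum_{f} s_f(\text{age}) \cdot \mathbb{1}[f \text{ present, not vetoed}],$$

where each clinical feature $f$ has an integer base score $s_f \in
\{0,\dots,3\}$, optionally raised (capped at 3) when the feature appears
below an age threshold. Patients with $R \ge$ cut-off (default 4) are
flagged for manual review. The assumptions are explicit: feature evidence
is binary (a feature either has supporting evidence or not; repetition does
not accumulate), features contribute independently and additively, and a
documented alternative cause fully discounts a feature.

### The 13-feature catalog

The shipped catalog (`default_catalog()`) is a *reconstructed default*, not
a published table: hypertrophic cardiomyopathy, myocardial infarction,
arrhythmia/conduction abnormality (cardiovascular); renal
failure/impairment, proteinuria (kidney); angiokeratoma,
hypohidrosis/heat–cold intolerance (skin); stroke/TIA, neuropathic
pain/acroparesthesia, hearing impairment, gastrointestinal symptoms,
recurrent fever (neurological); cornea verticillata/eye fundus lesions
(eye). Base scores follow two principles: features common in the general
population score low (1: cardiomyopathy, infarction, arrhythmia,
proteinuria, hearing, GI symptoms, fever), while features specific to the
disease score high (3: angiokeratoma, cornea verticillata). Features that
are normally diseases of the elderly — stroke, myocardial infarction, renal
failure, hearing loss — carry an age modifier (+1, capped at 3) below age
55. The 55-year threshold and the precise score values are package
defaults, declared in `inst/extdata/catalog.yaml`; membership and weights
are configuration, not code, so a site can substitute its own catalog. A
present feature never scores 0 in the default catalog (minimum 1); a score
of 0 is reserved for absence or veto.

Vetoes ("feature exclusion criteria") discount renal failure when
nephropathy, amyloidosis, sarcoidosis, Alport syndrome, nephrectomy,
urolithiasis or congenital renal defects are documented, and stroke when a
patent foramen ovale or trauma is documented. "Documented" means any
affirmed mention or matching ICD-10 code — no certainty grading, which is a
deliberate simplification. Cohort-level criteria exclude patients outside
18–75 years and patients with palliative care, alcohol dependency,
disseminated cancer, blood cancer or chemotherapy.

## The text pipeline

Extraction is a nine-stage rule pipeline: pattern compilation, sentence
splitting, typo correction + lemmatization, tokenization, pattern search,
negation evaluation, dictionary storage, similarity linking, and entity
emission. Choices that the pipeline contract leaves open are resolved as
follows:

* **Tokenization and spans.** Whitespace tokenization with punctuation
  split off; token spans are 0-based, half-open; sentence indices 0-based.
* **Typo correction** rewrites a token only when it is out-of-vocabulary,
  at least 4 characters long, not a negation cue or adversative token, and
  at Levenshtein distance exactly 1 from a vocabulary entry (first entry in
  vocabulary order wins). The cue guard is load-bearing: "never" is
  distance 1 from "fever", and an unguarded corrector would silently
  destroy negation detection. The lexicon also carries an
  `extra_vocabulary` of common note words ("patient", "examination", ...)
  so ordinary prose is never rewritten into medical terms.
* **Lemmatization** is an ordered suffix-rewrite table (first match wins),
  not a morphological analyzer: deterministic, testable, and portable
  across languages by editing configuration.
* **Overlap resolution** is longest-match-first, ties by leftmost start,
  then by lexicon order ("cornea verticillata" beats "cornea").
* **Negation** is a cue within 5 tokens before the mention, bounded by the
  sentence, reset by adversative conjunctions ("but", "however", ...).
  Window and cue list are configurable; the denial vocabulary shipped is
  English.
* **Similarity linking.** Out-of-vocabulary tokens are embedded and linked
  to the nearest dictionary term by cosine similarity when it reaches the
  threshold (default 0.85; ties to the earlier entry). The default embedder
  is a deterministic hashed character-trigram vector (dimension 256, signed
  buckets, L2-normalized): it requires no model download, makes
  byte-identical runs trivial, and sits behind a provider interface
  (`build_lexicon(embedder = ...)`) so pretrained word vectors can be
  substituted. Orthogonality of trigram-disjoint phrases holds up to hash
  collisions, which at dimension 256 are possible in principle; the test
  suite verifies it on collision-free pairs.
* **Abbreviations** match only when explicitly present in the lexicon
  (e.g. "pfo"); nothing is inferred.
* ICD-10 codes are expanded to descriptions (exact code first, then longest
  prefix) and the descriptions are processed as an additional note, on top
  of direct prefix matching against the catalog — so a code can contribute
  evidence through either route, but only ever to the same feature.

## Evaluation conventions

Predicted-positive means risk factor ≥ cut-off. ROC curves are built from
all distinct score thresholds and integrated trapezoidally; the
precision–recall area uses the step-wise precision-at-recall convention.
Metrics with zero denominators are reported `NA` rather than erroring,
because degenerate confusion matrices legitimately occur at extreme
cut-offs. The enrichment of the flagged group is reported as 1:k with
k = round(FP/TP) and fold = integer part of N/k against a 1-in-N population
rate. Group comparisons use the Mann–Whitney test for numeric attributes
and the chi-squared test when all expected counts are ≥ 5, otherwise
Fisher's exact test; a binary trait absent from one group entirely is
reported untested.

## What the synthetic cohort emulates — and what it does not

`cohort_spec()` defaults describe a deliberately imbalanced screening
cohort at desk scale: 5 cases against 7,450 controls (≈1:1,490), case ages
truncated-normal 45.2 (SD 10.5) and control ages 55.5 (SD 13.3) clipped to
18–75, 38.5% / 50.5% female. Control per-feature probabilities were chosen
so the five sign-group marginal frequencies match published hospital-cohort
values (cardiovascular 34.3%, skin 0.8%, neurological 26.0%, kidney 10.5%),
with probability shifted inside each group toward low-scoring features so
control risk factors concentrate in 0–3. The eye group is the one deliberate
deviation: the catalog's only eye feature is the pathognomonic cornea
verticillata (scored 3), so mapping the 1.5% generic eye-disorder marginal
onto it would be clinically wrong and inflate control scores; the default
uses 0.4%. Case probabilities were calibrated once so case risk factors
concentrate in roughly 3–11. Noise defaults (typo 0.1, paraphrase 0.2,
denial 0.3, confounder 0.25 per eligible feature) are all *recoverable by
construction*: planted typos are single-character edits whose unique
distance-1 vocabulary neighbour is the original token, so the no-noise and
default-noise pipelines both recover every intended risk factor, and noisy
runs exercise the correction machinery rather than degrade ground truth.

The audit-corpus generator (`generate_audit_corpus()`) plants exactly one
gold mention per description plus distractors and, at rate 0.06 per
description, a near-miss distractor — a single-character morphological
neighbour of a *different* term that the typo corrector normalizes into
that term, creating a controlled false positive. The noise defaults were
calibrated once so that per-term precision varies by symptom and stays
above the 0.70 floor (roughly 0.80–1.00), emulating the reported behaviour
of the human-audited extractor they stand in for.

The generator does **not** emulate: correlated comorbidity (features are
sampled independently), longitudinal records, section structure, real
clinical prose or any specific natural language's morphology, coded-lab
idiosyncrasies, or undiagnosed cases hiding among controls. Passing
end-to-end tests therefore demonstrates internal correctness of
extraction–mapping–scoring–evaluation under controlled noise, not clinical
performance on real EHRs.

## Problem sizes and determinism

Every generator draws from a single seeded RNG stream with a documented
per-patient draw order, so identical specs and seeds give byte-identical
cohorts. The test suite uses small cohorts (tens to a few hundred patients)
for unit and property checks, 100 random cohorts for the oracle-equivalence
properties, one full default cohort (7,455 patients) for the end-to-end
separation check, and 100 descriptions per term (2,700 total) for the
precision audit — sizes chosen so the whole suite runs comfortably on a
single CPU.

## Known limitations

* The lexicon, negation cues and lemma rules shipped are English; the
  original screening context was Polish-language EHRs. The method is
  language-agnostic but the shipped resources are not a translation of the
  original dictionary.
* The hashed-trigram embedder captures surface similarity only; true
  synonyms with different surface forms must be listed in the lexicon,
  whereas a pretrained embedding could link them.
* Negation handling is a window rule: scope ambiguity, coordination
  ("no X or Y"), and pre-mention cues beyond the window are out of reach;
  there is no coreference, temporality or section awareness.
* The cohort-level AUC/AUPRC of the original study depend on its private
  hospital cohort and cannot be reproduced here; the package instead
  verifies its evaluation code against closed-form and rank-statistic
  oracles and demonstrates separation on the synthetic default cohort.
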