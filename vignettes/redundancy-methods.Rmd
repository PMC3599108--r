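---
title: "Measuring and mitigating copy-paste redundancy in note corpora"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring and mitigating copy-paste redundancy in note corpora}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(noteredund)
```

## The phenomenon

Longitudinal clinical corpora are built from notes that clinicians partly
copy from the patient's earlier notes. Pairs of notes from one patient
therefore share long verbatim token sequences, while notes from different
patients share only common vocabulary. This vignette documents how the
package measures that redundancy, what it does to corpus statistics, how
the fingerprint-based reduction bounds it, and — because protected health
data cannot ship with a package — how the synthetic generators emulate the
regime and where the emulation stops.

## Alignment-based redundancy

`align_local()` runs token-level Smith–Waterman local alignment. The
scoring defaults (match +2, mismatch −1, linear gap −1) are the standard
text-alignment choice; nothing in the downstream statistics depends on
their absolute scale, only on the match/penalty ratio, and all four values
are configurable through `alignment_scoring()`.

Copy-paste produces *several* shared segments per note pair, which a
single local alignment misses, so the default mode extracts alignments
repeatedly: find the best local alignment, mask its spans in both
sequences (masked positions pin their dynamic-programming cells to zero,
so later segments can never reuse them), and repeat while the best
segment scores at least `min_segment_score = 4`. With the default match
score this requires two consecutive matching tokens, which suppresses
single shared-token noise — important because any two clinical notes share
function words. Traceback prefers diagonal over up over left moves; the
test suite's naive full-matrix oracle uses the same convention so
matched-token counts are comparable exactly.

Pair redundancy divides matched tokens by each document's length and
symmetrizes by averaging. A zero-length document has redundancy zero by
definition. `redundancy_profile()` samples unordered same-patient or
cross-patient pairs uniformly without replacement (seeded) and reports
per-pair records, a decile histogram and the mean.

On the two sentences "Pt developed abd pain and acute cholecystitis" /
"Pt developed acute abd pain and cholecystitis", shared-word identity is
100% while the alignment matches 6 of 7 tokens (85.7% per sequence, or
75% of the 8 alignment columns counting the two gaps): word-set overlap
cannot see sequence changes. No default parameterization of the aligner
produces exactly 73% for this pair; we report the parameterization and
the resulting numbers rather than forcing a target.

## Fingerprinting and the greedy reduction

Fingerprints are character-level substrings of length `n` taken line by
line; no fingerprint spans a line boundary. *Full* fingerprinting takes
all `m − n + 1` windows of an `m`-character line, *selective*
fingerprinting the `⌊m/n⌋` consecutive non-overlapping windows starting
at offset 0 (trailing remainder discarded). The default granularity
`n = 20` characters is long enough to be specific and short enough that
a typical 40–80 character note line still yields two or more selective
fingerprints. Profiles use set semantics — repeated boilerplate lines
within one document count once — and fingerprints are hashed with a
stable 64-bit FNV-1a (collisions accepted; tests also run unhashed).

Similarity of B to A is `|FP(A) ∩ FP(B)| / |FP(A)|`. The greedy
construction visits documents in a configurable order (input, date, or
seeded random), retains a document unless some already-retained document
exceeds the cutoff in *either* direction, and indexes retained
fingerprints in an inverted index so each candidate is scored only
against documents it actually shares fingerprints with. The source
definition of the ratio fixes only "similarity of B to A", not which
document plays A inside the loop; we apply the test symmetrically because
that is the conservative reading and it guarantees the final-set property
both ways — verified exhaustively in the tests, where the indexed
implementation must equal a quadratic oracle document for document.
Cutoff 1.0 rejects nothing (similarity cannot exceed 1); cutoff 0 retains
a maximal prefix-greedy set of pairwise fingerprint-disjoint documents.

`last_note_baseline()` implements the metadata alternative: keep each
patient's most recent note (ties broken by file position). It guarantees
zero same-patient redundancy but discards most of the corpus.

## Collocations and patient support

Bigrams are adjacent token pairs within a line (never across line
boundaries, consistent with line-based fingerprinting; the concept layer,
which has no lines, is treated as one sequence per document). PMI is
`log2(n11·npp / (n1p·np1))`; TMI is the mutual information of the full
2×2 contingency table in log base 2, empty cells contributing zero. Both
are computed as ratios of exact integer products before dividing, so
uniformly duplicating a corpus (all counts × K) leaves every score
bit-identical — the duplication-invariance property is exact, not
approximate. Extraction supports a score threshold or a deterministic
top-n (ties: score, then count, then lexicographic), an optional
vocabulary restriction (used to control for corpus size), and a
minimum-count floor.

Patient support counts the distinct patients whose notes contain the
bigram; the low-support fraction uses "3 patients or fewer". Note one
subtlety: with no frequency floor, most extracted bigrams in a modest
corpus are singleton pairs whose support is 1 regardless of redundancy,
saturating the statistic. The support audit is therefore run at
`min_count = 5` — the scale at which a note pasted five times turns a
signature into a top collocation — and the package default remains
`min_count = 1` for plain extraction.

## Frequency-of-frequencies diagnostics

`frequency_spectrum()` maps each occurrence count f to the number of
terms occurring exactly f times and coarsens into log2 bins
`[2^k, 2^(k+1))`, including empty bins up to the maximum count. Under
Zipfian sampling the spectrum is hapax-dominated and the binned counts
decrease; copy-paste moves mass into mid-frequency bins. The secondary
peak is defined on the bins (raw counts jitter too much): the first bin
`b ≥ 2` whose count exceeds the previous bin's, unset exactly when the
bin sequence is non-increasing after its first bin. Defining the peak
this way (rather than demanding an explicit fall before the rise) keeps
the x5-duplication signature detectable: a corpus duplicated five times
has *empty* low bins — every count is a multiple of 5 — and its mass
reappears in the `[4, 8)` bin. The log-log slope is an unweighted least
squares fit of `log2(n_terms)` on `log2(f)` over non-empty spectrum
cells; it is a descriptive diagnostic, not an estimator of a power-law
exponent, hence no maximum-likelihood machinery.

## Topic models

`fit_lda()` is a collapsed Gibbs sampler with fixed symmetric priors
α = 50/T and β = 0.01. Prior (hyper-parameter) optimization is
deliberately out of scope: the redundancy penalty is a corpus property
and reproducing its direction does not require tuned priors. Sampling
uses a private Mersenne-Twister stream seeded from the configuration, so
a fit is bit-reproducible and independent of R's global RNG state.

Held-out likelihood uses the left-to-right sequential estimator: within
each document, word n's predictive probability is averaged over particle
states of topic assignments to words 1..n−1, each particle resampling
those assignments before scoring. Ten particles are the default;
estimator noise at these sizes is below 0.1 nats per token (tested).
Out-of-vocabulary held-out tokens are dropped and counted. Reporting is
in natural-log nats, normalized per token so corpora of different sizes
are comparable.

Two evaluation rules matter when comparing corpora:

* **Disjoint splits.** `topic_curve()` refuses a held-out set sharing
  documents — or, when patient ids exist, patients — with the training
  corpus, because a patient's notes partially duplicate each other and
  would leak training text into the evaluation.
* **Shared vocabulary.** When comparing corpora of different sizes, all
  models are fit over one fixed vocabulary (`vocab` argument). With
  per-corpus frequency-filtered vocabularies, the larger corpus admits
  extra rare words, its held-out evaluation scores extra hard tokens, and
  the per-token values are not comparable — the artifact is large enough
  to reverse the direction of the size effect. The default vocabulary
  rule for a single fit remains "words occurring at least twice in
  training".

## The synthetic generators

`duplicate_corpus()` (xK) repeats every document exactly K times —
grouped, with derived ids — and is used to exercise the exact
invariances. `sample_corpus()` (sK) draws each document's multiplicity
i.i.d. uniformly on {1..K}; with K = 5 the expected corpus size is 3×
the base with standard deviation `sqrt(2 n)`. (The uniform{1..5} law is
the stated construction for this scheme; we note that the originally
reported corpus size for it matches uniform{1..4} instead — the stated
law is implemented and the discrepancy recorded, not resolved.)

`generate_ehr_corpus()` simulates the EHR regime:

* **Vocabulary**: `vocab_size` words with Zipf(`zipf_exponent = 1.1`)
  weights; the top ranks form a common pool every note draws from with
  probability `common_word_frac = 0.4` (this shared vocabulary is what
  creates the small cross-patient alignment floor). The remaining words
  are split into `n_topics` interleaved blocks, one per latent topic, so
  every topic has a comparable weight profile.
* **Patients**: a Dirichlet(0.3) topic mixture and
  `name_tokens_per_patient = 2` unique name tokens written as an
  adjacent pair on a dedicated line of every note — the signature that
  reconstructs the single-patient collocation artifact.
* **Copy-paste**: each note copies `round(copy_fraction · L)` of its L
  content lines verbatim from the patient's immediately preceding note
  (chain copying, which compounds along the record the way clinical
  copy-paste does; the first note copies nothing). Because a pair of
  notes at gap g shares roughly `copy_fraction^g` of its lines, the
  corpus-mean same-patient redundancy sits well below the per-note
  fraction: the default `copy_fraction = 0.55` was calibrated once so
  the default corpus lands at ≈30% mean same-patient and ≈3%
  cross-patient alignment redundancy, the regime reported for
  informative clinical notes.
* **Burstiness**: within a note, each fresh token repeats an earlier
  token of the same note with probability `burstiness = 0.4` (a Polya
  urn). Real prose is bursty, and burstiness is what gives a document
  idiosyncratic content. This matters for the duplication experiments:
  if tokens were conditionally i.i.d. given the patient mixture, a
  duplicated document would be statistically exchangeable with a fresh
  one and non-uniform duplication would be a harmless reweighting; with
  burstiness, duplication inflates document-specific words and the
  topic-model penalty appears for the same reason it does in real text.
* **Metadata**: sequential weekly dates (so the last-note baseline is
  well defined) and rotating informative note types.

Identical configuration and seed reproduce a corpus byte for byte; the
`synth_truth` attribute exposes the generating vocabulary, topic blocks
and patient mixtures for recovery studies.

What the generator does *not* emulate: clinical language and templates,
section structure, within-copy edits (copied lines are verbatim),
de-identification artifacts, and note-length/type heterogeneity beyond
the configured uniform ranges. Tests passing on these corpora show the
algorithms behave as claimed under controlled redundancy; they do not
certify performance on any particular real EHR.

## Numerical choices and degenerate inputs

* Alignment of an empty sequence returns zero matches; ties in the DP
  argmax resolve to the first maximum in row-major scan order.
* Fingerprint profiles of documents whose lines are all shorter than `n`
  are empty; similarity against an empty reference profile is 0; an
  empty candidate shares nothing and is always retained.
* `score_bigram()` on an empty table is an error; TMI cells with zero
  count contribute zero.
* A one-cell spectrum yields `NA` slope without error. A lone term with
  count ≥ 2 sits above empty lower bins and is reported as a (vacuous)
  rise.
* Collocation extraction with a threshold above every score returns a
  zero-row frame; support statistics on it are `n = 0`,
  `frac_low_support = 0`.
* Per-T seeds in `topic_curve()` are derived as
  `(seed + 7919 T) mod 2^31 − 1` so grid entries are independent but
  reproducible.

## Problem sizes used by the shipped studies

The test suite and acceptance script run at sizes chosen to make every
stochastic direction stable under their fixed seeds: redundancy and
mitigation studies on 50-patient corpora (≈350 notes) with 300 sampled
pairs; reduction-oracle equivalence on 100 documents at cutoffs 0.20,
0.25 and 0.33; alignment-oracle equivalence on 200 random pairs up to
length 40; the topic-model study on a 300-document base corpus
(vocabulary 2,000) against its s5 sample and a 3×-larger corpus, at
T ∈ {10, 20, 40}, 250 Gibbs sweeps, 10 particles and three seeds; topic
recovery on a 5-topic, 400-word generator. The spectrum studies use a
6,000-word vocabulary: at these note counts a 2,000-word vocabulary
saturates (mean occurrences per type ≈ 3.5) and no corpus — redundant or
not — is hapax-dominated, which would confound the Zipf-shape contrast.

## Known limitations

* The greedy reduction is order-dependent (as any online algorithm);
  the final-set guarantee holds for every order, but *which* documents
  survive differs. Date order is the natural choice for clinical
  corpora.
* Fingerprint similarity is a proxy for alignment; its correlation with
  alignment redundancy is high on copy-paste corpora (tested ≥ 0.7,
  observed ≈ 0.99) but character-level coincidences can inflate it on
  highly templated text.
* The left-to-right estimator is sequential and O(n²) per document;
  held-out documents should be modest (hundreds of tokens).
* PMI/TMI are the only association measures implemented; log-likelihood
  ratio and friends are out of scope, as are n-grams beyond bigrams.
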