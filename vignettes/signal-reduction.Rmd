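---
title: "Signal reduction for expected speech input: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Signal reduction for expected speech input: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cohorttrace)
```

## The question and the design

A recurring inference in the cognitive neuroscience of speech runs: *reduced
activity for expected input implies predictive coding* — the idea that only
the mismatch between input and a top-down prediction is propagated upward.
`cohorttrace` implements the simulation apparatus needed to probe that
inference in the novel-word-learning paradigm: an existing **source** word
(e.g. *formula*), a **novel** nonword sharing its onset (*formubo*) that is
"lexicalized" by training, and a matched untrained **baseline** nonword
(*formuty*).  The three items share a prefix up to the **deviation point**
(DP) and diverge, pairwise, immediately after it.  Training is modeled
purely as lexicon insertion: the novel form is added at its source's
frequency, and all model quantities are recomputed.  Which of the two
nonwords counts as "novel" is counterbalanced and results are averaged over
both assignments.

Signals are aligned on the DP.  For the prediction model the alignment unit
is phoneme position (relative position ≤ 0 is pre-DP, ≥ 1 post-DP); for the
network model it is the update cycle relative to the onset of the divergent
phoneme's input.

Three empirical target patterns (`check_findings()`) operationalize signal
reduction:

1. pre-training, post-DP: source < novel ≈ baseline;
2. post-training, post-DP: source ≈ novel < baseline;
3. a pre-DP training effect whose direction depends on the signal:
   prediction error and word-layer totals decrease, total lexical feedback
   increases (the added entry is also a new competitor), phoneme-layer
   totals are unchanged.

"≈" is a relative tolerance, default 10%: the paradigm argues ordinal
patterns, not point values.

## The cohort prediction model

`predict_next()` computes the frequency-weighted distribution of the next
phoneme given a prefix: each lexical entry that strictly continues the
prefix votes for its next phoneme with its frequency (raw by default; a
`log1p` compression is exposed because the historical weighting choice is
not documented — with one entry per continuation the two coincide up to
normalization).  `prediction_error()` scores the presented phoneme by the
summed absolute difference between the predicted distribution and the
one-hot input, `2(1 − P(observed))` for a normalized prediction, bounded in
[0, 2].

Two boundary decisions matter:

* **Word-final entries are not continuations.**  An entry identical to the
  prefix has no next phoneme and is dropped from the cohort; no end-of-word
  symbol is modeled, since the model predicts phonemes, not boundaries.
* **Empty cohorts** arise for nonword prefixes past the divergence point.
  The default fallback is a uniform distribution over the inventory (error
  `2(1 − 1/|inventory|)`), flagged `empty_cohort = TRUE` in every output; an
  all-zeros alternative (`fallback = "zero"`, error exactly 1) is exposed.
  Headline comparisons use positions up to DP + 1, where pre-training
  cohorts are non-empty, so the choice only affects diagnostic tails.

Duplicate forms merge by summing frequency (homophones preserve total cohort
mass).  Positions are 1-based throughout and `dp` counts shared phonemes, so
the divergent phoneme sits at `dp + 1` and DP-relative position is
`position − dp`.

## The interactive-activation simulator

`run_iam()` implements a TRACE-family interactive-activation network:
phoneme units replicated at every time slice, word units replicated at every
alignment whose extent fits the trace, feedforward phoneme→word excitation
over each word unit's constituent (phoneme, slice) positions, excitatory
word→phoneme feedback over the same constituency, lateral inhibition within
each layer, shunting updates `Δa = net·(act_max − a) − decay·(a − rest)` for
positive net input (mirrored through `act_min` for negative), synchronous
across units, clamped to `[act_min, act_max]`.  Only positive activations
transmit.  There is no stochastic component anywhere in the module.

Parameter defaults follow the classic public settings of this model family
(phoneme→word 0.05, word→phoneme 0.03, lateral inhibition 0.04/0.03, decay
0.03/0.05, rest −0.1/−0.01, range [−0.3, 1], six slices per phoneme, input
spread ±3, 100 cycles); all are overridable through `iam_params()` and are
echoed into every result object.

Design choices where the architecture was genuinely open:

* **The feature layer is abstracted.**  Bottom-up input drives phoneme units
  directly via `encode_input()`: phoneme *i* peaks (drive 1) at slice
  `(i−1)·spp + 1` with a triangular ramp over ±`input_spread` slices
  (coarticulatory overlap).  No measured quantity here refers to feature
  units, so this preserves every reported signal while removing the
  feature-geometry bookkeeping.
* **Input is a transient sweep.**  The unit at slice *t* is driven only
  while `|cycle − t| ≤ input_spread`; afterwards activation is carried by
  the network's own dynamics.  A persistent-drive variant was rejected
  because it makes the recognized word grow without bound, an artifact with
  no analog in speech input.  Consequently the divergent input's earliest
  arrival — and the pre/post-DP boundary `dp_onset_cycle()` — is
  `dp·spp + 1 − 2·input_spread`.
* **Word–word inhibition is graded by overlap**, measured in phoneme widths
  (slice overlap / `slices_per_phoneme`).  An all-or-none overlap rule lets
  a dominant candidate suppress barely-overlapping units at full strength,
  which eliminates precisely the weakly active, mid-item-aligned spurious
  candidates whose breadth the layer totals are supposed to register.
  Phoneme–phoneme inhibition applies within ±`input_spread` slices.
* **Word resting levels are frequency-independent** (novel items are
  frequency-matched to their sources by design, so frequency is outside the
  measured contrasts), making the dynamics invariant to uniform frequency
  scaling.
* **`total_feedback` sums transmitted excitation** — weight × positive
  sender activation per word→phoneme connection — rather than
  post-rectification receiver change: the flow is well defined before the
  receiver integrates it.  Layer totals sum raw, negative-capable
  activations (their resting-state values are therefore negative).
* **Readout** (`phoneme_timecourse()`) is from the input-aligned unit: the
  phoneme's unit at the slice where the item's corresponding position peaks.

## The synthetic stated world

`generate_lexicon()` and `generate_triples()` make the whole pipeline
runnable with no external data.  Defaults were chosen once, as the package's
stated world, to emulate a small natural vocabulary of the kind the
experiments assume:

* 200 words over a 14-phoneme inventory (the size of the classic simulator's
  phoneme set);
* word lengths 2–7 with probabilities (.08, .27, .27, .18, .12, .08) —
  peaked at 3–4 phonemes, like a small content-word vocabulary, with enough
  six-phoneme words to supply stimulus triples;
* rank-frequency `f(r) = 1000·r^(−s)` with `s = 1` (Zipf's law);
* **phoneme symbols drawn with Zipf(1)-skewed probabilities.**  Natural
  phoneme frequencies are strongly non-uniform, and this skew is what gives
  the vocabulary its cohort and neighborhood structure.  With uniform
  phonemes a 200-word lexicon is effectively neighborless: prefixes are
  almost surely unique, cohorts are singletons, and lexical competition —
  the mechanism under study — is vacuous.
* Triples: 15 six-phoneme sources with distinct pre-DP prefixes, divergence
  at position 5 (`dp = 4`, the final-two-phonemes replacement design).
  Replacement phonemes are drawn from the lexicon's empirical segment
  distribution (excluding the source's phoneme at the divergence position
  and each other, guaranteeing pairwise divergence exactly at `dp + 1`);
  uniform replacements would systematically hand nonwords rarer
  continuations than real words have.  Construction is rejection sampling
  with a 1000-attempt cap, so infeasible requests fail fast instead of
  hanging.

What the generator does **not** emulate: phonotactics (any phoneme sequence
is a legal word), morphology, and the long-tailed length distribution of a
full 37k-word corpus.  A green test on synthetic data therefore establishes
that the *mechanisms* produce the target patterns under realistic
frequency/neighborhood statistics — not that the specific published
magnitudes (e.g. pre-DP error means of 1.66/1.62 on the English Lexicon
Project vocabulary) are recovered; those depend on the empirical lexicon.

## What passes, and a known divergence

On the stated world (seeds 1/2; see `tests/testthat/test-acceptance.R`) the
cohort model reproduces all three findings, and the network model
reproduces: the anticipation effect (the lexically supported post-DP phoneme
out-activates the replacement phonemes before the DP; after training the
trained replacement rises pre-DP) and its ablation (no anticipation with
feedback weight 0); the post-DP orderings of both raw layer totals; and all
three pre-DP training directions — including the increase in total feedback
with training, the signature of added lexical competition, and the exact
invariance of the phoneme-layer pre-DP total.

The one divergence: the post-DP orderings of **total lexical feedback**
(findings 1–2) come out inverted here — the source word produces the *most*
feedback.  Total feedback counts only positive senders, and in this reduced
simulator the single best-supported candidate (activation ~0.6 across six
constituents) outweighs the breadth of weakly positive spurious candidates
(~10 extra units near 0.03) that unexpected input recruits.  Reference runs
of the full model imply pre-DP flow sums an order of magnitude larger
relative to the winner — cohort-dominated totals that require the
neighborhood density of a real English lexicon (and a feature front-end)
rather than a 200-word phonotactics-free sample.  The corresponding
acceptance expectations are left failing rather than weakened: an inverted
ordering is a result about the model/world combination, not a tolerance to
be widened.  The raw word-layer total — which the same argument would call
the coarser measure — does reproduce the published orderings, because
blanket lateral suppression below resting level tracks how concentrated the
evidence is.

## Numerical and procedural notes

* Normalization of non-empty-cohort predictions is exact to 1e-9 and tested.
* All experiment outputs (`cells.csv`, `findings.json`) are byte-identical
  across repeated runs of a fixed configuration; figures are re-rendered
  from the aggregated cells only.
* The sparse-matrix step update is verified against a naive dense
  re-implementation of the update rules on randomized states, and the
  analytic two-unit step against hand arithmetic.
* Desk-scale tests use reduced worlds (≤ 80 words, ≤ 4 triples, 30 cycles);
  the acceptance file runs the full stated world once and shares it across
  criteria.  A full counterbalanced network experiment (15 triples × 3
  conditions × 2 phases × 2 assignments, with caching of the
  assignment-independent runs) takes ~30 s on one CPU.
* `uniqueness_point()` (earliest prefix unshared with any other entry) is
  provided as a diagnostic; the experimental alignment uses the triple-based
  deviation point, not lexicon-wide uniqueness.

## Limitations

Beyond the feedback divergence above: no statistical inference across items
(the design compares means and orderings); no acoustic/feature front-end; no
learning dynamics inside the network (training is lexicon insertion); the
simulator is not a bit-compatible port of any published implementation, so
its absolute magnitudes are not comparable to published figures — only
directions and orderings are.
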