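---
title: "Fingerprint-based metabolite annotation from MS/MS spectra: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fingerprint-based metabolite annotation from MS/MS spectra: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ms2fp)
```

## The problem

Spectral-library matching can only annotate a metabolite whose reference
MS/MS spectrum has been measured. `ms2fp` implements the alternative:
predict a *molecular fingerprint* — a binary vector of substructure
presence/absence — directly from the fragmentation spectrum, then rank
candidate compounds retrieved by precursor mass according to the Tanimoto
similarity between their known fingerprints and the prediction, optionally
fused with an external molecular-formula prediction score. Because the
model predicts structure features rather than identities, it can rank
compounds it has never seen a spectrum of.

## Spectrum processing

Peak intensities are scaled so each spectrum's maximum is 100. Spectra are
kept only if they carry exactly one precursor mass and at least 5 peaks.
Peaks outside 100–1010 Da or with scaled intensity below 1 are removed, the
20 most intense peaks are kept (ties broken toward lower m/z for
determinism), and the survivors are summed into 0.01 Da bins. The closed
grid over [100, 1010] Da has exactly 91,001 bins; a peak at exactly
1010.0 Da falls in the last bin. Bins occupied by fewer than 0.1% of the
training spectra are dropped, separately per ionization mode. The stage
order is fixed — scale, spectrum filter, peak restriction, top-N, bin,
occupancy filter — and the package treats the bin grid as 1-based
(`bin_index` returns `floor((mz - 100)/0.01) + 1`), the natural indexing
for R matrices.

Two details are deliberate readings of ambiguous conventions: a bin exactly
at the occupancy threshold survives ("fewer than" removes strictly below),
and the intensity floor applies to *scaled* intensities, after the ceiling.
Bin-edge values are protected against floating-point representation error
by rounding the quotient to six decimals before flooring — an m/z printed
as 250.12 belongs to the bin starting at 250.12, not the one below it.

## Fingerprints

The fingerprint is a fixed concatenation of five families: FP3 (55 bits),
FP4 (307), PubChem (881), MACCS keys 1–166 (166), and Klekota–Roth (4860) —
6,269 bits total. FP3, FP4 and MACCS are computed with Open Babel's pattern
definitions via ChemmineOB, truncating Open Babel's word-padded vectors to
the published pattern counts. The PubChem- and Klekota–Roth-length blocks
are deterministic hashed linear-fragment keys: after Open Babel
canonicalization the molecular graph is traversed for all simple atom/bond
paths up to six bonds, each path is canonicalized (lexicographic minimum of
its two spellings) and hashed into the block with a family-specific salt.
Hashed path keys preserve everything the pipeline relies on — fixed length,
determinism, invariance to SMILES spelling, and substructure-driven
Tanimoto similarity — at the published block sizes.

Across a training compound set, bits constant across all compounds are
dropped and duplicate columns are condensed to one representative (the
lowest original index). The resulting `condensed_map` is a partition of the
6,269 bits and is serialized with any trained model: predictions only make
sense in the condensed space the model was trained in. The condensed
length reported for large spectral-library corpora (4,606 bits on a
43,386-compound training set) is a property of that particular compound
set; the package asserts the algebraic invariants (partition, exact
reconstruction of training compounds) instead.

## Supervised feature selection

Bins are scored by training, per bin, a one-hidden-layer perceptron from
that bin's intensity alone to all condensed fingerprint bits, and recording
the micro-averaged F1 on held-out folds of a 5-fold cross-validation
blocked by compound (replicate spectra of one compound never straddle a
fold). The top 500 bins are retained. A permutation-importance variant
(one joint perceptron; score = held-out F1 drop when a bin is permuted) is
available behind `selection_config(method = "permutation")`.

Fingerprint bits are then scored by a single multi-output convolutional
probe (one convolution layer of 32 width-5 filters, dense 64, sigmoid
outputs, plus the same linear bypass as the main models) under the same
fold scheme; bits with mean held-out F1 strictly above 0.8 are retained.
A held-out fold with no positive example for a bit is excluded from that
bit's mean by default: such a fold carries no evidence, and zeroing it
(available as `empty_fold = "zero"`) systematically punishes rare bits
until the selected space becomes too small to separate near-identical
candidates — on the synthetic benchmark it collapses the end-to-end top-1
rate from ~1 to near 0 because decoys tie with the true compound in a
16-bit space.

## Models and the training objective

Three multi-label architectures map the selected-bin vector to
probabilities over the selected fingerprint bits:

* **dense** — input → 512 → 256 → sigmoid(L);
* **conv** — the vector as a 1-channel sequence → two blocks of
  (convolution width 5; 64 then 32 filters; max-pool 2) → dense 128 →
  sigmoid(L);
* **recurrent** — the vector split into 20 contiguous chunks (zero-padded
  to divide) as a sequence → LSTM(128) → dense 128 → sigmoid(L).

Inputs are multiplied by 0.01 on entry so the 0–100 intensity scale maps to
unit-order activations. All sizes are `layer_plan` configuration values,
not constants.

The training loss is a differentiable Tanimoto: for a true bit vector $y$
and predicted probabilities $p$,
$\mathcal{L} = 1 - \frac{\sum_i y_i p_i}{\sum_i y_i + \sum_i p_i - \sum_i y_i p_i}$,
which on binarized predictions reduces to $1 - \mathrm{TP}/(\mathrm{TP} +
\mathrm{FP} + \mathrm{FN})$, the standard Tanimoto similarity on the
confusion counts. Binary cross-entropy is available as an alternative. The
degenerate all-zero/all-zero case is defined as loss 0. All forward and
backward passes are analytic and the test suite checks them against
numerical differentiation for every architecture and both losses.

### Why a linear bypass and sparse-proximal SGD

Each architecture adds a zero-initialized linear map from the input
directly to the output logits. The default optimizer is momentum SGD with a
proximal (soft-threshold) L1 penalty on weight matrices — 0.01 on the deep
layers, 0.003 on the bypass — applied after every step; Adam is available
by configuration.

This is the one place the package departs from a plain feed-forward
reading, and it is forced by sample size. At desk scale a training corpus
has tens of compounds, and replicate spectra of a compound are identical up
to noise, so the effective sample count is the compound count. In that
regime adaptive optimizers drive any of these architectures to interpolate
the training compounds through arbitrary co-adapted features: training
similarity saturates while validation similarity on held-out *compounds*
stays near the base rate, even though a single bin predicts each bit
almost perfectly (we confirmed the failure is optimizer inductive bias,
not data, with per-bit logistic fits). The true spectrum-to-fingerprint
map is sparse — a substructure emits a handful of characteristic
fragments — and the L1-regularized bypass recovers exactly that sparse
structure, while the penalized deep path is free to add what the bypass
cannot express. With this design all three architectures generalize across
compounds at desk scale under the Tanimoto objective; the property is
asserted in the test suite (validation soft-Tanimoto ≥ 0.8 per
architecture on the default synthetic study).

Training details: mini-batches of 32, up to 400 epochs, early stopping on
a compound-disjoint validation split (20% of compounds, patience 50),
best-epoch weights restored. Everything is seeded: building a model twice
from one spec gives identical parameters, and training twice gives
identical losses. Failure modes abort loudly — all-zero labels and
non-finite losses are errors, not warnings.

The probe hyperparameters in feature selection follow the same logic: the
bin probe (scalar input, no memorization risk) trains with Adam for 30
epochs at rate 0.05; the fingerprint probe shares the bypass design and
trains with the sparse-proximal SGD recipe for 150 epochs. Shorter budgets
leave the probes at chance, which would make the bin ranking arbitrary.

## Candidate retrieval, score fusion and ranking

Queries are matched against a user-supplied compound table by neutral-mass
hypotheses under the mode's adducts — [M+H]+, [M+NH4]+, [M+Na]+ in positive
mode; [M−H]−, [M+Cl]−, [M+FA−H]− in negative — with pinned monoisotopic
shifts (+1.007276, +18.033823, +22.989218, −1.007276, +34.969401,
+44.998201 Da; electron mass folded in). A compound is a candidate when its
monoisotopic mass lies within 5 ppm (relative to the hypothesis mass) for
any adduct; matching under several adducts yields one candidate tagged with
all labels. Retrieval is windowed on a sorted mass index and is tested for
equality against a brute-force linear scan.

Each candidate's condensed fingerprint is scored against the prediction —
Tanimoto on the binarized prediction by default, or the soft overlap on raw
probabilities (`score_space = "probability"`). External formula-prediction
scores, read from a CSV keyed by challenge and formula, are min–max
normalized within each challenge and fused as
$0.7 \cdot s_\mathrm{fp} + 0.3 \cdot s_\mathrm{formula}$. Candidates
without a formula score keep their fingerprint score unchanged. When all
candidates share one formula score (or there is a single candidate), the
normalized value is 1 for all: any constant leaves the ranking unchanged,
and 1 keeps the fused score's upper bound attainable. Ranking is by
descending overall score with *pessimistic* ties — every member of a tied
block gets the block's worst rank — so top-k rates are never inflated by
ties.

## Evaluation conventions

Confusion-count metrics use the standard forms: Tanimoto
$\mathrm{TP}/(\mathrm{TP}+\mathrm{FP}+\mathrm{FN})$, F1
$2PR/(P+R)$, and MCC with the four-factor square-root denominator. A
printed variant of the Tanimoto denominator ($\mathrm{FP}+\mathrm{FN}-\mathrm{TP}$)
circulates in the literature; it is not bounded in [0, 1] and is exposed
only behind `tanimoto_score(..., printed_form = TRUE)` for comparison.
Degenerate cases are pinned so tests are exact: empty-vs-empty Tanimoto and
F1 are 1; zero MCC denominators give 0. F1 and Tanimoto are micro-averaged
over all bits and samples; MCC is computed per bit and averaged ("mean
MCC"). The identity $F1 = 2T/(1+T)$ on shared counts is asserted
numerically against brute-force recomputation.

A candidate is a *hit* when it shares the first 14 InChIKey characters
(the connectivity skeleton) with the truth, so salt and protonation forms
count as the same structure. The same block rule drives the
structure-disjoint filter: training spectra whose skeleton appears among
test compounds are removed (records without an InChIKey are dropped and
counted, since they cannot be verified). Top-k tables report the fraction
of challenges with a hit at rank ≤ k for k ∈ {1, 3, 5, 10}, overall and per
ionization mode.

## The synthetic study

The generator plants a known spectrum-to-fingerprint rule so every stage
has ground truth without any external data. A per-seed codebook assigns
each fingerprint bit `peaks_per_bit` fixed fragment m/z values (distinct
bin centers in 100–1010 Da). A compound is a random Bernoulli fingerprint
(mean activity `bits_per_compound/n_bits`, at least one active bit), a
mass uniform in [150, 900] Da, and an InChIKey-like 14-10-1 identifier.
Each spectrum emits the codebook peaks of the compound's active bits with
log-normal intensity jitter, Poisson-many spurious peaks, and exactly one
proton-shifted precursor. Decoy database entries sit at a uniform ppm
offset (default 0.5–4 ppm, inside the 5 ppm retrieval window, so ranking
is decided by fingerprint similarity rather than by retrieval) and at an
exact fingerprint Hamming distance (default 4), with InChIKey skeletons
guaranteed distinct from every true compound. Synthetic formula scores
draw the true formula from N(0.9, 0.05) and decoys from N(0.4, 0.15),
clipped to [0, 1], with a configurable fraction of challenges missing the
true formula to exercise the fingerprint-only fallback.

The default study — 50 compounds, 64 bits, 4 spectra per compound, 5
decoys per compound, noiseless — is the condition under which the test
suite asserts the recovery properties: each architecture's validation
soft-Tanimoto ≥ 0.8, and end-to-end top-1 ≥ 0.9 with pessimistic
tie-ranking. Problem sizes elsewhere in the tests (for example 520- and
800-bin pools for the selection-cardinality checks, with intensity jitter
0.2 to break top-20 ties) were chosen as the smallest sizes at which the
properties are non-trivial.

What the generator does *not* emulate: chemically valid fragmentation
(fragment masses are arbitrary codebook draws, not substructure masses),
real fingerprint correlation structure (bits are independent Bernoulli),
isotope patterns, adducts beyond the protonated form, chimeric spectra,
or instrument-dependent noise. Passing the synthetic suite therefore
shows the pipeline machinery is correct and recoverable under a faithful
planted model — it does not certify performance on real libraries, where
bin-bit relationships are many-to-many and noisier.

## Known limitations

* The hashed path blocks are not the dictionary PubChem/Klekota–Roth keys;
  absolute Tanimoto values against literature fingerprints differ, though
  within-run rankings are consistent.
* The engine is plain R; it is sized for hundreds of selected features and
  desk-scale corpora, not for million-spectrum training runs.
* Condensation assumes the training compound set defines the output space;
  projecting an unseen compound can create within-group disagreements,
  which are counted and reported but resolved by the group representative.
* The recurrent architecture imposes an arbitrary sequence order on binned
  m/z; it is included for architectural parity, and nothing in the planted
  benchmark favors it.
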