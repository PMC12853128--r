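---
title: "Predicting carbohydrate-binding residues: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting carbohydrate-binding residues: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The prediction problem

Non-covalent protein–carbohydrate recognition underlies host–pathogen
adhesion, immune signalling and glycan processing. Given a protein chain,
`glycobind` asks, residue by residue, *does this residue bind a
carbohydrate?* — a heavily imbalanced binary classification, since a typical
chain offers only a handful of binding residues among hundreds of
non-binding ones.

Ground truth comes from co-complex structures: a residue is labelled
**positive** when at least one of its heavy atoms lies within 3.5 Å
(inclusive) of any heavy atom of a carbohydrate ligand, identified by its
HET code against an editable lexicon. We chose the inclusive comparison and
expose the cutoff as a parameter, since the boundary convention matters for
residues sitting exactly at 3.5 Å; the synthetic fixtures deliberately
straddle this boundary (nearest planted contact 3.4 Å, all other residues
≥ 3.7 Å) so tests exercise it. Water (`HOH`) is refused as a carbohydrate
regardless of lexicon content. The shipped lexicon is a documented,
editable stand-in covering common saccharide components — curations differ,
so the file under `inst/extdata/carb_lexicon.txt` is meant to be replaced
by the user's own list.

Deposited FASTA sequences routinely contain residues that were never
modelled in the crystal. We align the full sequence to the modelled
sequence by Needleman–Wunsch with match +1, mismatch −1, linear gap −2 and
a deterministic traceback (diagonal > up > left, which places unavoidable
gaps later in the sequence). The sequences are near-identical, so any sane
scheme produces the same alignment; fixing one scheme makes annotation
reproducible. Unmodelled positions carry the label `gap` (`-` in the
annotation files) and never become training samples.

Chains enter the dataset only when they have *strictly more than* five
binding residues and contain no nonstandard amino acids (the
physicochemical table is undefined for those).

## The feature system

Each residue is described by three ingested/derived blocks feeding the
feed-forward branch — 1024-wide ProtT5-type embeddings, the 36-wide
structural descriptor, and 1280-wide ESM-2-type embeddings, concatenated
in that order to width 2340 — plus a discrete 31-long window encoding
feeding the convolutional branch.

**Language-model embeddings are ingested, never computed.** Running the
underlying protein language models is far outside desk scale; the package
reads per-residue matrices (TSV or RDS) with strict shape checks. Users
who run the models themselves drop the matrices in; the synthetic
generator stands in for them during testing.

**The 36-dimensional structural descriptor** concatenates, in fixed order:

| block | width | notes |
|---|---|---|
| secondary structure one-hot | 9 | alpha helix, isolated beta-bridge, strand, 3-10 helix, pi helix, turn, bend, none, irregular |
| relative solvent accessibility bins | 10 | bin k is ((k−1)/10, k/10]; bin 1 closed at 0 |
| phi, psi | 2 | radians, 0 at termini/missing atoms |
| neighbour count | 1 | residues with centre atom within 12 Å (inclusive), self excluded |
| virtual surface area | 1 | convex-hull surface area of the residue's atoms, Å² |
| relative positions | 2 | 1/index and 1/(distance to centre-atom centroid), ε = 1e−6 Å |
| direction vectors | 9 | to previous/next centre atom and CA→CB, unit length |
| C=O and CA–CA angles | 2 | radians in [0, π] |

Design choices the descriptor depends on, none of which are forced by the
feature definitions themselves, are fixed as follows. The *centre atom* is
CA, falling back to the residue's heavy-atom centroid when CA is absent.
Direction vectors are unit-normalised, with the zero triple for undefined
cases (termini; glycine's missing CB). Angles are stored raw in radians
with no sin/cos expansion, since each angle is allotted width 1. Degenerate
convex hulls (fewer than four affinely independent atoms) report area 0.

Secondary structure and solvent accessibility use internal backends: a
Kabsch–Sander-style hydrogen-bond-energy assignment mapped onto the nine
classes (with *Irregular* the catch-all for assignable residues matching no
pattern, and *None* reserved for missing backbone atoms or chains shorter
than three residues), and Shrake–Rupley SASA with a 1.4 Å probe and 960
deterministic Fibonacci-lattice sphere points per atom. An external
DSSP-style executable can be plugged in through the `backend` argument of
`secondary_structure()`, honouring the same nine-class contract. RSA
normalises by the theoretical residue-type maxima of Tien et al., shipped
as an editable table; ratios above 1 (possible for highly exposed termini)
clamp to 1.

**PSSM-derived features** (per-residue 20-wide profile, 400-wide dipeptide
composition from products of neighbouring profile rows, and the 1-wide
monogram row sum) and the seven **physicochemical properties** are
implemented for completeness of the feature study, but are *not* part of
the final model input — group-level feature selection settles on the two
embedding blocks plus the structural descriptor. PSSM values default to
sigmoid scaling (`1/(1+e^{-x})`) before derived features, with a `raw` mode
available; the DPC block is flattened row-major. The shipped
physicochemical table uses the Meiler et al. normalized property set as a
documented stand-in, since published tables of these seven quantities vary
by source.

**Window encoding.** The 20 residues and the gap, `ARNDCQEGHILKMFPSTWYV-`,
are numbered 0–20. Each sample takes 15 upstream and 15 downstream
positions around its residue (31 total); positions beyond the sequence and
gap characters map to index 20. The encoding is computed over the
*gap-masked* full sequence, so unmodelled neighbours look like gaps, which
is exactly what the model will see at prediction time on partially
modelled structures.

## Feature-group selection

Feature blocks are compared as groups. Columns are first made more
Gaussian by a per-column Yeo–Johnson transform, with λ estimated by
maximum likelihood (1-D `optimize` over [−5, 5] of the closed-form
profile likelihood); constant columns pass through with a warning and the
transform is exactly invertible on its fitted domain.

Greedy incremental selection (IFS) starts from the best single group by
cross-validated F1 and adds the group with the largest improvement,
stopping when no addition *strictly* improves the score — a tie keeps the
smaller set (Occam's razor). Cross-validation folds are stratified by
label under a fixed seed; the learner is pluggable (logistic regression
default, SVM available), as is the scoring oracle itself, which is what
the tests exploit to verify the greedy path by hand.

Two bespoke scores rank groups after standard wrapper fits, both
normalised by the square root of group width so large embedding blocks are
not over-penalised: `count_in_top100 / sqrt(width)` after recursive
feature elimination, and `n_selected_in_group / (n_selected_total *
sqrt(width))` after an Elastic Net fit (the wrapper fits themselves are
delegated to standard estimators; only the scores and aggregation are
bespoke).

## The two-branch network

The classifier joins a residual-convolutional branch over the discrete
window with a feed-forward branch over the 2340-wide features:

* **ResNet branch.** A trainable 21×21 lookup embeds the window
  (B×31 → B×31×21, permuted to B×21×31). Three residual blocks follow;
  each applies two conv1d layers (kernel 3, padding 1, stride 1, 10
  filters, batch-norm then ReLU after each) and *concatenates* the block
  input with the second conv's output along channels instead of adding —
  so channels grow 21 → 31 → 41 → 51 while kernel-2 max-pooling after
  each block shrinks positions 31 → 15 → 7 → 3 (floor division). The
  final 51×3 tensor flattens to 153 and a linear layer maps it to 32.
* **FNN branch.** 2340 → 512 → 256, each linear layer followed by
  batch-norm, dropout (0.5) and ReLU.
* **Fusion head.** The concatenated 288-vector passes one hidden linear
  layer (batch-norm, dropout, ReLU) and a final linear unit with a
  sigmoid, yielding the binding probability; the decision threshold is
  0.5 throughout.

The embedding width (21) is pinned by the architecture's printed shape
trace, which the test suite reproduces stage by stage. Two details are
genuinely open in the source architecture and are fixed here as package
choices: the fusion head's hidden width defaults to 128 (`head_hidden`,
configurable), and batch normalisation sits after each convolution before
its ReLU (stated only for the linear layers). Dropout is not applied
inside residual blocks. With these choices the network holds ~1.4 M
parameters, dominated by the 2340×512 layer; `net_n_params()` reports the
exact count for any configuration.

The layers, backpropagation and the Adam optimiser are a compact
self-contained implementation in matrix code (conv1d via im2col of the
time-shifted activations). Analytic gradients are verified against central
finite differences in the test suite, and evaluation-mode forward passes
are pure functions of (parameters, input).

## Class imbalance and the ensemble

Five strategies address the positive/negative imbalance:

* **RU** — random undersampling: keep all positives, sample an equal
  number of negatives without replacement;
* **WO** — weighted oversampling: resample each epoch with probability
  inverse to class frequency;
* **CWL** — class-weighted binary cross-entropy with
  `w_pos/w_neg = freq_neg/freq_pos`, `w_neg = 1`;
* **SMOTE/ADASYN-style** synthetic oversampling: synthetics interpolate
  uniformly between a minority sample and one of its k = 5 nearest
  minority neighbours *in the continuous 2340-wide feature block only*;
  the discrete window indices are inherited from the seed sample (how the
  original pipeline treated the mixed discrete/continuous input is
  unstated; interpolating integer indices would produce invalid symbols).
  ADASYN allocates synthetics per minority sample in proportion to the
  fraction of majority neighbours among its k nearest in the full set.

The final predictor ensembles the RU, WO and CWL models by a fixed
weighted average with the undersampling model counted twice:
`p = (2·p_RU + p_WO + p_CWL) / 4`. The two synthetic-oversampling models
are implemented and tested but not ensembled, mirroring the model-selection
outcome of the source study design.

Training uses Adam on (weighted) binary cross-entropy computed on logits
for numerical stability. The shipped full-scale defaults are learning rate
1e−5, batch 2048, and per-strategy epochs (RU 180, WO 100, CWL 325). For
desk-scale synthetic data those settings are inert — at 1e−5 with a few
thousand samples and a handful of epochs Adam cannot move the parameters
appreciably — so `net_config_desk()` (learning rate 1e−3, batch 64) is the
profile used by the examples and tests; it changes no architectural
constant. All randomness (initialisation, shuffling, resampling, dropout)
flows from explicit integer seeds, and training on one CPU is
bit-reproducible.

## Metrics

`evaluate_predictions()` reports confusion counts at the threshold plus
sensitivity, specificity, balanced accuracy (their mean), accuracy,
precision, F1, MCC, AUC and AUPR. AUC uses trapezoidal integration over
all unique thresholds (equal, to 1e−9, to the scaled Mann–Whitney U on
tie-free data); AUPR uses step-wise precision interpolation, the
conservative convention under heavy imbalance. MCC with a zero denominator
is 0 by convention; single-class label vectors make AUC/AUPR `NaN` with a
warning rather than an error.

## What the synthetic generator emulates — and what it does not

`make_toy_complex()` builds ideal poly-alanine backbones (helix
φ = −57°, ψ = −47°, or extended coil) from standard internal coordinates
and plants rigid six-atom pseudo-carbohydrate rings whose nearest atom sits
exactly 3.4 Å from a chosen residue while staying ≥ 3.7 Å from every other
residue — so annotation has an exact, boundary-straddling ground truth.
`make_synth_pssm()` writes parseable PSI-BLAST-dialect files.
`make_separable_embeddings()` draws the two classes as isotropic Gaussians
whose means differ by an effect size *d* along a random direction in each
embedding space.

These fixtures validate the machinery, not the biology: real embeddings
have rich covariance structure and nonlinear class boundaries, real
binding sites cluster spatially, and real chains mix residue types. A
model that reaches AUC ≈ 1 on d = 4 Gaussians demonstrates that the
optimiser, loss weighting and ensemble plumbing work — it says nothing
about attainable accuracy on real protein–carbohydrate complexes, which
additionally requires the real language-model embeddings and sequence
profiles this package deliberately ingests rather than computes.

Problem sizes in the tests were chosen for single-CPU runs: fixtures of
15–40 residues, learning-sanity sets of 4000 samples (10% positive,
d = 4) trained for at most a dozen epochs, and SASA at 960 sphere points
(120–240 in smoke tests).

## Numerical choices and limitations

* Distances compare squared norms with a 1e−12 slack so the inclusive
  3.5 Å boundary is exact under floating point.
* The incremental 3-D hull treats points within 1e−9 of a facet plane as
  non-visible; points exactly coplanar-outside a facet are skipped, which
  cannot change the surface area. Residue atom sets are small and generic,
  and the facet-enumeration oracle in the tests guards the construction.
* Alternate conformers keep only the highest-occupancy copy; hydrogens are
  flagged and excluded from every distance and surface computation.
* The Kabsch–Sander backend approximates the amide H along the previous
  carbonyl direction; on ideal geometry its helix assignments are exact,
  but on real structures an external DSSP remains the reference — hence
  the pluggable backend.
* Batch-norm running statistics make zero-epoch "trained" models usable
  (they fall back to the initialisation's statistics); prediction batches
  are only a memory bound, never a statistics bound, because evaluation
  uses running statistics.
* The pipeline evaluates on its own training samples at desk scale; with
  multiple chains configured, held-out evaluation is the user's
  responsibility (split the input records across two configs).
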