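---
title: "Hierarchical classification of ROS-scavenging enzymes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical classification of ROS-scavenging enzymes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Reactive oxygen species (ROS) — superoxide anion, hydrogen peroxide,
hydroxyl radical, singlet oxygen — are unavoidable by-products of aerobic
metabolism, and microorganisms carry a diverse arsenal of scavenging
enzymes (ROSes) such as catalases, superoxide dismutases, peroxidases and
thioredoxin reductases to keep them at steady state. Annotating these
enzymes from raw protein sequence is hard: the families are functionally
diverse, share no single diagnostic motif, and alignment-based transfer of
annotations breaks down for remote homologs.

`scavengeR` frames the annotation task as *hierarchical classification*:

1. **Level 1 (gate):** is this protein a ROS-scavenging enzyme at all?
2. **Level 2 (class):** if so, which enzyme family does it belong to?

Each level is answered by an ensemble of three heterogeneous component
classifiers that see three different representations of the same
sequence:

| component | representation | learner |
|---|---|---|
| `cnn` | frequency-ranked integer tokens | embedding + 3 convolutions + self-attention |
| `ffnn` | CKSAAGP group-pair composition | 4-layer feed-forward net, ReLU |
| `gbt` | CKSAAP residue-pair composition | gradient-boosted trees |

The level-1 decision is a **hard 2-of-3 majority vote** of the three
binary models; gate-accepted sequences then receive the **soft vote**
(unweighted mean of class-probability vectors, argmax of the mean) of the
three multiclass models. Gate-rejected sequences carry the sentinel class
`"non-ROSes"` and, by construction, never a concrete enzyme class. The
rationale for mixing architectures is variance reduction: the three
learners make partially decorrelated errors, and the majority/mean
operations cancel some of them.

## Feature encoders

**Tokenization (CNN input).** Characters are ranked by corpus frequency
(rank 1 = most frequent; ties broken lexicographically so the vocabulary
is a pure function of the corpus) and sequences become integer rows,
post-padded with the reserved index 0. The working alphabet has 23
letters: the 20 standard residues plus `X` (unknown), `B` (Asx) and `Z`
(Glx); the nonstandard residues `U` and `O` are remapped to `C` and `K` on
input, with a substitution count reported, so real-world FASTA remains
usable without widening the alphabet.

**CKSAAP (boosted-tree input).** For each ordered residue pair $(a,b)$
and spacing $k = 0,\dots,k_{\max}$, the descriptor is

$$f(a,b,k) \;=\; \frac{\#\{i : s_i = a,\; s_{i+k+1} = b\}}{L - k - 1},$$

where $L$ is the full sequence length. Pairs involving `X`/`B`/`Z`
contribute to the denominator but to no numerator cell, so each spacing
block sums to exactly 1 only for ambiguity-free sequences. With the
default $k_{\max} = 5$ the descriptor has $400 \times 6 = 2{,}400$
dimensions.

**CKSAAGP (feed-forward input).** The same composition computed over the
standard five physicochemical groups — aliphatic `GAVLMI`, aromatic
`FYW`, positively charged `KRH`, negatively charged `DE`, uncharged polar
`STCPNQ` — giving $25 \times 6 = 150$ dimensions. Ambiguous residues
belong to no group. The descriptor's name sometimes carries a "gap
penalty" suffix; no penalty beyond the spacing itself is defined here (or,
to our knowledge, anywhere precisely), so the spacing *is* the gap
treatment. The group-aggregation identity — CKSAAGP equals CKSAAP summed
through the partition — holds exactly and is tested.

$k_{\max} = 5$ is the common convention for both descriptors and the
package default.

## Component models and their numerical choices

**Convolutional network.** Embedding dimension 64; three convolutional
layers (64 filters, kernel widths 3/5/7, same padding, rectifier
activations); single-head scaled dot-product self-attention applied after
the convolution stack; global max pooling over positions; linear softmax
head. Trained with Adam (step 1e-3, batch 32, 20 epochs) on the
cross-entropy loss. This is the smallest standard design satisfying the
stated layer inventory; attention is placed after convolution because the
layer inventory lists it last, and whether the alternative order matters
was left open deliberately. Forward and backward passes are explicit
matrix algebra, vectorized over the minibatch (samples stacked row-wise so
each convolution is one matrix product against an index-unfolded patch
matrix); training is exactly reproducible from the seed, and padding is
prevented from leaking across stacked samples by routing out-of-range
patch positions to a sentinel zero row.

Token rows are padded to `pad_length` (default 1000, covering typical
enzyme lengths), but `ros_classifier()` uses the *effective* length
`min(pad_length, longest training sequence)`: padding 80–200-residue
training sequences to 1000 columns would multiply the convolution cost
several-fold while adding only zeros.

**Feed-forward network.** Four linear layers with the narrowing
16–8–4 hidden pattern, rectifier activations, softmax cross-entropy,
full-batch gradient descent. The input layer is sized to the actual
feature dimension (150 for the default CKSAAGP) and the output layer to
the number of classes — the published 20-wide input of this architecture
family only fits a 20-dimensional descriptor and cannot carry a
k-spaced group composition, so sizing to the data is the only coherent
reading. Inputs are standardized per feature (centre/scale stored with
the model) because the raw compositions live on the scale of $1/25$ and
gradients would otherwise be minuscule. Defaults are step size 0.1 for
1000 epochs: on standardized inputs the loss plateaus well within this
budget, whereas visibly smaller budgets (e.g. 0.01 for 100 epochs) leave
the net underfit to the point of predicting the majority class — it then
fails the package's own sanity floor of 0.95 training accuracy on a
linearly separable fixture, which is the criterion by which these two
defaults were chosen.

**Boosted trees.** `xgboost` with the framework's stated
hyperparameters: learning rate 0.1, maximum depth 20, 150 rounds, gamma
0, row subsampling 0.9. The histogram tree method with a single thread
makes training deterministic given the seed.

All three kinds sit behind one contract — `predict_proba()` returns an
$n \times$ classes matrix with rows summing to 1 within 1e-6 — so they
are interchangeable behind the voting ensemble, and the same three
architectures serve at both levels. Class imbalance is deliberately not
reweighted inside the learners; the dataset builder controls the
negative:positive ratio instead. Soft-vote ties (measure-zero but
possible in principle) break deterministically toward the lowest class
index.

## Dataset construction

The builder mirrors a standard redundancy-reduction + hard-negative
pipeline with exactly testable in-package algorithms rather than external
binaries:

- **Identity** is Needleman–Wunsch global alignment (match +1, mismatch
  0, linear gap −1) with identity = matches / alignment length, computed
  in C++ with a deterministic traceback tie-break (diagonal, then up,
  then left).
- **Clustering** is greedy and incremental at a configurable threshold
  (0.99 by default, the framework's redundancy-reduction setting):
  records are processed longest-first (ties by id) and join the first
  representative within the threshold, mirroring the greedy strategy of
  the usual clustering tools. Re-clustering representatives is a fixed
  point.
- **Hard negatives** are candidates ranked by their best k-mer cosine
  similarity (word size 3, the smallest word with usable specificity on
  proteins) against any positive; the top fraction — 1.8 negatives per
  positive by default, echoing the roughly 1.8:1 corpus this emulates —
  is kept. This is an alignment-free stand-in for similarity-search
  ranking; it produces no E-values and does not attempt to reproduce any
  particular search tool's scores.
- **Splitting** is stratified jointly on gate label and enzyme class,
  seeded; strata with fewer than two members cannot be split and stay in
  training with a warning.

## The synthetic benchmark

Because the corpus the framework was designed around is not
redistributable, the package ships a generator whose output has the
*statistical shape* the method assumes: several positive families of
unequal size, each defined by a family-specific motif implanted (with
per-residue substitution noise) at a random position in a uniform random
background; background negatives; and near-positive *hard negatives*
carrying only the first half of a family motif, so the positive/negative
boundary is sharp but learnable. The reference configuration is 5
families with sizes 100/80/60/60/40 (340 positives), lengths 80–200,
5% motif mutation, 1.8 negatives per positive with 30% hard negatives,
seed 42. Generation is a pure function of the specification.

What the generator does **not** emulate: real enzyme domain
architecture, phylogenetic correlation between family members,
compositional bias of real proteomes, or multi-motif families. Passing
the end-to-end recovery test therefore demonstrates that the machinery —
encoders, learners, votes, hierarchy — is wired correctly and can
extract a planted signal from held-out data; it is not evidence about
accuracy on real curated enzyme corpora. With zero mutation the benchmark
has a closed-form ceiling (a nearest-motif-substring oracle classifies
positives perfectly), which the test suite checks.

## Evaluation machinery

Level-1 performance uses the standard binary metrics (accuracy,
precision, recall — identical to sensitivity for a binary task, so
reported once — specificity, F1). Ratios with zero denominators are
reported as absent (`NA`) with a warning, never coerced to 0. Level-2
metrics are computed over truly positive examples only, and a gate false
negative propagates as a level-2 error (the sentinel is wrong for every
true class) — matching how the hierarchy is actually deployed. The
three-method Venn attribution partitions evaluated ids into the seven
correctness regions plus the all-wrong remainder; the eight counts
provably sum to the universe.

## Problem sizes and reproducibility

The reference benchmark (952 sequences, 762 train / 190 held out) trains
the full six-model hierarchy in a few minutes on one CPU; the test suite
uses this size for end-to-end checks and much smaller fixtures
elsewhere. All randomness — generation, splitting, initialization,
shuffling, subsampling — flows from explicit integer seeds;
`ros_classifier()` derives distinct per-model seeds from its single
`seed` argument, and retraining with the same data and seed reproduces
predictions byte-for-byte.

## Known limitations

- The feed-forward component is the weakest voter on motif benchmarks:
  group-level compositions dilute a short motif's signal far more than
  residue-level pairs do, and its held-out accuracy caps well below the
  other two components (the gate vote absorbs this by design). On real
  corpora with longer, group-conserved signals the balance may differ.
- Greedy clustering computes full alignments against representatives and
  is quadratic in the worst case; it is meant for corpus curation, not
  for millions of sequences.
- Probabilities are raw softmax/tree outputs, not calibrated; the gate
  has no rejection band beyond the majority vote.
- Sequences shorter than $k_{\max} + 2$ cannot be encoded by the pair
  descriptors and are reported as per-record errors at prediction time
  rather than failing the batch.
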