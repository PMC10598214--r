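---
title: "Predicting protein-protein interfaces and prioritizing guide peptides"
author: "pepprior authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting protein-protein interfaces and prioritizing guide peptides}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pepprior)
```

# The model

`pepprior` treats interface prediction as per-position binary
classification on a protein sequence. Each residue of an interacting
partner is either an interface residue (it contributes to binding the
target) or not, and the classifier outputs `p_i`, the probability of the
former, from sequence alone — no structure, no multiple sequence
alignment.

The training signal comes from linear-peptide energy scans: every
fixed-length window of a chain carries a binding-energy score in Rosetta
energy units (REU; lower is more favorable binding). The package never
computes these energies itself — they are an input format — but it owns
everything from there on.

## From window energies to labels

For a sequence of length $n$ with window records $w$ (start, length,
REU), the per-position energy is

$$E_i = \frac{1}{|W_i|} \sum_{w \in W_i} \mathrm{REU}(w), \qquad
  W_i = \{w : w \text{ covers } i\},$$

with $E_i$ explicitly missing (and the position masked) when $|W_i| = 0$.
Two record-level filters precede aggregation: windows below $-1000$ REU
are discarded as numerical artifacts, and sequences with length outside
the open interval $(50, 1023)$ are dropped entirely (strict on both
sides). We read the $-1000$ filter as applying to individual window
records rather than whole chains, because it precedes the per-position
averaging step; either reading is defensible, and the operation takes the
records it is given.

Profiles with *exactly identical* residue strings are merged — at each
position the unweighted mean of the member energies that are non-missing
there — so the dataset contains no redundant entries. We deliberately do
not weight this mean by window coverage: the members are equally valid
energy scans of the same chain, and an unweighted mean is the plainest
reading of "averaged". The merged profile takes the lexicographically
smallest member id and records all members.

Labels are then
$$y_i = \mathbb{1}[E_i < \tau], \qquad \tau = -1 \text{ REU (strict)},$$
with masked positions labeled 0 but excluded from loss and every metric.
Masking rather than imputing matters: uncovered positions carry no
evidence either way, and treating them as confident negatives would bias
the classifier toward the sequence ends, where fewer windows fit.

## Homology-aware splitting

Train/validation/test splits are assigned to whole clusters, never to
individual sequences: the clusters are connected components of a graph
with an edge wherever pairwise identity $\ge$ 0.25. Any sequence that is
(transitively) similar to a training sequence is therefore in the
training split, and held-out metrics measure generalization, not homolog
recall.

The identity oracle is pluggable. The built-in estimator is shared-5-mer
containment — distinct 5-mers shared by a pair, divided by the 5-mer
count of the shorter sequence — which is cheap, deterministic, and errs
toward *over*-connecting (containment is generous to subsequences), i.e.
toward the conservative side for leakage. When output from a dedicated
clustering tool is available, a precomputed id-to-cluster table can be
passed instead (`clusters =`) and the built-in estimator is bypassed.

Cluster-to-split assignment is largest-first into the split furthest
below its target fraction (defaults 0.77/0.10/0.13), with seeded
tie-breaking, and clusters containing any *forced-test* id (e.g. partners
of proteins chosen for laboratory follow-up) are routed to test before
anything else. Forced-test overflow beyond the test fraction warns rather
than errors: the user asked for those sequences to be held out, so they
are.

## The classifier

An *embedding backend* maps the sequence to one $d$-vector per residue;
the classifier head is four fully connected layers (three hidden, default
sizes 256/128/64, ReLU; one sigmoid output unit) applied independently at
each position. The depth is fixed at four weight layers; the widths are
conventions — the head only has to be expressive enough to read the
backend's features, and these sizes train in seconds at desk scale while
leaving room for richer backends.

Two backends are built in:

* **`oneHotBackend(radius = 7)`** — concatenated one-hot encodings (21
  symbols: 20 amino acids + `X`) over a symmetric window of radius $r$,
  $d = 21(2r+1)$; boundary positions get all-zero context blocks.
  Parameter-free, linear-time, deterministic. Radius 7 spans a 15-residue
  context, comfortably wider than the motifs the synthetic generator
  plants, and is the default everywhere.
* **`tinyTransformerBackend()`** — a small residual self-attention
  encoder (single head, ReLU feed-forward, sinusoidal positions, no layer
  normalization) with seeded random initialization. Its role is to
  exercise the *fine-tuning contract*: `setTrainable(backend, k)` marks
  exactly the final $k$ blocks trainable, `k = 0` is the frozen
  condition, and training updates trainable blocks jointly with the head
  by backpropagation through the attention and feed-forward layers. It
  is a desk-scale stand-in for the "fine-tune the last few layers of a
  pretrained protein language model" regime, not an approximation of any
  pretrained model's representations; a real pretrained backend can be
  plugged in by subclassing `EmbeddingBackend`.

Training minimizes the masked, per-sequence-weighted binary cross
entropy

$$\mathcal{L}(s) = w_s \cdot \frac{1}{|M_s|} \sum_{i \in M_s}
  -\big(y_i \log p_i + (1-y_i)\log(1-p_i)\big)$$

with $p$ clamped to $[10^{-7}, 1-10^{-7}]$. The mean (not sum) over
unmasked positions $M_s$ keeps per-sequence losses comparable across
lengths, which stabilizes mixed-length minibatches; the weight $w_s$
multiplies the whole per-sequence mean, matching datasets that ship a
per-protein importance weight. Optimization is plain Adam (rate $10^{-3}$,
batch of 8 sequences, no padding — sequences are processed individually
and gradients averaged). After each epoch the validation loss is
computed; training stops after `patience` (default 2) consecutive
non-improving epochs and restores the best checkpoint. Patience 1 is the
literal "stop when validation loss begins to increase", but at small
dataset sizes single-epoch noise triggers it spuriously; patience 2 with
best-checkpoint restore keeps the same semantics while tolerating one
blip.

With a frozen backend, embeddings are precomputed once per sequence;
with `k` trainable blocks, the frozen prefix is cached and only the last
`k` blocks are re-run each step. Both paths are exactly reproducible
from the training seed.

## Peptide prioritization

Given a predicted track $p$ and a user-specified peptide length $L$
(default 15), every window start $i$ gets the score
$s(i) = \mathrm{mean}(p_i,\dots,p_{i+L-1})$, masked positions excluded
(an all-masked window is missing). The mean — rather than sum or max —
makes scores comparable across different $L$.

Candidates are windows at *local maxima* of $s$: strictly greater than
the nearest differing neighbor on each side, with three discrete
conventions the continuous notion leaves open: a plateau strictly above
both flanks contributes its leftmost index; a boundary index qualifies
against its single neighbor; a constant profile has one maximum, at
index 1. Missing scores rank below everything. Window means are computed
per window (not by a cumulative-sum trick) so that windows with
identical content score bit-identically and the deterministic
smaller-start tie rule is exact.

Maxima are ranked by score (ties to the smaller start), filtered
greedily so no kept window shares a position with an earlier one
(`allowOverlap = TRUE` disables this), and truncated to `topN`. For a
degradation target, candidates are cut per partner and then pooled and
re-ranked globally; both the pooled ranking and the per-partner tables
are available, since either reading of "top peptides across partners" is
legitimate.

## Evaluation

* **AUROC** uses the Mann–Whitney rank formulation, equal to pairwise
  positive-vs-negative comparison with half credit for ties.
* **Spearman** is the Pearson correlation of average ranks; the energy
  is negated first, so probability tracking *favorable* energy gives
  positive correlation.
* **Top-n energy**: mean energy of the n highest-probability positions,
  and the percentage of them below the binding threshold (default
  $-1$ REU) — a proxy for "would the residues we would pick actually
  bind".

Metrics run over unmasked positions only. The default is macro
averaging (per sequence, then mean across sequences), with micro
(pool-everything) as an option; the two differ when sequences vary in
length or class balance, and neither is canonically "the" AUROC, so both
are exposed.

## Interactome policies

PPI evidence records are kept under the stringent policy if they are
IMEX entries, BioGRID entries with low-throughput (LTP) physical
evidence, or PROPER entries with $p < 0.01$; the lenient policy widens
BioGRID to LTP or HTP and PROPER to $p < 0.05$ (both comparisons
strict). Stringent-surviving records are a subset of lenient-surviving
ones for any input. Partner tables are symmetric, deduped, and route
self-interactions to a separate homogeneous set; proteome coverage is
the percentage of supplied symbols with at least one heterogeneous
partner (self-binders optionally included). Symbol matching is exact
after uppercasing — reconciling synonymous gene symbols is upstream
curation, not this package's job.

# The synthetic generator

`generateLabeledCorpus()` emulates the statistical structure the
pipeline assumes, with defaults fixed once as the package's standard
study conditions:

| parameter | default | rationale |
|---|---|---|
| sequences | 200 | large enough for stable held-out metrics, trains in seconds |
| length | 60–120 | short binding domains; above the window length |
| motifs per sequence | 1, length 8–12 | the scale of linear interaction motifs |
| motif alphabet bias | 0.9 on `AVLIFMWY` | interface motifs are strongly compositionally biased; 0.9 leaves 10% off-subset residues so motifs are noisy, not trivial |
| energy effect | $-2$ REU | two noise SDs below the $-1$ threshold |
| noise SD | 0.5 | background positions cross the threshold at rate $\Phi(-2) \approx 2.3\%$, i.e. labels contain irreducible noise |

True energy is `energyEffect * 1[motif] + N(0, noiseSigma)`; labels are
produced by running that energy through `binarizeProfile()` itself, so
the generator and the builder cannot drift apart. `generateWindowRecords()`
defines each window's REU as the mean of the true position energies it
covers — the exact inverse of the builder's aggregation — so in the
noiseless limit aggregation recovers the planted energies up to boundary
smoothing, and oracle tests can be exact. Note the aggregation of
windowed energies is a triangular smoothing of width $2w-1$: labels for
*training* are taken from the true per-position energies, not from the
doubly smoothed window path, which would dilute short motifs toward the
threshold.

What the generator does **not** emulate: real interface labels are
spatially determined by a partner's structure, not by residue
composition; real energy scans have chain-specific baselines, correlated
errors, and invalid regions; real homology is phylogenetic, not shared
k-mers from planted motifs. Passing the recovery tests therefore shows
the pipeline's machinery is correct and well calibrated on its own
assumptions — it says nothing about accuracy on real proteins, which
depends on the embedding backend used.

`generatePpiTable()` produces targets with motif-bearing partner
sequences (noiseless by default, so prioritizer recall against the
planted motif is well defined) and evidence records cycling through
classes that span both filter policies, plus decoys surviving neither.

# Numerical and design notes

* Strict inequalities throughout (`< -1000`, `< -1`, `< 0.01`,
  `< 0.05`, length in the open interval `(50, 1023)`): boundary values
  fall on the conservative side in every case.
* Interaction dedup keeps records greedily in input order, dropping a
  record only when an already-kept record of the same unordered pair is
  within 100 Å² of buried surface area.
* AUROC ties get half credit; Spearman uses average ranks; top-n
  selection breaks score ties by position order. All three conventions
  are stated because the alternatives are equally defensible.
* The single pipeline seed fans out to per-stage seeds by a stable
  string hash of the stage name (`stageSeed`), so inserting or removing
  a stage does not perturb the random streams of the others; every seed
  stays below $2^{31}$.
* Degenerate inputs: zero window records give an all-missing profile
  (not an error); a target with no surviving partners returns an empty
  candidate table with a warning; single-class AUROC and constant-input
  Spearman are errors, and macro averaging skips sequences where a
  metric is undefined.
* Checkpoints embed the backend (with any fine-tuned weights), the head,
  its configuration, and the training seed in one file.

## Problem sizes used in the checks

The shipped tests and the acceptance script run at the generator's
default conditions: a 200-sequence corpus (about 18k labeled positions)
for training and held-out evaluation, 120 noiseless partner sequences
for guide-peptide recovery, 500 × 100 background positions for the
label-prevalence calibration, and oracle-equivalence sweeps of 200–500
random instances per operation. These sizes give stable estimates
(recovery rates vary by 1–3 percentage points across seeds) while a
full run of everything stays within a couple of minutes on one CPU.

# Limitations

* The built-in backends carry no evolutionary information; they are
  reference implementations of the embedding contract, and realistic
  accuracy requires plugging in a pretrained protein language model.
* The shared-k-mer identity estimate is not an alignment; at the 0.25
  threshold it is conservative about leakage but can over-merge
  sequences sharing repeated motifs.
* Window-mean candidate scoring penalizes motifs shorter than the
  requested peptide length `L` — a long window spanning a short motif
  averages in background residues — so `L` should be chosen near the
  expected motif scale.
* Per-position classification ignores the identity of the *target*: the
  model predicts "interface-ness" of partner residues generally, not
  interface residues specific to one interaction.
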