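---
title: "Drug HIN embeddings for adverse drug reaction prediction: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Drug HIN embeddings for adverse drug reaction prediction: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hinadr)
```

## The problem and the model

Adverse drug reactions (ADRs) — side effects of single drugs and of drug
combinations — are expensive to discover experimentally, and computational
screens that rank candidate ADRs are a standard complement to
pharmacovigilance. `hinadr` implements a network-embedding approach to three
ranking tasks: predicting the side effects of a single drug (multi-label),
predicting whether two drugs interact (binary), and predicting the event
types of an interacting pair (multi-label).

The input is a *drug heterogeneous information network* (HIN) with five node
types — drugs, chemical substructures, target proteins, side effects,
diseases — and six binary relations, including protein–protein interactions
(PPI). All relations live in a `drug_hin` container whose invariants
(binary entries, symmetry of the two homogeneous adjacencies, shared protein
registry between drug–target links and the PPI graph) are enforced by
`validate_hin()`.

The pipeline has four stages:

1. **Meta-path proximities.** Each meta-path (a typed walk Drug–X–Drug)
   induces a drugs-by-drugs similarity:
   * `DD`: Jaccard similarity of binary interaction profiles.
   * `DCD`, `DPD`, `DDID`, `DSED`: PathSim,
     `S[i,j] = 2 C[i,j] / (C[i,i] + C[j,j])` with `C = M M'` the path-instance
     counts through shared substructures, targets, diseases, or side
     effects.
   * `DPnD` (*target propagation*, the distinctive component): drugs are
     scored by damped random-walk reachability between their target sets
     through the PPI graph. With `P` the degree-normalized transition matrix
     and damping `mu`, the Katz kernel
     `K = sum_{m >= 1} (mu P)^m = (I - mu P)^{-1} - I`
     accumulates all walks of length >= 1, and the raw proximity is
     `R = M_dp K M_dp'`. Zero-hop (shared-target) similarity is deliberately
     excluded from `K`: it is already `DPD`'s job.

2. **Per-sub-network encoders.** Each proximity matrix is encoded by a
   semi-supervised stacked denoising auto-encoder (SDAE): the input for drug
   `i` is row `i` of the proximity matrix, inputs are corrupted by randomly
   zeroing neurons, and the loss is
   `L1 + alpha * L2 + beta * Lreg`, where `L1` is squared reconstruction
   error of the clean row, `L2 = sum_ij S[i,j] ||e_i - e_j||^2` pulls
   embeddings of similar drugs together, and `Lreg` penalizes all weight
   matrices. All neurons are sigmoid; optimization is full-batch Adam.

3. **Secondary encoder.** The per-meta-path embeddings are concatenated and
   fused by a second SDAE of the same form, supervised by the weighted
   average proximity `S-bar = sum_p alpha(p) S(p) / sum_p alpha(p)`.
   The result is the final drug embedding (64 dimensions by default).

4. **Prediction heads.** Each task is a single fully-connected sigmoid layer
   on the final embeddings (pairs: the two embeddings concatenated, trained
   in both orders and averaged at prediction time), minimizing
   cross-entropy with a ridge penalty on the weights.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `mu` | 0.98 | Katz damping: weight of an `m`-hop walk is `mu^m`. See the note below on network scale. |
| `layer_dims` | `c(256, 64)` | encoder widths; the last entry is the embedding dimension. 64 is the default final dimension (larger dimensions stopped helping in the source experiments). |
| `corruption_p` | 0.2 | probability of zeroing each input neuron per epoch (denoising). |
| `alpha` | 0.1 | weight of the proximity-supervision term. |
| `beta` | 1e-4 | L2 penalty on encoder/decoder weights. |
| `epochs`, `learning_rate` | 200, 0.01 | full-batch Adam schedule. |
| `alpha_p` | 0.3 each | meta-path weights in `S-bar`; optionally searched on a {0.1..0.5} grid. |
| `neg_ratio`, `lambda` | 1, 1e-4 | negatives per positive for pair tasks; head ridge weight. |

Two of these deserve explanation, because the design was genuinely open:

**The supervision weight `alpha`.** The pairwise term
`sum_ij S[i,j] ||e_i - e_j||^2` is minimized by collapsing every embedding
to a single point; only reconstruction opposes the collapse. With
`alpha = 1` the collapse actually happens on some inputs — the supervision
loss falls to ~0 while reconstruction stalls, and planted cluster structure
is destroyed. The default `alpha = 0.1` keeps supervision an effective
regularizer: on the bundled synthetic benchmark, k-means on the final
embeddings recovers the planted drug clusters with adjusted Rand index
close to 1 across seeds.

**The damping `mu` and network scale.** `mu^m` is the only brake on long
walks, and `mu = 0.98` is the default throughout. One caveat worth knowing:
on small, well-connected graphs the walk mixes within a few steps, and near
`mu = 1` the kernel drifts toward the rank-one matrix of stationary visit
probabilities, losing pairwise resolution (on a dense 150-protein block
model the leading singular value carries ~40% of the kernel's spectrum at
0.98 versus ~14% at 0.9). The bundled benchmark therefore keeps its PPI
graph sparse (see below), which preserves kernel resolution at the default
damping; users embedding very small dense networks may want to lower `mu`,
which is a single argument everywhere (`katz_kernel(P, mu = ...)`).

## The synthetic benchmark

No public release of the integrated multi-database drug network exists, so
the package generates networks with known structure (`generate_hin()`):

* Drugs belong to planted clusters; each cluster has prototype
  substructure and disease vectors, and each drug's vectors are noisy
  copies (bit-flip rate `bit_flip_noise = 0.1` by default). Flips are
  density-preserving — ones flip off at the nominal rate and zeros flip on
  at a rate scaled by the prototype's sparsity — so sparse vectors do not
  acquire many spurious bits from a 10% flip rate.
* The PPI graph is a stochastic block model whose communities align with
  the drug clusters (within-community edge probability 0.07, between 0.01
  by default). Target sets are sampled *per drug* from the cluster's
  community (3 targets by default, plus rare off-community flips): drugs of
  one cluster have nearby but individually distinct targets. Together with
  the sparse within-community connectivity — which keeps 2-hop
  neighborhoods specific subsets of a community instead of covering it —
  this is what gives the propagation meta-path information that exact
  target sharing does not carry: two drugs whose targets are one PPI hop
  apart share side-effect anchors without sharing a single target. An
  earlier design with cluster-level prototype target sets and denser
  communities made side-effect labels nearly constant within a cluster, so
  every cluster-aware meta-path predicted them equally well and the
  propagation channel was redundant; the per-drug design restores the
  planted multi-hop signal that the benchmark exists to test.
* Each side effect is anchored at a protein; a drug carries the side effect
  (noise-free) iff one of its targets lies within `propagation_hops = 2` PPI
  hops of the anchor. Observed labels flip with `se_noise = 0.05`. Planting
  by hop-bounded reachability (not diffusion weights) keeps the ground
  truth exactly computable by breadth-first search, which the test suite
  uses as an independent oracle for the propagation machinery.
* Drug pairs interact with probability 0.35 within a cluster and 0.05
  across; event types of an interacting pair reuse the side-effect
  mechanism on the union of the pair's targets.

The default scale is 120 drugs / 4 clusters / 150 proteins / 60
substructures / 40 side effects / 30 diseases: large enough for stable AUC
estimates, small enough that a full pipeline run takes tens of seconds.

What passing tests on this generator do and do not show: side-effect labels
are *by construction* a function of multi-hop PPI reachability, so the
benchmark can demonstrate that the propagation meta-path captures signal the
shared-target meta-path misses — the direction of the real ablation — but it
says nothing about the magnitudes on curated pharmacological databases, and
it does not emulate their degree distributions, label sparsity (1318 ADR
event types), or reporting biases.

## Evaluation protocol

`make_split()` draws a drug-level partition: 10% of drugs are the test set;
of the remainder, 95% train and 5% validate (all `floor` arithmetic, so 100
drugs split 10/86/4). `scrub_hin()` then zeroes all drug–drug interaction
rows/columns and side-effect rows of test drugs in the training network, so
no proximity, embedding, or head can read a test drug's ADR labels; a
sentinel-poisoning test asserts this. `run_protocol()` repeats
split → scrub → proximities → encoders → heads → metrics for a configurable
number of repetitions (5 by default at desk scale; the full protocol uses
30) and reports mean and standard deviation of MAP@{20,50,100} and ROC-AUC
per task.

Metric choices:

* **AP@K** is `sum_{k<=K} Precision(k) * rel(k) / min(L, K)` — the standard
  average precision, which stays in [0, 1]. A literal reading of the
  printed formula that sums `Precision(k)` over *all* ranks `k <= K`
  exceeds 1 for perfect rankings (L = 1, K = 3 gives 1.83); it is available
  as `mode = "as_printed"` so both readings can be computed, and the
  default keeps MAP comparable with published tables. Ranking ties break by
  item index (stable), so MAP is deterministic.
* **ROC-AUC** is the Mann–Whitney statistic with midrank ties, checked
  exactly against a brute-force pairwise comparison in the tests.
* MAP cutoffs larger than the ranked list (e.g. K = 100 over 40 side
  effects) cap at the list length.

## Numerical choices and degenerate inputs

* PathSim and Jaccard return 0 (not NaN) when a denominator is 0 (drugs
  isolated in that relation); PathSim's diagonal is 1 exactly for drugs with
  at least one neighbor.
* The raw propagation matrix is asymmetric because row normalization of `P`
  breaks symmetry; it is symmetrized by averaging and then min–max scaled to
  [0, 1] so all meta-paths share one supervision scale. Drugs without
  targets keep all-zero rows. The normalization constants are recorded as
  attributes (and in the pipeline manifest).
* `mu >= 1` is rejected (the walk series diverges); `mu = 0` returns the
  zero kernel exactly. The closed form is computed by a dense linear solve;
  a truncated-series backend exists and the two agree to 1e-8 at `mu = 0.9`
  on random graphs, which the test suite asserts.
* Isolated proteins get all-zero transition rows (the walker stops), so the
  kernel is well defined on graphs with singletons.
* The supervision term is evaluated through the generalized Laplacian
  identity `sum_ij S[i,j]||e_i - e_j||^2 = tr(E'(Dr + Dc - S - S')E)`,
  which reduces to `2 tr(E' L E)` for symmetric `S`; the tests verify the
  identity against a literal double loop.
* The SDAE aborts with a diagnostic if the loss becomes non-finite; the
  convex prediction heads start from zero weights, so their fits are
  deterministic without a seed.
* All randomness (initialization, corruption, sampling, splits) flows from
  explicit seeds; a master seed fans out to stage seeds through a fixed
  integer recurrence (`derive_seed()`), so every stage is independently
  reproducible and two runs of `run_all()` with the same seed produce
  byte-identical artifacts.

## Design decisions in brief

* **Encoder input**: row `i` of the sub-network proximity matrix (the SDNE
  convention); the source description leaves the encoded object unstated.
* **Architecture**: `[n_drugs -> 256 -> 64]` per sub-network and
  `[K*64 -> 256 -> 64]` for the secondary encoder; sizes were not reported,
  and 64 output dimensions follows the reported dimension sweep.
* **Training**: end-to-end full-batch Adam. Greedy layer-wise pre-training
  is not implemented; at these widths end-to-end training converges
  reliably, and the loss logs (epoch, L1, L2, Lreg, total) are attached to
  every embedding for inspection.
* **Secondary reconstruction target**: the concatenated embedding vector
  itself (the loss is `||e-hat - e||^2`), reading the integration loss
  literally.
* **Meta-path weights**: uniform 0.3 unless the grid search is enabled.
  The search is coordinate ascent (2 sweeps) over {0.1..0.5} per meta-path —
  the full grid is 5^6 = 15,625 secondary fits — and scores each candidate
  by cross-validated ROC-AUC of a ridge logistic head on rows of the
  combined supervision matrix. Retraining the secondary encoder inside
  every grid cell would multiply cost by the number of cells; the
  supervision-matrix head is a monotone proxy for what the encoder is asked
  to preserve. Ties keep the incumbent weight, so a single meta-path
  returns the 0.3 midpoint.
* **Pair ordering**: unordered pairs are trained in both orders and scored
  as the average of both orders, keeping DDI scores symmetric.
* **Task-1 head**: all side-effect outputs are trained jointly with a
  shared input; with no shared hidden layer this is mathematically
  equivalent to independent per-label logistic fits (train a single column
  for the literal per-label protocol). Negative sampling is used for the
  pair tasks, whose universes are quadratic in the drug count.

## Known limitations

* **The pair head is additive.** The DDI heads score a pair by a single
  sigmoid layer on the concatenation `[e_i || e_j]`, trained on both orders
  and averaged. Such a layer computes (after symmetrization) a function of
  the form `f(i) + f(j)`: it can express per-drug interaction *propensity*
  but not purely relational predicates like "these two drugs are similar".
  On the synthetic benchmark, DDI occurrence is planted as same-cluster
  membership — purely relational — so the occurrence task sits at chance
  there (a same-cluster oracle reaches AUC ~0.76 and an explicitly
  symmetric feature map `|e_i - e_j|, e_i * e_j` reaches ~0.72, which
  bounds what a relational head could do). On real interaction databases
  the additive form is far less restrictive because interaction degrees are
  heavy-tailed. The DDI-type task is only mildly affected: its labels
  derive from the union of the pair's targets, which is largely additive.

* Embeddings are not equivariant to drug reindexing: weight initialization
  is tied to index order, so permuting drugs changes the trained network
  even under per-ID corruption noise. The deterministic stages
  (proximities) are exactly equivariant, and the tests assert that.
* The desk-scale benchmark cannot reproduce database-scale metric
  magnitudes; only directions and internal consistency are testable.
* Probabilities from the heads are uncalibrated; only rankings are
  evaluated.
* The grid search optimizes a proxy objective (see above), not the full
  retrained pipeline.

## Problem sizes used by the test and acceptance runs

Unit tests run on networks of 3–40 drugs. The end-to-end checks use the
default 120-drug benchmark: cluster recovery trains the full embedding
stack on 5 seeds; the ablation comparison runs the complete protocol
(5 repetitions, both variants) on the Task-1 ranking; the acceptance script
additionally reports the pair tasks from 3 protocol repetitions.
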