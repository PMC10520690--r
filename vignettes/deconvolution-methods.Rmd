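---
title: "Deconvoluting bulk Hi-C contact maps: model and methods"
author: "decooc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deconvoluting bulk Hi-C contact maps: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A bulk Hi-C library measures the contact frequencies of a *mixture* of
cells. When the tissue is heterogeneous, the observed contact matrix is,
to first order, the composition-weighted average of the cell types'
matrices. `decooc` estimates those cell-type proportions directly from
the bulk contact map with a convolutional network trained on simulated
mixtures with known ground truth — no marker genes and no reference
expression profiles, only chromatin contacts.

The package covers the whole workflow: contact I/O and normalisation
(`readContactPairs`, `krBalance`, `observedExpected`), the mixture
simulation framework (`makeTemplates`, `drawFractions`,
`synthesizeBulkFromPure`, `synthesizeBulkFromCells`), tensor
preprocessing (`scaleRows`, `extractWindows`, `stitchPairs`,
`buildDataset`), model training and prediction (`modelConfig`,
`trainEnsemble`, `predictSample`), concordance metrics (`rmse`,
`linCCC`, `modifiedCCC`), transfer-learning fine-tuning
(`finetuneEnsemble`) and expected-gradients SHAP interpretation
(`shapAttribute` and friends).

## Simulating mixtures with known truth

Ground truth is obtained by construction. A *template* is the pooled
contact profile of one cell type — aggregated single cells or a pure
cell-line library. A simulated bulk sample fixes a composition and
samples contacts accordingly:

1. **Composition.** For each cell type $i$ in the chosen subset, draw
   $r_i \sim \mathrm{Uniform}(0,1)$ and set $f_i = r_i / \sum_j r_j$,
   rounded to three decimals (`drawFractions`). Types outside the subset
   get 0. The design enumerates *every* combination of at least two of
   the $K$ types (`enumerateCombinations`; $2^K - K - 1$ subsets, 11
   for $K = 4$) and draws many compositions per combination.
2. **Cell-population route** (`synthesizeBulkFromCells`): a population
   of $N_{\mathrm{sum}}$ single cells is assembled with
   $N_i = N_{\mathrm{sum}} f_i$ cells per type. When a type has fewer
   real cells than requested, extra in-silico cells are generated by
   downsampling the pooled template to the type's median per-cell
   contact count (`synthSingleCell`).
3. **Pure-profile route** (`synthesizeBulkFromPure`): $M_i =
   M_{\mathrm{sum}} f_i$ contacts are drawn from each type's pooled
   contact multiset, without replacement, and merged. The library size
   $M_{\mathrm{sum}}$ is drawn uniformly from a configurable range
   (`drawLibrarySize`); the default range, 1.48e8–2.35e8 contacts,
   matches deeply sequenced tissue libraries, while desk-scale runs use
   smaller libraries (see *Problem sizes* below).

$N_i$ and $M_i$ are made integral by largest-remainder rounding so the
totals are exact. The three-decimal rounding of the fractions is itself
sum-preserving (1000 thousandths allocated by largest remainder):
independent per-coordinate rounding would push the sum as far as
$1 \pm 0.0005K$ off the simplex, violating the $\pm 0.001$ slack
already at $K \ge 3$ in the worst case. Containers still tolerate a
0.001 defect for externally supplied fraction tables, and such a defect
is never re-normalised away; integer apportionment then works on the
normalised proportions so totals stay exact. All randomness flows from a
single master seed through named substreams (fractions, cell draws,
contact draws), so every sample is individually reproducible.

**What the synthetic template generator emulates.** `makeTemplates`
builds $K$ per-type templates sharing a distance-decay backbone
$P(d) \propto (1+d)^{-1}$, each with its own block-structured A/B
checkerboard (compartments) and a few enriched diagonal squares
(TAD-like domains). That captures the three features that make contact
maps cell-type specific at coarse resolution — decay, compartments,
domains — while keeping types globally similar, which is the regime in
which deconvolution is non-trivial. It does **not** emulate
translocations, copy-number variation, mappability artefacts, or the
heavy-tailed per-cell coverage variation of real single-cell data, so
passing tests demonstrate the machinery recovers compositions under the
stated generative model, not performance on any particular real
dataset.

## Preprocessing into window-pair tensors

Each sample's contacts are binned per chromosome (`toMatrix`), balanced
with the Knight-Ruiz algorithm, row-scaled, and cut into diagonal
windows:

* **KR balancing** (`krBalance`): finds $x$ such that
  $\mathrm{diag}(x)\,A\,\mathrm{diag}(x)$ has equal row sums
  (normalised to 1), via the inner–outer Newton/conjugate-gradient
  iteration. Defaults: tolerance `1e-6` on the residual, at most 1000
  matrix–vector products, and bins with fewer than 10% nonzero entries
  are masked beforehand — rows of zeros make the problem infeasible and
  low-coverage bins are unreliable anyway. The row-sum constant is
  fixed at exactly 1 (the choice is free in KR).
* **Row scaling** (`scaleRows`): every unmasked row is divided by its
  row sum, $V^{\mathrm{scaled}}_{ij} = V_{ij}/S_i$, giving each row the
  form of a contact probability distribution.
* **Windows** (`extractWindows`): `size` × `size` submatrices (default
  30 bins) slide along the diagonal with a fixed `step` (default 20
  bins), giving $\lfloor (n - \mathrm{size})/\mathrm{step} \rfloor + 1$
  windows. The diagonal band is where bulk Hi-C is dense; far
  off-diagonal regions are ultra-sparse and uninformative at this
  scale.
* **Stitching** (`stitchPairs`): windows from two chromosomes are
  paired *by index* and stacked along the row axis into a
  $2w \times w$ tensor. Using two chromosomes hedges against an
  unluckily chosen single chromosome. The pairing rule is a package
  choice: index alignment keeps genomic position roughly matched and is
  deterministic; each window pair is a separate training example
  carrying the sample-level fraction vector as its label. Masked bins
  inside a window are kept as zeros by default; a flag rejects windows
  with more than a given masked fraction.

## The network and its training

The model (`modelConfig`, `buildModel`) is a small CNN: four 3×3
convolution layers (tanh), 2×2 max-pooling after the first three, two
tanh dense layers, and a $K$-unit output layer. The output activation
is softmax — the labels live on the simplex and softmax enforces it
structurally; a linear output with post-hoc renormalisation is
config-selectable for ablation. Channel widths and dense sizes are
config-exposed; the defaults (16-32-64-64 channels, 64/32 dense) suit
the 60×30 input through three poolings. A window must be at least 8
bins to survive the pooling stages; the constructor enforces this.

Training (`trainEnsemble`) is five-fold cross-validation *at the sample
level* — all tensors of a sample stay on one side of the split,
otherwise near-duplicate windows would leak between training and
validation. Each fold minimises MSE with Adam (learning rate 0.001),
multiplies the learning rate by 0.98 whenever validation RMSE fails to
improve for 4 epochs, and stops early after 20 epochs without
improvement (minimum delta 1e-5); the best-epoch weights are kept. The
network and its gradients are implemented in compiled code
(RcppArmadillo); backpropagation is verified against central finite
differences in the test suite.

Prediction (`predictSample`) averages the per-tensor outputs over the
sample's tensors and over the fold models, then renormalises onto the
simplex. The tensor-to-sample aggregation rule is a package choice (the
mean); it is invariant to duplicating or permuting a sample's tensors,
which the tests assert.

## Metrics

For truth $y$ and prediction $\hat y$ of length $n$ (population
moments, $1/n$, throughout; a sample-moment mode is available):

$$\mathrm{RMSE} = \sqrt{\tfrac1n \sum_i (\hat y_i - y_i)^2}, \qquad
\mathrm{CCC} = \frac{2\,\mathrm{cov}(y,\hat y)}
 {\sigma_y^2 + \sigma_{\hat y}^2 + (\mu_y - \mu_{\hat y})^2}.$$

Because both vectors lie on the simplex, $\mu_y = \mu_{\hat y}$ (up to
rounding) for *every* sample, so the location penalty of Lin's CCC
vanishes and within-sample errors are under-penalised. The modified
CCC replaces $(\mu_y-\mu_{\hat y})^2$ with the full mean squared error:

$$\mathrm{CCC}_{\mathrm{mod}} = \frac{2\,\mathrm{cov}(y,\hat y)}
 {\sigma_y^2 + \sigma_{\hat y}^2 + \tfrac1n\sum_i(\hat y_i - y_i)^2}.$$

Since $\mathrm{MSE} \ge (\mu_y-\mu_{\hat y})^2$, the modified value
never exceeds the plain one when the covariance is positive, and equals
1 iff $\hat y = y$. Degenerate cases: both vectors constant and equal
gives 1; a zero denominator with unequal vectors gives 0 (pure location
error, fully penalised).

## Fine-tuning for real samples

Real tissue differs systematically from the training domain. Given a
few real samples with reference compositions (from any external
source), `finetuneEnsemble` freezes the convolutional stack of every
fold model and retrains only the dense layers at a small learning rate
(default 4e-4, at most 100 epochs, plateau patience 10 — the epochs and
patience are package defaults). All five fold models are fine-tuned
independently on the same samples and their predictions averaged.

Even frozen-conv fine-tuning can memorise a handful of samples within
tens of epochs: tracking held-out error during fine-tuning shows it
improving for the first few dozen epochs and then degrading steadily,
at some seeds ending worse than no fine-tuning at all. The package
therefore holds out a fraction of the fine-tune samples (default 25%,
used whenever at least four samples are supplied) as a validation set:
early stopping and the scheduler monitor its RMSE and the best-epoch
weights are restored. With fewer samples the training RMSE is
monitored instead.

The package ships a batch-effect emulator for testing this path
(`perturbTemplates`). One subtlety dictated its design: a smooth
*per-bin* gain $g_i g_j$ is exactly the bias class that KR balancing
removes, so such a perturbation would vanish in preprocessing and the
fine-tuning probe would be vacuous. The emulator therefore applies a
symmetric but *non-separable* gain — a distance-decay exponent shift
(library preparation changes the short- vs long-range contact ratio)
plus a smooth sinusoid in $i+j$ — both of which survive balancing.

## SHAP interpretation

`shapAttribute` implements expected gradients, the sampling
approximation of integrated Shapley values behind gradient-based SHAP
explainers: for input $x$, background draw $b$ and path position
$\alpha$, the attribution of entry $p$ is the average of
$(x_p - b_p)\,\partial f_k/\partial x_p$ at $b + \alpha(x-b)$.
Backgrounds are drawn from the supplied background set (capped at 100
tensors by default); $\alpha$ is stratified over $(0,1)$ with the
midpoint rule rather than drawn uniformly — a variance-reduction choice
that makes the completeness identity
$\sum_p \phi_p = f_k(x) - \mathbb{E}_b f_k(b)$ hold tightly at moderate
sample counts, which the tests check directly. Per-model attributions
are averaged over the five fold models.

Downstream utilities mirror common practice: `shapHicCorrelation`
correlates attributions with observed/expected contacts (the
distance-decay-removed map, `observedExpected`) over positive-SHAP
positions; `openFraction` computes the per-bin accessible fraction
$O_f = \sum L_r / \mathrm{bin\ length}$ from ATAC-style BED intervals,
flagging bins with $O_f < 0.008$ (the boundary value is retained — the
filter is strictly "less than"); `pairwiseOpenFraction` assigns matrix
element $(i,j)$ the mean $(O_{f_i}+O_{f_j})/2$;
`shapAccessibilityBins` compares accessibility across attribution
strata with one-sided Mann–Whitney U tests; and `highShapRegions`
exports the top decile of bins per cell type as BED. Window-level
attributions are aggregated to bins by the *maximum positive*
attribution over covering windows — a conservative, peak-preserving
summary (another package choice; the alternatives, mean or sum, dilute
localised signals across overlapping windows).

## Problem sizes and numerical choices

The desk-scale study used by the test suite and the acceptance script
runs on one CPU: 4 synthetic cell types on two 50-bin chromosomes,
libraries of 5e4–1e5 contacts, 300 training and 60 held-out mixtures
over the 11 combinations, and a narrow 8-16-16-16-channel network
trained for at most 100 epochs per fold. These sizes are the package's
choice of a CPU-friendly study; the wider default network and the
deep-library default range are what a full-scale run would use.

Other numerical choices collected in one place:

* Coordinates are 0-based bins; bp map to bins by floor division; bin
  $k$ covers $[k\cdot\mathrm{res}, (k+1)\cdot\mathrm{res})$.
* Contact records are canonicalised (`(chrom_a, bin_a) <=
  (chrom_b, bin_b)`) with duplicate pairs summed; matrices are
  symmetrised exactly.
* KR tolerance 1e-6, max 1000 matrix–vector products, sparsity mask at
  <10% nonzero; all three config-exposed.
* Observed/expected offsets with zero mean yield 0, not NaN.
* Sampling from contact multisets is without replacement
  ("downsampling"); with replacement only when a draw exceeds the pool,
  and then with a message.
* Ties in top-fraction selections are broken by stable (bin or index)
  order everywhere.

## Known limitations

* The simulation assumes bulk = weighted sum of pure profiles; real
  tissue may violate this through cell-cell interactions or
  microenvironment effects no mixing model captures.
* Templates are stationary along the genome; real compartment strength
  varies regionally.
* Only intra-chromosomal, diagonal-band information is used; a signal
  residing in far off-diagonal or inter-chromosomal contacts is
  invisible to the model.
* Bit-level reproducibility across hardware/BLAS builds is not
  promised for training; fold assignment, initialisation and data
  draws are deterministic given the seed.
* The `.hic` and cooler binary containers are not parsed; contacts
  enter as text (pairs or dense TSV).
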