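---
title: "Methods: from sorted-gate reads to an affinity and epistasis landscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from sorted-gate reads to an affinity and epistasis landscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sortscape)
```

## The experiment being modelled

`sortscape` analyses sort-seq deep mutational scanning of a protein–protein
binding interface. The reference system is the complex of bovine pancreatic
trypsin inhibitor (BPTI, residues 1–54) with chymotrypsin: a yeast-displayed
library of BPTI variants carrying one or two substitutions at 12 interface
positions (11–13, 15–18, 34–37, 39) is sorted by FACS into four affinity
windows — high affinity (`HI`), wild-type-like (`WT_GATE`), slightly lower
than wild type (`SL`), and low affinity (`LO`) — and each sorted fraction,
plus the pre-sort library, is deep-sequenced. The variant universe is the
wild type, 19 × 12 = 228 single mutants and 19 × 19 × C(12,2) = 23,826
double mutants (24,055 genotypes). Only a fraction of the doubles is ever
observed experimentally; the machine-learning stage exists to impute the
missing part of the landscape.

## Stage 1: reads to enrichment ratios

Raw reads are translated and filtered by five rules, applied as a cascade
but logically independent (the accepted set does not depend on rule order,
which the test suite verifies against a naive per-read oracle):

1. the `TAGC` primer must occur in the read — translation starts right
   after its *first* occurrence, which makes the pipeline robust to leading
   adapter bases (the alternative, requiring the primer at the read start,
   would discard otherwise perfect reads);
2. at least 162 nt of coding sequence must follow (54 codons); trailing
   bases beyond codon 54 are ignored;
3. the coding region must contain only A/C/G/T;
4. the translation must not contain a stop codon (such a read cannot encode
   a 54-residue protein);
5. at the protein level, differences from the wild type must be confined to
   the 12 mutable positions; 0–2 substitutions are accepted, and variants
   with 3 or more substitutions at allowed positions are tallied separately
   (`higher_order`) because the library is single/double by construction.

Rejections are data, not errors: every rule keeps a per-gate tally.
Counting is at the protein level, so synonymous DNA variants collapse.

For each variant *j* and gate *A* the pipeline computes the frequency
$f_{j,A} = n_{j,A} / \sum_k n_{k,A}$, the wild-type-normalized frequency
$NF_{j,A} = f_{j,A} / f_{\mathrm{WT},A}$, and the enrichment ratio
$ER_{j,A} = NF_{j,A} / NF_{j,\mathrm{presort}}$; the modelled label is
$\log_2 ER$. The wild type therefore has $ER = 1$ and $\log_2 ER = 0$ in
every gate, exactly. There are **no pseudocounts**: a variant absent from
the pre-sort library (or from a gate) simply gets no record there — the
ratio would be undefined, and inventing a floor count would bias exactly
the rare variants the models are meant to impute.

## Stage 2: features

Each variant is encoded as a 240-dimensional one-hot block (12 positions ×
20 amino acids, alphabetical within each block) concatenated with a
D-dimensional embedding averaged over the 12 mutable positions of the
full-length mutant sequence. Each one-hot block encodes the *actual*
residue at the position — wild-type residues included — so the wild type is
representable and every genotype maps to a distinct vector even at D = 0.
The amino-acid ordering inside a block is an arbitrary fixed choice; only
determinism matters.

The default embedding provider is a deterministic hash stub: every
(residue, position) pair maps to a fixed pseudo-random vector, D = 64 by
default. It preserves the *interface contract* of a protein language model
(same sequence, same matrix; one row per residue) but none of its
biological content — it is context-free, so a residue's vector ignores its
neighbours. Passing tests with the stub therefore demonstrates pipeline
correctness, not that embeddings help; a real pretrained model can be
plugged in through the same interface (a function from sequence to an
L × D matrix). Mean pooling over the mutable positions is the default and
only tested aggregation.

## Stage 3: per-gate ensembles

Each gate gets its own regressor mapping features to $\log_2 ER$: a fully
connected network with ReLU hidden layers, inverted dropout, a single
linear output, mean-squared-error loss and Adam updates over shuffled
mini-batches, trained for a fixed number of epochs (no early stopping, no
schedule). The per-gate defaults are the selected configurations of the
original study: HI `[64,32,32,32]` (batch 256, 50 epochs, dropout 0.1),
WT-like `[64,32,32]` (32, 30, 0.3), SL `[64,64,32,32]` (32, 20, 0.1), LO
`[64,64,32,32,32]` (32, 30, 0.2), learning rate $10^{-3}$ everywhere.
Embedding columns are z-scored with training-set statistics (stored with
the model and reapplied at prediction time); one-hot columns stay binary.
The optimizer choice (Adam) and the train-only standardization are our own
defaults where the procedure left them open.

Robustness comes from a seed ensemble: 10 members with independent
initializations, mini-batch orders and dropout masks; predictions are the
member mean, and the member SD is the empirical uncertainty. A random
hyperparameter search over the published ranges is available
(`hyperparameter_search()`, default 20 trials, selection by validation
Pearson correlation, ties broken by parameter count then sampling order);
trial models are evaluated with a single member for tractability and the
winner is re-trained at full ensemble size.

Variants missing from a gate are excluded from that gate's training set and
later *imputed* by prediction — that imputation is the point of the
modelling stage.

## Stage 4: calibration to ΔΔG~bind~

The four predicted $\log_2 ER$ values are combined into a binding
free-energy change by a linear map fitted by ordinary least squares on
literature measurements (27 single mutants in the original study):
$\Delta\Delta G = w_{HI} x_{HI} + w_{SL} x_{SL} + w_{WT} x_{WT} +
w_{LO} x_{LO} + b$. The published fit,
$(-0.397, -0.348, +0.184, +0.597, -0.560)$, ships as
`calibration_preset()`. When fitting fresh, the inputs are the
*model-predicted* ratios of the measured variants, and those variants are
removed from the training sets first (`exclude_from_training()`), so the
calibration is never fitted on memorized points. In-sample, the OLS
combination is necessarily at least as correlated with the measurements as
any single gate — a useful sanity check that the tests assert.

Each ensemble member is carried through calibration *independently*, then
anchored by subtracting its own predicted wild-type value, so
$\Delta\Delta G(\mathrm{WT}) = 0$ per seed. Anchoring makes the landscape
invariant to any global additive offset in the calibration (the test suite
injects a constant into the bias and checks nothing moves).

## Stage 5: landscape and epistasis

For each double mutant *ij*, epistasis is the double-mutant-cycle residual
$\varepsilon_{ij} = \Delta\Delta G_i + \Delta\Delta G_j -
\Delta\Delta G_{ij}$, computed seed-wise from that seed's own single- and
double-mutant values, then averaged; the seed SD is the uncertainty.
Positive $\varepsilon$ means the double binds more tightly than the
additive expectation. (A verbal definition with the opposite sign exists in
the source literature; the convention above is the one consistent with the
printed worked example, $\varepsilon(-2.382, -1.042, -1.681) = -1.743$.)
Position-pair summaries average $\Delta\Delta G$ and $\varepsilon$ over the
361 substitution combinations of each of the 66 pairs, symmetrically.
`gate_position_frequency()` reproduces the per-position gate-occupancy
summary used to flag hotspot positions (mutations over-represented in the
low-affinity gate).

## The synthetic generator, and what it does not emulate

Because the real sequencing data is not required, every stage is validated
against a generator with known ground truth. `plant_landscape()` draws an
additive effect per single substitution from
$\mathcal{N}(0.5, 1.2^2)$ kcal/mol — most interface mutations are
deleterious, hence the positive mean — and a sparse epistasis term
($\mathcal{N}(0, 1)$, 15% of doubles) with
$\Delta\Delta G_{ij} = e_i + e_j - \varepsilon_{ij}$.
`simulate_sort()` draws log-normal pre-sort abundances, assigns cells to
gates with probabilities proportional to Gaussian kernels centred at
(−1.5, 0, 1.5, 3) kcal/mol with bandwidth 1.2 — a smooth, monotone
stand-in for the real FACS windows, whose widths and overlaps are unknowable
from the published record — and samples reads multinomially per fraction
(default 50K per gate, 100K pre-sort, matching the real study's order of
magnitude). Corrupt reads exercising each filter rule are injected at a
configurable fraction. Everything flows from one integer seed through
labelled seed derivation, so each stage is independently reproducible.

A useful property of this design: for Gaussian gate kernels with a common
bandwidth, the expected $\log_2 ER$ of each gate is a quadratic in the true
$\Delta\Delta G$ whose quadratic and normalization terms are *shared across
gates*, so a linear combination of the four gate values with weights
summing appropriately recovers $\Delta\Delta G$ up to sampling noise — the
linear calibration stage is exactly the right model for this generator,
as it empirically was for the real data.

The generator does **not** emulate substitution/indel sequencing error
profiles, PCR amplification bias, synonymous codon diversity, cell-cycle
or expression effects, or gate spillover beyond Gaussian noise. Passing
the end-to-end tests therefore shows the pipeline's inference machinery is
correct and well-calibrated under its own assumptions — not that the
models would reach the same accuracy on real reads.

## Validation scale and numerical choices

The deep end-to-end check uses ~2,000 sampled variants (wild type, all 228
singles, ~1,770 doubles), 50K reads per gate, 100K pre-sort reads, cell
noise 0.15 kcal/mol, 2% corrupt reads, literature noise 0.05 kcal/mol and
10-member ensembles — the scale at which a full run takes a couple of
minutes on one CPU. Under these conditions the Spearman correlation between
predicted and planted $\Delta\Delta G$ exceeds 0.95, and the sign of
predicted epistasis agrees with the planted sign for ≥ 85% of doubles with
$|\varepsilon_{\mathrm{true}}| \ge 1$ kcal/mol — the magnitude of the
worked example above, used as the "clearly above noise" cut. Smaller
planted interactions shrink toward zero under ensemble averaging and their
sign is not reliably recoverable at this depth; that is a property of the
data, not a defect of the estimator.

Other numerical conventions: ties in the read-depth split and in the
inclusion-mode position holdout are broken by a canonical variant ordering
(substitution count, then positions, then amino acids) so every split is
bit-reproducible; rank-deficient calibration designs are an error rather
than a silent pseudo-inverse; a zero-variance prediction vector is an error
in correlation reports; and the stop-codon rule rejects reads the original
filtering description never mentions, because they cannot encode a
54-residue protein at all.

## Evaluation schemes

`split_by_read_count()` implements the depth-ranked partition (top 10% by
pre-sort + gate reads as test, next 10% validation, 80% training): the most
deeply sequenced variants have the most reliable enrichment values, so the
model is judged where the labels are trustworthy.
`split_position_holdout()` excludes all variants touching a position
(strict mode) or returns 90% of them to training (inclusion mode),
quantifying how much mutational effects generalize across positions.
`additive_baseline_comparison()` scores direct double-mutant predictions
against the sum of the component singles' predictions over *every* subset
of sizes n−2, n−1, n of the measured doubles (56 subsets for n = 10 —
exhaustive, not bootstrap-sampled), with the doubles and their singles
excluded from training.

## Known limitations

* The stub embedding carries no evolutionary information; real-data
  performance claims require a real protein language model behind the
  provider interface.
* Epistasis is derived from predicted $\Delta\Delta G$ surfaces, not
  modelled directly; smoothing by the networks can attenuate genuine
  interactions (and does, below ~1 kcal/mol at the validation depth).
* The Gaussian gate model is a stand-in; inference on real data should not
  assume its convenient linearization property holds exactly.
* Training is plain R matrix algebra: adequate for the library sizes here
  (seconds per member), not for orders-of-magnitude larger designs.
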