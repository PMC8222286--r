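---
title: "Modeling C-terminal antigen processing from eluted-ligand data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling C-terminal antigen processing from eluted-ligand data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(procleave)
```

## The problem

Before a peptide can be presented on an MHC molecule it has to be cut out of
its source protein: the proteasome (class I) or cathepsins (class II)
generate the peptide's C-terminus, and this proteolytic step is one of the
main bottlenecks of the presentation pathway. `procleave` models the
*C-terminal processing* signal directly from immunopeptidomics data: peptides
eluted from MHC molecules and identified by mass spectrometry are treated as
positive evidence that their C-terminal scissile bond is cleaved in vivo.

The unit of modeling is a seven-residue *cleavage window* spanning the cut in
Schechter–Berger nomenclature: four residues before the scissile bond
(P4–P1) and three after it (P1′–P3′). The trained classifier maps a window
to a probability in (0, 1) that the corresponding bond is a true processing
site.

## Data generation

1. **Ligand selection.** An eluted-ligand CSV (IEDB-style export, local file)
   is filtered on any of its metadata fields (host, MHC class, allele, assay
   technique, presenting cell type) and deduplicated to unique
   (peptide, source-protein) pairs.
2. **Flank retrieval.** Each peptide is located in its source protein
   (local FASTA) by exact substring search. The positive window is the
   peptide's last four residues plus the three protein residues after its
   C-terminus; `cut_index` is the 0-based index of the first residue after
   the cut.
3. **Decoy negatives.** Elution experiments produce no negatives, so the two
   windows obtained by shifting the cut one residue upstream (between P2 and
   P1) and one downstream (between P1′ and P2′) serve as decoys, under the
   standard assumption that an observed site out-cleaves its immediate
   neighbours. Decoys that run off a protein end or contain non-standard
   residues are dropped and counted.
4. **Assembly.** Windows are deduplicated by string; a string observed both
   as positive and decoy keeps label 1 (a measured observation outranks a
   presumptive negative — this resolution is our choice, documented rather
   than inherited). Output is sorted in radix order, so the stage is a pure
   function of its file inputs.

### Peptide localization

When a peptide occurs more than once in its protein, the first occurrence is
used and the ambiguity is logged. This is a deliberate, deterministic choice;
with realistic peptide lengths (≥ 8) multiple occurrences are vanishingly
rare, but silence about them would make reruns hard to audit.

## Feature encoding: 46 vs 48 descriptors

Each residue is encoded by a vector of physicochemical QSAR descriptors
partitioned into **16 hydrophobic, 17 steric and 15 electronic** features,
and a window concatenates its seven per-residue blocks position-major into a
**336-feature** vector, of which the network's hidden layer is one third
(**112** units).

These printed quantities fix the per-residue descriptor count at
16 + 17 + 15 = **48** (and 7 × 48 = 336, 336 / 3 = 112). The same source
description elsewhere labels the set "46 descriptors", which is arithmetically
incompatible with all three other quantities (7 × 46 = 322); we therefore
treat "46" as a typo and implement the internally consistent 48-column table.

The packaged table (`inst/extdata/aa_descriptors_48_synthetic.csv`) is a
**synthetic stand-in**, clearly labeled as such: the published tables of this
exact shape are not redistributable here. Each category is anchored by
accurately known scales — Kyte–Doolittle hydropathy and Hopp–Woods
hydrophilicity (hydrophobic); residue mass, Zamyatnin volume, maximal
accessible surface area and Charton polarizability (steric); side-chain
charge, isoelectric point and Grantham polarity (electronic) — and filled to
width with seeded linear combinations of the category anchors plus
residue-specific variation (`data-raw/make_descriptor_table.R`, seed 46).
The pipeline depends only on the table's shape, category semantics and
row-distinctness (which makes the encoding injective); any conforming table
can be substituted via `load_descriptor_table(path)`.

### Standardization

Features are standardized by removing the mean and scaling by the standard
deviation. Three choices the source description leaves open, fixed here:

* **Population** standard deviation (recorded in the model metadata; either
  convention is fine as long as training and prediction agree).
* The standardizer is fitted on the **training partition only** and persisted
  with the model, preventing leakage into validation and test.
* Zero-variance features get scale 1, so they standardize to exactly 0.

## Network and training

The classifier is a one-hidden-layer feed-forward network implemented
directly on base-R matrices (no external ML backend, hence bit-reproducible
under a seed on a fixed BLAS):

* input 336 → hidden `floor(336/3) = 112`, tanh activation;
* **inverted dropout** 0.5 on the hidden layer during training (survivors
  scaled by 2, inference path untouched — the modern convention; the source
  states the rate but not the convention);
* single sigmoid output, score in (0, 1);
* Glorot-normal initialization, `N(0, 2/(fan_in + fan_out))`, zero biases;
* plain SGD (no momentum), learning rate 1e-2, mean binary cross-entropy
  loss;
* data split 60 / 30 / 10 into train / validation / test by uniform shuffle
  (not stratified — following the literal description; per-split class
  balance is reported so pathological draws are visible). Fractional
  remainders are assigned train-first.

Epoch budget, batch size and stopping rule are not pinned by the source.
Defaults: `max_epochs = 200`, `batch_size = 64`, early stopping on
validation loss with `patience = 10`, restoring the best-validation weights
— the 30 % validation split exists precisely to monitor this. All are
exposed in `model_config()`.

Numerical details: the loss clamps probabilities to `[1e-12, 1 - 1e-12]`;
gradients use the exact `(p - y)` form and are verified against central
finite differences to 1e-5 relative error in the test suite; a non-finite
loss aborts with a diagnostic rather than silently diverging.

## Evaluation

`confusion_at_threshold()` calls a prediction positive when
`score >= threshold` (ties at the threshold are positive — fixed,
documented). From the counts: PPV = TP/(TP+FP), TPR = TP/(TP+FN),
MCC = (TP·TN − FP·FN)/√((TP+FP)(TP+FN)(TN+FP)(TN+FN)), accuracy, and ROC
AUC via the rank/Mann–Whitney estimator with 0.5 tie credit (exactly the
trapezoidal ROC area; verified against a brute-force pairwise oracle).
Degenerate denominators return 0 carrying a `degenerate` attribute instead
of failing, because benchmark subsets can be one-sided.

`curate_immunogenicity()` implements the benchmark curation protocol:
restrict to one assay technique (ELISPOT by default), collapse the
five-level qualitative vocabulary to binary with any `Positive*` call
counting as positive regardless of strength, and discard peptides reported
both negative and positive for the same allele.

## The synthetic world

`synthetic_config()` defines the stated world used by the tests: 60 uniform
random proteins of 200–300 residues; candidate cut sites accepted with
probability 0.9 when P1 ∈ {F, L, Y} (a chymotrypsin-like, single-position
motif) and 0.01 otherwise; accepted sites emit peptides of length 8–11
ending at the cut. This yields ≈ 2,000 positives and ≈ 4,000 decoys, and a
Bayes-style analysis of the one-position signal puts the achievable held-out
AUC near 0.95 — comfortably above the 0.9 acceptance bar without tuning.

What the generator emulates: the CSV/FASTA interface, the window geometry,
decoy adjacency, motif learnability, and curation conflicts (at a
configurable rate). What it does **not** emulate: natural residue
frequencies (uniform background by design — the simplest null),
multi-position or context-dependent protease specificity, peptide-length
biases, MHC binding preferences, or mass-spectrometry noise. A green
pipeline test therefore establishes that the machinery learns a planted,
learnable signal — not that the model's biology is right.

## Known limitations

* The descriptor table is a stand-in; absolute scores are not comparable to
  those of the original tool, even though the architecture and data
  semantics match.
* Class II data pass through the same pipeline unchanged; nothing
  class-II-specific (cathepsin repertoires, length promiscuity) is modeled.
* No live database retrieval: inputs are local files by design.
* Single-threaded, desk-scale training; no GPU, no hyperparameter search.
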