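---
title: "Spatial aggregation and charge descriptors for antibody Fv regions: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial aggregation and charge descriptors for antibody Fv regions: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(abprop)
```

## The problem

Highly concentrated antibody formulations can aggregate or become too
viscous to inject. Two structure-based scores are widely used to flag
problematic candidates early: the *spatial aggregation propensity* (SAP),
which locates exposed hydrophobic surface patches, and the *spatial charge
map* (SCM), which measures the local charge environment on the solvent
face. Both are usually computed as ensemble averages over molecular-dynamics
snapshots of the antibody variable fragment (Fv), which makes them
expensive. This package implements (i) the full structure-side calculation
of both scores over ten antibody domains, (ii) the sequence side: fixed-size
Chothia-template encoding of paired heavy/light variable sequences and a
convolutional surrogate that predicts the 30 descriptors from sequence
alone, and (iii) a small-data regression pipeline (exhaustive feature
selection, four model families, leave-one-out validation) that uses the
descriptors to model antibody aggregation rates.

The ten scoring domains are the six Chothia CDR loops, their union
(`CDR`), the heavy and light variable domains (`Hv`, `Lv`) and the whole
variable fragment (`Fv`); with three properties (`SAP_pos`, `SCM_pos`,
`SCM_neg`) these give the 30 canonical descriptors named
`<Property>_<Region>` (see `descriptor_names()`).

## The scores

For one structure snapshot, the per-atom charge field is

> SCM_i = sum of partial charges q_j over all atoms j ≠ i of *exposed*
> residues within 10 Å of atom i,

where a residue is exposed when its side-chain solvent-accessible area is at
least 10 Å². Domain scores split the field by sign: `SCM_pos(D)` sums
`SCM_i H(SCM_i)` and `SCM_neg(D)` sums `|SCM_i| H(−SCM_i)` over the atoms of
domain D (`H` the Heaviside step, `H(0) = 0`), so both are nonnegative and
their difference is the plain domain sum. The per-atom aggregation field is

> SAP_i = sum over residues r with at least one side-chain atom within R of
> atom i of [SASA of r's side-chain atoms within R] / [SASA of r's fully
> exposed side chain] × hydrophobicity(r),

with hydrophobicity on a glycine-centred Black & Mould scale (Gly = 0,
hydrophobic positive). `SAP_pos(D)` is the positive part summed over the
domain. The neighbourhood radius for the charge field is 10 Å; the radius
for the aggregation field is not uniquely fixed by convention (5 Å is the
classical patch radius, 10 Å matches the charge field) — the package
defaults to 10 Å and exposes both as parameters.

Across snapshots (MODEL blocks of a multi-model PDB), `score_structure()`
reports the ensemble mean, the population standard deviation (denominator
N, an ensemble average over frames) and the relative standard deviation
(sd/|mean|, `NA` when the mean is zero but the spread is not).

Two algebraic identities hold exactly by construction and are enforced in
the test suite: `Fv = Hv + Lv` and `CDR = Σ` of the six CDR loops, for every
property and snapshot, because an atom belongs to a domain exactly when its
residue does and the partitions are disjoint.

## Parameter tables

All numeric tables ship as editable plain text under
`inst/extdata/params/`:

* **Partial charges** (`charges.tsv`): a package-curated all-atom charge set
  in the CHARMM style (amide/carbonyl backbone group charges, chemically
  motivated side-chain groups). It is a synthetic stand-in for a
  force-field topology — the header says so — with the defining invariant
  enforced exactly: every residue sums to its formal charge. Histidine is
  tabulated only in its doubly protonated (+1) form, the fixed protonation
  rule for the mildly acidic formulation pH regime (~pH 6) where only His
  titrates; acids are −1, Lys/Arg +1. Terminal patches (`patches.tsv`)
  convert the termini to the charged amine/carboxylate forms.
* **Radii** (`radii.tsv`): Bondi van der Waals radii by element.
* **Hydrophobicity** (`hydrophobicity.tsv`): the Black & Mould normalized
  scale; the loader shifts it so glycine is exactly 0.
* **Reference side-chain SASA** (`ref_sasa.tsv`): package-curated fully
  exposed side-chain areas (Gly-X-Gly-like); glycine gets a small positive
  area because its alpha hydrogens are classified as side chain, keeping the
  exposure ratio defined while its hydrophobicity of 0 still zeroes its SAP
  contribution.
* **Chothia CDR boundaries** (`cdr_chothia.tsv`): CDRH1 26–32, CDRH2 52–56,
  CDRH3 95–102, CDRL1 24–34, CDRL2 50–56, CDRL3 89–97; insertion codes
  inherit the membership of their base number. The scheme is data, not
  code.

## Solvent-accessible surface area

`shrake_rupley()` is a point-sampling implementation: each atom's
solvent-expanded sphere (radius r + probe, probe 1.4 Å) carries a
deterministic golden-section spiral lattice (960 points by default), and a
point is accessible iff it lies strictly outside every other expanded
sphere; a point exactly on another sphere counts as buried (a measure-zero
tie-break that makes results reproducible bit for bit). An isolated atom
therefore scores `4π(r+w)²` up to lattice quantization. Exposure is
evaluated per snapshot — each frame has its own exposed-residue set —
because the ensemble average wraps the whole per-frame score. The engine is
validated against an independently coded latitude-band sampler at ~10×
density and against spherical-cap closed forms on two-sphere systems.

## Sequence side: templates, filters, encoding

Paired Fv sequences are aligned onto fixed Chothia-style templates of 145
(heavy) and 127 (light) slots, built from base positions 1–113 / 1–107 plus
insertion slots (heavy: 31A–B, 35A–B, 52A–C, 82A–C, 100A–V; light: 27A–F,
30A–D, 95A–J). The CDRH3 insertion block gives that loop a capacity of
exactly 30 residues, which is what makes 145 the heavy template length.
The bundled `align_chain()` is a deterministic template aligner for
canonical-framework sequences: framework segments take their fixed lengths,
CDR1/CDR2 default to their modal lengths and the remainder is attributed to
CDR3; known loop lengths can be passed explicitly, and a wrapper around an
external numbering annotator can be substituted through the `numberer`
argument of `number_and_align()` for real-world sequences. CDR residues
occupy base slots first, then insertion slots, in template order, so
stripping gaps always recovers the input sequence.

Filters accumulate (never short-circuit) the reason codes `UNPAIRED`,
`DUPLICATE`, `NUMBERING_FAIL`, `INSERTION` (non-canonical framework or
loops beyond what the template affords), `CDRH3_TOO_LONG` (over the
30-residue capacity) and `CYS_MISSING` (the conserved cysteines at scheme
positions 23 and 104 of each chain; extra cysteines elsewhere are tolerated
by default, rejected in strict mode).

One-hot encoding concatenates the aligned heavy and light chains (272
positions) over 21 channels — the 20 amino acids in alphabetical one-letter
order, then the gap. Any fixed order is equivalent for learning; this one
is asserted in tests so that stored models remain valid.

## The convolutional surrogate

`train_cnn()` fits the architecture: input (272 × 21) → three blocks of
[1-D convolution (ReLU) → batch normalization → dropout] → width-2 pooling
→ flatten → dense (ReLU) → linear output of width 10, one output per
region, one model per property. Hyperparameters are restricted to the
tuning grid (filters 16–128 step 16, kernel 3–5, dropout 0–0.5 step 0.1,
dense 32–128 step 16, learning rate {1e-2, 5e-3, 1e-3, 1e-4});
`tune_cnn()` searches it with a random, successive-halving ("hyperband") or
greedy adaptive ("bayesian" — a perturbation search, not a Gaussian
process) strategy. Training uses Adam, minibatches of 32, 50 epochs by
default, and *model checkpointing*: the returned parameters are those of
the epoch with minimum validation MAE, never the final epoch. The
train/validation/test split is 65/25/10, seeded and unstratified. Labels
are standardized per output inside the trainer (reported losses are on the
original scale). An optional multiplicative per-epoch learning-rate decay
is available; the default — used by every bundled experiment, including the
recovery suite — is a constant rate.

Implementation: the numerical core exists twice — a pure-R reference
(`cnn_forward()`/`cnn_backward()`, written on BLAS matrix products with a
channels-first layout) and an RcppArmadillo fast path used by default. The
test suite asserts the two agree to machine precision on identical RNG
streams and that backpropagation matches central-difference numeric
gradients; this dual-route design means the compiled code is never the only
witness of its own correctness.

Two initialization choices matter and were made after observing a concrete
failure mode (a dense-layer ReLU collapse in which the network permanently
predicts the training mean): the dense bias starts at +0.1 and the output
layer starts at zero, so early training cannot kill the hidden layer by
shrinking output variance. Max pooling (width 2) is the default pooling
type, with average pooling selectable; pooling type and width are recorded
in the saved model descriptor. Models persist as two plain-text files —
`architecture.json` and `weights.json` — so that a trained model travels
with a repository; binary container formats are deliberately avoided.

## The synthetic data

`make_synthetic_sequences()` emits template-compatible pairs: canonical
framework lengths, modal CDR1/CDR2, CDRH3 varying over 10–16 residues,
cysteines planted at scheme 23/104, with violation modes that plant
specific filter failures. It emulates length variation only in CDR3 and
draws residues uniformly; it does not attempt real germline structure,
positional amino-acid preferences, or somatic-mutation clustering, so
passing tests say nothing about numbering accuracy on real antibodies —
that is what the pluggable external annotator is for.

`make_surrogate_dataset()` is the ground truth for surrogate recovery. Its
labels are a fixed sparse linear map of the one-hot encoding plus Gaussian
noise (sd 0.1), structured the way one spatial property decomposes over
domains: a single random 20-vector of residue-type weights (the synthetic
analogue of a hydrophobicity or charge scale) is summed over each region's
slots, one output per region. This mirrors the multi-output design (one
model, ten domain outputs of one property) and makes the task identifiable
at n = 2000: the region outputs share their weight vector, exactly as real
domain scores share their underlying physics. Two earlier candidate designs
were rejected as statistically unlearnable at this sample size (scattered
independent coefficient cells give an effective dimension of thousands
against 1300 training rows; penalized linear baselines cap near r ≈ 0.5),
which would have tested sample size, not the model. The generator returns
the full coefficient array so tests can verify the noise-free labels
exactly, and the recovery suite requires held-out Pearson r ≥ 0.9 on every
output head at n = 2000 while a shuffled-label control stays near zero.

`make_agg_dataset()` emulates the shape of a small aggregation-rate study:
21 antibodies × 30 descriptors (equicorrelated standard normals, pairwise
correlation 0.3) and a target that is a linear signal in three descriptors
(coefficients 1.5, −1.2, 0.8 on `SAP_pos_CDRH3`, `SCM_pos_CDRL3`,
`SCM_neg_CDRH3`) plus Gaussian noise of sd 0.5. These defaults were chosen
once, by a power consideration (signal variance ≈ 3.4 against noise
variance 0.25 keeps k = 3 exhaustive selection identifiable in most seeds at
n = 21) and are not tuned thereafter. Columns are jointly Gaussian; real
descriptor tables are heavier-tailed and more collinear.

## Descriptor-based aggregation modelling

`exhaustive_select()` scores every size-k descriptor subset by mean MSE
under seeded repeated k-fold cross-validation (4 folds, 5 repeats by
default; the fold layout is identical across subsets within a seed) and
ranks ascending with lexicographic tie-breaks. For the ordinary
least-squares family a Gram-matrix fast path solves each subset from slices
of the per-fold cross-product matrix; a test asserts it equals the generic
fold loop to 1e-10.

`fit_and_tune()` tunes k-nearest neighbours (k 2–8), support-vector
regression (radial kernel, C 5–15, ε 0.1–0.5) and random forest (depth
2–6) over their stated ranges — values outside them are rejected — using
leave-one-out MSE as the default selection criterion (switchable to
k-fold), then refits on all rows. Features are standardized inside the
fit for the distance- and kernel-based families only. The random-forest
backend has no direct depth parameter, so depth d acts through the leaf
cap `maxnodes = min(2^d, n)`. `loocv()` returns the held-out predictions,
their Pearson r and MSE; `reliability_check()` accepts a model when the
fit-to-LOOCV correlation drop is at most 0.3. All correlations are
Pearson.

## Numerical choices and degenerate inputs

* SASA tie-break: points on a neighbouring sphere's surface are buried;
  lattice and results are fully deterministic.
* `ensemble_stats()` uses denominator N and reports relative sd as `NA`
  (not infinity) when the mean is zero with nonzero spread, 0 for constant
  series.
* Constant actuals make Pearson r undefined: `evaluate_cnn()` and `loocv()`
  return `NA` rather than an arbitrary number; `fit_and_tune()` raises an
  error for a constant target but still reports the MSE in the message.
* Empty exposed-residue sets produce an all-zero charge field with a
  warning, not an error.
* Subset ranking ties break lexicographically on sorted feature names so
  rankings are reproducible across platforms.
* All stochastic steps (splits, initialization, dropout, fold layout,
  forests) are driven by explicit seeds; the C++ path draws from R's RNG so
  the two backends see identical streams.

## Problem sizes used in the validation suite

The bundled tests and the acceptance script run at desk scale, chosen as
the package's own validation design: 10–20-atom toy structures for the
oracle comparisons (where brute force is exact), 960-point SASA lattices,
n = 2000 sequences / 50 epochs for surrogate recovery (the shuffled-label
control trains 15 epochs — with permuted labels there is no signal for
additional epochs to find), and 25 seeds × C(30,3) = 4060 subsets for the
selection-recovery rate. The published-scale experiment (tens of thousands
of MD-labelled antibodies) is out of scope by design: those labels cannot
be regenerated here, and the package's claims are correctness claims, not
claims about reproducing simulation-scale correlations.

## Known limitations

* The bundled charge and reference-SASA tables are curated stand-ins with
  exact invariants, not a validated force field; for production scoring,
  swap in tables derived from your force field of choice (the file format
  is documented in each header).
* The template aligner assumes canonical framework lengths; real sequences
  with framework indels need an external numbering tool behind the
  `numberer` interface.
* SASA is sampling-based (no analytic power-diagram surface); accuracy is
  controlled by `n_points`.
* The surrogate trained by `exec/abprop train-surrogate` learns the
  synthetic generator's labels — it demonstrates the pipeline end to end
  but is not a substitute for training on simulation-derived scores.
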