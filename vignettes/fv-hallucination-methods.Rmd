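---
title: "Structure-conditioned Fv subsequence design: model and methods"
author: "FvDesign authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structure-conditioned Fv subsequence design: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(FvDesign)
```

## The design problem

Antibody engineering often needs many candidate sequences for a
complementarity-determining region (CDR) or for the VH-VL interface that
all fold into one known backbone conformation: libraries conditioned on
structure stay compatible with the binding mode while exploring sequence
space. FvDesign frames this as *hallucination*: the variable fragment
sequence `S` is split into designable positions `S_D` and fixed positions
`S_F`, and we seek the `S_D` that maximizes `P(S | T)` for a target
backbone structure `T`. By Bayes' rule this is equivalent to maximizing
`log P(T | S) + log P(S)`, which the package minimizes as a weighted sum
of losses

```
L = w_G * L_G + w_S * L_S + w_M * L_M
```

with all weights 1 by default. `L_G` scores agreement between a
structure predictor's output and the target geometry; `L_S` and `L_M`
encode sequence priors for the two restricted design modes.

## Target geometry and the geometric loss

The target structure enters as binned inter-residue geometry labels over
six channels: the CA-CA, CB-CB and N-O distances and the theta/phi/omega
orientation channels. The orientation conventions follow the
trRosetta-style definitions: `omega` is the CA(i)-CB(i)-CB(j)-CA(j)
dihedral (symmetric), `theta` the N(i)-CA(i)-CB(i)-CB(j) dihedral and
`phi` the CA(i)-CB(i)-CB(j) planar angle (both ordered-pair). The N-O
channel is stored as the smaller of the two directed N(i)-O(j) distances
so that all distance channels are symmetric matrices; this is a package
convention, since the channel names alone do not fix a direction.
Glycine has no CB, so CB-dependent pair-channels are masked invalid
rather than imputed from a virtual CB; masked pair-channels simply
contribute no loss terms.

Default bin edges are configuration, not constants: distances are binned
0-20 Å in 0.5 Å steps with a catch-all bin beyond 20 Å, dihedrals in 15°
bins over (-180°, 180°], the planar angle in 12° bins over [0°, 180°].
Bins are half-open `[edge_k, edge_{k+1})`, so a value sitting exactly on
an interior edge belongs to the higher bin, and the angular domain
closes on the right so +180° is binned, not rejected.

The geometric loss is the categorical cross entropy of the predicted bin
distributions at the target labels, restricted to residue pairs in
contact:

```
L_G = -(1 / (2C)) * sum over channels X, contact pairs k of log p_{X = T}(k)
```

The contact set contains the *ordered* pairs `(i, j)` with `i` in the
design set, `j` any other residue, and CA-CA distance at or below 10 Å
on the target structure (the mask is fixed; it is not re-derived from
intermediate predictions). The count `C` follows the double sum
literally, so a pair with both endpoints designable is counted in both
orders. Self-pairs are excluded: a zero distance carries no design
pressure.

## Sequence-based losses

*Sequence-restricted* design adds the negative log-likelihood of the
wildtype letters under the design distribution,
`L_S = -sum_i log p[i, wildtype_i]`. The negative sign is a deliberate
reading: a cross entropy that is minimized must be the negative
log-likelihood, and the package treats `L_S = 0` (all probability on the
wildtype) as its optimum. *Motif-restricted* design adds the KL
divergence from a per-position target distribution `q0` at a subset of
design positions, with the convention `0 * log(0/x) = 0`. Probabilities
inside logarithms are floored at `1e-12` (logged when hit) so neither
loss can become infinite. Published restricted-mode configurations use
`w_S = 25` and `w_M = 100`; both are ordinary `lossWeights()` settings
here.

## The design loop

The optimization variable is a `|D| x 20` real matrix over the design
positions in a fixed alphabetical amino-acid column order (A, C, D, ...,
Y), shared by every matrix and PSSM in the package. Each entry is
initialized from U(0, 1); with *wildtype seeding* 0.5 is added to the
wildtype letter's entry at each position, biasing (not forcing) the
initial decoded sequence toward the wildtype. Decoding takes the row
argmax of the softmax, breaking exact ties toward the alphabetically
earlier letter.

Each iteration feeds the one-hot encoding of the decoded sequence (fixed
positions one-hot wildtype) through the oracle, evaluates the losses,
and backpropagates with a straight-through estimator: the argmax/one-hot
step is treated as the identity on the softmax rows in the backward
pass, so the gradient flows through the softmax Jacobian to the design
matrix. The gradient is zeroed at disallowed letters, normalized to unit
global L2 norm, and applied as `a <- a - lr * g` with `lr = 0.05` by
default — every effective step displaces the matrix by exactly `lr`.
Per-position normalization was rejected to keep that unit-displacement
property. Cysteine is disallowed at all design positions by default
(overridable), implemented exactly as reduced-alphabet sampling:
excluded letters are pinned to a large negative sentinel at
initialization and their gradient entries are zeroed, so they can never
be decoded.

Runs stop at 60 iterations by default (convergence is typically reached
within 40-60) or earlier when the total loss changes by less than
`1e-3` over a 5-iteration window; both are package defaults since no
sharper stopping rule is established. Libraries are batches of
independent runs with consecutive seeds; identical configuration and
seed reproduce a run bit-for-bit.

## The toy oracle

The real predictor behind this design approach is an ensemble of
pretrained deep models; re-implementing or shipping one is out of scope,
and external predictors plug in through the oracle contract
(`oracleForward` / `oracleBackward`, with `checkOracleGradient()` as the
admission test and probability-mean ensembling in `ensembleForward()`;
the mean is taken on probabilities rather than logits, a package
choice). For everything testable offline the package bundles a toy
oracle: fixed standard-normal weights `W[a, a', X, b]` drawn once from a
seed define pair logits bilinear in the two residues' probability rows,
and `softmax(logits / temperature)` gives the bin distributions. It is
deterministic, differentiable in closed form, and `toyTarget()` turns
any reference sequence into a target whose labels are the argmax bins of
that reference — making the reference a verifiable optimum candidate, so
design-recovery experiments can be checked against exhaustive
enumeration. The default temperature is 1; lower values sharpen the
landscape and speed recovery experiments.

## Library evaluation and developability

`aar()` is the mean percentage of design positions matching the
wildtype. `buildPssm()` uses raw empirical frequencies with no
pseudo-counts. The Bhattacharyya coefficient is the standard
`BC_i = sum_AA sqrt(p * q)` (the square root is part of the definition;
`BD_i = -ln BC_i` with BC floored at `1e-6` so disjoint one-hots give a
finite `BD = -ln(1e-6) ≈ 13.82`). Perplexity is `2^entropy` with base-2
entropy, spanning 1 (one-hot) to 20 (uniform). Edit distances use the
standard unit-cost Levenshtein metric (via `utils::adist`), reported per
design against the wildtype and as the minimum over a reference set. FR
scores are plain lookup sums of per-position amino-acid enrichment
tables supplied as TSV inputs.

Developability metrics follow the conventions used for antibody design
libraries: the instability index is computed on the full heavy chain
with the published Guruprasad dipeptide weights (shipped as a plain-text
table with provenance header); GRAVY is the mean Kyte-Doolittle
hydropathy over the designed stretch padded by 10 residues on each side,
clipped at chain boundaries; net charge is a Henderson-Hasselbalch sum
over the full Fv with the EMBOSS pKa set at pH 7 by default — the pH and
pKa set are configurable because no single convention is canonical.
Structure- or tool-dependent metrics (solubility, spatial aggregation
propensity, MHC-II immunogenicity) are external-tool territory and are
deliberately absent rather than imitated.

## Screening pipeline

`runPipeline()` is the fold-then-bind screen: a folding adapter maps
each sequence to backbone coordinates, and the design passes the fold
gate iff its design-region backbone RMSD to the target is at most 2.0 Å.
The RMSD convention is two-stage: superpose on the N/CA/C atoms of all
*non*-design (framework) residues, then measure RMSD over the N/CA/C
atoms of the design residues in that frame (O excluded; per-residue
values come from the same framework frame). A binding adapter returns
five decoy binding energies per design; the design's dG is the decoy
minimum and it passes iff it is at or below the wildtype reference
(margin 0 by default). The screened library is the intersection of the
two gates. Adapters are plain functions, so licensed folding/energy
engines stay outside the package; bundled mock adapters (deterministic
displacement folder, seeded-draw binder) make the pipeline fully
testable offline. RMSD values below `1e-12` are snapped to zero so a
bit-identical fold passes even a degenerate 0 Å threshold.

## What the synthetic fixtures emulate — and what they do not

`generateFixtures()` builds, deterministically per seed: a cysteine-free
random Fv (7 + 5 residues by default), CA coordinates from a
self-avoiding random walk with the canonical 3.8 Å spacing (minimum
3.5 Å separation otherwise), idealized local placements for N, C, O and
CB around each CA, a 3-position design region centered on the heavy
chain, its 10 Å contact mask, a toy oracle, the toy target built from
the Fv itself, and a reference library sampled from a known random PSSM
so profile metrics have computable expectations. These sizes keep
exhaustive enumeration (8^3 candidates) and multi-run experiments cheap;
the test suite uses 20-50-run libraries, 100-probe finite-difference
checks, 10,000-draw initialization statistics and 200-design mock
screens.

The fixtures exercise every contract, but they are not antibodies: the
walk has no secondary structure or chain pairing, the toy oracle's
landscape is an arbitrary bilinear form rather than learned
sequence-structure statistics, and the toy target is constructed to have
a known optimum. Passing tests therefore demonstrate the correctness of
the losses, gradients, optimizer, metrics and gates — not that designs
against a real predictor will recover native CDRs or bind an antigen.
Quantities that require a pretrained ensemble, a relational database of
CDR clusters, or Rosetta-style energetics (benchmark sequence-recovery
rates, cluster-overlap margins, fold-retention fractions on real
antibodies) are out of reach at this scale and are not claimed.

## Numerical choices and limitations

* Natural logarithms throughout the losses; any other base rescales all
  losses uniformly. BD also uses the natural log.
* Probability floors: `1e-12` inside loss logarithms, `1e-6` inside BD.
* Decode ties break to the alphabetically earlier letter; disallowed
  letters are sentinel-pinned at `-1e9`.
* Residue indexing is 1-based internally (idiomatic R); file interfaces
  use chain + Chothia-style labels, and the numbering TSV carries
  1-based per-chain sequence indices, so no 0/1 convention crosses the
  package boundary.
* Chothia-style numbering is consumed, never computed: renumbering is an
  input requirement, and only H/L amino-acid chains are supported.
* The contact mask derives from the target structure once; whether an
  iterating predictor should refresh it is an open modelling question we
  resolve as "fixed mask".
* The dihedral sign convention is the standard IUPAC/atan2 form; it was
  cross-checked against an independent two-plane derivation in the test
  suite.
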