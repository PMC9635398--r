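# FvDesign

Structure-conditioned design of antibody Fv subsequences — CDR loops and
VH-VL interface positions — by gradient-based *hallucination* through a
differentiable sequence-to-geometry oracle. The package is for antibody
engineers and method developers who need targeted, structure-conditioned
CDR libraries (for affinity maturation, interface humanization, or
screening studies) and a fully offline-testable implementation of the
design machinery.

## The method

Given a target backbone structure `T` and a split of the Fv sequence
into designable positions `S_D` and fixed positions `S_F`, the design
problem is

```
max_{S_D} log P(S | T)  =  max_{S_D} [ log P(T | S) + log P(S) ]
```

which is minimized as a weighted loss `L = w_G L_G + w_S L_S + w_M L_M`:

* **Geometric loss** `L_G = -(1/(2C)) Σ_X Σ_{k=1..C} log p_{X=T}(k)` —
  categorical cross entropy of the oracle's predicted bin distributions
  at the target's binned geometry labels, over six channels
  `X ∈ {d_CA, d_CB, d_N-O, θ, φ, ω}` and the `C` ordered residue pairs
  with CA-CA distance ≤ 10 Å involving a design position.
* **Sequence loss** `L_S = -Σ_{i∈D} log p_{i,wt_i}` (sequence-restricted
  mode, typically `w_S = 25`).
* **Motif loss** `L_M = Σ_{i∈M} KL(q⁰_i ‖ p_i)` (motif-restricted mode,
  typically `w_M = 100`).

The optimization variable is a `|D| × 20` design matrix; each iteration
decodes it (softmax + argmax), feeds the one-hot sequence through the
oracle, and updates the matrix by normalized SGD with a straight-through
gradient. Initialization is U(0,1), optionally with a +0.5 *wildtype
seeding* bonus; cysteine is excluded by default via reduced-alphabet
sampling. A bundled deterministic toy oracle with a verifiable optimum
makes design-recovery experiments checkable by exhaustive enumeration;
external structure predictors plug in through a forward/backward oracle
contract with a finite-difference admission test.

Around the design loop the package provides library metrics (amino-acid
recovery, PSSMs, Bhattacharyya coefficient/distance, perplexity,
Levenshtein profiles, FR-score sums), sequence-level developability
metrics (Guruprasad instability index, Kyte-Doolittle GRAVY over the
padded design window, Henderson-Hasselbalch net charge), and a fold/bind
screening pipeline (framework-aligned design-region backbone RMSD ≤
2.0 Å gate; decoy-minimum binding-energy gate) with mock adapters for
offline use.

## Worked example

```r
library(FvDesign)

fx <- generateFixtures(fixtureSpec(seed = 42))   # synthetic design problem
fx$fv
#> FvSequence: H 7 aa, L 5 aa
#>   H: VGAMFWV
#>   L: SIFGR
fx$mask
#> ContactMask: C = 30 ordered pairs (cutoff 10.0 A)

cfg <- hallucinationConfig(seed = 7, maxIterations = 60)
rec <- hallucinate(cfg, fx$oracle, fx$target, fx$mask, fx$fv, fx$region)
rec
#> DesignRecord: 'AMF' (seed 7, 60 iterations, final loss 7.4750)

lib <- generateLibrary(hallucinationConfig(maxIterations = 25), fx$oracle,
                       fx$target, fx$mask, fx$fv, fx$region,
                       nDesigns = 20, seedBase = 100)
aar(designedSequences(lib), fx$fv, fx$region)
#> [1] 88.33333
mean(perplexity(buildPssm(designedSequences(lib))))
#> [1] 1.626486
developabilityReport(lib[1:2], fx$region)
#>   id designed instability_index    gravy net_charge
#> 1  1      AMF         -27.81429 1.942857  0.9758914
#> 2  2      AMF         -27.81429 1.942857  0.9758914
```

The toy target is built from the fixture's own wildtype, so the designed
subsequence `AMF` *is* the wildtype design region: the loop has
recovered the sequence whose geometry it was conditioned on. At 60
iterations the run converges on that optimum (the residual loss is the
sequence-loss term of the default weights); shorter 25-iteration runs
leave some diversity, giving the 88.3% recovery and mean per-position
perplexity of 1.63 above. The developability rows report the full
heavy-chain instability index, the GRAVY of the padded design window and
the Fv net charge at pH 7 for each design.

A thin command-line front end (`inst/scripts/fvdesign.R`) exposes the
same machinery as `fixtures`, `hallucinate`, `extract-geometry`,
`evaluate` and `screen` subcommands, all runnable end-to-end on
generated fixtures with no network access.

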