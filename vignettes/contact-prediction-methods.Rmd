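---
title: "Contact prediction from sequence covariation: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contact prediction from sequence covariation: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Residues that are close in a protein's 3D structure constrain each other's
evolution: a destabilizing substitution at one site is often compensated at
its spatial neighbor. Given a deep multiple sequence alignment (MSA) of a
protein family, this leaves a statistical fingerprint — correlated
substitution patterns between alignment columns — from which residue-residue
contacts can be inferred. The difficulty is that raw correlation mixes
direct structural coupling with indirect, chained correlations and with
phylogenetic bias, and that different decoupling strategies (sparse inverse
covariance, mean-field inversion, pseudolikelihood maximization) recover
partially non-overlapping sets of true contacts. `metacontact` implements
these engines plus mutual information, and a two-stage neural-network
meta-predictor that combines them with "classical" alignment-derived
features (profiles, gap structure, entropy, sequence separation) so that
predictions degrade gracefully when the alignment is shallow.

All components are trainable and testable offline: a Potts-model simulator
generates families with known contact topologies.

## Alignment handling and effective depth

Alignments are read from FASTA, A3M (lowercase insertion states are deleted
so all rows match the query length) or a flat one-sequence-per-line format.
Characters are uppercased; the ambiguity/non-standard codes B, Z, U, O, J
are canonicalized to a dedicated unknown `X`. For *frequency counting* `X`
is treated as a gap, keeping the statistical state space at 21 (20 amino
acids + gap). For *identity calculations* `X` is an ordinary (mismatching,
or matching another `X`) character and only `-` is a gap; identity is
matches divided by the number of columns where at least one sequence is
non-gap.

Alignment depth is measured as the effective sequence count `N_eff`: the
number of single-linkage clusters at 62% pairwise identity, the threshold
used to compile BLOSUM62. Single linkage (transitive closure over the
identity graph) is chosen to mirror that precedent. Per-sequence weights
are reciprocal cluster sizes, so they sum exactly to `N_eff`; the same
weights enter every frequency computation.

The hybrid alignment-generation protocol of the upstream server (HHblits
with E-value 1e-3, 50% coverage, 3 iterations; a jackHMMer supplement with
E-value 10, 3 iterations when the first pass returns fewer than 2000
sequences; the deeper alignment wins, ties to the first branch) is recorded
as a machine-checkable configuration and decision function
(`pipeline_config()`, `needs_supplement()`, `select_deeper_alignment()`);
the external tools themselves are deliberately not executed.

## Frequency model

With per-sequence weights `w_s` (total `W`) and pseudocount mass `lambda`,

    f_i(a)    = (lambda/q   + sum_s w_s [x_si = a]) / (lambda + W)
    f_ij(a,b) = (lambda/q^2 + sum_s w_s [x_si = a][x_sj = b]) / (lambda + W)

so pair frequencies marginalize exactly to the single-site ones. The joint
of a column with itself is exactly `diag(f_i)`: this keeps the full
`21L x 21L` second-moment matrix a genuine mixture moment matrix, hence the
connected correlation `C = f2 - f1 f1'` is positive semi-definite — a
property the matrix-inversion engines rely on.

Defaults: `lambda = 1` (a near-raw model, used for mutual information and
as the graphical-lasso input, which has its own shrinkage) and
`lambda = W` (relative pseudocount 0.5, the customary mean-field choice)
for the mean-field engine, where the 20-state correlation matrix would
otherwise be numerically singular whenever columns have few gaps (the 20
indicator frequencies then sum to almost 1).

## Covariation engines

All engines produce a symmetric `L x L` score matrix with pairs closer
than `min_separation = 4` masked ("four residues or more apart" read as
`|i - j| >= 4`; the alternative reading `>= 5` is configurable).
All scores receive the average product correction (APC)

    S'(i,j) = S(i,j) - S_i S_j / S_bar

with row means and grand mean taken over unmasked entries; APC removes
per-column background (conservation/phylogeny) signal. Mutual information
is additionally available uncorrected.

* **Mutual information**: `MI(i,j) = sum_ab f_ij ln(f_ij / (f_i f_j))` in
  nats, `0 ln 0 = 0`.
* **Mean-field DCA**: the gap state is dropped per column (removing the
  simplex degeneracy) and couplings are read off the negated inverse of the
  20-state connected correlation matrix; the pair score is the Frobenius
  norm of the zero-sum-gauged `20 x 20` coupling block.
* **Sparse inverse covariance (graphical lasso)**: maximizes
  `log det Theta - tr(S Theta) - rho ||Theta||_1` by block coordinate
  descent (Friedman-style, written for this package since no graphical
  lasso implementation is available in the dependency set). The sample
  covariance is first shrunk toward its diagonal, `S' = (1-g)S + g diag(S)`,
  with `g` grown from 0.1 until positive definite. Default `rho = 0.005`.
  The pair score is the L1 norm of the `(i,j)` precision block.
  Non-convergence within `max_iter` sweeps is flagged with a warning; the
  result is still returned.
* **Pseudolikelihood Potts couplings**: minimizes the weighted, L2-penalized
  negative log-pseudolikelihood by L-BFGS from zero initialization
  (deterministic by construction — no random restarts). Fields and
  couplings are penalized separately (defaults 0.01 and 0.05). The
  iteration cap (default 50) is part of the regularization: coupling
  rankings stabilize long before full convergence, and on simulated
  families a capped fit ranks contacts as well as or better than a fully
  converged one. Scores are zero-sum-gauged block Frobenius norms.

Score ties are broken by lexicographic `(i, j)` order everywhere a ranking
is materialized.

## The two-stage meta-predictor

Stage 1 is a one-hidden-layer logistic MLP over per-pair features:

* each included engine's score at `(i, j)` (default: MIp, mean-field,
  graphical lasso, pseudolikelihood);
* windowed column profiles (default ±2 columns around each of `i` and `j`):
  21 state frequencies, gap fraction and Shannon entropy per column,
  out-of-range columns filled with a pad sentinel;
* a one-hot sequence-separation bin (4–8, 9–13, 14–18, 19–23, 24–38, ≥39);
* global depth terms `ln(1 + N_eff)` and `ln(1 + N)`;
* optionally, per-residue 3-state secondary-structure probabilities and
  solvent accessibility from an external predictor's table.

Depth modulation — down-weighting covariation evidence for shallow
alignments — is not hard-coded: the depth terms are features and the
network learns the gating.

Stage 2 re-scores every pair from the 11×11 window of the stage-1 map
centered on it (row-major, out-of-map cells padded), concatenated with the
depth and separation features. Its role is local consistency: isolated
high-probability pixels without support in their neighborhood are
suppressed, and holes inside dense contact blocks are filled. Because a
well-trained stage 1 on simulated families emits few isolated false
positives, stage-2 training would otherwise collapse to copying the center
pixel; a denoising augmentation (a configurable fraction of training
windows duplicated with their center corrupted against the label) forces
the network to weigh the neighborhood against an inconsistent center. Both
effects are verified on constructed outlier/gap suites in the tests.

Architecture choices that were genuinely open and are therefore
configuration, not doctrine: one hidden layer of 50 units per stage;
weighted cross-entropy with non-contacts down-weighted to an effective 5:1
ratio; mini-batch Adam (rate 0.005, batch 64; 30 epochs for stage 1 and 60
for stage 2, which sees fewer effective patterns per family). Training is
bitwise deterministic: initialization and shuffling come from an internal
xorshift generator seeded by `train_seed`, recorded in the model container.
Models serialize with R's native serialization and reload bit-exactly.

Training labels come from the simulator's ground truth: contact iff the
pair's chain distance is at most 8 distance units, matching the restraint
threshold.

## The family simulator

`sample_topology()` grows a self-avoiding 3D chain (bond length 3.8,
excluded volume 4.0 — conventional Calpha-like values, with distance units
read as Angstroms) confined to a sphere sized for ~150 cubic units per
residue, compact enough that long-range contacts form. Contacts are pairs
with `|i - j| >= 4` within 8 units. `build_potts()` places random
zero-sum-gauge 21×21 coupling blocks, scaled by `beta`, on contact pairs
only; fields encode a near-uniform amino-acid composition with rare gaps.
`gibbs_sample_msa()` runs single-site Gibbs sweeps (burn-in 100, thinning
10) and is exact-enumeration-tested on two-site models.

The default `beta = 1.2` is calibrated once so that the covariation
engines' contact-ranking AUC exceeds 0.8 at `L = 30`, `N = 2000` — i.e. the
simulator emits learnable signal at benchmark depth; it is a property of
the study conditions, not a tuning knob of any test.

Shallow families are emulated by redundancy padding: `target_neff` diverse
sequences are Gibbs-sampled and the alignment is filled to `n_sequences`
with near-duplicates (per-site mutation rate 0.1, keeping copies well
inside their parent's 62% cluster). This reproduces the only depth
covariate the evaluation uses (`N_eff`), not true phylogenetic structure.
What passing tests show is therefore recoverability of Potts-generated
couplings under realistic depth variation — not performance on real
families, whose phylogeny, alignment errors and non-pairwise constraints
the simulator does not model. One global seed fans out to per-stage
sub-seeds by a fixed affine scheme, so every artifact is reproducible from
the config alone.

## Evaluation

Predictions are ranked lists `(i, j, probability)`, `i < j`, probability
descending, ties lexicographic. Top-`L/5` precision selects
`floor(L/5)` (at least 1) pairs after filtering to a separation class:
long-range means separation > 23 (i.e. `>= 24`), short-range 4–23, so the
classes partition the eligible range; the rounding convention is a
documented choice. CASP RR files are written as `i j 0 8 p` with
probabilities to 3 decimals between `PFRMAT RR`/`MODEL 1` and `END`
records, and round-trip losslessly up to that rounding.

The depth benchmark (`benchmark_by_neff()`, and the stratified harness in
the acceptance tests) uses a paired design: the same topology seeds appear
in every `N_eff` stratum, so depth effects are isolated from
topology-to-topology variation. Problem sizes used in the shipped tests —
`L = 30`, 600–2000 sequences, 10 families per condition, 24 training
families — were chosen as the smallest sizes at which the depth trend and
the engines' rankings are stable and the whole suite stays desk-scale.

## Contact restraints

A probability map becomes restraints by keeping pairs with probability
≥ 0.5 (the PPV cutoff) and splitting short-range (separation ≤ 23) from
long-range (≥ 24) — separation exactly 23 goes to the short-range class so
the two potentials partition the range, a choice the source conventions
leave open. Each restraint is a square well of depth equal to its
probability: `E = -w` within 8 Å (Cbeta-Cbeta; Calpha for glycine), and
beyond the threshold a decay that is Gaussian by default
(`exp(-(d-d0)^2 / (2 sigma^2))`, `sigma = 2 Å`) with an
exponential-in-distance alternative behind the same configuration; the
exact decay form and constant are not pinned down by the upstream
description, so both are offered and documented. Energies are summed
separately over the two classes (`E_SR-RR`, `E_LR-RR`) because a single
pooled potential lets abundant, easy short-range contacts swamp the
long-range ones. Structure scoring reads Cbeta coordinates from PDB ATOM
records (first model, first alternate location).

## Known limitations

* The simulator's families lack phylogenetic correlation structure;
  redundancy padding imitates shallow depth, not tree topology, so
  phylogenetic-bias robustness is untested here.
* The exact feature inventories of the original two-stage predictor (672
  and 731 features) live in that work's supplementary material; this
  package implements the named feature *groups* with a configurable layout
  and records the resulting counts in the model container, without claiming
  feature-for-feature parity.
* The graphical lasso targets desk-scale alignments (`20L` up to a few
  thousand variables); no large-L approximations are included.
* External homology search, secondary-structure prediction and fragment
  assembly folding are out of scope by design; their interfaces (alignment
  files, auxiliary feature tables, RR files, PDB coordinates) are the
  package boundary.
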