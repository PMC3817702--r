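---
title: "The MRsearch engine: model, scoring backend and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The MRsearch engine: model, scoring backend and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

MRsearch is a decision engine for automated molecular replacement (MR): it
decides which partial solutions to extend, with which models, when a peak
is a clear solution, when two solutions are the same solution, and when a
space-group ambiguity can be resolved.  This vignette explains the model
behind the package, the synthetic scoring backend it ships with, the
parameters that matter, and the places where the design was genuinely open
and a choice had to be made.

## The search model

A *partial solution* is a set of rigid-body placements of prepared search
models in one space group, with a score, ancestry, and the
translation-function Z-score (TFZ) each placement had when it was added.
The engine runs *extension cycles*.  One cycle, per active space group:

1. **Composition analysis.**  The placed models' sequence coverage is
   subtracted from the declared asymmetric-unit contents; solutions with
   nothing left to place become complete.  Models are admissible for a
   remaining copy when their coverage fits into its uncovered intervals up
   to a 10% overlap tolerance.
2. **Pending predictions.**  Amalgamation partners and assembly
   predictions recorded in the previous cycle are evaluated by a quick
   packing-plus-scoring job.  A confirmed (clear) prediction extends the
   solution and the search phase is skipped for it this cycle.
3. **Search.**  For each admissible (partial, model) pair: rotation search
   over a quasi-uniform orientation grid, translation search over a
   fractional grid, packing check.  Children of the best-scoring parent
   are evaluated first (depth-first).  In quick mode only the best partial
   is processed, and model iteration stops at the first clear solution.
4. **Categorization.**  A peak is *clear* when it packs and its TFZ
   reaches `tfzClear` (default 7); solutions produced by
   alternative-model rescoring are clear irrespective of score.
5. **Selection.**  Packing failures are removed; peaks with
   `LLG ≥ best − f·|best − parent LLG|` (select fraction `f`, default
   0.25) are kept, clear peaks are retained even below the threshold, and
   the set is capped at `maxActiveBranches` (default 25).
6. **Refinement.**  Each selected peak's solution is rigid-body refined.
7. **Propagation.**  The same percentage rule, with the purge fraction,
   applied to the refined scores decides which children stay active.
8. **Branch reduction.**  With template equivalence on, solutions that
   use models from the same source templates and are spatially equivalent
   under a crystal symmetry operation plus an allowed origin move collapse
   to their best representative.
9. **Solution analyses.**  Clear siblings sharing a parent and compatible
   compositions become amalgamation candidates; NCS point groups are
   detected on clear solutions and missing orbit members become pending
   predictions; user-supplied assemblies are completed by a local grid
   search around the predicted pose.

The run ends when no space group produces an extension (quick mode also
stops once a complete clear solution exists and nothing is pending).
Output selection sorts all recorded solutions, applies the percentage
threshold, removes solutions that are symmetry-aware subsets of a
strictly better solution, and merges incomplete ancestors into
descendants that actually improve on them — so with an overestimated
composition the correct-count solution stays listed first.

## The synthetic backend

The bundled backend replaces diffraction data with a synthetic ground
truth so that every engine behaviour can be exercised at desk scale.

**Generator.**  Each component is a seeded compact self-avoiding Cα walk
(bond 3.8 Å, radius-of-gyration cap).  The cell is sized from the total
scattering weight and a target solvent fraction through the Matthews
relation `V_M = V/(n_ops · Z · ΣMW)`, `solvent = 1 − 1.23/V_M`; cell axes
take gently unequal ratios within the crystal system.  Copies are placed
by rejection sampling (packing must pass), with centers stratified over a
shuffled fractional grid so crowded cells are covered systematically; a
failed pass restarts with a fresh derived stream (up to 20 passes) before
the generator reports failure.  Assembly copies are placed as exact Cn/Dn
orbits; each orbit draws its own random axis, and the default ring radius
separates adjacent members by two cloud radii plus 2.5 Å.  Assembly
crystals are generated at 60% solvent in the worked examples — large
point-group assemblies pack loosely, and denser cells make the rejection
sampler fail.  The generator also emits one perturbed template model per
component (default coordinate noise 0.8 Å; the examples in this package
use 0.3 Å).

**Score.**  The LLG analogue of a solution is

> max over allowed global origin moves of
> Σ placements `w·ov(placement, matched truth)` − 0.5·mean(w)·clashes
> + per-placement noise,

where `ov` is the structure-wise Gaussian overlap — the mean over
hypothesis-group images of the placement of the best per-residue
`exp(−d²/2σ²)` agreement with any true-group image of the truth (σ
default 1.5 Å; rigid lattice adjustment from the centroid difference) —
and matching is greedy without truth reuse.  Scoring under a *hypothesis*
space group other than the generator's is what makes enantiomorph
arbitration meaningful: in the wrong enantiomorph only the identity image
matches, so the score falls to roughly 1/n_ops of the correct group's.
Clashes are Cα pairs closer than 3 Å between different placements or
their symmetry images.  The noise term (sd `ε·w`, `ε` default 0.02) is
keyed on discretized placement bins (1 Å, ~5° quaternion bins) through a
hash, so identical placements always rescore identically — runs are
deterministic for a fixed seed, deliberately removing the scheduling
variability a real multi-process pipeline would show, and identical
archives across worker counts become a testable invariant.

**Searches.**  The rotation search scores a super-Fibonacci quaternion
grid (default step 15°) by orientation-only overlap
`exp(−Δθ²/2σ_rot²)` (σ_rot default 10°) against unmatched truths.  The
translation search scans a fractional grid (default step 2 Å; polar axes
pinned to 0 for the first placement, the standard convention) and scores
each position by the gain in the mock LLG; the scan evaluates the gain at
the partial solution's optimal origin move (all discrete shifts are
enumerated; a continuous polar component is frozen from the partial), and
the reported top peaks are rescored with the full shift-optimizing
scorer.  TFZ standardizes a peak against the mean and standard deviation
of the *clash-free* grid points: positions dominated by the clash penalty
belong to the packing function, and letting them into the background
statistics would drown the Z-scores of genuine peaks.  The background
Z-score used for non-search candidates (amalgamation partners, assembly
predictions) standardizes the candidate's weighted overlap gain against
the same quantity for seeded random placements of the same model, for the
same reason computed without the clash term — packing is tested
separately.

**Refinement.**  Derivative-free (Nelder-Mead) maximization over the six
rigid-body parameters of each in-scope placement, bounded to ±15°/±5 Å,
iterated until a full pass improves the score by less than 1e−4.  While
one placement moves, the overlap rows of the fixed placements are cached
per candidate shift, so each objective evaluation scores only the moving
placement.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `tfzClear` | 7 | TFZ at which a packing peak is clear |
| `selectFraction`, `purgeFraction`, `sgFraction` | 0.25 | percentage pruning rules (pre-refinement, post-refinement, space-group) |
| `maxActiveBranches` | 25 | cap on active partials per group |
| `gridStep` | 2 Å | translation grid (3 Å in the coarse assembly runs) |
| `rotStep` | 15° | orientation grid (20–24° in the coarse runs) |
| `nKeep` | 5 | orientations kept per rotation search |
| `sigma` / `sigmaRot` / `epsilon` | 1.5 Å / 10° / 0.02 | overlap width, orientation width, noise level of the backend |
| `tolRot`, `tolTrans` | 5°, 2 Å | spatial-equivalence tolerances |

The clear-solution threshold of 7 is anchored to the TFZ contrast the
backend is designed to produce: at the default geometry a correct
placement standardizes above 7 and noise peaks stay below about 4.  The
percentage fractions default to 0.25; the rules are structural, the value
is a package choice.  Assembly detection uses angle/axis tolerances of
5°, a maximum screw component of 1 Å and a maximum group order of 12.

## Design choices where the design was open

* **Superposition is alignment-paired Kabsch**, not secondary-structure
  matching: the models that need superposing always share a target
  alignment here, and Kabsch on paired Cα positions is deterministic and
  exact.  Superposition fails (and the model is skipped) on fewer than
  three shared residues or collinear inputs.
* **Seven chiral space groups** (P1, P2₁, C2, P2₁2₁2₁, P2₁2₁2, P4₁,
  P4₃) span every branch the engine distinguishes: fully polar,
  monoclinic polar, orthorhombic nonpolar with nontrivial discrete
  origin shifts, and a tetragonal enantiomorph pair.  Origin shifts are
  enumerated by conjugation rather than tabulated.
* **Cα-only models.**  The engine's decisions depend on rigid-body
  geometry and scattering weights only; full-atom support would change no
  algorithm.  Readers accept full-atom PDB files and extract the Cα trace.
* **Six editing protocols** (pruning mode × B-value scheme, reduced grid)
  stand in for a larger protocol library; 9-residue identity windows with
  a 0.2 identity floor and `B = 20 + 60·(1 − identity)` are the package's
  own parameterization.
* **Prediction identification.**  A pending prediction is confirmed when
  it packs, its background Z reaches `tfzClear`, *and* its score gain
  reaches half the parent's mean per-copy gain.  The last condition is
  self-calibrating (no new absolute constant) and exists because a
  partial-overlap impostor can standardize far above any fixed Z
  threshold while contributing a fraction of a genuine placement's gain.
* **NCS detection is symmetry-aware.**  Search placements land in
  arbitrary asymmetric units, so point-group relations are computed
  against the crystal-symmetry images of the partner placement (with the
  lattice offset minimizing the screw component), and orbit positions
  already occupied modulo crystal symmetry are not re-predicted.
* **Clear retention through the second threshold.**  Clear solutions are
  retained through post-refinement propagation as well, and this is
  visible in the archive.
* **Predictions of purged parents are dropped** together with the parent;
  only associations of live solutions are ever evaluated.
* **Selection-threshold direction.**  In `keep if score ≥ best − f·|Δ|`,
  *larger* fractions keep more branches; the tested monotonicity is that
  growing `f` never shrinks the selected set.

## What the synthetic data do and do not show

The generator emulates rigid-body placements with controllable blur,
orientation tolerance and score noise, exact point-group orbits, and
crystallographic symmetry with origin freedom — enough to exercise every
decision rule of the engine.  It does not emulate structure factors,
resolution dependence, anisotropy, model incompleteness beyond coverage
intervals, or the score landscapes of real likelihood targets; passing
tests demonstrate that the *decision logic* behaves as specified, not
that any particular real crystal would be solved.  Problem sizes in the
tests are deliberately small — components of 10–20 residues, one to four
copies, and a 20-copy four-pentamer crystal at a 3 Å / 24° search grid —
chosen so the full suite exercises every pathway in minutes.

## Known limitations

Non-chiral space groups, non-standard settings and nucleic-acid
components are out of scope.  Quick mode commits to the best lineage
early; with very round (small) components, orientation discrimination is
weak and a wrong-orientation placement can survive into the final
solution as a lower-scoring extra.  Underestimated compositions are not
handled (the search stops at the declared contents).  The executor ships
with a local scheduler only, though the contract accepts alternatives.
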