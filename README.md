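# MRsearch

Automated molecular replacement (MR) solves the crystallographic phase
problem by placing known homologous models into the unit cell through
rotation and translation searches.  When several copies, several
components, several candidate models and an uncertain space group all meet
in one problem, MR stops being a single search and becomes a decision
problem: which partial solution to extend next, which models to try, when a
peak is *clear*, when two partial solutions are really the same one, and
when the space group can finally be chosen.

MRsearch implements that decision engine for R users — crystallographic
methods developers and students of MR automation — at desk scale:

* **Extension cycles with branching and pruning.**  Active partial
  solutions are extended one rigid-body placement at a time
  (rotation search → translation search → packing → refinement), and both
  before and after refinement the peak set is thresholded by the percentage
  rule `keep if LLG ≥ best − f·|best − parent|`.
* **Clear-solution categorization.**  A peak that packs and reaches a
  translation-function Z-score (TFZ) of at least 7 is clear; clear
  solutions drive amalgamation, assembly analysis and the quick strategy.
* **Alternative-model rescoring.**  In quick mode, once one model gives a
  clear solution the remaining models of the component are *not* searched:
  equivalent solutions are generated by Kabsch superposition onto the
  placed model and scored directly (same-template alternatives without
  refinement), so `k` alternative models cost one search plus `k − 1`
  rescorings per cycle.
* **Amalgamation.**  Clear siblings extending the same parent are combined;
  with an empty parent the relative origin is recovered by trying every
  allowed discrete origin shift (nonpolar groups) or by re-running only the
  translation search with the reused rotation (polar groups).
* **NCS assembly detection and completion.**  Pairwise rigid transforms
  between placed copies (crystal-symmetry images included) are tested for
  point-group membership (angle ≈ 360·m/n, negligible screw component),
  clustered by axis, closed into Cn/Dn hypotheses with subgroup
  absorption, and the missing orbit positions are scored as predictions —
  a confirmed prediction extends the solution *without* any search.
* **Space-group arbitration.**  With enantiomorph or point-group-level
  uncertainty the search runs in all compatible groups and prunes groups
  whose best score falls behind, delaying the choice until it is clear.
* **Solution archive.**  Every solution ever scored is kept, with
  ancestry, TFZ history, status and the job ledger, in a line-delimited
  JSON archive; final output discards symmetry-aware subset solutions and
  merges incomplete ancestors into their completions.

The scoring backend is pluggable.  The bundled backend is a **synthetic
toy-crystal generator plus a mock maximum-likelihood-style scorer**: the
generator builds a ground-truth crystal (seeded compact Cα clouds, cell
sized through the Matthews relation, copies placed by rejection sampling,
optionally on exact Cn/Dn orbits), and the scorer returns a log-likelihood
gain (LLG) analogue — the symmetry- and origin-aware Gaussian overlap of
the proposed placements onto the ground truth, weighted by scattering
weight, with a clash penalty and deterministic bin-keyed noise.  Scores
are comparable across all solutions of a run, which is the only property
the engine relies on, so the whole pipeline runs in seconds to minutes
without diffraction data or external crystallography binaries.

## A worked example

A four-copy crystal of one 15-residue component, searched in quick mode
with 13 perturbed variants of one template model:

```r
library(MRsearch)

gen <- generateCrystal(list(
  components = list(list(id = "A", length = 15, copies = 4)),
  spaceGroup = "P212121", epsilon = 0.02, templateNoise = 0.3), seed = 5)
models  <- makeModelVariants(gen$models[[1]], 13, noise = 0.3, seed = 5)
backend <- toyBackend(gen$crystal)
cfg     <- engineConfig(mode = "quick", seed = 5, gridStep = 2.0,
                        rotStep = 20, nKeep = 3)

arch <- runSearch(gen$crystal@components, models, backend, "P212121",
                  cfg, asu = list(copies = c(A = 4L)))
jobLedger(arch)
#>          rotation_search       translation_search                  packing
#>                        4                        4                        4
#> rescore_by_superposition         prediction_score                   refine
#>                       48                        0                        4
modelEvaluations(jobLedger(arch))
#> [1] 52

rk <- finalizeOutput(arch, cfg)
length(rk[[1]]$placements)
#> [1] 4
```

Four extension cycles, each costing one translation search plus twelve
superposition rescorings: 52 model evaluations where exhaustive branching
would enumerate 13⁴ = 28 561 quasi-equivalent complete assignments
(`dryRunEnumerate()` reports that count without any scoring).  The best
solution places all four copies; `spatiallyEquivalent()` confirms it
matches the generator's ground truth up to a symmetry operation and origin
shift.

A command-line wrapper is installed as `exec/mrsearch`
(`mrsearch run <config.yaml> [outdir]`, `mrsearch enumerate <config.yaml>`,
`mrsearch solutions list <archive.jsonl>`, `mrsearch solutions export …`);
run configs are YAML files naming the components, the synthetic crystal
spec and the engine settings (see `runFromConfig()`).

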