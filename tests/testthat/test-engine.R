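# Peak categorization, thresholding rules, branch reduction, alternative
# rescoring, space-group arbitration, enumeration and small live runs.

mkPeak <- function(llg, tfz = 0, packs = TRUE, rescored = FALSE) {
  list(llg = llg, tfz = tfz, packs = packs, rescored = rescored)
}

test_that("categorization follows the TFZ and packing rules", {
  cfg <- engineConfig()
  expect_equal(categorize(mkPeak(10, tfz = 7.2), cfg), "clear")
  expect_equal(categorize(mkPeak(10, tfz = 6.9), cfg), "ordinary")
  ## packing failure precedes a high Z-score
  expect_equal(categorize(mkPeak(10, tfz = 12, packs = FALSE), cfg),
               "ordinary")
  ## rescored alternatives are clear irrespective of the score
  expect_equal(categorize(mkPeak(10, tfz = 2, rescored = TRUE), cfg), "clear")
})

test_that("selection applies the percentage rule with clear retention", {
  cfg <- engineConfig(selectFraction = 0.25)
  peaks <- list(mkPeak(100), mkPeak(90), mkPeak(70))
  sel <- selectForRefinement(peaks, parentLlg = 0, cfg)
  expect_equal(sort(vapply(sel, `[[`, numeric(1), "llg")), c(90, 100))
  ## a clear peak below the threshold is retained
  sel2 <- selectForRefinement(c(peaks, list(mkPeak(60, tfz = 9))), 0, cfg)
  expect_equal(sort(vapply(sel2, `[[`, numeric(1), "llg")), c(60, 90, 100))
  ## packing failures are excluded before thresholding
  none <- selectForRefinement(list(mkPeak(100, packs = FALSE)), 0, cfg)
  expect_length(none, 0)
  ## widening the fraction never shrinks the selected set (the threshold
  ## best - f|best - parent| admits more peaks as f grows)
  prev <- 0L
  for (f in c(0.05, 0.15, 0.25, 0.35, 0.45)) {
    n <- length(selectForRefinement(peaks, 0,
                                    engineConfig(selectFraction = f)))
    expect_gte(n, prev)
    prev <- n
  }
})

test_that("propagation applies the purge rule after refinement", {
  cfg <- engineConfig(purgeFraction = 0.25)
  out <- propagate(list(mkPeak(200), mkPeak(120)), 0, cfg)
  expect_equal(vapply(out, `[[`, numeric(1), "llg"), 200)
  both <- propagate(list(mkPeak(150), mkPeak(150)), 0, cfg)
  expect_length(both, 2)
  expect_length(propagate(list(mkPeak(42)), 0, cfg), 1)
  ## clear survivors are retained below the threshold
  cl <- propagate(list(mkPeak(200), list(llg = 100, clear = TRUE)), 0, cfg)
  expect_length(cl, 2)
})

test_that("space-group arbitration keeps groups near the best score", {
  cfg <- engineConfig(sgFraction = 0.25)
  keep <- arbitrateSpaceGroups(c(P41 = 150, P43 = 40), prevBest = 0, cfg)
  expect_equal(keep, "P41")
  tie <- arbitrateSpaceGroups(c(P41 = 150, P43 = 150), prevBest = 0, cfg)
  expect_equal(sort(tie), c("P41", "P43"))
  expect_equal(arbitrateSpaceGroups(c(P21 = 99), prevBest = 0, cfg), "P21")
})

test_that("dry-run enumeration counts quasi-equivalent assignments", {
  comps <- list(A = componentSpec("A", strrep("A", 10)))
  tmpl <- new("EnsembleModel", modelId = "t", componentId = "A",
              members = list(matrix(0, 3, 3)), resIdx = 0:2,
              bvals = rep(20, 3), coverage = cbind(0L, 10L), weight = 300,
              sourceTemplateId = "tm", protocolId = "p")
  models13 <- makeModelVariants(tmpl, 13, noise = 0)
  en <- dryRunEnumerate(comps, models13, list(copies = c(A = 4L)))
  expect_identical(en$assignments, 13^4)        # 28561
  expect_identical(en$lineages, 1)              # one template, one lineage
  expect_equal(en$evaluationsPerStep, 13)
  one <- dryRunEnumerate(comps, models13[1], list(copies = c(A = 1L)))
  expect_identical(one$assignments, 1)
  ## two components multiply through the interleaving of extension orders
  comps2 <- list(A = componentSpec("A", strrep("A", 10)),
                 B = componentSpec("B", strrep("G", 10)))
  tB <- tmpl; tB@componentId <- "B"; tB@modelId <- "tB"
  tB@sourceTemplateId <- "tmB"
  en2 <- dryRunEnumerate(comps2, list(tmpl, tB),
                         list(copies = c(A = 1L, B = 1L)))
  expect_identical(en2$assignments, 2)  # A-then-B and B-then-A
})

test_that("branch reduction merges template-equivalent solutions", {
  gen <- tinyCrystal(copies = 1, sg = "P212121", seed = 9,
                     templateNoise = 0.3)
  cr <- gen$crystal
  vars <- makeModelVariants(gen$models[[1]], 13, noise = 0.2, seed = 2)
  reg <- asRegistry(vars)
  tr <- truthPlacements(cr)[[1]]
  mk <- function(i, llg, dt = c(0, 0, 0)) {
    s <- asSolution(list(placement("A", vars[[i]]@modelId, tr@rot,
                                   tr@trans + dt)),
                    "P212121", paste0("s", i, "_", llg))
    s@llg <- llg
    s
  }
  ## same template, same position: best survivor only
  red <- reduceBranches(list(mk(1, 100), mk(2, 95)), cr@sg, cr@cell, reg)
  expect_length(red$kept, 1)
  expect_equal(red$kept[[1]]@llg, 100)
  expect_equal(red$merged[[1]]@status, "merged")
  ## genuinely different positions both survive
  red2 <- reduceBranches(list(mk(1, 100), mk(2, 95, dt = c(9, 0, 0))),
                         cr@sg, cr@cell, reg)
  expect_length(red2$kept, 2)
  ## 13 same-template variants at the same position collapse to one
  sols <- lapply(1:13, function(i) mk(i, 100 - i))
  red3 <- reduceBranches(sols, cr@sg, cr@cell, reg)
  expect_length(red3$kept, 1)
  expect_length(red3$merged, 12)
})

test_that("alternative models are rescored by superposition", {
  gen <- tinyCrystal(copies = 1, sg = "P212121", seed = 9,
                     templateNoise = 0.3, epsilon = 0.02)
  cr <- gen$crystal
  backend <- toyBackend(cr)
  vars <- makeModelVariants(gen$models[[1]], 13, noise = 0.2, seed = 2)
  reg <- asRegistry(vars)
  tr <- truthPlacements(cr)[[1]]
  clearSol <- asSolution(list(placement("A", vars[[1]]@modelId, tr@rot,
                                        tr@trans)), "P212121", "c1")
  ledger <- MRsearch:::.newLedger()
  out <- rescoreAlternatives(clearSol, vars[-1], backend, reg,
                             ledger = ledger)
  ## 12 same-template variants: 12 rescore jobs, no refinement jobs
  expect_length(out, 12)
  expect_equal(unname(ledger$counts["rescore_by_superposition"]), 12)
  expect_equal(unname(ledger$counts["refine"]), 0)
  expect_true(all(vapply(out, function(o) isTRUE(o$clear), logical(1))))
  ## superposed placements stay on the truth
  for (o in out) {
    p <- o$placements[[1]]
    expect_lt(sqrt(sum((p@trans - tr@trans)^2)), 1.5)
  }
  ## an alternative with no common residues is skipped
  alien <- vars[[2]]
  alien@modelId <- "alien"
  alien@resIdx <- alien@resIdx + 200L
  alien@coverage <- alien@coverage + 200L
  regA <- c(reg, list(alien = alien))
  out2 <- rescoreAlternatives(clearSol, list(alien), backend, regA)
  expect_length(out2, 0)
})

test_that("a one-copy search terminates with the truth placed", {
  gen <- tinyCrystal(copies = 1, sg = "P212121", seed = 9, epsilon = 0,
                     templateNoise = 0)
  cr <- gen$crystal
  backend <- toyBackend(cr)
  cfg <- engineConfig(mode = "full", seed = 9, gridStep = 2.5, rotStep = 20,
                      nKeep = 3)
  arch <- runSearch(cr@components, unname(gen$models), backend, "P212121",
                    cfg, asu = list(copies = c(A = 1L)))
  rk <- finalizeOutput(arch, cfg)
  expect_gte(length(rk), 1)
  best <- rk[[1]]
  expect_equal(length(best$placements), 1)
  expect_equal(best$status, "complete")
  ## the placement sits on a truth image
  sol <- MRsearch:::.recordToSolution(best)
  truthSol <- asSolution(lapply(truthPlacements(cr), function(t)
    placement("A", sol@placements[[1]]@modelId, t@rot, t@trans)), "P212121")
  expect_true(spatiallyEquivalent(sol, truthSol, cr@sg, cr@cell,
                                  tolRot = 5, tolTrans = 2))
  ## monotone ancestry on the noiseless crystal
  byId <- stats::setNames(arch@records,
                          vapply(arch@records, `[[`, character(1),
                                 "solution_id"))
  for (r in arch@records) {
    if (nzchar(r$parent_id) && r$parent_id %in% names(byId))
      expect_gte(r$llg, byId[[r$parent_id]]$llg - 1e-6)
  }
  expect_error(runSearch(cr@components, list(), backend, "P212121", cfg),
               "nothing to search")
})

test_that("overestimated composition still ranks the correct count first", {
  gen <- tinyCrystal(copies = 1, sg = "P212121", seed = 9, epsilon = 0,
                     templateNoise = 0)
  cr <- gen$crystal
  backend <- toyBackend(cr)
  cfg <- engineConfig(mode = "full", seed = 9, gridStep = 2.5, rotStep = 20,
                      nKeep = 2)
  ## ask for one copy more than the crystal holds
  arch <- runSearch(cr@components, unname(gen$models), backend, "P212121",
                    cfg, asu = list(copies = c(A = 2L)))
  rk <- finalizeOutput(arch, cfg)
  expect_gte(length(rk), 1)
  nbest <- length(rk[[1]]$placements)
  llgs <- vapply(rk, `[[`, numeric(1), "llg")
  oneCopy <- Filter(function(r) length(r$placements) == 1, rk)
  expect_gte(length(oneCopy), 1)
  ## the correct-count solution scores at least as well as any over-placed one
  over <- Filter(function(r) length(r$placements) > 1, rk)
  if (length(over)) {
    expect_gte(max(vapply(oneCopy, `[[`, numeric(1), "llg")),
               max(vapply(over, `[[`, numeric(1), "llg")) - 1e-6)
  }
})

test_that("engine best matches brute-force grid enumeration", {
  gen <- tinyCrystal(copies = 1, sg = "P21212", seed = 15, epsilon = 0,
                     templateNoise = 0)
  cr <- gen$crystal
  models <- makeModelVariants(gen$models[[1]], 2, noise = 0.2, seed = 4)
  reg <- asRegistry(models)
  backend <- toyBackend(cr)
  cfg <- engineConfig(mode = "full", seed = 15, gridStep = 3.0, rotStep = 30,
                      nKeep = 5, refine = FALSE, templateEquivalence = FALSE)
  arch <- runSearch(cr@components, models, backend, "P21212", cfg,
                    asu = list(copies = c(A = 1L)))
  engineBest <- max(vapply(arch@records, `[[`, numeric(1), "llg"))
  ## independent oracle: exhaustive scan over the full rotation grid and the
  ## same translation grid for every model
  ctx <- MRsearch:::.scoreCtx(cr, NULL)
  grid <- MRsearch:::.translationGrid(cr, ctx, 3.0, pinPolar = TRUE)
  rots <- MRsearch:::rotationGrid(30)
  oracle <- -Inf
  shifts <- ctx$shifts
  pov <- lapply(seq_len(nrow(shifts)), function(i)
    MRsearch:::cppOvMatrix(list(), ctx$truths, ctx$hypOps, shifts[i, ],
                           ctx$O, ctx$Oinv, cr@sigma))
  for (m in models) {
    for (i in seq_len(nrow(rots))) {
      R <- MRsearch:::quatToRot(rots[i, ])
      raw <- MRsearch:::cppTranslationScan(
        grid$cart, m@members[[1]] %*% t(R), m@resIdx + 1L, 1L, m@weight,
        pov, list(), numeric(0), ctx$truths, ctx$hypOps, shifts,
        ctx$O, ctx$Oinv, cr@sigma, 3.0, 0, cr@epsilon, cr@seed, R)
      oracle <- max(oracle, max(raw$raw))
    }
  }
  ## the unrefined engine cannot beat the exhaustive grid, and the designed
  ## landscape puts its best peak on the oracle optimum
  expect_lte(engineBest, oracle + 1e-6)
  expect_gt(engineBest, 0.98 * oracle)
})

test_that("archives are identical across worker counts", {
  gen <- tinyCrystal(copies = 1, sg = "P212121", seed = 9, epsilon = 0.02,
                     templateNoise = 0.3)
  cr <- gen$crystal
  models <- makeModelVariants(gen$models[[1]], 3, noise = 0.2, seed = 4)
  runW <- function(w) {
    backend <- toyBackend(cr)
    cfg <- engineConfig(mode = "full", seed = 9, gridStep = 3.0,
                        rotStep = 24, nKeep = 2, workers = w)
    runSearch(cr@components, models, backend, "P212121", cfg,
              asu = list(copies = c(A = 1L)))
  }
  a1 <- runW(1L)
  a4 <- runW(4L)
  expect_equal(a1@records, a4@records)
  expect_equal(a1@ledger, a4@ledger)
})
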