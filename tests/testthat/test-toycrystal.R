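# Synthetic crystal generator and the mock scoring backend: score
# contract, symmetry invariance, searches, packing, refinement,
# background Z-scores.

test_that("generated crystals honour the requested composition and solvent", {
  gen <- tinyCrystal(copies = 1, sg = "P1", seed = 3)
  cr <- gen$crystal
  expect_length(truthPlacements(cr), 1)
  ## solvent implied by the generated cell is the 0.50 target
  mw <- cr@components$A@mw
  vm <- cellVolume(cr@cell) / (length(symOps(cr@sg)) * mw)
  expect_equal(1 - 1.23 / vm, 0.5, tolerance = 0.02)
  ## orbit-size mismatch is rejected
  expect_error(tinyCrystal(copies = 4, assembly = list(component = "A",
                                                       group = "C5")),
               "not a multiple")
  ## a C5 orbit is an exact 72-degree rotation sequence about one axis
  gen5 <- tinyCrystal(copies = 5, sg = "P1", seed = 8, length = 12,
                      assembly = list(component = "A", group = "C5"),
                      solvent = 0.6)
  tr <- truthPlacements(gen5$crystal)
  expect_length(tr, 5)
  rel <- MRsearch:::.ncsTransform(tr[[1]], tr[[2]])
  aa <- rotationAngleAxis(rel$rot)
  expect_equal(aa$theta, 72, tolerance = 1e-6)
  for (k in 2:5) {
    relk <- MRsearch:::.ncsTransform(tr[[1]], tr[[k]])
    aak <- rotationAngleAxis(relk$rot)
    expect_equal(min(abs(aak$theta - c(72, 144))), 0, tolerance = 1e-6)
  }
  ## truths of a generated crystal pack
  pk <- packingCheck(truthPlacements(gen5$crystal), gen5$crystal)
  expect_true(pk$passes)
})

test_that("model variants share identity and coverage, differ by seed", {
  gen <- tinyCrystal(seed = 4)
  tmpl <- gen$models[[1]]
  vars <- makeModelVariants(tmpl, 13, noise = 0.3, seed = 5)
  expect_length(vars, 13)
  expect_equal(unique(vapply(vars, function(m) m@sourceTemplateId,
                             character(1))), tmpl@sourceTemplateId)
  expect_equal(vapply(vars, function(m) m@protocolId, character(1)),
               sprintf("variant_%d", 1:13))
  ## zero noise reproduces the template exactly
  v0 <- makeModelVariants(tmpl, 2, noise = 0, seed = 5)
  expect_equal(v0[[1]]@members[[1]], tmpl@members[[1]])
  ## different seeds: different coordinates, same coverage and weight
  vA <- makeModelVariants(tmpl, 1, noise = 0.3, seed = 5)[[1]]
  vB <- makeModelVariants(tmpl, 1, noise = 0.3, seed = 6)[[1]]
  expect_gt(max(abs(vA@members[[1]] - vB@members[[1]])), 0)
  expect_equal(vA@coverage, vB@coverage)
  expect_equal(vA@weight, vB@weight)
})

test_that("mock LLG obeys the comparable-score and symmetry contracts", {
  gen <- tinyCrystal(copies = 2, sg = "P212121", seed = 11, epsilon = 0)
  cr <- gen$crystal
  tr <- truthPlacements(cr)
  ## empty solution scores zero
  e <- mockLLG(list(), cr)
  expect_equal(e$llg, 0)
  expect_equal(e$clashCount, 0L)
  ## a placement exactly on a truth scores its full weight (overlap 1)
  s1 <- mockLLG(list(tr[[1]]), cr)
  expect_equal(s1$perPlacementOverlap, 1, tolerance = 1e-9)
  w <- molecularWeight(cr@components$A@sequence) - 18.02
  expect_equal(s1$llg, w, tolerance = 1e-6)
  ## uniformly closer-to-truth placements never score lower (epsilon = 0)
  set.seed(2)
  dirs <- matrix(rnorm(15), 5, 3)
  for (i in 1:5) {
    d <- dirs[i, ] / sqrt(sum(dirs[i, ]^2))
    near <- placement("A", "truth", tr[[1]]@rot, tr[[1]]@trans + 0.5 * d)
    far <- placement("A", "truth", tr[[1]]@rot, tr[[1]]@trans + 1.5 * d)
    expect_gte(mockLLG(list(near), cr)$llg, mockLLG(list(far), cr)$llg)
  }
  ## invariance under one catalogue op + allowed origin shift applied jointly
  O <- orthogonalizationMatrix(cr@cell)
  base <- mockLLG(tr, cr)$llg
  for (op in symOps(cr@sg)) {
    moved <- lapply(tr, applySymop, op = op, cell = cr@cell)
    expect_equal(mockLLG(moved, cr)$llg, base, tolerance = 1e-6)
  }
  for (i in seq_len(nrow(originShifts(cr@sg)))) {
    sh <- as.vector(O %*% originShifts(cr@sg)[i, ])
    moved <- lapply(tr, function(p)
      placement(p@componentId, p@modelId, p@rot, p@trans + sh))
    expect_equal(mockLLG(moved, cr)$llg, base, tolerance = 1e-6)
  }
  ## NOT invariant when one placement takes the origin shift alone
  sh <- as.vector(O %*% c(0.5, 0.5, 0))
  lop <- tr
  lop[[2]] <- placement("A", "truth", lop[[2]]@rot, lop[[2]]@trans + sh)
  expect_lt(mockLLG(lop, cr)$llg, base - 1)
  ## single placement on a shifted truth image scores identically
  img <- applySymop(tr[[1]], symOps(cr@sg)[[2]], cr@cell)
  img <- placement("A", "truth", img@rot, img@trans + sh)
  expect_equal(mockLLG(list(img), cr)$llg, s1$llg, tolerance = 1e-6)
})

test_that("scores are deterministic and noise is bin-keyed", {
  gen <- tinyCrystal(copies = 1, sg = "P21212", seed = 6, epsilon = 0.02,
                     templateNoise = 0.3)
  cr <- gen$crystal
  reg <- asRegistry(gen$models)
  p <- placement("A", gen$models[[1]]@modelId, diag(3), c(3, 4, 5))
  a <- mockLLG(list(p), cr, reg)
  b <- mockLLG(list(p), cr, reg)
  expect_identical(a$llg, b$llg)
  ## the same geometric bin gives the same noise on repeated scoring
  n1 <- MRsearch:::cppPlacementNoise(diag(3), c(3.1, 4.1, 5.1), 1L, 100, 0.02, 6L)
  n2 <- MRsearch:::cppPlacementNoise(diag(3), c(3.2, 3.9, 5.2), 1L, 100, 0.02, 6L)
  expect_identical(n1, n2)  # same 1 A bin
  n3 <- MRsearch:::cppPlacementNoise(diag(3), c(8.0, 4.1, 5.1), 1L, 100, 0.02, 6L)
  expect_false(identical(n1, n3))
})

test_that("rotation search ranks truth orientations first", {
  gen <- tinyCrystal(copies = 1, sg = "P212121", seed = 9, epsilon = 0)
  cr <- gen$crystal
  reg <- asRegistry(gen$models)
  m <- gen$models[[1]]
  rs <- rotationSearch(cr, m, NULL, nKeep = 3, step = 18, models = reg)
  expect_length(rs, 3)
  ## best orientation within roughly one grid step of a truth image
  ctx <- MRsearch:::.scoreCtx(cr, NULL)
  tq <- lapply(ctx$trueOps, function(co) co$A %*% truthPlacements(cr)[[1]]@rot)
  dmin <- min(vapply(tq, function(R)
    MRsearch:::rotationDistance(rs[[1]]$rot, R), numeric(1)))
  expect_lt(dmin, 18)
  expect_gt(rs[[1]]$rfz, 5)
  ## nKeep = 1 returns exactly one orientation
  expect_length(rotationSearch(cr, m, NULL, nKeep = 1, step = 18,
                               models = reg), 1)
  ## a component with no remaining truths sees a flat landscape
  pTruth <- truthPlacements(cr)[[1]]
  rsDone <- rotationSearch(cr, m, list(pTruth), nKeep = 3, step = 18,
                           models = reg)
  expect_lt(max(vapply(rsDone, function(o) o$rfz, numeric(1))), 3)
})

test_that("translation search finds the truth and standardizes TFZ", {
  gen <- tinyCrystal(copies = 2, sg = "P212121", seed = 11, epsilon = 0,
                     templateNoise = 0)
  cr <- gen$crystal
  reg <- asRegistry(gen$models)
  m <- gen$models[[1]]
  tr1 <- truthPlacements(cr)[[1]]
  ts <- translationSearch(cr, m, tr1@rot, NULL, gridStep = 2.0, models = reg)
  expect_lte(length(ts), 10)
  ## top peak within one grid step of a truth image position
  top <- asSolution(list(ts[[1]]$placement), "P212121")
  truthSols <- lapply(truthPlacements(cr), function(t)
    asSolution(list(placement("A", m@modelId, t@rot, t@trans)), "P212121"))
  hit <- any(vapply(truthSols, function(s)
    spatiallyEquivalent(top, s, cr@sg, cr@cell, tolRot = 10, tolTrans = 2.5),
    logical(1)))
  expect_true(hit)
  ## the designed maximum dominates the landscape
  expect_gt(ts[[1]]$tfz, 7)
  if (length(ts) > 1)
    expect_gt(ts[[1]]$tfz, max(vapply(ts[-1], function(p) p$tfz, numeric(1))))
  ## a model of a component with no truths sees pure noise: low TFZ
  gen2 <- generateCrystal(list(components = list(
    list(id = "A", length = 15, copies = 1), list(id = "B", length = 15,
                                                  copies = 1)),
    spaceGroup = "P212121", epsilon = 0.02, templateNoise = 0),
    seed = 13)
  cr2 <- gen2$crystal
  regB <- asRegistry(gen2$models)
  mB <- gen2$models[["B_tmpl"]]
  pA <- truthPlacements(cr2)[[which(vapply(truthPlacements(cr2), function(t)
    t@componentId == "B", logical(1)))]]
  tsB <- translationSearch(cr2, mB, pA@rot, list(pA), gridStep = 2.5,
                           models = regB)
  expect_lt(max(vapply(tsB, function(p) p$tfz, numeric(1))), 4)
})

test_that("packing check counts symmetry clashes", {
  gen <- tinyCrystal(copies = 1, sg = "P212121", seed = 9)
  cr <- gen$crystal
  tr <- truthPlacements(cr)[[1]]
  expect_true(packingCheck(list(tr), cr)$passes)
  ## two copies at the identical position always fail
  two <- list(tr, tr)
  pk <- packingCheck(two, cr)
  expect_false(pk$passes)
  expect_gt(pk$clashCount, 0)
})

test_that("rigid refinement converges to the truth and respects scope", {
  gen <- tinyCrystal(copies = 2, sg = "P212121", seed = 11, epsilon = 0,
                     templateNoise = 0)
  cr <- gen$crystal
  reg <- asRegistry(gen$models)
  m <- gen$models[[1]]
  tr <- truthPlacements(cr)
  ## already on the optimum: essentially unchanged
  exact <- placement("A", m@modelId, tr[[1]]@rot, tr[[1]]@trans)
  rr0 <- rigidRefine(list(exact), cr, reg)
  expect_lt(sqrt(sum((rr0$placements[[1]]@trans - tr[[1]]@trans)^2)), 1e-3)
  ## 2 A / 5 degrees off refines back within 0.2 A / 1 degree
  off <- placement("A", m@modelId,
                   axisAngleRotation(c(1, 2, 1), 5) %*% tr[[1]]@rot,
                   tr[[1]]@trans + c(1.2, -1.2, 0.8))
  rr <- rigidRefine(list(off), cr, reg)
  expect_lt(sqrt(sum((rr$placements[[1]]@trans - tr[[1]]@trans)^2)), 0.2)
  expect_lt(MRsearch:::rotationDistance(rr$placements[[1]]@rot, tr[[1]]@rot), 1)
  ## scope = last leaves earlier placements untouched
  p1 <- placement("A", m@modelId, tr[[1]]@rot, tr[[1]]@trans + c(1, 0, 0))
  p2 <- placement("A", m@modelId, tr[[2]]@rot, tr[[2]]@trans + c(0, 1, 0))
  rl <- rigidRefine(list(p1, p2), cr, reg, scope = "last")
  expect_equal(rl$placements[[1]]@trans, p1@trans)
  expect_equal(rl$placements[[1]]@rot, p1@rot)
  expect_lt(sqrt(sum((rl$placements[[2]]@trans - tr[[2]]@trans)^2)), 0.3)
  expect_error(rigidRefine(list(), cr, reg), "empty")
})

test_that("background Z-scores separate truths from random placements", {
  gen <- tinyCrystal(copies = 1, sg = "P212121", seed = 9, epsilon = 0)
  cr <- gen$crystal
  reg <- asRegistry(gen$models)
  m <- gen$models[[1]]
  tr <- truthPlacements(cr)[[1]]
  cand <- placement("A", m@modelId, tr@rot, tr@trans)
  bz <- backgroundZscore(NULL, cand, m, cr, reg, nSamples = 100, seed = 2)
  expect_gt(bz$z, 7)
  ## one of the background's own draws scores like background
  set.seed(77)
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  rnd <- placement("A", m@modelId, MRsearch:::quatToRot(q),
                   as.vector(orthogonalizationMatrix(cr@cell) %*% runif(3)))
  bzr <- backgroundZscore(NULL, rnd, m, cr, reg, nSamples = 100, seed = 2)
  expect_lt(abs(bzr$z), 4)
  expect_error(backgroundZscore(NULL, cand, m, cr, reg, nSamples = 10),
               "at least 50")
})
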