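# NCS point-group detection, missing-member prediction, NCS refresh,
# amalgamation rules and known-assembly completion.

test_that("point groups are detected exactly on constructed orbits", {
  set.seed(3)
  for (n in 2:6) {
    axis <- rnorm(3); axis <- axis / sqrt(sum(axis^2))
    center <- runif(3, 10, 30)
    pls <- orbitPlacements(n, axis, center, radius = 14,
                           base = randomRotationFixture())
    hyps <- detectAssemblies(pls)
    expect_length(hyps, 1)
    expect_equal(hyps[[1]]@groupLabel, paste0("C", n))
    dAng <- acos(min(1, abs(sum(hyps[[1]]@axis * axis)))) * 180 / pi
    expect_lt(dAng, 1)
    expect_equal(sort(hyps[[1]]@memberIndices), seq_len(n))
  }
})

test_that("a generic screw relation is rejected by the axial-shift test", {
  set.seed(5)
  axis <- c(0, 0, 1)
  base <- randomRotationFixture()
  p1 <- placement("A", "m", base, c(10, 10, 10))
  ## 100-degree turn with an 8 A shift along the axis: not a point group
  R <- axisAngleRotation(axis, 100)
  p2 <- placement("A", "m", R %*% base,
                  as.vector(R %*% (p1@trans - c(10, 10, 10))) +
                    c(10, 10, 10) + 8 * axis)
  expect_length(detectAssemblies(list(p1, p2)), 0)
})

test_that("D2 orbits absorb their C2 subgroups", {
  set.seed(9)
  axis <- c(0, 0, 1)
  pls <- orbitPlacements(2, axis, c(20, 20, 20), radius = 12,
                         base = randomRotationFixture(), flip = TRUE)
  hyps <- detectAssemblies(pls)
  labels <- vapply(hyps, function(h) h@groupLabel, character(1))
  expect_true("D2" %in% labels)
  d2 <- hyps[[which(labels == "D2")[1]]]
  expect_equal(sort(d2@memberIndices), 1:4)
  ## no standalone C2 sharing the D2's members survives
  for (h in hyps) {
    if (h@groupLabel == "C2")
      expect_false(all(h@memberIndices %in% d2@memberIndices))
  }
})

test_that("missing members are predicted from the orbit", {
  set.seed(13)
  axis <- c(0, 1, 0)
  full <- orbitPlacements(5, axis, c(15, 15, 15), radius = 14)
  partial <- full[1:4]
  hyps <- detectAssemblies(partial)
  expect_gte(length(hyps), 1)
  h <- hyps[[1]]
  preds <- predictMissing(h, partial)
  expect_length(preds, 1)
  ## the predicted pose matches the withheld truth member
  miss <- full[[5]]
  expect_lt(sqrt(sum((preds[[1]]$placement@trans - miss@trans)^2)), 1)
  expect_lt(MRsearch:::rotationDistance(preds[[1]]$placement@rot, miss@rot), 2)
  ## complete assemblies predict nothing
  expect_length(predictMissing(detectAssemblies(full)[[1]], full), 0)
})

test_that("NCS refresh keeps re-established groups and demotes broken ones", {
  set.seed(17)
  axis <- c(1, 0, 0)
  pls <- orbitPlacements(4, axis, c(18, 18, 18), radius = 13)
  hyps <- detectAssemblies(pls)
  expect_length(updateNCS(pls, hyps), length(hyps))
  ## small perturbation: axis drift below tolerance
  pert <- lapply(pls, function(p)
    placement(p@componentId, p@modelId, p@rot, p@trans + rnorm(3, sd = 0.1)))
  upd <- updateNCS(pert, hyps)
  expect_gte(length(upd), 1)
  dAng <- acos(min(1, abs(sum(upd[[1]]@axis * axis)))) * 180 / pi
  expect_lt(dAng, 5)
  ## minimal C2: moving one member 10 A away demotes the hypothesis
  pls2 <- orbitPlacements(2, axis, c(18, 18, 18), radius = 13)
  hyps2 <- detectAssemblies(pls2)
  expect_length(hyps2, 1)
  broken <- pls2
  broken[[2]] <- placement("A", "truth", broken[[2]]@rot,
                           broken[[2]]@trans + c(10, 0, 0))
  expect_length(updateNCS(broken, hyps2), 0)
})

test_that("amalgamation recovers origin shifts in nonpolar groups", {
  gen <- tinyCrystal(copies = 2, sg = "P212121", seed = 11, epsilon = 0,
                     templateNoise = 0)
  cr <- gen$crystal
  reg <- asRegistry(gen$models)
  m <- gen$models[[1]]
  backend <- toyBackend(cr)
  tr <- truthPlacements(cr)
  O <- orthogonalizationMatrix(cr@cell)
  parent <- asSolution(list(), "P212121", "root")
  a <- asSolution(list(placement("A", m@modelId, tr[[1]]@rot, tr[[1]]@trans)),
                  "P212121", "a", parent = "root")
  ## sibling B solved on a different origin: truth 2 shifted by (1/2, 0, 1/2)
  sh <- as.vector(O %*% c(0.5, 0, 0.5))
  b <- asSolution(list(placement("A", m@modelId, tr[[2]]@rot,
                                 tr[[2]]@trans + sh)),
                  "P212121", "b", parent = "root")
  am <- amalgamate(a, b, list(), cr@sg, cr@cell, backend, reg,
                   c(A = 2L))
  expect_length(am$candidates, 1)
  expect_null(am$needsTranslation)
  cand <- am$candidates[[1]]
  expect_length(cand, 2)
  ## the combination scores like the two-truth solution (shift undone)
  sc <- backend$score(cand, reg)
  both <- backend$score(lapply(tr, function(t)
    placement("A", m@modelId, t@rot, t@trans)), reg)
  expect_equal(sc$llg, both$llg, tolerance = 1e-3)
  ## amalgamated candidates never score below either input sibling
  expect_gte(sc$llg, backend$score(a@placements, reg)$llg - 1e-6)
  expect_gte(sc$llg, backend$score(b@placements, reg)$llg - 1e-6)
})

test_that("amalgamation in a polar group reuses only the rotation", {
  gen <- tinyCrystal(copies = 2, sg = "P21", seed = 19, epsilon = 0,
                     templateNoise = 0)
  cr <- gen$crystal
  reg <- asRegistry(gen$models)
  m <- gen$models[[1]]
  backend <- toyBackend(cr)
  tr <- truthPlacements(cr)
  a <- asSolution(list(placement("A", m@modelId, tr[[1]]@rot, tr[[1]]@trans)),
                  "P21", "a", parent = "root")
  b <- asSolution(list(placement("A", m@modelId, tr[[2]]@rot, tr[[2]]@trans)),
                  "P21", "b", parent = "root")
  am <- amalgamate(a, b, list(), cr@sg, cr@cell, backend, reg, c(A = 2L))
  expect_length(am$candidates, 0)
  expect_length(am$needsTranslation, 1)
  expect_equal(am$needsTranslation[[1]], tr[[2]]@rot)
  ## composition conflicts yield nothing
  am2 <- amalgamate(a, b, list(), cr@sg, cr@cell, backend, reg, c(A = 1L))
  expect_length(am2$candidates, 0)
  expect_null(am2$needsTranslation)
})

test_that("known assemblies are completed by local search", {
  gen <- generateCrystal(list(components = list(
    list(id = "A", length = 14, copies = 1),
    list(id = "B", length = 14, copies = 1)),
    spaceGroup = "P1", epsilon = 0, templateNoise = 0), seed = 21)
  cr <- gen$crystal
  reg <- asRegistry(gen$models)
  backend <- toyBackend(cr)
  tr <- truthPlacements(cr)
  trA <- tr[[which(vapply(tr, function(t) t@componentId == "A", logical(1)))]]
  trB <- tr[[which(vapply(tr, function(t) t@componentId == "B", logical(1)))]]
  ## heteromeric user assembly: B relative to A in A's local frame
  ## (P_B = P_A o T_B), deliberately 3 A off
  relRot <- t(trA@rot) %*% trB@rot
  relTr <- as.vector(t(trA@rot) %*% (trB@trans - trA@trans)) + c(3, 0, 0)
  ua <- list(members = list(
    list(component = "A", transform = list(rot = diag(3), trans = c(0, 0, 0))),
    list(component = "B", transform = list(rot = relRot, trans = relTr))))
  sol <- asSolution(list(placement("A", "A_tmpl", trA@rot, trA@trans)), "P1")
  preds <- completeKnownAssembly(ua, sol, backend, reg)
  expect_length(preds, 1)
  expect_equal(preds[[1]]$placement@componentId, "B")
  ## the local grid recovers the true pose despite the 3 A offset
  expect_lt(sqrt(sum((preds[[1]]$placement@trans - trB@trans)^2)), 1.5)
  ## anchor absent: nothing generated
  none <- completeKnownAssembly(ua, asSolution(list(), "P1"), backend, reg)
  expect_length(none, 0)
})
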