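# Space-group catalogue, operator algebra, superposition and equivalence.

test_that("catalogue groups have the expected operators and metadata", {
  ## operator counts cross-checked against an independent symmetry library
  expected <- list(
    P1 = list(nops = 1, polar = c(TRUE, TRUE, TRUE), enant = NA),
    P21 = list(nops = 2, polar = c(FALSE, TRUE, FALSE), enant = NA),
    C2 = list(nops = 4, polar = c(FALSE, TRUE, FALSE), enant = NA),
    P212121 = list(nops = 4, polar = c(FALSE, FALSE, FALSE), enant = NA),
    P21212 = list(nops = 4, polar = c(FALSE, FALSE, FALSE), enant = NA),
    P41 = list(nops = 4, polar = c(FALSE, FALSE, TRUE), enant = "P43"),
    P43 = list(nops = 4, polar = c(FALSE, FALSE, TRUE), enant = "P41"))
  for (sym in names(expected)) {
    sg <- buildSpaceGroup(sym)
    expect_length(symOps(sg), expected[[sym]]$nops)
    expect_equal(polarAxes(sg), expected[[sym]]$polar)
    if (is.na(expected[[sym]]$enant)) expect_true(is.na(sg@enantiomorph))
    else expect_equal(sg@enantiomorph, expected[[sym]]$enant)
  }
  ## both spellings accepted; unknown symbols rejected
  expect_equal(buildSpaceGroup("P 21 21 21")@symbol, "P212121")
  expect_error(buildSpaceGroup("X9"), "unsupported space group")
})

test_that("operator sets are closed and origin moves conjugate the group", {
  for (sym in c("P1", "P21", "C2", "P212121", "P21212", "P41", "P43")) {
    sg <- buildSpaceGroup(sym)
    ops <- symOps(sg)
    for (o1 in ops) for (o2 in ops) {
      comp <- MRsearch:::.composeOps(o1, o2)
      expect_true(MRsearch:::.opInGroup(comp, ops),
                  info = paste("closure fails in", sym))
    }
    mv <- allowedOriginMoves(sg)
    for (i in seq_len(nrow(mv$shifts))) {
      s <- mv$shifts[i, ]
      for (o in ops) {
        conj <- list(rot = o$rot,
                     trans = MRsearch:::fracWrap(
                       o$trans + as.vector((diag(3) - o$rot) %*% s)))
        expect_true(MRsearch:::.opInGroup(conj, ops),
                    info = paste("origin move invalid in", sym))
      }
    }
  }
  ## derived shift enumerations: {0, 1/2}^3 survives conjugation in P212121;
  ## P21 has continuous b and {0, 1/2} on a and c
  expect_equal(nrow(originShifts(buildSpaceGroup("P212121"))), 8)
  p21 <- allowedOriginMoves(buildSpaceGroup("P21"))
  expect_true(p21$polar[2] && !p21$polar[1] && !p21$polar[3])
  expect_equal(nrow(p21$shifts), 4)
  expect_true(all(p21$shifts[, 2] == 0))
})

test_that("orthogonalization follows the PDB convention", {
  cell <- unitCell(10, 10, 10)
  expect_equal(orthogonalizationMatrix(cell), diag(c(10, 10, 10)))
  expect_equal(as.vector(orthogonalizationMatrix(cell) %*% c(0.5, 0.5, 0.5)),
               c(5, 5, 5))
  ## monoclinic closed form: a along x, V/(a b sin gamma) on the z diagonal
  cm <- unitCell(10, 12, 14, 90, 105, 90)
  O <- orthogonalizationMatrix(cm)
  expect_equal(O[1, 1], 10)
  expect_equal(O[2, 2], 12)
  expect_equal(O[1, 3], 14 * cos(105 * pi / 180))
  expect_equal(O[3, 3], cellVolume(cm) / (10 * 12))
  expect_equal(O[2, 1], 0)
  expect_equal(O[3, 1], 0)
  ## round trip through the fractionalization matrix
  x <- c(3.2, -1.5, 7.7)
  expect_equal(as.vector(O %*% fractionalizationMatrix(cm) %*% x), x)
  expect_error(orthogonalizationMatrix(unitCell(10, 10, 10, 1e-9, 90, 90)),
               "degenerate")
})

test_that("applySymop is a group action on placements", {
  cell <- unitCell(20, 24, 28)
  sg <- buildSpaceGroup("P212121")
  p <- placement("A", "m", randomRotationFixture(), c(3, 4, 5))
  idOp <- symOps(sg)[[1]]
  pid <- applySymop(p, idOp, cell)
  expect_equal(pid@rot, p@rot)
  expect_equal(pid@trans, p@trans)
  ## applying the P21 screw twice translates by one full b lattice vector
  sgm <- buildSpaceGroup("P21")
  cellm <- unitCell(20, 24, 28, 90, 105, 90)
  screw <- Filter(function(o) !all(o$rot == diag(3)), symOps(sgm))[[1]]
  p2 <- applySymop(applySymop(p, screw, cellm), screw, cellm)
  bvec <- as.vector(orthogonalizationMatrix(cellm) %*% c(0, 1, 0))
  expect_equal(p2@rot, p@rot, tolerance = 1e-9)
  expect_equal(p2@trans, p@trans + bvec, tolerance = 1e-9)
  ## composing operators equals composing the action
  for (o1 in symOps(sg)) for (o2 in symOps(sg)) {
    oc <- MRsearch:::.composeOps(o1, o2)
    a <- applySymop(applySymop(p, o2, cell), o1, cell)
    b <- applySymop(p, oc, cell)
    ## may differ by a lattice translation after wrapping
    d <- fractionalizationMatrix(cell) %*% (a@trans - b@trans)
    expect_equal(a@rot, b@rot, tolerance = 1e-9)
    expect_equal(as.vector(d - round(d)), c(0, 0, 0), tolerance = 1e-9)
  }
})

test_that("Kabsch superposition recovers exact and noisy transforms", {
  set.seed(42)
  A <- matrix(rnorm(30), 10, 3)
  same <- kabschSuperpose(A, A)
  expect_equal(same$rmsd, 0, tolerance = 1e-12)
  expect_equal(same$rot, diag(3), tolerance = 1e-9)
  ## B rotated by +90 degrees about z is recovered by the inverse rotation
  Rz <- axisAngleRotation(c(0, 0, 1), 90)
  fit <- kabschSuperpose(A, A %*% t(Rz))
  expect_equal(fit$rot, t(Rz), tolerance = 1e-9)
  expect_lt(fit$rmsd, 1e-9)
  ## 1000 random noiseless transforms recovered to 1e-6
  for (i in 1:1000) {
    R <- randomRotationFixture()
    tr <- rnorm(3, sd = 10)
    B <- (A - matrix(tr, 10, 3, TRUE)) %*% R  # rows b = R^T (a - tr)
    f <- kabschSuperpose(A, B)
    expect_lt(MRsearch:::rotationDistance(f$rot, R), 1e-4)
    expect_lt(sqrt(sum((f$trans - tr)^2)), 1e-6)
  }
  ## noisy recovery within 1 degree / 0.2 A at sigma = 0.1
  set.seed(7)
  A <- matrix(rnorm(30, sd = 8), 10, 3)   # molecule-sized cloud
  R <- randomRotationFixture(); tr <- c(1, -2, 3)
  B <- sweep(A, 2, tr) %*% R
  Bn <- B + matrix(rnorm(30, sd = 0.1), 10, 3)
  f <- kabschSuperpose(A, Bn)
  expect_lt(MRsearch:::rotationDistance(f$rot, R), 1)
  expect_lt(sqrt(sum((f$trans - tr)^2)), 0.2)
  ## degenerate inputs fail
  expect_error(kabschSuperpose(A[1:2, ], A[1:2, ]), "degenerate")
  line <- cbind(1:10, 0, 0)
  expect_error(kabschSuperpose(line, line), "degenerate")
})

test_that("rotation angle/axis decomposition round-trips", {
  id <- rotationAngleAxis(diag(3))
  expect_equal(id$theta, 0)
  flip <- rotationAngleAxis(axisAngleRotation(c(0, 0, 1), 180))
  expect_equal(flip$theta, 180, tolerance = 1e-9)
  expect_equal(flip$axis, c(0, 0, 1), tolerance = 1e-9)
  ## C5 closure: five 72-degree turns about a random axis give the identity
  set.seed(1)
  ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
  R5 <- axisAngleRotation(ax, 72)
  acc <- diag(3)
  for (i in 1:5) acc <- R5 %*% acc
  expect_equal(acc, diag(3), tolerance = 1e-9)
  ## 1000 random rotations reconstruct within 1e-6
  for (i in 1:1000) {
    R <- randomRotationFixture()
    aa <- rotationAngleAxis(R)
    expect_equal(axisAngleRotation(aa$axis, aa$theta), R, tolerance = 1e-6)
    expect_gte(aa$theta, 0)
    expect_lte(aa$theta, 180)
  }
})

test_that("spatial equivalence is symmetry- and origin-aware", {
  cell <- unitCell(30, 34, 38)
  sg <- buildSpaceGroup("P212121")
  set.seed(11)
  pls <- list(placement("A", "m", randomRotationFixture(), c(4, 6, 9)),
              placement("A", "m", randomRotationFixture(), c(15, 20, 11)))
  sol <- asSolution(pls, "P212121", "a")
  expect_true(spatiallyEquivalent(sol, sol, sg, cell))
  ## image under any catalogue operator is equivalent
  for (op in symOps(sg)) {
    img <- asSolution(lapply(pls, applySymop, op = op, cell = cell),
                      "P212121", "b")
    expect_true(spatiallyEquivalent(sol, img, sg, cell))
  }
  ## image under every allowed origin shift is equivalent
  O <- orthogonalizationMatrix(cell)
  for (i in seq_len(nrow(originShifts(sg)))) {
    sh <- as.vector(O %*% originShifts(sg)[i, ])
    img <- asSolution(lapply(pls, function(p)
      placement(p@componentId, p@modelId, p@rot, p@trans + sh)),
      "P212121", "c")
    expect_true(spatiallyEquivalent(sol, img, sg, cell))
  }
  ## displacing one molecule by 10 A breaks equivalence at tol 2 A
  moved <- pls
  moved[[2]] <- placement("A", "m", moved[[2]]@rot, moved[[2]]@trans + c(10, 0, 0))
  expect_false(spatiallyEquivalent(sol, asSolution(moved, "P212121", "d"),
                                   sg, cell, tolRot = 5, tolTrans = 2))
  ## polar group: continuous shift along b is equivalent
  sgp <- buildSpaceGroup("P21")
  cellp <- unitCell(30, 34, 38, 90, 105, 90)
  solp <- asSolution(pls, "P21", "e")
  bshift <- as.vector(orthogonalizationMatrix(cellp) %*% c(0, 0.237, 0))
  imgp <- asSolution(lapply(pls, function(p)
    placement(p@componentId, p@modelId, p@rot, p@trans + bshift)), "P21", "f")
  expect_true(spatiallyEquivalent(solp, imgp, sgp, cellp))
  ## mismatched groups are an error
  expect_error(spatiallyEquivalent(sol, solp, sg, cell), "different space groups")
})

test_that("spatial equivalence is reflexive and symmetric over random sets", {
  cell <- unitCell(25, 28, 31)
  sg <- buildSpaceGroup("P21212")
  set.seed(23)
  sols <- lapply(1:5, function(i)
    asSolution(list(placement("A", "m", randomRotationFixture(),
                              runif(3, 0, 20))), "P21212", paste0("s", i)))
  for (i in 1:5) {
    expect_true(spatiallyEquivalent(sols[[i]], sols[[i]], sg, cell))
    for (j in 1:5) {
      expect_equal(spatiallyEquivalent(sols[[i]], sols[[j]], sg, cell),
                   spatiallyEquivalent(sols[[j]], sols[[i]], sg, cell))
    }
  }
})
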