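# Shared fixtures: tiny crystals and model registries built in code.

randomRotationFixture <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  MRsearch:::quatToRot(q)
}

## registry keyed by model id
asRegistry <- function(models) {
  stats::setNames(models, vapply(models, function(m) m@modelId, character(1)))
}

## small single-component crystal; templateNoise 0 gives a noiseless model
tinyCrystal <- function(copies = 1, sg = "P1", seed = 3, epsilon = 0,
                        templateNoise = 0, length = 15, assembly = NULL,
                        solvent = 0.5) {
  gs <- list(components = list(list(id = "A", length = length,
                                    copies = copies)),
             spaceGroup = sg, epsilon = epsilon,
             templateNoise = templateNoise, solvent = solvent)
  if (!is.null(assembly)) gs$assembly <- assembly
  generateCrystal(gs, seed = seed)
}

## solution wrapper for a placement list
asSolution <- function(placements, sgSymbol, id = "sX", parent = "") {
  new("PartialSolution", solutionId = id, parentId = parent,
      sgSymbol = sgSymbol, placements = placements, llg = 0,
      tfzHistory = rep(0, length(placements)), status = "active")
}

## exact Cn orbit of placements about an axis/center
orbitPlacements <- function(n, axis, center, radius, componentId = "A",
                            base = diag(3), flip = FALSE) {
  axis <- axis / sqrt(sum(axis^2))
  perp <- if (abs(axis[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  perp <- perp - sum(perp * axis) * axis
  perp <- perp / sqrt(sum(perp^2))
  t0 <- center + radius * perp
  out <- lapply(0:(n - 1), function(k) {
    Rk <- axisAngleRotation(axis, k * 360 / n)
    placement(componentId, "truth", Rk %*% base,
              as.vector(Rk %*% (t0 - center)) + center)
  })
  if (flip) {
    Rf <- axisAngleRotation(perp, 180)
    out <- c(out, lapply(0:(n - 1), function(k) {
      Rk <- axisAngleRotation(axis, k * 360 / n) %*% Rf
      placement(componentId, "truth", Rk %*% base,
                as.vector(Rk %*% (t0 - center)) + center)
    }))
  }
  out
}

## per-placement truth recovery: each placement must sit within tolerance
## of a crystal-symmetry image of a distinct ground-truth copy
placementsOnTruths <- function(sol, crystal, tolRot = 2, tolTrans = 0.5) {
  pl <- if (is(sol, "PartialSolution")) sol@placements else sol
  tr <- truthPlacements(crystal)
  O <- orthogonalizationMatrix(crystal@cell)
  Oinv <- solve(O)
  used <- rep(FALSE, length(tr))
  for (p in pl) {
    hit <- NA
    for (k in seq_along(tr)) {
      if (used[k] || tr[[k]]@componentId != p@componentId) next
      for (op in symOps(crystal@sg)) {
        co <- MRsearch:::opToCartesian(op, crystal@cell)
        R <- co$A %*% tr[[k]]@rot
        tt <- as.vector(co$A %*% tr[[k]]@trans) + co$b
        if (MRsearch:::rotationDistance(p@rot, R) > tolRot) next
        d <- as.vector(Oinv %*% (p@trans - tt))
        if (sqrt(sum((O %*% MRsearch:::fracMin(d))^2)) <= tolTrans) {
          hit <- k
          break
        }
      }
      if (!is.na(hit)) break
    }
    if (is.na(hit)) return(FALSE)
    used[hit] <- TRUE
  }
  TRUE
}
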