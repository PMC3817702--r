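# Synthetic crystal generator and the mock maximum-likelihood scoring
# backend: rotation search, translation search, packing, rigid-body
# refinement and LLG/TFZ analogues obeying the comparable-score contract
# (a geometrically better solution never scores lower, noiseless case).

## ---- caches -------------------------------------------------------------

.crystalEnv <- function(crystal) {
  if (is.null(attr(crystal, ".cache"))) {
    ## attribute-attached environment survives with the object
    attr(crystal, ".cache") <- new.env(parent = emptyenv())
  }
  attr(crystal, ".cache")
}

## Per-(crystal, hypothesis-group) geometry cache: orthogonalization, the
## cartesian operator lists, truth images under the TRUE group, and the
## discrete origin-shift candidates of the hypothesis group.
.scoreCtx <- function(crystal, sgHyp = NULL) {
  sgHyp <- sgHyp %||% crystal@sg
  key <- paste0("ctx:", sgHyp@symbol)
  env <- .crystalEnv(crystal)
  if (!is.null(env[[key]])) return(env[[key]])
  O <- orthogonalizationMatrix(crystal@cell)
  Oinv <- solve(O)
  toCart <- function(sg) lapply(sg@ops, function(op)
    list(A = O %*% op$rot %*% Oinv, b = as.vector(O %*% op$trans)))
  trueOps <- toCart(crystal@sg)
  hypOps <- toCart(sgHyp)
  compNames <- names(crystal@components)
  truths <- lapply(crystal@truths, function(tr) {
    cloud <- crystal@clouds[[tr@componentId]]
    base <- cloud %*% t(tr@rot) +
      matrix(tr@trans, nrow(cloud), 3, byrow = TRUE)
    images <- lapply(trueOps, function(co)
      base %*% t(co$A) + matrix(co$b, nrow(base), 3, byrow = TRUE))
    list(comp = match(tr@componentId, compNames), images = images)
  })
  shifts <- sgHyp@originShifts %*% t(O)   # cartesian rows
  if (nrow(shifts) == 0) shifts <- matrix(0, 1, 3)
  ctx <- list(O = O, Oinv = Oinv, trueOps = trueOps, hypOps = hypOps,
              truths = truths, shifts = shifts, sgHyp = sgHyp,
              truthComp = vapply(truths, function(t) t$comp, integer(1)),
              compNames = compNames)
  env[[key]] <- ctx
  ctx
}

## coords/res/comp/weight entry for one placement, resolved via the model
## registry ("truth" placements use the full component cloud).
.plcEntry <- function(p, models, crystal) {
  cid <- p@componentId
  if (identical(p@modelId, "truth") || is.null(models[[p@modelId]])) {
    cloud <- crystal@clouds[[cid]]
    coords <- cloud %*% t(p@rot) + matrix(p@trans, nrow(cloud), 3, byrow = TRUE)
    res <- seq_len(nrow(cloud))
    w <- molecularWeight(crystal@components[[cid]]@sequence) - .WATER_MASS
  } else {
    m <- models[[p@modelId]]
    mm <- m@members[[1]]
    coords <- mm %*% t(p@rot) + matrix(p@trans, nrow(mm), 3, byrow = TRUE)
    res <- m@resIdx + 1L
    w <- m@weight
  }
  list(coords = coords, res = as.integer(res),
       comp = match(cid, names(crystal@components)), w = w)
}

.plcList <- function(placements, models, crystal) {
  lapply(placements, .plcEntry, models = models, crystal = crystal)
}

## ---- mock LLG -----------------------------------------------------------

.matchedTotal <- function(plc, ctx, shift, sigma) {
  ov <- cppOvMatrix(plc, ctx$truths, ctx$hypOps, as.numeric(shift),
                    ctx$O, ctx$Oinv, sigma)
  w <- vapply(plc, function(e) e$w, numeric(1))
  gm <- cppGreedyMatch(ov, w)
  list(total = gm$total, matched = gm$matched, overlap = gm$overlap)
}

## golden-section maximization on [lo, hi]
.golden <- function(f, lo, hi, tol = 0.01) {
  gr <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  c1 <- b - gr * (b - a); c2 <- a + gr * (b - a)
  f1 <- f(c1); f2 <- f(c2)
  while (b - a > tol) {
    if (f1 < f2) { a <- c1; c1 <- c2; f1 <- f2; c2 <- a + gr * (b - a); f2 <- f(c2) }
    else { b <- c2; c2 <- c1; f2 <- f1; c1 <- b - gr * (b - a); f1 <- f(c1) }
  }
  (a + b) / 2
}

## Best global origin move: all discrete shifts, then golden-section along
## each continuous (polar) axis from the best discrete start.
.bestShift <- function(plc, ctx, sigma, polarOpt = TRUE) {
  shifts <- ctx$shifts
  vals <- vapply(seq_len(nrow(shifts)), function(i)
    .matchedTotal(plc, ctx, shifts[i, ], sigma)$total, numeric(1))
  best <- which.max(vals)
  s <- shifts[best, ]
  polar <- ctx$sgHyp@polarAxes
  if (polarOpt && any(polar) && length(ctx$truths) > 0) {
    cellLen <- c(ctx$O[1, 1], sqrt(sum(ctx$O[, 2]^2)), sqrt(sum(ctx$O[, 3]^2)))
    for (pass in 1:2) {
      for (ax in which(polar)) {
        e <- as.vector(ctx$O %*% replace(numeric(3), ax, 1))
        e <- e / sqrt(sum(e^2))
        f <- function(d) .matchedTotal(plc, ctx, s + d * e, sigma)$total
        d <- .golden(f, -cellLen[ax] / 2, cellLen[ax] / 2, tol = 0.01)
        if (f(d) > f(0)) s <- s + d * e
      }
    }
  }
  list(shift = s, total = .matchedTotal(plc, ctx, s, sigma))
}

#' Mock log-likelihood-gain score
#'
#' Scores a set of placements against the synthetic ground truth: the best,
#' over all allowed global origin moves of the hypothesis space group, of
#' the weighted sum of greedy-matched Gaussian overlaps between each
#' placement and a distinct truth copy (symmetry images considered on both
#' sides), minus a clash penalty of half the mean placement weight per
#' clash, plus a deterministic bin-keyed noise term per placement.
#'
#' @param solPlacements list of [Placement-class] (or a
#'   [PartialSolution-class]).
#' @param crystal a [ToyCrystal-class].
#' @param models named list of [EnsembleModel-class] resolving model ids.
#' @param sgHyp hypothesis [SpaceGroup-class] (default: the crystal's own).
#' @param polarOpt optimize continuous polar origin components (default TRUE).
#' @return list(llg, perPlacementOverlap, matchedTruthIndices, clashCount,
#'   shift).
#' @export
mockLLG <- function(solPlacements, crystal, models = list(), sgHyp = NULL,
                    polarOpt = TRUE) {
  if (is(solPlacements, "PartialSolution")) solPlacements <- solPlacements@placements
  if (length(solPlacements) == 0)
    return(list(llg = 0, perPlacementOverlap = numeric(0),
                matchedTruthIndices = integer(0), clashCount = 0L,
                shift = c(0, 0, 0)))
  ctx <- .scoreCtx(crystal, sgHyp)
  plc <- .plcList(solPlacements, models, crystal)
  bs <- .bestShift(plc, ctx, crystal@sigma, polarOpt = polarOpt)
  clash <- cppClashMatrix(plc, ctx$hypOps, ctx$O, ctx$Oinv, 3.0)
  clashTot <- sum(clash)
  w <- vapply(plc, function(e) e$w, numeric(1))
  noise <- sum(vapply(seq_along(solPlacements), function(i) {
    p <- solPlacements[[i]]
    cppPlacementNoise(p@rot, p@trans, plc[[i]]$comp, plc[[i]]$w,
                      crystal@epsilon, crystal@seed)
  }, numeric(1)))
  llg <- bs$total$total - 0.5 * mean(w) * clashTot + noise
  list(llg = llg, perPlacementOverlap = bs$total$overlap,
       matchedTruthIndices = as.integer(bs$total$matched),
       clashCount = as.integer(clashTot), shift = bs$shift)
}

## llg(partial + p) - llg(partial); lighter shift handling for repeated calls
.scoreDelta <- function(partial, newPlacements, crystal, models, sgHyp = NULL,
                        polarOpt = FALSE) {
  base <- mockLLG(partial, crystal, models, sgHyp, polarOpt = polarOpt)
  ext <- mockLLG(c(partial, newPlacements), crystal, models, sgHyp,
                 polarOpt = polarOpt)
  ext$llg - base$llg
}

## ---- rotation grid ------------------------------------------------------

## Super-Fibonacci quasi-uniform quaternion grid (deterministic); n chosen
## so the typical spacing matches `step` degrees.
rotationGrid <- function(step = 15) {
  stepRad <- deg2rad(step)
  n <- max(40L, as.integer(ceiling(8 * pi^2 / stepRad^3)))
  i <- seq_len(n) - 0.5
  phi <- sqrt(2)
  psi <- 1.533751168755204288118041
  t <- i / n
  d <- 2 * pi * i
  r <- sqrt(t); R <- sqrt(1 - t)
  a <- d / phi; b <- d / psi
  cbind(r * sin(a), r * cos(a), R * sin(b), R * cos(b))
}

rotToQuatR <- function(R) {
  tr <- sum(diag(R))
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else if (R[1, 1] > R[2, 2] && R[1, 1] > R[3, 3]) {
    s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
    q <- c((R[3, 2] - R[2, 3]) / s, 0.25 * s, (R[1, 2] + R[2, 1]) / s,
           (R[1, 3] + R[3, 1]) / s)
  } else if (R[2, 2] > R[3, 3]) {
    s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
    q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s, 0.25 * s,
           (R[2, 3] + R[3, 2]) / s)
  } else {
    s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
    q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
           (R[2, 3] + R[3, 2]) / s, 0.25 * s)
  }
  q / sqrt(sum(q^2))
}

quatToRot <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         3, 3)
}

#' Rotation search on the toy crystal
#'
#' Scores every orientation of a quasi-uniform quaternion grid by the best
#' orientation-only overlap exp(-dAngle^2 / (2 sigmaRot^2)) against the
#' truths not yet matched by the partial solution (symmetry images of the
#' truth orientations included), plus seeded noise, and returns the top
#' `nKeep` with Z-scores over the grid score distribution.
#'
#' @param crystal a [ToyCrystal-class].
#' @param model an [EnsembleModel-class].
#' @param partial a [PartialSolution-class] (or list of placements).
#' @param nKeep orientations returned (default 5).
#' @param step grid step in degrees (default 15).
#' @param models model registry for resolving the partial's placements.
#' @param sgHyp hypothesis space group.
#' @return list of list(rot, score, rfz), best first.
#' @export
rotationSearch <- function(crystal, model, partial = NULL, nKeep = 5L,
                           step = 15, models = list(), sgHyp = NULL) {
  ctx <- .scoreCtx(crystal, sgHyp)
  partialPl <- if (is.null(partial)) list() else
    if (is(partial, "PartialSolution")) partial@placements else partial
  matched <- if (length(partialPl))
    mockLLG(partialPl, crystal, models, sgHyp)$matchedTruthIndices else integer(0)
  compInt <- match(model@componentId, ctx$compNames)
  unmatched <- setdiff(which(ctx$truthComp == compInt), matched)

  grid <- rotationGrid(step)
  if (nrow(grid) == 0) stopf("empty rotation grid")
  targets <- NULL
  for (k in unmatched) {
    Rk <- crystal@truths[[k]]@rot
    for (co in ctx$trueOps) targets <- rbind(targets, rotToQuatR(co$A %*% Rk))
  }
  base <- if (is.null(targets)) rep(0, nrow(grid)) else {
    dots <- abs(grid %*% t(targets))       # |q . q_t|
    dots[dots > 1] <- 1
    dAng <- rad2deg(2 * acos(dots))        # rotation angle difference
    apply(exp(-dAng^2 / (2 * crystal@sigmaRot^2)), 1, max)
  }
  noise <- vapply(seq_len(nrow(grid)), function(i)
    cppPlacementNoise(quatToRot(grid[i, ]), c(0, 0, 0), compInt, 1,
                      crystal@epsilon, crystal@seed + 7L), numeric(1))
  score <- base + noise
  mu <- mean(score); sdv <- stats::sd(score)
  z <- if (sdv > 0) (score - mu) / sdv else rep(0, length(score))
  ord <- order(-score)[seq_len(min(nKeep, length(score)))]
  lapply(ord, function(i)
    list(rot = quatToRot(grid[i, ]), score = score[i], rfz = z[i]))
}

## ---- translation search -------------------------------------------------

.translationGrid <- function(crystal, ctx, gridStep, pinPolar) {
  cellLen <- c(crystal@cell@a, crystal@cell@b, crystal@cell@c)
  axes <- lapply(1:3, function(i) {
    if (pinPolar && ctx$sgHyp@polarAxes[i]) return(0)
    n <- max(1L, ceiling(cellLen[i] / gridStep))
    (seq_len(n) - 1) / n
  })
  fr <- as.matrix(expand.grid(a = axes[[1]], b = axes[[2]], c = axes[[3]]))
  list(frac = fr, cart = fr %*% t(ctx$O),
       dims = vapply(axes, length, integer(1)))
}

## periodic 26-neighbour local maxima of a vector laid out on a 3d grid
.localMaxima <- function(v, dims) {
  arr <- array(v, dim = dims)
  n <- prod(dims)
  best <- array(TRUE, dim = dims)
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    if (dims[1] == 1 && dx != 0) next
    if (dims[2] == 1 && dy != 0) next
    if (dims[3] == 1 && dz != 0) next
    sh <- arr[(seq_len(dims[1]) - 1 + dx) %% dims[1] + 1,
              (seq_len(dims[2]) - 1 + dy) %% dims[2] + 1,
              (seq_len(dims[3]) - 1 + dz) %% dims[3] + 1, drop = FALSE]
    best <- best & (arr >= sh)
  }
  which(as.vector(best))
}

#' Translation search on the toy crystal
#'
#' Scans a fractional grid over the cell (polar axes pinned to zero when the
#' partial is empty), scoring each position by the mock-LLG gain of adding
#' the oriented model there, and returns the top local maxima as peaks with
#' translation-function Z-scores (raw peak height standardized over the
#' whole grid).
#'
#' @param crystal a [ToyCrystal-class].
#' @param model an [EnsembleModel-class].
#' @param orientation 3x3 rotation for the model.
#' @param partial a [PartialSolution-class] or placement list.
#' @param gridStep grid step in Angstrom (default 2).
#' @param models model registry.
#' @param sgHyp hypothesis space group.
#' @param nPeaks maximum peaks returned (default 10).
#' @return list of peaks: list(placement, raw, tfz, llg).
#' @export
translationSearch <- function(crystal, model, orientation, partial = NULL,
                              gridStep = 2.0, models = list(), sgHyp = NULL,
                              nPeaks = 10L) {
  ctx <- .scoreCtx(crystal, sgHyp)
  partialPl <- if (is.null(partial)) list() else
    if (is(partial, "PartialSolution")) partial@placements else partial
  plcPart <- .plcList(partialPl, models, crystal)
  compInt <- match(model@componentId, ctx$compNames)
  w <- model@weight
  empty <- length(partialPl) == 0

  if (empty) {
    scanShifts <- matrix(0, 1, 3)
    partialGeo <- 0
    partialFull <- 0
  } else {
    bs <- .bestShift(plcPart, ctx, crystal@sigma)
    clash <- sum(cppClashMatrix(plcPart, ctx$hypOps, ctx$O, ctx$Oinv, 3.0))
    wbarOld <- mean(vapply(plcPart, function(e) e$w, numeric(1)))
    partialGeo <- bs$total$total - 0.5 * wbarOld * clash
    partialFull <- mockLLG(partialPl, crystal, models, sgHyp)$llg
    ## discrete shifts with the partial's optimal polar components folded in
    scanShifts <- ctx$shifts
    polar <- ctx$sgHyp@polarAxes
    if (any(polar)) {
      sf <- as.vector(ctx$Oinv %*% bs$shift)
      fr <- ctx$sgHyp@originShifts
      if (nrow(fr) == 0) fr <- matrix(0, 1, 3)
      fr[, polar] <- matrix(sf[polar], nrow(fr), sum(polar), byrow = TRUE)
      fr <- unique(rbind(sf, fr))
      scanShifts <- fr %*% t(ctx$O)
    }
  }

  partialOv <- lapply(seq_len(nrow(scanShifts)), function(i)
    cppOvMatrix(plcPart, ctx$truths, ctx$hypOps, scanShifts[i, ],
                ctx$O, ctx$Oinv, crystal@sigma))

  grid <- .translationGrid(crystal, ctx, gridStep, pinPolar = empty)
  mm <- model@members[[1]] %*% t(orientation)
  scan <- cppTranslationScan(grid$cart, mm, model@resIdx + 1L, compInt, w,
                             partialOv, plcPart,
                             vapply(plcPart, function(e) e$w, numeric(1)),
                             ctx$truths, ctx$hypOps, scanShifts, ctx$O,
                             ctx$Oinv, crystal@sigma, 3.0, partialGeo,
                             crystal@epsilon, crystal@seed, orientation)
  raw <- scan$raw
  ## TFZ background over clash-free grid points: positions dominated by the
  ## clash penalty belong to the packing function, not the score landscape
  bg <- raw[scan$clashFree]
  if (length(bg) < 10) bg <- raw
  mu <- mean(bg); sdv <- stats::sd(bg)
  tfz <- if (is.finite(sdv) && sdv > 0) (raw - mu) / sdv else rep(0, length(raw))

  lm <- .localMaxima(raw, grid$dims)
  lm <- lm[order(-raw[lm])]
  lm <- lm[seq_len(min(nPeaks, length(lm)))]
  lapply(lm, function(i) {
    p <- placement(model@componentId, model@modelId, orientation, grid$cart[i, ])
    llg <- mockLLG(c(partialPl, list(p)), crystal, models, sgHyp)$llg
    list(placement = p, raw = if (empty) llg else llg - partialFull,
         scanRaw = raw[i], tfz = tfz[i], llg = llg)
  })
}

## ---- packing ------------------------------------------------------------

#' Packing check
#'
#' Counts Calpha clash pairs (< `cutoff` Angstrom) between different
#' placements and their symmetry images; a solution packs when no offending
#' pair exceeds 5 percent of the smaller molecule's residue count.
#'
#' @param solPlacements placements or a [PartialSolution-class].
#' @param crystal a [ToyCrystal-class].
#' @param models model registry.
#' @param sgHyp hypothesis space group.
#' @param cutoff clash distance (default 3.0).
#' @param maxFrac per-pair tolerated clash fraction (default 0.05).
#' @return list(passes, clashCount).
#' @export
packingCheck <- function(solPlacements, crystal, models = list(),
                         sgHyp = NULL, cutoff = 3.0, maxFrac = 0.05) {
  if (is(solPlacements, "PartialSolution")) solPlacements <- solPlacements@placements
  if (length(solPlacements) == 0) return(list(passes = TRUE, clashCount = 0L))
  ctx <- .scoreCtx(crystal, sgHyp)
  plc <- .plcList(solPlacements, models, crystal)
  cm <- cppClashMatrix(plc, ctx$hypOps, ctx$O, ctx$Oinv, cutoff)
  sizes <- vapply(plc, function(e) nrow(e$coords), integer(1))
  passes <- TRUE
  for (i in seq_along(plc)) for (j in i:length(plc)) {
    if (cm[i, j] > 0 && cm[i, j] > maxFrac * min(sizes[i], sizes[j]))
      passes <- FALSE
  }
  list(passes = passes, clashCount = as.integer(sum(cm)))
}

## ---- rigid-body refinement ----------------------------------------------

.expmap <- function(r) {
  th <- sqrt(sum(r^2))
  if (th < 1e-12) return(diag(3))
  axisAngleRotation(r / th, rad2deg(th))
}

#' Rigid-body refinement of a solution
#'
#' Derivative-free local maximization of the mock LLG over the six
#' rigid-body parameters of each in-scope placement (small-angle rotation
#' vector about the current orientation plus a translation offset), bounded
#' to +/- 15 degrees and +/- 5 Angstrom from the start, iterated until the
#' score improves by less than 1e-4 over a full pass.
#'
#' @param solPlacements placements or a [PartialSolution-class].
#' @param crystal a [ToyCrystal-class].
#' @param models model registry.
#' @param scope "all" or "last".
#' @param sgHyp hypothesis space group.
#' @return list(placements, llg, converged).
#' @export
rigidRefine <- function(solPlacements, crystal, models = list(),
                        scope = c("all", "last"), sgHyp = NULL) {
  scope <- match.arg(scope)
  pl <- if (is(solPlacements, "PartialSolution")) solPlacements@placements
        else solPlacements
  if (length(pl) == 0) stopf("cannot refine an empty solution")
  idx <- if (scope == "last") length(pl) else seq_along(pl)
  maxRot <- deg2rad(15); maxTrans <- 5
  ctx <- .scoreCtx(crystal, sgHyp)
  converged <- FALSE
  for (pass in 1:4) {
    improved <- FALSE
    for (i in idx) {
      p0 <- pl[[i]]
      others <- pl[-i]
      ## cache the fixed placements' overlap rows per candidate shift so
      ## each objective call scores only the moving placement
      plcOther <- .plcList(others, models, crystal)
      scanShifts <- ctx$shifts
      if (any(ctx$sgHyp@polarAxes) && length(others)) {
        bs <- .bestShift(plcOther, ctx, crystal@sigma)
        sf <- as.vector(ctx$Oinv %*% bs$shift)
        fr <- ctx$sgHyp@originShifts
        if (nrow(fr) == 0) fr <- matrix(0, 1, 3)
        fr[, ctx$sgHyp@polarAxes] <-
          matrix(sf[ctx$sgHyp@polarAxes], nrow(fr),
                 sum(ctx$sgHyp@polarAxes), byrow = TRUE)
        scanShifts <- unique(rbind(sf, fr)) %*% t(ctx$O)
      }
      partialOv <- lapply(seq_len(nrow(scanShifts)), function(s)
        cppOvMatrix(plcOther, ctx$truths, ctx$hypOps, scanShifts[s, ],
                    ctx$O, ctx$Oinv, crystal@sigma))
      ent <- .plcEntry(p0, models, crystal)
      base <- if (identical(p0@modelId, "truth") ||
                  is.null(models[[p0@modelId]]))
        crystal@clouds[[p0@componentId]] else
          models[[p0@modelId]]@members[[1]]
      otherW <- vapply(plcOther, function(e) e$w, numeric(1))
      rawOf <- function(R, tr) {
        mm <- base %*% t(R)
        sc <- cppTranslationScan(matrix(tr, 1, 3), mm, ent$res, ent$comp,
                                 ent$w, partialOv, plcOther, otherW,
                                 ctx$truths, ctx$hypOps, scanShifts, ctx$O,
                                 ctx$Oinv, crystal@sigma, 3.0, 0,
                                 crystal@epsilon, crystal@seed, R)
        sc$raw[1]
      }
      cur0 <- rawOf(p0@rot, p0@trans)
      obj <- function(par) {
        r <- par[1:3]; dt <- par[4:6]
        if (sqrt(sum(r^2)) > maxRot || sqrt(sum(dt^2)) > maxTrans) return(1e12)
        -rawOf(.expmap(r) %*% p0@rot, p0@trans + dt)
      }
      fit <- stats::optim(rep(0, 6), obj, method = "Nelder-Mead",
                          control = list(maxit = 300, reltol = 1e-8,
                                         parscale = c(rep(0.05, 3), rep(1, 3))))
      if (-fit$value > cur0 + 1e-4) {
        r <- fit$par[1:3]; dt <- fit$par[4:6]
        pl[[i]] <- placement(p0@componentId, p0@modelId,
                             .expmap(r) %*% p0@rot, p0@trans + dt)
        improved <- TRUE
      }
    }
    if (!improved) { converged <- TRUE; break }
  }
  list(placements = pl, llg = mockLLG(pl, crystal, models, sgHyp)$llg,
       converged = converged)
}

## ---- background Z -------------------------------------------------------

#' Background Z-score of a candidate extension
#'
#' Standardizes the raw score gain of a candidate placement against the raw
#' gains of seeded random placements of the same model: the TFZ analogue
#' used for non-search peaks (amalgamation partners, assembly predictions).
#'
#' @param partial the parent placements (list or [PartialSolution-class]).
#' @param candidate the proposed [Placement-class].
#' @param model the [EnsembleModel-class] placed.
#' @param crystal a [ToyCrystal-class].
#' @param models model registry.
#' @param nSamples background sample count (>= 50, default 200).
#' @param seed sampling seed.
#' @param sgHyp hypothesis space group.
#' @return list(z, raw, backgroundMean, backgroundSd).
#' @export
backgroundZscore <- function(partial, candidate, model, crystal,
                             models = list(), nSamples = 200L, seed = 1L,
                             sgHyp = NULL) {
  if (nSamples < 50L) stopf("nSamples must be at least 50")
  partialPl <- if (is.null(partial)) list() else
    if (is(partial, "PartialSolution")) partial@placements else partial
  ctx <- .scoreCtx(crystal, sgHyp)
  base <- mockLLG(partialPl, crystal, models, sgHyp, polarOpt = FALSE)
  unmatched <- setdiff(which(ctx$truthComp ==
                               match(candidate@componentId, ctx$compNames)),
                       base$matchedTruthIndices)
  w <- .plcEntry(candidate, models, crystal)$w
  ## raw = weighted overlap gain against the truths the partial leaves
  ## unmatched, at the partial's origin frame (the clash term belongs to
  ## the packing function, which is evaluated separately)
  rawOf <- function(p) {
    ov <- cppOvMatrix(.plcList(list(p), models, crystal), ctx$truths,
                      ctx$hypOps, base$shift, ctx$O, ctx$Oinv,
                      crystal@sigma)
    if (length(unmatched) == 0) return(0)
    w * max(ov[1, unmatched])
  }
  rawCand <- rawOf(candidate)
  O <- orthogonalizationMatrix(crystal@cell)
  bg <- withSeed(deriveSeed(seed, "bgz"), {
    vapply(seq_len(nSamples), function(i) {
      q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
      fr <- stats::runif(3)
      rawOf(placement(candidate@componentId, candidate@modelId,
                      quatToRot(q), as.vector(O %*% fr)))
    }, numeric(1))
  })
  sdv <- stats::sd(bg)
  z <- if (is.finite(sdv) && sdv > 0) (rawCand - mean(bg)) / sdv else 0
  list(z = z, raw = rawCand, backgroundMean = mean(bg), backgroundSd = sdv)
}

## ---- generator ----------------------------------------------------------

## compact self-avoiding Calpha walk: bond 3.8 A, excluded volume 3.8 A,
## radius-of-gyration cap pulling the chain back toward its centroid
.randomCloud <- function(n, seed) {
  withSeed(seed, {
    rgCap <- 2.5 * n^(1 / 3) + 2
    pts <- matrix(0, n, 3)
    for (i in 2:n) {
      for (attempt in 1:200) {
        dir <- stats::rnorm(3)
        dir <- dir / sqrt(sum(dir^2))
        cen <- colMeans(pts[1:(i - 1), , drop = FALSE])
        pull <- cen - pts[i - 1, ]
        pn <- sqrt(sum(pull^2))
        if (pn > rgCap) dir <- 0.4 * dir + 0.6 * pull / pn
        dir <- dir / sqrt(sum(dir^2))
        cand <- pts[i - 1, ] + 3.8 * dir
        if (i < 3 || min(sqrt(rowSums(sweep(pts[1:(i - 2), , drop = FALSE],
                                            2, cand)^2))) > 3.8) break
      }
      pts[i, ] <- cand
    }
    sweep(pts, 2, colMeans(pts))
  })
}

.randomSequence <- function(n, seed) {
  withSeed(seed, paste(sample(names(.RESIDUE_MASS)[1:20], n, replace = TRUE),
                       collapse = ""))
}

.randomRotation <- function() {
  q <- stats::rnorm(4); quatToRot(q / sqrt(sum(q^2)))
}

## cell with the crystal system of `sg`, volume V, gently unequal edges
.cellForVolume <- function(V, sg) {
  sys <- .SG_META[[sg@symbol]]$system
  if (sys == "tetragonal") {
    a <- (V / 1.2)^(1 / 3)
    unitCell(a, a, 1.2 * a)
  } else if (sys == "monoclinic") {
    beta <- 105
    abc <- (V / (1 * 1.15 * 1.3) / sin(deg2rad(beta)))^(1 / 3)
    unitCell(abc, 1.15 * abc, 1.3 * abc, 90, beta, 90)
  } else {
    abc <- (V / (1 * 1.15 * 1.3))^(1 / 3)
    unitCell(abc, 1.15 * abc, 1.3 * abc)
  }
}

.parseGroupLabel <- function(label) {
  m <- regmatches(label, regexec("^([CD])([0-9]+)$", label))[[1]]
  if (length(m) != 3) stopf("unsupported point-group label '%s'", label)
  list(family = m[2], order = as.integer(m[3]),
       size = as.integer(m[3]) * (if (m[2] == "D") 2L else 1L))
}

## placements of one Cn/Dn orbit: base placement rotated about (axis, center)
.assemblyOrbit <- function(componentId, R0, t0, axis, center, label) {
  g <- .parseGroupLabel(label)
  out <- list()
  for (k in 0:(g$order - 1)) {
    Rk <- axisAngleRotation(axis, k * 360 / g$order)
    out[[length(out) + 1L]] <- placement(componentId, "truth", Rk %*% R0,
      as.vector(Rk %*% (t0 - center)) + center)
  }
  if (g$family == "D") {
    perp <- if (abs(axis[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    perp <- perp - sum(perp * axis) * axis
    perp <- perp / sqrt(sum(perp^2))
    flip <- axisAngleRotation(perp, 180)
    for (k in 0:(g$order - 1)) {
      Rk <- axisAngleRotation(axis, k * 360 / g$order) %*% flip
      out[[length(out) + 1L]] <- placement(componentId, "truth", Rk %*% R0,
        as.vector(Rk %*% (t0 - center)) + center)
    }
  }
  out
}

#' Generate a synthetic toy crystal
#'
#' Builds seeded compact Calpha clouds for each component, sizes the cell
#' from the total weight and target solvent fraction through the Matthews
#' relation, places the requested copies (optionally as exact Cn/Dn
#' point-group orbits) by rejection sampling until packing passes, and emits
#' a perturbed template model per component.
#'
#' @param genspec list: `components` (list of list(id, length, copies)),
#'   optional `assembly` (list(component, group, axis, radius)), `solvent`
#'   (default 0.5), `spaceGroup` (default "P1"), `sigma`, `sigmaRot`,
#'   `epsilon`, `templateNoise` (default 0.8 Angstrom).
#' @param seed generator seed.
#' @param outDir optional directory for ground-truth PDB and FASTA files.
#' @return list(crystal, models (one template [EnsembleModel-class] per
#'   component), sequences, files).
#' @export
generateCrystal <- function(genspec, seed = 1L, outDir = NULL) {
  sg <- buildSpaceGroup(genspec$spaceGroup %||% "P1")
  solvent <- genspec$solvent %||% 0.5
  sigma <- genspec$sigma %||% 1.5
  sigmaRot <- genspec$sigmaRot %||% 10
  epsilon <- genspec$epsilon %||% 0.02
  tmplNoise <- genspec$templateNoise %||% 0.8

  comps <- list(); clouds <- list(); copies <- c()
  for (i in seq_along(genspec$components)) {
    gc <- genspec$components[[i]]
    sq <- .randomSequence(gc$length, deriveSeed(seed, paste0("seq", gc$id)))
    comps[[gc$id]] <- componentSpec(gc$id, sq)
    clouds[[gc$id]] <- .randomCloud(gc$length,
                                    deriveSeed(seed, paste0("cloud", gc$id)))
    copies[gc$id] <- gc$copies %||% 1L
  }

  mwAsu <- sum(vapply(names(comps), function(id)
    comps[[id]]@mw * copies[[id]], numeric(1)))
  vm <- 1.23 / (1 - solvent)
  V <- vm * length(sg@ops) * mwAsu
  cell <- .cellForVolume(V, sg)
  validateCellForGroup(cell, sg)
  O <- orthogonalizationMatrix(cell)

  asm <- genspec$assembly
  ## placement units: whole orbits for the assembly component, single copies
  ## otherwise
  units <- list()
  for (id in names(copies)) {
    if (!is.null(asm) && identical(asm$component, id)) {
      g <- .parseGroupLabel(asm$group)
      if (copies[[id]] %% g$size != 0L)
        stopf("copy count %d of '%s' is not a multiple of the %s orbit size %d",
              copies[[id]], id, asm$group, g$size)
      for (k in seq_len(copies[[id]] %/% g$size))
        units[[length(units) + 1L]] <- list(kind = "orbit", component = id)
    } else {
      for (k in seq_len(copies[[id]]))
        units[[length(units) + 1L]] <- list(kind = "single", component = id)
    }
  }

  cloudRad <- vapply(clouds, function(cl)
    max(sqrt(rowSums(cl^2))), numeric(1))

  crystal <- NULL
  truths <- list()
  placedAll <- FALSE
  for (pass in seq_len(20L)) {
    if (placedAll) break
    truths <- list()
    passFailed <- FALSE
    withSeed(deriveSeed(seed, paste0("place", pass)), {
    ## stratified center candidates: shuffled fractional grid + jitter, so
    ## crowded cells are covered systematically rather than by luck
    gridPts <- as.matrix(expand.grid(seq(0.05, 0.95, by = 0.1),
                                     seq(0.05, 0.95, by = 0.1),
                                     seq(0.05, 0.95, by = 0.1)))
    for (u in units) {
      id <- u$component
      placed <- FALSE
      centerOrder <- gridPts[sample.int(nrow(gridPts)), , drop = FALSE]
      for (attempt in seq_len(1000L)) {
        ctr <- fracWrap(centerOrder[(attempt - 1L) %% nrow(centerOrder) + 1L, ] +
                          stats::runif(3, -0.05, 0.05))
        if (u$kind == "single") {
          cand <- list(placement(id, "truth", .randomRotation(),
                                 as.vector(O %*% ctr)))
        } else {
          g <- .parseGroupLabel(asm$group)
          axis <- if (!is.null(asm$axis)) {
            ax <- as.numeric(asm$axis); ax / sqrt(sum(ax^2))
          } else { ax <- stats::rnorm(3); ax / sqrt(sum(ax^2)) }
          radius <- asm$radius %||%
            ((2 * cloudRad[[id]] + 2.5) / (2 * sin(pi / g$order)))
          center <- as.vector(O %*% ctr)
          perp <- stats::rnorm(3)
          perp <- perp - sum(perp * axis) * axis
          perp <- perp / sqrt(sum(perp^2))
          cand <- .assemblyOrbit(id, .randomRotation(),
                                 center + radius * perp, axis, center,
                                 asm$group)
        }
        trial <- c(truths, cand)
        tmpCrystal <- new("ToyCrystal", cell = cell, sg = sg,
                          components = comps, clouds = clouds, truths = trial,
                          sigma = sigma, sigmaRot = sigmaRot,
                          epsilon = epsilon, seed = as.integer(seed))
        pk <- packingCheck(trial, tmpCrystal)
        if (pk$passes) {
          truths <- trial
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        passFailed <- TRUE
        break
      }
    }
    })
    if (!passFailed) placedAll <- TRUE
  }
  if (!placedAll)
    stopf("could not place all copies without clashes in 1000 attempts")

  crystal <- new("ToyCrystal", cell = cell, sg = sg, components = comps,
                 clouds = clouds, truths = truths, sigma = sigma,
                 sigmaRot = sigmaRot, epsilon = epsilon,
                 seed = as.integer(seed))

  ## one perturbed template model per component
  models <- list()
  for (id in names(comps)) {
    cl <- clouds[[id]]
    noise <- withSeed(deriveSeed(seed, paste0("tmpl", id)),
                      matrix(stats::rnorm(length(cl), sd = tmplNoise),
                             nrow(cl), 3))
    L <- nrow(cl)
    cov <- cbind(0L, L)
    em <- new("EnsembleModel", modelId = paste0(id, "_tmpl"),
              componentId = id, members = list(cl + noise),
              resIdx = 0:(L - 1L), bvals = rep(20, L), coverage = cov,
              weight = .coverageWeight(cov, comps[[id]]@sequence),
              sourceTemplateId = paste0(id, "_tmpl"), protocolId = "template")
    models[[em@modelId]] <- em
  }

  files <- list()
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    chains <- lapply(truths, function(tr) {
      cl <- clouds[[tr@componentId]]
      list(coords = cl %*% t(tr@rot) + matrix(tr@trans, nrow(cl), 3, TRUE),
           resIdx = 0:(nrow(cl) - 1L),
           sequence = comps[[tr@componentId]]@sequence)
    })
    files$truth <- writeCaPdb(chains, file.path(outDir, "truth.pdb"),
                              cell = cell, sgSymbol = sg@symbol)
    files$fasta <- writeComponentFasta(comps, file.path(outDir, "components.fasta"))
    for (id in names(models)) {
      m <- models[[id]]
      files[[paste0("model_", id)]] <- writeCaPdb(
        list(list(coords = m@members[[1]], resIdx = m@resIdx,
                  sequence = comps[[m@componentId]]@sequence)),
        file.path(outDir, paste0(id, ".pdb")))
    }
  }
  list(crystal = crystal, models = models,
       sequences = lapply(comps, function(cs) cs@sequence), files = files)
}

#' Perturbed model variants from one template
#'
#' Produces `n` independently perturbed copies of a template model sharing
#' its source-template identity (protocol ids variant_1..n) -- the fixture
#' for multi-model combinatorics.
#'
#' @param template an [EnsembleModel-class].
#' @param n number of variants.
#' @param noise coordinate noise sd in Angstrom.
#' @param seed perturbation seed.
#' @return list of `n` [EnsembleModel-class].
#' @export
makeModelVariants <- function(template, n, noise = 0.3, seed = 1L) {
  stopifnot(n >= 1)
  lapply(seq_len(n), function(i) {
    base <- template@members[[1]]
    pert <- if (noise > 0)
      withSeed(deriveSeed(seed, paste0("variant", i)),
               matrix(stats::rnorm(length(base), sd = noise), nrow(base), 3))
    else matrix(0, nrow(base), 3)
    new("EnsembleModel", modelId = sprintf("%s_variant_%d", template@modelId, i),
        componentId = template@componentId, members = list(base + pert),
        resIdx = template@resIdx, bvals = template@bvals,
        coverage = template@coverage, weight = template@weight,
        sourceTemplateId = template@sourceTemplateId,
        protocolId = sprintf("variant_%d", i))
  })
}

#' Toy-crystal scoring backend
#'
#' Packages the toy-crystal scoring operations behind the pluggable backend
#' contract consumed by the search engine: score, rotationSearch,
#' translationSearch, packingCheck, rigidRefine, backgroundZscore, plus the
#' cell and native space group.  Any conforming backend may replace it.
#'
#' @param crystal a [ToyCrystal-class].
#' @return named list of closures.
#' @export
toyBackend <- function(crystal) {
  list(
    cell = function() crystal@cell,
    nativeSg = function() crystal@sg@symbol,
    score = function(placements, models, sgHyp = NULL)
      mockLLG(placements, crystal, models, sgHyp),
    rotationSearch = function(model, partial, models, sgHyp = NULL,
                              nKeep = 5L, step = 15)
      rotationSearch(crystal, model, partial, nKeep, step, models, sgHyp),
    translationSearch = function(model, orientation, partial, models,
                                 sgHyp = NULL, gridStep = 2.0)
      translationSearch(crystal, model, orientation, partial, gridStep,
                        models, sgHyp),
    packingCheck = function(placements, models, sgHyp = NULL)
      packingCheck(placements, crystal, models, sgHyp),
    rigidRefine = function(placements, models, scope = "all", sgHyp = NULL)
      rigidRefine(placements, crystal, models, scope, sgHyp),
    backgroundZscore = function(partial, candidate, model, models,
                                nSamples = 200L, seed = 1L, sgHyp = NULL)
      backgroundZscore(partial, candidate, model, crystal, models,
                       nSamples, seed, sgHyp)
  )
}
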