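# Post-cycle solution analyses: amalgamation of clear siblings, NCS
# point-group detection, missing-member prediction, NCS refresh,
# known-assembly completion and composite assembly search models.

## NCS transform mapping placement i onto placement j (orthogonal frame):
## x -> R x + t with R = Rj Ri^T, t = tj - R ti.
.ncsTransform <- function(pi, pj) {
  R <- pj@rot %*% t(pi@rot)
  list(rot = R, trans = pj@trans - as.vector(R %*% pi@trans))
}

## axis-point of a rotation-with-translation: t = (I - R) c + tau * axis,
## with c perpendicular to the axis (ridge along the axis makes M regular)
.axisPoint <- function(R, tr, axis, tau) {
  M <- (diag(3) - R) + axis %o% axis
  as.vector(solve(M, tr - tau * axis))
}

## smallest point-group order n <= maxOrder with theta ~ 360*m/n (gcd(m,n)=1)
.inferOrder <- function(theta, tolAngle, maxOrder) {
  for (n in 2:maxOrder) {
    for (m in seq_len(n %/% 2)) {
      if (.gcd(m, n) != 1L) next
      if (abs(theta - 360 * m / n) <= tolAngle) return(n)
    }
  }
  NA_integer_
}

.gcd <- function(a, b) if (b == 0) a else .gcd(b, a %% b)

## distance between two axis lines (direction a through point c); uses the
## skew-line formula when the directions differ, the parallel projection
## otherwise
.lineDistance <- function(a1, c1, a2, c2) {
  n <- c(a1[2] * a2[3] - a1[3] * a2[2],
         a1[3] * a2[1] - a1[1] * a2[3],
         a1[1] * a2[2] - a1[2] * a2[1])
  nn <- sqrt(sum(n^2))
  d <- c2 - c1
  if (nn < 1e-6) return(sqrt(sum((d - sum(d * a1) * a1)^2)))
  abs(sum(d * n)) / nn
}

#' Detect noncrystallographic point-group assemblies
#'
#' Computes pairwise NCS transforms between same-component placements
#' (alternative models matched transparently through their shared target
#' numbering), keeps transforms whose rotation angle matches 360 m/n for
#' some order n up to `maxOrder` and whose screw (axial) translation is
#' within `tolPerp`, clusters the candidate axes, tests each cluster for
#' group closure, and merges identical groups and subgroups (a Cn inside a
#' detected Dn is absorbed).
#'
#' @param solution a [PartialSolution-class] or placement list.
#' @param sg,cell optional [SpaceGroup-class] and [UnitCell-class]: when
#'   given, crystal-symmetry images of the placements participate in the
#'   pairwise relations (placements recorded in different asymmetric units
#'   are still recognized as assembly partners).
#' @param tolAxis axis clustering tolerance in degrees (default 5).
#' @param tolAngle rotation-angle tolerance in degrees (default 5).
#' @param tolPerp maximum axial screw component in Angstrom (default 1).
#' @param maxOrder maximum group order considered (default 12).
#' @param maxRadius maximum orbit radius considered in Angstrom (default 50).
#' @return list of [AssemblyHypothesis-class].
#' @export
detectAssemblies <- function(solution, sg = NULL, cell = NULL, tolAxis = 5,
                             tolAngle = 5, tolPerp = 1.0, maxOrder = 12L,
                             maxRadius = 50) {
  pl <- if (is(solution, "PartialSolution")) solution@placements else solution
  if (length(pl) < 2) return(list())

  ## crystal-symmetry images of each placement participate in the pairwise
  ## relations: a point-group partner may be recorded in another asymmetric
  ## unit (the identity with no lattice offset reproduces the direct pair)
  imageOps <- list(list(A = diag(3), b = c(0, 0, 0)))
  latOff <- matrix(0, 1, 3)
  if (!is.null(sg) && !is.null(cell)) {
    imageOps <- lapply(sg@ops, opToCartesian, cell = cell)
    O <- orthogonalizationMatrix(cell)
    latOff <- as.matrix(expand.grid(-1:1, -1:1, -1:1)) %*% t(O)
  }

  ## candidate rotational relations
  cands <- list()
  for (i in seq_along(pl)) for (j in seq_along(pl)) {
    if (j <= i) next
    if (pl[[i]]@componentId != pl[[j]]@componentId) next
    for (co in imageOps) {
      pj <- placement(pl[[j]]@componentId, pl[[j]]@modelId,
                      co$A %*% pl[[j]]@rot,
                      as.vector(co$A %*% pl[[j]]@trans) + co$b)
      tf0 <- .ncsTransform(pl[[i]], pj)
      aa <- rotationAngleAxis(tf0$rot)
      if (aa$theta < tolAngle) next
      n <- .inferOrder(aa$theta, tolAngle, maxOrder)
      if (is.na(n)) next
      ## pick the lattice offset minimizing the screw component
      taus <- abs((matrix(tf0$trans, nrow(latOff), 3, TRUE) + latOff) %*%
                    aa$axis)
      bestL <- which.min(taus)
      tr <- tf0$trans + latOff[bestL, ]
      tau <- sum(tr * aa$axis)
      if (abs(tau) > tolPerp) next
      center <- .axisPoint(tf0$rot, tr, aa$axis, tau)
      if (sqrt(sum((center - pl[[i]]@trans)^2)) > maxRadius) next
      cands[[length(cands) + 1L]] <- list(i = i, j = j, order = n,
                                          theta = aa$theta, axis = aa$axis,
                                          center = center,
                                          comp = pl[[i]]@componentId)
    }
  }
  if (length(cands) == 0) return(list())

  ## cluster by axis direction and axis-line proximity
  clusters <- list()
  for (cd in cands) {
    placed <- FALSE
    for (k in seq_along(clusters)) {
      ref <- clusters[[k]][[1]]
      dAng <- rad2deg(acos(min(1, abs(sum(cd$axis * ref$axis)))))
      if (dAng <= tolAxis &&
          .lineDistance(ref$axis, ref$center, cd$axis, cd$center) <= 2.0) {
        clusters[[k]] <- c(clusters[[k]], list(cd))
        placed <- TRUE
        break
      }
    }
    if (!placed) clusters[[length(clusters) + 1L]] <- list(cd)
  }

  ## one Cn hypothesis per cluster: order = lcm of member orders
  lcm2 <- function(a, b) a * b / .gcd(a, b)
  hyps <- list()
  for (cl in clusters) {
    n <- Reduce(lcm2, vapply(cl, function(c) c$order, integer(1)))
    if (n > maxOrder) next
    axis <- colMeans(do.call(rbind, lapply(cl, function(c) {
      s <- sign(sum(c$axis * cl[[1]]$axis)); s[s == 0] <- 1
      s * c$axis
    })))
    axis <- axis / sqrt(sum(axis^2))
    nz <- which(abs(axis) > 1e-9)[1]
    if (axis[nz] < 0) axis <- -axis
    center <- colMeans(do.call(rbind, lapply(cl, function(c) c$center)))
    members <- sort(unique(unlist(lapply(cl, function(c) c(c$i, c$j)))))
    Rg <- axisAngleRotation(axis, 360 / n)
    gen <- list(list(rot = Rg,
                     trans = as.vector((diag(3) - Rg) %*% center)))
    hyps[[length(hyps) + 1L]] <- new("AssemblyHypothesis",
      groupLabel = paste0("C", n), axis = axis, center = center,
      memberIndices = as.integer(members), generators = gen,
      source = "detected")
  }
  if (length(hyps) == 0) return(list())

  ## combine a Cn axis with perpendicular C2 axes into Dn
  isC2 <- vapply(hyps, function(h) h@groupLabel == "C2", logical(1))
  absorbed <- rep(FALSE, length(hyps))
  out <- list()
  for (k in seq_along(hyps)) {
    if (absorbed[k]) next
    h <- hyps[[k]]
    n <- as.integer(sub("^C", "", h@groupLabel))
    perp <- which(isC2 & !absorbed & seq_along(hyps) != k)
    perp <- perp[vapply(perp, function(q) {
      dAng <- rad2deg(acos(min(1, abs(sum(hyps[[q]]@axis * h@axis)))))
      abs(dAng - 90) <= tolAxis &&
        .lineDistance(h@axis, h@center, hyps[[q]]@axis, hyps[[q]]@center) <= 3.0
    }, logical(1))]
    if (length(perp) >= 1 && n >= 2) {
      flip <- hyps[[perp[1]]]
      Rf <- axisAngleRotation(flip@axis, 180)
      gens <- c(h@generators,
                list(list(rot = Rf,
                          trans = as.vector((diag(3) - Rf) %*% flip@center))))
      members <- sort(unique(c(h@memberIndices,
                               unlist(lapply(perp, function(q)
                                 hyps[[q]]@memberIndices)))))
      out[[length(out) + 1L]] <- new("AssemblyHypothesis",
        groupLabel = paste0("D", n), axis = h@axis, center = h@center,
        memberIndices = as.integer(members), generators = gens,
        source = "detected")
      absorbed[perp] <- TRUE
      absorbed[k] <- TRUE
    }
  }
  for (k in seq_along(hyps)) if (!absorbed[k]) out[[length(out) + 1L]] <- hyps[[k]]

  ## dedupe: same label, same member set, same axis line
  if (length(out) > 1) {
    keep <- rep(TRUE, length(out))
    for (a in seq_along(out)) {
      if (!keep[a]) next
      for (b in seq_along(out)) {
        if (b <= a || !keep[b]) next
        ha <- out[[a]]; hb <- out[[b]]
        if (ha@groupLabel != hb@groupLabel) next
        if (!identical(ha@memberIndices, hb@memberIndices)) next
        dAng <- rad2deg(acos(min(1, abs(sum(ha@axis * hb@axis)))))
        if (dAng <= tolAxis) keep[b] <- FALSE
      }
    }
    out <- out[keep]
  }

  ## subgroup absorption among the survivors: Cn inside Cm (n | m, same axis)
  drop <- rep(FALSE, length(out))
  ordOf <- function(h) as.integer(sub("^[CD]", "", h@groupLabel))
  sizeOf <- function(h) ordOf(h) * (if (startsWith(h@groupLabel, "D")) 2L else 1L)
  for (a in seq_along(out)) for (b in seq_along(out)) {
    if (a == b || drop[a] || drop[b]) next
    ha <- out[[a]]; hb <- out[[b]]
    dAng <- rad2deg(acos(min(1, abs(sum(ha@axis * hb@axis)))))
    sameAxis <- dAng <= tolAxis &&
      .lineDistance(ha@axis, ha@center, hb@axis, hb@center) <= 3.0
    inDn <- startsWith(hb@groupLabel, "D") &&
      abs(dAng - 90) <= tolAxis && startsWith(ha@groupLabel, "C") &&
      ordOf(ha) == 2L
    if ((sameAxis && sizeOf(ha) < sizeOf(hb) &&
         ordOf(hb) %% ordOf(ha) == 0L &&
         all(ha@memberIndices %in% hb@memberIndices)) ||
        (inDn && all(ha@memberIndices %in% hb@memberIndices)))
      drop[a] <- TRUE
  }
  out[!drop]
}

## full element list of a hypothesis group as affine transforms
.groupElements <- function(assembly) {
  n <- as.integer(sub("^[CD]", "", assembly@groupLabel))
  axis <- assembly@axis; center <- assembly@center
  els <- list()
  for (k in 0:(n - 1)) {
    R <- axisAngleRotation(axis, k * 360 / n)
    els[[length(els) + 1L]] <- list(rot = R,
      trans = as.vector((diag(3) - R) %*% center))
  }
  if (startsWith(assembly@groupLabel, "D") && length(assembly@generators) >= 2) {
    flip <- assembly@generators[[length(assembly@generators)]]
    for (k in 0:(n - 1)) {
      R <- axisAngleRotation(axis, k * 360 / n)
      els[[length(els) + 1L]] <- list(rot = R %*% flip$rot,
        trans = as.vector(R %*% flip$trans) + as.vector((diag(3) - R) %*% center))
    }
  }
  els
}

.applyAffine <- function(tf, p) {
  placement(p@componentId, p@modelId, tf$rot %*% p@rot,
            as.vector(tf$rot %*% p@trans) + tf$trans)
}

#' Predict missing assembly members
#'
#' Generates the orbit of the assembly's members under the full point group
#' and returns pending predicted placements for orbit positions not matched
#' by an existing placement.
#'
#' @param assembly an [AssemblyHypothesis-class].
#' @param solution the [PartialSolution-class] it was detected on.
#' @param sg,cell optional group/cell for symmetry-aware occupancy matching.
#' @param tolRot,tolTrans match tolerances (degrees / Angstrom).
#' @return list of list(placement, originAssembly, status = "pending").
#' @export
predictMissing <- function(assembly, solution, sg = NULL, cell = NULL,
                           tolRot = 10, tolTrans = 3.0) {
  pl <- if (is(solution, "PartialSolution")) solution@placements else solution
  if (length(assembly@memberIndices) == 0) return(list())
  anchor <- pl[[assembly@memberIndices[1]]]
  sameComp <- Filter(function(p) p@componentId == anchor@componentId, pl)
  ## symmetry-aware occupancy test: an orbit position already held by a
  ## crystal-symmetry image of a placement is not re-predicted
  samePos <- function(p, q) {
    if (is.null(sg) || is.null(cell)) {
      return(rotationDistance(p@rot, q@rot) <= tolRot &&
               sqrt(sum((p@trans - q@trans)^2)) <= tolTrans)
    }
    O <- orthogonalizationMatrix(cell)
    Oinv <- solve(O)
    for (op in sg@ops) {
      co <- opToCartesian(op, cell)
      pr <- co$A %*% p@rot
      pt <- as.vector(co$A %*% p@trans) + co$b
      if (rotationDistance(pr, q@rot) > tolRot) next
      d <- as.vector(Oinv %*% (q@trans - pt))
      d <- as.vector(O %*% fracMin(d))
      if (sqrt(sum(d^2)) <= tolTrans) return(TRUE)
    }
    FALSE
  }
  preds <- list()
  for (el in .groupElements(assembly)) {
    cand <- .applyAffine(el, anchor)
    matched <- any(vapply(sameComp, function(p) samePos(p, cand),
                          logical(1)))
    if (!matched) {
      dup <- any(vapply(preds, function(q)
        rotationDistance(q$placement@rot, cand@rot) <= tolRot &&
          sqrt(sum((q$placement@trans - cand@trans)^2)) <= tolTrans,
        logical(1)))
      if (!dup)
        preds[[length(preds) + 1L]] <- list(placement = cand,
                                            originAssembly = assembly@groupLabel,
                                            status = "pending")
    }
  }
  preds
}

#' Refresh NCS hypotheses after refinement
#'
#' Re-detects point groups on the current (refined) placements and updates
#' each stored hypothesis whose group is re-established (same label, axis
#' within tolerance); hypotheses that no longer hold are demoted (dropped).
#'
#' @param solution the refined [PartialSolution-class].
#' @param assemblies list of [AssemblyHypothesis-class] to refresh.
#' @param tolAxis axis agreement tolerance in degrees (default 5).
#' @param ... passed to [detectAssemblies()].
#' @return refreshed list of hypotheses.
#' @export
updateNCS <- function(solution, assemblies, tolAxis = 5, ...) {
  if (length(assemblies) == 0) return(assemblies)
  fresh <- detectAssemblies(solution, tolAxis = tolAxis, ...)
  out <- list()
  for (h in assemblies) {
    hit <- NULL
    for (f in fresh) {
      if (f@groupLabel != h@groupLabel) next
      dAng <- rad2deg(acos(min(1, abs(sum(f@axis * h@axis)))))
      if (dAng <= tolAxis) { hit <- f; break }
    }
    if (!is.null(hit)) out[[length(out) + 1L]] <- hit
  }
  out
}

#' Amalgamate two clear sibling solutions
#'
#' Combines two clear solutions that extend the same parent with
#' non-conflicting compositions into one more complete candidate.  With an
#' empty parent in a nonpolar group every discrete origin shift of the
#' second sibling's additions is tried and the best packing combination
#' kept; with an empty parent in a polar group only the second sibling's
#' rotation is reused and a translation search is requested instead.
#'
#' @param clearA,clearB [PartialSolution-class] siblings.
#' @param parent their common parent (placement list, possibly empty).
#' @param sg [SpaceGroup-class]; `cell` the [UnitCell-class].
#' @param cell unit cell.
#' @param backend scoring backend (see [toyBackend()]).
#' @param models model registry.
#' @param asuCopies named per-component total copy counts.
#' @param ledger optional environment whose counters are incremented.
#' @return list(candidates = list of placement lists,
#'   needsTranslation = orientation matrix or NULL).
#' @export
amalgamate <- function(clearA, clearB, parent, sg, cell, backend, models,
                       asuCopies, ledger = NULL) {
  parentPl <- if (is(parent, "PartialSolution")) parent@placements else
    (parent %||% list())
  np <- length(parentPl)
  aAdd <- clearA@placements[seq_len(length(clearA@placements) - np) + np]
  bAdd <- clearB@placements[seq_len(length(clearB@placements) - np) + np]
  counts <- table(vapply(c(parentPl, aAdd, bAdd),
                         function(p) p@componentId, character(1)))
  for (cid in names(counts)) {
    if (is.na(asuCopies[cid]) || counts[[cid]] > asuCopies[cid])
      return(list(candidates = list(), needsTranslation = NULL))
  }
  base <- c(parentPl, aAdd)
  if (np > 0) {
    return(list(candidates = list(c(base, bAdd)), needsTranslation = NULL))
  }
  if (!any(sg@polarAxes)) {
    O <- orthogonalizationMatrix(cell)
    shifts <- sg@originShifts
    if (nrow(shifts) == 0) shifts <- matrix(0, 1, 3)
    best <- NULL; bestScore <- -Inf
    for (i in seq_len(nrow(shifts))) {
      sh <- as.vector(O %*% shifts[i, ])
      bShift <- lapply(bAdd, function(p)
        placement(p@componentId, p@modelId, p@rot, p@trans + sh))
      cand <- c(base, bShift)
      pk <- backend$packingCheck(cand, models)
      if (!is.null(ledger)) .ledgerAdd(ledger, "packing")
      if (!pk$passes) next
      sc <- backend$score(cand, models)$llg
      if (sc > bestScore) { bestScore <- sc; best <- cand }
    }
    return(list(candidates = if (is.null(best)) list() else list(best),
                needsTranslation = NULL))
  }
  ## polar group, undefined relative origin: reuse the rotation only
  list(candidates = list(),
       needsTranslation = lapply(bAdd, function(p) p@rot))
}

#' Complete a known (user-supplied) assembly
#'
#' Given a user assembly -- member components with transforms relative to
#' member 1, not required to obey point-group symmetry -- and a solution in
#' which an anchor member is placed, predicts each missing member and runs a
#' local grid search (translations +/- `dT` Angstrom step `dTStep`,
#' orientation offsets +/- `dR` degrees step `dRStep`) around the predicted
#' pose, returning the best-scoring pose per missing member as a pending
#' prediction.
#'
#' @param userAssembly list(members = list(list(component, transform 4x4 or
#'   list(rot, trans)))).
#' @param solution [PartialSolution-class] with the anchor placed.
#' @param backend scoring backend.
#' @param models model registry; missing members are predicted for the
#'   first registry model of their component.
#' @param dT,dTStep,dR,dRStep local search extents/steps (4, 1, 10, 5).
#' @return list of pending predictions (as in [predictMissing()]).
#' @export
completeKnownAssembly <- function(userAssembly, solution, backend, models,
                                  dT = 4, dTStep = 1, dR = 10, dRStep = 5) {
  pl <- if (is(solution, "PartialSolution")) solution@placements else solution
  mems <- userAssembly$members
  tfs <- lapply(mems, function(m) {
    tf <- m$transform
    if (is.matrix(tf) && all(dim(tf) == c(4, 4)))
      list(rot = tf[1:3, 1:3], trans = tf[1:3, 4])
    else tf
  })
  ## anchor: first member whose component has a placement
  anchorIdx <- NULL; anchorPl <- NULL
  for (k in seq_along(mems)) {
    hit <- Filter(function(p) p@componentId == mems[[k]]$component, pl)
    if (length(hit)) { anchorIdx <- k; anchorPl <- hit[[1]]; break }
  }
  if (is.null(anchorIdx)) return(list())
  ## member-1 frame: M1 = anchor o inv(T_anchor)
  Ta <- tfs[[anchorIdx]]
  RaInv <- t(Ta$rot)
  M1rot <- anchorPl@rot %*% RaInv
  M1tr <- anchorPl@trans - as.vector(M1rot %*% Ta$trans)
  preds <- list()
  for (k in seq_along(mems)) {
    if (k == anchorIdx) next
    comp <- mems[[k]]$component
    if (any(vapply(pl, function(p) p@componentId == comp, logical(1)))) next
    mdl <- Filter(function(m) m@componentId == comp, models)
    if (length(mdl) == 0) next
    mdl <- mdl[[1]]
    Tk <- tfs[[k]]
    pred <- placement(comp, mdl@modelId, M1rot %*% Tk$rot,
                      as.vector(M1rot %*% Tk$trans) + M1tr)
    scoreOf <- function(p) backend$score(c(pl, list(p)), models)$llg
    ## translation stage
    offs <- seq(-dT, dT, by = dTStep)
    best <- pred; bestS <- scoreOf(pred)
    for (dx in offs) for (dy in offs) for (dz in offs) {
      if (dx == 0 && dy == 0 && dz == 0) next
      cand <- placement(comp, mdl@modelId, pred@rot,
                        pred@trans + c(dx, dy, dz))
      s <- scoreOf(cand)
      if (s > bestS) { bestS <- s; best <- cand }
    }
    ## orientation stage around the best translation
    rofs <- seq(-dR, dR, by = dRStep)
    bestT <- best
    for (rx in rofs) for (ry in rofs) for (rz in rofs) {
      if (rx == 0 && ry == 0 && rz == 0) next
      Rd <- axisAngleRotation(c(1, 0, 0), rx) %*%
        axisAngleRotation(c(0, 1, 0), ry) %*%
        axisAngleRotation(c(0, 0, 1), rz)
      cand <- placement(comp, mdl@modelId, Rd %*% bestT@rot, bestT@trans)
      s <- scoreOf(cand)
      if (s > bestS) { bestS <- s; best <- cand }
    }
    preds[[length(preds) + 1L]] <- list(placement = best,
                                        originAssembly = "user",
                                        status = "pending")
  }
  preds
}

#' Composite rigid search model from a detected assembly
#'
#' Returns the relative member transforms of an assembly (member k relative
#' to member 1) so a whole assembly can be searched as one rigid body: a
#' single translation peak for member 1 expands to per-member placements,
#' which are disassembled before refinement.
#'
#' @param assembly an [AssemblyHypothesis-class].
#' @param solution the solution it was detected on.
#' @return list of list(rot, trans) relative transforms (first = identity).
#' @export
assemblyRelativeTransforms <- function(assembly, solution) {
  pl <- if (is(solution, "PartialSolution")) solution@placements else solution
  anchor <- pl[[assembly@memberIndices[1]]]
  lapply(.groupElements(assembly), function(el) {
    ## transform in the anchor's local frame: inv(anchor) o el o anchor
    list(rot = el$rot, trans = el$trans)
  })
}
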