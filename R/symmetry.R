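# Crystallographic symmetry machinery: the supported chiral space-group
# catalogue, operator application, allowed origin moves, rigid-body
# superposition and spatial-equivalence testing.

## Generators (fractional basis) for the supported catalogue.  The closed
## operator lists are produced by composing these modulo unit translations.
.SG_GENERATORS <- list(
  "P1"       = list(),
  "P21"      = list(list(rot = diag(c(-1, 1, -1)), trans = c(0, 0.5, 0))),
  "C2"       = list(list(rot = diag(c(-1, 1, -1)), trans = c(0, 0, 0)),
                    list(rot = diag(3),            trans = c(0.5, 0.5, 0))),
  "P212121"  = list(list(rot = diag(c(-1, -1, 1)), trans = c(0.5, 0, 0.5)),
                    list(rot = diag(c(-1, 1, -1)), trans = c(0, 0.5, 0.5))),
  "P21212"   = list(list(rot = diag(c(-1, -1, 1)), trans = c(0, 0, 0)),
                    list(rot = diag(c(1, -1, -1)), trans = c(0.5, 0.5, 0))),
  "P41"      = list(list(rot = matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3),
                         trans = c(0, 0, 0.25))),
  "P43"      = list(list(rot = matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3),
                         trans = c(0, 0, 0.75)))
)

.SG_META <- list(
  "P1"      = list(polar = c(TRUE, TRUE, TRUE),   enant = NA_character_, pg = "1",   system = "triclinic"),
  "P21"     = list(polar = c(FALSE, TRUE, FALSE), enant = NA_character_, pg = "2",   system = "monoclinic"),
  "C2"      = list(polar = c(FALSE, TRUE, FALSE), enant = NA_character_, pg = "2",   system = "monoclinic"),
  "P212121" = list(polar = c(FALSE, FALSE, FALSE), enant = NA_character_, pg = "222", system = "orthorhombic"),
  "P21212"  = list(polar = c(FALSE, FALSE, FALSE), enant = NA_character_, pg = "222", system = "orthorhombic"),
  "P41"     = list(polar = c(FALSE, FALSE, TRUE), enant = "P43",          pg = "4",   system = "tetragonal"),
  "P43"     = list(polar = c(FALSE, FALSE, TRUE), enant = "P41",          pg = "4",   system = "tetragonal")
)

## Normalize a Hermann-Mauguin symbol: strip blanks, map unicode subscripts.
normalizeSymbol <- function(symbol) {
  s <- gsub("[[:space:]]", "", as.character(symbol))
  s <- chartr("₁₂₃₄", "1234", s)
  toupper(s)
}

.composeOps <- function(o1, o2) {
  list(rot = o1$rot %*% o2$rot,
       trans = fracWrap(as.vector(o1$rot %*% o2$trans) + o1$trans))
}

.opKey <- function(o) paste(c(o$rot, round(o$trans * 10080)), collapse = ",")

.closeGroup <- function(gens) {
  ops <- list(list(rot = diag(3), trans = c(0, 0, 0)))
  names(ops) <- .opKey(ops[[1]])
  queue <- gens
  while (length(queue)) {
    g <- queue[[1]]; queue <- queue[-1]
    g$trans <- fracWrap(g$trans)
    k <- .opKey(g)
    if (!is.null(ops[[k]])) next
    ops[[k]] <- g
    for (o in ops) {
      queue <- c(queue, list(.composeOps(g, o), .composeOps(o, g)))
    }
    if (length(ops) > 192) stopf("operator closure runaway")
  }
  unname(ops)
}

.opInGroup <- function(op, ops, tol = 1e-9) {
  for (o in ops) {
    if (all(abs(op$rot - o$rot) < 0.5) &&
        all(abs(fracMin(op$trans - o$trans)) < tol)) return(TRUE)
  }
  FALSE
}

## Discrete origin shifts: candidates on the {0, 1/4, 1/2, 3/4} grid (zero on
## polar axes, whose freedom is continuous); a shift s is allowed when
## conjugating every operator (R, t) -> (R, t + (I - R) s) lands back in the
## group modulo unit translations.
.enumerateShifts <- function(ops, polar) {
  vals <- c(0, 0.25, 0.5, 0.75)
  axes <- lapply(1:3, function(i) if (polar[i]) 0 else vals)
  grid <- as.matrix(expand.grid(axes[[1]], axes[[2]], axes[[3]]))
  keep <- apply(grid, 1, function(s) {
    all(vapply(ops, function(o) {
      conj <- list(rot = o$rot,
                   trans = fracWrap(o$trans + as.vector((diag(3) - o$rot) %*% s)))
      .opInGroup(conj, ops)
    }, logical(1)))
  })
  m <- grid[keep, , drop = FALSE]
  dimnames(m) <- NULL
  m[order(m[, 1], m[, 2], m[, 3]), , drop = FALSE]
}

.sgCache <- new.env(parent = emptyenv())

#' Build a supported space group
#'
#' Constructs the full operator list, polar-axis flags, discrete origin
#' shifts and enantiomorph partner for one of the supported chiral groups:
#' P1, P21, C2, P212121, P21212, P41, P43 (spaced spellings such as
#' "P 21 21 21" are accepted).
#'
#' @param symbol Hermann-Mauguin symbol.
#' @return A [SpaceGroup-class] object.
#' @examples
#' buildSpaceGroup("P 21 21 21")
#' @export
buildSpaceGroup <- function(symbol) {
  s <- normalizeSymbol(symbol)
  if (!s %in% names(.SG_GENERATORS))
    stopf("unsupported space group: %s (supported: %s)", symbol,
          paste(names(.SG_GENERATORS), collapse = ", "))
  if (!is.null(.sgCache[[s]])) return(.sgCache[[s]])
  ops <- .closeGroup(.SG_GENERATORS[[s]])
  meta <- .SG_META[[s]]
  shifts <- .enumerateShifts(ops, meta$polar)
  sg <- new("SpaceGroup", symbol = s, ops = ops, polarAxes = meta$polar,
            originShifts = shifts, enantiomorph = meta$enant,
            pointGroup = meta$pg)
  .sgCache[[s]] <- sg
  sg
}

#' Crystal-system compatible cell check
#'
#' Verifies that a cell's angles and lengths satisfy the constraints of a
#' space group's crystal system.
#'
#' @param cell a [UnitCell-class].
#' @param sg a [SpaceGroup-class].
#' @return invisibly `TRUE`; errors otherwise.
#' @export
validateCellForGroup <- function(cell, sg) {
  meta <- .SG_META[[sg@symbol]]
  ang <- c(cell@alpha, cell@beta, cell@gamma)
  ok <- switch(meta$system,
    triclinic    = TRUE,
    monoclinic   = abs(ang[1] - 90) < 1e-6 && abs(ang[3] - 90) < 1e-6,
    orthorhombic = all(abs(ang - 90) < 1e-6),
    tetragonal   = all(abs(ang - 90) < 1e-6) && abs(cell@a - cell@b) < 1e-6)
  if (!ok) stopf("cell incompatible with the %s crystal system of %s",
                 meta$system, sg@symbol)
  invisible(TRUE)
}

#' Cell volume
#'
#' @param cell a [UnitCell-class].
#' @return volume in cubic Angstrom.
#' @export
cellVolume <- function(cell) {
  ca <- cos(deg2rad(cell@alpha)); cb <- cos(deg2rad(cell@beta))
  cg <- cos(deg2rad(cell@gamma))
  cell@a * cell@b * cell@c *
    sqrt(pmax(0, 1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg))
}

#' Orthogonalization matrix
#'
#' Fractional-to-orthogonal conversion in the standard PDB convention
#' (a along x, b in the xy plane): orthogonal = O %*% fractional.
#'
#' @param cell a [UnitCell-class].
#' @return 3x3 matrix (Angstrom per fractional unit).
#' @export
orthogonalizationMatrix <- function(cell) {
  v <- cellVolume(cell)
  if (v < 1e-6) stopf("degenerate cell: near-zero volume")
  ca <- cos(deg2rad(cell@alpha)); cb <- cos(deg2rad(cell@beta))
  cg <- cos(deg2rad(cell@gamma)); sg <- sin(deg2rad(cell@gamma))
  matrix(c(cell@a, cell@b * cg, cell@c * cb,
           0,      cell@b * sg, cell@c * (ca - cb * cg) / sg,
           0,      0,           v / (cell@a * cell@b * sg)),
         nrow = 3, byrow = TRUE)
}

#' @rdname orthogonalizationMatrix
#' @export
fractionalizationMatrix <- function(cell) solve(orthogonalizationMatrix(cell))

## Cartesian (affine) form of a fractional operator: x -> A x + b.
opToCartesian <- function(op, cell) {
  O <- orthogonalizationMatrix(cell)
  list(A = O %*% op$rot %*% solve(O), b = as.vector(O %*% op$trans))
}

#' Apply a symmetry operator to a placement
#'
#' Returns the symmetry image of a placement in the orthogonal frame.
#'
#' @param p a [Placement-class].
#' @param op an operator from the group's `symOps()` list.
#' @param cell the [UnitCell-class] defining orthogonalization.
#' @return the transformed [Placement-class].
#' @export
applySymop <- function(p, op, cell) {
  co <- opToCartesian(op, cell)
  placement(p@componentId, p@modelId, co$A %*% p@rot,
            as.vector(co$A %*% p@trans) + co$b)
}

#' Kabsch rigid-body superposition
#'
#' Least-squares proper rigid transform of paired point sets: finds
#' (rot, trans) minimizing the RMSD of `rot %*% t(B) + trans` onto A.
#'
#' @param A,B N x 3 coordinate matrices, rows paired, N >= 3.
#' @return list(rot, trans, rmsd).
#' @examples
#' A <- matrix(rnorm(30), 10, 3)
#' kabschSuperpose(A, A)$rmsd
#' @export
kabschSuperpose <- function(A, B) {
  if (!is.matrix(A) || !is.matrix(B) || nrow(A) != nrow(B) ||
      ncol(A) != 3 || ncol(B) != 3)
    stopf("degenerate superposition: paired N x 3 matrices required")
  n <- nrow(A)
  if (n < 3) stopf("degenerate superposition: need at least 3 paired points")
  ca <- colMeans(A); cb <- colMeans(B)
  Ac <- sweep(A, 2, ca); Bc <- sweep(B, 2, cb)
  ## collinear input leaves the rotation about the line undetermined
  if (svd(Ac)$d[2] < 1e-8 * max(1, svd(Ac)$d[1]) ||
      svd(Bc)$d[2] < 1e-8 * max(1, svd(Bc)$d[1]))
    stopf("degenerate superposition: collinear points")
  H <- crossprod(Bc, Ac)              # sum_i b_i a_i^T
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tr <- ca - as.vector(R %*% cb)
  fit <- Bc %*% t(R)
  rmsd <- sqrt(mean(rowSums((fit - Ac)^2)))
  list(rot = R, trans = tr, rmsd = rmsd)
}

#' Rotation angle/axis decomposition
#'
#' Decomposes a proper rotation into its angle (degrees, in [0, 180]) and
#' unit axis with canonical sign (first nonzero component positive).
#'
#' @param rot proper orthonormal 3x3 matrix.
#' @return list(theta, axis).
#' @export
rotationAngleAxis <- function(rot) {
  if (!isOrthonormal(rot, tol = 1e-6)) stopf("not a proper rotation matrix")
  ct <- (sum(diag(rot)) - 1) / 2
  ct <- min(1, max(-1, ct))
  theta <- acos(ct)
  if (theta < 1e-9) return(list(theta = 0, axis = c(1, 0, 0)))
  if (pi - theta > 1e-6) {
    ax <- c(rot[3, 2] - rot[2, 3], rot[1, 3] - rot[3, 1], rot[2, 1] - rot[1, 2])
    ax <- ax / (2 * sin(theta))
  } else {
    ## theta ~ 180: axis from the dominant column of (R + I) / 2
    M <- (rot + diag(3)) / 2
    j <- which.max(diag(M))
    ax <- M[, j] / sqrt(M[j, j])
  }
  ax <- ax / sqrt(sum(ax^2))
  ## the axis sign is free only at theta ~ 180 (R(u) = R(-u)); canonicalize
  ## there, keep the sign the sine term determines elsewhere
  if (pi - theta <= 1e-6) {
    nz <- which(abs(ax) > 1e-9)[1]
    if (ax[nz] < 0) ax <- -ax
  }
  list(theta = rad2deg(theta), axis = ax)
}

#' Axis/angle to rotation matrix
#'
#' @param axis 3-vector (normalized internally).
#' @param theta angle in degrees.
#' @return 3x3 rotation matrix.
#' @export
axisAngleRotation <- function(axis, theta) {
  u <- axis / sqrt(sum(axis^2))
  th <- deg2rad(theta)
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

## Rotation angle (degrees) between two rotation matrices.
rotationDistance <- function(R1, R2) {
  ct <- (sum(diag(crossprod(R1, R2))) - 1) / 2
  rad2deg(acos(min(1, max(-1, ct))))
}

#' Allowed origin moves of a space group
#'
#' The discrete fractional origin shifts plus the continuous (polar) axis
#' flags.  Shifting the origin by any returned move maps every operator of
#' the group onto an operator of the group.
#'
#' @param sg a [SpaceGroup-class].
#' @return list(shifts = n x 3 matrix, polar = logical(3)).
#' @export
allowedOriginMoves <- function(sg) {
  list(shifts = sg@originShifts, polar = sg@polarAxes)
}

## Exact bipartite matching (augmenting paths) on a logical compatibility
## matrix; returns TRUE when a perfect matching exists.
.perfectMatching <- function(compat) {
  n <- nrow(compat)
  if (n != ncol(compat)) return(FALSE)
  matchR <- rep(0L, n)
  tryRow <- function(i, seen) {
    for (j in which(compat[i, ])) {
      if (seen[j]) next
      seen[j] <- TRUE
      if (matchR[j] == 0L || Recall(matchR[j], seen)) {
        matchR[j] <<- i
        return(TRUE)
      }
    }
    FALSE
  }
  for (i in seq_len(n)) if (!tryRow(i, rep(FALSE, n))) return(FALSE)
  TRUE
}

#' Spatial equivalence of two solutions
#'
#' Two solutions are spatially equivalent when one global symmetry operator
#' plus an allowed origin move maps every placement of one onto a distinct
#' placement of the other within tolerance (lattice translations allowed).
#'
#' @param solA,solB [PartialSolution-class] objects in the same space group.
#' @param sg the [SpaceGroup-class].
#' @param cell the [UnitCell-class].
#' @param tolRot rotation tolerance in degrees (default 5).
#' @param tolTrans translation tolerance in Angstrom (default 2).
#' @return logical flag.
#' @export
spatiallyEquivalent <- function(solA, solB, sg, cell,
                                tolRot = 5, tolTrans = 2.0) {
  if (solA@sgSymbol != solB@sgSymbol)
    stopf("solutions live in different space groups (%s vs %s)",
          solA@sgSymbol, solB@sgSymbol)
  pa <- solA@placements; pb <- solB@placements
  if (length(pa) != length(pb)) return(FALSE)
  n <- length(pa)
  if (n == 0) return(TRUE)
  O <- orthogonalizationMatrix(cell)
  Oinv <- solve(O)
  polar <- sg@polarAxes
  shifts <- sg@originShifts

  testShift <- function(pbT, shiftCart) {
    compat <- matrix(FALSE, n, n)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (pa[[i]]@componentId != pbT[[j]]@componentId) next
      if (rotationDistance(pa[[i]]@rot, pbT[[j]]@rot) > tolRot) next
      d <- pa[[i]]@trans - (pbT[[j]]@trans + shiftCart)
      d <- as.vector(O %*% fracMin(as.vector(Oinv %*% d)))
      compat[i, j] <- sqrt(sum(d^2)) <= tolTrans
    }
    .perfectMatching(compat)
  }

  for (g in sg@ops) {
    co <- opToCartesian(g, cell)
    pbT <- lapply(pb, function(p)
      placement(p@componentId, p@modelId, co$A %*% p@rot,
                as.vector(co$A %*% p@trans) + co$b))
    for (si in seq_len(nrow(shifts))) {
      base <- as.vector(O %*% shifts[si, ])
      if (!any(polar)) {
        if (testShift(pbT, base)) return(TRUE)
      } else {
        ## solve the continuous components from each candidate anchor pairing
        for (i in seq_len(n)) {
          if (pa[[i]]@componentId != pbT[[1]]@componentId) next
          if (rotationDistance(pa[[i]]@rot, pbT[[1]]@rot) > tolRot) next
          df <- as.vector(Oinv %*% (pa[[i]]@trans - pbT[[1]]@trans)) - shifts[si, ]
          sfrac <- shifts[si, ]
          sfrac[polar] <- sfrac[polar] + df[polar]
          if (testShift(pbT, as.vector(O %*% sfrac))) return(TRUE)
        }
      }
    }
  }
  FALSE
}
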