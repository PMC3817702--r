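#' @import methods
NULL

#' Unit cell
#'
#' Cell edge lengths in Angstrom and angles in degrees.  The cell volume is
#' the quantity consumed by Matthews-coefficient composition estimation; the
#' orthogonalization matrix derived from the cell converts between fractional
#' and orthogonal coordinates throughout the package.
#'
#' @slot a,b,c edge lengths (Angstrom), all positive.
#' @slot alpha,beta,gamma angles (degrees), each in (0, 180).
#' @export
setClass("UnitCell",
  representation(a = "numeric", b = "numeric", c = "numeric",
                 alpha = "numeric", beta = "numeric", gamma = "numeric"),
  validity = function(object) {
    v <- c(object@a, object@b, object@c)
    ang <- c(object@alpha, object@beta, object@gamma)
    if (any(!is.finite(v)) || any(v <= 0)) return("cell lengths must be positive")
    if (any(!is.finite(ang)) || any(ang <= 0) || any(ang >= 180))
      return("cell angles must lie in (0, 180)")
    TRUE
  })

#' Construct a unit cell
#'
#' @param a,b,c edge lengths in Angstrom.
#' @param alpha,beta,gamma angles in degrees.
#' @return A [UnitCell-class] object.
#' @examples
#' unitCell(10, 10, 10)
#' @export
unitCell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90) {
  new("UnitCell", a = as.numeric(a), b = as.numeric(b), c = as.numeric(c),
      alpha = as.numeric(alpha), beta = as.numeric(beta), gamma = as.numeric(gamma))
}

#' Space group description
#'
#' Symmetry operators in the fractional basis, polar-axis flags, the discrete
#' origin shifts that conjugate the group onto itself, and the enantiomorph
#' partner where one exists.  Only the chiral catalogue built by
#' [buildSpaceGroup()] is supported.
#'
#' @slot symbol normalized Hermann-Mauguin symbol.
#' @slot ops list of operators, each a list with integer 3x3 `rot` and
#'   fractional `trans` in [0, 1).
#' @slot polarAxes logical(3): axes with continuous origin freedom.
#' @slot originShifts numeric matrix (n x 3) of discrete fractional shifts.
#' @slot enantiomorph partner symbol or `NA`.
#' @slot pointGroup point-group label.
#' @export
setClass("SpaceGroup",
  representation(symbol = "character", ops = "list", polarAxes = "logical",
                 originShifts = "matrix", enantiomorph = "character",
                 pointGroup = "character"),
  validity = function(object) {
    if (length(object@ops) < 1) return("operator list empty")
    idok <- any(vapply(object@ops, function(o)
      all(o$rot == diag(3)) && all(abs(o$trans) < 1e-12), logical(1)))
    if (!idok) return("identity operator missing")
    for (o in object@ops) {
      if (round(det(o$rot)) != 1) return("operators must be proper (det +1)")
      if (any(o$trans < -1e-12 | o$trans >= 1)) return("translations must lie in [0,1)")
    }
    if (length(object@polarAxes) != 3) return("polarAxes must be logical(3)")
    TRUE
  })

#' Rigid-body placement
#'
#' One copy of a search model (or ground-truth molecule) positioned in the
#' orthogonal Angstrom frame: coordinates map as `x -> rot %*% x + trans`.
#'
#' @slot componentId component the copy belongs to.
#' @slot modelId identifier of the model placed (or "truth").
#' @slot rot proper orthonormal 3x3 matrix.
#' @slot trans numeric(3) translation in Angstrom.
#' @export
setClass("Placement",
  representation(componentId = "character", modelId = "character",
                 rot = "matrix", trans = "numeric"),
  validity = function(object) {
    if (!isOrthonormal(object@rot)) return("rot must be proper orthonormal (det +1)")
    if (length(object@trans) != 3 || any(!is.finite(object@trans)))
      return("trans must be numeric(3)")
    TRUE
  })

#' @rdname Placement-class
#' @param componentId,modelId identifiers.
#' @param rot 3x3 proper rotation.
#' @param trans numeric(3), Angstrom.
#' @export
placement <- function(componentId, modelId, rot, trans) {
  new("Placement", componentId = as.character(componentId),
      modelId = as.character(modelId), rot = rot, trans = as.numeric(trans))
}

#' Search component
#'
#' A protein component of the asymmetric unit: sequence, stoichiometry and
#' the molecular weight that defines its scattering power.
#'
#' @slot componentId identifier.
#' @slot sequence one-letter amino-acid sequence (20 standard residues + X).
#' @slot stoichiometry copies per complex.
#' @slot mw molecular weight in Da (derived from the sequence).
#' @export
setClass("ComponentSpec",
  representation(componentId = "character", sequence = "character",
                 stoichiometry = "integer", mw = "numeric"),
  validity = function(object) {
    if (nchar(object@sequence) < 1) return("sequence must be non-empty")
    if (grepl(sprintf("[^%s]", paste(names(.RESIDUE_MASS), collapse = "")),
              object@sequence))
      return("sequence contains characters outside the 20 standard residues + X")
    if (object@stoichiometry < 1L) return("stoichiometry must be >= 1")
    if (object@mw <= 0) return("mw must be positive")
    TRUE
  })

#' @rdname ComponentSpec-class
#' @param componentId identifier.
#' @param sequence amino-acid string.
#' @param stoichiometry positive integer.
#' @export
componentSpec <- function(componentId, sequence, stoichiometry = 1L) {
  sequence <- toupper(gsub("\\s", "", sequence))
  new("ComponentSpec", componentId = as.character(componentId),
      sequence = sequence, stoichiometry = as.integer(stoichiometry),
      mw = molecularWeight(sequence))
}

#' Prepared search ensemble
#'
#' A ready search model: one or more superposed coordinate members on a common
#' target-sequence residue indexing, per-residue B values, sequence coverage,
#' scattering weight and the identity of the template it derives from.
#'
#' @slot modelId identifier.
#' @slot componentId target component.
#' @slot members list of N x 3 coordinate matrices (Angstrom), identical
#'   residue indexing across members.
#' @slot resIdx integer vector of 0-based target residue indices, one per row.
#' @slot bvals per-residue B values.
#' @slot coverage n x 2 matrix of half-open 0-based intervals [start, end).
#' @slot weight scattering weight in Da of the covered sequence.
#' @slot sourceTemplateId template identity (branch-reduction key).
#' @slot protocolId editing-protocol or variant label.
#' @export
setClass("EnsembleModel",
  representation(modelId = "character", componentId = "character",
                 members = "list", resIdx = "integer", bvals = "numeric",
                 coverage = "matrix", weight = "numeric",
                 sourceTemplateId = "character", protocolId = "character"),
  validity = function(object) {
    if (length(object@members) < 1) return("at least one member required")
    n <- nrow(object@members[[1]])
    for (m in object@members)
      if (!is.matrix(m) || ncol(m) != 3 || nrow(m) != n)
        return("members must be N x 3 matrices with identical N")
    if (length(object@resIdx) != n) return("resIdx length must match member rows")
    if (is.unsorted(object@resIdx, strictly = TRUE))
      return("resIdx must be strictly increasing")
    if (object@weight <= 0) return("weight must be positive")
    TRUE
  })

#' Partial molecular-replacement solution
#'
#' A set of rigid-body placements in one space group together with its score,
#' ancestry, per-placement translation-function Z-scores at placement time,
#' and pending association records (amalgamation partners, assembly
#' predictions) to be evaluated at the start of the next extension cycle.
#'
#' @slot solutionId,parentId identifiers ("" for the root).
#' @slot sgSymbol space group the solution lives in.
#' @slot placements list of [Placement-class].
#' @slot llg log-likelihood-gain analogue of the solution.
#' @slot tfzHistory TFZ recorded when each placement was added.
#' @slot status one of active, complete, rejected, merged.
#' @slot associations list of pending association records.
#' @export
setClass("PartialSolution",
  representation(solutionId = "character", parentId = "character",
                 sgSymbol = "character", placements = "list", llg = "numeric",
                 tfzHistory = "numeric", status = "character",
                 associations = "list"),
  prototype(placements = list(), llg = 0, tfzHistory = numeric(0),
            status = "active", associations = list()),
  validity = function(object) {
    if (!object@status %in% c("active", "complete", "rejected", "merged"))
      return("invalid status")
    if (length(object@tfzHistory) != length(object@placements))
      return("tfzHistory must have one entry per placement")
    TRUE
  })

#' Synthetic toy crystal
#'
#' The synthetic ground truth and scoring-backend state: cell, space group,
#' true rigid-body placements of the component clouds, the overlap width
#' sigma, the orientation tolerance sigmaRot, the score-noise level epsilon
#' and the generator seed.
#'
#' @slot cell [UnitCell-class].
#' @slot sg [SpaceGroup-class] the crystal was generated in.
#' @slot components named list of [ComponentSpec-class].
#' @slot clouds named list of reference Calpha coordinate matrices (rows =
#'   residues 0..L-1 of each component).
#' @slot truths list of [Placement-class] ground-truth copies.
#' @slot sigma positional overlap width (Angstrom, default 1.5).
#' @slot sigmaRot orientation overlap width (degrees, default 10).
#' @slot epsilon score-noise standard deviation as a fraction of the
#'   placement weight (default 0.02).
#' @slot seed generator seed.
#' @export
setClass("ToyCrystal",
  representation(cell = "UnitCell", sg = "SpaceGroup", components = "list",
                 clouds = "list", truths = "list", sigma = "numeric",
                 sigmaRot = "numeric", epsilon = "numeric", seed = "integer"),
  validity = function(object) {
    if (length(object@truths) < 1) return("at least one truth required")
    for (tr in object@truths)
      if (!tr@componentId %in% names(object@clouds))
        return("truth references unknown component cloud")
    if (object@sigma <= 0 || object@sigmaRot <= 0) return("sigma values must be positive")
    if (object@epsilon < 0) return("epsilon must be non-negative")
    TRUE
  })

#' Point-group assembly hypothesis
#'
#' A detected or user-supplied noncrystallographic point-group arrangement:
#' group label (Cn or Dn), rotation axis and center, the solution placements
#' participating, and the generator transforms.
#'
#' @slot groupLabel e.g. "C5" or "D2".
#' @slot axis unit 3-vector (canonical sign).
#' @slot center point on the axis (Angstrom).
#' @slot memberIndices placement indices participating.
#' @slot generators list of affine transforms (list(rot, trans)).
#' @slot source "detected" or "user".
#' @export
setClass("AssemblyHypothesis",
  representation(groupLabel = "character", axis = "numeric", center = "numeric",
                 memberIndices = "integer", generators = "list",
                 source = "character"),
  validity = function(object) {
    if (abs(sqrt(sum(object@axis^2)) - 1) > 1e-6) return("axis must be unit length")
    if (!object@source %in% c("detected", "user")) return("source must be detected/user")
    TRUE
  })

#' Engine configuration
#'
#' Tunable parameters of the search controller.  Fractions are the pruning
#' percentages of the thresholding rules; `tfzClear` is the
#' translation-function Z-score above which a packing solution is categorized
#' as clear.
#'
#' @slot mode "full" or "quick".
#' @slot tfzClear clear-solution TFZ threshold (default 7).
#' @slot selectFraction,purgeFraction,sgFraction pruning fractions in (0,1).
#' @slot maxActiveBranches cap on active partials per space group.
#' @slot templateEquivalence collapse branches sharing a template.
#' @slot assemblySearchModels use detected assemblies as composite models.
#' @slot seed run seed.
#' @slot workers executor worker count.
#' @slot poolThreshold fast-job pooling batch size.
#' @slot gridStep translation-search grid step (Angstrom).
#' @slot rotStep rotation-search grid step (degrees).
#' @slot nKeep orientations kept per rotation search.
#' @slot tolRot,tolTrans spatial-equivalence tolerances (degrees, Angstrom).
#' @slot refine run rigid-body refinement on selected peaks (default TRUE;
#'   disabling reproduces raw grid-resolution scores).
#' @export
setClass("EngineConfig",
  representation(mode = "character", tfzClear = "numeric",
                 selectFraction = "numeric", purgeFraction = "numeric",
                 sgFraction = "numeric", maxActiveBranches = "integer",
                 templateEquivalence = "logical", assemblySearchModels = "logical",
                 seed = "integer", workers = "integer", poolThreshold = "integer",
                 gridStep = "numeric", rotStep = "numeric", nKeep = "integer",
                 tolRot = "numeric", tolTrans = "numeric",
                 refine = "logical"),
  prototype(mode = "full", tfzClear = 7.0, selectFraction = 0.25,
            purgeFraction = 0.25, sgFraction = 0.25, maxActiveBranches = 25L,
            templateEquivalence = TRUE, assemblySearchModels = FALSE,
            seed = 1L, workers = 1L, poolThreshold = 20L, gridStep = 2.0,
            rotStep = 15, nKeep = 5L, tolRot = 5, tolTrans = 2.0,
            refine = TRUE),
  validity = function(object) {
    fr <- c(object@selectFraction, object@purgeFraction, object@sgFraction)
    if (any(fr <= 0 | fr >= 1)) return("fractions must lie in (0,1)")
    if (object@tfzClear <= 0 || object@gridStep <= 0 || object@rotStep <= 0)
      return("thresholds must be positive")
    if (!object@mode %in% c("full", "quick")) return("mode must be full/quick")
    TRUE
  })

#' @rdname EngineConfig-class
#' @param ... slot values overriding the defaults.
#' @export
engineConfig <- function(...) {
  args <- list(...)
  for (nm in c("maxActiveBranches", "seed", "workers", "poolThreshold", "nKeep"))
    if (!is.null(args[[nm]])) args[[nm]] <- as.integer(args[[nm]])
  do.call(new, c(list("EngineConfig"), args))
}

#' Solution archive
#'
#' Every solution ever scored during a run, with ancestry, scores and status,
#' plus the detected assemblies, the job ledger and a header snapshot of the
#' configuration.  Serialized as line-delimited JSON by [writeArchive()].
#'
#' @slot header list: format version, config snapshot, seed, registries.
#' @slot records list of solution records.
#' @slot assemblies list of assembly records.
#' @slot ledger named integer vector of job counts.
#' @export
setClass("SolutionArchive",
  representation(header = "list", records = "list", assemblies = "list",
                 ledger = "numeric"),
  prototype(header = list(), records = list(), assemblies = list(),
            ledger = numeric(0)))

## ---- show methods -------------------------------------------------------

setMethod("show", "UnitCell", function(object) {
  cat(sprintf("UnitCell  %.2f %.2f %.2f A  %.1f %.1f %.1f deg  V = %.0f A^3\n",
              object@a, object@b, object@c, object@alpha, object@beta,
              object@gamma, cellVolume(object)))
})

setMethod("show", "SpaceGroup", function(object) {
  cat(sprintf("SpaceGroup %s  (%d ops, point group %s)\n", object@symbol,
              length(object@ops), object@pointGroup))
  cat(sprintf("  polar axes: %s;  discrete origin shifts: %d;  enantiomorph: %s\n",
              paste(c("a", "b", "c")[object@polarAxes], collapse = " ") |>
                (\(x) if (nzchar(x)) x else "none")(),
              nrow(object@originShifts),
              if (is.na(object@enantiomorph)) "none" else object@enantiomorph))
})

setMethod("show", "Placement", function(object) {
  aa <- rotationAngleAxis(object@rot)
  cat(sprintf("Placement %s/%s  rot %.1f deg about (%.2f %.2f %.2f)  t = (%.2f %.2f %.2f) A\n",
              object@componentId, object@modelId, aa$theta, aa$axis[1],
              aa$axis[2], aa$axis[3], object@trans[1], object@trans[2],
              object@trans[3]))
})

setMethod("show", "EnsembleModel", function(object) {
  cat(sprintf("EnsembleModel %s (component %s): %d member(s), %d residues, %.0f Da, template %s, protocol %s\n",
              object@modelId, object@componentId, length(object@members),
              length(object@resIdx), object@weight, object@sourceTemplateId,
              object@protocolId))
})

setMethod("show", "PartialSolution", function(object) {
  cat(sprintf("PartialSolution %s [%s] in %s: %d placement(s), LLG %.2f\n",
              object@solutionId, object@status, object@sgSymbol,
              length(object@placements), object@llg))
})

setMethod("show", "ToyCrystal", function(object) {
  cat(sprintf("ToyCrystal in %s, %d truth placement(s), sigma %.2f A, sigmaRot %.1f deg, epsilon %.3f\n",
              object@sg@symbol, length(object@truths), object@sigma,
              object@sigmaRot, object@epsilon))
  show(object@cell)
})

setMethod("show", "AssemblyHypothesis", function(object) {
  cat(sprintf("AssemblyHypothesis %s (%s): %d member(s), axis (%.2f %.2f %.2f)\n",
              object@groupLabel, object@source, length(object@memberIndices),
              object@axis[1], object@axis[2], object@axis[3]))
})

setMethod("show", "SolutionArchive", function(object) {
  cat(sprintf("SolutionArchive: %d solution record(s), %d assembly record(s)\n",
              length(object@records), length(object@assemblies)))
  if (length(object@ledger))
    cat("  ledger:", paste(names(object@ledger), object@ledger,
                           sep = "=", collapse = " "), "\n")
})

## ---- accessors ----------------------------------------------------------

#' @rdname accessors
#' @param object an MRsearch object.
#' @export
setGeneric("spaceGroupSymbol", function(object) standardGeneric("spaceGroupSymbol"))
#' @rdname accessors
#' @export
setMethod("spaceGroupSymbol", "SpaceGroup", function(object) object@symbol)
#' @rdname accessors
#' @export
setMethod("spaceGroupSymbol", "PartialSolution", function(object) object@sgSymbol)
#' @rdname accessors
#' @export
setMethod("spaceGroupSymbol", "ToyCrystal", function(object) object@sg@symbol)

#' Accessors for MRsearch classes
#'
#' Small read-only accessors; slots are implementation detail.
#' @name accessors
#' @param object an MRsearch object.
#' @return the requested component.
NULL

#' @rdname accessors
#' @export
setGeneric("symOps", function(object) standardGeneric("symOps"))
#' @rdname accessors
#' @export
setMethod("symOps", "SpaceGroup", function(object) object@ops)

#' @rdname accessors
#' @export
setGeneric("polarAxes", function(object) standardGeneric("polarAxes"))
#' @rdname accessors
#' @export
setMethod("polarAxes", "SpaceGroup", function(object) object@polarAxes)

#' @rdname accessors
#' @export
setGeneric("originShifts", function(object) standardGeneric("originShifts"))
#' @rdname accessors
#' @export
setMethod("originShifts", "SpaceGroup", function(object) object@originShifts)

#' @rdname accessors
#' @export
setGeneric("placements", function(object) standardGeneric("placements"))
#' @rdname accessors
#' @export
setMethod("placements", "PartialSolution", function(object) object@placements)

#' @rdname accessors
#' @export
setGeneric("solutionScore", function(object) standardGeneric("solutionScore"))
#' @rdname accessors
#' @export
setMethod("solutionScore", "PartialSolution", function(object) object@llg)

#' @rdname accessors
#' @export
setGeneric("coverage", function(object) standardGeneric("coverage"))
#' @rdname accessors
#' @export
setMethod("coverage", "EnsembleModel", function(object) object@coverage)

#' @rdname accessors
#' @export
setGeneric("modelWeight", function(object) standardGeneric("modelWeight"))
#' @rdname accessors
#' @export
setMethod("modelWeight", "EnsembleModel", function(object) object@weight)

#' @rdname accessors
#' @export
setGeneric("truthPlacements", function(object) standardGeneric("truthPlacements"))
#' @rdname accessors
#' @export
setMethod("truthPlacements", "ToyCrystal", function(object) object@truths)

#' @rdname accessors
#' @export
setGeneric("jobLedger", function(object) standardGeneric("jobLedger"))
#' @rdname accessors
#' @export
setMethod("jobLedger", "SolutionArchive", function(object) object@ledger)
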