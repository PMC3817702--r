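# Sequence bookkeeping: FASTA parsing, alignment coverage, scattering
# weight, Matthews-based ASU content estimation and model admissibility.

## Monoisotopic-free average residue masses (Da) of the 20 standard amino
## acids; X counts as the average residue (110.0).  A free molecule adds one
## water (18.02).
.RESIDUE_MASS <- c(
  A = 71.08, R = 156.19, N = 114.10, D = 115.09, C = 103.14,
  E = 129.12, Q = 128.13, G = 57.05,  H = 137.14, I = 113.16,
  L = 113.16, K = 128.17, M = 131.19, F = 147.18, P = 97.12,
  S = 87.08,  T = 101.10, W = 186.21, Y = 163.18, V = 99.13,
  X = 110.00)

.WATER_MASS <- 18.02

#' Parse FASTA sequences
#'
#' Reads amino-acid FASTA from a file path or literal text (auto-detected on
#' the presence of a leading ">").  Sequences are upper-cased with whitespace
#' stripped; records are returned in file order.
#'
#' @param input path to a FASTA file, or FASTA text.
#' @return list of `list(id, sequence)` in file order.
#' @examples
#' parseFasta(">a\nGG\n")
#' @export
parseFasta <- function(input) {
  if (length(input) == 1 && !startsWith(trimws(input)[1], ">") &&
      file.exists(input)) {
    path <- input
  } else {
    path <- tempfile(fileext = ".fasta")
    on.exit(unlink(path))
    writeLines(input, path)
  }
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stopf("FASTA parse failure: %s",
                                            conditionMessage(e)))
  if (length(set) == 0) stopf("empty FASTA input")
  ids <- sub("\\s.*$", "", names(set))
  seqs <- toupper(gsub("\\s", "", as.character(set)))
  for (i in seq_along(seqs))
    if (!nzchar(seqs[i])) stopf("empty sequence for FASTA record '%s'", ids[i])
  unname(Map(function(id, s) list(id = id, sequence = s), ids, seqs))
}

#' Molecular weight of a protein sequence
#'
#' Sum of standard average residue masses plus one water; X counts as the
#' average residue mass (110.0 Da).
#'
#' @param sequence one-letter amino-acid string.
#' @return weight in Da.
#' @examples
#' molecularWeight("GG")
#' @export
molecularWeight <- function(sequence) {
  sequence <- toupper(gsub("\\s", "", sequence))
  if (nchar(sequence) < 1) stopf("empty sequence")
  aa <- strsplit(sequence, "")[[1]]
  bad <- setdiff(unique(aa), names(.RESIDUE_MASS))
  if (length(bad)) stopf("invalid residue character(s): %s",
                         paste(bad, collapse = ", "))
  sum(.RESIDUE_MASS[aa]) + .WATER_MASS
}

#' Pairwise alignment
#'
#' Builds an alignment-pair record from two aligned sequences of equal
#' length (aligned FASTA convention, "-" gaps): the strictly increasing
#' (target, model) column pairs and the identity over aligned columns.
#'
#' @param targetAligned,modelAligned gapped aligned sequences, equal length.
#' @param targetId,modelId identifiers.
#' @return list(targetId, modelId, columns = n x 2 zero-based matrix,
#'   identity).
#' @export
alignmentPair <- function(targetAligned, modelAligned,
                          targetId = "target", modelId = "model") {
  ta <- strsplit(toupper(targetAligned), "")[[1]]
  ma <- strsplit(toupper(modelAligned), "")[[1]]
  if (length(ta) != length(ma))
    stopf("aligned sequences differ in length (%d vs %d)", length(ta), length(ma))
  ti <- cumsum(ta != "-") - 1L
  mi <- cumsum(ma != "-") - 1L
  keep <- ta != "-" & ma != "-"
  cols <- cbind(target = ti[keep], model = mi[keep])
  matches <- ta[keep] == ma[keep]
  ident <- if (any(keep)) mean(matches) else 0
  list(targetId = targetId, modelId = modelId,
       columns = cols, identity = ident, matches = matches)
}

#' Read a pairwise aligned-FASTA file
#'
#' Two records of equal aligned length: target first, model second.
#'
#' @param path aligned FASTA file or text.
#' @return an alignment pair as from [alignmentPair()].
#' @export
readAlignmentPair <- function(path) {
  recs <- parseFasta(path)
  if (length(recs) != 2)
    stopf("pairwise alignment must contain exactly 2 records (got %d)",
          length(recs))
  alignmentPair(recs[[1]]$sequence, recs[[2]]$sequence,
                recs[[1]]$id, recs[[2]]$id)
}

#' Sequence coverage from an alignment
#'
#' Merges runs of consecutive aligned target indices into half-open 0-based
#' intervals; interior gaps of up to `bridge` target residues are bridged.
#'
#' @param al alignment pair (see [alignmentPair()]).
#' @param targetLength length of the target sequence.
#' @param bridge maximum interior gap bridged (default 2).
#' @return n x 2 matrix of half-open [start, end) intervals.
#' @export
coverageFromAlignment <- function(al, targetLength, bridge = 2L) {
  idx <- sort(unique(al$columns[, 1]))
  if (length(idx) == 0) return(matrix(integer(0), 0, 2))
  if (any(idx < 0) || any(idx >= targetLength))
    stopf("alignment target index out of bounds (length %d)", targetLength)
  brk <- which(diff(idx) > bridge + 1L)
  starts <- idx[c(1L, brk + 1L)]
  ends <- idx[c(brk, length(idx))] + 1L
  cbind(start = starts, end = ends)
}

## interval utilities: sets are n x 2 half-open matrices
.ivNorm <- function(iv) {
  if (nrow(iv) == 0) return(iv)
  iv <- iv[order(iv[, 1]), , drop = FALSE]
  out <- iv[1, , drop = FALSE]
  for (i in seq_len(nrow(iv))[-1]) {
    if (iv[i, 1] <= out[nrow(out), 2]) {
      out[nrow(out), 2] <- max(out[nrow(out), 2], iv[i, 2])
    } else out <- rbind(out, iv[i, ])
  }
  out
}

.ivLength <- function(iv) if (nrow(iv) == 0) 0L else sum(iv[, 2] - iv[, 1])

.ivSubtract <- function(a, b) {
  ## residues in a not in b
  a <- .ivNorm(a); b <- .ivNorm(b)
  out <- matrix(integer(0), 0, 2)
  for (i in seq_len(nrow(a))) {
    s <- a[i, 1]; e <- a[i, 2]
    cur <- s
    for (j in seq_len(nrow(b))) {
      bs <- b[j, 1]; be <- b[j, 2]
      if (be <= cur || bs >= e) next
      if (bs > cur) out <- rbind(out, c(cur, bs))
      cur <- max(cur, be)
    }
    if (cur < e) out <- rbind(out, c(cur, e))
  }
  colnames(out) <- c("start", "end")
  out
}

.ivIntersectLength <- function(a, b) {
  a <- .ivNorm(a); b <- .ivNorm(b)
  tot <- 0L
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    tot <- tot + max(0L, min(a[i, 2], b[j, 2]) - max(a[i, 1], b[j, 1]))
  }
  tot
}

#' Matthews-coefficient composition selection
#'
#' Computes the Matthews coefficient V_M(Z) = V_cell / (n_ops * Z * sum(MW *
#' stoichiometry)) for increasing complex counts Z and selects the Z whose
#' implied solvent fraction (1 - 1.23 / V_M) is most plausible under a
#' Gaussian centred at `centre` with standard deviation `sd`.
#'
#' @param cell a [UnitCell-class].
#' @param sg a [SpaceGroup-class] (its operator count enters V_M).
#' @param components list of [ComponentSpec-class].
#' @param centre,sd plausibility Gaussian on solvent fraction (0.50, 0.12).
#' @return list(nComplexes, copies, solventFraction, vm, candidates) where
#'   candidates tabulates every Z up to the first with solvent < 0.20.
#' @export
matthewsSelect <- function(cell, sg, components, centre = 0.50, sd = 0.12) {
  if (length(components) < 1) stopf("at least one component required")
  mwAsu <- sum(vapply(components, function(cs) cs@mw * cs@stoichiometry,
                      numeric(1)))
  v <- cellVolume(cell)
  nops <- length(sg@ops)
  rows <- list()
  z <- 0L
  repeat {
    z <- z + 1L
    vm <- v / (nops * z * mwAsu)
    solv <- 1 - 1.23 / vm
    plaus <- stats::dnorm(solv, centre, sd) / stats::dnorm(0, 0, sd)
    rows[[z]] <- c(z = z, vm = vm, solvent = solv, plausibility = plaus)
    if (solv < 0.20 || z > 60L) break
  }
  cand <- do.call(rbind, rows)
  ok <- cand[, "solvent"] > 0.20
  if (!any(ok))
    stopf("cell too small: no complex count gives solvent fraction > 0.20")
  best <- cand[ok, , drop = FALSE]
  zSel <- as.integer(best[which.max(best[, "plausibility"]), "z"])
  vmSel <- cand[zSel, "vm"]
  copies <- vapply(components, function(cs) cs@stoichiometry * zSel, integer(1))
  names(copies) <- vapply(components, function(cs) cs@componentId, character(1))
  list(nComplexes = zSel, copies = copies,
       solventFraction = unname(cand[zSel, "solvent"]), vm = unname(vmSel),
       candidates = cand)
}

#' Missing composition of a partial solution
#'
#' Compares the placed models (via their recorded coverage) with the defined
#' asymmetric-unit contents: per component, the remaining copy count and the
#' uncovered intervals of every remaining copy.  Partially covered copies
#' (placed domain models) report their uncovered residue intervals.
#'
#' @param partial a [PartialSolution-class].
#' @param asu contents from [matthewsSelect()] (or a compatible list).
#' @param components named list of [ComponentSpec-class].
#' @param models named list of [EnsembleModel-class] resolving the placed
#'   model ids to coverage.
#' @return named list per component: list(remaining, copies = list of
#'   uncovered interval matrices, one per remaining copy).
#' @export
missingComposition <- function(partial, asu, components, models) {
  out <- list()
  for (cid in names(asu$copies)) {
    L <- nchar(components[[cid]]@sequence)
    total <- asu$copies[[cid]]
    placed <- Filter(function(p) p@componentId == cid, partial@placements)
    covs <- lapply(placed, function(p) {
      if (p@modelId %in% names(models)) {
        models[[p@modelId]]@coverage
      } else if (identical(p@modelId, "truth")) {
        cbind(0L, L)
      } else stopf("placement references unknown model '%s'", p@modelId)
    })
    full <- cbind(0L, L)
    ## assign placed models to copies greedily: each full-ish model fills one
    ## copy; domain models stack on the same copy while disjoint
    copyCov <- list()
    for (cv in covs) {
      placedInto <- FALSE
      for (k in seq_along(copyCov)) {
        if (.ivIntersectLength(copyCov[[k]], cv) == 0L) {
          copyCov[[k]] <- .ivNorm(rbind(copyCov[[k]], cv))
          placedInto <- TRUE
          break
        }
      }
      if (!placedInto) copyCov[[length(copyCov) + 1L]] <- .ivNorm(cv)
    }
    if (length(copyCov) > total)
      copyCov <- copyCov[seq_len(total)]  # over-placed: clamp at contents
    rem <- list()
    for (k in seq_along(copyCov)) {
      unc <- .ivSubtract(full, copyCov[[k]])
      if (nrow(unc) > 0) rem[[length(rem) + 1L]] <- unc
    }
    nEmpty <- total - length(copyCov)
    if (nEmpty > 0) for (k in seq_len(nEmpty)) rem[[length(rem) + 1L]] <- full
    out[[cid]] <- list(remaining = length(rem), copies = rem)
  }
  out
}

#' Is a composition complete?
#'
#' @param missing result of [missingComposition()].
#' @return TRUE when nothing remains to place.
#' @export
compositionComplete <- function(missing) {
  all(vapply(missing, function(m) m$remaining == 0L, logical(1)))
}

#' Model admissibility against missing composition
#'
#' A model is admissible when some remaining copy's uncovered intervals
#' contain the model's coverage up to an overlap tolerance of
#' `overlapTol` of the model's covered length.
#'
#' @param model an [EnsembleModel-class].
#' @param missing result of [missingComposition()].
#' @param overlapTol tolerated covered-overlap fraction (default 0.10).
#' @return logical flag.
#' @export
modelAdmissible <- function(model, missing, overlapTol = 0.10) {
  m <- missing[[model@componentId]]
  if (is.null(m) || m$remaining == 0L) return(FALSE)
  covLen <- .ivLength(model@coverage)
  for (unc in m$copies) {
    inside <- .ivIntersectLength(model@coverage, unc)
    if (covLen - inside <= overlapTol * covLen) return(TRUE)
  }
  FALSE
}
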