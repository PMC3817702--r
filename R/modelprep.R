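# Model preparation: template editing protocols (pruning + B-value
# schemes), collection superposition/trimming into ensembles, and
# priority-ordered expansion of heterogeneous model inputs.

#' Model input at one stage of the preparation hierarchy
#'
#' @param stage one of ensemble, collection, template, homology_hit,
#'   sequence_only.
#' @param coords N x 3 Calpha matrix (model-local indexing) or, for
#'   collections, via `members`.
#' @param resIdx 0-based residue indices per row.
#' @param bvals per-residue B values (default 20).
#' @param alignment alignment pair onto the target (templates/hits).
#' @param identity sequence identity of a homology hit.
#' @param sourceTemplateId template identity label.
#' @param members for collection stage: list of coordinate sets.
#' @return a model-input record (plain list).
#' @export
modelInput <- function(stage, coords = NULL, resIdx = NULL, bvals = NULL,
                       alignment = NULL, identity = NA_real_,
                       sourceTemplateId = NULL, members = NULL) {
  stage <- match.arg(stage, c("ensemble", "collection", "template",
                              "homology_hit", "sequence_only"))
  if (stage %in% c("template", "homology_hit") && is.null(alignment))
    stopf("%s input requires an alignment", stage)
  if (!is.null(coords) && is.null(bvals)) bvals <- rep(20, nrow(coords))
  list(stage = stage, coords = coords, resIdx = resIdx, bvals = bvals,
       alignment = alignment, identity = identity,
       sourceTemplateId = sourceTemplateId %||% "tmpl", members = members)
}

#' Template-editing protocols
#'
#' The finite protocol grid: pruning mode (none / unaligned /
#' unaligned_plus_lowid) crossed with B-value scheme (asis / constant /
#' similarity), reduced to six named combinations.
#'
#' @return named list of protocols (protocolId, pruneMode, bScheme).
#' @export
defaultProtocols <- function() {
  mk <- function(id, prune, b) list(protocolId = id, pruneMode = prune, bScheme = b)
  list(
    p1_asis        = mk("p1_asis",        "none",                 "asis"),
    p2_prune       = mk("p2_prune",       "unaligned",            "asis"),
    p3_prune_bconst = mk("p3_prune_bconst", "unaligned",          "constant"),
    p4_prune_bsim  = mk("p4_prune_bsim",  "unaligned",            "similarity"),
    p5_lowid_bconst = mk("p5_lowid_bconst", "unaligned_plus_lowid", "constant"),
    p6_lowid_bsim  = mk("p6_lowid_bsim",  "unaligned_plus_lowid", "similarity")
  )
}

## Windowed identity over aligned columns: fraction of identical pairs in a
## `win`-column window centred on each column.
.windowIdentity <- function(matches, win = 9L) {
  n <- length(matches)
  half <- win %/% 2L
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    mean(matches[lo:hi])
  }, numeric(1))
}

#' Edit a template into a search ensemble
#'
#' Applies a pruning/B-value protocol to a template with its target
#' alignment: unaligned residues are deleted (pruning modes), low-identity
#' windows (9 columns, identity < 0.2) are additionally deleted in the
#' strictest mode, B values are rewritten per the scheme (constant: B = 20;
#' similarity: B = 20 + 60 * (1 - window identity)), and residues are
#' renumbered to target indexing.
#'
#' @param tmpl model input of stage template or homology_hit.
#' @param al alignment pair (target, model); defaults to the input's.
#' @param proto a protocol from [defaultProtocols()].
#' @param targetSeq target sequence (for coverage weight).
#' @param modelId,componentId identifiers for the resulting ensemble.
#' @return an [EnsembleModel-class].
#' @export
editTemplate <- function(tmpl, al = tmpl$alignment, proto, targetSeq,
                         modelId = "model", componentId = "comp") {
  if (is.null(al)) stopf("alignment required for template editing")
  cols <- al$columns
  modelRows <- match(cols[, 2], tmpl$resIdx)
  keep <- !is.na(modelRows)
  cols <- cols[keep, , drop = FALSE]
  modelRows <- modelRows[keep]
  matches <- if (!is.null(al$matches)) al$matches[keep] else rep(TRUE, nrow(cols))
  wid <- .windowIdentity(matches)

  if (proto$pruneMode == "none") {
    ## keep all model residues; aligned ones renumber to target indexing,
    ## unaligned ones are dropped from coverage accounting but kept only if
    ## they can carry a target index -- without one they cannot enter the
    ## target frame, so pruning is effectively applied to them regardless
    selected <- seq_len(nrow(cols))
  } else if (proto$pruneMode == "unaligned") {
    selected <- seq_len(nrow(cols))
  } else {
    selected <- which(wid >= 0.2)
  }
  if (length(selected) == 0) stopf("model vanished: no residues left after pruning")

  rows <- modelRows[selected]
  tIdx <- cols[selected, 1]
  ord <- order(tIdx)
  rows <- rows[ord]; tIdx <- tIdx[ord]
  widSel <- wid[selected][ord]
  coords <- tmpl$coords[rows, , drop = FALSE]
  b <- switch(proto$bScheme,
    asis = tmpl$bvals[rows],
    constant = rep(20, length(rows)),
    similarity = 20 + 60 * (1 - widSel))
  cov <- coverageFromAlignment(list(columns = cbind(tIdx, tIdx)),
                               nchar(targetSeq))
  new("EnsembleModel", modelId = modelId, componentId = componentId,
      members = list(coords), resIdx = as.integer(tIdx), bvals = b,
      coverage = cov, weight = .coverageWeight(cov, targetSeq),
      sourceTemplateId = tmpl$sourceTemplateId, protocolId = proto$protocolId)
}

.coverageWeight <- function(cov, targetSeq) {
  if (nrow(cov) == 0) return(0)
  aa <- strsplit(toupper(targetSeq), "")[[1]]
  idx <- unlist(lapply(seq_len(nrow(cov)), function(i) (cov[i, 1] + 1):cov[i, 2]))
  sum(.RESIDUE_MASS[aa[idx]], na.rm = TRUE)
}

#' Superpose a model collection into an ensemble
#'
#' Members beyond the first are Kabsch-superposed onto the first on their
#' common residues; residues whose inter-member spread (maximum pairwise
#' distance) exceeds `trimThreshold` are removed and the superposition is
#' repeated until stable (at most 10 rounds).
#'
#' @param collection list of coordinate sets (coords, resIdx, bvals).
#' @param trimThreshold spread cutoff in Angstrom (default 2.5).
#' @param targetSeq target sequence for the coverage weight.
#' @param modelId,componentId,sourceTemplateId identifiers.
#' @return an [EnsembleModel-class].
#' @export
buildEnsemble <- function(collection, trimThreshold = 2.5, targetSeq,
                          modelId = "ens", componentId = "comp",
                          sourceTemplateId = "tmpl") {
  stopifnot(length(collection) >= 1)
  common <- Reduce(intersect, lapply(collection, function(m) m$resIdx))
  for (round in seq_len(10L)) {
    if (length(common) < 3) stopf("fewer than 3 common residues in collection")
    ref <- collection[[1]]
    refRows <- match(common, ref$resIdx)
    aligned <- list(ref$coords[refRows, , drop = FALSE])
    if (length(collection) > 1) {
      for (k in 2:length(collection)) {
        m <- collection[[k]]
        rows <- match(common, m$resIdx)
        fit <- kabschSuperpose(ref$coords[refRows, , drop = FALSE],
                               m$coords[rows, , drop = FALSE])
        aligned[[k]] <- m$coords[rows, , drop = FALSE] %*% t(fit$rot) +
          matrix(fit$trans, length(common), 3, byrow = TRUE)
      }
    }
    ## per-residue spread: max pairwise member distance
    spread <- rep(0, length(common))
    if (length(aligned) > 1) {
      for (i in seq_along(aligned)) for (j in seq_along(aligned)) {
        if (j <= i) next
        d <- sqrt(rowSums((aligned[[i]] - aligned[[j]])^2))
        spread <- pmax(spread, d)
      }
    }
    bad <- spread > trimThreshold
    if (!any(bad)) {
      cov <- coverageFromAlignment(list(columns = cbind(common, common)),
                                   nchar(targetSeq))
      b <- rep(20, length(common))
      return(new("EnsembleModel", modelId = modelId, componentId = componentId,
                 members = aligned, resIdx = as.integer(common), bvals = b,
                 coverage = cov, weight = .coverageWeight(cov, targetSeq),
                 sourceTemplateId = sourceTemplateId, protocolId = "ensemble"))
    }
    common <- common[!bad]
  }
  stopf("ensemble trimming failed to stabilize within 10 rounds")
}

#' Expand model inputs into priority-ordered search ensembles
#'
#' Ready ensembles come first, then collections, then templates and homology
#' hits (each expanded into one ensemble per protocol).  Homology hits are
#' ordered by descending identity; within one template the protocol variants
#' are shuffled with the seeded generator.  Sequence-only inputs contribute
#' no models.
#'
#' @param spec the target [ComponentSpec-class].
#' @param inputs list of model inputs (see [modelInput()]).
#' @param protocols protocol list (default [defaultProtocols()]).
#' @param seed shuffle seed.
#' @return list of [EnsembleModel-class] in priority order.
#' @export
expandToEnsembles <- function(spec, inputs, protocols = defaultProtocols(),
                              seed = 1L) {
  targetSeq <- spec@sequence
  cid <- spec@componentId
  ready <- list(); colls <- list(); tmpls <- list()
  for (inp in inputs) {
    switch(inp$stage,
      ensemble = { ready[[length(ready) + 1L]] <- inp },
      collection = { colls[[length(colls) + 1L]] <- inp },
      template = ,
      homology_hit = { tmpls[[length(tmpls) + 1L]] <- inp },
      sequence_only = NULL)
  }
  out <- list()
  k <- 0L
  for (inp in ready) {
    k <- k + 1L
    cov <- coverageFromAlignment(list(columns = cbind(inp$resIdx, inp$resIdx)),
                                 nchar(targetSeq))
    mem <- inp$members %||% list(inp$coords)
    out[[length(out) + 1L]] <- new("EnsembleModel",
      modelId = sprintf("%s_ready_%d", cid, k), componentId = cid,
      members = mem, resIdx = as.integer(inp$resIdx),
      bvals = inp$bvals %||% rep(20, length(inp$resIdx)), coverage = cov,
      weight = .coverageWeight(cov, targetSeq),
      sourceTemplateId = inp$sourceTemplateId, protocolId = "ready")
  }
  for (inp in colls) {
    k <- k + 1L
    out[[length(out) + 1L]] <- buildEnsemble(inp$members, targetSeq = targetSeq,
      modelId = sprintf("%s_coll_%d", cid, k), componentId = cid,
      sourceTemplateId = inp$sourceTemplateId)
  }
  ## templates keep input order; hits sort by descending identity after them
  isHit <- vapply(tmpls, function(x) x$stage == "homology_hit", logical(1))
  hitOrd <- order(-vapply(tmpls[isHit], function(x) x$identity %||% 0, numeric(1)))
  tmpls <- c(tmpls[!isHit], tmpls[isHit][hitOrd])
  for (inp in tmpls) {
    k <- k + 1L
    ord <- withSeed(deriveSeed(seed, paste0("protocols:", cid, ":", k)),
                    sample.int(length(protocols)))
    for (pi in ord) {
      proto <- protocols[[pi]]
      em <- tryCatch(
        editTemplate(inp, proto = proto, targetSeq = targetSeq,
                     modelId = sprintf("%s_t%d_%s", cid, k, proto$protocolId),
                     componentId = cid),
        error = function(e) NULL)
      if (!is.null(em)) out[[length(out) + 1L]] <- em
    }
  }
  out
}

#' Read a homology-hit table
#'
#' Tab-separated columns: hit_id, template_pdb_path, alignment_path,
#' identity.  Paths are resolved relative to the table's directory.
#'
#' @param path TSV file.
#' @return list of model inputs of stage homology_hit.
#' @export
readHitTable <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  need <- c("hit_id", "template_pdb_path", "alignment_path", "identity")
  if (!all(need %in% names(tab)))
    stopf("hit table must have columns: %s", paste(need, collapse = ", "))
  base <- dirname(path)
  resolve <- function(p) if (file.exists(p)) p else file.path(base, p)
  lapply(seq_len(nrow(tab)), function(i) {
    cs <- readCoordSet(resolve(tab$template_pdb_path[i]))
    al <- readAlignmentPair(resolve(tab$alignment_path[i]))
    modelInput("homology_hit", coords = cs$coords, resIdx = cs$resIdx,
               bvals = cs$bvals, alignment = al,
               identity = as.numeric(tab$identity[i]),
               sourceTemplateId = tab$hit_id[i])
  })
}
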