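# The blackboard search controller: extension cycles, peak categorization,
# thresholded selection and propagation, quick/full strategies,
# alternative-model rescoring, branch reduction, space-group arbitration,
# output selection and dry-run enumeration.

## ---- job ledger ---------------------------------------------------------

.LEDGER_KINDS <- c("rotation_search", "translation_search", "packing",
                   "rescore_by_superposition", "prediction_score", "refine")

.newLedger <- function() {
  e <- new.env(parent = emptyenv())
  e$counts <- stats::setNames(rep(0, length(.LEDGER_KINDS)), .LEDGER_KINDS)
  e$history <- list()
  e
}

.ledgerAdd <- function(ledger, kind, n = 1) {
  if (is.null(ledger)) return(invisible(NULL))
  ledger$counts[kind] <- ledger$counts[kind] + n
  invisible(NULL)
}

.ledgerSnapshot <- function(ledger) ledger$counts

#' Model evaluations recorded in a ledger
#'
#' Translation searches plus superposition rescorings: the per-cycle count
#' of models evaluated against the data.
#'
#' @param ledger a named job-count vector (see [jobLedger()]).
#' @return integer count.
#' @export
modelEvaluations <- function(ledger) {
  as.integer(ledger[["translation_search"]] +
               ledger[["rescore_by_superposition"]])
}

## ---- peak categorization / thresholding ---------------------------------

#' Categorize a peak
#'
#' A peak is clear when it passes packing and its translation-function
#' Z-score reaches the configured threshold; solutions produced by
#' alternative-model rescoring are clear irrespective of the score.
#'
#' @param peak list with `tfz` and `packs` (and optionally `rescored`).
#' @param cfg an [EngineConfig-class].
#' @return "clear" or "ordinary".
#' @export
categorize <- function(peak, cfg = engineConfig()) {
  if (isTRUE(peak$rescored)) return("clear")
  if (isTRUE(peak$packs) && is.finite(peak$tfz) && peak$tfz >= cfg@tfzClear)
    "clear" else "ordinary"
}

#' Select peaks for refinement
#'
#' Removes packing failures, then keeps every peak whose score reaches
#' best - selectFraction * |best - parent|, plus all clear peaks below the
#' threshold, capped at the configured branch limit by descending score.
#'
#' @param peaks list of peaks (each: llg, tfz, packs, ...).
#' @param parentLlg the parent solution's score.
#' @param cfg an [EngineConfig-class].
#' @return the selected subset (list).
#' @export
selectForRefinement <- function(peaks, parentLlg, cfg = engineConfig()) {
  peaks <- Filter(function(p) isTRUE(p$packs), peaks)
  if (length(peaks) == 0) return(list())
  llgs <- vapply(peaks, function(p) p$llg, numeric(1))
  best <- max(llgs)
  thr <- best - cfg@selectFraction * abs(best - parentLlg)
  keep <- llgs >= thr |
    vapply(peaks, function(p) categorize(p, cfg) == "clear", logical(1))
  sel <- peaks[keep]
  ord <- order(-vapply(sel, function(p) p$llg, numeric(1)))
  sel[ord][seq_len(min(length(sel), cfg@maxActiveBranches))]
}

#' Post-refinement propagation thresholding
#'
#' Applies the percentage rule with the purge fraction to the refined
#' scores; clear solutions are retained even below the threshold.
#'
#' @param refined list of refined candidates (each: llg, clear flag).
#' @param parentLlg parent score.
#' @param cfg an [EngineConfig-class].
#' @return surviving subset (list).
#' @export
propagate <- function(refined, parentLlg, cfg = engineConfig()) {
  if (length(refined) == 0) return(list())
  llgs <- vapply(refined, function(p) p$llg, numeric(1))
  best <- max(llgs)
  thr <- best - cfg@purgeFraction * abs(best - parentLlg)
  keep <- llgs >= thr | vapply(refined, function(p) isTRUE(p$clear), logical(1))
  refined[keep]
}

#' Space-group arbitration
#'
#' Given the per-group best scores of a cycle, keeps every group whose best
#' reaches B - sgFraction * |delta|, where B is the overall best and delta
#' its improvement over the cycle.
#'
#' @param perSgBestLlg named numeric: best score per active group.
#' @param prevBest overall best before the cycle.
#' @param cfg an [EngineConfig-class].
#' @return character vector of surviving group symbols.
#' @export
arbitrateSpaceGroups <- function(perSgBestLlg, prevBest = 0,
                                 cfg = engineConfig()) {
  if (length(perSgBestLlg) <= 1) return(names(perSgBestLlg))
  B <- max(perSgBestLlg)
  delta <- B - prevBest
  thr <- B - cfg@sgFraction * abs(delta)
  names(perSgBestLlg)[perSgBestLlg >= thr]
}

## ---- branch reduction ---------------------------------------------------

.templateKey <- function(sol, models) {
  keys <- vapply(sol@placements, function(p) {
    tid <- if (!is.null(models[[p@modelId]]))
      models[[p@modelId]]@sourceTemplateId else p@modelId
    paste0(p@componentId, ":", tid)
  }, character(1))
  paste(sort(keys), collapse = "|")
}

#' Reduce excessive branching
#'
#' Partitions solutions by the multiset of source templates per component
#' and by spatial equivalence (model identity relaxed to template identity)
#' and keeps only the best-scoring representative of each class; the others
#' are marked merged.
#'
#' @param partials list of [PartialSolution-class] in one space group.
#' @param sg the [SpaceGroup-class]; `cell` the [UnitCell-class].
#' @param cell unit cell.
#' @param models model registry (for template identity).
#' @param cfg an [EngineConfig-class].
#' @return list(kept, merged) of [PartialSolution-class] lists.
#' @export
reduceBranches <- function(partials, sg, cell, models = list(),
                           cfg = engineConfig()) {
  if (length(partials) <= 1) return(list(kept = partials, merged = list()))
  keys <- vapply(partials, .templateKey, character(1), models = models)
  kept <- list(); merged <- list()
  for (key in unique(keys)) {
    grp <- partials[keys == key]
    ord <- order(-vapply(grp, function(s) s@llg, numeric(1)))
    grp <- grp[ord]
    reps <- list()
    for (s in grp) {
      dup <- FALSE
      for (r in reps) {
        if (spatiallyEquivalent(r, s, sg, cell, cfg@tolRot, cfg@tolTrans)) {
          dup <- TRUE
          break
        }
      }
      if (dup) {
        s@status <- "merged"
        merged[[length(merged) + 1L]] <- s
      } else reps[[length(reps) + 1L]] <- s
    }
    kept <- c(kept, reps)
  }
  list(kept = kept, merged = merged)
}

## ---- alternative-model rescoring ----------------------------------------

#' Rescore alternative models by superposition
#'
#' For a clear solution, generates an equivalent solution for every
#' alternative model of the placed component by Kabsch superposition on the
#' shared target-numbered residues: same-template alternatives are scored
#' without refinement, different-template alternatives are rigid-body
#' refined (last placement only) before scoring; superposition failures are
#' skipped.  All results are marked clear irrespective of the score.
#'
#' @param clearSol the clear [PartialSolution-class]; its last placement is
#'   the one substituted.
#' @param alternatives list of [EnsembleModel-class] to substitute.
#' @param backend scoring backend.
#' @param models model registry (must include placed and alternatives).
#' @param cfg an [EngineConfig-class].
#' @param ledger optional ledger environment.
#' @return list of list(placements, llg, clear = TRUE, modelId).
#' @export
rescoreAlternatives <- function(clearSol, alternatives, backend, models,
                                cfg = engineConfig(), ledger = NULL) {
  pl <- clearSol@placements
  last <- pl[[length(pl)]]
  placed <- models[[last@modelId]]
  if (is.null(placed)) return(list())
  out <- list()
  for (alt in alternatives) {
    if (identical(alt@modelId, last@modelId)) next
    common <- intersect(placed@resIdx, alt@resIdx)
    if (length(common) < 3) next  # no usable sequence overlap
    pa <- placed@members[[1]][match(common, placed@resIdx), , drop = FALSE]
    A <- pa %*% t(last@rot) + matrix(last@trans, length(common), 3, TRUE)
    B <- alt@members[[1]][match(common, alt@resIdx), , drop = FALSE]
    fit <- tryCatch(kabschSuperpose(A, B), error = function(e) NULL)
    if (is.null(fit)) next  # superposition failure: model not evaluated
    cand <- placement(alt@componentId, alt@modelId, fit$rot, fit$trans)
    newPl <- c(pl[-length(pl)], list(cand))
    if (identical(alt@sourceTemplateId, placed@sourceTemplateId)) {
      llg <- backend$score(newPl, models)$llg
    } else {
      rr <- backend$rigidRefine(newPl, models, scope = "last")
      .ledgerAdd(ledger, "refine")
      newPl <- rr$placements
      llg <- rr$llg
    }
    .ledgerAdd(ledger, "rescore_by_superposition")
    out[[length(out) + 1L]] <- list(placements = newPl, llg = llg,
                                    clear = TRUE, modelId = alt@modelId)
  }
  out
}

## ---- dry-run enumeration ------------------------------------------------

#' Enumerate the unscored extension tree
#'
#' Counts the leaves of the extension tree without any backend call: with
#' branch reduction off, the product over extension steps of the
#' admissible-model counts; with template equivalence on, branches through
#' models of the same template collapse to one lineage per step.
#'
#' @param components named list of [ComponentSpec-class].
#' @param models list of [EnsembleModel-class].
#' @param asu contents (list with per-component `copies`).
#' @param cfg an [EngineConfig-class]; `templateEquivalence` toggles
#'   reduction.
#' @return list(assignments, lineages, evaluationsPerStep, steps).
#' @export
dryRunEnumerate <- function(components, models, asu, cfg = engineConfig()) {
  compOf <- vapply(models, function(m) m@componentId, character(1))
  tmplOf <- vapply(models, function(m)
    paste0(m@componentId, ":", m@sourceTemplateId), character(1))
  copies <- asu$copies
  memo <- new.env(parent = emptyenv())
  count <- function(rem, labels) {
    if (all(rem == 0)) return(1)
    key <- paste(rem, collapse = ",")
    if (!is.null(memo[[key]])) return(memo[[key]])
    tot <- 0
    avail <- names(rem)[rem > 0]
    for (cid in avail) {
      nm <- sum(labels$comp == cid)
      if (nm == 0) next
      rem2 <- rem
      rem2[cid] <- rem2[cid] - 1L
      tot <- tot + nm * count(rem2, labels)
    }
    memo[[key]] <- tot
    tot
  }
  rem0 <- copies
  assignments <- count(rem0, list(comp = compOf))
  ## collapsed: one lineage per distinct template per step
  memo2 <- new.env(parent = emptyenv())
  countT <- function(rem) {
    if (all(rem == 0)) return(1)
    key <- paste(rem, collapse = ",")
    if (!is.null(memo2[[key]])) return(memo2[[key]])
    tot <- 0
    for (cid in names(rem)[rem > 0]) {
      nt <- length(unique(tmplOf[compOf == cid]))
      if (nt == 0) next
      rem2 <- rem
      rem2[cid] <- rem2[cid] - 1L
      tot <- tot + nt * countT(rem2)
    }
    memo2[[key]] <- tot
    tot
  }
  lineages <- countT(rem0)
  list(assignments = assignments, lineages = lineages,
       evaluationsPerStep = length(models), steps = sum(copies))
}

## ---- engine state -------------------------------------------------------

.newSolutionId <- function(st) {
  st$counter <- st$counter + 1L
  sprintf("s%05d", st$counter)
}

.registerSolution <- function(st, sol, clear = FALSE, cycle = 0L) {
  st$solutions[[sol@solutionId]] <- sol
  st$meta[[sol@solutionId]] <- list(clear = clear, cycle = cycle)
  sol@solutionId
}

.solCounts <- function(sol) {
  table(vapply(sol@placements, function(p) p@componentId, character(1)))
}

.childSolution <- function(st, parent, placements, llg, tfz, clear, cycle,
                           associations = list()) {
  sol <- new("PartialSolution", solutionId = .newSolutionId(st),
             parentId = parent@solutionId, sgSymbol = parent@sgSymbol,
             placements = placements, llg = llg,
             tfzHistory = c(parent@tfzHistory,
                            rep(tfz, length(placements) -
                                  length(parent@placements))),
             status = "active", associations = associations)
  .registerSolution(st, sol, clear = clear, cycle = cycle)
  sol
}

## ---- extension cycle ----------------------------------------------------

.evaluatePredictions <- function(st, parent, sg, cycle) {
  ## returns list of new clear children created from pending associations
  children <- list()
  assocs <- parent@associations
  if (length(assocs) == 0) return(children)
  parent@associations <- list()
  st$solutions[[parent@solutionId]] <- parent
  backend <- st$backend
  models <- st$models
  cfg <- st$cfg
  ## self-calibrating identification gate: a confirmed extension must
  ## deliver a score gain comparable to the parent's mean per-copy gain
  ## (in addition to the background Z threshold), so partial-overlap
  ## impostors with high Z are still rejected
  meanGain <- if (length(parent@placements))
    parent@llg / length(parent@placements) else NA_real_
  gainOk <- function(raw) is.na(meanGain) || raw >= 0.5 * meanGain

  predGroups <- list()
  for (as_ in assocs) {
    if (as_$kind == "assembly_prediction") {
      predGroups[[length(predGroups) + 1L]] <- as_
    } else if (as_$kind == "amalgamation") {
      partner <- st$solutions[[as_$partnerId]]
      if (is.null(partner) || partner@status == "merged") next
      gp <- st$solutions[[parent@parentId]]
      gpPl <- if (is.null(gp)) list() else gp@placements
      am <- amalgamate(parent, partner, gpPl, sg, st$cell, backend, models,
                       st$asu$copies, ledger = st$ledger)
      for (cand in am$candidates) {
        .ledgerAdd(st$ledger, "prediction_score")
        rr <- backend$rigidRefine(cand, models, scope = "all")
        .ledgerAdd(st$ledger, "refine")
        cand <- rr$placements
        sc <- backend$score(cand, models)
        pk <- backend$packingCheck(cand, models)
        newIdx <- setdiff(seq_along(cand), seq_along(parent@placements))
        bzs <- lapply(newIdx, function(i)
          backend$backgroundZscore(cand[-i], cand[[i]],
                                   models[[cand[[i]]@modelId]], models,
                                   nSamples = 60L,
                                   seed = deriveSeed(cfg@seed,
                                                     parent@solutionId)))
        zs <- min(vapply(bzs, function(b) b$z, numeric(1)))
        gains <- all(vapply(bzs, function(b) gainOk(b$raw), logical(1)))
        if (pk$passes && zs >= cfg@tfzClear && gains) {
          children[[length(children) + 1L]] <-
            .childSolution(st, parent, cand, sc$llg, zs, TRUE, cycle)
        }
      }
      if (!is.null(am$needsTranslation)) {
        for (ori in am$needsTranslation) {
          ## polar rule: rotation reused, translation searched
          mdl <- models[[as_$modelId %||% names(models)[1]]]
          ts <- backend$translationSearch(mdl, ori, parent, models,
                                          sgHyp = sg, gridStep = cfg@gridStep)
          .ledgerAdd(st$ledger, "translation_search")
          if (length(ts)) {
            pk1 <- ts[[1]]
            pkck <- backend$packingCheck(c(parent@placements,
                                           list(pk1$placement)), models)
            .ledgerAdd(st$ledger, "packing")
            if (pkck$passes && pk1$tfz >= cfg@tfzClear) {
              children[[length(children) + 1L]] <-
                .childSolution(st, parent,
                               c(parent@placements, list(pk1$placement)),
                               pk1$llg, pk1$tfz, TRUE, cycle)
            }
          }
        }
      }
    }
  }

  ## assembly / known-assembly predictions: confirm sequentially into one
  ## growing completion of the parent
  if (length(predGroups)) {
    cur <- parent@placements
    added <- 0L
    lastZ <- NA_real_
    zsAll <- c()
    for (as_ in predGroups) {
      cand <- as_$placement
      mdl <- models[[cand@modelId]]
      if (is.null(mdl)) next
      .ledgerAdd(st$ledger, "prediction_score")
      pkck <- backend$packingCheck(c(cur, list(cand)), models)
      bz <- backend$backgroundZscore(cur, cand, mdl, models, nSamples = 60L,
                                     seed = deriveSeed(cfg@seed,
                                                       paste0(parent@solutionId,
                                                              ":pred")))
      if (pkck$passes && bz$z >= cfg@tfzClear && gainOk(bz$raw)) {
        cur <- c(cur, list(cand))
        added <- added + 1L
        zsAll <- c(zsAll, bz$z)
      }
    }
    if (added > 0L) {
      rr <- backend$rigidRefine(cur, models, scope = "all")
      .ledgerAdd(st$ledger, "refine")
      child <- new("PartialSolution", solutionId = .newSolutionId(st),
                   parentId = parent@solutionId, sgSymbol = parent@sgSymbol,
                   placements = rr$placements, llg = rr$llg,
                   tfzHistory = c(parent@tfzHistory, zsAll),
                   status = "active", associations = list())
      .registerSolution(st, child, clear = TRUE, cycle = cycle)
      children[[length(children) + 1L]] <- child
    }
  }
  children
}

.admissibleModels <- function(st, parent) {
  missing <- missingComposition(parent, st$asu, st$components, st$models)
  if (compositionComplete(missing)) return(list(complete = TRUE, models = list()))
  adm <- Filter(function(m) modelAdmissible(m, missing), st$modelList)
  list(complete = FALSE, models = adm)
}

## One (parent, model) search: rotation search, then translation search per
## kept orientation (stopping at the first clear peak in quick mode).
## Pure apart from the backend: job counts are returned, not recorded, so
## the same code runs in executor child processes.
.searchParentModel <- function(st, parent, model, sg, stopAtClear) {
  backend <- st$backend
  cfg <- st$cfg
  rs <- backend$rotationSearch(model, parent, st$models, sgHyp = sg,
                               nKeep = cfg@nKeep, step = cfg@rotStep)
  peaks <- list()
  nTrans <- 0L
  for (ori in rs) {
    ts <- backend$translationSearch(model, ori$rot, parent, st$models,
                                    sgHyp = sg, gridStep = cfg@gridStep)
    nTrans <- nTrans + 1L
    for (pk in ts) {
      pkck <- backend$packingCheck(c(parent@placements, list(pk$placement)),
                                   st$models)
      pk$packs <- pkck$passes
      pk$parentId <- parent@solutionId
      pk$modelId <- model@modelId
      peaks[[length(peaks) + 1L]] <- pk
    }
    anyClear <- any(vapply(peaks, function(p)
      categorize(p, cfg) == "clear", logical(1)))
    if (stopAtClear && anyClear) break
  }
  list(peaks = peaks, nRot = 1L, nTrans = nTrans)
}

.extensionCycle <- function(st, sgSym, cycle) {
  sg <- buildSpaceGroup(sgSym)
  cfg <- st$cfg
  backend <- st$backend
  activeIds <- st$active[[sgSym]]
  if (length(activeIds) == 0) return(FALSE)
  sols <- lapply(activeIds, function(id) st$solutions[[id]])
  ord <- order(-vapply(sols, function(s) s@llg, numeric(1)))
  sols <- sols[ord]

  extended <- FALSE
  newActive <- list()

  ## (1) composition analysis: complete solutions leave the active pool
  pending <- list()
  for (s in sols) {
    am <- .admissibleModels(st, s)
    if (am$complete) {
      s@status <- "complete"
      st$solutions[[s@solutionId]] <- s
    } else pending[[length(pending) + 1L]] <- list(sol = s, models = am$models)
  }

  ## (2) pending predictions: clear predictions bypass the search phase;
  ## quick mode evaluates only the best partial's pending associations
  bypassed <- character(0)
  stillPending <- list()
  for (pi in seq_along(pending)) {
    p <- pending[[pi]]
    if (cfg@mode == "quick" && pi > 1L) {
      stillPending[[length(stillPending) + 1L]] <- p
      next
    }
    kids <- .evaluatePredictions(st, p$sol, sg, cycle)
    if (length(kids)) {
      extended <- TRUE
      bypassed <- c(bypassed, p$sol@solutionId)
      newActive <- c(newActive, kids)
    } else stillPending[[length(stillPending) + 1L]] <- p
  }

  ## (3) search phase, depth-first (children of the best parent first);
  ## quick mode: only the best parent, stop scheduling once clear
  searchSet <- Filter(function(p) !(p$sol@solutionId %in% bypassed),
                      stillPending)
  if (cfg@mode == "quick") {
    ## a clear prediction extended the best partial: the search is skipped
    ## for this cycle entirely
    searchSet <- if (length(bypassed)) list() else
      searchSet[seq_len(min(1, length(searchSet)))]
  }

  cycleChildren <- newActive

  ## full mode: all (parent, model) searches are pure jobs executed through
  ## the pooled executor; results are consumed in canonical (parent
  ## priority, model priority) order so any worker count gives the same run
  peaksPrecomputed <- NULL
  if (cfg@mode == "full" && length(searchSet)) {
    jobs <- list(); keys <- NULL
    for (pi in seq_along(searchSet)) {
      for (mi in seq_along(searchSet[[pi]]$models)) {
        jobs[[length(jobs) + 1L]] <- list(
          kind = "search", costHint = "slow",
          fun = .searchParentModel,
          args = list(st = st, parent = searchSet[[pi]]$sol,
                      model = searchSet[[pi]]$models[[mi]], sg = sg,
                      stopAtClear = FALSE))
        keys <- rbind(keys, c(pi, mi))
      }
    }
    pm <- parallelMap(jobs, workers = cfg@workers,
                      poolThreshold = cfg@poolThreshold)
    peaksPrecomputed <- vector("list", length(searchSet))
    for (k in seq_along(jobs)) {
      if (pm$errors[k]) next  # a failing job rejects that branch only
      r <- pm$results[[k]]
      .ledgerAdd(st$ledger, "rotation_search", r$nRot)
      .ledgerAdd(st$ledger, "translation_search", r$nTrans)
      .ledgerAdd(st$ledger, "packing", r$nTrans)
      pi <- keys[k, 1]
      peaksPrecomputed[[pi]] <- c(peaksPrecomputed[[pi]], r$peaks)
    }
  }

  for (pi in seq_along(searchSet)) {
    p <- searchSet[[pi]]
    parent <- p$sol
    peaks <- list()
    clearFound <- FALSE
    clearModel <- NULL
    if (!is.null(peaksPrecomputed)) {
      peaks <- peaksPrecomputed[[pi]] %||% list()
      clearFound <- any(vapply(peaks, function(x)
        categorize(x, cfg) == "clear", logical(1)))
    } else {
      for (model in p$models) {
        if (clearFound) break
        mp <- .searchParentModel(st, parent, model, sg, stopAtClear = TRUE)
        .ledgerAdd(st$ledger, "rotation_search", mp$nRot)
        .ledgerAdd(st$ledger, "translation_search", mp$nTrans)
        .ledgerAdd(st$ledger, "packing", mp$nTrans)
        peaks <- c(peaks, mp$peaks)
        if (any(vapply(mp$peaks, function(x) categorize(x, cfg) == "clear",
                       logical(1)))) {
          clearFound <- TRUE
          clearModel <- model
        }
      }
    }
    if (length(peaks) == 0) {
      parent@status <- if (length(parent@placements)) "rejected" else "complete"
      st$solutions[[parent@solutionId]] <- parent
      next
    }

    ## (4)+(5) categorization + selection
    sel <- selectForRefinement(peaks, parent@llg, cfg)
    if (length(sel) == 0) {
      parent@status <- "rejected"
      st$solutions[[parent@solutionId]] <- parent
      next
    }

    ## (6) refinement
    refined <- lapply(sel, function(pk) {
      if (cfg@refine) {
        rr <- backend$rigidRefine(c(parent@placements, list(pk$placement)),
                                  st$models, scope = "all", sgHyp = sg)
        .ledgerAdd(st$ledger, "refine")
        list(placements = rr$placements, llg = rr$llg, tfz = pk$tfz,
             clear = categorize(pk, cfg) == "clear", modelId = pk$modelId)
      } else {
        list(placements = c(parent@placements, list(pk$placement)),
             llg = pk$llg, tfz = pk$tfz,
             clear = categorize(pk, cfg) == "clear", modelId = pk$modelId)
      }
    })

    ## (7) second thresholding and propagation
    surv <- propagate(refined, parent@llg, cfg)
    kids <- lapply(surv, function(rp)
      .childSolution(st, parent, rp$placements, rp$llg, rp$tfz, rp$clear,
                     cycle))
    cycleChildren <- c(cycleChildren, kids)
    if (length(kids)) extended <- TRUE

    ## quick mode: evaluate every alternative model through superposition
    if (cfg@mode == "quick" && clearFound && length(kids)) {
      clearKids <- Filter(function(k) isTRUE(st$meta[[k@solutionId]]$clear),
                          kids)
      if (length(clearKids)) {
        bestClear <- clearKids[[which.max(vapply(clearKids, function(k) k@llg,
                                                 numeric(1)))]]
        alts <- Filter(function(m)
          m@componentId == clearModel@componentId &&
            m@modelId != clearModel@modelId, p$models)
        res <- rescoreAlternatives(bestClear, alts, backend, st$models, cfg,
                                   ledger = st$ledger)
        for (r in res) {
          kid <- .childSolution(st, parent, r$placements, r$llg, NA_real_,
                                TRUE, cycle)
          cycleChildren <- c(cycleChildren, list(kid))
        }
      }
    }
  }

  ## (8) branch reduction
  if (cfg@templateEquivalence && length(cycleChildren) > 1) {
    red <- reduceBranches(cycleChildren, sg, st$cell, st$models, cfg)
    for (m in red$merged) st$solutions[[m@solutionId]] <- m
    cycleChildren <- red$kept
  }
  if (length(cycleChildren) > cfg@maxActiveBranches) {
    ord2 <- order(-vapply(cycleChildren, function(s) s@llg, numeric(1)))
    dropped <- cycleChildren[ord2][-seq_len(cfg@maxActiveBranches)]
    for (d in dropped) {
      d@status <- "rejected"
      st$solutions[[d@solutionId]] <- d
    }
    cycleChildren <- cycleChildren[ord2][seq_len(cfg@maxActiveBranches)]
  }

  ## (9) solution analyses on this cycle's clear children
  clearKids <- Filter(function(k) isTRUE(st$meta[[k@solutionId]]$clear),
                      cycleChildren)
  ## 9a: amalgamation associations between clear siblings
  byParent <- split(clearKids, vapply(clearKids, function(k) k@parentId,
                                      character(1)))
  nAssoc <- 0L
  for (grp in byParent) {
    if (length(grp) < 2) next
    for (i in seq_along(grp)) for (j in seq_along(grp)) {
      if (j <= i || nAssoc >= 10L) next
      a <- grp[[i]]; b <- grp[[j]]
      if (spatiallyEquivalent(a, b, sg, st$cell, cfg@tolRot, cfg@tolTrans))
        next
      a@associations <- c(a@associations,
                          list(list(kind = "amalgamation",
                                    partnerId = b@solutionId)))
      st$solutions[[a@solutionId]] <- a
      for (k in seq_along(cycleChildren)) {
        if (cycleChildren[[k]]@solutionId == a@solutionId)
          cycleChildren[[k]] <- a
      }
      nAssoc <- nAssoc + 1L
    }
  }
  ## 9b: NCS assembly detection and missing-member prediction
  for (k in seq_along(cycleChildren)) {
    kid <- cycleChildren[[k]]
    if (!isTRUE(st$meta[[kid@solutionId]]$clear)) next
    if (length(kid@placements) < 2) next
    prev <- st$assemblies[[kid@parentId]] %||% list()
    hyps <- detectAssemblies(kid, sg = sg, cell = st$cell, tolAxis = 5,
                             tolAngle = 5, tolPerp = 1.0)
    if (length(prev))
      hyps <- unique(c(updateNCS(kid, prev, sg = sg, cell = st$cell), hyps))
    ## prefer well-supported, low-order hypotheses; cap the pending
    ## prediction count so spurious relations cannot dominate a cycle
    if (length(hyps) > 1) {
      ordN <- vapply(hyps, function(h)
        as.integer(sub("^[CD]", "", h@groupLabel)), integer(1))
      hyps <- hyps[order(-vapply(hyps, function(h)
        length(h@memberIndices), integer(1)), ordN)]
    }
    preds <- list()
    samePred <- function(a, b)
      rotationDistance(a@rot, b@rot) <= 10 &&
        sqrt(sum((a@trans - b@trans)^2)) <= 3
    for (h in hyps) {
      if (length(preds) >= 40L) break
      for (pr in predictMissing(h, kid, sg = sg, cell = st$cell)) {
        if (any(vapply(preds, function(q)
          samePred(q$placement, pr$placement), logical(1)))) next
        ## predictions placed with the model of the anchor member
        anchor <- kid@placements[[h@memberIndices[1]]]
        pr$placement <- placement(pr$placement@componentId, anchor@modelId,
                                  pr$placement@rot, pr$placement@trans)
        pr$kind <- "assembly_prediction"
        preds[[length(preds) + 1L]] <- pr
      }
    }
    ## 9c: user-supplied assemblies
    for (ua in st$userAssemblies) {
      for (pr in completeKnownAssembly(ua, kid, backend, st$models)) {
        pr$kind <- "assembly_prediction"
        preds[[length(preds) + 1L]] <- pr
      }
    }
    if (length(preds)) {
      kid@associations <- c(kid@associations, preds)
      st$solutions[[kid@solutionId]] <- kid
      cycleChildren[[k]] <- kid
    }
  }

  ## active set for the next cycle
  st$active[[sgSym]] <- vapply(cycleChildren, function(s) s@solutionId,
                               character(1))
  extended
}

## ---- run ----------------------------------------------------------------

.resolveSgChoice <- function(sgChoice) {
  if (is.character(sgChoice)) {
    return(normalizeSymbol(sgChoice))
  }
  level <- sgChoice$level %||% "exact"
  sym <- normalizeSymbol(sgChoice$symbol)
  if (level == "exact") return(sym)
  sg <- buildSpaceGroup(sym)
  if (level == "enantiomorph") {
    if (is.na(sg@enantiomorph)) return(sym)
    return(c(sym, sg@enantiomorph))
  }
  if (level == "point_group") {
    all <- names(.SG_GENERATORS)
    return(all[vapply(all, function(s)
      .SG_META[[s]]$pg == sg@pointGroup, logical(1))])
  }
  stopf("unknown space-group choice level '%s'", level)
}

#' Run the molecular-replacement search
#'
#' Iterates extension cycles per active space group until no extension is
#' produced (quick mode additionally stops once a complete clear solution
#' exists), arbitrating between active space groups after every cycle, and
#' returns an archive of every solution scored, the job ledger, the
#' configuration and the seed.
#'
#' @param components named list of [ComponentSpec-class].
#' @param models list of [EnsembleModel-class] in priority order.
#' @param backend scoring backend (see [toyBackend()]).
#' @param sgChoice space-group knowledge: a symbol (exact), or
#'   list(level = "exact"|"enantiomorph"|"point_group", symbol = ...).
#' @param cfg an [EngineConfig-class].
#' @param asu optional contents (default: [matthewsSelect()] on the
#'   backend's cell).
#' @param userAssemblies optional list of known assemblies (see
#'   [completeKnownAssembly()]).
#' @param maxCycles safety cap on extension cycles.
#' @return a [SolutionArchive-class].
#' @export
runSearch <- function(components, models, backend, sgChoice,
                      cfg = engineConfig(), asu = NULL,
                      userAssemblies = list(), maxCycles = NULL) {
  if (length(models) == 0) stopf("nothing to search with: no models given")
  modelReg <- stats::setNames(models,
                              vapply(models, function(m) m@modelId,
                                     character(1)))
  sgSyms <- .resolveSgChoice(sgChoice)
  cell <- backend$cell()
  if (is.null(asu))
    asu <- matthewsSelect(cell, buildSpaceGroup(sgSyms[1]), components)
  maxCycles <- maxCycles %||% (sum(asu$copies) + 5L)

  st <- new.env(parent = emptyenv())
  st$cfg <- cfg
  st$backend <- backend
  st$components <- components
  st$models <- modelReg
  st$modelList <- models
  st$asu <- asu
  st$cell <- cell
  st$solutions <- list()
  st$meta <- list()
  st$assemblies <- list()
  st$active <- list()
  st$counter <- 0L
  st$ledger <- .newLedger()
  st$userAssemblies <- userAssemblies

  for (s in sgSyms) {
    root <- new("PartialSolution", solutionId = .newSolutionId(st),
                parentId = "", sgSymbol = s, placements = list(), llg = 0,
                tfzHistory = numeric(0), status = "active",
                associations = list())
    .registerSolution(st, root, clear = FALSE, cycle = 0L)
    st$active[[s]] <- root@solutionId
  }

  activeSgs <- sgSyms
  prevBest <- 0
  for (cycle in seq_len(maxCycles)) {
    anyExt <- FALSE
    for (s in activeSgs) {
      ext <- .extensionCycle(st, s, cycle)
      anyExt <- anyExt || ext
    }
    ## per-cycle ledger snapshot (cumulative counts at end of cycle)
    st$ledger$history[[length(st$ledger$history) + 1L]] <-
      c(cycle = cycle, st$ledger$counts)
    if (isTRUE(getOption("MRsearch.verbose"))) {
      nact <- sum(lengths(st$active))
      best <- max(vapply(st$solutions, function(s) s@llg, numeric(1)))
      maxPl <- max(vapply(st$solutions, function(s) length(s@placements),
                          integer(1)))
      message(sprintf("cycle %d: %d active, best llg %.1f, max placed %d, %s",
                      cycle, nact, best, maxPl,
                      paste(names(st$ledger$counts), st$ledger$counts,
                            sep = "=", collapse = " ")))
    }
    ## space-group arbitration
    if (length(activeSgs) > 1) {
      perSg <- vapply(activeSgs, function(s) {
        ids <- names(st$solutions)
        ll <- vapply(ids, function(id) {
          sol <- st$solutions[[id]]
          if (sol@sgSymbol == s) sol@llg else -Inf
        }, numeric(1))
        if (all(!is.finite(ll))) 0 else max(ll)
      }, numeric(1))
      keep <- arbitrateSpaceGroups(perSg, prevBest, cfg)
      prevBest <- max(perSg)
      for (s in setdiff(activeSgs, keep)) st$active[[s]] <- character(0)
      activeSgs <- keep
    }
    if (!anyExt) break
    if (cfg@mode == "quick") {
      completeClear <- any(vapply(names(st$solutions), function(id) {
        sol <- st$solutions[[id]]
        sol@status == "complete" ||
          (isTRUE(st$meta[[id]]$clear) &&
             compositionComplete(missingComposition(sol, st$asu,
                                                    st$components,
                                                    st$models)))
      }, logical(1)))
      pendingAssoc <- any(vapply(names(st$solutions), function(id)
        length(st$solutions[[id]]@associations) > 0, logical(1)))
      if (completeClear && !pendingAssoc) break
    }
  }

  ## final status bookkeeping: active leaves with full composition complete
  for (id in names(st$solutions)) {
    sol <- st$solutions[[id]]
    if (sol@status == "active" &&
        compositionComplete(missingComposition(sol, st$asu, st$components,
                                               st$models))) {
      sol@status <- "complete"
      st$solutions[[id]] <- sol
    }
  }

  .archiveFromState(st, sgSyms, activeSgs)
}

## ---- output selection ---------------------------------------------------

.subsetEquivalent <- function(solSmall, solBig, sg, cell, tolRot, tolTrans) {
  if (length(solSmall@placements) > length(solBig@placements)) return(FALSE)
  if (length(solSmall@placements) == 0) return(TRUE)
  ## pad the smaller solution conceptually: reuse the matcher with a
  ## rectangular compatibility matrix
  pa <- solBig@placements; pb <- solSmall@placements
  O <- orthogonalizationMatrix(cell)
  Oinv <- solve(O)
  polar <- sg@polarAxes
  shifts <- sg@originShifts
  if (nrow(shifts) == 0) shifts <- matrix(0, 1, 3)
  testShift <- function(pbT, shiftCart) {
    compat <- matrix(FALSE, length(pbT), length(pa))
    for (i in seq_along(pbT)) for (j in seq_along(pa)) {
      if (pa[[j]]@componentId != pbT[[i]]@componentId) next
      if (rotationDistance(pa[[j]]@rot, pbT[[i]]@rot) > tolRot) next
      d <- pa[[j]]@trans - (pbT[[i]]@trans + shiftCart)
      d <- as.vector(O %*% fracMin(as.vector(Oinv %*% d)))
      compat[i, j] <- sqrt(sum(d^2)) <= tolTrans
    }
    .rowSaturatedMatching(compat)
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
        for (j in seq_along(pa)) {
          if (pa[[j]]@componentId != pbT[[1]]@componentId) next
          if (rotationDistance(pa[[j]]@rot, pbT[[1]]@rot) > tolRot) next
          df <- as.vector(Oinv %*% (pa[[j]]@trans - pbT[[1]]@trans)) -
            shifts[si, ]
          sfrac <- shifts[si, ]
          sfrac[polar] <- sfrac[polar] + df[polar]
          if (testShift(pbT, as.vector(O %*% sfrac))) return(TRUE)
        }
      }
    }
  }
  FALSE
}

.rowSaturatedMatching <- function(compat) {
  n <- nrow(compat); m <- ncol(compat)
  if (n > m) return(FALSE)
  matchR <- rep(0L, m)
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
  for (i in seq_len(n)) if (!tryRow(i, rep(FALSE, m))) return(FALSE)
  TRUE
}

#' Final output selection
#'
#' Sorts all scored solutions by score, applies the percentage threshold,
#' discards solutions that are symmetry-aware subsets of a better solution,
#' and merges incomplete ancestors into their completions.
#'
#' @param archive a [SolutionArchive-class].
#' @param cfg an [EngineConfig-class].
#' @return list of ranked solution records (best first).
#' @export
finalizeOutput <- function(archive, cfg = engineConfig()) {
  recs <- Filter(function(r) r$status != "merged" && length(r$placements) > 0,
                 archive@records)
  if (length(recs) == 0) return(list())
  sols <- lapply(recs, .recordToSolution)
  llgs <- vapply(sols, function(s) s@llg, numeric(1))
  ord <- order(-llgs)
  sols <- sols[ord]; recs <- recs[ord]; llgs <- llgs[ord]
  thr <- llgs[1] - cfg@selectFraction * abs(llgs[1])
  keepIdx <- which(llgs >= thr)
  sols <- sols[keepIdx]; recs <- recs[keepIdx]

  ## ancestor merging: an incomplete ancestor is merged into a retained
  ## descendant only when the descendant actually improves on it -- with an
  ## overestimated composition the correct-count solution outscores its
  ## over-placed children and must stay listed
  ids <- vapply(recs, function(r) r$solution_id, character(1))
  ancestorOf <- rep(FALSE, length(recs))
  parentOf <- stats::setNames(vapply(archive@records, function(r)
    r$parent_id, character(1)),
    vapply(archive@records, function(r) r$solution_id, character(1)))
  for (i in seq_along(recs)) {
    p <- parentOf[[recs[[i]]$solution_id]]
    while (!is.null(p) && nzchar(p)) {
      hit <- which(ids == p)
      for (h in hit) {
        if (recs[[i]]$llg > recs[[h]]$llg + 1e-9) ancestorOf[h] <- TRUE
      }
      p <- if (p %in% names(parentOf)) parentOf[[p]] else ""
    }
  }
  sols <- sols[!ancestorOf]; recs <- recs[!ancestorOf]

  ## symmetry-aware subset removal
  drop <- rep(FALSE, length(sols))
  for (i in seq_along(sols)) {
    if (drop[i]) next
    for (j in seq_along(sols)) {
      if (i == j || drop[j]) next
      ## j is a subset of the better i (i earlier in llg order)
      if (j > i && sols[[i]]@llg > sols[[j]]@llg + 1e-9 &&
          length(sols[[j]]@placements) <= length(sols[[i]]@placements)) {
        sg <- buildSpaceGroup(sols[[i]]@sgSymbol)
        if (sols[[j]]@sgSymbol == sols[[i]]@sgSymbol &&
            length(sols[[j]]@placements) < length(sols[[i]]@placements) &&
            .subsetEquivalent(sols[[j]], sols[[i]], sg,
                              .cellFromArchive(archive), cfg@tolRot,
                              cfg@tolTrans))
          drop[j] <- TRUE
      }
    }
  }
  recs[!drop]
}
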