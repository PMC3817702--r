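# Solution archive (line-delimited JSON), PDB/FASTA export, the executor
# contract with fast-job pooling, config-driven runs and the command-line
# utility surface.

.ARCHIVE_VERSION <- 1L

## variant count from a config block; YAML 1.1 reads a bare `n` key as the
## boolean FALSE, so `count` is the documented spelling and both work
.variantCount <- function(v) {
  as.integer(v$count %||% v$n %||% v[["FALSE"]] %||% 1L)
}

.cfgToList <- function(cfg) {
  list(mode = cfg@mode, tfz_clear = cfg@tfzClear,
       select_fraction = cfg@selectFraction,
       purge_fraction = cfg@purgeFraction, sg_fraction = cfg@sgFraction,
       max_active_branches = cfg@maxActiveBranches,
       template_equivalence = cfg@templateEquivalence,
       assembly_search_models = cfg@assemblySearchModels, seed = cfg@seed,
       workers = cfg@workers, pool_threshold = cfg@poolThreshold,
       grid_step = cfg@gridStep, rot_step = cfg@rotStep, n_keep = cfg@nKeep,
       tol_rot = cfg@tolRot, tol_trans = cfg@tolTrans)
}

.cfgFromList <- function(x) {
  engineConfig(mode = x$mode %||% "full", tfzClear = x$tfz_clear %||% 7,
               selectFraction = x$select_fraction %||% 0.25,
               purgeFraction = x$purge_fraction %||% 0.25,
               sgFraction = x$sg_fraction %||% 0.25,
               maxActiveBranches = x$max_active_branches %||% 25,
               templateEquivalence = x$template_equivalence %||% TRUE,
               assemblySearchModels = x$assembly_search_models %||% FALSE,
               seed = x$seed %||% 1, workers = x$workers %||% 1,
               poolThreshold = x$pool_threshold %||% 20,
               gridStep = x$grid_step %||% 2, rotStep = x$rot_step %||% 15,
               nKeep = x$n_keep %||% 5, tolRot = x$tol_rot %||% 5,
               tolTrans = x$tol_trans %||% 2)
}

.solutionToRecord <- function(sol, meta) {
  list(type = "solution", solution_id = sol@solutionId,
       parent_id = sol@parentId, sg = sol@sgSymbol, llg = sol@llg,
       status = sol@status, clear = isTRUE(meta$clear),
       cycle = meta$cycle %||% 0L,
       tfz_history = as.numeric(sol@tfzHistory),
       placements = lapply(sol@placements, function(p)
         list(component = p@componentId, model = p@modelId,
              rot = as.numeric(p@rot), trans = as.numeric(p@trans))))
}

.recordToSolution <- function(rec) {
  new("PartialSolution", solutionId = rec$solution_id,
      parentId = rec$parent_id, sgSymbol = rec$sg,
      placements = lapply(rec$placements, function(pp)
        placement(pp$component, pp$model, matrix(as.numeric(pp$rot), 3, 3),
                  as.numeric(pp$trans))),
      llg = rec$llg, tfzHistory = as.numeric(rec$tfz_history %||% numeric(0)),
      status = rec$status, associations = list())
}

.archiveFromState <- function(st, sgSyms, activeSgs) {
  cell <- st$cell
  header <- list(type = "header", format_version = .ARCHIVE_VERSION,
                 config = .cfgToList(st$cfg), seed = st$cfg@seed,
                 cell = c(cell@a, cell@b, cell@c, cell@alpha, cell@beta,
                          cell@gamma),
                 space_groups = as.list(sgSyms),
                 active_space_groups = as.list(activeSgs),
                 ledger_cycles = lapply(st$ledger$history, as.list),
                 components = lapply(st$components, function(cs)
                   list(id = cs@componentId, sequence = cs@sequence,
                        stoichiometry = cs@stoichiometry)),
                 models = lapply(st$modelList, function(m)
                   list(model_id = m@modelId, component = m@componentId,
                        source_template = m@sourceTemplateId,
                        protocol = m@protocolId, weight = m@weight,
                        n_res = length(m@resIdx))))
  ids <- names(st$solutions)
  ids <- ids[order(ids)]
  records <- lapply(ids, function(id)
    .solutionToRecord(st$solutions[[id]], st$meta[[id]]))
  assemblies <- list()
  for (id in names(st$assemblies)) {
    for (h in st$assemblies[[id]]) {
      assemblies[[length(assemblies) + 1L]] <-
        list(type = "assembly", solution_id = id, group = h@groupLabel,
             axis = as.numeric(h@axis), center = as.numeric(h@center),
             members = as.integer(h@memberIndices), source = h@source)
    }
  }
  new("SolutionArchive", header = header, records = records,
      assemblies = assemblies, ledger = .ledgerSnapshot(st$ledger))
}

.cellFromArchive <- function(archive) {
  cl <- as.numeric(archive@header$cell)
  unitCell(cl[1], cl[2], cl[3], cl[4], cl[5], cl[6])
}

#' Write / read a solution archive
#'
#' Line-delimited JSON with a version-tagged header record: one record per
#' line, unknown fields preserved on read, identical files on a
#' write/read/write round trip.
#'
#' @param archive a [SolutionArchive-class].
#' @param path file path.
#' @return `writeArchive` the path (invisibly); `readArchive` the archive.
#' @export
writeArchive <- function(archive, path) {
  ser <- function(x) jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                                      null = "null")
  lines <- c(ser(archive@header),
             vapply(archive@records, function(r) as.character(ser(r)),
                    character(1)),
             vapply(archive@assemblies, function(r) as.character(ser(r)),
                    character(1)),
             ser(list(type = "ledger", counts = as.list(archive@ledger))))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writeArchive
#' @export
readArchive <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0) stopf("empty archive file %s", path)
  parsed <- vector("list", length(lines))
  offset <- 0L
  for (i in seq_along(lines)) {
    parsed[[i]] <- tryCatch(
      jsonlite::fromJSON(lines[i], simplifyVector = FALSE),
      error = function(e)
        stopf("archive truncated or corrupt at line %d (byte offset %d): %s",
              i, offset, conditionMessage(e)))
    offset <- offset + nchar(lines[i], type = "bytes") + 1L
  }
  header <- parsed[[1]]
  if (!identical(header$type, "header"))
    stopf("archive does not start with a header record")
  ver <- header$format_version
  if (!identical(as.integer(ver), .ARCHIVE_VERSION))
    stopf("archive format version mismatch: file has %s, reader supports %d",
          ver, .ARCHIVE_VERSION)
  recs <- list(); asms <- list(); ledger <- numeric(0)
  for (p in parsed[-1]) {
    if (identical(p$type, "solution")) recs[[length(recs) + 1L]] <- p
    else if (identical(p$type, "assembly")) asms[[length(asms) + 1L]] <- p
    else if (identical(p$type, "ledger"))
      ledger <- unlist(p$counts)
  }
  new("SolutionArchive", header = header, records = recs,
      assemblies = asms, ledger = ledger)
}

#' Export a solution as PDB
#'
#' Writes the placements of one archived solution as a PDB file with a
#' CRYST1 record, chains lettered by placement order.  Multi-member
#' ensembles are written either as one chain with successive
#' alternate-location indicators per member (`altloc`) or as the single
#' member scoring best against the backend (`best_member`).
#'
#' @param archive a [SolutionArchive-class].
#' @param solutionId the solution to export.
#' @param models model registry resolving placed model ids to coordinates.
#' @param mode "altloc" or "best_member".
#' @param backend scoring backend (required for best_member).
#' @param path output file.
#' @return invisibly the path.
#' @export
exportSolution <- function(archive, solutionId, models, path,
                           mode = c("altloc", "best_member"),
                           backend = NULL) {
  mode <- match.arg(mode)
  rec <- NULL
  for (r in archive@records) if (r$solution_id == solutionId) rec <- r
  if (is.null(rec)) stopf("solution '%s' not found in archive", solutionId)
  sol <- .recordToSolution(rec)
  if (mode == "best_member" && is.null(backend))
    stopf("best_member export requires a backend")
  cell <- .cellFromArchive(archive)
  comps <- archive@header$components
  seqOf <- stats::setNames(vapply(comps, function(c) c$sequence, character(1)),
                           vapply(comps, function(c) c$id, character(1)))
  chains <- list()
  for (p in sol@placements) {
    m <- models[[p@modelId]]
    if (is.null(m)) stopf("model '%s' not in registry", p@modelId)
    if (length(m@members) == 1L || mode == "best_member") {
      memIdx <- 1L
      if (length(m@members) > 1L) {
        scores <- vapply(seq_along(m@members), function(k) {
          mk <- m
          mk@members <- m@members[k]
          mk@modelId <- paste0(m@modelId, "#", k)
          reg <- models
          reg[[mk@modelId]] <- mk
          pk <- placement(p@componentId, mk@modelId, p@rot, p@trans)
          backend$score(list(pk), reg)$llg
        }, numeric(1))
        memIdx <- which.max(scores)
      }
      coords <- m@members[[memIdx]] %*% t(p@rot) +
        matrix(p@trans, length(m@resIdx), 3, TRUE)
      chains[[length(chains) + 1L]] <-
        list(coords = coords, resIdx = m@resIdx,
             sequence = seqOf[[p@componentId]], bvals = m@bvals)
    } else {
      if (length(m@members) > 26)
        stopf("altloc exhaustion: ensemble has more than 26 members")
      ## all members in one chain under successive altloc indicators
      coordsAll <- NULL; alts <- NULL
      for (k in seq_along(m@members)) {
        ck <- m@members[[k]] %*% t(p@rot) +
          matrix(p@trans, length(m@resIdx), 3, TRUE)
        coordsAll <- rbind(coordsAll, ck)
        alts <- c(alts, rep(LETTERS[k], nrow(ck)))
      }
      chains[[length(chains) + 1L]] <-
        list(coords = coordsAll, resIdx = rep(m@resIdx, length(m@members)),
             sequence = seqOf[[p@componentId]],
             bvals = rep(m@bvals, length(m@members)), altVec = alts)
    }
  }
  ## writeCaPdb handles per-chain constant alt; expand per-atom alt here
  .writeChainsWithAlt(chains, path, cell, sol@sgSymbol)
}

.writeChainsWithAlt <- function(chains, path, cell, sgSymbol) {
  if (length(chains) > 26)
    stopf("chain-id exhaustion: %d placements exceed 26 chain letters",
          length(chains))
  xyz <- c(); resno <- c(); chainId <- c(); resid <- c(); b <- c(); alt <- c()
  for (i in seq_along(chains)) {
    ch <- chains[[i]]
    n <- nrow(ch$coords)
    xyz <- c(xyz, as.vector(t(ch$coords)))
    resno <- c(resno, ch$resIdx + 1L)
    chainId <- c(chainId, rep(LETTERS[i], n))
    rid <- if (!is.null(ch$sequence))
      bio3d::aa123(strsplit(ch$sequence, "")[[1]][ch$resIdx + 1L])
    else rep("ALA", n)
    resid <- c(resid, rid)
    b <- c(b, if (!is.null(ch$bvals)) ch$bvals else rep(20, n))
    alt <- c(alt, if (!is.null(ch$altVec)) ch$altVec else rep("", n))
  }
  tmp <- tempfile(fileext = ".pdb")
  bio3d::write.pdb(file = tmp, xyz = xyz, resno = resno, chain = chainId,
                   resid = resid, b = b, alt = alt,
                   elety = rep("CA", length(resno)))
  body <- readLines(tmp, warn = FALSE)
  unlink(tmp)
  writeLines(c(.cryst1Line(cell, sgSymbol), body), path)
  invisible(path)
}

## ---- executor -----------------------------------------------------------

#' Deterministic parallel map with fast-job pooling
#'
#' Executes a list of pure jobs: jobs with cost hint "fast" are packaged
#' into batches of `poolThreshold` and executed as one unit; "slow" jobs run
#' individually.  Results are returned in input order regardless of worker
#' count; a failing job yields a recorded error, not an abort.
#'
#' @param jobs list of list(fun, args = list(), kind, costHint).
#' @param workers worker processes (1 = in-process).
#' @param poolThreshold fast-job batch size (default 20).
#' @return list(results, errors (logical), nBatches).
#' @export
parallelMap <- function(jobs, workers = 1L, poolThreshold = 20L) {
  if (length(jobs) == 0)
    return(list(results = list(), errors = logical(0), nBatches = 0L))
  idx <- seq_along(jobs)
  fast <- vapply(jobs, function(j)
    identical(j$costHint %||% "slow", "fast"), logical(1))
  units <- list()
  fastIdx <- idx[fast]
  if (length(fastIdx)) {
    starts <- seq(1, length(fastIdx), by = poolThreshold)
    for (s in starts)
      units[[length(units) + 1L]] <-
        fastIdx[s:min(s + poolThreshold - 1, length(fastIdx))]
  }
  for (i in idx[!fast]) units[[length(units) + 1L]] <- i
  runUnit <- function(u) {
    lapply(u, function(i) {
      j <- jobs[[i]]
      tryCatch(list(ok = TRUE,
                    value = do.call(j$fun, j$args %||% list())),
               error = function(e) list(ok = FALSE,
                                        value = conditionMessage(e)))
    })
  }
  unitRes <- if (workers > 1L) {
    parallel::mclapply(units, runUnit, mc.cores = workers,
                       mc.preschedule = FALSE)
  } else lapply(units, runUnit)
  results <- vector("list", length(jobs))
  errors <- logical(length(jobs))
  for (k in seq_along(units)) {
    for (q in seq_along(units[[k]])) {
      i <- units[[k]][q]
      r <- unitRes[[k]][[q]]
      results[[i]] <- r$value
      errors[i] <- !r$ok
    }
  }
  list(results = results, errors = errors, nBatches = length(units))
}

## ---- config-driven runs -------------------------------------------------

## Build (cfg, crystal, models, sgChoice) from a YAML config without
## running the search.
.materializeConfig <- function(configPath, outDir = NULL) {
  cf <- yaml::read_yaml(configPath)
  cfg <- .cfgFromList(c(cf$engine %||% list(),
                        list(mode = cf$mode %||% (cf$engine$mode %||% "full"),
                             seed = cf$seed %||% (cf$engine$seed %||% 1))))
  if (is.null(cf$genspec))
    stopf("config must contain a genspec block (synthetic crystal)")
  gs <- cf$genspec
  gspec <- list(components = lapply(gs$components, function(g)
    list(id = g$id, length = g$length, copies = g$copies %||% 1L)),
    spaceGroup = gs$space_group %||% "P1", solvent = gs$solvent %||% 0.5,
    sigma = gs$sigma, sigmaRot = gs$sigma_rot, epsilon = gs$epsilon,
    templateNoise = gs$template_noise)
  gspec <- Filter(Negate(is.null), gspec)
  if (!is.null(gs$assembly))
    gspec$assembly <- list(component = gs$assembly$component,
                           group = gs$assembly$group,
                           axis = gs$assembly$axis,
                           radius = gs$assembly$radius)
  gen <- generateCrystal(gspec, seed = cfg@seed, outDir = outDir)
  models <- gen$models
  if (!is.null(cf$variants)) {
    tmpl <- models[[1]]
    models <- makeModelVariants(tmpl, .variantCount(cf$variants),
                                noise = cf$variants$noise %||% 0.3,
                                seed = cfg@seed)
  }
  ## the config's stated copy counts are the ASU contents (known
  ## stoichiometry); without them the engine falls back to the Matthews
  ## estimate
  copies <- vapply(gs$components, function(g)
    as.integer(g$copies %||% 1L), integer(1))
  names(copies) <- vapply(gs$components, function(g) g$id, character(1))
  list(cfg = cfg, crystal = gen$crystal, models = models,
       asu = list(copies = copies, nComplexes = 1L),
       sgChoice = cf$space_group %||% gen$crystal@sg@symbol)
}

#' Run a search from a config file
#'
#' The structured-text (YAML) run configuration names the components, the
#' model inputs (at any stage of the preparation hierarchy), the
#' space-group knowledge, the engine settings, and either a synthetic
#' crystal specification (`genspec`) or a user crystal description.
#'
#' @param configPath YAML config file.
#' @param outDir optional output directory: archive + exported best
#'   solution are written there.
#' @return list(archive, ranked, crystal, models).
#' @export
runFromConfig <- function(configPath, outDir = NULL) {
  res <- .materializeConfig(configPath, outDir = outDir)
  cfg <- res$cfg; crystal <- res$crystal; models <- res$models
  backend <- toyBackend(crystal)
  arch <- runSearch(crystal@components, unname(models), backend,
                    res$sgChoice, cfg, asu = res$asu)
  ranked <- finalizeOutput(arch, cfg)
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    writeArchive(arch, file.path(outDir, "archive.jsonl"))
    if (length(ranked)) {
      reg <- stats::setNames(models, vapply(models, function(m) m@modelId,
                                            character(1)))
      exportSolution(arch, ranked[[1]]$solution_id, reg,
                     file.path(outDir, "best.pdb"), mode = "altloc")
    }
  }
  list(archive = arch, ranked = ranked, crystal = crystal, models = models)
}

#' Command-line entry point
#'
#' Subcommands: `run <config> [outdir]`, `enumerate <config>`,
#' `solutions list <archive>`, `solutions export <archive> <id> <mode>
#' <out.pdb>` (export requires a config-driven rerun for coordinates and is
#' supported through `run`'s output directory instead).
#'
#' @param argv character vector of arguments.
#' @return integer exit status.
#' @export
cli <- function(argv = commandArgs(trailingOnly = TRUE)) {
  usage <- function() {
    cat("usage:\n",
        "  run <config.yaml> [outdir]\n",
        "  enumerate <config.yaml>\n",
        "  solutions list <archive.jsonl>\n",
        "  solutions export <archive.jsonl> <solution_id> <altloc|best_member> <out.pdb> <config.yaml>\n",
        sep = "")
    1L
  }
  if (length(argv) < 1) return(usage())
  cmd <- argv[1]
  if (cmd == "run") {
    if (length(argv) < 2) return(usage())
    out <- runFromConfig(argv[2], outDir = if (length(argv) >= 3) argv[3])
    rk <- out$ranked
    cat(sprintf("run complete: %d solution(s) above threshold\n", length(rk)))
    for (r in utils::head(rk, 5))
      cat(sprintf("  %s  sg %s  placed %d  llg %.2f\n", r$solution_id,
                  r$sg, length(r$placements), r$llg))
    return(0L)
  }
  if (cmd == "enumerate") {
    if (length(argv) < 2) return(usage())
    cf <- yaml::read_yaml(argv[2])
    cfg <- .cfgFromList(c(cf$engine %||% list(), list(seed = cf$seed %||% 1)))
    gs <- cf$genspec
    comps <- list()
    copies <- c()
    for (g in gs$components) {
      sq <- paste(rep("A", g$length), collapse = "")
      comps[[g$id]] <- componentSpec(g$id, sq)
      copies[g$id] <- g$copies %||% 1L
    }
    nModels <- if (is.null(cf$variants)) 1L else .variantCount(cf$variants)
    tmpl <- new("EnsembleModel", modelId = "m1", componentId = names(comps)[1],
                members = list(matrix(0, 3, 3)), resIdx = 0:2,
                bvals = rep(20, 3), coverage = cbind(0L, 3L), weight = 300,
                sourceTemplateId = "t1", protocolId = "p")
    models <- makeModelVariants(tmpl, nModels, noise = 0)
    en <- dryRunEnumerate(comps, models, list(copies = copies), cfg)
    cat(sprintf("complete assignments (no reduction): %.0f\n", en$assignments))
    cat(sprintf("lineages with template equivalence:  %.0f\n", en$lineages))
    cat(sprintf("model evaluations per step:          %d\n",
                en$evaluationsPerStep))
    return(0L)
  }
  if (cmd == "solutions") {
    if (length(argv) < 3) return(usage())
    sub <- argv[2]
    arch <- readArchive(argv[3])
    if (sub == "list") {
      recs <- Filter(function(r) length(r$placements) > 0, arch@records)
      ord <- order(-vapply(recs, function(r) r$llg, numeric(1)))
      cat(sprintf("%-8s %-10s %8s %6s %10s  %s\n", "id", "sg", "placed",
                  "status", "llg", "tfz_history"))
      for (r in recs[ord])
        cat(sprintf("%-8s %-10s %8d %6s %10.2f  %s\n", r$solution_id, r$sg,
                    length(r$placements), substr(r$status, 1, 6), r$llg,
                    paste(sprintf("%.1f", unlist(r$tfz_history)),
                          collapse = ",")))
      return(0L)
    }
    if (sub == "export") {
      if (length(argv) < 7) return(usage())
      id <- argv[4]; mode <- argv[5]; outPdb <- argv[6]; cfPath <- argv[7]
      ## coordinates are not stored in the archive: regenerate the model
      ## registry from the config's synthetic crystal (same seed)
      res <- .materializeConfig(cfPath)
      reg <- stats::setNames(res$models,
                             vapply(res$models, function(m) m@modelId,
                                    character(1)))
      exportSolution(arch, id, reg, outPdb, mode = mode,
                     backend = toyBackend(res$crystal))
      cat(sprintf("wrote %s\n", outPdb))
      return(0L)
    }
    return(usage())
  }
  usage()
}
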