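# Template editing protocols, ensemble building, priority expansion,
# PDB round trip.

mkTemplate <- function(L = 30, seed = 2) {
  set.seed(seed)
  coords <- matrix(rnorm(L * 3, sd = 6), L, 3)
  modelInput("template", coords = coords, resIdx = 0:(L - 1L),
             bvals = runif(L, 10, 60),
             alignment = alignmentPair(strrep("A", L), strrep("A", L)),
             sourceTemplateId = "tmplX")
}

test_that("template editing applies pruning and B-value schemes", {
  L <- 30
  tmpl <- mkTemplate(L)
  target <- strrep("A", L)
  protos <- defaultProtocols()
  ## identity alignment, no pruning, B as-is: coordinates unchanged
  em <- editTemplate(tmpl, proto = protos$p1_asis, targetSeq = target,
                     modelId = "m1", componentId = "A")
  expect_equal(em@members[[1]], tmpl$coords)
  expect_equal(coverage(em), cbind(start = 0, end = L), ignore_attr = TRUE)
  expect_equal(em@bvals, tmpl$bvals)
  ## alignment covering [10, 30): pruned model has exactly 20 residues
  ta <- strrep("A", L)
  ma <- paste0(strrep("-", 10), strrep("A", 20))
  alPart <- alignmentPair(ta, ma)
  emp <- editTemplate(modelInput("template", coords = tmpl$coords[1:20, ],
                                 resIdx = 0:19, bvals = tmpl$bvals[1:20],
                                 alignment = alPart,
                                 sourceTemplateId = "tmplX"),
                      proto = protos$p2_prune, targetSeq = target,
                      modelId = "m2", componentId = "A")
  expect_equal(nrow(emp@members[[1]]), 20)
  expect_equal(emp@resIdx, 10:29)
  ## perfect identity + similarity scheme: all B equal 20
  ems <- editTemplate(tmpl, proto = protos$p4_prune_bsim, targetSeq = target,
                      modelId = "m3", componentId = "A")
  expect_true(all(abs(ems@bvals - 20) < 1e-9))
  ## constant scheme sets B = 20 regardless of input
  emc <- editTemplate(tmpl, proto = protos$p3_prune_bconst,
                      targetSeq = target, modelId = "m4", componentId = "A")
  expect_true(all(emc@bvals == 20))
  ## low-identity windows are deleted in the strictest mode
  mismatched <- alignmentPair(strrep("A", L),
                              paste0(strrep("V", 15), strrep("A", 15)))
  emx <- editTemplate(modelInput("template", coords = tmpl$coords,
                                 resIdx = 0:(L - 1L), bvals = tmpl$bvals,
                                 alignment = mismatched,
                                 sourceTemplateId = "tmplX"),
                      proto = protos$p5_lowid_bconst, targetSeq = target,
                      modelId = "m5", componentId = "A")
  expect_lt(length(emx@resIdx), L)
  expect_true(all(emx@resIdx >= 10))  # low-identity N-terminal windows gone
})

test_that("template editing is idempotent for a fixed protocol", {
  L <- 30
  tmpl <- mkTemplate(L)
  target <- strrep("A", L)
  proto <- defaultProtocols()$p3_prune_bconst
  em1 <- editTemplate(tmpl, proto = proto, targetSeq = target,
                      modelId = "m", componentId = "A")
  again <- modelInput("template", coords = em1@members[[1]],
                      resIdx = em1@resIdx, bvals = em1@bvals,
                      alignment = alignmentPair(target, target),
                      sourceTemplateId = em1@sourceTemplateId)
  em2 <- editTemplate(again, proto = proto, targetSeq = target,
                      modelId = "m", componentId = "A")
  expect_equal(em2@members[[1]], em1@members[[1]])
  expect_equal(em2@bvals, em1@bvals)
  expect_equal(em2@coverage, em1@coverage)
})

test_that("ensemble building superposes members and trims outliers", {
  L <- 20
  set.seed(9)
  base <- matrix(rnorm(L * 3, sd = 6), L, 3)
  mkSet <- function(coords) list(coords = coords, resIdx = 0:(L - 1L),
                                 bvals = rep(20, L))
  target <- strrep("A", L)
  ## single member returned unchanged
  one <- buildEnsemble(list(mkSet(base)), targetSeq = target)
  expect_equal(one@members[[1]], base)
  ## two identical members under a known rotation superpose to rmsd 0
  R <- axisAngleRotation(c(0, 1, 1), 40)
  rot <- base %*% t(R) + matrix(c(3, -2, 5), L, 3, TRUE)
  two <- buildEnsemble(list(mkSet(base), mkSet(rot)), targetSeq = target)
  expect_equal(length(two@members), 2)
  expect_lt(max(abs(two@members[[1]] - two@members[[2]])), 1e-6)
  expect_equal(length(two@resIdx), L)
  ## one residue displaced 10 A is trimmed, and only that residue
  moved <- base
  moved[7, ] <- moved[7, ] + c(10, 0, 0)
  tr <- buildEnsemble(list(mkSet(base), mkSet(moved)), targetSeq = target)
  expect_equal(length(tr@resIdx), L - 1)
  expect_false(6 %in% tr@resIdx)  # residue index 6 (0-based) was trimmed
  ## too few common residues fails
  expect_error(buildEnsemble(list(list(coords = base[1:2, ], resIdx = 0:1,
                                       bvals = rep(20, 2))),
                             targetSeq = target), "common residues")
})

test_that("model inputs expand into ensembles in priority order", {
  L <- 25
  spec <- componentSpec("A", strrep("A", L))
  set.seed(4)
  mkCoords <- function() matrix(rnorm(L * 3, sd = 6), L, 3)
  ident <- alignmentPair(strrep("A", L), strrep("A", L))
  ready <- modelInput("ensemble", coords = mkCoords(), resIdx = 0:(L - 1L),
                      sourceTemplateId = "ready1")
  tmpl <- modelInput("template", coords = mkCoords(), resIdx = 0:(L - 1L),
                     alignment = ident, sourceTemplateId = "tm1")
  hitHi <- modelInput("homology_hit", coords = mkCoords(),
                      resIdx = 0:(L - 1L), alignment = ident,
                      identity = 0.4, sourceTemplateId = "hit_hi")
  hitLo <- modelInput("homology_hit", coords = mkCoords(),
                      resIdx = 0:(L - 1L), alignment = ident,
                      identity = 0.2, sourceTemplateId = "hit_lo")
  out <- expandToEnsembles(spec, list(hitLo, tmpl, ready, hitHi), seed = 1)
  ## ready ensemble first; one ensemble per protocol per template/hit
  expect_equal(out[[1]]@protocolId, "ready")
  nproto <- length(defaultProtocols())
  expect_length(out, 1 + 3 * nproto)
  srcs <- vapply(out[-1], function(m) m@sourceTemplateId, character(1))
  ## the plain template precedes the hits; 0.4 identity precedes 0.2
  expect_equal(unique(srcs), c("tm1", "hit_hi", "hit_lo"))
  ## sequence-only inputs contribute nothing
  out2 <- expandToEnsembles(spec, list(modelInput("sequence_only")), seed = 1)
  expect_length(out2, 0)
  ## shuffle reproducibility: identical seeds give identical protocol order
  outA <- expandToEnsembles(spec, list(tmpl), seed = 42)
  outB <- expandToEnsembles(spec, list(tmpl), seed = 42)
  expect_equal(vapply(outA, function(m) m@protocolId, character(1)),
               vapply(outB, function(m) m@protocolId, character(1)))
})

test_that("Calpha PDB files round-trip through write and read", {
  L <- 18
  set.seed(5)
  coords <- matrix(rnorm(L * 3, sd = 6), L, 3)
  cell <- unitCell(30, 34, 38)
  path <- tempfile(fileext = ".pdb")
  writeCaPdb(list(list(coords = coords, resIdx = 0:(L - 1L),
                       sequence = strrep("A", L))),
             path, cell = cell, sgSymbol = "P212121")
  cs <- readCoordSet(path)
  expect_equal(cs$coords, coords, tolerance = 1e-3)  # PDB precision
  expect_equal(cs$resIdx, 0:(L - 1L))
  expect_equal(cs$cell@a, 30, tolerance = 1e-3)
  expect_equal(cs$cell@beta, 90)
})

test_that("homology-hit tables resolve templates and alignments", {
  dir <- tempfile()
  dir.create(dir)
  L <- 12
  set.seed(6)
  coords <- matrix(rnorm(L * 3, sd = 5), L, 3)
  pdb <- file.path(dir, "hit1.pdb")
  writeCaPdb(list(list(coords = coords, resIdx = 0:(L - 1L),
                       sequence = strrep("A", L))), pdb)
  aln <- file.path(dir, "hit1.aln.fasta")
  writeLines(c(">target", strrep("A", L), ">hit1", strrep("A", L)), aln)
  tab <- file.path(dir, "hits.tsv")
  utils::write.table(data.frame(hit_id = "hit1", template_pdb_path = "hit1.pdb",
                                alignment_path = "hit1.aln.fasta",
                                identity = 0.35),
                     tab, sep = "\t", row.names = FALSE, quote = FALSE)
  hits <- readHitTable(tab)
  expect_length(hits, 1)
  expect_equal(hits[[1]]$stage, "homology_hit")
  expect_equal(hits[[1]]$identity, 0.35)
  expect_equal(nrow(hits[[1]]$coords), L)
  expect_equal(nrow(hits[[1]]$alignment$columns), L)
})
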