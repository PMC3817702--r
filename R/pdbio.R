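# PDB coordinate I/O behind bio3d.  Models are Calpha-only: readers extract
# CA atoms from full-atom files; writers emit one CA per residue, with an
# optional CRYST1 record (bio3d's writer does not emit one itself).

#' Read a Calpha coordinate set from a PDB file
#'
#' Extracts the Calpha trace: coordinates, 0-based residue indices
#' (resno - 1) and B values.  Full-atom files are accepted.
#'
#' @param path PDB file.
#' @param chain optional chain selector.
#' @return list(coords = N x 3 matrix, resIdx = integer, bvals = numeric,
#'   cell = [UnitCell-class] or NULL).
#' @export
readCoordSet <- function(path, chain = NULL) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  sel <- if (is.null(chain)) bio3d::atom.select(pdb, "calpha", verbose = FALSE)
         else bio3d::atom.select(pdb, "calpha", chain = chain, verbose = FALSE)
  at <- pdb$atom[sel$atom, , drop = FALSE]
  if (nrow(at) == 0) stopf("no Calpha atoms in %s", path)
  cell <- NULL
  ## bio3d does not parse CRYST1; read it directly when present
  ln <- grep("^CRYST1", readLines(path, warn = FALSE), value = TRUE)
  if (length(ln) >= 1) {
    f <- as.numeric(c(substr(ln[1], 7, 15), substr(ln[1], 16, 24),
                      substr(ln[1], 25, 33), substr(ln[1], 34, 40),
                      substr(ln[1], 41, 47), substr(ln[1], 48, 54)))
    if (all(is.finite(f))) cell <- unitCell(f[1], f[2], f[3], f[4], f[5], f[6])
  }
  list(coords = unname(as.matrix(at[, c("x", "y", "z")])),
       resIdx = as.integer(at$resno) - 1L,
       bvals = as.numeric(at$b), cell = cell)
}

.cryst1Line <- function(cell, sgSymbol) {
  spaced <- c(P1 = "P 1", P21 = "P 1 21 1", C2 = "C 1 2 1",
              P212121 = "P 21 21 21", P21212 = "P 21 21 2",
              P41 = "P 41", P43 = "P 43")[normalizeSymbol(sgSymbol)]
  if (is.na(spaced)) spaced <- sgSymbol
  sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f %-11s%4d",
          cell@a, cell@b, cell@c, cell@alpha, cell@beta, cell@gamma, spaced, 1L)
}

#' Write Calpha chains as a PDB file
#'
#' Each entry of `chains` is a list(coords, resIdx, sequence?, bvals?,
#' alt?); chains are lettered A, B, ... in order.  A CRYST1 record is
#' written when a cell is supplied.
#'
#' @param chains list of coordinate sets.
#' @param path output file.
#' @param cell optional [UnitCell-class].
#' @param sgSymbol space-group symbol for CRYST1.
#' @return invisibly the path.
#' @export
writeCaPdb <- function(chains, path, cell = NULL, sgSymbol = "P1") {
  if (length(chains) > 26)
    stopf("chain-id exhaustion: %d placements exceed 26 chain letters; export fewer placements per file", length(chains))
  xyz <- c(); resno <- c(); chainId <- c(); resid <- c(); b <- c(); alt <- c()
  for (i in seq_along(chains)) {
    ch <- chains[[i]]
    n <- nrow(ch$coords)
    xyz <- c(xyz, as.vector(t(ch$coords)))
    resno <- c(resno, ch$resIdx + 1L)
    chainId <- c(chainId, rep(LETTERS[i], n))
    rid <- if (!is.null(ch$sequence)) {
      bio3d::aa123(strsplit(ch$sequence, "")[[1]][ch$resIdx + 1L])
    } else rep("ALA", n)
    resid <- c(resid, rid)
    b <- c(b, if (!is.null(ch$bvals)) ch$bvals else rep(20, n))
    alt <- c(alt, if (!is.null(ch$alt)) rep(ch$alt, n) else rep("", n))
  }
  tmp <- tempfile(fileext = ".pdb")
  bio3d::write.pdb(file = tmp, xyz = xyz, resno = resno, chain = chainId,
                   resid = resid, b = b, alt = alt,
                   elety = rep("CA", length(resno)))
  body <- readLines(tmp, warn = FALSE)
  unlink(tmp)
  out <- if (!is.null(cell)) c(.cryst1Line(cell, sgSymbol), body) else body
  writeLines(out, path)
  invisible(path)
}

#' Write component sequences as FASTA
#'
#' @param components list of [ComponentSpec-class].
#' @param path output file.
#' @return invisibly the path.
#' @export
writeComponentFasta <- function(components, path) {
  lines <- unlist(lapply(components, function(cs)
    c(paste0(">", cs@componentId), cs@sequence)))
  writeLines(lines, path)
  invisible(path)
}
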