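#' @import methods
#' @importFrom stats median setNames hclust cutree dist as.dist sd rnorm runif coef resid ave
#' @importFrom utils read.csv write.csv head combn
NULL

setClassUnion("matrixOrNull", c("matrix", "NULL"))

#' Molecule: a small-molecule graph with optional 3D conformer
#'
#' Heavy-atom molecular graph with perceived aromaticity, integer formal
#' charges and implicit hydrogen counts.  Hydrogens are implicit: they are
#' counted per heavy atom (`nH`) but never stored as graph nodes.  A single
#' conformer (one 3D coordinate per heavy atom, in Angstrom) may be attached
#' by [embedConformer()].
#'
#' @slot id molecule identifier (e.g. a catalogue code).
#' @slot smiles the SMILES string the molecule was built from.
#' @slot atoms data.frame with columns `element`, `charge` (integer formal
#'   charge), `aromatic` (logical), `nH` (implicit hydrogen count).
#' @slot bonds data.frame with columns `a1`, `a2` (1-based atom indices),
#'   `order` (1, 2, 3), `aromatic` (logical).
#' @slot conformer numeric matrix (n_atoms x 3) of coordinates in Angstrom,
#'   or NULL when no conformer is attached.
#' @slot meta list of free-form metadata (e.g. the embedding seed).
#' @export
setClass("Molecule",
  representation(id = "character", smiles = "character",
                 atoms = "data.frame", bonds = "data.frame",
                 conformer = "matrixOrNull", meta = "list"),
  prototype(conformer = NULL, meta = list()))

setValidity("Molecule", function(object) {
  n <- nrow(object@atoms)
  msgs <- character()
  if (!all(c("element", "charge", "aromatic", "nH") %in% names(object@atoms)))
    msgs <- c(msgs, "atoms must have element/charge/aromatic/nH columns")
  if (nrow(object@bonds) > 0) {
    idx <- c(object@bonds$a1, object@bonds$a2)
    if (any(idx < 1 | idx > n)) msgs <- c(msgs, "bond endpoints out of range")
  }
  if (!is.null(object@conformer)) {
    if (nrow(object@conformer) != n || ncol(object@conformer) != 3)
      msgs <- c(msgs, "conformer must be n_atoms x 3")
    if (any(!is.finite(object@conformer)))
      msgs <- c(msgs, "conformer coordinates must be finite")
  }
  if (length(object@atoms$charge) && any(object@atoms$charge != round(object@atoms$charge)))
    msgs <- c(msgs, "formal charges must be integers")
  if (length(msgs)) msgs else TRUE
})

#' @describeIn Molecule number of heavy atoms
#' @param x,object a `Molecule`
#' @export
natoms <- function(x) nrow(x@atoms)

#' @describeIn Molecule molecule identifier
#' @export
molId <- function(x) x@id

#' @describeIn Molecule conformer coordinates (or NULL)
#' @export
conformer <- function(x) x@conformer

#' @describeIn Molecule TRUE when a conformer is attached
#' @export
hasConformer <- function(x) !is.null(x@conformer)

setMethod("show", "Molecule", function(object) {
  cat("Molecule", object@id, "\n")
  cat(" ", natoms(object), "heavy atoms,", nrow(object@bonds), "bonds,",
      sum(object@atoms$aromatic), "aromatic atoms\n")
  cat("  conformer:", if (hasConformer(object)) "yes" else "no", "\n")
})

# legacy V2000 per-atom charge field -> formal charge
.v2000Charge <- function(code) {
  map <- c(`0` = 0L, `1` = 3L, `2` = 2L, `3` = 1L, `4` = 0L,
           `5` = -1L, `6` = -2L, `7` = -3L)
  unname(map[as.character(code)])
}

# Convert SMILES text (one per line, name after whitespace) through
# OpenBabel into an SDF string.  `addH` adds explicit hydrogens; `gen3d`
# also generates one 3D conformer (deterministic builder).
.obSmilesToSdf <- function(smilesLines, addH = TRUE, gen3d = FALSE) {
  opts <- data.frame(names = character(), args = character(),
                     stringsAsFactors = FALSE)
  if (gen3d) opts <- rbind(opts, data.frame(names = "gen3D", args = ""))
  else if (addH) opts <- rbind(opts, data.frame(names = "h", args = ""))
  out <- tryCatch(
    ChemmineOB::convertFormat("SMI", "SDF",
                              source = paste(smilesLines, collapse = "\n"),
                              options = if (nrow(opts)) opts else NULL),
    error = function(e) "")
  out
}

.sdfTextToSdfset <- function(txt) {
  tf <- tempfile(fileext = ".sdf")
  on.exit(unlink(tf))
  writeLines(txt, tf)
  ChemmineR::read.SDFset(tf)
}

# "M  CHG" property lines of one V2000 block -> full-length charge vector,
# or NULL when the block carries no charge properties.  Per the format,
# any M CHG line supersedes the legacy atom-block charge column entirely.
.mchgCharges <- function(blockLines, nAll) {
  lines <- grep("^M  CHG", blockLines, value = TRUE)
  if (!length(lines)) return(NULL)
  chg <- rep(0L, nAll)
  for (ln in lines) {
    nums <- suppressWarnings(
      as.integer(strsplit(trimws(substring(ln, 7)), "[[:space:]]+")[[1]]))
    cnt <- nums[1]
    for (k in seq_len(cnt)) chg[nums[2 * k]] <- nums[2 * k + 1]
  }
  chg
}

# Build a Molecule from one ChemmineR SDF component.  Explicit hydrogens
# are folded into per-heavy-atom nH counts; aromaticity comes from ring
# perception on the full structure.  `chargeOverride` (full-length integer
# vector from .mchgCharges) replaces the legacy atom-block charge column.
.sdfToMolecule <- function(sdf, id, smiles = NA_character_, keepCoords = FALSE,
                           chargeOverride = NULL) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elements <- sub("_.*$", "", rownames(ab))
  nAll <- nrow(ab)
  heavy <- which(elements != "H")
  idxMap <- rep(NA_integer_, nAll)
  idxMap[heavy] <- seq_along(heavy)

  charge <- if (!is.null(chargeOverride)) chargeOverride
            else .v2000Charge(if ("C5" %in% colnames(ab)) ab[, "C5"]
                              else rep(0, nAll))
  nH <- integer(length(heavy))
  b1 <- integer(0); b2 <- integer(0); bo <- integer(0)
  if (!is.null(bb) && nrow(bb) > 0) {
    for (i in seq_len(nrow(bb))) {
      u <- bb[i, 1]; v <- bb[i, 2]; o <- bb[i, 3]
      uH <- elements[u] == "H"; vH <- elements[v] == "H"
      if (uH && vH) next
      if (uH) { nH[idxMap[v]] <- nH[idxMap[v]] + 1L; next }
      if (vH) { nH[idxMap[u]] <- nH[idxMap[u]] + 1L; next }
      b1 <- c(b1, idxMap[u]); b2 <- c(b2, idxMap[v]); bo <- c(bo, o)
    }
  }

  aromAtoms <- rep(FALSE, length(heavy))
  aromBonds <- rep(FALSE, length(b1))
  rngs <- tryCatch(
    suppressWarnings(ChemmineR::rings(sdf, type = "all", arom = TRUE, inner = FALSE)),
    error = function(e) NULL)
  if (!is.null(rngs) && length(rngs$RINGS)) {
    for (k in seq_along(rngs$RINGS)) {
      if (!isTRUE(rngs$AROMATIC[[k]])) next
      ringIdx <- idxMap[as.integer(sub("^.*_", "", rngs$RINGS[[k]]))]
      ringIdx <- ringIdx[!is.na(ringIdx)]
      aromAtoms[ringIdx] <- TRUE
      inRing <- b1 %in% ringIdx & b2 %in% ringIdx
      aromBonds[inRing] <- TRUE
    }
  }

  conf <- NULL
  if (keepCoords) {
    conf <- unname(as.matrix(ab[heavy, c("C1", "C2", "C3"), drop = FALSE]))
    storage.mode(conf) <- "double"
  }

  new("Molecule", id = id, smiles = smiles,
      atoms = data.frame(element = elements[heavy],
                         charge = as.integer(charge[heavy]),
                         aromatic = aromAtoms, nH = nH,
                         stringsAsFactors = FALSE),
      bonds = data.frame(a1 = b1, a2 = b2, order = as.integer(bo),
                         aromatic = aromBonds),
      conformer = conf, meta = list())
}

.smilesCharOK <- function(s) {
  cls <- "^[]A-Za-z0-9@+()=#$:/%.*[\\\\-]*$"
  if (grepl(cls, s, perl = TRUE)) return(0L)
  chars <- strsplit(s, "")[[1]]
  bad <- !vapply(chars, grepl, logical(1), pattern = cls, perl = TRUE)
  which(bad)[1]
}

# balanced-delimiter check for SMILES branches and bracket atoms; returns
# an error message or NULL
.smilesBalanced <- function(s) {
  chars <- strsplit(s, "")[[1]]
  depthP <- 0L; depthB <- 0L
  for (i in seq_along(chars)) {
    c <- chars[i]
    if (c == "(") depthP <- depthP + 1L
    if (c == ")") {
      depthP <- depthP - 1L
      if (depthP < 0) return(paste0("unmatched ')' at position ", i))
    }
    if (c == "[") {
      if (depthB > 0) return(paste0("nested '[' at position ", i))
      depthB <- depthB + 1L
    }
    if (c == "]") {
      depthB <- depthB - 1L
      if (depthB < 0) return(paste0("unmatched ']' at position ", i))
    }
  }
  if (depthP != 0) return("unclosed '(' branch")
  if (depthB != 0) return("unclosed '[' bracket atom")
  NULL
}

#' Parse a SMILES string into a Molecule
#'
#' Aromaticity is perceived on the parsed structure; hydrogens are kept
#' implicit; no conformer is attached.
#'
#' @param s SMILES string (organic subset).
#' @param id identifier to attach.
#' @return a [Molecule-class] object.
#' @examples
#' m <- parseSmiles("c1ccccc1", "benzene")
#' natoms(m)
#' @export
parseSmiles <- function(s, id = "mol") {
  stopifnot(is.character(s), length(s) == 1)
  pos <- .smilesCharOK(s)
  if (pos > 0)
    stop("SMILES parse error for '", id, "': illegal character '",
         substr(s, pos, pos), "' at position ", pos)
  bal <- .smilesBalanced(s)
  if (!is.null(bal))
    stop("SMILES parse error for '", id, "': ", bal)
  txt <- .obSmilesToSdf(paste(s, id), addH = TRUE)
  if (!nzchar(txt) || !grepl("V2000", txt))
    stop("SMILES parse error for '", id, "': could not interpret '", s, "'")
  sdfset <- .sdfTextToSdfset(txt)
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
  m <- .sdfToMolecule(sdfset[[1]], id = id, smiles = s,
                      chargeOverride = .mchgCharges(
                        lines, nrow(ChemmineR::atomblock(sdfset[[1]]))))
  validObject(m)
  m
}

# Batch 3D embedding through the bundled distance-geometry helper script
# (ETKDG with a fixed random seed + MMFF cleanup).  Returns one record per
# input: list(ok, coords) with heavy-atom coordinates in SMILES atom order.
.embedBatch <- function(smiles, ids, seed = 1L) {
  py <- Sys.which("python3")
  if (!nzchar(py)) py <- Sys.which("python")
  if (!nzchar(py))
    stop("conformer embedding requires a python interpreter on PATH")
  script <- system.file("python", "embed3d.py", package = "hetscreen")
  if (!nzchar(script)) stop("embedding helper script not found")
  inp <- tempfile(fileext = ".tsv")
  on.exit(unlink(inp))
  writeLines(paste(smiles, ids, sep = "\t"), inp)
  out <- suppressWarnings(
    system2(py, c(shQuote(script), as.integer(seed)),
            stdin = inp, stdout = TRUE, stderr = FALSE))
  recs <- tryCatch(jsonlite::fromJSON(paste(out, collapse = ""),
                                      simplifyVector = FALSE),
                   error = function(e) NULL)
  if (is.null(recs) || length(recs) != length(smiles))
    stop("conformer embedding helper failed")
  lapply(recs, function(r)
    list(ok = isTRUE(r$ok),
         coords = if (isTRUE(r$ok))
           do.call(rbind, lapply(r$coords, as.numeric))))
}

#' Attach a single low-energy 3D conformer
#'
#' One conformer is generated by seeded distance-geometry embedding
#' (ETKDG) followed by MMFF94 force-field cleanup; rerunning with the same
#' molecule and seed reproduces identical coordinates.  The seed is
#' recorded in the molecule metadata.  On embedding failure the molecule
#' is returned conformer-free with `meta$embed_failed = TRUE`.
#'
#' @param m a [Molecule-class].
#' @param seed integer random seed for the embedding.
#' @return the molecule with `conformer` filled in.
#' @export
embedConformer <- function(m, seed = 1L) {
  stopifnot(is(m, "Molecule"))
  embedLibrary(list(m), seed)[[1]]
}

#' Embed conformers for a whole library in one pass
#'
#' Same contract as [embedConformer()] but embeds all molecules in a
#' single helper invocation, which is much faster for libraries.
#' Molecules that already carry a conformer are returned unchanged.
#'
#' @param mols list of [Molecule-class] objects.
#' @param seed integer random seed for the embedding.
#' @return list of molecules, conformers attached where embedding
#'   succeeded.
#' @export
embedLibrary <- function(mols, seed = 1L) {
  todo <- which(!vapply(mols, hasConformer, logical(1)))
  if (!length(todo)) return(mols)
  recs <- .embedBatch(vapply(mols[todo], slot, character(1), "smiles"),
                      vapply(mols[todo], molId, character(1)), seed)
  for (k in seq_along(todo)) {
    i <- todo[k]; m <- mols[[i]]; r <- recs[[k]]
    if (!r$ok || nrow(r$coords) != natoms(m)) {
      warning("conformer embedding failed for ", molId(m))
      m@meta$embed_failed <- TRUE
    } else {
      m@conformer <- r$coords
      m@meta$embed_seed <- as.integer(seed)
      m@meta$embed_failed <- FALSE
      validObject(m)
    }
    mols[[i]] <- m
  }
  mols
}

#' Read a SMILES file (one molecule per line, optional id after whitespace)
#'
#' @param path file path.
#' @return list of [Molecule-class] objects.
#' @export
readSmilesFile <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    parts <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
    id <- if (length(parts) >= 2) parts[2] else paste0("mol", i)
    out[[i]] <- parseSmiles(parts[1], id)
  }
  names(out) <- vapply(out, molId, character(1))
  out
}

#' Read molecules from an SDF (V2000) file
#'
#' Coordinates present in the file are kept as the conformer; a canonical
#' SMILES is generated so downstream operations that re-derive structures
#' can run.
#'
#' @param path SDF file path.
#' @return list of [Molecule-class] objects.
#' @export
readSdfFile <- function(path) {
  sdfset <- ChemmineR::read.SDFset(path)
  fileLines <- readLines(path)
  recEnds <- grep("^\\$\\$\\$\\$", fileLines)
  recStarts <- c(1L, head(recEnds, -1) + 1L)
  smis <- tryCatch(
    strsplit(ChemmineOB::convertFormat("SDF", "SMI",
             source = paste(fileLines, collapse = "\n")), "\n")[[1]],
    error = function(e) rep(NA_character_, length(sdfset)))
  out <- vector("list", length(sdfset))
  for (i in seq_along(sdfset)) {
    hdr <- ChemmineR::header(sdfset[[i]])[["Molecule_Name"]]
    id <- if (nzchar(trimws(hdr))) trimws(hdr) else paste0("mol", i)
    smi <- if (i <= length(smis)) trimws(sub("\t.*$", "", smis[i])) else NA_character_
    has3d <- any(ChemmineR::atomblock(sdfset[[i]])[, "C3"] != 0)
    recLines <- if (i <= length(recStarts) && i <= length(recEnds))
      fileLines[recStarts[i]:recEnds[i]] else character(0)
    out[[i]] <- .sdfToMolecule(sdfset[[i]], id = id, smiles = smi,
                               keepCoords = has3d,
                               chargeOverride = .mchgCharges(
                                 recLines,
                                 nrow(ChemmineR::atomblock(sdfset[[i]]))))
  }
  names(out) <- vapply(out, molId, character(1))
  out
}

#' Write molecules to an SDF (V2000) file
#'
#' Implicit hydrogens are not written; conformer coordinates are used when
#' present, zeros otherwise.
#'
#' @param mols list of [Molecule-class] objects.
#' @param path output path.
#' @export
writeSdfFile <- function(mols, path) {
  blocks <- vapply(mols, function(m) {
    n <- natoms(m); nb <- nrow(m@bonds)
    coords <- if (hasConformer(m)) m@conformer else matrix(0, n, 3)
    lines <- c(m@id, " hetscreen", "",
               sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nb))
    for (i in seq_len(n))
      lines <- c(lines, sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                                coords[i, 1], coords[i, 2], coords[i, 3],
                                m@atoms$element[i]))
    for (i in seq_len(nb))
      lines <- c(lines, sprintf("%3d%3d%3d  0  0  0  0",
                                m@bonds$a1[i], m@bonds$a2[i], m@bonds$order[i]))
    chg <- which(m@atoms$charge != 0)
    if (length(chg))
      lines <- c(lines, paste0("M  CHG", sprintf("%3d", length(chg)),
                               paste0(sprintf("%4d%4d", chg, m@atoms$charge[chg]),
                                      collapse = "")))
    paste(c(lines, "M  END", "$$$$"), collapse = "\n")
  }, character(1))
  writeLines(paste(blocks, collapse = "\n"), path)
  invisible(path)
}
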