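# Physicochemical property block from the OpenBabel descriptor engine
# (additive-fragment logP and topological polar surface area).
.obProps <- function(m) {
  txt <- .obSmilesToSdf(paste(m@smiles, m@id), addH = TRUE)
  sdfset <- .sdfTextToSdfset(txt)
  suppressWarnings(ChemmineR::propOB(sdfset))
}

#' Compute the seven-descriptor record used by the drug-likeness filter
#'
#' Molecular weight, additive-fragment logP estimate and topological polar
#' surface area come from the OpenBabel descriptor engine; hydrogen-bond
#' donor/acceptor counts use the same perception rules as
#' [perceiveFeatures()]; rotatable bonds are single non-ring bonds between
#' two non-terminal heavy atoms, excluding amide C-N; ring count is the
#' cyclomatic number of the heavy-atom graph.
#'
#' @param m a [Molecule-class].
#' @return one-row data.frame `mw, logp_est, hbd, hba, rotatable_bonds,
#'   ring_count, tpsa_est`.
#' @export
computeDescriptors <- function(m) {
  stopifnot(is(m, "Molecule"))
  p <- .obProps(m)
  deg <- tabulate(c(m@bonds$a1, m@bonds$a2), nbins = natoms(m))
  ringAtoms <- .inRing(m)
  rot <- 0L
  if (nrow(m@bonds)) {
    for (i in seq_len(nrow(m@bonds))) {
      a <- m@bonds$a1[i]; b <- m@bonds$a2[i]
      if (m@bonds$order[i] != 1) next
      if (deg[a] < 2 || deg[b] < 2) next
      if (ringAtoms[a] && ringAtoms[b]) {
        # non-ring bond check: bond is in a ring iff both ends share a ring
        inR <- FALSE
        for (r in .findRings(m)) if (a %in% r && b %in% r) { inR <- TRUE; break }
        if (inR) next
      }
      amide <- FALSE
      for (pair in list(c(a, b), c(b, a))) {
        if (m@atoms$element[pair[1]] == "C" && m@atoms$element[pair[2]] == "N") {
          dn <- c(m@bonds$a2[m@bonds$a1 == pair[1] & m@bonds$order == 2],
                  m@bonds$a1[m@bonds$a2 == pair[1] & m@bonds$order == 2])
          if (any(m@atoms$element[dn] == "O")) amide <- TRUE
        }
      }
      if (!amide) rot <- rot + 1L
    }
  }
  nComp <- .nComponents(m)
  data.frame(mw = p$MW[1], logp_est = p$logP[1],
             hbd = length(.hbdAtoms(m)), hba = length(.hbaAtoms(m)),
             rotatable_bonds = rot,
             ring_count = nrow(m@bonds) - natoms(m) + nComp,
             tpsa_est = p$TPSA[1])
}

.nComponents <- function(m) {
  n <- natoms(m)
  if (n == 0) return(0L)
  adj <- .adjacency(m)
  comp <- rep(NA_integer_, n); cid <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cid <- cid + 1L
    queue <- s; comp[s] <- cid
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      for (v in adj[[u]]) if (is.na(comp[v])) { comp[v] <- cid; queue <- c(queue, v) }
    }
  }
  cid
}

#' Default Lipinski descriptor ranges
#'
#' Inclusive bounds: mw <= 500, logp <= 5, hbd <= 5, hba <= 10.
#' @return named list of c(min, max) ranges.
#' @export
lipinskiRanges <- function() {
  list(mw = c(-Inf, 500), logp_est = c(-Inf, 5),
       hbd = c(-Inf, 5), hba = c(-Inf, 10))
}

#' Drug-likeness range filter
#'
#' Both range boundaries are inclusive.  The result lists every violated
#' descriptor.
#'
#' @param d one-row descriptor data.frame from [computeDescriptors()].
#' @param ranges named list of c(min, max) per descriptor; defaults to
#'   [lipinskiRanges()].
#' @return list(pass = logical, violations = character vector).
#' @export
druglikeFilter <- function(d, ranges = lipinskiRanges()) {
  if (!length(ranges)) stop("druglikeFilter: empty descriptor ranges")
  bad <- character(0)
  for (nm in names(ranges)) {
    if (!nm %in% names(d)) stop("descriptor '", nm, "' missing from record")
    v <- d[[nm]][1]
    if (v < ranges[[nm]][1] || v > ranges[[nm]][2]) bad <- c(bad, nm)
  }
  list(pass = length(bad) == 0, violations = bad)
}

#' Descriptor table for a set of molecules
#'
#' @param mols list of [Molecule-class] objects.
#' @return data.frame with an `id` column followed by the seven descriptors.
#' @export
computeDescriptorTable <- function(mols) {
  rows <- lapply(mols, function(m) cbind(id = molId(m), computeDescriptors(m)))
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Write the descriptor table as CSV
#' @param tab data.frame from [computeDescriptorTable()].
#' @param path output path.
#' @export
writeDescriptorCsv <- function(tab, path) {
  write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
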