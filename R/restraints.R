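#' Select active/passive residues for data-driven docking restraints
#'
#' Active residues are those with CSP above mean + SD (see
#' [thresholdResidues()]) together with residues that disappeared on
#' ligand binding.  Passive residues are solvent-accessible neighbours:
#' relative SASA at least `sasaMin` and at least one heavy atom within
#' `neighborCutoff` of an active residue, excluding the actives
#' themselves.  Ambiguous restraints carry a 2.0 Angstrom bound; optional
#' unambiguous (NOE-derived) contacts carry a 5.0 Angstrom bound.
#'
#' @param profile result of [computeCsp()].
#' @param structure a [ReceptorStructure-class].
#' @param sasaMin relative-SASA cutoff for passives (default 0.4).
#' @param neighborCutoff heavy-atom neighbour cutoff in Angstrom
#'   (default 6.5).
#' @param noePairs optional data.frame `resno, partner_atom` of unambiguous
#'   contacts.
#' @return list `active`, `passive` (residue numbers), `ambiguous`
#'   (data.frame resno, bound), `unambiguous` (data.frame with 5 A bound).
#' @export
selectActivePassive <- function(profile, structure, sasaMin = 0.4,
                                neighborCutoff = 6.5, noePairs = NULL) {
  a <- structure@atoms
  have <- unique(a$resno)
  cspRes <- as.integer(names(profile$csp))
  unmapped <- setdiff(union(cspRes, profile$disappeared), have)
  if (length(unmapped))
    warning("residues absent from structure skipped: ",
            paste(unmapped, collapse = ", "))
  active <- intersect(union(thresholdResidues(profile), profile$disappeared),
                      have)
  if (!length(active))
    warning("no active residues: nothing above mean + SD and none disappeared")

  sasa <- shrakeRupleySasa(structure)$residues
  heavy <- a[toupper(a$element) != "H", , drop = FALSE]
  actAtoms <- as.matrix(heavy[heavy$resno %in% active, c("x", "y", "z"),
                              drop = FALSE])
  passive <- integer(0)
  if (length(active) && nrow(actAtoms)) {
    for (r in setdiff(have, active)) {
      rel <- sasa$rel_sasa[sasa$resno == r][1]
      if (is.na(rel) || rel < sasaMin) next
      X <- as.matrix(heavy[heavy$resno == r, c("x", "y", "z"), drop = FALSE])
      d2 <- outer(rowSums(X^2), rowSums(actAtoms^2), "+") -
        2 * X %*% t(actAtoms)
      if (min(d2) <= neighborCutoff^2) passive <- c(passive, r)
    }
  }
  amb <- if (length(active))
    data.frame(resno = sort(active), bound = 2.0)
  else data.frame(resno = integer(), bound = numeric())
  unamb <- if (!is.null(noePairs) && nrow(noePairs))
    cbind(noePairs, bound = 5.0)
  else data.frame(resno = integer(), partner_atom = character(),
                  bound = numeric())
  list(active = sort(active), passive = sort(passive),
       ambiguous = amb, unambiguous = unamb)
}

#' Write restraints as CNS-style ambiguous-restraint text plus JSON mirror
#'
#' @param restraints result of [selectActivePassive()].
#' @param tblPath text output path (NULL = skip).
#' @param jsonPath JSON output path (NULL = skip).
#' @param segidA,segidB segment identifiers for the two molecules.
#' @export
writeRestraints <- function(restraints, tblPath = NULL, jsonPath = NULL,
                            segidA = "A", segidB = "B") {
  if (!is.null(tblPath)) {
    lines <- vapply(seq_len(nrow(restraints$ambiguous)), function(i)
      sprintf("assign (resid %d and segid %s) (segid %s) 2.0 2.0 0.0",
              restraints$ambiguous$resno[i], segidA, segidB), character(1))
    if (nrow(restraints$unambiguous))
      lines <- c(lines, vapply(seq_len(nrow(restraints$unambiguous)),
        function(i) sprintf(
          "assign (resid %d and segid %s) (name %s and segid %s) 5.0 5.0 0.0",
          restraints$unambiguous$resno[i], segidA,
          restraints$unambiguous$partner_atom[i], segidB), character(1)))
    writeLines(lines, tblPath)
  }
  if (!is.null(jsonPath))
    jsonlite::write_json(restraints, jsonPath, auto_unbox = TRUE, digits = NA)
  invisible(restraints)
}
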