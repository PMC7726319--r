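# van der Waals radii (Angstrom) for SASA computation
.vdwRadii <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
               F = 1.47, CL = 1.75, BR = 1.85, I = 1.98, SE = 1.90)

# Maximum solvent accessibility of residue X in an extended Gly-X-Gly
# tripeptide (theoretical values, Angstrom^2), used to normalize
# per-residue SASA.
.gxgReference <- c(ALA = 129, ARG = 274, ASN = 195, ASP = 193, CYS = 167,
                   GLN = 225, GLU = 223, GLY = 104, HIS = 224, ILE = 197,
                   LEU = 201, LYS = 236, MET = 224, PHE = 240, PRO = 159,
                   SER = 155, THR = 172, TRP = 285, TYR = 263, VAL = 174)

# deterministic quasi-uniform sphere sampling (golden-spiral lattice)
.spherePoints <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Samples `nPoints` quasi-uniform points on each atom's solvent-expanded
#' sphere (vdW radius + probe) and counts points not buried inside any
#' neighbouring sphere.  Atom areas are summed per residue; relative SASA
#' divides by the extended Gly-X-Gly reference for the residue type (NA
#' for non-standard residues).
#'
#' @param structure a [ReceptorStructure-class].
#' @param probe probe radius in Angstrom (default 1.4).
#' @param nPoints sphere sample points per atom (default 960).
#' @return list `atoms` (data.frame with per-atom `sasa`) and `residues`
#'   (data.frame `chain, resno, resname, sasa, rel_sasa`).
#' @export
shrakeRupleySasa <- function(structure, probe = 1.4, nPoints = 960L) {
  a <- structure@atoms
  el <- toupper(a$element)
  unknown <- setdiff(unique(el), names(.vdwRadii))
  if (length(unknown))
    stop("no van der Waals radius for element(s): ",
         paste(unknown, collapse = ", "))
  r <- .vdwRadii[el] + probe
  xyz <- as.matrix(a[, c("x", "y", "z")])
  n <- nrow(xyz)
  pts <- .spherePoints(nPoints)
  sasa <- numeric(n)
  for (i in seq_len(n)) {
    d2 <- rowSums(sweep(xyz, 2, xyz[i, ])^2)
    nbr <- which(d2 < (r[i] + r)^2 & seq_len(n) != i)
    p <- sweep(pts * r[i], 2, xyz[i, ], "+")
    exposed <- rep(TRUE, nPoints)
    for (j in nbr) {
      dj2 <- rowSums(sweep(p, 2, xyz[j, ])^2)
      exposed <- exposed & dj2 >= r[j]^2
      if (!any(exposed)) break
    }
    sasa[i] <- 4 * pi * r[i]^2 * sum(exposed) / nPoints
  }
  atoms <- cbind(a, sasa = sasa)
  key <- paste(a$chain, a$resno, sep = ":")
  resRows <- lapply(unique(key), function(k) {
    sel <- key == k
    data.frame(chain = a$chain[sel][1], resno = a$resno[sel][1],
               resname = a$resname[sel][1], sasa = sum(sasa[sel]))
  })
  res <- do.call(rbind, resRows)
  res$rel_sasa <- res$sasa / unname(.gxgReference[res$resname])
  list(atoms = atoms, residues = res)
}
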