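# Ring perception on the heavy-atom graph: for every bond, the smallest
# ring through it (BFS on the graph with that bond removed); deduplicated.
.adjacency <- function(m) {
  n <- natoms(m)
  adj <- vector("list", n)
  for (i in seq_len(nrow(m@bonds))) {
    a <- m@bonds$a1[i]; b <- m@bonds$a2[i]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  adj
}

.findRings <- function(m) {
  nb <- nrow(m@bonds)
  if (nb == 0) return(list())
  adj <- .adjacency(m)
  n <- natoms(m)
  rings <- list()
  seen <- character()
  for (i in seq_len(nb)) {
    s <- m@bonds$a1[i]; t <- m@bonds$a2[i]
    # BFS from s to t avoiding the direct edge
    prev <- rep(NA_integer_, n)
    dist <- rep(NA_integer_, n)
    dist[s] <- 0L
    queue <- s
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      for (v in adj[[u]]) {
        if (u == s && v == t) next
        if (is.na(dist[v])) {
          dist[v] <- dist[u] + 1L
          prev[v] <- u
          queue <- c(queue, v)
        }
      }
    }
    if (is.na(dist[t])) next
    path <- t
    while (!is.na(prev[path[1]])) path <- c(prev[path[1]], path)
    ring <- sort(path)
    key <- paste(ring, collapse = ",")
    if (!key %in% seen) {
      seen <- c(seen, key)
      rings[[length(rings) + 1]] <- path
    }
  }
  rings
}

.inRing <- function(m) {
  flags <- rep(FALSE, natoms(m))
  for (r in .findRings(m)) flags[r] <- TRUE
  flags
}

# Hydrogen-bond acceptor atoms: O with non-positive formal charge; N with
# non-positive formal charge that retains a lone pair (not an amide or
# aniline-type aromatic NH, not quaternary).
.hbaAtoms <- function(m) {
  at <- m@atoms
  deg <- tabulate(c(m@bonds$a1, m@bonds$a2), nbins = natoms(m))
  out <- integer(0)
  for (i in seq_len(natoms(m))) {
    if (at$charge[i] > 0) next
    if (at$element[i] == "O") { out <- c(out, i); next }
    if (at$element[i] != "N") next
    if (deg[i] + at$nH[i] >= 4) next
    if (at$aromatic[i] && at$nH[i] > 0) next    # pyrrole-type N
    nbrs <- c(m@bonds$a2[m@bonds$a1 == i], m@bonds$a1[m@bonds$a2 == i])
    amide <- FALSE
    for (c in nbrs[at$element[nbrs] == "C"]) {
      cN <- c(m@bonds$a2[m@bonds$a1 == c & m@bonds$order == 2],
              m@bonds$a1[m@bonds$a2 == c & m@bonds$order == 2])
      if (any(at$element[cN] == "O")) amide <- TRUE
    }
    if (!amide) out <- c(out, i)
  }
  out
}

.hbdAtoms <- function(m) {
  which(m@atoms$element %in% c("N", "O") & m@atoms$nH >= 1)
}

# Acid groups (carboxylic/carboxylate, sulfonic, phosphonic): central atom
# plus its oxygens.  Returns list of atom-index vectors.
.acidGroups <- function(m) {
  at <- m@atoms
  groups <- list()
  for (i in seq_len(natoms(m))) {
    if (!at$element[i] %in% c("C", "S", "P")) next
    bi <- m@bonds[m@bonds$a1 == i | m@bonds$a2 == i, , drop = FALSE]
    nbr <- ifelse(bi$a1 == i, bi$a2, bi$a1)
    oI <- nbr[at$element[nbr] == "O"]
    if (length(oI) < 2) next
    oBo <- bi$order[match(oI, nbr)]
    hasDouble <- any(oBo == 2)
    acidic <- any(oBo == 1 & (at$nH[oI] >= 1 | at$charge[oI] < 0))
    if (at$element[i] == "C" && length(oI) != 2) next
    if (hasDouble && acidic) groups[[length(groups) + 1]] <- c(i, oI)
  }
  groups
}

.centroid <- function(coords, idx) colMeans(coords[idx, , drop = FALSE])

#' Perceive pharmacophoric feature points from a conformer
#'
#' Applies a fixed, documented rule table:
#' \itemize{
#'   \item HBA: N/O with a lone pair available and non-positive formal
#'     charge (each carboxylate oxygen counts); point at the atom.
#'   \item HBD: N/O bearing at least one (implicit) hydrogen.
#'   \item AROMATIC: centroid of each aromatic ring.
#'   \item HYDROPHOBIC: centroid of each all-carbon ring (aromatic or
#'     aliphatic) and of each connected aliphatic chain of >= 3 carbons
#'     (non-ring sp3 carbons bonded only to carbons).
#'   \item NEG_IONIZABLE: centroid of each carboxylic/carboxylate (or
#'     sulfonic/phosphonic) acid group.
#' }
#'
#' @param m a [Molecule-class] with a conformer attached.
#' @return data.frame with columns `kind`, `x`, `y`, `z` and a list column
#'   `atoms` of source atom indices.
#' @export
perceiveFeatures <- function(m) {
  stopifnot(is(m, "Molecule"))
  if (!hasConformer(m))
    stop("perceiveFeatures requires a conformer; call embedConformer() first")
  co <- m@conformer
  at <- m@atoms
  rows <- list()
  add <- function(kind, idx) {
    ctr <- .centroid(co, idx)
    rows[[length(rows) + 1]] <<- data.frame(
      kind = kind, x = ctr[1], y = ctr[2], z = ctr[3],
      atoms = I(list(idx)), stringsAsFactors = FALSE)
  }

  for (i in .hbaAtoms(m)) add("HBA", i)
  for (i in .hbdAtoms(m)) add("HBD", i)

  rings <- .findRings(m)
  ringAtoms <- rep(FALSE, natoms(m))
  for (r in rings) ringAtoms[r] <- TRUE
  for (r in rings) {
    if (all(at$aromatic[r])) add("AROMATIC", r)
    if (all(at$element[r] == "C")) add("HYDROPHOBIC", r)
  }

  # aliphatic chains: non-ring, non-aromatic carbons bonded only to carbons
  chainOk <- at$element == "C" & !ringAtoms & !at$aromatic
  for (i in which(chainOk)) {
    nbrs <- c(m@bonds$a2[m@bonds$a1 == i], m@bonds$a1[m@bonds$a2 == i])
    if (any(at$element[nbrs] != "C")) chainOk[i] <- FALSE
  }
  if (any(chainOk)) {
    comp <- rep(NA_integer_, natoms(m))
    cid <- 0L
    adj <- .adjacency(m)
    for (s in which(chainOk)) {
      if (!is.na(comp[s])) next
      cid <- cid + 1L
      queue <- s; comp[s] <- cid
      while (length(queue)) {
        u <- queue[1]; queue <- queue[-1]
        for (v in adj[[u]]) if (chainOk[v] && is.na(comp[v])) {
          comp[v] <- cid; queue <- c(queue, v)
        }
      }
    }
    for (k in seq_len(cid)) {
      idx <- which(comp == k & chainOk)
      if (length(idx) >= 3) add("HYDROPHOBIC", idx)
    }
  }

  for (g in .acidGroups(m)) add("NEG_IONIZABLE", g)

  if (!length(rows))
    return(data.frame(kind = character(), x = numeric(), y = numeric(),
                      z = numeric(), atoms = I(list())))
  do.call(rbind, rows)
}
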