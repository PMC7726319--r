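# --- maximum common substructure by exhaustive connected-subgraph search ---

# light graph view of a Molecule used by the MCS search
.molGraph <- function(m) {
  n <- natoms(m)
  lab <- vapply(seq_len(n), function(i)
    paste0(m@atoms$element[i], if (m@atoms$aromatic[i]) "a" else ""),
    character(1))
  blab <- matrix(NA_character_, n, n)
  if (nrow(m@bonds))
    for (i in seq_len(nrow(m@bonds))) {
      l <- if (m@bonds$aromatic[i]) "a" else as.character(m@bonds$order[i])
      blab[m@bonds$a1[i], m@bonds$a2[i]] <- l
      blab[m@bonds$a2[i], m@bonds$a1[i]] <- l
    }
  list(n = n, lab = lab, blab = blab, adj = .adjacency(m))
}

# Is the pattern graph (connected; atom labels pat$lab, bond labels
# pat$blab) subgraph-isomorphic to the target?  Non-induced containment:
# every pattern bond must exist with a matching label; extra target bonds
# are allowed.  Returns a logical; `counter` is an environment with a
# mutable node-expansion budget.
.subgraphIso <- function(pat, tgt, counter = NULL) {
  np <- pat$n
  if (np == 0) return(TRUE)
  # BFS order so each new pattern atom touches an already-mapped one
  ordv <- integer(0); seen <- rep(FALSE, np)
  queue <- 1L; seen[1] <- TRUE
  while (length(queue)) {
    u <- queue[1]; queue <- queue[-1]
    ordv <- c(ordv, u)
    for (v in pat$adj[[u]]) if (!seen[v]) { seen[v] <- TRUE; queue <- c(queue, v) }
  }
  if (length(ordv) < np) stop("MCS pattern must be connected")
  mapv <- rep(NA_integer_, np)
  usedT <- rep(FALSE, tgt$n)
  rec <- function(k) {
    if (!is.null(counter)) {
      counter$nodes <- counter$nodes + 1L
      if (counter$nodes > counter$budget) { counter$exceeded <- TRUE; return(FALSE) }
    }
    if (k > np) return(TRUE)
    u <- ordv[k]
    mappedNbr <- pat$adj[[u]][!is.na(mapv[pat$adj[[u]]])]
    cand <- if (length(mappedNbr)) {
      # candidates adjacent to the image of one mapped neighbour
      tgt$adj[[mapv[mappedNbr[1]]]]
    } else seq_len(tgt$n)
    for (t in cand) {
      if (usedT[t] || tgt$lab[t] != pat$lab[u]) next
      ok <- TRUE
      for (w in mappedNbr) {
        bl <- tgt$blab[t, mapv[w]]
        if (is.na(bl) || bl != pat$blab[u, w]) { ok <- FALSE; break }
      }
      if (!ok) next
      mapv[u] <<- t; usedT[t] <<- TRUE
      if (rec(k + 1)) return(TRUE)
      usedT[t] <<- FALSE; mapv[u] <<- NA_integer_
    }
    FALSE
  }
  rec(1L)
}

# all connected vertex subsets of a graph (Avis-Fukuda style growth with
# an exclusion frontier, each subset emitted once); subject to the budget
.connectedSubsets <- function(g, counter) {
  out <- list()
  n <- g$n
  grow <- function(set, frontier, excluded) {
    counter$nodes <- counter$nodes + 1L
    if (counter$nodes > counter$budget) { counter$exceeded <- TRUE; return() }
    out[[length(out) + 1]] <<- set
    ext <- setdiff(frontier, c(set, excluded))
    excl <- excluded
    for (v in ext) {
      newFrontier <- union(frontier, g$adj[[v]])
      grow(c(set, v), newFrontier, excl)
      excl <- c(excl, v)
    }
  }
  excl <- integer(0)
  for (s in seq_len(n)) {
    grow(s, g$adj[[s]], excl)
    excl <- c(excl, s)
    if (counter$exceeded) break
  }
  out
}

.subMolecule <- function(m, idx) {
  keep <- sort(idx)
  remap <- setNames(seq_along(keep), keep)
  bsel <- m@bonds$a1 %in% keep & m@bonds$a2 %in% keep
  b <- m@bonds[bsel, , drop = FALSE]
  if (nrow(b)) {
    b$a1 <- as.integer(remap[as.character(b$a1)])
    b$a2 <- as.integer(remap[as.character(b$a2)])
  }
  rownames(b) <- NULL
  new("Molecule", id = paste0(m@id, "_sub"), smiles = NA_character_,
      atoms = m@atoms[keep, , drop = FALSE],
      bonds = b, conformer = NULL, meta = list())
}

#' Maximum common substructure of a molecule cluster
#'
#' Finds the largest connected subgraph (atom count first, bond count as
#' tiebreak; atoms labelled by element and aromaticity, bonds by order)
#' that is subgraph-isomorphic to at least `ceiling(minFraction * n)`
#' cluster members.  The search enumerates connected induced subgraphs of
#' each member in turn and verifies quorum membership by backtracking
#' subgraph isomorphism; it is exact within a node-expansion `budget`,
#' beyond which the best structure found so far is returned flagged
#' approximate.
#'
#' @param mols list of [Molecule-class] objects (>= 2).
#' @param minFraction minimum matching fraction (default 0.5).
#' @param budget node-expansion budget (default 2e5).
#' @return list `scaffold` ([Molecule-class] subgraph), `matched_fraction`,
#'   `n_matched`, `approximate`, `smiles_like` (linear serialization).
#' @export
maxCommonSubstructure <- function(mols, minFraction = 0.5, budget = 2e5) {
  stopifnot(length(mols) >= 2)
  q <- ceiling(minFraction * length(mols))
  graphs <- lapply(mols, .molGraph)
  counter <- new.env()
  counter$nodes <- 0L; counter$budget <- budget; counter$exceeded <- FALSE

  best <- NULL; bestScore <- c(-1, -1); bestMatched <- 0L
  sizes <- vapply(graphs, `[[`, integer(1), "n")
  for (ri in order(sizes)) {
    ref <- mols[[ri]]
    subs <- .connectedSubsets(graphs[[ri]], counter)
    if (counter$exceeded && is.null(best)) break
    nb <- vapply(subs, function(s) {
      sum(ref@bonds$a1 %in% s & ref@bonds$a2 %in% s)
    }, integer(1))
    na <- lengths(subs)
    ordS <- order(-na, -nb)
    for (si in ordS) {
      score <- c(na[si], nb[si])
      if (score[1] < bestScore[1] ||
          (score[1] == bestScore[1] && score[2] <= bestScore[2])) next
      pat <- .molGraph(.subMolecule(ref, subs[[si]]))
      nMatch <- 0L
      for (g in graphs) {
        if (.subgraphIso(pat, g, counter)) nMatch <- nMatch + 1L
        if (counter$exceeded) break
      }
      if (nMatch >= q) {
        best <- .subMolecule(ref, subs[[si]])
        bestScore <- score
        bestMatched <- nMatch
      }
      if (counter$exceeded) break
    }
    if (counter$exceeded) break
  }

  if (is.null(best) || bestScore[2] == 0) {
    if (is.null(best)) {
      # fall back to the most common single atom label across the quorum
      labCount <- table(unlist(lapply(graphs, function(g) unique(g$lab))))
      lab <- names(labCount)[which.max(labCount)]
      el <- sub("a$", "", lab)
      best <- new("Molecule", id = "scaffold", smiles = NA_character_,
                  atoms = data.frame(element = el, charge = 0L,
                                     aromatic = grepl("a$", lab), nH = 0L),
                  bonds = data.frame(a1 = integer(), a2 = integer(),
                                     order = integer(), aromatic = logical()),
                  conformer = NULL, meta = list())
      bestMatched <- max(labCount)
    }
    if (nrow(best@bonds) == 0)
      warning("no common edge among the quorum; single-atom scaffold returned")
  }
  list(scaffold = best,
       matched_fraction = bestMatched / length(mols),
       n_matched = bestMatched,
       approximate = counter$exceeded,
       smiles_like = scaffoldString(best))
}

#' Linear serialization of a scaffold subgraph
#'
#' DFS notation resembling SMILES: lowercase for aromatic atoms, `=`/`#`
#' for double/triple bonds, parentheses for branches, digits for ring
#' closures.  Not canonical; intended for reporting.
#'
#' @param m a [Molecule-class] (typically an MCS scaffold).
#' @return character string.
#' @export
scaffoldString <- function(m) {
  n <- natoms(m)
  if (n == 0) return("")
  adj <- .adjacency(m)
  bondOf <- function(a, b) which((m@bonds$a1 == a & m@bonds$a2 == b) |
                                 (m@bonds$a1 == b & m@bonds$a2 == a))[1]
  visited <- rep(FALSE, n)
  ringN <- 0L
  ringLabel <- list()
  treeEdge <- matrix(FALSE, max(n, 1), max(n, 1))
  # pre-walk to identify ring-closure edges
  walk0 <- function(u) {
    visited[u] <<- TRUE
    for (v in adj[[u]]) {
      if (!visited[v]) { treeEdge[u, v] <<- TRUE; treeEdge[v, u] <<- TRUE; walk0(v) }
    }
  }
  walk0(1L)
  closure <- which(!treeEdge & upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
  if (nrow(m@bonds)) {
    isBond <- matrix(FALSE, n, n)
    for (i in seq_len(nrow(m@bonds))) {
      isBond[m@bonds$a1[i], m@bonds$a2[i]] <- TRUE
      isBond[m@bonds$a2[i], m@bonds$a1[i]] <- TRUE
    }
    closure <- closure[isBond[closure], , drop = FALSE]
  } else closure <- closure[0, , drop = FALSE]
  ringIdx <- new.env()
  if (nrow(closure))
    for (i in seq_len(nrow(closure))) {
      for (a in closure[i, ]) {
        key <- as.character(a)
        ringIdx[[key]] <- c(if (!is.null(ringIdx[[key]])) ringIdx[[key]], i)
      }
    }
  atomStr <- function(i) {
    el <- m@atoms$element[i]
    s <- if (m@atoms$aromatic[i]) tolower(el) else el
    rings <- ringIdx[[as.character(i)]]
    paste0(s, paste0(rings %||% "", collapse = ""))
  }
  bondStr <- function(bi) {
    if (is.na(bi)) return("")
    if (m@bonds$aromatic[bi]) "" else switch(m@bonds$order[bi], "", "=", "#")
  }
  visited2 <- rep(FALSE, n)
  emit <- function(u, fromBond) {
    visited2[u] <<- TRUE
    s <- paste0(bondStr(fromBond), atomStr(u))
    kids <- adj[[u]][treeEdge[u, adj[[u]]] & !visited2[adj[[u]]]]
    if (length(kids)) {
      parts <- vapply(kids, function(v) emit(v, bondOf(u, v)), character(1))
      if (length(parts) > 1)
        s <- paste0(s, paste0("(", parts[-length(parts)], ")", collapse = ""),
                    parts[length(parts)])
      else s <- paste0(s, parts)
    }
    s
  }
  emit(1L, NA_integer_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
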