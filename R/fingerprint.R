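# Deterministic string hash (31-polynomial modulo the Mersenne prime
# 2^31 - 1), stable across platforms; folded to the bit width.
.hashString <- function(s, nBits) {
  codes <- utf8ToInt(s)
  h <- 0
  for (c in codes) h <- (h * 31 + c) %% 2147483647
  (h %% nBits) + 1L
}

.atomLabel <- function(m, i) {
  paste0(m@atoms$element[i], if (m@atoms$aromatic[i]) "a" else "",
         if (m@atoms$charge[i] != 0) sprintf("%+d", m@atoms$charge[i]) else "")
}

.bondLabel <- function(m, bi) {
  if (m@bonds$aromatic[bi]) "a" else as.character(m@bonds$order[bi])
}

#' Binary 2D linear-path fingerprint
#'
#' Enumerates all linear (non-self-intersecting) atom-bond paths of 0 to
#' `maxPath` bonds, labels them by element, aromaticity, formal charge and
#' bond order, canonicalizes each path by taking the lexicographically
#' smaller reading direction, and hashes the label strings onto a fixed-
#' width bit vector.  Single-atom (length-0) paths are included so no
#' fingerprint is empty.
#'
#' @param m a [Molecule-class].
#' @param nBits fingerprint width (default 1024).
#' @param maxPath maximum path length in bonds (default 7).
#' @return logical vector of length `nBits` with attributes `nBits` and
#'   `maxPath`.
#' @export
linearFingerprint <- function(m, nBits = 1024L, maxPath = 7L) {
  n <- natoms(m)
  bondIdx <- matrix(0L, n, n)
  if (nrow(m@bonds))
    for (i in seq_len(nrow(m@bonds))) {
      bondIdx[m@bonds$a1[i], m@bonds$a2[i]] <- i
      bondIdx[m@bonds$a2[i], m@bonds$a1[i]] <- i
    }
  adj <- .adjacency(m)
  paths <- new.env(hash = TRUE)
  labels <- vapply(seq_len(n), function(i) .atomLabel(m, i), character(1))

  addPath <- function(atomSeq) {
    fwd <- character(2 * length(atomSeq) - 1)
    for (k in seq_along(atomSeq)) {
      fwd[2 * k - 1] <- labels[atomSeq[k]]
      if (k < length(atomSeq))
        fwd[2 * k] <- .bondLabel(m, bondIdx[atomSeq[k], atomSeq[k + 1]])
    }
    f <- paste(fwd, collapse = "|")
    r <- paste(rev(fwd), collapse = "|")
    assign(min(f, r), TRUE, envir = paths)
  }

  walk <- function(seq) {
    addPath(seq)
    if (length(seq) > maxPath) return()
    tip <- seq[length(seq)]
    for (v in adj[[tip]]) if (!v %in% seq) walk(c(seq, v))
  }
  for (s in seq_len(n)) walk(s)

  bits <- rep(FALSE, nBits)
  for (key in ls(paths)) bits[.hashString(key, nBits)] <- TRUE
  attr(bits, "nBits") <- as.integer(nBits)
  attr(bits, "maxPath") <- as.integer(maxPath)
  bits
}

#' Tanimoto distance matrix over fingerprints
#'
#' d = 1 - |a AND b| / |a OR b|; two empty fingerprints have distance 0.
#'
#' @param fps named list of fingerprints from [linearFingerprint()] with
#'   identical widths.
#' @return symmetric distance matrix with zero diagonal.
#' @export
tanimotoDistanceMatrix <- function(fps) {
  widths <- vapply(fps, function(f) attr(f, "nBits"), integer(1))
  if (length(unique(widths)) > 1)
    stop("fingerprints have mixed widths: ", paste(unique(widths), collapse = ", "))
  n <- length(fps)
  M <- do.call(rbind, lapply(fps, as.numeric))
  inter <- M %*% t(M)
  pop <- rowSums(M)
  uni <- outer(pop, pop, "+") - inter
  D <- 1 - ifelse(uni == 0, 1, inter / pmax(uni, 1e-300))
  D[uni == 0] <- 0
  diag(D) <- 0
  dimnames(D) <- list(names(fps), names(fps))
  D
}

#' Average-linkage hierarchical clustering with a K-cluster cut
#'
#' Unweighted average (UPGMA) agglomeration on a distance matrix, cut to
#' exactly `K` clusters (`K >= n` gives singletons).  Cluster labels are
#' renumbered by decreasing size (ties by first occurrence), so the result
#' is invariant to input permutation up to this documented relabelling.
#'
#' @param D symmetric distance matrix with zero diagonal.
#' @param K number of clusters (default 20).
#' @return list `labels` (named integer vector), `sizes` (per cluster),
#'   `K`, `tree` (the hclust object).
#' @export
averageLinkage <- function(D, K = 20L) {
  if (!isSymmetric(unname(D), tol = 1e-8))
    stop("averageLinkage: distance matrix must be symmetric")
  n <- nrow(D)
  ord <- order(rownames(D))          # permutation-invariant internal order
  Ds <- D[ord, ord, drop = FALSE]
  if (K >= n) {
    labels <- seq_len(n)
    names(labels) <- rownames(Ds)
    tree <- NULL
  } else {
    tree <- hclust(as.dist(Ds), method = "average")
    labels <- cutree(tree, k = K)
  }
  sz <- table(labels)
  newId <- setNames(rank(-as.numeric(sz), ties.method = "first"), names(sz))
  labels <- setNames(as.integer(newId[as.character(labels)]), names(labels))
  labels <- labels[rownames(D)]
  list(labels = labels, sizes = sort(table(labels), decreasing = TRUE),
       K = min(K, n), tree = tree)
}

#' Keep clusters with population above a threshold
#'
#' @param assignment result of [averageLinkage()].
#' @param minSize strict lower bound + 1; default 11 keeps clusters with
#'   more than 10 members.
#' @return data.frame `cluster, size` ordered from most to least populated.
#' @export
selectMajorClusters <- function(assignment, minSize = 11L) {
  sz <- table(assignment$labels)
  keep <- sz[sz >= minSize]
  if (!length(keep))
    return(data.frame(cluster = integer(), size = integer()))
  out <- data.frame(cluster = as.integer(names(keep)),
                    size = as.integer(keep))
  out[order(-out$size, out$cluster), , drop = FALSE]
}

#' Pick a cluster representative
#'
#' The medoid minimizes the summed Tanimoto distance to all other cluster
#' members; ties are broken by lexicographic id.
#'
#' @param memberIds character ids of the cluster members.
#' @param D distance matrix covering the ids.
#' @param strategy only `"medoid"` is implemented.
#' @return the representative id.
#' @export
pickRepresentative <- function(memberIds, D, strategy = "medoid") {
  stopifnot(length(memberIds) >= 1, strategy == "medoid")
  if (length(memberIds) == 1) return(memberIds)
  sums <- rowSums(D[memberIds, memberIds, drop = FALSE])
  cand <- memberIds[sums == min(sums)]
  sort(cand)[1]
}

#' Cluster report table
#'
#' @param assignment result of [averageLinkage()].
#' @param D distance matrix (for medoid picking).
#' @return data.frame `id, cluster, cluster_size, is_representative`.
#' @export
clusterReport <- function(assignment, D) {
  labels <- assignment$labels
  rows <- lapply(sort(unique(labels)), function(cl) {
    ids <- names(labels)[labels == cl]
    rep <- pickRepresentative(ids, D)
    data.frame(id = ids, cluster = cl, cluster_size = length(ids),
               is_representative = ids == rep)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Export a clustering tree as Newick text
#'
#' @param assignment result of [averageLinkage()] (needs a tree, i.e. K < n).
#' @param path output path.
#' @export
writeDendrogramNewick <- function(assignment, path) {
  if (is.null(assignment$tree))
    stop("no tree available (K >= n produced singletons)")
  phy <- ape::as.phylo(assignment$tree)
  ape::write.tree(phy, file = path)
  invisible(path)
}
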