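#' PharmacophoreModel: tolerance-sphere feature model
#'
#' A set of labelled feature points (kind HBA or HYDROPHOBIC) with
#' tolerance-sphere radii in Angstrom, a minimum-match rule and a record of
#' radius adjustments applied during refinement.  Coordinates live in the
#' anchor frame used to align the actives (origin at the anchor group).
#'
#' @slot features data.frame `label, kind, x, y, z, radius, optional,
#'   support` (support = number of actives backing the feature).
#' @slot minMatch minimum number of matched features for a pass.
#' @slot radiusAdjustments named list of radius increments applied.
#' @slot meta list (base radius, grouping radius, quorum, n actives used).
#' @export
setClass("PharmacophoreModel",
  representation(features = "data.frame", minMatch = "integer",
                 radiusAdjustments = "list", meta = "list"),
  prototype(minMatch = 3L, radiusAdjustments = list(), meta = list()))

setValidity("PharmacophoreModel", function(object) {
  f <- object@features
  msgs <- character()
  if (nrow(f)) {
    if (any(f$radius <= 0)) msgs <- c(msgs, "feature radii must be > 0")
    if (anyDuplicated(f$label)) msgs <- c(msgs, "feature labels must be unique")
    if (!all(f$kind %in% c("HBA", "HYDROPHOBIC")))
      msgs <- c(msgs, "model feature kinds must be HBA or HYDROPHOBIC")
  }
  if (object@minMatch > max(nrow(f), 1L))
    msgs <- c(msgs, "minMatch exceeds feature count")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "PharmacophoreModel", function(object) {
  cat("PharmacophoreModel:", nrow(object@features), "features, min match",
      object@minMatch, "\n")
  if (nrow(object@features)) {
    f <- object@features
    for (i in seq_len(nrow(f)))
      cat(sprintf("  %-6s %-11s r=%.2f A%s (support %s)\n", f$label[i],
                  f$kind[i], f$radius[i],
                  if (f$optional[i]) " [optional]" else "",
                  f$support[i]))
  }
})

#' @describeIn PharmacophoreModel feature table accessor
#' @param x a `PharmacophoreModel`
#' @export
modelFeatures <- function(x) x@features

#' @describeIn PharmacophoreModel minimum-match rule accessor
#' @export
minMatch <- function(x) x@minMatch

# Least-squares rigid superposition (proper rotation).  Returns a function
# mapping source points onto the target frame, plus the rmsd of the fit.
.kabsch <- function(P, Q) {
  cP <- colMeans(P); cQ <- colMeans(Q)
  Pc <- sweep(P, 2, cP); Qc <- sweep(Q, 2, cQ)
  H <- t(Pc) %*% Qc
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)
  transform <- function(X) sweep(sweep(X, 2, cP) %*% t(R), 2, cQ, "+")
  rmsd <- sqrt(mean(rowSums((transform(P) - Q)^2)))
  list(transform = transform, rmsd = rmsd)
}

# Anchor frame for an active: origin at the centroid of its first
# negative-ionizable group (by atom order); axes from the two heavy atoms
# nearest that origin (ties by atom index).  Feature centers are expressed
# in this frame so that features can be pooled across aligned actives.
.anchorFrame <- function(m, feats) {
  neg <- feats[feats$kind == "NEG_IONIZABLE", , drop = FALSE]
  if (!nrow(neg)) return(NULL)
  origin <- as.numeric(neg[1, c("x", "y", "z")])
  co <- m@conformer
  d <- sqrt(rowSums(sweep(co, 2, origin)^2))
  ord <- order(d, seq_along(d))
  a1 <- co[ord[1], ]; a2 <- co[ord[2], ]
  e1 <- a1 - origin; n1 <- sqrt(sum(e1^2))
  if (n1 < 1e-9) { a1 <- co[ord[2], ]; a2 <- co[ord[3], ]; e1 <- a1 - origin; n1 <- sqrt(sum(e1^2)) }
  e1 <- e1 / n1
  v2 <- a2 - origin
  e2 <- v2 - sum(v2 * e1) * e1
  n2 <- sqrt(sum(e2^2))
  e2 <- if (n2 < 1e-9) {
    # degenerate collinear case: any perpendicular
    p <- if (abs(e1[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    q <- p - sum(p * e1) * e1; q / sqrt(sum(q^2))
  } else e2 / n2
  e3 <- c(e1[2] * e2[3] - e1[3] * e2[2],
          e1[3] * e2[1] - e1[1] * e2[3],
          e1[1] * e2[2] - e1[2] * e2[1])
  function(X) sweep(X, 2, origin) %*% cbind(e1, e2, e3)
}

# Pooled feature points of one molecule in its anchor frame.  AROMATIC
# centroids are folded into HYDROPHOBIC (they are matchable by hydrophobic
# model features); coincident duplicates are dropped.
.pooledPoints <- function(m) {
  feats <- perceiveFeatures(m)
  toFrame <- .anchorFrame(m, feats)
  if (is.null(toFrame)) return(NULL)
  keep <- feats$kind %in% c("HBA", "HYDROPHOBIC", "AROMATIC")
  feats <- feats[keep, , drop = FALSE]
  if (!nrow(feats)) return(data.frame())
  xyz <- toFrame(as.matrix(feats[, c("x", "y", "z")]))
  kind <- ifelse(feats$kind == "AROMATIC", "HYDROPHOBIC", feats$kind)
  df <- data.frame(kind = kind, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
  # deduplicate coincident points of the same kind (aromatic carbocycles)
  dup <- duplicated(data.frame(df$kind, round(df$x, 4), round(df$y, 4), round(df$z, 4)))
  df[!dup, , drop = FALSE]
}

#' Build a candidate pharmacophore model from aligned actives
#'
#' Each active is expressed in its anchor frame (negative-ionizable group
#' centroid plus the two nearest heavy atoms).  Feature points of one kind
#' lying within `groupingRadius` of each other (single linkage) and backed
#' by at least `quorum` distinct actives become candidate features at the
#' group centroid, with `baseRadius` tolerance spheres.
#'
#' @param actives list of [Molecule-class] objects with conformers.
#' @param groupingRadius grouping radius in Angstrom (default 1.0).
#' @param quorum minimum number of supporting actives (default 4).
#' @param baseRadius tolerance-sphere base radius in Angstrom (default 1.5).
#' @return a [PharmacophoreModel-class] (pre-refinement candidate set).
#' @export
buildModel <- function(actives, groupingRadius = 1.0, quorum = 4L,
                       baseRadius = 1.5) {
  if (!length(actives)) stop("buildModel: empty actives list")
  pts <- list()
  used <- 0L
  for (m in actives) {
    if (!hasConformer(m)) stop("active ", molId(m), " has no conformer")
    p <- .pooledPoints(m)
    if (is.null(p)) {
      warning("active ", molId(m), " lacks an anchor (negative-ionizable) group; excluded")
      next
    }
    used <- used + 1L
    if (nrow(p)) { p$mol <- molId(m); pts[[length(pts) + 1]] <- p }
  }
  if (used < 2) stop("buildModel: fewer than 2 usable actives")
  pool <- do.call(rbind, pts)
  feats <- list()
  for (kind in c("HBA", "HYDROPHOBIC")) {
    sub <- pool[pool$kind == kind, , drop = FALSE]
    if (!nrow(sub)) next
    grp <- if (nrow(sub) == 1) 1L else {
      d <- dist(sub[, c("x", "y", "z")])
      cutree(hclust(d, method = "single"), h = groupingRadius)
    }
    for (g in unique(grp)) {
      rowsG <- sub[grp == g, , drop = FALSE]
      support <- length(unique(rowsG$mol))
      if (support < quorum) next
      ctr <- colMeans(rowsG[, c("x", "y", "z")])
      feats[[length(feats) + 1]] <- data.frame(
        kind = kind, x = ctr[1], y = ctr[2], z = ctr[3],
        radius = baseRadius, optional = FALSE, support = support)
    }
  }
  f <- if (length(feats)) do.call(rbind, feats) else
    data.frame(kind = character(), x = numeric(), y = numeric(), z = numeric(),
               radius = numeric(), optional = logical(), support = integer())
  if (nrow(f)) {
    # stable labels: HBA ordered by distance to anchor, HYD by support
    f$distAnchor <- sqrt(f$x^2 + f$y^2 + f$z^2)
    f <- f[order(f$kind, ifelse(f$kind == "HBA", f$distAnchor, -f$support)), ]
    lab <- character(nrow(f))
    for (kind in unique(f$kind)) {
      i <- which(f$kind == kind)
      lab[i] <- paste0(ifelse(kind == "HBA", "HBA", "H"), "cand", seq_along(i))
    }
    f$label <- lab
    f <- f[, c("label", "kind", "x", "y", "z", "radius", "optional",
               "support", "distAnchor")]
    rownames(f) <- NULL
  }
  new("PharmacophoreModel", features = f,
      minMatch = as.integer(min(3L, max(nrow(f), 1L))),
      radiusAdjustments = list(),
      meta = list(base_radius = baseRadius, grouping_radius = groupingRadius,
                  quorum = quorum, n_actives_used = used))
}

#' Refine a candidate model to the four-feature screening model
#'
#' Keeps exactly HBA1, HBA2 (the two acceptor candidates nearest the
#' anchor), H1 and H2 (the two hydrophobic candidates with the strongest
#' active support).  Acceptor tolerance spheres grow by 0.15 Angstrom and
#' H1 by 0.3 Angstrom; H2 is marked optional; the minimum-match rule is 3.
#'
#' @param model candidate [PharmacophoreModel-class] from [buildModel()].
#' @return refined four-feature [PharmacophoreModel-class].
#' @export
refineModel <- function(model) {
  f <- model@features
  hba <- f[f$kind == "HBA", , drop = FALSE]
  hyd <- f[f$kind == "HYDROPHOBIC", , drop = FALSE]
  if (nrow(hba) < 2 || nrow(hyd) < 2)
    stop("refineModel: need >= 2 HBA and >= 2 HYDROPHOBIC candidates; have ",
         nrow(hba), " HBA and ", nrow(hyd), " HYDROPHOBIC")
  hba <- hba[order(hba$distAnchor), ][1:2, ]
  hyd <- hyd[order(-hyd$support, hyd$distAnchor), ][1:2, ]
  out <- rbind(hba, hyd)
  out$label <- c("HBA1", "HBA2", "H1", "H2")
  out$radius <- out$radius + c(0.15, 0.15, 0.3, 0)
  out$optional <- c(FALSE, FALSE, FALSE, TRUE)
  rownames(out) <- NULL
  new("PharmacophoreModel", features = out, minMatch = 3L,
      radiusAdjustments = list(HBA1 = 0.15, HBA2 = 0.15, H1 = 0.3, H2 = 0),
      meta = model@meta)
}

#' Build and refine a screening model, relaxing the quorum if needed
#'
#' Runs [buildModel()] at the requested quorum and, when the candidate set
#' does not contain the two acceptor and two hydrophobic candidates that
#' [refineModel()] requires, lowers the quorum one step at a time (down to
#' 1) until it does.  Structurally diverse training actives often share
#' only one hydrophobic consensus position at a strict quorum, so the
#' relaxation trades consensus strength for model completeness; the quorum
#' actually used is recorded in the model metadata (`quorum`, alongside
#' `quorum_requested`) and a warning is raised whenever it differs from
#' the request.
#'
#' @inheritParams buildModel
#' @param quorum starting quorum (default 4).
#' @return refined four-feature [PharmacophoreModel-class].
#' @export
trainModel <- function(actives, groupingRadius = 1.0, quorum = 4L,
                       baseRadius = 1.5) {
  q <- as.integer(quorum)
  repeat {
    cand <- buildModel(actives, groupingRadius, q, baseRadius)
    f <- cand@features
    ok <- sum(f$kind == "HBA") >= 2 && sum(f$kind == "HYDROPHOBIC") >= 2
    if (ok || q <= 1L) break
    q <- q - 1L
  }
  if (q < quorum)
    warning("trainModel: quorum relaxed from ", quorum, " to ", q,
            " to obtain two candidates of each kind")
  m <- refineModel(cand)
  m@meta$quorum_requested <- as.integer(quorum)
  m
}

# injective assignments of candidate ligand feature indices to the model
# subset; returns matrix (one row per assignment) or NULL when impossible
.assignments <- function(cands) {
  parts <- list(integer(0))
  for (i in seq_along(cands)) {
    nxt <- list()
    for (p in parts) for (c in setdiff(cands[[i]], p))
      nxt[[length(nxt) + 1]] <- c(p, c)
    parts <- nxt
    if (!length(parts)) return(NULL)
  }
  do.call(rbind, parts)
}

#' Match ligand feature points against a pharmacophore model
#'
#' Enumerates kind-compatible injective mappings (model HBA to ligand HBA;
#' model HYDROPHOBIC to ligand HYDROPHOBIC or AROMATIC) of every subset of
#' model features down to the effective minimum, superposes the mapped
#' ligand centers onto the model centers by least squares, and accepts a
#' mapping when every mapped center falls inside its tolerance sphere.
#' Returns the valid mapping with the highest matched count (ties broken by
#' lowest fit rmsd).  The ranking score is
#' `matched_count - fit_rmsd / 10`.
#'
#' @param model a [PharmacophoreModel-class].
#' @param ligFeatures data.frame from [perceiveFeatures()].
#' @return list `mapping` (named ligand row indices), `matched_count`,
#'   `fit_rmsd`, `passed`, `score`.
#' @export
matchPharmacophore <- function(model, ligFeatures) {
  f <- model@features
  nF <- nrow(f)
  effMin <- min(model@minMatch, sum(!f$optional))
  noMatch <- list(mapping = integer(0), matched_count = 0L,
                  fit_rmsd = NA_real_, passed = FALSE, score = 0)
  if (!nF || !nrow(ligFeatures)) return(noMatch)
  ligKind <- ifelse(ligFeatures$kind == "AROMATIC", "HYDROPHOBIC",
                    ligFeatures$kind)
  candsAll <- lapply(seq_len(nF), function(i) which(ligKind == f$kind[i]))
  best <- noMatch
  for (size in seq(nF, max(effMin, 1L))) {
    subsets <- combn(nF, size, simplify = FALSE)
    for (S in subsets) {
      A <- .assignments(candsAll[S])
      if (is.null(A)) next
      Q <- as.matrix(f[S, c("x", "y", "z")])
      radii <- f$radius[S]
      for (r in seq_len(nrow(A))) {
        P <- as.matrix(ligFeatures[A[r, ], c("x", "y", "z")])
        k <- .kabsch(P, Q)
        dev <- sqrt(rowSums((k$transform(P) - Q)^2))
        if (all(dev <= radii)) {
          if (size > best$matched_count ||
              (size == best$matched_count && k$rmsd < best$fit_rmsd)) {
            mp <- A[r, ]
            names(mp) <- f$label[S]
            best <- list(mapping = mp, matched_count = as.integer(size),
                         fit_rmsd = k$rmsd,
                         passed = size >= effMin,
                         score = size - k$rmsd / 10)
          }
        }
      }
    }
    if (best$matched_count == size) break
  }
  best
}

#' Screen a molecule library against a pharmacophore model
#'
#' Molecules without a conformer are embedded first (fixed seed); embedding
#' failures are recorded and marked not passed.
#'
#' @param model a [PharmacophoreModel-class].
#' @param library list of [Molecule-class] objects.
#' @param seed embedding seed.
#' @return data.frame `id, matched_count, fit_rmsd, score, passed,
#'   embed_failed`.
#' @export
screenLibrary <- function(model, library, seed = 1L) {
  library <- embedLibrary(library, seed)
  rows <- lapply(library, function(m) {
    if (!hasConformer(m))
      return(data.frame(id = molId(m), matched_count = 0L, fit_rmsd = NA_real_,
                        score = 0, passed = FALSE, embed_failed = TRUE))
    res <- matchPharmacophore(model, perceiveFeatures(m))
    data.frame(id = molId(m), matched_count = res$matched_count,
               fit_rmsd = res$fit_rmsd, score = res$score,
               passed = res$passed, embed_failed = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' ROC curve and AUC from scores
#'
#' Threshold sweep over unique scores (ties grouped, contributing diagonal
#' segments); the AUC equals the Mann-Whitney U statistic divided by
#' n_active * n_decoy, with half credit for ties.
#'
#' @param scores numeric scores (higher = more active-like).
#' @param labels character/logical: `"active"`/`TRUE` vs `"decoy"`/`FALSE`.
#' @return list `points` (data.frame fpr, tpr) and `auc`.
#' @export
rocFromScores <- function(scores, labels) {
  act <- if (is.logical(labels)) labels else labels == "active"
  nA <- sum(act); nD <- sum(!act)
  if (nA == 0 || nD == 0) stop("ROC needs both classes present")
  rk <- rank(scores)                      # average ranks: tie half-credit
  U <- sum(rk[act]) - nA * (nA + 1) / 2
  auc <- U / (nA * nD)
  th <- sort(unique(scores), decreasing = TRUE)
  pts <- data.frame(fpr = 0, tpr = 0)
  for (t in th) {
    pts <- rbind(pts, data.frame(fpr = sum(!act & scores >= t) / nD,
                                 tpr = sum(act & scores >= t) / nA))
  }
  list(points = pts, auc = auc)
}

#' ROC validation of a model against an actives/decoys training set
#'
#' @param model a [PharmacophoreModel-class].
#' @param trainingSet data.frame `id, smiles, label` or list with elements
#'   `molecules` (list of [Molecule-class]) and `labels`.
#' @param seed embedding seed.
#' @return list `points`, `auc`, `scores` (data.frame id, score, label).
#' @export
rocAuc <- function(model, trainingSet, seed = 1L) {
  if (is.data.frame(trainingSet)) {
    mols <- mapply(parseSmiles, trainingSet$smiles, trainingSet$id,
                   SIMPLIFY = FALSE)
    labels <- trainingSet$label
  } else {
    mols <- trainingSet$molecules
    labels <- trainingSet$labels
  }
  if (length(unique(labels)) < 2) stop("training set must contain both classes")
  scr <- screenLibrary(model, mols, seed = seed)
  roc <- rocFromScores(scr$score, labels)
  roc$scores <- data.frame(id = scr$id, score = scr$score, label = labels,
                           matched_count = scr$matched_count)
  roc
}

#' Serialize a pharmacophore model to JSON
#' @param model a [PharmacophoreModel-class].
#' @param path output path.
#' @export
writeModelJson <- function(model, path) {
  obj <- list(features = model@features[, c("label", "kind", "x", "y", "z",
                                            "radius", "optional", "support")],
              min_match = model@minMatch,
              radius_adjustments = model@radiusAdjustments)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a pharmacophore model from JSON
#' @param path JSON path written by [writeModelJson()].
#' @return a [PharmacophoreModel-class].
#' @export
readModelJson <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  f <- as.data.frame(obj$features)
  if (is.null(f$support)) f$support <- NA_integer_
  f$support <- as.integer(f$support)
  f$distAnchor <- sqrt(f$x^2 + f$y^2 + f$z^2)
  f <- f[, c("label", "kind", "x", "y", "z", "radius", "optional",
             "support", "distAnchor")]
  new("PharmacophoreModel", features = f,
      minMatch = as.integer(obj$min_match),
      radiusAdjustments = as.list(obj$radius_adjustments))
}
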