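#' ReceptorStructure: receptor atoms plus anchor residues
#'
#' @slot atoms data.frame `serial, name, element, chain, resno, resname,
#'   x, y, z` (coordinates in Angstrom, residue numbering as in the source
#'   file, 1-based).
#' @slot anchors data.frame `chain, resno` of anchor residues (the residues
#'   at the center of the targeted pocket).
#' @export
setClass("ReceptorStructure",
  representation(atoms = "data.frame", anchors = "data.frame"),
  prototype(anchors = data.frame(chain = character(), resno = integer())))

setValidity("ReceptorStructure", function(object) {
  a <- object@atoms
  msgs <- character()
  need <- c("serial", "name", "element", "chain", "resno", "resname",
            "x", "y", "z")
  if (!all(need %in% names(a))) msgs <- c(msgs, "atoms missing required columns")
  else if (nrow(a) && any(!is.finite(c(a$x, a$y, a$z))))
    msgs <- c(msgs, "coordinates must be finite")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "ReceptorStructure", function(object) {
  a <- object@atoms
  cat("ReceptorStructure:", nrow(a), "atoms,",
      nrow(unique(a[, c("chain", "resno")])), "residues\n")
  if (nrow(object@anchors))
    cat("  anchors:", paste(object@anchors$chain, object@anchors$resno,
                            sep = ":", collapse = ", "), "\n")
})

#' @describeIn ReceptorStructure atom table accessor
#' @param x a `ReceptorStructure`
#' @export
receptorAtoms <- function(x) x@atoms

#' Read a receptor from a PDB file
#'
#' ATOM/HETATM records only; for alternate locations only altloc ' ' or 'A'
#' is kept; residue numbering is preserved as in the file.
#'
#' @param path PDB file path.
#' @param anchors optional data.frame `chain, resno`.
#' @return a [ReceptorStructure-class].
#' @export
readPdb <- function(path, anchors = NULL) {
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e) NULL, warning = function(w) NULL)
  if (is.null(pdb) || nrow(pdb$atom) == 0)
    stop("PDB format error: no ATOM/HETATM records in ", path)
  at <- pdb$atom
  at <- at[is.na(at$alt) | at$alt %in% c("", "A"), , drop = FALSE]
  elem <- at$elesy
  missing <- is.na(elem) | !nzchar(trimws(elem))
  elem[missing] <- substr(trimws(at$elety[missing]), 1, 1)
  st <- new("ReceptorStructure",
            atoms = data.frame(serial = at$eleno, name = trimws(at$elety),
                               element = trimws(elem), chain = at$chain,
                               resno = at$resno, resname = trimws(at$resid),
                               x = at$x, y = at$y, z = at$z,
                               stringsAsFactors = FALSE))
  if (!is.null(anchors)) st@anchors <- anchors
  validObject(st)
  st
}

#' Construct a docked pose
#'
#' @param id compound identifier.
#' @param engine docking-engine tag.
#' @param rank pose rank (1 = best).
#' @param score engine score (convention declared per adapter).
#' @param coords heavy-atom coordinate matrix (n x 3, Angstrom).
#' @return a pose (list with class `dockedPose`).
#' @export
dockedPose <- function(id, engine, rank, score, coords) {
  stopifnot(rank >= 1, all(is.finite(coords)))
  structure(list(id = id, engine = engine, rank = as.integer(rank),
                 score = score, coords = coords), class = "dockedPose")
}

#' Read poses from a PDBQT-subset file (ATOM/HETATM/MODEL records)
#'
#' Each MODEL block becomes one pose ranked in file order; files without
#' MODEL records yield a single pose.
#'
#' @param path PDBQT file path.
#' @param id compound id; @param engine engine tag.
#' @param engine engine tag recorded in each pose.
#' @return list of poses.
#' @export
readPdbqtPoses <- function(path, id, engine = "pdbqt") {
  lines <- readLines(path)
  poses <- list()
  cur <- NULL
  flush <- function() {
    if (!is.null(cur) && nrow(cur))
      poses[[length(poses) + 1]] <<- dockedPose(id, engine,
                                                length(poses) + 1L, NA_real_,
                                                as.matrix(cur))
    cur <<- NULL
  }
  for (ln in lines) {
    tag <- substr(ln, 1, 6)
    if (grepl("^MODEL", ln)) { flush(); cur <- data.frame(x = numeric(), y = numeric(), z = numeric()) }
    else if (tag %in% c("ATOM  ", "HETATM")) {
      el <- trimws(substr(ln, 77, 78))
      if (identical(el, "H") || identical(el, "HD") || identical(el, "HS")) next
      row <- data.frame(x = as.numeric(substr(ln, 31, 38)),
                        y = as.numeric(substr(ln, 39, 46)),
                        z = as.numeric(substr(ln, 47, 54)))
      if (is.null(cur)) cur <- row else cur <- rbind(cur, row)
    } else if (grepl("^ENDMDL", ln)) flush()
  }
  flush()
  if (!length(poses)) stop("PDBQT format error: no ATOM records in ", path)
  poses
}

#' Read poses from an SDF file (one pose per record)
#'
#' @param path SDF path; record names are used as compound ids.
#' @param engine engine tag.
#' @return list of poses ranked in file order per compound.
#' @export
readSdfPoses <- function(path, engine = "sdf") {
  mols <- readSdfFile(path)
  ranks <- stats::ave(seq_along(mols), vapply(mols, molId, character(1)),
                      FUN = seq_along)
  mapply(function(m, r) dockedPose(molId(m), engine, r, NA_real_,
                                   if (hasConformer(m)) m@conformer
                                   else matrix(0, natoms(m), 3)),
         mols, ranks, SIMPLIFY = FALSE)
}

.anchorAtoms <- function(receptor, anchor) {
  a <- receptor@atoms
  hit <- a$chain == anchor$chain & a$resno == anchor$resno & a$element != "H"
  if (!any(hit))
    stop("anchor residue not found: chain ", anchor$chain, " resno ",
         anchor$resno)
  as.matrix(a[hit, c("x", "y", "z")])
}

#' Minimum heavy-atom distance between a pose and an anchor residue
#'
#' @param pose a pose from [dockedPose()].
#' @param receptor a [ReceptorStructure-class].
#' @param anchor list/data.frame with `chain` and `resno`.
#' @return minimum Euclidean distance in Angstrom.
#' @export
minDistance <- function(pose, receptor, anchor) {
  A <- .anchorAtoms(receptor, anchor)
  L <- pose$coords
  d2 <- outer(rowSums(L^2), rowSums(A^2), "+") - 2 * L %*% t(A)
  sqrt(max(0, min(d2)))
}

#' Keep poses whose anchor distance is within the cutoff (inclusive)
#'
#' @param poses list of poses.
#' @param receptor a [ReceptorStructure-class].
#' @param anchor anchor residue (`chain`, `resno`).
#' @param cutoff distance cutoff in Angstrom (default 6.0).
#' @return surviving poses (order preserved).
#' @export
distanceFilter <- function(poses, receptor, anchor, cutoff = 6.0) {
  stopifnot(cutoff > 0)
  keep <- vapply(poses, function(p) minDistance(p, receptor, anchor) <= cutoff,
                 logical(1))
  poses[keep]
}

#' Top-k poses per engine by rank
#'
#' Stable per-engine selection: poses are ordered by rank (ties keep input
#' order) and the first `k` are retained.
#'
#' @param poses list of poses.
#' @param k rank cut (default 50000).
#' @return surviving poses.
#' @export
rankCut <- function(poses, k = 50000) {
  if (!length(poses)) return(poses)
  engines <- vapply(poses, `[[`, character(1), "engine")
  keep <- logical(length(poses))
  for (e in unique(engines)) {
    idx <- which(engines == e)
    ord <- idx[order(vapply(poses[idx], `[[`, integer(1), "rank"))]
    keep[utils::head(ord, k)] <- TRUE
  }
  poses[keep]
}

#' Merge per-engine/per-target hit lists with provenance
#'
#' @param lists named list of character id vectors (names are source tags).
#' @return list `ids` (distinct ids, first-seen order), `provenance`
#'   (data.frame id, source), `n_distinct`, `per_source` counts.
#' @export
mergeHitlists <- function(lists) {
  prov <- do.call(rbind, lapply(names(lists), function(nm)
    if (length(lists[[nm]])) data.frame(id = lists[[nm]], source = nm,
                                        stringsAsFactors = FALSE)))
  if (is.null(prov)) prov <- data.frame(id = character(), source = character())
  ids <- unique(prov$id)
  list(ids = ids, provenance = prov, n_distinct = length(ids),
       per_source = vapply(lists, length, integer(1)))
}

#' Run the post-docking filtering funnel
#'
#' Stage order: per-engine rank cut, anchor distance filter, optional
#' binding-site proximity check (geometric surrogate for visual
#' inspection), drug-likeness filter, per-engine hit-list merge, and the
#' pharmacophore screen.  Counts are non-increasing across stages.
#'
#' @param config list with elements `poses` (list of poses), `receptor`,
#'   `anchor`, optional `rank_k` (default 50000), `distance_cutoff`
#'   (default 6), optional `site_center`/`site_radius` (proximity
#'   surrogate; omitted = disabled), `molecules` (named list of
#'   [Molecule-class] keyed by compound id), optional `descriptor_ranges`
#'   (default [lipinskiRanges()]), optional `model`
#'   ([PharmacophoreModel-class]), `seed`.
#' @return list `report` (data.frame stage, n_in, n_out), `survivors`
#'   (id character vector per stage, as list), `screen` (screen report or
#'   NULL).
#' @export
runFunnel <- function(config) {
  for (need in c("poses", "receptor", "anchor", "molecules"))
    if (is.null(config[[need]]))
      stop("funnel config error: missing '", need, "'")
  seed <- if (is.null(config$seed)) 1L else config$seed
  poses <- config$poses
  report <- data.frame(stage = character(), n_in = integer(),
                       n_out = integer())
  ids <- function(ps) unique(vapply(ps, `[[`, character(1), "id"))
  survivors <- list()
  note <- function(stage, nin, nout, surv) {
    report <<- rbind(report, data.frame(stage = stage, n_in = nin,
                                        n_out = nout))
    survivors[[stage]] <<- surv
  }

  k <- if (is.null(config$rank_k)) 50000 else config$rank_k
  p1 <- rankCut(poses, k)
  note("rank_cut", length(poses), length(p1), ids(p1))

  cutoff <- if (is.null(config$distance_cutoff)) 6.0 else config$distance_cutoff
  p2 <- distanceFilter(p1, config$receptor, config$anchor, cutoff)
  note("distance_filter", length(p1), length(p2), ids(p2))

  if (!is.null(config$site_center)) {
    rad <- if (is.null(config$site_radius)) 10 else config$site_radius
    keep <- vapply(p2, function(p)
      sqrt(sum((colMeans(p$coords) - config$site_center)^2)) <= rad,
      logical(1))
    p3 <- p2[keep]
    note("site_proximity", length(p2), length(p3), ids(p3))
  } else p3 <- p2

  surv <- ids(p3)
  ranges <- if (is.null(config$descriptor_ranges)) lipinskiRanges()
            else config$descriptor_ranges
  keep <- vapply(surv, function(id) {
    m <- config$molecules[[id]]
    if (is.null(m)) return(FALSE)
    druglikeFilter(computeDescriptors(m), ranges)$pass
  }, logical(1))
  surv2 <- surv[keep]
  note("druglike_filter", length(surv), length(surv2), surv2)

  engines <- vapply(p3, `[[`, character(1), "engine")
  perEngine <- lapply(split(seq_along(p3), engines), function(i)
    intersect(ids(p3[i]), surv2))
  merged <- mergeHitlists(perEngine)
  note("merge", length(surv2), merged$n_distinct, merged$ids)

  screenRep <- NULL
  if (!is.null(config$model)) {
    mols <- config$molecules[merged$ids]
    screenRep <- screenLibrary(config$model, mols, seed = seed)
    passIds <- screenRep$id[screenRep$passed]
    note("pharmacophore_screen", merged$n_distinct, length(passIds), passIds)
  }
  list(report = report, survivors = survivors, screen = screenRep,
       merged = merged)
}

#' Write a funnel report as CSV and JSON
#' @param funnel result of [runFunnel()].
#' @param csvPath,jsonPath output paths (NULL = skip).
#' @export
writeFunnelReport <- function(funnel, csvPath = NULL, jsonPath = NULL) {
  if (!is.null(csvPath))
    write.csv(funnel$report, csvPath, row.names = FALSE, quote = FALSE)
  if (!is.null(jsonPath))
    jsonlite::write_json(list(report = funnel$report,
                              survivors = funnel$survivors),
                         jsonPath, auto_unbox = TRUE, digits = NA)
  invisible(funnel)
}

#' Aggregate consensus sites into hot spots (single linkage)
#'
#' Sites whose centers fall within `linkCutoff` of each other (single
#' linkage, inclusive) form one hot spot; hot spots are ranked by summed
#' probe count.
#'
#' @param sites data.frame `label, x, y, z, probes`.
#' @param linkCutoff linkage cutoff in Angstrom (default 8.0).
#' @return data.frame `hotspot, members, n_sites, probe_sum`, ranked by
#'   probe sum (decreasing).
#' @export
aggregateConsensusSites <- function(sites, linkCutoff = 8.0) {
  stopifnot(nrow(sites) >= 1)
  grp <- if (nrow(sites) == 1) 1L else
    cutree(hclust(dist(sites[, c("x", "y", "z")]), method = "single"),
           h = linkCutoff)
  out <- do.call(rbind, lapply(unique(grp), function(g) {
    s <- sites[grp == g, , drop = FALSE]
    data.frame(members = paste(s$label, collapse = "+"),
               n_sites = nrow(s), probe_sum = sum(s$probes))
  }))
  out <- out[order(-out$probe_sum), , drop = FALSE]
  out$hotspot <- seq_len(nrow(out))
  rownames(out) <- NULL
  out[, c("hotspot", "members", "n_sites", "probe_sum")]
}
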