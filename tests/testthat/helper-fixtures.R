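# Shared cached fixtures: embedding and model training are the slow steps,
# so each is computed once per test run.
fx <- new.env()

fxMol <- function(key, smiles) {
  if (is.null(fx[[key]]))
    fx[[key]] <- embedConformer(parseSmiles(smiles, key), 1L)
  fx[[key]]
}

fxSalicylic <- function() fxMol("sal", "OC(=O)c1ccccc1O")
fxDiflunisal <- function() fxMol("dif", "OC(=O)c1cc(-c2ccc(F)cc2F)ccc1O")
fxBenzene <- function() fxMol("benzene", "c1ccccc1")
fxCresotic <- function()
  fxMol("bis_cresotic",
        "OC(=O)c1cc(Cc2cc(C(O)=O)c(O)c(C)c2)cc(C)c1O")

# two-active refined model (quorum relaxes; cheap to build)
fxMiniModel <- function() {
  if (is.null(fx$model))
    fx$model <- suppressWarnings(
      trainModel(list(fxSalicylic(), fxDiflunisal())))
  fx$model
}

# full literature training set: molecules, labels and screen results
fxTraining <- function() {
  if (is.null(fx$training)) {
    train <- trainingSetFixture()
    mols <- embedLibrary(lapply(seq_len(nrow(train)), function(i)
      parseSmiles(train$smiles[i], train$id[i])), 1L)
    model <- suppressWarnings(trainModel(mols[train$label == "active"]))
    screen <- screenLibrary(model, mols, seed = 1L)
    fx$training <- list(table = train, molecules = mols, model = model,
                        screen = screen,
                        labels = train$label[match(screen$id, train$id)])
  }
  fx$training
}

fxReceptor <- function() {
  if (is.null(fx$receptor))
    fx$receptor <- genReceptorAndPoses(c(2, 4, 5, 7, 9, 12), seed = 1L)
  fx$receptor
}

# exhaustive-mapping oracle for pharmacophore matching (independent of the
# production search order; same geometric acceptance rule)
oracleMatch <- function(model, lig) {
  f <- modelFeatures(model)
  nF <- nrow(f)
  effMin <- min(minMatch(model), sum(!f$optional))
  ligKind <- ifelse(lig$kind == "AROMATIC", "HYDROPHOBIC", lig$kind)
  best <- list(matched_count = 0L, fit_rmsd = NA_real_)
  for (size in seq(effMin, nF)) {
    for (S in utils::combn(nF, size, simplify = FALSE)) {
      cands <- lapply(S, function(i) which(ligKind == f$kind[i]))
      rec <- function(k, chosen) {
        if (k > length(S)) {
          P <- as.matrix(lig[chosen, c("x", "y", "z")])
          Q <- as.matrix(f[S, c("x", "y", "z")])
          kb <- hetscreen:::.kabsch(P, Q)
          dev <- sqrt(rowSums((kb$transform(P) - Q)^2))
          if (all(dev <= f$radius[S]) &&
              (size > best$matched_count ||
               (size == best$matched_count && kb$rmsd < best$fit_rmsd)))
            best <<- list(matched_count = size, fit_rmsd = kb$rmsd)
          return(invisible())
        }
        for (c in setdiff(cands[[k]], chosen)) rec(k + 1, c(chosen, c))
      }
      rec(1, integer(0))
    }
  }
  best
}

# independent subgraph-isomorphism check through igraph (LAD, non-induced,
# element-compatibility domains)
igraphContains <- function(pattern, target) {
  gP <- igraph::graph_from_data_frame(
    pattern@bonds[, c("a1", "a2")], directed = FALSE,
    vertices = data.frame(name = seq_len(natoms(pattern))))
  gT <- igraph::graph_from_data_frame(
    target@bonds[, c("a1", "a2")], directed = FALSE,
    vertices = data.frame(name = seq_len(natoms(target))))
  domains <- lapply(seq_len(natoms(pattern)), function(i)
    which(target@atoms$element == pattern@atoms$element[i]))
  if (any(vapply(domains, length, integer(1)) == 0)) return(FALSE)
  igraph::subgraph_isomorphic(gP, gT, method = "lad", induced = FALSE,
                              domains = domains)
}

rot3 <- function(ax, ay, az) {
  Rx <- rbind(c(1, 0, 0), c(0, cos(ax), -sin(ax)), c(0, sin(ax), cos(ax)))
  Ry <- rbind(c(cos(ay), 0, sin(ay)), c(0, 1, 0), c(-sin(ay), 0, cos(ay)))
  Rz <- rbind(c(cos(az), -sin(az), 0), c(sin(az), cos(az), 0), c(0, 0, 1))
  Rz %*% Ry %*% Rx
}
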