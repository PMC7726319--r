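# ---- synthetic-data generators: every artifact carries its ground truth ----

# salicylate-family SMILES used to decorate planted actives; all share the
# carboxylate + adjacent aromatic ring arrangement the screening model
# encodes
.activeScaffolds <- c(
  "OC(=O)c1ccccc1O",
  "Cc1cccc(C(O)=O)c1O",
  "OC(=O)c1cc(Cc2cc(C(O)=O)c(O)c(C)c2)cc(C)c1O",
  "OC(=O)c1cc(-c2ccccc2)ccc1O",
  "CCc1cccc(C(O)=O)c1O",
  "OC(=O)c1ccc(C)cc1O",
  "COc1ccc(C(O)=O)c(O)c1",
  "OC(=O)c1cc(CC)cc(C)c1O")

# feature-poor scaffolds for decoys (no acceptor pair in the anchored
# arrangement: plain hydrocarbons, single-heteroatom chains)
.decoyScaffolds <- c(
  "CCCCCC", "CCCCCCCC", "CC(C)CC(C)C", "CCCCO", "CCN(CC)CC",
  "C1CCCCC1", "CC1CCCCC1", "CCCC(C)CC", "CCOCC", "CCCCCN")

#' Generate a compound library with a planted fraction of actives
#'
#' Actives are drawn from a salicylate-family scaffold pool and verified at
#' generation time to match at least `model@minMatch` features of the
#' supplied pharmacophore model; decoys come from feature-poor scaffolds
#' verified to fail.  Scaffolds failing verification are discarded, so the
#' planted label is a guarantee, not a probability.
#'
#' @param n library size.
#' @param fracActive planted active fraction in \[0, 1\].
#' @param model a [PharmacophoreModel-class] used for verification.
#' @param seed RNG seed.
#' @return list `molecules` (list of [Molecule-class], embedded) and
#'   `truth` (data.frame id, label).
#' @export
genLibrary <- function(n, fracActive, model, seed = 1L) {
  stopifnot(fracActive >= 0, fracActive <= 1)
  set.seed(seed)
  nAct <- round(n * fracActive)
  pool <- c(.activeScaffolds, .decoyScaffolds)
  probes <- embedLibrary(lapply(seq_along(pool), function(i)
    parseSmiles(pool[i], sprintf("probe%02d", i))), seed)
  verdict <- vapply(probes, function(m)
    if (!hasConformer(m)) NA else
      matchPharmacophore(model, perceiveFeatures(m))$passed, logical(1))
  okAct <- .activeScaffolds[which(verdict[seq_along(.activeScaffolds)])]
  okDec <- .decoyScaffolds[
    which(!verdict[length(.activeScaffolds) + seq_along(.decoyScaffolds)])]
  if (nAct > 0 && !length(okAct))
    stop("genLibrary: no active scaffold satisfies the model")
  if (nAct < n && !length(okDec))
    stop("genLibrary: no decoy scaffold fails the model")
  labels <- sample(c(rep("active", nAct), rep("decoy", n - nAct)))
  mols <- embedLibrary(lapply(seq_len(n), function(i) {
    src <- if (labels[i] == "active") okAct else okDec
    parseSmiles(src[[sample.int(length(src), 1)]], sprintf("lib%04d", i))
  }), seed)
  names(mols) <- vapply(mols, molId, character(1))
  list(molecules = mols,
       truth = data.frame(id = names(mols), label = labels))
}

# ideal-ish alpha helix backbone: one N/CA/C/O/CB per residue
.toyHelix <- function(nRes = 12L, chain = "A") {
  rise <- 1.5; radius <- 2.3; perTurn <- 3.6
  rows <- list()
  serial <- 0L
  for (i in seq_len(nRes)) {
    ang <- 2 * pi * (i - 1) / perTurn
    ca <- c(radius * cos(ang), radius * sin(ang), rise * (i - 1))
    offs <- list(N = c(-0.8, -0.9, -0.6), CA = c(0, 0, 0),
                 C = c(0.9, 0.7, 0.6), O = c(1.1, 1.7, 0.5),
                 CB = c(1.0, -1.0, -0.9))
    for (nm in names(offs)) {
      serial <- serial + 1L
      p <- ca + offs[[nm]]
      rows[[serial]] <- data.frame(serial = serial, name = nm,
                                   element = substr(nm, 1, 1), chain = chain,
                                   resno = i, resname = "ALA",
                                   x = p[1], y = p[2], z = p[3])
    }
  }
  new("ReceptorStructure", atoms = do.call(rbind, rows),
      anchors = data.frame(chain = chain, resno = ceiling(nRes / 2)))
}

#' Generate a toy receptor and poses at planned anchor distances
#'
#' Builds a small helical receptor with a designated anchor residue and
#' places one rigid 5-atom ligand per planned distance along the outward
#' normal through the anchor, adjusted until the measured minimum
#' heavy-atom distance equals the plan to within 0.01 Angstrom.
#'
#' @param distancePlan numeric vector of planned minimum distances (> 0).
#' @param seed RNG seed (pose orientation jitter).
#' @param engine engine tag for the generated poses.
#' @return list `receptor` ([ReceptorStructure-class]), `poses`, `truth`
#'   (data.frame id, planned_distance).
#' @export
genReceptorAndPoses <- function(distancePlan, seed = 1L, engine = "synthetic") {
  stopifnot(all(distancePlan > 0))
  set.seed(seed)
  receptor <- .toyHelix()
  anchor <- list(chain = receptor@anchors$chain[1],
                 resno = receptor@anchors$resno[1])
  A <- .anchorAtoms(receptor, anchor)
  anchorCtr <- colMeans(A)
  axisCtr <- c(0, 0, anchorCtr[3])
  u <- anchorCtr - axisCtr; u <- u / sqrt(sum(u^2))
  template <- rbind(c(0, 0, 0), c(1.4, 0, 0), c(-1.4, 0, 0),
                    c(0, 1.4, 0), c(0, -1.4, 0))
  poses <- list()
  for (i in seq_along(distancePlan)) {
    d <- distancePlan[i]
    coords <- sweep(template, 2, anchorCtr + (d + 2) * u, "+")
    p <- dockedPose(sprintf("pose%03d", i), engine, i, NA_real_, coords)
    for (iter in 1:50) {
      m <- minDistance(p, receptor, anchor)
      if (abs(m - d) <= 0.005) break
      p$coords <- sweep(p$coords, 2, (d - m) * u, "+")
    }
    poses[[i]] <- p
  }
  list(receptor = receptor, poses = poses,
       truth = data.frame(id = vapply(poses, `[[`, character(1), "id"),
                          planned_distance = distancePlan))
}

#' Simulate a CSP titration series from the quadratic binding model
#'
#' Per-residue peak trajectories follow
#' `delta_i = modelShift(Kd, delta_b_r, Pt, Lt_i)` partitioned into the
#' two dimensions with the fixed ratio `d_dN = 5 * d_dHN`, which makes the
#' scalar CSP reproduce delta_i exactly (a simulation convenience, not a
#' physical claim); Gaussian noise of `sigma` ppm is added independently
#' to each dimension at every point.
#'
#' @param Kd generating dissociation constant (molar).
#' @param deltaB per-residue bound-state shifts (ppm); names become
#'   residue numbers (default 1..length).
#' @param Pt total protein concentration (molar, default 1e-4).
#' @param equivalents ligand-equivalent schedule (default
#'   0.5, 1, 2, 3, 5, 10).
#' @param sigma Gaussian noise per dimension in ppm (default 0.002).
#' @param seed RNG seed.
#' @param disappearResidues residues absent from every bound spectrum
#'   (slow/intermediate exchange emulation).
#' @param intensityProfile optional intensity multiplier per titration
#'   point (AIDA scenarios); default constant 1.
#' @return a [TitrationSeries-class] with `truth` filled in.
#' @export
genTitration <- function(Kd, deltaB, Pt = 1e-4,
                         equivalents = c(0.5, 1, 2, 3, 5, 10),
                         sigma = 0.002, seed = 1L,
                         disappearResidues = integer(0),
                         intensityProfile = NULL) {
  stopifnot(Kd > 0, Pt > 0)
  set.seed(seed)
  residues <- if (is.null(names(deltaB))) seq_along(deltaB)
              else as.integer(names(deltaB))
  lt <- c(0, equivalents * Pt)
  if (is.null(intensityProfile)) intensityProfile <- rep(1, length(lt))
  dH0 <- runif(length(residues), 7.5, 9.5)
  dN0 <- runif(length(residues), 105, 130)
  pls <- vector("list", length(lt))
  for (i in seq_along(lt)) {
    di <- vapply(deltaB, function(db) modelShift(Kd, db, Pt, lt[i]),
                 numeric(1))
    present <- rep(TRUE, length(residues))
    if (i > 1) present[residues %in% disappearResidues] <- FALSE
    pls[[i]] <- data.frame(
      residue = residues,
      dH = dH0 + di + rnorm(length(residues), 0, sigma),
      dN = dN0 + 5 * di + rnorm(length(residues), 0, sigma),
      intensity = 100 * intensityProfile[i] *
        runif(length(residues), 0.95, 1.05),
      present = present)
  }
  new("TitrationSeries", pt = Pt, ligandTotals = lt, peakLists = pls,
      truth = list(Kd = Kd, delta_b = deltaB, Pt = Pt, sigma = sigma,
                   seed = seed, equivalents = equivalents))
}

#' Simulate a 16-point MST binding or competition trace
#'
#' Binding: quadratic-isotherm bound-fraction signal at a fixed labelled
#' target concentration.  Competition: Hill-shaped decay of the
#' preformed-complex signal as the competitor displaces the partner.
#' Concentrations are a 1:2 serial dilution from `maxConc`; noise is
#' multiplicative Gaussian, so the default plateaus span the normalized
#' response 0 (free) to 1 (bound) and the relative noise scales with the
#' response itself.  Instrument-scale plateaus can be supplied instead.
#'
#' @param kind `"binding"` or `"competition"`.
#' @param value generating Kd (binding) or EC50 (competition), molar.
#' @param hillN Hill coefficient for competition traces (default 4).
#' @param Pt labelled-target concentration, molar (default 50e-9).
#' @param maxConc top concentration of the dilution series (default 5e-3).
#' @param nPoints dilution points (default 16).
#' @param sigmaRel relative (multiplicative) noise SD (default 0.01).
#' @param seed RNG seed.
#' @param signalFree,signalBound plateau signals in instrument units.
#' @return list `trace` (data.frame conc_M, signal) and `truth`.
#' @export
genMst <- function(kind = c("binding", "competition"), value, hillN = 4,
                   Pt = 50e-9, maxConc = 5e-3, nPoints = 16L,
                   sigmaRel = 0.01, seed = 1L,
                   signalFree = 0, signalBound = 1) {
  kind <- match.arg(kind)
  stopifnot(value > 0, maxConc > 0)
  set.seed(seed)
  conc <- maxConc / 2^(seq_len(nPoints) - 1)
  clean <- if (kind == "binding") {
    signalFree + (signalBound - signalFree) * fracBound(value, Pt, conc)
  } else {
    # preformed complex: signal runs from the bound plateau back toward
    # the free-state value as the competitor displaces the partner
    signalBound + (signalFree - signalBound) / (1 + (value / conc)^hillN)
  }
  signal <- clean * (1 + rnorm(nPoints, 0, sigmaRel))
  list(trace = data.frame(conc_M = conc, signal = signal),
       truth = list(kind = kind, value = value, hill_n = hillN, Pt = Pt,
                    max_conc = maxConc, sigma_rel = sigmaRel, seed = seed))
}

#' The embedded actives/decoys training-set fixture
#'
#' Seven literature-reported binders of the target protein (labelled
#' active) and ten inactive drugs (labelled decoy), shipped as SMILES
#' transcribed from their public canonical structures.  One active
#' (`inflachromene_synthetic`) is a synthetic structural stand-in
#' preserving the compound class (non-acidic chromene) because no public
#' structure could be transcribed verbatim.  The file checksum is verified
#' on load.
#'
#' @return data.frame `id, smiles, label`.
#' @export
trainingSetFixture <- function() {
  path <- system.file("extdata", "training_set.csv", package = "hetscreen")
  sum <- unname(tools::md5sum(path))
  expected <- .trainingSetMd5
  if (!is.na(expected) && !identical(sum, expected))
    warning("training_set.csv checksum mismatch: expected ", expected,
            " got ", sum)
  read.csv(path, stringsAsFactors = FALSE)
}

.trainingSetMd5 <- "25d05f5a2f76b0623b315f42d6d33e27"
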