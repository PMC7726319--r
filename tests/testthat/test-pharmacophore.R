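test_that("two actives sharing only a carboxylate give HBA candidates only", {
  acids <- embedLibrary(list(parseSmiles("CC(O)=O", "acetic"),
                             parseSmiles("CCC(O)=O", "propanoic")), 1L)
  m <- buildModel(acids, quorum = 2L)
  f <- modelFeatures(m)
  expect_gte(sum(f$kind == "HBA"), 2L)
  expect_equal(sum(f$kind == "HYDROPHOBIC"), 0L)
})

test_that("refinement fixes labels, radii, optionality and min-match", {
  model <- fxMiniModel()
  f <- modelFeatures(model)
  expect_equal(f$label, c("HBA1", "HBA2", "H1", "H2"))
  expect_equal(f$radius, c(1.65, 1.65, 1.8, 1.5))
  expect_equal(f$optional, c(FALSE, FALSE, FALSE, TRUE))
  expect_equal(minMatch(model), 3L)
  expect_equal(model@radiusAdjustments,
               list(HBA1 = 0.15, HBA2 = 0.15, H1 = 0.3, H2 = 0))
})

test_that("refinement refuses a candidate set without two of each kind", {
  acids <- embedLibrary(list(parseSmiles("CC(O)=O", "acetic"),
                             parseSmiles("CCC(O)=O", "propanoic")), 1L)
  cand <- buildModel(acids, quorum = 2L)
  expect_error(refineModel(cand), "HYDROPHOBIC")
})

test_that("matching agrees with the exhaustive-mapping oracle", {
  model <- fxMiniModel()
  ligands <- list(perceiveFeatures(fxSalicylic()),
                  perceiveFeatures(fxDiflunisal()),
                  perceiveFeatures(fxCresotic()),
                  perceiveFeatures(fxBenzene()))
  # plus jittered variants to probe near-boundary geometry
  set.seed(11)
  for (lig in ligands) {
    jit <- lig
    jit[, c("x", "y", "z")] <- jit[, c("x", "y", "z")] +
      matrix(rnorm(3 * nrow(jit), 0, 0.4), ncol = 3)
    for (lf in list(lig, jit)) {
      got <- matchPharmacophore(model, lf)
      want <- oracleMatch(model, lf)
      expect_equal(got$matched_count, want$matched_count)
      if (got$matched_count > 0)
        expect_equal(got$fit_rmsd, want$fit_rmsd, tolerance = 1e-8)
    }
  }
})

test_that("score is matched count minus fit rmsd over ten", {
  model <- fxMiniModel()
  res <- matchPharmacophore(model, perceiveFeatures(fxSalicylic()))
  expect_gt(res$matched_count, 0)
  expect_equal(res$score, res$matched_count - res$fit_rmsd / 10)
})

test_that("a three-feature match that excludes the optional feature passes", {
  # model features exactly at salicylate geometry => the three non-optional
  # features match; matched_count below four must still pass
  model <- fxMiniModel()
  res <- matchPharmacophore(model, perceiveFeatures(fxSalicylic()))
  expect_gte(res$matched_count, 3L)
  expect_true(res$passed)
  # a ligand with no acceptors cannot reach min match
  res2 <- matchPharmacophore(model, perceiveFeatures(fxBenzene()))
  expect_equal(res2$matched_count, 0L)
  expect_false(res2$passed)
  expect_equal(res2$score, 0)
})

test_that("matching is invariant under rigid rotation of the ligand", {
  model <- fxMiniModel()
  lig <- perceiveFeatures(fxCresotic())
  r0 <- matchPharmacophore(model, lig)
  lig2 <- lig
  lig2[, c("x", "y", "z")] <-
    as.matrix(lig[, c("x", "y", "z")]) %*% t(rot3(1.2, 0.4, -0.7))
  r1 <- matchPharmacophore(model, lig2)
  expect_equal(r1$matched_count, r0$matched_count)
  expect_equal(r1$fit_rmsd, r0$fit_rmsd, tolerance = 1e-6)
})

test_that("ROC computation matches frozen examples and the pROC oracle", {
  # actives score {3, 1}, decoys {2, 0}: concordant 3/4 pairs -> AUC 0.75
  r <- rocFromScores(c(3, 1, 2, 0), c("active", "active", "decoy", "decoy"))
  expect_equal(r$auc, 0.75)
  # perfect separation
  expect_equal(rocFromScores(c(5, 4, 1), c(TRUE, TRUE, FALSE))$auc, 1)
  # complete ties -> half credit
  expect_equal(rocFromScores(c(2, 2, 2, 2), c(TRUE, TRUE, FALSE, FALSE))$auc, 0.5)
  # random scores against the pROC reference implementation
  set.seed(99)
  sc <- round(rnorm(40), 2)   # rounding forces some ties
  lb <- sample(c(TRUE, FALSE), 40, replace = TRUE)
  want <- as.numeric(pROC::auc(pROC::roc(lb, sc, quiet = TRUE,
                                         direction = "<", levels = c(FALSE, TRUE))))
  expect_equal(rocFromScores(sc, lb)$auc, want, tolerance = 1e-12)
  expect_error(rocFromScores(c(1, 2), c(TRUE, TRUE)), "both classes")
})

test_that("model JSON serialization round trips", {
  model <- fxMiniModel()
  tf <- tempfile(fileext = ".json")
  writeModelJson(model, tf)
  back <- readModelJson(tf)
  expect_equal(modelFeatures(back), modelFeatures(model))
  expect_equal(minMatch(back), minMatch(model))
})

test_that("quorum relaxation is reported in the model metadata", {
  model <- fxMiniModel()  # two actives cannot satisfy quorum 4
  expect_equal(model@meta$quorum_requested, 4L)
  expect_lt(model@meta$quorum, 4L)
})
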