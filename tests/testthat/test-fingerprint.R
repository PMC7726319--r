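test_that("Tanimoto distance matches the hand calculation 1 - 2/3", {
  mkfp <- function(on) {
    v <- rep(FALSE, 16)
    v[on] <- TRUE
    structure(v, nBits = 16L, maxPath = 7L)
  }
  a <- mkfp(c(1, 2, 3))     # |A| = 3
  b <- mkfp(c(2, 3, 4))     # |B| = 3, intersection 2, union 4
  D <- tanimotoDistanceMatrix(list(m1 = a, m2 = b))
  expect_equal(D["m1", "m2"], 1 - 2 / 4)
  # identical sets -> distance 0; both empty -> 0 by convention
  e <- mkfp(integer(0))
  D2 <- tanimotoDistanceMatrix(list(x = a, y = a, z = e, w = e))
  expect_equal(D2["x", "y"], 0)
  expect_equal(D2["z", "w"], 0)
})

test_that("fingerprints are deterministic and sensitive to structure", {
  f1 <- linearFingerprint(fxSalicylic())
  f2 <- linearFingerprint(fxSalicylic())
  expect_identical(f1, f2)
  f3 <- linearFingerprint(fxBenzene())
  expect_false(identical(as.logical(f1), as.logical(f3)))
  expect_length(f1, 1024)
})

test_that("Tanimoto distances form a proper bounded metric on real molecules", {
  train <- trainingSetFixture()
  mols <- lapply(seq_len(nrow(train)), function(i)
    parseSmiles(train$smiles[i], train$id[i]))
  fps <- lapply(mols, linearFingerprint)
  names(fps) <- train$id
  D <- tanimotoDistanceMatrix(fps)
  expect_true(all(D >= 0 & D <= 1))
  expect_equal(unname(diag(D)), rep(0, nrow(D)))
  expect_equal(D, t(D))
  # Soergel distance satisfies the triangle inequality
  n <- nrow(D)
  triangleOk <- vapply(seq_len(n), function(k)
    all(D <= outer(D[, k], D[k, ], "+") + 1e-12), logical(1))
  expect_true(all(triangleOk))
})

test_that("average-linkage clustering is invariant to input order", {
  train <- trainingSetFixture()
  fps <- lapply(seq_len(nrow(train)), function(i)
    linearFingerprint(parseSmiles(train$smiles[i], train$id[i])))
  names(fps) <- train$id
  D <- tanimotoDistanceMatrix(fps)
  cl1 <- averageLinkage(D, K = 4L)
  perm <- sample(seq_len(nrow(D)))
  cl2 <- averageLinkage(D[perm, perm], K = 4L)
  expect_equal(cl1$labels[sort(names(cl1$labels))],
               cl2$labels[sort(names(cl2$labels))])
  expect_equal(cl1$sizes, cl2$sizes)
  # size-ordered labels: cluster 1 is the largest
  expect_true(all(diff(cl1$sizes) <= 0))
})

test_that("major clusters require more than ten members", {
  lab <- c(rep(1L, 12), rep(2L, 11), rep(3L, 10), rep(4L, 2))
  names(lab) <- paste0("m", seq_along(lab))
  cl <- list(labels = lab, sizes = setNames(c(12L, 11L, 10L, 2L), 1:4), K = 4L)
  major <- selectMajorClusters(cl)
  expect_equal(major$cluster, c(1L, 2L))
  expect_equal(major$size, c(12L, 11L))
  expect_equal(selectMajorClusters(cl, minSize = 3L)$cluster, c(1L, 2L, 3L))
  expect_equal(nrow(selectMajorClusters(cl, minSize = 100L)), 0L)
})

test_that("representative selection picks the medoid deterministically", {
  D <- matrix(c(0, 1, 4,
                1, 0, 1,
                4, 1, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  lab <- setNames(rep(1L, 3), c("a", "b", "c"))
  cl <- list(labels = lab, sizes = setNames(3L, "1"), K = 1L)
  expect_equal(pickRepresentative(c("a", "b", "c"), D), "b")
  expect_equal(pickRepresentative("a", D), "a")
  rep <- clusterReport(cl, D)
  expect_equal(rep$id[rep$is_representative], "b")
  expect_true(all(rep$cluster_size == 3L))
})

test_that("the dendrogram exports as parseable Newick", {
  train <- trainingSetFixture()[1:6, ]
  fps <- lapply(seq_len(nrow(train)), function(i)
    linearFingerprint(parseSmiles(train$smiles[i], train$id[i])))
  names(fps) <- train$id
  cl <- averageLinkage(tanimotoDistanceMatrix(fps), K = 2L)
  tf <- tempfile(fileext = ".nwk")
  writeDendrogramNewick(cl, tf)
  tree <- ape::read.tree(tf)
  expect_setequal(tree$tip.label, train$id)
})
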