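test_that("minimum anchor distance is the pairwise minimum", {
  rp <- fxReceptor()
  anchor <- list(chain = "A", resno = rp$receptor@anchors$resno[1])
  A <- hetscreen:::.anchorAtoms(rp$receptor, anchor)
  pose <- dockedPose("p", "e", 1L, NA_real_, A[1, , drop = FALSE] + c(3, 0, 0))
  d <- minDistance(pose, rp$receptor, anchor)
  brute <- min(sqrt(rowSums(sweep(A, 2, pose$coords[1, ])^2)))
  expect_equal(d, brute, tolerance = 1e-10)
})

test_that("generated poses sit at their planned anchor distances", {
  rp <- fxReceptor()
  anchor <- list(chain = "A", resno = rp$receptor@anchors$resno[1])
  d <- vapply(rp$poses, minDistance, numeric(1), rp$receptor, anchor)
  expect_equal(d, rp$truth$planned_distance, tolerance = 0.01)
})

test_that("distance filter boundary is inclusive and behavior monotone", {
  rp <- fxReceptor()
  anchor <- list(chain = "A", resno = rp$receptor@anchors$resno[1])
  A <- hetscreen:::.anchorAtoms(rp$receptor, anchor)
  # place one ligand atom about 6 A from an anchor atom, then test the
  # boundary with the measured distance itself: inclusive at the cutoff
  far <- A[which.max(A[, 3]), ]
  exact <- dockedPose("exact", "e", 1L, NA_real_,
                      matrix(far + c(0, 0, 6.0), ncol = 3))
  d0 <- minDistance(exact, rp$receptor, anchor)
  expect_equal(d0, 6.0, tolerance = 1e-9)
  expect_length(distanceFilter(list(exact), rp$receptor, anchor, d0), 1L)
  expect_length(distanceFilter(list(exact), rp$receptor, anchor, d0 - 1e-9), 0L)

  surv4 <- distanceFilter(rp$poses, rp$receptor, anchor, 4)
  surv6 <- distanceFilter(rp$poses, rp$receptor, anchor, 6)
  surv9 <- distanceFilter(rp$poses, rp$receptor, anchor, 9)
  expect_lte(length(surv4), length(surv6))
  expect_lte(length(surv6), length(surv9))
  ids <- function(ps) vapply(ps, `[[`, character(1), "id")
  expect_true(all(ids(surv4) %in% ids(surv6)))
  # idempotence
  expect_equal(ids(distanceFilter(surv6, rp$receptor, anchor, 6)), ids(surv6))
  expect_error(distanceFilter(rp$poses, rp$receptor, anchor, 0))
})

test_that("rank cut keeps the top k per engine", {
  mk <- function(id, engine, rank) dockedPose(id, engine, rank, NA_real_,
                                              matrix(0, 1, 3))
  poses <- list(mk("a", "vina", 2L), mk("b", "vina", 1L), mk("c", "vina", 3L),
                mk("d", "ad4", 1L), mk("e", "ad4", 2L))
  keep <- rankCut(poses, 2)
  expect_setequal(vapply(keep, `[[`, character(1), "id"), c("a", "b", "d", "e"))
})

test_that("PDBQT-subset poses parse per MODEL block without hydrogens", {
  tf <- tempfile(fileext = ".pdbqt")
  writeLines(c(
    "MODEL 1",
    "ATOM      1  C   LIG A   1       1.000   2.000   3.000  0.00  0.00    +0.000 C ",
    "ATOM      2  H   LIG A   1       1.500   2.000   3.000  0.00  0.00    +0.000 HD",
    "ATOM      3  O   LIG A   1       2.000   2.000   3.000  0.00  0.00    -0.300 OA",
    "ENDMDL",
    "MODEL 2",
    "ATOM      1  C   LIG A   1       4.000   5.000   6.000  0.00  0.00    +0.000 C ",
    "ENDMDL"), tf)
  poses <- readPdbqtPoses(tf, "zinc1", "vina")
  expect_length(poses, 2)
  expect_equal(poses[[1]]$rank, 1L)
  expect_equal(nrow(poses[[1]]$coords), 2)   # H skipped
  expect_equal(poses[[2]]$coords[1, ], c(x = 4, y = 5, z = 6))
  expect_error(suppressWarnings(readPdbqtPoses(tempfile(), "x")),
               "cannot open|No such|format", ignore.case = TRUE)
})

test_that("hit-list merge keeps provenance and distinct counts", {
  m <- mergeHitlists(list(vina = c("a", "b"), ad4 = c("b", "c"), glide = character(0)))
  expect_equal(m$n_distinct, 3L)
  expect_setequal(m$ids, c("a", "b", "c"))
  expect_equal(unname(m$per_source), c(2L, 2L, 0L))
  expect_equal(sum(m$provenance$id == "b"), 2L)
})

test_that("funnel stages never increase the compound count", {
  rp <- fxReceptor()
  model <- fxMiniModel()
  lib <- genLibrary(6, 0.5, model, seed = 4L)
  poses <- rp$poses
  for (i in seq_along(poses)) poses[[i]]$id <- names(lib$molecules)[i]
  cfg <- list(poses = poses, receptor = rp$receptor,
              anchor = list(chain = "A", resno = rp$receptor@anchors$resno[1]),
              molecules = lib$molecules, model = model, seed = 4L)
  fn <- runFunnel(cfg)
  expect_true(all(fn$report$n_out <= fn$report$n_in))
  expect_equal(fn$report$stage[1], "rank_cut")
  expect_equal(tail(fn$report$stage, 1), "pharmacophore_screen")
  # chained stages: each stage consumes the previous stage's survivors
  expect_equal(fn$report$n_in[-1], fn$report$n_out[-nrow(fn$report)])
  expect_error(runFunnel(list(poses = poses)), "missing")
})

test_that("consensus sites within 8 A aggregate into one hot spot", {
  sites <- data.frame(label = c("CS1", "CS2", "CS3"),
                      x = c(0, 7, 30), y = 0, z = 0,
                      probes = c(10, 5, 8))
  hs <- aggregateConsensusSites(sites)
  expect_equal(nrow(hs), 2L)
  expect_equal(hs$probe_sum[1], 15)            # ranked by probe sum
  expect_equal(hs$members[1], "CS1+CS2")
  far <- aggregateConsensusSites(data.frame(label = c("a", "b"),
                                            x = c(0, 9), y = 0, z = 0,
                                            probes = c(1, 1)))
  expect_equal(nrow(far), 2L)
})
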