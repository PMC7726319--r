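.mkPeaks <- function(residue, dH, dN, intensity = 100,
                     present = rep(TRUE, length(residue))) {
  data.frame(residue = residue, dH = dH, dN = dN,
             intensity = intensity, present = present)
}

test_that("combined CSP matches the hand calculation", {
  free <- .mkPeaks(1:2, c(8.0, 8.5), c(120, 115))
  bound <- .mkPeaks(1:2, c(8.05, 8.5), c(120.25, 115))
  prof <- computeCsp(free, bound)
  # residue 1: sqrt((0.05^2 + 0.25^2/25)/2) = 0.05
  expect_equal(unname(prof$csp["1"]), 0.05, tolerance = 1e-12)
  expect_equal(unname(prof$csp["2"]), 0)
  expect_equal(prof$mean, mean(prof$csp))
})

test_that("disappeared residues are reported, not averaged", {
  free <- .mkPeaks(1:3, c(8, 8, 8), c(120, 121, 122))
  bound <- .mkPeaks(1:3, c(8.1, 8, 8), c(120, 121, 122),
                    present = c(TRUE, TRUE, FALSE))
  prof <- computeCsp(free, bound)
  expect_equal(prof$disappeared, 3L)
  expect_equal(length(prof$csp), 2L)
})

test_that("threshold keeps only residues strictly above mean + SD", {
  csp <- c(`10` = 0.1, `11` = 0.1, `12` = 0.1, `13` = 0.5)
  prof <- list(csp = csp, disappeared = integer(0),
               mean = mean(csp), sd = sd(csp))
  # mean 0.2, sd 0.2 -> threshold 0.4: only 0.5 passes
  expect_equal(thresholdResidues(prof), 13L)
  # a value exactly at the threshold does not pass
  csp2 <- c(`1` = 0.0, `2` = 0.2, `3` = 0.4)
  prof2 <- list(csp = csp2, mean = mean(csp2), sd = sd(csp2))
  expect_equal(thresholdResidues(prof2), integer(0))
})

test_that("threshold refuses fewer than three residues", {
  prof <- list(csp = c(`1` = 0.1, `2` = 0.2), mean = 0.15, sd = 0.07)
  expect_error(thresholdResidues(prof), "at least 3")
})

test_that("peak-list CSV IO preserves values and marks blank rows absent", {
  tf <- tempfile(fileext = ".csv")
  writeLines(c("residue,dH,dN,intensity",
               "5,8.21,119.4,95.2",
               "6,,,12.0",
               "7,7.95,124.1,101.0"), tf)
  pl <- readPeaklist(tf)
  expect_equal(pl$present, c(TRUE, FALSE, TRUE))
  expect_equal(pl$dH[1], 8.21)
  tf2 <- tempfile(fileext = ".csv")
  writePeaklist(pl, tf2)
  back <- readPeaklist(tf2)
  expect_equal(back$present, pl$present)
  expect_equal(back$dH[c(1, 3)], pl$dH[c(1, 3)])
})

test_that("duplicate residues in a peak list are rejected", {
  tf <- tempfile(fileext = ".csv")
  writeLines(c("residue,dH,dN,intensity",
               "5,8.2,119.4,95", "5,8.3,120.0,90"), tf)
  expect_error(readPeaklist(tf), "duplicate residue 5")
})

test_that("series validity enforces the ligand-free reference point", {
  pl <- .mkPeaks(1:3, c(8, 8, 8), c(120, 121, 122))
  expect_error(new("TitrationSeries", pt = 1e-4,
                   ligandTotals = c(1e-4, 2e-4),
                   peakLists = list(pl, pl)), "ligand-free")
  expect_error(new("TitrationSeries", pt = 1e-4,
                   ligandTotals = c(0, 2e-4, 1e-4),
                   peakLists = list(pl, pl, pl)), "increasing")
})
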