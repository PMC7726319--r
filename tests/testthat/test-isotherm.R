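test_that("the quadratic-coefficient form equals delta_b times bound fraction", {
  Kd <- 0.9e-3; db <- 0.2; Pt <- 0.1e-3
  Lt <- c(0, 0.05e-3, 0.1e-3, 0.5e-3, 1e-3, 5e-3)
  expect_equal(modelShift(Kd, db, Pt, Lt, form = "abc"),
               modelShift(Kd, db, Pt, Lt, form = "standard"),
               tolerance = 1e-12)
  # hand value at Lt = 1.0 mM: s = 2.0 mM, disc = 3.6e-6,
  # fracBound = (2 - sqrt(3.6)) / 0.2 = 0.5131670...
  expect_equal(modelShift(Kd, db, Pt, 1e-3), 0.2 * 0.51316701949486,
               tolerance = 1e-10)
})

test_that("bound fraction is bounded, zero without ligand and monotone", {
  Pt <- 1e-4
  Lt <- seq(0, 2e-3, length.out = 50)
  fb <- fracBound(5e-4, Pt, Lt)
  expect_true(all(fb >= 0 & fb <= 1))
  expect_equal(fb[1], 0)
  expect_true(all(diff(fb) > 0))                 # increasing in ligand
  expect_true(all(fracBound(1e-3, Pt, Lt[-1]) <
                  fracBound(1e-4, Pt, Lt[-1])))  # decreasing in Kd
  expect_error(fracBound(0, Pt, Lt), "> 0")
  expect_error(fracBound(1e-4, Pt, -1), ">= 0")
})

test_that("a noiseless titration returns the generating Kd and delta_b", {
  series <- genTitration(Kd = 0.9e-3,
                         deltaB = c(`10` = 0.20, `11` = 0.15,
                                    `12` = 0.25, `13` = 0.18),
                         Pt = 1e-4, sigma = 0, seed = 3L)
  fit <- fitResidue(series, 10L)
  expect_true(fit$converged)
  expect_equal(fit$Kd, 0.9e-3, tolerance = 1e-4)
  expect_equal(fit$delta_b, 0.20, tolerance = 1e-4)
  expect_lt(fit$rss, 1e-12)
})

test_that("fitting requires at least four titration points for the residue", {
  series <- genTitration(Kd = 0.9e-3, deltaB = c(`10` = 0.2, `11` = 0.2),
                         Pt = 1e-4, sigma = 0, seed = 1L,
                         disappearResidues = 11L)
  expect_error(fitResidue(series, 11L), "fewer than 4")
})

test_that("aggregation averages converged fits and rejects incomplete input", {
  mk <- function(r, kd, conv = TRUE)
    list(residue = r, Kd = kd, delta_b = 0.2, residuals = 0, rss = 0,
         converged = conv)
  fits <- list(mk(1L, 1e-3), mk(2L, 2e-3), mk(3L, 3e-3))
  agg <- aggregateKd(fits, c(1L, 2L, 3L))
  expect_equal(agg$mean_Kd, 2e-3)
  expect_equal(agg$sd_Kd, 1e-3)
  expect_error(aggregateKd(fits, c(1L, 9L)), "no fit for residue 9")
  expect_error(aggregateKd(list(mk(1L, 1e-3, conv = FALSE)), 1L),
               "did not converge")
  expect_error(aggregateKd(fits, integer(0)), "empty")
})

test_that("fitAllResidues covers every residue present at enough points", {
  series <- genTitration(Kd = 1.1e-3, deltaB = rep(0.2, 5),
                         Pt = 1e-4, sigma = 0, seed = 2L,
                         disappearResidues = 4L)
  fits <- fitAllResidues(series)
  expect_setequal(vapply(fits, `[[`, numeric(1), "residue"), c(1, 2, 3, 5))
  tfc <- tempfile(fileext = ".csv"); tfj <- tempfile(fileext = ".json")
  agg <- aggregateKd(fits, c(1L, 2L, 3L, 5L))
  writeFitReport(fits, agg, tfc, tfj)
  rep <- read.csv(tfc)
  expect_equal(nrow(rep), 4L)
  back <- jsonlite::read_json(tfj, simplifyVector = TRUE)
  expect_equal(back$mean_Kd, agg$mean_Kd, tolerance = 1e-9)
})
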