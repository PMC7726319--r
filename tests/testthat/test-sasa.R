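.mkStructure <- function(element, x, y, z, resno = seq_along(element),
                         resname = "ALA", name = element) {
  new("ReceptorStructure",
      atoms = data.frame(serial = seq_along(element), name = name,
                         element = element, chain = "A", resno = resno,
                         resname = resname, x = x, y = y, z = z),
      anchors = data.frame(chain = character(), resno = integer()))
}

test_that("an isolated atom exposes its full solvent-expanded sphere", {
  s <- .mkStructure("C", 0, 0, 0)
  res <- shrakeRupleySasa(s)
  r <- 1.70 + 1.4
  expect_equal(res$atoms$sasa, 4 * pi * r^2, tolerance = 1e-9)
  # oxygen has a different radius
  s2 <- .mkStructure("O", 0, 0, 0)
  expect_equal(shrakeRupleySasa(s2)$atoms$sasa, 4 * pi * (1.52 + 1.4)^2,
               tolerance = 1e-9)
})

test_that("well-separated atoms are additive; close contact buries area", {
  far <- .mkStructure(c("C", "C"), c(0, 50), c(0, 0), c(0, 0))
  resFar <- shrakeRupleySasa(far)
  iso <- 4 * pi * (1.70 + 1.4)^2
  expect_equal(sum(resFar$atoms$sasa), 2 * iso, tolerance = 1e-9)

  near <- .mkStructure(c("C", "C"), c(0, 1.5), c(0, 0), c(0, 0))
  resNear <- shrakeRupleySasa(near)
  expect_true(all(resNear$atoms$sasa < iso))
  # symmetric pair loses the same area on each side, up to the sampling
  # resolution of the deterministic spiral lattice
  expect_equal(resNear$atoms$sasa[1], resNear$atoms$sasa[2], tolerance = 0.01)
})

test_that("a fully enclosed atom has (near) zero accessible area", {
  # carbon caged by octahedral + cubic shell of neighbours at 2 A
  shell <- rbind(c(2, 0, 0), c(-2, 0, 0), c(0, 2, 0), c(0, -2, 0),
                 c(0, 0, 2), c(0, 0, -2),
                 2 / sqrt(3) * as.matrix(expand.grid(c(-1, 1), c(-1, 1),
                                                     c(-1, 1))) * 1.2)
  s <- .mkStructure(rep("C", 1 + nrow(shell)),
                    c(0, shell[, 1]), c(0, shell[, 2]), c(0, shell[, 3]))
  res <- shrakeRupleySasa(s)
  expect_lt(res$atoms$sasa[1], 0.02 * 4 * pi * (1.7 + 1.4)^2)
})

test_that("per-residue totals and relative SASA use the Gly-X-Gly scale", {
  s <- .mkStructure(c("C", "C", "O"), c(0, 20, 20.5), c(0, 0, 0), c(0, 0, 0),
                    resno = c(1L, 2L, 2L), resname = c("ALA", "SER", "SER"))
  res <- shrakeRupleySasa(s)
  expect_equal(nrow(res$residues), 2L)
  a <- res$atoms$sasa
  expect_equal(res$residues$sasa, c(a[1], a[2] + a[3]), tolerance = 1e-9)
  expect_equal(res$residues$rel_sasa,
               res$residues$sasa / c(129, 155), tolerance = 1e-9)
  # non-standard residue names give NA relative SASA
  s2 <- .mkStructure("C", 0, 0, 0, resname = "LIG")
  expect_true(is.na(shrakeRupleySasa(s2)$residues$rel_sasa))
})

test_that("unknown elements are refused", {
  s <- .mkStructure("XX", 0, 0, 0)
  expect_error(shrakeRupleySasa(s), "van der Waals")
})
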