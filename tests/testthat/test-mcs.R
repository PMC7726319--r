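test_that("benzene and toluene share the six-atom aromatic ring", {
  benzene <- parseSmiles("c1ccccc1", "benzene")
  toluene <- parseSmiles("Cc1ccccc1", "toluene")
  res <- maxCommonSubstructure(list(benzene, toluene), minFraction = 1)
  expect_equal(natoms(res$scaffold), 6L)
  expect_equal(res$n_matched, 2L)
  expect_equal(res$matched_fraction, 1)
  expect_false(res$approximate)
  expect_true(igraphContains(res$scaffold, benzene))
  expect_true(igraphContains(res$scaffold, toluene))
})

test_that("the scaffold is contained in every matched member (igraph oracle)", {
  mols <- list(parseSmiles("OC(=O)c1ccccc1O", "sal"),
               parseSmiles("Cc1cccc(C(O)=O)c1O", "cresotic"),
               parseSmiles("OC(=O)c1ccc(C)cc1O", "methylsal"))
  res <- maxCommonSubstructure(mols, minFraction = 1)
  for (m in mols) expect_true(igraphContains(res$scaffold, m))
  # the shared salicylate core: ring + COOH + phenol O = 10 atoms
  expect_equal(natoms(res$scaffold), 10L)
})

test_that("the monomer unit is recovered from the methylene-bridged dimer", {
  mono <- parseSmiles("Cc1cccc(C(O)=O)c1O", "mono")
  dimer <- parseSmiles("OC(=O)c1cc(Cc2cc(C(O)=O)c(O)c(C)c2)cc(C)c1O", "dimer")
  res <- maxCommonSubstructure(list(mono, dimer), minFraction = 1)
  # the whole monomer embeds in the dimer (non-induced containment)
  expect_equal(natoms(res$scaffold), natoms(mono))
  expect_true(igraphContains(res$scaffold, dimer))
})

test_that("the quorum fraction controls which members must match", {
  mols <- list(parseSmiles("c1ccccc1", "a"),
               parseSmiles("Cc1ccccc1", "b"),
               parseSmiles("CCCC", "c"))       # no ring
  # all three share no labelled edge (aromatic vs aliphatic carbon), so the
  # strict search degrades to a single-atom scaffold with a warning
  expect_warning(strict <- maxCommonSubstructure(mols, minFraction = 1),
                 "single-atom")
  loose <- maxCommonSubstructure(mols, minFraction = 0.6)  # quorum 2 of 3
  expect_lt(natoms(strict$scaffold), natoms(loose$scaffold))
  expect_equal(loose$n_matched, 2L)
  expect_equal(natoms(loose$scaffold), 6L)
})

test_that("an exhausted search budget is flagged approximate", {
  mols <- list(parseSmiles("OC(=O)c1cc(-c2ccccc2)ccc1O", "big1"),
               parseSmiles("OC(=O)c1ccc(-c2ccccc2)cc1O", "big2"))
  res <- suppressWarnings(
    maxCommonSubstructure(mols, minFraction = 1, budget = 200))
  expect_true(res$approximate)
})

test_that("scaffold serialization is a parseable ring notation", {
  benzene <- parseSmiles("c1ccccc1", "benzene")
  toluene <- parseSmiles("Cc1ccccc1", "toluene")
  res <- maxCommonSubstructure(list(benzene, toluene), minFraction = 1)
  s <- res$smiles_like
  expect_true(nchar(s) > 0)
  back <- parseSmiles(s, "roundtrip")
  expect_equal(natoms(back), 6L)
  expect_equal(nrow(back@bonds), 6L)
})
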