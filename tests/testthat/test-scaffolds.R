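# Scaffold extraction, dissection and enumerative parent generation.

test_that("Murcko scaffolds prune terminal chains and keep exocyclic multibonds", {
  expect_identical(canonicalSmiles(murckoScaffold(parseSmiles("Cc1ccccc1"))),
                   canonicaliseSmiles("c1ccccc1"))
  expect_null(murckoScaffold(parseSmiles("CCCCCC")))
  # nothing terminal to prune in diphenylmethane
  dpm <- "c1ccc(Cc2ccccc2)cc1"
  expect_identical(canonicalSmiles(murckoScaffold(parseSmiles(dpm))),
                   canonicaliseSmiles(dpm))
  # a ring carbonyl oxygen stays with the scaffold
  m <- parseSmiles("O=C1CCCCC1CC")
  expect_identical(canonicalSmiles(murckoScaffold(m)),
                   canonicaliseSmiles("O=C1CCCCC1"))
  # idempotence over the panel
  for (cs in toyPanel()) {
    sc <- murckoScaffold(parseSmiles(cs$smiles))
    if (is.null(sc)) next
    sc2 <- murckoScaffold(sc)
    expect_identical(canonicalSmiles(sc2), canonicalSmiles(sc), info = cs$name)
  }
})

test_that("atom accounting: scaffold plus side chains cover every heavy atom", {
  for (cs in toyPanel()) {
    mol <- parseSmiles(cs$smiles)
    p <- scaffoldParts(mol)
    covered <- as.integer(unname(c(p$scaffold_atoms, unlist(p$side_chains))))
    expect_identical(sort(covered), seq_len(heavyAtomCount(mol)),
                     info = cs$name)
  }
})

test_that("dissection modes produce the documented fragment sets", {
  side <- makeFragmenter("scaffold",
                         list(fragmentation_type = "SIDE_CHAINS_ONLY"))
  # anisole: the O-ring bond is cut and saturated -> methanol
  expect_identical(fragmentMolecule(side, parseSmiles("COc1ccccc1")),
                   cano("CO"))
  expect_identical(fragmentMolecule(side, parseSmiles("Cc1ccccc1")),
                   cano("C"))
  scaf <- makeFragmenter("scaffold")
  expect_identical(fragmentMolecule(scaf, parseSmiles("Cc1ccccc1")),
                   cano("c1ccccc1"))
  # acyclic molecules yield an empty list
  expect_length(fragmentMolecule(scaf, parseSmiles("CCCCCC")), 0L)
  # rings and linkers of diphenylmethane: two benzenes + CH2 linker
  rl <- makeFragmenter("scaffold",
                       list(fragmentation_type = "RINGS_AND_LINKERS"))
  expect_same_multiset(fragmentMolecule(rl, parseSmiles("c1ccc(Cc2ccccc2)cc1")),
                       c("c1ccccc1", "c1ccccc1", "C"))
})

test_that("enumerated parents match the independent subchain enumerator", {
  expect_length(enumerateParents(parseSmiles("c1ccccc1")), 0L)
  expect_identical(enumerateParents(parseSmiles("c1ccc(Cc2ccccc2)cc1")),
                   cano("c1ccccc1"))
  # three distinct rings in a linear chain: all contiguous proper
  # subchains, enumerated independently by textual template assembly
  chain <- "c1ccc(CC2CCC(Cc3ccncc3)CC2)cc1"
  got <- enumerateParents(parseSmiles(chain))
  oracle <- enumerateSubchainsOracle(c("bz", "ch", "py"))
  expect_length(got, 5L)
  expect_identical(sort(got), oracle)
})

test_that("every enumerated parent has strictly fewer rings than its child", {
  chain <- parseSmiles("c1ccc(CC2CCC(Cc3ccncc3)CC2)cc1")
  nRings <- function(s) length(findRings(parseSmiles(s)))
  childRings <- length(findRings(chain))
  for (p in enumerateParents(chain)) {
    expect_lt(nRings(p), childRings)
  }
})
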