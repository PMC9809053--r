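# Functional-group identification: marking rules, group/remnant
# extraction, and the independent brute-force oracle.

test_that("atom marking follows the five rules on hand-derived cases", {
  # ethane: nothing to mark
  expect_length(markAtoms(parseSmiles("CC"))$marked, 0L)
  # phenol: only the hydroxyl oxygen (aromatic ring carbons unmarked)
  m <- parseSmiles("Oc1ccccc1")
  mk <- markAtoms(m)
  expect_identical(mk$marked, which(atomTable(m)$element == "O"))
  expect_identical(mk$reason[mk$marked], "HETEROATOM")
  # acetic acid: both oxygens and the carbonyl carbon; methyl unmarked
  m2 <- parseSmiles("CC(=O)O")
  mk2 <- markAtoms(m2)
  el <- atomTable(m2)$element
  expect_length(mk2$marked, 3L)                 # two O + carbonyl C
  expect_true(all(which(el == "O") %in% mk2$marked))
  expect_true("C_MULTIBOND_HETERO" %in% mk2$reason)
  methyl <- which(el == "C" & atomTable(m2)$nH == 3L)
  expect_false(methyl %in% mk2$marked)
  # non-aromatic C=C marks both carbons; aromatic bonds never do
  expect_length(markAtoms(parseSmiles("C=C"))$marked, 2L)
  expect_length(markAtoms(parseSmiles("c1ccccc1"))$marked, 0L)
  # acetal carbon (anomeric centre of glucopyranose)
  mk3 <- markAtoms(parseSmiles("OCC1OC(O)C(O)C(O)C1O"))
  expect_true("ACETAL_C" %in% mk3$reason)
  # heteroatom-containing three-ring marks all its atoms
  mk4 <- markAtoms(parseSmiles("C1CO1"))
  expect_length(mk4$marked, 3L)
  expect_true("THREE_RING_HETERO" %in% mk4$reason)
})

test_that("brute-force marking oracle agrees with markAtoms on the panel", {
  for (cs in toyPanel()) {
    mol <- parseSmiles(cs$smiles)
    expect_identical(markAtoms(mol)$marked, bruteForceMarking(mol),
                     info = cs$name)
  }
})

test_that("generalized functional groups match the printed exemplar convention", {
  # phenol: exactly one FG, canonical-equal to the "[H]Oc" depiction
  m <- parseSmiles("Oc1ccccc1")
  fg <- extractFunctionalGroups(m, markAtoms(m), "generalized")
  expect_length(fg, 1L)
  expect_identical(fg, canonicaliseSmiles("[H]Oc"))
  # the aromatic-environment hydroxy differs from the aliphatic one
  m2 <- parseSmiles("CCO")
  fg2 <- extractFunctionalGroups(m2, markAtoms(m2), "generalized")
  expect_identical(fg2, canonicaliseSmiles("[H]OC"))
  expect_false(fg == fg2)
  # ethene: the whole double bond, no environment
  m3 <- parseSmiles("C=C")
  expect_identical(extractFunctionalGroups(m3, markAtoms(m3), "generalized"),
                   cano("C=C"))
  # acetic acid: carboxyl with one aliphatic environment carbon and the
  # acidic hydrogen explicit
  m4 <- parseSmiles("CC(=O)O")
  expect_identical(extractFunctionalGroups(m4, markAtoms(m4), "generalized"),
                   cano("CC(=O)O[H]"))
})

test_that("full environment mode keeps real hydrogen counts", {
  m <- parseSmiles("CCO")  # environment carbon is a CH2
  full <- extractFunctionalGroups(m, markAtoms(m), "full")
  gen <- extractFunctionalGroups(m, markAtoms(m), "generalized")
  expect_false(identical(full, gen))
  expect_identical(full, cano("[H]O[CH2]"))
})

test_that("remnants are the hydrogen-saturated unmarked components", {
  m <- parseSmiles("CC(=O)O")
  expect_identical(extractRemnants(m, markAtoms(m)), cano("C"))
  m2 <- parseSmiles("Oc1ccccc1")
  expect_identical(extractRemnants(m2, markAtoms(m2)), cano("c1ccccc1"))
  m3 <- parseSmiles("CC")
  expect_identical(extractRemnants(m3, markAtoms(m3)), cano("CC"))
  # partially excised aromatic ring reverts to kekulised orders
  m4 <- parseSmiles("c1ccncc1")
  rem <- extractRemnants(m4, markAtoms(m4))
  expect_length(rem, 1L)
  expect_identical(rem, cano("C=CC=CC"))
})

test_that("panel expectations for the functional-group fragmenter hold", {
  f <- makeFragmenter("ertl-fg")
  for (cs in toyPanel()) {
    exp <- cs$expected[["ertl-fg"]]
    if (is.null(exp)) next
    got <- fragmentMolecule(f, parseSmiles(cs$smiles))
    expect_same_multiset(got, exp)
  }
})

test_that("marked and unmarked components partition the heavy atoms", {
  for (cs in toyPanel()) {
    mol <- parseSmiles(cs$smiles)
    mk <- markAtoms(mol)
    unmarked <- setdiff(seq_len(heavyAtomCount(mol)), mk$marked)
    expect_length(intersect(mk$marked, unmarked), 0L)
    expect_equal(length(mk$marked) + length(unmarked), heavyAtomCount(mol))
    # each marked atom has exactly one primary reason
    expect_true(all(!is.na(mk$reason[mk$marked])))
    expect_true(all(is.na(mk$reason[unmarked])))
  }
})
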