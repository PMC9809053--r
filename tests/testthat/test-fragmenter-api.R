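# Plugin contract: filtering, preprocessing, typed settings.

test_that("functional-group fragmenter filters metal-containing structures", {
  f <- makeFragmenter("ertl-fg")
  r <- shouldFilter(f, parseSmiles("CC(=O)O[Na]"))
  expect_true(r$filter)
  expect_match(r$reason, "metal")
  expect_false(shouldFilter(f, parseSmiles("CCO"))$filter)
  # sugar removal accepts any valid organic structure
  g <- makeFragmenter("sugar-removal")
  for (cs in toyPanel()) {
    expect_false(shouldFilter(g, parseSmiles(cs$smiles))$filter)
  }
})

test_that("charge neutralisation adds/removes hydrogens or demotes", {
  f <- makeFragmenter("ertl-fg")
  # ethanolate -> ethanol
  p <- preprocessMolecule(f, parseSmiles("CC[O-]"))
  expect_true(p$ok); expect_true(p$changed)
  expect_identical(canonicalSmiles(p$mol), canonicaliseSmiles("CCO"))
  expect_true(all(atomTable(p$mol)$charge == 0L))
  # neutral input unchanged
  m <- parseSmiles("CCO")
  p2 <- preprocessMolecule(f, m)
  expect_false(p2$changed)
  expect_identical(canonicalSmiles(p2$mol), canonicalSmiles(m))
  # quaternary ammonium: no hydrogen to remove -> demoted
  p3 <- preprocessMolecule(f, parseSmiles("C[N+](C)(C)C"))
  expect_false(p3$ok)
  expect_match(p3$reason, "charge")
  # protonated amine is neutralisable
  p4 <- preprocessMolecule(f, parseSmiles("CC[NH3+]"))
  expect_true(p4$ok)
  expect_identical(canonicalSmiles(p4$mol), canonicaliseSmiles("CCN"))
})

test_that("every structure yields exactly one of filtered / failed / fragments", {
  for (id in registeredFragmenters()) {
    f <- makeFragmenter(id)
    for (cs in toyPanel()) {
      r <- fragmentR:::.processOne(f, parseSmiles(cs$smiles))
      expect_true(r$status %in% c("OK", "PREPROCESSED", "FILTERED", "FAILED"))
      if (r$status %in% c("OK", "PREPROCESSED")) {
        expect_true(is.character(r$fragments))
        # every returned fragment re-parses after canonicalisation
        for (fr in r$fragments) {
          expect_identical(canonicaliseSmiles(fr), fr)
        }
      } else {
        expect_null(r$fragments)
      }
    }
  }
})

test_that("setting descriptors validate types, enums and unknown keys", {
  f <- makeFragmenter("ertl-fg")
  d <- settingDescriptors(f)
  expect_setequal(names(d), c("environment_mode", "return_remnants"))
  expect_identical(d$environment_mode@default, "generalized")
  expect_error(makeFragmenter("ertl-fg", list(environment_mode = "bogus")),
               "invalid value")
  expect_error(makeFragmenter("ertl-fg", list(no_such_key = TRUE)),
               "unknown setting")
  expect_error(makeFragmenter("nope"), "unknown fragmenter")
  # string forms coerce per declared type
  g <- makeFragmenter("sugar-removal",
                      list(detect_linear = "true",
                           min_aglycone_heavy_atoms = "7"))
  expect_identical(fragmenterSettings(g)$detect_linear, TRUE)
  expect_identical(fragmenterSettings(g)$min_aglycone_heavy_atoms, 7L)
  expect_error(makeFragmenter("sugar-removal",
                              list(min_aglycone_heavy_atoms = "x")),
               "invalid value")
})
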