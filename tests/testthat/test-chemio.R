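# Import/export: SMILES files, SDF/Molfile, CSV and SD writers.

test_that("SMILES file import parses lines in order with names and skips", {
  tmp <- withr::local_tempfile(fileext = ".smi")
  writeLines(c("CCO ethanol", "c1ccccc1 benzene"), tmp)
  s <- readSmilesFile(tmp)
  expect_equal(length(s), 2L)
  expect_equal(s@records$name, c("ethanol", "benzene"))
  expect_equal(s@records$record_id, c(0L, 1L))
  expect_equal(s@records$canonical_smiles, cano(c("CCO", "c1ccccc1")))

  # invalid line skipped and counted; auto-generated names
  tmp2 <- withr::local_tempfile(fileext = ".smi")
  writeLines(c("CCO", "not_a_smiles", "CC"), tmp2)
  s2 <- readSmilesFile(tmp2)
  expect_equal(length(s2), 2L)
  expect_equal(s2@nSkipped, 1L)
  expect_equal(s2@records$name, c("Molecule_0", "Molecule_1"))

  # header auto-detection: first token unparsable, rest imported
  tmp3 <- withr::local_tempfile(fileext = ".smi")
  writeLines(c("smiles name", "CCO ethanol", "CC ethane", "C methane"), tmp3)
  s3 <- readSmilesFile(tmp3)
  expect_equal(length(s3), 3L)
  expect_equal(s3@nSkipped, 0L)
  expect_equal(s3@records$name, c("ethanol", "ethane", "methane"))
})

test_that("SMILES import fails fatally on missing or fully unparsable files", {
  expect_error(readSmilesFile(file.path(tempdir(), "nope.smi")), "not found")
  tmp <- withr::local_tempfile(fileext = ".smi")
  writeLines("not_a_smiles", tmp)
  expect_error(readSmilesFile(tmp), "no parsable")
})

test_that("SDF import handles V2000, V3000 and corrupt blocks", {
  # single V2000 molfile written by the package
  tmp <- withr::local_tempfile(fileext = ".sdf")
  writeLines(c(fragmentR:::.stableMolblock("CCO", title = "ethanol"), "$$$$"), tmp)
  s <- readSdf(tmp)
  expect_equal(length(s), 1L)
  expect_equal(s@records$name, "ethanol")
  expect_equal(s@records$canonical_smiles, cano("CCO"))

  # V3000 fixture written by an independent structure writer
  v3 <- system.file("extdata", "benzene_v3000.mol", package = "fragmentR")
  s3 <- readSdf(v3)
  expect_equal(s3@records$canonical_smiles, cano("c1ccccc1"))

  # 3 blocks, one corrupt -> 2 records + 1 skip
  tmp2 <- withr::local_tempfile(fileext = ".sdf")
  writeLines(c(fragmentR:::.stableMolblock("CCO", "a"), "$$$$",
               "garbage", "not a molfile", "$$$$",
               fragmentR:::.stableMolblock("CC", "b"), "$$$$"), tmp2)
  s2 <- readSdf(tmp2)
  expect_equal(length(s2), 2L)
  expect_equal(s2@nSkipped, 1L)
})

test_that("canonicalisation is idempotent and merges equivalent notations", {
  expect_identical(canonicaliseSmiles("OCC"), canonicaliseSmiles("CCO"))
  expect_identical(canonicaliseSmiles("c1ccccc1"),
                   canonicaliseSmiles("C1=CC=CC=C1"))
  for (cs in toyPanel()) {
    can <- canonicaliseSmiles(cs$smiles)
    expect_identical(canonicaliseSmiles(can), can)
  }
  expect_error(canonicaliseSmiles("not_a_smiles"), "unparsable")
})

test_that("SMILES -> record -> SD -> record round trip preserves canonical form", {
  dir <- withr::local_tempdir()
  writePanelFiles(dir)
  a <- readSmilesFile(file.path(dir, "toy_panel.smi"))
  b <- readSdf(file.path(dir, "toy_panel.sdf"))
  expect_identical(canonicalSmiles(a), canonicalSmiles(b))
  expect_identical(a@records$name, b@records$name)
  # re-emission is byte-identical
  dir2 <- withr::local_tempdir()
  writePanelFiles(dir2)
  expect_identical(readLines(file.path(dir, "toy_panel.sdf")),
                   readLines(file.path(dir2, "toy_panel.sdf")))
})

test_that("fragment CSV, items CSV and SD export have the documented shape", {
  tmp <- withr::local_tempfile(fileext = ".smi")
  writeLines(c("CCO ethanol", "OCCO glycol"), tmp)
  run <- runSingle(readSmilesFile(tmp), "ertl-fg")

  fcsv <- withr::local_tempfile(fileext = ".csv")
  writeFragmentsCsv(run, fcsv)
  df <- read.csv(fcsv, stringsAsFactors = FALSE)
  expect_identical(names(df), c("rank", "fragment_smiles", "frequency",
                                "molecule_frequency", "sample_parent_name"))
  expect_true(all(diff(df$frequency) <= 0))  # sorted descending

  icsv <- withr::local_tempfile(fileext = ".csv")
  writeItemsCsv(run, icsv)
  di <- read.csv(icsv, stringsAsFactors = FALSE)
  expect_identical(names(di), c("molecule_name", "molecule_smiles",
                                "fragment_smiles", "count_in_molecule"))
  # ethanol has 2 distinct fragments -> 2 rows
  expect_equal(sum(di$molecule_name == "ethanol"), 2L)

  sdf <- withr::local_tempfile(fileext = ".sdf")
  writeFragmentsSdf(run, sdf)
  back <- readSdf(sdf)
  expect_identical(sort(canonicalSmiles(back)),
                   sort(fragmentRecords(run)$fragment_smiles))
  txt <- readLines(sdf)
  expect_true(any(grepl("^> <frequency>$", txt)))
  expect_true(any(grepl("^> <molecule_frequency>$", txt)))
})

test_that("molecular graph parsing captures charges, aromaticity and H counts", {
  m <- parseSmiles("CC[O-]")
  expect_equal(atomTable(m)$charge, c(0L, 0L, -1L))
  m2 <- parseSmiles("Oc1ccccc1")
  expect_equal(sum(atomTable(m2)$aromatic), 6L)
  expect_equal(atomTable(m2)$nH[1], 1L)  # hydroxyl H
  expect_equal(sum(bondTable(m2)$aromatic), 6L)
  # deterministic writer output re-canonicalises to the same structure
  expect_identical(canonicaliseSmiles(writeSmiles(m2)), canonicalSmiles(m2))
})
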