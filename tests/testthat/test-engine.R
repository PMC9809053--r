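# Orchestration: frequency semantics, conservation, determinism,
# pipelines, settings persistence, histogram data.

makeSet <- function(lines) {
  tmp <- tempfile(fileext = ".smi")
  writeLines(lines, tmp)
  on.exit(unlink(tmp))
  readSmilesFile(tmp)
}

test_that("frequency counts occurrences, molecule frequency counts molecules", {
  set <- makeSet(c("CCO ethanol", "OCCO glycol"))
  run <- runSingle(set, "ertl-fg")
  f <- fragmentRecords(run)
  oh <- f[f$fragment_smiles == canonicaliseSmiles("[H]OC"), ]
  expect_equal(oh$frequency, 3L)            # 1 in ethanol + 2 in the diol
  expect_equal(oh$molecule_frequency, 2L)
  # conservation over the whole run
  expect_equal(sum(f$frequency), sum(itemRecords(run)$count))
  # ranks sorted by frequency, ties by canonical key
  expect_true(all(diff(f$frequency) <= 0))
})

test_that("aggregation is deterministic and seeded parents are reproducible", {
  items <- data.frame(record_id = c(0L, 1L, 1L),
                      fragment_smiles = c("x", "x", "y"),
                      count = c(1L, 2L, 1L))
  status <- data.frame(record_id = 0:1, name = c("A", "B"),
                       canonical_smiles = c("C", "CC"),
                       status = "OK", reason = NA_character_)
  agg <- aggregateFragments(items, status, seed = 5L)
  expect_identical(agg$fragment_smiles, c("x", "y"))
  expect_equal(agg$frequency, c(3L, 1L))
  expect_equal(agg$molecule_frequency, c(2L, 1L))
  agg2 <- aggregateFragments(items, status, seed = 5L)
  expect_identical(agg, agg2)
  # equal frequencies tie-break by key
  items2 <- data.frame(record_id = c(0L, 0L), fragment_smiles = c("z", "a"),
                       count = c(1L, 1L))
  expect_identical(aggregateFragments(items2, status, 0L)$fragment_smiles,
                   c("a", "z"))
})

test_that("results are identical for any thread count", {
  panel <- toyPanel()
  lines <- vapply(panel, function(cs) paste(cs$smiles, cs$name), character(1))
  set <- makeSet(lines)
  r1 <- runSingle(set, "ertl-fg", nThreads = 1L, seed = 3L)
  r2 <- runSingle(set, "ertl-fg", nThreads = 3L, seed = 3L)
  expect_identical(fragmentRecords(r1), fragmentRecords(r2))
  expect_identical(itemRecords(r1), itemRecords(r2))
  expect_identical(moleculeStatus(r1), moleculeStatus(r2))
})

test_that("a one-stage pipeline equals the single run", {
  set <- makeSet(c("CCO ethanol", "Oc1ccccc1 phenol", "CC(=O)O acid"))
  single <- runSingle(set, "ertl-fg", seed = 2L, runName = "r")
  piped <- runPipeline(set, "ertl-fg", seed = 2L, runName = "r")
  expect_identical(fragmentRecords(single), fragmentRecords(piped))
  expect_identical(itemRecords(single), itemRecords(piped))
})

test_that("the three-stage pipeline reproduces the cleave-and-saturate story", {
  set <- makeSet("COc1ccccc1 anisole")
  pl <- list(list(id = "sugar-removal", settings = list()),
             list(id = "scaffold",
                  settings = list(fragmentation_type = "SIDE_CHAINS_ONLY")),
             list(id = "ertl-fg", settings = list()))
  run <- runPipeline(set, pl)
  f <- fragmentRecords(run)
  # the methoxy side chain becomes methanol, whose hydroxy FG is extracted
  expect_true(canonicaliseSmiles("[H]OC") %in% f$fragment_smiles)
  # frequencies trace back to the original molecule
  expect_true(all(f$molecule_frequency == 1L))
  expect_equal(sum(f$frequency), sum(itemRecords(run)$count))
})

test_that("pipeline frequencies aggregate against original molecules", {
  set <- makeSet(c("COc1ccccc1 anisole1", "COc1ccccc1 anisole2"))
  pl <- list(list(id = "scaffold",
                  settings = list(fragmentation_type = "SIDE_CHAINS_ONLY")),
             list(id = "ertl-fg", settings = list()))
  run <- runPipeline(set, pl)
  f <- fragmentRecords(run)
  oh <- f[f$fragment_smiles == canonicaliseSmiles("[H]OC"), ]
  expect_equal(oh$frequency, 2L)
  expect_equal(oh$molecule_frequency, 2L)  # two distinct original molecules
})

test_that("sugar-free molecules pass a sugar-removal stage unchanged", {
  caffeine <- "Cn1cnc2c1c(=O)n(C)c(=O)n2C"
  set <- makeSet(paste(caffeine, "caffeine"))
  run <- runSingle(set, "sugar-removal")
  f <- fragmentRecords(run)
  expect_equal(nrow(f), 1L)
  expect_identical(f$fragment_smiles, canonicaliseSmiles(caffeine))
  expect_equal(f$frequency, 1L)
})

test_that("empty input errors; all-filtered run warns with empty fragments", {
  empty <- new("MoleculeSet",
               records = fragmentR:::.makeRecords(character(0), character(0),
                                                  character(0)),
               molecules = list(), nSkipped = 0L)
  expect_error(runSingle(empty, "ertl-fg"), "no input")
  set <- makeSet("CC(=O)O[Na] metal")
  expect_warning(run <- runSingle(set, "ertl-fg"), "no fragments")
  expect_equal(nrow(fragmentRecords(run)), 0L)
  expect_identical(moleculeStatus(run)$status, "FILTERED")
})

test_that("settings persist and reload as identity; bad values degrade safely", {
  for (id in registeredFragmenters()) {
    f <- makeFragmenter(id)
    p <- tempfile(fileext = ".settings")
    persistSettings(f, p)
    g <- loadSettings(makeFragmenter(id), p)
    expect_identical(fragmenterSettings(f), fragmenterSettings(g))
    unlink(p)
  }
  # invalid value -> default retained with a warning
  p <- tempfile(fileext = ".settings")
  writeLines("environment_mode=bogus", p)
  expect_warning(g <- loadSettings(makeFragmenter("ertl-fg"), p), "invalid")
  expect_identical(fragmenterSettings(g)$environment_mode, "generalized")
  # unknown key -> ignored with a warning
  writeLines("foo=1", p)
  expect_warning(g2 <- loadSettings(makeFragmenter("ertl-fg"), p), "unknown")
  expect_identical(fragmenterSettings(g2),
                   fragmenterSettings(makeFragmenter("ertl-fg")))
  unlink(p)
})

test_that("histogram data ranks by the chosen measure and caps at the size", {
  set <- makeSet(c("CCO a", "OCCO b", "CC(=O)O c", "C=C d"))
  run <- runSingle(set, "ertl-fg")
  h <- histogramData(run, topN = 2L)
  expect_equal(nrow(h), 2L)
  expect_true(all(diff(h$count) <= 0))
  hAll <- histogramData(run, topN = 1000L)
  expect_equal(nrow(hAll), nrow(fragmentRecords(run)))
  hm <- histogramData(run, topN = 3L, by = "molecule_frequency")
  f <- fragmentRecords(run)
  expect_identical(hm$count,
                   sort(f$molecule_frequency, decreasing = TRUE)[1:3])
})
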