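# Shared fixtures and independent oracles for the test suite.

cano <- function(x) vapply(x, canonicaliseSmiles, character(1), USE.NAMES = FALSE)

# canonicalised multiset comparison
expect_same_multiset <- function(got, expected_raw) {
  expect_identical(sort(got), sort(cano(expected_raw)))
}

panelSet <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      dir <- file.path(tempdir(), "fragmentR-panel")
      writePanelFiles(dir)
      cache <<- readSmilesFile(file.path(dir, "toy_panel.smi"))
    }
    cache
  }
})

# ---- independent brute-force functional-group marking oracle ----
# Re-derives the marked atom set per atom by exhaustive neighbourhood
# inspection, sharing no code with markAtoms(): plain loops over the
# atom/bond tables, 3-rings by a triple loop.
bruteForceMarking <- function(mol) {
  a <- atomTable(mol)
  b <- bondTable(mol)
  n <- nrow(a)
  adj <- function(v) {
    rows <- which(b$a1 == v | b$a2 == v)
    data.frame(nb = ifelse(b$a1[rows] == v, b$a2[rows], b$a1[rows]),
               order = b$order[rows], aromatic = b$aromatic[rows])
  }
  singleOnly <- function(v) {
    e <- adj(v)
    nrow(e) == 0L || all(e$order == 1L & !e$aromatic)
  }
  marked <- logical(n)
  for (v in seq_len(n)) {
    e <- adj(v)
    if (a$element[v] != "C") { marked[v] <- TRUE; next }   # rule 1
    multi <- e[e$order >= 2L & !e$aromatic, , drop = FALSE]
    if (nrow(multi) > 0L) {
      if (any(a$element[multi$nb] != "C")) { marked[v] <- TRUE; next }  # rule 3
      if (any(a$element[multi$nb] == "C")) { marked[v] <- TRUE; next }  # rule 2
    }
    if (!a$aromatic[v] && singleOnly(v)) {                 # rule 4
      ons <- e$nb[e$order == 1L & !e$aromatic &
                    a$element[e$nb] %in% c("O", "N", "S")]
      if (sum(vapply(ons, singleOnly, logical(1))) >= 2L) {
        marked[v] <- TRUE; next
      }
    }
  }
  # rule 5: heteroatom-containing 3-rings by triple loop
  hasBond <- function(u, v) any((b$a1 == u & b$a2 == v) | (b$a1 == v & b$a2 == u))
  if (n >= 3L) {
    for (i in seq_len(n - 2L)) for (j in seq(i + 1L, n - 1L)) for (k in seq(j + 1L, n)) {
      if (hasBond(i, j) && hasBond(j, k) && hasBond(i, k) &&
          any(a$element[c(i, j, k)] != "C")) {
        marked[c(i, j, k)] <- TRUE
      }
    }
  }
  which(marked)
}

# ---- independent subchain enumerator for linear ring chains ----
# All contiguous proper subchains of a linear chain of rings joined by
# CH2 linkers, assembled textually from per-ring templates and
# deduplicated by canonical SMILES.
enumerateSubchainsOracle <- function(ringIds) {
  # each nesting level uses its own ring-closure digit
  bare <- function(id, d) switch(id,
    bz = sprintf("c%dccccc%d", d, d),
    ch = sprintf("C%dCCCCC%d", d, d),
    py = sprintf("c%dccncc%d", d, d))
  mono <- function(id, d, inner) switch(id,
    bz = sprintf("c%dccc(%s)cc%d", d, inner, d),
    ch = sprintf("C%dCCC(%s)CC%d", d, inner, d),
    py = sprintf("c%dcc(%s)ccn%d", d, inner, d))
  build <- function(ids, d) {
    if (length(ids) == 1L) return(bare(ids[1], d))
    mono(ids[1], d, paste0("C", build(ids[-1], d + 1L)))
  }
  k <- length(ringIds)
  out <- character(0)
  for (i in seq_len(k)) for (j in seq(i, k)) {
    if (i == 1L && j == k) next   # proper subchains only
    out <- c(out, build(ringIds[i:j], 1L))
  }
  sort(unique(cano(out)))
}
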