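# The deterministic toy-molecule panel: a hand-curated set of small
# structures spanning every algorithm's behaviour (no-FG alkanes,
# classic functional groups, aromatics, scaffolds, sugars, a charged and
# a metal-containing species), with hand-derived expected fragments for
# the key cases. Expected values come from manual application of each
# algorithm's stated rules, cross-checked with an independent
# brute-force marking oracle; they are never produced by running the
# implementation on itself.

#' The toy molecule panel
#'
#' Returns the built-in fixture panel: name, SMILES, and per-fragmenter
#' expected fragment multisets (raw SMILES; canonicalise before
#' comparing) under default settings where a hand-derived expectation
#' exists.
#'
#' @return A list of cases, each \code{list(name =, smiles =, expected =
#'   list(...))}. \code{expected[["ertl-fg"]]} is the full fragment
#'   multiset (generalized mode, remnants on); \code{"sugar-removal"}
#'   the aglycone set; \code{"scaffold"} the SCAFFOLD_ONLY output;
#'   \code{"scaffold-parents"} the enumerated parent set;
#'   \code{"filtered"} a character vector of fragmenter ids expected to
#'   filter the case.
#' @export
toyPanel <- function() {
  case <- function(name, smiles, expected = list()) {
    list(name = name, smiles = smiles, expected = expected)
  }
  list(
    case("methane", "C", list(`ertl-fg` = c("C"))),
    case("ethane", "CC", list(`ertl-fg` = c("CC"))),
    case("n-hexane", "CCCCCC", list(`ertl-fg` = c("CCCCCC"),
                                    scaffold = character(0))),
    case("cyclohexane", "C1CCCCC1",
         list(`ertl-fg` = c("C1CCCCC1"),
              `sugar-removal` = c("C1CCCCC1"),
              scaffold = c("C1CCCCC1"))),
    case("benzene", "c1ccccc1",
         list(`ertl-fg` = c("c1ccccc1"),
              scaffold = c("c1ccccc1"),
              `scaffold-parents` = character(0))),
    case("toluene", "Cc1ccccc1",
         list(`ertl-fg` = c("Cc1ccccc1"),
              scaffold = c("c1ccccc1"),
              `scaffold-side-chains` = c("C"))),
    case("phenol", "Oc1ccccc1",
         list(`ertl-fg` = c("[H]Oc", "c1ccccc1"))),
    case("ethanol", "CCO",
         list(`ertl-fg` = c("[H]OC", "CC"))),
    case("ethylene-glycol", "OCCO",
         list(`ertl-fg` = c("[H]OC", "[H]OC", "CC"))),
    case("ethene", "C=C", list(`ertl-fg` = c("C=C"))),
    case("acetic-acid", "CC(=O)O",
         list(`ertl-fg` = c("CC(=O)O[H]", "C"))),
    case("methyl-acetate", "COC(C)=O",
         list(`ertl-fg` = c("COC(C)=O", "C", "C"))),
    case("diethyl-ether", "CCOCC",
         list(`ertl-fg` = c("COC", "CC", "CC"))),
    case("acetamide", "CC(N)=O",
         list(`ertl-fg` = c("CC(=O)N([H])[H]", "C"))),
    case("anisole", "COc1ccccc1",
         list(`ertl-fg` = c("COc", "C", "c1ccccc1"),
              `scaffold-side-chains` = c("CO"))),
    case("diphenylmethane", "c1ccc(Cc2ccccc2)cc1",
         list(scaffold = c("c1ccc(Cc2ccccc2)cc1"),
              `scaffold-parents` = c("c1ccccc1"))),
    case("three-ring-chain", "c1ccc(CC2CCC(Cc3ccncc3)CC2)cc1",
         list(`scaffold-parents` = c(
           "c1ccc(CC2CCCCC2)cc1",          # benzene-CH2-cyclohexane
           "c1cc(CC2CCCCC2)ccn1",          # cyclohexane-CH2-pyridine
           "c1ccccc1", "C1CCCCC1", "c1ccncc1"))),
    case("glucopyranose", "OCC1OC(O)C(O)C(O)C1O",
         list(`sugar-removal` = character(0))),
    case("salicin", "OCc1ccccc1OC1OC(CO)C(O)C(O)C1O",
         list(`sugar-removal` = c("OCc1ccccc1O"))),
    case("glycerol", "OCC(O)CO",
         list(`sugar-removal` = c("OCC(O)CO"))),
    case("ribose-open", "OCC(O)C(O)C(O)C=O"),
    case("tetrahydropyran", "C1CCOCC1",
         list(`sugar-removal` = c("C1CCOCC1"))),
    case("oxirane", "C1CO1",
         list(`ertl-fg` = c("C1CO1"))),
    case("caffeine", "Cn1cnc2c1c(=O)n(C)c(=O)n2C",
         list(`sugar-removal` = c("Cn1cnc2c1c(=O)n(C)c(=O)n2C"))),
    case("tetramethylammonium", "C[N+](C)(C)C",
         list(filtered = c("ertl-fg"))),
    case("sodium-acetate", "CC(=O)O[Na]",
         list(filtered = c("ertl-fg")))
  )
}

#' Write the fixture panel to disk
#'
#' Emits the panel both as a SMILES file (structure + name columns) and
#' as an SD file so both import paths can be exercised. Output is
#' byte-stable across runs.
#'
#' @param dir output directory (created if missing).
#' @return named character vector with the two file paths, invisibly.
#' @export
writePanelFiles <- function(dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  panel <- toyPanel()
  smi <- file.path(dir, "toy_panel.smi")
  writeLines(vapply(panel, function(cs) paste(cs$smiles, cs$name),
                    character(1)), smi)
  sdf <- file.path(dir, "toy_panel.sdf")
  con <- file(sdf, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  for (cs in panel) {
    writeLines(.stableMolblock(cs$smiles, title = cs$name), con)
    writeLines("$$$$", con)
  }
  invisible(c(smiles = smi, sdf = sdf))
}
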