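#' Molecule: an immutable molecular graph
#'
#' Heavy-atom graph of one structure. Atoms carry element, formal charge,
#' a perceived aromaticity flag and the number of attached hydrogens;
#' bonds carry a kekulised order (1, 2, 3) plus an aromaticity flag.
#' Structure perception (kekulisation, aromaticity, hydrogen counts) is
#' done once, on construction, by OpenBabel; all algorithms in the package
#' operate on this fixed perception.
#'
#' @slot atoms data.frame: \code{element}, \code{charge}, \code{aromatic},
#'   \code{nH}, \code{hcount} (depiction-only explicit H count, \code{NA}
#'   unless set by a fragment builder).
#' @slot bonds data.frame: \code{a1}, \code{a2}, \code{order},
#'   \code{aromatic}.
#' @slot smiles character: canonical SMILES, or \code{NA} for derived
#'   fragments whose canonical form has not been computed yet.
#'
#' @export
setClass("Molecule", representation(
  atoms = "data.frame",
  bonds = "data.frame",
  smiles = "character"
))

setValidity("Molecule", function(object) {
  a <- object@atoms; b <- object@bonds
  need_a <- c("element", "charge", "aromatic", "nH", "hcount")
  need_b <- c("a1", "a2", "order", "aromatic")
  if (!all(need_a %in% names(a))) return("atoms table lacks required columns")
  if (!all(need_b %in% names(b))) return("bonds table lacks required columns")
  if (nrow(b) > 0L && (any(b$a1 < 1L) || any(b$a2 > nrow(a)) || any(b$a1 == b$a2)))
    return("bond endpoints out of range")
  TRUE
})

#' @describeIn Molecule number of heavy atoms and bonds
#' @param object a Molecule
#' @export
setMethod("show", "Molecule", function(object) {
  cat(sprintf("Molecule: %d heavy atoms, %d bonds\n",
              nrow(object@atoms), nrow(object@bonds)))
  if (!is.na(object@smiles)) cat("  SMILES:", object@smiles, "\n")
})

#' @rdname atomTable
#' @export
setMethod("atomTable", "Molecule", function(x) x@atoms)

#' @rdname bondTable
#' @export
setMethod("bondTable", "Molecule", function(x) x@bonds)

#' @rdname canonicalSmiles
#' @export
setMethod("canonicalSmiles", "Molecule", function(x) {
  if (!is.na(x@smiles)) return(x@smiles)
  canonicaliseSmiles(writeSmiles(x))
})

#' MoleculeSet: an imported, ordered set of structures
#'
#' One record per successfully parsed input entry, in import order
#' (\code{record_id} is the 0-based import position). The canonical SMILES
#' is the only retained long-term structure information; parsed
#' \linkS4class{Molecule} graphs are kept alongside for fragmentation.
#'
#' @slot records data.frame with columns \code{record_id}, \code{name},
#'   \code{input_smiles}, \code{canonical_smiles}, \code{status}.
#' @slot molecules list of \linkS4class{Molecule} objects parallel to
#'   \code{records}.
#' @slot nSkipped integer: number of unparsable input entries skipped
#'   (and logged) during import.
#'
#' @export
setClass("MoleculeSet", representation(
  records = "data.frame",
  molecules = "list",
  nSkipped = "integer"
))

setValidity("MoleculeSet", function(object) {
  r <- object@records
  need <- c("record_id", "name", "input_smiles", "canonical_smiles", "status")
  if (!all(need %in% names(r))) return("records table lacks required columns")
  if (anyDuplicated(r$record_id)) return("record_id must be unique")
  if (length(object@molecules) != nrow(r)) return("molecules list length mismatch")
  ok <- r$status %in% c("OK", "FILTERED", "PREPROCESSED", "FAILED")
  if (!all(ok)) return("invalid status value")
  TRUE
})

#' @describeIn MoleculeSet summary display
#' @param object a MoleculeSet
#' @export
setMethod("show", "MoleculeSet", function(object) {
  cat(sprintf("MoleculeSet: %d molecules (%d skipped on import)\n",
              nrow(object@records), object@nSkipped))
  if (nrow(object@records) > 0L) {
    n <- min(5L, nrow(object@records))
    print(utils::head(object@records[, c("record_id", "name", "canonical_smiles")], n))
    if (nrow(object@records) > n) cat("  ...\n")
  }
})

#' @rdname canonicalSmiles
#' @export
setMethod("canonicalSmiles", "MoleculeSet", function(x) x@records$canonical_smiles)

#' @describeIn MoleculeSet number of molecules
#' @param x a MoleculeSet
#' @export
setMethod("length", "MoleculeSet", function(x) nrow(x@records))

#' SettingDescriptor: one typed, documented algorithm setting
#'
#' Mirrors the per-algorithm settings a user can adjust: a key, a value
#' type, a default, an optional set of allowed values (required for ENUM)
#' and a description used as help text. Descriptors drive validation,
#' command-line \code{--set} parsing and settings-file persistence.
#'
#' @slot key character.
#' @slot valueType one of \code{"BOOLEAN"}, \code{"INTEGER"},
#'   \code{"FLOAT"}, \code{"STRING"}, \code{"ENUM"}.
#' @slot default default value, of the declared type.
#' @slot allowed list of allowed values (ENUM only).
#' @slot description character help text.
#'
#' @export
setClass("SettingDescriptor", representation(
  key = "character",
  valueType = "character",
  default = "ANY",
  allowed = "list",
  description = "character"
))

setValidity("SettingDescriptor", function(object) {
  types <- c("BOOLEAN", "INTEGER", "FLOAT", "STRING", "ENUM")
  if (!object@valueType %in% types) return("unknown valueType")
  if (object@valueType == "ENUM") {
    if (length(object@allowed) == 0L) return("ENUM requires allowed values")
    if (!object@default %in% unlist(object@allowed))
      return("ENUM default must be a member of allowed")
  }
  ok <- switch(object@valueType,
    BOOLEAN = is.logical(object@default),
    INTEGER = is.numeric(object@default) && object@default == round(object@default),
    FLOAT = is.numeric(object@default),
    STRING = is.character(object@default),
    ENUM = is.character(object@default))
  if (!ok) return("default is not of the declared valueType")
  TRUE
})

#' @describeIn SettingDescriptor display
#' @param object a SettingDescriptor
#' @export
setMethod("show", "SettingDescriptor", function(object) {
  cat(sprintf("%s <%s> default=%s  %s\n", object@key, object@valueType,
              formatSettingValue(object@default), object@description))
})

#' Fragmenter: the plugin contract for fragmentation algorithms
#'
#' Virtual base class. A concrete fragmenter supplies an identifier,
#' setting descriptors, an input filter (\code{\link{shouldFilter}}), a
#' preprocessing step (\code{\link{preprocessMolecule}}) and the central
#' \code{\link{fragmentMolecule}} operation. For every structure, exactly
#' one of: it is filtered, it fails with a logged cause, or it yields a
#' (possibly empty) fragment list.
#'
#' @slot settings named list of current setting values.
#'
#' @export
setClass("Fragmenter", representation(settings = "list", "VIRTUAL"))

#' @describeIn Fragmenter display with current settings
#' @param object a Fragmenter
#' @export
setMethod("show", "Fragmenter", function(object) {
  cat(sprintf("<%s> fragmenter\n", fragmenterId(object)))
  s <- object@settings
  for (k in names(s)) cat(sprintf("  %s = %s\n", k, formatSettingValue(s[[k]])))
})

#' @rdname fragmenterSettings
#' @export
setMethod("fragmenterSettings", "Fragmenter", function(x) x@settings)

#' @rdname fragmenterSettings
#' @export
setReplaceMethod("fragmenterSettings", "Fragmenter", function(x, value) {
  x@settings <- applySettings(settingDescriptors(x), x@settings, value,
                              strict = TRUE)
  x
})

#' ErtlFragmenter: functional groups by atom-marking rules
#'
#' Identifies functional groups with per-atom marking rules (heteroatoms;
#' carbons in non-aromatic multiple bonds; carbons multiply bonded to
#' heteroatoms; acetal-like carbons; heteroatom-containing three-membered
#' rings) and returns the marked components as functional-group fragments
#' plus, by default, the hydrogen-saturated unmarked remnants.
#'
#' @seealso \code{\link{markAtoms}}, \code{\link{makeFragmenter}}
#' @export
setClass("ErtlFragmenter", contains = "Fragmenter")

#' SugarRemovalFragmenter: glycosidic moiety detection and removal
#'
#' Detects circular (furanose/pyranose-like) and optionally linear sugar
#' moieties and returns the aglycone (and optionally the sugars), with a
#' terminal-only removal mode.
#'
#' @seealso \code{\link{removeSugars}}, \code{\link{makeFragmenter}}
#' @export
setClass("SugarRemovalFragmenter", contains = "Fragmenter")

#' ScaffoldFragmenter: Murcko scaffold dissection
#'
#' Extracts molecular scaffolds (ring systems plus connecting linkers),
#' dissects molecules into scaffold vs side chains or rings and linkers,
#' and enumerates parent scaffolds by terminal-ring removal.
#'
#' @seealso \code{\link{murckoScaffold}}, \code{\link{enumerateParents}},
#'   \code{\link{makeFragmenter}}
#' @export
setClass("ScaffoldFragmenter", contains = "Fragmenter")

#' FragmentationRun: one fragmentation execution and its results
#'
#' Captures a single-algorithm run or a pipeline run: the stage
#' specification, a snapshot of all stage settings, the per-molecule
#' statuses, the per-molecule fragment occurrence lists, and the
#' aggregated deduplicated fragment table sorted by descending frequency.
#'
#' @slot runName character, unique per session.
#' @slot stages list of \code{list(id =, settings =)} stage entries.
#' @slot settingsSnapshot named list of per-stage settings at run time.
#' @slot status data.frame: per-molecule \code{record_id}, \code{name},
#'   \code{canonical_smiles}, \code{status}, \code{reason}.
#' @slot items data.frame: \code{record_id}, \code{fragment_smiles},
#'   \code{count}.
#' @slot fragments data.frame: aggregated fragment records (see
#'   \code{\link{fragmentRecords}}).
#' @slot seed integer seed used for sample-parent selection.
#'
#' @export
setClass("FragmentationRun", representation(
  runName = "character",
  stages = "list",
  settingsSnapshot = "list",
  status = "data.frame",
  items = "data.frame",
  fragments = "data.frame",
  seed = "integer"
))

setValidity("FragmentationRun", function(object) {
  f <- object@fragments
  if (nrow(f) > 0L) {
    if (any(f$molecule_frequency > f$frequency))
      return("molecule_frequency must not exceed frequency")
    if (any(f$frequency < 1L)) return("frequency must be >= 1")
  }
  if (nrow(object@items) > 0L && any(object@items$count < 1L))
    return("per-molecule fragment counts must be >= 1")
  TRUE
})

#' @describeIn FragmentationRun summary display
#' @param object a FragmentationRun
#' @export
setMethod("show", "FragmentationRun", function(object) {
  cat(sprintf("FragmentationRun '%s' (%d stage%s)\n", object@runName,
              length(object@stages), if (length(object@stages) == 1L) "" else "s"))
  st <- table(factor(object@status$status,
                     levels = c("OK", "PREPROCESSED", "FILTERED", "FAILED")))
  cat(sprintf("  molecules: %d fragmented, %d preprocessed, %d filtered, %d failed\n",
              st[["OK"]], st[["PREPROCESSED"]], st[["FILTERED"]], st[["FAILED"]]))
  cat(sprintf("  distinct fragments: %d\n", nrow(object@fragments)))
  if (nrow(object@fragments) > 0L)
    print(utils::head(object@fragments, 5L))
})

#' @rdname fragmentRecords
#' @export
setMethod("fragmentRecords", "FragmentationRun", function(x) x@fragments)

#' @rdname itemRecords
#' @export
setMethod("itemRecords", "FragmentationRun", function(x) x@items)

#' @rdname moleculeStatus
#' @export
setMethod("moleculeStatus", "FragmentationRun", function(x) x@status)
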