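#' @import methods
NULL

#' Fragmenter identifier
#'
#' Returns the registry identifier of a fragmentation algorithm
#' (e.g. \code{"ertl-fg"}, \code{"sugar-removal"}, \code{"scaffold"}).
#'
#' @param x a \linkS4class{Fragmenter} object.
#' @return A length-one character vector.
#' @export
setGeneric("fragmenterId", function(x) standardGeneric("fragmenterId"))

#' Setting descriptors of a fragmenter
#'
#' Each fragmentation algorithm documents its tunable settings as a list of
#' \linkS4class{SettingDescriptor} objects; these drive validation,
#' command-line parsing and persistence to line-based settings files.
#'
#' @param x a \linkS4class{Fragmenter} object.
#' @return A named list of \linkS4class{SettingDescriptor} objects.
#' @export
setGeneric("settingDescriptors", function(x) standardGeneric("settingDescriptors"))

#' Current settings of a fragmenter
#'
#' @param x a \linkS4class{Fragmenter} object.
#' @return A named list of setting values.
#' @export
setGeneric("fragmenterSettings", function(x) standardGeneric("fragmenterSettings"))

#' @rdname fragmenterSettings
#' @param value named list of new setting values (validated against the
#'   descriptors; unknown keys or type-invalid values are an error).
#' @export
setGeneric("fragmenterSettings<-", function(x, value) standardGeneric("fragmenterSettings<-"))

#' Input filter of a fragmentation algorithm
#'
#' Decides whether a structure must be excluded from a run (for example,
#' the functional-group fragmenter rejects structures containing metal or
#' metalloid atoms). Total: never throws on a valid structure.
#'
#' @param x a \linkS4class{Fragmenter} object.
#' @param mol a \linkS4class{Molecule}.
#' @return A list with elements \code{filter} (logical) and \code{reason}
#'   (character, \code{NA} when \code{filter} is \code{FALSE}).
#' @export
setGeneric("shouldFilter", function(x, mol) standardGeneric("shouldFilter"))

#' Preprocess a structure for a fragmentation algorithm
#'
#' Establishes the algorithm's preconditions where possible (for the
#' functional-group fragmenter, neutralises formal charges by adding a
#' hydrogen to negatively charged atoms or removing one from positively
#' charged atoms that bear one). Structures that cannot be made to satisfy
#' the preconditions are demoted to filtered rather than erroring.
#'
#' @param x a \linkS4class{Fragmenter} object.
#' @param mol a \linkS4class{Molecule}.
#' @return A list with elements \code{mol} (the possibly modified
#'   \linkS4class{Molecule}), \code{ok} (logical; \code{FALSE} means demotion
#'   to filtered), \code{changed} (logical) and \code{reason} (character).
#' @export
setGeneric("preprocessMolecule", function(x, mol) standardGeneric("preprocessMolecule"))

#' Fragment one molecule
#'
#' The central plugin operation: applies the algorithm to a single
#' preprocessed structure and returns its fragments as canonical SMILES.
#' Duplicates in the returned vector encode per-molecule multiplicity; an
#' empty vector is legal (e.g. a pure sugar under aglycone-only removal).
#'
#' @param x a \linkS4class{Fragmenter} object.
#' @param mol a \linkS4class{Molecule} for which \code{shouldFilter} is
#'   \code{FALSE}, after \code{preprocessMolecule}.
#' @return A character vector of canonical SMILES (possibly empty).
#' @export
setGeneric("fragmentMolecule", function(x, mol) standardGeneric("fragmentMolecule"))

#' Atom table of a molecule
#'
#' @param x a \linkS4class{Molecule}.
#' @return A data.frame with one row per heavy atom: \code{element},
#'   \code{charge}, \code{aromatic}, \code{nH} (attached hydrogens),
#'   \code{hcount} (explicit bracket H count for depiction, usually
#'   \code{NA}).
#' @export
setGeneric("atomTable", function(x) standardGeneric("atomTable"))

#' Bond table of a molecule
#'
#' @param x a \linkS4class{Molecule}.
#' @return A data.frame with one row per bond: \code{a1}, \code{a2}
#'   (1-based atom indices), \code{order} (1, 2 or 3; kekulised), and
#'   \code{aromatic} (perceived aromatic flag).
#' @export
setGeneric("bondTable", function(x) standardGeneric("bondTable"))

#' Canonical SMILES of an object
#'
#' @param x a \linkS4class{Molecule} or \linkS4class{MoleculeSet}.
#' @return Character vector of framework-canonical SMILES.
#' @export
setGeneric("canonicalSmiles", function(x) standardGeneric("canonicalSmiles"))

#' Aggregated fragment table of a fragmentation run
#'
#' @param x a \linkS4class{FragmentationRun}.
#' @return A data.frame sorted by descending frequency (ties by canonical
#'   SMILES) with columns \code{fragment_smiles}, \code{frequency},
#'   \code{molecule_frequency}, \code{sample_parent_id},
#'   \code{sample_parent_name}.
#' @export
setGeneric("fragmentRecords", function(x) standardGeneric("fragmentRecords"))

#' Per-molecule fragment occurrences of a run
#'
#' @param x a \linkS4class{FragmentationRun}.
#' @return A data.frame with columns \code{record_id},
#'   \code{fragment_smiles}, \code{count}.
#' @export
setGeneric("itemRecords", function(x) standardGeneric("itemRecords"))

#' Per-molecule status table of a run
#'
#' @param x a \linkS4class{FragmentationRun}.
#' @return A data.frame with columns \code{record_id}, \code{name},
#'   \code{canonical_smiles}, \code{status} (\code{OK}, \code{PREPROCESSED},
#'   \code{FILTERED} or \code{FAILED}) and \code{reason}.
#' @export
setGeneric("moleculeStatus", function(x) standardGeneric("moleculeStatus"))
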