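# Molecule set import (SMILES text files, SDF/Molfile V2000+V3000) and
# result export (CSV tables, SD files). File parsing and writing of the
# chemical formats themselves is handled by OpenBabel; this module owns
# the record bookkeeping: stable 0-based record ids in import order,
# skip-and-log of unparsable entries, and name derivation.

.makeRecords <- function(names, input, canonical) {
  data.frame(
    record_id = seq_along(names) - 1L,
    name = names,
    input_smiles = input,
    canonical_smiles = canonical,
    status = rep("OK", length(names)),
    stringsAsFactors = FALSE)
}

#' Read a molecule set from a SMILES text file
#'
#' Dialect: one structure per line; the first whitespace- or tab-separated
#' token is the SMILES, an optional second token is the name. A single
#' leading header line is auto-detected (its first token does not parse
#' as SMILES) and skipped. Unparsable lines are skipped, counted and
#' logged. Molecules without a name column are named
#' \code{Molecule_<record_id>}.
#'
#' @param path path to a UTF-8 text file.
#' @param separator \code{"auto"} (any whitespace), \code{"tab"} or
#'   \code{"space"}.
#' @return A \linkS4class{MoleculeSet}.
#' @export
readSmilesFile <- function(path, separator = c("auto", "tab", "space")) {
  separator <- match.arg(separator)
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("no input lines in ", path, call. = FALSE)
  sep <- switch(separator, auto = "[ \t]+", tab = "\t", space = " +")
  toks <- strsplit(trimws(lines), sep)

  parseOne <- function(tk) {
    smi <- tk[[1]]
    can <- tryCatch(canonicaliseSmiles(smi), error = function(e) NA_character_)
    if (is.na(can)) return(NULL)
    mol <- tryCatch(parseSmiles(smi), error = function(e) NULL)
    if (is.null(mol)) return(NULL)
    list(smiles = smi, canonical = can, mol = mol,
         name = if (length(tk) >= 2L) tk[[2]] else NA_character_)
  }

  first <- parseOne(toks[[1]])
  startAt <- 1L
  headerSkipped <- FALSE
  if (is.null(first) && length(toks) > 1L) {
    logInfo("readSmilesFile: header line detected and skipped: '", lines[1], "'")
    startAt <- 2L
    headerSkipped <- TRUE
  }
  out <- list(); input <- character(0); nms <- character(0); nskip <- 0L
  for (i in seq(startAt, length(toks))) {
    p <- if (i == 1L) first else parseOne(toks[[i]])
    if (is.null(p)) {
      nskip <- nskip + 1L
      logWarn("readSmilesFile: skipped unparsable line ", i, ": '", lines[i], "'")
      next
    }
    out[[length(out) + 1L]] <- p
    input <- c(input, p$smiles)
    nms <- c(nms, p$name)
  }
  if (length(out) == 0L)
    stop("no parsable SMILES in ", path, " (", nskip, " line(s) failed)",
         call. = FALSE)
  auto <- is.na(nms)
  nms[auto] <- paste0("Molecule_", seq_along(nms)[auto] - 1L)
  new("MoleculeSet",
      records = .makeRecords(nms, input, vapply(out, `[[`, "", "canonical")),
      molecules = lapply(out, `[[`, "mol"),
      nSkipped = nskip)
}

#' Read a molecule set from an SD file or single Molfile
#'
#' V2000 and V3000 connection tables are supported. The record name is
#' taken from the Molfile title line, else from the SD property named by
#' \code{nameProperty}, else auto-generated. Invalid blocks are skipped
#' and logged.
#'
#' @param path path to the SD file / Molfile.
#' @param nameProperty SD property tag to fall back on for names.
#' @return A \linkS4class{MoleculeSet}.
#' @export
readSdf <- function(path, nameProperty = "name") {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L || !any(nzchar(trimws(lines))))
    stop("empty SD file: ", path, call. = FALSE)
  seps <- which(trimws(lines) == "$$$$")
  starts <- c(1L, seps + 1L)
  ends <- c(seps, length(lines))
  blocks <- character(0)
  for (k in seq_along(starts)) {
    if (starts[k] > ends[k]) next
    blk <- lines[starts[k]:ends[k]]
    blk <- blk[!(trimws(blk) == "$$$$")]
    if (!any(nzchar(trimws(blk)))) next
    blocks <- c(blocks, paste(blk, collapse = "\n"))
  }
  out <- list(); nms <- character(0); input <- character(0)
  canonical <- character(0); nskip <- 0L
  for (k in seq_along(blocks)) {
    blk <- blocks[k]
    mol <- tryCatch(parseMolblock(blk), error = function(e) NULL)
    if (is.null(mol)) {
      nskip <- nskip + 1L
      logWarn("readSdf: skipped invalid block ", k, " in ", path)
      next
    }
    blines <- strsplit(blk, "\n")[[1]]
    nm <- trimws(blines[1])
    if (!nzchar(nm)) {
      tag <- paste0("> *<", nameProperty, ">")
      hit <- grep(tag, blines)
      if (length(hit) > 0L && hit[1] < length(blines))
        nm <- trimws(blines[hit[1] + 1L])
    }
    if (!nzchar(nm)) nm <- NA_character_
    out[[length(out) + 1L]] <- mol
    nms <- c(nms, nm)
    input <- c(input, mol@smiles)
    canonical <- c(canonical, mol@smiles)
  }
  if (length(out) == 0L)
    stop("no valid structure blocks in ", path, call. = FALSE)
  auto <- is.na(nms)
  nms[auto] <- paste0("Molecule_", seq_along(nms)[auto] - 1L)
  new("MoleculeSet",
      records = .makeRecords(nms, input, canonical),
      molecules = out, nSkipped = nskip)
}

#' Export the aggregated fragment table as CSV
#'
#' Columns: \code{rank}, \code{fragment_smiles}, \code{frequency},
#' \code{molecule_frequency}, \code{sample_parent_name}; rows sorted by
#' descending frequency. RFC-4180 quoting, UTF-8.
#'
#' @param run a \linkS4class{FragmentationRun}.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeFragmentsCsv <- function(run, path) {
  f <- fragmentRecords(run)
  if (nrow(f) == 0L) stop("run has no fragments to export", call. = FALSE)
  df <- data.frame(
    rank = seq_len(nrow(f)),
    fragment_smiles = f$fragment_smiles,
    frequency = f$frequency,
    molecule_frequency = f$molecule_frequency,
    sample_parent_name = f$sample_parent_name,
    stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Export per-molecule fragment occurrences as CSV
#'
#' Columns: \code{molecule_name}, \code{molecule_smiles},
#' \code{fragment_smiles}, \code{count_in_molecule}; one row per distinct
#' fragment of each molecule.
#'
#' @param run a \linkS4class{FragmentationRun}.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeItemsCsv <- function(run, path) {
  it <- itemRecords(run)
  if (nrow(it) == 0L) stop("run has no per-molecule items to export", call. = FALSE)
  st <- moleculeStatus(run)
  m <- match(it$record_id, st$record_id)
  df <- data.frame(
    molecule_name = st$name[m],
    molecule_smiles = st$canonical_smiles[m],
    fragment_smiles = it$fragment_smiles,
    count_in_molecule = it$count,
    stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

# OpenBabel stamps molblock line 2 with a timestamp; overwrite it so
# emitted files are byte-stable across runs.
.stableMolblock <- function(smiles, title = "") {
  sdf <- .obConvert("SMI", "SDF", smiles)
  if (!nzchar(sdf)) stop("cannot build molblock for '", smiles, "'", call. = FALSE)
  lines <- strsplit(sdf, "\n")[[1]]
  lines[1] <- title
  lines[2] <- "  fragmentR          2D"
  stop <- which(trimws(lines) == "M  END")[1]
  paste(lines[1:stop], collapse = "\n")
}

#' Export fragments as an SD file
#'
#' One V2000 block per fragment with \code{frequency},
#' \code{molecule_frequency} and \code{sample_parent_name} as SD
#' properties. Output is byte-stable across runs.
#'
#' @param run a \linkS4class{FragmentationRun}.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeFragmentsSdf <- function(run, path) {
  f <- fragmentRecords(run)
  if (nrow(f) == 0L) stop("run has no fragments to export", call. = FALSE)
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_len(nrow(f))) {
    mb <- .stableMolblock(f$fragment_smiles[i], title = f$fragment_smiles[i])
    writeLines(mb, con)
    writeLines(c(
      "> <frequency>", as.character(f$frequency[i]), "",
      "> <molecule_frequency>", as.character(f$molecule_frequency[i]), "",
      "> <sample_parent_name>", as.character(f$sample_parent_name[i]), "",
      "$$$$"), con)
  }
  invisible(path)
}
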