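# Structure parsing and canonicalisation, delegated to OpenBabel via
# ChemmineOB. A molecule is parsed once into a heavy-atom graph with a
# fixed perception: kekulised bond orders and explicit hydrogen counts
# come from an SDF conversion with added hydrogens, aromatic atom/bond
# flags from a MOL2 conversion of the same source (OpenBabel preserves
# input atom order and appends added hydrogens last, so the two tables
# align).

.obConvert <- function(from, to, source, addH = FALSE) {
  opts <- if (addH) data.frame(names = "h", args = "", stringsAsFactors = FALSE)
          else NULL
  out <- tryCatch({
    if (is.null(opts)) ChemmineOB::convertFormat(from, to, source)
    else ChemmineOB::convertFormat(from, to, source, options = opts)
  }, error = function(e) "")
  out
}

#' Canonicalise SMILES strings
#'
#' Maps any SMILES denoting a structure to the framework-wide canonical
#' form (OpenBabel canonical SMILES). Deterministic and idempotent; two
#' inputs denoting the same structure after aromaticity perception map to
#' the same output. All fragment deduplication in the package is string
#' equality on this form.
#'
#' @param smiles character vector of SMILES strings.
#' @return character vector of canonical SMILES.
#' @examples
#' \dontrun{
#' canonicaliseSmiles(c("OCC", "CCO"))  # identical outputs
#' }
#' @export
canonicaliseSmiles <- function(smiles) {
  vapply(smiles, function(s) {
    out <- .obConvert("SMI", "CAN", s)
    out <- strsplit(out, "[ \t\r\n]", fixed = FALSE)[[1]][1]
    if (is.na(out) || !nzchar(out))
      stop("unparsable SMILES: '", s, "'", call. = FALSE)
    out
  }, character(1), USE.NAMES = FALSE)
}

.emptyAtoms <- function() data.frame(
  element = character(0), charge = integer(0), aromatic = logical(0),
  nH = integer(0), hcount = integer(0), stringsAsFactors = FALSE)

.emptyBonds <- function() data.frame(
  a1 = integer(0), a2 = integer(0), order = integer(0),
  aromatic = logical(0), stringsAsFactors = FALSE)

newMolecule <- function(atoms, bonds, smiles = NA_character_) {
  rownames(atoms) <- NULL
  rownames(bonds) <- NULL
  new("Molecule", atoms = atoms, bonds = bonds, smiles = smiles)
}

# Parse a V2000 molblock (as emitted by OpenBabel) into atom/bond tables.
.parseMolblock <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  counts <- lines[4]
  natoms <- as.integer(substr(counts, 1, 3))
  nbonds <- as.integer(substr(counts, 4, 6))
  if (is.na(natoms)) stop("bad molblock counts line")
  atom_lines <- lines[5:(4 + natoms)]
  element <- trimws(substr(atom_lines, 32, 34))
  charge <- integer(natoms)
  if (nbonds > 0L) {
    bond_lines <- lines[(5 + natoms):(4 + natoms + nbonds)]
    a1 <- as.integer(substr(bond_lines, 1, 3))
    a2 <- as.integer(substr(bond_lines, 4, 6))
    ord <- as.integer(substr(bond_lines, 7, 9))
  } else {
    a1 <- a2 <- ord <- integer(0)
  }
  for (ln in grep("^M  CHG", lines, value = TRUE)) {
    toks <- as.integer(strsplit(trimws(sub("^M  CHG", "", ln)), "[ ]+")[[1]])
    n <- toks[1]
    for (k in seq_len(n)) charge[toks[2 * k]] <- toks[2 * k + 1]
  }
  list(element = element, charge = charge,
       bonds = data.frame(a1 = a1, a2 = a2, order = ord,
                          stringsAsFactors = FALSE))
}

# Aromatic atom and bond flags from a MOL2 conversion.
.parseMol2Aromatic <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  ai <- which(lines == "@<TRIPOS>ATOM")
  bi <- which(lines == "@<TRIPOS>BOND")
  if (length(ai) == 0L) stop("bad MOL2 output")
  sec_end <- function(start) {
    nxt <- which(startsWith(lines, "@<TRIPOS>") & seq_along(lines) > start)
    if (length(nxt) == 0L) length(lines) else min(nxt) - 1L
  }
  atom_lines <- lines[(ai + 1L):sec_end(ai)]
  atom_lines <- atom_lines[nzchar(trimws(atom_lines))]
  types <- vapply(strsplit(trimws(atom_lines), "[ \t]+"),
                  function(f) f[6], character(1))
  arom_atom <- grepl("\\.ar$", types)
  arom_pairs <- character(0)
  if (length(bi) == 1L && bi < length(lines)) {
    bond_lines <- lines[(bi + 1L):sec_end(bi)]
    bond_lines <- bond_lines[nzchar(trimws(bond_lines))]
    if (length(bond_lines) > 0L) {
      f <- strsplit(trimws(bond_lines), "[ \t]+")
      ba1 <- vapply(f, function(x) as.integer(x[2]), integer(1))
      ba2 <- vapply(f, function(x) as.integer(x[3]), integer(1))
      bt <- vapply(f, function(x) x[4], character(1))
      keep <- bt == "ar" & arom_atom[ba1] & arom_atom[ba2]
      arom_pairs <- paste(pmin(ba1, ba2), pmax(ba1, ba2))[keep]
    }
  }
  list(atom = arom_atom, bondKeys = arom_pairs)
}

.parseStructure <- function(src, from) {
  can <- .obConvert(from, "CAN", src)
  can <- strsplit(can, "[ \t\r\n]")[[1]][1]
  if (is.na(can) || !nzchar(can))
    stop("unparsable structure input", call. = FALSE)
  sdf <- .obConvert(from, "SDF", src, addH = TRUE)
  mol2 <- .obConvert(from, "MOL2", src)
  if (!nzchar(sdf) || !nzchar(mol2))
    stop("structure conversion failed", call. = FALSE)
  mb <- .parseMolblock(sdf)
  ar <- .parseMol2Aromatic(mol2)
  norig <- length(ar$atom)

  heavy <- mb$element != "H"
  n <- length(mb$element)
  nH <- integer(n)
  if (nrow(mb$bonds) > 0L) {
    isH1 <- !heavy[mb$bonds$a1]
    isH2 <- !heavy[mb$bonds$a2]
    for (i in seq_len(nrow(mb$bonds))) {
      if (isH2[i] && heavy[mb$bonds$a1[i]]) nH[mb$bonds$a1[i]] <- nH[mb$bonds$a1[i]] + 1L
      if (isH1[i] && heavy[mb$bonds$a2[i]]) nH[mb$bonds$a2[i]] <- nH[mb$bonds$a2[i]] + 1L
    }
  }
  if (!any(heavy)) stop("structure has no heavy atoms", call. = FALSE)
  idx <- cumsum(heavy)  # old -> new for heavy atoms
  aromAtom <- logical(n)
  aromAtom[seq_len(min(norig, n))] <- ar$atom[seq_len(min(norig, n))]
  atoms <- data.frame(
    element = mb$element[heavy],
    charge = as.integer(mb$charge[heavy]),
    aromatic = aromAtom[heavy],
    nH = nH[heavy],
    hcount = NA_integer_,
    stringsAsFactors = FALSE)
  b <- mb$bonds
  keep <- heavy[b$a1] & heavy[b$a2]
  b <- b[keep, , drop = FALSE]
  key <- paste(pmin(b$a1, b$a2), pmax(b$a1, b$a2))
  bonds <- data.frame(
    a1 = idx[b$a1], a2 = idx[b$a2],
    order = as.integer(b$order),
    aromatic = key %in% ar$bondKeys,
    stringsAsFactors = FALSE)
  newMolecule(atoms, bonds, smiles = can)
}

#' Parse a SMILES string into a Molecule
#'
#' @param smiles a single SMILES string.
#' @return A \linkS4class{Molecule}. Errors on unparsable input.
#' @export
parseSmiles <- function(smiles) .parseStructure(smiles, "SMI")

#' Parse an SDF/Molfile block into a Molecule
#'
#' Accepts one V2000 or V3000 connection-table block (with or without a
#' trailing record separator).
#'
#' @param text the Molfile/SDF block as a single string.
#' @return A \linkS4class{Molecule}. Errors on unreadable input.
#' @export
parseMolblock <- function(text) {
  if (!grepl("\\$\\$\\$\\$", text)) text <- paste0(text, "\n$$$$\n")
  .parseStructure(text, "SDF")
}

#' Heavy atom count
#'
#' @param mol a \linkS4class{Molecule}.
#' @return integer number of non-hydrogen atoms.
#' @export
heavyAtomCount <- function(mol) nrow(mol@atoms)

# Induced submolecule on a set of atom indices. Aromaticity is demoted
# for atoms that are no longer part of a fully-contained aromatic ring:
# such atoms fall back to their kekulised bond orders. This implements
# the framework-wide cut-bond convention (cleave, saturate with hydrogen
# on re-parse, preserve nothing).
subMolecule <- function(mol, atomIdx, demoteAromatic = TRUE) {
  atomIdx <- sort(unique(as.integer(atomIdx)))
  map <- integer(nrow(mol@atoms))
  map[atomIdx] <- seq_along(atomIdx)
  atoms <- mol@atoms[atomIdx, , drop = FALSE]
  b <- mol@bonds
  keep <- b$a1 %in% atomIdx & b$a2 %in% atomIdx
  bonds <- b[keep, , drop = FALSE]
  bonds$a1 <- map[bonds$a1]
  bonds$a2 <- map[bonds$a2]
  sub <- newMolecule(atoms, bonds)
  if (demoteAromatic && any(atoms$aromatic)) sub <- .demoteBrokenAromatics(sub)
  sub
}

# Keep an atom aromatic only if it lies on a ring whose bonds are all
# still aromatic within this (sub)structure; everything else reverts to
# kekulised orders.
.demoteBrokenAromatics <- function(mol) {
  if (!any(mol@atoms$aromatic)) return(mol)
  rings <- findRings(mol)
  keepArom <- logical(nrow(mol@atoms))
  if (length(rings) > 0L) {
    bk <- paste(pmin(mol@bonds$a1, mol@bonds$a2),
                pmax(mol@bonds$a1, mol@bonds$a2))
    aromKey <- bk[mol@bonds$aromatic]
    for (r in rings) {
      m <- length(r)
      nxt <- c(r[-1], r[1])
      rk <- paste(pmin(r, nxt), pmax(r, nxt))
      if (all(rk %in% aromKey)) keepArom[r] <- TRUE
    }
  }
  mol@atoms$aromatic <- mol@atoms$aromatic & keepArom
  dem <- !keepArom
  drop <- mol@bonds$aromatic &
    (dem[mol@bonds$a1] | dem[mol@bonds$a2])
  mol@bonds$aromatic[drop] <- FALSE
  mol
}

# Connected components of the heavy-atom graph (list of atom index sets).
molComponents <- function(mol, atomIdx = seq_len(nrow(mol@atoms))) {
  if (length(atomIdx) == 0L) return(list())
  g <- molGraph(mol)
  sg <- igraph::induced_subgraph(g, atomIdx)
  comp <- igraph::components(sg)
  vids <- as.integer(igraph::V(sg)$name)
  split(vids, comp$membership)
}
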