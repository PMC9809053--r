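# Murcko scaffold extraction, dissection into scaffold / side chains /
# rings and linkers, and enumerative parent-scaffold generation by
# terminal-ring removal.

#' Decompose a molecule into scaffold parts
#'
#' Partitions the heavy atoms into ring systems, linkers, exocyclic
#' multiply-bonded scaffold appendages (e.g. a carbonyl oxygen on a
#' ring, which belongs to the scaffold by convention) and side chains.
#'
#' @param mol a \linkS4class{Molecule}.
#' @return A list with \code{scaffold_atoms} (integer), \code{ring_systems}
#'   (list of integer vectors), \code{linker_atoms} (integer),
#'   \code{exo_atoms} (integer; scaffold atoms kept via exocyclic multiple
#'   bonds) and \code{side_chains} (list of integer vectors). For acyclic
#'   input all scaffold sets are empty and every atom is side chain.
#' @export
scaffoldParts <- function(mol) {
  n <- nrow(mol@atoms)
  b <- mol@bonds
  inRing <- ringAtomFlags(mol)
  empty <- list(scaffold_atoms = integer(0), ring_systems = list(),
                linker_atoms = integer(0), exo_atoms = integer(0),
                side_chains = if (n > 0L) list(seq_len(n)) else list())
  if (!any(inRing)) return(empty)

  # iteratively prune terminal non-ring atoms; what survives is rings
  # plus linkers
  alive <- rep(TRUE, n)
  repeat {
    deg <- integer(n)
    for (i in seq_len(nrow(b))) {
      if (alive[b$a1[i]] && alive[b$a2[i]]) {
        deg[b$a1[i]] <- deg[b$a1[i]] + 1L
        deg[b$a2[i]] <- deg[b$a2[i]] + 1L
      }
    }
    drop <- which(alive & !inRing & deg <= 1L)
    if (length(drop) == 0L) break
    alive[drop] <- FALSE
  }
  core <- which(alive)

  # exocyclic multiply-bonded atoms directly attached to the core stay
  # with the scaffold
  exo <- integer(0)
  for (i in which(b$order >= 2L & !b$aromatic)) {
    u <- b$a1[i]; v <- b$a2[i]
    if (alive[u] && !alive[v]) exo <- c(exo, v)
    if (alive[v] && !alive[u]) exo <- c(exo, u)
  }
  exo <- sort(unique(exo))
  scaffold <- sort(c(core, exo))
  side <- setdiff(seq_len(n), scaffold)
  sideComps <- if (length(side) > 0L) molComponents(mol, side) else list()
  list(scaffold_atoms = scaffold,
       ring_systems = ringSystems(mol),
       linker_atoms = setdiff(core, which(inRing)),
       exo_atoms = exo,
       side_chains = sideComps)
}

#' Murcko scaffold of a molecule
#'
#' Iteratively prunes terminal atoms that are neither in rings nor on
#' ring--ring paths; exocyclic multiply-bonded atoms attached to retained
#' atoms are kept. Idempotent.
#'
#' @param mol a \linkS4class{Molecule}.
#' @return A \linkS4class{Molecule}, or \code{NULL} for acyclic input.
#' @export
murckoScaffold <- function(mol) {
  p <- scaffoldParts(mol)
  if (length(p$scaffold_atoms) == 0L) return(NULL)
  subMolecule(mol, p$scaffold_atoms, demoteAromatic = TRUE)
}

#' Enumerate parent scaffolds
#'
#' Breadth-first removal of one terminal ring at a time: a terminal ring
#' is one whose exclusive atoms (atoms in no other ring) can be deleted
#' --- followed by Murcko re-pruning of exposed linkers --- leaving a
#' connected scaffold. Every distinct canonical parent down to single
#' rings is collected; the input itself is excluded.
#'
#' @param mol a scaffold \linkS4class{Molecule} (a fixed point of
#'   \code{\link{murckoScaffold}}); non-scaffold input is reduced first.
#' @return character vector of canonical parent-scaffold SMILES.
#' @export
enumerateParents <- function(mol) {
  start <- murckoScaffold(mol)
  if (is.null(start)) return(character(0))
  startKey <- canonicalSmiles(start)
  seen <- character(0)
  queue <- list(start)
  parents <- character(0)
  while (length(queue) > 0L) {
    cur <- queue[[1]]
    queue <- queue[-1]
    for (child in .removeOneTerminalRing(cur)) {
      key <- canonicalSmiles(child)
      if (key == startKey || key %in% seen) next
      seen <- c(seen, key)
      parents <- c(parents, key)
      queue[[length(queue) + 1L]] <- child
    }
  }
  sort(parents)
}

# all scaffolds obtainable from `mol` by removing one terminal ring
.removeOneTerminalRing <- function(mol) {
  rings <- findRings(mol)
  if (length(rings) <= 1L) return(list())
  n <- nrow(mol@atoms)
  ringCount <- integer(n)
  for (r in rings) ringCount[r] <- ringCount[r] + 1L
  out <- list()
  for (r in rings) {
    excl <- r[ringCount[r] == 1L]
    if (length(excl) == 0L) next  # fully shared; not a terminal ring
    rest <- setdiff(seq_len(n), excl)
    if (length(rest) == 0L) next
    remainder <- subMolecule(mol, rest, demoteAromatic = TRUE)
    parent <- murckoScaffold(remainder)
    if (is.null(parent)) next
    if (length(molComponents(parent)) != 1L) next  # disconnected: not terminal
    out[[length(out) + 1L]] <- parent
  }
  out
}

# ---- plugin contract ----

#' @rdname fragmenterId
#' @export
setMethod("fragmenterId", "ScaffoldFragmenter", function(x) "scaffold")

#' @rdname settingDescriptors
#' @export
setMethod("settingDescriptors", "ScaffoldFragmenter", function(x) {
  list(
    fragmentation_type = settingDescriptor(
      "fragmentation_type", "ENUM", "SCAFFOLD_ONLY",
      allowed = list("SCAFFOLD_ONLY", "SIDE_CHAINS_ONLY",
                     "RINGS_AND_LINKERS", "ENUMERATIVE_PARENTS"),
      description = "what to return: the scaffold, the pruned side chains, ring systems plus linkers, or all enumerated parent scaffolds"))
})

#' @rdname fragmentMolecule
#' @export
setMethod("fragmentMolecule", "ScaffoldFragmenter", function(x, mol) {
  type <- x@settings$fragmentation_type
  p <- scaffoldParts(mol)
  if (length(p$scaffold_atoms) == 0L) {
    logWarn("scaffold: acyclic molecule yields no fragments")
    return(character(0))
  }
  if (type == "SCAFFOLD_ONLY") {
    sc <- subMolecule(mol, p$scaffold_atoms, demoteAromatic = TRUE)
    return(canonicaliseSmiles(writeSmiles(sc)))
  }
  if (type == "SIDE_CHAINS_ONLY") {
    return(vapply(p$side_chains, function(cp) {
      sub <- subMolecule(mol, cp, demoteAromatic = TRUE)
      canonicaliseSmiles(writeSmiles(sub))
    }, character(1), USE.NAMES = FALSE))
  }
  if (type == "RINGS_AND_LINKERS") {
    out <- character(0)
    # exocyclic scaffold appendages go with the part they are bonded to
    exoHost <- function(part) {
      ext <- part
      for (v in p$exo_atoms) {
        rows <- which(mol@bonds$a1 == v | mol@bonds$a2 == v)
        nb <- ifelse(mol@bonds$a1[rows] == v, mol@bonds$a2[rows],
                     mol@bonds$a1[rows])
        if (any(nb %in% part)) ext <- c(ext, v)
      }
      sort(unique(ext))
    }
    for (rs in p$ring_systems) {
      sub <- subMolecule(mol, exoHost(rs), demoteAromatic = TRUE)
      out <- c(out, canonicaliseSmiles(writeSmiles(sub)))
    }
    if (length(p$linker_atoms) > 0L) {
      for (cp in molComponents(mol, p$linker_atoms)) {
        sub <- subMolecule(mol, exoHost(cp), demoteAromatic = TRUE)
        out <- c(out, canonicaliseSmiles(writeSmiles(sub)))
      }
    }
    return(out)
  }
  if (type == "ENUMERATIVE_PARENTS") {
    sc <- subMolecule(mol, p$scaffold_atoms, demoteAromatic = TRUE)
    return(enumerateParents(sc))
  }
  stop("unknown fragmentation_type: ", type)
})
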