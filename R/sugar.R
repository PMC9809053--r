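# Glycosidic-moiety detection and removal: circular (furanose/pyranose-
# like) sugar rings rich in exocyclic oxygens, optionally linear sugar
# chains, removed iteratively (terminal moieties only by default) with
# cleaved bonds saturated by hydrogen. The bridging glycosidic oxygen
# stays with the aglycone.

#' Detect circular sugar moieties
#'
#' A hit is a non-fused 5- or 6-membered ring with exactly one ring
#' oxygen, all ring carbons sp3, whose count of exocyclic single-bonded
#' oxygens divided by the ring size is at least
#' \code{exocyclic_oxygen_ratio_min}. The hit's atom set is the ring plus
#' those exocyclic oxygens.
#'
#' @param mol a \linkS4class{Molecule}.
#' @param settings named list of sugar-removal settings (see
#'   \code{makeFragmenter("sugar-removal")}).
#' @return list of hits, each \code{list(kind = "CIRCULAR", atoms =
#'   integer vector, ring = integer vector)}.
#' @export
detectCircularSugars <- function(mol, settings = list()) {
  s <- .sugarDefaults(settings)
  a <- mol@atoms
  b <- mol@bonds
  rings <- findRings(mol)
  if (length(rings) == 0L) return(list())
  # bond ring-membership counts to exclude fused rings
  bondKey <- paste(pmin(b$a1, b$a2), pmax(b$a1, b$a2))
  ringBondCount <- table(unlist(lapply(rings, function(r) {
    nxt <- c(r[-1], r[1])
    paste(pmin(r, nxt), pmax(r, nxt))
  })))
  hasMulti <- logical(nrow(a))
  hasMulti[c(b$a1[b$order >= 2L | b$aromatic],
             b$a2[b$order >= 2L | b$aromatic])] <- TRUE
  hits <- list()
  for (r in rings) {
    m <- length(r)
    if (!m %in% c(5L, 6L)) next
    el <- a$element[r]
    if (sum(el == "O") != 1L || any(!el %in% c("C", "O"))) next
    ringC <- r[el == "C"]
    if (any(hasMulti[ringC]) || any(a$aromatic[r])) next
    nxt <- c(r[-1], r[1])
    rk <- paste(pmin(r, nxt), pmax(r, nxt))
    if (any(ringBondCount[rk] > 1L)) next  # fused
    # exocyclic single-bonded oxygens on ring atoms
    exo <- integer(0)
    for (v in r) {
      rows <- which((b$a1 == v | b$a2 == v) & b$order == 1L & !b$aromatic)
      nb <- ifelse(b$a1[rows] == v, b$a2[rows], b$a1[rows])
      exo <- c(exo, nb[!(nb %in% r) & a$element[nb] == "O"])
    }
    exo <- unique(exo)
    if (length(exo) / m < s$exocyclic_oxygen_ratio_min) next
    hits[[length(hits) + 1L]] <-
      list(kind = "CIRCULAR", atoms = sort(c(r, exo)), ring = r)
  }
  hits
}

#' Detect linear sugar moieties
#'
#' Matches acyclic chains of 3--7 carbons in which every chain carbon
#' bears exactly one oxygen substituent (a terminal hydroxy oxygen or a
#' double-bonded carbonyl oxygen) and no chain atom is in a ring.
#' Stereochemistry is ignored.
#'
#' @inheritParams detectCircularSugars
#' @return list of hits, each \code{list(kind = "LINEAR", atoms =
#'   integer vector)}.
#' @export
detectLinearSugars <- function(mol, settings = list()) {
  a <- mol@atoms
  b <- mol@bonds
  inRing <- ringAtomFlags(mol)
  n <- nrow(a)
  degAll <- integer(n)
  for (i in seq_len(nrow(b))) {
    degAll[b$a1[i]] <- degAll[b$a1[i]] + 1L
    degAll[b$a2[i]] <- degAll[b$a2[i]] + 1L
  }
  oxy <- vector("list", n)   # qualifying oxygen substituents per carbon
  nOxyAll <- integer(n)      # any oxygen neighbours
  for (i in seq_len(nrow(b))) {
    pairs <- list(c(b$a1[i], b$a2[i]), c(b$a2[i], b$a1[i]))
    for (p in pairs) {
      c_ <- p[1]; o_ <- p[2]
      if (a$element[c_] == "C" && a$element[o_] == "O") {
        nOxyAll[c_] <- nOxyAll[c_] + 1L
        if ((b$order[i] == 1L && degAll[o_] == 1L) || b$order[i] == 2L)
          oxy[[c_]] <- c(oxy[[c_]], o_)
      }
    }
  }
  cand <- which(a$element == "C" & !inRing & !a$aromatic &
                nOxyAll == 1L &
                vapply(oxy, length, integer(1)) == 1L)
  if (length(cand) < 3L) return(list())
  # components of candidate carbons over C-C single bonds
  keep <- b$a1 %in% cand & b$a2 %in% cand & b$order == 1L
  g <- igraph::make_empty_graph(n = length(cand), directed = FALSE)
  igraph::V(g)$name <- as.character(cand)
  if (any(keep)) {
    emap <- match(c(rbind(b$a1[keep], b$a2[keep])), cand)
    g <- igraph::add_edges(g, emap)
  }
  comp <- igraph::components(g)
  hits <- list()
  for (cid in seq_len(comp$no)) {
    atoms <- cand[comp$membership == cid]
    if (length(atoms) < 3L || length(atoms) > 7L) next
    # must be a simple path: all internal degrees <= 2
    sg <- igraph::induced_subgraph(g, match(atoms, cand))
    if (any(igraph::degree(sg) > 2L)) next
    os <- unlist(oxy[atoms])
    hits[[length(hits) + 1L]] <-
      list(kind = "LINEAR", atoms = sort(unique(c(atoms, os))))
  }
  hits
}

.sugarDefaults <- function(settings) {
  d <- list(detect_circular = TRUE, detect_linear = FALSE,
            remove_only_terminal = TRUE, exocyclic_oxygen_ratio_min = 0.5,
            min_aglycone_heavy_atoms = 5L, return_sugars = FALSE)
  for (k in names(settings)) d[[k]] <- settings[[k]]
  d
}

# atoms of a hit that are actually deleted: the bridging glycosidic
# oxygen (an exocyclic hit oxygen with a heavy neighbour outside the
# hit) stays with the aglycone.
.removableAtoms <- function(mol, hit) {
  b <- mol@bonds
  atoms <- hit$atoms
  keepO <- vapply(atoms, function(v) {
    if (mol@atoms$element[v] != "O") return(FALSE)
    if (!is.null(hit$ring) && v %in% hit$ring) return(FALSE)
    rows <- which(b$a1 == v | b$a2 == v)
    nb <- ifelse(b$a1[rows] == v, b$a2[rows], b$a1[rows])
    any(!(nb %in% atoms))
  }, logical(1))
  atoms[!keepO]
}

#' Remove sugar moieties from a structure
#'
#' Iteratively deletes detected sugar hits (terminal ones only when
#' \code{remove_only_terminal}), saturating cleaved bonds with hydrogen,
#' until no removable hit remains. Returns the aglycone (and the removed
#' sugar fragments when \code{return_sugars}); an empty result means the
#' entire molecule is sugar. Disconnected leftovers smaller than
#' \code{min_aglycone_heavy_atoms} heavy atoms are discarded.
#'
#' @inheritParams detectCircularSugars
#' @return character vector of canonical SMILES (possibly empty).
#' @export
removeSugars <- function(mol, settings = list()) {
  s <- .sugarDefaults(settings)
  cur <- mol
  sugarsOut <- character(0)
  anyRemoved <- FALSE
  repeat {
    hits <- list()
    if (isTRUE(s$detect_circular))
      hits <- c(hits, detectCircularSugars(cur, s))
    if (isTRUE(s$detect_linear))
      hits <- c(hits, detectLinearSugars(cur, s))
    if (length(hits) == 0L) break
    removed <- FALSE
    # deterministic order: smallest first atom index first
    ord <- order(vapply(hits, function(h) min(h$atoms), integer(1)))
    for (h in hits[ord]) {
      del <- .removableAtoms(cur, h)
      if (length(del) == 0L) next
      rest <- setdiff(seq_len(nrow(cur@atoms)), del)
      if (isTRUE(s$remove_only_terminal) && length(rest) > 0L) {
        comps <- molComponents(cur, rest)
        # sub-threshold leftovers (e.g. the sugar's own exocyclic CH2OH
        # orphaned by ring deletion) are discarded later and do not make
        # a removal non-terminal
        big <- sum(vapply(comps, length, integer(1)) >=
                     s$min_aglycone_heavy_atoms)
        if (big > 1L) next  # not terminal
      }
      if (isTRUE(s$return_sugars)) {
        sugarMol <- subMolecule(cur, h$atoms, demoteAromatic = TRUE)
        sugarsOut <- c(sugarsOut, canonicaliseSmiles(writeSmiles(sugarMol)))
      }
      if (length(rest) == 0L) {
        cur <- NULL
      } else {
        cur <- subMolecule(cur, rest, demoteAromatic = TRUE)
      }
      removed <- TRUE
      anyRemoved <- TRUE
      break
    }
    if (!removed || is.null(cur)) break
  }
  out <- character(0)
  if (!is.null(cur)) {
    if (!anyRemoved) {
      # identity on sugar-free input, regardless of size
      out <- canonicalSmiles(mol)
    } else {
      comps <- molComponents(cur)
      comps <- Filter(function(cp) length(cp) >= s$min_aglycone_heavy_atoms,
                      comps)
      for (cp in comps) {
        sub <- subMolecule(cur, cp, demoteAromatic = TRUE)
        out <- c(out, canonicaliseSmiles(writeSmiles(sub)))
      }
    }
  }
  c(out, sugarsOut)
}

# ---- plugin contract ----

#' @rdname fragmenterId
#' @export
setMethod("fragmenterId", "SugarRemovalFragmenter", function(x) "sugar-removal")

#' @rdname settingDescriptors
#' @export
setMethod("settingDescriptors", "SugarRemovalFragmenter", function(x) {
  list(
    detect_circular = settingDescriptor(
      "detect_circular", "BOOLEAN", TRUE,
      description = "detect furanose/pyranose-like sugar rings"),
    detect_linear = settingDescriptor(
      "detect_linear", "BOOLEAN", FALSE,
      description = "detect open-chain polyol/carbonyl sugar chains"),
    remove_only_terminal = settingDescriptor(
      "remove_only_terminal", "BOOLEAN", TRUE,
      description = "only remove moieties whose removal leaves the remainder connected"),
    exocyclic_oxygen_ratio_min = settingDescriptor(
      "exocyclic_oxygen_ratio_min", "FLOAT", 0.5,
      description = "minimum exocyclic-oxygen count / ring size for a circular hit"),
    min_aglycone_heavy_atoms = settingDescriptor(
      "min_aglycone_heavy_atoms", "INTEGER", 5L,
      description = "discard disconnected leftovers smaller than this"),
    return_sugars = settingDescriptor(
      "return_sugars", "BOOLEAN", FALSE,
      description = "also return the removed sugar moieties as fragments"))
})

#' @rdname fragmentMolecule
#' @export
setMethod("fragmentMolecule", "SugarRemovalFragmenter", function(x, mol) {
  removeSugars(mol, x@settings)
})
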