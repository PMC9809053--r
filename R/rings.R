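# Ring perception over the heavy-atom graph, built on igraph primitives.
# The ring set used throughout the package is the set of smallest rings
# through each ring bond (per-bond shortest cycles), which coincides with
# the smallest-set-of-smallest-rings on the fused ring systems this
# framework handles and is deterministic.

molGraph <- function(mol) {
  n <- nrow(mol@atoms)
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  igraph::V(g)$name <- as.character(seq_len(n))
  if (nrow(mol@bonds) > 0L) {
    g <- igraph::add_edges(g, as.vector(t(as.matrix(mol@bonds[, c("a1", "a2")]))))
  }
  g
}

# Logical flag per bond row: does the bond lie on a ring?
ringBondFlags <- function(mol) {
  nb <- nrow(mol@bonds)
  if (nb == 0L) return(logical(0))
  g <- molGraph(mol)
  br <- igraph::bridges(g)
  flags <- rep(TRUE, nb)
  flags[as.integer(br)] <- FALSE
  flags
}

# Logical flag per atom: member of at least one ring.
ringAtomFlags <- function(mol) {
  flags <- logical(nrow(mol@atoms))
  rb <- ringBondFlags(mol)
  if (any(rb)) {
    flags[unique(c(mol@bonds$a1[rb], mol@bonds$a2[rb]))] <- TRUE
  }
  flags
}

#' Perceived rings of a molecule
#'
#' Returns the smallest ring through each ring bond, deduplicated: for
#' every bond that is not a bridge, the shortest cycle containing it is
#' found by a shortest-path search with the bond removed. Each ring is an
#' integer vector of atom indices in cycle order.
#'
#' @param mol a \linkS4class{Molecule}.
#' @return list of integer vectors (possibly empty).
#' @export
findRings <- function(mol) {
  rb <- which(ringBondFlags(mol))
  if (length(rb) == 0L) return(list())
  g <- molGraph(mol)
  seen <- character(0)
  rings <- list()
  for (i in rb) {
    a1 <- mol@bonds$a1[i]; a2 <- mol@bonds$a2[i]
    g2 <- igraph::delete_edges(g, i)
    sp <- suppressWarnings(
      igraph::shortest_paths(g2, from = a1, to = a2, output = "vpath"))
    vp <- sp$vpath[[1]]
    if (length(vp) < 3L) next
    ring <- as.integer(igraph::as_ids(vp))
    key <- paste(sort(ring), collapse = ",")
    if (!key %in% seen) {
      seen <- c(seen, key)
      rings[[length(rings) + 1L]] <- ring
    }
  }
  rings
}

# Fused ring systems: connected components of the subgraph induced by
# ring bonds. Returns a list of atom index vectors.
ringSystems <- function(mol) {
  rb <- ringBondFlags(mol)
  if (!any(rb)) return(list())
  b <- mol@bonds[rb, , drop = FALSE]
  atoms <- sort(unique(c(b$a1, b$a2)))
  g <- igraph::make_empty_graph(n = length(atoms), directed = FALSE)
  igraph::V(g)$name <- as.character(atoms)
  emap <- match(c(rbind(b$a1, b$a2)), atoms)
  g <- igraph::add_edges(g, emap)
  comp <- igraph::components(g)
  split(atoms, comp$membership)
}
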