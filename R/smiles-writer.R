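# A small deterministic SMILES writer for molecular (sub)graphs.
#
# Fragment depiction is part of this framework's contract: generalized
# functional-group environments are written with bare environment carbons
# and explicit heteroatom hydrogens ("[H]Oc" style), which no structure
# library emits directly. The writer therefore produces a deterministic,
# valid SMILES for any atom/bond table; the framework-wide *canonical*
# form of a fragment is always obtained by feeding this output through
# canonicaliseSmiles(), never from the writer itself.

.ORGANIC_SUBSET <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")
.AROMATIC_LOWER <- c("B", "C", "N", "O", "P", "S")

.atomToken <- function(element, charge, aromatic, nH, hcount) {
  sym <- element
  if (aromatic && element %in% .AROMATIC_LOWER) sym <- tolower(element)
  else if (aromatic && element == "Se") sym <- "se"
  showH <- hcount
  # aromatic N/P with a hydrogen must carry it explicitly ([nH])
  if (is.na(showH) && aromatic && element %in% c("N", "P") && nH > 0L)
    showH <- nH
  bracket <- element == "H" || charge != 0L || !is.na(showH) ||
    !(element %in% .ORGANIC_SUBSET) ||
    (aromatic && !element %in% c(.AROMATIC_LOWER, "Se"))
  if (!bracket) return(sym)
  h <- if (is.na(showH)) {
    if (charge != 0L || !(element %in% .ORGANIC_SUBSET)) nH else 0L
  } else showH
  hs <- if (h == 1L) "H" else if (h > 1L) paste0("H", h) else ""
  cs <- if (charge == 0L) "" else if (charge == 1L) "+" else if (charge == -1L) "-"
        else if (charge > 0L) paste0("+", charge) else as.character(charge)
  paste0("[", sym, hs, cs, "]")
}

.bondToken <- function(order, aromatic, arom1, arom2) {
  if (aromatic) return("")
  if (order == 2L) return("=")
  if (order == 3L) return("#")
  if (arom1 && arom2) return("-")  # explicit single between aromatic atoms
  ""
}

#' Write a deterministic SMILES for a molecule
#'
#' Depth-first traversal from the first atom of each connected component
#' (components joined with \code{"."}), neighbours visited in atom-index
#' order, ring-closure digits assigned in order of discovery. The output
#' is deterministic but not canonical; use \code{\link{canonicaliseSmiles}}
#' on it for deduplication keys.
#'
#' @param mol a \linkS4class{Molecule}.
#' @return a single SMILES string.
#' @export
writeSmiles <- function(mol) {
  a <- mol@atoms
  b <- mol@bonds
  n <- nrow(a)
  if (n == 0L) return("")
  nbr <- vector("list", n)
  if (nrow(b) > 0L) {
    for (i in seq_len(nrow(b))) {
      nbr[[b$a1[i]]] <- rbind(nbr[[b$a1[i]]], c(b$a2[i], i))
      nbr[[b$a2[i]]] <- rbind(nbr[[b$a2[i]]], c(b$a1[i], i))
    }
    nbr <- lapply(nbr, function(m) {
      if (is.null(m)) NULL else m[order(m[, 1]), , drop = FALSE]
    })
  }
  visited <- logical(n)
  bondUsed <- logical(nrow(b))
  ringBonds <- list()   # bond index -> digit
  digitAt <- vector("list", n)  # atom -> list of (digit, bondRow)
  nextDigit <- 0L

  # pass 1: spanning-tree DFS to find back edges and assign digits
  assignDigits <- function(start) {
    stack <- list(c(start, 0L))
    visited[start] <<- TRUE
    while (length(stack) > 0L) {
      top <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      v <- top[1]
      nb <- nbr[[v]]
      if (!is.null(nb)) {
        for (k in rev(seq_len(nrow(nb)))) {
          w <- nb[k, 1]; bi <- nb[k, 2]
          if (bondUsed[bi]) next
          if (visited[w]) {
            bondUsed[bi] <<- TRUE
            nextDigit <<- nextDigit + 1L
            digitAt[[v]] <<- c(digitAt[[v]], list(c(nextDigit, bi)))
            digitAt[[w]] <<- c(digitAt[[w]], list(c(nextDigit, bi)))
          } else {
            bondUsed[bi] <<- TRUE
            visited[w] <<- TRUE
            stack[[length(stack) + 1L]] <- c(w, bi)
          }
        }
      }
    }
  }

  # pass 2: emit
  emit <- function(v, fromBond) {
    tok <- .atomToken(a$element[v], a$charge[v], a$aromatic[v], a$nH[v],
                      a$hcount[v])
    for (d in digitAt[[v]]) {
      bi <- d[2]
      sym <- .bondToken(b$order[bi], b$aromatic[bi],
                        a$aromatic[b$a1[bi]], a$aromatic[b$a2[bi]])
      dg <- if (d[1] > 9L) paste0("%", d[1]) else as.character(d[1])
      tok <- paste0(tok, sym, dg)
    }
    kids <- list()
    nb <- nbr[[v]]
    if (!is.null(nb)) {
      for (k in seq_len(nrow(nb))) {
        w <- nb[k, 1]; bi <- nb[k, 2]
        if (bi == fromBond || emitted[w]) next
        if (any(vapply(digitAt[[v]], function(d) d[2] == bi, logical(1))))
          next  # ring-closure bond, already encoded as digit
        kids[[length(kids) + 1L]] <- c(w, bi)
      }
    }
    emitted[v] <<- TRUE
    out <- tok
    if (length(kids) > 0L) {
      parts <- character(length(kids))
      for (k in seq_along(kids)) {
        w <- kids[[k]][1]; bi <- kids[[k]][2]
        if (emitted[w]) { parts[k] <- ""; next }
        sym <- .bondToken(b$order[bi], b$aromatic[bi],
                          a$aromatic[b$a1[bi]], a$aromatic[b$a2[bi]])
        parts[k] <- paste0(sym, emit(w, bi))
      }
      parts <- parts[nzchar(parts)]
      if (length(parts) > 1L) {
        out <- paste0(out,
                      paste0("(", paste(parts[-length(parts)], collapse = ")("), ")"),
                      parts[length(parts)])
      } else if (length(parts) == 1L) {
        out <- paste0(out, parts[1])
      }
    }
    out
  }

  pieces <- character(0)
  emitted <- logical(n)
  for (start in seq_len(n)) {
    if (visited[start]) next
    assignDigits(start)
    pieces <- c(pieces, emit(start, 0L))
  }
  paste(pieces, collapse = ".")
}
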