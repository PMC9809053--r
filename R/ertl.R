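# Functional-group identification by per-atom marking rules, with
# generalized or full-environment depiction of the extracted groups and
# hydrogen-saturated carbon-skeleton remnants.
#
# Marking rules (applied to the fixed import-time perception):
#   1. every heteroatom (not C, not H) is marked              HETEROATOM
#   2. every C in a non-aromatic C=C or C#C is marked         C_C_MULTIBOND
#   3. every C double/triple-bonded to a heteroatom is marked C_MULTIBOND_HETERO
#   4. every acetal-like sp3 C with >= 2 single bonds to O/N/S
#      atoms that themselves bear only single bonds is marked ACETAL_C
#   5. all atoms of 3-membered rings with a heteroatom        THREE_RING_HETERO
# An atom's primary reason is the first applicable in enum order
# HETEROATOM, C_MULTIBOND_HETERO, C_C_MULTIBOND, ACETAL_C,
# THREE_RING_HETERO.

.ERTL_ORGANIC <- c("H", "C", "N", "O", "S", "P", "Se", "F", "Cl", "Br", "I")

#' Mark functional-group atoms
#'
#' Applies the five per-atom marking rules and returns the marked atom
#' set together with each atom's primary reason. Deterministic; rule 2
#' applies only to non-aromatic multiple bonds.
#'
#' @param mol a \linkS4class{Molecule} (organic subset, neutral; the
#'   fragmenter's filter and preprocessing guarantee this).
#' @return A list with \code{marked} (integer atom indices) and
#'   \code{reason} (character vector over all atoms, \code{NA} for
#'   unmarked).
#' @export
markAtoms <- function(mol) {
  a <- mol@atoms
  b <- mol@bonds
  n <- nrow(a)
  reason <- rep(NA_character_, n)
  isC <- a$element == "C"

  mark <- function(idx, why) {
    fresh <- idx[is.na(reason[idx])]
    reason[fresh] <<- why
  }

  # rule 1: heteroatoms
  mark(which(!isC), "HETEROATOM")

  multi <- which(b$order >= 2L & !b$aromatic)
  # rule 3 before rule 2 (enum priority)
  for (i in multi) {
    u <- b$a1[i]; v <- b$a2[i]
    if (isC[u] && !isC[v]) mark(u, "C_MULTIBOND_HETERO")
    if (isC[v] && !isC[u]) mark(v, "C_MULTIBOND_HETERO")
  }
  # rule 2: non-aromatic C=C / C#C
  for (i in multi) {
    u <- b$a1[i]; v <- b$a2[i]
    if (isC[u] && isC[v]) mark(c(u, v), "C_C_MULTIBOND")
  }

  # rule 4: acetal-like carbons
  if (n > 0L) {
    hasMulti <- logical(n)
    hasMulti[c(b$a1[b$order >= 2L | b$aromatic],
               b$a2[b$order >= 2L | b$aromatic])] <- TRUE
    singleBondsOnly <- !hasMulti
    for (v in which(isC & !a$aromatic & singleBondsOnly)) {
      nbrRows <- which((b$a1 == v | b$a2 == v) & b$order == 1L & !b$aromatic)
      nbrs <- ifelse(b$a1[nbrRows] == v, b$a2[nbrRows], b$a1[nbrRows])
      ons <- nbrs[a$element[nbrs] %in% c("O", "N", "S")]
      if (sum(singleBondsOnly[ons]) >= 2L) mark(v, "ACETAL_C")
    }
  }

  # rule 5: heteroatom-containing 3-membered rings
  for (r in findRings(mol)) {
    if (length(r) == 3L && any(a$element[r] != "C"))
      mark(r, "THREE_RING_HETERO")
  }

  list(marked = which(!is.na(reason)), reason = reason)
}

# Build a functional-group fragment from a marked component plus its
# first-sphere unmarked carbon environment. Environment atoms are typed
# aromatic (lowercase) or aliphatic; in generalized mode they carry no
# hydrogens of their own and heteroatom hydrogens are written as explicit
# [H] atoms; in full mode environment carbons keep their real hydrogen
# counts. Cleaved bonds carry no attachment labels.
.buildFgFragment <- function(mol, comp, marked, mode) {
  a <- mol@atoms
  b <- mol@bonds
  inComp <- logical(nrow(a)); inComp[comp] <- TRUE
  isMarked <- logical(nrow(a)); isMarked[marked] <- TRUE

  env <- integer(0)
  for (v in comp) {
    rows <- which(b$a1 == v | b$a2 == v)
    nb <- ifelse(b$a1[rows] == v, b$a2[rows], b$a1[rows])
    env <- c(env, nb[!isMarked[nb] & a$element[nb] == "C"])
  }
  env <- sort(unique(env))

  sel <- c(sort(comp), env)
  map <- integer(nrow(a)); map[sel] <- seq_along(sel)
  fa <- a[sel, , drop = FALSE]
  isEnv <- c(rep(FALSE, length(comp)), rep(TRUE, length(env)))

  keep <- (b$a1 %in% comp & b$a2 %in% comp) |
          (b$a1 %in% comp & b$a2 %in% env) |
          (b$a1 %in% env & b$a2 %in% comp)
  fb <- b[keep, , drop = FALSE]
  fb$a1 <- map[fb$a1]; fb$a2 <- map[fb$a2]

  # hydrogens: heteroatom H always explicit as [H] atoms; core carbons
  # use implicit refill; environment carbons bare (generalized) or with
  # their real H count (full).
  het <- !isEnv & fa$element != "C"
  extraH <- integer(0)
  for (k in which(het)) {
    nh <- fa$nH[k]
    if (nh > 0L) extraH <- c(extraH, rep(k, nh))
    fa$nH[k] <- 0L
    fa$hcount[k] <- NA_integer_
  }
  if (mode == "full") {
    fa$hcount[isEnv] <- fa$nH[isEnv]
  }
  fa$nH[isEnv] <- 0L
  # aromatic N et al. in the core keep nH = 0 after explicitation, so the
  # writer will not double-count.
  if (length(extraH) > 0L) {
    hstart <- nrow(fa)
    fa <- rbind(fa, data.frame(
      element = rep("H", length(extraH)), charge = 0L, aromatic = FALSE,
      nH = 0L, hcount = NA_integer_, stringsAsFactors = FALSE))
    fb <- rbind(fb, data.frame(
      a1 = extraH, a2 = hstart + seq_along(extraH),
      order = 1L, aromatic = FALSE, stringsAsFactors = FALSE))
  }
  newMolecule(fa, fb)
}

#' Extract functional-group fragments
#'
#' One fragment per connected component of marked atoms, each carrying
#' its first-sphere unmarked carbon neighbours as environment atoms.
#'
#' @param mol a \linkS4class{Molecule}.
#' @param marking result of \code{\link{markAtoms}}.
#' @param mode \code{"generalized"} (bare environment carbons, explicit
#'   heteroatom hydrogens) or \code{"full"} (environment carbons keep
#'   their real hydrogen counts).
#' @return character vector of canonical SMILES, one per component (in
#'   per-molecule multiplicity).
#' @export
extractFunctionalGroups <- function(mol, marking,
                                    mode = c("generalized", "full")) {
  mode <- match.arg(mode)
  if (length(marking$marked) == 0L) return(character(0))
  comps <- molComponents(mol, marking$marked)
  out <- character(0)
  for (comp in comps) {
    frag <- .buildFgFragment(mol, comp, marking$marked, mode)
    out <- c(out, canonicaliseSmiles(writeSmiles(frag)))
  }
  out
}

#' Extract carbon-skeleton remnant fragments
#'
#' One fragment per connected component of unmarked heavy atoms; bonds to
#' marked atoms are cleaved and open valences saturated with hydrogen.
#' Aromatic systems wholly contained in a component stay aromatic;
#' partially excised aromatic atoms revert to their kekulised orders.
#'
#' @param mol a \linkS4class{Molecule}.
#' @param marking result of \code{\link{markAtoms}}.
#' @return character vector of canonical SMILES.
#' @export
extractRemnants <- function(mol, marking) {
  unmarked <- setdiff(seq_len(nrow(mol@atoms)), marking$marked)
  if (length(unmarked) == 0L) return(character(0))
  comps <- molComponents(mol, unmarked)
  vapply(comps, function(comp) {
    sub <- subMolecule(mol, comp, demoteAromatic = TRUE)
    canonicaliseSmiles(writeSmiles(sub))
  }, character(1), USE.NAMES = FALSE)
}

# ---- plugin contract ----

#' @rdname fragmenterId
#' @export
setMethod("fragmenterId", "ErtlFragmenter", function(x) "ertl-fg")

#' @rdname settingDescriptors
#' @export
setMethod("settingDescriptors", "ErtlFragmenter", function(x) {
  list(
    environment_mode = settingDescriptor(
      "environment_mode", "ENUM", "generalized",
      allowed = list("generalized", "full"),
      description = "FG environment depiction: bare (generalized) or real H counts (full)"),
    return_remnants = settingDescriptor(
      "return_remnants", "BOOLEAN", TRUE,
      description = "also return hydrogen-saturated carbon-skeleton remnants"))
})

#' @rdname shouldFilter
#' @export
setMethod("shouldFilter", "ErtlFragmenter", function(x, mol) {
  bad <- setdiff(unique(mol@atoms$element), .ERTL_ORGANIC)
  if (length(bad) > 0L) {
    return(list(filter = TRUE,
                reason = paste0("metal or metalloid atom: ",
                                paste(bad, collapse = ","))))
  }
  list(filter = FALSE, reason = NA_character_)
})

#' @rdname preprocessMolecule
#' @export
setMethod("preprocessMolecule", "ErtlFragmenter", function(x, mol) {
  ch <- mol@atoms$charge
  if (all(ch == 0L)) {
    return(list(mol = mol, ok = TRUE, changed = FALSE, reason = NA_character_))
  }
  a <- mol@atoms
  for (i in which(ch != 0L)) {
    if (ch[i] < 0L) {
      # neutralise anions by adding hydrogens
      a$nH[i] <- a$nH[i] + abs(ch[i])
      a$charge[i] <- 0L
    } else {
      if (a$nH[i] >= ch[i]) {
        a$nH[i] <- a$nH[i] - ch[i]
        a$charge[i] <- 0L
      } else {
        return(list(mol = mol, ok = FALSE, changed = FALSE,
                    reason = "non-neutralisable charge"))
      }
    }
  }
  m2 <- mol
  m2@atoms <- a
  # re-perceive through the canonical pipeline so aromaticity and
  # hydrogen counts are consistent with the neutralised form
  neutral <- parseSmiles(canonicaliseSmiles(writeSmiles(.withExplicitHetH(m2))))
  list(mol = neutral, ok = TRUE, changed = TRUE, reason = "charges neutralised")
})

# write all hydrogens explicitly so the neutralised H counts survive the
# SMILES round trip
.withExplicitHetH <- function(mol) {
  mol@atoms$hcount <- mol@atoms$nH
  mol
}

#' @rdname fragmentMolecule
#' @export
setMethod("fragmentMolecule", "ErtlFragmenter", function(x, mol) {
  s <- x@settings
  marking <- markAtoms(mol)
  out <- extractFunctionalGroups(mol, marking, mode = s$environment_mode)
  if (isTRUE(s$return_remnants)) {
    out <- c(out, extractRemnants(mol, marking))
  }
  out
})
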