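## Atomic-contribution octanol/water logP (Wildman & Crippen 1999).
##
## The calculator works on a light molecular-graph representation extracted
## from a ChemmineR SDF object: element symbols, formal charges, and a
## kekulized bond list. Aromaticity is perceived internally (Hueckel 4n+2 over
## 5- and 6-membered rings) because atom classes distinguish aromatic from
## aliphatic environments. Implicit hydrogens are derived from standard
## valences adjusted for formal charge.

## Published per-class contributions (Wildman & Crippen, J Chem Inf Comput
## Sci 1999, 39, 868-873, Table 1). Only the logP column is carried.
.WC_LOGP <- c(
  C1 = 0.1441,  C2 = 0,       C3 = -0.2035, C4 = -0.2051, C5 = -0.2783,
  C6 = 0.1551,  C7 = 0.0017,  C8 = 0.08452, C9 = -0.1444, C10 = -0.0516,
  C11 = 0.1193, C12 = -0.0967, C13 = -0.5443, C14 = 0,    C15 = 0.245,
  C16 = 0.198,  C17 = 0,      C18 = 0.1581, C19 = 0.2955, C20 = 0.2713,
  C21 = 0.136,  C22 = 0.4619, C23 = 0.5437, C24 = 0.1893, C25 = -0.8186,
  C26 = 0.264,  C27 = 0.2148, CS = 0.08129,
  H1 = 0.123,   H2 = -0.2677, H3 = 0.2142,  H4 = 0.298,   HS = 0.1125,
  N1 = -1.019,  N2 = -0.7096, N3 = -1.027,  N4 = -0.5188, N5 = 0.08387,
  N6 = 0.1836,  N7 = -0.3187, N8 = -0.4458, N9 = 0.01508, N10 = -1.95,
  N11 = -0.3239, N12 = -1.119, N13 = -0.3396, N14 = 0.2887, NS = -0.4806,
  O1 = 0.1552,  O2 = -0.2893, O3 = -0.0684, O4 = -0.4195, O5 = 0.0335,
  O6 = -0.3339, O7 = -1.189,  O8 = 0.1788,  O9 = -0.1526, O10 = 0.1129,
  O11 = 0.4833, O12 = -1.326, OS = -0.1188,
  F = 0.4202,   Cl = 0.6895,  Br = 0.8456,  I = 0.8857,   Hal = -2.996,
  P = 0.8612,   S1 = 0.6482,  S2 = -0.0024, S3 = 0.6237,
  Me1 = -0.3808, Me2 = -0.0025
)

.ME1_Z <- c(3, 11, 19, 37, 55, 4, 12, 20, 38, 56, 5, 13, 31, 49, 81,
            14, 32, 50, 82, 33, 51, 83, 34, 52, 84)
.ME2_Z <- c(21:30, 39:48, 72:80)

.ELEMENT_Z <- c(H = 1, B = 5, C = 6, N = 7, O = 8, F = 9, Na = 11, Mg = 12,
                Al = 13, Si = 14, P = 15, S = 16, Cl = 17, K = 19, Ca = 20,
                Fe = 26, Cu = 29, Zn = 30, As = 33, Se = 34, Br = 35, I = 53)

## Allowed valences for implicit-hydrogen assignment (smallest >= bond sum).
.VALENCES <- list(H = 1, B = 3, C = 4, N = 3, O = 2, F = 1, Si = 4,
                  P = c(3, 5), S = c(2, 4, 6), Cl = 1, Se = c(2, 4, 6),
                  Br = 1, I = 1)

## ---------------------------------------------------------------------------
## Molecular graph construction

#' Build an internal molecular graph from a ChemmineR SDF object
#'
#' @param sdf a \code{ChemmineR::SDF} object (kekulized bond orders).
#' @param charges optional integer vector of formal charges per atom index
#'   (as read from \code{M  CHG} lines); defaults to the legacy atom-block
#'   charge column when absent.
#' @param seToS map selenium atoms to sulfur before typing.
#' @return a list with elements, charges, bonds, hydrogens and aromaticity
#'   annotations, used by \code{\link{wcLogP}}.
#' @keywords internal
.molFromSDF <- function(sdf, charges = NULL, seToS = FALSE) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elements <- gsub("_[0-9]+$", "", rownames(ab))
  n <- length(elements)
  if (n == 0L) stop("empty molecule")
  chg <- integer(n)
  ## legacy atom-block charge column (codes 1..7 = +3..-3, 4 = radical)
  if ("C6" %in% colnames(ab)) {
    code <- ab[, "C6"]
    chg <- ifelse(code >= 1 & code <= 3, 4 - code,
                  ifelse(code >= 5 & code <= 7, 4 - code, 0))
  }
  if (!is.null(charges)) {
    chg <- integer(n)
    idx <- as.integer(names(charges))
    chg[idx] <- as.integer(charges)
  }
  bonds <- if (is.null(dim(bb)) || nrow(bb) == 0) {
    matrix(integer(0), ncol = 3)
  } else {
    cbind(as.integer(bb[, 1]), as.integer(bb[, 2]), as.integer(bb[, 3]))
  }
  if (seToS) elements[elements == "Se"] <- "S"
  .buildMol(elements, as.integer(chg), bonds)
}

.buildMol <- function(elements, charges, bonds) {
  n <- length(elements)
  nbrs <- vector("list", n)
  border <- vector("list", n)
  if (nrow(bonds)) {
    ## bond type 4 (aromatic input) is treated as order 1.5 for valence
    for (k in seq_len(nrow(bonds))) {
      a <- bonds[k, 1]; b <- bonds[k, 2]; o <- bonds[k, 3]
      nbrs[[a]] <- c(nbrs[[a]], b); nbrs[[b]] <- c(nbrs[[b]], a)
      border[[a]] <- c(border[[a]], o); border[[b]] <- c(border[[b]], o)
    }
  }
  ordsum <- vapply(border, function(o) {
    if (!length(o)) return(0)
    sum(ifelse(o == 4, 1.5, o))
  }, numeric(1))
  nH <- integer(n)
  for (i in seq_len(n)) {
    el <- elements[i]
    if (el == "H") next
    expH <- sum(elements[nbrs[[i]]] == "H")
    val <- .VALENCES[[el]]
    if (is.null(val)) { nH[i] <- 0L; next }
    v <- val[1]
    ch <- charges[i]
    if (ch > 0 && el %in% c("N", "O", "S", "P")) v <- v + ch
    if (ch < 0) v <- v - abs(ch)
    bs <- ceiling(ordsum[i])
    if (length(val) > 1) {
      if (ch != 0) {
        v <- bs                       # charged hypervalent: no implicit H
      } else {
        cand <- val[val >= bs]
        v <- if (length(cand)) min(cand) else bs
      }
    }
    nH[i] <- max(0L, as.integer(v - bs))
    ## explicit hydrogens already count in the bond sum
    if (expH > 0 && nH[i] > 0) nH[i] <- max(0L, nH[i])
  }
  mol <- list(elements = elements, charges = charges, bonds = bonds,
              nbrs = nbrs, border = border, nH = nH, n = n)
  mol <- .perceiveAromaticity(mol)
  mol
}

## Hueckel-style perception on the kekulized graph: a 5- or 6-membered ring is
## aromatic when every member can be sp2 and the pi-electron count is 4n + 2.
## Carbons double-bonded into a fused ring contribute one electron; carbons
## with an exocyclic double bond to a non-ring atom contribute zero;
## N/O/S without a double bond contribute a lone pair (two).
.perceiveAromaticity <- function(mol) {
  n <- mol$n
  aromAtom <- logical(n)
  aromBond <- logical(nrow(mol$bonds))
  ringList <- .ringAtoms(mol)
  allRingAtoms <- unique(unlist(ringList))
  for (ring in ringList) {
    sz <- length(ring)
    if (sz < 5L || sz > 6L) next
    pis <- integer(sz)
    ok <- TRUE
    for (j in seq_len(sz)) {
      i <- ring[j]
      el <- mol$elements[i]
      dbl <- which(mol$border[[i]] == 2)
      dblTo <- mol$nbrs[[i]][dbl]
      if (el == "C") {
        if (!length(dbl)) { ok <- FALSE; break }
        if (any(dblTo %in% ring)) pis[j] <- 1L
        else if (any(dblTo %in% allRingAtoms)) pis[j] <- 1L  # fused system
        else pis[j] <- 0L                                    # exocyclic C=X
      } else if (el == "N") {
        pis[j] <- if (length(dbl)) 1L else 2L
        if (length(dbl) && !any(dblTo %in% allRingAtoms)) pis[j] <- 0L
      } else if (el %in% c("O", "S")) {
        if (any(dblTo %in% ring)) { ok <- FALSE; break }
        pis[j] <- 2L
      } else { ok <- FALSE; break }
      ## sp3 centers (4 sigma connections) cannot be aromatic
      if (length(mol$nbrs[[i]]) + mol$nH[i] > 3) { ok <- FALSE; break }
    }
    if (ok && (sum(pis) - 2) %% 4 == 0) {
      aromAtom[ring] <- TRUE
      for (j in seq_len(sz)) {
        a <- ring[j]; b <- ring[if (j == sz) 1L else j + 1L]
        hit <- which((mol$bonds[, 1] == a & mol$bonds[, 2] == b) |
                       (mol$bonds[, 1] == b & mol$bonds[, 2] == a))
        aromBond[hit] <- TRUE
      }
    }
  }
  mol$aromAtom <- aromAtom
  mol$aromBond <- aromBond
  mol
}

## Minimal cycle enumeration (bounded DFS, rings up to size 6). Sufficient for
## aromaticity perception; avoids depending on ChemmineR's aromatic flag,
## which tests only for the presence of a ring double bond.
.ringAtoms <- function(mol, maxSize = 6L) {
  rings <- list()
  seen <- character(0)
  n <- mol$n
  for (start in seq_len(n)) {
    stack <- list(c(start))
    while (length(stack)) {
      path <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      last <- path[length(path)]
      for (nb in mol$nbrs[[last]]) {
        if (mol$elements[nb] == "H") next
        if (nb == start && length(path) >= 3L) {
          key <- paste(sort(path), collapse = "-")
          if (!(key %in% seen)) { seen <- c(seen, key); rings[[length(rings) + 1L]] <- path }
        } else if (!(nb %in% path) && length(path) < maxSize && nb > start) {
          stack[[length(stack) + 1L]] <- c(path, nb)
        }
      }
    }
  }
  ## drop rings that are unions of smaller rings (keep 3..6 simple cycles,
  ## preferring the smallest cycles covering each bond)
  rings
}

## ---------------------------------------------------------------------------
## Atom typing

.HETERO_AL <- c("N", "O", "P", "S", "F", "Cl", "Br", "I")

#' @keywords internal
.typeAtoms <- function(mol) {
  n <- mol$n
  types <- character(n)
  hTypes <- vector("list", n)
  el <- mol$elements
  arom <- mol$aromAtom
  for (i in seq_len(n)) {
    if (el[i] == "H") { types[i] <- ""; next }
    heavy <- mol$nbrs[[i]][el[mol$nbrs[[i]]] != "H"]
    ho <- mol$border[[i]][el[mol$nbrs[[i]]] != "H"]
    types[i] <- switch(el[i],
      C = .typeCarbon(mol, i, heavy, ho),
      N = .typeNitrogen(mol, i, heavy, ho),
      O = .typeOxygen(mol, i, heavy, ho),
      S = if (mol$charges[i] != 0 ||
              any(ho == 2 & el[heavy] %in% c("N", "O", "P", "S"))) "S2"
          else if (arom[i]) "S3" else "S1",
      P = "P",
      F = if (mol$charges[i] < 0) "Hal" else "F",
      Cl = if (mol$charges[i] < 0) "Hal" else "Cl",
      Br = if (mol$charges[i] < 0) "Hal" else "Br",
      I = if (mol$charges[i] != 0) "Hal" else "I",
      .typeOther(el[i], mol$charges[i])
    )
    nh <- mol$nH[i] + sum(el[mol$nbrs[[i]]] == "H")
    if (nh > 0) hTypes[[i]] <- rep(.typeHydrogen(mol, i), nh)
  }
  list(types = types, hTypes = hTypes)
}

.typeOther <- function(elm, charge) {
  z <- .ELEMENT_Z[elm]
  if (is.na(z)) return(NA_character_)
  if (charge > 0 && z %in% c(3, 11, 19, 37, 55)) return("Hal")
  if (z %in% .ME1_Z) return("Me1")
  if (z %in% .ME2_Z) return("Me2")
  NA_character_
}

.typeCarbon <- function(mol, i, heavy, ho) {
  el <- mol$elements
  arom <- mol$aromAtom
  nH <- mol$nH[i] + sum(el[mol$nbrs[[i]]] == "H")
  if (arom[i]) {
    hel <- el[heavy]
    alPartner <- heavy[!arom[heavy]]
    if (nH == 0 && any(!(el[alPartner] %in% c("C", "N", "O", "S", .HETERO_AL))))
      return("C13")
    if (any(hel == "F")) return("C14")
    if (any(hel == "Cl")) return("C15")
    if (any(hel == "Br")) return("C16")
    if (any(hel == "I")) return("C17")
    if (nH > 0) return("C18")
    ## third substituent beyond the two in-ring aromatic bonds
    aromNbr <- arom[heavy]
    aromBondToNbr <- vapply(seq_along(heavy), function(k) {
      a <- i; b <- heavy[k]
      any(mol$aromBond[(mol$bonds[, 1] == a & mol$bonds[, 2] == b) |
                         (mol$bonds[, 1] == b & mol$bonds[, 2] == a)])
    }, logical(1))
    ext <- which(!aromBondToNbr)
    if (!length(ext)) return("C19")          # three aromatic ring bonds
    k <- ext[1]
    x <- heavy[k]
    if (ho[k] == 2) {
      if (el[x] %in% c("C", "N", "O")) return("C25")
      return("CS")
    }
    if (arom[x]) return("C20")
    if (el[x] == "C") return("C21")
    if (el[x] == "N") return("C22")
    if (el[x] == "O") return("C23")
    if (el[x] == "S") return("C24")
    return("CS")
  }
  dbl <- which(ho == 2); trp <- which(ho == 3)
  if (length(trp)) {
    if (length(heavy) <= 2 && !arom[heavy[trp[1]]]) return("C7")
    return("CS")
  }
  if (length(dbl)) {
    dTo <- heavy[dbl]
    if (any(el[dTo] != "C" & !arom[dTo])) return("C5")
    others <- setdiff(seq_along(heavy), dbl)
    othersAl <- !arom[heavy[others]]
    if (length(dbl) >= 2 && all(el[dTo] == "C") && all(!arom[dTo]))
      return("C6")                            # allene C(=C)=C
    if (all(!arom[dTo])) {                    # =C aliphatic
      if (nH == 2 && !length(others)) return("C6")
      if (nH == 1 && length(others) == 1 && othersAl[1]) return("C6")
      if (nH == 0 && length(others) == 2 && all(othersAl)) return("C6")
      if (any(arom[heavy[others]])) return("C26")
      return("CS")
    }
    if (any(arom[dTo])) return("C26")         # C=c exocyclic to aromatic ring
    return("CS")
  }
  ## sp3
  hel <- el[heavy]; hArom <- arom[heavy]
  allAlC <- length(heavy) > 0 && all(hel == "C" & !hArom)
  if (nH == 4) return("C1")
  if (nH == 3 && length(heavy) == 1 && allAlC) return("C1")
  if (nH == 2 && length(heavy) == 2 && allAlC) return("C1")
  if (nH <= 1 && length(heavy) == (4 - nH) && allAlC) return("C2")
  het <- hel %in% .HETERO_AL & !hArom
  alOther <- !hArom
  if (nH == 3 && length(heavy) == 1 && het[1]) return("C3")
  if (nH == 2 && length(heavy) == 2 && any(het) && all(alOther)) return("C3")
  if (nH <= 1 && length(heavy) == (4 - nH) && any(het) && all(alOther)) return("C4")
  if (nH == 3 && length(heavy) == 1 && hArom[1])
    return(if (hel[1] == "C") "C8" else "C9")
  if (any(hArom)) {
    if (nH == 2) return("C10")
    if (nH == 1) return("C11")
    if (nH == 0) return("C12")
  }
  if (any(!hArom & !(hel %in% c("C", .HETERO_AL)))) return("C27")
  "CS"
}

.typeNitrogen <- function(mol, i, heavy, ho) {
  el <- mol$elements; arom <- mol$aromAtom
  ch <- mol$charges[i]
  nH <- mol$nH[i] + sum(el[mol$nbrs[[i]]] == "H")
  if (arom[i]) return(if (ch > 0) "N12" else "N11")
  if (ch < 0) return("N14")
  if (ch > 0) {
    if (any(ho == 3)) return("N14")
    if (nH > 0) return("N10")
    return("N13")
  }
  if (any(ho == 3)) return("N9")
  dbl <- which(ho == 2)
  if (length(dbl)) {
    if (nH >= 1) return("N5")
    if (length(heavy) >= 2) return("N6")
    return("NS")
  }
  hasAr <- any(arom[heavy])
  if (nH == 2 && length(heavy) == 1) return(if (hasAr) "N3" else "N1")
  if (nH == 1 && length(heavy) == 2) return(if (hasAr) "N4" else "N2")
  if (nH == 0 && length(heavy) == 3) return(if (hasAr) "N8" else "N7")
  "NS"
}

.typeOxygen <- function(mol, i, heavy, ho) {
  el <- mol$elements; arom <- mol$aromAtom
  ch <- mol$charges[i]
  nH <- mol$nH[i] + sum(el[mol$nbrs[[i]]] == "H")
  if (arom[i]) return("O1")
  if (nH >= 1) return("O2")
  if (ch < 0) {
    if (length(heavy) == 1) {
      w <- heavy[1]
      if (el[w] == "N") return("O5")
      if (el[w] == "S") return("O6")
      if (el[w] == "C") {
        wd <- mol$nbrs[[w]][mol$border[[w]] == 2]
        if (any(el[wd] == "O")) return("O12")   # carboxylate
      }
      if (!(el[w] %in% c("N", "S"))) return("O7")
    }
    return("O7")
  }
  dbl <- which(ho == 2)
  if (length(dbl)) {
    w <- heavy[dbl[1]]
    if (el[w] %in% c("N", "O")) return("O5")
    if (el[w] == "S") return("O6")
    if (el[w] == "C" && arom[w]) return("O8")
    if (el[w] == "C") {
      ## classify the carbonyl by the carbon's other substituents
      oth <- mol$nbrs[[w]][mol$nbrs[[w]] != i]
      oth <- oth[el[oth] != "H"]
      othH <- mol$nH[w] + sum(el[mol$nbrs[[w]]] == "H")
      oel <- el[oth]; oar <- arom[oth]
      if (othH > 0) {
        if (any(oar)) return("O10")
        return("O9")                            # aldehydes, formamide-like
      }
      if (any(oar) && any(oel == "C")) return("O10")
      if (any(oar) && any(oel %in% c("C"))) return("O10")
      if (any(oar)) {
        if (all(!(oel %in% c("C")))) return("O11") else return("O10")
      }
      if (any(oel == "C")) return("O9")
      if (length(oth) && all(!(oel %in% c("C")))) return("O11")
      return("O9")
    }
    return("OS")
  }
  if (length(heavy) == 2) {
    if (any(arom[heavy])) return("O4")
    return("O3")
  }
  "OS"
}

.typeHydrogen <- function(mol, i) {
  el <- mol$elements
  elm <- el[i]
  if (elm == "C") return("H1")
  if (elm == "N") return("H3")
  if (elm == "O") {
    heavy <- mol$nbrs[[i]][el[mol$nbrs[[i]]] != "H"]
    if (!length(heavy)) return("HS")
    w <- heavy[1]
    if (el[w] == "N") return("H3")
    if (el[w] %in% c("O", "S")) return("H4")
    if (el[w] == "C") {
      if (mol$aromAtom[w]) return("H2")          # phenol
      wd <- which(mol$border[[w]] == 2)
      if (length(wd)) {
        dTo <- mol$nbrs[[w]][wd]
        if (any(el[dTo] %in% c("C", "N", "O", "S"))) return("H4")  # acids/enols
      }
      con <- length(mol$nbrs[[w]]) + mol$nH[w]
      if (con == 4) return("H2")                 # alcohol on sp3 carbon
      return("HS")
    }
    if (!(el[w] %in% c("C", "N", "O", "S"))) return("H2")
    return("HS")
  }
  if (!(elm %in% c("C", "N", "O"))) return("H2")
  "HS"
}

## ---------------------------------------------------------------------------

#' Wildman-Crippen logP of a molecular graph
#'
#' Computes the octanol/water partition coefficient by summing published
#' atomic contributions over typed heavy atoms and their (implicit) hydrogens.
#' Deterministic: the same graph always yields the same value.
#'
#' @param mol an internal molecular graph (see \code{.molFromSDF}).
#' @param details if \code{TRUE}, also return the per-atom types.
#' @return numeric logP estimate (dimensionless), or a list when
#'   \code{details = TRUE}.
#' @keywords internal
.wcLogP <- function(mol, details = FALSE) {
  tp <- .typeAtoms(mol)
  heavyTypes <- tp$types[mol$elements != "H"]
  if (anyNA(heavyTypes)) {
    warning("atoms of unparameterized elements contribute 0 to logP")
    heavyTypes <- heavyTypes[!is.na(heavyTypes)]
  }
  hts <- unlist(tp$hTypes)
  total <- sum(.WC_LOGP[heavyTypes]) + if (length(hts)) sum(.WC_LOGP[hts]) else 0
  if (details) list(logp = total, types = tp$types, hTypes = tp$hTypes)
  else as.numeric(total)
}
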