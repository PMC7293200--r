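#' Molecular graphs
#'
#' Molecules are hydrogen-suppressed coloured graphs: a data frame of heavy
#' atoms (element, aromatic flag, formal charge, implicit/explicit hydrogen
#' count, atom-map number) plus a data frame of bonds with orders 1, 2, 3 or
#' 1.5 (aromatic).  They are read from a pragmatic subset of SMILES: the
#' organic subset plus bracket atoms with charge, hydrogen count and atom-map
#' class; ring closures (including `%nn`); branches; dot-separated components.
#' Stereo markers (`/ \ @`) and isotopes are accepted and ignored.
#' Aromaticity is taken from the notation (lowercase atoms / `:` bonds);
#' kekulized input is not re-perceived as aromatic.
#'
#' @param smiles a single SMILES string
#' @return an object of class `rxv_mol`
#' @examples
#' m <- mol_from_smiles("CC(=O)Nc1ccccc1")
#' m
#' canonical_smiles(m)
#' @seealso [canonical_smiles()], [mol_id()], [molecule_descriptor()]
#' @export
mol_from_smiles <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L, !is.na(smiles))
  s <- gsub("[[:space:]]", "", smiles)
  element <- character(); aromatic <- logical(); charge <- integer()
  hcount <- integer(); map <- integer()
  b1 <- integer(); b2 <- integer(); bord <- numeric()
  n_atom <- 0L
  prev <- 0L                      # index of atom to bond the next atom to
  stack <- integer()
  rings <- list()                 # ring-closure id -> list(atom, order)
  pend <- NA_real_                # pending bond order symbol
  add_atom <- function(el, arom, chg, hc, mp) {
    n_atom <<- n_atom + 1L
    element[n_atom] <<- el; aromatic[n_atom] <<- arom
    charge[n_atom] <<- chg; hcount[n_atom] <<- hc; map[n_atom] <<- mp
    if (prev > 0L) {
      o <- pend
      if (is.na(o)) o <- if (aromatic[prev] && arom) 1.5 else 1
      b1[length(b1) + 1L] <<- prev; b2[length(b2) + 1L] <<- n_atom
      bord[length(bord) + 1L] <<- o
    }
    prev <<- n_atom
    pend <<- NA_real_
  }
  close_ring <- function(id) {
    if (is.null(rings[[id]])) {
      rings[[id]] <<- list(atom = prev, order = pend)
    } else {
      opened <- rings[[id]]
      o <- pend
      if (is.na(o)) o <- opened$order
      if (is.na(o)) o <- if (aromatic[opened$atom] && aromatic[prev]) 1.5 else 1
      b1[length(b1) + 1L] <<- opened$atom; b2[length(b2) + 1L] <<- prev
      bord[length(bord) + 1L] <<- o
      rings[[id]] <<- NULL
    }
    pend <<- NA_real_
  }
  i <- 1L; nc <- nchar(s)
  organic2 <- c("Cl", "Br")
  organic1 <- c("B", "C", "N", "O", "P", "S", "F", "I")
  aromatic1 <- c("b", "c", "n", "o", "p", "s")
  while (i <= nc) {
    ch <- substr(s, i, i)
    ch2 <- if (i < nc) substr(s, i, i + 1L) else ""
    if (ch == "(") { stack <- c(stack, prev); i <- i + 1L }
    else if (ch == ")") {
      if (length(stack) == 0L) stop("unbalanced ')' in SMILES: ", smiles)
      prev <- stack[length(stack)]; stack <- stack[-length(stack)]; i <- i + 1L
    }
    else if (ch == ".") { prev <- 0L; pend <- NA_real_; i <- i + 1L }
    else if (ch == "-") { pend <- 1; i <- i + 1L }
    else if (ch == "=") { pend <- 2; i <- i + 1L }
    else if (ch == "#") { pend <- 3; i <- i + 1L }
    else if (ch == ":") { pend <- 1.5; i <- i + 1L }
    else if (ch == "/" || ch == "\\") { pend <- 1; i <- i + 1L }
    else if (grepl("^[0-9]$", ch)) { close_ring(ch); i <- i + 1L }
    else if (ch == "%") {
      id <- substr(s, i + 1L, i + 2L)
      if (!grepl("^[0-9]{2}$", id)) stop("bad ring closure '%' in SMILES: ", smiles)
      close_ring(id); i <- i + 3L
    }
    else if (ch == "[") {
      j <- regexpr("]", substr(s, i, nc), fixed = TRUE)
      if (j < 0) stop("unclosed bracket atom in SMILES: ", smiles)
      body <- substr(s, i + 1L, i + j - 2L)
      m <- regexec("^([0-9]+)?([A-Za-z][a-z]?|\\*)(@+[A-Z]*)?(H[0-9]*)?([+-]+[0-9]*)?(:[0-9]+)?$",
                   body)
      g <- regmatches(body, m)[[1]]
      if (length(g) == 0L) stop("cannot parse bracket atom [", body, "]")
      sym <- g[3]
      arom <- grepl("^[a-z]", sym)
      el <- paste0(toupper(substr(sym, 1, 1)), substr(sym, 2, nchar(sym)))
      hc <- if (g[5] == "") 0L
            else if (g[5] == "H") 1L
            else as.integer(sub("H", "", g[5]))
      chg <- 0L
      if (g[6] != "") {
        sgn <- if (substr(g[6], 1, 1) == "+") 1L else -1L
        num <- gsub("[+-]", "", g[6])
        chg <- if (nzchar(num)) sgn * as.integer(num)
               else sgn * nchar(gsub("[0-9]", "", g[6]))
      }
      mp <- if (g[7] == "") 0L else as.integer(sub(":", "", g[7]))
      add_atom(el, arom, chg, hc, mp)
      i <- i + j
    }
    else if (ch2 %in% organic2) { add_atom(ch2, FALSE, 0L, NA_integer_, 0L); i <- i + 2L }
    else if (ch %in% organic1) { add_atom(ch, FALSE, 0L, NA_integer_, 0L); i <- i + 1L }
    else if (ch %in% aromatic1) { add_atom(toupper(ch), TRUE, 0L, NA_integer_, 0L); i <- i + 1L }
    else stop("unexpected character '", ch, "' in SMILES: ", smiles)
  }
  if (length(stack) > 0L) stop("unbalanced '(' in SMILES: ", smiles)
  if (length(Filter(Negate(is.null), rings)) > 0L)
    stop("unclosed ring bond in SMILES: ", smiles)
  mol <- structure(list(
    atoms = data.frame(element = element, aromatic = aromatic, charge = charge,
                       hcount = hcount, map = map, stringsAsFactors = FALSE),
    bonds = data.frame(a1 = b1, a2 = b2, order = bord)
  ), class = "rxv_mol")
  fill_hydrogens(mol)
}

# Allowed valences by element; formal charge is added to each allowed value
# (N+ -> 4, O- -> 1, ...).  The smallest allowed valence that accommodates
# the bond-order sum is used to derive implicit hydrogen counts.
.valences <- list(B = 3, C = 4, N = c(3, 5), O = 2, P = c(3, 5),
                  S = c(2, 4, 6), F = 1, Cl = 1, Br = 1, I = 1, H = 0,
                  Si = 4, Se = c(2, 4, 6))

# Integer valence consumption per atom.  Non-aromatic bonds contribute their
# order.  Aromatic bonds contribute per element: carbon uses floor(1.5 * n)
# (benzene C -> 3, ring-fusion C -> 4); nitrogen/phosphorus n + 1
# (pyridine-type, pi-bond donor); oxygen/sulfur n (lone-pair donor).
bond_order_sums <- function(mol) {
  n <- nrow(mol$atoms)
  plain <- numeric(n); narom <- integer(n)
  if (nrow(mol$bonds)) {
    for (k in seq_len(nrow(mol$bonds))) {
      i <- mol$bonds$a1[k]; j <- mol$bonds$a2[k]; o <- mol$bonds$order[k]
      if (o == 1.5) { narom[i] <- narom[i] + 1L; narom[j] <- narom[j] + 1L }
      else { plain[i] <- plain[i] + o; plain[j] <- plain[j] + o }
    }
  }
  el <- mol$atoms$element
  ar_contrib <- ifelse(narom == 0L, 0,
                ifelse(el %in% c("O", "S"), narom,
                ifelse(el %in% c("N", "P"), narom + 1L, floor(1.5 * narom))))
  ceiling(plain + ar_contrib)
}

# Fill implicit hydrogen counts (atoms with hcount NA, or the given subset).
# Returns the molecule, or NULL if an atom exceeds its maximum valence (used
# as a validity signal by the structure generator).
fill_hydrogens <- function(mol, atoms = NULL, strict = TRUE) {
  bs <- bond_order_sums(mol)
  idx <- if (is.null(atoms)) which(is.na(mol$atoms$hcount)) else atoms
  for (i in idx) {
    el <- mol$atoms$element[i]
    vals <- .valences[[el]]
    if (is.null(vals)) {
      if (strict) stop("unknown element: ", el)
      return(NULL)
    }
    vals <- vals + mol$atoms$charge[i]
    ok <- vals[vals >= bs[i]]
    if (length(ok) == 0L) {
      if (strict) stop("valence of ", el, " exceeded (bond order sum ", bs[i], ")")
      return(NULL)
    }
    mol$atoms$hcount[i] <- as.integer(min(ok) - bs[i])
  }
  mol
}

#' @export
print.rxv_mol <- function(x, ...) {
  cat("<molecule> ", canonical_smiles(x), "  (", nrow(x$atoms), " heavy atoms, ",
      nrow(x$bonds), " bonds)\n", sep = "")
  invisible(x)
}

#' Number of heavy atoms / carbon atoms
#' @param mol an `rxv_mol`
#' @return an integer count
#' @export
n_heavy_atoms <- function(mol) nrow(mol$atoms)

#' @rdname n_heavy_atoms
#' @export
n_carbons <- function(mol) sum(mol$atoms$element == "C")

# Heavy-atom degree vector.
atom_degrees <- function(mol) {
  n <- nrow(mol$atoms)
  if (n == 0L) return(integer(0))
  tabulate(c(mol$bonds$a1, mol$bonds$a2), nbins = n)
}

# Neighbour (adjacency) list: for each atom, data frame of (nbr, order).
adjacency <- function(mol) {
  n <- nrow(mol$atoms)
  adj <- vector("list", n)
  for (i in seq_len(n)) adj[[i]] <- list(nbr = integer(), order = numeric())
  if (nrow(mol$bonds)) {
    for (k in seq_len(nrow(mol$bonds))) {
      i <- mol$bonds$a1[k]; j <- mol$bonds$a2[k]; o <- mol$bonds$order[k]
      adj[[i]]$nbr <- c(adj[[i]]$nbr, j); adj[[i]]$order <- c(adj[[i]]$order, o)
      adj[[j]]$nbr <- c(adj[[j]]$nbr, i); adj[[j]]$order <- c(adj[[j]]$order, o)
    }
  }
  adj
}

# Connected-component id per atom.
component_ids <- function(mol) {
  n <- nrow(mol$atoms)
  comp <- integer(n)
  adj <- adjacency(mol)
  cid <- 0L
  for (start in seq_len(n)) {
    if (comp[start] != 0L) next
    cid <- cid + 1L
    queue <- start
    comp[start] <- cid
    while (length(queue)) {
      a <- queue[1]; queue <- queue[-1]
      for (nb in adj[[a]]$nbr) if (comp[nb] == 0L) { comp[nb] <- cid; queue <- c(queue, nb) }
    }
  }
  comp
}

# Induced subgraph on a set of atom indices (attributes preserved).
mol_subset <- function(mol, atoms) {
  atoms <- sort(unique(atoms))
  newidx <- match(seq_len(nrow(mol$atoms)), atoms)
  keep <- !is.na(newidx[mol$bonds$a1]) & !is.na(newidx[mol$bonds$a2])
  structure(list(
    atoms = mol$atoms[atoms, , drop = FALSE],
    bonds = data.frame(a1 = newidx[mol$bonds$a1[keep]],
                       a2 = newidx[mol$bonds$a2[keep]],
                       order = mol$bonds$order[keep])
  ), class = "rxv_mol")
}

#' Split a multi-component molecule into its connected components
#' @param mol an `rxv_mol`
#' @return a list of `rxv_mol`, one per component, in order of appearance
#' @export
mol_components <- function(mol) {
  comp <- component_ids(mol)
  if (length(comp) == 0L) return(list())
  lapply(seq_len(max(comp)), function(k) mol_subset(mol, which(comp == k)))
}

#' Combine molecules into one (disconnected) graph
#' @param ... `rxv_mol` objects
#' @return a single `rxv_mol` whose components are the inputs, in order
#' @export
mol_combine <- function(...) {
  mols <- Filter(Negate(is.null), list(...))
  atoms <- do.call(rbind, lapply(mols, `[[`, "atoms"))
  off <- cumsum(c(0L, vapply(mols, n_heavy_atoms, integer(1))))
  bonds <- do.call(rbind, lapply(seq_along(mols), function(i) {
    b <- mols[[i]]$bonds
    if (nrow(b)) data.frame(a1 = b$a1 + off[i], a2 = b$a2 + off[i], order = b$order)
    else b
  }))
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, bonds = bonds), class = "rxv_mol")
}

## ---- canonicalization -----------------------------------------------------

# Iterative refinement of atom ranks: the initial invariant covers element,
# aromaticity, charge, hydrogen count and degree; each sweep appends the
# sorted (bond order, neighbour rank) signature until the partition is stable.
refine_ranks <- function(adj, inv0, ranks) {
  n <- length(ranks)
  repeat {
    sig <- vapply(seq_len(n), function(i) {
      nb <- adj[[i]]
      if (length(nb$nbr) == 0L) return(sprintf("%04d|", ranks[i]))
      pieces <- sprintf("%.1f:%04d", nb$order, ranks[nb$nbr])
      sprintf("%04d|%s", ranks[i], paste(sort_c(pieces), collapse = ","))
    }, character(1))
    new <- match(sig, sort_c(unique(sig)))
    if (length(unique(new)) == length(unique(ranks))) return(new)
    ranks <- new
  }
}

# Serialize a rank permutation into a graph certificate string (atoms in rank
# order plus rank-space bond list); used to select among tie-break branches.
rank_certificate <- function(mol, inv0, ranks) {
  perm <- order(ranks)
  atom_part <- paste(inv0[perm], collapse = ";")
  if (nrow(mol$bonds)) {
    r1 <- ranks[mol$bonds$a1]; r2 <- ranks[mol$bonds$a2]
    lo <- pmin(r1, r2); hi <- pmax(r1, r2)
    bs <- sprintf("%04d-%.1f-%04d", lo, mol$bonds$order, hi)
    bond_part <- paste(sort_c(bs), collapse = ";")
  } else bond_part <- ""
  paste(atom_part, bond_part, sep = "##")
}

# Canonical atom ranks by individualization-refinement: refine; if classes
# remain, branch on every atom of the smallest tied class and keep the branch
# with the bytewise-smallest certificate.  Complete (order-invariant) because
# all atoms of an orbit candidate class are explored.
canonical_ranks <- function(mol) {
  n <- nrow(mol$atoms)
  if (n == 0L) return(integer(0))
  adj <- adjacency(mol)
  a <- mol$atoms
  inv0 <- paste(a$element, as.integer(a$aromatic), a$charge, a$hcount,
                atom_degrees(mol), sep = "_")
  ranks0 <- match(inv0, sort_c(unique(inv0)))
  rec <- function(ranks) {
    ranks <- refine_ranks(adj, inv0, ranks)
    tab <- table(ranks)
    tied <- as.integer(names(tab)[tab > 1])
    if (length(tied) == 0L) return(ranks)
    cls <- min(tied)
    members <- which(ranks == cls)
    best <- NULL; best_cert <- NULL
    for (aidx in members) {
      r2 <- ranks
      r2[aidx] <- r2[aidx] - 0.5
      r2 <- match(r2, sort(unique(r2)))
      out <- rec(r2)
      cert <- rank_certificate(mol, inv0, out)
      if (is.null(best_cert) || sort_c(c(cert, best_cert))[1] == cert && cert != best_cert) {
        best <- out; best_cert <- cert
      }
    }
    best
  }
  rec(ranks0)
}

## ---- SMILES writing -------------------------------------------------------

.organic_subset <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")

# Token for one atom, bracketing only when required.
atom_token <- function(mol, i, keep_maps = FALSE) {
  a <- mol$atoms[i, ]
  sym <- if (a$aromatic) tolower(a$element) else a$element
  need_bracket <- a$charge != 0L || (keep_maps && a$map > 0L) ||
    !(a$element %in% .organic_subset)
  if (!need_bracket) {
    # would the organic-subset valence rule reproduce the stored H count?
    bs <- bond_order_sums(mol)[i]
    vals <- .valences[[a$element]]
    ok <- vals[vals >= bs]
    imp <- if (length(ok)) min(ok) - bs else -1
    if (imp != a$hcount) need_bracket <- TRUE
  }
  if (!need_bracket) return(sym)
  h <- if (a$hcount == 0L) "" else if (a$hcount == 1L) "H" else paste0("H", a$hcount)
  chg <- if (a$charge == 0L) ""
         else if (a$charge == 1L) "+"
         else if (a$charge == -1L) "-"
         else if (a$charge > 1L) paste0("+", a$charge)
         else paste0("-", abs(a$charge))
  mp <- if (keep_maps && a$map > 0L) paste0(":", a$map) else ""
  paste0("[", sym, h, chg, mp, "]")
}

bond_token <- function(mol, i, j, order) {
  arom_pair <- mol$atoms$aromatic[i] && mol$atoms$aromatic[j]
  if (order == 1) { if (arom_pair) "-" else "" }
  else if (order == 1.5) { if (arom_pair) "" else ":" }
  else if (order == 2) "="
  else if (order == 3) "#"
  else stop("bad bond order ", order)
}

write_component <- function(mol, atoms_in, ranks, keep_maps) {
  adj <- adjacency(mol)
  root <- atoms_in[which.min(ranks[atoms_in])]
  visited <- rep(FALSE, nrow(mol$atoms))
  ring_open <- list()          # "i-j" key -> digit
  ring_cnt <- 0L
  # first pass: build a rank-determined DFS spanning tree; the remaining
  # edges become ring closures.  emit() then follows exactly this tree.
  tree_child <- vector("list", nrow(mol$atoms))
  ring_at <- vector("list", nrow(mol$atoms))   # atom -> list of c(other, order)
  seen_edge <- character()
  visited[root] <- TRUE
  dfs <- function(a) {
    nb <- adj[[a]]
    ord <- order(ranks[nb$nbr])
    for (t in ord) {
      j <- nb$nbr[t]; o <- nb$order[t]
      ekey <- paste(min(a, j), max(a, j))
      if (ekey %in% seen_edge) next
      seen_edge <<- c(seen_edge, ekey)
      if (!visited[j]) {
        visited[j] <<- TRUE
        tree_child[[a]] <<- c(tree_child[[a]], j)
        dfs(j)
      } else {
        ring_at[[a]] <<- c(ring_at[[a]], list(c(j, o)))
        ring_at[[j]] <<- c(ring_at[[j]], list(c(a, o)))
      }
    }
  }
  dfs(root)
  visited2 <- rep(FALSE, nrow(mol$atoms))
  digit_for <- function() {
    ring_cnt <<- ring_cnt + 1L
    if (ring_cnt <= 9L) as.character(ring_cnt) else sprintf("%%%02d", ring_cnt)
  }
  emit <- function(a, parent, bond_o) {
    visited2[a] <<- TRUE
    out <- if (parent > 0L) bond_token(mol, parent, a, bond_o) else ""
    out <- paste0(out, atom_token(mol, a, keep_maps))
    # ring closures at this atom
    for (rc in ring_at[[a]]) {
      other <- rc[1]; o <- rc[2]
      ekey <- paste(min(a, other), max(a, other))
      if (is.null(ring_open[[ekey]])) {
        d <- digit_for()
        ring_open[[ekey]] <<- d
        out <- paste0(out, bond_token(mol, a, other, o), d)
      } else {
        out <- paste0(out, bond_token(mol, a, other, o), ring_open[[ekey]])
      }
    }
    kids <- tree_child[[a]]
    if (length(kids) > 1L) kids <- kids[order(ranks[kids])]
    for (t in seq_along(kids)) {
      j <- kids[t]
      o <- adj[[a]]$order[match(j, adj[[a]]$nbr)]
      sub <- emit(j, a, o)
      if (t < length(kids)) out <- paste0(out, "(", sub, ")")
      else out <- paste0(out, sub)
    }
    out
  }
  emit(root, 0L, 0)
}

#' Write a molecule as SMILES
#'
#' @param mol an `rxv_mol`
#' @param canonical use canonical atom ranks (the default); otherwise input order
#' @param keep_maps write atom-map numbers (`[CH3:1]`) when present
#' @return a SMILES string; components are dot-joined in byte order of their
#'   component strings when canonical
#' @export
mol_to_smiles <- function(mol, canonical = TRUE, keep_maps = FALSE) {
  if (nrow(mol$atoms) == 0L) return("")
  ranks <- if (canonical) canonical_ranks(mol) else seq_len(nrow(mol$atoms))
  comp <- component_ids(mol)
  parts <- vapply(seq_len(max(comp)), function(k) {
    write_component(mol, which(comp == k), ranks, keep_maps)
  }, character(1))
  if (canonical) parts <- sort_c(parts)
  paste(parts, collapse = ".")
}

#' Canonical SMILES and canonical identifier
#'
#' `canonical_smiles()` returns an order-invariant SMILES string computed via
#' individualization-refinement canonical atom ranking.  `mol_id()` is the
#' package's canonical identifier: the canonical SMILES with atom maps
#' stripped.  It is a pure function of the structure and is used for all
#' deduplication (training entries, product libraries, rediscovery checks).
#'
#' @param mol an `rxv_mol` (for `mol_id`, alternatively a SMILES string)
#' @return a character scalar
#' @export
canonical_smiles <- function(mol) mol_to_smiles(mol, canonical = TRUE, keep_maps = FALSE)

#' @rdname canonical_smiles
#' @export
mol_id <- function(mol) {
  if (is.character(mol)) mol <- mol_from_smiles(mol)
  canonical_smiles(mol)
}
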