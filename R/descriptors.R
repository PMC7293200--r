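#' Atom typing for atom-pair descriptors
#'
#' Atoms are typed by the Carhart-style triple (element, heavy-atom degree,
#' pi attachment count).  Hydrogens are never typed; the heavy degree is the
#' number of non-hydrogen neighbours in the parent molecule.  The pi count is
#' the number of pi electrons contributed by incident bonds: 1 per double
#' bond, 2 per triple bond, and 1 if the atom carries any aromatic bond.
#'
#' @param mol an `rxv_mol`
#' @param atom_index 1-based heavy-atom index
#' @return a list with `element`, `heavy_degree`, `pi_count` and the packed
#'   type string `"element.degree.pi"`
#' @examples
#' atom_type(mol_from_smiles("CC(C)=O"), 2)  # acetone carbonyl: C, 3, 1
#' @export
atom_type <- function(mol, atom_index) {
  n <- nrow(mol$atoms)
  if (!(is.numeric(atom_index) && length(atom_index) == 1L &&
        atom_index >= 1 && atom_index <= n))
    stop("atom_index must be a single index in 1..", n)
  ts <- type_strings(mol)[atom_index]
  parts <- strsplit(ts, ".", fixed = TRUE)[[1]]
  list(element = parts[1], heavy_degree = as.integer(parts[2]),
       pi_count = as.integer(parts[3]), type = ts)
}

# Vector of packed type strings "element.degree.pi" for all atoms.
type_strings <- function(mol) {
  n <- nrow(mol$atoms)
  if (n == 0L) return(character(0))
  deg <- atom_degrees(mol)
  ndb <- integer(n); ntr <- integer(n); nar <- integer(n)
  if (nrow(mol$bonds)) {
    for (k in seq_len(nrow(mol$bonds))) {
      i <- mol$bonds$a1[k]; j <- mol$bonds$a2[k]; o <- mol$bonds$order[k]
      if (o == 2) { ndb[i] <- ndb[i] + 1L; ndb[j] <- ndb[j] + 1L }
      else if (o == 3) { ntr[i] <- ntr[i] + 1L; ntr[j] <- ntr[j] + 1L }
      else if (o == 1.5) { nar[i] <- nar[i] + 1L; nar[j] <- nar[j] + 1L }
    }
  }
  pi <- ndb + 2L * ntr + as.integer(nar > 0L)
  paste(mol$atoms$element, deg, pi, sep = ".")
}

# Single-character bond-order codes used inside feature keys.
bond_code <- function(order) {
  out <- character(length(order))
  out[order == 1] <- "1"; out[order == 2] <- "2"
  out[order == 3] <- "3"; out[order == 1.5] <- "a"
  if (any(out == "")) stop("bad bond order in molecule")
  out
}

#' Path-descriptor multisets (AP2 / AP3)
#'
#' Enumerates all simple heavy-atom paths of 2 atoms (AP2: one per bond) or
#' 3 atoms (AP3: one per pair of adjacent bonds, i.e. per angle), types the
#' atoms along the path, and returns the multiset of canonically oriented
#' path features.  A feature key reads
#' `"2:type,bond,type"` or `"3:type,bond,type,bond,type"`, where types are
#' `element.degree.pi` and bond codes are `1`, `2`, `3` or `a` (aromatic);
#' of the two reading directions the bytewise-smaller one is stored.
#'
#' @param mol an `rxv_mol`
#' @param length path length in atoms: 2 or 3
#' @return a descriptor multiset (see [ms()]); all counts positive
#' @examples
#' path_descriptor_multiset(mol_from_smiles("CCO"), 3)
#' @export
path_descriptor_multiset <- function(mol, length) {
  if (!(is.numeric(length) && length(length) == 1L && length %in% c(2, 3)))
    stop("path length must be 2 or 3")
  t <- type_strings(mol)
  if (length == 2) {
    if (nrow(mol$bonds) == 0L) return(ms())
    t1 <- t[mol$bonds$a1]; t2 <- t[mol$bonds$a2]
    o <- bond_code(mol$bonds$order)
    fwd <- t1 <= t2    # bytewise order of type strings is ASCII-only, locale-safe
    keys <- ifelse(fwd, paste0("2:", t1, ",", o, ",", t2),
                        paste0("2:", t2, ",", o, ",", t1))
    return(ms(keys, 1))
  }
  adj <- adjacency(mol)
  keys <- character(0)
  for (j in seq_len(nrow(mol$atoms))) {
    nb <- adj[[j]]
    d <- length(nb$nbr)
    if (d < 2L) next
    for (u in seq_len(d - 1L)) for (v in seq((u + 1L), d)) {
      i <- nb$nbr[u]; k <- nb$nbr[v]
      o1 <- bond_code(nb$order[u]); o2 <- bond_code(nb$order[v])
      fwd <- paste0(t[i], ",", o1) <= paste0(t[k], ",", o2)
      keys[length(keys) + 1L] <- if (fwd)
        paste0("3:", t[i], ",", o1, ",", t[j], ",", o2, ",", t[k])
      else
        paste0("3:", t[k], ",", o2, ",", t[j], ",", o1, ",", t[i])
    }
  }
  if (length(keys) == 0L) return(ms())
  ms(keys, 1)
}

#' Whole-molecule AP2+AP3 descriptor multiset
#'
#' The disjoint union of the AP2 and AP3 multisets (keys are tagged by path
#' length, so the union is automatically disjoint).  For a multi-component
#' molecule this equals the sum over components: paths never cross
#' components.  An empty molecule gives the empty multiset.
#'
#' @param mol an `rxv_mol`
#' @return a descriptor multiset
#' @export
molecule_descriptor <- function(mol) {
  ms_add(path_descriptor_multiset(mol, 2), path_descriptor_multiset(mol, 3))
}

#' Serialize / read a descriptor multiset as JSON
#' @param x a descriptor multiset
#' @param path file path; for `descriptor_from_json`, the file to read
#' @export
descriptor_to_json <- function(x, path) {
  jsonlite::write_json(as.list(x), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname descriptor_to_json
#' @export
descriptor_from_json <- function(path) {
  v <- jsonlite::read_json(path, simplifyVector = TRUE)
  ms(names(v), as.numeric(v))
}
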