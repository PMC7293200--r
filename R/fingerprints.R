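## Whole-molecule fingerprints: a registry of named schemes producing binary
## or count fingerprints.  Bundled schemes:
##   keys166   - 166-key structural dictionary (elements, rings, functional
##               groups, element-level path patterns, atom-type presences)
##   fg        - 36-key functional-group dictionary
##   hashed1024 / hashed2048 / hashed4096
##             - AP2+AP3 feature keys hashed onto n bits
##   circ1 / circ2
##             - feature-class circular environments of radius 1 / 2 (1024 bits)
##   morgan1024c
##             - count fingerprint: typed circular environments of radius 2
##               hashed onto 1024 identifiers (used for similarity retrieval)

.fp_registry <- new.env(parent = emptyenv())

#' Register a fingerprint scheme
#'
#' A scheme is a deterministic function from a molecule to a fixed-length
#' binary fingerprint (type `"binary"`) or a sparse count map (type
#' `"count"`).  Identical structures under the same scheme always give
#' identical fingerprints.
#'
#' @param id scheme identifier
#' @param n_bits fingerprint length (binary) or hash space size (count)
#' @param type `"binary"` or `"count"`
#' @param fun `function(mol)` returning sorted distinct bit indices in
#'   `1..n_bits` (binary) or a named count vector (count)
#' @export
register_fp_scheme <- function(id, n_bits, type = c("binary", "count"), fun) {
  type <- match.arg(type)
  assign(id, list(id = id, n_bits = as.integer(n_bits), type = type, fun = fun),
         envir = .fp_registry)
  invisible(id)
}

ensure_fp_schemes <- function() {
  if (length(ls(.fp_registry)) == 0L) register_builtin_schemes()
}

#' List registered fingerprint schemes
#' @return data frame of scheme id, length and type
#' @export
fp_schemes <- function() {
  ensure_fp_schemes()
  ids <- sort_c(ls(.fp_registry))
  data.frame(
    scheme = ids,
    n_bits = vapply(ids, function(i) get(i, envir = .fp_registry)$n_bits, integer(1)),
    type = vapply(ids, function(i) get(i, envir = .fp_registry)$type, character(1)),
    row.names = NULL)
}

get_scheme <- function(id, type = NULL) {
  ensure_fp_schemes()
  if (!exists(id, envir = .fp_registry))
    stop("unknown fingerprint scheme '", id, "'; registered: ",
         paste(sort_c(ls(.fp_registry)), collapse = ", "))
  sch <- get(id, envir = .fp_registry)
  if (!is.null(type) && sch$type != type)
    stop("scheme '", id, "' is not a ", type, " scheme")
  sch
}

#' Compute a binary fingerprint
#'
#' @param mol an `rxv_mol` or SMILES string
#' @param scheme a registered binary scheme id (see [fp_schemes()])
#' @return object of class `rxv_bfp`: list with `scheme`, `n_bits`, `bits`
#'   (sorted indices of set bits)
#' @examples
#' fp <- binary_fingerprint("CCO", "keys166")
#' @export
binary_fingerprint <- function(mol, scheme) {
  if (is.character(mol)) mol <- mol_from_smiles(mol)
  sch <- get_scheme(scheme, "binary")
  bits <- sort(unique(as.integer(sch$fun(mol))))
  stopifnot(length(bits) <= sch$n_bits)
  structure(list(scheme = sch$id, n_bits = sch$n_bits, bits = bits),
            class = "rxv_bfp")
}

#' @export
print.rxv_bfp <- function(x, ...) {
  cat("<fingerprint ", x$scheme, "> ", length(x$bits), "/", x$n_bits,
      " bits set\n", sep = "")
  invisible(x)
}

#' Compute a count fingerprint
#'
#' @inheritParams binary_fingerprint
#' @param scheme a registered count scheme id (default the radius-2 circular
#'   count scheme used for similarity retrieval)
#' @return object of class `rxv_cfp`: list with `scheme` and `counts`
#' @export
count_fingerprint <- function(mol, scheme = "morgan1024c") {
  if (is.character(mol)) mol <- mol_from_smiles(mol)
  sch <- get_scheme(scheme, "count")
  counts <- sch$fun(mol)
  structure(list(scheme = sch$id, counts = counts[counts > 0]),
            class = "rxv_cfp")
}

#' Euclidean distance between count fingerprints
#'
#' Distance over the union of feature identifiers; 0 exactly when the count
#' maps are identical.  Both fingerprints must come from the same scheme.
#'
#' @param a,b `rxv_cfp` objects
#' @return a non-negative number
#' @export
count_distance <- function(a, b) {
  if (!identical(a$scheme, b$scheme))
    stop("count fingerprints from different schemes: ", a$scheme, " vs ", b$scheme)
  keys <- union(names(a$counts), names(b$counts))
  va <- a$counts[keys]; va[is.na(va)] <- 0
  vb <- b$counts[keys]; vb[is.na(vb)] <- 0
  sqrt(sum((va - vb)^2))
}

## ---- structural facts used by dictionary schemes --------------------------

# Ring perception: an edge is in a ring iff its endpoints stay connected
# without it; the smallest ring through an edge is 1 + the shortest such
# alternative path.  Adequate for the small molecules this package handles.
ring_info <- function(mol) {
  nb <- adjacency(mol)
  n <- nrow(mol$atoms)
  bond_ring_size <- rep(NA_integer_, nrow(mol$bonds))
  atom_in_ring <- rep(FALSE, n)
  if (nrow(mol$bonds)) {
    for (k in seq_len(nrow(mol$bonds))) {
      i <- mol$bonds$a1[k]; j <- mol$bonds$a2[k]
      # BFS from i to j avoiding edge k
      dist <- rep(NA_integer_, n); dist[i] <- 0L
      queue <- i
      while (length(queue) && is.na(dist[j])) {
        a <- queue[1]; queue <- queue[-1]
        for (t in seq_along(nb[[a]]$nbr)) {
          v <- nb[[a]]$nbr[t]
          if (a == i && v == j || a == j && v == i) {
            # skip only the edge k itself (parallel edges impossible)
            if (min(a, v) == min(i, j) && max(a, v) == max(i, j)) next
          }
          if (is.na(dist[v])) { dist[v] <- dist[a] + 1L; queue <- c(queue, v) }
        }
      }
      if (!is.na(dist[j])) {
        bond_ring_size[k] <- dist[j] + 1L
        atom_in_ring[c(i, j)] <- TRUE
      }
    }
  }
  list(bond_ring_size = bond_ring_size, atom_in_ring = atom_in_ring,
       ring_sizes = sort(unique(bond_ring_size[!is.na(bond_ring_size)])))
}

# One-pass structural profile consumed by the dictionary schemes.
mol_facts <- function(mol) {
  n <- nrow(mol$atoms)
  el <- mol$atoms$element
  arom <- mol$atoms$aromatic
  hc <- mol$atoms$hcount
  chg <- mol$atoms$charge
  nb <- adjacency(mol)
  deg <- atom_degrees(mol)
  t <- type_strings(mol)
  rings <- ring_info(mol)
  halogens <- c("F", "Cl", "Br", "I")
  # per-atom bond-order summaries
  has_nb <- function(i, pred) {
    any(vapply(seq_along(nb[[i]]$nbr), function(k)
      pred(nb[[i]]$nbr[k], nb[[i]]$order[k]), logical(1)))
  }
  n_nb <- function(i, pred) {
    sum(vapply(seq_along(nb[[i]]$nbr), function(k)
      pred(nb[[i]]$nbr[k], nb[[i]]$order[k]), logical(1)))
  }
  is_carbonyl_c <- vapply(seq_len(n), function(i)
    el[i] == "C" && has_nb(i, function(j, o) el[j] == "O" && o == 2), logical(1))
  grp <- c(
    oh_any = any(el == "O" & hc > 0),
    nh_any = any(el == "N" & hc > 0),
    carbonyl = any(is_carbonyl_c),
    carboxylic_acid = any(vapply(seq_len(n), function(i)
      is_carbonyl_c[i] && has_nb(i, function(j, o) el[j] == "O" && o == 1 && hc[j] > 0),
      logical(1))),
    ester = any(vapply(seq_len(n), function(i)
      is_carbonyl_c[i] && has_nb(i, function(j, o)
        el[j] == "O" && o == 1 && hc[j] == 0 && deg[j] == 2), logical(1))),
    amide = any(vapply(seq_len(n), function(i)
      is_carbonyl_c[i] && has_nb(i, function(j, o) el[j] == "N" && o == 1),
      logical(1))),
    ketone = any(vapply(seq_len(n), function(i)
      is_carbonyl_c[i] && hc[i] == 0 &&
        n_nb(i, function(j, o) el[j] == "C") == 2, logical(1))),
    aldehyde = any(is_carbonyl_c & hc >= 1),
    carbamate = any(vapply(seq_len(n), function(i)
      is_carbonyl_c[i] &&
        has_nb(i, function(j, o) el[j] == "N" && o == 1) &&
        has_nb(i, function(j, o) el[j] == "O" && o == 1), logical(1))),
    alcohol_aliphatic = any(vapply(seq_len(n), function(i)
      el[i] == "O" && hc[i] > 0 && deg[i] == 1 &&
        has_nb(i, function(j, o) el[j] == "C" && !arom[j] && !is_carbonyl_c[j]),
      logical(1))),
    phenol = any(vapply(seq_len(n), function(i)
      el[i] == "O" && hc[i] > 0 && deg[i] == 1 &&
        has_nb(i, function(j, o) arom[j]), logical(1))),
    ether = any(vapply(seq_len(n), function(i)
      el[i] == "O" && hc[i] == 0 && deg[i] == 2 && !arom[i] &&
        all(el[nb[[i]]$nbr] == "C") && !any(is_carbonyl_c[nb[[i]]$nbr]),
      logical(1))),
    aryl_ether = any(vapply(seq_len(n), function(i)
      el[i] == "O" && hc[i] == 0 && deg[i] == 2 && !arom[i] &&
        any(arom[nb[[i]]$nbr]) && !any(is_carbonyl_c[nb[[i]]$nbr]),
      logical(1))),
    amine_primary = any(vapply(seq_len(n), function(i)
      el[i] == "N" && !arom[i] && hc[i] == 2 && deg[i] == 1 &&
        !any(is_carbonyl_c[nb[[i]]$nbr]) &&
        all(nb[[i]]$order == 1), logical(1))),
    amine_secondary = any(vapply(seq_len(n), function(i)
      el[i] == "N" && !arom[i] && hc[i] == 1 && deg[i] == 2 &&
        !any(is_carbonyl_c[nb[[i]]$nbr]) &&
        all(nb[[i]]$order == 1), logical(1))),
    amine_tertiary = any(vapply(seq_len(n), function(i)
      el[i] == "N" && !arom[i] && hc[i] == 0 && deg[i] == 3 &&
        !any(is_carbonyl_c[nb[[i]]$nbr]) &&
        all(nb[[i]]$order == 1), logical(1))),
    aniline = any(vapply(seq_len(n), function(i)
      el[i] == "N" && !arom[i] && hc[i] > 0 &&
        any(arom[nb[[i]]$nbr]) && !any(is_carbonyl_c[nb[[i]]$nbr]),
      logical(1))),
    nitro = any(vapply(seq_len(n), function(i)
      el[i] == "N" && n_nb(i, function(j, o) el[j] == "O" && o == 2) == 2,
      logical(1))),
    nitrile = any(vapply(seq_len(n), function(i)
      el[i] == "C" && has_nb(i, function(j, o) el[j] == "N" && o == 3),
      logical(1))),
    halogen_f = any(el == "F"), halogen_cl = any(el == "Cl"),
    halogen_br = any(el == "Br"), halogen_i = any(el == "I"),
    alkyl_halide = any(vapply(seq_len(n), function(i)
      el[i] %in% halogens && deg[i] == 1 &&
        has_nb(i, function(j, o) el[j] == "C" && !arom[j]), logical(1))),
    aryl_halide = any(vapply(seq_len(n), function(i)
      el[i] %in% halogens && deg[i] == 1 &&
        has_nb(i, function(j, o) arom[j]), logical(1))),
    boronic_acid = any(vapply(seq_len(n), function(i)
      el[i] == "B" &&
        n_nb(i, function(j, o) el[j] == "O" && hc[j] > 0) >= 2, logical(1))),
    boron_any = any(el == "B"),
    alkene = any(mol$bonds$order == 2 &
                 el[mol$bonds$a1] == "C" & el[mol$bonds$a2] == "C"),
    alkyne = any(mol$bonds$order == 3 &
                 el[mol$bonds$a1] == "C" & el[mol$bonds$a2] == "C"),
    aromatic_ring = any(arom),
    aromatic_n = any(arom & el == "N"),
    sulfur_any = any(el == "S"),
    thiol = any(el == "S" & hc > 0),
    benzylic = any(vapply(seq_len(n), function(i)
      arom[i] && el[i] == "C" &&
        has_nb(i, function(j, o) el[j] == "C" && !arom[j] && o == 1),
      logical(1))),
    tert_butyl = any(vapply(seq_len(n), function(i)
      el[i] == "C" &&
        n_nb(i, function(j, o) el[j] == "C" && deg[j] == 1 && !arom[j]) >= 3,
      logical(1))),
    positive_charge = any(chg > 0),
    negative_charge = any(chg < 0)
  )
  d <- molecule_descriptor(mol)
  keys <- names(d)
  reduce_key <- function(k) {
    body <- sub("^[23]:", "", k)
    parts <- strsplit(body, ",", fixed = TRUE)[[1]]
    idx <- seq(1, length(parts), by = 2)
    parts[idx] <- type_element(parts[idx])
    fwd <- paste(parts, collapse = ",")
    rev <- paste(rev(parts), collapse = ",")
    paste0(substr(k, 1, 2), if (fwd <= rev) fwd else rev)
  }
  reduced <- unique(vapply(keys, reduce_key, character(1), USE.NAMES = FALSE))
  list(el = el, deg = deg, hc = hc, arom = arom, types = unique(t),
       rings = rings, grp = grp, reduced = reduced,
       n_halogen = sum(el %in% halogens))
}

.fg_keys <- c("oh_any", "nh_any", "carbonyl", "carboxylic_acid", "ester",
  "amide", "ketone", "aldehyde", "carbamate", "alcohol_aliphatic", "phenol",
  "ether", "aryl_ether", "amine_primary", "amine_secondary", "amine_tertiary",
  "aniline", "nitro", "nitrile", "halogen_f", "halogen_cl", "halogen_br",
  "halogen_i", "alkyl_halide", "aryl_halide", "boronic_acid", "boron_any",
  "alkene", "alkyne", "aromatic_ring", "aromatic_n", "sulfur_any", "thiol",
  "benzylic", "tert_butyl", "positive_charge")

# The 166 dictionary predicates: evaluated against mol_facts().
.keys166_defs <- function() {
  elems <- c("B", "N", "O", "S", "P", "F", "Cl", "Br", "I")
  thresholds <- c("C>=5", "C>=7", "C>=10", "C>=13", "N>=2", "N>=3", "O>=2",
                  "O>=3", "O>=4", "S>=2", "X>=1", "X>=2")
  rings <- c("ring:any", "ring:arom", "ring:nonarom", "ring:3", "ring:4",
             "ring:5", "ring:6", "ring:7", "ring:8", "ringatoms>=7",
             "ringatoms>=10", "aromatoms>=10")
  ap2 <- c("C,1,C", "C,1,N", "C,1,O", "C,1,S", "C,1,P", "B,1,C", "C,1,F",
           "C,1,Cl", "Br,1,C", "C,1,I", "N,1,N", "N,1,O", "N,1,S", "O,1,S",
           "B,1,O", "O,1,P", "C,2,C", "C,2,N", "C,2,O", "C,2,S", "N,2,N",
           "N,2,O", "O,2,S", "C,3,C", "C,3,N", "C,a,C", "C,a,N", "C,a,O",
           "C,a,S", "N,a,N")
  ap3 <- c("O,2,C,1,O", "O,2,C,1,N", "C,1,C,2,O", "N,1,C,1,N", "O,1,C,1,O",
           "C,1,O,1,C", "C,1,N,1,C", "C,1,C,1,O", "C,1,C,1,N", "C,1,C,1,S",
           "C,1,S,1,C", "O,2,N,2,O", "O,1,B,1,O", "C,1,C,2,C", "C,1,C,3,C",
           "N,1,C,2,N", "C,a,C,1,N", "C,a,C,1,O", "C,a,C,1,C", "C,a,C,2,C",
           "C,a,C,1,F", "C,a,C,1,Cl", "Br,1,C,a,C", "C,a,C,1,I", "C,a,N,a,C",
           "C,1,C,1,F", "C,1,C,1,Cl", "Br,1,C,1,C", "C,1,C,1,I", "C,1,C,1,C",
           "B,1,C,a,C", "C,1,N,1,N", "C,1,O,1,N", "N,1,C,1,O")
  types <- c("C.1.0", "C.2.0", "C.3.0", "C.4.0", "C.1.1", "C.2.1", "C.3.1",
             "C.2.2", "C.3.2", "C.1.2", "N.1.0", "N.2.0", "N.3.0", "N.1.1",
             "N.2.1", "N.3.2", "N.2.2", "O.1.0", "O.2.0", "O.1.1", "S.1.0",
             "S.2.0", "S.1.1", "B.3.0", "F.1.0", "Cl.1.0", "Br.1.0", "I.1.0",
             "P.3.0", "C.2.3", "N.1.2", "O.2.1", "B.2.0")
  # orient path patterns the same way reduced descriptor keys are oriented
  canon_path <- function(p) {
    parts <- strsplit(p, ",", fixed = TRUE)[[1]]
    fwd <- paste(parts, collapse = ",")
    rev <- paste(rev(parts), collapse = ",")
    if (fwd <= rev) fwd else rev
  }
  ap2 <- vapply(ap2, canon_path, character(1), USE.NAMES = FALSE)
  ap3 <- vapply(ap3, canon_path, character(1), USE.NAMES = FALSE)
  defs <- c(paste0("el:", elems),
            paste0("cnt:", thresholds),
            rings,
            paste0("grp:", .fg_keys),
            paste0("ap2:", ap2),
            paste0("ap3:", ap3),
            paste0("type:", types))
  stopifnot(length(defs) == 166L, !anyDuplicated(defs))
  defs
}

eval_key <- function(def, facts) {
  if (startsWith(def, "el:")) return(sub("el:", "", def) %in% facts$el)
  if (startsWith(def, "cnt:")) {
    spec <- sub("cnt:", "", def)
    el <- sub(">=.*", "", spec); k <- as.integer(sub(".*>=", "", spec))
    cnt <- if (el == "X") facts$n_halogen else sum(facts$el == el)
    return(cnt >= k)
  }
  if (def == "ring:any") return(any(facts$rings$atom_in_ring))
  if (def == "ring:arom") return(any(facts$arom))
  if (def == "ring:nonarom")
    return(any(facts$rings$atom_in_ring & !facts$arom))
  if (startsWith(def, "ring:"))
    return(as.integer(sub("ring:", "", def)) %in% facts$rings$ring_sizes)
  if (def == "ringatoms>=7") return(sum(facts$rings$atom_in_ring) >= 7)
  if (def == "ringatoms>=10") return(sum(facts$rings$atom_in_ring) >= 10)
  if (def == "aromatoms>=10") return(sum(facts$arom) >= 10)
  if (startsWith(def, "grp:")) return(isTRUE(facts$grp[[sub("grp:", "", def)]]))
  if (startsWith(def, "ap2:")) return(paste0("2:", sub("ap2:", "", def)) %in% facts$reduced)
  if (startsWith(def, "ap3:")) return(paste0("3:", sub("ap3:", "", def)) %in% facts$reduced)
  if (startsWith(def, "type:")) return(sub("type:", "", def) %in% facts$types)
  stop("bad key definition: ", def)
}

# Circular environment strings of radius 0..r around every atom.
env_strings <- function(mol, radius, init) {
  nb <- adjacency(mol)
  e <- init
  out <- paste0("r0|", e)
  if (radius >= 1) for (r in seq_len(radius)) {
    e <- vapply(seq_along(e), function(i) {
      if (length(nb[[i]]$nbr) == 0L) return(paste0(e[i], "|"))
      pieces <- paste0(bond_code(nb[[i]]$order), e[nb[[i]]$nbr])
      paste0(e[i], "|", paste(sort_c(pieces), collapse = "+"))
    }, character(1))
    out <- c(out, paste0("r", r, "|", e))
  }
  out
}

register_builtin_schemes <- function() {
  register_fp_scheme("keys166", 166L, "binary", function(mol) {
    facts <- mol_facts(mol)
    which(vapply(.keys166_defs(), eval_key, logical(1), facts = facts))
  })
  register_fp_scheme("fg", length(.fg_keys), "binary", function(mol) {
    facts <- mol_facts(mol)
    which(unname(facts$grp[.fg_keys]))
  })
  for (nb in c(1024L, 2048L, 4096L)) {
    local({
      nbits <- nb
      register_fp_scheme(paste0("hashed", nbits), nbits, "binary", function(mol) {
        keys <- names(molecule_descriptor(mol))
        if (length(keys) == 0L) return(integer(0))
        unique(as.integer(str_hash(keys) %% nbits) + 1L)
      })
    })
  }
  for (rr in c(1L, 2L)) {
    local({
      radius <- rr
      register_fp_scheme(paste0("circ", radius), 1024L, "binary", function(mol) {
        if (nrow(mol$atoms) == 0L) return(integer(0))
        a <- mol$atoms
        hal <- a$element %in% c("F", "Cl", "Br", "I")
        init <- paste0(
          "D", as.integer((a$element %in% c("N", "O")) & a$hcount > 0),
          "A", as.integer(a$element %in% c("N", "O")),
          "R", as.integer(a$aromatic),
          "X", as.integer(hal),
          "C", sign(a$charge))
        envs <- env_strings(mol, radius, init)
        unique(as.integer(str_hash(envs) %% 1024L) + 1L)
      })
    })
  }
  register_fp_scheme("morgan1024c", 1024L, "count", function(mol) {
    if (nrow(mol$atoms) == 0L) return(stats::setNames(numeric(0), character(0)))
    init <- paste0(type_strings(mol), "H", mol$atoms$hcount, "c", mol$atoms$charge)
    envs <- env_strings(mol, 2L, init)
    ids <- as.character(as.integer(str_hash(envs) %% 1024L) + 1L)
    ms(ids, 1)
  })
  invisible(NULL)
}

.onLoad <- function(libname, pkgname) {
  register_builtin_schemes()
}
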