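#' Reactions
#'
#' A reaction holds lists of reactant and product molecular graphs plus an
#' optional hierarchical class label.  Atom-map numbers, when present in the
#' reaction SMILES, are kept on the atoms and drive starting-material
#' selection.  Agents (the middle field of `reactants>agents>products`) are
#' dropped on read.
#'
#' @param rxn_smiles a reaction SMILES string `reactants>agents>products`
#' @param label optional class label: a string (parsed with
#'   [parse_label()]) or an `rxv_label`
#' @return an object of class `rxv_rxn`
#' @examples
#' parse_reaction("CCBr.N>>CCN.Br", "C-N Bond Formation (Alkylation)")
#' @export
parse_reaction <- function(rxn_smiles, label = NULL) {
  parts <- strsplit(rxn_smiles, ">", fixed = TRUE)[[1]]
  if (length(parts) == 2L) parts <- c(parts[1], "", parts[2])
  if (length(parts) != 3L) stop("not a reaction SMILES: ", rxn_smiles)
  split_side <- function(s) {
    s <- gsub("[[:space:]]", "", s)
    if (!nzchar(s)) return(list())
    lapply(strsplit(s, ".", fixed = TRUE)[[1]], mol_from_smiles)
  }
  reactants <- split_side(parts[1])
  products <- split_side(parts[3])
  if (length(reactants) == 0L || length(products) == 0L)
    stop("reaction must have at least one reactant and one product")
  new_reaction(reactants, products, label)
}

new_reaction <- function(reactants, products, label = NULL) {
  if (is.character(label)) label <- parse_label(label)
  structure(list(reactants = reactants, products = products, label = label),
            class = "rxv_rxn")
}

#' @export
print.rxv_rxn <- function(x, ...) {
  cat("<reaction> ", reaction_smiles(x), "\n", sep = "")
  if (!is.null(x$label)) cat("  label: ", label_text(x$label), "\n", sep = "")
  invisible(x)
}

#' @rdname parse_reaction
#' @param rxn an `rxv_rxn`
#' @param keep_maps write atom maps
#' @export
reaction_smiles <- function(rxn, keep_maps = FALSE) {
  side <- function(mols) paste(vapply(mols, mol_to_smiles, character(1),
                                      canonical = !keep_maps,
                                      keep_maps = keep_maps), collapse = ".")
  paste0(side(rxn$reactants), ">>", side(rxn$products))
}

#' Read / write classified reactions as CSV
#'
#' The CSV has columns `rxn_smiles` and `label` (label may be empty).
#'
#' @param path file path
#' @return for the reader, a list of `rxv_rxn`
#' @export
read_reactions_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!("rxn_smiles" %in% names(df))) stop("CSV must have an rxn_smiles column")
  lab <- if ("label" %in% names(df)) df$label else rep(NA_character_, nrow(df))
  lapply(seq_len(nrow(df)), function(i) {
    l <- lab[i]
    parse_reaction(df$rxn_smiles[i],
                   if (!is.na(l) && nzchar(l)) l else NULL)
  })
}

#' @rdname read_reactions_csv
#' @param rxns list of `rxv_rxn`
#' @param keep_maps write atom maps into the SMILES column
#' @export
write_reactions_csv <- function(rxns, path, keep_maps = TRUE) {
  df <- data.frame(
    rxn_smiles = vapply(rxns, reaction_smiles, character(1), keep_maps = keep_maps),
    label = vapply(rxns, function(r)
      if (is.null(r$label)) "" else label_text(r$label), character(1)),
    stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

total_carbons <- function(mols) sum(vapply(mols, n_carbons, integer(1)))

mol_formula_key <- function(mol) {
  tab <- table(mol$atoms$element)
  paste(paste0(names(tab), tab), collapse = "")
}

# Carbon-free leaving groups that may be appended to the lighter side to
# restore heavy-atom balance (the balancing step never invents carbon).
.leaving_groups <- c("O", "Br", "Cl", "I", "OBO")

#' Balance a reaction on carbon count
#'
#' A reaction is accepted when both sides carry the same number of carbon
#' atoms.  A multi-product reaction whose products are isomeric alternatives
#' (identical molecular formulae, each individually carbon-balanced against
#' the reactants) is split into one reaction per product.  When the sides
#' are carbon-balanced but differ in carbon-free heavy atoms by a known
#' small leaving group (water, hydrogen halide, boronic-acid residue), the
#' missing fragment is appended.  Anything else is rejected with a reason
#' code, not an error.
#'
#' @param rxn an `rxv_rxn`
#' @return a list of balanced `rxv_rxn` (possibly empty); rejections carry a
#'   `"rejections"` attribute with reason codes
#' @export
balance_reaction <- function(rxn) {
  if (length(rxn$reactants) == 0L || length(rxn$products) == 0L)
    stop("reaction has an empty side")
  cr <- total_carbons(rxn$reactants)
  cp <- total_carbons(rxn$products)
  if (cr == cp) return(list(insert_leaving_group(rxn)))
  if (length(rxn$products) > 1L) {
    forms <- vapply(rxn$products, mol_formula_key, character(1))
    percomp <- vapply(rxn$products, n_carbons, integer(1))
    if (length(unique(forms)) == 1L && all(percomp == cr)) {
      out <- lapply(rxn$products, function(p)
        new_reaction(rxn$reactants, list(p), rxn$label))
      return(out)
    }
  }
  out <- list()
  attr(out, "rejections") <- "carbon_imbalance"
  out
}

# Append a known carbon-free leaving group when the heavy-atom element
# multisets differ by exactly one dictionary entry; otherwise return as is.
insert_leaving_group <- function(rxn) {
  er <- table(unlist(lapply(rxn$reactants, function(m) m$atoms$element)))
  ep <- table(unlist(lapply(rxn$products, function(m) m$atoms$element)))
  all_el <- sort_c(unique(c(names(er), names(ep))))
  r <- stats::setNames(rep(0L, length(all_el)), all_el); r[names(er)] <- er
  p <- stats::setNames(rep(0L, length(all_el)), all_el); p[names(ep)] <- ep
  diff <- r - p
  if (all(diff == 0)) return(rxn)
  if (any(diff < 0)) return(rxn)   # products heavier: leave untouched
  for (lg in .leaving_groups) {
    lgm <- mol_from_smiles(lg)
    lt <- table(lgm$atoms$element)
    want <- stats::setNames(rep(0L, length(all_el)), all_el)
    if (!all(names(lt) %in% all_el)) next
    want[names(lt)] <- lt
    if (all(diff == want)) {
      return(new_reaction(rxn$reactants, c(rxn$products, list(lgm)), rxn$label))
    }
  }
  rxn
}

#' Select the starting material of a reaction
#'
#' With one reactant, that reactant is the starting material.  With several,
#' the reactant with strictly the most mapped atoms is chosen; a tie is an
#' ambiguity and the reaction is discarded (returns `NULL` with a
#' `"reason"` attribute).  Multiple reactants without an atom map are an
#' error.
#'
#' @param rxn an `rxv_rxn`
#' @return an `rxv_mol`, or `NULL` (discard) when mapped-atom counts tie
#' @export
select_starting_material <- function(rxn) {
  rs <- rxn$reactants
  if (length(rs) == 1L) return(rs[[1]])
  mapped <- vapply(rs, function(m) sum(m$atoms$map > 0L), integer(1))
  if (all(mapped == 0L))
    stop("multiple reactants but no atom map; cannot select starting material")
  best <- max(mapped)
  if (sum(mapped == best) > 1L) return(NULL)   # ambiguous: discard signal
  rs[[which.max(mapped)]]
}

## ---- reaction vectors -----------------------------------------------------

#' Compute the reaction vector of a balanced reaction
#'
#' The AP2+AP3 descriptors of all products are summed, the reactant
#' descriptors subtracted, and the signed difference split into the
#' `negative` multiset (features lost from the reactants) and the `positive`
#' multiset (features gained in the products).  The conservation identity
#' `product_sum - reactant_sum == positive - negative` holds exactly by
#' construction.
#'
#' @param rxn a carbon-balanced `rxv_rxn`
#' @param id optional stable identifier; defaults to a hash of the feature
#'   content
#' @return an object of class `rxv_rvec` with fields `negative`, `positive`,
#'   `label`, `id`
#' @export
compute_reaction_vector <- function(rxn, id = NULL) {
  if (total_carbons(rxn$reactants) != total_carbons(rxn$products))
    stop("reaction is not carbon-balanced; run balance_reaction() first")
  dr <- Reduce(ms_add, lapply(rxn$reactants, molecule_descriptor), ms())
  dp <- Reduce(ms_add, lapply(rxn$products, molecule_descriptor), ms())
  delta <- ms_subtract(dp, dr)
  neg <- ms_positive(ms_subtract(ms(), delta))
  pos <- ms_positive(delta)
  if (is.null(id)) {
    content <- paste(c(names(neg), neg, "+", names(pos), pos), collapse = ";")
    id <- sprintf("rv%010.0f", str_hash(content))
  }
  structure(list(negative = neg, positive = pos, label = rxn$label, id = id),
            class = "rxv_rvec")
}

#' @export
print.rxv_rvec <- function(x, ...) {
  cat("<reaction vector> ", x$id, "\n", sep = "")
  if (!is.null(x$label)) cat("  label: ", label_text(x$label), "\n", sep = "")
  cat("  lost:   ", length(x$negative), " features (",
      sum(x$negative), " total)\n", sep = "")
  cat("  gained: ", length(x$positive), " features (",
      sum(x$positive), " total)\n", sep = "")
  invisible(x)
}

#' Compute reaction vectors for a set of classified reactions
#'
#' Balances each reaction, computes one vector per balanced entry, and drops
#' exact duplicates (same lost/gained features and same label).
#'
#' @param rxns list of `rxv_rxn`
#' @return list of `rxv_rvec`
#' @export
reaction_vectors <- function(rxns) {
  out <- list()
  seen <- character(0)
  for (r in rxns) {
    for (b in balance_reaction(r)) {
      rv <- compute_reaction_vector(b)
      key <- paste(rv$id, if (is.null(rv$label)) "" else label_text(rv$label))
      if (key %in% seen) next
      seen <- c(seen, key)
      out[[length(out) + 1L]] <- rv
    }
  }
  out
}

#' Serialize reaction vectors to JSON / read them back
#' @param rvs list of `rxv_rvec`
#' @param path file path
#' @export
rv_to_json <- function(rvs, path) {
  payload <- lapply(rvs, function(rv) list(
    id = rv$id,
    label = if (is.null(rv$label)) NULL else label_text(rv$label),
    negative = as.list(rv$negative),
    positive = as.list(rv$positive)))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname rv_to_json
#' @export
rv_from_json <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(payload, function(p) structure(list(
    negative = ms(names(p$negative), as.numeric(unlist(p$negative))),
    positive = ms(names(p$positive), as.numeric(unlist(p$positive))),
    label = if (is.null(p$label)) NULL else parse_label(p$label),
    id = p$id), class = "rxv_rvec"))
}

#' Applicability of a reaction vector to a starting material
#'
#' A vector is applicable when its negative (lost) features are wholly
#' present — count-aware multiset containment — in the starting material, or
#' in the starting material combined with a reagent.
#'
#' @param rv an `rxv_rvec`
#' @param sm starting material (`rxv_mol`)
#' @param reagent optional reagent (`rxv_mol`)
#' @param sm_descriptor,reagent_descriptor optional precomputed descriptors
#'   (an optimisation for enumeration loops)
#' @return `TRUE` or `FALSE`
#' @export
is_applicable <- function(rv, sm, reagent = NULL,
                          sm_descriptor = NULL, reagent_descriptor = NULL) {
  d <- sm_descriptor %||% molecule_descriptor(sm)
  if (!is.null(reagent) || !is.null(reagent_descriptor))
    d <- ms_add(d, reagent_descriptor %||% molecule_descriptor(reagent))
  ms_contains(d, rv$negative)
}

## ---- structure generation -------------------------------------------------

# Parse a vector of AP2 keys into a data frame of (t1, code, t2).
parse_ap2 <- function(keys) {
  keys <- keys[startsWith(keys, "2:")]
  if (length(keys) == 0L)
    return(data.frame(t1 = character(), code = character(), t2 = character()))
  body <- substring(keys, 3)
  parts <- strsplit(body, ",", fixed = TRUE)
  data.frame(t1 = vapply(parts, `[`, "", 1),
             code = vapply(parts, `[`, "", 2),
             t2 = vapply(parts, `[`, "", 3), stringsAsFactors = FALSE)
}

type_element <- function(ts) vapply(strsplit(ts, ".", fixed = TRUE), `[`, "", 1)
type_degree <- function(ts) as.integer(vapply(strsplit(ts, ".", fixed = TRUE), `[`, "", 2))
code_order <- function(code) c(`1` = 1, `2` = 2, `3` = 3, a = 1.5)[code]

# Apply a set of bond edits to a combined graph; returns the edited molecule
# with hydrogen counts recomputed on affected atoms, or NULL when an atom
# exceeds its allowed valence.
apply_edits <- function(G, breaks, forms) {
  bonds <- G$bonds
  if (length(breaks)) bonds <- bonds[-breaks, , drop = FALSE]
  affected <- integer(0)
  if (length(breaks))
    affected <- c(affected, G$bonds$a1[breaks], G$bonds$a2[breaks])
  for (f in forms) {
    i <- f[1]; j <- f[2]; o <- f[3]
    if (any(bonds$a1 == min(i, j) & bonds$a2 == max(i, j)) ||
        any(bonds$a1 == max(i, j) & bonds$a2 == min(i, j))) return(NULL)
    bonds <- rbind(bonds, data.frame(a1 = i, a2 = j, order = o))
    affected <- c(affected, i, j)
  }
  out <- structure(list(atoms = G$atoms, bonds = bonds), class = "rxv_mol")
  out$atoms$hcount[unique(affected)] <- NA_integer_
  fill_hydrogens(out, strict = FALSE)
}

#' Apply a reaction vector to a starting material
#'
#' Structure generation by bounded bond-edit search: candidate
#' reaction-centre atoms are those involved in the vector's lost features
#' (or typable into its gained features); bounded combinations of bond
#' breaks and bond formations (up to 3 of each, at most 4 changes in total,
#' smallest edit sets first) over those atoms are enumerated, and an edit is
#' accepted exactly when the AP2+AP3 descriptor delta of the whole edited
#' graph equals `positive - negative`.  By-products (the fragments not
#' containing the starting-material core) are reconstructed implicitly by
#' this identity; only the fragment retaining the most starting-material
#' atoms is reported, with the by-product SMILES attached as attribute
#' `"byproducts"`.  Products are deduplicated by canonical identifier and
#' returned in byte order.
#'
#' @param rv an `rxv_rvec`
#' @param sm starting material (`rxv_mol`)
#' @param reagent optional reagent (`rxv_mol`)
#' @param max_products cap on returned products
#' @return list of product `rxv_mol` (empty when applicability holds but no
#'   valid edit exists); the empty vector returns `list(sm)`
#' @export
apply_reaction_vector <- function(rv, sm, reagent = NULL, max_products = 10L) {
  if (length(rv$negative) == 0L && length(rv$positive) == 0L) return(list(sm))
  if (!is_applicable(rv, sm, reagent))
    stop("reaction vector is not applicable to this starting material")
  G <- if (is.null(reagent)) sm else mol_combine(sm, reagent)
  n_sm <- n_heavy_atoms(sm)
  D0 <- molecule_descriptor(G)
  target <- ms_subtract(rv$positive, rv$negative)
  tG <- type_strings(G)
  deg <- atom_degrees(G)
  el <- type_element(tG)

  neg2 <- parse_ap2(names(rv$negative))
  pos2 <- parse_ap2(names(rv$positive))
  neg_types <- unique(unlist(strsplit(names(rv$negative), "[:,]"))
                      [grepl("\\.", unlist(strsplit(names(rv$negative), "[:,]")))])

  # candidate breaks: existing bonds whose AP2 feature is a lost feature
  bond_keys <- if (nrow(G$bonds)) {
    t1 <- tG[G$bonds$a1]; t2 <- tG[G$bonds$a2]; o <- bond_code(G$bonds$order)
    ifelse(t1 <= t2, paste0("2:", t1, ",", o, ",", t2),
           paste0("2:", t2, ",", o, ",", t1))
  } else character(0)
  cand_breaks <- which(bond_keys %in% names(rv$negative))

  active_neg <- unique(c(G$bonds$a1[cand_breaks], G$bonds$a2[cand_breaks],
                         which(tG %in% neg_types)))
  # atoms whose element can reach a gained endpoint type by gaining a bond
  pos_types <- unique(c(pos2$t1, pos2$t2))
  pos_el <- type_element(pos_types); pos_deg <- type_degree(pos_types)
  pos_active <- which(vapply(seq_along(tG), function(a) {
    any(pos_el == el[a] & (pos_deg == deg[a] + 1L | pos_deg == deg[a]))
  }, logical(1)))
  cand_atoms <- union(active_neg, pos_active)

  # candidate formations: unbonded candidate pairs whose elements match a
  # gained AP2 feature; the order comes from that feature
  bonded_key <- paste(pmin(G$bonds$a1, G$bonds$a2), pmax(G$bonds$a1, G$bonds$a2))
  cand_forms <- list()
  if (nrow(pos2) && length(cand_atoms) >= 2L) {
    pe1 <- type_element(pos2$t1); pe2 <- type_element(pos2$t2)
    ords <- unname(code_order(pos2$code))
    pairs <- utils::combn(sort(cand_atoms), 2L)
    for (c_i in seq_len(ncol(pairs))) {
      i <- pairs[1, c_i]; j <- pairs[2, c_i]
      if (paste(i, j) %in% bonded_key) next
      hit <- which((pe1 == el[i] & pe2 == el[j]) | (pe1 == el[j] & pe2 == el[i]))
      for (o in unique(ords[hit]))
        cand_forms[[length(cand_forms) + 1L]] <- c(i, j, o)
    }
  }

  sm_atoms <- seq_len(n_sm)
  results <- character(0)
  products <- list()
  consider <- function(edited) {
    delta <- ms_subtract(molecule_descriptor(edited), D0)
    if (!ms_equal(delta, target)) return(invisible(NULL))
    comp <- component_ids(edited)
    in_sm <- tabulate(comp[sm_atoms], nbins = max(comp))
    sizes <- tabulate(comp, nbins = max(comp))
    hetero <- vapply(seq_len(max(comp)), function(k)
      sum(edited$atoms$element[comp == k] != "C"), integer(1))
    # the reported product keeps the starting-material core: most sm atoms,
    # then largest, then most functionalized (heteroatom-rich) fragment
    best <- which(in_sm == max(in_sm))
    if (length(best) > 1L) best <- best[sizes[best] == max(sizes[best])]
    if (length(best) > 1L) best <- best[which.max(hetero[best])]
    frag <- mol_subset(edited, which(comp == best[1]))
    others <- setdiff(seq_len(max(comp)), best[1])
    attr(frag, "byproducts") <- vapply(others, function(k)
      canonical_smiles(mol_subset(edited, which(comp == k))), character(1))
    id <- mol_id(frag)
    if (!(id %in% results)) {
      results <<- c(results, id)
      products[[length(products) + 1L]] <<- frag
    }
    invisible(NULL)
  }
  nb <- length(cand_breaks); nf <- length(cand_forms)
  # bond-count conservation: the number of formed minus broken bonds must
  # equal the net AP2 count change of the vector
  ap2_sum <- function(v) sum(v[startsWith(names(v), "2:")])
  net <- ap2_sum(rv$positive) - ap2_sum(rv$negative)
  for (total in 1:4) {
    found_before <- length(results)
    for (k_b in 0:min(3L, nb, total)) {
      k_f <- total - k_b
      if (k_f > min(3L, nf)) next
      if (k_f - k_b != net) next
      bsets <- if (k_b == 0L) list(integer(0)) else
        asplit(utils::combn(cand_breaks, k_b), 2)
      fsets <- if (k_f == 0L) list(integer(0)) else
        asplit(utils::combn(seq_len(nf), k_f), 2)
      for (bs in bsets) for (fs in fsets) {
        edited <- apply_edits(G, as.integer(bs), cand_forms[as.integer(fs)])
        if (!is.null(edited)) consider(edited)
      }
    }
    if (length(results) > found_before || length(results) >= max_products) break
  }
  ord <- order_c(results)
  products[ord][seq_len(min(length(products), max_products))]
}
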