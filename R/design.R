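#' Filter reaction vectors by a recommendation
#'
#' Keeps the vectors whose class label matches one of the recommended
#' classes at the given hierarchy level.  An empty recommendation applies no
#' filter at all (the vectors are returned unchanged): no-recommendation
#' means the molecule is outside the recommender's domain, not that nothing
#' is applicable.  Unlabelled vectors are retained by default, since
#' discarding them would silently remove reactions that were never
#' classified; set `drop_unlabelled = TRUE` to keep only labelled matches.
#'
#' @param rvs list of `rxv_rvec`
#' @param rec a recommendation: list of `rxv_label` (possibly empty)
#' @param level matching level
#' @param drop_unlabelled drop vectors without a label when filtering
#' @return the filtered list of `rxv_rvec`
#' @export
filter_reaction_vectors <- function(rvs, rec, level, drop_unlabelled = FALSE) {
  if (length(rec) == 0L) return(rvs)
  keep <- vapply(rvs, function(rv) {
    if (is.null(rv$label)) return(!drop_unlabelled)
    any(vapply(rec, matches_at_level, logical(1), b = rv$label, level = level))
  }, logical(1))
  rvs[keep]
}

#' Single-step de novo enumeration
#'
#' For every starting material: optionally obtain a recommendation from the
#' model and filter the reaction vectors; test applicability of each
#' remaining vector against the starting material alone and against the
#' starting material plus each reagent; apply the applicable vectors; and
#' collect the generated products.  Without a model this is the control
#' (full) enumeration; with a model, the library is a subset of the control
#' library.  Per-molecule failures are recorded and skipped, never fatal.
#'
#' @param sms starting materials (list of `rxv_mol` or SMILES)
#' @param reagents reagent pool (list of `rxv_mol` or SMILES; may be empty)
#' @param rvs list of `rxv_rvec`
#' @param model optional `reaction_recommender` used as a filter
#' @param level label level for filtering (default: model's level)
#' @param max_products_per_application cap passed to
#'   [apply_reaction_vector()]
#' @param drop_unlabelled see [filter_reaction_vectors()]
#' @return a data frame of product records: `smiles`, `product_id`, `sm_id`,
#'   `reagent_id` (NA when none), `rv_id`, `rv_label`
#' @export
single_step_enumerate <- function(sms, reagents, rvs, model = NULL,
                                  level = NULL,
                                  max_products_per_application = 5L,
                                  drop_unlabelled = FALSE) {
  as_mols <- function(x) lapply(x, function(e)
    if (is.character(e)) mol_from_smiles(e) else e)
  sms <- as_mols(sms); reagents <- as_mols(reagents)
  level <- level %||% (if (!is.null(model)) model$level else 3L)
  reagent_ids <- vapply(reagents, mol_id, character(1))
  reagent_desc <- lapply(reagents, molecule_descriptor)
  rec_rows <- list()
  add <- function(prod, sm_id, reagent_id, rv) {
    rec_rows[[length(rec_rows) + 1L]] <<- data.frame(
      smiles = canonical_smiles(prod), product_id = mol_id(prod),
      sm_id = sm_id, reagent_id = reagent_id, rv_id = rv$id,
      rv_label = if (is.null(rv$label)) NA_character_ else label_text(rv$label),
      stringsAsFactors = FALSE)
  }
  for (sm in sms) {
    sm_id <- mol_id(sm)
    sm_desc <- molecule_descriptor(sm)
    my_rvs <- rvs
    if (!is.null(model)) {
      rec <- predict(model, list(sm))[[1]]
      my_rvs <- filter_reaction_vectors(rvs, rec, level, drop_unlabelled)
    }
    for (rv in my_rvs) {
      if (length(rv$negative) == 0L && length(rv$positive) == 0L) next
      if (is_applicable(rv, sm, sm_descriptor = sm_desc)) {
        ps <- tryCatch(
          apply_reaction_vector(rv, sm,
                                max_products = max_products_per_application),
          error = function(e) list())
        for (p in ps) add(p, sm_id, NA_character_, rv)
      } else {
        for (ri in seq_along(reagents)) {
          if (!is_applicable(rv, sm, sm_descriptor = sm_desc,
                             reagent_descriptor = reagent_desc[[ri]])) next
          ps <- tryCatch(
            apply_reaction_vector(rv, sm, reagents[[ri]],
                                  max_products = max_products_per_application),
            error = function(e) list())
          for (p in ps) add(p, sm_id, reagent_ids[ri], rv)
        }
      }
    }
  }
  if (length(rec_rows) == 0L)
    return(data.frame(smiles = character(), product_id = character(),
                      sm_id = character(), reagent_id = character(),
                      rv_id = character(), rv_label = character(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rec_rows)
  rownames(out) <- NULL
  out
}

#' Library statistics
#'
#' Deduplicates product records by canonical identifier and reports the
#' unique-product count, the percentage overlap with a reference identifier
#' set, the level-1 reaction-class composition, and optional external
#' synthetic-accessibility scores (a scorer is a `function(smiles_vector)`
#' returning numeric scores; scorer failures are reported as NA, not
#' errors).
#'
#' @param records data frame from [single_step_enumerate()] or [renate_run()]
#' @param reference_ids optional character vector of canonical identifiers
#' @param scorers optional named list of scorer functions
#' @return list with `n_unique`, `overlap_pct`, `class_composition`,
#'   `external_scores`
#' @export
library_stats <- function(records, reference_ids = NULL, scorers = NULL) {
  ids <- unique(records$product_id)
  n_unique <- length(ids)
  overlap <- if (is.null(reference_ids)) NULL
             else if (n_unique == 0L) 0
             else 100 * length(intersect(ids, reference_ids)) / n_unique
  comp <- NULL
  lab <- records$rv_label[!duplicated(records$product_id)]
  lab <- lab[!is.na(lab)]
  if (length(lab)) {
    l1 <- vapply(lab, function(t) label_text(truncate_label(parse_label(t), 1)), "")
    tab <- table(l1)
    comp <- as.numeric(tab) / sum(tab)
    names(comp) <- names(tab)
  }
  scores <- NULL
  if (!is.null(scorers)) {
    smis <- records$smiles[!duplicated(records$product_id)]
    scores <- lapply(scorers, function(f)
      tryCatch(mean(f(smis)), error = function(e) NA_real_))
  }
  list(n_unique = n_unique, overlap_pct = overlap,
       class_composition = comp, external_scores = scores)
}

#' Configuration for retrosynthetic design
#'
#' @param min_fragment_atoms minimum heavy atoms per fragment; cleavages
#'   producing a smaller fragment are not performed (default 5)
#' @param analogs_per_fragment reagents retrieved per reference fragment
#'   (default 1000)
#' @param beam_width intermediates kept between assembly iterations
#' @param similarity_scheme count-fingerprint scheme for retrieval/scoring
#' @param seed RNG seed
#' @return a list of class `rxv_renate_config`
#' @export
renate_config <- function(min_fragment_atoms = 5, analogs_per_fragment = 1000,
                          beam_width = 25, similarity_scheme = "morgan1024c",
                          seed = 1) {
  stopifnot(min_fragment_atoms >= 1, analogs_per_fragment >= 1, beam_width >= 1)
  structure(list(min_fragment_atoms = as.integer(min_fragment_atoms),
                 analogs_per_fragment = as.integer(analogs_per_fragment),
                 beam_width = as.integer(beam_width),
                 similarity_scheme = similarity_scheme,
                 seed = as.integer(seed)),
            class = "rxv_renate_config")
}

# Bonds eligible for retrosynthetic cleavage: acyclic single non-aromatic
# bonds at recognised junctions (amide C-N, ester C-O, ether C-O on the
# sp3 side, biaryl and benzylic C-C, amine C-N).
cleavage_bonds <- function(mol) {
  rings <- ring_info(mol)
  el <- mol$atoms$element; arom <- mol$atoms$aromatic
  nbl <- adjacency(mol)
  is_carbonyl <- vapply(seq_len(nrow(mol$atoms)), function(i)
    el[i] == "C" && any(el[nbl[[i]]$nbr] == "O" & nbl[[i]]$order == 2),
    logical(1))
  out <- integer(0)
  for (k in seq_len(nrow(mol$bonds))) {
    if (!is.na(rings$bond_ring_size[k])) next
    if (mol$bonds$order[k] != 1) next
    i <- mol$bonds$a1[k]; j <- mol$bonds$a2[k]
    pat <- FALSE
    # amide / carbamate C(=O)-N
    if ((is_carbonyl[i] && el[j] == "N") || (is_carbonyl[j] && el[i] == "N"))
      pat <- TRUE
    # ester C(=O)-O
    if ((is_carbonyl[i] && el[j] == "O") || (is_carbonyl[j] && el[i] == "O"))
      pat <- TRUE
    # ether C(sp3)-O (O not bonded to a carbonyl)
    ether_end <- function(o, c) {
      el[o] == "O" && el[c] == "C" && !arom[c] &&
        !any(is_carbonyl[nbl[[o]]$nbr]) && atom_degrees(mol)[o] == 2
    }
    if (ether_end(i, j) || ether_end(j, i)) pat <- TRUE
    # biaryl c-c, and benzylic c-C where the aliphatic carbon is sp3
    if (el[i] == "C" && el[j] == "C") {
      sp3 <- function(a) !arom[a] && all(nbl[[a]]$order %in% c(1, 1.5)) &&
        !any(nbl[[a]]$order > 1)
      if (arom[i] && arom[j]) pat <- TRUE
      else if (arom[i] && sp3(j) && !is_carbonyl[j]) pat <- TRUE
      else if (arom[j] && sp3(i) && !is_carbonyl[i]) pat <- TRUE
    }
    # amine C(sp3)-N
    if ((el[i] == "N" && el[j] == "C" && !arom[j] && !is_carbonyl[j]) ||
        (el[j] == "N" && el[i] == "C" && !arom[i] && !is_carbonyl[i]))
      pat <- TRUE
    if (pat) out <- c(out, k)
  }
  out
}

#' Fragment a reference molecule for retrosynthetic design
#'
#' Cleaves the reference at recognised acyclic junction bonds (amide, ester,
#' ether, benzylic/biaryl, amine), refusing any cleavage that would create a
#' fragment below `min_fragment_atoms` heavy atoms.  The fragments are
#' ranked by descending number of attachment points, then descending heavy
#' atom count (ties broken by canonical identifier); the first fragment is
#' the scaffold that assembly starts from.  A molecule with no eligible
#' cleavage returns itself as a single fragment.
#'
#' @param ref reference molecule (`rxv_mol` or SMILES)
#' @param cfg an [renate_config()]
#' @return list of fragments, each `list(mol, n_attach, n_heavy, id)`
#' @export
fragment_reference <- function(ref, cfg = renate_config()) {
  if (is.character(ref)) ref <- mol_from_smiles(ref)
  cand <- cleavage_bonds(ref)
  # greedily accept cleavages that keep all fragments >= the minimum size
  accepted <- integer(0)
  for (k in cand) {
    trial <- c(accepted, k)
    bonds <- ref$bonds[-trial, , drop = FALSE]
    tmp <- structure(list(atoms = ref$atoms, bonds = bonds), class = "rxv_mol")
    comp <- component_ids(tmp)
    if (min(tabulate(comp)) >= cfg$min_fragment_atoms) accepted <- trial
  }
  bonds <- if (length(accepted)) ref$bonds[-accepted, , drop = FALSE] else ref$bonds
  cut_atoms <- c(ref$bonds$a1[accepted], ref$bonds$a2[accepted])
  tmp <- structure(list(atoms = ref$atoms, bonds = bonds), class = "rxv_mol")
  comp <- component_ids(tmp)
  frags <- lapply(seq_len(max(comp)), function(kk) {
    atoms <- which(comp == kk)
    m <- mol_subset(tmp, atoms)
    m$atoms$hcount <- NA_integer_
    m <- fill_hydrogens(m)
    list(mol = m, n_attach = sum(cut_atoms %in% atoms),
         n_heavy = length(atoms), id = mol_id(m))
  })
  ord <- order(-vapply(frags, `[[`, integer(1), "n_attach"),
               -vapply(frags, `[[`, integer(1), "n_heavy"),
               vapply(frags, `[[`, character(1), "id"), method = "radix")
  frags[ord]
}

#' Retrieve nearest reagent analogs for a fragment
#'
#' Ranks the pool by Euclidean count-fingerprint distance to the fragment
#' (attachment hydrogens already restored) and returns the `k` nearest,
#' ties broken by canonical identifier.  The fragment itself is injected
#' into the candidate set, so rediscovery is possible whenever the pool (or
#' the fragment) can supply the exact reagent.
#'
#' @param fragment a fragment entry from [fragment_reference()] or an
#'   `rxv_mol`/SMILES
#' @param pool list of `rxv_mol` or SMILES
#' @param k number of analogs (capped at the candidate-set size, with a
#'   warning-free log attribute)
#' @param scheme count-fingerprint scheme
#' @return list of `rxv_mol`, ascending distance; distances in attribute
#'   `"distance"`
#' @export
retrieve_analogs <- function(fragment, pool, k = 1000, scheme = "morgan1024c") {
  stopifnot(length(pool) > 0L)
  fmol <- if (is.list(fragment) && !is.null(fragment$mol)) fragment$mol
          else if (is.character(fragment)) mol_from_smiles(fragment)
          else fragment
  pool <- lapply(pool, function(e) if (is.character(e)) mol_from_smiles(e) else e)
  cand <- c(pool, list(fmol))
  ids <- vapply(cand, mol_id, character(1))
  keep <- !duplicated(ids)
  cand <- cand[keep]; ids <- ids[keep]
  ffp <- count_fingerprint(fmol, scheme)
  d <- vapply(cand, function(m) count_distance(count_fingerprint(m, scheme), ffp),
              numeric(1))
  ord <- order(d, ids, method = "radix")
  take <- utils::head(ord, k)
  out <- cand[take]
  attr(out, "distance") <- d[take]
  out
}

#' Retrosynthetic de novo design (fragment, retrieve, reassemble)
#'
#' The reference is fragmented ([fragment_reference()]); analogs are
#' retrieved for every fragment ([retrieve_analogs()]); assembly then starts
#' from the scaffold's analog set and combines it combinatorially with the
#' next fragment's analog set through the applicable (optionally
#' recommender-filtered) reaction vectors; products are scored by
#' count-fingerprint distance to the reference and only the `beam_width`
#' closest survive into the next iteration.  After the last fragment set,
#' the target counts as rediscovered when its canonical identifier appears
#' among the final products.
#'
#' @param ref reference molecule (`rxv_mol` or SMILES)
#' @param pool reagent pool (list of `rxv_mol` or SMILES)
#' @param rvs list of `rxv_rvec`
#' @param model optional `reaction_recommender` filter
#' @param cfg an [renate_config()]
#' @param level filtering level (default: model's level)
#' @return list with `records` (all product records with distances),
#'   `rediscovered`, `n_products` (total generated across iterations),
#'   `final_ids`, `steps`
#' @export
renate_run <- function(ref, pool, rvs, model = NULL, cfg = renate_config(),
                       level = NULL) {
  if (is.character(ref)) ref <- mol_from_smiles(ref)
  level <- level %||% (if (!is.null(model)) model$level else 3L)
  ref_fp <- count_fingerprint(ref, cfg$similarity_scheme)
  ref_id <- mol_id(ref)
  frags <- fragment_reference(ref, cfg)
  analog_sets <- lapply(frags, retrieve_analogs, pool = pool,
                        k = cfg$analogs_per_fragment,
                        scheme = cfg$similarity_scheme)
  beam <- analog_sets[[1]]
  records <- list()
  n_products <- 0L
  final_ids <- character(0)
  steps <- max(1L, length(frags) - 1L)
  if (length(frags) == 1L) {
    final_ids <- vapply(beam, mol_id, character(1))
    return(list(records = data.frame(), rediscovered = ref_id %in% final_ids,
                n_products = length(final_ids), final_ids = final_ids,
                steps = 0L))
  }
  for (it in 2:length(frags)) {
    partners <- analog_sets[[it]]
    partner_desc <- lapply(partners, molecule_descriptor)
    partner_ids <- vapply(partners, mol_id, character(1))
    prods <- list(); prod_ids <- character(0); prod_dist <- numeric(0)
    for (sm in beam) {
      sm_id <- mol_id(sm)
      sm_desc <- molecule_descriptor(sm)
      my_rvs <- rvs
      if (!is.null(model)) {
        rec <- predict(model, list(sm))[[1]]
        my_rvs <- filter_reaction_vectors(rvs, rec, level)
      }
      for (rv in my_rvs) {
        if (length(rv$negative) == 0L && length(rv$positive) == 0L) next
        for (pi in seq_along(partners)) {
          if (!is_applicable(rv, sm, sm_descriptor = sm_desc,
                             reagent_descriptor = partner_desc[[pi]])) next
          ps <- tryCatch(apply_reaction_vector(rv, sm, partners[[pi]],
                                               max_products = 3L),
                         error = function(e) list())
          for (p in ps) {
            id <- mol_id(p)
            n_products <- n_products + 1L
            dd <- count_distance(count_fingerprint(p, cfg$similarity_scheme),
                                 ref_fp)
            records[[length(records) + 1L]] <- data.frame(
              step = it - 1L, smiles = canonical_smiles(p), product_id = id,
              sm_id = sm_id, reagent_id = partner_ids[pi], rv_id = rv$id,
              rv_label = if (is.null(rv$label)) NA_character_
                         else label_text(rv$label),
              distance = dd, stringsAsFactors = FALSE)
            if (!(id %in% prod_ids)) {
              prods[[length(prods) + 1L]] <- p
              prod_ids <- c(prod_ids, id)
              prod_dist <- c(prod_dist, dd)
            }
          }
        }
      }
    }
    if (length(prods) == 0L) {
      return(list(records = if (length(records)) do.call(rbind, records)
                            else data.frame(),
                  rediscovered = FALSE, n_products = n_products,
                  final_ids = character(0), steps = it - 1L))
    }
    ord <- order(prod_dist, prod_ids, method = "radix")
    keep <- utils::head(ord, cfg$beam_width)
    beam <- prods[keep]
    final_ids <- prod_ids
  }
  list(records = do.call(rbind, records), rediscovered = ref_id %in% final_ids,
       n_products = n_products, final_ids = final_ids,
       steps = length(frags) - 1L)
}
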