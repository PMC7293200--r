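#' Extract labeled starting materials from classified reactions
#'
#' For every classified reaction, the starting material is selected (the
#' reactant with strictly the most mapped atoms; ambiguous reactions are
#' discarded and counted), its label truncated to `level`, and exact
#' duplicates — same canonical identifier and same truncated label — are
#' removed.
#'
#' @param rxns list of classified `rxv_rxn`
#' @param level label hierarchy level for the entries
#' @return a list of entries, each `list(structure, canonical_id, label)`;
#'   attributes `n_discarded` (mapping ties) and `n_duplicates` report the
#'   filtering
#' @export
build_labeled_entries <- function(rxns, level = 3) {
  out <- list()
  seen <- character(0)
  n_disc <- 0L; n_dup <- 0L
  for (r in rxns) {
    if (is.null(r$label)) next
    sm <- select_starting_material(r)
    if (is.null(sm)) { n_disc <- n_disc + 1L; next }
    lab <- truncate_label(r$label, level)
    id <- mol_id(sm)
    key <- paste(id, label_text(lab), sep = "\r")
    if (key %in% seen) { n_dup <- n_dup + 1L; next }
    seen <- c(seen, key)
    out[[length(out) + 1L]] <- list(structure = sm, canonical_id = id, label = lab)
  }
  attr(out, "n_discarded") <- n_disc
  attr(out, "n_duplicates") <- n_dup
  out
}

#' Pivot-merge labeled starting materials into a multi-label dataset
#'
#' Entries are fingerprinted under `scheme` and grouped by identical
#' fingerprint; the labels of a group are unioned, so starting materials
#' that the descriptor cannot distinguish become a single multi-label
#' training entry.  Coarser schemes merge more.  The result materializes the
#' binary feature matrix `X` and label matrix `Y`.
#'
#' @param entries output of [build_labeled_entries()] (all labels at one level)
#' @param scheme a registered binary fingerprint scheme id
#' @return an object of class `rxv_mlds`: list with `X`, `Y`, `vocabulary`,
#'   `scheme`, `level`, `member_count`, `entry_ids`
#' @export
pivot_merge <- function(entries, scheme) {
  stopifnot(length(entries) > 0L)
  depth <- unique(vapply(entries, function(e) length(e$label), integer(1)))
  lvl <- max(depth)
  vocab <- label_vocabulary(lapply(entries, `[[`, "label"), lvl)
  # fingerprint each distinct structure once
  ids <- vapply(entries, `[[`, "", "canonical_id")
  uniq <- !duplicated(ids)
  fps <- stats::setNames(lapply(entries[uniq], function(e)
    binary_fingerprint(e$structure, scheme)), ids[uniq])
  n_bits <- get_scheme(scheme, "binary")$n_bits
  fpkey <- vapply(ids, function(i) paste(fps[[i]]$bits, collapse = ","), "")
  groups <- split(seq_along(entries), fpkey)
  groups <- groups[order_c(names(groups))]
  n <- length(groups)
  X <- matrix(0L, n, n_bits,
              dimnames = list(NULL, paste0("b", seq_len(n_bits))))
  Y <- matrix(0L, n, length(vocab$labels),
              dimnames = list(NULL, vocab$text))
  member_count <- integer(n)
  entry_ids <- vector("list", n)
  for (g in seq_len(n)) {
    idx <- groups[[g]]
    bits <- fps[[ids[idx[1]]]]$bits
    X[g, bits] <- 1L
    labs <- unique(vapply(entries[idx], function(e) label_text(e$label), ""))
    Y[g, match(labs, vocab$text)] <- 1L
    member_count[g] <- length(unique(ids[idx]))
    entry_ids[[g]] <- unique(ids[idx])
  }
  structure(list(X = X, Y = Y, vocabulary = vocab, scheme = scheme,
                 level = lvl, member_count = member_count,
                 entry_ids = entry_ids), class = "rxv_mlds")
}

#' @export
print.rxv_mlds <- function(x, ...) {
  cat("<multi-label dataset> ", nrow(x$X), " entries x ", ncol(x$X),
      " bits (", x$scheme, "), ", length(x$vocabulary$labels),
      " classes at level ", x$level, "\n", sep = "")
  cat("  label cardinality: ", round(mean(rowSums(x$Y)), 3), "\n", sep = "")
  invisible(x)
}

#' @export
summary.rxv_mlds <- function(object, ...) {
  per_class <- colSums(object$Y)
  out <- list(n_entries = nrow(object$X), n_classes = ncol(object$Y),
              scheme = object$scheme, level = object$level,
              median_examples_per_class = stats::median(per_class),
              mean_labels_per_entry = mean(rowSums(object$Y)),
              merged_entries = sum(object$member_count > 1))
  class(out) <- "summary.rxv_mlds"
  out
}

#' @export
print.summary.rxv_mlds <- function(x, ...) {
  cat("Multi-label dataset (", x$scheme, ", level ", x$level, ")\n", sep = "")
  cat("  entries:                  ", x$n_entries, "\n")
  cat("  classes:                  ", x$n_classes, "\n")
  cat("  median examples/class:    ", x$median_examples_per_class, "\n")
  cat("  mean labels/entry:        ", round(x$mean_labels_per_entry, 3), "\n")
  cat("  pivot-merged entries:     ", x$merged_entries, "\n")
  invisible(x)
}

mlds_subset <- function(ds, idx) {
  structure(list(X = ds$X[idx, , drop = FALSE], Y = ds$Y[idx, , drop = FALSE],
                 vocabulary = ds$vocabulary, scheme = ds$scheme,
                 level = ds$level, member_count = ds$member_count[idx],
                 entry_ids = ds$entry_ids[idx]), class = "rxv_mlds")
}

#' Stratified train/test split by label count
#'
#' Entries are stratified by their number of labels (counts of
#' `pool_from` and above are pooled into one stratum, since very rare label
#' counts are unsplittable) and each stratum is split to within one entry of
#' the target fraction.  Singleton strata go to the training set.
#' Reproducible under `seed`.
#'
#' @param ds an `rxv_mlds`
#' @param train_fraction fraction assigned to training (0 < f < 1)
#' @param seed RNG seed
#' @param pool_from label counts >= this value share one stratum
#' @return list with `train` and `test` datasets (disjoint, exhaustive)
#' @export
stratified_split <- function(ds, train_fraction = 0.8, seed = 1, pool_from = 5) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  counts <- pmin(rowSums(ds$Y), pool_from)
  train_idx <- integer(0)
  with_seed(seed, {
    for (s in sort(unique(counts))) {
      members <- which(counts == s)
      if (length(members) == 1L) { train_idx <- c(train_idx, members); next }
      n_train <- round(train_fraction * length(members))
      n_train <- max(1L, min(length(members) - 1L, n_train))
      train_idx <- c(train_idx, sample(members, n_train))
    }
  })
  train_idx <- sort(train_idx)
  list(train = mlds_subset(ds, train_idx),
       test = mlds_subset(ds, setdiff(seq_len(nrow(ds$X)), train_idx)))
}
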