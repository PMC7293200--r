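#' Hierarchical reaction-class labels
#'
#' Reaction classes live in a four-level hierarchy written as
#' `"Level1 (Level2) (Level3) (Level4)"`, e.g.
#' `"C-C Bond Formation (Coupling) (Suzuki) (Iodo)"`.  Level 1 is the most
#' generic category; truncating a label to a lower level merges specific
#' classes into their parent.  On parse, whitespace is squeezed and the
#' typographic en dash in e.g. `"C–C"` is normalized to a plain hyphen.
#'
#' @param text the textual label form
#' @return an object of class `rxv_label` (a character vector of 1-4 levels)
#' @examples
#' parse_label("C-C Bond Formation (Coupling) (Suzuki) (Iodo)")
#' parse_label("Deprotection")
#' @export
parse_label <- function(text) {
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  s <- gsub("–|—", "-", text)
  s <- gsub("[[:space:]]+", " ", trimws(s))
  n_open <- lengths(regmatches(s, gregexpr("(", s, fixed = TRUE)))
  n_close <- lengths(regmatches(s, gregexpr(")", s, fixed = TRUE)))
  if (n_open != n_close) stop("unbalanced parentheses in label: ", text)
  inner <- regmatches(s, gregexpr("\\(([^()]*)\\)", s))[[1]]
  inner <- trimws(gsub("^\\(|\\)$", "", inner))
  first <- trimws(sub("\\(.*$", "", s))
  levels <- c(first, inner)
  levels <- levels[nzchar(levels)]
  if (length(levels) < 1L || length(levels) > 4L)
    stop("label must have 1 to 4 levels: ", text)
  structure(levels, class = "rxv_label")
}

#' @rdname parse_label
#' @param label an `rxv_label`
#' @export
label_text <- function(label) {
  if (is.null(label)) return(NA_character_)
  if (length(label) == 1L) return(unclass(label)[1])
  paste0(label[1], " ", paste0("(", label[-1], ")", collapse = " "))
}

#' @export
print.rxv_label <- function(x, ...) {
  cat("<label> ", label_text(x), "  [", length(x), " level",
      if (length(x) > 1) "s", "]\n", sep = "")
  invisible(x)
}

#' @export
format.rxv_label <- function(x, ...) label_text(x)

#' Truncate a label to a hierarchy level
#'
#' Keeps the first `min(level, depth)` components; truncation to a level at
#' or beyond the label's depth returns it unchanged, so truncation is
#' idempotent and composes (`truncate(truncate(l, 3), 1) == truncate(l, 1)`).
#'
#' @param label an `rxv_label`
#' @param level target level, 1-4
#' @return an `rxv_label`
#' @export
truncate_label <- function(label, level) {
  if (!(is.numeric(level) && length(level) == 1L && level >= 1))
    stop("level must be >= 1")
  structure(unclass(label)[seq_len(min(as.integer(level), length(label)))],
            class = "rxv_label")
}

#' Compare two labels at a hierarchy level
#'
#' `TRUE` when the truncations of both labels to `level` are identical, so
#' e.g. Suzuki and Heck couplings match at level 2 ("C-C Bond Formation
#' (Coupling)") but not at level 3.
#'
#' @param a,b `rxv_label` objects
#' @param level comparison level
#' @return `TRUE` or `FALSE`
#' @export
matches_at_level <- function(a, b, level) {
  ta <- truncate_label(a, level); tb <- truncate_label(b, level)
  length(ta) == length(tb) && all(unclass(ta) == unclass(tb))
}

#' Build the vocabulary of distinct labels at a level
#'
#' Truncates every label to `level` and returns the sorted distinct set.
#' Vocabulary size is non-increasing as the level decreases.
#'
#' @param labels list of `rxv_label`
#' @param level vocabulary level
#' @return an object of class `rxv_vocab`: list with `level` and `labels`
#'   (list of `rxv_label` in byte order of their text)
#' @export
label_vocabulary <- function(labels, level) {
  trunc <- lapply(labels, truncate_label, level = level)
  txt <- vapply(trunc, label_text, character(1))
  keep <- !duplicated(txt)
  trunc <- trunc[keep]; txt <- txt[keep]
  ord <- order_c(txt)
  structure(list(level = as.integer(level), labels = trunc[ord],
                 text = txt[ord]), class = "rxv_vocab")
}

#' @export
print.rxv_vocab <- function(x, ...) {
  cat("<label vocabulary> level ", x$level, ", ", length(x$labels),
      " classes\n", sep = "")
  for (t in utils::head(x$text, 10)) cat("  ", t, "\n", sep = "")
  if (length(x$text) > 10) cat("  ...\n")
  invisible(x)
}

# Index of a label (truncated to the vocabulary level) in a vocabulary;
# NA when absent.
vocab_index <- function(vocab, label) {
  match(label_text(truncate_label(label, vocab$level)), vocab$text)
}
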