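#' Signed multisets of path-descriptor features
#'
#' Descriptor multisets are represented as named numeric vectors: names are
#' canonical feature keys (see [molecule_descriptor()]) and values are signed
#' integer counts.  Molecule-derived multisets have all counts positive; the
#' difference of two molecule multisets (a reaction vector, before splitting
#' into lost/gained parts) is signed.  Zero counts are never stored.
#'
#' @param keys character vector of feature keys
#' @param counts numeric vector of counts, recycled against `keys`
#' @return a named numeric vector with no zero entries, keys in byte order
#' @examples
#' ms(c("a", "b"), c(2, 1))
#' @export
ms <- function(keys = character(), counts = numeric()) {
  v <- stats::setNames(rep(as.numeric(counts), length.out = length(keys)), keys)
  ms_norm(v)
}

# Collapse duplicate keys, drop zeros, order keys bytewise.
ms_norm <- function(v) {
  if (length(v) == 0L) return(stats::setNames(numeric(0), character(0)))
  keys <- sort_c(unique(names(v)))
  s <- tapply(unname(v), factor(names(v), levels = keys), sum)
  out <- as.numeric(s)
  names(out) <- keys
  out[out != 0]
}

#' @rdname ms
#' @param a,b descriptor multisets
#' @export
ms_add <- function(a, b) ms_norm(c(a, b))

#' @rdname ms
#' @export
ms_subtract <- function(a, b) {
  if (length(b)) b <- -b
  ms_norm(c(a, b))
}

#' @rdname ms
#' @export
ms_positive <- function(a) a[a > 0]

#' @rdname ms
#' @details `ms_contains(a, b)` tests count-aware containment: every key of
#'   `b` must be present in `a` with at least the same count.
#' @export
ms_contains <- function(a, b) {
  if (length(b) == 0L) return(TRUE)
  have <- a[names(b)]
  have[is.na(have)] <- 0
  all(have >= b)
}

ms_equal <- function(a, b) {
  a <- ms_norm(a); b <- ms_norm(b)
  length(a) == length(b) && all(names(a) == names(b)) && all(a == b)
}
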