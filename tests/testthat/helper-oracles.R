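# Independent brute-force oracles.  These re-derive quantities from the raw
# atom/bond tables with deliberately naive code, so they share no logic with
# the implementation paths they check.

# Adjacency matrix of bond orders.
oracle_bond_matrix <- function(mol) {
  n <- nrow(mol$atoms)
  A <- matrix(0, n, n)
  for (k in seq_len(nrow(mol$bonds))) {
    i <- mol$bonds$a1[k]; j <- mol$bonds$a2[k]
    A[i, j] <- A[j, i] <- mol$bonds$order[k]
  }
  A
}

# Naive Carhart typing straight from the bond matrix.
oracle_types <- function(mol) {
  A <- oracle_bond_matrix(mol)
  n <- nrow(mol$atoms)
  sapply(seq_len(n), function(i) {
    deg <- sum(A[i, ] > 0)
    pi <- sum(A[i, ] == 2) + 2 * sum(A[i, ] == 3) + as.integer(any(A[i, ] == 1.5))
    paste(mol$atoms$element[i], deg, pi, sep = ".")
  })
}

oracle_code <- function(o) c("1", "a", "2", "3")[match(o, c(1, 1.5, 2, 3))]

# Enumerate every simple 2- or 3-atom path by exhaustive index loops and
# return the canonical-key multiset as a named vector.
oracle_paths <- function(mol, len) {
  A <- oracle_bond_matrix(mol)
  t <- oracle_types(mol)
  n <- nrow(mol$atoms)
  keys <- character(0)
  if (len == 2) {
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i < j && A[i, j] > 0) {
        o <- oracle_code(A[i, j])
        fwd <- paste0("2:", t[i], ",", o, ",", t[j])
        rev <- paste0("2:", t[j], ",", o, ",", t[i])
        keys <- c(keys, min(fwd, rev))
      }
    }
  } else {
    for (i in seq_len(n)) for (j in seq_len(n)) for (k in seq_len(n)) {
      if (i < k && j != i && j != k && A[i, j] > 0 && A[j, k] > 0) {
        o1 <- oracle_code(A[i, j]); o2 <- oracle_code(A[j, k])
        fwd <- paste0("3:", t[i], ",", o1, ",", t[j], ",", o2, ",", t[k])
        rev <- paste0("3:", t[k], ",", o2, ",", t[j], ",", o1, ",", t[i])
        keys <- c(keys, min(fwd, rev))
      }
    }
  }
  if (length(keys) == 0) return(numeric(0))
  tab <- table(keys)
  out <- as.numeric(tab)
  names(out) <- names(tab)
  out[order(names(out), method = "radix")]
}

oracle_descriptor <- function(mol) {
  c(oracle_paths(mol, 2), oracle_paths(mol, 3))
}

# Signed multiset difference of two oracle descriptors.
oracle_diff <- function(dp, dr) {
  keys <- sort(unique(c(names(dp), names(dr))), method = "radix")
  p <- dp[keys]; p[is.na(p)] <- 0
  r <- dr[keys]; r[is.na(r)] <- 0
  d <- p - r
  names(d) <- keys
  d[d != 0]
}

expect_ms_equal <- function(a, b) {
  a <- a[order(names(a), method = "radix")]
  b <- b[order(names(b), method = "radix")]
  expect_identical(names(a), names(b))
  expect_equal(unname(as.numeric(a)), unname(as.numeric(b)))
}

# Brute-force micro confusion counting, cell by cell.
oracle_micro <- function(Yt, Yp) {
  tp <- fp <- fn <- 0
  for (i in seq_len(nrow(Yt))) for (j in seq_len(ncol(Yt))) {
    if (Yt[i, j] == 1 && Yp[i, j] == 1) tp <- tp + 1
    if (Yt[i, j] == 0 && Yp[i, j] == 1) fp <- fp + 1
    if (Yt[i, j] == 1 && Yp[i, j] == 0) fn <- fn + 1
  }
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  f1 <- if (r + p > 0) 2 * r * p / (r + p) else 0
  list(recall = r, precision = p, f1 = f1)
}
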