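# Internal helpers shared across modules.

# Locale-independent (byte-order) character sort/order.  All canonical keys,
# tie-breaks and vocabulary orderings go through these so results do not
# depend on LC_COLLATE.
sort_c <- function(x) sort(x, method = "radix")
order_c <- function(...) order(..., method = "radix")

# Evaluate `expr` with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards so library code never perturbs user-level randomness.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Deterministic 31-bit string hash (polynomial rolling hash, modulus 2^31-1).
# Implemented with doubles only (31 * 2^31 < 2^53, so arithmetic is exact);
# stable across platforms and R sessions, unlike any environment-dependent
# hashing.
str_hash <- function(s) {
  n <- length(s)
  if (n == 0L) return(numeric(0))
  codes <- lapply(s, utf8ToInt)
  len <- lengths(codes)
  h <- numeric(n)
  maxlen <- max(len)
  for (pos in seq_len(maxlen)) {
    live <- len >= pos
    cp <- vapply(codes[live], `[`, numeric(1), pos)
    h[live] <- (h[live] * 31 + cp) %% 2147483647
  }
  h
}

`%||%` <- function(a, b) if (is.null(a)) b else a

pkg_version <- function() {
  tryCatch(as.character(utils::packageVersion("rvdesign")),
           error = function(e) "0.0.0")
}
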