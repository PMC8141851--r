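# Independent oracles kept deliberately naive: they re-derive expected
# values by enumeration / double loops, never by calling the code they check.

# brute-force count of satisfying genotypes by full enumeration
brute_count_optimal <- function(pattern) {
  sym <- strsplit(unclass(pattern), "")[[1]]
  L <- length(sym)
  g <- expand.grid(rep(list(0:1), L))
  n <- 0L
  for (r in seq_len(nrow(g))) {
    ok <- TRUE
    for (i in seq_len(L)) {
      if (sym[i] == "1" && g[r, i] != 1) ok <- FALSE
      if (sym[i] == "0" && g[r, i] != 0) ok <- FALSE
    }
    if (ok) n <- n + 1L
  }
  n
}

# direct per-position check of one genotype string against one pattern
brute_is_optimal <- function(bits, pattern) {
  b <- strsplit(bits, "")[[1]]
  p <- strsplit(unclass(pattern), "")[[1]]
  all(mapply(function(bi, pi) {
    if (pi == "1") bi == "1" else if (pi == "0") bi == "0" else TRUE
  }, b, p))
}

# naive two-loop Game of Life step on a torus (B3/S23)
naive_life_step <- function(m) {
  n <- nrow(m); k <- ncol(m)
  out <- matrix(0L, n, k)
  for (i in seq_len(n)) {
    for (j in seq_len(k)) {
      s <- 0L
      for (di in -1:1) for (dj in -1:1) {
        if (di == 0L && dj == 0L) next
        s <- s + m[(i - 1L + di) %% n + 1L, (j - 1L + dj) %% k + 1L]
      }
      out[i, j] <- if (m[i, j] == 1L) as.integer(s == 2L || s == 3L)
                   else as.integer(s == 3L)
    }
  }
  out
}

random_pattern <- function(L) {
  paste(sample(c("1", "0", "x"), L, replace = TRUE), collapse = "")
}

random_bits <- function(L) paste(sample(0:1, L, replace = TRUE), collapse = "")
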