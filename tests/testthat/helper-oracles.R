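# Independent oracles and fixture builders used across the suite.

BASES <- c("A", "C", "G", "T")

rand_seq <- function(n) paste(sample(BASES, n, replace = TRUE),
                              collapse = "")

# From-scratch k-mer frequency vector (string chopping, no sliding).
naive_profile <- function(seq, i, w, k) {
  win <- substr(seq, i + 1L, i + w)
  kmers <- substring(win, 1:(w - k + 1L), k:w)
  counts <- integer(4^k)
  for (km in kmers) {
    x <- sum((match(strsplit(km, "")[[1]], BASES) - 1L) *
               4^((k - 1L):0L))
    counts[x + 1L] <- counts[x + 1L] + 1L
  }
  counts
}

# Brute-force wraparound distance: minimal edit distance between the
# region and any prefix of r^M over every rotation r of u (a unit is
# defined up to rotation, so the tandem extensions of u are the prefixes
# of the repetitions of its rotations).  Plain Sellers DP on the explicit
# concatenation, free end; independent of the wraparound column
# recurrence.
brute_wrap_delta <- function(u, region) {
  n <- nchar(u)
  dd <- paste0(u, u)
  rots <- unique(substring(dd, 1:n, n:(2L * n - 1L)))
  min(vapply(rots, function(r) .sellers_prefix_delta(r, region),
             numeric(1)))
}

.sellers_prefix_delta <- function(u, region) {
  M <- ceiling((nchar(region) + 2L * nchar(u)) / nchar(u)) + 2L
  U <- strsplit(strrep(u, M), "")[[1]]
  Rg <- strsplit(region, "")[[1]]
  n <- length(Rg); m <- length(U)
  prev <- 0:m
  for (i in seq_len(n)) {
    cur <- numeric(m + 1L); cur[1L] <- i
    for (j in seq_len(m)) {
      cur[j + 1L] <- min(prev[j] + (Rg[i] != U[j]),
                         prev[j + 1L] + 1, cur[j] + 1)
    }
    prev <- cur
  }
  min(prev)
}

# Exhaustive pseudo-disjoint chain: maximum total sigma over all subsets
# whose end-sorted consecutive pairs satisfy s_j >= e_i - l with strict
# overlap < l (matching the chain predicate).
brute_chain_weight <- function(s, e, sigma, l) {
  n <- length(s)
  best <- 0
  for (mask in 0:(2^n - 1L)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0L)
    if (length(idx) == 0L) next
    idx <- idx[order(e[idx], s[idx])]
    ok <- TRUE
    if (length(idx) > 1L) {
      for (t in seq_len(length(idx) - 1L)) {
        if (s[idx[t + 1L]] < e[idx[t]] - l + 1L) { ok <- FALSE; break }
      }
    }
    if (ok) best <- max(best, sum(sigma[idx]))
  }
  best
}

# Direct term-by-term binomial upper tail (independent of pbinom).
brute_tail <- function(K, d, eps) {
  if (K == 0) return(1)
  p <- eps / 4
  sum(vapply(K:d, function(k) choose(d, k) * p^k * (1 - p)^(d - k),
             numeric(1)))
}

# Uniform random PRIMITIVE unit (not a perfect power of a shorter one).
rand_unit <- function(len) {
  repeat {
    u <- rand_seq(len)
    ch <- strsplit(u, "")[[1]]
    divs <- which(len %% seq_len(max(len - 1L, 1L)) == 0L)
    ok <- !any(vapply(divs, function(d) {
      identical(rep(ch[1:d], len / d), ch)
    }, logical(1)))
    if (len == 1L || ok) return(u)
  }
}

# Plant a tandem repeat with random flanks of the same total length.
planted_read <- function(unit, copies, flank = nchar(unit) * copies) {
  paste0(rand_seq(flank), strrep(unit, copies), rand_seq(flank))
}
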