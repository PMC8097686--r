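#' k-mer frequencies along a cyclic unit
#'
#' Frequency, inside a de Bruijn graph, of each of the `|u|` k-mers read
#' cyclically along the unit (the k-mer starting at each unit position,
#' wrapping at the end).  An error embedded in the consensus shows up as
#' a run of low-frequency k-mers covering it, flanked by sharp rises back
#' to the modal frequency.
#'
#' @param u Unit string.
#' @param g A `"debruijn"` graph (same k the unit was assembled at).
#' @return Integer vector of length `nchar(u)`.
#' @export
unit_kmer_freqs <- function(u, g) {
  stopifnot(inherits(g, "debruijn"))
  .unit_kmer_freqs_codes(.encode_bases(u), g)
}

.unit_kmer_freqs_codes <- function(ucodes, g) {
  k <- g$k
  m <- length(ucodes)
  if (m < 1L) return(integer(0))
  ext <- c(ucodes, ucodes[seq_len(min(k - 1L, m))])
  while (length(ext) < m + k - 1L) ext <- c(ext, ext)  # units shorter than k
  kc <- cpp_kmer_codes(ext[seq_len(m + k - 1L)], k)
  .dbg_freq(g, kc)
}

# Sum of graph frequencies of the k k-mer starts covering position `locus`
# of the cyclic unit `uc` (1-based).  Used to compare repair operations.
.locus_score <- function(uc, locus, g) {
  k <- g$k
  m <- length(uc)
  if (m < 1L) return(-Inf)
  starts <- ((locus - k):(locus - 1L)) %% m  # 0-based starts locus-k+1..locus
  ext <- c(uc, uc, uc)
  kcs <- vapply(starts, function(st) {
    idx <- (st:(st + k - 1L)) %% m + 1L
    sum(uc[idx] * 4^((k - 1L):0L))
  }, numeric(1))
  sum(.dbg_freq(g, as.integer(kcs)))
}

#' Repair a consensus unit by k-mer frequency transitions
#'
#' Scans the k-mer frequency sequence along the cyclic unit; any position
#' covered by a low-frequency k-mer (below `low_frac` of the median
#' frequency along the unit) is a suspected embedded error.  At each such
#' position the nine candidate operations - no-op, the three
#' substitutions, deletion, and the four insertions - are evaluated by
#' the sum of graph frequencies of the k k-mers covering the edited
#' locus, and the operation with the largest sum is applied (no-op wins
#' ties, so a correct unit is never touched).  Passes repeat until
#' nothing qualifies or `max_pass` is reached.
#'
#' When the modal k-mer frequency is below `min_modal` (default 10) the
#' unit is returned unchanged: for low-copy repeats a low-frequency k-mer
#' may simply be correct, and frequency evidence cannot distinguish the
#' two cases.
#'
#' @param u Unit string.
#' @param g The `"debruijn"` graph of the candidate range at the k the
#'   unit was assembled with.
#' @param low_frac Fraction of the median frequency below which a k-mer
#'   counts as low (default 0.5).
#' @param min_modal Minimal modal (median) frequency for repair to act.
#' @param max_pass Pass budget.
#' @return The repaired unit string.
#' @export
transition_repair <- function(u, g, low_frac = 0.5, min_modal = 10L,
                              max_pass = 5L) {
  stopifnot(inherits(g, "debruijn"))
  uc <- .encode_bases(u)
  k <- g$k
  for (pass in seq_len(max_pass)) {
    m <- length(uc)
    if (m < 1L) break
    freqs <- .unit_kmer_freqs_codes(uc, g)
    med <- stats::median(freqs)
    if (med < min_modal) break
    low <- which(freqs < low_frac * med)
    if (length(low) == 0L) break
    # unit char positions covered by a low k-mer (1-based, cyclic)
    cov <- sort(unique(unlist(lapply(low - 1L, function(p) {
      (p + 0:(k - 1L)) %% m + 1L
    }))))
    # evaluate every suspect position and apply the single operation with
    # the largest frequency gain over its no-op; applying the first local
    # improvement instead can patch around the true error
    best_gain <- 0; best_uc <- NULL
    for (p in cov) {
      ops <- .repair_ops(uc, p)
      scores <- vapply(ops, function(op) {
        .locus_score(op$uc, op$locus, g)
      }, numeric(1))
      pick <- which.max(scores)  # no-op is first: it wins ties
      gain <- scores[pick] - scores[1L]
      if (pick != 1L && gain > best_gain) {
        best_gain <- gain
        best_uc <- ops[[pick]]$uc
      }
    }
    if (is.null(best_uc)) break
    uc <- best_uc  # re-scan frequencies after each applied edit
  }
  .decode_bases(uc)
}

# The operation table at unit position p: no-op, 3 substitutions,
# deletion, 4 insertions.  Each entry carries the modified unit codes and
# the locus at which covering k-mers are scored.
.repair_ops <- function(uc, p) {
  m <- length(uc)
  ops <- list(list(uc = uc, locus = p))
  for (a in setdiff(0:3, uc[p])) {
    v <- uc; v[p] <- a
    ops[[length(ops) + 1L]] <- list(uc = v, locus = p)
  }
  if (m > 1L) {
    v <- uc[-p]
    ops[[length(ops) + 1L]] <- list(uc = v,
                                    locus = if (p > 1L) p - 1L else m - 1L)
  }
  for (a in 0:3) {
    v <- append(uc, a, after = p)
    ops[[length(ops) + 1L]] <- list(uc = v, locus = p + 1L)
  }
  ops
}

#' Binomial upper tail for a multiple-alignment column
#'
#' `p(K)` is the probability of observing `K` or more identical events
#' (replacements by a fixed base, deletions, or insertions of a fixed
#' base) in an alignment column of depth `d` when each row errs that way
#' independently with probability `eps / 4`:
#' `p(K) = sum_{k=K}^{d} C(d, k) (eps/4)^k (1 - eps/4)^(d-k)`.
#'
#' @param K Observed count (0 <= K <= d).
#' @param d Column depth (number of unit copies in the alignment).
#' @param eps Average error rate of the alignment, in `[0, 1)`.
#' @return The exact binomial tail probability.
#' @export
column_tail <- function(K, d, eps) {
  stopifnot(K >= 0, d >= 0, eps >= 0, eps < 1)
  if (K > d) stop("K cannot exceed the depth d")
  if (K == 0) return(1)
  stats::pbinom(K - 1, d, eps / 4, lower.tail = FALSE)
}

#' Polish a unit by multiple-alignment column tests
#'
#' Wraparound-aligns the unit to `R[s, e]`; the induced decomposition of
#' the interval into unit copies gives, for each unit position `j`,
#' column counts: how often each base is aligned there, how often the
#' unit base is deleted, and how often each base is inserted after `j`.
#' Each of the `8 |u|` correction hypotheses (3 substitutions, 1
#' deletion, 4 insertions per position) is tested with the exact binomial
#' tail [column_tail()] at the alignment's average error rate; an edit is
#' applied when `p(K) <= 0.01 / (8 |u|)` (Bonferroni over the hypothesis
#' family).  At most one edit per position per pass (the most significant
#' one); the unit is re-aligned and the procedure repeats until fixpoint
#' or `max_pass` passes.  Columns of depth below 2 are never edited, and
#' an alignment whose maximal depth is below 2 leaves the unit unchanged.
#'
#' A genuine consensus error is visible in nearly every aligned copy
#' (a fraction ~`1 - eps` of rows), so an edit additionally requires
#' support from `K >= max(3, 0.3 d)` rows.  This guards against
#' alignment edge artifacts - the anchored first copy and a terminal
#' partial copy can each contribute one systematic event per column,
#' which at a near-zero estimated error rate would otherwise reach
#' formal significance.
#'
#' @param u Unit string.
#' @param seq Read sequence.
#' @param s,e Repeat interval (0-based half-open).
#' @param alpha_total Family-wise significance level (default 0.01).
#' @param max_pass Pass budget.
#' @return The polished unit string.
#' @export
ma_polish <- function(u, seq, s = 0L, e = nchar(seq), alpha_total = 0.01,
                      max_pass = 5L) {
  codes <- .encode_bases(seq)
  .ma_polish_codes(.encode_bases(u), codes, s, e, alpha_total, max_pass)
}

.ma_polish_codes <- function(uc, codes, s, e, alpha_total = 0.01,
                             max_pass = 5L) {
  region <- codes[(s + 1L):e]
  for (pass in seq_len(max_pass)) {
    m <- length(uc)
    if (m < 1L) break
    if ((length(region) + 1) * m > 2.5e8) break  # traceback too large
    aln <- cpp_wraparound(uc, region, TRUE)
    cc <- aln$col_counts
    depth <- colSums(cc[1:5, , drop = FALSE])
    if (max(depth) < 2) break
    eps <- 1 - aln$matches / aln$columns
    if (eps <= 0) break
    alpha <- alpha_total / (8 * m)
    edits <- list()
    for (j in seq_len(m)) {
      d <- depth[j]
      if (d < 2) next
      k_min <- max(3, 0.3 * d)
      best <- NULL
      for (a in setdiff(0:3, uc[j])) {          # replace u[j] by a
        K <- cc[a + 1L, j]
        if (K >= k_min) {
          p <- column_tail(K, d, eps)
          if (is.null(best) || p < best$p) best <- list(p = p, type = "sub",
                                                        a = a)
        }
      }
      K <- cc[5L, j]                            # delete u[j]
      if (K >= k_min) {
        p <- column_tail(K, d, eps)
        if (is.null(best) || p < best$p) best <- list(p = p, type = "del",
                                                      a = NA)
      }
      for (a in 0:3) {                          # insert a after u[j]
        # one copy can carry several identical insertions after the same
        # position; the row-level event count is capped at the depth
        K <- min(cc[5L + a + 1L, j], d)
        if (K >= k_min) {
          p <- column_tail(K, d, eps)
          if (is.null(best) || p < best$p) best <- list(p = p, type = "ins",
                                                        a = a)
        }
      }
      if (!is.null(best) && best$p <= alpha) {
        edits[[length(edits) + 1L]] <- c(best, list(j = j))
      }
    }
    if (length(edits) == 0L) break
    for (ed in rev(edits)) {  # descending j keeps earlier indices valid
      if (ed$type == "sub") uc[ed$j] <- ed$a
      else if (ed$type == "del") uc <- uc[-ed$j]
      else uc <- append(uc, ed$a, after = ed$j)
    }
  }
  .decode_bases(uc)
}
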