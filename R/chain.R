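#' Pseudo-disjoint chaining of repeat calls
#'
#' Selects the subset of candidate calls on one read that maximizes the
#' total alignment score `sigma`, treating two calls as compatible when
#' they overlap by less than `overlap_limit` nt (`T_i -> T_j` allowed iff
#' `s_j >= e_i - l`).  Tolerating small overlaps keeps the problem a
#' weighted interval chain solvable in O(n log n) (sort by end, best
#' predecessor by binary search over a running prefix maximum), instead
#' of the O(n^2) non-disjoint formulation.  Residual overlaps are
#' resolved exactly afterwards by [finalize_calls()].
#'
#' Calls with identical intervals (typically the same repeat found at
#' several grid patterns) are first deduplicated, keeping the best
#' `sigma`.  Calls spanning less than `overlap_limit` nt are dropped:
#' the overlap notion presumes `s_i < s_j < e_i < e_j`, and an interval
#' shorter than the tolerated overlap could nest inside another while
#' formally passing the predicate, derailing the split step.  Once every
#' span is at least `l`, `e_i <= s_j + l - 1` forces `s_i < s_j`, so
#' chains progress rightward at both ends.
#'
#' @param calls A tibble of candidate calls with columns `read_id`, `s`,
#'   `e`, `sigma` (one read only).
#' @param overlap_limit Overlap tolerated as "disjoint", in nt
#'   (default 10).
#' @return The selected calls, in coordinate order.
#' @export
chain_calls <- function(calls, overlap_limit = 10L) {
  if (nrow(calls) == 0L) return(calls)
  if (length(unique(calls$read_id)) > 1L) {
    stop("chain_calls expects calls from a single read")
  }
  calls <- calls[calls$e - calls$s >= overlap_limit, ]
  if (nrow(calls) == 0L) return(calls)
  # dedup identical intervals, keep max sigma
  calls <- dplyr::slice_max(
    dplyr::group_by(calls, .data$s, .data$e),
    order_by = .data$sigma, n = 1L, with_ties = FALSE)
  calls <- dplyr::ungroup(calls)

  ord <- order(calls$e, calls$s)
  calls <- calls[ord, ]
  n <- nrow(calls)
  ends <- calls$e
  best <- numeric(n)       # best chain weight ending at call i
  pred <- integer(n)       # predecessor call index (0 = none)
  prefmax <- numeric(n)    # running max of best[1..i]
  prefarg <- integer(n)
  for (j in seq_len(n)) {
    cutoff <- calls$s[j] + overlap_limit - 1L  # overlap strictly below l
    idx <- findInterval(cutoff, ends)
    idx <- min(idx, j - 1L)
    base <- if (idx >= 1L) prefmax[idx] else 0
    pred[j] <- if (idx >= 1L && base > 0) prefarg[idx] else 0L
    best[j] <- calls$sigma[j] + max(base, 0)
    if (j == 1L || best[j] > prefmax[j - 1L]) {
      prefmax[j] <- best[j]; prefarg[j] <- j
    } else {
      prefmax[j] <- prefmax[j - 1L]; prefarg[j] <- prefarg[j - 1L]
    }
  }
  sel <- integer(0)
  j <- prefarg[n]
  while (j > 0L) {
    sel <- c(j, sel)
    j <- pred[j]
  }
  out <- calls[sel, ]
  out[order(out$s), ]
}

#' Finalize chained calls into strictly disjoint repeat records
#'
#' Chained calls may still overlap by up to the chaining tolerance; each
#' consecutive overlapping pair is cut at the optimal split point
#' [split_point()], and scores, copy numbers and identities are
#' recomputed on the trimmed intervals (trimming can only lower a call's
#' `sigma`).  Calls trimmed below one unit length are dropped.
#'
#' @param calls Chained calls for one read (tibble with `s`, `e`, `unit`,
#'   `sigma`, ...).
#' @param seq The read sequence.
#' @return A tibble of strictly disjoint calls sorted by start.
#' @export
finalize_calls <- function(calls, seq) {
  codes <- .encode_bases(seq)
  .finalize_calls_codes(calls, codes)
}

.finalize_calls_codes <- function(calls, codes) {
  if (nrow(calls) <= 1L) return(calls)
  calls <- calls[order(calls$s), ]
  for (r in seq_len(nrow(calls) - 1L)) {
    ei <- calls$e[r]; sj <- calls$s[r + 1L]
    if (sj < ei) {
      xstar <- .split_point_codes(
        .encode_bases(calls$unit[r]), .encode_bases(calls$unit[r + 1L]),
        calls$s[r], ei, sj, calls$e[r + 1L], codes)
      calls$e[r] <- xstar
      calls$s[r + 1L] <- xstar
    }
  }
  keep <- logical(nrow(calls))
  last_e <- -1L
  for (r in seq_len(nrow(calls))) {
    span <- calls$e[r] - calls$s[r]
    ulen <- nchar(calls$unit[r])
    if (span >= max(ulen, 1L) && calls$s[r] >= last_e) {
      met <- .call_metrics_codes(.encode_bases(calls$unit[r]), codes,
                                 calls$s[r], calls$e[r])
      calls$sigma[r] <- met$sigma
      if (!is.null(calls$copies)) calls$copies[r] <- met$copies
      if (!is.null(calls$identity)) calls$identity[r] <- met$identity
      keep[r] <- TRUE
      last_e <- calls$e[r]
    }
  }
  calls[keep, ]
}
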