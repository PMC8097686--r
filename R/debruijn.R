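#' de Bruijn graph of a read range
#'
#' Counts every k-mer of `R[s, e]` (0-based half-open).  Nodes are the
#' observed k-mers; edges `v -> z` exist when `v = bx`, `z = xa` for
#' single bases `a`, `b` and a (k-1)-mer `x`, so each node has at most
#' four successors and four predecessors.  Edges are implicit: only node
#' frequencies are stored.
#'
#' @param seq Read sequence.
#' @param s,e Range (0-based half-open); defaults to the whole read.
#' @param k k-mer length (`e - s >= k`).
#' @return An object of class `"debruijn"`: list with `k`, sorted unique
#'   `codes`, their `counts`, and `span = e - s`.
#' @export
build_debruijn <- function(seq, s = 0L, e = nchar(seq), k = 5L) {
  codes <- .encode_bases(seq)
  .build_debruijn_codes(codes, s, e, k)
}

.build_debruijn_codes <- function(codes, s, e, k) {
  if (e - s < k) stop("range shorter than k")
  if (s < 0L || e > length(codes)) stop("range outside the read")
  kc <- cpp_kmer_codes(codes[(s + 1L):e], k)
  r <- rle(sort.int(kc, method = "radix"))
  structure(list(k = k, codes = r$values, counts = r$lengths,
                 span = e - s),
            class = "debruijn")
}

#' @export
print.debruijn <- function(x, ...) {
  cat(sprintf("de Bruijn graph: k = %d, %d nodes, %d k-mers over %d nt\n",
              x$k, length(x$codes), sum(x$counts), x$span))
  invisible(x)
}

# Frequency lookup of k-mer codes in a debruijn graph (0 when absent).
.dbg_freq <- function(g, v) {
  idx <- findInterval(v, g$codes)
  ok <- idx > 0L
  ok[ok] <- g$codes[idx[ok]] == v[ok]
  out <- integer(length(v))
  out[ok] <- g$counts[idx[ok]]
  out
}

#' Greedy heaviest-cycle traversal of a de Bruijn graph
#'
#' From a start k-mer `kappa`, frontiers `next^h({v})` are expanded, where
#' `next(V)` keeps the successors of maximum frequency over the whole
#' frontier, until the frontier is empty (failure), a singleton, or
#' contains `kappa` (the cycle closes).  Multi-step paths through a
#' frontier are reconstructed by parent pointers, preferring at each
#' backtrack step the predecessor of maximal frequency (ties: smallest
#' code).  Edge labels concatenated along the closed walk spell the unit.
#' With `forward = FALSE` edges are traversed backwards and the spelled
#' labels reversed.  Expansion is capped at `max_steps` frontier steps and
#' the cycle at `max_len` edges, so pathological graphs terminate.
#'
#' @param g A `"debruijn"` graph.
#' @param kappa Start k-mer, as a string or integer code; must be a node.
#' @param forward Traverse edges forwards (default) or backwards.
#' @param max_len Maximum cycle length (edges).
#' @return `NULL` on failure, else a list with `unit` (string spelled by
#'   the cycle), `nodes` (k-mer codes on the cycle) and `weight` (sum of
#'   node frequencies on the cycle).
#' @export
greedy_cycle <- function(g, kappa, forward = TRUE,
                         max_len = floor(g$span / 2)) {
  stopifnot(inherits(g, "debruijn"))
  if (is.character(kappa)) kappa <- encode_kmer(kappa)
  if (.dbg_freq(g, kappa) == 0L) stop("start k-mer is not in the graph")
  res <- cpp_greedy_cycle(g$codes, g$counts, g$k, kappa, forward,
                          as.integer(max_len), g$span)
  if (!isTRUE(res$found)) return(NULL)
  labels <- res$labels
  if (!forward) labels <- rev(labels)
  list(unit = .decode_bases(labels), nodes = res$nodes,
       weight = res$weight)
}

#' Assemble the consensus repeat unit of a candidate range
#'
#' For each k in `k_range`, builds the de Bruijn graph of `R[s, e]`,
#' starts a greedy heaviest-cycle search at every most-frequent k-mer
#' (backward traversal is retried when every forward search fails), and
#' keeps the heaviest cycle.  Each successful cycle `u` is scored against
#' `R[s, e]` by wraparound alignment, `sigma = (e - s) - delta` with
#' `delta` the Levenshtein distance to the best tandem extension of `u`,
#' and the candidate with the best `sigma` over all k wins (ties: shorter
#' unit, then smaller k, so a doubled unit never beats its primitive
#' root).  Returns `NULL` when every k fails, in which case the range is
#' ignored.
#'
#' @param seq Read sequence.
#' @param s,e Candidate range (0-based half-open).
#' @param k_range k-mer lengths to sweep (default 2..15).
#' @param max_unit Cap on the unit length; additionally a unit longer
#'   than half the range cannot repeat in it and is rejected.
#' @return `NULL`, or a list with `unit`, `k_used`, `cycle_weight`,
#'   `sigma`.
#' @export
assemble_unit <- function(seq, s = 0L, e = nchar(seq), k_range = 2:15,
                          max_unit = 500L) {
  codes <- .encode_bases(seq)
  .assemble_unit_codes(codes, s, e, k_range, max_unit)
}

.assemble_unit_codes <- function(codes, s, e, k_range, max_unit,
                                 eval_span = 5000L,
                                 eval_s = s, eval_e = e) {
  span <- e - s
  # candidate units from different k are ranked by sigma on a bounded
  # window at the CENTER of the evaluation interval.  The graph range
  # [s, e] may carry padding, but scoring must not: random flank in the
  # scored region rewards long overfitted cycles that soak up flank and
  # error text.  A central window holding many unit copies ranks the k
  # sweep like the full span at a fraction of the cost; final scores are
  # recomputed on the full interval downstream.
  ev <- min(eval_e - eval_s, max(eval_span, 10L * max_unit))
  off <- (eval_e - eval_s - ev) %/% 2L
  region <- codes[(eval_s + off + 1L):(eval_s + off + ev)]
  best <- NULL
  for (k in k_range) {
    if (span < k + 1L) next
    g <- .build_debruijn_codes(codes, s, e, k)
    cap <- min(max_unit, floor(span / 2))
    if (cap < 1L) next
    maxf <- max(g$counts)
    # a unit cycle revisits its k-mers once per copy; a graph whose modal
    # count is 1 carries no tandem signal at this k
    if (maxf < 2L) next
    kappas <- g$codes[g$counts == maxf]
    # ties are normally rare; cap degenerate tie sets (smallest codes kept,
    # codes are sorted) so pathological ranges stay cheap
    if (length(kappas) > 64L) kappas <- kappas[seq_len(64L)]
    cyc <- .best_cycle(g, kappas, TRUE, cap)
    if (is.null(cyc)) cyc <- .best_cycle(g, kappas, FALSE, cap)
    if (is.null(cyc)) next
    ucodes <- .encode_bases(cyc$unit)
    delta <- cpp_wraparound(ucodes, region, FALSE)$delta
    sigma <- length(region) - delta
    cand <- list(unit = cyc$unit, k_used = k, cycle_weight = cyc$weight,
                 sigma = sigma)
    if (is.null(best) ||
        sigma > best$sigma ||
        (sigma == best$sigma && nchar(cand$unit) < nchar(best$unit))) {
      best <- cand
    }
  }
  best
}

# Heaviest successful greedy cycle over a set of start vertices.
.best_cycle <- function(g, kappas, forward, max_len) {
  best <- NULL
  for (kap in kappas) {
    res <- cpp_greedy_cycle(g$codes, g$counts, g$k, kap, forward,
                            as.integer(max_len), g$span)
    if (!isTRUE(res$found)) next
    labels <- res$labels
    if (!forward) labels <- rev(labels)
    cand <- list(unit = .decode_bases(labels), weight = res$weight)
    if (is.null(best) || cand$weight > best$weight ||
        (cand$weight == best$weight && cand$unit < best$unit)) {
      best <- cand
    }
  }
  best
}
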