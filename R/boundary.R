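#' The (k, w) scanning grid
#'
#' The geometric grid of k-mer length and window size pairs used to scan a
#' read: `(k, w) = (5, 5 * 2^l)` for `l = 0..11`, `(3, 5 * 2^l)` for
#' `l = 0..4` and `(1, 5 * 2^l)` for `l = 0..2` - twenty patterns in all.
#' A tandem repeat of span `L` with unit `u` is detectable at a pattern
#' when `2|u| <= w <= L/2` and `k <= |u| < c * 4^k` (with `c = 1/4`), and
#' for units up to ~500 nt and spans below 1e5 at least one grid pattern
#' satisfies both.
#'
#' @return A tibble with columns `k` and `w`, one row per pattern.
#' @export
parameter_grid <- function() {
  tibble::tibble(
    k = c(rep(5L, 12L), rep(3L, 5L), rep(1L, 3L)),
    w = c(5L * 2L^(0:11), 5L * 2L^(0:4), 5L * 2L^(0:2))
  )
}

#' Boundary scores B and E along a read
#'
#' For window size `w`, `S(i, i+w)` is the similarity of the k-mer
#' frequency vectors of the adjacent windows `[i, i+w)` and `[i+w, i+2w)`.
#' The start statistic is `B(i, w) = S(i, i+w) - S(i-w, i)`: at the left
#' boundary of a tandem repeat the two windows to the right of `i` lie
#' inside the repeat and correlate strongly, while the window pair
#' straddling `i` does not, so `B` peaks there.  Symmetrically
#' `E(i, w) = S(i-2w, i-w) - S(i-w, i) = -B(i-w, w)` peaks at the right
#' boundary.  `B` is defined for `i` in `[w, n-2w]`, `E` for
#' `[2w, n-w]`; a read shorter than `3w` yields no scores.
#'
#' @param seq Read sequence.
#' @param w Window size (nt).
#' @param k k-mer length.
#' @param method Similarity measure, `"manhattan"` or `"pearson"`.
#' @return A tibble with columns `pos`, `stat` (`"B"` or `"E"`) and
#'   `score`.
#' @export
boundary_scores <- function(seq, w, k, method = c("manhattan", "pearson")) {
  m <- .similarity_code(method)
  codes <- .encode_bases(seq)
  .boundary_scores_codes(codes, w, k, m)
}

.boundary_scores_codes <- function(codes, w, k, mcode) {
  n <- length(codes)
  if (n < 3L * w) {
    return(tibble::tibble(pos = integer(), stat = character(),
                          score = numeric()))
  }
  B <- .b_scores_codes(codes, w, k, mcode)
  ib <- w:(n - 2L * w)
  tibble::tibble(
    pos = c(ib, ib + w),
    stat = rep(c("B", "E"), each = length(ib)),
    score = c(B, -B)
  )
}

# B(i, w) for i = w .. n-2w as a bare numeric vector (index t = i - w + 1).
.b_scores_codes <- function(codes, w, k, mcode) {
  S <- cpp_window_sims(codes, k, w, mcode)  # S[t+1] = S(t, t+w)
  n <- length(codes)
  ib <- w:(n - 2L * w)
  S[ib + 1L] - S[ib - w + 1L]
}

#' Candidate tandem repeat ranges at one grid pattern
#'
#' Applies the boundary-peak rule at a single `(k, w)` pattern: a start
#' `b` locally maximizes `B(j, w)` within distance `w` (leftmost position
#' on ties) and reaches the acceptance floor `theta_b`; its end `e` is the
#' closest position with `e >= b + w` that locally maximizes `E` within
#' distance `w` and also reaches the floor.  After a range is emitted the
#' start scan resumes at `e`, so several repeats per read can be
#' reported.  Peak local-maximality alone fires on random fluctuation,
#' hence the configurable floor (default 0.2); it applies to both
#' statistics symmetrically - otherwise small in-repeat fluctuations of
#' `E` would terminate ranges long before the true end.
#'
#' @param seq Read sequence.
#' @param k,w Grid pattern.
#' @param method Similarity measure.
#' @param theta_b Peak acceptance floor for `B` (>= 0).
#' @param read_id Optional read identifier copied into the result.
#' @return A tibble with columns `read_id`, `b`, `e`, `k`, `w`, `peak_b`,
#'   `peak_e`; zero rows when no peak qualifies.
#' @export
detect_candidates <- function(seq, k, w, method = c("manhattan", "pearson"),
                              theta_b = 0.2, read_id = NA_character_) {
  stopifnot(theta_b >= 0)
  m <- .similarity_code(method)
  codes <- .encode_bases(seq)
  .detect_candidates_codes(codes, k, w, m, theta_b, read_id)
}

.detect_candidates_codes <- function(codes, k, w, mcode, theta_b, read_id) {
  empty <- tibble::tibble(read_id = character(), b = integer(),
                          e = integer(), k = integer(), w = integer(),
                          peak_b = numeric(), peak_e = numeric())
  n <- length(codes)
  if (n < 3L * w) return(empty)
  B <- .b_scores_codes(codes, w, k, mcode)
  hits <- cpp_detect_ranges(B, w, theta_b)
  if (nrow(hits) == 0L) return(empty)
  tibble::tibble(
    read_id = read_id,
    b = as.integer(hits[, 1L]),
    e = as.integer(hits[, 2L]),
    k = k, w = w,
    peak_b = hits[, 3L],
    peak_e = hits[, 4L]
  )
}

#' Scan a read over the whole (k, w) grid
#'
#' Runs [detect_candidates()] for every pattern of [parameter_grid()]
#' (patterns wider than a third of the read are skipped, as their score
#' domain is empty) and concatenates the results.  Overlapping or
#' duplicated candidates from different patterns are deliberately kept:
#' they are resolved downstream by unit assembly, scoring and chaining.
#'
#' @inheritParams detect_candidates
#' @param grid A tibble of `(k, w)` patterns; defaults to the standard
#'   twenty.
#' @return A tibble of candidate ranges as in [detect_candidates()].
#' @export
scan_read <- function(seq, method = c("manhattan", "pearson"),
                      theta_b = 0.2, grid = parameter_grid(),
                      read_id = NA_character_) {
  m <- .similarity_code(method)
  codes <- .encode_bases(seq)
  .scan_read_codes(codes, m, theta_b, grid, read_id)
}

.scan_read_codes <- function(codes, mcode, theta_b, grid, read_id) {
  out <- purrr::map(seq_len(nrow(grid)), function(r) {
    .detect_candidates_codes(codes, grid$k[r], grid$w[r], mcode, theta_b,
                             read_id)
  })
  dplyr::bind_rows(out)
}
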