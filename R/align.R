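#' Wraparound alignment of a unit against a read interval
#'
#' Aligns `R[s, e]` to the tandem extensions of `u` - any substring of
#' the unbounded repetition of `u` - with wraparound dynamic programming:
#' DP columns are unit positions and wrap from the last column back to
#' the first, so the unit can be traversed any number of times, and both
#' terminal phases are free (a repeat interval may begin and end with a
#' partial copy).  The score is therefore exactly invariant under
#' rotation of the unit.  Costs are unit (substitution = insertion =
#' deletion = 1); the score is `sigma = (e - s) - delta` with `delta`
#' the minimal Levenshtein distance, i.e. matches minus differences of
#' the optimal alignment.
#'
#' Row minima give the whole prefix-score array
#' `prefix_sigma[x - s + 1] = sigma(u, R[s, x])` in the same single pass;
#' it is the ingredient for optimal split points between overlapping
#' calls and for trimming repeat boundaries.
#'
#' @param unit Unit string (non-empty).
#' @param seq Read sequence.
#' @param s,e Interval (0-based half-open), default whole read.
#' @param full Also run the traceback, yielding `copies` (unit traversals
#'   of the optimal alignment, wrap count plus final fractional phase),
#'   `identity` (matches over alignment columns) and the per-unit-position
#'   column counts used by [ma_polish()].
#' @return An object of class `"wraparound_alignment"`: list with
#'   `sigma`, `delta`, `prefix_sigma`, and when `full = TRUE` also
#'   `copies`, `identity`, `matches`, `columns`, `col_counts` (9 x |u|
#'   matrix with rows A, C, G, T, del, insA, insC, insG, insT).
#' @examples
#' a <- wraparound_align("ACG", "ACGACGACGACG")
#' a$sigma   # 12
#' a$copies  # 4
#' @export
wraparound_align <- function(unit, seq, s = 0L, e = nchar(seq),
                             full = TRUE) {
  if (!is.character(unit) || length(unit) != 1L || nchar(unit) < 1L) {
    stop("unit must be a non-empty string")
  }
  if (e <= s) stop("interval must be non-empty")
  codes <- .encode_bases(seq)
  .wraparound_codes(.encode_bases(unit), codes, s, e, full)
}

.wraparound_codes <- function(ucodes, codes, s, e, full) {
  region <- codes[(s + 1L):e]
  raw <- cpp_wraparound(ucodes, region, full)
  span <- e - s
  out <- list(
    sigma = span - raw$delta,
    delta = raw$delta,
    prefix_sigma = seq(0L, span) - as.numeric(raw$prefix_delta),
    unit = .decode_bases(ucodes),
    s = s, e = e
  )
  if (full) {
    cc <- raw$col_counts
    rownames(cc) <- c("A", "C", "G", "T", "del",
                      "insA", "insC", "insG", "insT")
    out$copies <- raw$copies
    out$identity <- if (raw$columns > 0) raw$matches / raw$columns else 0
    out$matches <- raw$matches
    out$columns <- raw$columns
    out$col_counts <- cc
  }
  class(out) <- "wraparound_alignment"
  out
}

#' @export
print.wraparound_alignment <- function(x, ...) {
  cat(sprintf(
    "wraparound alignment: |u| = %d over [%d, %d), sigma = %d, delta = %d\n",
    nchar(x$unit), x$s, x$e, x$sigma, x$delta))
  if (!is.null(x$copies)) {
    cat(sprintf("  copies = %.2f, identity = %.4f\n", x$copies, x$identity))
  }
  invisible(x)
}

#' Longest-common-subsequence similarity of two strings
#'
#' `|LCS(a, b)|` divided by the average of the two lengths.  This is the
#' similarity used to decide whether a string is an approximate tandem
#' repeat of a perfect one.
#'
#' @param a,b Non-empty strings over A/C/G/T.
#' @return A value in `[0, 1]`; 1 when the strings are equal.
#' @examples
#' lcs_similarity("ACAACGACGGCG", "ACGACGACGACG")  # 10/12
#' @export
lcs_similarity <- function(a, b) {
  stopifnot(nchar(a) >= 1L, nchar(b) >= 1L)
  l <- cpp_lcs(.encode_bases(a), .encode_bases(b))
  l / ((nchar(a) + nchar(b)) / 2)
}

#' Optimal split point between two overlapping repeat calls
#'
#' For calls `T_i` (left) and `T_j` (right) on the same read, the split
#' score is `o(x) = sigma(u_i, R[s_i, x]) + sigma(u_j, R[x, e_j])`; the
#' split point `x*` maximizes `o(x)` over `x` in `[s_j, e_i]` (smallest
#' `x` on ties).  Disjoint calls split at `x* = e_i`.  The two sigma
#' terms come from the prefix-score array of a forward alignment of
#' `u_i` and of a reversed alignment of `u_j`.
#'
#' @param call_i,call_j Lists or one-row data frames with `s`, `e`,
#'   `unit` (and `call_i$s < call_j$s`).
#' @param seq The read sequence.
#' @return The split position `x*` (0-based).
#' @export
split_point <- function(call_i, call_j, seq) {
  si <- call_i$s[[1L]]; ei <- call_i$e[[1L]]
  sj <- call_j$s[[1L]]; ej <- call_j$e[[1L]]
  stopifnot(si < sj)
  if (ei <= sj) return(ei)
  codes <- .encode_bases(seq)
  .split_point_codes(.encode_bases(call_i$unit[[1L]]),
                     .encode_bases(call_j$unit[[1L]]),
                     si, ei, sj, ej, codes)
}

.split_point_codes <- function(ui, uj, si, ei, sj, ej, codes) {
  if (ei <= sj) return(ei)
  # clamp against pathological nesting left over from earlier trims
  lo <- max(sj, si); hi <- max(lo, min(ei, ej))
  # sigma(u_i, R[s_i, x]) for x = s_i..e_i from the forward prefix array
  fwd <- cpp_wraparound(ui, codes[(si + 1L):ei], FALSE)
  pre_i <- seq(0L, ei - si) - as.numeric(fwd$prefix_delta)
  # sigma(u_j, R[x, e_j]) for x = s_j..e_j from a reversed alignment
  rev_ <- cpp_wraparound(rev(uj), rev(codes[(sj + 1L):ej]), FALSE)
  suf_j <- seq(0L, ej - sj) - as.numeric(rev_$prefix_delta)
  xs <- lo:hi
  o <- pre_i[xs - si + 1L] + suf_j[ej - xs + 1L]
  xs[which.max(o)]  # which.max takes the first (smallest x) on ties
}

#' Canonical rotation of a repeat unit
#'
#' Rotations of a unit describe the same tandem repeat; the
#' lexicographically least rotation is used for reporting so results are
#' deterministic and comparable.
#'
#' @param u Unit string.
#' @return The smallest rotation of `u`.
#' @examples
#' canonical_rotation("CGA")  # "ACG"
#' @export
canonical_rotation <- function(u) {
  n <- nchar(u)
  if (n <= 1L) return(u)
  dd <- paste0(u, u)
  rots <- substring(dd, 1:n, n:(2L * n - 1L))
  min(rots)
}

#' Rotation-aware identity between two units
#'
#' Maximum over the cyclic rotations `r` of `pred` of
#' `1 - levenshtein(r, truth) / max(|r|, |truth|)`.
#'
#' @param pred,truth Unit strings.
#' @return Identity in `[0, 1]`; 1 iff some rotation of `pred` equals
#'   `truth`.
#' @export
rotation_identity <- function(pred, truth) {
  n <- nchar(pred)
  tc <- .encode_bases(truth)
  if (n == nchar(truth) &&
      grepl(pred, paste0(truth, truth), fixed = TRUE)) {
    return(1)
  }
  dd <- .encode_bases(paste0(pred, pred))
  mx <- max(n, nchar(truth))
  best <- 0
  for (r in 0:(n - 1L)) {
    d <- cpp_edit(dd[(r + 1L):(r + n)], tc)
    ident <- 1 - d / mx
    if (ident > best) best <- ident
    if (best == 1) break
  }
  best
}
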