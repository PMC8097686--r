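#' Encode a k-mer as a quaternary integer
#'
#' Maps the nucleotides A, C, G, T to the digits 0, 1, 2, 3 and reads the
#' k-mer as a k-digit quaternary number, leftmost character most
#' significant.  `k` is limited to 15 so every code fits in a 32-bit
#' integer.
#'
#' @param s A single string over A/C/G/T.
#' @return The integer code in `[0, 4^k)`.
#' @examples
#' encode_kmer("ACG")  # 6
#' @export
encode_kmer <- function(s) {
  stopifnot(is.character(s), length(s) == 1L)
  k <- nchar(s)
  if (k < 1L) stop("k-mer must be non-empty")
  if (k > 15L) stop("k-mers longer than 15 are not supported")
  codes <- .encode_bases(s)
  as.integer(sum(codes * 4^((k - 1L):0L)))
}

#' Decode a quaternary k-mer code back to a string
#'
#' @param code Integer code in `[0, 4^k)`.
#' @param k k-mer length.
#' @export
decode_kmer <- function(code, k) {
  stopifnot(k >= 1L, k <= 15L, code >= 0, code < 4^k)
  digits <- integer(k)
  x <- code
  for (j in k:1L) {
    digits[j] <- x %% 4L
    x <- x %/% 4L
  }
  paste(.BASES[digits + 1L], collapse = "")
}

#' k-mer frequency vector of a window
#'
#' Counts all `4^k` k-mers inside the window `R[i, i+w]` of a read.
#' Positions are inter-base and 0-based: position `i` lies between the
#' i-th and (i+1)-th character, so `R[a, b]` has length `b - a`.
#'
#' @param seq Read sequence (single string over A/C/G/T).
#' @param i Window start position (0-based, inter-base).
#' @param w Window length in nt.
#' @param k k-mer length (`k <= w`).
#' @return An integer vector of length `4^k` with attributes `k`, `w`,
#'   `start`, of class `"kmer_profile"`.  Its entries sum to `w - k + 1`.
#' @examples
#' window_profile("TCAGACACACACGGTC", 4, 4, 1)  # (2, 2, 0, 0)
#' @export
window_profile <- function(seq, i, w, k) {
  codes <- .encode_bases(seq)
  .window_profile_codes(codes, i, w, k)
}

.window_profile_codes <- function(codes, i, w, k) {
  n <- length(codes)
  if (k < 1L || k > 12L) stop("k must be in 1..12")
  if (w < k) stop("window length w must be at least k")
  if (i < 0L || i + w > n) stop("window lies outside the read")
  kc <- cpp_kmer_codes(codes[(i + 1L):(i + w)], k)
  counts <- tabulate(kc + 1L, nbins = 4L^k)
  structure(counts, k = k, w = w, start = i, class = "kmer_profile")
}

#' Slide a window profile one position to the right
#'
#' Updates the k-mer frequency vector incrementally: the count of the
#' k-mer leaving at the left edge is decremented and the one entering at
#' the right edge is incremented, so a full scan over a read costs time
#' linear in its length.
#'
#' @param p A `kmer_profile` (from [window_profile()]).
#' @param seq The read the profile was computed on.
#' @return The profile of the window starting at `start + 1`.
#' @export
slide_profile <- function(p, seq) {
  k <- attr(p, "k"); w <- attr(p, "w"); i <- attr(p, "start")
  codes <- .encode_bases(seq)
  n <- length(codes)
  if (i + 1L + w > n) stop("cannot slide past the end of the read")
  out_code <- cpp_kmer_codes(codes[(i + 1L):(i + k)], k)
  in_code <- cpp_kmer_codes(codes[(i + 2L + w - k):(i + 1L + w)], k)
  q <- unclass(p)
  q[out_code + 1L] <- q[out_code + 1L] - 1L
  q[in_code + 1L] <- q[in_code + 1L] + 1L
  structure(q, k = k, w = w, start = i + 1L, class = "kmer_profile")
}

#' Similarity of two k-mer frequency vectors
#'
#' Two normalized measures on profiles of equal `k` and `w`:
#' * `"manhattan"`: `1 - L1(p, q) / (2w)`, in `[0, 1]` since the L1
#'   distance of two count vectors summing to `w - k + 1` is at most `2w`.
#' * `"pearson"`: `(rho + 1) / 2` with `rho` the Pearson correlation over
#'   the `4^k` entries.  A zero-variance profile (e.g. a homopolymer
#'   window) has no defined correlation; the similarity is then 0.5, the
#'   "no correlation" midpoint, so boundary scores degrade gracefully on
#'   low-complexity flanks instead of spiking.
#'
#' @param p,q `kmer_profile` objects with identical `k` and `w`.
#' @param method `"manhattan"` or `"pearson"`.
#' @return A similarity in `[0, 1]`.
#' @export
profile_similarity <- function(p, q, method = c("manhattan", "pearson")) {
  method <- match.arg(method)
  if (!identical(attr(p, "k"), attr(q, "k")) ||
      !identical(attr(p, "w"), attr(q, "w"))) {
    stop("profiles must share k and w")
  }
  w <- attr(p, "w")
  pv <- as.numeric(p); qv <- as.numeric(q)
  if (method == "manhattan") {
    1 - sum(abs(pv - qv)) / (2 * w)
  } else {
    if (stats::var(pv) == 0 || stats::var(qv) == 0) return(0.5)
    rho <- stats::cor(pv, qv)
    (rho + 1) / 2
  }
}

.similarity_code <- function(method) {
  match(match.arg(method, c("manhattan", "pearson")),
        c("manhattan", "pearson"))
}
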