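#' Pipeline configuration
#'
#' Collects the tunable parameters of the repeat caller.  Defaults follow
#' the method's standard setting; all values are echoed into logs and
#' output headers by the command-line wrappers for reproducibility.
#'
#' @param similarity Window similarity measure, `"manhattan"` or
#'   `"pearson"` (both perform comparably; Manhattan is the default).
#' @param theta_b Acceptance floor for boundary peaks (see
#'   [detect_candidates()]).
#' @param k_range k-mer sweep for unit assembly (default 2..15).
#' @param max_unit Maximal unit length considered (default 500 nt).
#' @param overlap_limit Chaining overlap tolerance `l` in nt (default 10).
#' @param min_sigma_frac Minimal `sigma / (e - s)` for a call to enter
#'   chaining; drops junk candidates on repeat-free stretches.
#' @param min_span Minimal repeat span in nt (at least the chaining
#'   overlap tolerance, so no call can nest inside another's tolerated
#'   overlap).
#' @param pad Pad candidate ranges by `w / 2` on each side before unit
#'   assembly (boundaries from the window scan are only `w`-accurate;
#'   final boundaries come from the alignment).
#' @param max_cand_per_pattern At each `(k, w)` pattern, keep at most this
#'   many candidate ranges, the strongest by combined peak height
#'   `peak_b + peak_e`.  Genuine boundaries show both a strong start and
#'   a strong end peak, while random fluctuation (frequent at the
#'   smallest windows) rarely does; the cap bounds per-read work without
#'   touching detectability.
#' @param grid The `(k, w)` scanning grid (default [parameter_grid()]).
#' @param low_frac,min_modal Transition-repair triggers (see
#'   [transition_repair()]).
#' @param alpha_total Family-wise level for [ma_polish()].
#' @param max_pass Pass budget of each refinement stage.
#' @return A list of class `"tr_config"`.
#' @export
tr_config <- function(similarity = c("manhattan", "pearson"),
                      theta_b = 0.2,
                      k_range = 2:15,
                      max_unit = 500L,
                      overlap_limit = 10L,
                      min_sigma_frac = 0.2,
                      min_span = 10L,
                      pad = TRUE,
                      max_cand_per_pattern = 12L,
                      grid = parameter_grid(),
                      low_frac = 0.5,
                      min_modal = 10L,
                      alpha_total = 0.01,
                      max_pass = 5L) {
  similarity <- match.arg(similarity)
  structure(list(similarity = similarity, theta_b = theta_b,
                 k_range = k_range, max_unit = max_unit,
                 overlap_limit = overlap_limit,
                 min_sigma_frac = min_sigma_frac, min_span = min_span,
                 pad = pad, max_cand_per_pattern = max_cand_per_pattern,
                 grid = grid, low_frac = low_frac,
                 min_modal = min_modal, alpha_total = alpha_total,
                 max_pass = max_pass),
            class = "tr_config")
}

# sigma / copies / identity of a unit on an interval; traceback is
# restricted to a prefix of the interval if the DP matrix would not fit.
.call_metrics_codes <- function(ucodes, codes, s, e) {
  m <- length(ucodes)
  span <- e - s
  region <- codes[(s + 1L):e]
  full_ok <- (span + 1) * m <= 2.5e8
  raw <- cpp_wraparound(ucodes, region, full_ok)
  sigma <- span - raw$delta
  if (full_ok) {
    copies <- raw$copies
    identity <- if (raw$columns > 0) raw$matches / raw$columns else 0
  } else {
    sub_e <- s + floor(2.5e8 / m) - 1L
    sub <- cpp_wraparound(ucodes, codes[(s + 1L):sub_e], TRUE)
    identity <- if (sub$columns > 0) sub$matches / sub$columns else 0
    copies <- sub$copies * span / (sub_e - s)
  }
  list(sigma = sigma, copies = copies, identity = identity)
}

# Trim a padded candidate range to the interval best explained by the
# unit.  The trimming score x - 3 * delta(u, prefix) (match +1,
# difference -2) decreases on random sequence (whose per-base distance to
# the tandem language is ~0.5) and increases inside the repeat, so its
# argmax marks the boundary; plain sigma = x - 2 * delta drifts into
# random flanks because its expected slope there is slightly positive.
# The end maximizes the forward score, the start the reversed (suffix)
# score; ties resolve toward the tighter interval.  Returns c(s, e) or
# NULL when degenerate.
.trim_range_codes <- function(ucodes, codes, s, e) {
  region <- codes[(s + 1L):e]
  fwd <- cpp_wraparound(ucodes, region, FALSE)
  pre <- seq(0L, e - s) - 3 * as.numeric(fwd$prefix_delta)
  e2 <- s + which.max(pre) - 1L
  rv <- cpp_wraparound(rev(ucodes), rev(region), FALSE)
  suf <- seq(0L, e - s) - 3 * as.numeric(rv$prefix_delta)
  s2 <- e - (which.max(suf) - 1L)
  if (s2 >= e2) return(NULL)
  c(s2, e2)
}

# Candidate ranges produced by different grid patterns for the same
# repeat are largely coincident; assembling each would repeat identical
# work.  A range is dropped when a kept (wider) range overlaps it by at
# least 80% of the *wider* span, i.e. the two are mutually
# near-coincident.  A narrow range inside a much wider one survives, so
# adjacent distinct repeats covered by one broad candidate are still
# assembled individually.
.merge_near_duplicates <- function(cand) {
  if (nrow(cand) <= 1L) return(cand)
  cand <- cand[order(cand$e - cand$s, decreasing = TRUE), ]
  keep <- rep(TRUE, nrow(cand))
  for (r in seq_len(nrow(cand))[-1L]) {
    prev <- seq_len(r - 1L)
    ov <- pmin(cand$e[prev], cand$e[r]) - pmax(cand$s[prev], cand$s[r])
    longer <- cand$e[prev] - cand$s[prev]
    if (any(keep[prev] & ov >= 0.8 * longer)) keep[r] <- FALSE
  }
  cand[keep, ]
}

# Assemble, refine and score one padded candidate range.  The range is
# trimmed to the interval the raw unit explains BEFORE any consensus
# repair: the padding is putative random flank, and rows of flank forced
# through the unit in the multiple alignment concentrate spurious
# indel counts on specific columns, which would mislead the column
# tests.  After repair the boundaries are re-trimmed with the final
# unit.
.process_range <- function(codes, s, e, k_used_w, cfg,
                           eval_s = s, eval_e = e) {
  au <- .assemble_unit_codes(codes, s, e, cfg$k_range, cfg$max_unit,
                             eval_s = eval_s, eval_e = eval_e)
  if (is.null(au)) return(NULL)
  tr <- .trim_range_codes(.encode_bases(au$unit), codes, s, e)
  if (is.null(tr)) return(NULL)
  s1 <- tr[1L]; e1 <- tr[2L]
  if (e1 - s1 < max(2L * nchar(au$unit), au$k_used + 1L)) return(NULL)
  g <- .build_debruijn_codes(codes, s1, e1, au$k_used)
  u <- transition_repair(au$unit, g, cfg$low_frac, cfg$min_modal,
                         cfg$max_pass)
  u <- .ma_polish_codes(.encode_bases(u), codes, s1, e1, cfg$alpha_total,
                        cfg$max_pass)
  if (nchar(u) < 1L) return(NULL)
  uc <- .encode_bases(u)
  tr2 <- .trim_range_codes(uc, codes, s, e)
  if (is.null(tr2)) return(NULL)
  s2 <- tr2[1L]; e2 <- tr2[2L]
  if (e2 - s2 < 2L * nchar(u)) return(NULL)  # a tandem needs two copies
  met <- .call_metrics_codes(uc, codes, s2, e2)
  tibble::tibble(s = s2, e = e2, unit = u, sigma = met$sigma,
                 copies = met$copies, identity = met$identity,
                 k_used = au$k_used, w_used = k_used_w)
}

# Full per-read pipeline on base codes.
.call_read_codes <- function(codes, read_id, cfg) {
  empty <- tibble::tibble(
    read_id = character(), s = integer(), e = integer(),
    unit = character(), sigma = numeric(), copies = numeric(),
    identity = numeric(), k_used = integer(), w_used = integer())
  n <- length(codes)
  if (n == 0L) return(empty)
  mcode <- .similarity_code(cfg$similarity)
  cand <- .scan_read_codes(codes, mcode, cfg$theta_b, cfg$grid, read_id)
  if (nrow(cand) == 0L) return(empty)
  mc <- cfg$max_cand_per_pattern
  if (!is.null(mc) && is.finite(mc)) {
    cand <- dplyr::ungroup(dplyr::slice_max(
      dplyr::group_by(cand, .data$k, .data$w),
      order_by = .data$peak_b + .data$peak_e, n = as.integer(mc),
      with_ties = FALSE))
  }
  cand$e0 <- cand$e  # detected interval, kept for unit scoring
  if (cfg$pad) {
    cand$s <- pmax(0L, cand$b - cand$w %/% 2L)
    cand$e <- pmin(n, cand$e + cand$w %/% 2L)
  } else {
    cand$s <- cand$b
  }
  cand <- cand[!duplicated(cand[, c("s", "e")]), ]
  cand <- .merge_near_duplicates(cand)
  # widest first (the merge step returns them so); once a confident call
  # explains a stretch of the read, narrower candidate ranges that lie
  # almost entirely inside already-called intervals are redundant
  calls <- list()
  done_s <- integer(0); done_e <- integer(0)
  for (r in seq_len(nrow(cand))) {
    if (length(done_s) > 0L) {
      ov <- pmin(done_e, cand$e[r]) - pmax(done_s, cand$s[r])
      if (sum(pmax(ov, 0L)) >= 0.8 * (cand$e[r] - cand$s[r])) next
    }
    pr <- .process_range(codes, cand$s[r], cand$e[r], cand$w[r], cfg,
                         eval_s = cand$b[r], eval_e = cand$e0[r])
    if (is.null(pr)) next
    calls[[length(calls) + 1L]] <- pr
    if (pr$sigma >= cfg$min_sigma_frac * (pr$e - pr$s) &&
        pr$identity >= 0.7) {
      done_s <- c(done_s, pr$s); done_e <- c(done_e, pr$e)
    }
  }
  calls <- dplyr::bind_rows(calls)
  if (nrow(calls) == 0L) return(empty)
  calls$read_id <- read_id
  calls <- calls[calls$sigma >= cfg$min_sigma_frac * (calls$e - calls$s) &
                 (calls$e - calls$s) >= cfg$min_span, ]
  if (nrow(calls) == 0L) return(empty)
  calls <- chain_calls(calls, cfg$overlap_limit)
  calls <- .finalize_calls_codes(calls, codes)
  if (nrow(calls) == 0L) return(empty)
  calls$unit <- vapply(calls$unit, canonical_rotation, character(1),
                       USE.NAMES = FALSE)
  calls <- calls[order(calls$s), ]
  dplyr::select(calls, "read_id", "s", "e", "unit", "sigma", "copies",
                "identity", "k_used", "w_used")
}

#' Find tandem repeats in long reads
#'
#' Runs the complete caller on each read: window-profile boundary scan
#' over the `(k, w)` grid, unit assembly by greedy de Bruijn cycles over
#' a k sweep, consensus repair (frequency transitions, then
#' multiple-alignment column tests), boundary trimming by wraparound
#' alignment, and pseudo-disjoint chaining with optimal split points.
#' Reads are processed independently, so results do not depend on read
#' order.
#'
#' @param reads A tibble with columns `read_id` and `seq`, a (named)
#'   character vector of sequences, or a `Biostrings::DNAStringSet`.
#' @param config A [tr_config()] object.
#' @return A tibble with one row per reported repeat: `read_id`, `start`,
#'   `end` (0-based half-open), `repeat_len`, `unit_len`, `unit_seq`
#'   (canonical rotation), `copies`, `sigma`, `identity`, `k_used`,
#'   `w_used`.
#' @examples
#' read <- paste0(strrep("ACGGT", 60), strrep("TTAGGC", 50))
#' find_tandem_repeats(c(r1 = read))
#' @export
find_tandem_repeats <- function(reads, config = tr_config()) {
  reads <- .as_read_tbl(reads)
  out <- purrr::map(seq_len(nrow(reads)), function(r) {
    codes <- .encode_bases(reads$seq[r])
    .call_read_codes(codes, reads$read_id[r], config)
  })
  calls <- dplyr::bind_rows(out)
  if (nrow(calls) == 0L) {
    calls <- tibble::tibble(
      read_id = character(), s = integer(), e = integer(),
      unit = character(), sigma = numeric(), copies = numeric(),
      identity = numeric(), k_used = integer(), w_used = integer())
  }
  tibble::tibble(
    read_id = calls$read_id,
    start = calls$s,
    end = calls$e,
    repeat_len = calls$e - calls$s,
    unit_len = nchar(calls$unit),
    unit_seq = calls$unit,
    copies = calls$copies,
    sigma = calls$sigma,
    identity = calls$identity,
    k_used = calls$k_used,
    w_used = calls$w_used
  )
}

.as_read_tbl <- function(reads) {
  if (inherits(reads, "DNAStringSet")) {
    ids <- names(reads)
    if (is.null(ids)) ids <- paste0("read", seq_along(reads))
    return(tibble::tibble(read_id = ids, seq = as.character(reads)))
  }
  if (is.character(reads)) {
    ids <- names(reads)
    if (is.null(ids)) ids <- paste0("read", seq_along(reads))
    return(tibble::tibble(read_id = unname(ids), seq = unname(reads)))
  }
  if (is.data.frame(reads)) {
    stopifnot(all(c("read_id", "seq") %in% names(reads)))
    return(tibble::as_tibble(reads[, c("read_id", "seq")]))
  }
  stop("unsupported reads input")
}
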