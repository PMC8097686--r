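#' Sequencing error models
#'
#' Per-base i.i.d. error channel: each template base is substituted (to a
#' different base) with probability `sub`, deleted with probability
#' `del`, and followed by a random inserted base with probability `ins`.
#' Presets:
#' * `"nanopore_like"`: 10% mismatch, 5% insertion, 5% deletion - the
#'   worst-case long-read profile the method is designed for.
#' * `"pacbio_like"`: 5% / 6% / 4% - a stylized insertion-biased profile.
#' * `"accurate"`: 1% substitution, 0.5% insertion, 0.5% deletion - the
#'   low-error (~2% total) setting.
#' * `"none"`: error-free.
#'
#' @param sub,ins,del Per-base rates; `sub + ins + del < 1`.
#' @return A list of class `"error_model"`.
#' @export
error_model <- function(sub, ins, del) {
  stopifnot(sub >= 0, ins >= 0, del >= 0, sub + ins + del < 1)
  structure(list(sub = sub, ins = ins, del = del), class = "error_model")
}

#' @rdname error_model
#' @param name Preset name.
#' @export
error_preset <- function(name = c("nanopore_like", "pacbio_like",
                                  "accurate", "none")) {
  name <- match.arg(name)
  switch(name,
    nanopore_like = error_model(0.10, 0.05, 0.05),
    pacbio_like = error_model(0.05, 0.06, 0.04),
    accurate = error_model(0.01, 0.005, 0.005),
    none = error_model(0, 0, 0)
  )
}

.with_seed_if <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(as.integer(seed), code)
}

# Uniform random unit of the given length, rejecting units that are
# themselves perfect tandem repeats of a shorter unit (non-primitive).
.random_unit_codes <- function(len) {
  repeat {
    u <- sample(0:3, len, replace = TRUE)
    if (.is_primitive_codes(u)) return(u)
  }
}

.is_primitive_codes <- function(u) {
  len <- length(u)
  if (len == 1L) return(TRUE)
  divs <- which(len %% seq_len(len - 1L) == 0L)
  !any(vapply(divs, function(d) identical(rep(u[1:d], len %/% d), u),
              logical(1)))
}

#' Generate a pre-error template with a planted tandem repeat
#'
#' A random primitive unit of length `unit_len` repeated `copies` times,
#' flanked on each side by a random string of the same length as the
#' repeat (so boundary prediction is genuinely tested), giving a template
#' of three times the repeat span.  With `partial = TRUE` an additional
#' terminal half-copy of the unit is planted, exercising the prefix rule
#' of the perfect-repeat definition.
#'
#' @param unit_len Unit length in nt.
#' @param copies Number of unit copies.
#' @param seed Optional seed; the same seed yields the identical
#'   template.
#' @param partial Plant a terminal partial copy (default FALSE).
#' @return A one-row tibble: `template`, `unit`, `start`, `end`,
#'   `copies`, `template_len` (positions 0-based inter-base, pre-error).
#' @export
make_truth <- function(unit_len, copies, seed = NULL, partial = FALSE) {
  unit_len <- as.integer(unit_len)
  copies <- as.integer(copies)
  .with_seed_if(seed, {
    u <- .random_unit_codes(unit_len)
    rep_codes <- rep(u, copies)
    extra <- if (partial && unit_len > 1L) u[seq_len(unit_len %/% 2L)]
             else integer(0)
    rep_codes <- c(rep_codes, extra)
    span0 <- unit_len * copies
    fl1 <- sample(0:3, span0, replace = TRUE)
    fl2 <- sample(0:3, span0, replace = TRUE)
    tem <- c(fl1, rep_codes, fl2)
    tibble::tibble(
      template = .decode_bases(tem),
      unit = .decode_bases(u),
      start = as.integer(span0),
      end = as.integer(span0 + length(rep_codes)),
      copies = copies + length(extra) / unit_len,
      template_len = as.integer(length(tem))
    )
  })
}

# Error channel on base codes; returns the read codes and, for every
# template prefix length i, the number of read characters emitted by the
# first i template characters (for mapping truth coordinates into the
# read).
.apply_channel_codes <- function(codes, model) {
  n <- length(codes)
  if (n == 0L) return(list(codes = integer(0), emitted = integer(0)))
  del <- stats::runif(n) < model$del
  sub <- stats::runif(n) < model$sub
  ins <- stats::runif(n) < model$ins
  base <- codes
  nsub <- sum(sub & !del)
  if (nsub > 0) {
    base[sub & !del] <- (base[sub & !del] +
                         sample(1:3, nsub, replace = TRUE)) %% 4L
  }
  nins <- sum(ins)
  ins_base <- if (nins > 0) sample(0:3, nins, replace = TRUE) else integer(0)
  # per template char: 0 or 1 emitted base, then 0 or 1 inserted base
  emit <- as.integer(!del) + as.integer(ins)
  j <- 1L
  pieces <- integer(sum(emit))
  pos <- 1L
  ii <- 1L
  for (i in seq_len(n)) {
    if (!del[i]) { pieces[pos] <- base[i]; pos <- pos + 1L }
    if (ins[i]) { pieces[pos] <- ins_base[ii]; pos <- pos + 1L; ii <- ii + 1L }
  }
  list(codes = pieces, emitted = cumsum(emit))
}

#' Pass a sequence through a substitution/insertion/deletion channel
#'
#' @param seq Template sequence (string over A/C/G/T).
#' @param model An [error_model()].
#' @param seed Optional seed for reproducibility.
#' @return The noisy sequence.  Expected length is
#'   `n * (1 + ins - del)`.
#' @export
apply_errors <- function(seq, model, seed = NULL) {
  stopifnot(inherits(model, "error_model"))
  .with_seed_if(seed, {
    .decode_bases(.apply_channel_codes(.encode_bases(seq), model)$codes)
  })
}

#' Simulate noisy long reads with planted tandem repeats
#'
#' For each row of `design` and each replicate, builds a template with
#' [make_truth()] and passes it through the error channel; the planted
#' repeat's coordinates are mapped through the channel into read space.
#'
#' @param design A data frame with columns `unit_len` and `copies` (one
#'   row per condition).
#' @param error An [error_model()] or preset name.
#' @param n_reads Reads per condition.
#' @param seed Optional master seed (the whole set is reproducible).
#' @param partial Plant terminal partial copies (see [make_truth()]).
#' @return A tibble with one row per read: `read_id`, `seq`, `unit_len`,
#'   `copies`, `true_start`, `true_end`, `true_unit`, `true_copies`
#'   (read-space coordinates, 0-based half-open).
#' @export
simulate_tandem_reads <- function(design, error = error_preset("nanopore_like"),
                                  n_reads = 1L, seed = NULL,
                                  partial = FALSE) {
  if (is.character(error)) error <- error_preset(error)
  stopifnot(inherits(error, "error_model"),
            all(c("unit_len", "copies") %in% names(design)))
  .with_seed_if(seed, {
    rows <- list()
    for (r in seq_len(nrow(design))) {
      ul <- as.integer(design$unit_len[r])
      cp <- as.integer(design$copies[r])
      for (i in seq_len(n_reads)) {
        tr <- make_truth(ul, cp, seed = NULL, partial = partial)
        tem <- .encode_bases(tr$template)
        ch <- .apply_channel_codes(tem, error)
        st <- if (tr$start == 0L) 0L else ch$emitted[tr$start]
        en <- ch$emitted[tr$end]
        rows[[length(rows) + 1L]] <- tibble::tibble(
          read_id = sprintf("sim_u%d_c%d_r%d", ul, cp, i),
          seq = .decode_bases(ch$codes),
          unit_len = ul, copies = cp,
          true_start = st, true_end = en,
          true_unit = tr$unit, true_copies = tr$copies
        )
      }
    }
    dplyr::bind_rows(rows)
  })
}

#' Rotation-aware unit match
#'
#' TRUE when some cyclic rotation of `pred` reaches global-alignment
#' identity at least `tau` against `truth` (`tau = 1` demands an exact
#' rotation; `tau = 0.95` allows e.g. five errors in a 100-nt unit).
#'
#' @param pred Predicted unit.
#' @param truth True unit.
#' @param tau Identity threshold in (0, 1].
#' @export
unit_match <- function(pred, truth, tau = 1) {
  stopifnot(tau > 0, tau <= 1)
  if (nchar(pred) < 1L || nchar(truth) < 1L) return(FALSE)
  rotation_identity(pred, truth) >= tau - 1e-12
}

#' Relative error of a predicted repeat length
#'
#' `|pred_len - true_len| / true_len`.
#'
#' @param pred_len,true_len Lengths in nt (`true_len > 0`).
#' @export
length_error <- function(pred_len, true_len) {
  stopifnot(true_len > 0)
  abs(pred_len - true_len) / true_len
}

#' Score repeat calls against planted truth
#'
#' One row per truth record: whether any reported call on that read
#' matches the planted unit at identity `tau` (rotation-aware), plus the
#' repeat-length error of the best (max `sigma`) matching call.
#'
#' @param calls Calls as returned by [find_tandem_repeats()].
#' @param truth A tibble with `read_id`, `true_unit`, `true_start`,
#'   `true_end` (e.g. from [simulate_tandem_reads()]).
#' @param tau Unit identity threshold.
#' @param length_bound Optional bound on the repeat-length error; when
#'   given, success additionally requires the matching call to satisfy
#'   it.
#' @return A tibble with `read_id`, `success`, `pred_unit`, `pred_len`,
#'   `len_error`.
#' @export
evaluate_calls <- function(calls, truth, tau = 1, length_bound = NULL) {
  out <- purrr::map(seq_len(nrow(truth)), function(r) {
    tid <- truth$read_id[r]
    tu <- truth$true_unit[r]
    tlen <- truth$true_end[r] - truth$true_start[r]
    cc <- calls[calls$read_id == tid, , drop = FALSE]
    hit <- logical(nrow(cc))
    for (i in seq_len(nrow(cc))) hit[i] <- unit_match(cc$unit_seq[i], tu, tau)
    ok <- which(hit)
    if (length(ok) == 0L) {
      return(tibble::tibble(read_id = tid, success = FALSE,
                            pred_unit = NA_character_,
                            pred_len = NA_integer_, len_error = NA_real_))
    }
    best <- ok[which.max(cc$sigma[ok])]
    le <- length_error(cc$repeat_len[best], tlen)
    succ <- if (is.null(length_bound)) TRUE else le <= length_bound
    tibble::tibble(read_id = tid, success = succ,
                   pred_unit = cc$unit_seq[best],
                   pred_len = cc$repeat_len[best], len_error = le)
  })
  dplyr::bind_rows(out)
}

#' Run the synthetic benchmark
#'
#' Generates `n_reads` seeded reads for every `(unit_len, copies)` cell
#' of the design, runs the full caller on each, and reports per-cell
#' sensitivity: the fraction of reads with a reported call whose unit
#' matches the planted one at identity `tau` up to rotation (optionally
#' also within a repeat-length error bound).
#'
#' @inheritParams simulate_tandem_reads
#' @param tau Unit identity threshold (1 = exact).
#' @param length_bound Optional repeat-length error bound.
#' @param config Caller configuration ([tr_config()]).
#' @return A tibble of class `"tandem_benchmark"`: `unit_len`, `copies`,
#'   `n_reads`, `n_success`, `sensitivity`, `mean_len_error` (over
#'   matching reads).
#' @export
run_benchmark <- function(design = benchmark_design(),
                          error = error_preset("nanopore_like"),
                          n_reads = 10L, seed = NULL, tau = 1,
                          length_bound = NULL, config = tr_config()) {
  if (is.character(error)) error <- error_preset(error)
  if (nrow(design) == 0L) {
    return(structure(tibble::tibble(unit_len = integer(),
                                    copies = integer(), n_reads = integer(),
                                    n_success = integer(),
                                    sensitivity = numeric(),
                                    mean_len_error = numeric()),
                     class = c("tandem_benchmark", "tbl_df", "tbl",
                               "data.frame")))
  }
  reads <- simulate_tandem_reads(design, error, n_reads, seed)
  cells <- list()
  for (r in seq_len(nrow(design))) {
    ul <- design$unit_len[r]; cp <- design$copies[r]
    sub <- reads[reads$unit_len == ul & reads$copies == cp, ]
    calls <- find_tandem_repeats(sub, config)
    ev <- evaluate_calls(calls, sub, tau, length_bound)
    cells[[r]] <- tibble::tibble(
      unit_len = ul, copies = cp, n_reads = nrow(sub),
      n_success = sum(ev$success),
      sensitivity = mean(ev$success),
      mean_len_error = if (any(ev$success))
        mean(ev$len_error[ev$success]) else NA_real_
    )
  }
  out <- dplyr::bind_rows(cells)
  class(out) <- c("tandem_benchmark", class(out))
  out
}

#' @rdname run_benchmark
#' @param unit_len,copies Lattice values to cross (defaults: the standard
#'   benchmark lattice, unit lengths 2/5/10/20/50/100/200 and copy
#'   numbers 10/20/50/100/200).
#' @export
benchmark_design <- function(unit_len = c(2L, 5L, 10L, 20L, 50L, 100L, 200L),
                             copies = c(10L, 20L, 50L, 100L, 200L)) {
  g <- expand.grid(unit_len = as.integer(unit_len),
                   copies = as.integer(copies),
                   KEEP.OUT.ATTRS = FALSE)
  tibble::as_tibble(g[order(g$unit_len, g$copies), ])
}
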