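#' Read sequences from FASTA or FASTQ
#'
#' Auto-detects FASTQ by file extension (`.fq`/`.fastq`, optionally
#' gzipped); everything else is parsed as FASTA.  Qualities are
#' discarded.  Sequences are uppercased and any non-ACGT letters (N,
#' IUPAC ambiguity codes) are replaced by seeded random bases so the
#' dense 4-letter k-mer coding applies; the number of replacements is
#' reported.
#'
#' @param path Input file (plain or gzip).
#' @param seed Seed for the ambiguity-replacement draw (default 1).
#' @return A tibble with columns `read_id` (first word of the record
#'   name) and `seq`.
#' @export
read_sequences <- function(path, seed = 1L) {
  fmt <- if (grepl("\\.f(ast)?q(\\.gz)?$", path, ignore.case = TRUE))
    "fastq" else "fasta"
  xs <- Biostrings::readDNAStringSet(path, format = fmt)
  seqs <- toupper(as.character(xs))
  ids <- vapply(strsplit(names(xs), "\\s+"), `[`, character(1), 1L)
  n_repl <- 0L
  seqs <- .with_seed_if(seed, {
    vapply(seqs, function(s) {
      bad <- gregexpr("[^ACGT]", s)[[1L]]
      if (bad[1L] == -1L) return(s)
      n_repl <<- n_repl + length(bad)
      ch <- strsplit(s, "", fixed = TRUE)[[1L]]
      ch[bad] <- sample(.BASES, length(bad), replace = TRUE)
      paste(ch, collapse = "")
    }, character(1), USE.NAMES = FALSE)
  })
  if (n_repl > 0L) {
    rlang::inform(sprintf("replaced %d non-ACGT base(s) with random bases",
                          n_repl))
  }
  tibble::tibble(read_id = unname(ids), seq = seqs)
}

#' Write repeat calls to TSV (and optionally BED6)
#'
#' TSV columns: `read_id`, `start`, `end`, `repeat_len`, `unit_len`,
#' `unit_seq`, `copies`, `sigma`, `identity`, `k_used`, `w_used`;
#' coordinates are 0-based half-open, matching both the inter-base
#' position convention used throughout and BED.  The BED6 mirror names
#' each feature `<unit_len>x<copies>` with score `min(1000, sigma)`.
#'
#' @param calls Calls tibble from [find_tandem_repeats()].
#' @param path Output TSV path.
#' @param bed Optional BED6 output path.
#' @return `calls`, invisibly.
#' @export
write_calls <- function(calls, path, bed = NULL) {
  readr::write_tsv(calls, path)
  if (!is.null(bed)) {
    bed_tbl <- tibble::tibble(
      chrom = calls$read_id,
      start = calls$start,
      end = calls$end,
      name = sprintf("%dx%d", calls$unit_len, round(calls$copies)),
      score = pmin(1000, round(calls$sigma)),
      strand = "+"
    )
    readr::write_tsv(bed_tbl, bed, col_names = FALSE)
  }
  invisible(calls)
}

#' @rdname write_calls
#' @export
read_calls <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    read_id = readr::col_character(),
    start = readr::col_integer(),
    end = readr::col_integer(),
    repeat_len = readr::col_integer(),
    unit_len = readr::col_integer(),
    unit_seq = readr::col_character(),
    copies = readr::col_double(),
    sigma = readr::col_double(),
    identity = readr::col_double(),
    k_used = readr::col_integer(),
    w_used = readr::col_integer()
  ))
}

#' Write simulated reads as FASTA with a truth sidecar
#'
#' @param reads Tibble from [simulate_tandem_reads()].
#' @param out_prefix Paths will be `<out_prefix>.fasta` and
#'   `<out_prefix>.truth.tsv` (columns `read_id`, `start`, `end`, `unit`,
#'   `copies`).
#' @return The two paths, invisibly.
#' @export
write_synthetic_reads <- function(reads, out_prefix) {
  fa <- paste0(out_prefix, ".fasta")
  tsv <- paste0(out_prefix, ".truth.tsv")
  xs <- Biostrings::DNAStringSet(reads$seq)
  names(xs) <- reads$read_id
  Biostrings::writeXStringSet(xs, fa)
  readr::write_tsv(tibble::tibble(
    read_id = reads$read_id,
    start = reads$true_start,
    end = reads$true_end,
    unit = reads$true_unit,
    copies = reads$true_copies
  ), tsv)
  invisible(c(fasta = fa, truth = tsv))
}
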