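test_that("templates follow the flank + repeat + flank construction", {
  tr <- make_truth(5, 50, seed = 9)
  expect_identical(tr$template_len, 750L)       # 3 x repeat span
  expect_identical(tr$start, 250L)
  expect_identical(tr$end, 500L)
  expect_identical(substr(tr$template, 251, 500),
                   strrep(tr$unit, 50))
  # determinism: same seed, identical template
  expect_identical(make_truth(5, 50, seed = 9), tr)
  expect_false(identical(make_truth(5, 50, seed = 10)$template,
                         tr$template))
  # terminal partial copy extends the repeat interval
  trp <- make_truth(10, 20, seed = 4, partial = TRUE)
  expect_identical(trp$end - trp$start, 205L)
})

test_that("generated units are primitive", {
  set.seed(331)
  for (len in c(2L, 4L, 6L, 9L, 12L)) {
    for (t in 1:20) {
      u <- make_truth(len, 3)$unit
      ch <- strsplit(u, "")[[1]]
      divs <- which(len %% seq_len(len - 1L) == 0L)
      for (d in divs) {
        expect_false(identical(rep(ch[1:d], len / d), ch))
      }
    }
  }
})

test_that("the error channel preserves rate expectations", {
  tem <- rand_seq(2000)
  expect_identical(apply_errors(tem, error_model(0, 0, 0)), tem)
  m <- error_model(0.1, 0.05, 0.05)
  set.seed(341)
  lens <- replicate(200, nchar(apply_errors(tem, m)))
  # expected length n(1 + ins - del) = n; binomial SE of the mean
  se <- sqrt(2000 * (0.05 * 0.95 + 0.05 * 0.95)) / sqrt(200)
  expect_lt(abs(mean(lens) - 2000), 3 * se)
  # substitution fraction on a deletion/insertion-free channel
  ms <- error_model(0.1, 0, 0)
  nsub <- replicate(200, {
    out <- apply_errors(tem, ms)
    sum(strsplit(out, "")[[1]] != strsplit(tem, "")[[1]])
  })
  se_sub <- sqrt(2000 * 0.1 * 0.9) / sqrt(200)
  expect_lt(abs(mean(nsub) - 200), 3 * se_sub)
})

test_that("read-space truth coordinates track the channel", {
  set.seed(351)
  for (t in 1:10) {
    rd <- simulate_tandem_reads(data.frame(unit_len = 10, copies = 20),
                                error_preset("nanopore_like"), 1)
    # the recorded interval is a near-perfect repeat region: its
    # wraparound identity against the truth unit is far above flank level
    aln <- wraparound_align(rd$true_unit, rd$seq, rd$true_start,
                            rd$true_end)
    expect_gt(aln$identity, 0.6)
    expect_lt(abs((rd$true_end - rd$true_start) - 200L), 80L)
  }
})

test_that("unit matching is rotation-aware with the documented tolerance", {
  expect_true(unit_match("CGA", "ACG", tau = 1))
  expect_false(unit_match("ACT", "ACG", tau = 1))
  set.seed(361)
  truth <- rand_seq(100)
  mutate_n <- function(u, n) {
    pos <- sample(nchar(u), n)
    ch <- strsplit(u, "")[[1]]
    for (p in pos) ch[p] <- setdiff(BASES, ch[p])[sample(3, 1)]
    paste(ch, collapse = "")
  }
  expect_true(unit_match(mutate_n(truth, 5), truth, tau = 0.95))
  expect_false(unit_match(mutate_n(truth, 6), truth, tau = 0.95))
})

test_that("length error is the stated ratio", {
  expect_equal(length_error(1000, 1000), 0)
  expect_equal(length_error(1050, 1000), 0.05)
  expect_equal(length_error(900, 1000), 0.1)
})

test_that("simulation is byte-identical under a fixed seed", {
  des <- data.frame(unit_len = c(5L, 20L), copies = c(10L, 10L))
  r1 <- simulate_tandem_reads(des, error_preset("nanopore_like"), 2,
                              seed = 77)
  r2 <- simulate_tandem_reads(des, error_preset("nanopore_like"), 2,
                              seed = 77)
  expect_identical(r1, r2)
  d1 <- file.path(tempdir(), "sim_a")
  d2 <- file.path(tempdir(), "sim_b")
  write_synthetic_reads(r1, d1)
  write_synthetic_reads(r2, d2)
  expect_identical(readLines(paste0(d1, ".fasta")),
                   readLines(paste0(d2, ".fasta")))
})

test_that("benchmarks report per-cell sensitivity and handle empties", {
  empty <- run_benchmark(benchmark_design(integer(0), integer(0)))
  expect_identical(nrow(empty), 0L)
  set.seed(371)
  b <- run_benchmark(data.frame(unit_len = 20L, copies = 50L),
                     error_preset("none"), n_reads = 2, seed = 55)
  expect_identical(b$n_reads, 2L)
  expect_equal(b$sensitivity, 1)
})

test_that("sensitivity does not increase with the error rate", {
  models <- list(error_preset("none"), error_preset("accurate"),
                 error_model(0.15, 0.08, 0.08))
  sens <- vapply(models, function(m) {
    run_benchmark(data.frame(unit_len = 20L, copies = 50L), m,
                  n_reads = 6, seed = 88)$sensitivity
  }, numeric(1))
  expect_true(all(diff(sens) <= 0))
})
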