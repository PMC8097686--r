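test_that("cyclic unit k-mer frequencies reflect the graph", {
  R <- strrep("ACGTT", 30)
  g <- build_debruijn(R, k = 3)
  fr <- unit_kmer_freqs("ACGTT", g)
  expect_identical(length(fr), 5L)
  expect_true(all(fr >= 28L))  # every cyclic 3-mer occurs in every copy
})

test_that("transition repair fixes a planted substitution and is stable", {
  # perfect array; the assembled unit carries one wrong base whose
  # covering k-mers are rare in the graph
  set.seed(161)
  unit <- rand_seq(20)
  g <- build_debruijn(strrep(unit, 40), k = 5)
  expect_identical(transition_repair(unit, g), unit)  # no-op on the truth
  wrong <- unit
  substr(wrong, 8, 8) <- setdiff(BASES, substr(unit, 8, 8))[1]
  expect_identical(transition_repair(wrong, g), unit)
})

test_that("transition repair deletes a spurious inserted base", {
  set.seed(171)
  unit <- rand_seq(25)
  g <- build_debruijn(strrep(unit, 40), k = 5)
  bloated <- paste0(substr(unit, 1, 10), "A", substr(unit, 11, 25))
  repaired <- transition_repair(bloated, g)
  expect_identical(repaired, unit)
})

test_that("transition repair leaves low-coverage evidence alone", {
  set.seed(181)
  unit <- rand_seq(20)
  g <- build_debruijn(strrep(unit, 5), k = 5)  # modal frequency ~5 < 10
  wrong <- unit
  substr(wrong, 3, 3) <- setdiff(BASES, substr(unit, 3, 3))[1]
  expect_identical(transition_repair(wrong, g), wrong)
})

test_that("column tails are exact binomial and monotone", {
  expect_equal(column_tail(0, 17, 0.13), 1)
  expect_equal(column_tail(1, 1, 0.2), 0.05)
  expect_equal(column_tail(5, 20, 0.2), brute_tail(5, 20, 0.2))
  set.seed(191)
  for (t in 1:20) {
    d <- sample(2:40, 1); K <- sample(0:d, 1); eps <- runif(1, 0, 0.9)
    expect_equal(column_tail(K, d, eps), brute_tail(K, d, eps),
                 tolerance = 1e-12)
  }
  # monotone non-increasing in K, non-decreasing in eps
  p <- vapply(0:10, column_tail, numeric(1), d = 10, eps = 0.2)
  expect_true(all(diff(p) <= 0))
  pe <- vapply(c(0.05, 0.1, 0.2, 0.4), function(e) column_tail(3, 10, e),
               numeric(1))
  expect_true(all(diff(pe) >= 0))
  expect_error(column_tail(11, 10, 0.2), "exceed")
})

test_that("column polishing corrects a consensus against deep evidence", {
  set.seed(201)
  unit <- rand_seq(25)
  read <- apply_errors(strrep(unit, 100), error_model(0.03, 0.01, 0.01))
  wrong <- unit
  substr(wrong, 7, 7) <- setdiff(BASES, substr(unit, 7, 7))[1]
  polished <- ma_polish(wrong, read)
  expect_identical(polished, unit)
  # insertion error in the consensus is deleted
  bloat <- paste0(substr(unit, 1, 12), "C", substr(unit, 13, 25))
  expect_identical(ma_polish(bloat, read), unit)
})

test_that("null columns are not edited", {
  set.seed(211)
  edits <- 0L
  for (t in 1:40) {
    unit <- rand_seq(20)
    read <- apply_errors(strrep(unit, 60), error_model(0.05, 0.025, 0.025))
    if (!identical(ma_polish(unit, read), unit)) edits <- edits + 1L
  }
  expect_lte(edits / 40, 0.05)
})

test_that("polishing converges to the planted unit across unit lengths", {
  set.seed(221)
  n_ok <- 0L; n_tot <- 0L
  for (ulen in c(10L, 25L, 100L)) {
    for (t in 1:10) {
      unit <- rand_seq(ulen)
      read <- apply_errors(strrep(unit, 60),
                           error_model(0.10, 0.05, 0.05))
      au <- assemble_unit(read)
      if (is.null(au)) { n_tot <- n_tot + 1L; next }
      g <- build_debruijn(read, k = au$k_used)
      u <- transition_repair(au$unit, g)
      u <- ma_polish(u, read)
      n_tot <- n_tot + 1L
      if (rotation_identity(u, unit) == 1) n_ok <- n_ok + 1L
    }
  }
  expect_gte(n_ok / n_tot, 0.95)
})

test_that("polishing requires alignment depth", {
  set.seed(231)
  unit <- rand_seq(30)
  read <- paste0(unit, rand_seq(5))  # barely more than one copy
  expect_identical(ma_polish(unit, read), unit)
})
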