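test_that("wraparound alignment scores perfect and mutated repeats", {
  a <- wraparound_align("ACG", "ACGACGACGACG")
  expect_identical(a$sigma, 12L)
  expect_identical(a$delta, 0L)
  expect_equal(a$copies, 4)
  expect_equal(a$identity, 1)
  b <- wraparound_align("ACG", "ACAACGACGGCG")
  expect_identical(b$delta, 2L)
  expect_identical(b$sigma, 10L)
  expect_error(wraparound_align("", "ACGT"), "non-empty")
})

test_that("wraparound sigma equals the explicit-concatenation oracle", {
  set.seed(241)
  for (t in 1:120) {
    u <- rand_seq(sample(1:8, 1))
    region <- rand_seq(sample(1:60, 1))
    expect_identical(wraparound_align(u, region, full = FALSE)$delta,
                     as.integer(brute_wrap_delta(u, region)))
  }
  # biased cases: near-tandem regions
  for (t in 1:40) {
    u <- rand_seq(sample(2:6, 1))
    region <- apply_errors(strrep(u, sample(3:8, 1)),
                           error_model(0.1, 0.05, 0.05))
    if (nchar(region) == 0) next
    expect_identical(wraparound_align(u, region, full = FALSE)$delta,
                     as.integer(brute_wrap_delta(u, region)))
  }
})

test_that("prefix scores agree with from-scratch alignments", {
  set.seed(251)
  u <- rand_seq(7)
  region <- paste0(strrep(u, 10), rand_seq(30))
  aln <- wraparound_align(u, region)
  expect_equal(aln$prefix_sigma[1], 0)
  expect_equal(aln$prefix_sigma[nchar(region) + 1], aln$sigma)
  for (x in sample(1:nchar(region), 20)) {
    direct <- wraparound_align(u, substr(region, 1, x), full = FALSE)
    expect_equal(aln$prefix_sigma[x + 1], direct$sigma)
  }
})

test_that("sigma is invariant under unit rotation", {
  set.seed(261)
  for (t in 1:15) {
    u <- rand_seq(sample(4:12, 1))
    region <- apply_errors(strrep(u, 20), error_model(0.05, 0.02, 0.02))
    s0 <- wraparound_align(u, region, full = FALSE)$sigma
    r <- sample(nchar(u) - 1L, 1)
    ur <- paste0(substr(u, r + 1, nchar(u)), substr(u, 1, r))
    s1 <- wraparound_align(ur, region, full = FALSE)$sigma
    expect_identical(s0, s1)
  }
})

test_that("LCS similarity reproduces the worked values", {
  expect_equal(lcs_similarity("ACAACGACGGCG", "ACGACGACGACG"), 10 / 12)
  expect_equal(lcs_similarity("ACAACGACG", "ACGACGACG"), 8 / 9)
  set.seed(271)
  for (t in 1:10) {
    x <- rand_seq(sample(3:30, 1)); y <- rand_seq(sample(3:30, 1))
    expect_equal(lcs_similarity(x, x), 1)
    expect_equal(lcs_similarity(x, y), lcs_similarity(y, x))
  }
})

test_that("split points resolve overlaps at the true junction", {
  set.seed(281)
  R <- paste0(strrep("AC", 30), strrep("GT", 30))
  ci <- list(s = 0L, e = 66L, unit = "AC")    # overshoots by 6
  cj <- list(s = 54L, e = 120L, unit = "GT")  # starts 6 early
  expect_identical(split_point(ci, cj, R), 60L)
  # disjoint calls split at e_i
  cj2 <- list(s = 80L, e = 120L, unit = "GT")
  expect_identical(split_point(ci, cj2, R), 66L)
  # overlap region consistent only with the left unit
  ci3 <- list(s = 0L, e = 60L, unit = "AC")
  cj3 <- list(s = 50L, e = 120L, unit = "GT")
  expect_identical(split_point(ci3, cj3, R), 60L)
})

test_that("canonical rotations and rotation identity behave", {
  expect_identical(canonical_rotation("CGA"), "ACG")
  expect_identical(canonical_rotation("A"), "A")
  expect_equal(rotation_identity("CGA", "ACG"), 1)
  expect_lt(rotation_identity("ACT", "ACG"), 1)
  set.seed(291)
  for (t in 1:10) {
    u <- rand_seq(sample(2:20, 1))
    r <- sample(nchar(u), 1)
    ur <- paste0(substr(u, r, nchar(u)), substr(u, 1, r - 1L))
    expect_identical(canonical_rotation(ur), canonical_rotation(u))
  }
})
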