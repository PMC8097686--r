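mk_calls <- function(s, e, sigma) {
  tibble::tibble(read_id = "r", s = as.integer(s), e = as.integer(e),
                 unit = strrep("A", 3), sigma = as.numeric(sigma))
}

test_that("trivial chains pass through", {
  one <- mk_calls(10, 100, 50)
  expect_identical(chain_calls(one)$s, 10L)
  two <- mk_calls(c(200, 10), c(300, 100), c(40, 50))
  ch <- chain_calls(two)
  expect_identical(ch$s, c(10L, 200L))  # coordinate order
  expect_identical(nrow(ch), 2L)
  expect_error(chain_calls(tibble::tibble(read_id = c("a", "b"),
                                          s = c(1L, 1L), e = c(30L, 30L),
                                          unit = "A", sigma = 1)),
               "single read")
})

test_that("identical intervals deduplicate to the best sigma", {
  dup <- mk_calls(c(10, 10, 50), c(40, 40, 90), c(5, 9, 4))
  ch <- chain_calls(dup)
  expect_identical(nrow(ch), 2L)
  expect_equal(ch$sigma[ch$s == 10L], 9)
})

test_that("chain weight matches exhaustive subset search", {
  set.seed(301)
  for (t in 1:200) {
    n <- sample(2:8, 1)
    s <- sample(0:150, n, replace = TRUE)
    len <- sample(10:60, n, replace = TRUE)
    e <- s + len
    sigma <- sample(5:50, n, replace = TRUE)
    calls <- mk_calls(s, e, sigma)
    ch <- chain_calls(calls, overlap_limit = 10L)
    expect_equal(sum(ch$sigma), brute_chain_weight(s, e, sigma, 10L),
                 info = paste("trial", t))
    # returned chain is itself feasible
    if (nrow(ch) > 1L) {
      o <- order(ch$e)
      expect_true(all(ch$s[o][-1] >= ch$e[o][-nrow(ch)] - 9L))
    }
  }
})

test_that("finalize yields disjoint, sorted records without raising sigma", {
  set.seed(311)
  R <- paste0(strrep("AC", 30), strrep("GT", 30), rand_seq(20))
  calls <- tibble::tibble(
    read_id = "r",
    s = c(0L, 54L), e = c(66L, 120L),
    unit = c("AC", "GT"),
    sigma = c(wraparound_align("AC", R, 0, 66, full = FALSE)$sigma,
              wraparound_align("GT", R, 54, 120, full = FALSE)$sigma),
    copies = c(33, 33), identity = c(1, 1))
  fin <- finalize_calls(calls, R)
  expect_identical(nrow(fin), 2L)
  expect_identical(fin$e[1], fin$s[2])   # abutting at the split point
  expect_identical(fin$e[1], 60L)        # the true junction
  expect_true(all(fin$sigma <= calls$sigma))
  # already-disjoint chains are untouched
  calls2 <- tibble::tibble(read_id = "r", s = c(0L, 70L), e = c(60L, 110L),
                           unit = c("AC", "GT"), sigma = c(60, 40),
                           copies = c(30, 20), identity = c(1, 1))
  fin2 <- finalize_calls(calls2, R)
  expect_identical(fin2$s, c(0L, 70L))
  expect_identical(fin2$e, c(60L, 110L))
})

test_that("two adjacent planted repeats are both reported", {
  # neighbouring-repeat pairs drawn from the five standard generator
  # settings (size x frequency): spans 150..10000
  pairs <- list(list(c(3L, 50L), c(5L, 50L)),
                list(c(5L, 50L), c(10L, 100L)),
                list(c(10L, 100L), c(20L, 200L)))
  set.seed(321)
  for (p in pairs) {
    hits <- 0L
    for (t in 1:10) {
      u1 <- rand_unit(p[[1]][1]); u2 <- rand_unit(p[[2]][1])
      r1 <- strrep(u1, p[[1]][2]); r2 <- strrep(u2, p[[2]][2])
      gap <- rand_seq(max(nchar(r1), nchar(r2)))
      tem <- paste0(rand_seq(nchar(r1)), r1, gap, r2, rand_seq(nchar(r2)))
      read <- apply_errors(tem, error_preset("nanopore_like"))
      calls <- find_tandem_repeats(c(rr = read))
      got1 <- any(vapply(calls$unit_seq, unit_match, logical(1),
                         truth = u1, tau = 0.95))
      got2 <- any(vapply(calls$unit_seq, unit_match, logical(1),
                         truth = u2, tau = 0.95))
      if (got1 && got2) hits <- hits + 1L
    }
    expect_gte(hits, 9L)
  }
})
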