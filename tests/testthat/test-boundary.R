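test_that("the scanning grid holds exactly the twenty stated patterns", {
  g <- parameter_grid()
  expect_identical(nrow(g), 20L)
  expect_identical(g$k, c(rep(5L, 12), rep(3L, 5), rep(1L, 3)))
  expect_identical(g$w[g$k == 5L], 5L * 2L^(0:11))
  expect_identical(g$w[g$k == 3L], 5L * 2L^(0:4))
  expect_identical(g$w[g$k == 1L], 5L * 2L^(0:2))
  expect_true(any(g$k == 3L & g$w == 80L))
  expect_false(any(g$k == 1L & g$w == 40L))
})

test_that("boundary scores vanish on a homopolymer and E mirrors B", {
  H <- strrep("A", 200)
  bs <- boundary_scores(H, 20, 3)
  expect_true(all(bs$score == 0))
  set.seed(51)
  R <- rand_seq(700)
  for (m in c("manhattan", "pearson")) {
    sc <- boundary_scores(R, 40, 3, m)
    B <- sc[sc$stat == "B", ]; E <- sc[sc$stat == "E", ]
    # E(i, w) = -B(i - w, w), exactly
    expect_identical(E$pos, B$pos + 40L)
    expect_identical(E$score, -B$score)
  }
  # read shorter than 3w: empty result, no error
  expect_identical(nrow(boundary_scores("ACGTACGT", 5, 1)), 0L)
})

test_that("B peaks at a planted repeat start", {
  set.seed(61)
  R <- paste0(rand_seq(500), strrep("ACGTG", 100), rand_seq(500))
  sc <- boundary_scores(R, 80, 3)
  B <- sc[sc$stat == "B", ]
  expect_lt(abs(B$pos[which.max(B$score)] - 500L), 80L)
  E <- sc[sc$stat == "E", ]
  expect_lt(abs(E$pos[which.max(E$score)] - 1000L), 80L)
})

test_that("candidate detection localizes a noisy repeat within w", {
  set.seed(71)
  tru <- make_truth(25, 200, seed = 123)
  noisy <- apply_errors(tru$template, error_preset("nanopore_like"),
                        seed = 124)
  cand <- detect_candidates(noisy, 5, 160, theta_b = 0.2)
  expect_gte(nrow(cand), 1L)
  top <- cand[which.max(cand$peak_b + cand$peak_e), ]
  # template truth [5000, 10000] shifts by at most ~2.5% under the channel
  expect_lt(abs(top$b - 5000L), 160L + 150L)
  expect_lt(abs(top$e - 10000L), 160L + 150L)
})

test_that("scans of pure random sequence stay quiet", {
  # boundary-score noise shrinks with the window (more k-mers per
  # profile), so wide windows are silent on random input; the smallest
  # windows may rarely cross the floor, which downstream scoring absorbs
  set.seed(81)
  R <- rand_seq(4000)
  for (w in c(160L, 640L)) {
    expect_identical(nrow(detect_candidates(R, 5, w, theta_b = 0.2)), 0L)
  }
  expect_lte(nrow(detect_candidates(R, 5, 40, theta_b = 0.2)), 1L)
})

test_that("patterns inside the detectability window localize to w", {
  # unit 5, span 400: valid patterns need 2|u| <= w <= L/2 and k <= |u|
  set.seed(91)
  R <- paste0(rand_seq(2000), strrep("ACGTG", 80), rand_seq(2000))
  for (pat in list(c(3L, 10L), c(3L, 20L), c(5L, 40L), c(5L, 80L),
                   c(5L, 160L))) {
    cand <- detect_candidates(R, pat[1], pat[2], theta_b = 0.2)
    expect_gte(nrow(cand), 1L)
    top <- cand[which.max(cand$peak_b + cand$peak_e), ]
    expect_lte(abs(top$b - 2000L), pat[2])
    expect_lte(abs(top$e - 2400L), pat[2])
  }
})

test_that("scan_read covers several planted repeats and tolerates edge cases", {
  expect_identical(nrow(scan_read("")), 0L)
  expect_identical(nrow(scan_read("ACGT")), 0L)
  set.seed(101)
  units <- vapply(c(4L, 20L, 50L, 150L), rand_seq, character(1))
  copies <- c(100L, 40L, 30L, 12L)
  parts <- character(0)
  bounds <- integer(0)
  pos <- 0L
  for (i in seq_along(units)) {
    fl <- rand_seq(400)
    rp <- strrep(units[i], copies[i])
    parts <- c(parts, fl, rp)
    bounds <- c(bounds, pos + 400L, pos + 400L + nchar(rp))
    pos <- pos + 400L + nchar(rp)
  }
  R <- paste0(paste(parts, collapse = ""), rand_seq(400))
  cand <- scan_read(R)
  for (i in seq_along(units)) {
    st <- bounds[2L * i - 1L]; en <- bounds[2L * i]
    ov <- pmin(cand$e, en) - pmax(cand$b, st)
    expect_gt(max(ov), 0.5 * (en - st))
  }
})
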