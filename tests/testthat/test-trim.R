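test_that("Mott trimming keeps uniformly good reads and drops uniformly bad ones", {
  tr <- trim_mott(rep(60L, 40), cutoff = 1e-4)
  expect_equal(c(tr$start, tr$end), c(0, 40))
  tr2 <- trim_mott(rep(2L, 40), cutoff = 1e-4)
  expect_equal(c(tr2$start, tr2$end), c(0, 0))
  expect_error(trim_mott(integer(0)), class = "sk_value_error")
  expect_error(trim_mott(rep(30L, 5), cutoff = 1.5), class = "sk_value_error")
})

test_that("Mott picks the max-sum segment with its score", {
  tr <- trim_mott(c(10L, 30L, 30L, 10L), cutoff = 0.01)
  expect_equal(c(tr$start, tr$end), c(1, 3))
  expect_equal(tr$segment_score, 2 * (0.01 - 1e-3))
})

test_that("Mott equals the all-segments brute-force oracle", {
  set.seed(42)
  for (k in 1:300) {
    q <- random_qualities(sample(1:60, 1))
    cutoff <- sample(c(1e-4, 1e-3, 0.01, 0.05, 0.3), 1)
    got <- trim_mott(q, cutoff)
    want <- mott_oracle(q, cutoff)
    expect_equal(c(got$start, got$end), c(want$start, want$end),
                 info = paste("seed case", k))
    expect_equal(got$segment_score, want$val, tolerance = 1e-12)
  }
})

test_that("sliding window handles pass-all, fail-all, and the mixed case", {
  tr <- trim_sliding_window(rep(30L, 50), window = 10, quality_cutoff = 20)
  expect_equal(c(tr$start, tr$end), c(0, 50))
  tr2 <- trim_sliding_window(rep(10L, 50), window = 10, quality_cutoff = 20)
  expect_equal(c(tr2$start, tr2$end), c(0, 0))
  # twenty 30s then ten 5s: first failing window covers five 5s (mean 17.5)
  tr3 <- trim_sliding_window(c(rep(30L, 20), rep(5L, 10)), 10, 20)
  expect_equal(c(tr3$start, tr3$end), c(0, 15))
  # shorter than the window: treated as one window
  tr4 <- trim_sliding_window(rep(30L, 3), window = 10, quality_cutoff = 20)
  expect_equal(c(tr4$start, tr4$end), c(0, 3))
  expect_error(trim_sliding_window(integer(0)), class = "sk_value_error")
})

test_that("sliding window equals the brute-force window scan", {
  set.seed(7)
  for (k in 1:300) {
    q <- random_qualities(sample(1:80, 1))
    w <- sample(1:15, 1)
    cut <- sample(10:40, 1)
    got <- trim_sliding_window(q, w, cut)
    expect_equal(c(got$start, got$end), window_oracle(q, w, cut),
                 info = paste("case", k))
  }
})

test_that("kept regions improve on the whole read under each method's own criterion", {
  # Mott maximises the summed error-probability margin, so the kept
  # region's mean error probability never exceeds the full read's; the
  # sliding window guarantees a passing window at the start and (for a
  # proper cut) a failing window at the cut point.
  set.seed(9)
  for (k in 1:200) {
    q <- random_qualities(sample(5:100, 1))
    tr <- trim_mott(q, 0.01)
    if (tr$end > tr$start && (tr$end - tr$start) < length(q)) {
      p <- 10^(-q / 10)
      expect_lte(mean(p[(tr$start + 1):tr$end]), mean(p) + 1e-12)
    }
    w <- 10; cutq <- 20
    ts <- trim_sliding_window(q, w, cutq)
    if (ts$end > ts$start) {
      ww <- min(w, length(q))
      expect_gte(mean(q[(ts$start + 1):(ts$start + ww)]), cutq)
      if (ts$end <= length(q) - ww)
        expect_lt(mean(q[(ts$end + 1):(ts$end + ww)]), cutq)
    }
  }
})

test_that("a stricter Mott cutoff never lengthens the kept segment", {
  set.seed(13)
  cutoffs <- sort(c(1e-5, 1e-4, 1e-3, 0.01, 0.1), decreasing = TRUE)
  for (k in 1:50) {
    q <- random_qualities(sample(10:120, 1))
    lens <- vapply(cutoffs, function(cc) {
      tr <- trim_mott(q, cc); tr$end - tr$start
    }, 0L)
    expect_true(all(diff(lens) <= 0))
  }
})
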