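peak_trace <- function(...) {
  # build a one-peak-per-base trace from rows of c(A, C, G, T)
  rows <- list(...)
  n <- length(rows)
  L <- 10L * n
  ch <- list(A = numeric(L), C = numeric(L), G = numeric(L), T = numeric(L))
  locs <- integer(n)
  for (i in seq_len(n)) {
    locs[i] <- 10L * (i - 1L) + 5L
    for (b in 1:4) ch[[b]][locs[i] + 1L] <- rows[[i]][b]
  }
  trace_set(ch, peak_locations = locs)
}

test_that("primary and secondary calls follow the intensity-ratio rule", {
  tr <- peak_trace(c(100, 0, 0, 0), c(100, 40, 0, 0), c(100, 30, 0, 0),
                   c(0, 0, 0, 0))
  res <- call_bases(tr, secondary_ratio = 0.33)
  expect_equal(res$primary_seq, "AAAN")
  # 40/100 >= 0.33 -> M (A/C); 30/100 < 0.33 -> A; all-zero -> N
  expect_equal(res$secondary_seq, "AMAN")
})

test_that("primary ties break in fixed A<C<G<T order", {
  tr <- peak_trace(c(50, 50, 0, 0), c(0, 7, 7, 0))
  res <- call_bases(tr, secondary_ratio = 0.9)
  expect_equal(res$primary_seq, "AC")
  expect_equal(res$secondary_seq, "MS")
})

test_that("secondary-peak detection recovers injected peaks exactly", {
  spec <- flat_spec(secondary_positions = c(30L, 60L, 90L),
                    secondary_ratio = 0.5)
  sim <- simulate_read(simulate_template(150, seed = 5), "forward", spec,
                       seed = 8)
  calls <- detect_secondary_peaks(sim$trace, ratio = 0.33)
  expect_equal(calls$base_index, c(30L, 60L, 90L))
  expect_equal(calls$primary_base, sim$truth$secondary$primary_base)
  expect_equal(calls$secondary_base, sim$truth$secondary$secondary_base)
  expect_true(all(abs(calls$ratio - 0.5) < 0.05))
  # raising the threshold above the injected ratio empties the call set
  expect_equal(nrow(detect_secondary_peaks(sim$trace, ratio = 0.6)), 0)
})

test_that("detection is monotone non-increasing in the ratio threshold", {
  spec <- flat_spec(secondary_count = 5, secondary_ratio = 0.5)
  sim <- simulate_read(simulate_template(200, seed = 6), "forward", spec,
                       seed = 9)
  ratios <- c(0.1, 0.25, 0.4, 0.55, 0.7, 0.9)
  counts <- vapply(ratios, function(r)
    nrow(detect_secondary_peaks(sim$trace, ratio = r)), 0L)
  expect_true(all(diff(counts) <= 0))
  sets <- lapply(ratios, function(r)
    detect_secondary_peaks(sim$trace, ratio = r)$base_index)
  for (i in seq_len(length(sets) - 1))
    expect_true(all(sets[[i + 1]] %in% sets[[i]]))
})

test_that("clean traces yield no secondary calls and trim restriction works", {
  sim <- simulate_read(simulate_template(120, seed = 7), "forward",
                       flat_spec(), seed = 10)
  expect_equal(nrow(detect_secondary_peaks(sim$trace, ratio = 0.33)), 0)
  spec <- flat_spec(secondary_positions = c(10L, 60L), secondary_ratio = 0.5)
  sim2 <- simulate_read(simulate_template(120, seed = 7), "forward", spec,
                        seed = 11)
  within <- detect_secondary_peaks(sim2$trace, ratio = 0.33,
                                   within_trim_only = TRUE, trim = c(20L, 120L))
  expect_equal(within$base_index, 60L)
})
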