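## Quality trimming of Sanger reads.
##
## Two algorithms are offered. M1 is the modified Mott algorithm used by
## Phred-style pipelines: each base gets score cutoff - p_err and the kept
## segment is the contiguous window maximising the score sum. M2 is
## Trimmomatic-style sliding-window trimming on mean Phred quality.

new_trim_result <- function(method, params, start, end, segment_score,
                            qualities) {
  n <- length(qualities)
  kept <- if (end > start) qualities[(start + 1):end] else numeric(0)
  structure(list(
    method = method,
    params = params,
    start = as.integer(start),
    end = as.integer(end),
    segment_score = segment_score,
    mean_quality_before = mean(qualities),
    mean_quality_after = if (length(kept)) mean(kept) else NA_real_
  ), class = "trim_result")
}

#' @export
print.trim_result <- function(x, ...) {
  cat("<trim_result ", x$method, "> keep [", x$start, ", ", x$end, ") ",
      "mean Q ", round(x$mean_quality_before, 1), " -> ",
      round(x$mean_quality_after, 1), "\n", sep = "")
  invisible(x)
}

#' Modified Mott quality trimming
#'
#' Scores base i as `cutoff - 10^(-Q_i/10)` and keeps the contiguous
#' segment with the maximal score sum, i.e. the stretch whose per-base
#' error probabilities beat the cutoff on balance. If no segment has a
#' positive sum the whole read is trimmed, reported as the empty window
#' `(0, 0)`. Ties are broken by the smallest start, then the largest end.
#' Coordinates are 0-based half-open.
#'
#' @param qualities integer Phred scores (>= 0), non-empty
#' @param cutoff error-probability cutoff in (0, 1); default 1e-4
#' @return a `trim_result` with fields `start`, `end`, `segment_score`,
#'   `mean_quality_before`, `mean_quality_after`
#' @export
trim_mott <- function(qualities, cutoff = 1e-4) {
  if (length(qualities) == 0) stop_sk_value("qualities must be non-empty")
  if (!(cutoff > 0 && cutoff < 1)) stop_sk_value("cutoff must lie in (0, 1)")
  if (any(qualities < 0)) stop_sk_value("Phred qualities must be >= 0")
  s <- cutoff - phred_to_error(qualities)
  n <- length(s)
  P <- c(0, cumsum(s))          # P[k+1] = sum of first k scores
  best_val <- -Inf; best_s <- 0L; best_e <- 0L
  min_val <- P[1]; min_idx <- 0L  # min prefix over starts 0..e-1, earliest
  for (e in seq_len(n)) {
    val <- P[e + 1] - min_val
    if (val > best_val ||
        (val == best_val && (min_idx < best_s ||
                             (min_idx == best_s && e > best_e)))) {
      best_val <- val; best_s <- min_idx; best_e <- e
    }
    if (P[e + 1] < min_val) { min_val <- P[e + 1]; min_idx <- e }
  }
  if (!(best_val > 0)) {
    return(new_trim_result("M1", list(cutoff = cutoff), 0L, 0L, 0, qualities))
  }
  new_trim_result("M1", list(cutoff = cutoff), best_s, best_e, best_val,
                  qualities)
}

#' Sliding-window quality trimming
#'
#' Slides a window of `window` bases across the read and computes the mean
#' Phred quality of each. The kept segment starts at the first window whose
#' mean reaches `quality_cutoff` and is cut at the first subsequent window
#' whose mean falls below it (the cut point is that window's first base);
#' if no later window fails, the read is kept to its end. Reads shorter
#' than the window are treated as a single window. Coordinates are 0-based
#' half-open.
#'
#' @param qualities integer Phred scores (>= 0), non-empty
#' @param window window width in bases (default 10)
#' @param quality_cutoff mean-quality threshold (default 20)
#' @return a `trim_result`
#' @export
trim_sliding_window <- function(qualities, window = 10, quality_cutoff = 20) {
  if (length(qualities) == 0) stop_sk_value("qualities must be non-empty")
  if (window < 1) stop_sk_value("window must be >= 1")
  n <- length(qualities)
  w <- min(window, n)
  P <- c(0, cumsum(qualities))
  means <- (P[(w + 1):(n + 1)] - P[1:(n - w + 1)]) / w  # means[j+1] = m_j
  pass <- means >= quality_cutoff
  if (!any(pass)) {
    return(new_trim_result("M2", list(window = window, quality_cutoff = quality_cutoff),
                           0L, 0L, NA_real_, qualities))
  }
  start <- which(pass)[1] - 1L           # 0-based window index
  fail_after <- which(!pass & seq_along(pass) - 1L > start)
  end <- if (length(fail_after)) fail_after[1] - 1L else n
  new_trim_result("M2", list(window = window, quality_cutoff = quality_cutoff),
                  start, end, NA_real_, qualities)
}

#' Trim a read's qualities with the configured method
#'
#' @param qualities integer Phred scores
#' @param method `"M1"` (modified Mott) or `"M2"` (sliding window)
#' @param cutoff Mott error-probability cutoff
#' @param window,quality_cutoff sliding-window parameters
#' @return a `trim_result`
#' @export
trim_read <- function(qualities, method = c("M1", "M2"), cutoff = 1e-4,
                      window = 10, quality_cutoff = 20) {
  method <- match.arg(method)
  if (method == "M1") trim_mott(qualities, cutoff)
  else trim_sliding_window(qualities, window, quality_cutoff)
}
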