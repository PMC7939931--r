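# Brute-force oracles and tiny fixture builders shared across tests.

`%||%` <- function(a, b) if (is.null(a)) b else a
seq_chars <- sangerkit:::seq_chars
chars_seq <- sangerkit:::chars_seq

# enumerate every contiguous segment; maximise the Mott score sum with the
# same tie-breaks as the implementation (smallest start, then largest end)
mott_oracle <- function(qualities, cutoff) {
  s <- cutoff - 10^(-qualities / 10)
  n <- length(s)
  P <- c(0, cumsum(s))
  best <- list(val = 0, start = 0L, end = 0L)
  found <- FALSE
  for (start in 0:(n - 1)) for (end in (start + 1):n) {
    val <- P[end + 1] - P[start + 1]
    if (!found || val > best$val ||
        (val == best$val && (start < best$start ||
                             (start == best$start && end > best$end)))) {
      if (val > 0) { best <- list(val = val, start = start, end = end); found <- TRUE }
    }
  }
  if (!found) list(val = 0, start = 0L, end = 0L) else best
}

# direct window-mean scan with the spec semantics
window_oracle <- function(qualities, window, cutoff) {
  n <- length(qualities)
  w <- min(window, n)
  means <- vapply(0:(n - w), function(j) mean(qualities[(j + 1):(j + w)]), 0)
  pass <- means >= cutoff
  if (!any(pass)) return(c(0L, 0L))
  start <- which(pass)[1] - 1L
  later_fail <- which(!pass & seq_along(pass) - 1L > start)
  end <- if (length(later_fail)) later_fail[1] - 1L else n
  c(start, end)
}

random_qualities <- function(n) {
  base <- sample(0:60, 1)
  pmin(pmax(round(base + stats::rnorm(n, 0, 15)), 0), 60)
}

# one simulated trace read written to disk as ABIF, returned with its truth
write_sim_read <- function(template, direction = "forward",
                           spec = simulation_spec(), seed = 1,
                           path = tempfile(fileext = ".ab1")) {
  sim <- simulate_read(template, direction, spec, seed = seed)
  write_abif(sim$trace, sim$seq, sim$qualities, path)
  c(sim, list(path = path))
}

# a clean flat-quality spec: full-length coverage, no ramps, no errors
flat_spec <- function(...) {
  args <- utils::modifyList(list(ramp_len = 0, error_rate = 0,
                                 secondary_count = 0), list(...))
  do.call(simulation_spec, args)
}

AA_REF <- "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQAPILSRVGDGTQDNLSGAEKAVQVKVKALPDAQFEVVHSLAKWKR"
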