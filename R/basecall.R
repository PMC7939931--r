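## Base calling and secondary-peak (heterozygote) detection from traces.

peak_intensities <- function(trace, loc) {
  # loc is a 0-based sample index
  c(A = trace$channels$A[loc + 1L], C = trace$channels$C[loc + 1L],
    G = trace$channels$G[loc + 1L], T = trace$channels$T[loc + 1L])
}

call_one <- function(v, secondary_ratio) {
  # v: named intensities in fixed A,C,G,T order; ties go to the first max
  if (all(v == 0)) return(list(primary = "N", secondary = "N", ratio = NA_real_,
                               secondary_base = NA_character_))
  k <- which.max(v)
  primary <- names(v)[k]
  rest <- v[-k]
  k2 <- which.max(rest)
  second <- rest[k2]
  ratio <- unname(second / v[k])
  if (second >= secondary_ratio * v[k] && second > 0) {
    sec_base <- names(rest)[k2]
    list(primary = primary,
         secondary = iupac_code(c(primary, sec_base)),
         ratio = ratio, secondary_base = sec_base)
  } else {
    list(primary = primary, secondary = primary, ratio = ratio,
         secondary_base = NA_character_)
  }
}

#' Call primary and secondary base sequences from a chromatogram
#'
#' At every peak location the primary base is the channel with the highest
#' intensity (ties broken in fixed A < C < G < T order). If the
#' second-highest channel reaches `secondary_ratio` times the highest, the
#' secondary sequence carries the two-base IUPAC ambiguity code at that
#' position, otherwise it repeats the primary base. Peaks with all four
#' channels at zero are called `N`.
#'
#' @param trace a [trace_set()] with non-empty peak locations
#' @param secondary_ratio detection threshold in (0, 1]; default 1/3
#' @return list with `primary_seq` and `secondary_seq` strings
#' @export
call_bases <- function(trace, secondary_ratio = 0.33) {
  stopifnot(inherits(trace, "trace_set"))
  if (!(secondary_ratio > 0 && secondary_ratio <= 1))
    stop_sk_value("secondary_ratio must lie in (0, 1]")
  if (length(trace$peak_locations) == 0)
    stop_sk_value("trace has no peak locations")
  calls <- lapply(trace$peak_locations, function(loc)
    call_one(peak_intensities(trace, loc), secondary_ratio))
  list(primary_seq = chars_seq(vapply(calls, `[[`, "", "primary")),
       secondary_seq = chars_seq(vapply(calls, `[[`, "", "secondary")))
}

#' Detect secondary peaks along a read
#'
#' Reports every basecall position where the second-highest channel at the
#' peak reaches `ratio` times the highest — the classic heterozygote /
#' template-mixture signal. The call set is monotone non-increasing in
#' `ratio`.
#'
#' @param trace a [trace_set()]
#' @param ratio detection threshold in (0, 1]
#' @param within_trim_only restrict calls to the trim window?
#' @param trim 0-based half-open `c(start, end)` window (required when
#'   `within_trim_only` is `TRUE`)
#' @return tibble with columns `base_index` (1-based position in the read),
#'   `trace_position`, `primary_base`, `secondary_base`, `ratio`, sorted by
#'   `base_index`
#' @export
detect_secondary_peaks <- function(trace, ratio = 0.33,
                                   within_trim_only = FALSE, trim = NULL) {
  stopifnot(inherits(trace, "trace_set"))
  if (!(ratio > 0 && ratio <= 1)) stop_sk_value("ratio must lie in (0, 1]")
  locs <- trace$peak_locations
  rows <- list()
  for (i in seq_along(locs)) {
    v <- peak_intensities(trace, locs[i])
    cl <- call_one(v, ratio)
    if (!is.na(cl$secondary_base)) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        base_index = i, trace_position = locs[i],
        primary_base = cl$primary, secondary_base = cl$secondary_base,
        ratio = cl$ratio)
    }
  }
  out <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble::tibble(base_index = integer(0), trace_position = integer(0),
                   primary_base = character(0), secondary_base = character(0),
                   ratio = numeric(0))
  if (within_trim_only) {
    if (is.null(trim)) stop_sk_value("within_trim_only requires a trim window")
    out <- out[out$base_index - 1L >= trim[1] & out$base_index - 1L < trim[2], ]
  }
  out
}
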