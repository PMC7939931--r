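## The single-read object: basecalls, qualities, trim window, secondary
## peaks, and (for ABIF input) the chromatogram.

new_sanger_read <- function(id, direction, primary_seq, secondary_seq = NULL,
                            qualities = NULL, trace = NULL, trim = NULL,
                            secondary_peaks = NULL, origin = "abif",
                            path = NA_character_, params = list()) {
  n <- nchar(primary_seq)
  if (!is.null(qualities) && length(qualities) != n)
    stop_sk_value("read '", id, "': ", n, " bases but ", length(qualities),
                  " qualities")
  trim <- trim %||% c(0L, n)
  if (trim[1] < 0 || trim[2] > n || trim[1] > trim[2])
    stop_sk_value("trim window out of bounds for read '", id, "'")
  structure(list(
    id = id, direction = direction, origin = origin, path = path,
    primary_seq = toupper(primary_seq),
    secondary_seq = if (!is.null(secondary_seq)) toupper(secondary_seq) else NULL,
    qualities = if (!is.null(qualities)) as.integer(qualities) else NULL,
    trace = trace,
    trim = as.integer(trim),
    secondary_peaks = secondary_peaks,
    params = params
  ), class = "sanger_read")
}

#' Load and preprocess one Sanger read
#'
#' For ABIF input the bases are re-called from the trace (primary and
#' secondary sequence), the read is quality-trimmed with the configured
#' method, and secondary peaks are detected. For FASTA input only the
#' sequence is available: trimming, secondary-peak detection and
#' chromatogram plotting are disabled and the whole sequence is kept.
#'
#' @param path an `.ab1`/`.abi` ABIF file or a FASTA file
#' @param direction `"forward"` or `"reverse"`
#' @param trim_method `"M1"` (modified Mott, default) or `"M2"` (sliding
#'   window) or `"none"`
#' @param trim_cutoff Mott error-probability cutoff (default 1e-4)
#' @param trim_window,trim_quality_cutoff sliding-window parameters
#'   (defaults 10 and 20)
#' @param secondary_ratio secondary-peak threshold (default 0.33)
#' @param id read identifier; default the file name without extension
#' @param fasta_id for multi-record FASTA files, the record to use
#'   (default: first record)
#' @return a `sanger_read` object
#' @export
sanger_read <- function(path, direction = c("forward", "reverse"),
                        trim_method = c("M1", "M2", "none"),
                        trim_cutoff = 1e-4, trim_window = 10,
                        trim_quality_cutoff = 20, secondary_ratio = 0.33,
                        id = NULL, fasta_id = NULL) {
  direction <- match.arg(direction)
  trim_method <- match.arg(trim_method)
  if (!file.exists(path)) stop_sk_format("read file not found: ", path)
  params <- list(trim_method = trim_method, trim_cutoff = trim_cutoff,
                 trim_window = trim_window,
                 trim_quality_cutoff = trim_quality_cutoff,
                 secondary_ratio = secondary_ratio)
  id <- id %||% tools::file_path_sans_ext(basename(path))
  if (is_abif_file(path)) {
    ab <- read_abif(path)
    calls <- call_bases(ab$trace, secondary_ratio)
    trim <- if (trim_method == "none") c(0L, nchar(calls$primary_seq)) else {
      tr <- trim_read(ab$qualities, trim_method, cutoff = trim_cutoff,
                      window = trim_window, quality_cutoff = trim_quality_cutoff)
      c(tr$start, tr$end)
    }
    peaks <- detect_secondary_peaks(ab$trace, ratio = secondary_ratio)
    new_sanger_read(id, direction, calls$primary_seq, calls$secondary_seq,
                    ab$qualities, ab$trace, trim, peaks, origin = "abif",
                    path = normalizePath(path), params = params)
  } else {
    recs <- read_fasta(path)
    if (nrow(recs) == 0) stop_sk_format("FASTA file has no records: ", path)
    if (!is.null(fasta_id)) {
      recs <- recs[recs$id == fasta_id, ]
      if (nrow(recs) == 0) stop_sk_value("no FASTA record named '", fasta_id, "'")
    }
    new_sanger_read(id, direction, recs$sequence[1], origin = "fasta",
                    path = normalizePath(path), params = params)
  }
}

is_abif_file <- function(path) {
  if (grepl("\\.(ab1|abi)$", path, ignore.case = TRUE)) return(TRUE)
  if (grepl("\\.(fa|fasta|fna|txt)$", path, ignore.case = TRUE)) return(FALSE)
  # sniff the magic for unknown extensions
  con <- file(path, "rb"); on.exit(close(con))
  identical(rawToChar(readBin(con, "raw", 4)), "ABIF")
}

#' Trimmed portion of a read's primary sequence
#' @param read a `sanger_read`
#' @return the substring inside the trim window (may be empty)
#' @export
trimmed_seq <- function(read) {
  stopifnot(inherits(read, "sanger_read"))
  if (read$trim[2] <= read$trim[1]) return("")
  substr(read$primary_seq, read$trim[1] + 1L, read$trim[2])
}

# trimmed sequence in forward orientation (reverse reads complemented)
oriented_trimmed_seq <- function(read) {
  s <- trimmed_seq(read)
  if (read$direction == "reverse" && nchar(s)) reverse_complement(s) else s
}

#' @export
print.sanger_read <- function(x, ...) {
  cat("<sanger_read> ", x$id, " (", x$direction, ", ", x$origin, ")\n",
      "  ", nchar(x$primary_seq), " bases; trim [", x$trim[1], ", ",
      x$trim[2], ")", sep = "")
  if (!is.null(x$qualities))
    cat("; mean Q ", round(mean(x$qualities), 1), sep = "")
  if (!is.null(x$secondary_peaks))
    cat("; ", nrow(x$secondary_peaks), " secondary peak(s)", sep = "")
  cat("\n")
  invisible(x)
}
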