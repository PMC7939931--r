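## ABIF trace file input/output.
##
## ABIF is the tagged binary container written by Applied Biosystems
## sequencers: a 4-byte magic "ABIF", a 2-byte version, and a directory of
## 28-byte entries, all integers big-endian. Payloads of <= 4 bytes are
## stored inline in the entry's offset field.

ABIF_DIR_ENTRY_SIZE <- 28L
ABIF_WRITE_VERSION <- 101L

#' Construct a chromatogram trace set
#'
#' A trace set holds the four processed dye channels of a Sanger
#' chromatogram, the peak location (sample index) of every called base, and
#' the dye-to-base channel order recorded by the instrument.
#'
#' @param channels named list with elements `A`, `C`, `G`, `T`, each a
#'   numeric vector of non-negative intensities; all four the same length.
#' @param peak_locations integer vector of 0-based sample indices, strictly
#'   increasing, one per called base.
#' @param channel_order 4-character permutation of "ACGT" giving the dye
#'   order (the ABIF `FWO_` field).
#' @return an object of class `trace_set`
#' @export
trace_set <- function(channels, peak_locations = integer(0), channel_order = "GATC") {
  if (!setequal(names(channels), c("A", "C", "G", "T")))
    stop_sk_value("channels must be named A, C, G, T")
  channels <- lapply(channels[c("A", "C", "G", "T")], as.numeric)
  lens <- vapply(channels, length, integer(1))
  if (length(unique(lens)) != 1L)
    stop_sk_value("all four channel arrays must have the same length")
  if (any(unlist(channels) < 0)) stop_sk_value("channel intensities must be non-negative")
  peak_locations <- as.integer(peak_locations)
  L <- lens[[1L]]
  if (length(peak_locations)) {
    if (any(diff(peak_locations) <= 0L))
      stop_sk_value("peak_locations must be strictly increasing")
    if (min(peak_locations) < 0L || max(peak_locations) >= L)
      stop_sk_value("peak_locations out of bounds [0, ", L, ")")
  }
  if (!identical(sort(seq_chars(channel_order)), c("A", "C", "G", "T")))
    stop_sk_value("channel_order must be a permutation of ACGT")
  structure(list(channels = channels, peak_locations = peak_locations,
                 channel_order = channel_order),
            class = "trace_set")
}

#' @export
print.trace_set <- function(x, ...) {
  cat("<trace_set> ", length(x$channels$A), " samples, ",
      length(x$peak_locations), " peaks, channel order ", x$channel_order,
      "\n", sep = "")
  invisible(x)
}

## ---- low-level byte helpers (big-endian throughout) ----

be_int <- function(bytes, size, signed = TRUE) {
  readBin(bytes, "integer", n = length(bytes) %/% size, size = size,
          signed = signed, endian = "big")
}

be_raw_int <- function(x, size) {
  writeBin(as.integer(x), raw(), size = size, endian = "big")
}

parse_dir_entry <- function(bytes) {
  if (length(bytes) < ABIF_DIR_ENTRY_SIZE)
    stop_sk_format("truncated ABIF directory entry (", length(bytes), " bytes)")
  list(
    tag_name     = rawToChar(bytes[1:4]),
    tag_number   = be_int(bytes[5:8], 4L),
    element_type = be_int(bytes[9:10], 2L),
    element_size = be_int(bytes[11:12], 2L),
    num_elements = be_int(bytes[13:16], 4L),
    data_size    = be_int(bytes[17:20], 4L),
    data_offset  = be_int(bytes[21:24], 4L),
    offset_bytes = bytes[21:24]
  )
}

entry_payload <- function(entry, all_bytes) {
  n <- entry$data_size
  if (n <= 4L) return(entry$offset_bytes[seq_len(n)])
  from <- entry$data_offset + 1L
  to <- entry$data_offset + n
  if (to > length(all_bytes))
    stop_sk_format("truncated ABIF file: entry ", entry$tag_name, entry$tag_number,
                   " needs bytes up to ", to, " but file has ", length(all_bytes))
  all_bytes[from:to]
}

decode_payload <- function(entry, payload) {
  switch(as.character(entry$element_type),
    "1"  = be_int(payload, 1L, signed = FALSE),       # unsigned byte
    "2"  = rawToChar(payload),                        # char
    "4"  = be_int(payload, 2L, signed = TRUE),        # short
    "5"  = be_int(payload, 4L, signed = TRUE),        # long
    payload                                           # unknown: keep raw
  )
}

## ---- reading ----

#' Read an ABIF chromatogram file
#'
#' Parses the directory of an `.ab1` file and extracts the fields used by the
#' pipeline: the four processed trace channels (`DATA` tags 9-12, mapped to
#' bases via `FWO_`), the primary basecalls (`PBAS`), the peak location of
#' each call (`PLOC`) and the Phred quality of each call (`PCON`). `PBAS`,
#' `PLOC` and `PCON` are taken from tag number 1, falling back to tag
#' number 2. All other tags are preserved, undecoded, in `metadata`.
#'
#' @param path path to an ABIF file
#' @return a list with elements `trace` (a [trace_set()]), `primary_seq`
#'   (character), `qualities` (integer Phred scores), `metadata` (named list
#'   of raw payloads keyed `TAG.number`) and `version` (directory version).
#' @export
read_abif <- function(path) {
  if (!file.exists(path)) stop_sk_format("file not found: ", path)
  bytes <- readBin(path, "raw", n = file.info(path)$size)
  if (length(bytes) < 34L) stop_sk_format("file too short to be ABIF: ", path)
  magic <- rawToChar(bytes[1:4])
  if (magic != "ABIF")
    stop_sk_format("not an ABIF file: expected magic 'ABIF', found '", magic, "'")
  version <- be_int(bytes[5:6], 2L)
  tdir <- parse_dir_entry(bytes[7:34])
  n_entries <- tdir$num_elements
  dir_off <- tdir$data_offset
  if (dir_off + n_entries * ABIF_DIR_ENTRY_SIZE > length(bytes))
    stop_sk_format("truncated ABIF directory: ", n_entries, " entries at offset ",
                   dir_off, " exceed file size ", length(bytes))

  entries <- vector("list", n_entries)
  for (i in seq_len(n_entries)) {
    from <- dir_off + (i - 1L) * ABIF_DIR_ENTRY_SIZE + 1L
    entries[[i]] <- parse_dir_entry(bytes[from:(from + ABIF_DIR_ENTRY_SIZE - 1L)])
  }
  keys <- vapply(entries, function(e) paste0(e$tag_name, ".", e$tag_number), character(1))
  names(entries) <- keys

  get_entry <- function(tag, numbers, required = TRUE) {
    for (num in numbers) {
      e <- entries[[paste0(tag, ".", num)]]
      if (!is.null(e)) return(e)
    }
    if (required)
      stop_sk_format("required ABIF tag missing: ", tag,
                     " (numbers ", paste(numbers, collapse = "/"), ")")
    NULL
  }
  get_decoded <- function(tag, numbers, required = TRUE) {
    e <- get_entry(tag, numbers, required)
    if (is.null(e)) return(NULL)
    decode_payload(e, entry_payload(e, bytes))
  }

  fwo <- get_decoded("FWO_", 1L)
  if (!identical(sort(seq_chars(fwo)), c("A", "C", "G", "T")))
    stop_sk_format("FWO_ field is not a permutation of ACGT: '", fwo, "'")
  order_chars <- seq_chars(fwo)
  channels <- stats::setNames(vector("list", 4L), c("A", "C", "G", "T"))
  for (k in 1:4) {
    channels[[order_chars[k]]] <- get_decoded("DATA", 8L + k)
  }
  pbas <- get_decoded("PBAS", c(1L, 2L))
  ploc <- get_decoded("PLOC", c(1L, 2L))
  pcon <- get_decoded("PCON", c(1L, 2L))
  if (length(ploc) != nchar(pbas) || length(pcon) != nchar(pbas))
    stop_sk_format("inconsistent ABIF basecall layers: ", nchar(pbas), " bases, ",
                   length(ploc), " peak locations, ", length(pcon), " qualities")

  metadata <- lapply(entries, function(e) {
    c(e[c("tag_name", "tag_number", "element_type", "element_size",
          "num_elements", "data_size")],
      list(data = entry_payload(e, bytes)))
  })

  list(
    trace = trace_set(channels, peak_locations = ploc, channel_order = fwo),
    primary_seq = toupper(pbas),
    qualities = as.integer(pcon),
    metadata = metadata,
    version = version
  )
}

## ---- writing ----

make_entry <- function(tag_name, tag_number, element_type, element_size,
                       num_elements, payload) {
  list(tag_name = tag_name, tag_number = as.integer(tag_number),
       element_type = as.integer(element_type),
       element_size = as.integer(element_size),
       num_elements = as.integer(num_elements),
       payload = payload)
}

serialize_entry <- function(e, data_offset) {
  n <- length(e$payload)
  off_field <- if (n <= 4L) {
    c(e$payload, raw(4L - n))
  } else {
    be_raw_int(data_offset, 4L)
  }
  c(charToRaw(e$tag_name),
    be_raw_int(e$tag_number, 4L),
    be_raw_int(e$element_type, 2L),
    be_raw_int(e$element_size, 2L),
    be_raw_int(e$num_elements, 4L),
    be_raw_int(n, 4L),
    off_field,
    raw(4L))  # datahandle
}

#' Write a minimal valid ABIF chromatogram file
#'
#' Emits the magic, version 101, a directory and the tags the pipeline
#' reads (`DATA` 9-12, `PBAS.1`, `PLOC.1`, `PCON.1`, `FWO_.1`), so that
#' [read_abif()] round-trips every extracted field. Intended for fixtures
#' and simulated data; it is not a full re-implementation of vendor output.
#'
#' @param trace a [trace_set()]
#' @param primary_seq basecall string, same length as `trace$peak_locations`
#' @param qualities integer Phred scores, same length as `primary_seq`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_abif <- function(trace, primary_seq, qualities, path) {
  stopifnot(inherits(trace, "trace_set"))
  n <- nchar(primary_seq)
  if (length(qualities) != n || length(trace$peak_locations) != n)
    stop_sk_value("length mismatch: ", n, " bases, ", length(qualities),
                  " qualities, ", length(trace$peak_locations), " peak locations")
  if (any(qualities < 0L | qualities > 255L))
    stop_sk_value("Phred qualities must lie in [0, 255]")
  if (length(trace$channels$A) && max(unlist(trace$channels)) > 32767)
    stop_sk_value("channel intensities exceed int16 range")

  order_chars <- seq_chars(trace$channel_order)
  entries <- list()
  for (k in 1:4) {
    ch <- trace$channels[[order_chars[k]]]
    entries[[length(entries) + 1L]] <- make_entry(
      "DATA", 8L + k, 4L, 2L, length(ch),
      be_raw_int(round(ch), 2L))
  }
  entries[[length(entries) + 1L]] <- make_entry(
    "FWO_", 1L, 2L, 1L, 4L, charToRaw(trace$channel_order))
  entries[[length(entries) + 1L]] <- make_entry(
    "PBAS", 1L, 2L, 1L, n, charToRaw(primary_seq))
  entries[[length(entries) + 1L]] <- make_entry(
    "PLOC", 1L, 4L, 2L, n, be_raw_int(trace$peak_locations, 2L))
  entries[[length(entries) + 1L]] <- make_entry(
    "PCON", 1L, 1L, 1L, n, be_raw_int(qualities, 1L))

  # layout: 128-byte header | data blocks (payloads > 4 bytes) | directory
  header_size <- 128L
  offset <- header_size
  data_offsets <- integer(length(entries))
  data_blocks <- list()
  for (i in seq_along(entries)) {
    payload <- entries[[i]]$payload
    if (length(payload) > 4L) {
      data_offsets[i] <- offset
      data_blocks[[length(data_blocks) + 1L]] <- payload
      offset <- offset + length(payload)
    }
  }
  dir_offset <- offset
  dir_bytes <- do.call(c, lapply(seq_along(entries), function(i)
    serialize_entry(entries[[i]], data_offsets[i])))

  tdir <- make_entry("tdir", 1L, 1023L, ABIF_DIR_ENTRY_SIZE,
                     length(entries), raw(0))
  tdir_bytes <- serialize_entry(tdir, dir_offset)
  # tdir's data_size must report the directory size even though the payload
  # is carried separately
  tdir_bytes[17:20] <- be_raw_int(length(dir_bytes), 4L)
  tdir_bytes[21:24] <- be_raw_int(dir_offset, 4L)

  header <- c(charToRaw("ABIF"), be_raw_int(ABIF_WRITE_VERSION, 2L),
              tdir_bytes, raw(header_size - 34L))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(header, con)
  for (blk in data_blocks) writeBin(blk, con)
  writeBin(dir_bytes, con)
  invisible(path)
}
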