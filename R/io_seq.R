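## FASTA input/output and grouping of read files into contig groups.

#' Default filename suffix patterns for read direction
#'
#' The common naming convention encodes the contig group at the start of
#' the filename and the read direction in a suffix, e.g. `c01_F.ab1` and
#' `c01_R.ab1`. These defaults match that convention (case-insensitively)
#' for ABIF and FASTA extensions; both are configurable in every function
#' that takes them.
#' @name suffix-defaults
#' @export
default_fwd_suffix <- "_F\\.(ab1|abi|fasta|fa)$"

#' @rdname suffix-defaults
#' @export
default_rev_suffix <- "_R\\.(ab1|abi|fasta|fa)$"

new_grouping_plan <- function(entries, source, skipped = character(0)) {
  stopifnot(all(c("read_path", "direction", "contig") %in% names(entries)))
  if (anyDuplicated(entries$read_path))
    stop_sk_value("duplicate read path in grouping plan: ",
                  entries$read_path[duplicated(entries$read_path)][1])
  out <- tibble::as_tibble(entries[c("read_path", "direction", "contig")])
  structure(out, source = source, skipped = skipped,
            class = c("grouping_plan", class(out)))
}

#' Group read files into contigs by filename convention
#'
#' Recursively scans `root_dir` for read files whose names match a forward
#' or reverse direction suffix; the filename with the suffix removed is the
#' contig group. Files matching neither pattern are skipped and recorded in
#' the `skipped` attribute of the result.
#'
#' @param root_dir directory to scan (recursively)
#' @param fwd_suffix_regex,rev_suffix_regex case-insensitive regular
#'   expressions marking forward / reverse reads
#' @return a `grouping_plan` tibble with columns `read_path`, `direction`
#'   (`"forward"`/`"reverse"`) and `contig`, ordered lexicographically by
#'   path
#' @export
group_by_filename <- function(root_dir,
                              fwd_suffix_regex = default_fwd_suffix,
                              rev_suffix_regex = default_rev_suffix) {
  if (!dir.exists(root_dir)) stop_sk_value("directory not found: ", root_dir)
  files <- sort(list.files(root_dir, recursive = TRUE, full.names = TRUE))
  files <- files[!dir.exists(files)]
  base <- basename(files)
  is_fwd <- grepl(fwd_suffix_regex, base, ignore.case = TRUE)
  is_rev <- grepl(rev_suffix_regex, base, ignore.case = TRUE)
  both <- is_fwd & is_rev
  if (any(both))
    stop_sk_value("file matches both direction suffixes: ", files[both][1])
  keep <- is_fwd | is_rev
  if (!any(keep))
    stop_sk_value("no files in ", root_dir, " match either direction suffix")
  skipped <- files[!keep]
  strip <- function(x, pat) sub(pat, "", x, ignore.case = TRUE)
  contig <- ifelse(is_fwd, strip(base, fwd_suffix_regex),
                   strip(base, rev_suffix_regex))
  entries <- tibble::tibble(
    read_path = normalizePath(files[keep]),
    direction = ifelse(is_fwd[keep], "forward", "reverse"),
    contig = contig[keep]
  )
  entries <- entries[order(entries$read_path), ]
  new_grouping_plan(entries, source = "filename_regex", skipped = skipped)
}

normalize_direction <- function(tokens, context = "direction") {
  tok <- tolower(trimws(tokens))
  out <- ifelse(tok %in% c("f", "forward", "fwd"), "forward",
         ifelse(tok %in% c("r", "reverse", "rev"), "reverse", NA_character_))
  if (anyNA(out)) {
    row <- which(is.na(out))[1]
    stop_sk_value("unknown ", context, " token '", tokens[row], "' at row ", row)
  }
  out
}

#' Read a three-column grouping CSV
#'
#' The CSV must have a header with columns `reads`, `direction` and
#' `contig` (any order, case-insensitive): the read file name (relative
#' paths are resolved against the CSV's directory), the read orientation
#' (`F`/`forward` or `R`/`reverse`, case-insensitive), and the contig group.
#'
#' @param path path to the CSV file
#' @return a `grouping_plan` tibble, as [group_by_filename()]
#' @export
read_grouping_csv <- function(path) {
  if (!file.exists(path)) stop_sk_value("grouping CSV not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  names(df) <- tolower(trimws(names(df)))
  required <- c("reads", "direction", "contig")
  if (!all(required %in% names(df)))
    stop_sk_format("grouping CSV must have columns reads, direction, contig; found: ",
                   paste(names(df), collapse = ", "))
  if (nrow(df) == 0) stop_sk_value("grouping CSV has no rows: ", path)
  dirn <- normalize_direction(df$direction)
  paths <- df$reads
  rel <- !grepl("^(/|[A-Za-z]:)", paths)
  paths[rel] <- file.path(dirname(normalizePath(path)), paths[rel])
  if (anyDuplicated(paths))
    stop_sk_value("duplicate read name in grouping CSV: ",
                  df$reads[duplicated(paths)][1])
  entries <- tibble::tibble(
    read_path = ifelse(file.exists(paths), suppressWarnings(normalizePath(paths)), paths),
    direction = dirn,
    contig = as.character(df$contig)
  )
  entries <- entries[order(entries$read_path), ]
  new_grouping_plan(entries, source = "csv")
}

#' Read a FASTA file
#'
#' @param path path to a FASTA nucleotide file
#' @return tibble with columns `id` and `sequence` (uppercased)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop_sk_value("FASTA file not found: ", path)
  info <- file.info(path)
  if (info$size == 0) return(tibble::tibble(id = character(0), sequence = character(0)))
  set <- Biostrings::readBStringSet(path)
  tibble::tibble(id = names(set),
                 sequence = unname(toupper(as.character(set))))
}

#' Write sequences to a FASTA file
#'
#' @param records tibble/data frame with columns `id` and `sequence`, or a
#'   named character vector
#' @param path output path
#' @param line_width characters per sequence line (default 80)
#' @return `path`, invisibly
#' @export
write_fasta <- function(records, path, line_width = 80) {
  if (is.character(records)) {
    records <- tibble::tibble(id = names(records) %||% paste0("seq", seq_along(records)),
                              sequence = unname(records))
  }
  seqs <- toupper(records$sequence)
  for (k in seq_along(seqs)) {
    assert_iupac(seqs[k], allow_gap = TRUE,
                 what = paste0("sequence '", records$id[k], "'"))
  }
  set <- Biostrings::BStringSet(seqs)
  names(set) <- records$id
  Biostrings::writeXStringSet(set, path, width = line_width)
  invisible(path)
}
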