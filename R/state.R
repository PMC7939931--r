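## Versioned JSON state file: every parameter, trim window, alignment,
## table and the tree, so an analysis can be reloaded and its report
## regenerated byte-for-byte.

STATE_VERSION <- "1.0"

read_to_state <- function(r) {
  list(
    id = r$id, direction = r$direction, origin = r$origin, path = r$path,
    primary_seq = r$primary_seq, secondary_seq = r$secondary_seq,
    qualities = r$qualities, trim = r$trim,
    secondary_peaks = r$secondary_peaks, params = r$params
  )
}

rows_to_tibble <- function(x, template) {
  if (is.null(x) || length(x) == 0) return(template)
  dplyr::bind_rows(lapply(x, tibble::as_tibble))
}

empty_peaks_tibble <- function() {
  tibble::tibble(base_index = integer(0), trace_position = integer(0),
                 primary_base = character(0), secondary_base = character(0),
                 ratio = numeric(0))
}

state_to_read <- function(s, reload_trace = TRUE) {
  trace <- NULL
  if (reload_trace && identical(s$origin, "abif") && !is.null(s$path) &&
      file.exists(s$path)) {
    trace <- read_abif(s$path)$trace
  }
  peaks <- rows_to_tibble(s$secondary_peaks, empty_peaks_tibble())
  new_sanger_read(s$id, s$direction, s$primary_seq, s$secondary_seq,
                  unlist(s$qualities), trace, unlist(s$trim), peaks,
                  origin = s$origin, path = s$path %||% NA_character_,
                  params = s$params)
}

#' Save a contig set to a JSON state file
#'
#' The state holds all parameters, per-read sequences / qualities / trim
#' windows / secondary-peak calls, the read and contig alignments, the
#' analysis tables, the tree as Newick, and file provenance. Traces are
#' not embedded; they are re-read from the recorded ABIF paths on load
#' when available.
#'
#' @param contig_set a `sanger_contig_set`
#' @param path output `.json` path
#' @return `path`, invisibly
#' @export
save_state <- function(contig_set, path) {
  stopifnot(inherits(contig_set, "sanger_contig_set"))
  st <- list(
    format = "sangerkit-state",
    version = STATE_VERSION,
    params = contig_set$params,
    contigs = lapply(contig_set$contigs, function(ct) list(
      name = ct$name,
      included = ct$included, excluded = ct$excluded,
      reads = lapply(ct$reads, read_to_state),
      read_msa = as.list(ct$read_msa),
      consensus = ct$consensus,
      hamming = ct$hamming,
      indels = ct$indels, stops = ct$stops,
      aa_reference = ct$aa_reference,
      params = ct$params
    )),
    contig_msa = as.list(contig_set$contig_msa),
    distances = contig_set$distances,
    tree = if (!is.null(contig_set$tree)) newick_string(contig_set$tree, digits = 10)
  )
  jsonlite::write_json(st, path, auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(path)
}

#' Load a contig set from a JSON state file
#'
#' @param path state file written by [save_state()]
#' @param reload_traces re-read chromatograms from the recorded ABIF paths
#'   (when the files still exist)?
#' @return a `sanger_contig_set`
#' @export
load_state <- function(path, reload_traces = TRUE) {
  if (!file.exists(path)) stop_sk_format("state file not found: ", path)
  st <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                 error = function(e) stop_sk_format("cannot parse state file: ",
                                                    conditionMessage(e)))
  if (!identical(st$format, "sangerkit-state"))
    stop_sk_format("not a sangerkit state file: ", path)
  if (!identical(st$version, STATE_VERSION))
    stop_sk_format("state version mismatch: file has '", st$version,
                   "', this package reads '", STATE_VERSION, "'")
  tib <- rows_to_tibble
  contigs <- lapply(st$contigs, function(cs) {
    reads <- lapply(cs$reads, state_to_read, reload_trace = reload_traces)
    names(reads) <- vapply(reads, `[[`, "", "id")
    ham <- do.call(rbind, lapply(cs$hamming, unlist))
    if (!is.null(ham)) dimnames(ham) <- list(unlist(cs$included), unlist(cs$included))
    structure(list(
      name = cs$name,
      reads = reads,
      included = unlist(cs$included),
      excluded = unlist(cs$excluded) %||% character(0),
      read_msa = unlist(cs$read_msa),
      consensus = cs$consensus,
      hamming = ham,
      dendrogram = if (!is.null(ham) && nrow(ham) >= 2)
        stats::hclust(stats::as.dist(ham), method = "average"),
      indels = if (!is.null(cs$indels)) tib(cs$indels, empty_indels()),
      stops = if (!is.null(cs$stops)) tib(cs$stops, empty_stops()),
      aa_reference = cs$aa_reference,
      params = cs$params
    ), class = "sanger_contig")
  })
  names(contigs) <- vapply(contigs, `[[`, "", "name")
  dist <- if (!is.null(st$distances)) {
    m <- do.call(rbind, lapply(st$distances, unlist))
    dimnames(m) <- list(names(contigs), names(contigs))
    m
  }
  structure(list(
    contigs = contigs,
    contig_msa = unlist(st$contig_msa),
    distances = dist,
    tree = if (!is.null(st$tree)) parse_newick_text(st$tree),
    params = st$params
  ), class = "sanger_contig_set")
}
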