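## FASTA output modes.

#' Write pipeline results to FASTA files
#'
#' Four output modes: `"reads"` (all trimmed reads, oriented to the
#' forward strand), `"contigs"` (consensus of every contig),
#' `"aligned_contigs"` (the gapped contig MSA), and `"all"` (all three
#' files). Filenames are fixed (`reads.fasta`, `contigs.fasta`,
#' `contigs_aligned.fasta`) so runs are reproducible.
#'
#' @param contig_set a `sanger_contig_set`
#' @param which output mode
#' @param out_dir output directory (created if needed)
#' @return tibble with columns `mode` and `file`
#' @export
write_outputs <- function(contig_set,
                          which = c("all", "reads", "contigs", "aligned_contigs"),
                          out_dir = ".") {
  stopifnot(inherits(contig_set, "sanger_contig_set"))
  if (length(which) != 1 || !which %in% c("all", "reads", "contigs", "aligned_contigs"))
    stop_sk_value("unknown output mode: ", paste(which, collapse = ","))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- list()
  emit <- function(mode, file, records) {
    write_fasta(records, file.path(out_dir, file))
    out[[length(out) + 1L]] <<- tibble::tibble(mode = mode, file = file.path(out_dir, file))
  }
  if (which %in% c("all", "reads")) {
    recs <- purrr::map_dfr(contig_set$contigs, function(ct) {
      tibble::tibble(id = paste0(ct$name, "/", ct$included),
                     sequence = vapply(ct$reads[ct$included],
                                       oriented_trimmed_seq, ""))
    })
    emit("reads", "reads.fasta", recs)
  }
  if (which %in% c("all", "contigs")) {
    recs <- tibble::tibble(id = names(contig_set$contigs),
                           sequence = vapply(contig_set$contigs, `[[`, "", "consensus"))
    emit("contigs", "contigs.fasta", recs)
  }
  if (which %in% c("all", "aligned_contigs")) {
    recs <- tibble::tibble(id = names(contig_set$contig_msa),
                           sequence = unname(contig_set$contig_msa))
    emit("aligned_contigs", "contigs_aligned.fasta", recs)
  }
  dplyr::bind_rows(out)
}
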