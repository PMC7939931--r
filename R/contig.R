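## Contig assembly: orient reads, align them, call the consensus, and
## derive the Hamming matrix, read dendrogram and indel/stop-codon tables.

#' IUPAC consensus of a read alignment
#'
#' Per column, over the non-gap characters: if one character's fraction
#' exceeds `majority_threshold` it is the consensus; otherwise the IUPAC
#' code covering every character with fraction at least
#' `ambiguity_min_fraction` is emitted (falling back to the union of all
#' characters in the column if none qualifies). Columns in which more than
#' half the rows are gaps are omitted, so single-read overhangs do not
#' enter the contig.
#'
#' @param read_msa character vector of equal-length gapped rows
#' @param majority_threshold fraction above which a single base wins
#'   (default 0.5)
#' @param ambiguity_min_fraction minimum fraction for inclusion in the
#'   ambiguity code (default 0.25)
#' @return IUPAC consensus string
#' @export
consensus_sequence <- function(read_msa, majority_threshold = 0.5,
                               ambiguity_min_fraction = 0.25) {
  if (length(read_msa) == 0) stop_sk_value("empty alignment")
  rows <- lapply(read_msa, function(s) seq_chars(toupper(s)))
  lens <- lengths(rows)
  if (length(unique(lens)) != 1) stop_sk_value("alignment rows differ in length")
  mat <- do.call(rbind, rows)
  out <- character(0)
  for (j in seq_len(ncol(mat))) {
    col <- mat[, j]
    gap_frac <- mean(col == "-")
    if (gap_frac > 0.5) next
    ch <- col[col != "-"]
    tab <- sort(table(ch), decreasing = TRUE)
    frac <- as.numeric(tab) / length(ch)
    if (frac[1] > majority_threshold) {
      out <- c(out, names(tab)[1])
    } else {
      qual <- names(tab)[frac >= ambiguity_min_fraction]
      if (length(qual) == 0) qual <- names(tab)
      bases <- unique(unlist(lapply(qual, iupac_expand)))
      out <- c(out, iupac_code(bases))
    }
  }
  chars_seq(out)
}

#' Pairwise Hamming distances between aligned reads
#'
#' Entry (i, j) counts the alignment columns where rows i and j are both
#' non-gap and differ. The matrix is symmetric with a zero diagonal.
#'
#' @param read_msa named character vector of equal-length gapped rows
#' @return symmetric integer matrix with row/column names
#' @export
hamming_matrix <- function(read_msa) {
  rows <- lapply(read_msa, function(s) seq_chars(toupper(s)))
  lens <- lengths(rows)
  if (length(unique(lens)) > 1) stop_sk_value("alignment rows differ in length")
  n <- length(rows)
  nm <- names(read_msa) %||% paste0("read", seq_len(n))
  m <- matrix(0L, n, n, dimnames = list(nm, nm))
  if (n < 2) return(m)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    a <- rows[[i]]; b <- rows[[j]]
    shared <- a != "-" & b != "-"
    m[i, j] <- m[j, i] <- sum(a[shared] != b[shared])
  }
  m
}

#' Cluster a contig's reads on their Hamming distances
#'
#' Average-linkage (UPGMA) clustering; included as a quick quality-control
#' view of which reads agree.
#'
#' @param hamming symmetric distance matrix from [hamming_matrix()]
#' @return an `hclust` object, or `NULL` with a message for < 2 reads
#' @export
read_dendrogram <- function(hamming) {
  if (nrow(hamming) < 2) {
    message("fewer than 2 reads: no dendrogram")
    return(NULL)
  }
  stats::hclust(stats::as.dist(hamming), method = "average")
}

#' Assemble reads into a contig
#'
#' Reverse reads are reverse-complemented, trimmed sequences are aligned
#' (pairwise NW for two reads, progressive MSA otherwise), and the IUPAC
#' consensus is called. Reads whose trimmed sequence is shorter than
#' `min_read_length` are excluded and listed in the result rather than
#' silently dropped. If an amino-acid reference is given, indel and
#' stop-codon tables are computed for each read.
#'
#' @param reads list of `sanger_read` objects (>= 1)
#' @param name contig name
#' @param min_read_length minimum trimmed length to enter assembly
#'   (default 20)
#' @param majority_threshold,ambiguity_min_fraction consensus parameters,
#'   see [consensus_sequence()]
#' @param match,mismatch,gap alignment scores
#' @param aa_reference optional amino-acid reference for indel / stop-codon
#'   screening
#' @return a `sanger_contig` object
#' @export
build_contig <- function(reads, name = "contig",
                         min_read_length = 20,
                         majority_threshold = 0.5,
                         ambiguity_min_fraction = 0.25,
                         match = 2, mismatch = -1, gap = -2,
                         aa_reference = NULL) {
  if (length(reads) == 0) stop_sk_value("contig '", name, "': no reads")
  ids <- vapply(reads, `[[`, "", "id")
  names(reads) <- ids
  oriented <- vapply(reads, oriented_trimmed_seq, "")
  keep <- nchar(oriented) >= min_read_length
  excluded <- ids[!keep]
  if (!any(keep))
    stop_sk_value("contig '", name, "': all reads excluded after trimming ",
                  "(min_read_length = ", min_read_length, ")")
  seqs <- oriented[keep]
  msa <- align_msa(seqs, type = "dna", match = match, mismatch = mismatch,
                   gap = gap)
  cons <- consensus_sequence(msa, majority_threshold, ambiguity_min_fraction)
  ham <- hamming_matrix(msa)
  dendro <- if (length(msa) >= 2) read_dendrogram(ham) else NULL
  contig <- structure(list(
    name = name,
    reads = reads,
    included = ids[keep],
    excluded = excluded,
    read_msa = msa,
    consensus = cons,
    hamming = ham,
    dendrogram = dendro,
    indels = NULL,
    stops = NULL,
    aa_reference = aa_reference,
    params = list(min_read_length = min_read_length,
                  majority_threshold = majority_threshold,
                  ambiguity_min_fraction = ambiguity_min_fraction,
                  match = match, mismatch = mismatch, gap = gap)
  ), class = "sanger_contig")
  if (!is.null(aa_reference)) {
    tabs <- indel_and_stop_tables(contig, aa_reference)
    contig$indels <- tabs$indels
    contig$stops <- tabs$stops
  }
  contig
}

#' @export
print.sanger_contig <- function(x, ...) {
  cat("<sanger_contig> ", x$name, ": ", length(x$included), " read(s)",
      if (length(x$excluded)) paste0(" (+", length(x$excluded), " excluded)"),
      ", consensus ", nchar(x$consensus), " bp\n", sep = "")
  invisible(x)
}
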