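## Indel and stop-codon screening against an amino-acid reference, and
## frameshift correction.
##
## The reading frame and strand are chosen by translating all six frames
## and globally aligning each translation to the reference (BLOSUM62,
## linear gap). Indels are then located with a codon-aware DP that aligns
## the nucleotide read directly against the amino-acid reference, allowing
## whole-codon gaps and penalised 1-2 nt frameshift moves; end gaps are
## free, so partial reads and primer overhangs do not count as indels.

NT_CODE <- c(A = 1L, C = 2L, G = 3L, T = 4L)

encode_nt <- function(seq) {
  idx <- NT_CODE[seq_chars(toupper(seq))]
  idx[is.na(idx)] <- 0L
  unname(idx)
}

# 125-entry codon -> BLOSUM62 row lookup; base digits 0 = ambiguous, 1..4 = ACGT
codon2aa_table <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    S <- get_blosum62()
    syms <- rownames(S)
    gc <- Biostrings::GENETIC_CODE
    tab <- integer(125)
    letters4 <- c("A", "C", "G", "T")
    for (b1 in 0:4) for (b2 in 0:4) for (b3 in 0:4) {
      idx <- b1 * 25L + b2 * 5L + b3 + 1L
      aa <- if (b1 == 0 || b2 == 0 || b3 == 0) "X" else
        gc[[paste0(letters4[b1], letters4[b2], letters4[b3])]]
      row <- match(aa, syms)
      tab[idx] <- if (is.na(row)) match("X", syms) else row
    }
    cache <<- tab
    cache
  }
})

encode_aa <- function(aa) {
  syms <- rownames(get_blosum62())
  idx <- match(seq_chars(toupper(aa)), syms)
  idx[is.na(idx)] <- match("X", syms)
  idx
}

translate_frame <- function(seq, offset) {
  n <- nchar(seq)
  len <- ((n - offset) %/% 3) * 3
  if (len < 3) return("")
  sub <- substr(seq, offset + 1, offset + len)
  as.character(Biostrings::translate(Biostrings::DNAString(sub),
                                     if.fuzzy.codon = "X"))
}

#' Load an amino-acid reference from a string or FASTA file
#' @param x amino-acid sequence, or path to a FASTA file (first record used)
#' @return uppercase amino-acid string
#' @export
load_aa_reference <- function(x) {
  if (length(x) != 1 || !nzchar(x)) stop_sk_value("empty amino-acid reference")
  if (file.exists(x)) {
    recs <- read_fasta(x)
    if (nrow(recs) == 0) stop_sk_value("reference FASTA has no records: ", x)
    return(toupper(recs$sequence[1]))
  }
  toupper(gsub("\\s", "", x))
}

# choose the strand whose best reading frame scores highest against the
# reference (protein NW, BLOSUM62, gap -4); ties prefer forward
choose_strand <- function(seq, aa_reference) {
  best <- NULL
  for (strand in c("forward", "reverse")) {
    s <- if (strand == "reverse") reverse_complement(seq) else seq
    for (off in 0:2) {
      tr <- translate_frame(s, off)
      if (!nzchar(tr)) next
      sc <- align_pair_protein(tr, aa_reference)$score
      if (is.null(best) || sc > best$score)
        best <- list(strand = strand, offset = off, score = sc)
    }
  }
  if (is.null(best)) stop_sk_value("sequence too short to translate")
  best
}

# codon-aware alignment of one nucleotide sequence against the reference;
# returns the DP path plus the working-orientation sequence
codon_alignment <- function(seq, aa_reference, fs_pen = -12, gap3_pen = -8) {
  aa_reference <- load_aa_reference(aa_reference)
  st <- choose_strand(seq, aa_reference)
  work <- if (st$strand == "reverse") reverse_complement(seq) else seq
  res <- codon_align_cpp(encode_nt(work), encode_aa(aa_reference),
                         protein_score_matrix(), codon2aa_table(),
                         fs_pen, gap3_pen)
  c(res, list(strand = st$strand, work_seq = work,
              frame_offset = res$start_nt %% 3L,
              aa_reference = aa_reference))
}

# nt consumed / aa consumed / alignment columns per move code
MOVE_DNT <- c(3L, 3L, 0L, 2L, 1L, 2L, 1L)
MOVE_DAA <- c(1L, 0L, 1L, 1L, 1L, 0L, 0L)
MOVE_COL <- c(3L, 3L, 3L, 3L, 3L, 2L, 1L)
STOP_CODONS <- c("TAA", "TAG", "TGA")

empty_indels <- function() tibble::tibble(
  read_id = character(0), alignment_column_start = integer(0),
  length = integer(0), kind = character(0), frameshifting = logical(0))

empty_stops <- function() tibble::tibble(
  read_id = character(0), codon_index = integer(0), codon = character(0),
  nucleotide_position = integer(0))

scan_codon_path <- function(ca, read_id) {
  moves <- ca$moves
  m_ref <- nchar(ca$aa_reference)
  i <- ca$start_nt; j <- ca$start_aa; col <- 0L
  codon_count <- 0L
  indels <- list(); stops <- list()
  run <- NULL  # open indel run: list(kind, col_start, len)
  flush_run <- function() {
    if (!is.null(run)) {
      indels[[length(indels) + 1L]] <<- tibble::tibble(
        read_id = read_id, alignment_column_start = run$col_start,
        length = run$len, kind = run$kind,
        frameshifting = (run$len %% 3L) != 0L)
      run <<- NULL
    }
  }
  three_nt_moves <- which(moves %in% c(1L, 2L))
  last_3nt <- if (length(three_nt_moves)) three_nt_moves[length(three_nt_moves)] else 0L
  for (k in seq_along(moves)) {
    mv <- moves[k]
    dnt <- MOVE_DNT[mv]; daa <- MOVE_DAA[mv]
    if (mv %in% c(1L, 2L)) {            # a complete read codon
      codon_count <- codon_count + 1L
      codon <- substr(ca$work_seq, i + 1L, i + 3L)
      terminal <- (k == last_3nt) && (j + daa >= m_ref)
      if (codon %in% STOP_CODONS && !terminal) {
        stops[[length(stops) + 1L]] <- tibble::tibble(
          read_id = read_id, codon_index = codon_count, codon = codon,
          nucleotide_position = i + 1L)
      }
      if (mv == 2L) {                   # in-frame codon insertion
        if (!is.null(run) && run$kind == "insertion") run$len <- run$len + 3L
        else { flush_run(); run <- list(kind = "insertion", col_start = col + 1L, len = 3L) }
      } else flush_run()
    } else if (mv %in% c(3L, 4L, 5L)) { # missing read bases
      missing <- 3L * daa - dnt
      if (!is.null(run) && run$kind == "deletion") run$len <- run$len + missing
      else { flush_run(); run <- list(kind = "deletion", col_start = col + 1L, len = missing) }
    } else {                            # mv 6, 7: frameshift insertion
      if (!is.null(run) && run$kind == "insertion") run$len <- run$len + dnt
      else { flush_run(); run <- list(kind = "insertion", col_start = col + 1L, len = dnt) }
    }
    i <- i + dnt; j <- j + daa; col <- col + MOVE_COL[mv]
  }
  flush_run()
  list(
    indels = if (length(indels)) dplyr::bind_rows(indels) else empty_indels(),
    stops = if (length(stops)) dplyr::bind_rows(stops) else empty_stops()
  )
}

#' Indel and stop-codon tables for reads against an amino-acid reference
#'
#' For each read (or a single sequence) the best strand and reading frame
#' are found by six-frame translation, then a codon-aware alignment against
#' the reference locates insertions and deletions; indels whose length is
#' not a multiple of three are flagged as frameshifting. Stop codons (TAA,
#' TAG, TGA) are reported at their codon index in the chosen frame, except
#' a terminal stop aligned at the reference's end.
#'
#' @param x a `sanger_contig` (per-read tables on the trimmed, oriented
#'   reads), a `sanger_read`, or a character sequence
#' @param aa_reference amino-acid reference (string or FASTA path)
#' @param fs_pen,gap3_pen alignment penalties for frameshift (1-2 nt) and
#'   whole-codon gaps
#' @return list with tibbles `indels` (`read_id`, `alignment_column_start`,
#'   `length`, `kind`, `frameshifting`) and `stops` (`read_id`,
#'   `codon_index`, `codon`, `nucleotide_position`), plus `frames` (chosen
#'   strand and frame offset per read)
#' @export
indel_and_stop_tables <- function(x, aa_reference, fs_pen = -12, gap3_pen = -8) {
  if (is.null(aa_reference)) {
    message("no amino-acid reference: indel and stop-codon tables skipped")
    return(list(indels = empty_indels(), stops = empty_stops(),
                frames = tibble::tibble()))
  }
  seqs <- if (inherits(x, "sanger_contig")) {
    vapply(x$reads[x$included], oriented_trimmed_seq, "")
  } else if (inherits(x, "sanger_read")) {
    stats::setNames(oriented_trimmed_seq(x), x$id)
  } else {
    stats::setNames(as.character(x), names(x) %||% paste0("seq", seq_along(x)))
  }
  indels <- list(); stops <- list(); frames <- list()
  for (id in names(seqs)) {
    ca <- codon_alignment(seqs[[id]], aa_reference, fs_pen, gap3_pen)
    sc <- scan_codon_path(ca, id)
    indels[[id]] <- sc$indels
    stops[[id]] <- sc$stops
    frames[[id]] <- tibble::tibble(read_id = id, strand = ca$strand,
                                   frame_offset = ca$frame_offset,
                                   score = ca$score)
  }
  list(indels = dplyr::bind_rows(indels) %||% empty_indels(),
       stops = dplyr::bind_rows(stops) %||% empty_stops(),
       frames = dplyr::bind_rows(frames))
}

#' Correct frameshift errors against an amino-acid reference
#'
#' Frameshifting insertions (1-2 extra bases relative to the reference's
#' codon structure) are deleted, and frameshifting deletions are padded
#' with `N` to restore the reading frame. In-frame columns are never
#' changed, and the function is idempotent.
#'
#' @param seq nucleotide sequence
#' @param aa_reference amino-acid reference (string or FASTA path)
#' @param fs_pen,gap3_pen see [indel_and_stop_tables()]
#' @return list with `seq` (corrected sequence, in the input orientation)
#'   and `edits` (tibble: `position` in the coding-strand orientation,
#'   `kind`, `length`)
#' @export
correct_frameshifts <- function(seq, aa_reference, fs_pen = -12, gap3_pen = -8) {
  ca <- codon_alignment(seq, aa_reference, fs_pen, gap3_pen)
  work <- ca$work_seq
  n <- nchar(work)
  pieces <- character(0)
  edits <- list()
  i <- ca$start_nt
  if (i > 0) pieces <- substr(work, 1, i)
  for (mv in ca$moves) {
    dnt <- MOVE_DNT[mv]
    chunk <- if (dnt > 0) substr(work, i + 1L, i + dnt) else ""
    if (mv %in% c(1L, 2L)) {
      pieces <- c(pieces, chunk)
    } else if (mv %in% c(4L, 5L)) {     # frameshift deletion: pad to a codon
      pad <- strrep("N", 3L - dnt)
      pieces <- c(pieces, chunk, pad)
      edits[[length(edits) + 1L]] <- tibble::tibble(
        position = i + dnt, kind = "pad_deletion", length = 3L - dnt)
    } else if (mv %in% c(6L, 7L)) {     # frameshift insertion: drop the bases
      edits[[length(edits) + 1L]] <- tibble::tibble(
        position = i + 1L, kind = "delete_insertion", length = dnt)
    }                                   # mv 3: in-frame codon deletion, no pad
    i <- i + dnt
  }
  if (i < n) pieces <- c(pieces, substr(work, i + 1L, n))
  corrected <- paste(pieces, collapse = "")
  if (ca$strand == "reverse") corrected <- reverse_complement(corrected)
  list(seq = corrected,
       edits = if (length(edits)) dplyr::bind_rows(edits) else
         tibble::tibble(position = integer(0), kind = character(0),
                        length = integer(0)))
}
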