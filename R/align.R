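## Pairwise and progressive multiple alignment.
##
## A single Needleman-Wunsch core (compiled) serves nucleotide and protein
## alignment; progressive MSA builds a UPGMA guide tree from pairwise
## p-distances and merges profiles with a profile-profile NW.

DNA_SYMBOLS <- IUPAC_CODES  # 15 symbols, gap handled separately

dna_score_matrix <- function(match = 2, mismatch = -1) {
  K <- length(DNA_SYMBOLS)
  S <- matrix(mismatch, K, K, dimnames = list(DNA_SYMBOLS, DNA_SYMBOLS))
  for (i in seq_len(K)) for (j in seq_len(K)) {
    if (iupac_intersects(DNA_SYMBOLS[i], DNA_SYMBOLS[j])) S[i, j] <- match
  }
  S
}

encode_seq <- function(seq, symbols) {
  ch <- seq_chars(toupper(seq))
  idx <- match(ch, symbols)
  if (anyNA(idx)) {
    pos <- which(is.na(idx))[1]
    stop_sk_value("character '", ch[pos], "' at position ", pos,
                  " is not in the alignment alphabet")
  }
  idx
}

protein_score_matrix <- function() {
  S <- get_blosum62()
  storage.mode(S) <- "double"
  S
}

get_blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

#' Global pairwise alignment (Needleman-Wunsch)
#'
#' Linear gap penalty, deterministic traceback (diagonal preferred over a
#' gap in `b`, preferred over a gap in `a`). IUPAC ambiguity codes score as
#' a match whenever their base sets intersect.
#'
#' @param a,b non-empty IUPAC nucleotide strings
#' @param match,mismatch,gap scoring parameters (defaults +2 / -1 / -2)
#' @return list with `a_gapped`, `b_gapped` (equal-length gapped strings)
#'   and `score`
#' @export
align_pair <- function(a, b, match = 2, mismatch = -1, gap = -2) {
  if (nchar(a) == 0 || nchar(b) == 0)
    stop_sk_value("align_pair requires non-empty sequences")
  assert_iupac(a, what = "sequence a"); assert_iupac(b, what = "sequence b")
  S <- dna_score_matrix(match, mismatch)
  res <- nw_align_idx(encode_seq(a, DNA_SYMBOLS), encode_seq(b, DNA_SYMBOLS), S, gap)
  ca <- seq_chars(toupper(a)); cb <- seq_chars(toupper(b))
  list(
    a_gapped = chars_seq(ifelse(res$a_idx == 0, "-", ca[pmax(res$a_idx, 1)])),
    b_gapped = chars_seq(ifelse(res$b_idx == 0, "-", cb[pmax(res$b_idx, 1)])),
    score = res$score
  )
}

align_pair_protein <- function(a, b, gap = -4) {
  S <- protein_score_matrix()
  syms <- rownames(S)
  ea <- match(seq_chars(toupper(a)), syms); ea[is.na(ea)] <- match("X", syms)
  eb <- match(seq_chars(toupper(b)), syms); eb[is.na(eb)] <- match("X", syms)
  res <- nw_align_idx(ea, eb, S, gap)
  ca <- seq_chars(toupper(a)); cb <- seq_chars(toupper(b))
  list(
    a_gapped = chars_seq(ifelse(res$a_idx == 0, "-", ca[pmax(res$a_idx, 1)])),
    b_gapped = chars_seq(ifelse(res$b_idx == 0, "-", cb[pmax(res$b_idx, 1)])),
    score = res$score
  )
}

# p-distance from one pairwise alignment (mismatches over shared non-gap
# columns; 1 when nothing is shared)
pairwise_pdist <- function(aln) {
  ca <- seq_chars(aln$a_gapped); cb <- seq_chars(aln$b_gapped)
  shared <- ca != "-" & cb != "-"
  if (!any(shared)) return(1)
  mean(ca[shared] != cb[shared])
}

# alignment matrix (rows = sequences, ints, 0 = gap) -> profile for the C core
profile_freqs <- function(mat, K) {
  nr <- nrow(mat)
  out <- matrix(0, K + 1L, ncol(mat))
  for (j in seq_len(ncol(mat))) {
    col <- mat[, j]
    tab <- tabulate(col[col > 0L], nbins = K)
    out[seq_len(K), j] <- tab / nr
    out[K + 1L, j] <- sum(col == 0L) / nr
  }
  out
}

apply_col_map <- function(mat, idx) {
  out <- matrix(0L, nrow(mat), length(idx))
  nz <- idx > 0L
  out[, nz] <- mat[, idx[nz], drop = FALSE]
  out
}

#' Progressive multiple sequence alignment
#'
#' Pairwise NW alignments give p-distances, average-linkage (UPGMA)
#' clustering on those distances gives the guide order, and clusters are
#' merged by profile-profile NW. Deterministic for a fixed input; permuting
#' the input rows permutes the output rows but leaves columns identical.
#'
#' @param seqs named character vector of >= 1 sequences
#' @param type `"dna"` (IUPAC-aware scoring) or `"protein"` (BLOSUM62)
#' @param match,mismatch,gap nucleotide scoring (ignored for protein)
#' @param gap_protein protein gap penalty
#' @return named character vector of equal-length gapped rows, input order
#' @export
align_msa <- function(seqs, type = c("dna", "protein"),
                      match = 2, mismatch = -1, gap = -2, gap_protein = -4) {
  type <- match.arg(type)
  n <- length(seqs)
  if (n == 0) stop_sk_value("no sequences to align")
  nm <- names(seqs) %||% paste0("seq", seq_len(n))
  if (n == 1) return(stats::setNames(toupper(unname(seqs)), nm))
  if (type == "dna") {
    S <- dna_score_matrix(match, mismatch)
    symbols <- DNA_SYMBOLS
    gp <- gap
    enc <- lapply(seqs, encode_seq, symbols = symbols)
  } else {
    S <- protein_score_matrix()
    symbols <- rownames(S)
    gp <- gap_protein
    enc <- lapply(seqs, function(s) {
      e <- match(seq_chars(toupper(s)), symbols)
      e[is.na(e)] <- match("X", symbols)
      e
    })
  }
  K <- length(symbols)
  # canonical orientation keys make the column structure invariant to the
  # order in which sequences are supplied
  keys <- toupper(unname(seqs))
  cluster_key <- function(members) paste(sort(keys[members]), collapse = "\r")
  if (n == 2) {
    ord <- if (keys[2] < keys[1]) c(2L, 1L) else c(1L, 2L)
    res <- nw_align_idx(enc[[ord[1]]], enc[[ord[2]]], S, gp)
    rows <- rbind(ifelse(res$a_idx == 0, 0L, enc[[ord[1]]][pmax(res$a_idx, 1)]),
                  ifelse(res$b_idx == 0, 0L, enc[[ord[2]]][pmax(res$b_idx, 1)]))
    return(decode_msa(rows[order(ord), , drop = FALSE], symbols, nm))
  }
  # guide tree from pairwise distances
  D <- matrix(0, n, n)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    res <- nw_align_idx(enc[[i]], enc[[j]], S, gp)
    ai <- res$a_idx; bi <- res$b_idx
    shared <- ai > 0L & bi > 0L
    p <- if (any(shared)) mean(enc[[i]][ai[shared]] != enc[[j]][bi[shared]]) else 1
    D[i, j] <- D[j, i] <- p
  }
  hc <- stats::hclust(stats::as.dist(D), method = "average")
  # clusters: -k = singleton k, +k = merge row k
  store <- vector("list", n - 1)
  get_cluster <- function(id) {
    if (id < 0) {
      list(rows = matrix(enc[[-id]], nrow = 1), members = -id)
    } else store[[id]]
  }
  for (s in seq_len(n - 1)) {
    a <- get_cluster(hc$merge[s, 1]); b <- get_cluster(hc$merge[s, 2])
    if (cluster_key(b$members) < cluster_key(a$members)) { tmp <- a; a <- b; b <- tmp }
    res <- nw_profile_idx(profile_freqs(a$rows, K), profile_freqs(b$rows, K), S, gp)
    rows <- rbind(apply_col_map(a$rows, res$a_idx),
                  apply_col_map(b$rows, res$b_idx))
    store[[s]] <- list(rows = rows, members = c(a$members, b$members))
  }
  final <- store[[n - 1]]
  ord <- order(final$members)
  decode_msa(final$rows[ord, , drop = FALSE], symbols, nm)
}

decode_msa <- function(rows, symbols, nm) {
  out <- apply(rows, 1, function(r) chars_seq(ifelse(r == 0L, "-", symbols[pmax(r, 1L)])))
  stats::setNames(out, nm)
}

#' Reverse complement of an IUPAC nucleotide sequence
#'
#' Complements ambiguity codes too (R-Y, K-M, B-V, D-H; S, W, N map to
#' themselves) and reverses. Gaps pass through unchanged.
#'
#' @param seq IUPAC nucleotide string (may contain `-`)
#' @return the reverse complement
#' @export
reverse_complement <- function(seq) {
  assert_iupac(seq, allow_gap = TRUE)
  if (nchar(seq) == 0) return(seq)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(toupper(seq))))
}
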