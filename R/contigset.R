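## Alignment-level computation: align contig consensi, distance matrix,
## BIONJ quality-control tree, and the end-to-end pipeline.

#' Align contig consensus sequences
#'
#' Progressive alignment of the consensi (pairwise NW distances, UPGMA
#' guide tree, profile-profile merges). In translation mode the consensi
#' are aligned as proteins in their chosen reading frame and the
#' amino-acid columns are expanded back to codon triplets; this requires
#' an amino-acid reference to fix the frame.
#'
#' @param contigs list of `sanger_contig` objects, or a named character
#'   vector of consensus sequences
#' @param mode `"nucleotide"` (default) or `"translation"`
#' @param aa_reference required for translation mode
#' @param match,mismatch,gap nucleotide scores; `gap_protein` for
#'   translation mode
#' @return named character vector: the gapped contig MSA
#' @export
align_contigs <- function(contigs, mode = c("nucleotide", "translation"),
                          aa_reference = NULL, match = 2, mismatch = -1,
                          gap = -2, gap_protein = -4) {
  mode <- match.arg(mode)
  seqs <- if (is.character(contigs)) contigs else {
    nm <- vapply(contigs, `[[`, "", "name")
    stats::setNames(vapply(contigs, `[[`, "", "consensus"), nm)
  }
  if (any(!nzchar(seqs))) stop_sk_value("contig with empty consensus")
  if (length(seqs) == 1) return(stats::setNames(toupper(unname(seqs)), names(seqs)))
  if (mode == "nucleotide") {
    return(align_msa(seqs, "dna", match = match, mismatch = mismatch, gap = gap))
  }
  if (is.null(aa_reference))
    stop_sk_capability("translation mode requires an amino-acid reference")
  aa_reference <- load_aa_reference(aa_reference)
  # in-frame sub-sequence of each consensus, found by codon-aware alignment
  inframe <- lapply(seqs, function(s) {
    ca <- codon_alignment(s, aa_reference)
    len <- ca$end_nt - ca$start_nt
    len <- (len %/% 3) * 3
    substr(ca$work_seq, ca$start_nt + 1L, ca$start_nt + len)
  })
  prots <- vapply(inframe, function(s) translate_frame(s, 0), "")
  pmsa <- align_msa(stats::setNames(prots, names(seqs)), "protein",
                    gap_protein = gap_protein)
  # expand amino-acid columns to codons
  out <- vapply(names(seqs), function(nm) {
    aa_row <- seq_chars(pmsa[[nm]])
    nt <- inframe[[nm]]
    pos <- 0L
    chars_seq(vapply(aa_row, function(a) {
      if (a == "-") return("---")
      pos <<- pos + 3L
      substr(nt, pos - 2L, pos)
    }, ""))
  }, "")
  stats::setNames(out, names(seqs))
}

#' Pairwise distances from a multiple alignment
#'
#' @param msa named character vector of equal-length gapped rows
#' @param model `"p"` (proportion of differing shared sites, default) or
#'   `"JC69"` (Jukes-Cantor correction `-(3/4) ln(1 - (4/3) p)`)
#' @return symmetric numeric matrix with zero diagonal
#' @export
distance_matrix <- function(msa, model = c("p", "JC69")) {
  model <- match.arg(model)
  if (length(msa) < 2) stop_sk_value("need at least 2 aligned sequences")
  rows <- lapply(msa, function(s) seq_chars(toupper(s)))
  if (length(unique(lengths(rows))) != 1)
    stop_sk_value("alignment rows differ in length")
  n <- length(rows)
  nm <- names(msa) %||% paste0("seq", seq_len(n))
  m <- matrix(0, n, n, dimnames = list(nm, nm))
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    a <- rows[[i]]; b <- rows[[j]]
    shared <- a != "-" & b != "-"
    if (!any(shared))
      stop_sk_value("no shared non-gap sites between '", nm[i], "' and '", nm[j], "'")
    p <- mean(a[shared] != b[shared])
    if (model == "JC69") {
      if (p >= 0.75)
        stop_sk_value("JC69 undefined for p = ", round(p, 4), " between '",
                      nm[i], "' and '", nm[j], "'")
      p <- -0.75 * log(1 - 4 * p / 3)
    }
    m[i, j] <- m[j, i] <- p
  }
  m
}

#' Build a contig set (alignment level) from assembled contigs
#'
#' Aligns the contig consensi, computes the distance matrix and estimates
#' the BIONJ quality-control tree (for >= 3 contigs; 2 contigs give a
#' single-edge tree, 1 contig no tree).
#'
#' @param contigs list of `sanger_contig` objects
#' @param mode,aa_reference see [align_contigs()]
#' @param dist_model see [distance_matrix()]
#' @param tree_mode `"bionj"` or `"nj"`
#' @param params free-form list of pipeline parameters recorded for
#'   provenance
#' @return a `sanger_contig_set` object
#' @export
build_contig_set <- function(contigs, mode = "nucleotide", aa_reference = NULL,
                             dist_model = "p", tree_mode = "bionj",
                             params = list()) {
  if (length(contigs) == 0) stop_sk_value("no contigs")
  names(contigs) <- vapply(contigs, `[[`, "", "name")
  msa <- align_contigs(contigs, mode = mode, aa_reference = aa_reference)
  dist <- if (length(contigs) >= 2) distance_matrix(msa, dist_model) else NULL
  tree <- if (length(contigs) >= 2) bionj_tree(dist, mode = tree_mode) else NULL
  structure(list(
    contigs = contigs,
    contig_msa = msa,
    distances = dist,
    tree = tree,
    params = c(params, list(align_mode = mode, dist_model = dist_model,
                            tree_mode = tree_mode))
  ), class = "sanger_contig_set")
}

#' @export
print.sanger_contig_set <- function(x, ...) {
  cat("<sanger_contig_set> ", length(x$contigs), " contig(s), ",
      sum(vapply(x$contigs, function(ct) length(ct$included), 1L)),
      " read(s); MSA width ",
      if (length(x$contig_msa)) nchar(x$contig_msa[[1]]) else 0, "\n", sep = "")
  invisible(x)
}

load_reads_from_plan <- function(plan, trim_method = "M1", trim_cutoff = 1e-4,
                                 trim_window = 10, trim_quality_cutoff = 20,
                                 secondary_ratio = 0.33) {
  missing <- !file.exists(plan$read_path)
  if (any(missing))
    stop_sk_value("read file listed in grouping but missing on disk: ",
                  plan$read_path[missing][1])
  reads <- purrr::pmap(plan, function(read_path, direction, contig) {
    sanger_read(read_path, direction = direction, trim_method = trim_method,
                trim_cutoff = trim_cutoff, trim_window = trim_window,
                trim_quality_cutoff = trim_quality_cutoff,
                secondary_ratio = secondary_ratio)
  })
  split(reads, plan$contig)
}

#' Run the full Sanger processing pipeline
#'
#' Groups read files into contigs (by filename convention or CSV), loads
#' and trims every read, assembles each contig, aligns the contig
#' consensi and estimates the quality-control tree — the whole workflow in
#' one call.
#'
#' @param dir directory of read files (used with the suffix patterns)
#' @param csv three-column grouping CSV (alternative to `dir`)
#' @param fwd_suffix,rev_suffix direction suffix patterns for `dir` input
#' @param trim_method,trim_cutoff,trim_window,trim_quality_cutoff read
#'   trimming configuration, see [trim_read()]
#' @param secondary_ratio secondary-peak threshold
#' @param min_read_length minimum trimmed read length (default 20)
#' @param majority_threshold,ambiguity_min_fraction consensus parameters
#' @param align_mode `"nucleotide"` or `"translation"`
#' @param dist_model `"p"` or `"JC69"`
#' @param tree_mode `"bionj"` or `"nj"`
#' @param aa_reference optional amino-acid reference
#' @return a `sanger_contig_set`
#' @export
sanger_alignment <- function(dir = NULL, csv = NULL,
                             fwd_suffix = default_fwd_suffix,
                             rev_suffix = default_rev_suffix,
                             trim_method = "M1", trim_cutoff = 1e-4,
                             trim_window = 10, trim_quality_cutoff = 20,
                             secondary_ratio = 0.33, min_read_length = 20,
                             majority_threshold = 0.5,
                             ambiguity_min_fraction = 0.25,
                             align_mode = "nucleotide", dist_model = "p",
                             tree_mode = "bionj", aa_reference = NULL) {
  plan <- if (!is.null(csv)) read_grouping_csv(csv)
          else if (!is.null(dir)) group_by_filename(dir, fwd_suffix, rev_suffix)
          else stop_sk_value("provide either dir or csv")
  groups <- load_reads_from_plan(plan, trim_method, trim_cutoff, trim_window,
                                 trim_quality_cutoff, secondary_ratio)
  contigs <- purrr::imap(groups, function(reads, nm) {
    build_contig(reads, name = nm, min_read_length = min_read_length,
                 majority_threshold = majority_threshold,
                 ambiguity_min_fraction = ambiguity_min_fraction,
                 aa_reference = aa_reference)
  })
  params <- list(
    source = attr(plan, "source"), input = dir %||% csv,
    fwd_suffix = fwd_suffix, rev_suffix = rev_suffix,
    trim_method = trim_method, trim_cutoff = trim_cutoff,
    trim_window = trim_window, trim_quality_cutoff = trim_quality_cutoff,
    secondary_ratio = secondary_ratio, min_read_length = min_read_length,
    majority_threshold = majority_threshold,
    ambiguity_min_fraction = ambiguity_min_fraction,
    aa_reference = if (!is.null(aa_reference)) load_aa_reference(aa_reference)
  )
  build_contig_set(contigs, mode = align_mode, aa_reference = aa_reference,
                   dist_model = dist_model, tree_mode = tree_mode,
                   params = params)
}

#' Build one contig from grouped read files
#'
#' @param dir,csv,fwd_suffix,rev_suffix input grouping, as
#'   [sanger_alignment()]
#' @param contig_name the group to assemble
#' @param ... further parameters passed through to [sanger_alignment()]'s
#'   read-loading and assembly steps
#' @inheritParams sanger_alignment
#' @return a `sanger_contig`
#' @export
sanger_contig <- function(dir = NULL, csv = NULL, contig_name,
                          fwd_suffix = default_fwd_suffix,
                          rev_suffix = default_rev_suffix,
                          trim_method = "M1", trim_cutoff = 1e-4,
                          trim_window = 10, trim_quality_cutoff = 20,
                          secondary_ratio = 0.33, min_read_length = 20,
                          majority_threshold = 0.5,
                          ambiguity_min_fraction = 0.25, aa_reference = NULL) {
  plan <- if (!is.null(csv)) read_grouping_csv(csv)
          else if (!is.null(dir)) group_by_filename(dir, fwd_suffix, rev_suffix)
          else stop_sk_value("provide either dir or csv")
  plan_sub <- plan[plan$contig == contig_name, ]
  if (nrow(plan_sub) == 0)
    stop_sk_value("no reads grouped under contig '", contig_name, "'")
  groups <- load_reads_from_plan(plan_sub, trim_method, trim_cutoff,
                                 trim_window, trim_quality_cutoff,
                                 secondary_ratio)
  build_contig(groups[[contig_name]], name = contig_name,
               min_read_length = min_read_length,
               majority_threshold = majority_threshold,
               ambiguity_min_fraction = ambiguity_min_fraction,
               aa_reference = aa_reference)
}
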