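## broom-style tidiers and ggplot2 autoplot methods.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a read into a per-base tibble
#' @param x a `sanger_read`
#' @param ... unused
#' @return tibble with one row per base: `position`, `base`, `quality`,
#'   `in_trim`
#' @export
tidy.sanger_read <- function(x, ...) {
  n <- nchar(x$primary_seq)
  tibble::tibble(
    position = seq_len(n),
    base = seq_chars(x$primary_seq),
    quality = if (!is.null(x$qualities)) x$qualities else NA_integer_,
    in_trim = seq_len(n) > x$trim[1] & seq_len(n) <= x$trim[2]
  )
}

#' One-row summary of a read
#' @param x a `sanger_read`
#' @param ... unused
#' @export
glance.sanger_read <- function(x, ...) {
  fully <- x$trim[2] <= x$trim[1]
  tibble::tibble(
    id = x$id, direction = x$direction, origin = x$origin,
    n_bases = nchar(x$primary_seq),
    trim_start = x$trim[1], trim_end = x$trim[2],
    trimmed_length = max(x$trim[2] - x$trim[1], 0L),
    mean_quality = if (!is.null(x$qualities)) mean(x$qualities) else NA_real_,
    mean_quality_trimmed = if (!is.null(x$qualities) && !fully)
      mean(x$qualities[(x$trim[1] + 1):x$trim[2]]) else NA_real_,
    n_secondary_peaks = if (!is.null(x$secondary_peaks))
      nrow(x$secondary_peaks) else NA_integer_
  )
}

#' Per-read summary of a contig
#' @param x a `sanger_contig`
#' @param ... unused
#' @export
tidy.sanger_contig <- function(x, ...) {
  dplyr::bind_rows(lapply(x$reads, glance)) |>
    dplyr::mutate(contig = x$name, included = .data$id %in% x$included,
                  .before = 1)
}

#' One-row summary of a contig
#' @param x a `sanger_contig`
#' @param ... unused
#' @export
glance.sanger_contig <- function(x, ...) {
  tibble::tibble(
    contig = x$name,
    n_reads = length(x$included),
    n_excluded = length(x$excluded),
    consensus_length = nchar(x$consensus),
    max_hamming = if (nrow(x$hamming) >= 2) max(x$hamming) else NA_integer_,
    n_indels = if (!is.null(x$indels)) nrow(x$indels) else NA_integer_,
    n_stop_codons = if (!is.null(x$stops)) nrow(x$stops) else NA_integer_
  )
}

#' Per-contig summary of a contig set
#' @param x a `sanger_contig_set`
#' @param ... unused
#' @export
tidy.sanger_contig_set <- function(x, ...) {
  dplyr::bind_rows(lapply(x$contigs, glance))
}

#' One-row summary of a contig set
#' @param x a `sanger_contig_set`
#' @param ... unused
#' @export
glance.sanger_contig_set <- function(x, ...) {
  tibble::tibble(
    n_contigs = length(x$contigs),
    n_reads = sum(vapply(x$contigs, function(ct) length(ct$included), 1L)),
    msa_width = if (length(x$contig_msa)) nchar(x$contig_msa[[1]]) else 0L,
    mean_distance = if (!is.null(x$distances))
      mean(x$distances[upper.tri(x$distances)]) else NA_real_
  )
}

#' Hamming-distance heatmap for a contig
#' @param object a `sanger_contig`
#' @param ... unused
#' @export
autoplot.sanger_contig <- function(object, ...) {
  m <- object$hamming
  df <- tibble::tibble(
    read1 = rep(rownames(m), times = ncol(m)),
    read2 = rep(colnames(m), each = nrow(m)),
    hamming = as.vector(m))
  ggplot2::ggplot(df, ggplot2::aes(.data$read1, .data$read2,
                                   fill = .data$hamming)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$hamming), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "#d6604d") +
    ggplot2::labs(x = NULL, y = NULL, title = object$name) +
    ggplot2::theme_minimal()
}

#' Contig distance heatmap for a contig set
#' @param object a `sanger_contig_set`
#' @param ... unused
#' @export
autoplot.sanger_contig_set <- function(object, ...) {
  m <- object$distances
  if (is.null(m)) stop_sk_capability("single contig: no distance matrix")
  df <- tibble::tibble(
    contig1 = rep(rownames(m), times = ncol(m)),
    contig2 = rep(colnames(m), each = nrow(m)),
    distance = as.vector(m))
  ggplot2::ggplot(df, ggplot2::aes(.data$contig1, .data$contig2,
                                   fill = .data$distance)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "#2166ac") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
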