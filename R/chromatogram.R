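## Chromatogram rendering (SVG) and quality/trim plotting.

#' Channel palettes
#'
#' `default` uses the conventional chromatogram colors; `colorblind_safe`
#' draws from the Okabe-Ito palette so all four channels remain pairwise
#' distinguishable under common color-vision deficiencies.
#' @param palette `"default"` or `"colorblind_safe"`
#' @return named vector of colors for A, C, G, T
#' @export
channel_palette <- function(palette = c("default", "colorblind_safe")) {
  palette <- match.arg(palette)
  if (palette == "default")
    c(A = "#33a02c", C = "#1f78b4", G = "#000000", T = "#e31a1c")
  else
    c(A = "#009E73", C = "#0072B2", G = "#000000", T = "#D55E00")
}

svg_el <- function(tag, ..., children = NULL) {
  attrs <- list(...)
  a <- paste(vapply(names(attrs), function(k)
    sprintf('%s="%s"', k, attrs[[k]]), ""), collapse = " ")
  if (is.null(children)) sprintf("<%s %s/>", tag, a)
  else sprintf("<%s %s>%s</%s>", tag, a, paste(children, collapse = ""), tag)
}

#' Render a read's chromatogram to SVG
#'
#' Draws the four channel polylines in the palette colors, annotates each
#' peak with its called base (in the matching color) and Phred quality,
#' and overlays the 5' and 3' trimmed regions with red hatching. Output is
#' deterministic for a fixed read.
#'
#' @param read a `sanger_read` with a trace (ABIF origin)
#' @param palette `"default"` or `"colorblind_safe"`
#' @param out_path output `.svg` path
#' @param samples_per_px horizontal scale (trace samples per pixel)
#' @param height image height in pixels
#' @return `out_path`, invisibly
#' @export
render_chromatogram <- function(read, palette = c("default", "colorblind_safe"),
                                out_path, samples_per_px = 2, height = 220) {
  palette <- match.arg(palette)
  if (is.null(read$trace))
    stop_sk_capability("read '", read$id,
                       "' has no chromatogram (FASTA input)")
  cols <- channel_palette(palette)
  tr <- read$trace
  L <- length(tr$channels$A)
  width <- max(ceiling(L / samples_per_px), 1) + 20
  ymax <- max(1, unlist(tr$channels))
  plot_h <- height - 50
  sx <- function(i) 10 + i / samples_per_px            # sample index (0-based)
  sy <- function(v) 10 + plot_h * (1 - v / ymax)
  body <- character(0)
  # hatched trim overlays (5' and 3')
  hatch <- paste0(
    '<defs><pattern id="hatch" width="6" height="6" patternUnits="userSpaceOnUse" ',
    'patternTransform="rotate(45)"><line x1="0" y1="0" x2="0" y2="6" ',
    'stroke="#e31a1c" stroke-width="2"/></pattern></defs>')
  trim_rect <- function(from_base, to_base) {
    # bases are 0-based half-open over basecall indices
    if (to_base <= from_base) return(NULL)
    locs <- tr$peak_locations
    x1 <- if (from_base == 0) 0 else (locs[from_base] + locs[from_base + 1]) / 2
    x2 <- if (to_base >= length(locs)) L else (locs[to_base] + locs[to_base + 1]) / 2
    svg_el("rect", x = round(sx(x1), 1), y = 10,
           width = round(sx(x2) - sx(x1), 1), height = plot_h,
           fill = "url(#hatch)", class = "trimmed", opacity = "0.6")
  }
  n <- length(tr$peak_locations)
  rects <- c(trim_rect(0L, read$trim[1]), trim_rect(read$trim[2], n))
  for (b in c("A", "C", "G", "T")) {
    v <- tr$channels[[b]]
    pts <- paste(sprintf("%.1f,%.1f", sx(seq_along(v) - 1), sy(v)), collapse = " ")
    body <- c(body, svg_el("polyline", points = pts, fill = "none",
                           stroke = cols[[b]], "stroke-width" = "1"))
  }
  labels <- character(0)
  ch <- seq_chars(read$primary_seq)
  for (i in seq_len(n)) {
    x <- round(sx(tr$peak_locations[i]), 1)
    labels <- c(labels,
      svg_el("text", x = x, y = height - 28, "text-anchor" = "middle",
             "font-family" = "monospace", "font-size" = "11",
             fill = cols[[ch[i]]] %||% "#777777", children = ch[i]),
      if (!is.null(read$qualities))
        svg_el("text", x = x, y = height - 14, "text-anchor" = "middle",
               "font-family" = "monospace", "font-size" = "8",
               fill = "#555555", children = read$qualities[i]))
  }
  doc <- paste0(
    sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d">',
            width, height),
    hatch, paste(body, collapse = ""), paste(rects, collapse = ""),
    paste(labels, collapse = ""), "</svg>")
  writeLines(doc, out_path)
  invisible(out_path)
}

#' Per-base quality data for the trim plot
#'
#' @param read a `sanger_read` with qualities
#' @return tibble with `position` (1-based) and `phred`
#' @export
trim_plot_data <- function(read) {
  if (is.null(read$qualities))
    stop_sk_capability("read '", read$id, "' has no qualities (FASTA input)")
  tibble::tibble(position = seq_along(read$qualities), phred = read$qualities)
}

#' Quality/trim plot for a read
#'
#' Per-base Phred scores with the kept (trimmed-to) window shaded; the
#' 5' and 3' cut positions are drawn as red lines, mirroring the usual
#' trimming diagnostics view.
#'
#' @param object a `sanger_read`
#' @param ... unused
#' @return a ggplot object
#' @export
autoplot.sanger_read <- function(object, ...) {
  df <- trim_plot_data(object)
  g <- ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$phred)) +
    ggplot2::geom_line(color = "grey40") +
    ggplot2::labs(x = "position (base)", y = "Phred quality",
                  title = paste0(object$id, "  [",
                                 object$trim[1] + 1, "-", object$trim[2],
                                 " kept]")) +
    ggplot2::theme_minimal()
  if (object$trim[2] > object$trim[1]) {
    g <- g +
      ggplot2::annotate("rect", xmin = object$trim[1] + 1, xmax = object$trim[2],
                        ymin = -Inf, ymax = Inf, alpha = 0.15, fill = "orange") +
      ggplot2::geom_vline(xintercept = c(object$trim[1] + 1, object$trim[2]),
                          color = "red", linetype = "dashed")
  }
  g
}
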