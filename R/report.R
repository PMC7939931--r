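## Hierarchical static HTML report: alignment -> contig -> read pages.

#' Report configuration
#'
#' @param out_dir output directory
#' @param levels which levels to render (subset of `"read"`, `"contig"`,
#'   `"alignment"`; the hierarchy always includes parents of requested
#'   levels)
#' @param palette `"default"` or `"colorblind_safe"` base colors
#' @param include_chromatograms render chromatogram SVGs for trace reads?
#' @return a `report_config` list
#' @export
report_config <- function(out_dir, levels = c("read", "contig", "alignment"),
                          palette = "default", include_chromatograms = TRUE) {
  levels <- match.arg(levels, c("read", "contig", "alignment"), several.ok = TRUE)
  if (length(levels) == 0) stop_sk_value("levels must be non-empty")
  structure(list(out_dir = out_dir, levels = levels, palette = palette,
                 include_chromatograms = include_chromatograms),
            class = "report_config")
}

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

report_css <- function() paste(
  "body{font-family:sans-serif;margin:2em;max-width:1100px}",
  "table{border-collapse:collapse;margin:1em 0}",
  "td,th{border:1px solid #ccc;padding:4px 8px;font-size:14px}",
  "pre.seq{font-family:monospace;font-size:13px;overflow-x:auto;line-height:1.5}",
  ".fullytrimmed{color:#b00;font-weight:bold}",
  "h1,h2{color:#222}", "a{color:#0b62a4}",
  sep = "\n")

seq_html <- function(seq, cols) {
  ch <- seq_chars(seq)
  col <- cols[ch]
  col[is.na(col)] <- "#888888"
  paste0("<span style=\"color:", col, "\">", html_escape(ch), "</span>",
         collapse = "")
}

msa_html <- function(msa, cols, block = 100) {
  width <- max(nchar(msa))
  nm <- names(msa)
  pad <- max(nchar(nm)) + 2
  out <- character(0)
  for (from in seq(1, width, by = block)) {
    to <- min(from + block - 1, width)
    rows <- vapply(seq_along(msa), function(i) {
      paste0(formatC(nm[i], width = pad, flag = "-"),
             seq_html(substr(msa[[i]], from, to), cols))
    }, "")
    out <- c(out, paste(rows, collapse = "\n"),
             paste0(strrep(" ", pad), from, "-", to), "")
  }
  paste0("<pre class=\"seq\">", paste(out, collapse = "\n"), "</pre>")
}

heat_table_html <- function(m, digits = 3) {
  mx <- max(m, 1e-12)
  hdr <- paste0("<tr><th></th>",
                paste0("<th>", html_escape(colnames(m)), "</th>", collapse = ""),
                "</tr>")
  rows <- vapply(seq_len(nrow(m)), function(i) {
    cells <- vapply(seq_len(ncol(m)), function(j) {
      v <- m[i, j]
      alpha <- round(0.75 * v / mx, 3)
      sprintf('<td style="background:rgba(214,96,77,%s)">%s</td>', alpha,
              format(round(v, digits)))
    }, "")
    paste0("<tr><th>", html_escape(rownames(m)[i]), "</th>",
           paste(cells, collapse = ""), "</tr>")
  }, "")
  paste0("<table>", hdr, paste(rows, collapse = ""), "</table>")
}

tibble_html <- function(df, empty_msg = "none") {
  if (is.null(df) || nrow(df) == 0) return(paste0("<p><i>", empty_msg, "</i></p>"))
  hdr <- paste0("<tr>", paste0("<th>", html_escape(names(df)), "</th>",
                               collapse = ""), "</tr>")
  rows <- vapply(seq_len(nrow(df)), function(i) {
    paste0("<tr>", paste0("<td>", html_escape(as.character(unlist(df[i, ]))),
                          "</td>", collapse = ""), "</tr>")
  }, "")
  paste0("<table>", hdr, paste(rows, collapse = ""), "</table>")
}

page_html <- function(title, body) {
  paste0("<!DOCTYPE html><html><head><meta charset=\"utf-8\"/><title>",
         html_escape(title), "</title><style>", report_css(),
         "</style></head><body><h1>", html_escape(title), "</h1>",
         body, "</body></html>")
}

# rectangular cladogram SVG for the contig tree
tree_svg <- function(tree, width = 640) {
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  depth <- numeric(ntip + nnode)
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  el <- tree$edge.length %||% rep(1, nrow(tree$edge))
  y <- numeric(ntip + nnode)
  tip_i <- 0
  assign_y <- function(node) {
    if (node <= ntip) {
      tip_i <<- tip_i + 1
      y[node] <<- tip_i
      return(y[node])
    }
    ys <- vapply(kids[[as.character(node)]], function(r) {
      child <- tree$edge[r, 2]
      depth[child] <<- depth[node] + el[r]
      assign_y(child)
    }, 0)
    y[node] <<- mean(ys)
    y[node]
  }
  assign_y(ntip + 1L)
  h <- 24 * ntip + 40
  xmax <- max(depth, 1e-9)
  xs <- function(d) 20 + (width - 180) * d / xmax
  ys <- function(v) 20 + 24 * (v - 1)
  segs <- character(0)
  for (r in seq_len(nrow(tree$edge))) {
    p <- tree$edge[r, 1]; c <- tree$edge[r, 2]
    segs <- c(segs,
      sprintf('<line x1="%.1f" y1="%.1f" x2="%.1f" y2="%.1f" stroke="#333"/>',
              xs(depth[p]), ys(y[p]), xs(depth[p]), ys(y[c])),
      sprintf('<line x1="%.1f" y1="%.1f" x2="%.1f" y2="%.1f" stroke="#333"/>',
              xs(depth[p]), ys(y[c]), xs(depth[c]), ys(y[c])))
  }
  labs <- vapply(seq_len(ntip), function(t)
    sprintf('<text x="%.1f" y="%.1f" font-size="12" font-family="monospace">%s</text>',
            xs(depth[t]) + 5, ys(y[t]) + 4, html_escape(tree$tip.label[t])), "")
  paste0(sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d">',
                 width, h),
         paste(segs, collapse = ""), paste(labs, collapse = ""), "</svg>")
}

read_page <- function(read, contig, cols, cfg, read_dir) {
  fully_trimmed <- read$trim[2] <= read$trim[1]
  trim_txt <- if (fully_trimmed)
    "<p class=\"fullytrimmed\">Read is fully trimmed: no bases pass the quality cutoff.</p>"
  else
    sprintf("<p>Trim window (1-based, inclusive): %d&ndash;%d of %d bases.</p>",
            read$trim[1] + 1L, read$trim[2], nchar(read$primary_seq))
  qual_txt <- if (!is.null(read$qualities))
    sprintf("<p>Mean Phred quality: %.1f (kept region: %s).</p>",
            mean(read$qualities),
            if (fully_trimmed) "&mdash;" else
              sprintf("%.1f", mean(read$qualities[(read$trim[1] + 1):read$trim[2]])))
  else ""
  seqs <- paste0(
    "<h2>Sequences</h2><pre class=\"seq\">primary   ",
    seq_html(read$primary_seq, cols),
    if (!is.null(read$secondary_seq))
      paste0("\nsecondary ", seq_html(read$secondary_seq, cols)),
    "</pre>")
  peaks <- paste0("<h2>Secondary peaks</h2>",
                  tibble_html(read$secondary_peaks, "no secondary peaks"))
  chrom <- ""
  if (read$origin == "abif" && !is.null(read$trace) && cfg$include_chromatograms) {
    svg_path <- file.path(read_dir, paste0(read$id, "_chromatogram.svg"))
    render_chromatogram(read, palette = cfg$palette, out_path = svg_path)
    chrom <- paste0("<h2>Chromatogram</h2>",
                    paste(readLines(svg_path, warn = FALSE), collapse = "\n"))
  } else if (read$origin == "fasta") {
    chrom <- paste0("<h2>Chromatogram</h2><p><i>Not available: this read was ",
                    "loaded from FASTA, which carries no trace data.</i></p>")
  }
  if (!is.null(read$qualities)) {
    utils::write.table(trim_plot_data(read),
                       file.path(read_dir, paste0(read$id, "_qualities.tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  body <- paste0(
    sprintf("<p><a href=\"../index.html\">&larr; contig %s</a></p>",
            html_escape(contig$name)),
    sprintf("<p>Direction: %s; origin: %s.</p>", read$direction, read$origin),
    trim_txt, qual_txt, seqs, peaks, chrom)
  page_html(paste0("Read ", read$id), body)
}

contig_page <- function(ct, cols, cfg) {
  aln <- c(ct$read_msa, consensus = ct$consensus_padded %||% ct$consensus)
  body <- paste0(
    "<p><a href=\"../../index.html\">&larr; alignment overview</a></p>",
    sprintf("<p>%d read(s) assembled%s; consensus %d bp.</p>",
            length(ct$included),
            if (length(ct$excluded))
              sprintf(" (%d excluded as too short after trimming: %s)",
                      length(ct$excluded),
                      html_escape(paste(ct$excluded, collapse = ", "))) else "",
            nchar(ct$consensus)),
    "<h2>Read alignment and consensus</h2>", msa_html(aln, cols),
    "<h2>Hamming distances between reads</h2>",
    if (nrow(ct$hamming) >= 2) heat_table_html(ct$hamming, digits = 0)
    else "<p><i>single read: no distances</i></p>",
    "<h2>Indels</h2>",
    if (is.null(ct$aa_reference))
      "<p><i>no amino-acid reference supplied: table not computed</i></p>"
    else tibble_html(ct$indels, "no indels"),
    "<h2>Stop codons</h2>",
    if (is.null(ct$aa_reference))
      "<p><i>no amino-acid reference supplied: table not computed</i></p>"
    else tibble_html(ct$stops, "no stop codons"),
    "<h2>Reads</h2><ul>",
    paste0(sprintf("<li><a href=\"reads/%s.html\">%s</a> (%s)</li>",
                   vapply(ct$reads, `[[`, "", "id"),
                   html_escape(vapply(ct$reads, `[[`, "", "id")),
                   vapply(ct$reads, `[[`, "", "direction")), collapse = ""),
    "</ul>")
  page_html(paste0("Contig ", ct$name), body)
}

#' Generate the hierarchical HTML report
#'
#' Writes an alignment-level index page (contig alignment, embedded
#' quality-control tree, summary table), one page per contig (read
#' alignment with consensus, Hamming heatmap, indel and stop-codon
#' tables), and one page per read (sequences, qualities, trim window,
#' secondary peaks, chromatogram). Output is deterministic: regenerating
#' from the same state produces identical files.
#'
#' @param contig_set a `sanger_contig_set`
#' @param config a [report_config()]
#' @return path of the index page, invisibly
#' @export
generate_report <- function(contig_set, config) {
  stopifnot(inherits(contig_set, "sanger_contig_set"),
            inherits(config, "report_config"))
  cols <- channel_palette(if (config$palette == "colorblind_safe")
    "colorblind_safe" else "default")
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  summary_df <- tidy(contig_set)
  for (ct in contig_set$contigs) {
    cdir <- file.path(out, "contigs", ct$name)
    rdir <- file.path(cdir, "reads")
    dir.create(rdir, recursive = TRUE, showWarnings = FALSE)
    writeLines(contig_page(ct, cols, config), file.path(cdir, "index.html"))
    for (r in ct$reads) {
      writeLines(read_page(r, ct, cols, config, rdir),
                 file.path(rdir, paste0(r$id, ".html")))
    }
  }
  tree_block <- if (!is.null(contig_set$tree))
    paste0("<h2>Quality-control tree</h2>",
           "<p>The BIONJ tree of the aligned contigs is included for quality",
           " control only &mdash; it is not a best-practice phylogeny.</p>",
           tree_svg(contig_set$tree))
  else ""
  contig_links <- paste0(
    sprintf("<li><a href=\"contigs/%s/index.html\">%s</a></li>",
            names(contig_set$contigs),
            html_escape(names(contig_set$contigs))), collapse = "")
  body <- paste0(
    "<h2>Summary</h2>", tibble_html(summary_df),
    "<h2>Aligned contigs</h2>",
    if (length(contig_set$contig_msa) > 0)
      msa_html(contig_set$contig_msa, cols) else "",
    tree_block,
    "<h2>Contigs</h2><ul>", contig_links, "</ul>")
  idx <- file.path(out, "index.html")
  writeLines(page_html("Sanger contig alignment report", body), idx)
  invisible(idx)
}
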