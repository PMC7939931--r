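## Newick serialization. Writing is done by the package (ape's writer
## munges labels containing spaces, which would break round-tripping of
## quoted labels); parsing is delegated to ape with a light structural
## pre-check that can point at the offending character.

quote_newick_label <- function(x) {
  if (grepl("^[A-Za-z0-9_.|/+-]+$", x)) return(x)
  paste0("'", gsub("'", "''", x), "'")
}

unquote_newick_label <- function(x) {
  quoted <- grepl("^'.*'$", x)
  x[quoted] <- gsub("''", "'", sub("^'(.*)'$", "\\1", x[quoted]))
  x
}

#' Serialize a tree to a Newick string
#'
#' Branch lengths are written with 6 significant digits; labels containing
#' Newick metacharacters are single-quoted (with internal quotes doubled).
#'
#' @param tree an `ape` `phylo` object
#' @param digits significant digits for branch lengths
#' @return Newick string, semicolon-terminated
#' @export
newick_string <- function(tree, digits = 6) {
  stopifnot(inherits(tree, "phylo"))
  ntip <- length(tree$tip.label)
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  fmt <- function(x) sprintf(paste0("%.", digits, "g"), x)
  rec <- function(node) {
    if (node <= ntip) return(quote_newick_label(tree$tip.label[node]))
    rows <- kids[[as.character(node)]]
    parts <- vapply(rows, function(r) {
      child <- rec(tree$edge[r, 2])
      if (!is.null(tree$edge.length))
        paste0(child, ":", fmt(tree$edge.length[r])) else child
    }, "")
    paste0("(", paste(parts, collapse = ","), ")")
  }
  paste0(rec(ntip + 1L), ";")
}

#' Write a tree to a Newick file
#' @param tree an `ape` `phylo` object
#' @param path output path
#' @param digits significant digits for branch lengths (default 6)
#' @return `path`, invisibly
#' @export
write_newick <- function(tree, path, digits = 6) {
  writeLines(newick_string(tree, digits), path)
  invisible(path)
}

check_newick_syntax <- function(txt) {
  chars <- seq_chars(txt)
  depth <- 0L
  in_quote <- FALSE
  for (k in seq_along(chars)) {
    ch <- chars[k]
    if (ch == "'") in_quote <- !in_quote
    if (in_quote) next
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0)
        stop_sk_format("malformed Newick: unbalanced ')' at character ", k)
    }
  }
  if (in_quote) stop_sk_format("malformed Newick: unterminated quote at character ",
                               nchar(txt))
  if (depth != 0)
    stop_sk_format("malformed Newick: ", depth,
                   " unclosed '(' at character ", nchar(txt))
  if (!grepl(";", txt, fixed = TRUE))
    stop_sk_format("malformed Newick: missing ';' at character ", nchar(txt))
  invisible(TRUE)
}

parse_newick_text <- function(txt) {
  check_newick_syntax(txt)
  phy <- tryCatch(ape::read.tree(text = txt),
                  error = function(e) stop_sk_format("malformed Newick: ",
                                                     conditionMessage(e)))
  if (is.null(phy)) stop_sk_format("malformed Newick: ape could not parse input")
  phy$tip.label <- unquote_newick_label(phy$tip.label)
  phy
}

#' Parse a Newick file
#'
#' @param path path to a Newick file (or a single Newick string)
#' @return an `ape` `phylo` object; quoted labels are unquoted
#' @export
parse_newick <- function(path) {
  txt <- if (file.exists(path)) paste(readLines(path, warn = FALSE), collapse = "")
         else path
  parse_newick_text(txt)
}
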