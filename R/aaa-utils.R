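## IUPAC nucleotide codes and small shared helpers.

# code -> set of unambiguous bases
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  M = c("A", "C"), R = c("A", "G"), W = c("A", "T"),
  S = c("C", "G"), Y = c("C", "T"), K = c("G", "T"),
  V = c("A", "C", "G"), H = c("A", "C", "T"),
  D = c("A", "G", "T"), B = c("C", "G", "T"),
  N = c("A", "C", "G", "T")
)

IUPAC_CODES <- names(IUPAC_SETS)

# sorted base set (collapsed, e.g. "ACG") -> code
IUPAC_FROM_SET <- local({
  keys <- vapply(IUPAC_SETS, function(s) paste(sort(s), collapse = ""), character(1))
  stats::setNames(names(IUPAC_SETS), keys)
})

#' IUPAC code for a set of bases
#' @param bases character vector of unambiguous bases (subset of A, C, G, T)
#' @return single IUPAC letter
#' @keywords internal
iupac_code <- function(bases) {
  key <- paste(sort(unique(bases)), collapse = "")
  code <- IUPAC_FROM_SET[[key]]
  if (is.null(code)) stop_sk_value("no IUPAC code for base set {", key, "}")
  code
}

# expand one IUPAC character to its base set ("-" -> character(0))
iupac_expand <- function(code) {
  if (code == "-") return(character(0))
  s <- IUPAC_SETS[[code]]
  if (is.null(s)) stop_sk_value("not an IUPAC nucleotide code: '", code, "'")
  s
}

# do two IUPAC codes share at least one base?
iupac_intersects <- function(a, b) {
  length(intersect(iupac_expand(a), iupac_expand(b))) > 0L
}

phred_to_error <- function(q) 10^(-q / 10)

seq_chars <- function(x) if (nchar(x) == 0L) character(0) else strsplit(x, "", fixed = TRUE)[[1]]

chars_seq <- function(x) paste(x, collapse = "")

assert_iupac <- function(seq, allow_gap = FALSE, what = "sequence") {
  ch <- seq_chars(toupper(seq))
  ok <- ch %in% IUPAC_CODES | (allow_gap & ch == "-")
  if (!all(ok)) {
    pos <- which(!ok)[1L]
    stop_sk_value(what, " contains non-IUPAC character '", ch[pos],
                  "' at position ", pos)
  }
  invisible(TRUE)
}

## condition classes: sk_value_error / sk_format_error / sk_capability_error
## map to CLI exit codes 2 (value/format) and 3 (capability)
stop_sk <- function(class, ...) {
  stop(structure(class = c(class, "sk_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}
stop_sk_value      <- function(...) stop_sk("sk_value_error", ...)
stop_sk_format     <- function(...) stop_sk("sk_format_error", ...)
stop_sk_capability <- function(...) stop_sk("sk_capability_error", ...)

# seeded RNG scope that restores the caller's RNG state
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
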