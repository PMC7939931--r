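## BIONJ / neighbor-joining tree estimation from a distance matrix.
##
## Classic NJ agglomeration with the standard criterion
## (r - 2) d(i,j) - S_i - S_j; BIONJ additionally tracks variances and
## merges rows with the variance-weighted lambda, which degenerates to
## classical NJ at lambda = 1/2. The tree is meant as a quality-control
## view of the contigs, not as a best-practice phylogeny.

fmt_bl <- function(x) sprintf("%.10g", x)

#' Build a BIONJ (or NJ) tree from a distance matrix
#'
#' @param d symmetric numeric distance matrix with zero diagonal; row
#'   names are used as taxon labels
#' @param mode `"bionj"` (variance-weighted merging, default) or `"nj"`
#'   (classical neighbor joining, lambda fixed at 1/2)
#' @return an `ape` `phylo` tree (unrooted; basal trichotomy). Negative
#'   branch-length estimates are clamped to zero; the number clamped is
#'   recorded in the `clamped_branches` attribute.
#' @export
bionj_tree <- function(d, mode = c("bionj", "nj")) {
  mode <- match.arg(mode)
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 2) stop_sk_value("need at least 2 taxa")
  if (!isSymmetric(unname(d), tol = 1e-8))
    stop_sk_value("distance matrix must be symmetric")
  if (any(d < 0)) stop_sk_value("distances must be non-negative")
  if (any(abs(diag(d)) > 1e-12)) stop_sk_value("diagonal must be zero")
  labels <- rownames(d) %||% paste0("t", seq_len(n))
  clamped <- 0L
  clamp <- function(x) {
    if (x < 0) { clamped <<- clamped + 1L; 0 } else x
  }
  node <- vapply(labels, quote_newick_label, "")
  if (n == 2) {
    txt <- sprintf("(%s:%s,%s:%s);", node[1], fmt_bl(clamp(d[1, 2] / 2)),
                   node[2], fmt_bl(clamp(d[1, 2] / 2)))
    phy <- parse_newick_text(txt)
    attr(phy, "clamped_branches") <- clamped
    return(phy)
  }
  D <- d; V <- d
  while (nrow(D) > 3) {
    r <- nrow(D)
    S <- rowSums(D)
    # lowest (i, j) pair on ties
    best <- NULL
    for (i in 1:(r - 1)) for (j in (i + 1):r) {
      q <- (r - 2) * D[i, j] - S[i] - S[j]
      if (is.null(best) || q < best$q) best <- list(q = q, i = i, j = j)
    }
    i <- best$i; j <- best$j
    bi <- D[i, j] / 2 + (S[i] - S[j]) / (2 * (r - 2))
    bj <- D[i, j] - bi
    lambda <- if (mode == "nj" || V[i, j] <= 0) 0.5 else {
      k <- setdiff(seq_len(r), c(i, j))
      0.5 + sum(V[j, k] - V[i, k]) / (2 * (r - 2) * V[i, j])
    }
    lambda <- min(max(lambda, 0), 1)
    k <- setdiff(seq_len(r), c(i, j))
    du <- lambda * (D[i, k] - bi) + (1 - lambda) * (D[j, k] - bj)
    vu <- lambda * V[i, k] + (1 - lambda) * V[j, k] - lambda * (1 - lambda) * V[i, j]
    new_node <- sprintf("(%s:%s,%s:%s)", node[i], fmt_bl(clamp(bi)),
                        node[j], fmt_bl(clamp(bj)))
    D <- rbind(cbind(D[k, k, drop = FALSE], du), c(du, 0))
    V <- rbind(cbind(V[k, k, drop = FALSE], vu), c(vu, 0))
    node <- c(node[k], new_node)
  }
  b1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  b2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  b3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  txt <- sprintf("(%s:%s,%s:%s,%s:%s);",
                 node[1], fmt_bl(clamp(b1)), node[2], fmt_bl(clamp(b2)),
                 node[3], fmt_bl(clamp(b3)))
  phy <- parse_newick_text(txt)
  attr(phy, "clamped_branches") <- clamped
  phy
}
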