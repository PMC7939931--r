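test_that("contig alignment handles identical, indel and permuted inputs", {
  cons <- "ATGCATTTCAGGAGCTCGACCTAGATCAAGGTGCTAGCATCGATTACGGAACCTGGATTC"
  msa <- align_contigs(c(a = cons, b = cons, c = cons))
  expect_true(all(!grepl("-", msa)))
  # one 3-base deletion in locally unique context -> a single length-3 gap run
  del <- paste0(substr(cons, 1, 30), substr(cons, 34, 60))
  msa2 <- align_contigs(c(full = cons, short = del))
  expect_equal(nchar(msa2[["full"]]), 60)
  gaps <- gregexpr("-+", msa2[["short"]])[[1]]
  expect_equal(length(gaps), 1)
  expect_equal(attr(gaps, "match.length"), 3L)
  # permutation invariance
  seqs <- c(a = cons, b = del,
            c = paste0(substr(cons, 1, 40), "TT", substr(cons, 43, 60)))
  m1 <- align_contigs(seqs)
  m2 <- align_contigs(seqs[c(2, 3, 1)])
  expect_identical(m2[names(m1)], m1)
  # single contig: no-op
  expect_equal(unname(align_contigs(c(only = cons))), cons)
})

test_that("translation mode requires a reference and aligns codon-wise", {
  orf <- simulate_template(aa_reference = AA_REF)
  expect_error(align_contigs(c(a = orf, b = orf), mode = "translation"),
               class = "sk_capability_error")
  del <- paste0(substr(orf, 1, 30), substr(orf, 34, nchar(orf)))  # codon 11 gone
  msa <- align_contigs(c(a = orf, b = del), mode = "translation",
                       aa_reference = AA_REF)
  expect_equal(nchar(msa[["a"]]), nchar(msa[["b"]]))
  expect_equal(nchar(msa[["a"]]) %% 3, 0)
  gaps <- gregexpr("-+", msa[["b"]])[[1]]
  expect_equal(attr(gaps, "match.length"), 3L)
})

test_that("distance matrix implements p and JC69 with their error cases", {
  msa <- c(a = strrep("A", 100), b = strrep("A", 100))
  expect_equal(distance_matrix(msa)["a", "b"], 0)
  expect_equal(distance_matrix(msa, "JC69")["a", "b"], 0)
  msa2 <- c(a = paste0("C", strrep("A", 99)), b = strrep("A", 100))
  expect_equal(distance_matrix(msa2)["a", "b"], 0.01)
  # closed-form JC69 at p = 0.0075 (3 mismatches in 400)
  msa3 <- c(a = paste0(strrep("C", 3), strrep("A", 397)),
            b = strrep("A", 400))
  expect_equal(distance_matrix(msa3, "JC69")["a", "b"],
               -0.75 * log(1 - 0.01), tolerance = 1e-12)
  far <- c(a = strrep("A", 100), b = strrep("C", 100))
  expect_error(distance_matrix(far, "JC69"), class = "sk_value_error")
  nosites <- c(a = "AC--", b = "--AC")
  expect_error(distance_matrix(nosites), "shared", class = "sk_value_error")
})

test_that("three-taxon trees solve the three-point equations exactly", {
  d <- matrix(c(0, 5, 9, 5, 0, 8, 9, 8, 0), 3,
              dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  phy <- bionj_tree(d)
  cd <- as.matrix(ape::cophenetic.phylo(phy))[rownames(d), colnames(d)]
  expect_equal(cd, d, tolerance = 1e-12)
})

test_that("BIONJ and NJ recover additive trees exactly", {
  set.seed(77)
  for (k in 1:25) {
    n <- sample(4:12, 1)
    tr <- ape::unroot(ape::rtree(n, br = function(x) stats::runif(x, 0.05, 1)))
    D <- ape::cophenetic.phylo(tr)
    for (mode in c("bionj", "nj")) {
      est <- bionj_tree(D, mode = mode)
      expect_equal(ape::dist.topo(est, tr), 0, ignore_attr = TRUE)
      cd <- as.matrix(ape::cophenetic.phylo(est))[rownames(D), colnames(D)]
      expect_lt(max(abs(cd - D)), 1e-9)
    }
  }
})

test_that("identical rows form a zero-length cherry and tree length is permutation-invariant", {
  d <- matrix(c(0, 0, 7, 9,
                0, 0, 7, 9,
                7, 7, 0, 6,
                9, 9, 6, 0), 4,
              dimnames = list(letters[1:4], letters[1:4]))
  phy <- bionj_tree(d)
  cp <- ape::cophenetic.phylo(phy)
  expect_equal(cp["a", "b"], 0)
  set.seed(3)
  D <- ape::cophenetic.phylo(ape::rtree(7))
  perm <- sample(rownames(D))
  t1 <- bionj_tree(D)
  t2 <- bionj_tree(D[perm, perm])
  expect_equal(sum(t1$edge.length), sum(t2$edge.length), tolerance = 1e-9)
  expect_equal(ape::dist.topo(t1, t2), 0, ignore_attr = TRUE)
})

test_that("degenerate and invalid distance inputs error", {
  expect_error(bionj_tree(matrix(1, 1, 1)), class = "sk_value_error")
  bad <- matrix(c(0, 1, 2, 0), 2)
  expect_error(bionj_tree(bad), "symmetric", class = "sk_value_error")
  neg <- matrix(c(0, -1, -1, 0), 2)
  expect_error(bionj_tree(neg), class = "sk_value_error")
  two <- matrix(c(0, 4, 4, 0), 2, dimnames = list(c("p", "q"), c("p", "q")))
  phy <- bionj_tree(two)
  expect_setequal(phy$tip.label, c("p", "q"))
  expect_equal(sum(phy$edge.length), 4)
})

test_that("Newick writing round-trips, quoting labels when needed", {
  phy <- parse_newick("(a:1,b:1);")
  f <- tempfile(fileext = ".nwk")
  write_newick(phy, f)
  phy2 <- parse_newick(f)
  expect_setequal(phy2$tip.label, c("a", "b"))
  expect_equal(phy2$edge.length, phy$edge.length)

  set.seed(12)
  D <- ape::cophenetic.phylo(ape::rtree(8))
  est <- bionj_tree(D)
  write_newick(est, f)
  back <- parse_newick(f)
  expect_setequal(back$tip.label, est$tip.label)
  expect_equal(ape::dist.topo(back, est), 0, ignore_attr = TRUE)

  spaced <- bionj_tree(matrix(c(0, 3, 3, 0), 2,
                              dimnames = list(c("sample 1", "t2"),
                                              c("sample 1", "t2"))))
  write_newick(spaced, f)
  expect_match(paste(readLines(f), collapse = ""), "'sample 1'", fixed = TRUE)
  expect_true("sample 1" %in% parse_newick(f)$tip.label)
})

test_that("malformed Newick is rejected with a character offset", {
  expect_error(parse_newick("((a:1,b:2);"), "character",
               class = "sk_format_error")
  expect_error(parse_newick("(a:1,b:2))"), "character 10",
               class = "sk_format_error")
})
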