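test_that("consensus follows the majority / ambiguity / gap-column rules", {
  expect_equal(consensus_sequence(c("ACGT", "ACGT", "ACGT")), "ACGT")
  # column {A, A, C}: 2/3 > 0.5 majority
  expect_equal(consensus_sequence(c("A", "A", "C")), "A")
  # column {A, C}: no majority, both >= 0.25 -> M
  expect_equal(consensus_sequence(c("A", "C")), "M")
  # columns with > 50% gaps are omitted
  expect_equal(consensus_sequence(c("ACGT-", "AC---", "ACG--")), "ACG")
  expect_equal(consensus_sequence("TTAA"), "TTAA")
})

test_that("Hamming distances ignore gap columns and satisfy the triangle inequality", {
  expect_equal(hamming_matrix(c(a = "ACGT", b = "ACGT"))["a", "b"], 0L)
  expect_equal(hamming_matrix(c(a = "AC-T", b = "AG-T"))["a", "b"], 1L)
  expect_error(hamming_matrix(c("ACG", "AC")), class = "sk_value_error")
  set.seed(11)
  for (k in 1:30) {
    n <- sample(3:6, 1)
    rows <- vapply(seq_len(n), function(i)
      chars_seq(sample(c("A", "C", "G", "T", "-"), 40, TRUE)), "")
    m <- hamming_matrix(rows)
    expect_true(isSymmetric(m))
    expect_true(all(diag(m) == 0))
    for (i in 1:n) for (j in 1:n) for (l in 1:n)
      expect_lte(m[i, j], m[i, l] + m[l, j])
  }
})

test_that("read dendrogram joins the closest reads first", {
  m <- matrix(c(0, 0, 10, 0, 0, 10, 10, 10, 0), 3,
              dimnames = list(c("r1", "r2", "r3"), c("r1", "r2", "r3")))
  hc <- read_dendrogram(m)
  expect_identical(hc$merge[1, ], c(-1L, -2L))
  # ultrametric input: cophenetic distances reproduce the matrix exactly
  um <- matrix(c(0, 2, 8, 8, 2, 0, 8, 8, 8, 8, 0, 4, 8, 8, 4, 0), 4,
               dimnames = list(letters[1:4], letters[1:4]))
  expect_equal(as.matrix(stats::cophenetic(read_dendrogram(um))),
               um, ignore_attr = TRUE)
  # two reads: a single cherry with each leaf at height d/2
  m2 <- matrix(c(0, 6, 6, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  hc2 <- read_dendrogram(m2)
  expect_equal(hc2$height, 6)
  expect_equal(ape::as.phylo(hc2)$edge.length, c(3, 3))
  expect_message(expect_null(read_dendrogram(m2[1, 1, drop = FALSE])))
})

sim_read_pair <- function(template, spec = flat_spec(), seed = 1) {
  lapply(c(forward = "forward", reverse = "reverse"), function(d) {
    sr <- write_sim_read(template, d, spec, seed = seed + (d == "reverse"))
    sanger_read(sr$path, direction = d)
  })
}

test_that("error-free forward+reverse reads assemble to the exact template", {
  tmpl <- simulate_template(300, seed = 21)
  reads <- sim_read_pair(tmpl)
  ct <- build_contig(reads, name = "c1")
  expect_equal(ct$consensus, tmpl)
  expect_equal(max(ct$hamming), 0L)
  # ungap round-trip: MSA rows reproduce the trimmed, oriented reads
  for (id in ct$included)
    expect_equal(gsub("-", "", ct$read_msa[[id]]),
                 sangerkit:::oriented_trimmed_seq(ct$reads[[id]]))
})

test_that("single-read contigs pass through and disagreements become ambiguity codes", {
  tmpl <- simulate_template(200, seed = 22)
  reads <- sim_read_pair(tmpl)
  ct1 <- build_contig(reads[1], name = "single")
  expect_equal(ct1$consensus, tmpl)

  # mutate one site of the forward read's template: 50/50 column -> IUPAC
  ch <- seq_chars(tmpl)
  old <- ch[100]; ch[100] <- setdiff(c("A", "C", "G", "T"), old)[1]
  mut <- chars_seq(ch)
  r1 <- sanger_read(write_sim_read(mut, "forward", flat_spec(), 5)$path,
                    direction = "forward")
  r2 <- sanger_read(write_sim_read(tmpl, "reverse", flat_spec(), 6)$path,
                    direction = "reverse")
  ct2 <- build_contig(list(r1, r2), name = "het")
  expect_equal(nchar(ct2$consensus), 200)
  code <- substr(ct2$consensus, 100, 100)
  expect_equal(sort(sangerkit:::iupac_expand(code)), sort(c(old, ch[100])))
  expect_equal(ct2$hamming[1, 2], 1L)
})

test_that("short reads are excluded but reported; empty contigs error", {
  tmpl <- simulate_template(150, seed = 23)
  good <- sanger_read(write_sim_read(tmpl, "forward", flat_spec(), 1)$path,
                      direction = "forward")
  bad <- sanger_read(write_sim_read(substr(tmpl, 1, 10), "reverse",
                                    flat_spec(), 2)$path,
                     direction = "reverse")
  ct <- build_contig(list(good, bad), name = "mix", min_read_length = 20)
  expect_equal(ct$excluded, bad$id)
  expect_equal(ct$consensus, tmpl)
  expect_error(build_contig(list(bad), name = "none"),
               "excluded", class = "sk_value_error")
})
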