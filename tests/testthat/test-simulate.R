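test_that("templates are reproducible and honor composition settings", {
  expect_identical(simulate_template(100, seed = 4),
                   simulate_template(100, seed = 4))
  gc1 <- simulate_template(200, gc_content = 1, seed = 5)
  expect_true(all(seq_chars(gc1) %in% c("G", "C")))
  orf <- simulate_template(aa_reference = AA_REF)
  tr <- as.character(Biostrings::translate(Biostrings::DNAString(orf)))
  expect_identical(tr, AA_REF)
})

test_that("clean reads basecall back to the template and keep the full trim", {
  tmpl <- simulate_template(150, seed = 6)
  sim <- simulate_read(tmpl, "forward", flat_spec(), seed = 7)
  expect_identical(sim$seq, tmpl)
  called <- call_bases(sim$trace, 0.33)
  expect_identical(called$primary_seq, tmpl)
  tr <- trim_mott(sim$qualities, 1e-4)
  expect_equal(c(tr$start, tr$end), c(0, 150))
  # reverse reads observe the reverse complement
  simr <- simulate_read(tmpl, "reverse", flat_spec(), seed = 8)
  expect_identical(simr$seq, reverse_complement(tmpl))
})

test_that("quality ramps at the ends make both trimmers cut a proper sub-window", {
  tmpl <- simulate_template(200, seed = 9)
  sim <- simulate_read(tmpl, "forward", simulation_spec(), seed = 10)
  for (tr in list(trim_mott(sim$qualities, 1e-4),
                  trim_sliding_window(sim$qualities, 10, 20))) {
    expect_gt(tr$start, 0)
    expect_lt(tr$end, 200)
    expect_gt(tr$end, tr$start)
  }
})

test_that("fixture trees reproduce the two-subdirectory 16-file layout", {
  root <- tempfile("tree")
  man <- write_fixture_tree(simulation_spec(seed = 12), root)
  abfs <- list.files(root, pattern = "\\.ab1$", recursive = TRUE)
  expect_length(abfs, 16)
  expect_setequal(unique(dirname(abfs)), c("plateA", "plateB"))
  # every file independently parseable
  for (f in abfs) expect_silent(read_abif(file.path(root, f)))
  # manifest-driven CSV gives the same plan as the filename convention
  plan_fs <- group_by_filename(root)
  plan_csv <- read_grouping_csv(file.path(root, "grouping.csv"))
  expect_equal(plan_csv, plan_fs, ignore_attr = TRUE)
  # refuses to clobber without force
  expect_error(write_fixture_tree(simulation_spec(seed = 12), root),
               class = "sk_value_error")
})

test_that("fixtures are byte-identical under a fixed seed", {
  r1 <- tempfile(); r2 <- tempfile()
  write_fixture_tree(simulation_spec(seed = 33, n_contigs = 2), r1)
  write_fixture_tree(simulation_spec(seed = 33, n_contigs = 2), r2)
  f1 <- list.files(r1, recursive = TRUE)
  expect_identical(f1, list.files(r2, recursive = TRUE))
  for (f in f1) {
    expect_identical(readBin(file.path(r1, f), "raw", 1e6),
                     readBin(file.path(r2, f), "raw", 1e6),
                     info = f)
  }
})

test_that("the error-free end-to-end pipeline reproduces identical templates", {
  root <- tempfile("e2e")
  spec <- flat_spec(seed = 44, n_contigs = 3, divergence_subs = 0)
  man <- write_fixture_tree(spec, root)
  set <- sanger_alignment(dir = root)
  for (nm in names(set$contigs)) {
    expect_identical(set$contigs[[nm]]$consensus, man$templates[[nm]])
    expect_equal(max(set$contigs[[nm]]$hamming), 0L)
  }
  expect_true(all(!grepl("-", set$contig_msa)))
})

test_that("templates evolved on a known topology are recovered by the tree", {
  # three well-separated clades of two contigs each
  set.seed(55)
  anc <- simulate_template(400, seed = 56)
  mutate <- function(s, k) {
    ch <- seq_chars(s)
    for (p in sample(length(ch), k)) ch[p] <- sample(setdiff(c("A","C","G","T"), ch[p]), 1)
    chars_seq(ch)
  }
  cladeA <- mutate(anc, 40); cladeB <- mutate(anc, 40); cladeC <- mutate(anc, 40)
  cons <- c(a1 = mutate(cladeA, 3), a2 = mutate(cladeA, 3),
            b1 = mutate(cladeB, 3), b2 = mutate(cladeB, 3),
            c1 = mutate(cladeC, 3), c2 = mutate(cladeC, 3))
  msa <- align_contigs(cons)
  tree <- bionj_tree(distance_matrix(msa))
  sib <- function(x, y) {
    mrca <- ape::getMRCA(tree, c(x, y))
    length(ape::extract.clade(tree, mrca)$tip.label) == 2
  }
  expect_true(sib("a1", "a2"))
  expect_true(sib("b1", "b2"))
  expect_true(sib("c1", "c2"))
})
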