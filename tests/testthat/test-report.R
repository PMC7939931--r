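# one shared 3-contig pipeline run for the report/state/output tests
local_set <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      root <- tempfile("repfix")
      write_fixture_tree(simulation_spec(seed = 91, n_contigs = 3), root)
      cache <<- list(root = root, set = sanger_alignment(dir = root))
    }
    cache
  }
})

test_that("FASTA output modes produce the contracted files", {
  fx <- local_set()
  out <- tempfile("fasta_out")
  res <- write_outputs(fx$set, "contigs", out)
  expect_equal(nrow(res), 1)
  expect_equal(nrow(read_fasta(res$file)), 3)

  out2 <- tempfile("fasta_all")
  res2 <- write_outputs(fx$set, "all", out2)
  expect_equal(nrow(res2), 3)
  expect_setequal(res2$mode, c("reads", "contigs", "aligned_contigs"))
  aligned <- read_fasta(file.path(out2, "contigs_aligned.fasta"))
  expect_length(unique(nchar(aligned$sequence)), 1)
  reads <- read_fasta(file.path(out2, "reads.fasta"))
  expect_equal(nrow(reads), 6)
  expect_error(write_outputs(fx$set, "everything", out2),
               class = "sk_value_error")
})

test_that("the report renders one index, one page per contig and per read", {
  fx <- local_set()
  out <- tempfile("rep")
  idx <- generate_report(fx$set, report_config(out))
  pages <- list.files(out, pattern = "\\.html$", recursive = TRUE)
  expect_equal(length(pages), 1 + 3 + 6)
  expect_true(file.exists(idx))
  html <- paste(readLines(idx, warn = FALSE), collapse = "")
  expect_match(html, "quality control", ignore.case = TRUE)
  # chromatogram SVGs and quality TSVs alongside the read pages
  expect_length(list.files(out, pattern = "_chromatogram\\.svg$",
                           recursive = TRUE), 6)
  expect_length(list.files(out, pattern = "_qualities\\.tsv$",
                           recursive = TRUE), 6)
})

test_that("report sequences equal the FASTA output (single source of truth)", {
  fx <- local_set()
  out <- tempfile("rep2")
  generate_report(fx$set, report_config(out))
  fa_out <- tempfile("fa")
  write_outputs(fx$set, "contigs", fa_out)
  cons <- read_fasta(file.path(fa_out, "contigs.fasta"))
  for (i in seq_len(nrow(cons))) {
    page <- file.path(out, "contigs", cons$id[i], "index.html")
    html <- paste(readLines(page, warn = FALSE), collapse = "")
    stripped <- gsub("<[^>]+>", "", html)
    expect_match(stripped, substr(cons$sequence[i], 1, 60), fixed = TRUE)
  }
})

test_that("a fully trimmed read is flagged on its page", {
  root <- tempfile("lowq")
  dir.create(root)
  tmpl <- simulate_template(60, seed = 93)
  spec <- simulation_spec(peak_q = 8, floor_q = 2)  # hopeless quality
  sim <- simulate_read(tmpl, "forward", spec, seed = 94)
  write_abif(sim$trace, sim$seq, sim$qualities, file.path(root, "low_F.ab1"))
  sim2 <- simulate_read(tmpl, "reverse", flat_spec(), seed = 95)
  write_abif(sim2$trace, sim2$seq, sim2$qualities, file.path(root, "low_R.ab1"))
  set <- sanger_alignment(dir = root)
  out <- tempfile("rep3")
  generate_report(set, report_config(out))
  page <- paste(readLines(file.path(out, "contigs", "low", "reads", "low_F.html"),
                          warn = FALSE), collapse = "")
  expect_match(page, "fully trimmed", ignore.case = TRUE)
})

test_that("report generation is deterministic", {
  fx <- local_set()
  o1 <- tempfile(); o2 <- tempfile()
  generate_report(fx$set, report_config(o1))
  generate_report(fx$set, report_config(o2))
  files <- list.files(o1, recursive = TRUE)
  expect_identical(files, list.files(o2, recursive = TRUE))
  for (f in files)
    expect_identical(readLines(file.path(o1, f), warn = FALSE),
                     readLines(file.path(o2, f), warn = FALSE), info = f)
})

test_that("state files round-trip every analysis field", {
  fx <- local_set()
  st <- tempfile(fileext = ".json")
  save_state(fx$set, st)
  back <- load_state(st)
  expect_identical(names(back$contigs), names(fx$set$contigs))
  expect_identical(back$contig_msa, fx$set$contig_msa)
  expect_equal(back$distances, fx$set$distances)
  expect_equal(ape::dist.topo(back$tree, fx$set$tree), 0, ignore_attr = TRUE)
  for (nm in names(back$contigs)) {
    a <- back$contigs[[nm]]; b <- fx$set$contigs[[nm]]
    expect_identical(a$consensus, b$consensus)
    expect_identical(a$read_msa, b$read_msa)
    expect_equal(a$hamming, b$hamming)
    for (id in names(b$reads)) {
      expect_identical(a$reads[[id]]$primary_seq, b$reads[[id]]$primary_seq)
      expect_identical(a$reads[[id]]$qualities, b$reads[[id]]$qualities)
      expect_identical(a$reads[[id]]$trim, b$reads[[id]]$trim)
      expect_equal(a$reads[[id]]$secondary_peaks, b$reads[[id]]$secondary_peaks)
    }
  }
  # saving the reloaded object reproduces the file
  st2 <- tempfile(fileext = ".json")
  save_state(back, st2)
  expect_identical(readLines(st), readLines(st2))
  # stored parameters are reused downstream
  expect_equal(back$params$trim_cutoff, 1e-4)
})

test_that("truncated or mismatched state files error without partial objects", {
  fx <- local_set()
  st <- tempfile(fileext = ".json")
  save_state(fx$set, st)
  txt <- readLines(st)
  half <- tempfile(fileext = ".json")
  writeLines(txt[1:(length(txt) %/% 2)], half)
  expect_error(load_state(half), class = "sk_format_error")
  wrong <- tempfile(fileext = ".json")
  writeLines(gsub("\"1.0\"", "\"9.9\"", txt), wrong)
  expect_error(load_state(wrong), "9.9", class = "sk_format_error")
})
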