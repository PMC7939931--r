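test_that("an exact ORF of the reference has no indels or internal stops", {
  orf <- simulate_template(aa_reference = AA_REF)
  tabs <- indel_and_stop_tables(orf, AA_REF)
  expect_equal(nrow(tabs$indels), 0)
  expect_equal(nrow(tabs$stops), 0)
  expect_equal(tabs$frames$strand, "forward")
})

test_that("injected indels are reported with frameshift status, on either strand", {
  orf <- simulate_template(aa_reference = AA_REF)
  ch <- seq_chars(orf)
  # single-base deletion mid-ORF
  del1 <- chars_seq(ch[-100])
  t1 <- indel_and_stop_tables(del1, AA_REF)
  expect_equal(nrow(t1$indels), 1)
  expect_equal(t1$indels$kind, "deletion")
  expect_true(t1$indels$frameshifting)
  expect_lt(abs(t1$indels$alignment_column_start - 100), 4)
  # single-base insertion
  ins1 <- chars_seq(append(ch, "G", after = 120))
  t2 <- indel_and_stop_tables(ins1, AA_REF)
  expect_equal(t2$indels$kind, "insertion")
  expect_equal(t2$indels$length, 1L)
  expect_true(t2$indels$frameshifting)
  # whole-codon deletion is not frameshifting
  del3 <- chars_seq(ch[-(91:93)])
  t3 <- indel_and_stop_tables(del3, AA_REF)
  expect_equal(t3$indels$length, 3L)
  expect_false(t3$indels$frameshifting)
  # reverse-complement input: frame search finds the reverse strand
  t4 <- indel_and_stop_tables(reverse_complement(del1), AA_REF)
  expect_equal(t4$frames$strand, "reverse")
  expect_equal(t4$indels$kind, "deletion")
})

test_that("an in-frame stop codon is reported at its codon index", {
  orf <- simulate_template(aa_reference = AA_REF)
  ins <- paste0(substr(orf, 1, 90), "TAA", substr(orf, 91, nchar(orf)))
  tabs <- indel_and_stop_tables(ins, AA_REF)
  expect_equal(tabs$stops$codon, "TAA")
  expect_equal(tabs$stops$codon_index, 31L)
  expect_equal(tabs$stops$nucleotide_position, 91L)
  # a terminal stop aligned at the reference's end is not reported
  terminal <- paste0(orf, "TAA")
  tt <- indel_and_stop_tables(terminal, AA_REF)
  expect_equal(nrow(tt$stops), 0)
})

test_that("frameshift correction removes insertions, pads deletions, and is idempotent", {
  orf <- simulate_template(aa_reference = AA_REF)
  # unchanged input
  c0 <- correct_frameshifts(orf, AA_REF)
  expect_equal(c0$seq, orf)
  expect_equal(nrow(c0$edits), 0)
  # single-base insertion removed exactly
  ins <- paste0(substr(orf, 1, 100), "G", substr(orf, 101, nchar(orf)))
  c1 <- correct_frameshifts(ins, AA_REF)
  expect_equal(c1$seq, orf)
  expect_equal(c1$edits$kind, "delete_insertion")
  # two-base deletion padded with one NN
  del2 <- paste0(substr(orf, 1, 99), substr(orf, 102, nchar(orf)))
  c2 <- correct_frameshifts(del2, AA_REF)
  expect_equal(c2$edits$kind, "pad_deletion")
  expect_equal(c2$edits$length, 2L)
  expect_equal(nchar(c2$seq), nchar(orf))
  # re-analysis of corrected sequences shows no frameshifting records
  for (fixed in list(c1$seq, c2$seq)) {
    re <- indel_and_stop_tables(fixed, AA_REF)
    expect_equal(sum(re$indels$frameshifting), 0)
  }
  # idempotence
  expect_equal(correct_frameshifts(c2$seq, AA_REF)$seq, c2$seq)
})

test_that("a missing reference skips the tables with a notice", {
  expect_message(res <- indel_and_stop_tables("ATGGCT", NULL),
                 "skipped")
  expect_equal(nrow(res$indels), 0)
})
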