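# Reading chimeric records, fragment pairing, evidence classification and
# breakend inference.

test_that("discordance predicates select the right records", {
  path <- write_sam_fixture(
    c(split_fixture_lines(), concordant_pair_lines(),
      interchrom_pair_lines(), orphan_pair_line()),
    fixture_contigs
  )
  rec <- read_chimeric_records(path)
  # concordant FR pair (insert 300 < 450) skipped entirely
  expect_false("frag_conc" %in% rec$qname)
  # interchromosomal mates both yielded
  expect_equal(sum(rec$qname == "frag_inter"), 2)
  # split-read primary + supplementary both yielded
  expect_equal(sum(rec$qname == "frag_split"), 2)
  # orphan record yielded at record level (dropped later, at pairing)
  expect_equal(sum(rec$qname == "frag_orphan"), 1)
  expect_equal(attr(rec, "counters")$total, 7)
})

test_that("empty and missing inputs are handled explicitly", {
  empty <- write_sam_fixture(character(0), fixture_contigs)
  rec <- read_chimeric_records(empty)
  expect_equal(nrow(rec), 0)
  ev <- pair_read_fragments(rec)
  expect_equal(nrow(ev), 0)
  expect_error(read_chimeric_records(tempfile()), "not found")
})

test_that("fragment pairing reconstructs arms, orphans and collisions", {
  collision <- c(
    paste("frag_dup", 0, "chr1", 201, 60, "60M66S", "*", 0, 0,
          dummy_seq(126), "*", "SA:Z:chr2,901,+,60S66M,60,0;", sep = "\t"),
    paste("frag_dup", 0, "chr5", 301, 60, "50M76S", "*", 0, 0,
          dummy_seq(126), "*", "SA:Z:chr7,901,+,50S76M,60,0;", sep = "\t")
  )
  path <- write_sam_fixture(
    c(split_fixture_lines(), interchrom_pair_lines(), orphan_pair_line(),
      collision),
    fixture_contigs
  )
  ev <- pair_read_fragments(read_chimeric_records(path))
  cnt <- attr(ev, "counters")
  # split read -> exactly one evidence with the expected arms
  sp <- dplyr::filter(ev, fragment_id == "frag_split")
  expect_equal(nrow(sp), 1)
  expect_equal(sp$startA, 100L)
  expect_equal(sp$endA, 175L)
  expect_equal(sp$startB, 500L)
  expect_equal(sp$endB, 551L)
  # interchromosomal pair -> one spanning evidence
  expect_equal(sum(ev$fragment_id == "frag_inter"), 1)
  # orphan mate dropped and counted
  expect_false("frag_orphan" %in% ev$fragment_id)
  expect_equal(cnt$orphaned, 1)
  # name collision -> whole fragment dropped as malformed
  expect_false("frag_dup" %in% ev$fragment_id)
  expect_equal(cnt$malformed, 1)
  # conservation: every fragment is accounted for
  expect_equal(cnt$emitted + cnt$orphaned + cnt$malformed, cnt$fragments)
})

test_that("split-read breakends are base-precise with correct sides", {
  path <- write_sam_fixture(split_fixture_lines(), fixture_contigs)
  ev <- infer_breakends(pair_read_fragments(read_chimeric_records(path)))
  expect_equal(ev$posA, 174L)
  expect_equal(ev$sideA, "left")
  expect_equal(ev$posB, 500L)
  expect_equal(ev$sideB, "right")
  expect_true(ev$precise)
  expect_equal(ev$uncertA, 0L)
  # determinism: identical input -> identical breakends
  ev2 <- infer_breakends(pair_read_fragments(read_chimeric_records(path)))
  expect_identical(ev, ev2)
})

test_that("spanning breakends face the mate and carry bounded uncertainty", {
  # inverted-orientation same-chrom pair (both +), 1 Mb apart is emulated
  # by arms chr2:[10,85) and chr2:[900,975), both plus strand
  lines <- c(
    paste("frag_inv", 65, "chr2", 11, 60, "75M", "=", 901, 964,
          dummy_seq(75), "*", sep = "\t"),
    paste("frag_inv", 129, "chr2", 901, 60, "75M", "=", 11, -964,
          dummy_seq(75), "*", sep = "\t")
  )
  path <- write_sam_fixture(lines, fixture_contigs)
  layout <- library_layout()
  ev <- classify_evidence(
    infer_breakends(pair_read_fragments(read_chimeric_records(path, layout = layout)),
                    layout = layout), layout = layout)
  expect_equal(ev$category, "spanning_pair")
  # + strand mates: junction-facing bound is the last aligned base, side left
  expect_equal(ev$posA, 84L)
  expect_equal(ev$sideA, "left")
  expect_equal(ev$posB, 974L)
  expect_equal(ev$sideB, "left")
  expect_true(all(c(ev$uncertA, ev$uncertB) <= layout$expected_insert_max_nt))
  expect_equal(ev$uncertA, 450L - 75L)
})

test_that("head-to-tail splits are recognized and arm-order invariant", {
  # second-in-read arm maps 2 kb upstream of the first arm's end on chr5 (+)
  h2t <- c(
    paste("frag_h2t", 0, "chr5", 5001, 60, "70M56S", "*", 0, 0,
          dummy_seq(126), "*", "SA:Z:chr5,3001,+,70S56M,60,0;", sep = "\t"),
    paste("frag_h2t", 2048, "chr5", 3001, 60, "70S56M", "*", 0, 0,
          dummy_seq(126), "*", "SA:Z:chr5,5001,+,70M56S,60,0;", sep = "\t")
  )
  for (lines in list(h2t, rev(h2t))) {
    path <- write_sam_fixture(lines, fixture_contigs)
    ev <- classify_evidence(
      infer_breakends(pair_read_fragments(read_chimeric_records(path))))
    expect_equal(ev$category, "head_to_tail_split")
  }
})

test_that("splice motifs and exon boundaries set the provisional type", {
  ev <- make_ev("m1", "chrL", 99L, "left", "chrR", 500L, "right")
  out <- classify_evidence(ev, reference = motif_reference())
  expect_equal(out$provisional_type, "splice_like")
  # same geometry on motif-free context -> genomic
  plain <- Biostrings::DNAStringSet(c(chrL = dummy_seq(1000),
                                      chrR = dummy_seq(1000)))
  expect_equal(classify_evidence(ev, reference = plain)$provisional_type,
               "genomic")
  # exon-boundary mode (GENEA exon ends at 1099, GENEB exon starts 12000)
  ev2 <- make_ev("m2", "chr1", 1099L, "left", "chr1", 12000L, "right")
  expect_equal(classify_evidence(ev2, gene_models = toy_models())$provisional_type,
               "splice_like")
})

test_that("short arms are dropped by the per-arm floor", {
  lines <- c(
    paste("frag_short", 0, "chr1", 101, 60, "116M10S", "*", 0, 0,
          dummy_seq(126), "*", "SA:Z:chr8,501,+,116S10M,60,0;", sep = "\t"),
    paste("frag_short", 2048, "chr8", 501, 60, "116S10M", "*", 0, 0,
          dummy_seq(126), "*", "SA:Z:chr1,101,+,116M10S,60,0;", sep = "\t")
  )
  path <- write_sam_fixture(lines, fixture_contigs)
  ev <- pair_read_fragments(read_chimeric_records(path), min_arm_nt = 20L)
  expect_equal(nrow(ev), 0)
  expect_equal(attr(ev, "counters")$short_arm, 1)
})
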