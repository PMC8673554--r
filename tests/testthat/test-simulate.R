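# The rearrangement/read simulator: determinism, structural guarantees and
# truth scoring.

test_that("reference generation is deterministic and motif-embedded", {
  spec <- sim_spec(n_contigs = 2L, contig_length_nt = 60000L, n_genes = 8L,
                   seed = 3L)
  r1 <- generate_reference(spec)
  r2 <- generate_reference(spec)
  expect_identical(as.character(r1$sequences), as.character(r2$sequences))
  expect_equal(length(r1$sequences), 2)
  expect_equal(unname(r1$contig_lengths), c(60000L, 60000L))
  # every generated intron starts GT and ends AG (plus strand genes;
  # genome view CT..AC for minus strand)
  models <- generate_annotation(spec, r1)
  ex <- models$exons |> dplyr::group_by(gene_id) |> dplyr::arrange(start, .by_group = TRUE)
  introns <- ex |>
    dplyr::summarise(chrom = dplyr::first(chrom), strand = dplyr::first(strand),
                     s = list(utils::head(end, -1)), e = list(utils::tail(start, -1)),
                     .groups = "drop") |>
    tidyr::unnest(c(s, e))
  for (i in seq_len(nrow(introns))) {
    don <- as.character(Biostrings::subseq(r1$sequences[[introns$chrom[i]]],
                                           introns$s[i] + 1, introns$s[i] + 2))
    acc <- as.character(Biostrings::subseq(r1$sequences[[introns$chrom[i]]],
                                           introns$e[i] - 1, introns$e[i]))
    if (introns$strand[i] == "+") {
      expect_equal(don, "GT")
      expect_equal(acc, "AG")
    } else {
      expect_equal(don, "CT")
      expect_equal(acc, "AC")
    }
  }
})

test_that("annotation has the requested shape and round-trips through GTF", {
  spec <- sim_spec(n_contigs = 2L, contig_length_nt = 60000L, n_genes = 10L,
                   exons_per_gene = 5L, seed = 4L)
  models <- generate_annotation(spec)
  expect_equal(nrow(models$exons), 50)
  expect_equal(nrow(models$genes), 10)
  # genes non-overlapping by construction
  g <- models$genes |> dplyr::arrange(chrom, start)
  by_chrom <- split(g, g$chrom)
  for (gc in by_chrom) {
    if (nrow(gc) > 1) expect_true(all(utils::head(gc$end, -1) <= utils::tail(gc$start, -1)))
  }
  path <- tempfile(fileext = ".gtf")
  write_gtf(models, path)
  back <- read_gene_models(path)
  expect_equal(back$genes, models$genes)
  expect_equal(back$exons, models$exons)
})

test_that("planted truths have on-contig coordinates and correct geometry", {
  spec <- small_sim_spec(seed = 5L)
  ref <- generate_reference(spec)
  models <- generate_annotation(spec, ref)
  truths <- plant_rearrangements(spec, ref, models)
  expect_equal(length(unique(truths$event_id)), spec$n_events)
  expect_true(all(truths$posA >= 0 &
                    truths$posA < ref$contig_lengths[truths$chromA]))
  expect_true(all(truths$posB >= 0 &
                    truths$posB < ref$contig_lengths[truths$chromB]))
  # deletion: derived allele length = original - deleted span
  del <- truths |> dplyr::filter(event_type == "deletion", kind == "intronic")
  expect_true(all(del$derived_length ==
                    spec$contig_length_nt - (del$posB - del$posA - 1L)))
  # inversion breakends retain the same side (left/left join)
  inv <- truths |> dplyr::filter(event_type == "inversion")
  expect_true(all(inv$sideA == inv$sideB))
  # back-splice: head-to-tail geometry, acceptor upstream of donor
  bs <- truths |> dplyr::filter(event_type == "back_splice")
  expect_true(all(bs$sideA == "right" & bs$sideB == "left" &
                    bs$posA < bs$posB & bs$circ))
})

test_that("alignment simulation is deterministic and counts reads faithfully", {
  spec <- small_sim_spec(seed = 6L)
  ref <- generate_reference(spec)
  models <- generate_annotation(spec, ref)
  truths <- plant_rearrangements(spec, ref, models)
  p1 <- tempfile(fileext = ".sam")
  p2 <- tempfile(fileext = ".sam")
  t1 <- simulate_alignments(truths, spec, ref, p1)
  t2 <- simulate_alignments(truths, spec, ref, p2)
  expect_identical(readLines(p1), readLines(p2))
  # per-event totals equal the requested reads per event
  per_event <- t1 |>
    dplyr::group_by(event_id) |>
    dplyr::summarise(s = sum(n_split_planted), p = sum(n_spanning_planted))
  expect_true(all(per_event$s == spec$reads_per_event[["split"]]))
  expect_true(all(per_event$p == spec$reads_per_event[["spanning"]]))
})

test_that("pre_mrna_fraction = 0 emits no genomic-breakpoint reads for expressed events", {
  spec <- small_sim_spec(seed = 8L, pre_mrna_fraction = 0)
  ref <- generate_reference(spec)
  truths <- plant_rearrangements(spec, ref, generate_annotation(spec, ref))
  t1 <- simulate_alignments(truths, spec, ref, tempfile(fileext = ".sam"))
  silent <- t1 |> dplyr::filter(expressed, kind == "intronic")
  expect_true(all(silent$n_split_planted + silent$n_spanning_planted == 0))
})

test_that("truth scoring behaves at the boundaries", {
  truths <- tibble::tibble(
    event_id = c("e1", "e2"), event_type = "deletion",
    kind = c("exonic", "intronic"),
    chromA = "chr1", posA = c(1000L, 8000L), sideA = "left",
    chromB = "chr1", posB = c(5000L, 9000L), sideB = "right",
    n_split_planted = c(5L, 5L), n_spanning_planted = 0L
  )
  perfect <- truths |>
    dplyr::mutate(classification = kind, filter_status = "passed")
  sc <- score_against_truth(perfect, truths)
  expect_equal(sc$precision, 1)
  expect_equal(sc$recall, 1)
  expect_equal(sc$classification_accuracy, 1)
  expect_equal(sc$exact_fraction, 1)
  # empty calls: recall 0, precision undefined
  sc0 <- score_against_truth(perfect[0, ], truths)
  expect_equal(sc0$recall, 0)
  expect_true(is.nan(sc0$precision))
  # a +41 nt shift on one side is a false positive
  shifted <- perfect |> dplyr::mutate(posA = posA + 41L)
  sc41 <- score_against_truth(shifted, truths)
  expect_equal(sc41$n_matched, 0)
  expect_equal(sc41$precision, 0)
})

test_that("simulate_run writes all artefacts consistently", {
  dir <- tempfile("simrun_")
  run <- simulate_run(small_sim_spec(seed = 9L), dir = dir)
  expect_true(all(file.exists(unlist(run$paths))))
  # catalogue entries correspond 1:1 to planted back-splices
  expect_equal(nrow(run$catalogue),
               sum(run$truths$event_type == "back_splice"))
  # planted split reads with exact coordinates are recovered as evidence
  rec <- read_chimeric_records(run$paths$sam)
  ev <- infer_breakends(pair_read_fragments(rec))
  truth_keys <- with(run$truths[run$truths$n_split_planted > 0, ],
                     paste(chromA, posA, chromB, posB))
  ev_keys <- paste(ev$chromA, ev$posA, ev$chromB, ev$posB)
  expect_true(all(truth_keys %in% ev_keys))
})
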