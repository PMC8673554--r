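# Filters, exonic/intronic classification, gene annotation and circRNA
# flagging.

calls_from <- function(ev) {
  call_junctions(splice_variant_correction(
    extract_clusters(merge_nearby_breakends(build_graph(ev)))))
}

test_that("single-read junctions always fail; two reads pass defaults", {
  one <- apply_filters(calls_from(make_ev_stack(1)))
  expect_equal(one$filter_status, "failed")
  expect_match(one$filter_reasons, "insufficient_reads")
  two <- apply_filters(calls_from(make_ev_stack(2)))
  expect_equal(two$filter_status, "passed")
  expect_equal(two$filter_reasons, "")
  # the >1-read rule is structural: filter_params refuses min_reads < 2
  expect_error(filter_params(min_reads = 1L), "min_reads")
  expect_error(graph_params(min_reads = 1L), "min_reads")
})

test_that("nonstandard contigs are excluded and all reasons are reported", {
  ev <- make_ev("n1", "chr11_KI270721v1_random", 500L, "left",
                "chr11_KI270721v1_random", 9000L, "right")
  out <- apply_filters(calls_from(ev))
  expect_match(out$filter_reasons, "nonstandard_contig")
  expect_match(out$filter_reasons, "insufficient_reads")
  off <- apply_filters(calls_from(ev),
                       filter_params(exclude_nonstandard_contigs = FALSE))
  expect_false(grepl("nonstandard_contig", off$filter_reasons))
})

test_that("start diversity separates read stacks from genuine support", {
  stack <- apply_filters(calls_from(
    make_ev_stack(10, distinct_starts = FALSE)))
  expect_match(stack$filter_reasons, "low_start_diversity")
  diverse <- apply_filters(calls_from(make_ev_stack(10)))
  expect_equal(diverse$filter_status, "passed")
})

test_that("spanning-only calls fail no_split_support when min_split > 0", {
  ev <- dplyr::bind_rows(
    make_ev("p1", "chr2", 1000L, "left", "chr9", 9000L, "right",
            category = "spanning_pair", is_pair = TRUE, uncertA = 300L,
            uncertB = 300L),
    make_ev("p2", "chr2", 1005L, "left", "chr9", 9008L, "right",
            category = "spanning_pair", is_pair = TRUE, uncertA = 300L,
            uncertB = 300L, startA = 700L, startB = 9300L)
  )
  out <- apply_filters(calls_from(ev))
  expect_match(out$filter_reasons, "no_split_support")
  relaxed <- apply_filters(calls_from(ev), filter_params(min_split = 0L))
  expect_equal(relaxed$filter_status, "passed")
})

test_that("exon-boundary breakends are exonic, mid-intron breakends intronic", {
  models <- toy_models()
  # GENEA exon 2 ends at 1599 (0-based last base); GENEB exon 1 starts 12000
  exonic <- classify_junctions(
    calls_from(make_ev_stack(3, chromA = "chr1", posA = 1599L,
                             chromB = "chr1", posB = 12000L,
                             type = "splice_like")),
    gene_models = models)
  expect_equal(exonic$classification, "exonic")
  # within tolerance (2 nt) still exonic
  jitter <- classify_junctions(
    calls_from(make_ev_stack(3, chromA = "chr1", posA = 1601L,
                             chromB = "chr1", posB = 11999L,
                             type = "splice_like")),
    gene_models = models)
  expect_equal(jitter$classification, "exonic")
  # both breakends mid-intron, no motif -> intronic
  intronic <- classify_junctions(
    calls_from(make_ev_stack(3, chromA = "chr1", posA = 1750L,
                             chromB = "chr1", posB = 12250L)),
    gene_models = models)
  expect_equal(intronic$classification, "intronic")
})

test_that("cryptic junctions with splice motifs are exonic even off-annotation", {
  calls <- calls_from(make_ev_stack(3, chromA = "chrL", posA = 99L,
                                    chromB = "chrR", posB = 500L))
  out <- classify_junctions(calls, reference = motif_reference())
  expect_equal(out$classification, "exonic")
  # classification is total: every call gets exactly one label
  expect_true(all(out$classification %in% c("exonic", "intronic")))
})

test_that("contigs absent from the annotation classify intronic with a warning", {
  calls <- calls_from(make_ev_stack(3, chromA = "chrZ", chromB = "chrZ",
                                    posB = 9000L))
  expect_warning(out <- classify_junctions(calls, gene_models = toy_models()),
                 "absent")
  expect_equal(out$classification, "intronic")
})

test_that("gene membership and intergenic status are assigned from spans", {
  models <- toy_models()
  both <- annotate_genes(calls_from(make_ev_stack(
    2, chromA = "chr1", posA = 1200L, chromB = "chr1", posB = 13100L)), models)
  expect_equal(both$genesA, "GENEA")
  expect_equal(both$genesB, "GENEB")
  expect_equal(both$intergenic_status, "both_in_gene")
  one <- annotate_genes(calls_from(make_ev_stack(
    2, chromA = "chr1", posA = 1200L, chromB = "chr1", posB = 60000L)), models)
  expect_equal(one$intergenic_status, "one_intergenic")
  neither <- annotate_genes(calls_from(make_ev_stack(
    2, chromA = "chr1", posA = 50000L, chromB = "chr1", posB = 60000L)), models)
  expect_equal(neither$intergenic_status, "both_intergenic")
})

test_that("unstranded membership ignores gene strand", {
  models <- toy_models() # both genes '+'
  calls <- calls_from(make_ev_stack(2, chromA = "chr1", posA = 1200L,
                                    chromB = "chr1", posB = 13100L))
  calls$strandA <- "-"
  calls$strandB <- "-"
  un <- annotate_genes(calls, models, stranded = FALSE)
  expect_equal(un$intergenic_status, "both_in_gene")
  st <- annotate_genes(calls, models, stranded = TRUE)
  expect_equal(st$intergenic_status, "both_intergenic")
})

test_that("head-to-tail geometry drives the circRNA flag", {
  # acceptor (right-retaining) upstream of donor (left-retaining), one chrom
  h2t <- flag_head_to_tail(calls_from(make_ev(
    "c1", "chr4", 1000L, "right", "chr4", 2000L, "left")))
  expect_true(h2t$circ_flag)
  inter <- flag_head_to_tail(calls_from(make_ev(
    "c2", "chr4", 1000L, "right", "chr5", 2000L, "left")))
  expect_false(inter$circ_flag)
  linear <- flag_head_to_tail(calls_from(make_ev(
    "c3", "chr4", 1000L, "left", "chr4", 2000L, "right")))
  expect_false(linear$circ_flag)
})

test_that("catalogue matching requires 0-nt exactness", {
  calls <- calls_from(make_ev("c1", "chr4", 1000L, "right", "chr4", 2000L,
                              "left"))
  cat_exact <- tibble::tibble(chrom = "chr4", start = 1000L, end = 2001L,
                              strand = "+")
  out <- flag_head_to_tail(calls, cat_exact)
  expect_true(out$catalogue_match)
  cat_off <- tibble::tibble(chrom = "chr4", start = 1001L, end = 2001L,
                            strand = "+")
  off <- flag_head_to_tail(calls, cat_off)
  expect_true(off$circ_flag)
  expect_false(off$catalogue_match)
})

test_that("the catalogue reader skips malformed lines with a warning", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("chr1\t100\t200\t+", "broken line", "chr2\t5\t50\t-"), path)
  expect_warning(cat <- read_circ_catalogue(path), "malformed")
  expect_equal(nrow(cat), 2)
})

test_that("GTF round-trip preserves the gene models", {
  models <- toy_models()
  path <- tempfile(fileext = ".gtf")
  write_gtf(models, path)
  back <- read_gene_models(path)
  expect_equal(back$genes, models$genes)
  expect_equal(back$exons, models$exons)
})
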