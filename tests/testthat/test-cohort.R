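# Junction-set matching, interchromosomal restriction, density binning and
# cohort splitting.

junc <- function(chromA, posA, chromB, posB, circ = FALSE) {
  tibble::tibble(chromA = chromA, posA = as.integer(posA), chromB = chromB,
                 posB = as.integer(posB), sideA = "left", sideB = "right",
                 circ_flag = circ)
}

test_that("matching is windowed two-sided with an inclusive boundary", {
  a <- junc("chr1", 1000, "chr2", 5000)
  expect_equal(nrow(match_junction_sets(a, a)$matched), 1)
  m0 <- match_junction_sets(a, junc("chr1", 1040, "chr2", 5040))
  expect_equal(nrow(m0$matched), 1)
  expect_equal(m0$matched$dist_a, 40)
  m1 <- match_junction_sets(a, junc("chr1", 1041, "chr2", 5000))
  expect_equal(nrow(m1$matched), 0)
  expect_equal(nrow(m1$a_only), 1)
  expect_equal(nrow(m1$b_only), 1)
})

test_that("head-to-tail and alternate-locus junctions are excluded up front", {
  a <- dplyr::bind_rows(
    junc("chr1", 1000, "chr2", 5000),
    junc("chr3", 200, "chr3", 900, circ = TRUE),
    junc("chr1_alt", 100, "chr2", 400)
  )
  m <- match_junction_sets(a, junc("chr1", 1000, "chr2", 5000))
  expect_equal(nrow(m$a), 1)
  expect_equal(nrow(m$matched), 1)
  keep <- match_junction_sets(a, junc("chr3", 200, "chr3", 900),
                              match_params(exclude_head_to_tail = FALSE,
                                           exclude_alt_loci = FALSE))
  expect_equal(nrow(keep$a), 3)
})

test_that("matching reproduces a hand-enumerated partition of 20 junctions", {
  # 20 junctions: indices 1..8 have a B partner at offsets (0..7, 0..7)
  # -> 8 matches; 9..12 have partners off by 41 on side A -> unmatched;
  # 13..20 have no partner at all
  a <- junc("chr1", 1000 + (1:20) * 10000, "chr2", 5000 + (1:20) * 10000)
  b <- dplyr::bind_rows(
    junc("chr1", 1000 + (1:8) * 10000 + (0:7), "chr2",
         5000 + (1:8) * 10000 + (0:7)),
    junc("chr1", 1000 + (9:12) * 10000 + 41, "chr2",
         5000 + (9:12) * 10000)
  )
  m <- match_junction_sets(a, b)
  expect_equal(nrow(m$matched), 8)
  expect_equal(sort(m$matched$index_a), 1:8)
  expect_equal(m$matched$dist_a[order(m$matched$index_a)], 0:7)
  expect_equal(nrow(m$a_only), 12)
  expect_equal(nrow(m$b_only), 4)
  # symmetric up to partition labels; matched size bounded by min(|A|,|B|)
  m2 <- match_junction_sets(b, a)
  expect_equal(nrow(m2$matched), 8)
  expect_lte(nrow(m$matched), min(nrow(m$a), nrow(m$b)))
})

test_that("greedy assignment matches each junction at most once, nearest first", {
  a <- dplyr::bind_rows(junc("chr1", 1000, "chr2", 5000),
                        junc("chr1", 1030, "chr2", 5030))
  b <- junc("chr1", 1010, "chr2", 5010)
  m <- match_junction_sets(a, b)
  expect_equal(nrow(m$matched), 1)
  expect_equal(m$matched$index_a, 1) # total distance 20 beats 40
})

test_that("mixed genome builds are a hard error", {
  a <- junc("chr1", 1000, "chr2", 5000)
  b <- junc("1", 1000, "2", 5000)
  expect_error(match_junction_sets(a, b), "contig")
})

test_that("interchromosomal restriction counts and is idempotent", {
  x <- dplyr::bind_rows(
    junc(rep("chr1", 5), 1:5 * 100, rep("chr2", 5), 1:5 * 200),
    junc(rep("chr3", 3), 1:3 * 100, rep("chr3", 3), 1:3 * 500)
  )
  r <- restrict_interchromosomal(x)
  expect_equal(nrow(r), 5)
  expect_identical(restrict_interchromosomal(r), r)
  allintra <- junc("chr1", 100, "chr1", 900)
  expect_equal(nrow(restrict_interchromosomal(allintra)), 0)
})

test_that("density binning conserves endpoints and excludes circRNAs", {
  lens <- c(chr1 = 10000L, chr2 = 10000L)
  empty <- bin_junction_density(list(t1 = junc(character(0), integer(0),
                                               character(0), integer(0))),
                                1000L, lens)
  expect_true(all(empty$count == 0))
  x <- dplyr::bind_rows(
    junc(rep("chr1", 3), c(1100, 1200, 1300), rep("chr1", 3),
         c(1400, 1500, 1600)),
    junc("chr2", 500, "chr2", 700, circ = TRUE)
  )
  bins <- bin_junction_density(list(t1 = x), 1000L, lens)
  expect_equal(bins$count[bins$chrom == "chr1" & bins$bin_start == 1000], 6)
  expect_equal(sum(bins$count), 6) # circ junction discarded entirely
  # conservation: sum of bins = 2 x retained junctions
  expect_equal(sum(bins$count), 2 * 3)
  # a track correlated with itself has r = 1
  two <- bin_junction_density(list(t1 = x, t2 = x), 1000L, lens)
  expect_equal(attr(two, "correlation"), 1)
})

test_that("cohort splitting by locus partitions exactly", {
  sj <- dplyr::bind_rows(
    dplyr::mutate(junc("chr11", 65000000, "chr11", 66000000), sample = "s1",
                  filter_status = "passed"),
    dplyr::mutate(junc("chr11", 59999998, "chr11", 95000000), sample = "s2",
                  filter_status = "passed"),  # 1 bp before locus start
    dplyr::mutate(junc("chr11", 61000000, "chr11", 62000000), sample = "s3",
                  filter_status = "failed"),  # failed calls never count
    dplyr::mutate(junc("chr2", 100, "chr2", 900), sample = "s4",
                  filter_status = "passed")
  )
  sp <- split_cohort_by_locus(sj, "chr11:60000001-90000000",
                              samples = paste0("s", 1:5))
  expect_equal(sp$mutant_samples, "s1")
  expect_setequal(sp$wildtype_samples, c("s2", "s3", "s4", "s5"))
  expect_equal(sort(c(sp$mutant_samples, sp$wildtype_samples)),
               paste0("s", 1:5))
  # a single in-locus junction is enough
  one <- split_cohort_by_locus(
    dplyr::mutate(junc("chr11", 70000000, "chr11", 70500000), sample = "x1"),
    "chr11:60000001-90000000")
  expect_equal(one$mutant_samples, "x1")
  # no junctions in locus -> empty mutant set
  none <- split_cohort_by_locus(
    dplyr::mutate(junc("chr2", 1, "chr2", 10), sample = "y1"),
    "chr11:60000001-90000000")
  expect_equal(length(none$mutant_samples), 0)
})

test_that("locus strings parse 1-based inclusive coordinates", {
  loc <- parse_locus("chr11:60,000,000-90,000,000")
  expect_equal(loc$chrom, "chr11")
  expect_equal(loc$start, 59999999)
  expect_equal(loc$end, 90000000)
  expect_error(parse_locus("nonsense"), "parse")
})
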