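# Shared fixtures: hand-built SAM files, tiny references/gene models, and
# direct evidence-tibble constructors that bypass alignment parsing.

sam_header <- function(contigs) {
  c("@HD\tVN:1.6\tSO:unsorted",
    sprintf("@SQ\tSN:%s\tLN:%d", names(contigs), contigs))
}

write_sam_fixture <- function(lines, contigs, path = tempfile(fileext = ".sam")) {
  writeLines(c(sam_header(contigs), lines), path)
  path
}

dummy_seq <- function(n) paste(rep("A", n), collapse = "")

# the canonical split-read fixture: one read, 75 nt on chr1 + 51 nt on chr8,
# linked via SA tags. armA chr1:[100,175)+ right-clipped, armB chr8:[500,551)+
# left-clipped -> breakends (chr1:174, left) and (chr8:500, right)
split_fixture_lines <- function(qname = "frag_split") {
  c(
    paste(qname, 0, "chr1", 101, 60, "75M51S", "*", 0, 0, dummy_seq(126), "*",
          "SA:Z:chr8,501,+,75S51M,60,0;", sep = "\t"),
    paste(qname, 2048, "chr8", 501, 60, "75S51M", "*", 0, 0, dummy_seq(126),
          "*", "SA:Z:chr1,101,+,75M51S,60,0;", sep = "\t")
  )
}

# proper FR same-chrom pair, insert 300: concordant, must be skipped
concordant_pair_lines <- function(qname = "frag_conc") {
  c(
    paste(qname, 99, "chr1", 1001, 60, "126M", "=", 1175, 300,
          dummy_seq(126), "*", sep = "\t"),
    paste(qname, 147, "chr1", 1175, 60, "126M", "=", 1001, -300,
          dummy_seq(126), "*", sep = "\t")
  )
}

# interchromosomal mate pair chr1/chr7: discordant, both records yielded
interchrom_pair_lines <- function(qname = "frag_inter") {
  c(
    paste(qname, 65, "chr1", 5001, 60, "126M", "chr7", 9001, 0,
          dummy_seq(126), "*", sep = "\t"),
    paste(qname, 129, "chr7", 9001, 60, "126M", "chr1", 5001, 0,
          dummy_seq(126), "*", sep = "\t")
  )
}

# mate A observed, mate B absent from the file
orphan_pair_line <- function(qname = "frag_orphan") {
  paste(qname, 65, "chr2", 7001, 60, "126M", "chr5", 100, 0,
        dummy_seq(126), "*", sep = "\t")
}

fixture_contigs <- c(chr1 = 100000L, chr2 = 100000L, chr5 = 100000L,
                     chr7 = 100000L, chr8 = 100000L)

# direct evidence constructor (post-infer_breakends shape)
make_ev <- function(fragment_id, chromA, posA, sideA, chromB, posB, sideB,
                    category = "split_read", type = "genomic",
                    is_pair = FALSE, uncertA = 0L, uncertB = 0L,
                    startA = posA - 50L, startB = posB - 50L,
                    strandA = "+", strandB = "+") {
  tibble::tibble(
    fragment_id = fragment_id, category = category,
    chromA = chromA, startA = as.integer(startA),
    endA = as.integer(startA + 60L), strandA = strandA, offA = 0L,
    chromB = chromB, startB = as.integer(startB),
    endB = as.integer(startB + 60L), strandB = strandB, offB = 60L,
    posA = as.integer(posA), sideA = sideA, uncertA = as.integer(uncertA),
    posB = as.integer(posB), sideB = sideB, uncertB = as.integer(uncertB),
    precise = !is_pair, is_pair = is_pair, provisional_type = type
  )
}

# n identical split evidences for one junction, distinct fragment ids and
# (by default) distinct start positions
make_ev_stack <- function(n, chromA = "chr1", posA = 174L, sideA = "left",
                          chromB = "chr8", posB = 500L, sideB = "right",
                          type = "splice_like", distinct_starts = TRUE,
                          prefix = "f") {
  purrr::map_dfr(seq_len(n), function(i) {
    make_ev(paste0(prefix, i), chromA, posA, sideA, chromB, posB, sideB,
            type = type,
            startA = if (distinct_starts) posA - 20L - i else posA - 50L,
            startB = if (distinct_starts) posB + i else posB + 3L)
  })
}

# tiny two-gene annotation on one contig; exons of 100 nt spaced by 400-nt
# introns, genes 10 kb apart
toy_models <- function() {
  ex <- function(gid, chrom, strand, starts) {
    tibble::tibble(gene_id = gid, gene_name = gid, chrom = chrom,
                   strand = strand, start = as.integer(starts),
                   end = as.integer(starts + 100L))
  }
  gene_models(dplyr::bind_rows(
    ex("GENEA", "chr1", "+", c(1000, 1500, 2000, 2500)),
    ex("GENEB", "chr1", "+", c(12000, 12500, 13000, 13500))
  ))
}

# reference with a GT..AG context around a constructed junction:
# breakend left at pos 99 (0-based) on chrL (GT at 100,101),
# breakend right at pos 500 on chrR (AG at 498,499)
motif_reference <- function() {
  l <- rep("A", 1000)
  l[101:102] <- c("G", "T")
  r <- rep("C", 1000)
  r[499:500] <- c("A", "G")
  Biostrings::DNAStringSet(c(chrL = paste(l, collapse = ""),
                             chrR = paste(r, collapse = "")))
}

# independent brute-force connected components over edges: quadratic
# pairwise linkage closure, used as the clustering oracle
brute_force_clusters <- function(edges, window) {
  n <- nrow(edges)
  if (n == 0) return(integer(0))
  linked <- function(i, j) {
    share <- function(c1, p1, s1, h1, c2, p2, s2, h2) {
      c1 == c2 && p1 == p2 && s1 == s2 && h1 == h2
    }
    shared <- share(edges$chromA[i], edges$posA[i], edges$sideA[i], edges$h2t[i],
                    edges$chromA[j], edges$posA[j], edges$sideA[j], edges$h2t[j]) ||
      share(edges$chromA[i], edges$posA[i], edges$sideA[i], edges$h2t[i],
            edges$chromB[j], edges$posB[j], edges$sideB[j], edges$h2t[j]) ||
      share(edges$chromB[i], edges$posB[i], edges$sideB[i], edges$h2t[i],
            edges$chromA[j], edges$posA[j], edges$sideA[j], edges$h2t[j]) ||
      share(edges$chromB[i], edges$posB[i], edges$sideB[i], edges$h2t[i],
            edges$chromB[j], edges$posB[j], edges$sideB[j], edges$h2t[j])
    windowed <- edges$chromA[i] == edges$chromA[j] &&
      edges$chromB[i] == edges$chromB[j] &&
      edges$sideA[i] == edges$sideA[j] && edges$sideB[i] == edges$sideB[j] &&
      edges$h2t[i] == edges$h2t[j] &&
      abs(edges$posA[i] - edges$posA[j]) < window &&
      abs(edges$posB[i] - edges$posB[j]) < window
    shared || windowed
  }
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        if (comp[i] != comp[j] && linked(i, j)) {
          comp[comp == comp[j]] <- comp[i]
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  match(comp, unique(comp))
}

# random small evidence set for graph-law property tests
random_evidence <- function(n, n_sites = 6, seed_pos = 1000L) {
  sites <- tibble::tibble(
    chrom = sample(c("chr1", "chr2"), n_sites, replace = TRUE),
    pos = seed_pos + sample.int(5000L, n_sites),
    side = sample(c("left", "right"), n_sites, replace = TRUE)
  )
  purrr::map_dfr(seq_len(n), function(i) {
    ab <- sample.int(n_sites, 2)
    is_pair <- runif(1) < 0.3
    a <- sites[ab[1], ]
    b <- sites[ab[2], ]
    # canonical order
    if (b$chrom < a$chrom || (b$chrom == a$chrom && b$pos < a$pos)) {
      tmp <- a; a <- b; b <- tmp
    }
    make_ev(paste0("r", i), a$chrom, a$pos, a$side, b$chrom, b$pos, b$side,
            category = if (is_pair) "spanning_pair" else "split_read",
            type = sample(c("splice_like", "genomic"), 1),
            is_pair = is_pair,
            uncertA = if (is_pair) 300L else 0L,
            uncertB = if (is_pair) 300L else 0L,
            startA = a$pos - sample.int(60L, 1),
            startB = b$pos + sample.int(60L, 1))
  })
}

small_sim_spec <- function(seed, pre_mrna_fraction = 0.01) {
  sim_spec(n_contigs = 4L, contig_length_nt = 300000L, n_genes = 24L,
           n_events = 10L,
           reads_per_event = c(split = 12L, spanning = 8L),
           noise_reads = 40L, pre_mrna_fraction = pre_mrna_fraction,
           seed = seed)
}
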