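# Deterministic rearrangement/read simulator. Generates a random reference
# with canonical splice motifs baked into every intron, non-overlapping gene
# models, planted rearrangements (deletions, translocations, inversions,
# tandem duplications, back-splices) and a spec-conformant chimeric SAM with
# exact ground truth, emulating rRNA-minus (pre-mRNA-rich) vs poly(A)+
# (spliced-only) libraries. Everything is reproducible under the seed.

#' Simulation specification
#'
#' Defaults emulate the study conditions this package is tested under:
#' 126-nt stranded paired-end reads with 300-600-nt fragments, 20 planted
#' events with 30 split and 20 spanning reads each, 200 noise chimeras, and
#' a pre-mRNA read fraction of 1% (poly(A)+-like; use ~0.35 for an
#' rRNA-minus-like library).
#'
#' @param n_contigs,contig_length_nt Genome shape.
#' @param n_genes,exons_per_gene,exon_length_nt,intron_length_nt Gene models.
#' @param n_events Number of planted rearrangement events.
#' @param event_mix Named proportions over deletion, translocation,
#'   inversion, tandem_duplication, back_splice (must sum to 1).
#' @param reads_per_event Named vector: split and spanning read counts per
#'   event.
#' @param pre_mrna_fraction Probability that a read of an expressed event is
#'   a pre-mRNA (genomic-breakpoint) read rather than a spliced read.
#' @param read_length_nt,insert_min_nt,insert_max_nt Library geometry.
#' @param stranded Stranded library flag.
#' @param noise_reads Number of random-arm noise chimeras.
#' @param min_arm_nt Minimum arm length used when placing the in-read
#'   junction.
#' @param seed Integer seed; the entire simulation is a pure function of
#'   the spec.
#' @return A list of class `fusegraph_sim_spec`.
#' @export
sim_spec <- function(n_contigs = 4L, contig_length_nt = 500000L,
                     n_genes = 48L, exons_per_gene = 5L,
                     exon_length_nt = 160L, intron_length_nt = 700L,
                     n_events = 20L,
                     event_mix = c(deletion = 0.35, translocation = 0.25,
                                   inversion = 0.15,
                                   tandem_duplication = 0.10,
                                   back_splice = 0.15),
                     reads_per_event = c(split = 30L, spanning = 20L),
                     pre_mrna_fraction = 0.01,
                     read_length_nt = 126L,
                     insert_min_nt = 300L, insert_max_nt = 600L,
                     stranded = TRUE, noise_reads = 200L,
                     min_arm_nt = 20L, seed = 1L) {
  stopifnot(abs(sum(event_mix) - 1) < 1e-8,
            all(names(event_mix) %in% c("deletion", "translocation",
                                        "inversion", "tandem_duplication",
                                        "back_splice")),
            pre_mrna_fraction >= 0, pre_mrna_fraction <= 1,
            read_length_nt >= 2 * min_arm_nt,
            insert_max_nt >= insert_min_nt,
            exons_per_gene >= 4)
  spec <- list(
    n_contigs = as.integer(n_contigs),
    contig_length_nt = as.integer(contig_length_nt),
    n_genes = as.integer(n_genes),
    exons_per_gene = as.integer(exons_per_gene),
    exon_length_nt = as.integer(exon_length_nt),
    intron_length_nt = as.integer(intron_length_nt),
    n_events = as.integer(n_events),
    event_mix = event_mix,
    reads_per_event = reads_per_event,
    pre_mrna_fraction = pre_mrna_fraction,
    read_length_nt = as.integer(read_length_nt),
    insert_min_nt = as.integer(insert_min_nt),
    insert_max_nt = as.integer(insert_max_nt),
    stranded = isTRUE(stranded),
    noise_reads = as.integer(noise_reads),
    min_arm_nt = as.integer(min_arm_nt),
    seed = as.integer(seed)
  )
  class(spec) <- "fusegraph_sim_spec"
  spec
}

# deterministic gene layout (no RNG): genes evenly slotted per contig,
# every 4th gene on the minus strand
sim_gene_layout <- function(spec) {
  genes_per_contig <- ceiling(spec$n_genes / spec$n_contigs)
  gene_span <- spec$exons_per_gene * spec$exon_length_nt +
    (spec$exons_per_gene - 1L) * spec$intron_length_nt
  margin <- 10000L
  slot <- (spec$contig_length_nt - 2L * margin) %/% genes_per_contig
  if (slot < gene_span + 1000L) {
    abort("contigs too short for the requested gene layout")
  }
  idx <- seq_len(spec$n_genes)
  contig <- ((idx - 1L) %/% genes_per_contig) + 1L
  slot_i <- (idx - 1L) %% genes_per_contig
  gene_start <- margin + slot_i * slot
  genes <- tibble(
    gene_id = sprintf("g%03d", idx),
    gene_name = sprintf("g%03d", idx),
    chrom = paste0("chr", contig),
    strand = if_else(idx %% 4L == 0L, "-", "+"),
    start = gene_start
  )
  exon_step <- spec$exon_length_nt + spec$intron_length_nt
  exons <- genes |>
    tidyr::crossing(exon = seq_len(spec$exons_per_gene)) |>
    mutate(
      start = .data$start + (.data$exon - 1L) * exon_step,
      end = .data$start + spec$exon_length_nt
    ) |>
    select("gene_id", "gene_name", "chrom", "strand", "exon", "start", "end")
  list(genes = mutate(genes, end = .data$start + gene_span), exons = exons)
}

#' Generate a simulated reference genome
#'
#' Random nucleotide sequence with canonical splice motifs embedded at
#' every generated intron boundary (GT..AG on the plus strand; the genome
#' view CT..AC for minus-strand genes).
#'
#' @param spec A [sim_spec()].
#' @return List with `sequences` (a `DNAStringSet`) and `contig_lengths`
#'   (named integer vector). Deterministic under `spec$seed`.
#' @export
generate_reference <- function(spec) {
  layout <- sim_gene_layout(spec)
  withr::with_seed(spec$seed, {
    seqs <- lapply(seq_len(spec$n_contigs), function(i) {
      sample(c("A", "C", "G", "T"), spec$contig_length_nt, replace = TRUE)
    })
    names(seqs) <- paste0("chr", seq_len(spec$n_contigs))
    introns <- layout$exons |>
      group_by(.data$gene_id) |>
      arrange(.data$exon, .by_group = TRUE) |>
      summarise(
        chrom = first(.data$chrom), strand = first(.data$strand),
        int_start = list(head(.data$end, -1)),
        int_end = list(tail(.data$start, -1)),
        .groups = "drop"
      ) |>
      tidyr::unnest(c("int_start", "int_end"))
    for (i in seq_len(nrow(introns))) {
      ch <- introns$chrom[i]
      s <- introns$int_start[i] # 0-based first intron base
      e <- introns$int_end[i]   # 0-based one-past-last intron base
      if (introns$strand[i] == "+") {
        seqs[[ch]][(s + 1):(s + 2)] <- c("G", "T")
        seqs[[ch]][(e - 1):e] <- c("A", "G")
      } else {
        seqs[[ch]][(s + 1):(s + 2)] <- c("C", "T")
        seqs[[ch]][(e - 1):e] <- c("A", "C")
      }
    }
    dna <- Biostrings::DNAStringSet(vapply(seqs, paste, character(1),
                                           collapse = ""))
    list(
      sequences = dna,
      contig_lengths = setNames(Biostrings::width(dna), names(dna))
    )
  })
}

#' Generate the simulated gene annotation
#'
#' @param spec A [sim_spec()].
#' @param reference Optional output of [generate_reference()]; when given,
#'   exon bounds are validated against contig lengths.
#' @return A `fusegraph_models` object; genes are non-overlapping by
#'   construction.
#' @export
generate_annotation <- function(spec, reference = NULL) {
  layout <- sim_gene_layout(spec)
  if (!is.null(reference)) {
    lens <- reference$contig_lengths[layout$exons$chrom]
    stopifnot(all(layout$exons$end <= lens))
  }
  gene_models(select(layout$exons, -"exon"))
}

#' Write gene models as GTF
#'
#' @param models A `fusegraph_models`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(models, path) {
  ex <- models$exons
  lines <- sprintf(
    paste0("%s\tfusegraph_sim\texon\t%d\t%d\t.\t%s\t.\t",
           "gene_id \"%s\"; gene_name \"%s\"; transcript_id \"%s.t1\";"),
    ex$chrom, ex$start + 1L, ex$end, ex$strand,
    ex$gene_id, ex$gene_name, ex$gene_id
  )
  writeLines(lines, path)
  invisible(path)
}

# lost-side dinucleotide pair test used to keep planted genomic breakpoints
# free of accidental splice motifs
planted_pair_is_motif <- function(ref, chromA, posA, sideA, chromB, posB, sideB) {
  if (!((sideA == "left" & sideB == "right") |
        (sideA == "right" & sideB == "left"))) {
    return(FALSE)
  }
  fake <- tibble(chromA = chromA, posA = posA, sideA = sideA,
                 chromB = chromB, posB = posB, sideB = sideB)
  breakend_pair_has_splice_motif(fake, ref$sequences, strict = FALSE)
}

#' Plant rearrangements and derive the junction ground truth
#'
#' Chooses event genes deterministically under the seed and derives the
#' exact expected junctions: expressed events (deletions, translocations)
#' carry an exonic splice junction between the fused exons plus an intronic
#' genomic breakpoint planted 50-300 nt into the flanking introns;
#' inversions and tandem duplications are genomic-only; back-splices are
#' expressed head-to-tail exon junctions. Genomic breakpoint positions that
#' would by chance form a canonical splice-motif pair are re-drawn.
#'
#' @param spec A [sim_spec()].
#' @param reference Output of [generate_reference()].
#' @param models Output of [generate_annotation()].
#' @return Truth tibble, one row per expected junction (0-based breakends,
#'   canonical order), with event metadata, `kind` (`exonic`/`intronic`),
#'   `circ` geometry flag and, for deletions, the derived-allele length.
#' @export
plant_rearrangements <- function(spec, reference, models) {
  layout <- sim_gene_layout(spec)
  exons <- layout$exons
  plus_genes <- layout$genes |> filter(.data$strand == "+")
  counts <- floor(spec$event_mix * spec$n_events)
  rem <- spec$n_events - sum(counts)
  if (rem > 0) {
    frac <- spec$event_mix * spec$n_events - counts
    bump <- order(-frac, seq_along(frac))[seq_len(rem)]
    counts[bump] <- counts[bump] + 1L
  }
  types <- rep(names(counts), counts)

  withr::with_seed(spec$seed + 1L, {
    pool <- split(plus_genes$gene_id, plus_genes$chrom)
    take_pair_same <- function() {
      for (ch in names(pool)) {
        if (length(pool[[ch]]) >= 2) {
          g <- pool[[ch]][1:2]
          pool[[ch]] <<- pool[[ch]][-(1:2)]
          return(g)
        }
      }
      abort("gene pool exhausted: increase n_genes or reduce n_events")
    }
    take_pair_diff <- function() {
      chs <- names(pool)[vapply(pool, length, integer(1)) >= 1]
      if (length(chs) < 2) abort("gene pool exhausted for translocations")
      g1 <- pool[[chs[1]]][1]
      g2 <- pool[[chs[2]]][1]
      pool[[chs[1]]] <<- pool[[chs[1]]][-1]
      pool[[chs[2]]] <<- pool[[chs[2]]][-1]
      c(g1, g2)
    }
    take_single <- function() {
      chs <- names(pool)[vapply(pool, length, integer(1)) >= 1]
      if (length(chs) < 1) abort("gene pool exhausted for single-gene events")
      ch <- chs[length(chs)]
      g <- pool[[ch]][length(pool[[ch]])]
      pool[[ch]] <<- head(pool[[ch]], -1)
      g
    }
    gene_exons <- function(g) filter(exons, .data$gene_id == g)
    # draw an intronic position `delta` nt beyond a donor exon end (side
    # left) or before an acceptor exon start (side right); redraw while the
    # resulting pair would read as a splice motif
    draw_delta <- function() sample(50:300, 1)

    rows <- list()
    for (k in seq_along(types)) {
      ty <- types[k]
      ev <- sprintf("ev%02d", k)
      if (ty %in% c("deletion", "translocation")) {
        gg <- if (ty == "deletion") take_pair_same() else take_pair_diff()
        exA <- gene_exons(gg[1])
        exB <- gene_exons(gg[2])
        i <- sample(2:(spec$exons_per_gene - 1), 1)
        j <- sample(2:(spec$exons_per_gene - 1), 1)
        donor_end <- exA$end[i] - 1L       # last base of donor exon i
        acceptor_start <- exB$start[j]     # first base of acceptor exon j
        repeat {
          bpA <- donor_end + draw_delta()
          bpB <- acceptor_start - draw_delta()
          if (!planted_pair_is_motif(reference, exA$chrom[1], bpA, "left",
                                     exB$chrom[1], bpB, "right")) break
        }
        exonic <- tibble(event_id = ev, event_type = ty, kind = "exonic",
                         chromA = exA$chrom[1], posA = donor_end, sideA = "left",
                         chromB = exB$chrom[1], posB = acceptor_start,
                         sideB = "right",
                         geneA = gg[1], geneB = gg[2], circ = FALSE,
                         expressed = TRUE,
                         splice_chain = paste0(gg[1], ":1-", i, "|", gg[2],
                                               ":", j, "-", spec$exons_per_gene))
        intronic <- exonic |>
          mutate(kind = "intronic", posA = bpA, posB = bpB)
        if (ty == "deletion") {
          deleted <- bpB - bpA - 1L
          exonic$derived_length <- intronic$derived_length <-
            spec$contig_length_nt - deleted
        } else {
          exonic$derived_length <- intronic$derived_length <- NA_integer_
        }
        rows <- c(rows, list(exonic, intronic))
      } else if (ty == "inversion") {
        g <- take_single()
        exG <- gene_exons(g)
        ii <- sort(sample(seq_len(spec$exons_per_gene - 1L), 2))
        repeat {
          bpA <- exG$end[ii[1]] - 1L + draw_delta()
          bpB <- exG$end[ii[2]] - 1L + draw_delta()
          if (bpB - bpA > 2L * spec$read_length_nt) break
        }
        rows <- c(rows, list(tibble(
          event_id = ev, event_type = ty, kind = "intronic",
          chromA = exG$chrom[1], posA = bpA, sideA = "left",
          chromB = exG$chrom[1], posB = bpB, sideB = "left",
          geneA = g, geneB = g, circ = FALSE, expressed = FALSE,
          splice_chain = NA_character_, derived_length = NA_integer_
        )))
      } else if (ty == "tandem_duplication") {
        g <- take_single()
        exG <- gene_exons(g)
        repeat {
          bpA <- exG$end[1] - 1L + draw_delta()   # duplicated span start
          bpB <- exG$end[spec$exons_per_gene - 1L] - 1L + draw_delta()
          if (!planted_pair_is_motif(reference, exG$chrom[1], bpA, "right",
                                     exG$chrom[1], bpB, "left")) break
        }
        rows <- c(rows, list(tibble(
          event_id = ev, event_type = ty, kind = "intronic",
          chromA = exG$chrom[1], posA = bpA, sideA = "right",
          chromB = exG$chrom[1], posB = bpB, sideB = "left",
          geneA = g, geneB = g, circ = TRUE, expressed = FALSE,
          splice_chain = NA_character_, derived_length = NA_integer_
        )))
      } else if (ty == "back_splice") {
        g <- take_single()
        exG <- gene_exons(g)
        i <- 2L
        j <- sample((i + 1L):(spec$exons_per_gene - 1L), 1)
        rows <- c(rows, list(tibble(
          event_id = ev, event_type = ty, kind = "exonic",
          chromA = exG$chrom[1], posA = exG$start[i], sideA = "right",
          chromB = exG$chrom[1], posB = exG$end[j] - 1L, sideB = "left",
          geneA = g, geneB = g, circ = TRUE, expressed = TRUE,
          splice_chain = paste0(g, ":", i, "-", j, " (circular)"),
          derived_length = NA_integer_
        )))
      }
    }
    truths <- bind_rows(rows)
    # canonical ordering of the breakend pair
    swap <- truths$chromB < truths$chromA |
      (truths$chromB == truths$chromA & truths$posB < truths$posA)
    if (any(swap)) {
      tmp <- truths[swap, c("chromA", "posA", "sideA")]
      truths[swap, c("chromA", "posA", "sideA")] <-
        truths[swap, c("chromB", "posB", "sideB")]
      truths[swap, c("chromB", "posB", "sideB")] <- tmp
    }
    truths
  })
}

#' Back-splice catalogue implied by the planted truth
#'
#' @param truths Truth tibble from [plant_rearrangements()].
#' @return Catalogue tibble (chrom, start, end, strand; 0-based half-open),
#'   one entry per planted back-splice.
#' @export
circ_catalogue_from_truth <- function(truths) {
  truths |>
    filter(.data$event_type == "back_splice") |>
    mutate(chrom = .data$chromA, start = .data$posA, end = .data$posB + 1L,
           strand = "+") |>
    select("chrom", "start", "end", "strand")
}

ref_subseq <- function(ref, chrom, start0, len) {
  as.character(Biostrings::subseq(ref$sequences[[chrom]], start0 + 1L,
                                  start0 + len))
}

revcomp_chr <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# one split read across a junction; returns two SAM lines
split_read_sam <- function(ref, qname, chromA, posA, sideA, chromB, posB,
                           sideB, u, read_len) {
  arm <- function(chrom, pos, side, len, first_in_read) {
    # an arm retains `len` bases on the breakend's retained side; its strand
    # follows from which read end touches the junction
    if (side == "left") {
      start <- pos + 1L - len
      strand <- if (first_in_read) "+" else "-"
    } else {
      start <- pos
      strand <- if (first_in_read) "-" else "+"
    }
    list(chrom = chrom, start = start, len = len, strand = strand)
  }
  len2 <- read_len - u
  if (sideA == "left") {
    a1 <- arm(chromA, posA, "left", u, TRUE)
    a2 <- arm(chromB, posB, sideB, len2, FALSE)
  } else if (sideB == "left") {
    a1 <- arm(chromB, posB, "left", u, TRUE)
    a2 <- arm(chromA, posA, sideA, len2, FALSE)
  } else {
    # right/right join: first arm reverse-complemented
    a1 <- arm(chromA, posA, "right", u, FALSE)
    a1$strand <- "-"
    a2 <- arm(chromB, posB, "right", len2, FALSE)
  }
  seq1 <- ref_subseq(ref, a1$chrom, a1$start, a1$len)
  seq2 <- ref_subseq(ref, a2$chrom, a2$start, a2$len)
  read_seq <- paste0(if (a1$strand == "+") seq1 else revcomp_chr(seq1),
                     if (a2$strand == "+") seq2 else revcomp_chr(seq2))
  rec <- function(a, off, is_supp) {
    clip_l <- if (a$strand == "+") off else read_len - off - a$len
    clip_r <- read_len - clip_l - a$len
    cig <- paste0(if (clip_l > 0) paste0(clip_l, "S") else "",
                  a$len, "M",
                  if (clip_r > 0) paste0(clip_r, "S") else "")
    flag <- (if (a$strand == "-") 16L else 0L) + (if (is_supp) 2048L else 0L)
    seq_out <- if (a$strand == "+") read_seq else revcomp_chr(read_seq)
    list(chrom = a$chrom, pos1 = a$start + 1L, strand = a$strand,
         cigar = cig, flag = flag, seq = seq_out)
  }
  r1 <- rec(a1, 0L, FALSE)
  r2 <- rec(a2, u, TRUE)
  sa <- function(r) paste0(r$chrom, ",", r$pos1, ",", r$strand, ",",
                           r$cigar, ",60,0;")
  line <- function(r, other) {
    paste(qname, r$flag, r$chrom, r$pos1, 60, r$cigar, "*", 0, 0,
          r$seq, "*", paste0("SA:Z:", sa(other)), sep = "\t")
  }
  c(line(r1, r2), line(r2, r1))
}

# one discordant spanning pair flanking a junction; returns two SAM lines
spanning_pair_sam <- function(ref, qname, chromA, posA, sideA, chromB, posB,
                              sideB, g1, g2, read_len) {
  mate <- function(chrom, pos, side, gap) {
    if (side == "left") {
      list(chrom = chrom, start = pos - gap - read_len + 1L, strand = "+")
    } else {
      list(chrom = chrom, start = pos + gap, strand = "-")
    }
  }
  m1 <- mate(chromA, posA, sideA, g1)
  m2 <- mate(chromB, posB, sideB, g2)
  tlen <- 0L
  if (m1$chrom == m2$chrom) {
    lo <- min(m1$start, m2$start)
    hi <- max(m1$start, m2$start) + read_len
    tlen <- hi - lo
  }
  line <- function(m, o, first, tl) {
    flag <- 1L + (if (first) 64L else 128L) +
      (if (m$strand == "-") 16L else 0L) + (if (o$strand == "-") 32L else 0L)
    s <- ref_subseq(ref, m$chrom, m$start, read_len)
    if (m$strand == "-") s <- revcomp_chr(s)
    rnext <- if (o$chrom == m$chrom) "=" else o$chrom
    paste(qname, flag, m$chrom, m$start + 1L, 60,
          paste0(read_len, "M"), rnext, o$start + 1L, tl, s, "*", sep = "\t")
  }
  c(line(m1, m2, TRUE, tlen), line(m2, m1, FALSE, -tlen))
}

#' Simulate chimeric alignments for the planted truth
#'
#' Emits spliced split reads across exonic junctions, genomic-breakpoint
#' split reads and discordant spanning pairs, and uniform random-arm noise
#' chimeras, as spec-conformant SAM with `SA` cross-reference tags. For
#' expressed events each read is a pre-mRNA (genomic-breakpoint) read with
#' probability `pre_mrna_fraction`, else a spliced read. Byte-identical
#' output under a fixed seed.
#'
#' @param truths Truth tibble from [plant_rearrangements()].
#' @param spec A [sim_spec()].
#' @param reference Output of [generate_reference()].
#' @param path Output SAM path.
#' @return The truth tibble with `n_split_planted` and `n_spanning_planted`
#'   filled in; attribute `sam` holds the path.
#' @export
simulate_alignments <- function(truths, spec, reference, path) {
  read_len <- spec$read_length_nt
  if (read_len < 2L * spec$min_arm_nt) {
    abort("read length too short for two minimum-length arms")
  }
  withr::with_seed(spec$seed + 2L, {
    header <- c("@HD\tVN:1.6\tSO:unsorted",
                sprintf("@SQ\tSN:%s\tLN:%d", names(reference$contig_lengths),
                        reference$contig_lengths))
    lines <- list(header)
    truths$n_split_planted <- 0L
    truths$n_spanning_planted <- 0L
    n_split <- spec$reads_per_event[["split"]]
    n_span <- spec$reads_per_event[["spanning"]]
    draw_u <- function() {
      sample(spec$min_arm_nt:(read_len - spec$min_arm_nt), 1)
    }
    draw_gaps <- function() {
      insert <- runif(1, max(spec$insert_min_nt, 2 * read_len + 40),
                      spec$insert_max_nt)
      total <- max(0L, as.integer(round(insert)) - 2L * read_len)
      g1 <- sample.int(total + 1L, 1) - 1L
      c(g1, total - g1)
    }
    for (ev in unique(truths$event_id)) {
      rows <- which(truths$event_id == ev)
      expressed <- truths$expressed[rows[1]]
      kinds <- truths$kind[rows]
      pick_row <- function() {
        if (!expressed || length(rows) == 1) return(rows[1])
        if (runif(1) < spec$pre_mrna_fraction) {
          rows[kinds == "intronic"]
        } else {
          rows[kinds == "exonic"]
        }
      }
      for (k in seq_len(n_split)) {
        r <- pick_row()
        tr <- truths[r, ]
        lines[[length(lines) + 1]] <- split_read_sam(
          reference, sprintf("%s_s%03d", ev, k),
          tr$chromA, tr$posA, tr$sideA, tr$chromB, tr$posB, tr$sideB,
          draw_u(), read_len
        )
        truths$n_split_planted[r] <- truths$n_split_planted[r] + 1L
      }
      for (k in seq_len(n_span)) {
        r <- pick_row()
        tr <- truths[r, ]
        g <- draw_gaps()
        lines[[length(lines) + 1]] <- spanning_pair_sam(
          reference, sprintf("%s_p%03d", ev, k),
          tr$chromA, tr$posA, tr$sideA, tr$chromB, tr$posB, tr$sideB,
          g[1], g[2], read_len
        )
        truths$n_spanning_planted[r] <- truths$n_spanning_planted[r] + 1L
      }
    }
    # noise: uniform random-arm chimeras (mapping-ambiguity surrogate)
    chroms <- names(reference$contig_lengths)
    for (k in seq_len(spec$noise_reads)) {
      u <- draw_u()
      ca <- sample(chroms, 1)
      cb <- sample(chroms, 1)
      pa <- sample.int(reference$contig_lengths[[ca]] - 2L * read_len, 1) +
        read_len
      pb <- sample.int(reference$contig_lengths[[cb]] - 2L * read_len, 1) +
        read_len
      lines[[length(lines) + 1]] <- split_read_sam(
        reference, sprintf("noise_%04d", k),
        ca, pa, "left", cb, pb, "right", u, read_len
      )
    }
    writeLines(unlist(lines), path)
  })
  attr(truths, "sam") <- path
  truths
}

#' Run the full simulation, writing all artefacts
#'
#' Convenience wrapper: reference FASTA, GTF, chimeric SAM, truth table and
#' back-splice catalogue in `dir`.
#'
#' @param spec A [sim_spec()].
#' @param dir Output directory (created if needed).
#' @return List with `spec`, `reference`, `models`, `truths`, `catalogue`
#'   and the file `paths`.
#' @export
simulate_run <- function(spec = sim_spec(), dir = tempfile("fusegraph_sim_")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  reference <- generate_reference(spec)
  models <- generate_annotation(spec, reference)
  truths <- plant_rearrangements(spec, reference, models)
  paths <- list(
    fasta = file.path(dir, "reference.fa"),
    gtf = file.path(dir, "annotation.gtf"),
    sam = file.path(dir, "chimeric.sam"),
    truth = file.path(dir, "truth.tsv"),
    circ = file.path(dir, "circ_catalogue.tsv")
  )
  Biostrings::writeXStringSet(reference$sequences, paths$fasta)
  write_gtf(models, paths$gtf)
  truths <- simulate_alignments(truths, spec, reference, paths$sam)
  utils::write.table(truths, paths$truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  catalogue <- circ_catalogue_from_truth(truths)
  utils::write.table(catalogue, paths$circ, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  list(spec = spec, reference = reference, models = models, truths = truths,
       catalogue = catalogue, paths = paths)
}

#' Score junction calls against the planted truth
#'
#' A passing call is a true positive iff it matches a truth junction with
#' both sides within `window_nt` (the cross-assay matching rule).
#' Classification accuracy is computed over matched calls against the truth
#' `kind`. Truth junctions with fewer planted reads than
#' `min_planted_reads` are not expected to be recoverable and are excluded
#' from recall.
#'
#' A detectable truth junction that is not matched directly may still have
#' its (marginal) read support legitimately merged into a closely adjacent
#' (< `merge_window_nt`) passing junction of the same orientation -- the
#' behaviour real detectors show when a weakly covered genomic breakpoint
#' sits next to a dominant splice junction. Such truths are counted as
#' `n_absorbed` and credited to recall.
#'
#' @param calls Junction-call tibble (only passing calls are scored).
#' @param truths Truth tibble with planted read counts.
#' @param window_nt Matching window (default 40 nt).
#' @param min_planted_reads Detectability floor (default 2).
#' @param merge_window_nt Window within which an unmatched truth counts as
#'   absorbed by an adjacent passing call (default 450).
#' @return One-row tibble: counts, precision, recall (matched + absorbed
#'   over detectable), classification accuracy over matched calls and the
#'   fraction of matches with exact (0-nt) breakpoints.
#' @export
score_against_truth <- function(calls, truths, window_nt = 40L,
                                min_planted_reads = 2L,
                                merge_window_nt = 450L) {
  if ("filter_status" %in% names(calls)) calls <- passing_junctions(calls)
  detectable <- truths |>
    filter(.data$n_split_planted + .data$n_spanning_planted >=
             min_planted_reads)
  mp <- match_params(window_nt = window_nt, exclude_head_to_tail = FALSE,
                     exclude_alt_loci = FALSE)
  m <- match_junction_sets(calls, detectable, mp)
  tp <- nrow(m$matched)
  n_calls <- nrow(calls)
  n_truth <- nrow(detectable)
  # unmatched truths absorbed by an adjacent passing junction
  absorbed <- 0L
  if (nrow(m$b_only) > 0 && n_calls > 0) {
    for (i in seq_len(nrow(m$b_only))) {
      b <- m$b_only[i, ]
      hit <- calls$chromA == b$chromA & calls$chromB == b$chromB &
        calls$sideA == b$sideA & calls$sideB == b$sideB &
        abs(calls$posA - b$posA) < merge_window_nt &
        abs(calls$posB - b$posB) < merge_window_nt
      if (any(hit)) absorbed <- absorbed + 1L
    }
  }
  acc <- NA_real_
  exact <- NA_real_
  if (tp > 0 && "classification" %in% names(calls)) {
    acc <- mean(m$a$classification[m$matched$index_a] ==
                  m$b$kind[m$matched$index_b])
    exact <- mean(m$matched$dist_a == 0 & m$matched$dist_b == 0)
  }
  tibble(
    n_calls = n_calls, n_truth = n_truth, n_matched = tp,
    n_absorbed = absorbed,
    precision = if (n_calls > 0) tp / n_calls else NaN,
    recall = if (n_truth > 0) (tp + absorbed) / n_truth else NaN,
    classification_accuracy = acc,
    exact_fraction = exact
  )
}
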