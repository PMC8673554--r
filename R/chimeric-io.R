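# Reading chimeric/discordant alignments and reconstructing per-fragment
# evidence (arm pairs -> breakends). Built on Rsamtools/GenomicAlignments;
# the geometry rules (which flank a breakend retains, head-to-tail tests,
# split-read junction bases) are implemented here.

FLAG_PAIRED <- 0x1L
FLAG_UNMAPPED <- 0x4L
FLAG_MATE_UNMAPPED <- 0x8L
FLAG_REVERSE <- 0x10L
FLAG_MATE_REVERSE <- 0x20L
FLAG_FIRST <- 0x40L
FLAG_SUPPLEMENTARY <- 0x800L

cigar_clips <- function(cigar) {
  ops <- GenomicAlignments::explodeCigarOps(cigar)
  lens <- GenomicAlignments::explodeCigarOpLengths(cigar)
  clip_one <- function(op, len, from_end = FALSE) {
    if (from_end) {
      op <- rev(op)
      len <- rev(len)
    }
    total <- 0L
    for (i in seq_along(op)) {
      if (op[i] %in% c("S", "H")) total <- total + len[i] else break
    }
    total
  }
  tibble(
    clip_left = purrr::map2_int(ops, lens, ~ clip_one(.x, .y, FALSE)),
    clip_right = purrr::map2_int(ops, lens, ~ clip_one(.x, .y, TRUE))
  )
}

#' Read chimeric/discordant alignment records
#'
#' Streams a SAM or BAM file and keeps only records carrying chimeric or
#' discordant signal: supplementary alignments (flag 0x800), records with an
#' `SA` split-alignment tag, and paired records whose mate maps to a
#' different chromosome, in the same orientation, or beyond the expected
#' insert size. Concordant records are skipped.
#'
#' @param path Path to a SAM or BAM file. SAM input is converted on the fly.
#' @param region Optional `GRanges` of length 1 restricting the query; the
#'   file must then be coordinate-sorted and indexed.
#' @param layout A [library_layout()].
#' @return A tibble of raw records (0-based `pos`), one row per alignment
#'   record, with an attribute `counters` holding per-file totals.
#' @export
read_chimeric_records <- function(path, region = NULL, layout = library_layout()) {
  if (!file.exists(path)) {
    abort(paste0("alignment file not found: ", path))
  }
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(path, destination = dest,
                            overwrite = TRUE, indexDestination = TRUE)
  }
  param_args <- list(
    what = c("qname", "flag", "rname", "strand", "pos", "cigar",
             "mrnm", "mpos", "isize"),
    tag = "SA",
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE)
  )
  if (!is.null(region)) {
    idx <- paste0(bam, ".bai")
    if (!file.exists(idx)) {
      abort(paste0("region query requires a BAM index; missing: ", idx))
    }
    param_args$which <- region
  }
  res <- Rsamtools::scanBam(bam, param = do.call(Rsamtools::ScanBamParam, param_args))
  res <- res[[1]]
  if (length(res$qname) == 0) {
    rec <- empty_record_tibble()
    attr(rec, "counters") <- list(total = 0L, chimeric = 0L)
    return(rec)
  }
  flag <- as.integer(res$flag)
  sa <- res$tag$SA
  if (is.null(sa)) sa <- rep(NA_character_, length(flag))
  rec <- tibble(
    qname = res$qname,
    flag = flag,
    chrom = as.character(res$rname),
    pos = as.integer(res$pos) - 1L,
    strand = if_else(bitwAnd(flag, FLAG_REVERSE) > 0L, "-", "+"),
    cigar = res$cigar,
    mate_chrom = as.character(res$mrnm),
    mate_pos = as.integer(res$mpos) - 1L,
    isize = as.integer(res$isize),
    sa = sa,
    is_paired = bitwAnd(flag, FLAG_PAIRED) > 0L,
    is_first = bitwAnd(flag, FLAG_FIRST) > 0L,
    is_supp = bitwAnd(flag, FLAG_SUPPLEMENTARY) > 0L,
    mate_strand = if_else(bitwAnd(flag, FLAG_MATE_REVERSE) > 0L, "-", "+"),
    mate_mapped = !(bitwAnd(flag, FLAG_MATE_UNMAPPED) > 0L)
  )
  total <- nrow(rec)
  chimeric <- rec$is_supp | !is.na(rec$sa)
  pair_discordant <- rec$is_paired & rec$mate_mapped & !is.na(rec$mate_chrom) & (
    rec$mate_chrom != rec$chrom |
      rec$strand == rec$mate_strand |
      abs(dplyr::coalesce(rec$isize, 0L)) > layout$expected_insert_max_nt
  )
  rec <- rec[chimeric | pair_discordant, , drop = FALSE]
  attr(rec, "counters") <- list(total = total, chimeric = nrow(rec))
  rec
}

empty_record_tibble <- function() {
  tibble(
    qname = character(), flag = integer(), chrom = character(),
    pos = integer(), strand = character(), cigar = character(),
    mate_chrom = character(), mate_pos = integer(), isize = integer(),
    sa = character(), is_paired = logical(), is_first = logical(),
    is_supp = logical(), mate_strand = character(), mate_mapped = logical()
  )
}

empty_evidence_tibble <- function() {
  tibble(
    fragment_id = character(), category = character(),
    chromA = character(), startA = integer(), endA = integer(),
    strandA = character(), offA = integer(),
    chromB = character(), startB = integer(), endB = integer(),
    strandB = character(), offB = integer(),
    posA = integer(), sideA = character(), uncertA = integer(),
    posB = integer(), sideB = character(), uncertB = integer(),
    precise = logical(), is_pair = logical(),
    provisional_type = character()
  )
}

#' Reconstruct per-fragment evidence from chimeric records
#'
#' Groups records by fragment (and mate, for paired split reads), pairs the
#' arms of split alignments via the `SA` cross-reference, and pairs
#' discordant mates into spanning evidence. Fragments with more than two
#' chimeric segments are decomposed into adjacent-in-read arm pairs;
#' fragments whose partner arm never appears are dropped and counted as
#' orphans; fragments with primary-record name collisions are dropped as
#' malformed.
#'
#' @param records A record tibble from [read_chimeric_records()].
#' @param layout A [library_layout()].
#' @param min_arm_nt Minimum aligned arm length for split evidence
#'   (default 20 nt); shorter arms are dropped.
#' @return An evidence tibble (one row per arm pair), canonically ordered,
#'   with a `counters` attribute (`fragments`, `emitted`, `orphaned`,
#'   `malformed`, `short_arm`).
#' @export
pair_read_fragments <- function(records, layout = library_layout(),
                                min_arm_nt = 20L) {
  counters <- list(fragments = 0L, emitted = 0L, orphaned = 0L,
                   malformed = 0L, short_arm = 0L)
  if (nrow(records) == 0) {
    ev <- empty_evidence_tibble()
    attr(ev, "counters") <- counters
    return(ev)
  }
  rec <- records
  clips <- cigar_clips(rec$cigar)
  rec$clip_left <- clips$clip_left
  rec$clip_right <- clips$clip_right
  rec$ref_width <- GenomicAlignments::cigarWidthAlongReferenceSpace(rec$cigar)
  rec$end <- rec$pos + rec$ref_width
  rec$read_off <- if_else(rec$strand == "+", rec$clip_left, rec$clip_right)
  # read unit: a single sequenced read (mate) is the unit carrying a split
  rec$read_id <- paste0(rec$qname, "/", if_else(rec$is_paired & !rec$is_first, "2", "1"))

  counters$fragments <- dplyr::n_distinct(rec$qname)

  # malformed: several primary (non-supplementary) records for one read unit
  prim_counts <- rec |>
    filter(!.data$is_supp) |>
    count(.data$read_id, name = "n_primary")
  bad_reads <- prim_counts$read_id[prim_counts$n_primary > 1]
  bad_frags <- unique(sub("/[12]$", "", bad_reads))
  counters$malformed <- length(bad_frags)
  rec <- rec[!(sub("/[12]$", "", rec$read_id) %in% bad_frags), , drop = FALSE]

  arm_cols <- c("chrom", "pos", "end", "strand", "read_off")

  # --- split evidence: >= 2 segments of one read unit, adjacent in read ---
  seg_counts <- count(rec, .data$read_id, name = "n_seg")
  split_reads <- seg_counts$read_id[seg_counts$n_seg >= 2]
  split_ev <- NULL
  # records announcing a split (SA tag or supplementary flag) whose partner
  # segment is absent from the stream are orphans
  lonely <- rec |>
    filter(!(.data$read_id %in% split_reads), !is.na(.data$sa) | .data$is_supp)
  orphan_split <- dplyr::n_distinct(lonely$qname)
  if (length(split_reads) > 0) {
    segs <- rec |>
      filter(.data$read_id %in% split_reads) |>
      arrange(.data$read_id, .data$read_off, .data$chrom, .data$pos)
    split_ev <- segs |>
      group_by(.data$read_id) |>
      summarise(
        fragment_id = first(.data$qname),
        n_seg = n(),
        arms = list(dplyr::pick(dplyr::all_of(arm_cols))),
        .groups = "drop"
      ) |>
      mutate(pairs = purrr::map(.data$arms, function(a) {
        k <- nrow(a)
        tibble(
          chromA = a$chrom[-k], startA = a$pos[-k], endA = a$end[-k],
          strandA = a$strand[-k], offA = a$read_off[-k],
          chromB = a$chrom[-1], startB = a$pos[-1], endB = a$end[-1],
          strandB = a$strand[-1], offB = a$read_off[-1]
        )
      })) |>
      select("fragment_id", "pairs") |>
      tidyr::unnest("pairs") |>
      mutate(is_pair = FALSE)
  }

  # --- spanning evidence: discordant mate pairs with no split segments ---
  pair_rec <- rec |>
    filter(.data$is_paired, !.data$is_supp, is.na(.data$sa))
  # exclude read units that already produced split evidence
  pair_rec <- pair_rec[!(pair_rec$read_id %in% split_reads), , drop = FALSE]
  mate_counts <- count(pair_rec, .data$qname, name = "n_mates")
  paired_ok <- mate_counts$qname[mate_counts$n_mates == 2]
  orphan_pairs <- sum(mate_counts$n_mates == 1)
  span_ev <- NULL
  if (length(paired_ok) > 0) {
    span_ev <- pair_rec |>
      filter(.data$qname %in% paired_ok) |>
      arrange(.data$qname, dplyr::desc(.data$is_first)) |>
      group_by(.data$qname) |>
      summarise(
        chromA = .data$chrom[1], startA = .data$pos[1], endA = .data$end[1],
        strandA = .data$strand[1], offA = 0L,
        chromB = .data$chrom[2], startB = .data$pos[2], endB = .data$end[2],
        strandB = .data$strand[2], offB = 1L,
        .groups = "drop"
      ) |>
      rename(fragment_id = "qname") |>
      mutate(is_pair = TRUE)
  }

  ev <- bind_rows(split_ev, span_ev)
  counters$orphaned <- orphan_split + orphan_pairs
  if (is.null(ev) || nrow(ev) == 0) {
    ev <- empty_evidence_tibble()
    attr(ev, "counters") <- counters
    return(ev)
  }

  # per-arm floor for split evidence: short aligned arms are unreliable
  short <- !ev$is_pair &
    (ev$endA - ev$startA < min_arm_nt | ev$endB - ev$startB < min_arm_nt)
  counters$short_arm <- sum(short)
  ev <- ev[!short, , drop = FALSE]
  counters$emitted <- nrow(ev)
  ev <- ev |>
    mutate(category = NA_character_, provisional_type = NA_character_)
  attr(ev, "counters") <- counters
  ev
}

#' Derive breakends from evidence arms
#'
#' For split reads, the breakend is the last aligned base on the retained
#' side of each arm, at base precision. For spanning pairs, each breakend is
#' the junction-facing bound of the mate's aligned interval, carrying an
#' uncertainty of up to the expected insert size. Breakends are then put in
#' canonical order (lexicographic by chromosome, then position).
#'
#' @param evidence Evidence tibble from [pair_read_fragments()].
#' @param layout A [library_layout()].
#' @return The evidence tibble with `posA/sideA/uncertA`, `posB/sideB/uncertB`
#'   and `precise` columns filled in, sorted canonically.
#' @export
infer_breakends <- function(evidence, layout = library_layout()) {
  if (nrow(evidence) == 0) return(evidence)
  ev <- evidence
  split <- !ev$is_pair
  # earlier-in-read arm: junction at its read-later end
  a_first <- ev$offA <= ev$offB
  # helper: breakend of an arm given whether the junction is at the
  # read-later end of the arm (later = TRUE) and the arm's strand
  arm_breakend <- function(start, end, strand, later) {
    pos <- integer(length(start))
    side <- character(length(start))
    at_right <- (later & strand == "+") | (!later & strand == "-")
    pos[at_right] <- end[at_right] - 1L
    side[at_right] <- "left"
    pos[!at_right] <- start[!at_right]
    side[!at_right] <- "right"
    list(pos = pos, side = side)
  }
  beA <- beB <- list(pos = integer(nrow(ev)), side = character(nrow(ev)))
  if (any(split)) {
    a <- arm_breakend(ev$startA[split], ev$endA[split], ev$strandA[split],
                      later = a_first[split])
    b <- arm_breakend(ev$startB[split], ev$endB[split], ev$strandB[split],
                      later = !a_first[split])
    beA$pos[split] <- a$pos; beA$side[split] <- a$side
    beB$pos[split] <- b$pos; beB$side[split] <- b$side
  }
  if (any(ev$is_pair)) {
    p <- ev$is_pair
    # a mate points toward the junction: + strand faces right (side left
    # retained), - strand faces left (side right retained)
    beA$pos[p] <- if_else(ev$strandA[p] == "+", ev$endA[p] - 1L, ev$startA[p])
    beA$side[p] <- if_else(ev$strandA[p] == "+", "left", "right")
    beB$pos[p] <- if_else(ev$strandB[p] == "+", ev$endB[p] - 1L, ev$startB[p])
    beB$side[p] <- if_else(ev$strandB[p] == "+", "left", "right")
  }
  ev$posA <- beA$pos; ev$sideA <- beA$side
  ev$posB <- beB$pos; ev$sideB <- beB$side
  arm_len_A <- ev$endA - ev$startA
  arm_len_B <- ev$endB - ev$startB
  ev$uncertA <- if_else(ev$is_pair,
                        pmax(0L, layout$expected_insert_max_nt - arm_len_A), 0L)
  ev$uncertB <- if_else(ev$is_pair,
                        pmax(0L, layout$expected_insert_max_nt - arm_len_B), 0L)
  ev$precise <- !ev$is_pair
  canonicalize_evidence(ev) |>
    arrange(.data$chromA, .data$posA, .data$chromB, .data$posB, .data$fragment_id)
}

# swap A/B columns where (chromB,posB) precedes (chromA,posA)
canonicalize_evidence <- function(ev) {
  swap <- ev$chromB < ev$chromA | (ev$chromB == ev$chromA & ev$posB < ev$posA)
  if (!any(swap)) return(ev)
  acols <- c("chromA", "startA", "endA", "strandA", "offA", "posA", "sideA", "uncertA")
  bcols <- c("chromB", "startB", "endB", "strandB", "offB", "posB", "sideB", "uncertB")
  tmp <- ev[swap, acols]
  ev[swap, acols] <- ev[swap, bcols]
  ev[swap, bcols] <- tmp
  ev
}

#' Classify evidence category and provisional junction type
#'
#' Assigns the evidence category (`split_read`, `spanning_pair`, or
#' `head_to_tail_split`) and a provisional type. A split is head-to-tail when
#' both arms map to one chromosome and strand and the arm later in the read
#' maps upstream of (or overlapping) the earlier arm -- the back-splice /
#' tandem-duplication signature. The provisional type is `splice_like` when
#' the junction is base-precise and its flanks read as a canonical splice
#' motif on the reference, or both breakends sit on annotated exon
#' boundaries; otherwise `genomic`.
#'
#' @param evidence Evidence tibble with breakends ([infer_breakends()]).
#' @param layout A [library_layout()].
#' @param reference Optional reference: a `DNAStringSet` or FASTA path, used
#'   for splice-motif checks.
#' @param gene_models Optional gene models ([read_gene_models()]) used for
#'   exon-boundary checks.
#' @param strict_motifs If TRUE only GT..AG is accepted; otherwise GC..AG and
#'   AT..AC are accepted too.
#' @return The evidence tibble with `category` and `provisional_type` set.
#' @export
classify_evidence <- function(evidence, layout = library_layout(),
                              reference = NULL, gene_models = NULL,
                              strict_motifs = FALSE) {
  if (nrow(evidence) == 0) return(evidence)
  ev <- evidence
  later_is_A <- ev$offA > ev$offB
  st_later <- if_else(later_is_A, ev$startA, ev$startB)
  en_later <- if_else(later_is_A, ev$endA, ev$endB)
  st_earlier <- if_else(later_is_A, ev$startB, ev$startA)
  en_earlier <- if_else(later_is_A, ev$endB, ev$endA)
  same_cs <- ev$chromA == ev$chromB & ev$strandA == ev$strandB
  h2t <- !ev$is_pair & same_cs & (
    (ev$strandA == "+" & st_later < en_earlier) |
      (ev$strandA == "-" & en_later > st_earlier)
  )
  ev$category <- dplyr::case_when(
    ev$is_pair ~ "spanning_pair",
    h2t ~ "head_to_tail_split",
    TRUE ~ "split_read"
  )
  splice <- rep(FALSE, nrow(ev))
  base_precise <- !ev$is_pair
  if (!is.null(gene_models) && any(base_precise)) {
    splice[base_precise] <- splice[base_precise] |
      breakend_pair_on_exon_boundary(ev[base_precise, ], gene_models,
                                     tol = 2L, stranded = layout$stranded)
  }
  if (!is.null(reference) && any(base_precise & !splice)) {
    idx <- which(base_precise & !splice)
    splice[idx] <- breakend_pair_has_splice_motif(ev[idx, ],
                                                  load_reference(reference),
                                                  strict = strict_motifs)
  }
  ev$provisional_type <- if_else(splice, "splice_like", "genomic")
  ev
}

load_reference <- function(reference) {
  if (inherits(reference, "DNAStringSet")) return(reference)
  if (is.character(reference) && length(reference) == 1) {
    ref <- Biostrings::readDNAStringSet(reference)
    names(ref) <- sub("\\s.*$", "", names(ref))
    return(ref)
  }
  abort("reference must be a DNAStringSet or a FASTA path")
}

# dinucleotide lost at a breakend (the first two bases beyond the retained
# side); NA near contig edges or for unknown contigs
lost_dinucleotide <- function(chrom, pos, side, ref) {
  out <- rep(NA_character_, length(chrom))
  for (i in seq_along(chrom)) {
    if (!chrom[i] %in% names(ref)) next
    len <- Biostrings::width(ref[chrom[i]])
    if (side[i] == "left") {
      if (pos[i] + 3L <= len) {
        out[i] <- as.character(Biostrings::subseq(ref[[chrom[i]]], pos[i] + 2L, pos[i] + 3L))
      }
    } else {
      if (pos[i] - 1L >= 1L) {
        out[i] <- as.character(Biostrings::subseq(ref[[chrom[i]]], pos[i] - 1L, pos[i]))
      }
    }
  }
  out
}

splice_motif_pairs <- function(strict = FALSE) {
  # (lost dinuc at the side-"left" breakend, lost dinuc at the side-"right"
  # breakend); plus-strand GT..AG and the minus-strand genome view CT..AC
  m <- list(c("GT", "AG"), c("CT", "AC"))
  if (!strict) {
    m <- c(m, list(c("GC", "AG"), c("CT", "GC"), c("AT", "AC"), c("GT", "AT")))
  }
  m
}

breakend_pair_has_splice_motif <- function(ev, ref, strict = FALSE) {
  n <- nrow(ev)
  if (n == 0) return(logical(0))
  # need one left-retaining and one right-retaining breakend
  ok_geom <- (ev$sideA == "left" & ev$sideB == "right") |
    (ev$sideA == "right" & ev$sideB == "left")
  left_chrom <- if_else(ev$sideA == "left", ev$chromA, ev$chromB)
  left_pos <- if_else(ev$sideA == "left", ev$posA, ev$posB)
  right_chrom <- if_else(ev$sideA == "right", ev$chromA, ev$chromB)
  right_pos <- if_else(ev$sideA == "right", ev$posA, ev$posB)
  dL <- lost_dinucleotide(left_chrom, left_pos, rep("left", n), ref)
  dR <- lost_dinucleotide(right_chrom, right_pos, rep("right", n), ref)
  pairs <- splice_motif_pairs(strict)
  hit <- rep(FALSE, n)
  for (p in pairs) hit <- hit | (!is.na(dL) & !is.na(dR) & dL == p[1] & dR == p[2])
  ok_geom & hit
}

breakend_pair_on_exon_boundary <- function(ev, gene_models, tol = 2L,
                                           stranded = TRUE) {
  onA <- breakend_on_exon_boundary(ev$chromA, ev$posA, ev$sideA, gene_models, tol)
  onB <- breakend_on_exon_boundary(ev$chromB, ev$posB, ev$sideB, gene_models, tol)
  onA & onB
}
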