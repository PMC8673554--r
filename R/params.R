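#' Library layout description
#'
#' Describes the sequencing library whose alignments are analysed: whether it
#' is stranded (and with which protocol), the maximum insert size considered
#' concordant, and the read length. The insert bound doubles as the
#' positional merge window for spanning evidence, mirroring typical Illumina
#' fragment sizes (the emulated study library is 126-bp paired-end with
#' 300-600-bp fragments).
#'
#' @param stranded Logical; is the library strand-specific?
#' @param strand_protocol One of `"forward"`, `"reverse"`, `"none"`.
#' @param expected_insert_max_nt Inserts larger than this are discordant
#'   (default 450 nt).
#' @param read_length_nt Read length in nucleotides (default 126).
#' @return A list of class `fusegraph_layout`.
#' @export
library_layout <- function(stranded = TRUE,
                           strand_protocol = if (stranded) "forward" else "none",
                           expected_insert_max_nt = 450L,
                           read_length_nt = 126L) {
  stopifnot(expected_insert_max_nt > 0, read_length_nt > 0)
  strand_protocol <- match.arg(strand_protocol, c("forward", "reverse", "none"))
  structure(
    list(
      stranded = isTRUE(stranded),
      strand_protocol = strand_protocol,
      expected_insert_max_nt = as.integer(expected_insert_max_nt),
      read_length_nt = as.integer(read_length_nt)
    ),
    class = "fusegraph_layout"
  )
}

#' Breakpoint-graph parameters
#'
#' Evidence weights and thresholds used when aggregating read evidence into
#' graph edges and when merging interval-precise (spanning) breakends into
#' base-precise (split) ones.
#'
#' Split reads pin the junction to the base and are up-weighted relative to
#' spanning pairs; the default score threshold of 6 is met by two split reads,
#' or one split read plus three spanning pairs. `min_reads` is hard-wired to
#' at least 2: single-read junctions are never reported.
#'
#' @param merge_window_nt Strictly-less-than window (nt) for absorbing
#'   spanning breakends into split breakends and for event linkage
#'   (default 450, the insert-size bound).
#' @param w_split Weight of one split read (default 3).
#' @param w_spanning Weight of one spanning pair (default 1).
#' @param min_score Minimum edge score for a junction call (default 6).
#' @param min_reads Minimum supporting fragments (default 2, must be >= 2).
#' @return A list of class `fusegraph_graph_params`.
#' @export
graph_params <- function(merge_window_nt = 450L, w_split = 3, w_spanning = 1,
                         min_score = 6, min_reads = 2L) {
  stopifnot(merge_window_nt > 0)
  if (min_reads < 2L) {
    abort("min_reads must be >= 2: junctions require more than one read.")
  }
  structure(
    list(
      merge_window_nt = as.integer(merge_window_nt),
      w_split = as.numeric(w_split),
      w_spanning = as.numeric(w_spanning),
      min_score = as.numeric(min_score),
      min_reads = as.integer(min_reads)
    ),
    class = "fusegraph_graph_params"
  )
}

#' Junction filter parameters
#'
#' @param min_reads Minimum supporting fragments (default 2, must be >= 2).
#' @param min_split Minimum split-read support; spanning-only calls fail when
#'   this is > 0 (default 1).
#' @param min_arm_entropy Minimum fraction of distinct read start positions
#'   among supporting fragments, in `[0, 1]` (default 0.5). A stack of reads
#'   all starting at one base is a PCR/alignment artefact signature.
#' @param exclude_nonstandard_contigs Drop junctions touching unplaced or
#'   alternate-locus contigs (`chrUn_*`, `*_alt`, `*_random`; default TRUE).
#' @param exon_boundary_tolerance_nt Positional tolerance (nt) when testing
#'   whether a breakend sits on an annotated exon boundary (default 2).
#' @return A list of class `fusegraph_filter_params`.
#' @export
filter_params <- function(min_reads = 2L, min_split = 1L, min_arm_entropy = 0.5,
                          exclude_nonstandard_contigs = TRUE,
                          exon_boundary_tolerance_nt = 2L) {
  if (min_reads < 2L) {
    abort("min_reads must be >= 2: junctions require more than one read.")
  }
  stopifnot(min_split >= 0, min_arm_entropy >= 0, min_arm_entropy <= 1,
            exon_boundary_tolerance_nt >= 0)
  structure(
    list(
      min_reads = as.integer(min_reads),
      min_split = as.integer(min_split),
      min_arm_entropy = as.numeric(min_arm_entropy),
      exclude_nonstandard_contigs = isTRUE(exclude_nonstandard_contigs),
      exon_boundary_tolerance_nt = as.integer(exon_boundary_tolerance_nt)
    ),
    class = "fusegraph_filter_params"
  )
}

#' Junction-set matching parameters
#'
#' Controls the windowed matcher used to compare two junction sets (e.g.
#' RNA-derived junctions against WGS breakpoints). Both sides of a pair of
#' junctions must lie within `window_nt` genomic nucleotides (inclusive) to
#' be considered a match; head-to-tail junctions and junctions touching
#' alternate loci are excluded up front by default.
#'
#' @param window_nt Matching window in nt, inclusive (default 40).
#' @param exclude_head_to_tail Drop head-to-tail (circRNA-like) junctions
#'   before matching (default TRUE).
#' @param exclude_alt_loci Drop junctions touching non-primary contigs
#'   (default TRUE).
#' @param interchromosomal_only Restrict both sets to junctions whose two
#'   breakends lie on different chromosomes (default FALSE).
#' @return A list of class `fusegraph_match_params`.
#' @export
match_params <- function(window_nt = 40L, exclude_head_to_tail = TRUE,
                         exclude_alt_loci = TRUE,
                         interchromosomal_only = FALSE) {
  stopifnot(window_nt >= 0)
  structure(
    list(
      window_nt = as.integer(window_nt),
      exclude_head_to_tail = isTRUE(exclude_head_to_tail),
      exclude_alt_loci = isTRUE(exclude_alt_loci),
      interchromosomal_only = isTRUE(interchromosomal_only)
    ),
    class = "fusegraph_match_params"
  )
}

# Contigs regarded as unplaced/unlocalized/alternate loci.
is_nonstandard_contig <- function(chrom) {
  stringr::str_detect(chrom, "^chrUn_|_alt$|_random$|_decoy$|_fix$")
}

#' Parse a 1-based "chrom:start-end" locus string
#'
#' @param locus String such as `"chr11:60000000-90000000"` (1-based,
#'   inclusive). Commas are allowed as thousands separators.
#' @return A one-row tibble with `chrom`, `start`, `end` (0-based half-open).
#' @export
parse_locus <- function(locus) {
  m <- stringr::str_match(gsub(",", "", locus), "^([^:]+):([0-9]+)-([0-9]+)$")
  if (is.na(m[1, 1])) {
    abort(paste0("cannot parse locus '", locus, "'; expected chrom:start-end"))
  }
  start1 <- as.numeric(m[1, 3])
  end1 <- as.numeric(m[1, 4])
  stopifnot(start1 >= 1, end1 >= start1)
  tibble(chrom = m[1, 2], start = start1 - 1, end = end1)
}
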