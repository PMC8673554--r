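# Filtering of junction calls, exonic/intronic labelling, gene annotation
# and head-to-tail (circRNA-like) flagging.
#
# The exonic/intronic label encodes mechanism: "exonic" means the junction
# is a product of splicing between (possibly cryptic) exon boundaries;
# "intronic" means it spans the genomic breakpoint itself. A genomic
# breakpoint falling inside an annotated exon is therefore still labelled
# intronic -- the gene annotation records the exon.

#' Read gene models from a GTF/GFF file
#'
#' Uses exon features and their `gene_id`/`gene_name` attributes; exons are
#' collapsed to a transcript-union model per gene.
#'
#' @param path Path to a GTF or GFF3 file.
#' @return An object of class `fusegraph_models`: list with `genes`
#'   (gene_id, gene_name, chrom, strand, start, end; 0-based half-open span)
#'   and `exons` (gene_id, chrom, strand, start, end).
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path)
  gr <- gr[gr$type == "exon"]
  gene_name <- if (!is.null(gr$gene_name)) gr$gene_name else gr$gene_id
  ex <- tibble(
    gene_id = gr$gene_id,
    gene_name = gene_name,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  )
  gene_models(ex)
}

#' Build gene models from an exon table
#'
#' @param exons Tibble with columns gene_id, gene_name, chrom, strand,
#'   start, end (0-based half-open).
#' @return A `fusegraph_models` object.
#' @export
gene_models <- function(exons) {
  exons <- exons |>
    distinct(.data$gene_id, .data$chrom, .data$start, .data$end,
             .keep_all = TRUE) |>
    arrange(.data$chrom, .data$start)
  # union of overlapping exon intervals per gene
  exons <- exons |>
    group_by(.data$gene_id) |>
    group_modify(function(df, key) {
      df <- arrange(df, .data$start)
      ir <- IRanges::reduce(IRanges::IRanges(df$start + 1L, df$end))
      tibble(
        gene_name = df$gene_name[1], chrom = df$chrom[1],
        strand = df$strand[1],
        start = IRanges::start(ir) - 1L, end = IRanges::end(ir)
      )
    }) |>
    ungroup()
  genes <- exons |>
    group_by(.data$gene_id) |>
    summarise(
      gene_name = first(.data$gene_name), chrom = first(.data$chrom),
      strand = first(.data$strand),
      start = min(.data$start), end = max(.data$end), .groups = "drop"
    ) |>
    arrange(.data$chrom, .data$start)
  structure(list(genes = genes, exons = arrange(exons, .data$chrom, .data$start)),
            class = "fusegraph_models")
}

#' @export
print.fusegraph_models <- function(x, ...) {
  cat("<fusegraph gene models>", nrow(x$genes), "genes,",
      nrow(x$exons), "exons\n")
  invisible(x)
}

# is a breakend (0-based position of last retained base) on an annotated
# exon boundary of the matching side, within tol nt?
breakend_on_exon_boundary <- function(chrom, pos, side, gene_models, tol = 2L) {
  ex <- gene_models$exons
  out <- rep(FALSE, length(chrom))
  # side "left": retained bases end at pos -> donor-style boundary = exon end
  # side "right": retained bases start at pos -> acceptor-style = exon start
  ends_by_chrom <- split(ex$end - 1L, ex$chrom)
  starts_by_chrom <- split(ex$start, ex$chrom)
  for (i in seq_along(chrom)) {
    bnd <- if (side[i] == "left") ends_by_chrom[[chrom[i]]] else starts_by_chrom[[chrom[i]]]
    if (!is.null(bnd) && length(bnd) > 0) {
      out[i] <- min(abs(bnd - pos[i])) <= tol
    }
  }
  out
}

#' Apply junction filters
#'
#' Each call is tested against every filter and all firing reasons are
#' reported: `insufficient_reads` (fewer than `min_reads` supporting
#' fragments; single-read junctions never pass), `no_split_support`
#' (spanning-only while `min_split > 0`), `low_start_diversity` (fraction of
#' distinct supporting read start positions below `min_arm_entropy`), and
#' `nonstandard_contig` (a breakend on an unplaced/alternate-locus contig).
#'
#' @param calls Junction-call tibble from [call_junctions()].
#' @param params A [filter_params()].
#' @return The calls with `filter_status` (`"passed"`/`"failed"`) and
#'   `filter_reasons` (comma-separated, empty when passed).
#' @export
apply_filters <- function(calls, params = filter_params()) {
  if (nrow(calls) == 0) {
    return(mutate(calls, filter_status = character(0),
                  filter_reasons = character(0)))
  }
  n_total <- calls$n_split + calls$n_spanning
  diversity <- calls$n_distinct_starts / pmax(1L, n_total)
  reasons <- purrr::pmap_chr(
    list(n_total, calls$n_split, diversity, calls$chromA, calls$chromB),
    function(nt, ns, dv, ca, cb) {
      r <- character()
      if (nt < params$min_reads) r <- c(r, "insufficient_reads")
      if (params$min_split > 0 && ns < params$min_split) {
        r <- c(r, "no_split_support")
      }
      if (dv < params$min_arm_entropy) r <- c(r, "low_start_diversity")
      if (params$exclude_nonstandard_contigs &&
          (is_nonstandard_contig(ca) || is_nonstandard_contig(cb))) {
        r <- c(r, "nonstandard_contig")
      }
      paste(r, collapse = ",")
    }
  )
  calls |>
    mutate(
      filter_reasons = reasons,
      filter_status = if_else(reasons == "", "passed", "failed")
    )
}

#' Classify junctions as exonic (splice) or intronic (genomic breakpoint)
#'
#' A junction is exonic iff both breakends lie within the boundary tolerance
#' of an annotated exon boundary with splice-consistent orientation, or --
#' in motif mode, when a reference is supplied -- the junction's reference
#' context reads as a canonical splice motif on both sides (this admits
#' cryptic, unannotated exons, including intergenic ones). Everything else,
#' including interval-precise spanning-only calls and genomic breakpoints
#' that happen to fall inside exons, is intronic: the label encodes
#' mechanism (splicing vs breakage).
#'
#' @param calls Junction-call tibble.
#' @param gene_models Optional `fusegraph_models`.
#' @param reference Optional `DNAStringSet` or FASTA path for motif mode.
#' @param params A [filter_params()] (supplies the exon boundary tolerance).
#' @param strict_motifs Restrict motif mode to GT..AG.
#' @return The calls with a `classification` column (`"exonic"`/`"intronic"`).
#' @export
classify_junctions <- function(calls, gene_models = NULL, reference = NULL,
                               params = filter_params(),
                               strict_motifs = FALSE) {
  if (nrow(calls) == 0) return(mutate(calls, classification = character(0)))
  exonic <- rep(FALSE, nrow(calls))
  precise <- calls$preciseA & calls$preciseB
  known <- rep(TRUE, nrow(calls))
  if (!is.null(gene_models)) {
    chroms <- unique(gene_models$exons$chrom)
    known <- known & calls$chromA %in% chroms & calls$chromB %in% chroms
  }
  if (!is.null(gene_models) && any(precise)) {
    tol <- params$exon_boundary_tolerance_nt
    onA <- breakend_on_exon_boundary(calls$chromA, calls$posA, calls$sideA,
                                     gene_models, tol)
    onB <- breakend_on_exon_boundary(calls$chromB, calls$posB, calls$sideB,
                                     gene_models, tol)
    exonic <- exonic | (precise & onA & onB)
  }
  if (!is.null(reference)) {
    ref <- load_reference(reference)
    known <- calls$chromA %in% names(ref) & calls$chromB %in% names(ref)
    idx <- which(precise & !exonic)
    if (length(idx) > 0) {
      exonic[idx] <- breakend_pair_has_splice_motif(calls[idx, ], ref,
                                                    strict = strict_motifs)
    }
  }
  if (any(!known)) {
    warn(paste0(sum(!known), " junction(s) touch contigs absent from the ",
                "annotation/reference; classified intronic"))
  }
  mutate(calls, classification = if_else(exonic, "exonic", "intronic"))
}

#' Annotate gene membership and intergenic status
#'
#' A breakend is "in gene" iff it lies inside a gene's span (first to last
#' exon). For stranded libraries membership can additionally require the
#' evidence strand to match the gene strand; unstranded data ignores gene
#' strand.
#'
#' @param calls Junction-call tibble.
#' @param gene_models A `fusegraph_models`.
#' @param stranded Honour gene strand when the evidence strand is known
#'   (default FALSE).
#' @return The calls with `genesA`, `genesB` (comma-separated, sorted) and
#'   `intergenic_status` (`both_in_gene`, `one_intergenic`,
#'   `both_intergenic`).
#' @export
annotate_genes <- function(calls, gene_models, stranded = FALSE) {
  if (nrow(calls) == 0) {
    return(mutate(calls, genesA = character(0), genesB = character(0),
                  intergenic_status = character(0)))
  }
  genes <- gene_models$genes
  hit <- function(chrom, pos, strand) {
    vapply(seq_along(chrom), function(i) {
      sel <- genes$chrom == chrom[i] & genes$start <= pos[i] & genes$end > pos[i]
      if (stranded && !is.na(strand[i]) && strand[i] %in% c("+", "-")) {
        sel <- sel & genes$strand == strand[i]
      }
      paste(sort(genes$gene_name[sel]), collapse = ",")
    }, character(1))
  }
  calls |>
    mutate(
      genesA = hit(.data$chromA, .data$posA, .data$strandA),
      genesB = hit(.data$chromB, .data$posB, .data$strandB),
      intergenic_status = dplyr::case_when(
        .data$genesA != "" & .data$genesB != "" ~ "both_in_gene",
        .data$genesA == "" & .data$genesB == "" ~ "both_intergenic",
        TRUE ~ "one_intergenic"
      )
    )
}

#' Read a circRNA back-splice catalogue
#'
#' Tab-separated BED-like file: chrom, start, end, strand (0-based,
#' half-open exon-junction span: start = acceptor exon start, end = donor
#' exon end). Malformed lines are skipped with a warning.
#'
#' @param path File path.
#' @return Tibble with chrom, start, end, strand.
#' @export
read_circ_catalogue <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  parts <- stringr::str_split(lines, "\t")
  ok <- vapply(parts, function(p) length(p) >= 3 &&
                 !is.na(suppressWarnings(as.integer(p[2]))) &&
                 !is.na(suppressWarnings(as.integer(p[3]))), logical(1))
  if (any(!ok)) {
    warn(paste0("skipping ", sum(!ok), " malformed catalogue line(s)"))
  }
  parts <- parts[ok]
  tibble(
    chrom = vapply(parts, `[`, character(1), 1),
    start = as.integer(vapply(parts, `[`, character(1), 2)),
    end = as.integer(vapply(parts, `[`, character(1), 3)),
    strand = vapply(parts, function(p) if (length(p) >= 4) p[4] else "*",
                    character(1))
  )
}

#' Flag head-to-tail (circRNA-like) junctions
#'
#' A junction is head-to-tail when both breakends share one chromosome and
#' strand and the acceptor (right-retaining breakend) lies upstream of the
#' donor (left-retaining breakend) -- the back-splice signature, also
#' produced by small tandem duplications. When a catalogue is given,
#' `catalogue_match` requires both breakends to equal a back-splice entry
#' exactly (0-nt tolerance).
#'
#' @param calls Junction-call tibble (canonically ordered breakends).
#' @param circ_catalogue Optional catalogue tibble
#'   ([read_circ_catalogue()]).
#' @return The calls with `circ_flag` and (if a catalogue was supplied)
#'   `catalogue_match` columns.
#' @export
flag_head_to_tail <- function(calls, circ_catalogue = NULL) {
  if (nrow(calls) == 0) {
    calls <- mutate(calls, circ_flag = logical(0))
    if (!is.null(circ_catalogue)) calls$catalogue_match <- logical(0)
    return(calls)
  }
  same_strand <- is.na(calls$strandA) | is.na(calls$strandB) |
    calls$strandA == calls$strandB
  calls <- calls |>
    mutate(circ_flag = .data$chromA == .data$chromB & same_strand &
             .data$sideA == "right" & .data$sideB == "left")
  if (!is.null(circ_catalogue)) {
    key <- paste(circ_catalogue$chrom, circ_catalogue$start,
                 circ_catalogue$end - 1L)
    calls <- calls |>
      mutate(catalogue_match = .data$circ_flag &
               paste(.data$chromA, .data$posA, .data$posB) %in% key)
  }
  calls
}
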