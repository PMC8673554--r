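# One-call wrapper chaining the whole detector:
# read -> pair -> breakends -> classify -> graph -> merge -> clusters ->
# splice correction -> consensus calls -> filters -> classification ->
# gene annotation -> head-to-tail flagging.

#' Detect fusion junctions and genomic breakpoints in one call
#'
#' Runs the full detector over a chimeric SAM/BAM file and returns the final
#' junction table. Chimeric split alignments give base-precise breakends;
#' discordant pairs give interval-precise spanning support which is merged
#' into nearby split breakends (strictly within the insert-size window).
#' Junctions are clustered into events, splice-variant corrected, filtered,
#' labelled exonic (splice product) or intronic (genomic breakpoint), gene
#' annotated, and head-to-tail flagged.
#'
#' @param path Chimeric SAM/BAM file.
#' @param gene_models Optional `fusegraph_models` (or GTF path).
#' @param reference Optional `DNAStringSet` or FASTA path for splice-motif
#'   checks.
#' @param circ_catalogue Optional back-splice catalogue tibble or path.
#' @param layout A [library_layout()].
#' @param gparams A [graph_params()].
#' @param fparams A [filter_params()].
#' @param region Optional `GRanges` restricting the analysis.
#' @param strict_motifs Restrict motif checks to GT..AG.
#' @param min_arm_nt Minimum aligned arm length for split evidence.
#' @return The junction-call tibble (all calls, passed and failed), with a
#'   `counters` attribute carrying the per-file run report.
#' @export
detect_junctions <- function(path, gene_models = NULL, reference = NULL,
                             circ_catalogue = NULL,
                             layout = library_layout(),
                             gparams = graph_params(),
                             fparams = filter_params(), region = NULL,
                             strict_motifs = FALSE, min_arm_nt = 20L) {
  if (is.character(gene_models)) gene_models <- read_gene_models(gene_models)
  if (is.character(circ_catalogue)) {
    circ_catalogue <- read_circ_catalogue(circ_catalogue)
  }
  if (!is.null(reference)) reference <- load_reference(reference)
  rec <- read_chimeric_records(path, region = region, layout = layout)
  ev <- pair_read_fragments(rec, layout = layout, min_arm_nt = min_arm_nt)
  counters <- c(attr(rec, "counters"), attr(ev, "counters"))
  ev <- infer_breakends(ev, layout = layout)
  ev <- classify_evidence(ev, layout = layout, reference = reference,
                          gene_models = gene_models,
                          strict_motifs = strict_motifs)
  graph <- build_graph(ev, params = gparams) |>
    merge_nearby_breakends()
  calls <- extract_clusters(graph) |>
    splice_variant_correction() |>
    call_junctions() |>
    apply_filters(params = fparams) |>
    classify_junctions(gene_models = gene_models, reference = reference,
                       params = fparams, strict_motifs = strict_motifs)
  if (!is.null(gene_models)) {
    calls <- annotate_genes(calls, gene_models, stranded = FALSE)
  }
  calls <- flag_head_to_tail(calls, circ_catalogue = circ_catalogue)
  attr(calls, "counters") <- c(counters, graph$stats)
  attr(calls, "params") <- list(layout = layout, graph = gparams,
                                filter = fparams)
  calls
}

#' Keep only passing junction calls
#'
#' @param calls Junction-call tibble with `filter_status`.
#' @return The passing subset.
#' @export
passing_junctions <- function(calls) {
  filter(calls, .data$filter_status == "passed")
}

#' Write the final junction table
#'
#' Positions are written 1-based inclusive; the breakend is the last
#' retained aligned base. The coordinate convention is documented in the
#' header line.
#'
#' @param calls Junction-call tibble.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_junction_table <- function(calls, path) {
  out <- calls |>
    mutate(
      posA = .data$posA + 1L, posB = .data$posB + 1L,
      reportA = .data$reportA + 1L, reportB = .data$reportB + 1L
    ) |>
    select(-dplyr::any_of("starts"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# fusegraph junction table; coordinates 1-based ",
                    "inclusive; breakend = last retained aligned base"), con)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a junction table written by [write_junction_table()]
#'
#' Converts positions back to the internal 0-based convention.
#'
#' @param path TSV path.
#' @return Junction-call tibble.
#' @export
read_junction_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE) |>
    as_tibble() |>
    mutate(
      posA = .data$posA - 1L, posB = .data$posB - 1L,
      reportA = .data$reportA - 1L, reportB = .data$reportB - 1L
    )
  df
}

#' Export junction calls as BEDPE
#'
#' @param calls Junction-call tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_junction_bedpe <- function(calls, path) {
  label <- if ("classification" %in% names(calls)) {
    calls$classification
  } else {
    calls$provisional_type
  }
  bed <- calls |>
    mutate(
      start1 = .data$posA, end1 = .data$posA + 1L,
      start2 = .data$posB, end2 = .data$posB + 1L,
      name = paste0("event", .data$event_id, "_", label)
    ) |>
    select("chromA", "start1", "end1", "chromB", "start2", "end2",
           "name", "score", strand1 = "strandA", strand2 = "strandB")
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Run-report counters of a detection run
#'
#' @param calls Result of [detect_junctions()].
#' @return Named list of counters, serializable with
#'   [jsonlite::toJSON()].
#' @export
run_report <- function(calls) {
  attr(calls, "counters")
}
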