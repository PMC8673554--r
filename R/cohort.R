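# Cohort-level integration: windowed matching of two junction sets (e.g.
# RNA junctions vs WGS breakpoints), interchromosomal restriction, binned
# junction density, and locus-conditioned differential expression
# ("chromosomal differential expression plots").

normalize_junction_set <- function(x, params) {
  x <- as_tibble(x)
  req <- c("chromA", "posA", "chromB", "posB")
  if (!all(req %in% names(x))) {
    abort(paste0("junction set needs columns: ", paste(req, collapse = ", ")))
  }
  if (params$exclude_head_to_tail) {
    if ("circ_flag" %in% names(x)) {
      x <- filter(x, !.data$circ_flag)
    } else if (all(c("sideA", "sideB") %in% names(x))) {
      x <- filter(x, !(.data$chromA == .data$chromB &
                         .data$sideA == "right" & .data$sideB == "left"))
    }
  }
  if (params$exclude_alt_loci) {
    x <- filter(x, !is_nonstandard_contig(.data$chromA),
                !is_nonstandard_contig(.data$chromB))
  }
  if (params$interchromosomal_only) x <- restrict_interchromosomal(x)
  x
}

#' Match two junction sets within a genomic window
#'
#' Two junctions match when, after canonical ordering of both, both sides
#' lie within `window_nt` genomic nucleotides (inclusive). Head-to-tail
#' junctions and junctions touching alternate loci are excluded before
#' matching (configurable), and the comparison can be restricted to
#' interchromosomal junctions. Assignment is greedy nearest-pair: candidate
#' pairs are ranked by total distance and each junction is matched at most
#' once.
#'
#' @param A,B Junction tibbles (columns `chromA`, `posA`, `chromB`, `posB`;
#'   0-based breakend positions).
#' @param params A [match_params()].
#' @return A list with `matched` (indices into the filtered sets plus
#'   per-side distances), `a_only`, `b_only` (tibbles), and the filtered
#'   inputs `a`, `b`.
#' @export
match_junction_sets <- function(A, B, params = match_params()) {
  a <- normalize_junction_set(A, params)
  b <- normalize_junction_set(B, params)
  shared_a <- unique(c(a$chromA, a$chromB))
  shared_b <- unique(c(b$chromA, b$chromB))
  if (nrow(a) > 0 && nrow(b) > 0 && length(intersect(shared_a, shared_b)) == 0) {
    abort("no contig names shared between the two junction sets; mixed genome builds?")
  }
  w <- params$window_nt
  a$.ia <- seq_len(nrow(a))
  b$.ib <- seq_len(nrow(b))
  cand <- inner_join(
    a |> select(".ia", "chromA", "posA", "chromB", "posB"),
    b |> select(".ib", "chromA", "posA", "chromB", "posB"),
    by = c("chromA", "chromB"), suffix = c("_a", "_b"),
    relationship = "many-to-many"
  ) |>
    mutate(dA = abs(.data$posA_a - .data$posA_b),
           dB = abs(.data$posB_a - .data$posB_b)) |>
    filter(.data$dA <= w, .data$dB <= w) |>
    arrange(.data$dA + .data$dB, .data$.ia, .data$.ib)
  used_a <- logical(nrow(a))
  used_b <- logical(nrow(b))
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    ia <- cand$.ia[i]
    ib <- cand$.ib[i]
    if (!used_a[ia] && !used_b[ib]) {
      keep[i] <- TRUE
      used_a[ia] <- TRUE
      used_b[ib] <- TRUE
    }
  }
  matched <- cand[keep, c(".ia", ".ib", "dA", "dB")]
  names(matched) <- c("index_a", "index_b", "dist_a", "dist_b")
  list(
    matched = as_tibble(matched),
    a_only = a[!used_a, , drop = FALSE] |> select(-".ia"),
    b_only = b[!used_b, , drop = FALSE] |> select(-".ib"),
    a = select(a, -".ia"),
    b = select(b, -".ib")
  )
}

#' Restrict a junction set to interchromosomal junctions
#'
#' Avoids unfair cross-assay comparison with artefacts of RNA
#' post-processing (read-throughs, circRNAs) and small DNA indels.
#'
#' @param x Junction tibble.
#' @return The interchromosomal subset; idempotent.
#' @export
restrict_interchromosomal <- function(x) {
  filter(as_tibble(x), .data$chromA != .data$chromB)
}

#' Bin junction endpoint density along the genome
#'
#' Every junction contributes both endpoints to their bins; circRNA-flagged
#' junctions are discarded. When two tracks are given, the Pearson
#' correlation over matched bins is attached as attribute `correlation`.
#'
#' @param sets A named list of 1 or 2 junction tibbles.
#' @param bin_size_nt Bin width in nt.
#' @param contig_lengths Named integer vector of contig lengths.
#' @return Tibble with `track`, `chrom`, `bin_start`, `count` covering every
#'   bin of every contig.
#' @export
bin_junction_density <- function(sets, bin_size_nt, contig_lengths) {
  stopifnot(length(sets) >= 1, length(sets) <= 2, !is.null(names(contig_lengths)))
  if (is.null(names(sets))) names(sets) <- paste0("track", seq_along(sets))
  grid <- purrr::imap(contig_lengths, function(len, chrom) {
    tibble(chrom = chrom,
           bin_start = seq(0L, max(0L, len - 1L), by = bin_size_nt))
  }) |> bind_rows()
  out <- purrr::imap(sets, function(x, nm) {
    x <- as_tibble(x)
    if ("circ_flag" %in% names(x)) x <- filter(x, !.data$circ_flag)
    pts <- bind_rows(
      select(x, chrom = "chromA", pos = "posA"),
      select(x, chrom = "chromB", pos = "posB")
    ) |>
      mutate(bin_start = (.data$pos %/% bin_size_nt) * bin_size_nt) |>
      count(.data$chrom, .data$bin_start, name = "count")
    grid |>
      left_join(pts, by = c("chrom", "bin_start")) |>
      mutate(track = nm, count = dplyr::coalesce(.data$count, 0L))
  }) |> bind_rows() |>
    select("track", "chrom", "bin_start", "count")
  if (length(sets) == 2) {
    wide <- tidyr::pivot_wider(out, names_from = "track",
                               values_from = "count")
    tr <- names(sets)
    attr(out, "correlation") <- cor(wide[[tr[1]]], wide[[tr[2]]],
                                    method = "pearson")
  }
  out
}

#' Split a cohort into mutant and wild-type groups by locus
#'
#' A sample is mutant iff it has one or more passing intronic or exonic
#' junctions with at least one breakend inside the locus.
#'
#' @param sample_junctions Tibble of per-sample junction calls with a
#'   `sample` column (and `filter_status`, if available; only passing calls
#'   count).
#' @param locus One-row tibble (`chrom`, `start`, `end`; 0-based half-open)
#'   or a 1-based `"chrom:start-end"` string ([parse_locus()]).
#' @param samples Optional character vector of all cohort samples (samples
#'   without any junction rows are wild-type).
#' @return A list of class `fusegraph_locus_split` with `locus`,
#'   `mutant_samples`, `wildtype_samples`.
#' @export
split_cohort_by_locus <- function(sample_junctions, locus, samples = NULL) {
  if (is.character(locus)) locus <- parse_locus(locus)
  x <- as_tibble(sample_junctions)
  stopifnot("sample" %in% names(x))
  if ("filter_status" %in% names(x)) {
    x <- filter(x, .data$filter_status == "passed")
  }
  inside <- function(chrom, pos) {
    chrom == locus$chrom & pos >= locus$start & pos < locus$end
  }
  hit <- inside(x$chromA, x$posA) | inside(x$chromB, x$posB)
  mutant <- sort(unique(x$sample[hit]))
  all_samples <- sort(unique(c(x$sample, samples)))
  structure(
    list(locus = locus, mutant_samples = mutant,
         wildtype_samples = setdiff(all_samples, mutant)),
    class = "fusegraph_locus_split"
  )
}

#' @export
print.fusegraph_locus_split <- function(x, ...) {
  cat("<locus split> ", x$locus$chrom, ":", x$locus$start + 1, "-",
      x$locus$end, "  mutant: ", length(x$mutant_samples),
      "  wild-type: ", length(x$wildtype_samples), "\n", sep = "")
  invisible(x)
}
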