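# Cluster analysis of the breakpoint graph: maximal sets of edges connected
# via shared or within-window breakends with compatible orientation form one
# rearrangement event; splice isoforms of one event are grouped; consensus
# junction calls are emitted per event.

#' Extract event clusters from a breakpoint graph
#'
#' Two edges are linked when they share a breakend exactly (same contig,
#' position, and retained side), or when they connect the same chromosome
#' pair with identical retained-side orientation and both corresponding
#' breakends lie strictly within the merge window. Head-to-tail edges only
#' link with head-to-tail edges. Clusters are maximal connected sets under
#' this relation; incompatible orientations or different chromosome pairs
#' are never joined, keeping distinct events separated.
#'
#' @param graph A merged `fusegraph_graph`.
#' @return An object of class `fusegraph_clusters`: list with `edges` (the
#'   edge tibble plus an `event_id` column) and `clusters` (one row per
#'   event, sorted by descending total score then genomic order).
#' @export
extract_clusters <- function(graph) {
  edges <- graph$edges
  window <- graph$params$merge_window_nt
  if (nrow(edges) == 0) {
    out <- list(edges = mutate(edges, event_id = integer(0)),
                clusters = tibble(event_id = integer(), n_edges = integer(),
                                  total_score = numeric()),
                params = graph$params)
    class(out) <- "fusegraph_clusters"
    return(out)
  }
  n <- nrow(edges)
  links <- list()
  # exact shared breakends: connect edge-vertices through node-key vertices
  keyA <- paste(edges$chromA, edges$posA, edges$sideA, edges$h2t, sep = "\r")
  keyB <- paste(edges$chromB, edges$posB, edges$sideB, edges$h2t, sep = "\r")
  node_keys <- unique(c(keyA, keyB))
  ig <- igraph::make_empty_graph(n = n + length(node_keys), directed = FALSE)
  node_index <- setNames(seq_along(node_keys) + n, node_keys)
  ig <- igraph::add_edges(ig, rbind(seq_len(n), node_index[keyA]))
  ig <- igraph::add_edges(ig, rbind(seq_len(n), node_index[keyB]))
  # within-window linkage among same chrom-pair, same orientation edges
  grp_key <- paste(edges$chromA, edges$chromB, edges$sideA, edges$sideB,
                   edges$h2t, sep = "\r")
  for (idx in split(seq_len(n), grp_key)) {
    if (length(idx) < 2) next
    o <- idx[order(edges$posA[idx])]
    pa <- edges$posA[o]
    pb <- edges$posB[o]
    pairs <- NULL
    for (i in seq_along(o)[-1]) {
      j <- which(pa[seq_len(i - 1)] > pa[i] - window &
                   abs(pb[seq_len(i - 1)] - pb[i]) < window)
      if (length(j) > 0) pairs <- cbind(pairs, rbind(o[j], o[i]))
    }
    if (!is.null(pairs)) ig <- igraph::add_edges(ig, pairs)
  }
  memb <- igraph::components(ig)$membership[seq_len(n)]
  edges$event_id <- as.integer(memb)
  # deterministic event ids: descending total score, then genomic order
  ranks <- edges |>
    group_by(.data$event_id) |>
    summarise(total_score = sum(.data$score),
              chrom = min(.data$chromA), pos = min(.data$posA),
              .groups = "drop") |>
    arrange(dplyr::desc(.data$total_score), .data$chrom, .data$pos) |>
    mutate(new_id = row_number())
  edges$event_id <- ranks$new_id[match(edges$event_id, ranks$event_id)]
  clusters <- ranks |>
    select(event_id = "new_id", "total_score") |>
    left_join(count(edges, .data$event_id, name = "n_edges"), by = "event_id") |>
    select("event_id", "n_edges", "total_score")
  out <- list(edges = arrange(edges, .data$event_id, dplyr::desc(.data$score),
                              .data$chromA, .data$posA),
              clusters = clusters, params = graph$params)
  class(out) <- "fusegraph_clusters"
  out
}

#' Group splice isoforms of one event
#'
#' Within a cluster, splice-like edges that share one breakend while their
#' other breakends lie at distinct positions are splice isoforms of a single
#' event (e.g. one donor splicing to alternative acceptor exons). They keep
#' one `event_id` and receive a common `variant_group`; evidence counts are
#' never reassigned.
#'
#' @param clusters A `fusegraph_clusters`.
#' @return The same object with a `variant_group` column on `edges`.
#' @export
splice_variant_correction <- function(clusters) {
  edges <- clusters$edges
  if (nrow(edges) == 0) {
    clusters$edges <- mutate(edges, variant_group = integer(0))
    return(clusters)
  }
  edges$variant_group <- seq_len(nrow(edges))
  splice_idx <- which(edges$provisional_type == "splice_like")
  if (length(splice_idx) >= 2) {
    keyA <- paste(edges$event_id, edges$chromA, edges$posA, edges$sideA, sep = "\r")
    keyB <- paste(edges$event_id, edges$chromB, edges$posB, edges$sideB, sep = "\r")
    # union-find over splice-like edges sharing either breakend
    parent <- seq_len(nrow(edges))
    find <- function(i) {
      while (parent[i] != i) {
        parent[i] <<- parent[parent[i]]
        i <- parent[i]
      }
      i
    }
    both_keys <- c(keyA[splice_idx], keyB[splice_idx])
    owners <- c(splice_idx, splice_idx)
    for (grp in split(owners, both_keys)) {
      if (length(grp) >= 2) {
        r <- find(grp[1])
        for (i in grp[-1]) parent[find(i)] <- r
      }
    }
    roots <- vapply(seq_len(nrow(edges)), find, integer(1))
    edges$variant_group <- match(roots, unique(roots))
  }
  clusters$edges <- edges
  clusters
}

#' Emit consensus junction calls from event clusters
#'
#' One call is emitted per consensus breakend pair. Within an event, edges of
#' one type whose breakends lie within a small collapse window (aligner
#' jitter) are merged and the consensus position is the split-read mode,
#' ties resolved to the smallest coordinate. Spanning-only pairs report the
#' midpoint of their uncertainty interval together with its width.
#'
#' @param clusters A `fusegraph_clusters` (after
#'   [splice_variant_correction()]).
#' @param consensus_window_nt Collapse window for jittered split positions
#'   (default 5 nt).
#' @return A junction-call tibble, deterministically ordered, one row per
#'   consensus breakend pair, with 0-based `posA`/`posB`, reporting
#'   positions `reportA`/`reportB` (interval midpoints for spanning-only
#'   calls), uncertainties, evidence counts and `event_id`.
#' @export
call_junctions <- function(clusters, consensus_window_nt = 5L) {
  edges <- clusters$edges
  if (nrow(edges) == 0) {
    return(empty_call_tibble())
  }
  grp_key <- paste(edges$event_id, edges$chromA, edges$chromB, edges$sideA,
                   edges$sideB, edges$provisional_type, edges$h2t, sep = "\r")
  calls <- list()
  for (idx in split(seq_len(nrow(edges)), grp_key)) {
    sub <- edges[idx, , drop = FALSE]
    # greedy consensus: strongest split support first, ties to the smallest
    # coordinate; absorb members within the collapse window on both sides
    sub <- sub[order(-sub$n_split, sub$posA, sub$posB), , drop = FALSE]
    taken <- rep(FALSE, nrow(sub))
    merge_window <- clusters$params$merge_window_nt
    for (i in seq_len(nrow(sub))) {
      if (taken[i]) next
      # base-precise positions only jitter by a few nt; interval-precise
      # (spanning-only) bounds scatter within the insert size
      wA <- if_else(sub$preciseA & sub$preciseA[i],
                    as.integer(consensus_window_nt), merge_window)
      wB <- if_else(sub$preciseB & sub$preciseB[i],
                    as.integer(consensus_window_nt), merge_window)
      near <- !taken &
        abs(sub$posA - sub$posA[i]) <= wA &
        abs(sub$posB - sub$posB[i]) <= wB
      grp <- sub[near, , drop = FALSE]
      taken[near] <- TRUE
      calls[[length(calls) + 1]] <- tibble(
        event_id = grp$event_id[1],
        chromA = grp$chromA[1], posA = grp$posA[1], sideA = grp$sideA[1],
        chromB = grp$chromB[1], posB = grp$posB[1], sideB = grp$sideB[1],
        strandA = grp$strandA[1], strandB = grp$strandB[1],
        provisional_type = grp$provisional_type[1],
        h2t = grp$h2t[1],
        variant_group = grp$variant_group[1],
        n_split = sum(grp$n_split),
        n_spanning = sum(grp$n_spanning),
        n_head_to_tail = sum(grp$n_head_to_tail),
        preciseA = any(grp$preciseA), preciseB = any(grp$preciseB),
        uncertA = min(grp$uncertA), uncertB = min(grp$uncertB),
        starts = list(unlist(grp$starts))
      )
    }
  }
  calls <- bind_rows(calls)
  w_split <- clusters$params$w_split
  w_spanning <- clusters$params$w_spanning
  calls |>
    mutate(
      score = w_split * .data$n_split + w_spanning * .data$n_spanning,
      uncertA = if_else(.data$preciseA, 0L, .data$uncertA),
      uncertB = if_else(.data$preciseB, 0L, .data$uncertB),
      reportA = if_else(.data$preciseA, .data$posA,
                        .data$posA + if_else(.data$sideA == "left", 1L, -1L) *
                          .data$uncertA %/% 2L),
      reportB = if_else(.data$preciseB, .data$posB,
                        .data$posB + if_else(.data$sideB == "left", 1L, -1L) *
                          .data$uncertB %/% 2L),
      n_distinct_starts = purrr::map_int(.data$starts, dplyr::n_distinct)
    ) |>
    arrange(.data$event_id, dplyr::desc(.data$score), .data$chromA,
            .data$posA, .data$chromB, .data$posB)
}

empty_call_tibble <- function() {
  tibble(
    event_id = integer(), chromA = character(), posA = integer(),
    sideA = character(), chromB = character(), posB = integer(),
    sideB = character(), strandA = character(), strandB = character(),
    provisional_type = character(), h2t = logical(),
    variant_group = integer(), n_split = integer(), n_spanning = integer(),
    n_head_to_tail = integer(), preciseA = logical(), preciseB = logical(),
    uncertA = integer(), uncertB = integer(), starts = list(),
    score = numeric(), reportA = integer(), reportB = integer(),
    n_distinct_starts = integer()
  )
}
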