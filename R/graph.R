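# Aggregation of read evidence into a breakpoint graph: nodes are breakends,
# edges accumulate typed, weighted evidence between two breakends. Edges
# derived from splice-like and genomic evidence between the same positions
# are deliberately kept separate; they are only united at event level during
# cluster analysis.

edge_key_cols <- c("chromA", "posA", "sideA", "chromB", "posB", "sideB",
                   "provisional_type", "h2t")

#' Build a breakpoint graph from read evidence
#'
#' Each distinct (breakend pair, provisional type) accumulates one edge with
#' split/spanning counts and a weighted score
#' `w_split * n_split + w_spanning * n_spanning`. Head-to-tail splits are
#' base-precise split evidence; `n_head_to_tail` records how many of the
#' supporting fragments have head-to-tail geometry and such edges never mix
#' with non-head-to-tail ones.
#'
#' @param evidence Evidence tibble from [classify_evidence()].
#' @param params A [graph_params()].
#' @return An object of class `fusegraph_graph`: a list with `edges` (tibble),
#'   `params`, and `stats`.
#' @export
build_graph <- function(evidence, params = graph_params()) {
  if (nrow(evidence) == 0) {
    g <- list(edges = empty_edge_tibble(), params = params, stats = NULL)
    class(g) <- "fusegraph_graph"
    g$stats <- graph_summary(g)
    return(g)
  }
  ev <- evidence |>
    mutate(
      # head-to-tail by breakend geometry: same chromosome, acceptor
      # (right-retaining) upstream of donor (left-retaining); covers both
      # head-to-tail splits and everted spanning pairs
      h2t = .data$chromA == .data$chromB &
        .data$sideA == "right" & .data$sideB == "left",
      provisional_type = dplyr::coalesce(.data$provisional_type, "genomic")
    )
  edges <- ev |>
    group_by(across(all_of(edge_key_cols))) |>
    summarise(
      strandA = first(.data$strandA),
      strandB = first(.data$strandB),
      n_split = sum(!.data$is_pair),
      n_spanning = sum(.data$is_pair),
      n_head_to_tail = sum(.data$category == "head_to_tail_split" |
                             (.data$is_pair & .data$h2t)),
      preciseA = any(.data$precise),
      preciseB = any(.data$precise),
      uncertA = min(.data$uncertA),
      uncertB = min(.data$uncertB),
      starts = list(paste0(.data$startA, "_", .data$startB)),
      .groups = "drop"
    ) |>
    mutate(score = params$w_split * .data$n_split +
             params$w_spanning * .data$n_spanning) |>
    arrange(.data$chromA, .data$posA, .data$chromB, .data$posB,
            .data$provisional_type)
  g <- list(edges = edges, params = params, stats = NULL)
  class(g) <- "fusegraph_graph"
  g$stats <- graph_summary(g)
  g
}

empty_edge_tibble <- function() {
  tibble(
    chromA = character(), posA = integer(), sideA = character(),
    chromB = character(), posB = integer(), sideB = character(),
    provisional_type = character(), h2t = logical(),
    strandA = character(), strandB = character(),
    n_split = integer(), n_spanning = integer(), n_head_to_tail = integer(),
    preciseA = logical(), preciseB = logical(),
    uncertA = integer(), uncertB = integer(),
    starts = list(), score = numeric()
  )
}

graph_nodes <- function(edges) {
  bind_rows(
    edges |> select(chrom = "chromA", pos = "posA", side = "sideA",
                    precise = "preciseA", h2t = "h2t"),
    edges |> select(chrom = "chromB", pos = "posB", side = "sideB",
                    precise = "preciseB", h2t = "h2t")
  ) |>
    group_by(.data$chrom, .data$pos, .data$side, .data$h2t) |>
    summarise(precise = any(.data$precise), .groups = "drop")
}

#' Merge interval-precise breakends into nearby base-precise ones
#'
#' Spanning-pair breakends lying strictly within the merge window
#' (default < 450 nt, the insert-size bound) of a split-read breakend with
#' the same retained side are absorbed into the split-read node; the
#' base-precise position wins and counts are summed. Base-precise nodes are
#' never moved, and head-to-tail evidence never merges with
#' non-head-to-tail evidence. A spanning-only edge whose two endpoints land
#' exactly on the endpoints of a split-supported edge is folded into that
#' edge, so spanning fragments support whichever base-precise junction they
#' co-locate with.
#'
#' @param graph A `fusegraph_graph`.
#' @return The merged `fusegraph_graph`. Evidence counts are conserved and
#'   the operation is idempotent.
#' @export
merge_nearby_breakends <- function(graph) {
  edges <- graph$edges
  if (nrow(edges) == 0) return(graph)
  window <- graph$params$merge_window_nt
  # edge-aware pass first: a spanning-only edge whose two endpoints both lie
  # within the window of one split-supported edge (same sides/geometry) is
  # snapped onto that edge as a whole, so its support is never torn between
  # two different precise junctions by independent endpoint decisions
  span_idx <- which(edges$n_split == 0 & !edges$preciseA & !edges$preciseB)
  prec_idx <- which(edges$n_split > 0)
  if (length(span_idx) > 0 && length(prec_idx) > 0) {
    tgt <- edges[prec_idx, ] |>
      mutate(.tgt = prec_idx) |>
      select(".tgt", "chromA", "chromB", "sideA", "sideB", "h2t",
             tposA = "posA", tposB = "posB")
    snap <- edges[span_idx, ] |>
      mutate(.src = span_idx) |>
      select(".src", "chromA", "chromB", "sideA", "sideB", "h2t",
             "posA", "posB") |>
      inner_join(tgt, by = c("chromA", "chromB", "sideA", "sideB", "h2t"),
                 relationship = "many-to-many") |>
      mutate(dA = abs(.data$posA - .data$tposA),
             dB = abs(.data$posB - .data$tposB)) |>
      filter(.data$dA < window, .data$dB < window) |>
      arrange(.data$dA + .data$dB, .data$tposA, .data$tposB) |>
      group_by(.data$.src) |>
      slice(1) |>
      ungroup()
    if (nrow(snap) > 0) {
      edges$posA[snap$.src] <- snap$tposA
      edges$posB[snap$.src] <- snap$tposB
      edges$preciseA[snap$.src] <- TRUE
      edges$preciseB[snap$.src] <- TRUE
      edges$uncertA[snap$.src] <- 0L
      edges$uncertB[snap$.src] <- 0L
    }
  }
  nodes <- graph_nodes(edges)
  imprecise <- nodes |> filter(!.data$precise)
  precise <- nodes |> filter(.data$precise)
  if (nrow(imprecise) > 0 && nrow(precise) > 0) {
    # nearest base-precise node on the same contig/side/h2t class, strictly
    # within the window; ties go to the smallest coordinate
    cand <- imprecise |>
      inner_join(precise, by = c("chrom", "side", "h2t"),
                 suffix = c("", "_to"), relationship = "many-to-many") |>
      mutate(dist = abs(.data$pos - .data$pos_to)) |>
      filter(.data$dist < window) |>
      arrange(.data$dist, .data$pos_to) |>
      group_by(.data$chrom, .data$pos, .data$side, .data$h2t) |>
      slice(1) |>
      ungroup() |>
      select("chrom", "pos", "side", "h2t", new_pos = "pos_to")
    if (nrow(cand) > 0) {
      edges <- edges |>
        left_join(cand, by = c(chromA = "chrom", posA = "pos", sideA = "side",
                               h2t = "h2t")) |>
        mutate(
          movedA = !is.na(.data$new_pos) & !.data$preciseA,
          posA = if_else(.data$movedA, .data$new_pos, .data$posA)
        ) |>
        select(-"new_pos") |>
        left_join(cand, by = c(chromB = "chrom", posB = "pos", sideB = "side",
                               h2t = "h2t")) |>
        mutate(
          movedB = !is.na(.data$new_pos) & !.data$preciseB,
          posB = if_else(.data$movedB, .data$new_pos, .data$posB),
          preciseA = .data$preciseA | .data$movedA,
          preciseB = .data$preciseB | .data$movedB,
          uncertA = if_else(.data$movedA, 0L, .data$uncertA),
          uncertB = if_else(.data$movedB, 0L, .data$uncertB)
        ) |>
        select(-"new_pos", -"movedA", -"movedB")
    }
  }
  # re-canonicalize and re-aggregate coincident edges
  swap <- edges$chromB < edges$chromA |
    (edges$chromB == edges$chromA & edges$posB < edges$posA)
  if (any(swap)) {
    acols <- c("chromA", "posA", "sideA", "preciseA", "uncertA")
    bcols <- c("chromB", "posB", "sideB", "preciseB", "uncertB")
    tmp <- edges[swap, acols]
    edges[swap, acols] <- edges[swap, bcols]
    edges[swap, bcols] <- tmp
  }
  edges <- edges |>
    arrange(dplyr::desc(.data$n_split)) |>
    group_by(across(all_of(edge_key_cols))) |>
    summarise(
      strandA = first(.data$strandA),
      strandB = first(.data$strandB),
      n_split = sum(.data$n_split),
      n_spanning = sum(.data$n_spanning),
      n_head_to_tail = sum(.data$n_head_to_tail),
      preciseA = any(.data$preciseA),
      preciseB = any(.data$preciseB),
      uncertA = min(.data$uncertA),
      uncertB = min(.data$uncertB),
      starts = list(unlist(.data$starts)),
      .groups = "drop"
    )
  # fold spanning-only edges into a co-located split-supported edge
  # (regardless of provisional type: the base-precise junction defines the
  # event mechanism, the spanning fragments merely support it)
  edges <- edges |>
    group_by(.data$chromA, .data$posA, .data$sideA,
             .data$chromB, .data$posB, .data$sideB, .data$h2t) |>
    group_modify(function(df, key) {
      if (nrow(df) < 2 || !any(df$n_split > 0) || !any(df$n_split == 0)) {
        return(df)
      }
      host <- which(df$n_split > 0)
      host <- host[order(-df$n_split[host],
                         df$provisional_type[host] != "splice_like")][1]
      span_only <- which(df$n_split == 0)
      df$n_spanning[host] <- df$n_spanning[host] + sum(df$n_spanning[span_only])
      df$n_head_to_tail[host] <- df$n_head_to_tail[host] +
        sum(df$n_head_to_tail[span_only])
      df$starts[[host]] <- c(df$starts[[host]],
                             unlist(df$starts[span_only]))
      df[-span_only, , drop = FALSE]
    }) |>
    ungroup() |>
    mutate(score = graph$params$w_split * .data$n_split +
             graph$params$w_spanning * .data$n_spanning) |>
    arrange(.data$chromA, .data$posA, .data$chromB, .data$posB,
            .data$provisional_type)
  g <- list(edges = edges, params = graph$params, stats = NULL)
  class(g) <- "fusegraph_graph"
  g$stats <- graph_summary(g)
  g
}

#' Summarise a breakpoint graph
#'
#' @param graph A `fusegraph_graph`.
#' @return A list of counters (nodes, edges by type, evidence totals),
#'   serializable to a JSON run report.
#' @export
graph_summary <- function(graph) {
  edges <- graph$edges
  by_type <- as.list(table(edges$provisional_type))
  by_type <- setNames(as.integer(by_type), names(by_type))
  list(
    n_nodes = nrow(graph_nodes(edges)),
    n_edges = nrow(edges),
    edges_by_type = as.list(by_type),
    n_head_to_tail_edges = sum(edges$h2t),
    evidence_total = sum(edges$n_split + edges$n_spanning),
    n_split_total = sum(edges$n_split),
    n_spanning_total = sum(edges$n_spanning),
    score_total = sum(edges$score)
  )
}

#' @export
print.fusegraph_graph <- function(x, ...) {
  s <- x$stats
  cat("<fusegraph breakpoint graph>\n")
  cat("  nodes:", s$n_nodes, " edges:", s$n_edges,
      " evidence:", s$evidence_total,
      "(", s$n_split_total, "split /", s$n_spanning_total, "spanning )\n")
  invisible(x)
}

#' @method tidy fusegraph_graph
#' @export
tidy.fusegraph_graph <- function(x, ...) {
  x$edges |>
    select("chromA", "posA", "sideA", "chromB", "posB", "sideB",
           type = "provisional_type", "h2t", "n_split", "n_spanning",
           "n_head_to_tail", "score")
}

#' @method glance fusegraph_graph
#' @export
glance.fusegraph_graph <- function(x, ...) {
  s <- x$stats
  tibble(
    n_nodes = s$n_nodes, n_edges = s$n_edges,
    evidence_total = s$evidence_total,
    n_split_total = s$n_split_total,
    n_spanning_total = s$n_spanning_total,
    score_total = s$score_total
  )
}

#' Write a tab-separated edge-list dump of a breakpoint graph
#'
#' Positions are written 1-based (breakend = last retained base).
#'
#' @param graph A `fusegraph_graph`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_graph_dump <- function(graph, path) {
  e <- tidy(graph) |>
    mutate(posA = .data$posA + 1L, posB = .data$posB + 1L)
  utils::write.table(e, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
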