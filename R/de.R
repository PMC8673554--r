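# Locus-conditioned differential expression across a mutant/wild-type
# cohort split. The engine is a self-contained negative-binomial
# exact-style two-group test: total-count normalization, tagwise dispersion
# by a moment estimator shrunk toward the cohort-common value, conditional
# exact probabilities on the group sums, and Benjamini-Hochberg q-values.
# The contract (log2 fold change + BH q-values per gene, plotted at the
# gene's genomic center) matches standard count-based DE tooling.

nb_exact_pvalue <- function(s1, s2, n1, n2, phi) {
  t <- s1 + s2
  if (t == 0) return(1)
  mu <- t / (n1 + n2)
  size1 <- n1 / phi
  size2 <- n2 / phi
  m1 <- n1 * mu
  sd1 <- sqrt(m1 * (1 + phi * mu))
  lo <- max(0, floor(m1 - 25 * sd1))
  hi <- min(t, ceiling(m1 + 25 * sd1))
  k <- lo:hi
  if (!(s1 %in% k)) k <- sort(c(k, s1))
  logp <- dnbinom(k, size = size1, mu = m1, log = TRUE) +
    dnbinom(t - k, size = size2, mu = n2 * mu, log = TRUE)
  p_obs <- logp[match(s1, k)]
  w <- exp(logp - max(logp))
  sum(w[logp <= p_obs + 1e-10]) / sum(w)
}

#' Locus-conditioned chromosomal differential expression
#'
#' Tests every gene on the locus's chromosome for differential expression
#' between the mutant group (samples carrying >= 1 junction in the locus)
#' and the wild-type group. Counts are library-size normalized internally
#' (total count, geometric-mean target); per-gene dispersion is estimated
#' by a pooled moment estimator shrunk toward the cohort median
#' (`prior_df` weight); p-values come from a conditional negative-binomial
#' exact-style test on the group sums and are BH-adjusted.
#'
#' @param counts Raw gene-by-sample count matrix (or data frame) with gene
#'   ids as rownames and sample names as columns.
#' @param split A `fusegraph_locus_split` ([split_cohort_by_locus()]).
#' @param gene_models A `fusegraph_models`; supplies chromosome and genomic
#'   center per gene (matched on `gene_id`, falling back to `gene_name`).
#' @param q_threshold Significance threshold on BH q-values (default 0.05).
#' @param prior_df Shrinkage weight toward the common dispersion
#'   (default 10).
#' @param prior_count Pseudo-count stabilising logFC (default 0.5).
#' @return A tibble of class `fusegraph_de`, one row per gene on the locus
#'   chromosome ordered by genomic center, with `logFC` (mutant vs
#'   wild-type), `p_value`, `q_value`, `significant`, and `direction`
#'   (`up`/`down`/`ns`).
#' @export
chromosomal_de <- function(counts, split, gene_models, q_threshold = 0.05,
                           prior_df = 10, prior_count = 0.5) {
  counts <- as.matrix(counts)
  mut <- intersect(split$mutant_samples, colnames(counts))
  wt <- intersect(split$wildtype_samples, colnames(counts))
  if (length(mut) < 2 || length(wt) < 2) {
    abort(paste0("both groups need >= 2 samples for differential expression",
                 " (mutant: ", length(mut), ", wild-type: ", length(wt), ")"))
  }
  genes <- gene_models$genes
  chrom <- split$locus$chrom
  on_chrom <- genes |>
    filter(.data$chrom == !!chrom) |>
    mutate(genomic_center = (.data$start + .data$end) / 2)
  ids <- rownames(counts)
  sel <- on_chrom |>
    mutate(row = match(.data$gene_id, ids),
           row = if_else(is.na(.data$row), match(.data$gene_name, ids), .data$row)) |>
    filter(!is.na(.data$row))
  if (nrow(sel) == 0) {
    abort("no genes of the locus chromosome found in the count matrix")
  }
  y <- counts[, c(mut, wt), drop = FALSE]
  lib <- colSums(y)
  target <- exp(mean(log(pmax(lib, 1))))
  yn <- sweep(y, 2, target / pmax(lib, 1), `*`)
  n1 <- length(mut)
  n2 <- length(wt)
  g1 <- yn[, mut, drop = FALSE]
  g2 <- yn[, wt, drop = FALSE]
  mu_all <- rowMeans(yn)
  v1 <- apply(g1, 1, stats::var)
  v2 <- apply(g2, 1, stats::var)
  v_pool <- (v1 * (n1 - 1) + v2 * (n2 - 1)) / (n1 + n2 - 2)
  phi_raw <- (v_pool - mu_all) / pmax(mu_all, 1e-8)^2
  phi_raw <- pmax(phi_raw, 0)
  expressed <- mu_all > 1
  phi_common <- if (any(expressed)) median(phi_raw[expressed]) else 0.1
  df <- n1 + n2 - 2
  phi <- pmax((prior_df * phi_common + df * phi_raw) / (prior_df + df), 1e-4)

  rows <- sel$row
  s1 <- round(rowSums(g1[rows, , drop = FALSE]))
  s2 <- round(rowSums(g2[rows, , drop = FALSE]))
  pvals <- vapply(seq_along(rows), function(i) {
    nb_exact_pvalue(s1[i], s2[i], n1, n2, phi[rows[i]])
  }, numeric(1))
  logfc <- log2((s1 / n1 + prior_count) / (s2 / n2 + prior_count))
  res <- sel |>
    mutate(
      mean_mutant = s1 / n1,
      mean_wildtype = s2 / n2,
      logFC = logfc,
      p_value = pvals,
      q_value = p.adjust(pvals, method = "BH"),
      significant = .data$q_value < q_threshold,
      direction = dplyr::case_when(
        .data$significant & .data$logFC > 0 ~ "up",
        .data$significant & .data$logFC < 0 ~ "down",
        TRUE ~ "ns"
      )
    ) |>
    arrange(.data$genomic_center) |>
    select("gene_id", "gene_name", "chrom", "genomic_center",
           "mean_mutant", "mean_wildtype", "logFC", "p_value", "q_value",
           "significant", "direction")
  attr(res, "groups") <- list(mutant = mut, wildtype = wt)
  attr(res, "q_threshold") <- q_threshold
  attr(res, "locus") <- split$locus
  class(res) <- c("fusegraph_de", class(res))
  res
}

#' @method tidy fusegraph_de
#' @export
tidy.fusegraph_de <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "fusegraph_de")
  as_tibble(out)
}

#' @method glance fusegraph_de
#' @export
glance.fusegraph_de <- function(x, ...) {
  g <- attr(x, "groups")
  tibble(
    n_genes = nrow(x),
    n_significant = sum(x$significant),
    n_up = sum(x$direction == "up"),
    n_down = sum(x$direction == "down"),
    n_mutant = length(g$mutant),
    n_wildtype = length(g$wildtype),
    q_threshold = attr(x, "q_threshold")
  )
}
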