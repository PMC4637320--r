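#' Direct PPI network among seed genes
#'
#' Induces the subgraph of the PPI restricted to the seed genes; a seed
#' participates in the direct network when it has at least one edge to
#' another seed. Seeds absent from the PPI are dropped with a message.
#'
#' @param seeds Character vector of seed gene ids.
#' @param ppi Undirected [igraph::graph] (see [read_ppi()]).
#' @return List with `subgraph` (igraph), `seeds` (those found in the PPI),
#'   `participants` (seeds with within-seed degree >= 1) and `degree`
#'   (named within-seed degrees).
#' @export
direct_network <- function(seeds, ppi) {
  seeds <- unique(seeds)
  found <- intersect(seeds, igraph::V(ppi)$name)
  missing <- setdiff(seeds, found)
  if (length(missing)) {
    message(length(missing), " seed(s) absent from the PPI, excluded")
  }
  if (!length(found)) stop("no seeds present in the PPI network",
                           call. = FALSE)
  sub <- igraph::induced_subgraph(ppi, found)
  deg <- igraph::degree(sub)[found]
  list(
    subgraph = sub,
    seeds = found,
    participants = found[deg >= 1],
    degree = deg
  )
}

# Degree bins over the whole PPI: quantile cut of node degree into at most
# `degree_bins` groups; bins too small to host their seeds without
# replacement are merged upward into the next bin.
degree_bin_assignment <- function(ppi, seeds, degree_bins) {
  deg <- igraph::degree(ppi)
  brk <- unique(stats::quantile(deg, probs = seq(0, 1,
                                                 length.out = degree_bins + 1)))
  bin <- as.integer(cut(deg, breaks = brk, include.lowest = TRUE))
  names(bin) <- names(deg)
  # a bin hosting nearly all of its own nodes as seeds makes the without-
  # replacement draw degenerate (it mostly re-selects the seeds); merge such
  # bins into their neighbor until every bin is at least twice its seed count
  repeat {
    levels_ <- sort(unique(bin))
    if (length(levels_) < 2) break
    counts_seed <- table(factor(bin[seeds], levels = levels_))
    counts_all <- table(factor(bin, levels = levels_))
    short <- names(counts_seed)[counts_seed > 0 &
                                  counts_all < 2 * counts_seed]
    if (!length(short)) break
    b <- as.integer(short[1])
    nb <- if (b == max(levels_)) levels_[length(levels_) - 1] else
      levels_[which(levels_ == b) + 1]
    warning("degree bin too small to sample without replacement; ",
            "merging adjacent bins")
    bin[bin == b] <- nb
  }
  bin
}

#' Permutation test of seed connectivity in a PPI network
#'
#' For each seed, the observed statistic is its number of direct links to
#' other seeds. Each permutation replaces every seed by a node drawn
#' uniformly (without replacement within the permutation) from the seed's
#' degree bin — degree quantiles over the whole PPI — and recomputes the
#' within-set degree. The per-seed p-value uses the +1 pseudo-count
#' estimator p = (1 + #{permuted >= observed}) / (n_perm + 1), so p is never
#' zero and never below 1/(n_perm + 1).
#'
#' @param seeds Seed gene ids (those absent from the PPI are dropped).
#' @param ppi Undirected [igraph::graph].
#' @param n_perm Number of permutations (>= 100; the study used 10,000).
#' @param degree_bins Number of degree-quantile bins (default 10); bins too
#'   small for their seeds are merged with a warning.
#' @param rng_seed Integer seed making the permutations reproducible.
#' @param statistic `"degree"` (default; per-seed within-set links, tested
#'   per seed) or `"edges"` (total edge count of the seed subgraph, one
#'   global p-value).
#' @return A `seed_connectivity` object; `tidy()` returns a tibble with
#'   `gene_id`, `degree_in_seed_subgraph`, `p_perm`, `rank`, `prioritized`
#'   (p < 0.05).
#' @export
permutation_connectivity <- function(seeds, ppi, n_perm = 10000,
                                     degree_bins = 10, rng_seed = 1,
                                     statistic = c("degree", "edges")) {
  statistic <- match.arg(statistic)
  if (n_perm < 100) stop("`n_perm` must be >= 100", call. = FALSE)
  dn <- direct_network(seeds, ppi)
  seeds <- dn$seeds
  observed <- dn$degree
  nodes <- igraph::V(ppi)$name
  A <- igraph::as_adjacency_matrix(ppi, sparse = TRUE)
  # dense indexing is much faster for the permutation loop on small graphs
  if (length(nodes) <= 4000) A <- as.matrix(A)
  bin <- degree_bin_assignment(ppi, seeds, degree_bins)
  seed_bins <- bin[seeds]
  bins_used <- sort(unique(seed_bins))
  members <- lapply(bins_used, function(b) which(bin == b))
  names(members) <- as.character(bins_used)
  n_in_bin <- table(factor(seed_bins, levels = bins_used))
  seed_pos <- lapply(bins_used, function(b) which(seed_bins == b))

  set.seed(rng_seed)
  ns <- length(seeds)
  exceed <- numeric(ns)
  obs_edges <- sum(observed) / 2
  exceed_edges <- 0
  idx <- integer(ns)
  for (p in seq_len(n_perm)) {
    for (bi in seq_along(bins_used)) {
      take <- sample(members[[bi]], n_in_bin[bi], replace = FALSE)
      idx[seed_pos[[bi]]] <- take
    }
    sub <- A[idx, idx, drop = FALSE]
    perm_deg <- Matrix::colSums(sub)
    exceed <- exceed + (perm_deg >= observed)
    if (statistic == "edges") {
      exceed_edges <- exceed_edges + (sum(perm_deg) / 2 >= obs_edges)
    }
  }
  p_perm <- (1 + exceed) / (n_perm + 1)
  ord <- order(p_perm, seeds)
  tab <- tibble::tibble(
    gene_id = seeds,
    degree_in_seed_subgraph = as.integer(observed),
    p_perm = p_perm
  )
  tab$rank <- NA_integer_
  tab$rank[ord] <- seq_len(ns)
  tab <- dplyr::arrange(tab, .data$rank) |>
    dplyr::mutate(prioritized = .data$p_perm < 0.05)
  structure(
    list(
      table = tab,
      n_perm = n_perm,
      degree_bins = degree_bins,
      rng_seed = rng_seed,
      statistic = statistic,
      p_edges = if (statistic == "edges")
        (1 + exceed_edges) / (n_perm + 1) else NA_real_,
      participants = dn$participants
    ),
    class = "seed_connectivity"
  )
}

#' @export
print.seed_connectivity <- function(x, ...) {
  cat("<seed_connectivity> ", nrow(x$table), " seeds, ",
      length(x$participants), " in the direct network; ",
      sum(x$table$prioritized), " prioritized at p < 0.05 (",
      x$n_perm, " permutations)\n", sep = "")
  invisible(x)
}

#' @rdname permutation_connectivity
#' @param x A `seed_connectivity` object.
#' @param ... Unused.
#' @export
tidy.seed_connectivity <- function(x, ...) x$table

#' @rdname permutation_connectivity
#' @export
glance.seed_connectivity <- function(x, ...) {
  tibble::tibble(
    n_seeds = nrow(x$table),
    n_participants = length(x$participants),
    n_prioritized = sum(x$table$prioritized),
    n_perm = x$n_perm,
    degree_bins = x$degree_bins
  )
}

#' Integrate network prioritization with target-gene co-expression
#'
#' Keeps seeds with permutation p < `p_max` and joins the pooled
#' co-expression columns; a prioritized seed missing from the co-expression
#' table is still reported, with `NA` correlation columns.
#'
#' @param seed_scores A `seed_connectivity` object or its tidy table.
#' @param cor_records A `meta_cor` object or its tidy table.
#' @param annotation Optional annotation tibble; adds the cytoband column.
#' @param p_max Permutation p-value cutoff (default 0.05).
#' @return Tibble sorted by `p_perm`: `gene_id`, `cytoband` (if available),
#'   `p_perm`, `r_pooled`, `se_r`, `q_cor`.
#' @export
integrate_prioritization <- function(seed_scores, cor_records,
                                     annotation = NULL, p_max = 0.05) {
  ss <- if (inherits(seed_scores, "seed_connectivity")) seed_scores$table
        else seed_scores
  ct <- if (inherits(cor_records, "meta_cor")) cor_records$table
        else cor_records
  out <- ss |>
    dplyr::filter(.data$p_perm < p_max) |>
    dplyr::left_join(
      dplyr::select(ct, "gene_id", "r_pooled", "se_r", q_cor = "q"),
      by = "gene_id"
    ) |>
    dplyr::arrange(.data$p_perm, .data$gene_id)
  if (!is.null(annotation)) {
    out <- dplyr::left_join(
      out, dplyr::select(annotation, "gene_id", "cytoband"),
      by = "gene_id"
    ) |>
      dplyr::relocate("cytoband", .after = "gene_id")
  }
  out
}
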