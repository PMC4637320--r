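#' Hypergeometric upper-tail probability
#'
#' P(X >= k) for X ~ Hypergeometric(N, K, n): the chance of drawing at least
#' `k` members of a `K`-gene set when sampling `n` genes from a universe of
#' `N` without replacement.
#'
#' @param k Observed overlap.
#' @param K Set size within the universe.
#' @param n Query size.
#' @param N Universe size.
#' @return The p-value.
#' @export
hypergeom_tail <- function(k, K, n, N) {
  if (any(k < 0 | K < 0 | n < 0 | N < 0) ||
      any(k > pmin(K, n)) || any(K > N) || any(n > N)) {
    stop("inconsistent hypergeometric counts", call. = FALSE)
  }
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Gene-set over-representation analysis
#'
#' Hypergeometric test of each set against a query list within a universe,
#' BH-corrected across the tested sets. Sets are intersected with the
#' universe first; sets left empty are not tested.
#'
#' @param query_genes Character vector of query gene ids (subset of
#'   `universe`).
#' @param sets Named list of character vectors (see [read_gene_sets()]).
#' @param universe Character vector of background gene ids.
#' @param alpha Significance threshold recorded in the `significant` column.
#' @return Tibble with `set_name`, `k`, `K`, `n`, `N`, `p`, `q`,
#'   `significant`, sorted by `q` then `p`.
#' @export
overrepresentation <- function(query_genes, sets, universe, alpha = 0.05) {
  query_genes <- unique(query_genes)
  if (!length(query_genes)) stop("empty query", call. = FALSE)
  extra <- setdiff(query_genes, universe)
  if (length(extra)) {
    stop("query gene(s) outside the universe: ",
         paste(utils::head(extra, 5), collapse = ", "), call. = FALSE)
  }
  sets_u <- lapply(sets, intersect, y = universe)
  sets_u <- sets_u[lengths(sets_u) >= 1]
  if (!length(sets_u)) return(tibble::tibble(
    set_name = character(), k = integer(), K = integer(), n = integer(),
    N = integer(), p = numeric(), q = numeric(), significant = logical()
  ))
  N <- length(universe)
  n <- length(query_genes)
  K <- lengths(sets_u)
  k <- vapply(sets_u, function(s) length(intersect(s, query_genes)), 0L)
  p <- hypergeom_tail(k, K, n, N)
  tibble::tibble(
    set_name = names(sets_u), k = unname(k), K = unname(K), n = n, N = N,
    p = unname(p), q = bh_fdr(unname(p))
  ) |>
    dplyr::mutate(significant = .data$q < alpha) |>
    dplyr::arrange(.data$q, .data$p, .data$set_name)
}

#' Build one gene set per cytoband from an annotation table
#'
#' @param annotation Annotation tibble with a `cytoband` column.
#' @return Named list of gene-id vectors, one per distinct band string;
#'   genes without a band are skipped.
#' @export
cytoband_sets <- function(annotation) {
  ann <- annotation[!is.na(annotation$cytoband), ]
  if (!nrow(ann)) stop("annotation carries no cytobands", call. = FALSE)
  split(ann$gene_id, ann$cytoband)
}

#' Positional scan for query-enriched genomic regions
#'
#' Candidate regions are all genomic intervals delimited by two query genes
#' on the same chromosome that contain at least `min_genes` universe genes.
#' Each candidate is scored by [hypergeom_tail()] (k = query genes inside,
#' K = universe genes inside), BH-corrected across all candidates, and a
#' greedy pass by ascending p keeps non-overlapping regions only.
#'
#' @param query_genes Query gene ids (e.g. significantly down-regulated).
#' @param annotation Annotation tibble covering the universe; unannotated
#'   universe genes are dropped from the background with a warning.
#' @param universe Background gene ids.
#' @param min_genes Minimum universe genes a candidate region must contain.
#' @param alpha Threshold recorded in the `significant` column.
#' @return Tibble of non-overlapping regions sorted by `p`: `chromosome`,
#'   `start`, `end` (0-based half-open, spanning the member-gene extremes),
#'   `start_1based`, `end_1based`, `k`, `K`, `n`, `N`, `p`, `q`,
#'   `genes_in_region` (comma-separated query members), `significant`.
#' @export
positional_scan <- function(query_genes, annotation, universe,
                            min_genes = 5, alpha = 0.05) {
  query_genes <- unique(query_genes)
  unann <- setdiff(universe, annotation$gene_id)
  if (length(unann)) {
    warning(length(unann), " universe gene(s) lack annotation; ",
            "excluded from the positional background")
    universe <- setdiff(universe, unann)
  }
  query_genes <- intersect(query_genes, universe)
  ann <- annotation[annotation$gene_id %in% universe, ] |>
    dplyr::arrange(.data$chromosome, .data$start, .data$end)
  N <- nrow(ann)
  n <- length(query_genes)
  empty <- tibble::tibble(
    chromosome = character(), start = numeric(), end = numeric(),
    start_1based = numeric(), end_1based = numeric(),
    k = integer(), K = integer(), n = integer(), N = integer(),
    p = numeric(), q = numeric(), genes_in_region = character(),
    significant = logical()
  )
  if (n == 0) return(empty)

  cand <- list()
  for (chr in unique(ann$chromosome)) {
    a <- ann[ann$chromosome == chr, ]
    is_q <- a$gene_id %in% query_genes
    qidx <- which(is_q)
    if (!length(qidx)) next
    cum_q <- cumsum(is_q)
    pairs <- expand.grid(i = qidx, j = qidx)
    pairs <- pairs[pairs$j >= pairs$i, ]
    K <- pairs$j - pairs$i + 1L
    keep <- K >= min_genes
    if (!any(keep)) next
    pairs <- pairs[keep, ]; K <- K[keep]
    k <- cum_q[pairs$j] - cum_q[pairs$i] + 1L
    cand[[chr]] <- tibble::tibble(
      chromosome = chr,
      i = pairs$i, j = pairs$j,
      start = a$start[pairs$i], end = a$end[pairs$j],
      k = as.integer(k), K = as.integer(K),
      genes_in_region = vapply(seq_along(pairs$i), function(r) {
        paste(a$gene_id[pairs$i[r]:pairs$j[r]][is_q[pairs$i[r]:pairs$j[r]]],
              collapse = ",")
      }, "")
    )
  }
  if (!length(cand)) return(empty)
  cand <- dplyr::bind_rows(cand)
  cand$p <- hypergeom_tail(cand$k, cand$K, n, N)
  cand$q <- bh_fdr(cand$p)

  # greedy non-overlap selection by ascending p (ties: wider region first,
  # then leftmost)
  cand <- cand |>
    dplyr::arrange(.data$p, dplyr::desc(.data$K), .data$chromosome,
                   .data$start)
  kept <- logical(nrow(cand))
  occupied <- list()
  for (r in seq_len(nrow(cand))) {
    chr <- cand$chromosome[r]
    iv <- occupied[[chr]]
    s <- cand$start[r]; e <- cand$end[r]
    if (is.null(iv) || !any(s < iv$end & e > iv$start)) {
      kept[r] <- TRUE
      occupied[[chr]] <- rbind(iv, data.frame(start = s, end = e))
    }
  }
  cand[kept, ] |>
    dplyr::transmute(
      .data$chromosome, .data$start, .data$end,
      start_1based = .data$start + 1, end_1based = .data$end,
      .data$k, .data$K, n = n, N = N, .data$p, .data$q,
      .data$genes_in_region,
      significant = .data$q < alpha
    )
}

#' Kernel-smoothed expression profile along a chromosome
#'
#' Nadaraya-Watson estimate with a Gaussian kernel over gene midpoints of a
#' per-gene statistic (typically the pooled effect size, or the mean
#' expression), evaluated on a grid rounded to 1 kb.
#'
#' @param values Named numeric vector (names = gene ids) of the per-gene
#'   statistic to smooth; genes missing from the annotation are skipped.
#' @param annotation Annotation tibble.
#' @param chromosome Chromosome to profile (needs >= 2 annotated genes with
#'   values).
#' @param bandwidth Gaussian kernel standard deviation in bp (> 0).
#' @param n_grid Number of grid points.
#' @return Tibble with `position` (bp, 1 kb grid) and `smoothed`.
#' @export
chromosome_profile <- function(values, annotation, chromosome,
                               bandwidth = 2e6, n_grid = 200) {
  if (bandwidth <= 0) stop("`bandwidth` must be positive", call. = FALSE)
  ann <- annotation[annotation$chromosome == chromosome &
                      annotation$gene_id %in% names(values), ]
  y <- values[ann$gene_id]
  ok <- !is.na(y)
  ann <- ann[ok, ]; y <- y[ok]
  if (nrow(ann) < 2) stop("need >= 2 annotated genes with values on ",
                          chromosome, call. = FALSE)
  mid <- (ann$start + ann$end) / 2
  grid <- seq(min(mid), max(mid), length.out = n_grid)
  grid <- round(grid / 1000) * 1000
  sm <- vapply(grid, function(x0) {
    w <- stats::dnorm((mid - x0) / bandwidth)
    sum(w * y) / sum(w)
  }, 0)
  tibble::tibble(position = grid, smoothed = sm)
}
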