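#' Per-cohort Pearson correlations with a target gene
#'
#' Correlates every other gene with the target over pairwise-complete
#' samples. Pairs with fewer than 4 complete observations (the Fisher-z
#' variance 1/(n-3) needs n > 3) or with a constant vector are reported as
#' `NA`. The target is excluded from its own output.
#'
#' @param study An [expression_study].
#' @param target_gene Gene id of the target (e.g. `"NF2"`).
#' @return Tibble with `gene_id`, `r`, `n` (complete pairs), `study_id`.
#' @export
study_correlations <- function(study, target_gene) {
  stopifnot(inherits(study, "expression_study"))
  if (!target_gene %in% study$gene_ids) {
    stop("target gene '", target_gene, "' not in study ", study$study_id,
         call. = FALSE)
  }
  m <- study$values
  tgt <- m[target_gene, ]
  others <- setdiff(study$gene_ids, target_gene)
  mo <- m[others, , drop = FALSE]
  n <- as.integer((!is.na(mo)) %*% (!is.na(tgt)))
  r <- suppressWarnings(
    as.numeric(stats::cor(t(mo), tgt, use = "pairwise.complete.obs"))
  )
  r[n < 4] <- NA_real_
  tibble::tibble(gene_id = others, r = r, n = n, study_id = study$study_id)
}

#' Pool correlations across cohorts on the Fisher-z scale
#'
#' Each correlation is transformed to z = atanh(r) with sampling variance
#' 1/(n-3), pooled by [dersimonian_laird()], tested against a standard
#' normal, and back-transformed to the correlation scale. Correlations at
#' exactly +/-1 are clamped just inside the open interval with a warning.
#'
#' @param r Per-study correlations.
#' @param n Per-study complete-pair counts (each > 3).
#' @return Named numeric vector `pooled_z`, `se_z`, `r_pooled`, `se_r`
#'   (delta method), `tau2`, `Q`, `p`, `n_studies`.
#' @export
meta_correlation <- function(r, n) {
  ok <- !is.na(r) & !is.na(n) & n > 3
  r <- r[ok]; n <- n[ok]
  if (!length(r)) stop("no valid studies to pool", call. = FALSE)
  if (any(abs(r) >= 1)) {
    warning("|r| = 1 clamped before the z transform")
    r <- pmin(pmax(r, -(1 - 1e-12)), 1 - 1e-12)
  }
  z <- atanh(r)
  dl <- dersimonian_laird(z, 1 / (n - 3))
  zp <- meta_z(dl[["pooled"]], dl[["se"]])
  r_pooled <- tanh(dl[["pooled"]])
  c(pooled_z = dl[["pooled"]], se_z = dl[["se"]],
    r_pooled = r_pooled, se_r = dl[["se"]] * (1 - r_pooled^2),
    tau2 = dl[["tau2"]], Q = dl[["Q"]], p = zp[["p"]],
    n_studies = dl[["k"]])
}

#' Target-gene co-expression meta-analysis across cohorts
#'
#' Runs [study_correlations()] in each cohort and [meta_correlation()] per
#' gene over the common universe, with BH correction across all genes.
#'
#' @param studies List of [expression_study] cohorts (>= 2).
#' @param target_gene Target gene id present in every cohort.
#' @return A `meta_cor` object; `tidy()` returns a tibble with `gene_id`,
#'   per-pooling columns (`pooled_z`, `se_z`, `r_pooled`, `se_r`, `tau2`,
#'   `Q`, `p`, `q`, `n_studies`).
#' @export
run_meta_cor <- function(studies, target_gene) {
  cu <- common_universe(studies)
  if (!target_gene %in% cu$universe) {
    stop("target gene '", target_gene, "' absent from the common universe",
         call. = FALSE)
  }
  per <- dplyr::bind_rows(
    lapply(cu$studies, study_correlations, target_gene = target_gene)
  )
  genes <- setdiff(cu$universe, target_gene)
  rmat <- matrix(NA_real_, length(genes), length(studies),
                 dimnames = list(genes, NULL))
  nmat <- rmat
  for (j in seq_along(cu$studies)) {
    sj <- per[per$study_id == cu$studies[[j]]$study_id, ]
    rmat[sj$gene_id, j] <- sj$r
    nmat[sj$gene_id, j] <- sj$n
  }
  res <- matrix(NA_real_, length(genes), 8,
                dimnames = list(genes, c("pooled_z", "se_z", "r_pooled",
                                         "se_r", "tau2", "Q", "p",
                                         "n_studies")))
  for (i in seq_along(genes)) {
    mc <- tryCatch(meta_correlation(rmat[i, ], nmat[i, ]),
                   error = function(e) NULL)
    if (!is.null(mc)) res[i, ] <- mc
  }
  tab <- tibble::as_tibble(res)
  tab <- dplyr::bind_cols(tibble::tibble(gene_id = genes), tab)
  tab$q <- bh_fdr(tab$p)
  structure(
    list(table = tab, target_gene = target_gene,
         per_study = per, study_ids = vapply(studies, `[[`, "", "study_id")),
    class = "meta_cor"
  )
}

#' @export
print.meta_cor <- function(x, ...) {
  cat("<meta_cor> target ", x$target_gene, ": ", nrow(x$table),
      " genes pooled over ", length(x$study_ids), " cohorts\n", sep = "")
  invisible(x)
}

#' @rdname run_meta_cor
#' @param x A `meta_cor` object.
#' @param ... Unused.
#' @export
tidy.meta_cor <- function(x, ...) x$table

#' @rdname run_meta_cor
#' @export
glance.meta_cor <- function(x, ...) {
  tibble::tibble(
    target_gene = x$target_gene,
    n_genes = nrow(x$table),
    n_studies = length(x$study_ids),
    n_selected_default = nrow(select_coexpressed(x))
  )
}

#' Select significantly co-expressed genes
#'
#' Genes whose back-transformed pooled correlation exceeds `r_min` and whose
#' BH-adjusted p-value is below `alpha`, sorted by descending `r_pooled`
#' (ties broken by gene id).
#'
#' @param records A `meta_cor` object or its `tidy()` table.
#' @param r_min Minimum pooled correlation (default 0.4).
#' @param alpha FDR threshold (default 0.05).
#' @return Tibble of selected records.
#' @export
select_coexpressed <- function(records, r_min = 0.4, alpha = 0.05) {
  tab <- if (inherits(records, "meta_cor")) records$table else records
  tab |>
    dplyr::filter(!is.na(.data$r_pooled), !is.na(.data$q),
                  .data$r_pooled > r_min, .data$q < alpha) |>
    dplyr::arrange(dplyr::desc(.data$r_pooled), .data$gene_id)
}

#' Physical neighborhood report around a target gene
#'
#' Genes on the target's chromosome whose interval intersects the window
#' `[target_start - window, target_end + window)`, joined with
#' differential-expression direction and co-expression selection flags.
#'
#' @param target_gene Target gene id (must be annotated).
#' @param annotation Annotation tibble (see [read_annotation()]).
#' @param window Flank size in bp on each side (default 500 kb).
#' @param meta_de Optional `meta_de` object or tidy table to join
#'   (`direction`, `consensus`).
#' @param meta_cor Optional `meta_cor` object/table; adds `r_pooled`, `q_cor`
#'   and a `correlated` flag per [select_coexpressed()] thresholds.
#' @param r_min,alpha Selection thresholds used for the `correlated` flag.
#' @return Tibble of neighbors (target excluded) ordered by start, with
#'   1-based inclusive `start_1based`/`end_1based` report columns.
#' @export
flanking_genes <- function(target_gene, annotation, window = 5e5,
                           meta_de = NULL, meta_cor = NULL,
                           r_min = 0.4, alpha = 0.05) {
  tgt <- annotation[annotation$gene_id == target_gene, ]
  if (nrow(tgt) != 1) stop("target gene '", target_gene,
                           "' not annotated", call. = FALSE)
  lo <- tgt$start - window
  hi <- tgt$end + window
  nb <- annotation |>
    dplyr::filter(.data$chromosome == tgt$chromosome,
                  .data$gene_id != target_gene,
                  .data$start < hi, .data$end > lo) |>
    dplyr::arrange(.data$start) |>
    dplyr::mutate(start_1based = .data$start + 1, end_1based = .data$end)
  if (!is.null(meta_de)) {
    de <- if (inherits(meta_de, "meta_de")) meta_de$table else meta_de
    nb <- dplyr::left_join(
      nb, dplyr::select(de, "gene_id", "direction", "consensus"),
      by = "gene_id"
    )
  }
  if (!is.null(meta_cor)) {
    ct <- if (inherits(meta_cor, "meta_cor")) meta_cor$table else meta_cor
    sel <- select_coexpressed(ct, r_min = r_min, alpha = alpha)$gene_id
    nb <- dplyr::left_join(
      nb,
      dplyr::select(ct, "gene_id", "r_pooled", q_cor = "q"),
      by = "gene_id"
    ) |>
      dplyr::mutate(correlated = .data$gene_id %in% sel)
  }
  nb
}
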