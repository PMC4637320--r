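#' Filter out rows with too many missing values
#'
#' Removes genes whose fraction of missing samples is strictly greater than
#' `max_missing_frac` (the study filter is "more than 30% missing", so a row
#' at exactly the threshold is kept).
#'
#' @param study An [expression_study].
#' @param max_missing_frac Maximum tolerated missing fraction, in `[0, 1)`.
#' @return The filtered [expression_study].
#' @export
filter_missing <- function(study, max_missing_frac = 0.30) {
  stopifnot(inherits(study, "expression_study"))
  if (max_missing_frac < 0 || max_missing_frac >= 1) {
    stop("`max_missing_frac` must be in [0, 1)", call. = FALSE)
  }
  frac <- rowMeans(is.na(study$values))
  keep <- frac <= max_missing_frac
  if (!any(keep)) stop("all genes removed by the missing-value filter",
                       call. = FALSE)
  expression_study(study$values[keep, , drop = FALSE], study$group,
                   study_id = study$study_id)
}

#' Collapse multiple probes per gene to one row
#'
#' When several probes map to the same gene, the probe with the highest mean
#' expression over its non-missing samples is kept; ties go to the
#' lexicographically smallest probe id. Unmapped probes (`NA` gene) are
#' dropped.
#'
#' @param values Numeric matrix, probes x samples, probe ids as rownames.
#' @param probe_gene Named character vector mapping probe id -> gene id
#'   (many-to-one allowed); probes absent from the map are dropped.
#' @param group Per-sample group labels (see [expression_study]).
#' @param study_id Cohort identifier.
#' @return An [expression_study] with one row per gene.
#' @export
collapse_probes <- function(values, probe_gene, group, study_id = "study") {
  stopifnot(is.matrix(values), !is.null(rownames(values)))
  probes <- intersect(rownames(values), names(probe_gene))
  probes <- probes[!is.na(probe_gene[probes])]
  if (!length(probes)) stop("no mapped probes", call. = FALSE)
  means <- rowMeans(values[probes, , drop = FALSE], na.rm = TRUE)
  pick <- tibble::tibble(
    probe_id = probes,
    gene_id  = unname(probe_gene[probes]),
    mean     = unname(means)
  ) |>
    dplyr::arrange(.data$gene_id, dplyr::desc(.data$mean), .data$probe_id) |>
    dplyr::distinct(.data$gene_id, .keep_all = TRUE)
  m <- values[pick$probe_id, , drop = FALSE]
  rownames(m) <- pick$gene_id
  expression_study(m, group, study_id = study_id)
}

#' Common gene universe across cohorts
#'
#' Both combination methods require every gene to be measured in every
#' cohort, so the meta-analysis operates on the sorted intersection of the
#' studies' gene lists.
#'
#' @param studies List of [expression_study] objects (at least two).
#' @return List with `universe` (sorted gene ids) and `studies` (the inputs
#'   sliced and row-ordered to the universe).
#' @export
common_universe <- function(studies) {
  stopifnot(is.list(studies), length(studies) >= 2)
  universe <- Reduce(intersect, lapply(studies, function(s) s$gene_ids))
  if (!length(universe)) stop("empty gene intersection across studies",
                              call. = FALSE)
  universe <- sort(universe)
  sliced <- lapply(studies, function(s) {
    expression_study(s$values[universe, , drop = FALSE], s$group,
                     study_id = s$study_id)
  })
  list(universe = universe, studies = sliced)
}
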