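#' Construct and validate an expression cohort
#'
#' An `expression_study` bundles one cohort: a genes x samples matrix of
#' normalized log2 expression values (missing values allowed) together with a
#' two-level group label per sample, `"spinal"` or `"intracranial"`.
#'
#' @param values Numeric matrix, genes in rows (rownames = gene ids) and
#'   samples in columns (colnames = sample ids). `NA` marks missing cells.
#' @param group Character vector of per-sample labels, one per column of
#'   `values`, each `"spinal"` or `"intracranial"`. May be named by sample id.
#' @param study_id Short identifier for the cohort.
#'
#' @return An object of class `expression_study` with elements `study_id`,
#'   `gene_ids`, `sample_ids`, `values` and `group`.
#' @export
#' @examples
#' m <- matrix(rnorm(12), 3, 4,
#'             dimnames = list(paste0("G", 1:3), paste0("S", 1:4)))
#' expression_study(m, c("spinal", "spinal", "intracranial", "intracranial"))
expression_study <- function(values, group, study_id = "study") {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must carry gene ids as rownames and sample ids as colnames",
         call. = FALSE)
  }
  if (!is.null(names(group))) {
    if (!setequal(names(group), colnames(values))) {
      stop("names of `group` do not match the sample ids", call. = FALSE)
    }
    group <- group[colnames(values)]
  }
  group <- as.character(group)
  x <- structure(
    list(
      study_id   = as.character(study_id)[1],
      gene_ids   = rownames(values),
      sample_ids = colnames(values),
      values     = values,
      group      = group
    ),
    class = "expression_study"
  )
  validate_expression_study(x)
}

#' @rdname expression_study
#' @param x An `expression_study`.
#' @export
validate_expression_study <- function(x) {
  stopifnot(inherits(x, "expression_study"))
  if (anyDuplicated(x$gene_ids)) {
    dup <- unique(x$gene_ids[duplicated(x$gene_ids)])
    stop("duplicate gene ids: ", paste(utils::head(dup, 5), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(x$sample_ids)) {
    stop("duplicate sample ids", call. = FALSE)
  }
  if (nrow(x$values) != length(x$gene_ids) ||
      ncol(x$values) != length(x$sample_ids) ||
      length(x$group) != length(x$sample_ids)) {
    stop("matrix dimensions do not match id lists", call. = FALSE)
  }
  bad <- setdiff(unique(x$group), c("spinal", "intracranial"))
  if (length(bad)) {
    stop("unknown group label(s): ", paste(bad, collapse = ", "),
         "; expected 'spinal'/'intracranial' (see `group_map`)", call. = FALSE)
  }
  tab <- table(factor(x$group, levels = c("spinal", "intracranial")))
  if (any(tab < 2)) {
    stop("each group needs at least 2 samples (got spinal=", tab[["spinal"]],
         ", intracranial=", tab[["intracranial"]], ")", call. = FALSE)
  }
  x
}

#' @export
print.expression_study <- function(x, ...) {
  tab <- table(x$group)
  cat("<expression_study> ", x$study_id, ": ",
      length(x$gene_ids), " genes x ", length(x$sample_ids), " samples (",
      paste(names(tab), tab, sep = "=", collapse = ", "), "), ",
      sum(is.na(x$values)), " missing cells\n", sep = "")
  invisible(x)
}

resolve_groups <- function(groups, sample_ids, group_map = NULL) {
  if (is.character(groups) && length(groups) == 1 && file.exists(groups)) {
    tab <- utils::read.table(groups, header = TRUE, sep = "\t",
                             colClasses = "character")
    groups <- stats::setNames(tab[[2]], tab[[1]])
  }
  if (is.null(names(groups))) {
    if (length(groups) != length(sample_ids)) {
      stop("group labels must be named by sample id or match sample count",
           call. = FALSE)
    }
    names(groups) <- sample_ids
  }
  missing <- setdiff(sample_ids, names(groups))
  if (length(missing)) {
    stop("no group label for sample(s): ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  g <- as.character(groups[sample_ids])
  if (!is.null(group_map)) {
    unmapped <- setdiff(unique(g), names(group_map))
    if (length(unmapped)) {
      stop("group_map has no entry for label(s): ",
           paste(unmapped, collapse = ", "), call. = FALSE)
    }
    g <- unname(group_map[g])
  }
  g
}

#' Read an expression matrix with group labels
#'
#' Reads a genes x samples log2 expression matrix from TSV (first column =
#' gene id, remaining columns = samples) or GCT v1.2, attaches per-sample
#' group labels and validates the result. Cells that are empty or `NA` are
#' kept as missing values.
#'
#' @param path Path to the matrix file.
#' @param format `"tsv"` or `"gct"`.
#' @param groups Per-sample group labels: a (optionally named) character
#'   vector, or the path of a two-column TSV (`sample_id`, `group`) with a
#'   header row.
#' @param group_map Optional named character vector translating arbitrary
#'   labels in `groups` to `"spinal"`/`"intracranial"`,
#'   e.g. `c(SP = "spinal", IC = "intracranial")`.
#' @param study_id Cohort identifier stored on the returned object.
#'
#' @return A validated [expression_study].
#' @export
read_expression <- function(path, format = c("tsv", "gct"), groups,
                            group_map = NULL, study_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(study_id)) {
    study_id <- sub("\\.[^.]*$", "", basename(path))
  }
  if (format == "tsv") {
    tab <- readr::read_tsv(path, comment = "#", na = c("", "NA"),
                           show_col_types = FALSE)
    gene_ids <- as.character(tab[[1]])
    m <- as.matrix(tab[, -1, drop = FALSE])
  } else {
    lines <- readLines(path)
    if (length(lines) < 3 || !startsWith(lines[1], "#1.2")) {
      stop("not a GCT v1.2 file: ", path, call. = FALSE)
    }
    dims <- as.integer(strsplit(lines[2], "\t", fixed = TRUE)[[1]][1:2])
    body <- utils::read.table(text = lines[-(1:2)], header = TRUE, sep = "\t",
                              check.names = FALSE, na.strings = c("", "NA"),
                              quote = "")
    if (nrow(body) != dims[1] || ncol(body) - 2L != dims[2]) {
      stop("GCT header counts (", dims[1], " x ", dims[2],
           ") disagree with body (", nrow(body), " x ", ncol(body) - 2L, ")",
           call. = FALSE)
    }
    gene_ids <- as.character(body[[1]])
    m <- as.matrix(body[, -(1:2), drop = FALSE])
  }
  if (anyDuplicated(gene_ids)) {
    dup <- unique(gene_ids[duplicated(gene_ids)])
    stop("duplicate gene ids in ", path, ": ",
         paste(utils::head(dup, 5), collapse = ", "), call. = FALSE)
  }
  storage.mode(m) <- "double"
  rownames(m) <- gene_ids
  group <- resolve_groups(groups, colnames(m), group_map)
  expression_study(m, group, study_id = study_id)
}

#' Write an expression cohort to TSV (plus a sample sheet)
#'
#' @param study An [expression_study].
#' @param path Output TSV path for the matrix; a companion
#'   `<path>.samples.tsv` sample sheet (`sample_id`, `group`) is written
#'   alongside.
#' @return `path`, invisibly.
#' @export
write_expression <- function(study, path) {
  tab <- tibble::as_tibble(study$values, .name_repair = "minimal")
  tab <- dplyr::bind_cols(tibble::tibble(gene_id = study$gene_ids), tab)
  readr::write_tsv(tab, path, na = "NA")
  readr::write_tsv(
    tibble::tibble(sample_id = study$sample_ids, group = study$group),
    paste0(path, ".samples.tsv")
  )
  invisible(path)
}

#' Read gene genomic annotation from BED
#'
#' BED coordinates are 0-based half-open and are kept that way internally;
#' report writers add 1-based inclusive columns. The BED `name` column holds
#' the gene id; an optional 7th column holds the cytoband (e.g. `"22q13"`).
#'
#' @param path BED file path.
#' @return A tibble with columns `gene_id`, `chromosome`, `start`, `end`,
#'   `cytoband` (`NA` when absent).
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           comment.char = "#", quote = "",
                           colClasses = "character")
  if (ncol(tab) < 4) stop("BED needs at least 4 columns", call. = FALSE)
  ann <- tibble::tibble(
    gene_id    = tab[[4]],
    chromosome = tab[[1]],
    start      = as.numeric(tab[[2]]),
    end        = as.numeric(tab[[3]]),
    cytoband   = if (ncol(tab) >= 7) tab[[7]] else NA_character_
  )
  bad <- ann$start >= ann$end
  if (any(bad)) {
    stop("start >= end for gene(s): ",
         paste(utils::head(ann$gene_id[bad], 5), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(ann$gene_id)) {
    dup <- unique(ann$gene_id[duplicated(ann$gene_id)])
    stop("duplicated gene_id in annotation: ",
         paste(utils::head(dup, 5), collapse = ", "), call. = FALSE)
  }
  ann
}

#' Write gene annotation as BED
#'
#' @param annotation Tibble as returned by [read_annotation()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(annotation, path) {
  bed <- data.frame(
    chrom = annotation$chromosome,
    start = format(annotation$start, scientific = FALSE, trim = TRUE),
    end   = format(annotation$end, scientific = FALSE, trim = TRUE),
    name  = annotation$gene_id,
    score = ".",
    strand = "+",
    cytoband = ifelse(is.na(annotation$cytoband), ".", annotation$cytoband)
  )
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a gene-set collection from GMT
#'
#' One set per line: name, description, then tab-separated member ids.
#'
#' @param path GMT file path.
#' @return Named list of character vectors (the sets), with a
#'   `"description"` attribute holding the per-set descriptions.
#' @export
read_gene_sets <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty GMT file: ", path, call. = FALSE)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  names_ <- vapply(parts, `[[`, "", 1)
  if (anyDuplicated(names_)) stop("duplicate set names in GMT", call. = FALSE)
  desc <- vapply(parts, function(p) if (length(p) >= 2) p[2] else "", "")
  sets <- lapply(parts, function(p) unique(p[-(1:2)][nzchar(p[-(1:2)])]))
  empty <- lengths(sets) == 0
  if (any(empty)) {
    stop("empty gene set(s): ", paste(names_[empty], collapse = ", "),
         call. = FALSE)
  }
  names(sets) <- names_
  attr(sets, "description") <- stats::setNames(desc, names_)
  sets
}

#' Write a gene-set collection to GMT
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param description Optional named descriptions; defaults to the
#'   `"description"` attribute or `"na"`.
#' @return `path`, invisibly.
#' @export
write_gene_sets <- function(sets, path, description = NULL) {
  if (is.null(description)) description <- attr(sets, "description")
  if (is.null(description)) {
    description <- stats::setNames(rep("na", length(sets)), names(sets))
  }
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, description[[nm]], sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a protein-protein interaction network
#'
#' Accepts SIF (`node relation node`) or a two-column TSV edge list. The
#' network is undirected and simple: reciprocal duplicates are merged and
#' self-loops dropped.
#'
#' @param path Edge-list file.
#' @return An undirected simple [igraph::graph] on gene ids.
#' @export
read_ppi <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           comment.char = "#", quote = "",
                           colClasses = "character")
  if (ncol(tab) >= 3) {
    edges <- tab[, c(1, 3)]            # SIF: source, relation, target(s)
  } else if (ncol(tab) == 2) {
    edges <- tab
  } else {
    stop("PPI file needs 2 (TSV) or 3 (SIF) columns", call. = FALSE)
  }
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  if (igraph::ecount(g) == 0) stop("empty PPI network: ", path, call. = FALSE)
  g
}

#' Write a PPI network as SIF
#'
#' @param graph Undirected [igraph::graph].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ppi <- function(graph, path) {
  el <- igraph::as_edgelist(graph)
  writeLines(paste(el[, 1], "pp", el[, 2], sep = "\t"), path)
  invisible(path)
}

#' Write a result table as TSV with a provenance header
#'
#' Prepends `#`-prefixed comment lines recording the package version and any
#' parameters supplied, then the table itself with a header row.
#'
#' @param tbl A data frame.
#' @param path Output path.
#' @param params Optional named list recorded in the header (seed,
#'   thresholds, ...).
#' @return `path`, invisibly.
#' @export
write_result_table <- function(tbl, path, params = list()) {
  header <- paste0("# ependymeta ",
                   as.character(utils::packageVersion("ependymeta")))
  if (length(params)) {
    kv <- paste(names(params),
                vapply(params, function(v) paste(format(v), collapse = ","), ""),
                sep = "=", collapse = " ")
    header <- c(header, paste0("# ", kv))
  }
  writeLines(header, path)
  suppressWarnings(
    utils::write.table(tbl, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE,
                       append = TRUE, na = "NA")
  )
  invisible(path)
}

#' Read back a TSV result table, skipping provenance comments
#'
#' @param path TSV path written by [write_result_table()].
#' @return A tibble.
#' @export
read_result_table <- function(path) {
  readr::read_tsv(path, comment = "#", na = "NA", show_col_types = FALSE)
}
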