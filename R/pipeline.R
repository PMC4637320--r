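#' Pipeline configuration
#'
#' Bundles the analysis thresholds, the RNG seed, and the synthetic-cohort
#' configuration used by [run_pipeline()]. Can also be loaded from a
#' YAML/JSON file whose keys match the arguments.
#'
#' @param rng_seed Global seed; per-stage child seeds are derived from it so
#'   stages are reproducible in isolation.
#' @param alpha FDR threshold for differential expression and enrichment.
#' @param r_min Pooled-correlation threshold for co-expression selection.
#' @param flank Flanking window around the hub gene, bp.
#' @param min_genes Minimum universe genes per candidate region.
#' @param n_perm Permutations for the PPI connectivity test.
#' @param max_missing Missing-fraction filter threshold.
#' @param sim A [simulation_config()] describing the synthetic cohorts
#'   (its own `rng_seed` is overridden by the derived stage seed).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(rng_seed = 1, alpha = 0.05, r_min = 0.4,
                            flank = 5e5, min_genes = 5, n_perm = 10000,
                            max_missing = 0.30,
                            sim = simulation_config()) {
  stopifnot(alpha > 0, alpha < 1, r_min >= 0, r_min < 1, flank >= 0,
            min_genes >= 2, n_perm >= 100,
            max_missing >= 0, max_missing < 1)
  structure(
    list(rng_seed = as.integer(rng_seed), alpha = alpha, r_min = r_min,
         flank = flank, min_genes = min_genes, n_perm = n_perm,
         max_missing = max_missing, sim = sim),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML or JSON
#'
#' @param path Config file; top-level keys match [pipeline_config()]
#'   arguments, with an optional nested `sim` block matching
#'   [simulation_config()].
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                          simplifyVector = TRUE)
         else yaml::read_yaml(path)
  sim_args <- raw$sim %||% list()
  if (!is.null(sim_args$group_sizes)) {
    sim_args$group_sizes <- lapply(sim_args$group_sizes, as.numeric)
  }
  raw$sim <- NULL
  args <- raw[intersect(names(raw), names(formals(pipeline_config)))]
  args$sim <- do.call(simulation_config, sim_args)
  do.call(pipeline_config, args)
}

stage_seed <- function(rng_seed, stage) {
  as.integer((as.numeric(rng_seed) * 131 + stage * 7919) %% 2147483647)
}

write_stage_table <- function(tbl, path, params) {
  partial <- paste0(path, ".partial")
  write_result_table(tbl, partial, params)
  file.rename(partial, path)
  invisible(path)
}

#' Run the full multi-cohort analysis pipeline
#'
#' Executes simulate -> preprocess -> differential-expression meta-analysis
#' -> hub-gene co-expression meta-analysis -> enrichment (cytoband
#' over-representation, positional region scan, chromosome profile) ->
#' PPI permutation prioritization, writing every stage's TSV output with a
#' provenance header plus a JSON run manifest into `out_dir`. A stage
#' failure aborts with the stage named; its half-written output keeps a
#' `.partial` suffix.
#'
#' @param config A [pipeline_config()] or the path of a YAML/JSON config.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the fitted stage objects, the ground
#'   truth, and the manifest.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempfile("run")) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- character()
  rows <- integer()
  run_stage <- function(name, expr) {
    message("[ependymeta] stage: ", name)
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  base_params <- list(seed = config$rng_seed, alpha = config$alpha)

  # 1: simulate -------------------------------------------------------------
  sim <- run_stage("simulate", {
    cfg <- config$sim
    cfg$rng_seed <- stage_seed(config$rng_seed, 1)
    out <- simulate_cohorts(cfg)
    for (s in out$studies) {
      write_expression(s, file.path(out_dir, paste0(s$study_id, ".tsv")))
    }
    write_annotation(out$annotation, file.path(out_dir, "genes.bed"))
    write_gene_sets(out$gene_sets, file.path(out_dir, "sets.gmt"))
    write_ppi(out$ppi, file.path(out_dir, "ppi.sif"))
    out
  })
  stages <- c(stages, "simulate")
  rows <- c(rows, config$sim$n_genes)

  # 2: preprocess -----------------------------------------------------------
  prep <- run_stage("preprocess", {
    filtered <- lapply(sim$studies, filter_missing,
                       max_missing_frac = config$max_missing)
    common_universe(filtered)
  })
  stages <- c(stages, "preprocess")
  rows <- c(rows, length(prep$universe))

  # 3: differential-expression meta-analysis --------------------------------
  de <- run_stage("meta_de", {
    fit <- run_meta_de(prep$studies, alpha = config$alpha)
    write_stage_table(tidy(fit), file.path(out_dir, "meta_de.tsv"),
                      base_params)
    fit
  })
  stages <- c(stages, "meta_de")
  rows <- c(rows, nrow(de$table))

  # 4: hub-gene co-expression meta-analysis ---------------------------------
  coexpr <- run_stage("coexpr", {
    fit <- run_meta_cor(prep$studies, target_gene = sim$truth$hub_gene)
    write_stage_table(tidy(fit), file.path(out_dir, "coexpr.tsv"),
                      c(base_params, list(target = sim$truth$hub_gene,
                                          r_min = config$r_min)))
    flank <- flanking_genes(sim$truth$hub_gene, sim$annotation,
                            window = config$flank, meta_de = de,
                            meta_cor = fit, r_min = config$r_min,
                            alpha = config$alpha)
    write_stage_table(flank, file.path(out_dir, "flanking.tsv"),
                      c(base_params, list(flank = config$flank)))
    list(fit = fit, flank = flank)
  })
  stages <- c(stages, "coexpr")
  rows <- c(rows, nrow(coexpr$fit$table))

  # 5: enrichment -----------------------------------------------------------
  enrich <- run_stage("enrichment", {
    det <- tidy(de)
    down <- det$gene_id[det$consensus & det$direction == "down"]
    ov <- overrepresentation(down, sim$gene_sets, de$universe,
                             alpha = config$alpha)
    write_stage_table(ov, file.path(out_dir, "enrichment.tsv"), base_params)
    regions <- positional_scan(down, sim$annotation, de$universe,
                               min_genes = config$min_genes,
                               alpha = config$alpha)
    write_stage_table(regions, file.path(out_dir, "regions.tsv"),
                      c(base_params, list(min_genes = config$min_genes)))
    es <- stats::setNames(det$pooled_es, det$gene_id)
    profile <- chromosome_profile(es, sim$annotation,
                                  config$sim$block_chromosome)
    write_stage_table(profile, file.path(out_dir, "profile.tsv"),
                      c(base_params,
                        list(chromosome = config$sim$block_chromosome)))
    list(query_down = down, overrep = ov, regions = regions,
         profile = profile)
  })
  stages <- c(stages, "enrichment")
  rows <- c(rows, nrow(enrich$regions))

  # 6: PPI prioritization ---------------------------------------------------
  prior <- run_stage("prioritize", {
    ann <- sim$annotation
    chr_genes <- ann$gene_id[ann$chromosome == config$sim$block_chromosome]
    seeds <- setdiff(intersect(enrich$query_down, chr_genes),
                     sim$truth$hub_gene)
    if (!length(seeds)) stop("no down-regulated seeds on ",
                             config$sim$block_chromosome)
    fit <- permutation_connectivity(seeds, sim$ppi, n_perm = config$n_perm,
                                    rng_seed = stage_seed(config$rng_seed, 6))
    report <- integrate_prioritization(fit, coexpr$fit,
                                       annotation = sim$annotation)
    write_stage_table(tidy(fit), file.path(out_dir, "seed_scores.tsv"),
                      c(base_params, list(n_perm = config$n_perm)))
    write_stage_table(report, file.path(out_dir, "prioritized.tsv"),
                      c(base_params, list(n_perm = config$n_perm)))
    list(fit = fit, report = report)
  })
  stages <- c(stages, "prioritize")
  rows <- c(rows, nrow(prior$fit$table))

  manifest <- list(
    tool = "ependymeta",
    version = as.character(utils::packageVersion("ependymeta")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    rng_seed = config$rng_seed,
    parameters = config[c("alpha", "r_min", "flank", "min_genes", "n_perm",
                          "max_missing")],
    stages = data.frame(stage = stages, rows = rows)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(sim = sim, universe = prep$universe, meta_de = de,
                 meta_cor = coexpr$fit, flanking = coexpr$flank,
                 enrichment = enrich, prioritization = prior,
                 manifest = manifest, out_dir = out_dir))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
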