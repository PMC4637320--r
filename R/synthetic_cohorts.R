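#' Configuration for the synthetic three-cohort generator
#'
#' Defaults emulate the study design: three microarray cohorts with
#' intracranial/spinal group sizes 71/12, 85/19 and 65/10, a planted set of
#' differentially expressed genes, a contiguous suppressed block on one
#' chromosome (the chromosome-22 analog, containing the hub gene), a
#' hub-gene co-expression module driven by a shared latent factor, per-cohort
#' batch shift/scale, MCAR missingness, and a PPI network with a planted
#' clique among block genes.
#'
#' @param rng_seed Integer seed; the whole simulation is deterministic given
#'   it.
#' @param n_genes Universe size.
#' @param group_sizes List of `c(intracranial, spinal)` pairs, one per
#'   cohort.
#' @param de_fraction Fraction of genes planted as differentially expressed
#'   (outside the block).
#' @param de_effect_g Absolute standardized effect (Hedges-g scale) of
#'   planted DE genes; signs are split evenly.
#' @param block_chromosome,block_size,block_effect Suppressed block:
#'   chromosome name, number of contiguous genes, standardized effect
#'   (negative = down in spinal).
#' @param hub_gene Id given to the module hub (a central block gene).
#' @param module_size,module_r Co-expression module size (including the hub)
#'   and target pairwise correlation; the latent-factor loading is
#'   `sqrt(module_r)`.
#' @param missing_rate Per-cohort MCAR missing-cell probability.
#' @param study_shift,study_scale Per-cohort additive shift and
#'   multiplicative scale (batch structure the meta-analysis must absorb).
#' @param n_chromosomes Number of synthetic chromosomes; genes are assigned
#'   in consecutive chunks and spaced 100 kb apart, with cytobands of 30
#'   consecutive genes.
#' @param ppi_nodes,ppi_mean_degree,ppi_clique_size PPI: node count (block
#'   genes always included), mean degree of the random graph, and size of
#'   the planted clique among block genes (hub excluded).
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(rng_seed = 1,
                              n_genes = 3000,
                              group_sizes = list(c(71, 12), c(85, 19),
                                                 c(65, 10)),
                              de_fraction = 0.10,
                              de_effect_g = 1.5,
                              block_chromosome = "chr22",
                              block_size = 40,
                              block_effect = -1.2,
                              hub_gene = "NF2",
                              module_size = 50,
                              module_r = 0.6,
                              missing_rate = c(0, 0, 0.05),
                              study_shift = c(0, 0.4, -0.3),
                              study_scale = c(1, 1.1, 0.9),
                              n_chromosomes = 22,
                              ppi_nodes = 2000,
                              ppi_mean_degree = 6,
                              ppi_clique_size = 8) {
  cfg <- list(
    rng_seed = rng_seed, n_genes = n_genes, group_sizes = group_sizes,
    de_fraction = de_fraction, de_effect_g = de_effect_g,
    block_chromosome = block_chromosome, block_size = block_size,
    block_effect = block_effect, hub_gene = hub_gene,
    module_size = module_size, module_r = module_r,
    missing_rate = missing_rate, study_shift = study_shift,
    study_scale = study_scale, n_chromosomes = n_chromosomes,
    ppi_nodes = ppi_nodes, ppi_mean_degree = ppi_mean_degree,
    ppi_clique_size = ppi_clique_size
  )
  stopifnot(
    cfg$de_fraction >= 0, cfg$de_fraction <= 1,
    cfg$module_r >= 0, cfg$module_r < 1,
    all(vapply(cfg$group_sizes, min, 0) >= 2),
    all(cfg$missing_rate >= 0 & cfg$missing_rate < 1),
    is.finite(cfg$de_effect_g), is.finite(cfg$block_effect)
  )
  if (cfg$ppi_clique_size > cfg$block_size) {
    stop("clique_size cannot exceed block_size", call. = FALSE)
  }
  if (length(cfg$missing_rate) != length(cfg$group_sizes) ||
      length(cfg$study_shift) != length(cfg$group_sizes) ||
      length(cfg$study_scale) != length(cfg$group_sizes)) {
    stop("per-cohort vectors must match the number of cohorts",
         call. = FALSE)
  }
  structure(cfg, class = "simulation_config")
}

#' Generate synthetic cohorts with planted ground truth
#'
#' Expression for gene g, sample s of cohort j is
#' `shift_j + scale_j * (mu_g + delta_gs + sigma_g * e_gs)` where `mu_g ~
#' N(7, 1)` is a shared baseline, `sigma_g^2` follows a scaled inverse
#' chi-square (d0 = 4, s0^2 = 0.25), `delta_gs = g_true * sigma_g` for
#' spinal samples of planted genes (so the standardized effect equals
#' `g_true` regardless of the gene's noise level), and module genes share a
#' per-sample latent factor: `e = sqrt(r) f + sqrt(1 - r) eps`. Cells are
#' then masked MCAR at the cohort's missing rate.
#'
#' @param config A [simulation_config()].
#' @return List with `studies` (list of [expression_study]), `annotation`,
#'   `gene_sets` (cytoband sets plus decoys), `ppi` (igraph), and `truth`
#'   (list: `de` tibble of `gene_id`/`true_g`, `block_genes`,
#'   `block_region`, `module_members`, `clique_members`, `hub_gene`).
#' @export
simulate_cohorts <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$rng_seed)
  n <- config$n_genes
  gene_ids <- sprintf("G%05d", seq_len(n))

  # chromosomes in consecutive near-equal chunks, genes 100 kb apart,
  # 20 kb long
  chrom_of <- paste0("chr",
                     sort(rep_len(seq_len(config$n_chromosomes), n)))
  pos_in_chr <- stats::ave(seq_len(n), chrom_of, FUN = seq_along)
  start <- (pos_in_chr - 1) * 1e5
  end <- start + 2e4
  band_no <- ceiling(pos_in_chr / 30)
  cytoband <- paste0(sub("chr", "", chrom_of), "q", band_no)

  chr_idx <- which(chrom_of == config$block_chromosome)
  if (length(chr_idx) < config$block_size) {
    stop("block chromosome too small for the requested block", call. = FALSE)
  }
  off <- floor((length(chr_idx) - config$block_size) / 2)
  block_idx <- chr_idx[seq_len(config$block_size) + off]
  hub_idx <- block_idx[ceiling(config$block_size / 2)]
  gene_ids[hub_idx] <- config$hub_gene

  annotation <- tibble::tibble(
    gene_id = gene_ids, chromosome = chrom_of,
    start = start, end = end, cytoband = cytoband
  )

  # planted truth
  n_de <- round(config$de_fraction * n)
  de_pool <- setdiff(seq_len(n), block_idx)
  de_idx <- sort(sample(de_pool, n_de))
  de_sign <- if (n_de > 0) rep_len(c(1, -1), n_de)[sample.int(n_de)] else
    numeric(0)
  true_g <- numeric(n)
  true_g[de_idx] <- de_sign * config$de_effect_g
  true_g[block_idx] <- config$block_effect

  # module: hub + nearest same-chromosome genes + random distant genes
  n_near <- min(floor((config$module_size - 1) / 2),
                length(chr_idx) - 1)
  near <- setdiff(chr_idx[order(abs(chr_idx - hub_idx))], hub_idx)[seq_len(n_near)]
  n_far <- config$module_size - 1 - n_near
  far_pool <- setdiff(seq_len(n), c(hub_idx, near))
  far <- sample(far_pool, n_far)
  module_idx <- c(hub_idx, sort(c(near, far)))

  mu <- stats::rnorm(n, mean = 7, sd = 1)
  d0 <- 4; s0_sq <- 0.25
  sigma <- sqrt(d0 * s0_sq / stats::rchisq(n, df = d0))
  lam <- sqrt(config$module_r)

  studies <- vector("list", length(config$group_sizes))
  for (j in seq_along(config$group_sizes)) {
    n_ic <- config$group_sizes[[j]][1]
    n_sp <- config$group_sizes[[j]][2]
    ns <- n_ic + n_sp
    group <- c(rep("intracranial", n_ic), rep("spinal", n_sp))
    e <- matrix(stats::rnorm(n * ns), n, ns)
    f <- stats::rnorm(ns)
    e[module_idx, ] <- lam * matrix(f, length(module_idx), ns, byrow = TRUE) +
      sqrt(1 - lam^2) * e[module_idx, , drop = FALSE]
    x <- mu + sigma * e
    sp <- group == "spinal"
    x[, sp] <- x[, sp] + true_g * sigma
    x <- config$study_shift[j] + config$study_scale[j] * x
    if (config$missing_rate[j] > 0) {
      mask <- matrix(stats::runif(n * ns) < config$missing_rate[j], n, ns)
      x[mask] <- NA_real_
    }
    dimnames(x) <- list(gene_ids,
                        sprintf("S%d_%03d", j, seq_len(ns)))
    studies[[j]] <- expression_study(x, group,
                                     study_id = paste0("cohort", j))
  }

  # gene sets: one per cytoband plus random decoys
  sets <- split(gene_ids, cytoband)
  n_decoy <- 20
  decoys <- lapply(seq_len(n_decoy), function(i) sample(gene_ids, 50))
  names(decoys) <- sprintf("DECOY_%02d", seq_len(n_decoy))
  gene_sets <- c(sets, decoys)

  # PPI: random graph over a node sample that always includes the block,
  # with a planted clique among block genes (hub excluded)
  ppi_nodes <- min(config$ppi_nodes, n)
  node_idx <- union(block_idx,
                    sample(setdiff(seq_len(n), block_idx),
                           ppi_nodes - length(block_idx)))
  node_ids <- gene_ids[sort(node_idx)]
  p_edge <- config$ppi_mean_degree / (length(node_ids) - 1)
  g <- igraph::sample_gnp(length(node_ids), p_edge)
  igraph::V(g)$name <- node_ids
  clique_members <- gene_ids[
    setdiff(block_idx[order(abs(block_idx - hub_idx))], hub_idx)][
      seq_len(config$ppi_clique_size)]
  pairs <- t(utils::combn(clique_members, 2))
  g <- igraph::add_edges(g, as.vector(t(pairs)))
  g <- igraph::simplify(g)

  truth <- list(
    de = tibble::tibble(gene_id = gene_ids[true_g != 0],
                        true_g = true_g[true_g != 0]),
    block_genes = gene_ids[block_idx],
    block_region = c(start = min(start[block_idx]),
                     end = max(end[block_idx])),
    module_members = gene_ids[module_idx],
    clique_members = clique_members,
    hub_gene = config$hub_gene
  )
  list(studies = studies, annotation = annotation, gene_sets = gene_sets,
       ppi = g, truth = truth, config = config)
}

#' Confusion metrics against a planted truth set
#'
#' @param found Character vector of ids called by an analysis stage.
#' @param truth Character vector of planted ids.
#' @return One-row tibble: `n_true`, `n_found`, `tp`, `fp`, `fn`, `recall`,
#'   `precision`, `fdr` (`NA` when nothing was found).
#' @export
truth_metrics <- function(found, truth) {
  found <- unique(found); truth <- unique(truth)
  tp <- length(intersect(found, truth))
  fp <- length(setdiff(found, truth))
  fn <- length(setdiff(truth, found))
  tibble::tibble(
    n_true = length(truth), n_found = length(found),
    tp = tp, fp = fp, fn = fn,
    recall = if (length(truth)) tp / length(truth) else NA_real_,
    precision = if (length(found)) tp / length(found) else NA_real_,
    fdr = if (length(found)) fp / length(found) else NA_real_
  )
}
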