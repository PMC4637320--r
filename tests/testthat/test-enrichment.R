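test_that("hypergeometric tail matches exact enumeration", {
  expect_equal(hypergeom_tail(4, 5, 4, 10), 5 / 210, tolerance = 1e-12)
  expect_equal(hypergeom_tail(0, 5, 4, 10), 1)
  expect_equal(hypergeom_tail(5, 5, 10, 10), 1)   # saturated query

  set.seed(2)
  for (i in 1:30) {
    N <- sample(4:12, 1)
    K <- sample(1:N, 1)
    n <- sample(1:N, 1)
    k <- sample(0:min(K, n), 1)
    expect_equal(hypergeom_tail(k, K, n, N), brute_hyper(k, K, n, N),
                 tolerance = 1e-12, label = sprintf("k=%d K=%d n=%d N=%d",
                                                    k, K, n, N))
  }

  expect_error(hypergeom_tail(6, 5, 4, 10), "inconsistent")
})

test_that("over-representation ranks a fully recovered set first", {
  universe <- sprintf("G%02d", 1:40)
  sets <- list(HIT = universe[1:5], MISS1 = universe[11:20],
               MISS2 = universe[21:30], OUTSIDE = c("X1", "X2"))
  res <- overrepresentation(universe[1:5], sets, universe)
  expect_equal(res$set_name[1], "HIT")
  expect_false("OUTSIDE" %in% res$set_name)  # set fully outside universe
  expect_equal(res$k[res$set_name == "HIT"], 5L)
  expect_error(overrepresentation(character(0), sets, universe),
               "empty query")
  expect_error(overrepresentation("X9", sets, universe), "outside")
})

test_that("a planted cytoband signal reaches significance", {
  set.seed(12)
  universe <- sprintf("G%03d", 1:500)
  band <- sample(universe, 50)
  sets <- list(BAND = band)
  decoys <- lapply(1:10, function(i) sample(universe, 50))
  names(decoys) <- paste0("D", 1:10)
  query <- unique(c(sample(band, 30), sample(universe, 40)))  # 60% of band
  res <- overrepresentation(query, c(sets, decoys), universe)
  expect_lt(res$q[res$set_name == "BAND"], 0.05)
})

test_that("uniformly relabeled queries give uniform set p-values", {
  set.seed(31)
  universe <- sprintf("G%03d", 1:200)
  sets <- list(S = universe[1:40])
  p <- replicate(200, {
    q <- sample(universe, 30)
    overrepresentation(q, sets, universe)$p[1]
  })
  # discrete p-values are stochastically >= uniform under the null
  expect_gt(mean(p), 0.45)
  expect_gt(suppressWarnings(
    ks.test(p, "punif", alternative = "greater")$p.value), 0.01)
})

test_that("positional scan pins the planted block exactly", {
  sim <- simulate_cohorts(simulation_config(n_genes = 300, n_chromosomes = 1,
                                            block_chromosome = "chr1",
                                            block_size = 40,
                                            module_size = 10, ppi_nodes = 200,
                                            ppi_clique_size = 4,
                                            de_fraction = 0, rng_seed = 5))
  ann <- sim$annotation
  universe <- ann$gene_id
  query <- sim$truth$block_genes
  res <- positional_scan(query, ann, universe, min_genes = 5)
  expect_gte(nrow(res), 1)
  top <- res[1, ]
  expect_equal(top$start, unname(sim$truth$block_region["start"]))
  expect_equal(top$end, unname(sim$truth$block_region["end"]))
  expect_equal(top$k, 40L)
  expect_equal(top$K, 40L)
  # every reported p recomputes from its own counts
  expect_equal(res$p, hypergeom_tail(res$k, res$K, res$n, res$N))
})

test_that("scattered queries produce no significant region", {
  sim <- simulate_cohorts(simulation_config(n_genes = 400, block_size = 5,
                                            module_size = 10, ppi_nodes = 200,
                                            ppi_clique_size = 3,
                                            de_fraction = 0, rng_seed = 7))
  set.seed(19)
  query <- sample(sim$annotation$gene_id, 40)
  res <- positional_scan(query, sim$annotation, sim$annotation$gene_id)
  if (nrow(res)) expect_false(any(res$q < 0.05))
})

test_that("saturated and degenerate positional queries behave sanely", {
  ann <- tibble::tibble(
    gene_id = sprintf("G%02d", 1:20), chromosome = "chr1",
    start = (0:19) * 1e5, end = (0:19) * 1e5 + 2e4, cytoband = NA_character_
  )
  res <- positional_scan(ann$gene_id, ann, ann$gene_id, min_genes = 5)
  expect_true(all(res$p == 1))
  expect_equal(nrow(positional_scan("G01", ann, ann$gene_id, min_genes = 5)),
               0)
})

test_that("selected regions never overlap on a chromosome", {
  sim <- simulate_cohorts(simulation_config(n_genes = 400, block_size = 15,
                                            module_size = 10, ppi_nodes = 200,
                                            ppi_clique_size = 4,
                                            de_fraction = 0.2, rng_seed = 13))
  query <- unique(c(sim$truth$block_genes,
                    sample(sim$annotation$gene_id, 60)))
  res <- positional_scan(query, sim$annotation, sim$annotation$gene_id)
  expect_gte(nrow(res), 1)
  by_chr <- split(res, res$chromosome)
  for (b in by_chr) {
    if (nrow(b) < 2) next
    b <- b[order(b$start), ]
    expect_true(all(b$start[-1] >= b$end[-nrow(b)]))
  }
})

test_that("chromosome profile reproduces constants, limits and dips", {
  ann <- tibble::tibble(
    gene_id = sprintf("G%02d", 1:30), chromosome = "chr1",
    start = (0:29) * 1e5, end = (0:29) * 1e5 + 2e4, cytoband = NA_character_
  )
  vals <- setNames(rep(1.7, 30), ann$gene_id)
  prof <- chromosome_profile(vals, ann, "chr1", bandwidth = 2e5)
  expect_true(all(abs(prof$smoothed - 1.7) < 1e-10))

  set.seed(4)
  vals2 <- setNames(rnorm(30), ann$gene_id)
  wide <- chromosome_profile(vals2, ann, "chr1", bandwidth = 1e12)
  expect_true(all(abs(wide$smoothed - mean(vals2)) < 1e-6))

  step <- setNames(rep(0, 30), ann$gene_id)
  step[10:18] <- -1
  prof2 <- chromosome_profile(step, ann, "chr1", bandwidth = 1.5e5)
  block_span <- range((ann$start[10:18] + ann$end[10:18]) / 2)
  min_pos <- prof2$position[which.min(prof2$smoothed)]
  expect_gte(min_pos, block_span[1])
  expect_lte(min_pos, block_span[2])

  expect_error(chromosome_profile(vals, ann, "chr1", bandwidth = 0),
               "positive")
})

test_that("cytoband gene sets partition the annotated genes", {
  sim <- simulate_cohorts(simulation_config(n_genes = 200, block_size = 5,
                                            module_size = 6, ppi_nodes = 100,
                                            ppi_clique_size = 3,
                                            n_chromosomes = 4,
                                            block_chromosome = "chr2"))
  sets <- cytoband_sets(sim$annotation)
  expect_equal(sort(unlist(sets, use.names = FALSE)),
               sort(sim$annotation$gene_id))
  expect_true(all(lengths(sets) >= 1))
})
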