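test_that("Hedges' adjusted g matches hand-derived values", {
  res <- hedges_g(c(3, 4, 5), c(1, 2, 3))
  expect_equal(res[["g"]], 1.6, tolerance = 1e-12)
  expect_equal(res[["v"]], 6 / 9 + 1.6^2 / 12, tolerance = 1e-12)

  # identical groups -> g = 0, v = (n1+n0)/(n1 n0)
  res0 <- hedges_g(c(2, 3, 4, 5), c(2, 3, 4, 5))
  expect_equal(res0[["g"]], 0)
  expect_equal(res0[["v"]], 8 / 16)

  # swapping the groups negates g and leaves v unchanged
  set.seed(1)
  x1 <- rnorm(9); x0 <- rnorm(12)
  a <- hedges_g(x1, x0); b <- hedges_g(x0, x1)
  expect_equal(a[["g"]], -b[["g"]], tolerance = 1e-12)
  expect_equal(a[["v"]], b[["v"]], tolerance = 1e-12)

  expect_error(hedges_g(c(1, 1, 1), c(1, 1, 1)), "zero pooled variance")
  expect_error(hedges_g(1, c(1, 2)), ">= 2 non-missing")
})

test_that("DerSimonian-Laird pooling matches hand evaluation of the formulas", {
  one <- dersimonian_laird(1.2, 0.09)
  expect_equal(one[["pooled"]], 1.2)
  expect_equal(one[["se"]], 0.3)
  expect_equal(one[["tau2"]], 0)
  expect_equal(one[["Q"]], 0)

  homo <- dersimonian_laird(c(1, 1), c(0.25, 0.25))
  expect_equal(homo[["Q"]], 0)
  expect_equal(homo[["tau2"]], 0)
  expect_equal(homo[["pooled"]], 1)
  expect_equal(homo[["se"]], sqrt(0.125), tolerance = 1e-12)

  het <- dersimonian_laird(c(0, 2), c(0.5, 0.5))
  expect_equal(het[["Q"]], 4)
  expect_equal(het[["tau2"]], 1.5)
  expect_equal(het[["pooled"]], 1)
  expect_equal(het[["se"]], 1)

  expect_error(dersimonian_laird(numeric(0), numeric(0)), "no studies")
})

test_that("DL with Q <= k-1 equals fixed-effect inverse-variance pooling", {
  g <- c(0.50, 0.52, 0.49)
  v <- c(0.30, 0.25, 0.40)
  dl <- dersimonian_laird(g, v)
  expect_equal(dl[["tau2"]], 0)
  w <- 1 / v
  expect_equal(dl[["pooled"]], sum(w * g) / sum(w), tolerance = 1e-12)
  expect_equal(dl[["se"]], 1 / sqrt(sum(w)), tolerance = 1e-12)
})

test_that("DL agrees with metafor's DL estimator on random inputs", {
  skip_if_not_installed("metafor")
  set.seed(11)
  for (i in 1:5) {
    k <- sample(2:6, 1)
    g <- rnorm(k)
    v <- runif(k, 0.05, 0.5)
    dl <- dersimonian_laird(g, v)
    rma <- metafor::rma(yi = g, vi = v, method = "DL")
    expect_equal(dl[["pooled"]], as.numeric(rma$beta), tolerance = 1e-8)
    expect_equal(dl[["se"]], rma$se, tolerance = 1e-8)
    expect_equal(dl[["tau2"]], rma$tau2, tolerance = 1e-8)
  }
})

test_that("meta z-statistic and two-sided p behave as specified", {
  expect_equal(meta_z(0, 0.5), c(z = 0, p = 1))
  expect_equal(meta_z(qnorm(0.975) * 0.3, 0.3)[["p"]], 0.05,
               tolerance = 1e-12)
  expect_equal(meta_z(1.3, 0.4)[["p"]], meta_z(-1.3, 0.4)[["p"]])
  expect_error(meta_z(1, 0), "positive")
})

test_that("Fisher's sum of logs matches the chi-square oracle", {
  expect_equal(fisher_combine(c(1, 1, 1))[["X2"]], 0)
  expect_equal(fisher_combine(c(1, 1, 1))[["p_comb"]], 1)

  fc <- fisher_combine(rep(0.05, 3))
  expect_equal(fc[["X2"]], -6 * log(0.05), tolerance = 1e-12)
  expect_equal(fc[["p_comb"]],
               pchisq(-6 * log(0.05), df = 6, lower.tail = FALSE),
               tolerance = 1e-12)

  expect_equal(fisher_combine(0.123)[["p_comb"]], 0.123, tolerance = 1e-12)
  expect_warning(out <- fisher_combine(c(0, 0.5)), "clamped")
  expect_true(is.finite(out[["X2"]]))
})

test_that("decreasing any input p decreases the combined p", {
  set.seed(3)
  for (i in 1:20) {
    p <- runif(3, 0.01, 0.99)
    j <- sample(3, 1)
    p2 <- p
    p2[j] <- p[j] * 0.5
    expect_lt(fisher_combine(p2)[["p_comb"]], fisher_combine(p)[["p_comb"]])
  }
})

test_that("BH adjustment equals the brute-force step-up definition", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.37), 0.37)

  set.seed(5)
  for (i in 1:10) {
    p <- runif(sample(3:50, 1))
    expect_equal(bh_fdr(p), brute_bh(p), tolerance = 1e-12)
  }

  # permutation equivariance
  p <- runif(20)
  perm <- sample(20)
  expect_equal(bh_fdr(p)[perm], bh_fdr(p[perm]))
})

test_that("moderated t with d0 = 0 is the ordinary pooled two-sample t", {
  s <- make_study(50, n_sp = 5, n_ic = 8, seed = 21)
  fit <- moderated_t(s, d0 = 0)
  sp <- s$group == "spinal"
  for (i in c(1, 17, 50)) {
    tt <- t.test(s$values[i, sp], s$values[i, !sp], var.equal = TRUE)
    expect_equal(fit$table$t_mod[i], unname(tt$statistic), tolerance = 1e-10)
    expect_equal(fit$table$p[i], tt$p.value, tolerance = 1e-10)
  }
})

test_that("moderated t with infinite d0 shrinks every variance to s0^2", {
  s <- make_study(30, seed = 8)
  fit <- moderated_t(s, d0 = Inf, s0_sq = 1)
  expect_true(all(fit$table$s2_post == 1))
})

test_that("the empirical-Bayes prior is recovered on simulated variances", {
  set.seed(99)
  n <- 5000; n_sp <- 6; n_ic <- 9
  d0 <- 4; s0 <- 0.5
  sigma2 <- d0 * s0 / rchisq(n, df = d0)
  m <- matrix(rnorm(n * (n_sp + n_ic), sd = rep(sqrt(sigma2), n_sp + n_ic)),
              n, n_sp + n_ic,
              dimnames = list(sprintf("G%04d", 1:n),
                              sprintf("S%02d", 1:(n_sp + n_ic))))
  s <- expression_study(m, c(rep("spinal", n_sp), rep("intracranial", n_ic)))
  fit <- moderated_t(s)
  expect_lt(abs(fit$prior[["d0"]] - d0) / d0, 0.3)
  expect_lt(abs(fit$prior[["s0_sq"]] - s0) / s0, 0.3)
})

test_that("moderated t agrees with limma on a complete fixture", {
  skip_if_not_installed("limma")
  s <- make_study(200, n_sp = 6, n_ic = 9, seed = 31)
  fit <- moderated_t(s)
  design <- cbind(1, s$group == "spinal")
  lf <- limma::eBayes(limma::lmFit(s$values, design))
  expect_equal(fit$prior[["d0"]], lf$df.prior, tolerance = 1e-6)
  expect_equal(fit$prior[["s0_sq"]], lf$s2.prior, tolerance = 1e-6)
  expect_equal(fit$table$t_mod, unname(lf$t[, 2]), tolerance = 1e-8)
  expect_equal(fit$table$p, unname(lf$p.value[, 2]), tolerance = 1e-8)
})

test_that("two-route meta-analysis calls planted effects and skips bad genes", {
  sizes <- list(c(20, 8), c(25, 10), c(18, 6))
  set.seed(61)
  n <- 120
  studies <- lapply(seq_along(sizes), function(j) {
    n_ic <- sizes[[j]][1]; n_sp <- sizes[[j]][2]
    m <- matrix(rnorm(n * (n_ic + n_sp), 7), n, n_ic + n_sp,
                dimnames = list(sprintf("G%03d", 1:n),
                                sprintf("c%d_%02d", j, 1:(n_ic + n_sp))))
    grp <- c(rep("intracranial", n_ic), rep("spinal", n_sp))
    m[1, grp == "spinal"] <- m[1, grp == "spinal"] + 2   # planted g = 2
    m[2, ] <- 5                                          # constant gene
    expression_study(m, grp, study_id = paste0("c", j))
  })
  fit <- run_meta_de(studies)
  tab <- tidy(fit)
  expect_true(tab$consensus[tab$gene_id == "G001"])
  expect_equal(tab$direction[tab$gene_id == "G001"], "up")
  # constant gene: NA row, excluded from both FDR vectors
  bad <- tab[tab$gene_id == "G002", ]
  expect_true(is.na(bad$pooled_es) && is.na(bad$q_es) && is.na(bad$q_fisher))
  expect_false(bad$consensus)

  gl <- glance(fit)
  expect_equal(gl$n_genes, n)
  expect_gte(gl$n_consensus, 1)
})

test_that("global-null cohorts yield (near) empty consensus", {
  studies <- make_null_studies(n_genes = 300, seed = 17)
  fit <- run_meta_de(studies)
  expect_lte(sum(tidy(fit)$consensus), 1)
})
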