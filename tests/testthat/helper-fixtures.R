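# Fixture builders shared across test files. Everything is generated in
# code; nothing is read from disk except files the tests themselves write.

make_study <- function(n_genes = 30, n_sp = 5, n_ic = 8, seed = 1,
                       study_id = "s1", gene_ids = NULL) {
  set.seed(seed)
  m <- matrix(rnorm(n_genes * (n_sp + n_ic), mean = 7), n_genes, n_sp + n_ic)
  if (is.null(gene_ids)) gene_ids <- sprintf("G%03d", seq_len(n_genes))
  dimnames(m) <- list(gene_ids, sprintf("%s_S%02d", study_id,
                                        seq_len(n_sp + n_ic)))
  expression_study(m, c(rep("spinal", n_sp), rep("intracranial", n_ic)),
                   study_id = study_id)
}

# three independent global-null cohorts at the study's group sizes
make_null_studies <- function(n_genes = 300, seed = 1) {
  sizes <- list(c(71, 12), c(85, 19), c(65, 10))
  lapply(seq_along(sizes), function(j) {
    make_study(n_genes, n_sp = sizes[[j]][2], n_ic = sizes[[j]][1],
               seed = seed + j, study_id = paste0("c", j))
  })
}

# brute-force BH step-up, straight from the definition:
# q_i = min over ranks j with p_(j) >= p_i of m * p_(j) / j, capped at 1
brute_bh <- function(p) {
  m <- length(p)
  ps <- sort(p)
  vapply(p, function(pi) {
    cand <- m * ps / seq_len(m)
    min(1, min(cand[ps >= pi]))
  }, 0)
}

# exhaustive hypergeometric upper tail by enumerating all draws
brute_hyper <- function(k, K, n, N) {
  sum(vapply(k:min(K, n), function(x) {
    choose(K, x) * choose(N - K, n - x)
  }, 0)) / choose(N, n)
}

# straight-line DerSimonian-Laird, written independently of the package
brute_dl <- function(g, v) {
  w <- 1 / v
  gw <- sum(w * g) / sum(w)
  Q <- sum(w * (g - gw)^2)
  tau2 <- max(0, (Q - (length(g) - 1)) / (sum(w) - sum(w^2) / sum(w)))
  ws <- 1 / (v + tau2)
  c(pooled = sum(ws * g) / sum(ws), se = sqrt(1 / sum(ws)),
    tau2 = tau2, Q = Q)
}
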