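#' Hedges' adjusted g effect size
#'
#' Standardized mean difference (spinal minus intracranial) with the
#' small-sample bias correction J = 1 - 3 / (4(n1+n0-2) - 1), and its
#' large-sample sampling variance
#' v = (n1+n0)/(n1 n0) + g^2 / (2(n1+n0)).
#'
#' @param x_spinal,x_intracranial Numeric vectors of log2 expression for the
#'   two groups; `NA`s are dropped.
#' @return Named numeric vector with `g`, `v`, `n1` (spinal), `n0`
#'   (intracranial).
#' @export
#' @examples
#' hedges_g(c(3, 4, 5), c(1, 2, 3))  # g = 1.6, v = 0.88
hedges_g <- function(x_spinal, x_intracranial) {
  x1 <- x_spinal[!is.na(x_spinal)]
  x0 <- x_intracranial[!is.na(x_intracranial)]
  n1 <- length(x1); n0 <- length(x0)
  if (n1 < 2 || n0 < 2) stop("each group needs >= 2 non-missing values",
                             call. = FALSE)
  df <- n1 + n0 - 2
  sp2 <- ((n1 - 1) * stats::var(x1) + (n0 - 1) * stats::var(x0)) / df
  if (sp2 <= 0) stop("zero pooled variance (constant gene)", call. = FALSE)
  J <- 1 - 3 / (4 * df - 1)
  g <- J * (mean(x1) - mean(x0)) / sqrt(sp2)
  v <- (n1 + n0) / (n1 * n0) + g^2 / (2 * (n1 + n0))
  c(g = g, v = v, n1 = n1, n0 = n0)
}

#' DerSimonian-Laird random-effects pooling
#'
#' Moment estimator of the between-study variance tau^2:
#' with fixed-effect weights w_i = 1/v_i and Q = sum w_i (g_i - gbar_w)^2,
#' tau^2 = max(0, (Q - (k-1)) / (sum w_i - sum w_i^2 / sum w_i)); the pooled
#' estimate then uses weights 1/(v_i + tau^2). With Q <= k - 1 the estimator
#' reduces to fixed-effect inverse-variance pooling.
#'
#' @param g Per-study effect estimates.
#' @param v Per-study sampling variances (all > 0).
#' @return Named numeric vector `pooled`, `se`, `tau2`, `Q`, `k`.
#' @export
dersimonian_laird <- function(g, v) {
  ok <- !is.na(g) & !is.na(v)
  g <- g[ok]; v <- v[ok]
  k <- length(g)
  if (k == 0) stop("no studies to pool", call. = FALSE)
  if (any(v <= 0)) stop("sampling variances must be positive", call. = FALSE)
  w <- 1 / v
  gw <- sum(w * g) / sum(w)
  Q <- sum(w * (g - gw)^2)
  tau2 <- if (k > 1) max(0, (Q - (k - 1)) / (sum(w) - sum(w^2) / sum(w))) else 0
  ws <- 1 / (v + tau2)
  pooled <- sum(ws * g) / sum(ws)
  c(pooled = pooled, se = 1 / sqrt(sum(ws)), tau2 = tau2, Q = Q, k = k)
}

#' z-statistic and two-sided p for a pooled effect
#'
#' @param pooled Pooled effect size.
#' @param se Its standard error (> 0).
#' @return Named numeric vector `z`, `p`.
#' @export
meta_z <- function(pooled, se) {
  if (any(se <= 0)) stop("`se` must be positive", call. = FALSE)
  z <- pooled / se
  c(z = z, p = 2 * stats::pnorm(-abs(z)))
}

# Newton inversion of trigamma(x) = y, y > 0 (used by the empirical-Bayes
# prior fit; same iteration as the classic variance-shrinkage estimators).
trigamma_inverse <- function(y) {
  vapply(y, function(yi) {
    if (yi <= 0) return(Inf)
    if (yi > 1e7) return(1 / sqrt(yi))
    x <- 0.5 + 1 / yi
    for (i in 1:60) {
      tri <- trigamma(x)
      dif <- tri * (1 - tri / yi) / psigamma(x, 2)
      x <- x + dif
      if (abs(dif) < 1e-10 * x) break
    }
    x
  }, 0)
}

#' Empirical-Bayes moderated t-statistics for one cohort
#'
#' Per-gene pooled two-sample variances s_g^2 (d_g = n1 + n0 - 2, pairwise
#' NA dropping) are shrunk toward a scaled-F prior (d0, s0^2) fitted by
#' moment-matching on log s_g^2: the posterior variance is
#' s~_g^2 = (d0 s0^2 + d_g s_g^2) / (d0 + d_g), the moderated t is the mean
#' difference over s~_g sqrt(1/n1 + 1/n0), and p-values are two-sided from a
#' t distribution with d0 + d_g degrees of freedom. When the dispersion of
#' log s_g^2 falls below its expected sampling floor, d0 is infinite and all
#' posterior variances equal s0^2.
#'
#' @param study An [expression_study] with at least 20 genes.
#' @param d0,s0_sq Optional prior overrides; `d0 = 0` gives the ordinary
#'   pooled t, `d0 = Inf` total shrinkage to `s0_sq`.
#' @return List with `table` (tibble: `gene_id`, `t_mod`, `df`, `p`,
#'   `mean_diff`, `s2`, `s2_post`) and `prior` (named vector `d0`, `s0_sq`).
#' @export
moderated_t <- function(study, d0 = NULL, s0_sq = NULL) {
  stopifnot(inherits(study, "expression_study"))
  m <- study$values
  sp <- study$group == "spinal"
  x1 <- m[, sp, drop = FALSE]
  x0 <- m[, !sp, drop = FALSE]
  n1 <- rowSums(!is.na(x1))
  n0 <- rowSums(!is.na(x0))
  m1 <- rowMeans(x1, na.rm = TRUE)
  m0 <- rowMeans(x0, na.rm = TRUE)
  v1 <- apply(x1, 1, stats::var, na.rm = TRUE)
  v0 <- apply(x0, 1, stats::var, na.rm = TRUE)
  dg <- n1 + n0 - 2
  s2 <- ((n1 - 1) * v1 + (n0 - 1) * v0) / dg
  usable <- n1 >= 2 & n0 >= 2 & is.finite(s2) & s2 > 0
  if (sum(usable) < 20 && is.null(d0)) {
    stop("need >= 20 genes with positive variance to fit the prior",
         call. = FALSE)
  }

  if (is.null(d0) || is.null(s0_sq)) {
    # moment-matching of log s^2 to log scaled-F
    z <- log(s2[usable])
    e <- z - digamma(dg[usable] / 2) + log(dg[usable] / 2)
    ebar <- mean(e)
    excess <- stats::var(e) - mean(trigamma(dg[usable] / 2))
    if (excess > 0) {
      fit_d0 <- 2 * trigamma_inverse(excess)
      fit_s0 <- exp(ebar + digamma(fit_d0 / 2) - log(fit_d0 / 2))
    } else {
      fit_d0 <- Inf
      fit_s0 <- exp(ebar)
    }
    if (is.null(d0)) d0 <- fit_d0
    if (is.null(s0_sq)) s0_sq <- fit_s0
  }

  s2_post <- if (is.infinite(d0)) rep(s0_sq, length(s2)) else {
    (d0 * s0_sq + dg * s2) / (d0 + dg)
  }
  se <- sqrt(s2_post * (1 / n1 + 1 / n0))
  t_mod <- (m1 - m0) / se
  df <- d0 + dg
  p <- 2 * stats::pt(-abs(t_mod), df = df)
  t_mod[!usable] <- NA_real_
  p[!usable] <- NA_real_
  list(
    table = tibble::tibble(
      gene_id = study$gene_ids,
      t_mod = unname(t_mod), df = unname(df), p = unname(p),
      mean_diff = unname(m1 - m0), s2 = unname(s2),
      s2_post = unname(s2_post)
    ),
    prior = c(d0 = d0, s0_sq = s0_sq)
  )
}

#' Fisher's sum-of-logs p-value combination
#'
#' X2 = -2 sum(log p_i) is compared to a chi-square with 2k degrees of
#' freedom. Zero p-values are clamped to the smallest positive double with a
#' warning rather than propagated as -Inf.
#'
#' @param p Vector of per-study p-values in (0, 1].
#' @return Named numeric vector `X2`, `p_comb`, `k`.
#' @export
fisher_combine <- function(p) {
  p <- p[!is.na(p)]
  k <- length(p)
  if (k == 0) stop("no p-values to combine", call. = FALSE)
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]", call. = FALSE)
  if (any(p == 0)) {
    warning("p = 0 clamped to .Machine$double.xmin")
    p[p == 0] <- .Machine$double.xmin
  }
  X2 <- -2 * sum(log(p))
  c(X2 = X2, p_comb = stats::pchisq(X2, df = 2 * k, lower.tail = FALSE), k = k)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment (`stats::p.adjust(method = "BH")`); `NA`s are
#' preserved and excluded from the correction.
#'
#' @param p Vector of p-values.
#' @return Vector of q-values of the same length.
#' @export
bh_fdr <- function(p) {
  stats::p.adjust(p, method = "BH")
}

per_gene_effects <- function(study, universe) {
  m <- study$values[universe, , drop = FALSE]
  sp <- study$group == "spinal"
  out <- matrix(NA_real_, length(universe), 2,
                dimnames = list(universe, c("g", "v")))
  for (i in seq_along(universe)) {
    res <- tryCatch(hedges_g(m[i, sp], m[i, !sp]), error = function(e) NULL)
    if (!is.null(res)) out[i, ] <- res[c("g", "v")]
  }
  out
}

#' Two-route differential-expression meta-analysis
#'
#' Route 1 pools per-cohort Hedges' g with DerSimonian-Laird random effects
#' and tests the pooled effect against a standard normal; route 2 combines
#' per-cohort empirical-Bayes moderated-t p-values with Fisher's sum of
#' logs. Each route is BH-corrected over the common gene universe and the
#' consensus takes genes significant in both at `alpha`. Positive pooled
#' effects mean up-regulation in spinal tumors.
#'
#' @param studies List of [expression_study] cohorts (>= 2) sharing a gene
#'   universe (see [common_universe()]); genes failing in any cohort are
#'   reported as `NA` rows and excluded from both FDR vectors.
#' @param alpha FDR threshold for the consensus call.
#' @return A `meta_de` object; `tidy()` returns the per-gene table with
#'   columns `gene_id`, `pooled_es`, `se`, `tau2`, `Q`, `z`, `p_es`, `q_es`,
#'   `X2_fisher`, `p_fisher`, `q_fisher`, `direction`, `consensus`.
#' @export
run_meta_de <- function(studies, alpha = 0.05) {
  cu <- common_universe(studies)
  universe <- cu$universe
  studies <- cu$studies
  k <- length(studies)

  eff <- lapply(studies, per_gene_effects, universe = universe)
  gmat <- sapply(eff, function(e) e[, "g"])
  vmat <- sapply(eff, function(e) e[, "v"])
  complete <- rowSums(is.na(gmat)) == 0

  pooled <- se <- tau2 <- Q <- rep(NA_real_, length(universe))
  for (i in which(complete)) {
    dl <- dersimonian_laird(gmat[i, ], vmat[i, ])
    pooled[i] <- dl[["pooled"]]; se[i] <- dl[["se"]]
    tau2[i] <- dl[["tau2"]]; Q[i] <- dl[["Q"]]
  }
  z <- pooled / se
  p_es <- 2 * stats::pnorm(-abs(z))

  mods <- lapply(studies, moderated_t)
  pmat <- sapply(mods, function(m) m$table$p)
  tmat <- sapply(mods, function(m) m$table$t_mod)
  mod_complete <- rowSums(is.na(pmat)) == 0
  usable <- complete & mod_complete
  X2 <- p_fisher <- rep(NA_real_, length(universe))
  for (i in which(usable)) {
    fc <- fisher_combine(pmat[i, ])
    X2[i] <- fc[["X2"]]; p_fisher[i] <- fc[["p_comb"]]
  }
  p_es[!usable] <- NA_real_

  q_es <- bh_fdr(p_es)
  q_fisher <- bh_fdr(p_fisher)
  consensus <- !is.na(q_es) & !is.na(q_fisher) &
    q_es < alpha & q_fisher < alpha

  tab <- tibble::tibble(
    gene_id = universe,
    pooled_es = pooled, se = se, tau2 = tau2, Q = Q,
    z = z, p_es = p_es, q_es = q_es,
    X2_fisher = X2, p_fisher = p_fisher, q_fisher = q_fisher,
    direction = ifelse(is.na(pooled), NA_character_,
                       ifelse(pooled >= 0, "up", "down")),
    consensus = consensus
  )
  colnames(tmat) <- paste0("t_mod_", vapply(studies, `[[`, "", "study_id"))
  structure(
    list(
      table = dplyr::bind_cols(tab, tibble::as_tibble(tmat)),
      alpha = alpha,
      n_studies = k,
      study_ids = vapply(studies, `[[`, "", "study_id"),
      priors = lapply(mods, `[[`, "prior"),
      universe = universe
    ),
    class = "meta_de"
  )
}

#' @export
print.meta_de <- function(x, ...) {
  cat("<meta_de> ", length(x$universe), " genes, ", x$n_studies,
      " cohorts; consensus (FDR < ", x$alpha, "): ",
      sum(x$table$consensus), " genes (",
      sum(x$table$consensus & x$table$direction == "up"), " up, ",
      sum(x$table$consensus & x$table$direction == "down"), " down)\n",
      sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname run_meta_de
#' @param x A `meta_de` object.
#' @param ... Unused.
#' @export
tidy.meta_de <- function(x, ...) x$table

#' @rdname run_meta_de
#' @export
glance.meta_de <- function(x, ...) {
  tibble::tibble(
    n_genes = length(x$universe),
    n_studies = x$n_studies,
    alpha = x$alpha,
    n_consensus = sum(x$table$consensus),
    n_up = sum(x$table$consensus & x$table$direction == "up"),
    n_down = sum(x$table$consensus & x$table$direction == "down")
  )
}
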