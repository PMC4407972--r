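# Variance-component and combined tests: numeric tails, orderings,
# degenerate grids, stage independence.

perm_quadform_p <- function(co, stat_of_labels, B = 2000, seed = 1) {
  set.seed(seed)
  n <- length(co$phenotype)
  obs <- stat_of_labels(co$phenotype)
  perm <- replicate(B, stat_of_labels(sample(co$phenotype)))
  mean(perm >= obs - 1e-9)
}

skat_q <- function(co, flat = FALSE) {
  idx <- maf_filter(co, 0.01)
  G <- co$genotypes[, idx, drop = FALSE]
  w <- if (flat) rep(1, length(idx)) else dbeta(co$sites$maf[idx], 1, 25)
  function(y) {
    r <- y - mean(y)
    sum((w * as.vector(crossprod(G, r)))^2)
  }
}

test_that("the chi-square mixture tail matches simulation", {
  set.seed(81)
  lambda <- c(3, 1.2, 0.5, 0.5, 0.1)
  draws <- colSums(lambda * matrix(rchisq(5 * 2e4, 1), 5))
  for (q in quantile(draws, c(0.5, 0.9, 0.99))) {
    p_num <- rarepower:::chisq_mixture_tail(q, lambda)
    p_mc <- mean(draws > q)
    expect_equal(p_num, p_mc, tolerance = 0.05)
  }
  # far tail: numeric method stays finite and ordered
  p_far <- rarepower:::chisq_mixture_tail(500, lambda)
  expect_lt(p_far, 1e-10)
  expect_gt(p_far, 0)
})

test_that("SKAT's analytic p-value agrees with its permutation null", {
  panel <- get_test_panel()
  arch <- architecture_model("ar2")
  set.seed(82)
  for (i in 1:3) {
    eff <- sample_locus_effects(panel, arch, 0.01, seed = 5000 + i)
    co <- sample_cohort(panel, eff, n_case = 300, n_control = 300,
                        seed = 5100 + i)
    p_a <- test_skat(co)$p_value
    p_p <- perm_quadform_p(co, skat_q(co), B = 1500, seed = 5200 + i)
    # allow Monte-Carlo error plus the finite-sample gap of the
    # asymptotic null for a binary trait
    tol <- 3 * sqrt(max(p_p, 0.01) * (1 - min(p_p, 0.99)) / 1500) +
      0.25 * max(p_a, p_p) + 0.01
    expect_lt(abs(p_a - p_p), tol)
  }
})

test_that("SKAT errors on a constant phenotype", {
  g <- matrix(0L, 8, 2); g[1, 1] <- 1L; g[2, 2] <- 1L
  co <- cohort_from_genotypes(g, rep(1L, 8))
  expect_error(test_skat(co, test_spec(maf_threshold = 0.5)),
               "residual variance")
})

test_that("flat-weight SKAT orders label permutations exactly as C-alpha", {
  panel <- get_calibration_panel()
  co <- sample_cohort(panel, n_case = 100, n_control = 100, seed = 83)
  idx <- maf_filter(co, 0.01)
  G <- co$genotypes[, idx, drop = FALSE]
  qfun <- skat_q(co, flat = TRUE)
  tot <- colSums(G)
  calpha_stat <- function(y) {
    p0 <- mean(y)
    cc <- as.vector(crossprod(G, y))
    sum((cc - tot * p0)^2 - tot * p0 * (1 - p0))
  }
  set.seed(84)
  labels <- replicate(60, sample(co$phenotype), simplify = FALSE)
  qs <- vapply(labels, qfun, numeric(1))
  cs <- vapply(labels, calpha_stat, numeric(1))
  expect_equal(order(qs), order(cs))
})

test_that("SKAT-O degenerates to its endpoints and is grid-consistent", {
  panel <- get_test_panel()
  eff <- sample_locus_effects(panel, architecture_model("ar2"), 0.01,
                              seed = 85)
  co <- sample_cohort(panel, eff, n_case = 300, n_control = 300, seed = 86)
  p_skat <- test_skat(co)$p_value
  p_rho0 <- test_skato(co, test_spec(rho_grid = 0))$p_value
  expect_equal(p_rho0, p_skat, tolerance = 1e-8)
  # rho = 1 equals the weighted-burden score test (quadratic in the summed
  # score): check against its own mixture tail computed directly
  p_rho1 <- test_skato(co, test_spec(rho_grid = 1))$p_value
  idx <- maf_filter(co, 0.01)
  G <- co$genotypes[, idx, drop = FALSE]
  w <- dbeta(co$sites$maf[idx], 1, 25)
  b <- as.vector(G %*% w)
  y <- co$phenotype
  U <- sum(b * (y - mean(y)))
  Vu <- mean(y) * (1 - mean(y)) * sum((b - mean(b))^2)
  p_score <- 2 * pnorm(abs(U) / sqrt(Vu), lower.tail = FALSE)
  expect_equal(p_rho1, p_score, tolerance = 1e-3)
  # full grid: bounded by the best single rho and its Bonferroni cost
  full <- test_skato(co)
  expect_gte(full$p_value, min(p_rho0, p_rho1) * 0.999)
  expect_lte(full$p_value,
             min(7 * min(p_rho0, p_rho1), 1) + 1e-12)
})

test_that("SKAT-O tracks its permutation null across mixing regimes", {
  panel <- get_test_panel()
  set.seed(87)
  for (arch_id in c("ar2", "ar6")) {
    eff <- sample_locus_effects(panel, architecture_model(arch_id), 0.01,
                                seed = 6000 + nchar(arch_id))
    co <- sample_cohort(panel, eff, n_case = 300, n_control = 300,
                        seed = 6100 + nchar(arch_id))
    p_a <- test_skato(co)$p_value
    idx <- maf_filter(co, 0.01)
    G <- co$genotypes[, idx, drop = FALSE]
    w <- dbeta(co$sites$maf[idx], 1, 25)
    # permutation on the analytically selected-rho statistic brackets
    # the grid-calibrated SKAT-O p
    sel <- as.numeric(sub("rho=", "", test_skato(co)$diagnostics))
    stat_sel <- function(y) {
      r <- y - mean(y)
      u <- w * as.vector(crossprod(G, r))
      (1 - sel) * sum(u^2) + sel * sum(u)^2
    }
    p_sel <- perm_quadform_p(co, stat_sel, B = 1200, seed = 6200)
    # grid-min calibration: SKAT-O p lies between the selected-rho
    # permutation p and its 7-fold Bonferroni inflation (within MC error)
    expect_gte(p_a, max(p_sel - 0.06, 0))
    expect_lte(p_a, min(7 * (p_sel + 0.06), 1))
  }
})

mist_stage_ps <- function(r) {
  c(burden = as.numeric(sub(".*p_burden=([0-9.e+-]+);.*", "\\1",
                            r$diagnostics)),
    het = as.numeric(sub(".*p_heterogeneity=([0-9.e+-]+)$", "\\1",
                         r$diagnostics)))
}

test_that("MiST's stages split unidirectional and bidirectional signal", {
  spec <- test_spec(maf_threshold = 0.5)
  set.seed(95)
  n <- 400
  y <- rep(c(1L, 0L), each = n / 2)
  # unidirectional: every variant case-enriched -> burden stage leads
  G_uni <- sapply(1:14, function(v)
    rbinom(n, 1, ifelse(y == 1, 0.06, 0.015)))
  r_uni <- test_mist(cohort_from_genotypes(G_uni, y), spec)
  ps_uni <- mist_stage_ps(r_uni)
  expect_lt(ps_uni["burden"], 0.05)
  expect_lt(r_uni$p_value, 0.05)
  # bidirectional: balanced opposing skews -> heterogeneity stage leads
  G_bi <- cbind(
    sapply(1:7, function(v) rbinom(n, 1, ifelse(y == 1, 0.07, 0.01))),
    sapply(1:7, function(v) rbinom(n, 1, ifelse(y == 1, 0.01, 0.07))))
  r_bi <- test_mist(cohort_from_genotypes(G_bi, y), spec)
  ps_bi <- mist_stage_ps(r_bi)
  expect_lt(ps_bi["het"], ps_bi["burden"])
  expect_lt(ps_bi["het"], 0.05)
})

test_that("MiST's combined statistic is chi-square 4 df under the null", {
  panel <- get_test_panel()
  set.seed(90)
  stats <- vapply(1:150, function(i) {
    con <- sample_cohort(panel, n_case = 250, n_control = 250,
                         seed = 7000 + i)
    test_mist(con)$statistic
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(stats, "pchisq", df = 4))
  expect_gt(ks$p.value, 0.01)
})
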