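# Independent oracles used across the suite. These are deliberately naive
# (direct loops over definitions) so they share no code with the package's
# optimised implementations.

# Exhaustive phenotype-label enumeration: p-value of `stat` (a function of
# the case row indices) over all C(n, n_case) assignments, counting ties
# as exceedances.
oracle_exhaustive_p <- function(G, y, stat) {
  n <- nrow(G)
  n_case <- sum(y == 1)
  obs <- stat(which(y == 1))
  combos <- utils::combn(n, n_case)
  stats <- apply(combos, 2, stat)
  mean(stats >= obs - 1e-9 * (1 + abs(obs)))
}

o_burden <- function(G) function(idx) sum(G[idx, , drop = FALSE])

o_uniq <- function(G) function(idx) {
  s <- 0
  for (v in seq_len(ncol(G))) {
    cc <- sum(G[idx, v])
    if (cc > 0 && cc == sum(G[, v])) s <- s + cc
  }
  s
}

o_frqwgt <- function(G) function(idx) {
  n <- nrow(G)
  ctrl <- setdiff(seq_len(n), idx)
  s <- 0
  for (v in seq_len(ncol(G))) {
    q <- (sum(G[ctrl, v]) + 1) / (2 * length(ctrl) + 2)
    w <- 1 / sqrt(n * q * (1 - q))
    s <- s + w * sum(G[idx, v])
  }
  s
}

o_calpha <- function(G) function(idx) {
  n <- nrow(G)
  p0 <- length(idx) / n
  s <- 0
  for (v in seq_len(ncol(G))) {
    tot <- sum(G[, v])
    cc <- sum(G[idx, v])
    s <- s + (cc - tot * p0)^2 - tot * p0 * (1 - p0)
  }
  s
}

o_vt <- function(G, maf) function(idx) {
  n <- nrow(G)
  p0 <- length(idx) / n
  best <- -Inf
  for (t in sort(unique(maf))) {
    vs <- which(maf <= t)
    num <- 0; den <- 0
    for (v in vs) {
      num <- num + sum(G[idx, v]) - p0 * sum(G[, v])
      den <- den + sum(G[, v]^2)
    }
    z <- num / sqrt(den * p0 * (1 - p0))
    if (z > best) best <- z
  }
  best
}

o_kbac <- function(G) function(idx) {
  n <- nrow(G)
  n_case <- length(idx)
  key <- apply(G, 1, paste, collapse = ",")
  s <- 0
  for (k in setdiff(unique(key), paste(rep(0, ncol(G)), collapse = ","))) {
    rows <- which(key == k)
    cc <- sum(rows %in% idx)
    w <- phyper(cc, n_case, n - n_case, length(rows))
    s <- s + w * cc
  }
  s
}

# Liability-threshold variance explained by brute-force numeric
# integration: solve each genotype's liability mean shift from its
# penetrance by root-finding on the integrated normal tail.
oracle_ve <- function(maf, rr, K) {
  g <- c((1 - maf)^2, 2 * maf * (1 - maf), maf^2)
  m <- if (rr >= 1) c(1, rr, 2 * rr - 1) else c(2 / rr - 1, 1 / rr, 1)
  f0 <- K / sum(g * m)
  f <- f0 * m
  thr <- qnorm(1 - K)
  mu <- vapply(f, function(fg)
    uniroot(function(mm)
      integrate(function(x) dnorm(x, mm, 1), thr, Inf,
                rel.tol = 1e-12)$value - fg,
      c(-15, 15), tol = 1e-12)$root, numeric(1))
  vg <- sum(g * mu^2) - sum(g * mu)^2
  vg / (1 + vg)
}

# Two-sided Fisher p by direct hypergeometric tail enumeration
# (minimum-likelihood rule).
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  support <- max(0, k - n):min(k, m)
  dens <- dhyper(support, m, n, k)
  sum(dens[dens <= dhyper(a, m, n, k) * (1 + 1e-7)])
}

# Shared study-scale fixtures, built once per test run.
.fixture_env <- new.env(parent = emptyenv())

get_test_panel <- function() {
  if (is.null(.fixture_env$panel))
    .fixture_env$panel <- simulate_reference_panel(seed = 20240915)
  .fixture_env$panel
}

get_calibration_panel <- function() {
  # smaller locus for the many-replicate calibration runs
  if (is.null(.fixture_env$calib))
    .fixture_env$calib <- simulate_reference_panel(
      region_length_bp = 1000, seed = 4171)
  .fixture_env$calib
}
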