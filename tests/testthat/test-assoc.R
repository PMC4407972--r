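# Association tests: filters, exhaustive-oracle equality, symmetries.

fx <- make_fixtures(seed = 1)

test_that("the MAF filter is strict and matches hand enumeration", {
  # toy 8-individual cohort: four singleton sites (MAF 1/16) plus the
  # doubleton at site 3 (MAF 2/16 = 0.125)
  co <- fx$toy8
  expect_equal(co$sites$maf,
               c(1, 1, 2, 1)[co$sites$index + 1] / 16)
  expect_equal(maf_filter(co, 0.1), c(1L, 2L, 4L))
  expect_equal(maf_filter(co, 0.125), c(1L, 2L, 4L)) # at threshold: out
  expect_equal(maf_filter(co, 0.0625), integer(0))   # strict inequality
  expect_equal(maf_filter(co, 0.2), 1:4)
})

test_that("gene-based tests refuse a dataset with no qualifying variants", {
  co <- fx$toy8
  spec <- test_spec(maf_threshold = 1e-6)
  expect_error(test_burden(co, spec), "MAF filter")
  rows <- run_test_battery(co, c("burden", "skat"), spec, seed = 1)
  expect_true(all(rows$method == "failed"))
  expect_true(all(grepl("MAF filter", rows$diagnostics)))
})

test_that("permutation tests match exhaustive enumeration on toy cohorts", {
  spec <- test_spec(maf_threshold = 0.5)
  for (co in list(fx$toy8, fx$toy8_null, fx$toy10)) {
    G <- co$genotypes # all sites rare here; alt allele is minor
    y <- co$phenotype
    maf <- co$sites$maf
    expect_equal(test_burden(co, spec)$p_value,
                 oracle_exhaustive_p(G, y, o_burden(G)))
    expect_equal(test_uniq(co, spec)$p_value,
                 oracle_exhaustive_p(G, y, o_uniq(G)))
    expect_equal(test_frqwgt(co, spec)$p_value,
                 oracle_exhaustive_p(G, y, o_frqwgt(G)))
    expect_equal(test_calpha(co, spec)$p_value,
                 oracle_exhaustive_p(G, y, o_calpha(G)))
    expect_equal(test_vt(co, spec)$p_value,
                 oracle_exhaustive_p(G, y, o_vt(G, maf)))
    expect_equal(test_kbac(co, spec)$p_value,
                 oracle_exhaustive_p(G, y, o_kbac(G)))
  }
})

test_that("an all-case allele pattern reaches the exhaustive extreme tail", {
  g <- matrix(0L, 8, 3)
  g[1:4, 1] <- 1L # every minor allele in cases
  g[1, 2] <- 1L; g[2, 3] <- 1L
  co <- cohort_from_genotypes(g, rep(c(1L, 0L), each = 4))
  spec <- test_spec(maf_threshold = 0.5)
  r <- test_burden(co, spec)
  # identity labelling is the unique maximum: 1 of C(8,4) assignments
  expect_equal(r$p_value, 1 / choose(8, 4))
  expect_equal(r$method, "exhaustive")
})

test_that("null fixtures give non-extreme permutation p-values", {
  spec <- test_spec(maf_threshold = 0.5)
  for (t in c("burden", "uniq", "frqwgt", "kbac", "calpha")) {
    p <- get(paste0("test_", t))(fx$toy8_null, spec)$p_value
    expect_gte(p, 0.3)
  }
})

test_that("CMC handles degenerate and informative carriers", {
  g_all <- matrix(0L, 8, 2)
  g_all[1:4, 1] <- 1L
  g_all[5:8, 2] <- 1L # everyone carries exactly one rare allele
  co_all <- cohort_from_genotypes(g_all, rep(c(1L, 0L), each = 4))
  expect_equal(test_cmc(co_all, test_spec(maf_threshold = 0.5))$p_value, 1)
  # balanced carriers: near-null p
  expect_gt(test_cmc(fx$toy8_null, test_spec(maf_threshold = 0.5))$p_value,
            0.5)
})

test_that("CMC agrees with a carrier-table chi-square oracle at scale", {
  set.seed(71)
  n <- 400
  carrier <- rbinom(n, 1, 0.15)
  y <- rbinom(n, 1, plogis(-1 + 0.9 * carrier))
  G <- cbind(carrier, 0L)
  G[1, 2] <- 1L
  co <- cohort_from_genotypes(G, y)
  p_cmc <- test_cmc(co, test_spec(maf_threshold = 0.5))$p_value
  p_oracle <- chisq.test(table(carrier, y), correct = FALSE)$p.value
  expect_equal(p_cmc, p_oracle, tolerance = 0.3)
})

test_that("the rank-sum weighted test is degenerate-safe and one-sided", {
  expect_gt(test_wss(fx$toy8_null, test_spec(maf_threshold = 0.5))$p_value,
            0.3) # balanced scores: large p
  g <- matrix(0L, 10, 2)
  g[1:5, 1] <- 1L
  g[1, 2] <- 1L
  co_skew <- cohort_from_genotypes(g, rep(c(1L, 0L), each = 5))
  co_swap <- cohort_from_genotypes(g, rep(c(0L, 1L), each = 5))
  p_skew <- test_wss(co_skew, test_spec(maf_threshold = 0.5))$p_value
  p_swap <- test_wss(co_swap, test_spec(maf_threshold = 0.5))$p_value
  expect_lt(p_skew, 0.05)
  expect_gt(p_swap, 0.9) # one-sided: reversed direction loses all signal
})

test_that("VT reduces to the fixed-threshold statistic with one distinct MAF", {
  g <- matrix(0L, 10, 3)
  g[1, 1] <- 1L; g[2, 2] <- 1L; g[6, 3] <- 1L # three singletons
  co <- cohort_from_genotypes(g, rep(c(1L, 0L), each = 5))
  spec <- test_spec(maf_threshold = 0.5)
  p_vt <- test_vt(co, spec)$p_value
  p_burden <- test_burden(co, spec)$p_value
  # one threshold only: the z statistic is monotone in the burden count,
  # so exhaustive p-values coincide
  expect_equal(p_vt, p_burden)
})

test_that("C-alpha is sensitive in both directions of allele skew", {
  base <- matrix(0L, 20, 2)
  base[1:4, 1] <- 1L   # case-skewed site
  base[15:18, 2] <- 1L # control-skewed site
  co <- cohort_from_genotypes(base, rep(c(1L, 0L), each = 10))
  spec <- test_spec(maf_threshold = 0.5)
  stat_bidir <- test_calpha(co, spec)$statistic
  balanced <- matrix(0L, 20, 2)
  balanced[c(1, 2, 11, 12), 1] <- 1L
  balanced[c(3, 4, 13, 14), 2] <- 1L
  co_bal <- cohort_from_genotypes(balanced, rep(c(1L, 0L), each = 10))
  stat_bal <- test_calpha(co_bal, spec)$statistic
  expect_gt(stat_bidir, stat_bal)
  expect_lte(stat_bal, 0)
  expect_gt(test_calpha(co_bal, spec)$p_value, 0.5)
})

test_that("Fisher per-site p-values match hypergeometric-tail enumeration", {
  expect_equal(fisher.test(matrix(c(10, 10, 10, 10), 2))$p.value, 1)
  tabs <- list(c(6, 14, 1, 19), c(3, 7, 5, 5), c(0, 20, 4, 16))
  for (tt in tabs) {
    got <- fisher.test(matrix(tt, 2))$p.value
    want <- oracle_fisher_p(tt[1], tt[2], tt[3], tt[4])
    expect_equal(got, want, tolerance = 1e-7)
  }
  # label-swap symmetry at the locus level
  g <- matrix(0L, 12, 2)
  g[c(1, 2, 3), 1] <- 1L; g[10, 2] <- 1L
  co <- cohort_from_genotypes(g, rep(c(1L, 0L), each = 6))
  co_swap <- cohort_from_genotypes(g, rep(c(0L, 1L), each = 6))
  expect_equal(test_fisher(co)$p_value, test_fisher(co_swap)$p_value)
})

test_that("the battery returns one seeded, reproducible row per test", {
  panel <- get_calibration_panel()
  co <- sample_cohort(panel, n_case = 150, n_control = 150, seed = 72)
  spec <- test_spec(perm_max = 1000)
  r1 <- run_test_battery(co, spec = spec, seed = 73)
  r2 <- run_test_battery(co, spec = spec, seed = 73)
  expect_equal(nrow(r1), 12)
  expect_identical(r1$p_value, r2$p_value)
  # rows match individually invoked tests under the derived seeds
  i <- which(battery_tests() == "burden")
  solo <- test_burden(co, spec, seed = rarepower:::split_seed(73, i))
  expect_identical(solo$p_value, r1$p_value[r1$test == "burden"])
})

test_that("one-sided count tests stay calibrated under protective effects", {
  panel <- get_calibration_panel()
  site <- which.min(abs(panel$sites$panel_maf - 0.01))
  eff <- structure(list(effects = tibble::tibble(
    site = panel$sites$index[site], position = panel$sites$position[site],
    maf = panel$sites$panel_maf[site], rr = 1 / 4,
    direction = "protective", ve = NA_real_),
    achieved_ve = NA, target_ve = NA, n_restarts = 0L),
    class = "locus_effects")
  spec <- test_spec(perm_max = 500)
  set.seed(74)
  p_burden <- vapply(1:20, function(i) {
    co <- sample_cohort(panel, eff, n_case = 150, n_control = 150,
                        seed = 4000 + i)
    test_burden(co, spec, seed = 4100 + i)$p_value
  }, numeric(1))
  # protective-only signal: one-sided case-enrichment test sees nothing
  expect_gte(mean(p_burden), 0.35)
  expect_lt(mean(p_burden < 0.05), 0.2)
})
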