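# Power aggregation, FPR thresholds, concordance, composites, discordance.

test_that("power estimation is the strict-detection fraction with exact CI", {
  res <- tibble::tibble(test = "skat", p_value = rep(0.5, 40))
  pw <- estimate_power(res, alpha = 0.05)
  expect_equal(pw$power, 0)
  res2 <- tibble::tibble(test = "skat",
                         p_value = c(rep(0.01, 50), rep(0.5, 50)))
  pw2 <- estimate_power(res2, alpha = 0.05)
  expect_equal(pw2$power, 0.5)
  expect_lte(pw2$conf_low, 0.5)
  expect_gte(pw2$conf_high, 0.5)
  # ties at alpha are non-detections
  res3 <- tibble::tibble(test = "skat", p_value = rep(0.05, 10))
  expect_equal(estimate_power(res3, alpha = 0.05)$power, 0)
})

test_that("power is monotone along alpha stringency", {
  set.seed(91)
  res <- tibble::tibble(test = "x", p_value = rbeta(200, 0.4, 3))
  pw <- estimate_power(res, alpha = c(0.1, 0.01, 0.001))
  expect_true(all(diff(pw$power[order(-pw$alpha)]) <= 0))
})

test_that("FPR-corrected thresholds match a sort-based oracle", {
  set.seed(92)
  p_unif <- runif(1e4)
  thr <- fpr_corrected_threshold(p_unif, 0.01)
  k <- floor(0.01 * length(p_unif))
  expect_equal(thr, sort(p_unif)[k + 1])
  expect_equal(thr, 0.01, tolerance = 0.25)
  # conservative test: null p stochastically large -> threshold above target
  p_cons <- sqrt(runif(1e4))
  expect_gt(fpr_corrected_threshold(p_cons, 0.01), 0.01)
  expect_error(fpr_corrected_threshold(runif(50), 1e-4), "resolve")
  # realized FPR at the returned threshold never exceeds the target
  expect_lte(mean(p_unif < thr), 0.01)
})

test_that("concordance is affine-invariant and filters weak signals", {
  p <- 10^-runif(50, 1, 6)
  expect_equal(concordance(p, p)$r_squared, 1)
  expect_equal(concordance(p, p^2.5)$r_squared, 1) # affine in -log10
  few <- c(0.5, 0.9, 0.2)
  cc <- concordance(few, few)
  expect_true(is.na(cc$r_squared))
  expect_match(cc$reason, "fewer than 3")
  # p-values above 0.1 are excluded from the correlation
  pa <- c(p, 0.9); pb <- c(p, 1e-6)
  expect_equal(concordance(pa, pb)$n_pairs, 50)
})

test_that("combined detection decomposes unions of locus sets", {
  gene <- tibble::tibble(locus = 1:6,
                         p_value = c(1e-7, 0.5, 1e-7, 0.5, 1e-7, 0.5))
  sv <- tibble::tibble(locus = 1:6,
                       p_value = c(0.5, 1e-9, 1e-9, 0.5, 1e-9, 0.5))
  cp <- combined_power(gene, sv)
  expect_equal(cp$summary$power_union, 4 / 6)
  expect_equal(cp$summary$gene_only_increment, 1 / 3 - 1 / 6)
  expect_setequal(cp$by_locus$class[c(1, 2, 3, 6)],
                  c("gene-only", "sv-only", "both", "neither"))
  # disjoint detections: union is the sum; nested: union is the max
  expect_equal(cp$summary$power_union,
               cp$summary$power_sv + cp$summary$gene_only_increment)
})

test_that("greedy composite selection matches a hand-traced oracle", {
  # 6 loci; planted structure: start detects loci 1-2; testB adds 3-4
  # with wide margin; testC adds only locus 5 at margin 1
  wide <- tibble::tribble(
    ~locus, ~start, ~testB, ~testC,
    1, 1e-6, 0.5, 0.5,
    2, 1e-6, 0.5, 0.5,
    3, 0.5, 1e-6, 0.5,
    4, 0.5, 1e-6, 0.5,
    5, 1e-4, 0.5, 2e-5,
    6, 0.5, 0.5, 0.5)
  long <- tidyr::pivot_longer(wide, -locus, names_to = "test",
                              values_to = "p_value")
  comp100 <- forward_select_composite(long, "start", margin = 100,
                                      alpha = 1e-4)
  expect_equal(comp100$tests, c("start", "testB"))
  expect_equal(comp100$sensitivity, 4 / 6)
  comp1 <- forward_select_composite(long, "start", margin = 1,
                                    alpha = 1e-4)
  expect_equal(comp1$tests, c("start", "testB", "testC"))
  expect_equal(comp1$sensitivity, 5 / 6)
  # margin monotonicity: tighter margins select supersets
  expect_true(all(comp100$tests %in% comp1$tests))
  # a dominated field adds nothing
  solo <- tibble::tibble(locus = rep(1:4, 2),
                         test = rep(c("start", "other"), each = 4),
                         p_value = c(rep(1e-6, 4), rep(1e-3, 4)))
  expect_equal(forward_select_composite(solo, "start", 10, 1e-4)$tests,
               "start")
  expect_error(forward_select_composite(long, "nope", 10), "unknown start")
})

test_that("composite sensitivity dominates members; FPR adjustment can erase it", {
  set.seed(93)
  n_loci <- 300
  mk <- function(p) tibble::tibble(locus = 1:n_loci, p_value = p)
  pa <- rbeta(n_loci, 0.2, 4); pb <- rbeta(n_loci, 0.2, 4)
  long <- dplyr::bind_rows(dplyr::mutate(mk(pa), test = "a"),
                           dplyr::mutate(mk(pb), test = "b"))
  null_long <- dplyr::bind_rows(
    dplyr::mutate(mk(runif(n_loci)), test = "a"),
    dplyr::mutate(mk(runif(n_loci)), test = "b"))
  comp <- forward_select_composite(long, "a", margin = 1, alpha = 0.05,
                                   null_results = null_long,
                                   target_fpr = 0.05)
  best_single <- max(mean(pa < 0.05), mean(pb < 0.05))
  expect_gte(comp$sensitivity, best_single)
  expect_lte(comp$adjusted_threshold, 0.05) # min-p composite inflates FPR
  expect_lte(comp$adjusted_sensitivity, comp$sensitivity)
})

test_that("discordance profiles recover planted locus structures", {
  # locus A: many case-private singletons (a case-unique specialist's win)
  gA <- matrix(0L, 40, 12)
  for (v in 1:10) gA[v %% 20 + 1, v] <- 1L
  gA[c(2, 22), 11] <- 1L; gA[c(3, 23), 12] <- 1L
  coA <- cohort_from_genotypes(gA, rep(c(1L, 0L), each = 20))
  # locus B: one relatively common driver among balanced rare noise
  gB <- matrix(0L, 40, 4)
  gB[1:10, 1] <- 1L; gB[21:22, 1] <- 1L
  gB[c(5, 25), 2] <- 1L; gB[c(6, 26), 3] <- 1L; gB[c(7, 27), 4] <- 1L
  coB <- cohort_from_genotypes(gB, rep(c(1L, 0L), each = 20))
  res_a <- tibble::tibble(locus = c("A", "B"), p_value = c(0.001, 0.5))
  res_b <- tibble::tibble(locus = c("A", "B"), p_value = c(0.5, 0.001))
  prof <- discordance_profile(res_a, res_b, list(A = coA, B = coB),
                              p_cut = 0.01, maf_threshold = 0.05)
  expect_equal(nrow(prof), 2)
  a_row <- prof[prof$locus == "A", ]
  b_row <- prof[prof$locus == "B", ]
  expect_equal(a_row$only, "a")
  expect_equal(b_row$only, "b")
  expect_gt(a_row$case_unique_count, b_row$case_unique_count)
  expect_lt(b_row$top_sv_p, a_row$top_sv_p)
  # no discordance -> empty summary
  empty <- discordance_profile(res_a, res_a, list(A = coA, B = coB))
  expect_equal(nrow(empty), 0)
})
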