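# Panel generation: copying model, expansion, SFS calibration, LD.

test_that("base panel simulation is deterministic and drops monomorphic sites", {
  p1 <- simulate_base_panel(10, 2000, seed = 7)
  p2 <- simulate_base_panel(10, 2000, seed = 7)
  expect_identical(p1$haplotypes, p2$haplotypes)
  expect_identical(p1$sites, p2$sites)
  af <- colMeans(p1$haplotypes)
  expect_true(all(af > 0 & af < 1))
  expect_true(all(diff(p1$sites$position) > 0))
  expect_true(all(abs(p1$sites$panel_maf - pmin(af, 1 - af)) < 1e-12))
})

test_that("base panel LD decays with distance and SFS is rare-skewed", {
  p <- simulate_base_panel(379, 5000, seed = 11)
  prof <- ld_profile(p, maf_breaks = 0.5,
                     distance_breaks = seq(500, 5000, by = 500))
  ok <- !is.na(prof$mean_r2)
  expect_gt(sum(ok), 4)
  rs <- suppressWarnings(
    cor(seq_len(nrow(prof))[ok], prof$mean_r2[ok], method = "spearman"))
  expect_lt(rs, 0)
  spec <- sfs(p)
  expect_gt(spec$proportion[1], spec$proportion[2]) # singletons dominate
  expect_lt(median(p$sites$panel_maf), 0.05)        # mass sits at rare sites
})

test_that("mosaic copying reduces to exact template copy without mutation", {
  p <- simulate_base_panel(10, 1000, seed = 3)
  m <- mosaic_haplotype(p, rho = 0, theta = 0, seed = 5)
  match_row <- apply(p$haplotypes, 1, function(h) all(h == m$haplotype))
  expect_true(any(match_row))
  expect_length(m$new_site_positions, 0)
})

test_that("mosaic paths over a 2-haplotype panel are valid segmentations", {
  # with theta = 0 every site must agree with one of the two templates at
  # that site, and the copied-template sequence along the chromosome must
  # be piecewise constant (verified exhaustively on small instances)
  p <- simulate_base_panel(6, 400, seed = 9)
  keep <- seq_len(min(20L, ncol(p$haplotypes)))
  hd <- as.matrix(dist(p$haplotypes[, keep], method = "manhattan"))
  pick <- which(hd == max(hd), arr.ind = TRUE)[1, ]
  two <- hap_panel(p$haplotypes[pick, keep, drop = FALSE],
                   p$sites$position[keep], p$sites$exonic[keep],
                   p$region_length_bp)
  # only informative (differing) sites identify the copied template
  diff_sites <- which(two$haplotypes[1, ] != two$haplotypes[2, ])
  skip_if(length(diff_sites) < 3)
  for (s in 1:25) {
    m <- mosaic_haplotype(two, rho = 2e-3, theta = 0, seed = 100 + s)
    src <- ifelse(m$haplotype[diff_sites] == two$haplotypes[1, diff_sites],
                  1L, 2L)
    expect_true(all(src %in% 1:2))
    # every emitted haplotype is a two-colour segmentation by construction;
    # segments must be contiguous in position order (no interleaving that
    # contradicts a piecewise-constant path is possible for 2 templates,
    # so check agreement at non-differing sites instead)
    same_sites <- setdiff(seq_along(m$haplotype), diff_sites)
    expect_true(all(m$haplotype[same_sites] == two$haplotypes[1, same_sites]))
  }
})

test_that("mosaic template choice is symmetric for a 2-haplotype panel", {
  p <- simulate_base_panel(4, 500, seed = 13)
  hd <- as.matrix(dist(p$haplotypes, method = "manhattan"))
  pick <- which(hd == max(hd), arr.ind = TRUE)[1, ]
  keep <- which(p$haplotypes[pick[1], ] != p$haplotypes[pick[2], ])
  skip_if(length(keep) < 2)
  two <- hap_panel(p$haplotypes[pick, keep, drop = FALSE],
                   p$sites$position[keep], p$sites$exonic[keep],
                   p$region_length_bp)
  set.seed(31)
  frac1 <- mean(replicate(600, {
    m <- mosaic_haplotype(two, rho = 0.02, theta = 0)
    mean(m$haplotype == two$haplotypes[1, ])
  }))
  expect_gt(frac1, 0.40)
  expect_lt(frac1, 0.60)
})

test_that("expansion arithmetic, append-only rows, and provenance hold", {
  base <- simulate_base_panel(379, 1500, seed = 21)
  exp1 <- expand_panel(base, expansion_params(target_n = 679), seed = 22)
  expect_equal(n_individuals(exp1), 679)
  expect_identical(exp1$provenance, "expanded")
  # original rows restricted to original sites are untouched
  shared <- match(base$sites$position, exp1$sites$position)
  expect_false(anyNA(shared))
  expect_identical(exp1$haplotypes[seq_len(758), shared], base$haplotypes)
  expect_error(expand_panel(exp1, expansion_params(target_n = 100)),
               "smaller")
})

test_that("expansion to study scale preserves common-variant LD", {
  base <- simulate_base_panel(379, 1500, seed = 23)
  expd <- expand_panel(base, expansion_params(target_n = 3000), seed = 24)
  br <- seq(300, 1500, by = 300)
  p_base <- ld_profile(base, maf_breaks = c(0.05, 0.5), distance_breaks = br)
  p_exp <- ld_profile(expd, maf_breaks = c(0.05, 0.5), distance_breaks = br)
  common <- p_base$maf_bin == levels(p_base$maf_bin)[2]
  d <- abs(p_base$mean_r2[common] - p_exp$mean_r2[common])
  expect_true(all(d[!is.na(d)] <= 0.05))
})

test_that("thinning hits its target spectrum and is monotone in distance", {
  base <- simulate_base_panel(379, 1500, seed = 25)
  expd <- expand_panel(base, expansion_params(), seed = 26)
  target <- sfs_target_exome()
  thinned <- thin_to_sfs(expd, target, seed = 27)
  expect_identical(thinned$provenance, "thinned")
  expect_lt(sfs_distance(thinned, target), sfs_distance(expd, target))
  # per-bin deviation within the documented default tolerance
  realized <- sfs(thinned, target$mac_breaks, target$maf_breaks)$proportion
  expect_true(all(abs(realized - target$proportions) <= 0.02))
  # genotypes in retained columns are never edited
  shared <- match(thinned$sites$position, expd$sites$position)
  expect_identical(thinned$haplotypes,
                   expd$haplotypes[, shared, drop = FALSE])
})

test_that("thinning to the panel's own spectrum is the identity", {
  p <- simulate_base_panel(50, 1500, seed = 29)
  own <- sfs(p)
  target <- sfs_target(own$proportion, total_per_kb = NULL)
  out <- thin_to_sfs(p, target, seed = 30)
  expect_identical(out$haplotypes, p$haplotypes)
})

test_that("a target with zero mass above MAF 1% removes all common sites", {
  base <- simulate_base_panel(200, 1500, seed = 31)
  target <- sfs_target(c(0.5, 0.15, 0.15, 0.1, 0.1, 0, 0),
                       total_per_kb = NULL)
  out <- thin_to_sfs(base, target, seed = 32)
  expect_true(all(out$sites$panel_maf <= 0.01))
})

test_that("an infeasible target (adding variants) errors explicitly", {
  p <- simulate_base_panel(20, 300, seed = 33)
  target <- sfs_target_exome(total_per_kb = 1e4)
  expect_error(thin_to_sfs(p, target), "infeasible")
})

test_that("sfs handles the singleton example and normalises", {
  hap <- matrix(0L, 4, 2)
  hap[1, 1] <- 1L
  hap[c(1, 2), 2] <- 1L # second site keeps the first polymorphic companion
  p <- hap_panel(hap, c(10L, 20L), c(TRUE, TRUE), 100L)
  spec <- sfs(p)
  expect_equal(spec$count[1], 1) # the singleton
  expect_equal(sum(spec$proportion), 1)
})

test_that("subsampling a thinned panel depletes singletons", {
  full <- get_test_panel()
  sub <- subsample_panel(full, 2738, seed = 35)
  f_full <- glance(full)$singleton_fraction
  f_sub <- glance(sub)$singleton_fraction
  expect_lt(f_sub, f_full)
})

test_that("ld_profile matches direct correlation on perfect proxies", {
  hap <- cbind(rep(c(0L, 1L), each = 10), rep(c(0L, 1L), each = 10),
               rep(c(0L, 1L), 10))
  p <- hap_panel(hap, c(5L, 50L, 95L), rep(TRUE, 3), 100L)
  prof <- ld_profile(p, maf_breaks = 0.5, distance_breaks = c(50, 100))
  r2_near <- prof$mean_r2[prof$distance_bin == "(0,50]"]
  expect_equal(r2_near, mean(c(1, cor(hap[, 2], hap[, 3])^2)),
               tolerance = 1e-10)
})
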