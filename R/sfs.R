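#' Site frequency spectrum of a panel
#'
#' Bins variant sites by minor-allele count (MAC) for the rarest classes and
#' by minor-allele frequency (MAF) above them, the binning conventionally
#' used for exome spectra dominated by rare variation.
#'
#' @param panel a `hap_panel`.
#' @param mac_breaks upper MAC bounds of the count-based bins
#'   (default `c(1, 2, 5)`: singletons, doubletons, MAC 3-5).
#' @param maf_breaks upper MAF bounds of the frequency-based bins above the
#'   last MAC bin (default `c(0.001, 0.01, 0.05, 0.5)`).
#' @param exonic_only if `TRUE`, restrict to exonic sites.
#' @return Tibble with `bin` (ordered factor), `count`, `proportion`.
#' @export
sfs <- function(panel, mac_breaks = c(1, 2, 5),
                maf_breaks = c(0.001, 0.01, 0.05, 0.5),
                exonic_only = FALSE) {
  if (!inherits(panel, "hap_panel") || ncol(panel$haplotypes) == 0L)
    abort_param("`panel` must be a non-empty hap_panel")
  if (!length(mac_breaks) && !length(maf_breaks))
    abort_param("at least one bin must be specified")
  sites <- panel$sites
  if (exonic_only) sites <- sites[sites$exonic, , drop = FALSE]
  H <- nrow(panel$haplotypes)
  idx <- sfs_bin_index(round(sites$panel_maf * H), sites$panel_maf,
                       mac_breaks, maf_breaks)
  labs <- sfs_bin_labels(mac_breaks, maf_breaks)
  count <- tabulate(idx, nbins = length(labs))
  tibble::tibble(
    bin = factor(labs, levels = labs),
    count = count,
    proportion = if (sum(count)) count / sum(count) else rep(0, length(count))
  )
}

sfs_bin_index <- function(mac, maf, mac_breaks, maf_breaks) {
  n_mac <- length(mac_breaks)
  idx <- rep(NA_integer_, length(mac))
  prev <- 0
  for (b in seq_along(mac_breaks)) {
    sel <- is.na(idx) & mac <= mac_breaks[b]
    idx[sel] <- b
  }
  for (b in seq_along(maf_breaks)) {
    sel <- is.na(idx) & maf <= maf_breaks[b]
    idx[sel] <- n_mac + b
  }
  idx
}

sfs_bin_labels <- function(mac_breaks, maf_breaks) {
  mac_lab <- character(length(mac_breaks))
  lo <- 1
  for (b in seq_along(mac_breaks)) {
    mac_lab[b] <- if (mac_breaks[b] == lo) sprintf("MAC %d", lo)
                  else sprintf("MAC %d-%d", lo, mac_breaks[b])
    lo <- mac_breaks[b] + 1
  }
  prev <- 0
  maf_lab <- character(length(maf_breaks))
  for (b in seq_along(maf_breaks)) {
    maf_lab[b] <- sprintf("MAF (%g,%g]", prev, maf_breaks[b])
    prev <- maf_breaks[b]
  }
  c(mac_lab, maf_lab)
}

#' Target site frequency spectrum for rejection thinning
#'
#' Describes the spectrum a panel should be thinned towards: bin structure
#' (as in [sfs()]), target proportion per bin, and optionally a total
#' variant density. [sfs_target_exome()] is the bundled exome-like default:
#' a singleton-dominated spectrum with a power-law-like rare tail,
#' calibrated so that an average-coding-length (~1.5 kb) locus sampled at
#' 3,000 individuals segregates a median of ~38 exonic MAF < 1% variants.
#' It is a qualitative stand-in for published large-sample exome spectra,
#' not a copy of any published table.
#'
#' @param proportions numeric vector summing to 1, one entry per bin.
#' @param mac_breaks,maf_breaks bin structure, as in [sfs()].
#' @param total_per_kb expected retained variants per kb (optional; when
#'   `NULL`, thinning keeps the largest total compatible with the shape).
#' @return An `sfs_target` object.
#' @export
sfs_target <- function(proportions, mac_breaks = c(1, 2, 5),
                       maf_breaks = c(0.001, 0.01, 0.05, 0.5),
                       total_per_kb = NULL) {
  n_bins <- length(mac_breaks) + length(maf_breaks)
  if (length(proportions) != n_bins)
    abort_param("`proportions` must have one entry per bin")
  if (any(proportions < 0) || abs(sum(proportions) - 1) > 1e-9)
    abort_param("`proportions` must be non-negative and sum to 1")
  if (!is.null(total_per_kb)) check_scalar(total_per_kb, "total_per_kb", lower = 0)
  structure(list(proportions = proportions, mac_breaks = mac_breaks,
                 maf_breaks = maf_breaks, total_per_kb = total_per_kb),
            class = "sfs_target")
}

#' @rdname sfs_target
#' @export
sfs_target_exome <- function(total_per_kb = 60) {
  sfs_target(
    proportions = c(0.46, 0.13, 0.12, 0.12, 0.10, 0.035, 0.035),
    mac_breaks = c(1, 2, 5),
    maf_breaks = c(0.001, 0.01, 0.05, 0.5),
    total_per_kb = total_per_kb
  )
}

#' Thin a panel to match a target site frequency spectrum
#'
#' Removes whole variant columns by seeded rejection sampling so that the
#' retained spectrum matches the target per-bin proportions; genotypes
#' within retained columns are never edited (the approach that preserves
#' linkage structure while correcting variant density). Thinning can only
#' remove variation: a target that would require adding variants to a bin
#' raises an infeasibility error.
#'
#' @param panel a `hap_panel`.
#' @param target an [sfs_target()].
#' @param seed integer seed.
#' @param strict_total with `TRUE` (default), a requested total density the
#'   panel cannot supply is an error; with `FALSE` the largest feasible
#'   total compatible with the target shape is kept instead (used by the
#'   panel pipeline, where realised mutation counts vary stochastically).
#' @return A `hap_panel` with provenance `"thinned"`.
#' @export
thin_to_sfs <- function(panel, target = sfs_target_exome(), seed = NULL,
                        strict_total = TRUE) {
  if (!inherits(target, "sfs_target")) abort_param("`target` must be an sfs_target")
  H <- nrow(panel$haplotypes)
  mac <- round(panel$sites$panel_maf * H)
  idx <- sfs_bin_index(mac, panel$sites$panel_maf,
                       target$mac_breaks, target$maf_breaks)
  n_bins <- length(target$proportions)
  n_b <- tabulate(idx, nbins = n_bins)
  p <- target$proportions
  pos_bins <- p > 0
  feasible_total <- floor(min(n_b[pos_bins] / p[pos_bins]))
  n_keep <- if (is.null(target$total_per_kb)) feasible_total else
    round(target$total_per_kb * panel$region_length_bp / 1000)
  if (n_keep > feasible_total) {
    if (strict_total)
      abort_param(sprintf(
        "infeasible SFS target: would need to add variants (requested %d, feasible %d)",
        n_keep, feasible_total))
    n_keep <- feasible_total
  }
  r_b <- round(p * n_keep)
  keep <- logical(length(idx))
  retained <- with_seed(seed, {
    for (b in seq_len(n_bins)) {
      in_b <- which(idx == b)
      if (r_b[b] >= length(in_b)) keep[in_b] <- TRUE
      else if (r_b[b] > 0) keep[sample(in_b, r_b[b])] <- TRUE
    }
    keep
  })
  hap_panel(panel$haplotypes[, retained, drop = FALSE],
            panel$sites$position[retained], panel$sites$exonic[retained],
            panel$region_length_bp, provenance = "thinned")
}

#' Chi-square distance between a realized spectrum and a target
#'
#' @param panel a `hap_panel`.
#' @param target an [sfs_target()].
#' @return Scalar sum of `(realized - target)^2 / target` over bins with
#'   positive target mass.
#' @export
sfs_distance <- function(panel, target) {
  realized <- sfs(panel, target$mac_breaks, target$maf_breaks)$proportion
  p <- target$proportions
  sum((realized[p > 0] - p[p > 0])^2 / p[p > 0])
}

#' Simulate an exome-calibrated reference panel
#'
#' The full panel-generation pipeline: simulate a base panel (default 379
#' individuals, the size of a single-ancestry phased reference panel),
#' expand it by iterative mosaic simulation to `target_n` individuals
#' (default 12,514) with mutation parameter `theta = 0.08` (matched to the
#' singleton excess of large exome studies), then thin by rejection
#' sampling to the bundled exome-like spectrum. The defaults are calibrated
#' so that a 1.5 kb coding locus sampled at 3,000 individuals segregates a
#' median of ~38 exonic MAF < 1% variants.
#'
#' @param region_length_bp locus length (default 1500, an average
#'   coding length; the region is treated as concatenated coding sequence).
#' @param exon_fraction fraction of the region flagged exonic (default 1).
#' @param n_base base-panel individuals (default 379).
#' @param params an [expansion_params()].
#' @param target an [sfs_target()].
#' @param base_theta,base_rho base-panel generator parameters, see
#'   [simulate_base_panel()].
#' @param seed integer seed for the whole pipeline.
#' @return A `hap_panel` with provenance `"thinned"`.
#' @export
simulate_reference_panel <- function(region_length_bp = 1500,
                                     exon_fraction = 1,
                                     n_base = 379,
                                     params = expansion_params(),
                                     target = sfs_target_exome(),
                                     base_theta = 0.01, base_rho = 5e-4,
                                     seed = NULL) {
  base <- simulate_base_panel(n_base, region_length_bp, exon_fraction,
                              theta = base_theta, rho = base_rho,
                              seed = split_seed(seed, 1))
  expanded <- expand_panel(base, params, seed = split_seed(seed, 2))
  thin_to_sfs(expanded, target, seed = split_seed(seed, 3),
              strict_total = FALSE)
}
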