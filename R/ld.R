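#' Linkage-disequilibrium decay profile of a panel
#'
#' Mean pairwise squared Pearson correlation (r^2) of allele indicators for
#' all site pairs within each MAF stratum, binned by inter-site distance.
#' Used to verify that panel expansion preserves haplotype structure.
#'
#' @param panel a `hap_panel`.
#' @param maf_breaks upper bounds of MAF strata (default `c(0.05, 0.5)`:
#'   rare/low-frequency vs common). Pairs are formed within a stratum.
#' @param distance_breaks inter-site distance bin upper bounds in bp
#'   (default five equal bins over the region).
#' @param max_sites per-stratum cap on sites used (random subsample beyond
#'   it) to bound the pairwise computation.
#' @param seed seed for the subsampling, if triggered.
#' @return Tibble with `maf_bin`, `distance_bin`, `mean_r2`, `n_pairs`;
#'   empty cells are reported with `mean_r2 = NA`.
#' @export
ld_profile <- function(panel, maf_breaks = c(0.05, 0.5),
                       distance_breaks = NULL, max_sites = 400,
                       seed = NULL) {
  if (!inherits(panel, "hap_panel")) abort_param("`panel` must be a hap_panel")
  if (is.null(distance_breaks))
    distance_breaks <- seq(0, panel$region_length_bp, length.out = 6)[-1]
  maf_lab <- sprintf("MAF (%g,%g]", c(0, head(maf_breaks, -1)), maf_breaks)
  d_lab <- sprintf("(%g,%g]", c(0, head(distance_breaks, -1)), distance_breaks)
  out <- vector("list", length(maf_breaks))
  with_seed(seed, {
    for (s in seq_along(maf_breaks)) {
      lo <- if (s == 1) 0 else maf_breaks[s - 1]
      in_s <- which(panel$sites$panel_maf > lo &
                    panel$sites$panel_maf <= maf_breaks[s])
      if (length(in_s) > max_sites) in_s <- sort(sample(in_s, max_sites))
      cell <- tibble::tibble(maf_bin = maf_lab[s], distance_bin = d_lab,
                             mean_r2 = NA_real_, n_pairs = 0L)
      if (length(in_s) >= 2) {
        X <- panel$haplotypes[, in_s, drop = FALSE]
        r2 <- suppressWarnings(stats::cor(X))^2
        dd <- abs(outer(panel$sites$position[in_s],
                        panel$sites$position[in_s], "-"))
        ut <- upper.tri(r2)
        db <- findInterval(dd[ut], distance_breaks, left.open = TRUE) + 1L
        r2v <- r2[ut]
        ok <- is.finite(r2v) & db <= length(distance_breaks)
        if (any(ok)) {
          agg <- tapply(r2v[ok], db[ok], mean)
          cnt <- tapply(r2v[ok], db[ok], length)
          bi <- as.integer(names(agg))
          cell$mean_r2[bi] <- as.numeric(agg)
          cell$n_pairs[bi] <- as.integer(cnt)
        }
      }
      out[[s]] <- cell
    }
  })
  res <- dplyr::bind_rows(out)
  res$maf_bin <- factor(res$maf_bin, levels = maf_lab)
  res$distance_bin <- factor(res$distance_bin, levels = d_lab)
  class(res) <- c("ld_profile", class(res))
  res
}

#' @exportS3Method ggplot2::autoplot
autoplot.ld_profile <- function(object, ...) {
  ggplot2::ggplot(
    dplyr::filter(object, !is.na(.data$mean_r2)),
    ggplot2::aes(x = .data$distance_bin, y = .data$mean_r2,
                 colour = .data$maf_bin, group = .data$maf_bin)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "inter-site distance (bp)",
                  y = expression(mean ~ r^2),
                  colour = "MAF stratum") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.hap_panel <- function(object, ...) {
  spec <- sfs(object)
  ggplot2::ggplot(spec, ggplot2::aes(x = .data$bin, y = .data$proportion)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "frequency class", y = "proportion of sites",
                  title = sprintf("Site frequency spectrum (%d individuals)",
                                  n_individuals(object))) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 35, hjust = 1))
}
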