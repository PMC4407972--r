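#' Frequency-by-relative-risk sampling maps
#'
#' A `freq_rr_map` is a 2-D grid of non-negative sampling weights over
#' (MAF bin x RR bin). Normalising a MAF bin's row gives the conditional
#' distribution of per-allele relative risks for causal variants of that
#' frequency. Maps can be built on a parametric family
#' ([freq_rr_map_parametric()]), loaded from a TSV grid
#' ([read_freq_rr_map()]), or supplied directly.
#'
#' @param maf_edges increasing MAF bin edges starting at 0 and ending at
#'   <= 0.5 (length M + 1).
#' @param rr_edges increasing RR bin edges, all >= 1 (length R + 1); a draw
#'   is uniform on the log scale within its bin.
#' @param weights M x R matrix of non-negative weights.
#' @return A `freq_rr_map`.
#' @export
freq_rr_map <- function(maf_edges, rr_edges, weights) {
  if (any(diff(maf_edges) <= 0) || maf_edges[1] < 0 || tail(maf_edges, 1) > 0.5)
    abort_param("`maf_edges` must be increasing within [0, 0.5]")
  if (any(diff(rr_edges) < 0) || any(rr_edges < 1))
    abort_param("`rr_edges` must be non-decreasing and >= 1")
  weights <- as.matrix(weights)
  if (nrow(weights) != length(maf_edges) - 1L ||
      ncol(weights) != length(rr_edges) - 1L)
    abort_param("`weights` must be (length(maf_edges)-1) x (length(rr_edges)-1)")
  if (any(weights < 0)) abort_param("weights must be non-negative")
  structure(list(maf_edges = maf_edges, rr_edges = rr_edges,
                 weights = weights),
            class = "freq_rr_map")
}

default_maf_edges <- function() {
  c(0, 1e-4, 2.5e-4, 5e-4, 0.001, 0.0025, 0.005, 0.01, 0.025, 0.05,
    0.1, 0.25, 0.5)
}

default_rr_edges <- function() {
  exp(seq(log(1.001), log(6.5), length.out = 15))
}

#' @rdname freq_rr_map
#' @param coupling_exponent exponent c of the inverse frequency-effect
#'   coupling: the median log RR in a MAF bin is
#'   `log(rr_at_1pct) * (maf / 0.01)^(-c)` (capped at `log(rr_cap)`).
#'   `c = 0` gives frequency-independent effects.
#' @param rr_at_1pct median per-allele RR at MAF 1%.
#' @param sdlog spread of log RR within a MAF bin.
#' @param maf_support_max MAF above which the map has zero weight (set to
#'   0.01 for rare-only architectures).
#' @param rr_cap upper cap on the median RR (keeps penetrances feasible
#'   under a common-disease prevalence).
#' @export
freq_rr_map_parametric <- function(coupling_exponent = 0.15,
                                   rr_at_1pct = 1.65, sdlog = 0.3,
                                   maf_support_max = 0.5, rr_cap = 4.5,
                                   maf_edges = default_maf_edges(),
                                   rr_edges = default_rr_edges()) {
  M <- length(maf_edges) - 1L
  R <- length(rr_edges) - 1L
  mid <- sqrt(pmax(maf_edges[-length(maf_edges)], maf_edges[2] / 4) *
                maf_edges[-1]) # geometric bin midpoints
  mu <- pmin(log(rr_at_1pct) * (mid / 0.01)^(-coupling_exponent), log(rr_cap))
  W <- matrix(0, M, R)
  lo <- log(rr_edges[-length(rr_edges)])
  hi <- log(rr_edges[-1])
  for (m in seq_len(M)) {
    if (maf_edges[m] >= maf_support_max) next
    w <- pnorm(hi, mu[m], sdlog) - pnorm(lo, mu[m], sdlog)
    W[m, ] <- w / sum(w)
  }
  freq_rr_map(maf_edges, rr_edges, W)
}

#' Locus architecture models
#'
#' Six canonical architectures describing how causal-variant effect sizes
#' relate to allele frequency at a disease locus:
#' \describe{
#'   \item{ar1}{all risk-increasing, full frequency spectrum, strong
#'     inverse frequency-effect coupling (strong purifying selection).}
#'   \item{ar2}{as ar1 with moderate coupling.}
#'   \item{ar3}{as ar1 with no coupling (rare and common alleles have
#'     similar additive effects).}
#'   \item{ar4, ar5}{as ar1/ar2 but only rare (MAF < 1%) variants are
#'     causal.}
#'   \item{ar6}{the ar2 map with a 50/50 mixture of risk and protective
#'     effects (protective draws invert the relative risk).}
#' }
#' The bundled maps are parametric stand-ins reproducing these qualitative
#' regimes, not estimates from any specific forward simulation.
#'
#' @param id one of `"ar1"` ... `"ar6"`, or `"custom"` with `map` supplied.
#' @param map optional `freq_rr_map` overriding the bundled one.
#' @param direction_mix fraction of protective draws (overrides the
#'   architecture default when supplied).
#' @return An `architecture_model`: list with `id`, `map`,
#'   `maf_restriction`, `direction_mix`, `selection`.
#' @export
architecture_model <- function(id = c("ar1", "ar2", "ar3", "ar4", "ar5",
                                      "ar6", "custom"),
                               map = NULL, direction_mix = NULL) {
  id <- match.arg(id)
  spec <- switch(id,
    ar1 = list(c = 0.30, maf_max = 0.5, mix = 0, sel = "strong"),
    ar2 = list(c = 0.15, maf_max = 0.5, mix = 0, sel = "moderate"),
    ar3 = list(c = 0.00, maf_max = 0.5, mix = 0, sel = "weak"),
    ar4 = list(c = 0.30, maf_max = 0.01, mix = 0, sel = "strong"),
    ar5 = list(c = 0.15, maf_max = 0.01, mix = 0, sel = "moderate"),
    ar6 = list(c = 0.15, maf_max = 0.5, mix = 0.5, sel = "moderate"),
    custom = list(c = NA, maf_max = 0.5, mix = 0, sel = "custom")
  )
  if (id == "custom" && is.null(map))
    abort_param("a custom architecture needs an explicit `map`")
  if (is.null(map))
    map <- freq_rr_map_parametric(coupling_exponent = spec$c,
                                  maf_support_max = spec$maf_max)
  mix <- direction_mix %||% spec$mix
  check_scalar(mix, "direction_mix", lower = 0, upper = 1)
  structure(list(id = id, map = map,
                 maf_restriction = if (spec$maf_max < 0.5)
                   sprintf("rare-only(<%g)", spec$maf_max) else "full-spectrum",
                 maf_support_max = spec$maf_max,
                 direction_mix = mix, selection = spec$sel),
            class = "architecture_model")
}

#' @export
print.architecture_model <- function(x, ...) {
  cat(sprintf(
    "<architecture_model> %s: %s, %s selection, %.0f%% protective draws\n",
    x$id, x$maf_restriction, x$selection, 100 * x$direction_mix))
  invisible(x)
}

# Row index of the map's MAF bin containing each maf; NA when unsupported.
map_maf_bin <- function(map, maf) {
  b <- findInterval(maf, map$maf_edges, left.open = TRUE)
  b[b < 1 | b > nrow(map$weights)] <- NA_integer_
  b[!is.na(b) & rowSums(map$weights)[pmax(b, 1)] == 0] <- NA_integer_
  b
}

#' Sample per-allele relative risks from an architecture
#'
#' Draws a relative risk from the map's conditional distribution at each
#' variant's MAF bin (uniform on the log scale within the selected RR bin).
#' With probability `direction_mix` a draw is protective and the returned
#' relative risk is inverted (RR < 1).
#'
#' @param maf vector of minor-allele frequencies in (0, 0.5].
#' @param arch an [architecture_model()].
#' @param seed integer seed.
#' @return Numeric vector of per-allele relative risks (> 1 risk,
#'   < 1 protective).
#' @export
sample_rr <- function(maf, arch, seed = NULL) {
  if (!inherits(arch, "architecture_model"))
    abort_param("`arch` must be an architecture_model")
  if (any(maf <= 0 | maf > 0.5)) abort_param("`maf` must lie in (0, 0.5]")
  bin <- map_maf_bin(arch$map, maf)
  if (anyNA(bin))
    abort_param(sprintf(
      "architecture %s has no support at MAF %s",
      arch$id, paste(signif(maf[is.na(bin)], 3), collapse = ", ")))
  with_seed(seed, {
    W <- arch$map$weights
    rr <- vapply(bin, function(b) {
      r <- sample.int(ncol(W), 1L, prob = W[b, ])
      exp(runif(1, log(arch$map$rr_edges[r]), log(arch$map$rr_edges[r + 1L])))
    }, numeric(1))
    protective <- runif(length(rr)) < arch$direction_mix
    rr[protective] <- 1 / rr[protective]
    rr
  })
}
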