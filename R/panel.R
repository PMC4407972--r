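#' Phased haplotype panel objects
#'
#' A `hap_panel` holds phased binary haplotypes (rows) over ordered variant
#' sites (columns), the substrate of all downstream simulation. Sites carry
#' integer base-pair positions on a synthetic contig (0-based internally),
#' an exonic flag, and the panel minor-allele frequency. Monomorphic columns
#' are never stored.
#'
#' @param haplotypes binary integer matrix, rows = haplotypes (2 per
#'   individual), columns = sites.
#' @param position integer vector of 0-based site positions, one per column.
#' @param exonic logical vector, one per column.
#' @param region_length_bp length of the simulated contig in bp.
#' @param provenance one of `"base"`, `"expanded"`, `"thinned"`, `"imported"`.
#' @return A `hap_panel` object: list with elements `haplotypes`, `sites`
#'   (tibble with `index`, `position`, `exonic`, `panel_maf`),
#'   `region_length_bp`, `provenance`.
#' @export
hap_panel <- function(haplotypes, position, exonic,
                      region_length_bp, provenance = "base") {
  if (!is.matrix(haplotypes)) abort_param("`haplotypes` must be a matrix")
  if (nrow(haplotypes) %% 2L != 0L)
    abort_param("haplotype count must be even (2 per individual)")
  if (length(position) != ncol(haplotypes) || length(exonic) != ncol(haplotypes))
    abort_param("`position` and `exonic` must match the column count")
  storage.mode(haplotypes) <- "integer"
  dimnames(haplotypes) <- NULL
  position <- unname(position)
  if (length(position)) {
    ord <- order(position)
    haplotypes <- haplotypes[, ord, drop = FALSE]
    position <- position[ord]
    exonic <- exonic[ord]
    if (any(diff(position) <= 0))
      abort_param("site positions must be strictly increasing (duplicates found)")
  }
  af <- colMeans(haplotypes)
  poly <- af > 0 & af < 1
  haplotypes <- haplotypes[, poly, drop = FALSE]
  af <- af[poly]
  structure(
    list(
      haplotypes = haplotypes,
      sites = tibble::tibble(
        index = seq_len(ncol(haplotypes)) - 1L,
        position = as.integer(position[poly]),
        exonic = as.logical(exonic[poly]),
        panel_maf = pmin(af, 1 - af)
      ),
      region_length_bp = as.integer(region_length_bp),
      provenance = provenance
    ),
    class = "hap_panel"
  )
}

#' @export
print.hap_panel <- function(x, ...) {
  cat(sprintf(
    "<hap_panel> %d individuals (%d haplotypes) x %d sites over %s bp [%s]\n",
    n_individuals(x), nrow(x$haplotypes), ncol(x$haplotypes),
    format(x$region_length_bp, big.mark = ","), x$provenance))
  cat(sprintf("  exonic sites: %d; median panel MAF: %.4g\n",
              sum(x$sites$exonic), stats::median(x$sites$panel_maf)))
  invisible(x)
}

#' @rdname hap_panel
#' @param panel a `hap_panel`.
#' @export
n_individuals <- function(panel) nrow(panel$haplotypes) %/% 2L

#' Tidy site table of a haplotype panel
#'
#' @param x a `hap_panel`.
#' @param ... unused.
#' @return Tibble with one row per variant site.
#' @exportS3Method generics::tidy
tidy.hap_panel <- function(x, ...) x$sites

#' @exportS3Method generics::glance
glance.hap_panel <- function(x, ...) {
  tibble::tibble(
    n_individuals = n_individuals(x),
    n_haplotypes = nrow(x$haplotypes),
    n_sites = ncol(x$haplotypes),
    n_exonic = sum(x$sites$exonic),
    region_length_bp = x$region_length_bp,
    singleton_fraction = mean(round(x$sites$panel_maf * nrow(x$haplotypes)) == 1),
    provenance = x$provenance
  )
}

# Alternating exon/intron tiling covering exon_fraction of the region.
exon_intervals <- function(region_length_bp, exon_fraction,
                           target_exon_bp = 160) {
  if (exon_fraction >= 1)
    return(cbind(start = 0, end = region_length_bp))
  n_exon <- max(1L, round(region_length_bp * exon_fraction / target_exon_bp))
  exon_len <- region_length_bp * exon_fraction / n_exon
  gap <- region_length_bp * (1 - exon_fraction) / n_exon
  start <- gap / 2 + (seq_len(n_exon) - 1) * (exon_len + gap)
  cbind(start = floor(start), end = ceiling(start + exon_len))
}

in_intervals <- function(pos, iv) {
  hit <- rep(FALSE, length(pos))
  for (i in seq_len(nrow(iv))) hit <- hit | (pos >= iv[i, 1] & pos < iv[i, 2])
  hit
}

#' Simulate a base phased reference panel
#'
#' Sequentially builds haplotypes by a Li-and-Stephens style
#' copying-with-mutation scheme: each new haplotype is an imperfect mosaic of
#' the haplotypes generated before it, with template switches occurring at
#' per-bp intensity `rho` and copy errors at a per-site probability that
#' shrinks as the panel grows (so the site frequency spectrum comes out
#' rare-skewed, as for neutral variation). This stands in for a real phased
#' panel such as 1000 Genomes European haplotypes; real panels can be
#' imported instead via [read_panel_vcf()] or [read_panel_impute2()].
#'
#' @param n_individuals number of diploid individuals (>= 2).
#' @param region_length_bp contig length in bp.
#' @param exon_fraction fraction of the region flagged exonic, in (0, 1].
#'   Exons are laid out as evenly spaced contiguous blocks.
#' @param theta per-bp population-scaled mutation parameter controlling
#'   variant density (default 0.01, giving exome-like density at gene scale).
#' @param rho per-bp template-switch intensity of the copying chain
#'   (default 5e-4; larger values decay linkage disequilibrium faster).
#' @param seed integer seed; the run is bit-reproducible given it.
#' @return A `hap_panel` with provenance `"base"`.
#' @export
simulate_base_panel <- function(n_individuals, region_length_bp,
                                exon_fraction = 1, theta = 0.01,
                                rho = 5e-4, seed = NULL) {
  check_scalar(n_individuals, "n_individuals", lower = 2)
  check_scalar(region_length_bp, "region_length_bp", lower = 1)
  check_scalar(exon_fraction, "exon_fraction", lower = 0, upper = 1,
               strict_lower = TRUE)
  check_scalar(theta, "theta", lower = 0, strict_lower = TRUE)
  check_scalar(rho, "rho", lower = 0)
  with_seed(seed, {
    H <- 2L * as.integer(n_individuals)
    L <- as.integer(region_length_bp)
    pos <- 0:(L - 1L)
    hap <- matrix(0L, nrow = H, ncol = L)
    for (k in 2:H) {
      tmpl <- copy_one(hap, k - 1L, pos, rho)
      p_mut <- 0.5 * theta / (theta + (k - 1L)) # per-site copy-error probability
      n_flip <- rbinom(1L, L, p_mut)
      if (n_flip > 0L) {
        at <- sample.int(L, n_flip)
        tmpl[at] <- 1L - tmpl[at]
      }
      hap[k, ] <- tmpl
    }
    iv <- exon_intervals(L, exon_fraction)
    keep <- colMeans(hap) > 0 & colMeans(hap) < 1
    hap <- hap[, keep, drop = FALSE]
    pos <- pos[keep]
    # code 1 = minor allele in the base panel
    flip <- colMeans(hap) > 0.5
    hap[, flip] <- 1L - hap[, flip, drop = FALSE]
    hap_panel(hap, pos, in_intervals(pos, iv), L, provenance = "base")
  })
}

# Copy one mosaic over rows 1..n_avail of `hap`, switching templates at
# per-bp intensity rho. Returns the copied integer vector (no mutation).
# `cols` restricts to a column subset without materialising a submatrix.
copy_one <- function(hap, n_avail, pos, rho, cols = NULL, n_sw = NULL) {
  pr <- if (length(pos)) range(pos) else c(0, 0)
  L <- pr[2] - pr[1] + 1
  if (is.null(n_sw)) n_sw <- if (rho > 0) rpois(1L, rho * L) else 0L
  tmpl_idx <- sample.int(n_avail, n_sw + 1L, replace = TRUE)
  if (is.null(cols)) cols <- seq_len(ncol(hap))
  if (n_sw == 0L) return(hap[tmpl_idx, cols])
  brk <- sort(runif(n_sw, min = pr[1], max = pr[2]))
  seg <- findInterval(pos, brk) + 1L # segment id per site
  out <- integer(length(pos))
  for (s in seq_len(n_sw + 1L)) {
    idx <- seg == s
    if (any(idx)) out[idx] <- hap[tmpl_idx[s], cols[idx]]
  }
  out
}

#' Simulate one mosaic haplotype from a panel
#'
#' Draws a single new haplotype as a hidden-Markov copying path over the
#' panel's existing haplotypes: template switches occur at per-bp intensity
#' `rho`, and per-site copy errors (mutations) occur with probability
#' `0.5 * theta / (H + theta)` where `H` is the panel haplotype count, the
#' convention used by haplotype-resampling simulators. Optionally, brand-new
#' minor alleles are introduced at exonic positions not currently
#' segregating (rate `0.5 * theta` new sites per haplotype).
#'
#' @param panel a `hap_panel`.
#' @param rho per-bp template-switch intensity.
#' @param theta mutation parameter (see Description).
#' @param seed integer seed.
#' @param new_sites if `TRUE`, allow new singleton sites at free exonic
#'   positions; they are reported rather than added to the panel.
#' @return List with `haplotype` (integer vector over the panel's sites) and
#'   `new_site_positions` (integer vector, possibly empty).
#' @export
mosaic_haplotype <- function(panel, rho = 1e-5, theta = 0.08, seed = NULL,
                             new_sites = FALSE) {
  if (!inherits(panel, "hap_panel") || nrow(panel$haplotypes) == 0L)
    abort_param("`panel` must be a non-empty hap_panel")
  with_seed(seed, {
    H <- nrow(panel$haplotypes)
    out <- copy_one(panel$haplotypes, H, panel$sites$position, rho)
    p_mut <- 0.5 * theta / (H + theta)
    n_flip <- rbinom(1L, length(out), p_mut)
    if (n_flip > 0L) {
      at <- sample.int(length(out), n_flip)
      out[at] <- 1L - out[at]
    }
    newpos <- integer(0)
    if (new_sites) {
      free <- free_exonic_positions(panel)
      n_new <- min(rpois(1L, 0.5 * theta), length(free))
      if (n_new > 0L) newpos <- sample(free, n_new)
    }
    list(haplotype = out, new_site_positions = as.integer(newpos))
  })
}

free_exonic_positions <- function(panel) {
  iv <- attr(panel, "exon_iv")
  all_pos <- 0:(panel$region_length_bp - 1L)
  exonic <- if (!is.null(iv)) in_intervals(all_pos, iv) else {
    # reconstruct exon extent from flagged sites (conservative: positions
    # within the span of exonic sites)
    if (!any(panel$sites$exonic)) rep(FALSE, length(all_pos))
    else all_pos >= min(panel$sites$position[panel$sites$exonic]) &
         all_pos <= max(panel$sites$position[panel$sites$exonic])
  }
  setdiff(all_pos[exonic], panel$sites$position)
}

#' Expansion parameters for panel augmentation
#'
#' @param theta mutation parameter governing copy errors and new rare sites
#'   during expansion (default 0.08, matched to the singleton excess of
#'   large exome studies).
#' @param rho per-bp template-switch intensity during expansion (default
#'   1e-5, small so that linkage disequilibrium is preserved).
#' @param increment individuals added per iteration (default 300).
#' @param target_n final panel size in individuals (default 12514).
#' @param new_site_rate expected brand-new singleton sites per added
#'   haplotype, placed at free exonic positions (default `0.25 * theta`).
#' @return An `expansion_params` list.
#' @export
expansion_params <- function(theta = 0.08, rho = 1e-5, increment = 300,
                             target_n = 12514, new_site_rate = 0.25 * theta) {
  check_scalar(theta, "theta", lower = 0, strict_lower = TRUE)
  check_scalar(rho, "rho", lower = 0)
  check_scalar(increment, "increment", lower = 1)
  check_scalar(target_n, "target_n", lower = 1)
  check_scalar(new_site_rate, "new_site_rate", lower = 0)
  structure(list(theta = theta, rho = rho, increment = as.integer(increment),
                 target_n = as.integer(target_n),
                 new_site_rate = new_site_rate),
            class = "expansion_params")
}

#' Expand a reference panel by iterative mosaic simulation
#'
#' Augments the panel to `params$target_n` individuals by iteratively
#' simulating mosaic haplotypes (with no phenotypic effects) and appending
#' them, in increments of `params$increment` individuals per iteration.
#' Each added haplotype copies from all haplotypes present at the start of
#' its iteration. Copy errors introduce new rare alleles at existing sites;
#' new singleton sites arise at free exonic positions at rate
#' `params$new_site_rate` per haplotype, emulating the excess of rare coding
#' variation seen in large exome studies. Original rows are untouched.
#'
#' @param panel a `hap_panel`.
#' @param params an [expansion_params()] object.
#' @param seed integer seed.
#' @return A `hap_panel` with provenance `"expanded"`.
#' @export
expand_panel <- function(panel, params = expansion_params(), seed = NULL) {
  if (!inherits(panel, "hap_panel")) abort_param("`panel` must be a hap_panel")
  n0 <- n_individuals(panel)
  if (params$target_n < n0)
    abort_param("target_n is smaller than the current panel size")
  if (params$target_n == n0) return(panel)
  with_seed(seed, {
    L <- panel$region_length_bp
    n_add_hap <- 2L * (params$target_n - n0)
    # pool of free exonic positions for brand-new singleton sites
    free <- free_exonic_positions_base(panel)
    n_new_max <- length(free)
    S0 <- ncol(panel$haplotypes)
    hap <- matrix(0L, nrow = 2L * params$target_n, ncol = S0 + n_new_max)
    hap[seq_len(nrow(panel$haplotypes)), seq_len(S0)] <- panel$haplotypes
    pos <- c(panel$sites$position, rep(NA_integer_, n_new_max))
    exo <- c(panel$sites$exonic, rep(TRUE, n_new_max))
    S_cur <- S0
    H_cur <- nrow(panel$haplotypes)
    free_left <- sample(free) # randomized draw order
    while (H_cur < nrow(hap)) {
      blk <- min(2L * params$increment, nrow(hap) - H_cur)
      rows <- H_cur + seq_len(blk)
      tmpl <- sample.int(H_cur, blk, replace = TRUE)
      hap[rows, seq_len(S_cur)] <- hap[tmpl, seq_len(S_cur), drop = FALSE]
      # template switches (rare): redo affected haplotypes site-wise
      n_sw <- rpois(blk, params$rho * L)
      for (j in which(n_sw > 0L)) {
        hap[rows[j], seq_len(S_cur)] <-
          copy_one(hap, H_cur, pos[seq_len(S_cur)], params$rho,
                   cols = seq_len(S_cur), n_sw = n_sw[j])
      }
      # copy errors at existing sites
      p_mut <- 0.5 * params$theta / (H_cur + params$theta)
      n_flip <- rbinom(1L, blk * S_cur, p_mut)
      if (n_flip > 0L) {
        cells <- cbind(rows[sample.int(blk, n_flip, replace = TRUE)],
                       sample.int(S_cur, n_flip, replace = TRUE))
        hap[cells] <- 1L - hap[cells]
      }
      # brand-new singleton sites at free exonic positions
      n_new <- min(rpois(1L, blk * params$new_site_rate), length(free_left))
      if (n_new > 0L) {
        newpos <- free_left[seq_len(n_new)]
        free_left <- free_left[-seq_len(n_new)]
        cols <- S_cur + seq_len(n_new)
        pos[cols] <- newpos
        hap[cbind(rows[sample.int(blk, n_new, replace = TRUE)], cols)] <- 1L
        S_cur <- S_cur + n_new
      }
      H_cur <- H_cur + blk
    }
    out <- hap_panel(hap[, seq_len(S_cur), drop = FALSE],
                     pos[seq_len(S_cur)], exo[seq_len(S_cur)],
                     L, provenance = "expanded")
    out
  })
}

free_exonic_positions_base <- function(panel) {
  all_pos <- 0:(panel$region_length_bp - 1L)
  # exonic extent: union of blocks inferred from site flags; when every site
  # is exonic treat the whole region as coding (concatenated-exon locus)
  if (all(panel$sites$exonic)) return(setdiff(all_pos, panel$sites$position))
  free_exonic_positions(panel)
}

#' Draw a subset of individuals from a panel
#'
#' @param panel a `hap_panel`.
#' @param n_individuals number of individuals to retain (sampled without
#'   replacement).
#' @param seed integer seed.
#' @return A `hap_panel` restricted to the sampled individuals (monomorphic
#'   columns dropped).
#' @export
subsample_panel <- function(panel, n_individuals, seed = NULL) {
  check_scalar(n_individuals, "n_individuals", lower = 1,
               upper = n_individuals(panel))
  with_seed(seed, {
    ind <- sample.int(n_individuals(panel), n_individuals)
    rows <- as.vector(rbind(2L * ind - 1L, 2L * ind))
    hap_panel(panel$haplotypes[rows, , drop = FALSE], panel$sites$position,
              panel$sites$exonic, panel$region_length_bp,
              provenance = panel$provenance)
  })
}
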