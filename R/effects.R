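#' Sample a causal-variant set to hit a target locus effect size
#'
#' Implements the iterative sampling loop used to assign phenotypic effects
#' at a locus: repeatedly pick an exonic panel variant at random, draw a
#' per-allele relative risk from the architecture's frequency-effect map,
#' and accumulate liability-scale variance explained (VE). While the
#' cumulative VE is below `0.95 * target_ve` another variant is added; when
#' it overshoots `1.05 * target_ve` one of the introduced effects is
#' removed uniformly at random; acceptance requires the cumulative VE to
#' land inside the `(0.95, 1.05) * target_ve` window with at most
#' `max_causal` causal variants, otherwise the attempt restarts from
#' scratch. Draws whose effect would be infeasible under the prevalence
#' (penetrance outside (0,1)) are rejected and redrawn.
#'
#' @param panel a `hap_panel`.
#' @param arch an [architecture_model()].
#' @param target_ve target locus variance-explained fraction (e.g. 0.01).
#' @param disease a [disease_model()].
#' @param max_causal cap on the causal-set size (default 35).
#' @param max_restarts attempts before giving up with an error
#'   (default 1000).
#' @param seed integer seed.
#' @return A `locus_effects` object: list with `effects` (tibble: `site`,
#'   `position`, `maf`, `rr`, `direction`, `ve`), `achieved_ve`,
#'   `target_ve`, `n_restarts`.
#' @export
sample_locus_effects <- function(panel, arch, target_ve = 0.01,
                                 disease = disease_model(),
                                 max_causal = 35, max_restarts = 1000,
                                 seed = NULL) {
  check_scalar(target_ve, "target_ve", lower = 0, upper = 1,
               strict_lower = TRUE)
  sites <- panel$sites
  support <- which(sites$exonic &
                   !is.na(map_maf_bin(arch$map, sites$panel_maf)))
  if (!length(support))
    abort_param("panel has no exonic variants within the architecture's support")
  lo <- 0.95 * target_ve
  hi <- 1.05 * target_ve
  with_seed(seed, {
    for (restart in seq_len(max_restarts)) {
      chosen <- integer(0)
      rr <- numeric(0)
      ve <- numeric(0)
      iter <- 0L
      repeat {
        iter <- iter + 1L
        if (iter > 10000L) break # oscillation guard -> restart
        tot <- sum(ve)
        if (tot >= lo && tot <= hi) {
          if (length(chosen) > max_causal) break # cap exceeded -> restart
          eff <- tibble::tibble(
            site = sites$index[chosen], # 0-based panel site index
            position = sites$position[chosen],
            maf = sites$panel_maf[chosen],
            rr = rr,
            direction = ifelse(rr >= 1, "risk", "protective"),
            ve = ve
          )
          return(structure(
            list(effects = eff, achieved_ve = tot, target_ve = target_ve,
                 n_restarts = restart - 1L),
            class = "locus_effects"))
        }
        if (tot > hi) {
          drop <- sample.int(length(chosen), 1L)
          chosen <- chosen[-drop]; rr <- rr[-drop]; ve <- ve[-drop]
          next
        }
        avail <- setdiff(support, chosen)
        if (!length(avail)) break # candidates exhausted -> restart
        cand <- if (length(avail) == 1L) avail else sample(avail, 1L)
        r <- sample_rr(sites$panel_maf[cand], arch)
        v <- tryCatch(variance_explained(sites$panel_maf[cand], r, disease),
                      error = function(e) NA_real_)
        if (is.na(v)) next # infeasible penetrance: redraw
        chosen <- c(chosen, cand); rr <- c(rr, r); ve <- c(ve, v)
      }
    }
    abort_param(sprintf(
      "could not reach target VE %.3g within %d restarts (cap %d variants)",
      target_ve, max_restarts, max_causal))
  })
}

#' @export
print.locus_effects <- function(x, ...) {
  cat(sprintf(
    "<locus_effects> %d causal variants, achieved VE %.4f (target %.4f, window 0.95-1.05)\n",
    nrow(x$effects), x$achieved_ve, x$target_ve))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.locus_effects <- function(x, ...) x$effects

#' @exportS3Method generics::glance
glance.locus_effects <- function(x, ...) {
  tibble::tibble(
    n_causal = nrow(x$effects),
    n_protective = sum(x$effects$direction == "protective"),
    achieved_ve = x$achieved_ve,
    target_ve = x$target_ve,
    n_restarts = x$n_restarts
  )
}

#' Null (no-effect) locus
#'
#' @param panel a `hap_panel`; kept for interface symmetry.
#' @param target_ve ignored; the null locus explains nothing.
#' @return A `locus_effects` with an empty causal set, used for
#'   type-I-error simulations.
#' @export
null_locus_effects <- function(panel = NULL, target_ve = 0) {
  structure(list(
    effects = tibble::tibble(site = integer(0), position = integer(0),
                             maf = numeric(0), rr = numeric(0),
                             direction = character(0), ve = numeric(0)),
    achieved_ve = 0, target_ve = 0, n_restarts = 0L),
    class = "locus_effects")
}
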