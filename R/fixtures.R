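#' Bundled toy datasets for exhaustive-oracle validation
#'
#' Builds, in code, the small fixtures used throughout the test suite:
#' tiny cohorts whose permutation nulls can be enumerated exhaustively
#' (all case/control label assignments), plus one exome-calibrated locus
#' cohort at study scale. Fixture content is fully determined by `seed`.
#'
#' @param seed integer seed.
#' @param with_study_locus also build the study-scale calibrated locus
#'   (slower; default FALSE).
#' @return Named list of fixtures:
#' \describe{
#'   \item{toy8}{8 individuals (4 cases), 4 sites, hand-checkable counts:
#'     rare alleles concentrated in cases.}
#'   \item{toy8_null}{8 individuals (4 cases), balanced counts.}
#'   \item{toy10}{10 individuals (5 cases), 6 sites, mixed directions.}
#'   \item{locus3k}{only with `with_study_locus`: a 1500-case/1500-control
#'     cohort on a calibrated panel under the moderate-selection
#'     architecture at 1% VE.}
#' }
#' @export
make_fixtures <- function(seed = 1, with_study_locus = FALSE) {
  # toy8: carriers concentrated in cases (rows 1-4 are cases)
  g8 <- matrix(0L, 8, 4)
  g8[1, 1] <- 1L; g8[2, 2] <- 1L; g8[3, 3] <- 1L; g8[2, 4] <- 1L
  g8[5, 3] <- 1L
  toy8 <- cohort_from_genotypes(g8, rep(c(1L, 0L), each = 4))
  # toy8_null: perfectly balanced carriers
  g8n <- matrix(0L, 8, 4)
  g8n[c(1, 5), 1] <- 1L; g8n[c(2, 6), 2] <- 1L
  g8n[c(3, 7), 3] <- 1L; g8n[c(4, 8), 4] <- 1L
  toy8_null <- cohort_from_genotypes(g8n, rep(c(1L, 0L), each = 4))
  # toy10: one case-skewed site, one control-skewed, singletons, a hom
  g10 <- matrix(0L, 10, 6)
  g10[1:3, 1] <- 1L
  g10[8:10, 2] <- 1L
  g10[1, 3] <- 2L
  g10[6, 4] <- 1L
  g10[2, 5] <- 1L; g10[7, 5] <- 1L
  g10[4, 6] <- 1L
  toy10 <- cohort_from_genotypes(g10, rep(c(1L, 0L), each = 5))
  out <- list(toy8 = toy8, toy8_null = toy8_null, toy10 = toy10)
  if (with_study_locus) {
    panel <- simulate_reference_panel(seed = split_seed(seed, 101))
    eff <- sample_locus_effects(panel, architecture_model("ar2"), 0.01,
                                seed = split_seed(seed, 102))
    out$locus3k <- sample_cohort(panel, eff, seed = split_seed(seed, 103))
    out$locus3k_panel <- panel
    out$locus3k_effects <- eff
  }
  out
}
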