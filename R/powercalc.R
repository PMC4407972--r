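#' Analytic and Monte-Carlo power for single-variant association
#'
#' Computes case and control expected allele frequencies under the
#' prevalence-constrained relative-risk model (penetrances solved so the
#' population risk equals the prevalence), then evaluates power for the
#' two-sided allelic test either analytically (normal approximation on the
#' two-proportion comparison of allele frequencies) or by Monte-Carlo
#' simulation of genotype counts with Fisher's exact test on the allele
#' table. As a reference point, a variant with MAF 0.5% and RR 3 tested in
#' 1.5K cases / 1.5K controls at genome-wide significance (5e-8) under an
#' 8%-prevalence trait has power of roughly 5%.
#'
#' @param maf population minor-allele frequency of the risk allele.
#' @param rr per-allele relative risk.
#' @param n_case,n_control sample sizes.
#' @param prevalence trait prevalence (default 0.08).
#' @param alpha significance threshold (default 5e-8).
#' @param method `"analytic"` or `"montecarlo"`.
#' @param controls `"population"` (classical power-calculator convention:
#'   controls carry the population allele frequency, as for unselected
#'   controls) or `"screened"` (controls are disease-free, so the risk
#'   allele is depleted in them; matches the cohort simulator and yields
#'   somewhat higher power).
#' @param n_sim Monte-Carlo replicates (default 1e4).
#' @param seed Monte-Carlo seed.
#' @return Power in [0, 1].
#' @export
power_single_variant <- function(maf, rr, n_case = 1500, n_control = 1500,
                                 prevalence = 0.08, alpha = 5e-8,
                                 method = c("analytic", "montecarlo"),
                                 controls = c("population", "screened"),
                                 n_sim = 1e4, seed = NULL) {
  method <- match.arg(method)
  controls <- match.arg(controls)
  check_scalar(maf, "maf", lower = 0, upper = 0.5, strict_lower = TRUE)
  check_scalar(rr, "rr", lower = 0, strict_lower = TRUE)
  check_scalar(alpha, "alpha", lower = 0, upper = 1, strict_lower = TRUE)
  K <- prevalence
  g <- hwe_geno_freq(maf)
  f <- penetrances(maf, rr, K) # errors when the effect is infeasible
  p_case <- f * g / K
  p_ctrl <- if (controls == "population") g else (1 - f) * g / (1 - K)
  q_case <- p_case[2] / 2 + p_case[3]
  q_ctrl <- p_ctrl[2] / 2 + p_ctrl[3]
  if (method == "analytic") {
    n1 <- 2 * n_case; n2 <- 2 * n_control
    qbar <- (n1 * q_case + n2 * q_ctrl) / (n1 + n2)
    za <- qnorm(1 - alpha / 2)
    se0 <- sqrt(qbar * (1 - qbar) * (1 / n1 + 1 / n2))
    se1 <- sqrt(q_case * (1 - q_case) / n1 + q_ctrl * (1 - q_ctrl) / n2)
    d <- abs(q_case - q_ctrl)
    return(pnorm((d - za * se0) / se1) + pnorm((-d - za * se0) / se1))
  }
  with_seed(seed, {
    hits <- 0L
    for (b in seq_len(n_sim)) {
      gc_case <- as.vector(stats::rmultinom(1, n_case, p_case))
      gc_ctrl <- as.vector(stats::rmultinom(1, n_control, p_ctrl))
      a_case <- gc_case[2] + 2L * gc_case[3]
      a_ctrl <- gc_ctrl[2] + 2L * gc_ctrl[3]
      tab <- matrix(c(a_case, 2L * n_case - a_case,
                      a_ctrl, 2L * n_control - a_ctrl), 2)
      if (fisher.test(tab)$p.value < alpha) hits <- hits + 1L
    }
    hits / n_sim
  })
}

#' Exome-wide significance bookkeeping
#'
#' `exome_wide_alpha` is the Bonferroni threshold for a gene-level scan
#' (0.05 / 20,000 = 2.5e-6 by default); `expected_null_hits` is the
#' expected number of genes passing a threshold under the global null
#' (20,000 x 1e-4 = 2 at the follow-up threshold).
#'
#' @param n_genes number of genes tested exome-wide (default 20000).
#' @param alpha family-wise error target (for `exome_wide_alpha`) or
#'   per-gene threshold (for `expected_null_hits`).
#' @return A scalar.
#' @export
exome_wide_alpha <- function(n_genes = 20000, alpha = 0.05) {
  check_scalar(n_genes, "n_genes", lower = 1)
  alpha / n_genes
}

#' @rdname exome_wide_alpha
#' @export
expected_null_hits <- function(n_genes = 20000, alpha = 1e-4) {
  check_scalar(n_genes, "n_genes", lower = 1)
  n_genes * alpha
}
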