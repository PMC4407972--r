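#' Disease model for a common dichotomous trait
#'
#' @param prevalence population prevalence K in (0, 1); the default 0.08
#'   models a common complex disease such as type 2 diabetes.
#' @return A `disease_model` list.
#' @export
disease_model <- function(prevalence = 0.08) {
  check_scalar(prevalence, "prevalence", lower = 0, upper = 1,
               strict_lower = TRUE, strict_upper = TRUE)
  structure(list(prevalence = prevalence), class = "disease_model")
}

# Genotype risk multipliers for a per-allele relative risk under additive
# dosage coding: het = RR, hom = 2 RR - 1. A protective minor allele
# (rr < 1) is recoded as a risk effect of the major allele, which keeps all
# penetrances positive for any rr > 0:
#   multipliers over minor-allele dosage 0/1/2.
risk_multipliers <- function(rr) {
  if (rr >= 1) c(1, rr, 2 * rr - 1)
  else {
    R <- 1 / rr
    c(2 * R - 1, R, 1)
  }
}

# HWE genotype frequencies over minor-allele dosage 0/1/2.
hwe_geno_freq <- function(maf) c((1 - maf)^2, 2 * maf * (1 - maf), maf^2)

# Penetrances per genotype solved so the population risk equals K.
penetrances <- function(maf, rr, prevalence) {
  g <- hwe_geno_freq(maf)
  m <- risk_multipliers(rr)
  f0 <- prevalence / sum(g * m)
  f <- f0 * m
  if (any(f <= 0) || any(f >= 1))
    abort_param(sprintf(
      "infeasible effect: penetrance outside (0,1) for maf=%g, rr=%g, K=%g",
      maf, rr, prevalence))
  f
}

#' Liability-scale variance explained by one variant
#'
#' Computes the fraction of liability variance attributable to a biallelic
#' variant under the liability-threshold model: genotype frequencies follow
#' Hardy-Weinberg; genotype penetrances are solved so that the population
#' risk equals the prevalence, with additive dosage coding of the relative
#' risk (het RR, hom 2RR-1; protective minor alleles are recoded as risk
#' effects of the major allele); each penetrance is mapped to a mean shift
#' of a standard-normal liability truncated at the prevalence threshold;
#' the between-genotype variance of those shifts, normalised by the total
#' liability variance (1 + Vg), is returned.
#'
#' @param maf minor-allele frequency in (0, 0.5].
#' @param rr per-allele relative risk (> 0; 1 means no effect).
#' @param disease a [disease_model()].
#' @return Variance-explained fraction in [0, 1).
#' @export
variance_explained <- function(maf, rr, disease = disease_model()) {
  check_scalar(maf, "maf", lower = 0, upper = 0.5, strict_lower = FALSE)
  check_scalar(rr, "rr", lower = 0, strict_lower = TRUE)
  if (maf == 0 || rr == 1) return(0)
  K <- disease$prevalence
  f <- penetrances(maf, rr, K)
  g <- hwe_geno_freq(maf)
  thr <- qnorm(1 - K)
  mu <- thr - qnorm(1 - f) # liability mean shift per genotype
  vg <- sum(g * mu^2) - sum(g * mu)^2
  vg / (1 + vg)
}

#' Total variance explained by a causal-variant set
#'
#' Risk variants at a locus are assumed independent, so the locus total is
#' the sum of per-variant variance-explained fractions.
#'
#' @param effects a `locus_effects` object (or a data frame with a `ve`
#'   column).
#' @param disease unused; kept for interface symmetry.
#' @return Scalar total VE.
#' @export
locus_ve <- function(effects, disease = disease_model()) {
  if (inherits(effects, "locus_effects")) sum(effects$effects$ve)
  else sum(effects$ve)
}
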