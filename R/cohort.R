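#' Case-control cohort datasets
#'
#' A `cohort` holds an unphased genotype dosage matrix (individuals x
#' sites, values 0/1/2), a case/control phenotype vector, a per-site table
#' with observed minor-allele frequencies and case/control minor-allele
#' counts, and a causal-site mask used only for evaluation (association
#' tests never see it).
#'
#' @name cohort
NULL

new_cohort <- function(genotypes, phenotype, position, exonic, causal,
                       region_length_bp) {
  storage.mode(genotypes) <- "integer"
  dimnames(genotypes) <- NULL
  keep <- colSums(genotypes) > 0L & colSums(genotypes) < 2L * nrow(genotypes)
  genotypes <- genotypes[, keep, drop = FALSE]
  position <- position[keep]; exonic <- exonic[keep]; causal <- causal[keep]
  af <- colMeans(genotypes) / 2
  flipped <- af > 0.5
  n_case <- sum(phenotype == 1L)
  minor <- sweep(genotypes, 2, ifelse(flipped, 2L, 0L),
                 function(g, f) abs(g - f)) # minor-allele dosage
  case_counts <- colSums(minor[phenotype == 1L, , drop = FALSE])
  ctrl_counts <- colSums(minor[phenotype == 0L, , drop = FALSE])
  structure(list(
    genotypes = genotypes,
    phenotype = as.integer(phenotype),
    n_case = n_case,
    n_control = length(phenotype) - n_case,
    sites = tibble::tibble(
      index = seq_along(position) - 1L,
      position = as.integer(position),
      exonic = as.logical(exonic),
      maf = pmin(af, 1 - af),
      minor_is_alt = !flipped,
      case_minor_count = as.integer(case_counts),
      control_minor_count = as.integer(ctrl_counts),
      causal = as.logical(causal)
    ),
    region_length_bp = region_length_bp),
    class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf(
    "<cohort> %d cases / %d controls x %d segregating sites (%d causal)\n",
    x$n_case, x$n_control, ncol(x$genotypes), sum(x$sites$causal)))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.cohort <- function(x, ...) x$sites

#' @exportS3Method generics::glance
glance.cohort <- function(x, ...) {
  tibble::tibble(
    n_case = x$n_case, n_control = x$n_control,
    n_sites = ncol(x$genotypes),
    n_rare = sum(x$sites$maf < 0.01),
    n_causal = sum(x$sites$causal)
  )
}

# Per-variant multiplier lookup over dosages 0/1/2 for a set of effects.
effect_multiplier_matrix <- function(effects) {
  t(vapply(effects$rr, risk_multipliers, numeric(3)))
}

#' Disease probability of individuals given causal genotypes
#'
#' `P(disease | g) = f0 * prod_v m_v(g_v)` with per-variant multipliers
#' 1, RR, 2RR-1 over minor-allele dosage (protective variants recoded on
#' the major allele), and baseline `f0` solved so that the expected risk
#' over panel Hardy-Weinberg genotype frequencies equals the prevalence.
#' Risks are never clipped: a computed risk >= 1 raises an infeasibility
#' error.
#'
#' @param dosages numeric vector (one individual) or matrix (individuals x
#'   causal sites) of minor-allele dosages, columns ordered as
#'   `effects$effects` rows.
#' @param effects a `locus_effects`.
#' @param disease a [disease_model()].
#' @return Vector of disease probabilities.
#' @export
individual_risk <- function(dosages, effects, disease = disease_model()) {
  eff <- if (inherits(effects, "locus_effects")) effects$effects else effects
  if (is.null(dim(dosages))) dosages <- matrix(dosages, nrow = 1)
  K <- disease$prevalence
  if (nrow(eff) == 0L) return(rep(K, nrow(dosages)))
  if (ncol(dosages) != nrow(eff))
    abort_param("`dosages` columns must match the causal-effect rows")
  M <- effect_multiplier_matrix(eff) # v x 3
  expect <- vapply(seq_len(nrow(eff)), function(v)
    sum(hwe_geno_freq(eff$maf[v]) * M[v, ]), numeric(1))
  f0 <- K / prod(expect)
  logm <- log(M)
  lr <- rep(log(f0), nrow(dosages))
  for (v in seq_len(nrow(eff)))
    lr <- lr + logm[v, dosages[, v] + 1L]
  risk <- exp(lr)
  if (any(risk >= 1))
    abort_param("infeasible effects: some individuals reach disease probability >= 1")
  risk
}

# Draw `n` mosaic haplotypes from the panel in one vectorised block:
# template copy + rare switches + copy-error flips (no new sites).
mosaic_block <- function(panel, n, rho, theta) {
  H <- nrow(panel$haplotypes)
  S <- ncol(panel$haplotypes)
  tmpl <- sample.int(H, n, replace = TRUE)
  out <- panel$haplotypes[tmpl, , drop = FALSE]
  n_sw <- rpois(n, rho * panel$region_length_bp)
  for (j in which(n_sw > 0L))
    out[j, ] <- copy_one(panel$haplotypes, H, panel$sites$position, rho,
                         n_sw = n_sw[j])
  n_flip <- rbinom(1L, n * S, 0.5 * theta / (H + theta))
  if (n_flip > 0L) {
    cells <- cbind(sample.int(n, n_flip, replace = TRUE),
                   sample.int(S, n_flip, replace = TRUE))
    out[cells] <- 1L - out[cells]
  }
  out
}

#' Sample a case-control cohort at a locus
#'
#' Forms diploid individuals by drawing two mosaic-perturbed haplotypes
#' from the panel, assigns case/control status by a Bernoulli draw on
#' [individual_risk()], and retains individuals until both quotas are
#' filled (prevalence-constrained rejection sampling). Monomorphic sites
#' are dropped from the resulting dataset.
#'
#' @param panel a `hap_panel`.
#' @param effects a `locus_effects` (use [null_locus_effects()] for
#'   type-I-error datasets).
#' @param disease a [disease_model()].
#' @param n_case,n_control quotas (defaults 1500/1500, a contemporary
#'   sequencing-study size).
#' @param rho,theta mosaic perturbation parameters (defaults as in
#'   [expansion_params()]).
#' @param max_draw_factor sampling budget: at most
#'   `max_draw_factor * (n_case + n_control) / prevalence` individuals are
#'   drawn before an exhaustion error.
#' @param seed integer seed.
#' @return A `cohort`.
#' @export
sample_cohort <- function(panel, effects = null_locus_effects(),
                          disease = disease_model(),
                          n_case = 1500, n_control = 1500,
                          rho = 1e-5, theta = 0.08,
                          max_draw_factor = 20, seed = NULL) {
  check_scalar(n_case, "n_case", lower = 1)
  check_scalar(n_control, "n_control", lower = 1)
  eff <- if (inherits(effects, "locus_effects")) effects$effects else effects
  with_seed(seed, {
    K <- disease$prevalence
    if (nrow(eff) == 0L) {
      # null locus: risk is constant, so status is independent of genotype
      # and quota rejection sampling reduces to drawing the quotas directly
      n_tot <- as.integer(n_case + n_control)
      haps <- mosaic_block(panel, 2L * n_tot, rho, theta)
      geno <- haps[seq_len(n_tot) * 2L - 1L, , drop = FALSE] +
              haps[seq_len(n_tot) * 2L, , drop = FALSE]
      phenotype <- rep(c(1L, 0L), c(n_case, n_control))
      return(new_cohort(geno, phenotype, panel$sites$position,
                        panel$sites$exonic, rep(FALSE, ncol(geno)),
                        panel$region_length_bp))
    }
    budget <- ceiling(max_draw_factor * (n_case + n_control) / K)
    drawn <- 0L
    case_rows <- list(); ctrl_rows <- list()
    n_cases_have <- 0L; n_ctrls_have <- 0L
    while (n_cases_have < n_case || n_ctrls_have < n_control) {
      if (drawn >= budget)
        abort_param("cohort sampling exhausted its draw budget before filling quotas")
      need_cases <- n_case - n_cases_have
      need_ctrls <- n_control - n_ctrls_have
      # expected draws to finish, padded; capped for memory
      B <- min(20000L, max(200L, ceiling(1.3 * max(need_cases / K,
                                                   need_ctrls / (1 - K)))))
      B <- min(B, budget - drawn)
      drawn <- drawn + B
      haps <- mosaic_block(panel, 2L * B, rho, theta)
      geno <- haps[seq_len(B) * 2L - 1L, , drop = FALSE] +
              haps[seq_len(B) * 2L, , drop = FALSE]
      risk <- individual_risk(geno[, eff$site + 1L, drop = FALSE],
                              effects, disease)
      is_case <- runif(B) < risk
      if (n_cases_have < n_case && any(is_case)) {
        take <- utils::head(which(is_case), n_case - n_cases_have)
        case_rows[[length(case_rows) + 1L]] <- geno[take, , drop = FALSE]
        n_cases_have <- n_cases_have + length(take)
      }
      if (n_ctrls_have < n_control && any(!is_case)) {
        take <- utils::head(which(!is_case), n_control - n_ctrls_have)
        ctrl_rows[[length(ctrl_rows) + 1L]] <- geno[take, , drop = FALSE]
        n_ctrls_have <- n_ctrls_have + length(take)
      }
    }
    geno <- rbind(do.call(rbind, case_rows), do.call(rbind, ctrl_rows))
    phenotype <- rep(c(1L, 0L), c(n_case, n_control))
    causal <- seq_len(ncol(geno)) %in% (eff$site + 1L)
    new_cohort(geno, phenotype, panel$sites$position, panel$sites$exonic,
               causal, panel$region_length_bp)
  })
}

#' Dilute neutral variation to a fixed causal fraction
#'
#' Retains all causal sites and removes non-causal rare (MAF < `maf_threshold`)
#' sites uniformly at random so that the causal:total ratio among retained
#' rare sites equals `fraction` as closely as an integer count allows.
#' Sites at or above the MAF threshold are untouched. When too few neutral
#' rare sites exist to reach the requested ratio the achieved ratio is
#' reported in a warning rather than an error.
#'
#' @param dataset a `cohort`.
#' @param fraction requested causal fraction among tested rare sites, in
#'   (0, 1]; the study grid uses 0.25, 0.5, 0.75, 1.
#' @param maf_threshold rare-variant MAF threshold (default 0.01).
#' @param seed integer seed.
#' @return A `cohort` with neutral rare sites removed.
#' @export
causal_fraction_filter <- function(dataset, fraction, maf_threshold = 0.01,
                                   seed = NULL) {
  check_scalar(fraction, "fraction", lower = 0, upper = 1, strict_lower = TRUE)
  s <- dataset$sites
  if (!any(s$causal))
    abort_param("`dataset` carries no causal mask to filter on")
  rare <- s$maf < maf_threshold
  n_causal <- sum(rare & s$causal)
  neutral_idx <- which(rare & !s$causal)
  n_keep_neutral <- max(0L, round(n_causal / fraction) - n_causal)
  if (n_keep_neutral > length(neutral_idx)) {
    achieved <- n_causal / (n_causal + length(neutral_idx))
    warning(sprintf(
      "only %d neutral rare sites available; achieved causal fraction %.3f",
      length(neutral_idx), achieved), call. = FALSE)
    n_keep_neutral <- length(neutral_idx)
  }
  drop_idx <- with_seed(seed, {
    keep_neutral <- if (n_keep_neutral > 0L)
      sample(neutral_idx, n_keep_neutral) else integer(0)
    setdiff(neutral_idx, keep_neutral)
  })
  keep <- setdiff(seq_len(nrow(s)), drop_idx)
  new_cohort(dataset$genotypes[, keep, drop = FALSE], dataset$phenotype,
             s$position[keep], s$exonic[keep], s$causal[keep],
             dataset$region_length_bp)
}
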