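# Burden-family gene-based tests: collapsing, weighted-sum, and summary
# count methods. All operate on the rare-variant minor-dosage matrix after
# the strict MAF filter, and all permutation p-values exchange case/control
# labels via the shared engine in assoc-core.R.

#' Combined multivariate and collapsing (CMC) test
#'
#' Collapses all rare variants into one indicator (carrier of at least one
#' rare minor allele) and tests it against phenotype by a likelihood-ratio
#' test of logistic regression. A degenerate indicator (all carriers or
#' none) returns p = 1 by convention.
#'
#' @param dataset a `cohort`.
#' @param spec a [test_spec()].
#' @param seed unused (the test is deterministic); kept for interface
#'   uniformity.
#' @return One-row result tibble.
#' @export
test_cmc <- function(dataset, spec = test_spec(), seed = NULL) {
  rm_ <- rare_matrix(dataset, spec)
  carrier <- as.integer(rowSums(rm_$G) > 0L)
  y <- dataset$phenotype
  if (all(carrier == carrier[1]))
    return(result_row("cmc", 1, 0, length(rm_$idx), "degenerate"))
  fit <- glm(y ~ carrier, family = binomial())
  lrt <- fit$null.deviance - fit$deviance
  result_row("cmc", pchisq(lrt, 1, lower.tail = FALSE), lrt,
             length(rm_$idx), "asymptotic")
}

#' Permutation burden test (raw allele counts)
#'
#' Statistic: total rare minor-allele count in cases; one-sided phenotype
#' permutation p-value.
#'
#' @inheritParams test_cmc
#' @param seed permutation seed.
#' @return One-row result tibble.
#' @export
test_burden <- function(dataset, spec = test_spec(), seed = NULL) {
  rm_ <- rare_matrix(dataset, spec)
  s <- rowSums(rm_$G)
  pr <- perm_pvalue(length(s), which(dataset$phenotype == 1L),
                    function(cm) .colSums(s[cm], nrow(cm), ncol(cm)),
                    spec, seed)
  result_row("burden", pr$p, pr$obs, length(rm_$idx), pr$method, pr$n_perms)
}

#' Case-unique allele count (UNIQ) test
#'
#' Statistic: number of minor-allele observations at sites whose minor
#' alleles occur in cases only; one-sided permutation p-value.
#'
#' @inheritParams test_burden
#' @return One-row result tibble.
#' @export
test_uniq <- function(dataset, spec = test_spec(), seed = NULL) {
  rm_ <- rare_matrix(dataset, spec)
  G <- rm_$G
  tot <- colSums(G)
  n <- nrow(G)
  stat_fn <- function(cm) {
    C <- crossprod(G, case_indicator(n, cm))
    colSums(C * (C == tot))
  }
  pr <- perm_pvalue(n, which(dataset$phenotype == 1L), stat_fn, spec, seed)
  result_row("uniq", pr$p, pr$obs, length(rm_$idx), pr$method, pr$n_perms)
}

# Control-estimated inverse-frequency weights (with add-one smoothing).
madsen_browning_weights <- function(ctrl_counts, n_control, n_total) {
  q <- (ctrl_counts + 1) / (2 * n_control + 2)
  1 / sqrt(n_total * q * (1 - q))
}

#' Inverse-frequency weighted count (FRQWGT) test
#'
#' Per-individual score is the sum of minor-allele dosages weighted by
#' `1/sqrt(n q (1-q))` with `q` estimated from controls; the statistic is
#' the summed case score. Weights are re-estimated inside every
#' permutation (the label exchange moves individuals between the case and
#' control weight-estimation pools).
#'
#' @inheritParams test_burden
#' @return One-row result tibble.
#' @export
test_frqwgt <- function(dataset, spec = test_spec(), seed = NULL) {
  rm_ <- rare_matrix(dataset, spec)
  G <- rm_$G
  tot <- colSums(G)
  n <- nrow(G)
  n_control <- sum(dataset$phenotype == 0L)
  stat_fn <- function(cm) {
    C <- crossprod(G, case_indicator(n, cm))
    W <- madsen_browning_weights(tot - C, n_control, n)
    colSums(W * C)
  }
  pr <- perm_pvalue(n, which(dataset$phenotype == 1L), stat_fn, spec, seed)
  result_row("frqwgt", pr$p, pr$obs, length(rm_$idx), pr$method, pr$n_perms)
}

#' Wilcoxon weighted-sum (WILCOX-WSS) test
#'
#' Ranks the control-weighted per-individual scores and compares cases to
#' controls by a one-sided rank-sum test with normal approximation and tie
#' correction. Identical scores everywhere return p = 1.
#'
#' @inheritParams test_cmc
#' @return One-row result tibble.
#' @export
test_wss <- function(dataset, spec = test_spec(), seed = NULL) {
  rm_ <- rare_matrix(dataset, spec)
  G <- rm_$G
  y <- dataset$phenotype
  ctrl_counts <- colSums(G[y == 0L, , drop = FALSE])
  w <- madsen_browning_weights(ctrl_counts, sum(y == 0L), nrow(G))
  s <- as.vector(G %*% w)
  if (stats::var(s) == 0)
    return(result_row("wss", 1, 0, length(rm_$idx), "degenerate"))
  wt <- suppressWarnings(
    wilcox.test(s[y == 1L], s[y == 0L], alternative = "greater",
                exact = FALSE, correct = TRUE))
  result_row("wss", wt$p.value, unname(wt$statistic), length(rm_$idx),
             "asymptotic")
}

#' Variable-threshold (VT) burden test
#'
#' Computes a z-like burden statistic at every distinct observed MAF value
#' at or below the filter threshold and maximises over thresholds; the
#' permutation p-value of the maximum re-scans all thresholds in every
#' permutation.
#'
#' @inheritParams test_burden
#' @return One-row result tibble (diagnostics records the selected
#'   threshold).
#' @export
test_vt <- function(dataset, spec = test_spec(), seed = NULL) {
  rm_ <- rare_matrix(dataset, spec)
  G <- rm_$G
  n <- nrow(G)
  maf <- dataset$sites$maf[rm_$idx]
  ord <- order(maf)
  thr_maf <- maf[ord]
  ends <- which(!duplicated(thr_maf, fromLast = TRUE)) # last site per distinct MAF
  tot <- colSums(G)[ord]
  p0 <- sum(dataset$phenotype == 1L) / n
  den <- sqrt(cumsum(colSums(G^2)[ord])[ends] * p0 * (1 - p0))
  stat_fn <- function(cm) {
    C <- crossprod(G, case_indicator(n, cm))[ord, , drop = FALSE]
    num <- apply(C - p0 * tot, 2, cumsum)
    if (is.null(dim(num))) num <- matrix(num, ncol = ncol(C))
    z <- num[ends, , drop = FALSE] / den
    do.call(pmax, c(asplit(z, 1), list(na.rm = TRUE)))
  }
  pr <- perm_pvalue(n, which(dataset$phenotype == 1L), stat_fn, spec, seed)
  # recover the selected threshold from the observed scan
  Cobs <- crossprod(G, matrix(dataset$phenotype, ncol = 1))[ord, 1]
  zobs <- cumsum(Cobs - p0 * tot)[ends] / den
  sel <- thr_maf[ends][which.max(zobs)]
  result_row("vt", pr$p, pr$obs, length(rm_$idx), pr$method, pr$n_perms,
             diagnostics = sprintf("selected_maf_threshold=%g", sel))
}

#' Kernel-based adaptive cluster (KBAC) test
#'
#' Groups individuals by their multi-site rare-genotype pattern, weights
#' each non-null pattern by the hypergeometric-tail probability of its
#' observed case enrichment, and sums the weighted case counts; one-sided
#' permutation p-value with weights re-derived per permutation.
#'
#' @inheritParams test_burden
#' @return One-row result tibble.
#' @export
test_kbac <- function(dataset, spec = test_spec(), seed = NULL) {
  rm_ <- rare_matrix(dataset, spec)
  G <- rm_$G
  n <- nrow(G)
  key <- apply(G, 1, paste, collapse = "\r")
  null_key <- paste(rep("0", ncol(G)), collapse = "\r")
  carrier <- key != null_key
  pat <- factor(key[carrier])
  if (!nlevels(pat))
    return(result_row("kbac", 1, 0, length(rm_$idx), "degenerate"))
  Mpat <- matrix(0L, n, nlevels(pat))
  Mpat[cbind(which(carrier), as.integer(pat))] <- 1L
  n_i <- colSums(Mpat)
  n_case <- sum(dataset$phenotype == 1L)
  stat_fn <- function(cm) {
    Cp <- crossprod(Mpat, case_indicator(n, cm)) # pattern case counts
    W <- phyper(Cp, n_case, n - n_case, n_i)
    colSums(W * Cp)
  }
  pr <- perm_pvalue(n, which(dataset$phenotype == 1L), stat_fn, spec, seed)
  result_row("kbac", pr$p, pr$obs, length(rm_$idx), pr$method, pr$n_perms,
             diagnostics = sprintf("n_patterns=%d", nlevels(pat)))
}

#' C-alpha dispersion test
#'
#' Per-site statistic `(y_i - n_i p0)^2 - n_i p0 (1 - p0)` (observed case
#' minor-allele count against its binomial expectation under the case
#' fraction p0), summed over sites; sensitive to bidirectional skews.
#' One-sided permutation p-value of the sum.
#'
#' @inheritParams test_burden
#' @return One-row result tibble.
#' @export
test_calpha <- function(dataset, spec = test_spec(), seed = NULL) {
  rm_ <- rare_matrix(dataset, spec)
  G <- rm_$G
  n <- nrow(G)
  tot <- colSums(G)
  p0 <- sum(dataset$phenotype == 1L) / n
  stat_fn <- function(cm) {
    C <- crossprod(G, case_indicator(n, cm))
    colSums((C - tot * p0)^2 - tot * p0 * (1 - p0))
  }
  pr <- perm_pvalue(n, which(dataset$phenotype == 1L), stat_fn, spec, seed)
  result_row("calpha", pr$p, pr$obs, length(rm_$idx), pr$method, pr$n_perms)
}

#' Single-variant Fisher's exact test
#'
#' Two-sided Fisher's exact test on the 2x2 minor/major allele-count table
#' at every site (no MAF threshold), summarised per locus as the minimum
#' p-value. Per-site results are available via [single_variant_fisher()].
#'
#' @inheritParams test_cmc
#' @return One-row result tibble (diagnostics records the top site's MAF).
#' @export
test_fisher <- function(dataset, spec = test_spec(), seed = NULL) {
  per <- single_variant_fisher(dataset)
  top <- which.min(per$p_value)
  result_row("fisher", per$p_value[top], NA_real_, nrow(per), "exact",
             diagnostics = sprintf("top_site_maf=%g", per$maf[top]))
}

#' @rdname test_fisher
#' @param dataset a `cohort`.
#' @return For `single_variant_fisher`: tibble with one row per site
#'   (`index`, `position`, `maf`, `p_value`).
#' @export
single_variant_fisher <- function(dataset) {
  s <- dataset$sites
  n_case <- dataset$n_case
  n_control <- dataset$n_control
  p <- vapply(seq_len(nrow(s)), function(i) {
    tab <- matrix(c(s$case_minor_count[i], 2L * n_case - s$case_minor_count[i],
                    s$control_minor_count[i],
                    2L * n_control - s$control_minor_count[i]), 2)
    fisher.test(tab)$p.value
  }, numeric(1))
  tibble::tibble(index = s$index, position = s$position, maf = s$maf,
                 p_value = p)
}
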