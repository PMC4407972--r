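#' Estimate power from replicate test results
#'
#' Power is the fraction of simulation replicates in which a test reported
#' a p-value strictly below the significance threshold (ties at alpha
#' count as non-detections). Results are grouped by every design column
#' present (`gene`, `test`, `architecture`, `ve`, `n`, `maf_threshold`)
#' and an exact binomial confidence interval accompanies each estimate.
#'
#' @param results tibble with a `p_value` column, one row per
#'   (replicate, test); any of the design columns present are used as
#'   grouping keys.
#' @param alpha significance threshold(s); one output row per group x
#'   alpha.
#' @param conf_level confidence level of the exact binomial interval.
#' @return A `power_table` tibble: grouping keys, `alpha`, `n_replicates`,
#'   `n_detected`, `power`, `conf_low`, `conf_high`.
#' @export
estimate_power <- function(results, alpha = 0.05, conf_level = 0.95) {
  if (!"p_value" %in% names(results)) abort_param("`results` needs a p_value column")
  keys <- intersect(c("gene", "test", "architecture", "ve", "n",
                      "maf_threshold"), names(results))
  out <- purrr::map_dfr(alpha, function(a) {
    results |>
      dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
      dplyr::summarise(
        alpha = a,
        n_replicates = sum(!is.na(.data$p_value)),
        n_detected = sum(.data$p_value < a, na.rm = TRUE),
        .groups = "drop")
  })
  ci <- purrr::map2(out$n_detected, out$n_replicates, function(x, n) {
    if (n == 0) return(c(NA_real_, NA_real_))
    binom.test(x, n, conf.level = conf_level)$conf.int
  })
  out$power <- ifelse(out$n_replicates > 0,
                      out$n_detected / out$n_replicates, NA_real_)
  out$conf_low <- vapply(ci, `[`, numeric(1), 1)
  out$conf_high <- vapply(ci, `[`, numeric(1), 2)
  class(out) <- c("power_table", class(out))
  out
}

#' @exportS3Method ggplot2::autoplot
autoplot.power_table <- function(object, ...) {
  gg <- ggplot2::ggplot(object,
    ggplot2::aes(x = stats::reorder(.data$test, .data$power),
                 y = .data$power)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$conf_low,
                                        ymax = .data$conf_high),
                           width = 0.25) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "power") +
    ggplot2::theme_minimal()
  if ("alpha" %in% names(object) && length(unique(object$alpha)) > 1)
    gg <- gg + ggplot2::facet_wrap(~alpha, labeller = ggplot2::label_both)
  gg
}

#' Empirical false-positive-rate corrected thresholds
#'
#' Returns, per test, the largest p-value cutoff whose empirical
#' exceedance under the null is at most `target_fpr` (a sort-based
#' empirical quantile of the null p-values). Conservative tests receive a
#' threshold above the nominal level; anti-conservative tests below it.
#'
#' @param null_results tibble of null-replicate results with `test` and
#'   `p_value` columns (or a bare numeric vector of null p-values).
#' @param target_fpr desired false-positive rate.
#' @return Tibble with `test`, `threshold`, `n_null`; or a scalar
#'   threshold when given a vector.
#' @export
fpr_corrected_threshold <- function(null_results, target_fpr = 1e-4) {
  check_scalar(target_fpr, "target_fpr", lower = 0, upper = 1,
               strict_lower = TRUE)
  thr_one <- function(p) {
    p <- p[!is.na(p)]
    if (length(p) < 1 / target_fpr)
      abort_param(sprintf(
        "%d null replicates cannot resolve a false-positive rate of %g",
        length(p), target_fpr))
    k <- floor(target_fpr * length(p))
    sorted <- sort(p)
    if (k + 1 > length(sorted)) 1 else sorted[k + 1]
  }
  if (is.numeric(null_results)) return(thr_one(null_results))
  null_results |>
    dplyr::group_by(.data$test) |>
    dplyr::summarise(threshold = thr_one(.data$p_value),
                     n_null = sum(!is.na(.data$p_value)), .groups = "drop")
}

#' Concordance between two tests' p-values
#'
#' Squared Pearson correlation of -log10 p over shared loci, excluding
#' loci where either test reports p above `p_max` (weak signals carry no
#' ranking information).
#'
#' @param p_a,p_b aligned numeric vectors of p-values (same loci, same
#'   order).
#' @param p_max inclusion cutoff (default 0.1).
#' @return Tibble with `r_squared`, `n_pairs`, `reason` (`NA` when
#'   defined; fewer than 3 qualifying pairs leave `r_squared` `NA`).
#' @export
concordance <- function(p_a, p_b, p_max = 0.1) {
  if (length(p_a) != length(p_b))
    abort_param("`p_a` and `p_b` must be aligned vectors of equal length")
  ok <- !is.na(p_a) & !is.na(p_b) & p_a <= p_max & p_b <= p_max
  if (sum(ok) < 3)
    return(tibble::tibble(r_squared = NA_real_, n_pairs = sum(ok),
                          reason = "fewer than 3 loci with both p <= p_max"))
  r <- cor(-log10(p_a[ok]), -log10(p_b[ok]))
  tibble::tibble(r_squared = r^2, n_pairs = sum(ok), reason = NA_character_)
}

#' Pairwise concordance matrix across a battery of tests
#'
#' @param results long tibble with `locus`, `test`, `p_value` (a locus is
#'   one gene x replicate).
#' @param p_max inclusion cutoff, as in [concordance()].
#' @return A `concordance_matrix` tibble: `test_a`, `test_b`,
#'   `r_squared`, `n_pairs`.
#' @export
concordance_matrix <- function(results, p_max = 0.1) {
  wide <- tidyr::pivot_wider(results[, c("locus", "test", "p_value")],
                             names_from = "test", values_from = "p_value")
  tests <- setdiff(names(wide), "locus")
  grid <- expand.grid(test_a = tests, test_b = tests,
                      stringsAsFactors = FALSE)
  out <- purrr::pmap_dfr(grid, function(test_a, test_b) {
    cc <- concordance(wide[[test_a]], wide[[test_b]], p_max)
    tibble::tibble(test_a = test_a, test_b = test_b,
                   r_squared = cc$r_squared, n_pairs = cc$n_pairs)
  })
  class(out) <- c("concordance_matrix", class(out))
  out
}

#' @exportS3Method ggplot2::autoplot
autoplot.concordance_matrix <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$test_a, y = .data$test_b,
                                       fill = .data$r_squared)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = ifelse(is.na(.data$r_squared), "",
                     sprintf("%.2f", .data$r_squared))), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick",
                                 limits = c(0, 1), na.value = "grey90") +
    ggplot2::labs(x = NULL, y = NULL, fill = expression(R^2)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 35, hjust = 1))
}

#' Combined gene-based and single-variant detection
#'
#' Classifies each locus as detected by the single-variant test only, the
#' gene-based test only, both, or neither, at the two thresholds
#' (defaults: exome-wide 2.5e-6 for gene-based, genome-wide 5e-8 for
#' single-variant), and reports the union power and the gene-only
#' increment.
#'
#' @param gene_results tibble with `locus` and `p_value` for the
#'   gene-based test.
#' @param sv_results tibble with `locus` and `p_value` for single-variant
#'   association (locus-minimum p).
#' @param alpha_gene,alpha_sv detection thresholds.
#' @return List with `by_locus` (tibble: locus, detected_gene,
#'   detected_sv, class) and `summary` (one-row tibble: power_sv,
#'   power_gene, power_union, gene_only_increment).
#' @export
combined_power <- function(gene_results, sv_results,
                           alpha_gene = 2.5e-6, alpha_sv = 5e-8) {
  j <- dplyr::inner_join(
    dplyr::rename(gene_results[, c("locus", "p_value")], p_gene = "p_value"),
    dplyr::rename(sv_results[, c("locus", "p_value")], p_sv = "p_value"),
    by = "locus")
  by_locus <- j |>
    dplyr::mutate(
      detected_gene = .data$p_gene < alpha_gene,
      detected_sv = .data$p_sv < alpha_sv,
      class = dplyr::case_when(
        .data$detected_gene & .data$detected_sv ~ "both",
        .data$detected_gene ~ "gene-only",
        .data$detected_sv ~ "sv-only",
        TRUE ~ "neither"))
  summary <- tibble::tibble(
    power_sv = mean(by_locus$detected_sv),
    power_gene = mean(by_locus$detected_gene),
    power_union = mean(by_locus$detected_gene | by_locus$detected_sv),
    gene_only_increment = mean(by_locus$class == "gene-only"))
  list(by_locus = by_locus, summary = summary)
}

#' Greedy forward selection of a composite test
#'
#' Starting from one test, repeatedly adds the candidate reporting the
#' greatest number of novel signals: loci where the candidate's p-value is
#' below `alpha` and smaller than the best already-included p-value by the
#' multiplicative `margin`. Selection stops when no candidate contributes
#' a novel signal. The composite's per-locus p-value is the minimum over
#' members; unadjusted sensitivity applies `alpha` to that minimum, and,
#' when null results are supplied, an FPR-adjusted sensitivity applies the
#' empirical null quantile of the composite minimum instead.
#'
#' @param results long tibble with `locus`, `test`, `p_value` over causal
#'   loci.
#' @param start starting test name (the study design starts from each of
#'   the three strongest performers: mist, skato, kbac).
#' @param margin multiplicative novelty margin (100, 10, or 1).
#' @param alpha significance threshold for counting signals.
#' @param null_results optional long tibble of the same shape over null
#'   loci, used for the FPR adjustment.
#' @param target_fpr false-positive rate for the adjusted threshold
#'   (defaults to `alpha`).
#' @return A `composite_test` list: `tests` (in selection order),
#'   `margin`, `alpha`, `sensitivity`, `adjusted_threshold`,
#'   `adjusted_sensitivity`, `trace` (tibble of selection steps).
#' @export
forward_select_composite <- function(results, start, margin = 10,
                                     alpha = 1e-4, null_results = NULL,
                                     target_fpr = alpha) {
  check_scalar(margin, "margin", lower = 1)
  wide <- tidyr::pivot_wider(results[, c("locus", "test", "p_value")],
                             names_from = "test", values_from = "p_value")
  tests <- setdiff(names(wide), "locus")
  if (!start %in% tests)
    abort_param(sprintf("unknown start test '%s'", start))
  included <- start
  min_p <- wide[[start]]
  trace <- list(tibble::tibble(step = 1L, test = start, novel = NA_integer_))
  repeat {
    candidates <- setdiff(tests, included)
    if (!length(candidates)) break
    novel <- vapply(candidates, function(t)
      sum(wide[[t]] < alpha & wide[[t]] * margin < min_p, na.rm = TRUE),
      integer(1))
    if (max(novel) < 1L) break
    pick <- candidates[which.max(novel)]
    included <- c(included, pick)
    min_p <- pmin(min_p, wide[[pick]], na.rm = TRUE)
    trace[[length(trace) + 1L]] <-
      tibble::tibble(step = length(included), test = pick,
                     novel = max(novel))
  }
  sens <- mean(min_p < alpha, na.rm = TRUE)
  adj_thr <- NA_real_
  adj_sens <- NA_real_
  if (!is.null(null_results)) {
    null_wide <- tidyr::pivot_wider(
      null_results[, c("locus", "test", "p_value")],
      names_from = "test", values_from = "p_value")
    null_min <- do.call(pmin, c(unname(null_wide[included]),
                                list(na.rm = TRUE)))
    adj_thr <- fpr_corrected_threshold(as.numeric(null_min), target_fpr)
    adj_sens <- mean(min_p < adj_thr, na.rm = TRUE)
  }
  structure(list(tests = included, margin = margin, alpha = alpha,
                 sensitivity = sens, adjusted_threshold = adj_thr,
                 adjusted_sensitivity = adj_sens,
                 trace = dplyr::bind_rows(trace)),
            class = "composite_test")
}

#' @export
print.composite_test <- function(x, ...) {
  cat(sprintf(
    "<composite_test> %s (margin %g)\n  sensitivity %.3f at alpha %g; FPR-adjusted %.3f\n",
    paste(x$tests, collapse = " + "), x$margin, x$sensitivity, x$alpha,
    x$adjusted_sensitivity))
  invisible(x)
}

#' @exportS3Method generics::glance
glance.composite_test <- function(x, ...) {
  tibble::tibble(tests = paste(x$tests, collapse = "+"),
                 n_tests = length(x$tests), margin = x$margin,
                 alpha = x$alpha, sensitivity = x$sensitivity,
                 adjusted_threshold = x$adjusted_threshold,
                 adjusted_sensitivity = x$adjusted_sensitivity)
}

#' Properties of loci where two tests disagree
#'
#' For loci where one test reports p below `p_cut` and the other does not,
#' summarises the locus characteristics that drive such discordance: the
#' aggregate case:control minor-allele ratio over rare sites, the number
#' of case-unique minor-allele observations, and the top single-variant
#' p-value.
#'
#' @param results_a,results_b tibbles with `locus` and `p_value`, aligned
#'   with `datasets`.
#' @param datasets named list of `cohort` objects keyed by locus.
#' @param p_cut discordance cutoff (default 0.01).
#' @param maf_threshold rare-site threshold for the summaries.
#' @return Tibble with one row per discordant locus: `locus`,
#'   `only` (`"a"` or `"b"`), `case_control_ratio`, `case_unique_count`,
#'   `top_sv_p`.
#' @export
discordance_profile <- function(results_a, results_b, datasets,
                                p_cut = 0.01, maf_threshold = 0.01) {
  j <- dplyr::inner_join(
    dplyr::rename(results_a[, c("locus", "p_value")], p_a = "p_value"),
    dplyr::rename(results_b[, c("locus", "p_value")], p_b = "p_value"),
    by = "locus")
  j <- dplyr::filter(j, xor(.data$p_a < p_cut, .data$p_b < p_cut))
  if (!nrow(j))
    return(tibble::tibble(locus = character(0), only = character(0),
                          case_control_ratio = numeric(0),
                          case_unique_count = integer(0),
                          top_sv_p = numeric(0)))
  purrr::pmap_dfr(j, function(locus, p_a, p_b) {
    d <- datasets[[as.character(locus)]]
    s <- d$sites[d$sites$maf < maf_threshold, , drop = FALSE]
    tibble::tibble(
      locus = as.character(locus),
      only = if (p_a < p_cut) "a" else "b",
      case_control_ratio = sum(s$case_minor_count) /
        max(1L, sum(s$control_minor_count)),
      case_unique_count = sum(s$case_minor_count[s$control_minor_count == 0L]),
      top_sv_p = min(single_variant_fisher(d)$p_value))
  })
}
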