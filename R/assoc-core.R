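#' Test specification for the gene-based battery
#'
#' @param maf_threshold strict upper MAF bound for variant inclusion;
#'   sample MAF is computed from the combined case + control sample and a
#'   site at exactly the threshold is excluded (default 0.01; the study
#'   grid also uses 0.005 and 0.05).
#' @param n_permutations starting number of phenotype permutations for
#'   permutation-based tests (minimum 100).
#' @param perm_max adaptive ceiling: permutations escalate tenfold, up to
#'   this cap, while the p-value estimate remains near the resolution
#'   floor.
#' @param exhaustive_limit when `choose(n, n_case)` is at most this, the
#'   permutation null is enumerated exactly over all case/control label
#'   assignments instead of sampled.
#' @param weights_beta shape parameters of the Beta-density MAF weights
#'   used by SKAT-family tests (default c(1, 25)); set to c(1, 1) for flat
#'   weights.
#' @param rho_grid SKAT-O mixing grid between the variance-component
#'   (rho = 0) and burden (rho = 1) kernels.
#' @return A `test_spec` list.
#' @export
test_spec <- function(maf_threshold = 0.01, n_permutations = 1000,
                      perm_max = 1e6, exhaustive_limit = 50000,
                      weights_beta = c(1, 25),
                      rho_grid = c(0, 0.1^2, 0.2^2, 0.3^2, 0.4^2, 0.5^2, 1)) {
  check_scalar(maf_threshold, "maf_threshold", lower = 0, upper = 0.5,
               strict_lower = TRUE)
  check_scalar(n_permutations, "n_permutations", lower = 100)
  check_scalar(perm_max, "perm_max", lower = 100)
  structure(list(maf_threshold = maf_threshold,
                 n_permutations = as.integer(min(n_permutations, perm_max)),
                 perm_max = perm_max,
                 exhaustive_limit = exhaustive_limit,
                 weights_beta = weights_beta, rho_grid = rho_grid),
            class = "test_spec")
}

condition_no_variants <- function() {
  structure(class = c("no_qualifying_variants", "error", "condition"),
            list(message = "no variant passes the MAF filter",
                 call = NULL))
}

#' Rare-variant MAF filter
#'
#' Retains sites with sample MAF strictly below the threshold, computed
#' from the full case + control sample.
#'
#' @param dataset a `cohort`.
#' @param threshold strict MAF upper bound.
#' @return Integer vector of retained site indices (columns of the
#'   genotype matrix); may be empty.
#' @export
maf_filter <- function(dataset, threshold = 0.01) {
  which(dataset$sites$maf < threshold)
}

# Minor-allele dosage matrix of the given sites (alt dosage recoded so the
# counted allele is the sample minor allele).
minor_dosages <- function(dataset, sites_idx = seq_len(ncol(dataset$genotypes))) {
  G <- dataset$genotypes[, sites_idx, drop = FALSE]
  flip <- !dataset$sites$minor_is_alt[sites_idx]
  if (any(flip)) G[, flip] <- 2L - G[, flip, drop = FALSE]
  G
}

# Rare-variant minor-dosage matrix after the MAF filter; signals a
# no_qualifying_variants condition when empty.
rare_matrix <- function(dataset, spec) {
  idx <- maf_filter(dataset, spec$maf_threshold)
  if (!length(idx)) stop(condition_no_variants())
  list(G = minor_dosages(dataset, idx), idx = idx)
}

# One tidy result row shared by every test.
result_row <- function(test, p_value, statistic, n_variants, method,
                       n_perms = NA_real_, diagnostics = NA_character_) {
  tibble::tibble(test = test, p_value = p_value, statistic = statistic,
                 n_variants_tested = as.integer(n_variants), method = method,
                 n_perms = n_perms, diagnostics = diagnostics)
}

# Phenotype-permutation engine. `stat_fn(case_idx_matrix)` must return one
# statistic per column of a (n_case x B) matrix of case row indices; large
# statistics are extreme. Enumerates all label assignments exactly when
# feasible, otherwise samples with tenfold adaptive escalation and the
# add-one (Phipson-Smyth) correction, which keeps p-values valid
# (super-uniform) under the null.
perm_pvalue <- function(n, case_idx, stat_fn, spec, seed = NULL,
                        batch = 2000L) {
  stat_fn_raw <- stat_fn
  stat_fn <- function(cm) as.numeric(stat_fn_raw(cm))
  obs <- stat_fn(matrix(case_idx, ncol = 1))
  n_case <- length(case_idx)
  tol <- 1e-9 * (1 + abs(obs))
  if (choose(n, n_case) <= spec$exhaustive_limit) {
    combos <- combn(n, n_case)
    stats <- numeric(ncol(combos))
    for (b in seq(1, ncol(combos), by = batch)) {
      j <- b:min(b + batch - 1L, ncol(combos))
      stats[j] <- stat_fn(combos[, j, drop = FALSE])
    }
    return(list(p = mean(stats >= obs - tol), obs = obs,
                n_perms = ncol(combos), method = "exhaustive"))
  }
  with_seed(seed, {
    B_total <- 0L
    exceed <- 0L
    B_next <- spec$n_permutations
    repeat {
      draws <- B_next - B_total
      for (b in seq(1, draws, by = batch)) {
        nb <- min(batch, draws - b + 1L)
        cm <- vapply(seq_len(nb), function(i) sample.int(n, n_case),
                     integer(n_case))
        exceed <- exceed + sum(stat_fn(cm) >= obs - tol)
      }
      B_total <- B_next
      p <- (exceed + 1) / (B_total + 1)
      if (exceed >= 10L || B_total >= spec$perm_max) break
      B_next <- min(B_total * 10L, spec$perm_max)
    }
    list(p = p, obs = obs, n_perms = B_total, method = "permutation")
  })
}

# 0/1 case-indicator matrix (n x B) from a case-index matrix.
case_indicator <- function(n, case_idx_matrix) {
  B <- ncol(case_idx_matrix)
  Z <- matrix(0L, n, B)
  Z[cbind(as.vector(case_idx_matrix), rep(seq_len(B), each = nrow(case_idx_matrix)))] <- 1L
  Z
}

#' Run the full association-test battery on one dataset
#'
#' Applies all requested tests to the identically filtered dataset and
#' returns one tidy row per test. Permutation streams are independently
#' seeded per test (derived from `seed`), so single-test calls with the
#' matching derived seed reproduce the battery rows exactly. A test that
#' errors (e.g. no variant passes its filter) yields a row with `NA`
#' p-value and the reason in `diagnostics`.
#'
#' @param dataset a `cohort`.
#' @param tests character vector of test names among `"cmc"`, `"vt"`,
#'   `"frqwgt"`, `"wss"`, `"kbac"`, `"burden"`, `"uniq"`, `"calpha"`,
#'   `"skat"`, `"skato"`, `"mist"`, `"fisher"` (single-variant).
#' @param spec a [test_spec()].
#' @param seed integer master seed for the battery.
#' @return Tibble with one row per test (class `rv_battery`).
#' @export
run_test_battery <- function(dataset, tests = battery_tests(),
                             spec = test_spec(), seed = NULL) {
  tests <- match.arg(tests, battery_tests(), several.ok = TRUE)
  rows <- lapply(seq_along(tests), function(i) {
    fn <- get(paste0("test_", tests[i]), mode = "function")
    tryCatch(fn(dataset, spec, seed = split_seed(seed, i)),
             error = function(e) result_row(
               tests[i], NA_real_, NA_real_, NA_integer_, "failed",
               diagnostics = conditionMessage(e)))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("rv_battery", class(out))
  out
}

#' @rdname run_test_battery
#' @export
battery_tests <- function() {
  c("cmc", "vt", "frqwgt", "wss", "kbac", "burden", "uniq", "calpha",
    "skat", "skato", "mist", "fisher")
}

#' @exportS3Method ggplot2::autoplot
autoplot.rv_battery <- function(object, alpha = 0.05, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = stats::reorder(.data$test, -.data$p_value),
                               y = -log10(.data$p_value))) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = 2,
                        colour = "firebrick") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = expression(-log[10](p)),
                  title = "Gene-based test battery") +
    ggplot2::theme_minimal()
}
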