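#' Study configuration
#'
#' Bundles the full design grid of a simulation study: architecture,
#' locus effect size, sample sizes, prevalence, MAF threshold,
#' significance thresholds, number of gene loci, replicates per gene, and
#' the master seed from which all per-stage seeds are derived. Serialises
#' to YAML and round-trips identically.
#'
#' @param architecture architecture id (`"ar1"` ... `"ar6"`) or `"null"`
#'   for type-I-error runs.
#' @param target_ve locus variance explained (study grid: 0.005, 0.01,
#'   0.02).
#' @param n_case,n_control cohort quotas (grid: 1500/1500 or 5000/5000).
#' @param prevalence trait prevalence.
#' @param maf_threshold rare-variant threshold (grid: 0.005, 0.01, 0.05).
#' @param alphas significance thresholds reported in power tables.
#' @param n_genes gene loci simulated per run.
#' @param replicates phenotype-effect replicates per gene (the full study
#'   design uses 100; scaled-down runs report binomial intervals).
#' @param region_length_bp locus length.
#' @param tests battery subset to run.
#' @param perm_max adaptive permutation ceiling.
#' @param seed master seed.
#' @return A `study_config` list.
#' @export
study_config <- function(architecture = "ar2", target_ve = 0.01,
                         n_case = 1500, n_control = 1500,
                         prevalence = 0.08, maf_threshold = 0.01,
                         alphas = c(0.05, 1e-4, 2.5e-6, 5e-8),
                         n_genes = 1, replicates = 100,
                         region_length_bp = 1500,
                         tests = battery_tests(), perm_max = 1e4,
                         seed = 1) {
  cfg <- list(architecture = architecture, target_ve = target_ve,
              n_case = n_case, n_control = n_control,
              prevalence = prevalence, maf_threshold = maf_threshold,
              alphas = alphas, n_genes = n_genes, replicates = replicates,
              region_length_bp = region_length_bp, tests = tests,
              perm_max = perm_max, seed = seed)
  structure(cfg, class = "study_config")
}

#' @rdname study_config
#' @param path YAML file path.
#' @param config a `study_config`.
#' @export
write_study_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname study_config
#' @export
read_study_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(study_config, cfg)
}

config_hash <- function(config) rlang::hash(unclass(config))

#' Run a full simulation study
#'
#' Orchestrates the whole pipeline for one configuration: per gene locus,
#' an exome-calibrated reference panel is simulated; per replicate, causal
#' effects are drawn (unless the architecture is `"null"`), a case-control
#' cohort is sampled, and the requested test battery is run. Every result
#' row carries the gene, replicate, configuration hash, and seeds, so
#' identical configurations reproduce identical tables. Per-replicate
#' errors are recorded as failed rows and the run continues. With
#' `out_dir` set, per-gene TSVs are written and genes already on disk are
#' skipped, making long runs resumable.
#'
#' @param config a [study_config()].
#' @param out_dir optional directory for per-gene result TSVs.
#' @param progress print per-gene progress.
#' @return A `study_result` list: `results` (tibble: gene, replicate,
#'   test, p_value, ...), `power` (via [estimate_power()]), `config`,
#'   `config_hash`.
#' @export
run_study <- function(config, out_dir = NULL, progress = FALSE) {
  stopifnot(inherits(config, "study_config"))
  hash <- config_hash(config)
  disease <- disease_model(config$prevalence)
  arch <- if (identical(config$architecture, "null")) NULL
          else architecture_model(config$architecture)
  spec <- test_spec(maf_threshold = config$maf_threshold,
                    perm_max = config$perm_max)
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  gene_results <- vector("list", config$n_genes)
  for (g in seq_len(config$n_genes)) {
    gene_file <- if (!is.null(out_dir))
      file.path(out_dir, sprintf("gene%03d.tsv", g)) else NULL
    if (!is.null(gene_file) && file.exists(gene_file)) {
      gene_results[[g]] <- tibble::as_tibble(
        utils::read.table(gene_file, header = TRUE, sep = "\t"))
      next
    }
    gseed <- split_seed(config$seed, g)
    panel <- simulate_reference_panel(
      region_length_bp = config$region_length_bp, seed = gseed)
    reps <- vector("list", config$replicates)
    for (r in seq_len(config$replicates)) {
      rseed <- split_seed(gseed, r)
      row <- tryCatch({
        eff <- if (is.null(arch)) null_locus_effects() else
          sample_locus_effects(panel, arch, config$target_ve, disease,
                               seed = split_seed(rseed, 1))
        co <- sample_cohort(panel, eff, disease, config$n_case,
                            config$n_control, seed = split_seed(rseed, 2))
        res <- run_test_battery(co, config$tests, spec,
                                seed = split_seed(rseed, 3))
        dplyr::mutate(res, gene = g, replicate = r,
                      achieved_ve = if (is.null(arch)) 0 else eff$achieved_ve,
                      .before = 1)
      }, error = function(e)
        tibble::tibble(gene = g, replicate = r, achieved_ve = NA_real_,
                       test = NA_character_, p_value = NA_real_,
                       statistic = NA_real_, n_variants_tested = NA_integer_,
                       method = "failed", n_perms = NA_real_,
                       diagnostics = conditionMessage(e)))
      reps[[r]] <- row
    }
    gene_results[[g]] <- dplyr::bind_rows(reps) |>
      dplyr::mutate(architecture = config$architecture,
                    ve = config$target_ve,
                    n = config$n_case + config$n_control,
                    maf_threshold = config$maf_threshold,
                    config_hash = hash, seed = config$seed)
    if (!is.null(gene_file))
      write_results_tsv(gene_results[[g]], gene_file)
    if (progress)
      message(sprintf("gene %d/%d done", g, config$n_genes))
  }
  results <- dplyr::bind_rows(gene_results)
  structure(list(results = results,
                 power = estimate_power(results, config$alphas),
                 config = config, config_hash = hash),
            class = "study_result")
}

#' @export
print.study_result <- function(x, ...) {
  cat(sprintf("<study_result> %s: %d genes x %d replicates (hash %s)\n",
              x$config$architecture, x$config$n_genes,
              x$config$replicates, substr(x$config_hash, 1, 8)))
  print(x$power)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.study_result <- function(x, ...) x$results

#' @exportS3Method generics::glance
glance.study_result <- function(x, ...) {
  tibble::tibble(architecture = x$config$architecture,
                 ve = x$config$target_ve,
                 n = x$config$n_case + x$config$n_control,
                 n_genes = x$config$n_genes,
                 replicates = x$config$replicates,
                 config_hash = x$config_hash)
}
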