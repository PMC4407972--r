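# Readers and writers for the external formats: VCF 4.2 (phased panel GT,
# unphased cohort GT), IMPUTE2 .hap/.legend, phenotype TSV
# (PLINK-compatible FID/IID/status), frequency-RR map TSV, results TSV.
# Reading VCF goes through vcfR; the writers emit the small, fully
# specified subset of VCF these simulations need.

vcf_header <- function(contig, length_bp, phased) {
  c("##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", contig, length_bp),
    "##INFO=<ID=EXONIC,Number=0,Type=Flag,Description=\"Site is exonic\">",
    sprintf("##FORMAT=<ID=GT,Number=1,Type=String,Description=\"%s genotype\">",
            if (phased) "Phased" else "Unphased"))
}

#' Write and read phased haplotype panels as VCF
#'
#' Positions are written 1-based; internal coordinates are 0-based. Exonic
#' sites carry the `EXONIC` info flag. Genotypes are phased (`0|1`).
#'
#' @param panel a `hap_panel`.
#' @param path output / input file path (plain text).
#' @param contig contig name to write.
#' @return `write_panel_vcf` returns `path` invisibly; `read_panel_vcf`
#'   returns a `hap_panel` with provenance `"imported"`.
#' @export
write_panel_vcf <- function(panel, path, contig = "locus") {
  H <- panel$haplotypes
  n_ind <- n_individuals(panel)
  gt <- matrix(paste(H[seq_len(n_ind) * 2L - 1L, , drop = FALSE],
                     H[seq_len(n_ind) * 2L, , drop = FALSE], sep = "|"),
               nrow = n_ind)
  body <- cbind(contig, panel$sites$position + 1L, ".", "A", "C", ".",
                "PASS", ifelse(panel$sites$exonic, "EXONIC", "."), "GT",
                t(gt))
  lines <- c(vcf_header(contig, panel$region_length_bp, TRUE),
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", sprintf("I%04d", seq_len(n_ind))),
                   collapse = "\t"),
             apply(body, 1, paste, collapse = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_panel_vcf
#' @param region_length_bp contig length override when the VCF header does
#'   not declare one.
#' @export
read_panel_vcf <- function(path, region_length_bp = NULL) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    abort_param("reading VCF requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  pos <- as.integer(vcfR::getPOS(v)) - 1L
  exonic <- grepl("EXONIC", vcfR::getINFO(v))
  a1 <- substr(gt, 1, 1) == "1"
  a2 <- substr(gt, 3, 3) == "1"
  hap <- matrix(0L, nrow = 2L * ncol(gt), ncol = nrow(gt))
  hap[seq_len(ncol(gt)) * 2L - 1L, ] <- t(a1 * 1L)
  hap[seq_len(ncol(gt)) * 2L, ] <- t(a2 * 1L)
  if (is.null(region_length_bp)) {
    m <- regmatches(v@meta, regexec("length=([0-9]+)", v@meta))
    len <- suppressWarnings(as.integer(unlist(lapply(m, `[`, 2))))
    region_length_bp <- if (any(!is.na(len))) max(len, na.rm = TRUE)
                        else max(pos) + 1L
  }
  hap_panel(hap, pos, exonic, region_length_bp, provenance = "imported")
}

#' Write and read panels in IMPUTE2 .hap/.legend format
#'
#' The `.hap` file holds one row per site of space-separated 0/1 alleles
#' (haplotypes in columns); the `.legend` file holds `id position a0 a1`
#' with 1-based positions, plus an `exonic` column.
#'
#' @param panel a `hap_panel`.
#' @param prefix file prefix; `<prefix>.hap` and `<prefix>.legend` are
#'   written or read.
#' @return `write_panel_impute2` returns `prefix` invisibly;
#'   `read_panel_impute2` returns a `hap_panel`.
#' @export
write_panel_impute2 <- function(panel, prefix) {
  leg <- data.frame(id = sprintf("site%d", panel$sites$index),
                    position = panel$sites$position + 1L,
                    a0 = "A", a1 = "C",
                    exonic = as.integer(panel$sites$exonic))
  utils::write.table(leg, paste0(prefix, ".legend"), quote = FALSE,
                     row.names = FALSE)
  utils::write.table(t(panel$haplotypes), paste0(prefix, ".hap"),
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' @rdname write_panel_impute2
#' @param region_length_bp contig length (defaults to just past the last
#'   site).
#' @export
read_panel_impute2 <- function(prefix, region_length_bp = NULL) {
  leg <- utils::read.table(paste0(prefix, ".legend"), header = TRUE)
  hap <- as.matrix(utils::read.table(paste0(prefix, ".hap")))
  pos <- as.integer(leg$position) - 1L
  exonic <- if ("exonic" %in% names(leg)) leg$exonic == 1 else
    rep(TRUE, nrow(leg))
  if (is.null(region_length_bp)) region_length_bp <- max(pos) + 1L
  hap_panel(t(hap), pos, exonic, region_length_bp, provenance = "imported")
}

#' Export and import case-control cohorts
#'
#' The genotype matrix goes to an unphased VCF (heterozygous `0/1`,
#' homozygous `1/1` for dosage of the alternate allele), the phenotype to
#' a PLINK-compatible TSV (`FID IID status`, status 2 = case, 1 =
#' control), and the causal mask to a sidecar TSV (`position causal`).
#'
#' @param cohort a `cohort`.
#' @param vcf_path,phenotype_path,causal_path output / input paths
#'   (`causal_path` optional).
#' @param contig contig name.
#' @return `write_cohort` returns `vcf_path` invisibly; `read_cohort`
#'   returns a `cohort`.
#' @export
write_cohort <- function(cohort, vcf_path, phenotype_path,
                         causal_path = NULL, contig = "locus") {
  G <- cohort$genotypes
  code <- c("0/0", "0/1", "1/1")
  gt <- matrix(code[G + 1L], nrow = nrow(G))
  body <- cbind(contig, cohort$sites$position + 1L, ".", "A", "C", ".",
                "PASS", ifelse(cohort$sites$exonic, "EXONIC", "."), "GT",
                t(gt))
  lines <- c(vcf_header(contig, cohort$region_length_bp, FALSE),
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT",
                     sprintf("S%05d", seq_len(nrow(G)))), collapse = "\t"),
             apply(body, 1, paste, collapse = "\t"))
  writeLines(lines, vcf_path)
  phen <- data.frame(FID = sprintf("S%05d", seq_len(nrow(G))),
                     IID = sprintf("S%05d", seq_len(nrow(G))),
                     status = ifelse(cohort$phenotype == 1L, 2L, 1L))
  utils::write.table(phen, phenotype_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(causal_path))
    utils::write.table(
      data.frame(position = cohort$sites$position,
                 causal = as.integer(cohort$sites$causal)),
      causal_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(vcf_path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(vcf_path, phenotype_path, causal_path = NULL) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    abort_param("reading VCF requires the vcfR package")
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  dosage <- (substr(gt, 1, 1) == "1") + (substr(gt, 3, 3) == "1")
  pos <- as.integer(vcfR::getPOS(v)) - 1L
  exonic <- grepl("EXONIC", vcfR::getINFO(v))
  phen <- utils::read.table(phenotype_path, header = TRUE, sep = "\t")
  status <- as.integer(phen$status == 2L)
  causal <- rep(FALSE, length(pos))
  if (!is.null(causal_path)) {
    cz <- utils::read.table(causal_path, header = TRUE, sep = "\t")
    causal <- pos %in% cz$position[cz$causal == 1L]
  }
  m <- regmatches(v@meta, regexec("length=([0-9]+)", v@meta))
  len <- suppressWarnings(as.integer(unlist(lapply(m, `[`, 2))))
  region_length_bp <- if (any(!is.na(len))) max(len, na.rm = TRUE)
                      else max(pos) + 1L
  new_cohort(t(dosage), status, pos, exonic, causal, region_length_bp)
}

#' Build a cohort from an explicit genotype matrix
#'
#' Thin constructor for toy fixtures and externally generated data.
#'
#' @param genotypes individuals x sites dosage matrix (0/1/2 of the
#'   alternate allele).
#' @param phenotype 0/1 vector (1 = case).
#' @param position optional 0-based site positions (defaults to
#'   consecutive).
#' @param exonic,causal optional per-site flags.
#' @param region_length_bp contig length.
#' @return A `cohort`.
#' @export
cohort_from_genotypes <- function(genotypes, phenotype, position = NULL,
                                  exonic = TRUE, causal = FALSE,
                                  region_length_bp = NULL) {
  genotypes <- as.matrix(genotypes)
  m <- ncol(genotypes)
  if (is.null(position)) position <- seq_len(m) * 10L
  if (length(exonic) == 1L) exonic <- rep(exonic, m)
  if (length(causal) == 1L) causal <- rep(causal, m)
  if (is.null(region_length_bp)) region_length_bp <- max(position) + 10L
  new_cohort(genotypes, phenotype, position, exonic, causal,
             region_length_bp)
}

#' Serialise frequency-RR maps as TSV grids
#'
#' Long format: one row per (MAF bin x RR bin) cell with the bin edges and
#' weight.
#'
#' @param map a `freq_rr_map`.
#' @param path output / input path.
#' @return `write_freq_rr_map` returns `path` invisibly;
#'   `read_freq_rr_map` returns a `freq_rr_map`.
#' @export
write_freq_rr_map <- function(map, path) {
  M <- nrow(map$weights); R <- ncol(map$weights)
  grid <- expand.grid(maf_bin = seq_len(M), rr_bin = seq_len(R))
  df <- data.frame(
    maf_lo = map$maf_edges[grid$maf_bin],
    maf_hi = map$maf_edges[grid$maf_bin + 1L],
    rr_lo = map$rr_edges[grid$rr_bin],
    rr_hi = map$rr_edges[grid$rr_bin + 1L],
    weight = map$weights[cbind(grid$maf_bin, grid$rr_bin)])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_freq_rr_map
#' @export
read_freq_rr_map <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  maf_edges <- sort(unique(c(df$maf_lo, df$maf_hi)))
  rr_edges <- sort(unique(c(df$rr_lo, df$rr_hi)))
  W <- matrix(0, length(maf_edges) - 1L, length(rr_edges) - 1L)
  mi <- match(df$maf_lo, maf_edges)
  ri <- match(df$rr_lo, rr_edges)
  W[cbind(mi, ri)] <- df$weight
  freq_rr_map(maf_edges, rr_edges, W)
}

#' Write tidy result tables as TSV
#'
#' @param results any data frame (battery rows, power tables,
#'   concordance matrices).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_results_tsv <- function(results, path) {
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
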