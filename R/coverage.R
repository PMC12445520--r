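#' Assemble a coverage table from counts and genotype labels
#'
#' @param counts Genes x individuals matrix of nonnegative integer read
#'   counts (rownames = gene ids), or a TSV path whose first column is
#'   `gene_id`.
#' @param genotypes Tibble (`individual_id`, `genotype` in ST/SR) or a TSV
#'   path; order must cover the count columns.
#' @return A `coverage_table` (see [simulate_coverage()]).
#' @export
coverage_table <- function(counts, genotypes) {
  if (is.character(counts)) {
    tab <- readr::read_tsv(counts, show_col_types = FALSE)
    m <- as.matrix(tab[-1]); rownames(m) <- tab[[1]]
    counts <- m
  }
  if (is.character(genotypes)) {
    genotypes <- readr::read_tsv(genotypes, show_col_types = FALSE)
  }
  genotypes <- as_tibble(genotypes)
  if (!all(colnames(counts) %in% genotypes$individual_id)) {
    abort("every count column needs a genotype label")
  }
  genotypes <- genotypes[match(colnames(counts), genotypes$individual_id), ]
  if (any(table(genotypes$genotype) < 2)) {
    abort("need >= 2 individuals per genotype")
  }
  structure(list(counts = counts, individuals = genotypes,
                 truth = NULL), class = "coverage_table")
}

#' Per-gene coverage differences between genotypes
#'
#' NB conditional exact test (the same engine as the expression DE) on
#' per-individual per-gene DNA read counts, as a proxy for copy-number
#' differences. Library normalisation is plain total-count scaling by
#' default; BH-FDR across genes.
#'
#' @param tab A `coverage_table`.
#' @param norm_method `"total"` (default) or `"TMM"`.
#' @param dispersion `"tagwise"` (default) or `"common"`.
#' @param prior_genes Dispersion shrinkage weight.
#' @return Tibble: `gene_id`, `log2fc` (SR vs ST), `p_value`, `fdr`.
#' @export
coverage_exact_test <- function(tab, norm_method = c("total", "TMM"),
                                dispersion = c("tagwise", "common"),
                                prior_genes = 10) {
  stopifnot(inherits(tab, "coverage_table"))
  norm_method <- match.arg(norm_method)
  dispersion <- match.arg(dispersion)
  counts <- tab$counts
  geno <- factor(tab$individuals$genotype, levels = c("ST", "SR"))
  libs <- colSums(counts)
  if (norm_method == "TMM") {
    nf <- edgeR::calcNormFactors(counts, lib.size = libs, method = "TMM")
    libs <- libs * nf / exp(mean(log(nf)))
  }
  disp <- estimate_dispersions(counts, libs, geno, prior_genes)
  phi <- if (dispersion == "tagwise") disp$tagwise_phi else disp$common_phi
  res <- exact_test_engine(counts, libs, geno, phi)
  tibble(
    gene_id = rownames(counts),
    log2fc = res$log2fc,
    p_value = res$p_value,
    fdr = bh_adjust(res$p_value)
  )
}

#' Association between expression and coverage differences
#'
#' Spearman rank correlation (average-rank ties) between per-gene
#' expression and coverage log2 fold changes, across all shared genes or a
#' supplied subset.
#'
#' @param expr_log2fc,cov_log2fc Named (by gene) or aligned numeric
#'   vectors of log2 fold changes.
#' @param subset Optional gene ids / index vector restricting the test.
#' @param absolute Correlate magnitudes instead of signed values.
#' @return Tibble: `rho`, `p_value`, `n_genes`, `subset`.
#' @export
expression_coverage_association <- function(expr_log2fc, cov_log2fc,
                                            subset = NULL,
                                            absolute = FALSE) {
  if (!is.null(names(expr_log2fc)) && !is.null(names(cov_log2fc))) {
    shared <- intersect(names(expr_log2fc), names(cov_log2fc))
    expr_log2fc <- expr_log2fc[shared]; cov_log2fc <- cov_log2fc[shared]
  }
  stopifnot(length(expr_log2fc) == length(cov_log2fc))
  label <- if (is.null(subset)) "all" else "subset"
  if (!is.null(subset)) {
    expr_log2fc <- expr_log2fc[subset]; cov_log2fc <- cov_log2fc[subset]
  }
  keep <- !is.na(expr_log2fc) & !is.na(cov_log2fc)
  e <- expr_log2fc[keep]; cv <- cov_log2fc[keep]
  if (absolute) { e <- abs(e); cv <- abs(cv) }
  if (length(e) < 3) abort("need >= 3 genes for the association test")
  ct <- suppressWarnings(cor.test(e, cv, method = "spearman"))
  # report the tie-corrected rho (Pearson on average ranks); cor.test's
  # S-based estimate ignores tie correction
  tibble(rho = stats::cor(e, cv, method = "spearman"), p_value = ct$p.value,
         n_genes = length(e), subset = label)
}

#' Genes with both significant expression and coverage differences
#'
#' @param de Tibble of DE results (`gene_id`, `log2fc`, `p_value`).
#' @param cov Tibble of coverage results (`gene_id`, `log2fc`, `p_value`).
#' @param p_cut Significance cutoff on the raw p-values (default 0.05).
#' @return Tibble of jointly significant genes with both effect sizes
#'   (`expr_log2fc`, `cov_log2fc`).
#' @export
joint_candidates <- function(de, cov, p_cut = 0.05) {
  de_sig <- de |> filter(.data$p_value < p_cut) |>
    select("gene_id", expr_log2fc = "log2fc")
  cov_sig <- cov |> filter(.data$p_value < p_cut) |>
    select("gene_id", cov_log2fc = "log2fc")
  dplyr::inner_join(de_sig, cov_sig, by = "gene_id")
}
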