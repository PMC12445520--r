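#' Per-cell X:autosome expression metrics and X-inactivation calls
#'
#' For every cell, counts the expressed (count > 1) X-linked and autosomal
#' genes, their ratio, and the per-cell X:A CPM ratio used to classify
#' meiotic sex chromosome inactivation: CPM is computed within the cell
#' (mitochondrial genes excluded from numerator, denominator and library
#' size), the X and autosomal CPM distributions over *expressed* genes are
#' each summarised (median by default), and the cell is called
#' X-inactivated when the ratio is at or below `threshold`.
#'
#' @param x A [counts_experiment()] (post-QC).
#' @param threshold Inactivation cutoff on the CPM ratio (inclusive).
#' @param summary `"median"` (default) or `"mean"` over expressed genes.
#' @param expressed_min_count A gene is expressed in a cell when its count
#'   is >= this value (default 2, the "count > 1" rule).
#' @return Tibble, one row per cell: `barcode`, `sample_id`, `genotype`,
#'   `cell_type`, `n_expr_auto`, `n_expr_X`, `expressed_ratio`
#'   (`NA` when no expressed autosomal gene), `cpm_xa_ratio` (0 with
#'   `no_x_expression = TRUE` when no X gene is expressed; `NA` and
#'   excluded from classification when no autosomal gene is), and
#'   `inactivated`.
#' @export
cell_xa_stats <- function(x, threshold = 0.33, summary = c("median", "mean"),
                          expressed_min_count = 2L) {
  stopifnot(inherits(x, "counts_experiment"))
  summary <- match.arg(summary)
  sfun <- if (summary == "median") stats::median else mean
  chrom <- x$gene_anno$chromosome
  xg <- is_x_chrom(chrom); ag <- is_autosome(chrom)

  expr <- x$counts >= expressed_min_count
  n_expr_x <- Matrix::colSums(expr[xg, , drop = FALSE])
  n_expr_a <- Matrix::colSums(expr[ag, , drop = FALSE])

  nuc <- !is_mt_chrom(chrom)
  lib <- Matrix::colSums(x$counts[nuc, , drop = FALSE])
  ratio <- vapply(seq_len(ncol(x$counts)), function(i) {
    if (n_expr_a[i] == 0 || lib[i] == 0) return(NA_real_)
    if (n_expr_x[i] == 0) return(0)
    ci <- x$counts[, i]
    cpm <- ci * 1e6 / lib[i]
    sfun(cpm[xg & expr[, i]]) / sfun(cpm[ag & expr[, i]])
  }, numeric(1))

  tibble(
    barcode = x$cell_meta$barcode,
    sample_id = x$cell_meta$sample_id,
    genotype = x$cell_meta$genotype,
    cell_type = x$cell_meta$cell_type,
    n_expr_auto = as.integer(unname(n_expr_a)),
    n_expr_X = as.integer(unname(n_expr_x)),
    expressed_ratio = unname(ifelse(n_expr_a > 0, n_expr_x / n_expr_a, NA_real_)),
    no_x_expression = unname(n_expr_x == 0 & n_expr_a > 0),
    cpm_xa_ratio = ratio,
    inactivated = classify_inactivation(ratio, threshold)
  )
}

#' Expressed-gene counts for a single cell
#'
#' @param cell Named (by gene) or annotation-aligned count vector.
#' @param annotation Gene annotation tibble (`gene_id`, `chromosome`).
#' @param expressed_min_count Expression rule (default count > 1).
#' @return Named integer vector `c(n_expr_auto, n_expr_X)`; mitochondrial
#'   genes are excluded from both.
#' @export
expressed_gene_counts <- function(cell, annotation, expressed_min_count = 2L) {
  stopifnot(length(cell) == nrow(annotation))
  expr <- cell >= expressed_min_count
  c(
    n_expr_auto = sum(expr & is_autosome(annotation$chromosome)),
    n_expr_X = sum(expr & is_x_chrom(annotation$chromosome))
  )
}

#' Per-cell X:A CPM ratio
#'
#' @inheritParams expressed_gene_counts
#' @param summary Summary over expressed genes per class.
#' @return The ratio summary(X CPM) / summary(autosomal CPM), both over
#'   expressed genes; 0 if no X gene is expressed; `NA` if no autosomal
#'   gene is.
#' @export
cell_xa_cpm_ratio <- function(cell, annotation, summary = c("median", "mean"),
                              expressed_min_count = 2L) {
  summary <- match.arg(summary)
  sfun <- if (summary == "median") stats::median else mean
  nuc <- !is_mt_chrom(annotation$chromosome)
  lib <- sum(cell[nuc])
  if (lib == 0) return(NA_real_)
  cpm <- cell * 1e6 / lib
  expr <- cell >= expressed_min_count
  a <- expr & is_autosome(annotation$chromosome)
  xg <- expr & is_x_chrom(annotation$chromosome)
  if (!any(a)) return(NA_real_)
  if (!any(xg)) return(0)
  sfun(cpm[xg]) / sfun(cpm[a])
}

#' Classify cells as X-inactivated from their X:A CPM ratio
#'
#' A cell is called X-inactivated when its X:A ratio is at or below the
#' threshold (inclusive; the default 0.33 reflects one active X out of
#' three expected X-equivalents being silenced).
#'
#' @param ratio Numeric vector of per-cell X:A CPM ratios.
#' @param threshold Inclusive cutoff.
#' @return Logical vector (`NA` where the ratio is undefined).
#' @export
classify_inactivation <- function(ratio, threshold = 0.33) {
  ratio <= threshold
}

#' Chi-square contingency test of inactivation by compartment
#'
#' Tests whether the proportion of X-inactivated cells differs between the
#' germline and somatic compartments with a Pearson chi-square on the 2x2
#' table (no continuity correction). When any expected cell count is below
#' 5 a Fisher exact test is available via `method = "fisher"`.
#'
#' @param inactivated Logical vector of per-cell calls (`NA` dropped).
#' @param compartment Character/factor vector, two levels (e.g. `"germline"`,
#'   `"soma"`), aligned with `inactivated`.
#' @param method `"chisq"` (default) or `"fisher"`.
#' @return Tibble: `chi2`, `df`, `p_value`, `method`, and the 2x2 table as
#'   a `table` attribute. A zero margin yields statistic 0, p = 1, with a
#'   warning.
#' @export
inactivation_contingency_test <- function(inactivated, compartment,
                                          method = c("chisq", "fisher")) {
  method <- match.arg(method)
  keep <- !is.na(inactivated) & !is.na(compartment)
  inactivated <- inactivated[keep]; compartment <- compartment[keep]
  if (length(unique(compartment)) < 2) abort("both compartments must be non-empty")
  tab <- table(factor(inactivated, levels = c(FALSE, TRUE)), compartment)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warn("a margin of the contingency table is zero; statistic set to 0")
    out <- tibble(chi2 = 0, df = 1L, p_value = 1, method = "chisq")
    attr(out, "table") <- tab
    return(out)
  }
  if (method == "fisher") {
    ft <- fisher.test(tab)
    out <- tibble(chi2 = NA_real_, df = NA_integer_, p_value = ft$p.value,
                  method = "fisher")
  } else {
    ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
    if (any(ct$expected < 5)) {
      warn("expected counts below 5; consider method = 'fisher'")
    }
    out <- tibble(chi2 = unname(ct$statistic), df = as.integer(ct$parameter),
                  p_value = ct$p.value, method = "chisq")
  }
  attr(out, "table") <- tab
  out
}
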