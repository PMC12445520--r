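#' Dosage-analysis gene filter
#'
#' Within one cell type, keeps genes that are (i) expressed (count > 1) in
#' at least `min_cell_frac` of that cell type's cells and (ii) have
#' pseudobulk log2(CPM) above `min_log2cpm` in strictly more than half of
#' the standard males or strictly more than half of the drive males.
#'
#' @param x A [counts_experiment()] (cell-level, for the 5% rule).
#' @param p A normalised `pseudobulk` (see [normalize_libsizes()]).
#' @param cell_type Cell type to filter within.
#' @param min_cell_frac Minimum expressing-cell fraction (default 0.05).
#' @param min_log2cpm Pseudobulk log2 CPM cutoff (default 2, strict >).
#' @param expressed_min_count Cell-level expression rule (default count > 1).
#' @return Character vector of retained gene ids.
#' @export
dosage_gene_filter <- function(x, p, cell_type, min_cell_frac = 0.05,
                               min_log2cpm = 2, expressed_min_count = 2L) {
  stopifnot(inherits(x, "counts_experiment"), inherits(p, "pseudobulk"))
  if (is.null(p$cpm)) abort("run normalize_libsizes() on the pseudobulk first")
  cells <- x$cell_meta$cell_type == cell_type
  if (!any(cells)) abort(sprintf("no cells of type '%s'", cell_type))
  frac_expr <- Matrix::rowSums(
    x$counts[, cells, drop = FALSE] >= expressed_min_count
  ) / sum(cells)

  units <- p$units$cell_type == cell_type
  cpm <- p$cpm[, units, drop = FALSE]
  geno <- p$units$genotype[units]
  pass_geno <- function(g) {
    k <- geno == g
    if (!any(k)) return(rep(FALSE, nrow(cpm)))
    rowSums(log2(cpm[, k, drop = FALSE]) > min_log2cpm) > sum(k) / 2
  }
  keep <- frac_expr >= min_cell_frac & (pass_geno("ST") | pass_geno("SR"))
  x$gene_anno$gene_id[keep]
}

#' Per-gene log2(X:A) for one pseudobulk unit
#'
#' For each X-linked gene of a unit, log2 of its CPM over the unit's
#' median autosomal CPM (both restricted to filtered genes). X genes with
#' zero CPM are excluded (reported via the `n_zero_excluded` attribute).
#'
#' @param cpm Named per-gene CPM vector of one unit (filtered genes).
#' @param chromosome Chromosome label per gene, aligned with `cpm`.
#' @return Tibble: `gene_id`, `log2_xa`; attribute `autosomal_median`.
#' @export
unit_log2_xa <- function(cpm, chromosome) {
  stopifnot(length(cpm) == length(chromosome))
  auto <- is_autosome(chromosome)
  xg <- is_x_chrom(chromosome)
  if (!any(auto)) abort("no autosomal genes in unit after filtering")
  med_a <- stats::median(cpm[auto])
  if (med_a <= 0) abort("autosomal median CPM is zero")
  xv <- cpm[xg]
  ids <- if (!is.null(names(cpm))) names(cpm)[xg] else which(xg)
  zero <- xv <= 0
  out <- tibble(gene_id = as.character(ids[!zero]),
                log2_xa = unname(log2(xv[!zero] / med_a)))
  attr(out, "autosomal_median") <- med_a
  attr(out, "n_zero_excluded") <- sum(zero)
  out
}

#' One-sample Wilcoxon signed-rank test against mu
#'
#' Two-sided signed-rank test of location, used for deviations of
#' log2(X:A) from 0. Zero differences are dropped; for n <= `exact_max`
#' remaining values the null distribution of the positive-rank sum is
#' computed exactly over all 2^n sign assignments (a convolution that
#' tolerates ties), otherwise a normal approximation with tie correction
#' and continuity correction is used. The two-sided p doubles the smaller
#' tail, capped at 1.
#'
#' @param values Numeric vector.
#' @param mu Null location (default 0).
#' @param exact_max Largest n for the exact distribution (default 25).
#' @return Tibble: `statistic` (positive-rank sum W+), `n_nonzero`,
#'   `p_value`, `method`.
#' @export
dosage_test <- function(values, mu = 0, exact_max = 25L) {
  v <- values[!is.na(values)] - mu
  v <- v[v != 0]
  n <- length(v)
  if (n == 0) {
    return(tibble(statistic = 0, n_nonzero = 0L, p_value = 1,
                  method = "exact"))
  }
  r <- rank(abs(v))
  w <- sum(r[v > 0])
  if (n <= exact_max) {
    d <- as.integer(round(2 * r))  # doubled ranks are integers even with ties
    probs <- 1
    for (di in d) {
      shifted <- c(rep(0, di), probs)
      probs <- 0.5 * (c(probs, rep(0, di)) + shifted)
    }
    # probs[k + 1] = P(2 W+ = k)
    w2 <- as.integer(round(2 * w))
    p_low <- sum(probs[seq_len(w2 + 1L)])
    p_high <- sum(probs[(w2 + 1L):length(probs)])
    p <- min(1, 2 * min(p_low, p_high))
    method <- "exact"
  } else {
    mu_w <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (w - mu_w - sign(w - mu_w) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "normal"
  }
  tibble(statistic = w, n_nonzero = n, p_value = p, method = method)
}

#' Compare log2(X:A) values between genotypes
#'
#' Two-sided Mann-Whitney rank-sum test on the per-gene values of the two
#' genotypes.
#'
#' @param st_values,sr_values Per-gene log2(X:A) vectors.
#' @return Tibble: `statistic` (U), `p_value`, `n_st`, `n_sr`.
#' @export
dosage_compare <- function(st_values, sr_values) {
  st_values <- st_values[!is.na(st_values)]
  sr_values <- sr_values[!is.na(sr_values)]
  if (length(st_values) == 0 || length(sr_values) == 0) {
    abort("both genotype value vectors must be non-empty")
  }
  if (length(unique(c(st_values, sr_values))) == 1) {
    return(tibble(statistic = length(st_values) * length(sr_values) / 2,
                  p_value = 1, n_st = length(st_values),
                  n_sr = length(sr_values)))
  }
  wt <- suppressWarnings(wilcox.test(st_values, sr_values))
  tibble(statistic = unname(wt$statistic), p_value = wt$p.value,
         n_st = length(st_values), n_sr = length(sr_values))
}

#' Dosage-compensation analysis across cell types
#'
#' Full log2(X:A) pipeline: pseudobulk aggregation, TMM normalisation, the
#' two-stage gene filter, per-unit per-gene log2(CPM_X / median autosomal
#' CPM), per-gene means across each genotype's samples, a signed-rank test
#' of deviation from 0 per (cell type, genotype), and a rank-sum
#' comparison of ST vs SR per cell type.
#'
#' @param x A [counts_experiment()] (post-QC).
#' @param cell_types Cell types to analyse (default: all present).
#' @param norm_method `"TMM"` or `"total"` library normalisation.
#' @param min_cell_frac,min_log2cpm Filter parameters
#'   (see [dosage_gene_filter()]).
#' @return A `dosage_result` list: `per_gene` (gene_id, cell_type,
#'   genotype, log2_xa), `per_unit` (gene-by-unit values), and `summary`
#'   (cell_type, genotype, n_genes, median_log2_xa, p_vs_zero,
#'   p_st_vs_sr).
#' @export
dosage_analysis <- function(x, cell_types = NULL, norm_method = "TMM",
                            min_cell_frac = 0.05, min_log2cpm = 2) {
  stopifnot(inherits(x, "counts_experiment"))
  p <- normalize_libsizes(aggregate_pseudobulk(x), method = norm_method)
  cell_types <- cell_types %||% unique(p$units$cell_type)

  per_unit <- purrr::map_dfr(cell_types, function(ct) {
    genes <- dosage_gene_filter(x, p, ct, min_cell_frac, min_log2cpm)
    if (length(genes) == 0) return(tibble())
    gi <- match(genes, rownames(p$cpm))
    ui <- which(p$units$cell_type == ct)
    purrr::map_dfr(ui, function(u) {
      tab <- unit_log2_xa(setNames(p$cpm[gi, u], genes),
                          p$gene_anno$chromosome[gi])
      if (nrow(tab) == 0) return(tibble())
      tab$unit <- p$units$unit[u]
      tab$sample_id <- p$units$sample_id[u]
      tab$genotype <- p$units$genotype[u]
      tab$cell_type <- ct
      tab
    })
  })
  if (nrow(per_unit) == 0) abort("no X-linked genes passed the dosage filters")

  per_gene <- per_unit |>
    group_by(.data$gene_id, .data$cell_type, .data$genotype) |>
    summarise(log2_xa = mean(.data$log2_xa), .groups = "drop")

  summary_tbl <- per_gene |>
    group_by(.data$cell_type, .data$genotype) |>
    summarise(
      n_genes = n(),
      median_log2_xa = stats::median(.data$log2_xa),
      p_vs_zero = dosage_test(.data$log2_xa)$p_value,
      .groups = "drop"
    )
  comp <- per_gene |>
    group_by(.data$cell_type) |>
    summarise(
      p_st_vs_sr = {
        st <- .data$log2_xa[.data$genotype == "ST"]
        sr <- .data$log2_xa[.data$genotype == "SR"]
        if (length(st) && length(sr)) dosage_compare(st, sr)$p_value
        else NA_real_
      },
      .groups = "drop"
    )
  summary_tbl <- left_join(summary_tbl, comp, by = "cell_type")
  structure(
    list(per_gene = per_gene, per_unit = per_unit, summary = summary_tbl),
    class = "dosage_result"
  )
}

#' @export
print.dosage_result <- function(x, ...) {
  cat("<dosage_result>\n")
  print(x$summary)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.dosage_result <- function(x, ...) x$summary

#' Stratify a dosage result by gene class
#'
#' Recomputes the dosage summary within gene classes (e.g. testis-specific
#' vs broadly expressed). Classes with no genes are omitted with a warning.
#'
#' @param result A `dosage_result` from [dosage_analysis()].
#' @param gene_classes Tibble (`gene_id`, `class`); genes missing from it
#'   are labelled `"unclassified"`.
#' @return Summary tibble as in [dosage_analysis()] with a `class` column.
#' @export
stratify_by_class <- function(result, gene_classes) {
  stopifnot(inherits(result, "dosage_result"))
  pg <- result$per_gene |>
    left_join(as_tibble(gene_classes), by = "gene_id") |>
    mutate(class = dplyr::coalesce(.data$class, "unclassified"))
  present <- unique(pg$class)
  missing <- setdiff(unique(gene_classes$class), present)
  if (length(missing)) {
    warn(paste("empty gene class(es) omitted:", paste(missing, collapse = ", ")))
  }
  pg |>
    group_by(.data$class, .data$cell_type, .data$genotype) |>
    summarise(
      n_genes = n(),
      median_log2_xa = stats::median(.data$log2_xa),
      p_vs_zero = dosage_test(.data$log2_xa)$p_value,
      .groups = "drop"
    )
}
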