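#' Quality-control thresholds
#'
#' The cell and gene filters applied to droplet testis data: cells are
#' removed when they detect fewer than `min_features` genes or exceed
#' `max_mito` mitochondrial expression; genes are kept when they are
#' expressed (count > 1, i.e. count >= `expressed_min_count`) in at least
#' `min_cells_per_gene` cells. "Detected" for the feature rule means
#' count >= 1; "expressed" for the gene rule and all downstream biology
#' metrics means count > 1 — the two definitions are deliberately distinct.
#'
#' @param min_features Minimum detected genes per retained cell.
#' @param max_mito Maximum mitochondrial proportion per retained cell.
#' @param min_cells_per_gene Minimum expressing cells per retained gene.
#' @param expressed_min_count A gene is "expressed" in a cell when its
#'   count is >= this value (default 2, the strict "count > 1" rule).
#' @return A `qc_thresholds` list.
#' @export
qc_thresholds <- function(min_features = 200L, max_mito = 0.20,
                          min_cells_per_gene = 3L, expressed_min_count = 2L) {
  t <- list(
    min_features = as.integer(min_features),
    max_mito = max_mito,
    min_cells_per_gene = as.integer(min_cells_per_gene),
    expressed_min_count = as.integer(expressed_min_count)
  )
  if (any(unlist(t) < 0)) abort("all QC thresholds must be >= 0")
  structure(t, class = "qc_thresholds")
}

#' Per-cell mitochondrial expression fraction
#'
#' @param x A [counts_experiment()].
#' @return Tibble: `barcode`, `mito_fraction` (MT counts / total counts,
#'   in \[0, 1\]; 0 with a flag for zero-count cells).
#' @export
compute_mito_fraction <- function(x) {
  stopifnot(inherits(x, "counts_experiment"))
  mt <- is_mt_chrom(x$gene_anno$chromosome)
  if (!any(mt)) {
    warn("no mitochondrial genes annotated; mito_fraction set to 0")
    return(tibble(barcode = colnames(x$counts),
                  mito_fraction = 0, zero_total = FALSE))
  }
  total <- Matrix::colSums(x$counts)
  mito <- Matrix::colSums(x$counts[mt, , drop = FALSE])
  zero <- total == 0
  if (any(zero)) warn(sprintf("%d cells have zero total counts", sum(zero)))
  frac <- ifelse(zero, 0, mito / pmax(total, 1))
  tibble(barcode = colnames(x$counts), mito_fraction = unname(frac),
         zero_total = unname(zero))
}

#' Filter cells on detected features and mitochondrial load
#'
#' Removes cells detecting fewer than `min_features` genes or exceeding
#' `max_mito` mitochondrial proportion. `logic = "any"` (default) removes
#' a cell failing either criterion; `logic = "all"` removes only cells
#' failing both.
#'
#' @param x A [counts_experiment()].
#' @param thresholds A [qc_thresholds()].
#' @param logic `"any"` or `"all"` (which failures trigger removal).
#' @return The filtered `counts_experiment`, with a `qc_report` attribute:
#'   a per-sample tibble of cells in, removed by each rule, and retained.
#' @export
filter_cells <- function(x, thresholds = qc_thresholds(),
                         logic = c("any", "all")) {
  stopifnot(inherits(x, "counts_experiment"))
  logic <- match.arg(logic)
  mf <- compute_mito_fraction(x)
  detected <- Matrix::colSums(x$counts >= 1)
  fail_feat <- detected < thresholds$min_features
  fail_mito <- mf$mito_fraction > thresholds$max_mito
  drop <- if (logic == "any") fail_feat | fail_mito else fail_feat & fail_mito

  report <- tibble(
    sample_id = x$cell_meta$sample_id,
    fail_features = fail_feat, fail_mito = fail_mito, removed = drop
  ) |>
    group_by(.data$sample_id) |>
    summarise(
      cells_in = n(),
      removed_low_features = sum(.data$fail_features),
      removed_high_mito = sum(.data$fail_mito),
      cells_removed = sum(.data$removed),
      cells_kept = sum(!.data$removed),
      .groups = "drop"
    )
  if (all(drop)) {
    abort(sprintf(
      "all %d cells removed (%d below %d features, %d above %.0f%% mito)",
      length(drop), sum(fail_feat), thresholds$min_features,
      sum(fail_mito), 100 * thresholds$max_mito
    ))
  }
  out <- subset_experiment(x, cells = !drop)
  out$cell_meta$mito_fraction <- mf$mito_fraction[!drop]
  attr(out, "qc_report") <- report
  out
}

#' Filter genes on the expressed-in-enough-cells rule
#'
#' Keeps genes expressed (count >= `expressed_min_count`, default "> 1")
#' in at least `min_cells_per_gene` cells.
#'
#' @inheritParams filter_cells
#' @return The filtered `counts_experiment` with a `genes_removed`
#'   attribute (count).
#' @export
filter_genes <- function(x, thresholds = qc_thresholds()) {
  stopifnot(inherits(x, "counts_experiment"))
  n_expr <- Matrix::rowSums(x$counts >= thresholds$expressed_min_count)
  keep <- n_expr >= thresholds$min_cells_per_gene
  out <- subset_experiment(x, genes = keep)
  attr(out, "genes_removed") <- sum(!keep)
  out
}

#' Apply the full QC stage (cells then genes)
#'
#' @inheritParams filter_cells
#' @return Filtered `counts_experiment` carrying the `qc_report` attribute.
#' @export
apply_qc <- function(x, thresholds = qc_thresholds(), logic = "any") {
  out <- filter_cells(x, thresholds, logic)
  report <- attr(out, "qc_report")
  out <- filter_genes(out, thresholds)
  attr(out, "qc_report") <- report
  out
}
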