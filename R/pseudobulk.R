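#' Aggregate single cells to pseudobulk units
#'
#' Sums raw counts over all cells of each (sample, cell type) unit, so the
#' biological replicate downstream is the male, not the cell. Units with
#' zero cells do not appear.
#'
#' @param x A [counts_experiment()].
#' @return A `pseudobulk` object: list with `counts` (genes x units integer
#'   matrix), `units` (tibble: unit, sample_id, genotype, cell_type,
#'   n_cells, lib_size), and `gene_anno`.
#' @export
aggregate_pseudobulk <- function(x) {
  stopifnot(inherits(x, "counts_experiment"))
  meta <- x$cell_meta
  if (anyNA(meta$sample_id) || anyNA(meta$cell_type)) {
    abort("every cell needs sample and cell_type labels")
  }
  unit <- paste(meta$sample_id, meta$cell_type, sep = ".")
  f <- factor(unit, levels = unique(unit))
  # model-matrix trick: genes x cells %*% cells x units indicator
  ind <- Matrix::sparseMatrix(
    i = seq_along(f), j = as.integer(f), x = 1,
    dims = c(length(f), nlevels(f))
  )
  counts <- as.matrix(x$counts %*% ind)
  colnames(counts) <- levels(f)
  units <- meta |>
    mutate(unit = unit) |>
    group_by(.data$unit, .data$sample_id, .data$genotype, .data$cell_type) |>
    summarise(n_cells = n(), .groups = "drop")
  units <- units[match(levels(f), units$unit), ]
  units$lib_size <- colSums(counts)
  structure(
    list(counts = counts, units = units, gene_anno = x$gene_anno),
    class = "pseudobulk"
  )
}

#' @export
print.pseudobulk <- function(x, ...) {
  cat(sprintf("<pseudobulk> %d genes x %d units\n",
              nrow(x$counts), nrow(x$units)))
  invisible(x)
}

#' TMM library-size normalisation and CPM for pseudobulk units
#'
#' Computes trimmed-mean-of-M-values normalisation factors (30% M trim,
#' 5% A trim, reference unit chosen by upper quartile closest to the mean
#' upper quartile) and counts per million on the effective library size
#' `lib_size * norm_factor`. Factors are rescaled to geometric mean 1.
#' With `method = "total"` all factors are 1 (plain total-count scaling).
#'
#' @param p A `pseudobulk` object.
#' @param method `"TMM"` (default) or `"total"`.
#' @return `p` with `units$norm_factor` filled in and a `cpm` matrix added.
#' @export
normalize_libsizes <- function(p, method = c("TMM", "total")) {
  stopifnot(inherits(p, "pseudobulk"))
  method <- match.arg(method)
  if (any(p$units$lib_size <= 0)) abort("all pseudobulk units need lib_size > 0")
  single_gene <- colSums(p$counts > 0) <= 1
  if (any(single_gene)) {
    warn("unit(s) with <= 1 expressed gene; normalisation factor set to 1")
  }
  if (method == "TMM") {
    nf <- edgeR::calcNormFactors(p$counts, lib.size = p$units$lib_size,
                                 method = "TMM")
    nf[single_gene] <- 1
    nf <- nf / exp(mean(log(nf)))
  } else {
    nf <- rep(1, ncol(p$counts))
  }
  p$units$norm_factor <- nf
  p$cpm <- cpm_from_counts(p$counts, p$units$lib_size * nf)
  p
}
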