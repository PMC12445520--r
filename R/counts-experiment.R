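#' Assemble a single-cell counts experiment
#'
#' Bundles a sparse genes-by-cells count matrix with per-cell metadata and
#' per-gene annotation. This is the container every downstream stage (QC,
#' per-cell X:A metrics, pseudobulk, differential expression) consumes.
#'
#' @param counts Integer matrix or `Matrix::dgCMatrix`, genes in rows, cells
#'   in columns. Dimnames must carry `gene_id` (rows) and `barcode` (columns).
#' @param cell_meta Data frame with one row per cell: `barcode`, `sample_id`,
#'   `genotype` (`"ST"` or `"SR"`), `cell_type`. Extra columns are kept.
#' @param gene_anno Data frame with one row per gene: `gene_id`, `chromosome`
#'   (one of `chr1`, `chr2`, `chrX`, `MT`), optionally `class` (tissue
#'   specificity: `testis_specific`, `broad`, `unclassified`).
#'
#' @return An object of class `counts_experiment`: a list with elements
#'   `counts` (dgCMatrix), `cell_meta` (tibble, with `lib_size`,
#'   `n_features` and `mito_fraction` filled in), and `gene_anno` (tibble).
#' @export
counts_experiment <- function(counts, cell_meta, gene_anno) {
  counts <- methods::as(methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
    "dMatrix"), "generalMatrix"), "CsparseMatrix")
  cell_meta <- as_tibble(cell_meta)
  gene_anno <- as_tibble(gene_anno)
  if (is.null(rownames(counts))) rownames(counts) <- gene_anno$gene_id
  if (is.null(colnames(counts))) colnames(counts) <- cell_meta$barcode

  if (anyDuplicated(gene_anno$gene_id)) abort("duplicate gene_id in annotation")
  if (anyDuplicated(cell_meta$barcode)) abort("duplicate cell barcodes")
  if (!identical(rownames(counts), gene_anno$gene_id)) {
    abort("row names of counts must equal gene_anno$gene_id (same order)")
  }
  if (!identical(colnames(counts), cell_meta$barcode)) {
    abort("column names of counts must equal cell_meta$barcode (same order)")
  }
  vals <- counts@x
  if (any(vals < 0) || any(vals != round(vals))) {
    abort("counts must be nonnegative integers")
  }
  geno_per_sample <- cell_meta |>
    distinct(.data$sample_id, .data$genotype)
  if (anyDuplicated(geno_per_sample$sample_id)) {
    abort("each sample_id must map to exactly one genotype")
  }
  if (!all(cell_meta$genotype %in% c("ST", "SR"))) {
    abort("genotype must be 'ST' or 'SR'")
  }

  cell_meta$lib_size <- unname(Matrix::colSums(counts))
  cell_meta$n_features <- unname(Matrix::colSums(counts > 0))
  obj <- structure(
    list(counts = counts, cell_meta = cell_meta, gene_anno = gene_anno),
    class = "counts_experiment"
  )
  obj$cell_meta$mito_fraction <- compute_mito_fraction(obj)$mito_fraction
  obj
}

#' @export
print.counts_experiment <- function(x, ...) {
  cat(sprintf(
    "<counts_experiment> %d genes x %d cells\n", nrow(x$counts), ncol(x$counts)
  ))
  cat(sprintf(
    "  samples: %s\n",
    paste(sort(unique(x$cell_meta$sample_id)), collapse = ", ")
  ))
  chrom <- table(x$gene_anno$chromosome)
  cat("  genes per chromosome:",
      paste(names(chrom), chrom, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.counts_experiment <- function(x) dim(x$counts)

#' Per-cell metadata / per-gene annotation of a counts experiment
#' @param x A `counts_experiment`.
#' @return A tibble.
#' @export
cell_meta <- function(x) {
  stopifnot(inherits(x, "counts_experiment"))
  x$cell_meta
}

#' @rdname cell_meta
#' @export
gene_anno <- function(x) {
  stopifnot(inherits(x, "counts_experiment"))
  x$gene_anno
}

# Subset a counts_experiment by gene and/or cell logical/index vectors,
# keeping counts, metadata and annotation aligned.
subset_experiment <- function(x, genes = NULL, cells = NULL) {
  stopifnot(inherits(x, "counts_experiment"))
  if (!is.null(genes)) {
    x$counts <- x$counts[genes, , drop = FALSE]
    x$gene_anno <- x$gene_anno[genes, , drop = FALSE]
  }
  if (!is.null(cells)) {
    x$counts <- x$counts[, cells, drop = FALSE]
    x$cell_meta <- x$cell_meta[cells, , drop = FALSE]
  }
  x$cell_meta$lib_size <- unname(Matrix::colSums(x$counts))
  x$cell_meta$n_features <- unname(Matrix::colSums(x$counts > 0))
  x
}
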