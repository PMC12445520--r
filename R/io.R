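#' Read a count matrix into a counts experiment
#'
#' Reads either a MatrixMarket triplet (`matrix.mtx` with `features.tsv`
#' and `barcodes.tsv`, the droplet-platform layout) or a dense TSV with
#' genes in rows and cells in columns, together with a cell-metadata TSV
#' (`barcode`, `sample_id`, `genotype`, `cell_type`) and a gene-annotation
#' TSV (`gene_id`, `chromosome`, optional `class`). Counts are read
#' losslessly as integers; gene and cell order follow the input files.
#'
#' @param mtx,features,barcodes Paths of the MatrixMarket triplet.
#' @param dense_tsv Alternatively, a dense gene-by-cell TSV whose first
#'   column is `gene_id`.
#' @param cell_meta,gene_anno Paths of metadata and annotation TSVs, or
#'   data frames.
#' @return A [counts_experiment()].
#' @export
read_counts <- function(mtx = NULL, features = NULL, barcodes = NULL,
                        dense_tsv = NULL, cell_meta, gene_anno) {
  if (!is.null(dense_tsv)) {
    dense <- readr::read_tsv(dense_tsv, show_col_types = FALSE)
    genes <- dense[[1]]
    m <- as.matrix(dense[-1])
    if (any(m != round(m))) abort("dense matrix contains non-integer entries")
    rownames(m) <- genes
  } else {
    for (p in c(mtx, features, barcodes)) {
      if (!file.exists(p)) abort(paste0("file not found: ", p))
    }
    first <- readLines(mtx, n = 1L)
    if (!grepl("^%%MatrixMarket", first)) {
      abort(paste0("malformed MatrixMarket header at line 1 of ", mtx,
                   ": ", first))
    }
    m <- as.matrix(Matrix::readMM(mtx))
    if (any(m != round(m))) abort("MatrixMarket file contains non-integer entries")
    feat <- readr::read_tsv(features, col_names = FALSE, show_col_types = FALSE)
    bc <- readr::read_tsv(barcodes, col_names = FALSE, show_col_types = FALSE)
    if (nrow(feat) != nrow(m) || nrow(bc) != ncol(m)) {
      abort(sprintf(
        "dimension mismatch: matrix %d x %d but %d features / %d barcodes",
        nrow(m), ncol(m), nrow(feat), nrow(bc)
      ))
    }
    rownames(m) <- feat[[1]]
    colnames(m) <- bc[[1]]
  }
  if (is.character(cell_meta)) {
    cell_meta <- readr::read_tsv(cell_meta, show_col_types = FALSE)
  }
  if (is.character(gene_anno)) {
    gene_anno <- readr::read_tsv(gene_anno, show_col_types = FALSE)
  }
  counts_experiment(m, cell_meta, gene_anno)
}

#' Write a counts experiment to disk
#'
#' Writes the MatrixMarket triplet (`matrix.mtx`, `features.tsv`,
#' `barcodes.tsv`) plus `cell_metadata.tsv` and `gene_annotation.tsv` into
#' `dir`. The written files round-trip through [read_counts()].
#'
#' @param x A [counts_experiment()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_counts <- function(x, dir) {
  stopifnot(inherits(x, "counts_experiment"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("matrix.mtx", "features.tsv", "barcodes.tsv",
                            "cell_metadata.tsv", "gene_annotation.tsv"))
  Matrix::writeMM(x$counts, paths[1])
  readr::write_tsv(tibble(gene_id = rownames(x$counts)), paths[2],
                   col_names = FALSE)
  readr::write_tsv(tibble(barcode = colnames(x$counts)), paths[3],
                   col_names = FALSE)
  readr::write_tsv(x$cell_meta, paths[4])
  readr::write_tsv(x$gene_anno, paths[5])
  invisible(paths)
}

#' Write / read a simulation configuration as YAML
#' @param cfg A [sim_config()].
#' @param path YAML file path.
#' @return `read_sim_config()` returns a validated `sim_config`.
#' @export
write_sim_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "sim_config"))
  out <- unclass(cfg)
  # named atomic vectors lose their names in YAML sequences; write maps
  for (nm in c("cells_per_type", "stage_activity", "stage_inclusion",
               "genes_per_chrom")) {
    out[[nm]] <- as.list(out[[nm]])
  }
  out$x_dosage <- as.data.frame(normalize_x_dosage(cfg$x_dosage, cfg$cell_types))
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  for (nm in c("cells_per_type", "stage_activity", "stage_inclusion",
               "genes_per_chrom")) {
    raw[[nm]] <- unlist(raw[[nm]])
  }
  raw$x_dosage <- as_tibble(as.data.frame(lapply(raw$x_dosage, unlist)))
  raw$mito_fraction_beta <- unlist(raw$mito_fraction_beta)
  do.call(sim_config, raw[names(raw) %in% names(formals(sim_config))])
}
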