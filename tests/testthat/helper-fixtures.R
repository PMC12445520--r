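# Fixtures built in code: tiny hand-constructed experiments and small
# simulation configs reused across test files.

# A deterministic toy experiment: 6 genes (2 per autosome, 1 X, 1 MT),
# 4 cells across 2 samples / genotypes.
toy_experiment <- function() {
  counts <- matrix(
    c( # cells: ST1_a  ST1_b  SR1_a  SR1_b
      10, 10, 20, 20,   # g1 chr1
      30, 30, 60, 60,   # g2 chr1
      20, 20, 40, 40,   # g3 chr2
      40, 40, 80, 80,   # g4 chr2
      25, 25, 50, 50,   # g5 chrX
      5, 5, 10, 10      # g6 MT
    ),
    nrow = 6, byrow = TRUE,
    dimnames = list(paste0("g", 1:6), c("ST1_a", "ST1_b", "SR1_a", "SR1_b"))
  )
  counts_experiment(
    counts,
    cell_meta = tibble::tibble(
      barcode = colnames(counts),
      sample_id = c("ST1", "ST1", "SR1", "SR1"),
      genotype = c("ST", "ST", "SR", "SR"),
      cell_type = "cyst"
    ),
    gene_anno = tibble::tibble(
      gene_id = rownames(counts),
      chromosome = c("chr1", "chr1", "chr2", "chr2", "chrX", "MT"),
      class = c("broad", "broad", "testis_specific", "broad", "broad",
                "unclassified")
    )
  )
}

# Small but non-trivial simulation (2+2 samples, modest genes/cells) for
# pipeline-level tests; runs in a few seconds.
small_sim_config <- function(seed = 42L, ...) {
  sim_config(
    seed = seed,
    n_samples_ST = 2L, n_samples_SR = 2L,
    cells_per_type = c(muscle = 10L, cyst = 30L, gsc_spermatogonia = 40L,
                       primary_spermatocytes = 40L,
                       secondary_spermatocytes = 40L, spermatids = 40L),
    genes_per_chrom = c(chr1 = 150L, chr2 = 150L, chrX = 100L, MT = 5L),
    libsize_logmean = log(3000),
    ...
  )
}

# Homogeneous single-cell-type pool used by resampling-null tests: one
# cell type, no X dosage effect, no programmed DE.
flat_pool_config <- function(seed = 7L, n_cells = 400L, n_de = 0L,
                             de_log2fc = 0, de_x_fraction = 0.5,
                             dispersion = 0.1) {
  sim_config(
    seed = seed,
    n_samples_ST = 4L, n_samples_SR = 4L,
    cell_types = "cyst", germline_types = character(0),
    cells_per_type = c(cyst = as.integer(ceiling(n_cells / 8))),
    genes_per_chrom = c(chr1 = 160L, chr2 = 160L, chrX = 160L, MT = 5L),
    stage_activity = c(cyst = 1), stage_inclusion = c(cyst = 1),
    x_dosage = c(cyst = 1),
    n_de_genes = n_de, de_log2fc = de_log2fc, de_x_fraction = de_x_fraction,
    dispersion = dispersion,
    libsize_logmean = log(2500), libsize_logsd = 0.2
  )
}
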