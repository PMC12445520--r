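#' Simulation configuration for synthetic testis scRNA-seq data
#'
#' Defines the generative model the synthetic counts follow: eight males
#' (four standard ST, four drive SR), an ordered set of testis cell types
#' (somatic support cells first, then the germline stages of
#' spermatogenesis), three nuclear chromosomes (two autosomes and the X)
#' plus a small mitochondrial gene set, a log-normal distribution of
#' per-gene expression rates, stage-specific transcriptome-size decline,
#' stage-by-genotype X dosage factors, a set of drive-biased
#' (differentially expressed) genes, and negative-binomial count noise.
#'
#' The per-stage biology encoded by the defaults: somatic cell types have
#' fully compensated X expression (dosage 1); the early germline
#' (GSC/spermatogonia and primary spermatocytes) expresses the X at half
#' the autosomal rate (dosage 0.5, i.e. uncompensated single-X expression);
#' the late stages (secondary spermatocytes, spermatids) restore full
#' compensation. Dosage factors are identical for ST and SR genotypes, and
#' drive-biased genes are placed half on the X and half on the autosomes.
#'
#' @param seed Master seed; every operation draws from a named sub-stream
#'   derived from it.
#' @param n_samples_ST,n_samples_SR Number of male individuals per genotype.
#' @param cell_types Ordered character vector, somatic types first then the
#'   germline stages in developmental order.
#' @param germline_types Which of `cell_types` are germline stages.
#' @param cells_per_type Named integer vector: cells per sample for each
#'   cell type.
#' @param genes_per_chrom Named integer vector with entries `chr1`, `chr2`,
#'   `chrX`, `MT`.
#' @param baseline_logmean,baseline_logsd Meanlog/sdlog of the log-normal
#'   per-gene rate \eqn{\lambda_g} (arbitrary units; rates are renormalised
#'   within each cell).
#' @param stage_activity Named positive vector: multiplicative
#'   transcriptome-size factor per cell type (acts on the expected library
#'   size); must decline monotonically over the germline stages.
#' @param stage_inclusion Named vector in (0, 1]: probability a gene is
#'   transcriptionally active in a given cell type; together with
#'   `stage_activity` this produces the declining expressed-gene counts of
#'   late spermatogenesis.
#' @param x_dosage Data frame (`cell_type`, `genotype`, `dosage`) of
#'   X-linked rate multipliers, or a single named vector applied to both
#'   genotypes. All dosages must be positive.
#' @param n_de_genes Number of drive-biased genes (upregulated in SR).
#' @param de_log2fc Programmed log2 fold change of drive-biased genes.
#' @param de_x_fraction Fraction of drive-biased genes placed on the X.
#' @param dispersion Negative-binomial dispersion \eqn{\phi}
#'   (var = mu + phi mu^2); 0 gives Poisson counts.
#' @param libsize_logmean,libsize_logsd Meanlog/sdlog of the per-cell
#'   expected library size before the stage-activity multiplier.
#' @param mito_fraction_beta Length-2 vector of Beta shape parameters for
#'   the per-cell mitochondrial expression proportion.
#' @param doublet_rate Fraction of reported cells that are doublets
#'   (two cells' counts summed); default 0.
#' @param testis_specific_fraction Fraction of genes tagged
#'   `testis_specific` in the annotation (the rest are `broad`).
#'
#' @return A `sim_config` list, validated.
#' @export
sim_config <- function(seed = 1L,
                       n_samples_ST = 4L,
                       n_samples_SR = 4L,
                       cell_types = c("muscle", "cyst", "gsc_spermatogonia",
                                      "primary_spermatocytes",
                                      "secondary_spermatocytes", "spermatids"),
                       germline_types = c("gsc_spermatogonia",
                                          "primary_spermatocytes",
                                          "secondary_spermatocytes",
                                          "spermatids"),
                       cells_per_type = c(muscle = 40L, cyst = 110L,
                                          gsc_spermatogonia = 280L,
                                          primary_spermatocytes = 280L,
                                          secondary_spermatocytes = 290L,
                                          spermatids = 500L),
                       genes_per_chrom = c(chr1 = 1200L, chr2 = 1200L,
                                           chrX = 600L, MT = 10L),
                       baseline_logmean = 1,
                       baseline_logsd = 1,
                       stage_activity = c(muscle = 1, cyst = 1,
                                          gsc_spermatogonia = 1.2,
                                          primary_spermatocytes = 1,
                                          secondary_spermatocytes = 0.6,
                                          spermatids = 0.35),
                       stage_inclusion = c(muscle = 0.70, cyst = 0.70,
                                           gsc_spermatogonia = 0.95,
                                           primary_spermatocytes = 0.80,
                                           secondary_spermatocytes = 0.50,
                                           spermatids = 0.30),
                       x_dosage = c(muscle = 1, cyst = 1,
                                    gsc_spermatogonia = 0.5,
                                    primary_spermatocytes = 0.5,
                                    secondary_spermatocytes = 1,
                                    spermatids = 1),
                       n_de_genes = 50L,
                       de_log2fc = 2,
                       de_x_fraction = 0.5,
                       dispersion = 0.1,
                       libsize_logmean = log(6000),
                       libsize_logsd = 0.3,
                       mito_fraction_beta = c(2, 38),
                       doublet_rate = 0,
                       testis_specific_fraction = 0.3) {
  cfg <- list(
    seed = as.integer(seed),
    n_samples_ST = as.integer(n_samples_ST),
    n_samples_SR = as.integer(n_samples_SR),
    cell_types = cell_types,
    germline_types = germline_types,
    cells_per_type = cells_per_type,
    genes_per_chrom = genes_per_chrom,
    baseline_logmean = baseline_logmean,
    baseline_logsd = baseline_logsd,
    stage_activity = stage_activity,
    stage_inclusion = stage_inclusion,
    x_dosage = x_dosage,
    n_de_genes = as.integer(n_de_genes),
    de_log2fc = de_log2fc,
    de_x_fraction = de_x_fraction,
    dispersion = dispersion,
    libsize_logmean = libsize_logmean,
    libsize_logsd = libsize_logsd,
    mito_fraction_beta = mito_fraction_beta,
    doublet_rate = doublet_rate,
    testis_specific_fraction = testis_specific_fraction
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  ct <- cfg$cell_types
  if (length(ct) == 0 || anyDuplicated(ct)) {
    abort("cell_types must be non-empty and unique")
  }
  if (!all(cfg$germline_types %in% ct)) {
    abort("germline_types must be a subset of cell_types")
  }
  for (nm in c("cells_per_type", "stage_activity", "stage_inclusion")) {
    v <- cfg[[nm]]
    if (!all(ct %in% names(v))) abort(paste0(nm, " must name every cell type"))
  }
  if (any(cfg$cells_per_type < 0)) abort("cells_per_type must be >= 0")
  required_chrom <- c("chr1", "chr2", "chrX", "MT")
  if (!all(required_chrom %in% names(cfg$genes_per_chrom)) ||
      any(cfg$genes_per_chrom[required_chrom] <= 0)) {
    abort("genes_per_chrom must be positive for chr1, chr2, chrX and MT")
  }
  if (any(cfg$stage_activity <= 0)) abort("stage_activity must be > 0")
  germ_act <- cfg$stage_activity[cfg$germline_types]
  if (is.unsorted(rev(germ_act))) {
    abort("stage_activity must decline monotonically over germline stages")
  }
  if (any(cfg$stage_inclusion <= 0 | cfg$stage_inclusion > 1)) {
    abort("stage_inclusion must lie in (0, 1]")
  }
  cfg$x_dosage <- normalize_x_dosage(cfg$x_dosage, ct)
  if (any(cfg$x_dosage$dosage <= 0)) abort("x_dosage must be > 0")
  if (cfg$dispersion < 0) abort("dispersion must be >= 0")
  if (cfg$n_samples_ST < 0 || cfg$n_samples_SR < 0) {
    abort("sample numbers must be >= 0")
  }
  if (cfg$doublet_rate < 0 || cfg$doublet_rate >= 1) {
    abort("doublet_rate must lie in [0, 1)")
  }
  cfg
}

# Accept a named per-cell-type vector (shared across genotypes) or a long
# (cell_type, genotype, dosage) data frame; always return the long form.
normalize_x_dosage <- function(x_dosage, cell_types) {
  if (is.data.frame(x_dosage)) {
    need <- c("cell_type", "genotype", "dosage")
    if (!all(need %in% names(x_dosage))) {
      abort("x_dosage data frame needs cell_type, genotype, dosage")
    }
    return(as_tibble(x_dosage[need]))
  }
  if (!all(cell_types %in% names(x_dosage))) {
    abort("x_dosage vector must name every cell type")
  }
  tidyr::expand_grid(cell_type = cell_types, genotype = c("ST", "SR")) |>
    mutate(dosage = unname(x_dosage[.data$cell_type]))
}

lookup_dosage <- function(x_dosage_tbl, cell_type, genotype) {
  hit <- x_dosage_tbl$dosage[x_dosage_tbl$cell_type == cell_type &
                               x_dosage_tbl$genotype == genotype]
  if (length(hit) != 1) abort(sprintf(
    "x_dosage must define exactly one value for (%s, %s)", cell_type, genotype
  ))
  hit
}
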