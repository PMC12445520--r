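test_that("same config and seed reproduce the identical count matrix", {
  cfg <- small_sim_config(seed = 11L)
  a <- simulate_counts(cfg)
  b <- simulate_counts(cfg)
  expect_identical(as.matrix(a$experiment$counts), as.matrix(b$experiment$counts))
  expect_identical(a$truth$de_genes, b$truth$de_genes)
  c_other <- simulate_counts(small_sim_config(seed = 12L))
  expect_false(identical(as.matrix(a$experiment$counts),
                         as.matrix(c_other$experiment$counts)))
})

test_that("column sums equal recorded library sizes; entries are nonneg integers", {
  sim <- simulate_counts(small_sim_config())
  m <- sim$experiment$counts
  expect_identical(unname(Matrix::colSums(m)), unname(sim$experiment$cell_meta$lib_size))
  expect_true(all(m@x >= 0))
  expect_true(all(m@x == round(m@x)))
})

test_that("neutral dosage and no DE give X:A mean CPM ratio near 1", {
  cfg <- flat_pool_config(seed = 3L, n_cells = 800L, dispersion = 0.05)
  sim <- simulate_counts(cfg)
  x <- sim$experiment
  chrom <- x$gene_anno$chromosome
  cpm <- sweep(as.matrix(x$counts), 2, Matrix::colSums(x$counts), "/") * 1e6
  gm <- rowMeans(cpm)
  ratio <- mean(gm[chrom == "chrX"]) / mean(gm[chrom %in% c("chr1", "chr2")])
  expect_gt(ratio, 0.85)
  expect_lt(ratio, 1.15)
})

test_that("programmed X dosage 0.5 is recovered in empirical germline means", {
  # Monte-Carlo check against the programmed NB means: with d = 0.5 in a
  # stage, mean X-gene count / mean autosomal-gene count (per active gene)
  # should sit within 5% of 0.5.
  cfg <- sim_config(
    seed = 5L, n_samples_ST = 4L, n_samples_SR = 0L,
    cell_types = "gsc_spermatogonia", germline_types = "gsc_spermatogonia",
    cells_per_type = c(gsc_spermatogonia = 2500L),
    genes_per_chrom = c(chr1 = 300L, chr2 = 300L, chrX = 300L, MT = 5L),
    stage_activity = c(gsc_spermatogonia = 1),
    stage_inclusion = c(gsc_spermatogonia = 1),
    x_dosage = c(gsc_spermatogonia = 0.5),
    n_de_genes = 0L, dispersion = 0.1, baseline_logsd = 0.5
  )
  sim <- simulate_counts(cfg)
  x <- sim$experiment
  chrom <- x$gene_anno$chromosome
  tot <- Matrix::rowSums(x$counts)
  ratio <- mean(tot[chrom == "chrX"]) / mean(tot[chrom %in% c("chr1", "chr2")])
  expect_gt(ratio, 0.5 * 0.95)
  expect_lt(ratio, 0.5 * 1.05)
})

test_that("dispersion 0 approaches the Poisson variance/mean limit", {
  cfg <- flat_pool_config(seed = 9L, n_cells = 1600L, dispersion = 0)
  sim <- simulate_counts(cfg)
  m <- as.matrix(sim$experiment$counts)
  # condition on cells of one sample (shared mean within gene up to libsize
  # spread, kept small); variance/mean across high-mean genes near 1
  libs <- colSums(m)
  mscaled <- sweep(m, 2, mean(libs) / libs, "*")
  vm <- apply(mscaled, 1, stats::var) / rowMeans(mscaled)
  vm <- vm[rowMeans(m) > 5]
  expect_lt(median(vm, na.rm = TRUE), 1.3)
})

test_that("truth tables round-trip programmed effects", {
  sim <- simulate_counts(small_sim_config(seed = 2L))
  truth <- sim$truth
  expect_equal(anyDuplicated(truth$de_genes$gene_id), 0L)
  expect_true(all(truth$de_genes$gene_id %in% sim$experiment$gene_anno$gene_id))
  expect_true(all(truth$de_genes$true_log2fc == 2))
  expect_setequal(truth$ploidy$barcode, sim$experiment$cell_meta$barcode)
  expect_setequal(unique(truth$ploidy$ploidy), c("haploid", "diploid"))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(genes_per_chrom = c(chr1 = 10, chr2 = 10, chrX = 0, MT = 2)),
               "genes_per_chrom")
  expect_error(sim_config(dispersion = -1), "dispersion")
  expect_error(sim_config(x_dosage = c(muscle = 0, cyst = 1,
                                       gsc_spermatogonia = 1,
                                       primary_spermatocytes = 1,
                                       secondary_spermatocytes = 1,
                                       spermatids = 1)),
               "x_dosage")
})

test_that("simulated allele-count sites follow the programmed model", {
  ploidy <- c(h1 = "haploid", h2 = "haploid", d1 = "diploid")
  sites <- simulate_sites(ploidy, n_sites = 200L, depth_mean = 6,
                          het_rate = 0.5, error_rate = 0, seed = 4L)
  hap <- sites[sites$barcode %in% c("h1", "h2"), ]
  expect_true(all(hap$ref_count == 0 | hap$alt_count == 0))

  # het_rate 0 makes diploids site-level indistinguishable from haploids
  s0 <- simulate_sites(c(d = "diploid"), n_sites = 100L, het_rate = 0,
                       error_rate = 0, seed = 4L)
  expect_true(all(s0$ref_count == 0 | s0$alt_count == 0))

  # het-site fraction among genotyped sites matches the analytic expectation
  # under the calling rule (2 reads each allele), computed by enumeration
  dip <- simulate_sites(setNames(rep("diploid", 60), paste0("d", 1:60)),
                        n_sites = 100L, depth_mean = 6, het_rate = 0.5,
                        error_rate = 0, seed = 8L)
  calls <- call_site(dip$ref_count, dip$alt_count)
  p_het_called <- function(depth_mean) {
    # P(site called het | het) and P(called hom | het or hom), depths Poisson
    ds <- 0:60
    pd <- dpois(ds, depth_mean)
    p_het_given_het <- sum(pd * vapply(ds, function(d) {
      if (d < 4) return(0)
      sum(dbinom(2:(d - 2), d, 0.5))
    }, numeric(1)))
    p_hom_given_het <- sum(pd * vapply(ds, function(d) {
      if (d < 2) return(0)
      dbinom(0, d, 0.5) + dbinom(d, d, 0.5)
    }, numeric(1)))
    p_hom_given_hom <- sum(pd * (ds >= 2))
    het_g <- 0.5 * p_het_given_het
    hom_g <- 0.5 * p_hom_given_het + 0.5 * p_hom_given_hom
    het_g / (het_g + hom_g)
  }
  expected <- p_het_called(6)
  observed <- mean(calls[calls != "ungenotyped"] == "heterozygous")
  expect_lt(abs(observed - expected), 0.03)
})

test_that("simulate_sites validates inputs", {
  expect_error(simulate_sites(character(0)), "empty")
  expect_error(simulate_sites(c(a = "haploid"), depth_mean = 0), "depth_mean")
  expect_error(simulate_sites(c(a = "triploid")), "ploidy")
})

test_that("coverage simulation reproduces programmed CNV ratios", {
  cov <- simulate_coverage(n_ST = 50L, n_SR = 27L, n_genes = 300L,
                           cnv_genes = c(g00010 = 2), seed = 6L)
  expect_identical(dim(cov$counts), c(300L, 77L))
  # fixed seed -> identical table
  cov2 <- simulate_coverage(n_ST = 50L, n_SR = 27L, n_genes = 300L,
                            cnv_genes = c(g00010 = 2), seed = 6L)
  expect_identical(cov$counts, cov2$counts)

  norm <- sweep(cov$counts, 2, colSums(cov$counts), "/")
  st <- cov$individuals$genotype == "ST"
  ratio <- rowMeans(norm[, !st]) / rowMeans(norm[, st])
  expect_lt(abs(ratio[10] - 2), 0.2)
  # non-CNV genes stay near ratio 1
  expect_lt(max(abs(ratio[-10] - 1)), 0.35)
  expect_error(simulate_coverage(cnv_genes = c(g00001 = -2)), "ratios")
})
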