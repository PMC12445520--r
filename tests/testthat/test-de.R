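test_that("dispersion estimation recovers Poisson and NB truths", {
  set.seed(5)
  groups <- rep(c("ST", "SR"), each = 4)
  libs <- rep(1e5, 8)

  pois <- matrix(rpois(800 * 8, lambda = rep(exp(rnorm(800, 3, 1)), 8)),
                 ncol = 8)
  d_pois <- estimate_dispersions(pois, libs, groups)
  expect_lt(d_pois$common_phi, 0.05)

  mu <- rep(exp(rnorm(2000, 4, 0.8)), 8)
  nb <- matrix(rnbinom(2000 * 8, size = 1 / 0.4, mu = mu), ncol = 8)
  d_nb <- estimate_dispersions(nb, libs, groups)
  expect_gt(d_nb$common_phi, 0.3)
  expect_lt(d_nb$common_phi, 0.5)

  # a single gene has nothing to be shrunk toward but itself
  single <- matrix(rnbinom(8, size = 5, mu = 50), nrow = 1)
  d1 <- estimate_dispersions(single, libs, groups)
  expect_equal(d1$tagwise_phi, d1$common_phi, tolerance = 1e-3)

  expect_error(estimate_dispersions(pois[, 1:3], libs[1:3],
                                    c("ST", "ST", "SR")), "2 units")
})

test_that("exact test is symmetric, two-sided, and matches enumeration at phi = 0", {
  libs <- rep(1000, 4)
  groups <- c("ST", "ST", "SR", "SR")

  # equal counts, equal libraries -> p = 1
  r <- nb_exact_test(c(5, 5, 5, 5), libs, groups, phi = 0.1)
  expect_equal(r$p_value, 1)

  # binomial enumeration oracle via log-factorials, all totals <= 30
  enum_p <- function(y, n1, n2) {
    s1 <- sum(y[seq_len(n1)]); total <- sum(y)
    pr <- n1 / (n1 + n2)
    k <- 0:total
    logp <- lchoose(total, k) + k * log(pr) + (total - k) * log(1 - pr)
    probs <- exp(logp)
    p_low <- sum(probs[k <= s1]); p_high <- sum(probs[k >= s1])
    min(1, 2 * min(p_low, p_high))
  }
  set.seed(11)
  for (i in 1:50) {
    y <- rpois(4, sample(1:7, 1))
    if (sum(y) > 30 || sum(y) == 0) next
    mine <- nb_exact_test(y, libs, groups, phi = 0)$p_value
    expect_equal(mine, enum_p(y, 2, 2), tolerance = 1e-9)
  }

  # unequal replicate numbers too
  libs5 <- rep(1000, 5)
  groups5 <- c("ST", "ST", "ST", "SR", "SR")
  for (i in 1:30) {
    y <- rpois(5, 3)
    if (sum(y) > 30 || sum(y) == 0) next
    mine <- nb_exact_test(y, libs5, groups5, phi = 0)$p_value
    expect_equal(mine, enum_p(y, 3, 2), tolerance = 1e-9)
  }

  # two-sidedness: swapping group labels preserves p, flips log2fc
  y <- c(20, 25, 3, 4)
  a <- nb_exact_test(y, libs, factor(groups, levels = c("ST", "SR")), 0.1)
  b <- nb_exact_test(y, libs, factor(groups, levels = c("SR", "ST")), 0.1)
  expect_equal(a$p_value, b$p_value)
  expect_equal(a$log2fc, -b$log2fc)

  # both groups all-zero -> p = 1, log2fc = 0
  z <- nb_exact_test(c(0, 0, 0, 0), libs, groups, 0.1)
  expect_equal(z$p_value, 1)
  expect_equal(z$log2fc, 0)

  # group means 8 vs 2 at large counts -> log2fc near 2
  big <- nb_exact_test(c(200, 200, 800, 800), rep(1e5, 4), groups, 0.01)
  expect_equal(big$log2fc, 2, tolerance = 0.01)
  expect_lt(big$p_value, 0.05)
})

test_that("exact-test p-values track an established NB implementation", {
  set.seed(21)
  n_genes <- 300
  groups <- factor(rep(c("ST", "SR"), each = 4), levels = c("ST", "SR"))
  mu <- exp(rnorm(n_genes, 4, 1))
  fc <- rep(1, n_genes); fc[1:30] <- 4
  m <- cbind(
    matrix(rnbinom(n_genes * 4, size = 10, mu = mu), ncol = 4),
    matrix(rnbinom(n_genes * 4, size = 10, mu = mu * fc), ncol = 4)
  )
  libs <- colSums(m)
  mine <- exact_test_engine <- drivescope:::exact_test_engine(m, libs, groups, 0.1)
  dg <- edgeR::DGEList(counts = m, group = groups, lib.size = libs)
  ref <- edgeR::exactTest(dg, dispersion = 0.1)$table
  expect_gt(cor(log10(mine$p_value + 1e-300), log10(ref$PValue + 1e-300)),
            0.98)
  expect_gt(cor(mine$log2fc, ref$logFC), 0.99)
})

test_that("BH adjustment equals the hand step-up and the reference", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.04)), c(0.02, 0.04))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_identical(bh_adjust(numeric(0)), numeric(0))

  # hand step-up on a fixed vector
  p <- c(0.003, 0.04, 0.02, 0.9, 0.25)
  o <- order(p)
  m <- length(p)
  stepped <- p[o] * m / seq_len(m)
  stepped <- rev(cummin(rev(stepped)))
  hand <- numeric(m); hand[o] <- pmin(stepped, 1)
  expect_equal(bh_adjust(p), hand)

  # order independence: a permuted input gives the permuted output
  set.seed(2)
  p2 <- runif(50)
  perm <- sample(50)
  expect_equal(bh_adjust(p2)[perm], bh_adjust(p2[perm]))
  expect_error(bh_adjust(c(0.1, 2)), "0, 1")
})

test_that("per-cell-type DE applies the joint significance rule and finds truth", {
  cfg <- flat_pool_config(seed = 17L, n_cells = 800L, n_de = 30L,
                          de_log2fc = 2, dispersion = 0.05)
  sim <- simulate_counts(cfg)
  de <- de_per_celltype(sim$experiment, "cyst")
  expect_true(all(de$significant == (de$fdr < 0.05 & abs(de$log2fc) > 1)))
  expect_true(all(de$direction[de$significant & de$log2fc > 0] == "SR-biased"))

  truth <- sim$truth$de_genes$gene_id
  tested_truth <- intersect(truth, de$gene_id)
  expect_gt(length(tested_truth), 15)
  power <- mean(de$significant[de$gene_id %in% tested_truth])
  expect_gt(power, 0.8)
  # and the called set is strongly enriched for truth
  fdr_obs <- mean(!(de$gene_id[de$significant] %in% truth))
  expect_lt(fdr_obs, 0.2)

  # insufficient replicates -> skipped with a warning
  keep <- sim$experiment$cell_meta$sample_id %in% c("ST01", "SR01", "SR02")
  small <- drivescope:::subset_experiment(sim$experiment, cells = keep)
  expect_warning(r <- de_per_celltype(small, "cyst"), "replicates")
  expect_null(r)
})
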