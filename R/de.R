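# Negative-binomial conditional exact test engine for pseudobulk counts.
# Counts are quantile-adjusted to a common (geometric-mean) library size;
# group sums are then compared under their conditional distribution given
# the total, with NB(mean n_g * mu, dispersion phi / n_g) group-sum laws
# (binomial in the Poisson limit phi = 0). Two-sided p doubles the smaller
# tail, capped at 1.

# NB log-likelihood valid for continuous (library-adjusted) y.
nb_loglik <- function(y, mu, phi) {
  out <- numeric(length(y))
  zero_mu <- mu <= 0
  out[zero_mu] <- ifelse(y[zero_mu] == 0, 0, -Inf)
  ok <- !zero_mu
  if (phi <= 1e-12) {
    out[ok] <- y[ok] * log(mu[ok]) - mu[ok] - lgamma(y[ok] + 1)
  } else {
    r <- 1 / phi
    out[ok] <- lgamma(y[ok] + r) - lgamma(r) - lgamma(y[ok] + 1) +
      r * log(r / (r + mu[ok])) + y[ok] * log(mu[ok] / (r + mu[ok]))
  }
  out
}

# characters become factors in order of appearance (not alphabetical), so
# c("ST", ..., "SR") keeps SR as the treatment level
as_group_factor <- function(groups) {
  if (is.factor(groups)) groups else factor(groups, levels = unique(groups))
}

adjust_common_libsize <- function(counts, lib_sizes) {
  lref <- exp(mean(log(lib_sizes)))
  sweep(counts, 2L, lref / lib_sizes, "*")
}

#' Estimate common and tagwise NB dispersions
#'
#' Common dispersion maximises the profile likelihood of the NB model with
#' group-specific means on library-adjusted counts; tagwise dispersions
#' maximise each gene's likelihood plus `prior_genes` times the average
#' per-gene likelihood (weighted-likelihood shrinkage toward the common
#' value). Dispersions are floored at ~0 for underdispersed genes.
#'
#' @param counts Genes x units matrix of nonnegative counts.
#' @param lib_sizes Per-unit library sizes.
#' @param groups Factor/character of group labels per unit (2 groups).
#' @param prior_genes Shrinkage prior weight in gene-equivalents
#'   (default 10).
#' @param tagwise Also compute tagwise dispersions (default TRUE); with
#'   FALSE the tagwise slot simply repeats the common value, which is
#'   considerably faster for repeated small-replicate fits.
#' @return A `dispersion_estimate` list: `common_phi`, `tagwise_phi`
#'   (per gene), `prior_genes`.
#' @export
estimate_dispersions <- function(counts, lib_sizes, groups, prior_genes = 10,
                                 tagwise = TRUE) {
  counts <- as.matrix(counts)
  groups <- as_group_factor(groups)
  if (any(table(groups) < 2)) abort("need >= 2 units per group")
  pseudo <- adjust_common_libsize(counts, lib_sizes)
  mu <- matrix(0, nrow(counts), ncol(counts))
  for (g in levels(groups)) {
    k <- groups == g
    mu[, k] <- rowMeans(pseudo[, k, drop = FALSE])
  }

  gene_ll <- function(phi) {
    rowSums(matrix(nb_loglik(as.vector(pseudo), as.vector(mu), phi),
                   nrow(counts)))
  }
  # profile the shared likelihood on a log grid, then refine
  grid <- 10^seq(-6, 1, length.out = 36)
  ll_grid <- vapply(grid, function(phi) sum(gene_ll(phi)), numeric(1))
  i0 <- which.max(ll_grid)
  lo <- grid[max(1, i0 - 1)]; hi <- grid[min(length(grid), i0 + 1)]
  common <- optimize(function(lp) sum(gene_ll(exp(lp))),
                     interval = log(c(lo, hi)), maximum = TRUE)
  common_phi <- exp(common$maximum)
  if (common_phi < 2e-6) common_phi <- 0

  if (!tagwise) {
    return(structure(list(common_phi = common_phi,
                          tagwise_phi = rep(common_phi, nrow(counts)),
                          prior_genes = prior_genes),
                     class = "dispersion_estimate"))
  }
  ll_gene_grid <- vapply(grid, gene_ll, numeric(nrow(counts)))
  if (nrow(counts) == 1) ll_gene_grid <- matrix(ll_gene_grid, nrow = 1)
  mean_ll_grid <- colMeans(ll_gene_grid)
  mean_ll_fun <- stats::splinefun(log(grid), mean_ll_grid)
  tagwise <- vapply(seq_len(nrow(counts)), function(j) {
    obj <- ll_gene_grid[j, ] + prior_genes * mean_ll_grid
    i0 <- which.max(obj)
    lo <- grid[max(1, i0 - 1)]; hi <- grid[min(length(grid), i0 + 1)]
    yj <- pseudo[j, ]; mj <- mu[j, ]
    opt <- optimize(function(lp) {
      sum(nb_loglik(yj, mj, exp(lp))) + prior_genes * mean_ll_fun(lp)
    }, interval = log(c(lo, hi)), maximum = TRUE)
    phi <- exp(opt$maximum)
    if (phi < 2e-6) 0 else phi
  }, numeric(1))

  structure(list(common_phi = common_phi, tagwise_phi = tagwise,
                 prior_genes = prior_genes),
            class = "dispersion_estimate")
}

#' NB conditional exact test for one gene
#'
#' @param y Per-unit counts for one gene.
#' @param lib_sizes Per-unit library sizes.
#' @param groups Two-level factor (the second level is the "treatment";
#'   log2 fold changes are level2 vs level1). A character vector is taken
#'   in order of appearance, so the later-appearing group is the
#'   treatment.
#' @param phi NB dispersion (0 gives the Poisson/binomial conditional).
#' @param prior_count Offset added to adjusted group means for the fold
#'   change (default 0.5).
#' @return Tibble: `log2fc`, `p_value`.
#' @export
nb_exact_test <- function(y, lib_sizes, groups, phi, prior_count = 0.5) {
  groups <- as_group_factor(groups)
  stopifnot(nlevels(groups) == 2, all(y >= 0))
  pseudo <- as.numeric(y) * exp(mean(log(lib_sizes))) / lib_sizes
  g2 <- groups == levels(groups)[2]
  n1 <- sum(!g2); n2 <- sum(g2)
  s1 <- round(sum(pseudo[!g2])); s2 <- round(sum(pseudo[g2]))
  res <- exact_test_core(s1, s2, n1, n2, phi)
  lfc <- log2((s2 / n2 + prior_count) / (s1 / n1 + prior_count))
  if (s1 + s2 == 0) lfc <- 0
  tibble(log2fc = lfc, p_value = res)
}

# conditional two-sided exact p for group sums s1, s2 from n1, n2 units
exact_test_core <- function(s1, s2, n1, n2, phi) {
  total <- s1 + s2
  if (total == 0) return(1)
  if (phi <= 1e-12) {
    pr <- n1 / (n1 + n2)
    p_low <- stats::pbinom(s1, total, pr)
    p_high <- 1 - stats::pbinom(s1 - 1, total, pr)
  } else {
    mu <- total / (n1 + n2)
    r1 <- n1 / phi; r2 <- n2 / phi
    # support window with < ~1e-14 conditional mass outside, so huge
    # totals cost O(window), not O(total)
    lo <- max(0, min(stats::qnbinom(1e-15, size = r1, mu = n1 * mu),
                     total - stats::qnbinom(1e-15, size = r2, mu = n2 * mu,
                                            lower.tail = FALSE)) - 2)
    hi <- min(total, max(stats::qnbinom(1e-15, size = r1, mu = n1 * mu,
                                        lower.tail = FALSE),
                         total - stats::qnbinom(1e-15, size = r2,
                                                mu = n2 * mu)) + 2)
    lo <- min(lo, s1); hi <- max(hi, s1)
    ys <- lo:hi
    logf <- dnbinom(ys, size = r1, mu = n1 * mu, log = TRUE) +
      dnbinom(total - ys, size = r2, mu = n2 * mu, log = TRUE)
    logf <- logf - max(logf)
    f <- exp(logf); f <- f / sum(f)
    p_low <- sum(f[ys <= s1])
    p_high <- sum(f[ys >= s1])
  }
  min(1, 2 * min(p_low, p_high))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' @param p Vector of p-values in \[0, 1\].
#' @return Step-up adjusted FDR values (empty input gives empty output).
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

# Vectorised engine over a filtered genes x units count matrix.
exact_test_engine <- function(counts, lib_sizes, groups, phi,
                              prior_count = 0.5) {
  counts <- as.matrix(counts)
  groups <- as_group_factor(groups)
  g2 <- groups == levels(groups)[2]
  n1 <- sum(!g2); n2 <- sum(g2)
  pseudo <- adjust_common_libsize(counts, lib_sizes)
  s1 <- round(rowSums(pseudo[, !g2, drop = FALSE]))
  s2 <- round(rowSums(pseudo[, g2, drop = FALSE]))
  if (length(phi) == 1) phi <- rep(phi, nrow(counts))
  p <- vapply(seq_len(nrow(counts)), function(j) {
    exact_test_core(s1[j], s2[j], n1, n2, phi[j])
  }, numeric(1))
  lfc <- log2((s2 / n2 + prior_count) / (s1 / n1 + prior_count))
  lfc[s1 + s2 == 0] <- 0
  tibble(log2fc = lfc, p_value = p)
}

#' Pseudobulk differential expression for one cell type
#'
#' SR-vs-ST differential expression on pseudobulk counts of one cell type:
#' genes pre-filtered with [dosage_gene_filter()], NB dispersion estimated
#' (tagwise shrinkage by default), conditional exact test per gene, BH-FDR
#' within the cell type, and the joint significance rule
#' |log2FC| > `lfc_cutoff` and FDR < `fdr_cutoff`.
#'
#' @param x A [counts_experiment()] (post-QC).
#' @param cell_type Cell type to test.
#' @param p Optional pre-computed normalised `pseudobulk` of `x`.
#' @param lfc_cutoff,fdr_cutoff Significance thresholds (defaults 1, 0.05).
#' @param dispersion `"tagwise"` (default) or `"common"`.
#' @param min_cell_frac,min_log2cpm Pre-filter parameters.
#' @param prior_genes Dispersion shrinkage weight.
#' @return Tibble: `gene_id`, `chromosome`, `cell_type`, `log2fc`
#'   (SR vs ST), `p_value`, `fdr`, `significant`, `direction`
#'   (`SR-biased` / `ST-biased` / `unbiased`). `NULL` (with a warning)
#'   when either genotype has fewer than 2 units.
#' @export
de_per_celltype <- function(x, cell_type, p = NULL, lfc_cutoff = 1,
                            fdr_cutoff = 0.05,
                            dispersion = c("tagwise", "common"),
                            min_cell_frac = 0.05, min_log2cpm = 2,
                            prior_genes = 10) {
  dispersion <- match.arg(dispersion)
  if (is.null(p)) p <- normalize_libsizes(aggregate_pseudobulk(x))
  ui <- which(p$units$cell_type == cell_type)
  geno <- factor(p$units$genotype[ui], levels = c("ST", "SR"))
  if (sum(geno == "ST") < 2 || sum(geno == "SR") < 2) {
    warn(sprintf("cell type '%s' skipped: < 2 replicates per genotype",
                 cell_type))
    return(NULL)
  }
  genes <- dosage_gene_filter(x, p, cell_type, min_cell_frac, min_log2cpm)
  if (length(genes) == 0) {
    warn(sprintf("cell type '%s': no genes pass the filters", cell_type))
    return(NULL)
  }
  gi <- match(genes, rownames(p$counts))
  counts <- p$counts[gi, ui, drop = FALSE]
  libs <- p$units$lib_size[ui] * p$units$norm_factor[ui]
  disp <- estimate_dispersions(counts, libs, geno, prior_genes)
  phi <- if (dispersion == "tagwise") disp$tagwise_phi else disp$common_phi
  res <- exact_test_engine(counts, libs, geno, phi)
  res$fdr <- bh_adjust(res$p_value)
  tibble(
    gene_id = genes,
    chromosome = p$gene_anno$chromosome[gi],
    cell_type = cell_type,
    log2fc = res$log2fc,
    p_value = res$p_value,
    fdr = res$fdr,
    significant = res$fdr < fdr_cutoff & abs(res$log2fc) > lfc_cutoff
  ) |>
    mutate(direction = dplyr::case_when(
      .data$significant & .data$log2fc > 0 ~ "SR-biased",
      .data$significant & .data$log2fc < 0 ~ "ST-biased",
      TRUE ~ "unbiased"
    ))
}

#' Pseudobulk differential expression across cell types
#'
#' Runs [de_per_celltype()] for every requested cell type and binds the
#' results (FDR is computed within cell type).
#'
#' @inheritParams de_per_celltype
#' @param cell_types Cell types to test (default: all with enough
#'   replicates).
#' @return Tibble of per-gene per-cell-type results.
#' @export
de_analysis <- function(x, cell_types = NULL, ...) {
  p <- normalize_libsizes(aggregate_pseudobulk(x))
  cell_types <- cell_types %||% unique(p$units$cell_type)
  purrr::map_dfr(cell_types, function(ct) {
    de_per_celltype(x, ct, p = p, ...) %||% tibble()
  })
}
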