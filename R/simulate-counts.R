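#' Simulate a testis single-cell count matrix with known truth
#'
#' Draws a genes-by-cells negative-binomial count matrix under the
#' generative model described in [sim_config()]. For a cell of type t and
#' genotype g, the count at gene j is NB with mean
#' \eqn{L_c w_{t,g,j} / \sum_k w_{t,g,k}} and dispersion \eqn{\phi}, where
#' \eqn{w = \lambda_j \pi_{t,j} d_{t,g}^{[j on X]} 2^{\beta [j drive-biased, g = SR]}}.
#' The expected library size \eqn{L_c} is log-normal scaled by the cell
#' type's `stage_activity`, and mitochondrial genes receive an expected
#' share drawn from the configured Beta distribution. The same seed always
#' reproduces the identical matrix.
#'
#' @param config A [sim_config()].
#' @return A list with elements `experiment` (a [counts_experiment()]) and
#'   `truth`, itself a list of tibbles: `de_genes` (gene_id, true_log2fc),
#'   `x_dosage` (cell_type, genotype, dosage as realised), `ploidy`
#'   (barcode, ploidy), `active_genes` (cell_type, gene_id), and `doublets`
#'   (barcodes of synthetic doublets, empty at the default doublet rate 0).
#' @export
simulate_counts <- function(config = sim_config()) {
  cfg <- validate_sim_config(config)
  with_substream(cfg$seed, "counts", {
    anno <- simulate_gene_annotation(cfg)
    genes <- anno$gene_id
    n_genes <- length(genes)
    lambda <- rlnorm(n_genes, cfg$baseline_logmean, cfg$baseline_logsd)
    names(lambda) <- genes
    mt <- is_mt_chrom(anno$chromosome)

    # drive-biased genes: upregulated in SR, split X vs autosome
    n_de <- min(cfg$n_de_genes, sum(!mt))
    n_de_x <- round(n_de * cfg$de_x_fraction)
    x_pool <- genes[is_x_chrom(anno$chromosome)]
    a_pool <- genes[is_autosome(anno$chromosome)]
    de_genes <- c(
      sample(x_pool, min(n_de_x, length(x_pool))),
      sample(a_pool, min(n_de - min(n_de_x, length(x_pool)), length(a_pool)))
    )
    de_tbl <- tibble(gene_id = de_genes, true_log2fc = cfg$de_log2fc)

    # per-stage active gene sets (shared by all cells of a type); MT always on
    active <- lapply(cfg$cell_types, function(ct) {
      on <- runif(n_genes) < cfg$stage_inclusion[[ct]]
      on[mt] <- TRUE
      on
    })
    names(active) <- cfg$cell_types

    samples <- tibble(
      sample_id = c(
        sprintf("ST%02d", seq_len(cfg$n_samples_ST)),
        sprintf("SR%02d", seq_len(cfg$n_samples_SR))
      ),
      genotype = rep(c("ST", "SR"), c(cfg$n_samples_ST, cfg$n_samples_SR))
    )

    blocks <- list(); metas <- list()
    for (si in seq_len(nrow(samples))) {
      sid <- samples$sample_id[si]; geno <- samples$genotype[si]
      for (ct in cfg$cell_types) {
        n_cells <- cfg$cells_per_type[[ct]]
        if (n_cells == 0) next
        d <- lookup_dosage(cfg$x_dosage, ct, geno)
        w <- lambda * active[[ct]]
        w[is_x_chrom(anno$chromosome)] <- w[is_x_chrom(anno$chromosome)] * d
        if (geno == "SR" && nrow(de_tbl) > 0) {
          idx <- match(de_tbl$gene_id, genes)
          w[idx] <- w[idx] * 2^de_tbl$true_log2fc
        }
        w_nuc <- w; w_nuc[mt] <- 0
        w_mt <- w * mt
        if (sum(w_nuc) == 0) abort("no active nuclear genes in a cell type")

        L <- rlnorm(n_cells, cfg$libsize_logmean, cfg$libsize_logsd) *
          cfg$stage_activity[[ct]]
        m <- rbeta(n_cells, cfg$mito_fraction_beta[1], cfg$mito_fraction_beta[2])
        mu <- outer(w_nuc / sum(w_nuc), L * (1 - m)) +
          outer(w_mt / sum(w_mt), L * m)
        y <- if (cfg$dispersion > 0) {
          rnbinom(length(mu), size = 1 / cfg$dispersion, mu = as.vector(mu))
        } else {
          rpois(length(mu), as.vector(mu))
        }
        block <- matrix(y, nrow = n_genes)
        blocks[[length(blocks) + 1L]] <- methods::as(Matrix::Matrix(
          block, sparse = TRUE), "CsparseMatrix")
        metas[[length(metas) + 1L]] <- tibble(
          barcode = sprintf("%s_%s_c%04d", sid, ct, seq_len(n_cells)),
          sample_id = sid, genotype = geno, cell_type = ct
        )
      }
    }
    counts <- do.call(cbind, blocks)
    meta <- bind_rows(metas)
    colnames(counts) <- meta$barcode
    rownames(counts) <- genes

    doublet_barcodes <- character(0)
    if (cfg$doublet_rate > 0) {
      n_dbl <- floor(cfg$doublet_rate * ncol(counts) / 2)
      if (n_dbl > 0) {
        pick <- matrix(sample(ncol(counts), 2 * n_dbl), ncol = 2)
        dbl <- counts[, pick[, 1], drop = FALSE] +
          counts[, pick[, 2], drop = FALSE]
        doublet_barcodes <- sprintf("doublet_%04d", seq_len(n_dbl))
        colnames(dbl) <- doublet_barcodes
        dbl_meta <- meta[pick[, 1], ]
        dbl_meta$barcode <- doublet_barcodes
        counts <- cbind(counts, dbl)
        meta <- bind_rows(meta, dbl_meta)
      }
    }

    experiment <- counts_experiment(counts, meta, anno)
    haploid_types <- c("secondary_spermatocytes", "spermatids")
    truth <- list(
      de_genes = de_tbl,
      x_dosage = cfg$x_dosage,
      ploidy = tibble(
        barcode = meta$barcode,
        ploidy = ifelse(meta$cell_type %in% haploid_types, "haploid", "diploid")
      ),
      active_genes = purrr::map_dfr(cfg$cell_types, function(ct) {
        tibble(cell_type = ct, gene_id = genes[active[[ct]]])
      }),
      doublets = tibble(barcode = doublet_barcodes)
    )
    list(experiment = experiment, truth = truth)
  })
}

simulate_gene_annotation <- function(cfg) {
  with_substream(cfg$seed, "annotation", {
    chrom <- rep(names(cfg$genes_per_chrom), cfg$genes_per_chrom)
    anno <- tibble(
      gene_id = sprintf("g%05d", seq_along(chrom)),
      chromosome = chrom
    )
    anno$class <- ifelse(
      is_mt_chrom(anno$chromosome), "unclassified",
      ifelse(runif(nrow(anno)) < cfg$testis_specific_fraction,
             "testis_specific", "broad")
    )
    anno
  })
}

#' Simulate per-cell allele counts at polymorphic sites
#'
#' Emulates the allele-count tables used for haploid/diploid classification.
#' Each cell is genotyped at `n_sites` sites; per site, read depth is
#' Poisson(`depth_mean`). A haploid cell carries one allele per site, with
#' reads assigned to the other allele at `error_rate`. A diploid cell is
#' heterozygous at a site with probability `het_rate`; reads at a
#' heterozygous site split Binomial(depth, 1/2) between alleles, and
#' homozygous sites behave as in haploid cells.
#'
#' @param ploidy Named character vector (or tibble with `barcode`,
#'   `ploidy`) giving `"haploid"` or `"diploid"` per cell.
#' @param n_sites Sites genotyped per cell.
#' @param depth_mean Mean read depth per site (> 0).
#' @param het_rate Per-site heterozygosity probability of diploid cells.
#' @param error_rate Per-read probability of reporting the wrong allele.
#' @param seed RNG seed (named sub-stream `"sites"`).
#' @return Tibble: `barcode`, `site_id`, `ref_count`, `alt_count`.
#' @export
simulate_sites <- function(ploidy, n_sites = 50L, depth_mean = 6,
                           het_rate = 0.5, error_rate = 0, seed = 1L) {
  if (is.data.frame(ploidy)) {
    ploidy <- setNames(ploidy$ploidy, ploidy$barcode)
  }
  if (length(ploidy) == 0) abort("ploidy map is empty")
  if (depth_mean <= 0) abort("depth_mean must be > 0")
  if (het_rate < 0 || het_rate > 1 || error_rate < 0 || error_rate > 1) {
    abort("het_rate and error_rate must lie in [0, 1]")
  }
  if (!all(ploidy %in% c("haploid", "diploid"))) {
    abort("ploidy values must be 'haploid' or 'diploid'")
  }
  with_substream(seed, "sites", {
    purrr::map_dfr(names(ploidy), function(bc) {
      depth <- rpois(n_sites, depth_mean)
      het <- if (ploidy[[bc]] == "diploid") {
        runif(n_sites) < het_rate
      } else {
        rep(FALSE, n_sites)
      }
      true_ref <- runif(n_sites) < 0.5
      ref <- integer(n_sites); alt <- integer(n_sites)
      # homozygous sites: all reads from the carried allele, minus errors
      hom <- !het
      err <- rbinom(n_sites, depth, error_rate)
      ref[hom & true_ref] <- depth[hom & true_ref] - err[hom & true_ref]
      alt[hom & true_ref] <- err[hom & true_ref]
      alt[hom & !true_ref] <- depth[hom & !true_ref] - err[hom & !true_ref]
      ref[hom & !true_ref] <- err[hom & !true_ref]
      if (any(het)) {
        ref[het] <- rbinom(sum(het), depth[het], 0.5)
        alt[het] <- depth[het] - ref[het]
      }
      tibble(
        barcode = bc, site_id = sprintf("s%04d", seq_len(n_sites)),
        ref_count = ref, alt_count = alt
      )
    })
  })
}

#' Simulate per-individual DNA read counts per gene
#'
#' Emulates a genome-resequencing coverage table: negative-binomial read
#' counts per gene and individual, with per-individual depth factors and a
#' configurable set of copy-number-variant genes whose rate is scaled in
#' drive (SR) individuals.
#'
#' @param n_ST,n_SR Individuals per genotype.
#' @param n_genes Number of genes.
#' @param cnv_genes Named numeric vector: gene index or id -> coverage
#'   ratio (> 0) applied in SR individuals. Empty by default.
#' @param depth_mean Expected reads per gene per individual.
#' @param depth_dispersion NB dispersion of the per-gene counts.
#' @param gene_logsd Spread (sdlog) of relative per-gene rates.
#' @param indiv_logsd Spread (sdlog) of per-individual depth factors.
#' @param seed RNG seed (named sub-stream `"coverage"`).
#' @return A list of class `coverage_table`: `counts` (genes x individuals
#'   integer matrix), `individuals` (tibble: individual_id, genotype),
#'   `truth` (tibble: gene_id, cnv_ratio).
#' @export
simulate_coverage <- function(n_ST = 50L, n_SR = 27L, n_genes = 1000L,
                              cnv_genes = numeric(0), depth_mean = 100,
                              depth_dispersion = 0.05, gene_logsd = 0.5,
                              indiv_logsd = 0.1, seed = 1L) {
  if (length(cnv_genes) > 0 && any(cnv_genes <= 0)) {
    abort("cnv gene ratios must be > 0")
  }
  with_substream(seed, "coverage", {
    genes <- sprintf("g%05d", seq_len(n_genes))
    indiv <- tibble(
      individual_id = c(sprintf("ST_i%03d", seq_len(n_ST)),
                        sprintf("SR_i%03d", seq_len(n_SR))),
      genotype = rep(c("ST", "SR"), c(n_ST, n_SR))
    )
    rate <- rlnorm(n_genes, 0, gene_logsd)
    depth_factor <- rlnorm(nrow(indiv), 0, indiv_logsd)
    cnv_idx <- if (is.character(names(cnv_genes)) &&
                   !is.null(names(cnv_genes)) && all(nzchar(names(cnv_genes)))) {
      match(names(cnv_genes), genes)
    } else {
      as.integer(names(cnv_genes) %||% seq_along(cnv_genes))
    }
    if (length(cnv_genes) > 0 && anyNA(cnv_idx)) {
      abort("cnv_genes names must match simulated gene ids or indices")
    }
    mu <- outer(rate * depth_mean, depth_factor)
    if (length(cnv_genes) > 0) {
      sr_cols <- which(indiv$genotype == "SR")
      mu[cnv_idx, sr_cols] <- mu[cnv_idx, sr_cols] * cnv_genes
    }
    counts <- matrix(
      rnbinom(length(mu), size = 1 / depth_dispersion, mu = as.vector(mu)),
      nrow = n_genes, dimnames = list(genes, indiv$individual_id)
    )
    truth <- tibble(gene_id = genes, cnv_ratio = 1)
    truth$cnv_ratio[cnv_idx] <- unname(cnv_genes)
    structure(
      list(counts = counts, individuals = indiv, truth = truth),
      class = "coverage_table"
    )
  })
}
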