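#' Chromosomal enrichment of differentially expressed genes
#'
#' Fits the binomial GLM `significant ~ chromosome * cell_type` over genes
#' and compares nested models by likelihood-ratio chi-square: first the
#' interaction (full vs additive), then the chromosome main effect
#' (additive vs cell-type-only). Complete separation is detected and
#' reported; a Jeffreys-prior (Firth) penalised fit is available.
#'
#' @param de Tibble of per-gene DE calls with columns `significant`
#'   (logical), `chromosome`, `cell_type` (e.g. from [de_analysis()]).
#' @param firth Use the Firth-penalised fit (default FALSE; switched on
#'   automatically only in the returned `separation` flag, never silently).
#' @return An `enrichment_fit` list: `fit` (the glm), `coefficients`
#'   tibble, `lrt` tibble (term, chi2, df, p_value), `separation` flag.
#' @export
fit_enrichment_glm <- function(de, firth = FALSE) {
  de <- as_tibble(de)
  need <- c("significant", "chromosome", "cell_type")
  if (!all(need %in% names(de))) abort("de needs significant, chromosome, cell_type")
  de$chromosome <- factor(de$chromosome)
  de$cell_type <- factor(de$cell_type)
  if (nlevels(de$chromosome) < 2) abort("need >= 2 chromosome classes")

  one_ct <- nlevels(de$cell_type) < 2
  f_full <- if (one_ct) significant ~ chromosome else
    significant ~ chromosome * cell_type
  f_add <- if (one_ct) significant ~ chromosome else
    significant ~ chromosome + cell_type
  f_noc <- if (one_ct) significant ~ 1 else significant ~ cell_type

  fitter <- if (firth) firth_glm else function(f, data) {
    glm(f, family = binomial(), data = data)
  }
  full <- fitter(f_full, de)
  add <- fitter(f_add, de)
  noc <- fitter(f_noc, de)

  sep <- any(fitted(full) > 1 - 1e-8) || any(fitted(full) < 1e-8) ||
    any(abs(coef(full)) > 15, na.rm = TRUE)
  if (sep && !firth) {
    warn("possible complete separation; consider firth = TRUE")
  }

  lrt_row <- function(small, big, term) {
    chi2 <- stats::deviance(small) - stats::deviance(big)
    df <- small$df.residual - big$df.residual
    tibble(term = term, chi2 = chi2, df = df,
           p_value = pchisq(chi2, df, lower.tail = FALSE))
  }
  lrt <- bind_rows(
    if (!one_ct) lrt_row(add, full, "chromosome:cell_type"),
    lrt_row(noc, add, "chromosome")
  )
  structure(list(
    fit = full,
    coefficients = tibble(term = names(coef(full)),
                          estimate = unname(coef(full)),
                          std_error = sqrt(diag(vcov(full)))),
    lrt = lrt, separation = sep, firth = firth
  ), class = "enrichment_fit")
}

# Firth-penalised logistic regression (Jeffreys prior) via modified IRLS.
firth_glm <- function(formula, data) {
  mf <- stats::model.frame(formula, data)
  y <- as.numeric(stats::model.response(mf))
  X <- stats::model.matrix(formula, mf)
  beta <- rep(0, ncol(X))
  for (iter in 1:200) {
    eta <- drop(X %*% beta)
    p <- stats::plogis(eta)
    w <- p * (1 - p)
    WX <- X * w
    XtWX <- crossprod(X, WX)
    H <- WX %*% solve(XtWX, t(X))          # hat matrix * W
    h <- diag(H)
    U <- crossprod(X, y - p + h * (0.5 - p))
    step <- solve(XtWX, U)
    beta <- beta + step
    if (max(abs(step)) < 1e-8) break
  }
  eta <- drop(X %*% beta)
  p <- stats::plogis(eta)
  dev <- -2 * sum(y * log(p) + (1 - y) * log(1 - p))
  structure(list(
    coefficients = setNames(drop(beta), colnames(X)),
    fitted.values = p, deviance = dev,
    df.residual = length(y) - ncol(X),
    vcov = solve(crossprod(X, X * (p * (1 - p))))
  ), class = c("firth_glm"))
}

#' @export
deviance.firth_glm <- function(object, ...) object$deviance
#' @export
fitted.firth_glm <- function(object, ...) object$fitted.values
#' @export
coef.firth_glm <- function(object, ...) object$coefficients
#' @export
vcov.firth_glm <- function(object, ...) object$vcov

#' @export
print.enrichment_fit <- function(x, ...) {
  cat("<enrichment_fit>", if (x$separation) "(separation detected)", "\n")
  print(x$lrt)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.enrichment_fit <- function(x, ...) x$coefficients

#' @exportS3Method generics::glance
glance.enrichment_fit <- function(x, ...) {
  tibble(
    lrt_interaction_p = x$lrt$p_value[match("chromosome:cell_type", x$lrt$term)],
    lrt_chromosome_p = x$lrt$p_value[match("chromosome", x$lrt$term)],
    separation = x$separation
  )
}

#' Pseudo-replicate resampling null for X-enrichment of DE genes
#'
#' Calibrates the percent of differentially expressed genes expected from
#' cell-sampling noise alone. Per repeat, two groups of `n_pseudo`
#' pseudo-samples of `cells_per` cells are drawn with replacement — both
#' from the ST pool (`pool_b = NULL`, the ST-vs-ST null) or one from each
#' pool (ST-vs-SR) — aggregated to pseudobulk, filtered and tested with
#' the exact-test engine, and the percent of filtered genes called
#' significant is recorded separately for X-linked and autosomal genes.
#'
#' @param pool_a A [counts_experiment()] holding the first cell pool
#'   (e.g. all ST cells).
#' @param pool_b Optional second pool (e.g. all SR cells); `NULL` draws
#'   both groups from `pool_a`.
#' @param n_pseudo Pseudo-samples per group (default 4).
#' @param cells_per Cells per pseudo-sample (default 100).
#' @param repeats Number of repeats (default 1000).
#' @param seed RNG seed (sub-stream `"pseudo_null"`).
#' @param stratify_by_sample Draw cells within original samples instead of
#'   from the pooled cells (default FALSE, the pooled design).
#' @param lfc_cutoff,fdr_cutoff Significance thresholds.
#' @param min_cell_frac,min_log2cpm Per-repeat gene filters.
#' @return A `resampling_null` list: `percents` tibble (repeat, chromosome
#'   class, percent DE), `design` ("within-pool" or "between-pools"),
#'   and the call parameters.
#' @export
pseudo_replicate_null <- function(pool_a, pool_b = NULL, n_pseudo = 4L,
                                  cells_per = 100L, repeats = 1000L,
                                  seed = 1L, stratify_by_sample = FALSE,
                                  lfc_cutoff = 1, fdr_cutoff = 0.05,
                                  min_cell_frac = 0.05, min_log2cpm = 2) {
  stopifnot(inherits(pool_a, "counts_experiment"))
  design <- if (is.null(pool_b)) "within-pool" else "between-pools"
  if (ncol(pool_a$counts) < cells_per ||
      (!is.null(pool_b) && ncol(pool_b$counts) < cells_per)) {
    abort("cell pool smaller than cells_per")
  }
  ca <- pool_a$counts
  cb <- if (is.null(pool_b)) ca else pool_b$counts
  chrom <- pool_a$gene_anno$chromosome
  sample_a <- pool_a$cell_meta$sample_id
  sample_b <- if (is.null(pool_b)) sample_a else pool_b$cell_meta$sample_id

  draw_pseudo <- function(m, samples) {
    sapply(seq_len(n_pseudo), function(i) {
      idx <- if (stratify_by_sample) {
        sid <- sample(unique(samples), 1)
        sample(which(samples == sid), cells_per, replace = TRUE)
      } else {
        sample(ncol(m), cells_per, replace = TRUE)
      }
      Matrix::rowSums(m[, idx, drop = FALSE])
    })
  }

  # the 5%-of-cells rule is a property of the pool, not of a repeat
  cells_expr_a <- Matrix::rowSums(ca >= 2) / ncol(ca)
  percents <- with_substream(seed, "pseudo_null", {
    purrr::map_dfr(seq_len(repeats), function(rep_i) {
      counts <- cbind(draw_pseudo(ca, sample_a), draw_pseudo(cb, sample_b))
      groups <- factor(rep(c("A", "B"), each = n_pseudo),
                       levels = c("A", "B"))
      libs <- colSums(counts)
      cpm <- cpm_from_counts(counts, libs)
      pass_grp <- function(k) {
        rowSums(log2(cpm[, k, drop = FALSE]) > min_log2cpm) > sum(k) / 2
      }
      keep <- cells_expr_a >= min_cell_frac &
        (pass_grp(groups == "A") | pass_grp(groups == "B"))
      if (!any(keep)) return(tibble())
      kc <- counts[keep, , drop = FALSE]
      disp <- estimate_dispersions(kc, libs, groups, tagwise = FALSE)
      res <- exact_test_engine(kc, libs, groups, disp$common_phi)
      sig <- bh_adjust(res$p_value) < fdr_cutoff & abs(res$log2fc) > lfc_cutoff
      kchrom <- chrom[keep]
      pct <- function(cls) if (any(cls)) 100 * mean(sig[cls]) else NA_real_
      tibble(
        repeat_id = rep_i,
        chrom_class = c("X", "autosome"),
        percent_de = c(pct(is_x_chrom(kchrom)), pct(is_autosome(kchrom)))
      )
    })
  })
  structure(list(
    percents = percents, design = design, n_pseudo = n_pseudo,
    cells_per = cells_per, repeats = repeats, seed = seed
  ), class = "resampling_null")
}

#' @export
print.resampling_null <- function(x, ...) {
  cat(sprintf("<resampling_null> %s, %d repeats\n", x$design, x$repeats))
  print(x$percents |>
          group_by(.data$chrom_class) |>
          summarise(median_percent = stats::median(.data$percent_de),
                    q95 = quantile(.data$percent_de, 0.95),
                    .groups = "drop"))
  invisible(x)
}

#' Compare a null and an observed resampling distribution
#'
#' Two-sided rank-sum test of the percent-DE distributions (per chromosome
#' class) of two resampling runs, e.g. ST-vs-ST against ST-vs-SR.
#'
#' @param null_run,obs_run `resampling_null` objects.
#' @return Tibble: `chrom_class`, `p_value`, medians of both runs.
#' @export
compare_resampling_runs <- function(null_run, obs_run) {
  stopifnot(inherits(null_run, "resampling_null"),
            inherits(obs_run, "resampling_null"))
  purrr::map_dfr(c("X", "autosome"), function(cc) {
    a <- null_run$percents$percent_de[null_run$percents$chrom_class == cc]
    b <- obs_run$percents$percent_de[obs_run$percents$chrom_class == cc]
    p <- if (length(unique(c(a, b))) == 1) 1 else
      suppressWarnings(wilcox.test(a, b))$p.value
    tibble(chrom_class = cc, p_value = p,
           median_null = stats::median(a), median_obs = stats::median(b))
  })
}
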