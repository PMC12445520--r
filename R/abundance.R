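#' Build a binary cell-type contrast
#'
#' Maps cell-type labels onto the two classes of an abundance contrast and
#' returns the per-cell binary outcome (1 = first class). Cells whose type
#' belongs to neither class are dropped.
#'
#' Default class compositions: `germline_vs_cyst` compares all germline
#' stages against cyst cells; `early_vs_late_cyst` compares `early_cyst`
#' with `late_cyst` (only meaningful when the annotation distinguishes
#' them); `premeiotic_vs_postmeiotic` compares GSC/spermatogonia plus
#' primary spermatocytes against spermatids, with secondary spermatocytes
#' (meiotically active) excluded by default.
#'
#' @param cells Tibble with `cell_type` (and typically `sample_id`,
#'   `genotype`) per cell, e.g. [cell_meta()].
#' @param contrast One of `"germline_vs_cyst"`, `"early_vs_late_cyst"`,
#'   `"premeiotic_vs_postmeiotic"`, or a list
#'   `list(class1 = c(...), class2 = c(...))` of cell types.
#' @param germline_types Germline stages in developmental order (used by
#'   the built-in contrasts).
#' @return The input rows restricted to mapped cells, with an `outcome`
#'   column (1/0) and an attribute `mapping` recording both classes.
#' @export
build_contrast <- function(cells,
                           contrast = c("germline_vs_cyst",
                                        "early_vs_late_cyst",
                                        "premeiotic_vs_postmeiotic"),
                           germline_types = c("gsc_spermatogonia",
                                              "primary_spermatocytes",
                                              "secondary_spermatocytes",
                                              "spermatids")) {
  cells <- as_tibble(cells)
  if (is.list(contrast) && !is.character(contrast)) {
    mapping <- contrast
    if (!all(c("class1", "class2") %in% names(mapping))) {
      abort("a custom contrast must be list(class1 = ..., class2 = ...)")
    }
  } else {
    contrast <- match.arg(contrast)
    mapping <- switch(contrast,
      germline_vs_cyst = list(class1 = germline_types, class2 = "cyst"),
      early_vs_late_cyst = list(class1 = "early_cyst", class2 = "late_cyst"),
      premeiotic_vs_postmeiotic = list(
        class1 = c("gsc_spermatogonia", "primary_spermatocytes"),
        class2 = "spermatids"
      )
    )
  }
  keep <- cells$cell_type %in% c(mapping$class1, mapping$class2)
  out <- cells[keep, ]
  out$outcome <- as.integer(out$cell_type %in% mapping$class1)
  for (cl in c("class1", "class2")) {
    if (!any(out$cell_type %in% mapping[[cl]])) {
      abort(sprintf("contrast class '%s' (%s) has no cells", cl,
                    paste(mapping[[cl]], collapse = ", ")))
    }
  }
  attr(out, "mapping") <- mapping
  out
}

#' Random-intercept binomial model of cell-type abundance
#'
#' Fits `outcome ~ treatment + (1 | sample)` by Laplace-approximated
#' maximum likelihood (cells aggregated to per-sample binomial counts,
#' which is likelihood-identical to the cell-level Bernoulli fit) and
#' reports the Wald z test of the treatment log-odds. When the
#' random-intercept standard deviation is estimated at the boundary 0 the
#' model is refitted as an ordinary logistic regression and flagged.
#'
#' @param cells Tibble with `outcome` (0/1), `genotype` (treatment,
#'   `ST`/`SR`) and `sample_id` per cell — the output of
#'   [build_contrast()].
#' @param nAGQ Number of adaptive Gauss-Hermite quadrature nodes (1 =
#'   Laplace, the default; e.g. 15 for a quadrature cross-check).
#' @return An `abundance_fit` list: `beta_treatment` (log-odds, SR vs ST),
#'   `se`, `p_value` (Wald), `sigma_u`, `boundary` flag, `converged`,
#'   `n_cells`, `n_samples`, and the underlying `fit`.
#' @export
fit_binomial_glmm <- function(cells, nAGQ = 1L) {
  cells <- as_tibble(cells)
  need <- c("outcome", "genotype", "sample_id")
  if (!all(need %in% names(cells))) abort("cells needs outcome, genotype, sample_id")
  agg <- cells |>
    group_by(.data$sample_id, .data$genotype) |>
    summarise(k = sum(.data$outcome), n = n(), .groups = "drop") |>
    mutate(genotype = factor(.data$genotype, levels = c("ST", "SR")))
  if (any(table(agg$genotype) < 2)) abort("need >= 2 samples per treatment")

  # a variance estimate at exactly 0 can break the PIRLS step on tiny
  # aggregated datasets; treat that as the boundary case
  fit <- tryCatch(
    suppressMessages(lme4::glmer(
      cbind(k, n - k) ~ genotype + (1 | sample_id),
      data = agg, family = binomial(), nAGQ = nAGQ,
      control = lme4::glmerControl(check.conv.singular = "ignore")
    )),
    error = function(e) NULL
  )
  sigma_u <- if (is.null(fit)) 0 else
    sqrt(unname(lme4::VarCorr(fit)$sample_id[1]))
  boundary <- sigma_u < 1e-6
  if (boundary) {
    glmfit <- glm(cbind(k, n - k) ~ genotype, family = binomial(), data = agg)
    beta <- coef(glmfit)[["genotypeSR"]]
    se <- sqrt(diag(vcov(glmfit)))[["genotypeSR"]]
    used <- glmfit
  } else {
    beta <- lme4::fixef(fit)[["genotypeSR"]]
    se <- sqrt(diag(as.matrix(vcov(fit))))[[2]]
    used <- fit
  }
  conv <- is.null(fit) ||
    length(fit@optinfo$conv$lme4$messages %||% character(0)) == 0
  structure(list(
    beta_treatment = beta, se = se,
    p_value = 2 * pnorm(-abs(beta / se)),
    sigma_u = sigma_u, boundary = boundary, converged = conv,
    n_cells = nrow(cells), n_samples = nrow(agg), fit = used
  ), class = "abundance_fit")
}

#' @export
print.abundance_fit <- function(x, ...) {
  cat(sprintf(
    "<abundance_fit> beta = %.3f (se %.3f), p = %.3g, sigma_u = %.3f%s\n",
    x$beta_treatment, x$se, x$p_value, x$sigma_u,
    if (x$boundary) " [boundary: refit as plain logistic]" else ""
  ))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.abundance_fit <- function(x, ...) {
  tibble(term = "genotypeSR", estimate = x$beta_treatment,
         std_error = x$se, p_value = x$p_value)
}

#' @exportS3Method generics::glance
glance.abundance_fit <- function(x, ...) {
  tibble(sigma_u = x$sigma_u, boundary = x$boundary,
         converged = x$converged, n_cells = x$n_cells,
         n_samples = x$n_samples)
}

#' Cell-type abundance analysis across the standard contrasts
#'
#' @param cells Per-cell metadata tibble ([cell_meta()]).
#' @param contrasts Contrast names understood by [build_contrast()].
#' @param ... Passed to [build_contrast()].
#' @return Tibble with one row per contrast: estimate, SE, Wald p,
#'   `sigma_u`, sizes.
#' @export
abundance_analysis <- function(cells,
                               contrasts = c("germline_vs_cyst",
                                             "premeiotic_vs_postmeiotic"),
                               ...) {
  purrr::map_dfr(contrasts, function(cn) {
    fit <- fit_binomial_glmm(build_contrast(cells, cn, ...))
    tibble(contrast = cn, beta_treatment = fit$beta_treatment,
           se = fit$se, p_value = fit$p_value, sigma_u = fit$sigma_u,
           boundary = fit$boundary, n_cells = fit$n_cells,
           n_samples = fit$n_samples)
  })
}
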