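#' Run the analysis pipeline end-to-end
#'
#' Executes the stages in dependency order — simulate (or read), QC,
#' per-cell X:A metrics, dosage, differential expression, enrichment,
#' resampling null, abundance, ploidy, coverage — writing each stage's
#' result as TSV into `out_dir` together with a JSON manifest recording
#' the package version, seed, thresholds, stage status and MD5 checksums
#' of every output. A stage failure halts its dependents but completed
#' outputs are preserved.
#'
#' @param config A YAML path or a list with (all optional): `seed`,
#'   `out_dir`, `stages` (character vector to run), `simulate` (arguments
#'   for [sim_config()]), `input` (paths for [read_counts()] when not
#'   simulating), `qc` (threshold overrides), `null` (arguments for
#'   [pseudo_replicate_null()], e.g. `repeats`).
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) abort(paste0("config file not found: ", config))
    config <- yaml::read_yaml(config)
  }
  seed <- config$seed %||% 1L
  out_dir <- config$out_dir %||% "drivescope_out"
  stages <- config$stages %||% c("simulate", "qc", "msci", "dosage", "de",
                                 "enrich", "nulls", "abundance", "ploidy",
                                 "coverage")
  if (!is.null(config$input)) {
    for (p in unlist(config$input)) {
      if (!file.exists(p)) abort(paste0("input file not found: ", p))
    }
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    package = "drivescope",
    version = as.character(utils::packageVersion("drivescope")),
    seed = seed, stages = stages, started = format(Sys.time()),
    outputs = list(), status = list()
  )
  written <- function(name, tbl) {
    path <- file.path(out_dir, paste0(name, ".tsv"))
    readr::write_tsv(tbl, path)
    manifest$outputs[[name]] <<- list(
      path = path, md5 = unname(tools::md5sum(path))
    )
  }
  stage <- function(name, deps, code) {
    if (!name %in% stages) return(invisible(NULL))
    if (any(unlist(manifest$status[deps]) == "failed")) {
      manifest$status[[name]] <<- "skipped (failed dependency)"
      return(invisible(NULL))
    }
    res <- tryCatch({
      force(code); "ok"
    }, error = function(e) {
      inform(sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
      "failed"
    })
    manifest$status[[name]] <<- res
  }

  sim <- NULL; experiment <- NULL; filtered <- NULL; de <- NULL

  stage("simulate", character(0), {
    args <- config$simulate %||% list()
    args$seed <- seed
    sim <- simulate_counts(do.call(sim_config, args))
    experiment <- sim$experiment
    write_counts(experiment, file.path(out_dir, "counts"))
    written("truth_de_genes", sim$truth$de_genes)
    written("truth_ploidy", sim$truth$ploidy)
  })
  if (!"simulate" %in% stages && !is.null(config$input)) {
    experiment <- do.call(read_counts, config$input)
  }

  stage("qc", "simulate", {
    thr <- do.call(qc_thresholds, config$qc %||% list())
    filtered <- apply_qc(experiment, thr)
    written("qc_report", attr(filtered, "qc_report"))
  })
  stage("msci", "qc", {
    stats <- cell_xa_stats(filtered)
    written("cell_xa_stats", stats)
    germ <- filtered$cell_meta$cell_type %in%
      (config$germline_types %||% c("gsc_spermatogonia",
                                    "primary_spermatocytes",
                                    "secondary_spermatocytes", "spermatids"))
    written("msci_test", inactivation_contingency_test(
      stats$inactivated, ifelse(germ, "germline", "soma")
    ))
  })
  stage("dosage", "qc", {
    d <- dosage_analysis(filtered)
    written("dosage_per_gene", d$per_gene)
    written("dosage_summary", d$summary)
  })
  stage("de", "qc", {
    de <- de_analysis(filtered)
    written("de_results", de)
  })
  stage("enrich", "de", {
    fit <- fit_enrichment_glm(de |> filter(!is_mt_chrom(.data$chromosome)))
    written("enrichment_lrt", fit$lrt)
    written("enrichment_coefficients", fit$coefficients)
  })
  stage("nulls", "qc", {
    args <- config$null %||% list()
    st <- subset_experiment(filtered, cells = filtered$cell_meta$genotype == "ST")
    sr <- subset_experiment(filtered, cells = filtered$cell_meta$genotype == "SR")
    null_run <- do.call(pseudo_replicate_null, c(
      list(pool_a = st, seed = seed), args
    ))
    obs_run <- do.call(pseudo_replicate_null, c(
      list(pool_a = st, pool_b = sr, seed = seed + 1L), args
    ))
    written("null_percents", null_run$percents)
    written("observed_percents", obs_run$percents)
    written("null_comparison", compare_resampling_runs(null_run, obs_run))
  })
  stage("abundance", "qc", {
    written("abundance_fits", abundance_analysis(cell_meta(filtered)))
  })
  stage("ploidy", "simulate", {
    truth <- if (!is.null(sim)) sim$truth$ploidy else NULL
    bcs <- if (!is.null(truth)) truth else
      tibble(barcode = experiment$cell_meta$barcode, ploidy = "diploid")
    keep <- with_substream(seed, "pipeline_ploidy", {
      sample(nrow(bcs), min(nrow(bcs), config$ploidy_cells %||% 300L))
    })
    sites <- simulate_sites(bcs[keep, ], seed = seed)
    written("ploidy_calls", classify_ploidy(sites))
  })
  stage("coverage", character(0), {
    cov <- do.call(simulate_coverage, c(list(seed = seed),
                                        config$coverage %||% list()))
    res <- coverage_exact_test(cov)
    written("coverage_results", res)
    if (!is.null(de) && nrow(de) > 0) {
      de1 <- de |> group_by(.data$gene_id) |>
        summarise(log2fc = mean(.data$log2fc), .groups = "drop")
      assoc <- expression_coverage_association(
        setNames(de1$log2fc, de1$gene_id),
        setNames(res$log2fc, res$gene_id)
      )
      written("coverage_association", assoc)
    }
  })

  manifest$finished <- format(Sys.time())
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
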