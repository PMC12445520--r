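#' Genotype one site from its allele counts
#'
#' A site is homozygous when one allele has at least `hom_depth` reads and
#' the other has none; heterozygous when both alleles have at least
#' `het_depth_each` reads; otherwise ungenotyped (e.g. a 2/1 split is
#' neither). Symmetric in ref/alt.
#'
#' @param ref_count,alt_count Nonnegative read counts (vectorised).
#' @param hom_depth Minimum depth for a homozygous call (default 2).
#' @param het_depth_each Minimum depth on each allele for a heterozygous
#'   call (default 2).
#' @return Character vector: `"homozygous"`, `"heterozygous"`,
#'   `"ungenotyped"`.
#' @export
call_site <- function(ref_count, alt_count, hom_depth = 2L,
                      het_depth_each = 2L) {
  if (any(ref_count < 0) || any(alt_count < 0)) abort("counts must be >= 0")
  dplyr::case_when(
    (ref_count >= hom_depth & alt_count == 0) |
      (alt_count >= hom_depth & ref_count == 0) ~ "homozygous",
    ref_count >= het_depth_each & alt_count >= het_depth_each ~ "heterozygous",
    TRUE ~ "ungenotyped"
  )
}

#' Classify cells as haploid or diploid from site genotypes
#'
#' Computes, per cell, the fraction of genotyped sites that are homozygous
#' and calls the cell haploid when that fraction is at least
#' `hom_frac_cutoff` (default 1: any heterozygous genotyped site makes the
#' cell diploid), diploid otherwise, and unclassified when fewer than
#' `min_sites` sites are genotyped.
#'
#' @param sites Tibble of per-cell allele counts: `barcode`, `site_id`,
#'   `ref_count`, `alt_count` (e.g. from [simulate_sites()] or
#'   [read_site_genotypes()]).
#' @param min_sites Minimum genotyped sites for a call (default 10).
#' @param hom_frac_cutoff Homozygous-fraction threshold for haploid calls.
#' @param hom_depth,het_depth_each Site-calling depths ([call_site()]).
#' @return Tibble, one row per cell: `barcode`, `n_genotyped`,
#'   `frac_homozygous`, `call` (`haploid`/`diploid`/`unclassified`).
#' @export
classify_ploidy <- function(sites, min_sites = 10L, hom_frac_cutoff = 1,
                            hom_depth = 2L, het_depth_each = 2L) {
  sites <- as_tibble(sites)
  need <- c("barcode", "site_id", "ref_count", "alt_count")
  if (!all(need %in% names(sites))) {
    abort("sites needs barcode, site_id, ref_count, alt_count")
  }
  dup <- sites |> count(.data$barcode, .data$site_id) |> filter(n > 1)
  if (nrow(dup) > 0) abort("duplicate site_id within a cell")
  sites$site_call <- call_site(sites$ref_count, sites$alt_count,
                               hom_depth, het_depth_each)
  sites |>
    group_by(.data$barcode) |>
    summarise(
      n_genotyped = sum(.data$site_call != "ungenotyped"),
      n_homozygous = sum(.data$site_call == "homozygous"),
      .groups = "drop"
    ) |>
    mutate(
      frac_homozygous = ifelse(.data$n_genotyped == 0, NA_real_,
                               .data$n_homozygous / pmax(.data$n_genotyped, 1)),
      call = dplyr::case_when(
        .data$n_genotyped < min_sites ~ "unclassified",
        .data$frac_homozygous >= hom_frac_cutoff ~ "haploid",
        TRUE ~ "diploid"
      )
    )
}

#' Read a per-cell allele-count table
#'
#' @param path TSV with columns `barcode`, `site_id`, `ref_count`,
#'   `alt_count`.
#' @return Tibble suitable for [classify_ploidy()].
#' @export
read_site_genotypes <- function(path) {
  sites <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("barcode", "site_id", "ref_count", "alt_count")
  if (!all(need %in% names(sites))) {
    abort(paste("site table needs columns:", paste(need, collapse = ", ")))
  }
  sites
}
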