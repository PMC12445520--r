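# Internal helpers shared across modules.

# Named RNG sub-streams derived from one master seed, so each pipeline stage
# draws from its own reproducible stream (re-running a stage alone gives the
# same numbers as running the whole pipeline).
substream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, !is.na(seed))
  codes <- utf8ToInt(stream)
  h <- 0
  for (k in codes) h <- (h * 131 + k) %% 1000000007
  as.integer((as.numeric(seed) + h) %% .Machine$integer.max)
}

with_substream <- function(seed, stream, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(substream_seed(seed, stream))
  force(code)
}

# Counts-per-million on a genes x units matrix given effective library sizes.
cpm_from_counts <- function(counts, eff_lib) {
  stopifnot(ncol(counts) == length(eff_lib), all(eff_lib > 0))
  sweep(as.matrix(counts), 2L, eff_lib, "/") * 1e6
}

is_x_chrom <- function(chromosome) chromosome == "chrX"
is_mt_chrom <- function(chromosome) chromosome == "MT"
is_autosome <- function(chromosome) !is_x_chrom(chromosome) & !is_mt_chrom(chromosome)
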