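# Shared fixtures: a small genome whose origins are far enough apart that
# replicated windows (fork_speed * pulse_minutes on each side) never
# overlap, so each read can be attributed to its origin unambiguously.

toy_genome <- function(seed = 7, n_origins = 10, n_genes = 40) {
  make_genome(n_chroms = 1, chrom_length = 1e6, n_origins = n_origins,
              n_genes = n_genes, seed = seed)
}

# Stranded-track constructor for bias unit tests: one chromosome, given
# W/C count vectors.
counts_track <- function(w, c, bin_width = 5000) {
  gm <- list(chromosomes = tibble::tibble(chrom = "chr1",
                                          length = length(w) * bin_width))
  class(gm) <- "genome_model"
  grid <- parenthist:::genome_bins(gm, bin_width)
  grid$w <- w
  grid$c <- c
  structure(grid, bin_width = bin_width, n_rejected = 0L,
            class = c("stranded_track", class(grid)))
}

# Bias track directly from a value vector (NA = masked).
values_track <- function(values, bin_width = 5000, chrom = "chr1") {
  gm <- list(chromosomes = tibble::tibble(chrom = chrom,
                                          length = length(values) * bin_width))
  class(gm) <- "genome_model"
  grid <- parenthist:::genome_bins(gm, bin_width)
  grid$bias <- values
  grid$n_reads <- ifelse(is.na(values), 0L, 100L)
  structure(grid, bin_width = bin_width, min_reads = 4, provenance = "raw",
            class = c("bias_track", class(grid)))
}

# Count track from a vector of counts.
counts_only_track <- function(counts, bin_width = 5000) {
  gm <- list(chromosomes = tibble::tibble(chrom = "chr1",
                                          length = length(counts) * bin_width))
  class(gm) <- "genome_model"
  grid <- parenthist:::genome_bins(gm, bin_width)
  grid$count <- counts
  structure(grid, bin_width = bin_width,
            class = c("count_track", class(grid)))
}

density_from_counts <- function(counts, bin_width = 5000, sf = 1) {
  d <- counts_only_track(counts, bin_width)
  rpm_normalize(d, 1e6 / sf)
}

random_reads <- function(n, genome, seed) {
  withr::with_seed(seed, {
    lens <- setNames(genome$chromosomes$length, genome$chromosomes$chrom)
    chrom <- sample(names(lens), n, replace = TRUE)
    start <- floor(runif(n, 0, unname(lens[chrom]) - 100))
    tibble::tibble(chrom = chrom, start = start, end = start + 100,
                   strand = sample(c("W", "C"), n, replace = TRUE),
                   assay = "espan")
  })
}

# End-to-end helper: simulate a genotype and return its leading-bias
# score through the full count -> bias -> normalize -> smooth ->
# aggregate chain.
genotype_score <- function(genome, params, seed, n_cells = 10,
                           flank_bp = 50000) {
  cfg <- sim_config(seed = seed, n_cells = n_cells)
  sim <- simulate_espan(genome, params, cfg)
  eb <- compute_bias(count_stranded_reads(sim$espan, genome))
  cb <- compute_bias(count_stranded_reads(sim$brdu, genome))
  prof <- aggregate_origins(smooth_bias(normalize_bias(eb, cb)),
                            genome$origins, flank_bp)
  leading_bias_score(prof)
}
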