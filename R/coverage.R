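#' Bin read coverage
#'
#' Tallies reads (stranded or not) into fixed-width bins by midpoint, the
#' raw-count precursor of the normalized density tracks.
#'
#' @inheritParams count_stranded_reads
#' @return A `count_track` tibble (chrom, start, end, count) with
#'   attribute `bin_width`.
#' @export
bin_coverage <- function(reads, genome, bin_width = 5000) {
  stopifnot(inherits(genome, "genome_model"))
  if (bin_width <= 0) abort("`bin_width` must be positive.")
  lens <- chrom_lengths(genome)
  bad <- setdiff(unique(reads$chrom), names(lens))
  if (length(bad) > 0) abort(sprintf("Unknown chromosome(s): %s.",
                                     paste(bad, collapse = ", ")))
  grid <- genome_bins(genome, bin_width)
  if (nrow(reads) > 0) {
    mid <- (reads$start + reads$end) %/% 2
    ok <- mid >= 0 & mid < unname(lens[reads$chrom])
    tal <- tibble(chrom = reads$chrom[ok],
                  start = (mid[ok] %/% bin_width) * bin_width) |>
      count(.data$chrom, .data$start, name = "count")
    grid <- grid |>
      left_join(tal, by = c("chrom", "start")) |>
      mutate(count = replace_na(.data$count, 0L))
  } else {
    grid$count <- 0L
  }
  structure(grid, bin_width = bin_width,
            class = c("count_track", class(grid)))
}

new_density_track <- function(track, density, normalization, scale_factor,
                              library_size) {
  out <- tibble(chrom = track$chrom, start = track$start, end = track$end,
                density = density)
  structure(out, bin_width = attr(track, "bin_width"),
            normalization = normalization, scale_factor = scale_factor,
            library_size = library_size,
            class = c("density_track", class(out)))
}

#' Reads-per-million (RPM) normalization
#'
#' Scales raw bin counts by `1e6 / total_mapped_reads`, so densities are
#' comparable between libraries of different depth. Because the factor is
#' computed from the sample's own reads, global abundance changes (e.g.
#' dilution of a labeled histone pool) cancel out — by design.
#'
#' @param track A `count_track`.
#' @param total_mapped_reads Library size; defaults to the track's total
#'   count.
#' @return A `density_track` with `normalization = "rpm"` and the scale
#'   factor and library size recorded as attributes.
#' @export
rpm_normalize <- function(track, total_mapped_reads = sum(track$count)) {
  stopifnot(inherits(track, "count_track"))
  if (total_mapped_reads <= 0) abort("Library size must be positive.")
  sf <- 1e6 / total_mapped_reads
  new_density_track(track, track$count * sf, "rpm", sf, total_mapped_reads)
}

#' Spike-in normalization
#'
#' Scales raw bin counts by `1e6 / human_library_size`, the number of
#' reads aligned to the spike-in (human) genome. Because the spike-in is
#' a fixed external admixture, this normalization preserves absolute
#' abundance changes in the sample of interest. The identity
#' `scale_factor * human_library_size == 1e6` holds for every run.
#'
#' @param track A `count_track` of sample (mouse) counts.
#' @param human_library_size Reads aligned to the spike-in genome.
#' @return A `density_track` with `normalization = "spikein"`.
#' @export
spikein_normalize <- function(track, human_library_size) {
  stopifnot(inherits(track, "count_track"))
  if (human_library_size <= 0) abort("Human (spike-in) library size must be positive.")
  sf <- 1e6 / human_library_size
  new_density_track(track, track$count * sf, "spikein", sf, human_library_size)
}

density_at <- function(track_by_chrom, bw, chrom, pos) {
  # density value of the bin containing each genomic position
  map_dbl(seq_along(chrom), function(i) {
    tr <- track_by_chrom[[chrom[i]]]
    if (is.null(tr)) return(NA_real_)
    j <- pos[i] %/% bw + 1
    if (j < 1 || j > nrow(tr)) NA_real_ else tr$density[j]
  })
}

#' Metagene density profile by expression quartile
#'
#' Rescales every gene body to `n_scaled_bins` positions (strand-aware,
#' oriented TSS to TTS), adds fixed-width flanks sampled at
#' `n_flank_bins` positions each, looks up the density of the bin under
#' each position, and averages across genes within each expression
#' quartile. Genes shorter than one density bin are excluded (their body
#' cannot be resolved) and counted.
#'
#' @param density A `density_track`.
#' @param genes Tibble with gene_id, chrom, start, end, strand, quartile.
#' @param n_scaled_bins Positions across the gene body (default 40).
#' @param flank_bp Flank width in bp on each side (default 2000).
#' @param n_flank_bins Positions per flank (default 10).
#' @return A `metagene_profile` tibble (quartile, position, segment,
#'   rel_pos, mean_density, n_genes) with attribute `n_excluded`.
#'   `position` runs 1..(2*n_flank_bins + n_scaled_bins) in transcription
#'   direction.
#' @export
metagene_profile <- function(density, genes, n_scaled_bins = 40,
                             flank_bp = 2000, n_flank_bins = 10) {
  stopifnot(inherits(density, "density_track"))
  if (n_scaled_bins < 2) abort("`n_scaled_bins` must be >= 2.")
  bw <- attr(density, "bin_width")
  short <- (genes$end - genes$start) < bw
  n_excluded <- sum(short)
  if (n_excluded > 0) {
    warn(sprintf("%d gene(s) shorter than one density bin excluded.", n_excluded))
  }
  genes <- genes[!short, , drop = FALSE]
  if (nrow(genes) == 0) abort("No usable genes for the metagene profile.")
  by_chrom <- split(as_tibble(density), density$chrom)

  u <- (seq_len(n_flank_bins) - 0.5) / n_flank_bins       # flank fractions
  b <- (seq_len(n_scaled_bins) - 0.5) / n_scaled_bins     # body fractions
  n_pos <- 2L * n_flank_bins + n_scaled_bins

  per_gene <- map(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    if (g$strand == "+") {
      pos <- c(g$start - flank_bp + u * flank_bp,
               g$start + b * (g$end - g$start),
               g$end + u * flank_bp)
    } else {
      pos <- c(g$end + flank_bp - u * flank_bp,
               g$end - b * (g$end - g$start),
               g$start - u * flank_bp)
    }
    tibble(quartile = g$quartile, position = seq_len(n_pos),
           value = density_at(by_chrom, bw, rep(g$chrom, n_pos), pos))
  })

  prof <- list_rbind(per_gene) |>
    group_by(.data$quartile, .data$position) |>
    summarise(mean_density = mean(.data$value, na.rm = TRUE),
              n_genes = sum(!is.na(.data$value)), .groups = "drop") |>
    mutate(segment = dplyr::case_when(
      .data$position <= n_flank_bins ~ "upstream",
      .data$position <= n_flank_bins + n_scaled_bins ~ "body",
      TRUE ~ "downstream"),
      rel_pos = (.data$position - n_flank_bins - 0.5) / n_scaled_bins)

  structure(prof, n_excluded = n_excluded, n_scaled_bins = n_scaled_bins,
            n_flank_bins = n_flank_bins, flank_bp = flank_bp,
            class = c("metagene_profile", class(prof)))
}

#' @describeIn metagene_profile Quartile-coloured metagene plot.
#' @param object A `metagene_profile`.
#' @param ... Unused.
#' @method autoplot metagene_profile
#' @export
autoplot.metagene_profile <- function(object, ...) {
  ggplot(as_tibble(object),
         aes(x = .data$rel_pos, y = .data$mean_density,
             colour = factor(.data$quartile))) +
    geom_line(linewidth = 0.8) +
    geom_vline(xintercept = c(0, 1), linetype = 3, colour = "grey60") +
    scale_colour_brewer(palette = "RdYlBu", direction = -1,
                        name = "Expression\nquartile") +
    labs(x = "Scaled position (0 = TSS, 1 = TTS)", y = "Mean density",
         title = "Metagene density by expression quartile") +
    theme_bw()
}

#' Mean density over regions
#'
#' Length-weighted mean density of each region: bins are weighted by the
#' number of bp they overlap the region, so coarse bins at region edges
#' do not bias the mean. Regions that overlap no defined bin are flagged
#' with `NA`, never silently zeroed.
#'
#' @param density A `density_track`.
#' @param regions Tibble with chrom, start, end (and optionally
#'   region_id).
#' @return A `RegionDensityTable`-style tibble (region_id, chrom, start,
#'   end, mean_density).
#' @export
region_density <- function(density, regions) {
  stopifnot(inherits(density, "density_track"))
  bw <- attr(density, "bin_width")
  by_chrom <- split(as_tibble(density), density$chrom)
  lens <- map_dbl(by_chrom, function(tr) max(tr$end))
  if (!"region_id" %in% names(regions)) {
    regions <- mutate(regions, region_id = sprintf("region%04d", row_number()))
  }
  bad <- !(regions$chrom %in% names(by_chrom)) |
    regions$start < 0 | regions$end > unname(lens[regions$chrom]) |
    is.na(regions$start)
  if (any(bad)) {
    abort(sprintf("Region(s) outside the genome: %s.",
                  paste(regions$region_id[bad], collapse = ", ")))
  }
  means <- map_dbl(seq_len(nrow(regions)), function(i) {
    r <- regions[i, ]
    tr <- by_chrom[[r$chrom]]
    i0 <- r$start %/% bw + 1
    i1 <- (r$end - 1) %/% bw + 1
    idx <- i0:i1
    ov <- pmin(tr$end[idx], r$end) - pmax(tr$start[idx], r$start)
    v <- tr$density[idx]
    if (all(is.na(v))) return(NA_real_)
    sum(v * ov, na.rm = TRUE) / sum(ov[!is.na(v)])
  })
  tibble(region_id = regions$region_id, chrom = regions$chrom,
         start = regions$start, end = regions$end, mean_density = means)
}

#' Pairwise Pearson correlation of density tracks
#'
#' Re-bins each track by summation into `window_bp` windows (default
#' 50 kb) and computes the pairwise Pearson correlation over windows.
#' Windows with zero coverage in either member of a pair are dropped for
#' that pair.
#'
#' @param tracks Named list of `density_track`s on the same genome and
#'   bin width.
#' @param window_bp Correlation window in bp; must be a multiple of the
#'   bin width.
#' @return A symmetric correlation matrix with unit diagonal and
#'   attribute `window_bp`.
#' @export
correlation_matrix <- function(tracks, window_bp = 50000) {
  if (length(tracks) < 2) abort("Need at least two tracks.")
  bw <- attr(tracks[[1]], "bin_width")
  if (window_bp %% bw != 0) {
    abort(sprintf("`window_bp` must be a multiple of the bin width (%g).", bw))
  }
  if (is.null(names(tracks))) names(tracks) <- paste0("track", seq_along(tracks))
  rebinned <- map(tracks, function(tr) {
    stopifnot(inherits(tr, "density_track"))
    as_tibble(tr) |>
      mutate(win = .data$start %/% window_bp) |>
      group_by(.data$chrom, .data$win) |>
      summarise(v = sum(.data$density), .groups = "drop") |>
      arrange(.data$chrom, .data$win)
  })
  key <- rebinned[[1]] |> select("chrom", "win")
  vals <- map(rebinned, function(r) {
    if (nrow(r) != nrow(key)) abort("Tracks cover different genomes.")
    r$v
  })
  V <- do.call(cbind, vals)
  n <- ncol(V)
  M <- diag(1, n)
  dimnames(M) <- list(names(tracks), names(tracks))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      use <- V[, i] > 0 & V[, j] > 0
      if (sum(use) < 2) abort("Fewer than 2 usable windows for a track pair.")
      M[i, j] <- M[j, i] <- cor(V[use, i], V[use, j])
    }
  }
  structure(M, window_bp = window_bp)
}
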