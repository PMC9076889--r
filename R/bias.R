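#' Tally Watson/Crick reads into genomic bins
#'
#' Assigns each stranded read to exactly one fixed-width bin by its
#' midpoint (bins tiled from coordinate 0) and tallies Watson (`W`) and
#' Crick (`C`) reads per bin. The default 5 kb bin width is the window
#' size at which the strand-bias statistic is evaluated.
#'
#' @param reads Tibble with columns chrom, start, end, strand
#'   (`"W"`/`"C"`).
#' @param genome A `genome_model` providing chromosome bounds.
#' @param bin_width Bin width in bp (default 5000).
#' @return A `stranded_track` tibble (chrom, start, end, w, c) covering
#'   every bin of the genome, with attributes `bin_width` and
#'   `n_rejected` (reads whose midpoint lies beyond the chromosome end).
#'   Reads on unknown chromosomes are an error.
#' @export
count_stranded_reads <- function(reads, genome, bin_width = 5000) {
  stopifnot(inherits(genome, "genome_model"))
  if (bin_width <= 0) abort("`bin_width` must be positive.")
  lens <- chrom_lengths(genome)

  bad_chrom <- setdiff(unique(reads$chrom), names(lens))
  if (length(bad_chrom) > 0) {
    offending <- reads |> filter(.data$chrom %in% bad_chrom)
    abort(sprintf(
      "%d read(s) on unknown chromosome(s) %s (first: %s:%g-%g).",
      nrow(offending), paste(bad_chrom, collapse = ", "),
      offending$chrom[1], offending$start[1], offending$end[1]))
  }
  if (nrow(reads) > 0 && !all(reads$strand %in% c("W", "C"))) {
    abort("Every read must carry strand 'W' or 'C'.")
  }

  grid <- genome_bins(genome, bin_width)
  n_rejected <- 0L
  tallies <- grid |> mutate(w = 0, c = 0)
  if (nrow(reads) > 0) {
    mid <- (reads$start + reads$end) %/% 2
    beyond <- mid >= unname(lens[reads$chrom]) | mid < 0
    n_rejected <- sum(beyond)
    if (n_rejected > 0) {
      warn(sprintf("%d read(s) beyond chromosome bounds rejected.", n_rejected))
    }
    kept <- tibble(chrom = reads$chrom[!beyond],
                   start = (mid[!beyond] %/% bin_width) * bin_width,
                   strand = reads$strand[!beyond])
    tal <- kept |>
      count(.data$chrom, .data$start, .data$strand) |>
      pivot_wider(names_from = "strand", values_from = "n", values_fill = 0L)
    for (s in c("W", "C")) if (!s %in% names(tal)) tal[[s]] <- 0L
    tallies <- grid |>
      left_join(tal |> select("chrom", "start", w = "W", c = "C"),
                by = c("chrom", "start")) |>
      mutate(w = replace_na(.data$w, 0L), c = replace_na(.data$c, 0L))
  }
  structure(tallies, bin_width = bin_width, n_rejected = n_rejected,
            class = c("stranded_track", class(grid)))
}

#' Strand-bias statistic per bin
#'
#' Computes the Watson/Crick bias `(W - C) / (W + C)` for every bin of a
#' stranded tally. Bins with fewer than `min_reads` total reads are
#' masked (`NA`), never zero-filled: a bin with no coverage carries no
#' information about strand asymmetry.
#'
#' @param track A `stranded_track` from [count_stranded_reads()].
#' @param min_reads Minimum `W + C` for a bin to be evaluated (default 4).
#' @return A `bias_track` tibble (chrom, start, end, bias, n_reads) with
#'   attributes `bin_width`, `min_reads` and `provenance = "raw"`. Every
#'   unmasked bias lies in `[-1, 1]`.
#' @examples
#' # (6 - 2) / (6 + 2) = 0.5; a 3-read bin is masked
#' @export
compute_bias <- function(track, min_reads = 4) {
  stopifnot(inherits(track, "stranded_track"))
  total <- track$w + track$c
  bias <- ifelse(total >= min_reads, (track$w - track$c) / total, NA_real_)
  out <- tibble(chrom = track$chrom, start = track$start, end = track$end,
                bias = bias, n_reads = total)
  structure(out, bin_width = attr(track, "bin_width"), min_reads = min_reads,
            provenance = "raw", class = c("bias_track", class(out)))
}

#' Normalize an eSPAN bias track against its BrdU-IP control
#'
#' Subtracts the control's per-bin bias from the eSPAN bias. The control
#' library samples nascent DNA without the protein of interest, so any
#' strand asymmetry it shows is technical; subtraction removes it
#' additively (a ratio of signed quantities would be ill-defined near 0).
#' A bin masked in either input is masked in the output.
#'
#' @param espan,control `bias_track`s on identical bins.
#' @return A `bias_track` flagged `provenance = "normalized"`.
#' @export
normalize_bias <- function(espan, control) {
  stopifnot(inherits(espan, "bias_track"), inherits(control, "bias_track"))
  if (!identical(attr(espan, "bin_width"), attr(control, "bin_width")) ||
      nrow(espan) != nrow(control) ||
      !identical(espan$chrom, control$chrom) ||
      !identical(espan$start, control$start)) {
    abort("eSPAN and control tracks must share bin width and genome layout.")
  }
  out <- espan
  out$bias <- espan$bias - control$bias
  structure(out, bin_width = attr(espan, "bin_width"),
            min_reads = attr(espan, "min_reads"), provenance = "normalized",
            class = class(espan))
}

#' Smooth a bias track with a centered masked-aware window
#'
#' Replaces each bin with the mean of the unmasked values in the centered
#' window of `2 * flank_bins + 1` bins (default: five flanking bins per
#' side, an 11-bin window). Windows are truncated at chromosome ends;
#' bins whose window contains no unmasked value stay masked. The
#' `min_reads` filter is applied to the raw track only and never
#' re-applied after smoothing.
#'
#' @param track A `bias_track`.
#' @param flank_bins Bins on each side of the center (default 5).
#' @return A `bias_track` flagged `provenance = "smoothed"`.
#' @export
smooth_bias <- function(track, flank_bins = 5) {
  stopifnot(inherits(track, "bias_track"))
  flank_bins <- assert_count(flank_bins, "flank_bins")
  out <- track
  out$bias <- track |>
    as_tibble() |>
    group_by(.data$chrom) |>
    mutate(sm = roll_mean_masked(.data$bias, flank_bins)) |>
    ungroup() |>
    pull("sm")
  structure(out, bin_width = attr(track, "bin_width"),
            min_reads = attr(track, "min_reads"), provenance = "smoothed",
            class = class(track))
}
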