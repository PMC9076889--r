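#' Simulate a spike-in CUT&RUN time-course of labeled parental histones
#'
#' Models the pulse-chase dilution experiment: parental histones are
#' covalently labeled once, cells then replicate so chromatin content at a
#' collection time grows by a factor `1 + f` (`f` = replicated fraction)
#' while the labeled parental pool is retained but spread over the
#' enlarged population. Each collected sample is mixed with freshly
#' labeled human spike-in cells making up `spikein_fraction` of cells,
#' with equal per-cell labeled-chromatin yield for mouse and human cells.
#'
#' Reads sample labeled chromatin in proportion to each compartment's
#' yield, so the expected human read fraction at time with replicated
#' fraction `f` is `s / (s + (1 - s) / (1 + f))` with
#' `s = spikein_fraction` — exactly `s` at the first time point. Mouse
#' read positions mix a uniform background with gene bodies weighted by
#' their H3.3 enrichment (`h33_weight`), so highly expressed quartiles
#' carry more density.
#'
#' @param genome A `genome_model`.
#' @param times Numeric vector of collection times in hours
#'   (default `c(0, 5, 11)`).
#' @param replicated_fraction Numeric vector, same length as `times`: the
#'   fraction of the genome replicated (per cell-population chromatin
#'   gain) at each time; each value must lie in `[0, 1]`.
#' @param config A `sim_config`; `n_reads`, `spikein_fraction`,
#'   `background_fraction`, `read_length` and `seed` are used.
#' @return A list with `reads`, a tibble of mouse-genome reads (time_h,
#'   chrom, start, end, strand = NA, assay = "cutrun_mouse"), and
#'   `libraries`, a tibble (time_h, replicated_fraction, mouse_reads,
#'   human_reads) recording per-sample library sizes. Human reads are
#'   counted, not positioned.
#' @export
simulate_cutrun_timecourse <- function(genome, times = c(0, 5, 11),
                                       replicated_fraction = c(0, 0.5, 1),
                                       config = sim_config()) {
  stopifnot(inherits(genome, "genome_model"), inherits(config, "sim_config"))
  if (length(times) != length(replicated_fraction)) {
    abort("`times` and `replicated_fraction` must have the same length.")
  }
  if (any(replicated_fraction < 0 | replicated_fraction > 1)) {
    abort("Every `replicated_fraction` must lie in [0, 1].")
  }
  s <- config$spikein_fraction
  lens <- chrom_lengths(genome)
  genes <- genome$genes

  withr::local_seed(child_seed(config$seed, "cutrun"))

  out <- map2(times, replicated_fraction, function(t, f) {
    p_h <- if (s == 0) 0 else s / (s + (1 - s) / (1 + f))
    n_h <- rbinom(1L, config$n_reads, p_h)
    n_m <- config$n_reads - n_h

    if (n_m > 0) {
      from_bg <- nrow(genes) == 0 |
        (runif(n_m) < config$background_fraction)
      n_bg <- sum(from_bg)
      pos_bg <- chrom_bg <- NULL
      if (n_bg > 0) {
        chrom_bg <- sample(names(lens), n_bg, replace = TRUE,
                           prob = lens / sum(lens))
        pos_bg <- runif(n_bg, 0, unname(lens[chrom_bg]))
      }
      n_g <- n_m - n_bg
      pos_g <- chrom_g <- NULL
      if (n_g > 0) {
        w <- genes$h33_weight * (genes$end - genes$start)
        gi <- sample.int(nrow(genes), n_g, replace = TRUE, prob = w)
        chrom_g <- genes$chrom[gi]
        pos_g <- runif(n_g, genes$start[gi], genes$end[gi])
      }
      center <- c(pos_bg, pos_g)
      chrom <- c(chrom_bg, chrom_g)
      reads <- tibble(
        time_h = t, chrom = chrom,
        start = pmax(0, round(center - config$read_length / 2)),
        end = pmin(unname(lens[chrom]), round(center + config$read_length / 2)),
        strand = NA_character_, assay = "cutrun_mouse"
      ) |> filter(.data$end > .data$start)
    } else {
      reads <- tibble(time_h = numeric(), chrom = character(),
                      start = numeric(), end = numeric(),
                      strand = character(), assay = character())
    }
    list(reads = reads,
         lib = tibble(time_h = t, replicated_fraction = f,
                      mouse_reads = nrow(reads), human_reads = n_h))
  })

  list(reads = list_rbind(map(out, "reads")),
       libraries = list_rbind(map(out, "lib")))
}
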