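#' Histone-transfer parameters and genotype presets
#'
#' Bundles the three knobs of the parental-histone transfer model:
#' `p_leading`, the probability that a recycled parental histone is
#' deposited on the leading strand of the replication fork; `retain_prob`,
#' the probability that a parental histone is recycled at all during one
#' S phase; and `bleach_rate`, the per-hour fractional fluorescence loss
#' applied in the live-cell simulator.
#'
#' The named presets encode the qualitative strand-partition phenotypes of
#' the replisome mutants studied in this field: Mcm2-2A and Pola1-2A
#' (defective lagging-strand transfer, hence a leading-strand shift),
#' Pole3/Pole4 knockouts (defective leading-strand transfer, a lagging
#' shift), and the Mcm2-2A + Pole4 KO double mutant whose opposing defects
#' roughly cancel. The numeric values are simulator settings chosen to
#' reproduce that ordering; they are not measurements.
#'
#' @param genotype Preset name, one of
#'   `names(genotype_presets())`, or any label when the three
#'   probabilities are supplied explicitly.
#' @param p_leading,retain_prob,bleach_rate Override the preset values.
#' @return A `transfer_params` list with fields `genotype`, `p_leading`,
#'   `retain_prob`, `bleach_rate`.
#' @examples
#' transfer_params("Mcm2-2A")
#' transfer_params("custom", p_leading = 0.5, retain_prob = 1, bleach_rate = 0)
#' @export
transfer_params <- function(genotype = "WT", p_leading = NULL,
                            retain_prob = NULL, bleach_rate = NULL) {
  presets <- genotype_presets()
  if (genotype %in% names(presets)) {
    base <- presets[[genotype]]
  } else {
    if (is.null(p_leading) || is.null(retain_prob)) {
      abort(sprintf(
        "Unknown genotype '%s'; supply p_leading and retain_prob explicitly or use one of: %s.",
        genotype, paste(names(presets), collapse = ", ")))
    }
    base <- list(p_leading = p_leading, retain_prob = retain_prob,
                 bleach_rate = bleach_rate %||% 0)
  }
  out <- list(
    genotype = genotype,
    p_leading = p_leading %||% base$p_leading,
    retain_prob = retain_prob %||% base$retain_prob,
    bleach_rate = bleach_rate %||% base$bleach_rate
  )
  assert_prob(out$p_leading, "p_leading")
  assert_prob(out$retain_prob, "retain_prob")
  if (out$bleach_rate < 0) abort("`bleach_rate` must be >= 0.")
  structure(out, class = "transfer_params")
}

#' @rdname transfer_params
#' @export
genotype_presets <- function() {
  list(
    "WT"              = list(p_leading = 0.55, retain_prob = 1.00, bleach_rate = 0),
    "Mcm2-2A"         = list(p_leading = 0.75, retain_prob = 0.92, bleach_rate = 0),
    "Pola1-2A"        = list(p_leading = 0.75, retain_prob = 0.92, bleach_rate = 0),
    "Pole3KO"         = list(p_leading = 0.40, retain_prob = 0.92, bleach_rate = 0),
    "Pole4KO"         = list(p_leading = 0.40, retain_prob = 0.92, bleach_rate = 0),
    "Mcm2-2A+Pole4KO" = list(p_leading = 0.55, retain_prob = 0.85, bleach_rate = 0)
  )
}

#' @export
print.transfer_params <- function(x, ...) {
  cat(sprintf("<transfer_params> %s: p_leading=%.2f retain_prob=%.2f bleach_rate=%.3g/h\n",
              x$genotype, x$p_leading, x$retain_prob, x$bleach_rate))
  invisible(x)
}

#' Simulation configuration
#'
#' Collects the physical and sampling parameters shared by the three
#' simulators. Defaults follow the experimental design being emulated: a
#' 40-minute nucleotide-analog pulse, a 20% human spike-in cell fraction,
#' 20-minute imaging frames over a 16-hour movie. Fork speed (1 kb/min)
#' and nucleosome spacing (200 bp) are standard mammalian ballpark values.
#'
#' @param seed Root seed; all per-assay random streams derive from it.
#' @param n_cells Cell-equivalents sampled by the eSPAN simulator.
#' @param n_reads Total read budget per time point for the CUT&RUN
#'   time-course simulator.
#' @param fork_speed Replication fork speed, bp/min.
#' @param pulse_minutes Length of the labeling pulse, minutes.
#' @param nucleosome_spacing Spacing of histone positions, bp.
#' @param read_length Simulated read length, bp (reads are centered on the
#'   histone position).
#' @param spikein_fraction Fraction of labeled cells that are human
#'   spike-in cells, in `[0, 1)`.
#' @param background_fraction Fraction of bulk-coverage reads drawn from
#'   uniform background rather than weighted gene bodies.
#' @param frame_minutes Live-cell frame interval, minutes.
#' @param horizon_hours Live-cell movie length, hours.
#' @param geminin_noise_sd Gaussian noise SD on the 0/1 geminin channel.
#' @param partition_concentration Beta concentration of the symmetric
#'   daughter partition fraction (mean forced to 0.5).
#' @param signal_units Number of labeled-histone quanta per cell used to
#'   discretize retention (larger = less cell-to-cell variability).
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(seed = 1L, n_cells = 10L, n_reads = 100000L,
                       fork_speed = 1000, pulse_minutes = 40,
                       nucleosome_spacing = 200, read_length = 100,
                       spikein_fraction = 0.20, background_fraction = 0.3,
                       frame_minutes = 20, horizon_hours = 16,
                       geminin_noise_sd = 0.05,
                       partition_concentration = 50,
                       signal_units = 1000L) {
  seed <- assert_count(seed, "seed")
  n_cells <- assert_count(n_cells, "n_cells", min = 1L)
  n_reads <- assert_count(n_reads, "n_reads", min = 1L)
  if (fork_speed <= 0 || pulse_minutes <= 0 || nucleosome_spacing <= 0 ||
      read_length <= 0) {
    abort("fork_speed, pulse_minutes, nucleosome_spacing and read_length must be positive.")
  }
  assert_prob(spikein_fraction, "spikein_fraction")
  if (spikein_fraction >= 1) abort("`spikein_fraction` must be < 1.")
  assert_prob(background_fraction, "background_fraction")
  if (frame_minutes <= 0 || horizon_hours <= 0) {
    abort("frame_minutes and horizon_hours must be positive.")
  }
  structure(
    list(seed = seed, n_cells = n_cells, n_reads = n_reads,
         fork_speed = fork_speed, pulse_minutes = pulse_minutes,
         nucleosome_spacing = nucleosome_spacing, read_length = read_length,
         spikein_fraction = spikein_fraction,
         background_fraction = background_fraction,
         frame_minutes = frame_minutes, horizon_hours = horizon_hours,
         geminin_noise_sd = geminin_noise_sd,
         partition_concentration = partition_concentration,
         signal_units = as.integer(signal_units)),
    class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  seed=%d, n_cells=%d, n_reads=%d\n", x$seed, x$n_cells, x$n_reads))
  cat(sprintf("  fork %g bp/min x %g min pulse; nucleosome %g bp; spike-in %.0f%%\n",
              x$fork_speed, x$pulse_minutes, x$nucleosome_spacing,
              100 * x$spikein_fraction))
  invisible(x)
}
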