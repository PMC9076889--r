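#' Simulate live-cell pulse-chase traces of labeled parental histones
#'
#' Generates per-cell fluorescence time series mimicking a one-shot SNAP
#' pulse label followed by time-lapse imaging through one division. Each
#' mother cell carries an initial pool of labeled histone quanta; during S
#' phase (cell-cycle-locked from `cycle_hours` before mitosis to 1 h
#' before it) a fraction `retain_prob` of the pool is recycled (binomially
#' over `signal_units` quanta, so retention varies slightly between
#' cells); photobleaching removes signal continuously at `bleach_rate`
#' per hour. At mitosis the remaining signal is split between two
#' daughters by a symmetric Beta-distributed fraction (mean 0.5). A
#' geminin cell-cycle reporter channel rises at G1/S (with `cycle_sd`
#' hours of observation jitter), falls at mitosis, and carries Gaussian
#' noise.
#'
#' With `bleach_rate = 0` and `retain_prob = 1` the G2 signal equals the
#' G1/S signal and the two daughters sum exactly to the mother's G2
#' signal; with bleaching the whole lineage decays as `exp(-rate * t)`.
#'
#' @param params A `transfer_params` (uses `retain_prob`, `bleach_rate`).
#' @param n_cells Number of mother cells.
#' @param frame_minutes Imaging frame interval (min).
#' @param horizon_hours Movie length (h).
#' @param seed Integer seed.
#' @param cycle_hours Generative G1/S-to-mitosis duration (h).
#' @param cycle_sd SD of the geminin-rise observation jitter around the
#'   true G1/S transition (h).
#' @param mitosis_mean,mitosis_sd Mean/SD of the mitosis time (h from movie
#'   start); chosen so G1/S and 1 h of next G1 fall inside the movie.
#' @param config Optional `sim_config` supplying `frame_minutes`,
#'   `horizon_hours`, `geminin_noise_sd`, `partition_concentration`,
#'   `signal_units` (explicit arguments win).
#' @return A tibble of traces (cell_id, parent_id, time_h, signal,
#'   geminin) with one row per cell per frame. The attribute `"truth"`
#'   holds per-mother ground truth (mitosis_time, t_g1s, duration,
#'   initial signal, retained fraction, partition fraction); retrieve it
#'   with [sim_truth()].
#' @export
simulate_live_cell <- function(params, n_cells = 50L, frame_minutes = 20,
                               horizon_hours = 16, seed = 1L,
                               cycle_hours = 11, cycle_sd = 0.25,
                               mitosis_mean = 12.5, mitosis_sd = 0.3,
                               config = NULL) {
  stopifnot(inherits(params, "transfer_params"))
  n_cells <- assert_count(n_cells, "n_cells", min = 1L)
  if (!is.null(config)) {
    stopifnot(inherits(config, "sim_config"))
    frame_minutes <- config$frame_minutes
    horizon_hours <- config$horizon_hours
  }
  noise_sd <- if (is.null(config)) 0.05 else config$geminin_noise_sd
  conc <- if (is.null(config)) 50 else config$partition_concentration
  units <- if (is.null(config)) 1000L else config$signal_units

  dt <- frame_minutes / 60
  frames <- seq(0, horizon_hours, by = dt)
  beta <- params$bleach_rate

  withr::local_seed(child_seed(seed, "livecell"))

  per_cell <- map(seq_len(n_cells), function(i) {
    id <- sprintf("c%03d", i)
    # snap mitosis to a frame so division happens between frames cleanly
    t_m <- frames[which.min(abs(frames - rnorm(1, mitosis_mean, mitosis_sd)))]
    # S phase is cell-cycle-locked: it starts cycle_hours before mitosis
    # and ends 1 h before; the geminin rise is a noisy observation of the
    # G1/S transition, not the transition itself
    s_start <- max(dt, t_m - cycle_hours)
    t_g2 <- t_m - 1
    t_rise <- max(dt, s_start + rnorm(1, 0, cycle_sd))
    s0 <- rlnorm(1, log(1000), 0.2)
    r <- rbinom(1, units, params$retain_prob) / units
    q <- rbeta(1, conc, conc)             # daughter 1's share, mean 0.5

    # retention factor: 1 before S, linear to r across S, r after
    ret <- function(t) {
      ifelse(t <= s_start, 1,
             ifelse(t >= t_g2, r, 1 + (r - 1) * (t - s_start) / (t_g2 - s_start)))
    }

    tm <- frames[frames <= t_m]
    mother <- tibble(
      cell_id = id, parent_id = NA_character_, time_h = tm,
      signal = s0 * exp(-beta * tm) * ret(tm),
      geminin = as.numeric(tm >= t_rise & tm < t_m) +
        rnorm(length(tm), 0, noise_sd)
    )
    td <- frames[frames > t_m]
    daughters <- list_rbind(map(1:2, function(d) {
      share <- if (d == 1) q else 1 - q
      tibble(
        cell_id = sprintf("%s.d%d", id, d), parent_id = id, time_h = td,
        signal = s0 * exp(-beta * td) * r * share,
        geminin = rnorm(length(td), 0, noise_sd)
      )
    }))
    list(trace = bind_rows(mother, daughters),
         truth = tibble(cell_id = id, genotype = params$genotype,
                        mitosis_time = t_m, s_start = s_start,
                        t_g1s = t_rise, duration = t_m - t_rise, s0 = s0,
                        retained_frac = r, partition_q = q))
  })

  traces <- list_rbind(map(per_cell, "trace"))
  attr(traces, "truth") <- list_rbind(map(per_cell, "truth"))
  attr(traces, "frame_minutes") <- frame_minutes
  class(traces) <- c("cell_traces", class(traces))
  traces
}

#' Ground truth of a simulated live-cell cohort
#'
#' @param traces A tibble returned by [simulate_live_cell()].
#' @return The per-mother ground-truth tibble stored by the simulator.
#' @export
sim_truth <- function(traces) {
  tr <- attr(traces, "truth")
  if (is.null(tr)) abort("No ground truth attached; not a simulated cohort?")
  tr
}
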