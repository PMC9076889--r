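#' Call cell-cycle phase time points for live-cell traces
#'
#' Two modes are supported. `"offset"` places the phases at fixed offsets
#' from mitosis — G1/S at `g1s_offset_hours` before (default 11 h; use 12
#' for the double mutant), G2 at 1 h before, next G1 at 1 h after — and
#' snaps each to the nearest imaging frame (ties round toward mitosis).
#' `"geminin"` derives G1/S from the appearance of the geminin reporter
#' (first crossing above `appear` x trace maximum sustained for
#' `sustain` frames) and mitosis from its subsequent reduction (first
#' drop below `fall` x maximum).
#'
#' @param traces Trace tibble (cell_id, parent_id, time_h, signal,
#'   geminin); only mother cells (parent_id `NA`) are called.
#' @param mode `"offset"` or `"geminin"`.
#' @param g1s_offset_hours Hours before mitosis defining G1/S in offset
#'   mode (default 11).
#' @param g2_offset_hours,next_g1_offset_hours Hours before/after mitosis
#'   for G2 and next G1 (default 1 each).
#' @param mitosis Tibble (cell_id, mitosis_time) required in offset mode;
#'   defaults to the simulator's ground truth when present.
#' @param geminin_thresholds List with `appear` (fraction of max, default
#'   0.5), `fall` (default 0.25), `sustain` (frames, default 2).
#' @return A tibble of phase calls (cell_id, t_g1s, t_g2, t_mitosis,
#'   t_next_g1, mode). Cells whose geminin never falls raise an error in
#'   single-cell use; in cohort use they are dropped with a counted
#'   warning.
#' @export
call_phases <- function(traces, mode = c("offset", "geminin"),
                        g1s_offset_hours = 11, g2_offset_hours = 1,
                        next_g1_offset_hours = 1, mitosis = NULL,
                        geminin_thresholds = list(appear = 0.5, fall = 0.25,
                                                  sustain = 2)) {
  mode <- match.arg(mode)
  mothers <- traces |> filter(is.na(.data$parent_id))
  if (nrow(mothers) == 0) abort("No mother traces (parent_id NA) found.")
  frames <- sort(unique(traces$time_h))
  t0 <- frames[1]
  dt <- if (length(frames) > 1) min(diff(frames)) else 1 / 3

  snap <- function(t) {
    # nearest point of the frame grid, which extends arithmetically past
    # the observed frames (phase offsets can reach beyond a short trace);
    # exact midpoints round toward mitosis via the caller's epsilon
    t0 + round((t - t0) / dt) * dt
  }

  if (mode == "offset") {
    if (is.null(mitosis)) {
      tru <- attr(traces, "truth")
      if (!is.null(tru)) mitosis <- tru |> select("cell_id", "mitosis_time")
    }
    if (is.null(mitosis)) {
      abort("Offset mode requires `mitosis` (cell_id, mitosis_time).")
    }
    calls <- mothers |>
      distinct(.data$cell_id) |>
      inner_join(mitosis, by = "cell_id")
    if (nrow(calls) == 0) abort("mitosis not found for any cell.")
    calls |>
      mutate(
        # ties between frames round toward mitosis: bias by a microframe
        t_g1s = map_dbl(.data$mitosis_time - g1s_offset_hours + 1e-9, snap),
        t_g2 = map_dbl(.data$mitosis_time - g2_offset_hours + 1e-9, snap),
        t_mitosis = .data$mitosis_time,
        t_next_g1 = map_dbl(.data$mitosis_time + next_g1_offset_hours - 1e-9, snap),
        mode = "offset") |>
      select("cell_id", "t_g1s", "t_g2", "t_mitosis", "t_next_g1", "mode")
  } else {
    th <- geminin_thresholds
    if (!"geminin" %in% names(traces) || all(is.na(mothers$geminin))) {
      abort("Geminin mode requires a geminin channel.")
    }
    one <- function(df) {
      df <- arrange(df, .data$time_h)
      g <- df$geminin
      mx <- max(g, na.rm = TRUE)
      hi <- g >= th$appear * mx
      sustain <- th$sustain %||% 2
      run <- which(vapply(seq_along(hi), function(i) {
        all(hi[i:min(length(hi), i + sustain - 1L)]) &&
          (i + sustain - 1L) <= length(hi)
      }, logical(1)))
      if (length(run) == 0) abort(sprintf(
        "geminin appearance not found for cell %s.", df$cell_id[1]))
      i_up <- run[1]
      lo <- which(g < th$fall * mx & seq_along(g) > i_up)
      if (length(lo) == 0) abort(sprintf(
        "mitosis not found for cell %s (geminin never falls).", df$cell_id[1]))
      i_dn <- lo[1]
      tibble(cell_id = df$cell_id[1], t_g1s = df$time_h[i_up],
             t_mitosis = df$time_h[i_dn])
    }
    calls <- mothers |>
      group_by(.data$cell_id) |>
      dplyr::group_split() |>
      map(one) |>
      list_rbind()
    calls |>
      mutate(t_g2 = map_dbl(.data$t_mitosis - g2_offset_hours + 1e-9, snap),
             t_next_g1 = map_dbl(.data$t_mitosis + next_g1_offset_hours - 1e-9,
                                 snap),
             mode = "geminin") |>
      select("cell_id", "t_g1s", "t_g2", "t_mitosis", "t_next_g1", "mode")
  }
}

signal_at <- function(traces, cell, t) {
  map2(cell, t, function(cid, tt) {
    tr <- traces |> filter(.data$cell_id == cid)
    if (nrow(tr) == 0) return(NA_real_)
    tr$signal[which.min(abs(tr$time_h - tt))]
  }) |> unlist()
}

#' Quantify parental-histone inheritance per cell lineage
#'
#' For every mother with two linked daughters, reads the integrated
#' signal at the called G1/S and G2 time points and each daughter's
#' signal at next G1, normalizes everything to the mother's G1/S signal
#' (so G1/S is 1 by construction), and summarizes the cohort. The
#' conservation ratio `(d1 + d2) / G2` tests whether division itself
#' loses signal; `G2 / G1S` tests loss across S phase.
#'
#' @param traces Trace tibble including daughters (parent_id set).
#' @param calls Phase calls from [call_phases()].
#' @return An `inheritance_stats` object: list with `cells` (per-cell
#'   normalized values), `summary` (mean, SD, n per quantity), `tests`
#'   (pairwise Student t tests between the normalized quantities), and
#'   `n_excluded` (mothers without two daughters). `tidy()` returns the
#'   per-cell table, `glance()` the summary.
#' @export
quantify_inheritance <- function(traces, calls) {
  daughters <- traces |>
    filter(!is.na(.data$parent_id)) |>
    distinct(.data$cell_id, .data$parent_id)
  kids <- daughters |>
    group_by(.data$parent_id) |>
    summarise(d_ids = list(sort(.data$cell_id)), n_d = n(), .groups = "drop")
  usable <- kids |> filter(.data$n_d == 2)
  n_excluded <- nrow(calls) - nrow(usable |>
                                     inner_join(calls, by = c(parent_id = "cell_id")))
  if (n_excluded > 0) {
    warn(sprintf("%d mother(s) without two linked daughters excluded.", n_excluded))
  }
  work <- calls |>
    inner_join(usable, by = c(cell_id = "parent_id"))
  if (nrow(work) == 0) abort("No mother with two linked daughters and calls.")

  cells <- work |>
    mutate(
      g1s = signal_at(traces, .data$cell_id, .data$t_g1s),
      g2 = signal_at(traces, .data$cell_id, .data$t_g2),
      d1 = signal_at(traces, map(.data$d_ids, 1) |> unlist(), .data$t_next_g1),
      d2 = signal_at(traces, map(.data$d_ids, 2) |> unlist(), .data$t_next_g1)
    ) |>
    mutate(rel_g1s = 1,
           rel_g2 = .data$g2 / .data$g1s,
           rel_d1 = .data$d1 / .data$g1s,
           rel_d2 = .data$d2 / .data$g1s,
           rel_dsum = (.data$d1 + .data$d2) / .data$g1s,
           conservation = (.data$d1 + .data$d2) / .data$g2) |>
    select("cell_id", "g1s", "g2", "d1", "d2", "rel_g1s", "rel_g2",
           "rel_d1", "rel_d2", "rel_dsum", "conservation")

  long <- cells |>
    pivot_longer(dplyr::starts_with(c("rel_", "conservation")),
                 names_to = "quantity", values_to = "value")
  summary <- long |>
    group_by(.data$quantity) |>
    summarise(mean = mean(.data$value), sd = sd(.data$value), n = n(),
              .groups = "drop")

  pairings <- list(c("rel_g2", "rel_g1s"), c("rel_d1", "rel_d2"),
                   c("rel_dsum", "rel_g2"))
  tests <- map(pairings, function(p) {
    res <- ttest_two_sample(cells[[p[1]]], cells[[p[2]]])
    tibble(comparison = paste(p, collapse = " vs "),
           t = res$t, p_value = res$p)
  }) |> list_rbind()

  structure(list(cells = cells, summary = summary, tests = tests,
                 n_excluded = n_excluded),
            class = "inheritance_stats")
}

#' @export
print.inheritance_stats <- function(x, ...) {
  cat(sprintf("<inheritance_stats> %d cells (%d excluded)\n",
              nrow(x$cells), x$n_excluded))
  print(x$summary)
  invisible(x)
}

#' @describeIn quantify_inheritance Per-cell normalized values.
#' @param x An `inheritance_stats`.
#' @param ... Unused.
#' @method tidy inheritance_stats
#' @export
tidy.inheritance_stats <- function(x, ...) x$cells

#' @describeIn quantify_inheritance Cohort summary (mean, SD, n).
#' @method glance inheritance_stats
#' @export
glance.inheritance_stats <- function(x, ...) x$summary

#' @describeIn quantify_inheritance Boxplot of normalized signals.
#' @param object An `inheritance_stats`.
#' @method autoplot inheritance_stats
#' @export
autoplot.inheritance_stats <- function(object, ...) {
  long <- object$cells |>
    pivot_longer(c("rel_g1s", "rel_g2", "rel_d1", "rel_d2"),
                 names_to = "phase", values_to = "value") |>
    mutate(phase = factor(.data$phase,
                          levels = c("rel_g1s", "rel_g2", "rel_d1", "rel_d2"),
                          labels = c("G1/S", "G2", "Daughter 1", "Daughter 2")))
  ggplot(long, aes(x = .data$phase, y = .data$value)) +
    geom_boxplot(fill = "#92c5de", outlier.size = 0.6) +
    labs(x = NULL, y = "Signal relative to G1/S",
         title = "Parental-histone signal through one division") +
    theme_bw()
}

#' Two-sample Student t test (equal variance)
#'
#' The classic unpaired two-sided Student t test with pooled variance and
#' `n_a + n_b - 2` degrees of freedom, computed in closed form. Welch's
#' unequal-variance variant is available behind a flag. If the pooled
#' variance is zero and the means are equal, `t = 0, p = 1` by
#' convention.
#'
#' @param sample_a,sample_b Numeric vectors, each of length >= 2.
#' @param welch Use Welch's approximation instead (default `FALSE`).
#' @return A list with elements `t`, `p` (two-sided), `df`.
#' @export
ttest_two_sample <- function(sample_a, sample_b, welch = FALSE) {
  a <- sample_a[!is.na(sample_a)]
  b <- sample_b[!is.na(sample_b)]
  na <- length(a); nb <- length(b)
  if (na < 2 || nb < 2) abort("Each sample needs at least 2 observations.")
  ma <- mean(a); mb <- mean(b)
  va <- stats::var(a); vb <- stats::var(b)
  if (welch) {
    sem2 <- va / na + vb / nb
    if (sem2 == 0) {
      return(list(t = if (ma == mb) 0 else Inf * sign(ma - mb),
                  p = if (ma == mb) 1 else 0, df = NA_real_))
    }
    t <- (ma - mb) / sqrt(sem2)
    df <- sem2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  } else {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    if (sp2 == 0) {
      return(list(t = if (ma == mb) 0 else Inf * sign(ma - mb),
                  p = if (ma == mb) 1 else 0, df = na + nb - 2))
    }
    t <- (ma - mb) / sqrt(sp2 * (1 / na + 1 / nb))
    df <- na + nb - 2
  }
  list(t = t, p = 2 * pt(-abs(t), df), df = df)
}

#' G1/S-to-mitosis duration from the geminin reporter
#'
#' Calls G1/S (geminin appearance) and mitosis (geminin reduction) per
#' cell and summarizes the duration per group. Cells whose phases cannot
#' be called are excluded and counted.
#'
#' @param traces Trace tibble with a geminin channel; an optional
#'   `genotype` column (or the simulator truth) defines groups.
#' @param geminin_thresholds Passed to [call_phases()].
#' @return A tibble (genotype, mean_h, sd_h, n, n_failed).
#' @export
g1s_to_mitosis_duration <- function(traces,
                                    geminin_thresholds = list(appear = 0.5,
                                                              fall = 0.25,
                                                              sustain = 2)) {
  mothers <- traces |> filter(is.na(.data$parent_id))
  if (nrow(mothers) == 0) abort("No mother traces found.")
  geno <- NULL
  if ("genotype" %in% names(traces)) {
    geno <- traces |> distinct(.data$cell_id, .data$genotype)
  } else if (!is.null(attr(traces, "truth"))) {
    geno <- attr(traces, "truth") |> select("cell_id", "genotype")
  }
  ids <- unique(mothers$cell_id)
  rows <- map(ids, function(cid) {
    tryCatch({
      cl <- call_phases(mothers |> filter(.data$cell_id == cid),
                        mode = "geminin",
                        geminin_thresholds = geminin_thresholds)
      tibble(cell_id = cid, duration = cl$t_mitosis - cl$t_g1s)
    }, error = function(e) tibble(cell_id = cid, duration = NA_real_))
  }) |> list_rbind()
  n_failed <- sum(is.na(rows$duration))
  if (n_failed > 0) {
    warn(sprintf("%d cell(s) without callable phases excluded.", n_failed))
  }
  rows <- rows |> filter(!is.na(.data$duration))
  if (nrow(rows) == 0) abort("No cell with callable geminin phases.")
  if (!is.null(geno)) rows <- rows |> left_join(geno, by = "cell_id")
  else rows$genotype <- "all"
  rows |>
    group_by(.data$genotype) |>
    summarise(mean_h = mean(.data$duration), sd_h = sd(.data$duration),
              n = n(), .groups = "drop") |>
    mutate(n_failed = n_failed)
}
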