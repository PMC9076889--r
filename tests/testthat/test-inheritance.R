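make_trace <- function(cell_id, times, signal, geminin = NULL,
                       parent_id = NA_character_) {
  if (is.null(geminin)) geminin <- rep(0, length(times))
  tibble::tibble(cell_id = cell_id, parent_id = parent_id, time_h = times,
                 signal = signal, geminin = geminin)
}

test_that("offset-mode phase calls sit at 11/1/1 hours snapped to frames", {
  times <- seq(0, 16, by = 1 / 3)
  tr <- make_trace("m", times[times <= 12], 100)
  calls <- call_phases(tr, "offset",
                       mitosis = tibble::tibble(cell_id = "m",
                                                mitosis_time = 12))
  expect_equal(calls$t_g1s, 1)
  expect_equal(calls$t_g2, 11)
  expect_equal(calls$t_next_g1, 13)
  # double-mutant preset: 12 h before mitosis
  calls12 <- call_phases(tr, "offset", g1s_offset_hours = 12,
                         mitosis = tibble::tibble(cell_id = "m",
                                                  mitosis_time = 12))
  expect_equal(calls12$t_g1s, 0)
  # snapping to the 20-min grid, ties toward mitosis
  calls_off <- call_phases(tr, "offset",
                           mitosis = tibble::tibble(cell_id = "m",
                                                    mitosis_time = 12.1))
  expect_equal(calls_off$t_g1s, times[which.min(abs(times - 1.1))])
  expect_error(call_phases(tr, "offset"), "mitosis")
})

test_that("geminin-mode calls threshold crossings and flags missing mitosis", {
  times <- seq(0, 16, by = 1 / 3)
  gem <- as.numeric(times >= 2 & times < 13)
  tr <- make_trace("m", times, 100, geminin = gem)
  calls <- call_phases(tr, "geminin")
  expect_equal(calls$t_g1s, 2)
  expect_equal(calls$t_mitosis, times[which(times >= 13)[1]])
  # never-falling geminin is a degenerate trace
  tr_up <- make_trace("m", times, 100, geminin = as.numeric(times >= 2))
  expect_error(call_phases(tr_up, "geminin"), "mitosis not found")
  expect_error(call_phases(make_trace("m", times, 100), "offset",
                           mitosis = tibble::tibble(cell_id = "x",
                                                    mitosis_time = 1)),
               "mitosis not found")
})

test_that("lossless cohorts give exact unit ratios and symmetric daughters", {
  p <- transfer_params("lossless", p_leading = 0.5, retain_prob = 1,
                       bleach_rate = 0)
  tr <- simulate_live_cell(p, n_cells = 40, seed = 81)
  st <- quantify_inheritance(tr, call_phases(tr, "offset"))
  expect_equal(st$cells$rel_g2, rep(1, 40))
  expect_equal(st$cells$conservation, rep(1, 40))
  # re-normalizing already-normalized values changes nothing (idempotence)
  expect_equal(st$cells$rel_g2 / st$cells$rel_g1s, st$cells$rel_g2)
  # daughters split close to half and exactly complementarily
  expect_equal(st$cells$rel_d1 + st$cells$rel_d2, st$cells$rel_dsum)
  expect_lt(abs(mean(st$cells$rel_d1 - st$cells$rel_d2)),
            3 * sd(st$cells$rel_d1 - st$cells$rel_d2) / sqrt(40))
  expect_lt(abs(mean(st$cells$rel_d1) - 0.5), 0.05)
})

test_that("bleaching shows up between G1/S and daughters but barely across mitosis", {
  p <- transfer_params("bleachy", p_leading = 0.5, retain_prob = 1,
                       bleach_rate = 0.01)
  tr <- simulate_live_cell(p, n_cells = 30, seed = 82)
  st <- quantify_inheritance(tr, call_phases(tr, "offset"))
  expect_true(all(st$cells$rel_dsum < 1))
  # daughters measured 1 h after mitosis vs G2 1 h before: loss is only
  # the 2 h of continued bleaching, ~exp(-0.02)
  expect_equal(mean(st$cells$conservation), exp(-0.02), tolerance = 0.01)
})

test_that("mothers without two linked daughters are excluded with a count", {
  p <- transfer_params("lossless", p_leading = 0.5, retain_prob = 1)
  tr <- simulate_live_cell(p, n_cells = 5, seed = 83)
  tr_cut <- dplyr::filter(tr, cell_id != "c001.d2")
  attr(tr_cut, "truth") <- sim_truth(tr)
  calls <- call_phases(tr_cut, "offset")
  expect_warning(st <- quantify_inheritance(tr_cut, calls), "excluded")
  expect_equal(st$n_excluded, 1L)
  expect_equal(nrow(st$cells), 4)
})

test_that("Student t matches the closed-form cases", {
  r0 <- ttest_two_sample(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r0$t, 0)
  expect_equal(r0$p, 1)
  r1 <- ttest_two_sample(c(1, 2, 3, 4), c(11, 12, 13, 14))
  expect_lt(r1$p, 0.001)
  expect_equal(r1$df, 6)
  # zero pooled variance with equal means: p = 1 by convention
  expect_equal(ttest_two_sample(c(2, 2, 2), c(2, 2))$p, 1)
  expect_error(ttest_two_sample(1, c(1, 2)), "at least 2")
})

test_that("t statistic and p agree with the reference implementation", {
  withr::with_seed(91, {
    for (i in 1:25) {
      a <- rnorm(sample(3:30, 1), mean = runif(1, -2, 2))
      b <- rnorm(sample(3:30, 1), sd = runif(1, 0.5, 2))
      ours <- ttest_two_sample(a, b)
      ref <- t.test(a, b, var.equal = TRUE)
      expect_equal(ours$t, unname(ref$statistic), tolerance = 1e-12)
      expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
      oursw <- ttest_two_sample(a, b, welch = TRUE)
      refw <- t.test(a, b)
      expect_equal(oursw$t, unname(refw$statistic), tolerance = 1e-12)
      expect_equal(oursw$p, refw$p.value, tolerance = 1e-12)
    }
  })
})

test_that("geminin-based duration recovers the generative cell-cycle length", {
  p <- transfer_params("WT")
  tr <- simulate_live_cell(p, n_cells = 60, seed = 92, cycle_hours = 11)
  dur <- g1s_to_mitosis_duration(tr)
  expect_equal(dur$genotype, "WT")
  expect_lt(abs(dur$mean_h - 11), 1 / 3)
  # single synthetic cell: rise 2 h, fall 13 h -> 11 h
  times <- seq(0, 16, by = 1 / 3)
  one <- make_trace("m", times, 100,
                    geminin = as.numeric(times >= 2 & times < 13))
  d1 <- g1s_to_mitosis_duration(one)
  expect_equal(d1$mean_h, times[which(times >= 13)[1]] - 2)
  expect_error(g1s_to_mitosis_duration(one[0, ]), "mother")
})

test_that("tidy, glance and autoplot methods expose the fitted summaries", {
  p <- transfer_params("WT")
  tr <- simulate_live_cell(p, n_cells = 10, seed = 93)
  st <- quantify_inheritance(tr, call_phases(tr, "offset"))
  expect_s3_class(tidy(st), "tbl_df")
  expect_true(all(c("rel_g2", "conservation") %in% names(tidy(st))))
  expect_true(all(c("quantity", "mean", "sd", "n") %in% names(glance(st))))
  expect_s3_class(ggplot2::autoplot(st), "ggplot")
  gm <- toy_genome()
  sim <- simulate_espan(gm, p, sim_config(seed = 94, n_cells = 4))
  prof <- aggregate_origins(
    compute_bias(count_stranded_reads(sim$espan, gm)), gm$origins, 25000)
  expect_s3_class(tidy(prof), "tbl_df")
  expect_equal(nrow(tidy(prof)), 11)
  expect_s3_class(ggplot2::autoplot(prof), "ggplot")
  expect_true(is.numeric(glance(prof)$leading_bias_score))
})
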