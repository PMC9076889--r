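test_that("reads land in bins by midpoint and tallies match brute force", {
  gm <- toy_genome()
  # midpoint rule: a W read with midpoint 7,400 goes to bin [5000, 10000)
  one <- tibble::tibble(chrom = "chr1", start = 7350, end = 7450,
                        strand = "W", assay = "espan")
  tr <- count_stranded_reads(one, gm, 5000)
  expect_equal(tr$w[tr$start == 5000], 1)
  expect_equal(sum(tr$w) + sum(tr$c), 1)

  # empty input -> all-zero track covering the genome
  tr0 <- count_stranded_reads(one[0, ], gm, 5000)
  expect_true(all(tr0$w == 0 & tr0$c == 0))
  expect_equal(nrow(tr0), 200)

  # 1,000 random reads vs an independent one-read-at-a-time tally
  reads <- random_reads(1000, gm, seed = 21)
  tr <- count_stranded_reads(reads, gm, 5000)
  brute_w <- brute_c <- rep(0, nrow(tr))
  for (i in seq_len(nrow(reads))) {
    b <- ((reads$start[i] + reads$end[i]) %/% 2) %/% 5000 + 1
    if (reads$strand[i] == "W") brute_w[b] <- brute_w[b] + 1
    else brute_c[b] <- brute_c[b] + 1
  }
  expect_equal(tr$w, brute_w)
  expect_equal(tr$c, brute_c)
  expect_equal(sum(tr$w + tr$c), nrow(reads))
})

test_that("unknown chromosomes error and out-of-bounds reads are rejected", {
  gm <- toy_genome()
  bad <- tibble::tibble(chrom = "chrX", start = 0, end = 100,
                        strand = "W", assay = "espan")
  expect_error(count_stranded_reads(bad, gm), "chrX")
  beyond <- tibble::tibble(chrom = "chr1", start = 2e6, end = 2e6 + 100,
                           strand = "W", assay = "espan")
  expect_warning(tr <- count_stranded_reads(beyond, gm), "rejected")
  expect_equal(attr(tr, "n_rejected"), 1L)
  expect_equal(sum(tr$w + tr$c), 0)
})

test_that("bias follows the printed formula and the <4-read mask", {
  tr <- counts_track(w = c(5, 3, 6, 0, 2), c = c(5, 0, 2, 0, 2))
  b <- compute_bias(tr, min_reads = 4)
  expect_equal(b$bias[1], 0)          # W = C
  expect_true(is.na(b$bias[2]))       # total 3 < 4: masked, not zeroed
  expect_equal(b$bias[3], 0.5)        # (6 - 2) / (6 + 2)
  expect_true(is.na(b$bias[4]))       # empty bin masked
  expect_equal(b$bias[5], 0)          # total exactly 4 kept
  expect_true(all(b$bias[!is.na(b$bias)] >= -1 & b$bias[!is.na(b$bias)] <= 1))
})

test_that("bias is +/-1 exactly when one strand is empty and total passes", {
  tr <- counts_track(w = c(4, 0), c = c(0, 7))
  b <- compute_bias(tr)
  expect_equal(b$bias, c(1, -1))
})

test_that("control normalization subtracts per bin and propagates masks", {
  e <- values_track(c(0.3, 0.2, NA, 0.5))
  ctrl <- values_track(c(0.1, 0, 0.2, NA))
  nb <- normalize_bias(e, ctrl)
  expect_equal(nb$bias, c(0.2, 0.2, NA, NA))
  expect_equal(attr(nb, "provenance"), "normalized")
  # all-zero control is the identity
  z <- values_track(rep(0, 4))
  expect_equal(normalize_bias(e, z)$bias, e$bias)
  # shape mismatch errors
  expect_error(normalize_bias(e, values_track(c(0.1, 0.2))), "share")
})

test_that("smoothing is a masked-aware 11-bin window mean", {
  # unit impulse amid zeros: center becomes 1/11, support spreads 5 bins
  v <- rep(0, 31); v[16] <- 1
  sm <- smooth_bias(values_track(v), flank_bins = 5)
  expect_equal(sm$bias[16], 1 / 11)
  expect_equal(which(sm$bias > 0), 11:21)
  # brute-force window mean at every position
  brute <- vapply(seq_along(v), function(i) {
    mean(v[max(1, i - 5):min(length(v), i + 5)])
  }, numeric(1))
  expect_equal(sm$bias, brute)
  # constant track is invariant; flank 0 is the identity
  cst <- values_track(rep(0.3, 20))
  expect_equal(smooth_bias(cst, 5)$bias, rep(0.3, 20))
  expect_equal(smooth_bias(cst, 0)$bias, cst$bias)
  # masked bins are skipped, and an all-masked window stays masked
  w <- values_track(c(1, NA, 1, rep(NA, 15), 0.5))
  smw <- smooth_bias(w, 1)
  expect_equal(smw$bias[1:3], c(1, 1, 1))
  expect_true(is.na(smw$bias[10]))
})

test_that("smoothing never unmasks a min_reads-filtered interior truth", {
  # filter applies to the raw track only; smoothing may fill masked bins
  # from neighbours but bins with no unmasked neighbour stay masked
  v <- c(rep(NA, 7), 0.4, rep(NA, 7))
  sm <- smooth_bias(values_track(v), 5)
  expect_true(all(is.na(sm$bias[c(1, 2, 15)])))
  expect_equal(sm$bias[8], 0.4)
})

test_that("origin aggregation averages offsets and ranks by efficiency", {
  gm <- toy_genome(n_origins = 2, n_genes = 0)
  # identically zero bias -> zero profile
  nb <- values_track(rep(0, 200))
  prof <- aggregate_origins(nb, gm$origins, 25000)
  expect_true(all(prof$profile$mean_bias == 0))
  expect_equal(leading_bias_score(prof), 0)

  # single origin, antisymmetric -0.4 / +0.4 profile
  ori <- tibble::tibble(chrom = "chr1", position = 500000, efficiency = 0.9,
                        origin_id = "oriA")
  v <- rep(NA_real_, 200)
  cbin <- 500000 %/% 5000 + 1
  v[(cbin - 5):(cbin - 1)] <- -0.4
  v[(cbin + 1):(cbin + 5)] <- 0.4
  prof1 <- aggregate_origins(values_track(v), ori, 25000)
  left <- prof1$profile$offset_bp < 0
  right <- prof1$profile$offset_bp > 0
  expect_equal(prof1$profile$mean_bias[left], rep(-0.4, 5))
  expect_equal(prof1$profile$mean_bias[right], rep(0.4, 5))
  expect_equal(leading_bias_score(prof1), 0.4)

  # ranking: matrix rows ordered by descending efficiency
  gm10 <- toy_genome()
  prof10 <- aggregate_origins(values_track(rep(0.1, 200)), gm10$origins, 25000)
  expect_false(is.unsorted(rev(prof10$origins$efficiency)))
  expect_equal(nrow(prof10$matrix), 10)
  # mean recomputable from the matrix
  expect_equal(prof10$profile$mean_bias,
               unname(colMeans(prof10$matrix, na.rm = TRUE)))
  # flank must be a bin multiple; empty origins error
  expect_error(aggregate_origins(nb, gm10$origins, 12345), "multiple")
  expect_error(aggregate_origins(nb, gm10$origins[0, ], 25000), "origins")
})

test_that("leading_bias_score validates its window and masks", {
  v <- rep(NA_real_, 200)
  ori <- tibble::tibble(chrom = "chr1", position = 500000, efficiency = 1)
  cbin <- 500000 %/% 5000 + 1
  v[cbin + (1:5)] <- 0.2   # right side only
  prof <- aggregate_origins(values_track(v), ori, 25000)
  expect_error(leading_bias_score(prof, inner_bp = 30000, outer_bp = 25000),
               "inner_bp")
  expect_error(leading_bias_score(prof), "masked")
})

test_that("full simulated chain gives antisymmetric profile for forced leading", {
  gm <- toy_genome()
  p1 <- transfer_params("forced", p_leading = 1, retain_prob = 1)
  cfg <- sim_config(seed = 31, n_cells = 6)
  sim <- simulate_espan(gm, p1, cfg)
  eb <- compute_bias(count_stranded_reads(sim$espan, gm))
  cb <- compute_bias(count_stranded_reads(sim$brdu, gm))
  sm <- smooth_bias(normalize_bias(eb, cb))
  prof <- aggregate_origins(sm, gm$origins, 25000)
  with_sign <- prof$profile |> dplyr::filter(abs(offset_bp) >= 5000)
  expect_true(all(with_sign$mean_bias[with_sign$offset_bp > 0] > 0))
  expect_true(all(with_sign$mean_bias[with_sign$offset_bp < 0] < 0))
})

test_that("leading-bias score increases monotonically with p_leading", {
  gm <- toy_genome()
  scores <- vapply(c(0.3, 0.5, 0.7), function(p) {
    genotype_score(gm, transfer_params("x", p_leading = p, retain_prob = 1),
                   seed = 41, flank_bp = 25000)
  }, numeric(1))
  expect_true(all(diff(scores) > 0))
})
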