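#' Simulate strand-resolved eSPAN reads and a BrdU-IP control
#'
#' Emulates one pulse-labeling experiment at replication forks. Each
#' origin fires independently in each simulated cell-equivalent with
#' probability equal to its efficiency; a fired origin replicates a window
#' of `fork_speed * pulse_minutes` bp on each side. Parental histones sit
#' at `nucleosome_spacing` intervals across the replicated window, are
#' recycled with probability `retain_prob`, and land on the leading strand
#' with probability `p_leading` (else the lagging strand).
#'
#' Strand lettering follows the package's single fork-orientation
#' convention: for a rightward-moving fork the nascent leading strand is
#' the Watson (plus) strand, so right of an origin leading-strand
#' deposition yields `W` reads and left of it `C` reads (and vice versa
#' for the lagging strand). The matched BrdU-IP control draws reads
#' uniformly from both nascent strands of the same replicated windows, so
#' its expected strand bias is zero everywhere.
#'
#' @param genome A `genome_model`.
#' @param params A `transfer_params`.
#' @param config A `sim_config`; `n_cells`, `fork_speed`, `pulse_minutes`,
#'   `nucleosome_spacing`, `read_length` and `seed` are used.
#' @return A list with tibbles `espan` and `brdu`, each with columns
#'   chrom, start, end, strand (`"W"`/`"C"`), assay, origin_id.
#' @examples
#' gm <- make_genome(seed = 1)
#' sim <- simulate_espan(gm, transfer_params("WT"), sim_config(seed = 1))
#' head(sim$espan)
#' @export
simulate_espan <- function(genome, params, config = sim_config()) {
  stopifnot(inherits(genome, "genome_model"), inherits(params, "transfer_params"),
            inherits(config, "sim_config"))
  empty <- tibble(chrom = character(), start = numeric(), end = numeric(),
                  strand = character(), assay = character(),
                  origin_id = character())
  ors <- genome$origins
  if (nrow(ors) == 0) return(list(espan = empty, brdu = empty))

  half <- config$fork_speed * config$pulse_minutes   # bp replicated per side
  spacing <- config$nucleosome_spacing
  n_side <- max(1L, floor(half / spacing))
  offs <- (seq_len(n_side) - 0.5) * spacing          # histone offsets per side
  lens <- chrom_lengths(genome)

  withr::local_seed(child_seed(config$seed, "espan"))

  # which (cell, origin) pairs fire
  firings <- crossing(cell = seq_len(config$n_cells),
                      ors |> select("origin_id", "chrom", "position",
                                    "efficiency")) |>
    mutate(fired = rbinom(n(), 1L, .data$efficiency) == 1L) |>
    filter(.data$fired)

  if (nrow(firings) == 0) return(list(espan = empty, brdu = empty))

  nf <- nrow(firings)
  # histone positions: nf firings x 2 sides x n_side offsets
  side <- rep(rep(c(-1, 1), each = n_side), times = nf)
  off <- rep(rep(offs, times = 2L), times = nf)
  idx <- rep(seq_len(nf), each = 2L * n_side)
  center <- firings$position[idx] + side * off

  retained <- rbinom(length(center), 1L, params$retain_prob) == 1L
  leading <- rbinom(length(center), 1L, params$p_leading) == 1L
  # rightward fork (side = +1): leading strand is Watson; leftward inverts
  strand <- ifelse(xor(side < 0, leading), "W", "C")

  keep <- retained
  espan <- tibble(
    chrom = firings$chrom[idx][keep],
    center = center[keep],
    strand = strand[keep],
    origin_id = firings$origin_id[idx][keep]
  )
  espan <- espan |>
    mutate(start = pmax(0, round(.data$center - config$read_length / 2)),
           end = pmin(unname(lens[.data$chrom]),
                      round(.data$center + config$read_length / 2)),
           assay = "espan") |>
    filter(.data$end > .data$start) |>
    select("chrom", "start", "end", "strand", "assay", "origin_id")

  # BrdU-IP control: uniform over the replicated windows, unbiased strands
  n_brdu <- 2L * n_side
  bidx <- rep(seq_len(nf), each = n_brdu)
  bpos <- firings$position[bidx] + runif(nf * n_brdu, -half, half)
  brdu <- tibble(
    chrom = firings$chrom[bidx],
    center = bpos,
    strand = sample(c("W", "C"), nf * n_brdu, replace = TRUE),
    origin_id = firings$origin_id[bidx]
  ) |>
    mutate(start = pmax(0, round(.data$center - config$read_length / 2)),
           end = pmin(unname(lens[.data$chrom]),
                      round(.data$center + config$read_length / 2)),
           assay = "brdu_input") |>
    filter(.data$end > .data$start) |>
    select("chrom", "start", "end", "strand", "assay", "origin_id")

  list(espan = espan, brdu = brdu)
}
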