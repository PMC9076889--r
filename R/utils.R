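# Internal helpers shared across modules.

# Deterministic child seed for a named random stream, derived from one root
# seed so the assays draw from independent but reproducible streams.
child_seed <- function(seed, stream) {
  offsets <- c(genome = 101L, espan = 211L, brdu = 307L, cutrun = 401L,
               livecell = 503L, misc = 601L)
  off <- offsets[[stream]]
  as.integer((as.numeric(seed) * 48271 + off * 9973) %% 2147483587)
}

assert_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    abort(sprintf("`%s` must be a single probability in [0, 1], got %s.",
                  name, paste(format(x), collapse = ", ")))
  }
  invisible(x)
}

assert_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != as.integer(x)) {
    abort(sprintf("`%s` must be a single integer >= %d.", name, min))
  }
  invisible(as.integer(x))
}

# Masked-aware centered rolling mean: each position becomes the mean of the
# non-NA values in the window of 2*k+1 positions, truncated at the vector
# ends; positions whose window holds no defined value stay NA.
roll_mean_masked <- function(x, k) {
  n <- length(x)
  if (k == 0L || n == 0L) return(x)
  ok <- !is.na(x)
  v <- ifelse(ok, x, 0)
  cs <- c(0, cumsum(v))
  cn <- c(0, cumsum(ok))
  lo <- pmax(seq_len(n) - k, 1L)
  hi <- pmin(seq_len(n) + k, n)
  sums <- cs[hi + 1L] - cs[lo]
  cnts <- cn[hi + 1L] - cn[lo]
  out <- ifelse(cnts > 0, sums / cnts, NA_real_)
  out
}

chrom_lengths <- function(genome) {
  setNames(genome$chromosomes$length, genome$chromosomes$chrom)
}
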