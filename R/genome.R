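#' Build a toy genome with replication origins, genes and H3.3 regions
#'
#' Constructs the coordinate frame used by every simulator and analysis
#' stage: a set of chromosomes, replication origins with firing
#' efficiencies, gene models with expression quartiles, and H3.3-enriched
#' regions derived from the highly expressed genes. All coordinates are
#' 0-based half-open.
#'
#' Origins are placed at (lightly jittered) regular spacing and assigned
#' efficiencies that span `(0, 1]` in a seed-determined order, so ranked
#' heatmaps have a meaningful key. Genes are laid out in non-overlapping
#' slots, assigned expression quartiles in equal proportions
#' (Q1 = lowest expression, Q4 = highest) and an H3.3 enrichment weight
#' that increases with quartile, mirroring the preference of the H3.3
#' variant for actively transcribed genes.
#'
#' @param n_chroms Number of chromosomes.
#' @param chrom_length Length of each chromosome in bp.
#' @param n_origins Total number of replication origins (spread round-robin
#'   across chromosomes).
#' @param n_genes Total number of genes.
#' @param seed Integer seed; fixed seed gives an identical model.
#' @param min_origin_spacing Minimum center-to-center origin spacing in bp;
#'   placement that cannot honour it raises a capacity error.
#' @param gene_length Mean gene-body length in bp.
#' @param h33_weights Length-4 nonnegative, nondecreasing vector of H3.3
#'   enrichment multipliers for quartiles Q1..Q4.
#' @return A `genome_model`: a list of tibbles `chromosomes` (chrom,
#'   length), `origins` (chrom, position, efficiency, origin_id), `genes`
#'   (gene_id, chrom, start, end, strand, quartile, h33_weight) and
#'   `h33_regions` (chrom, start, end).
#' @examples
#' gm <- make_genome(1, 1e6, n_origins = 10, n_genes = 40, seed = 7)
#' table(gm$genes$quartile)
#' @export
make_genome <- function(n_chroms = 1L, chrom_length = 1e6, n_origins = 10L,
                        n_genes = 40L, seed = 1L,
                        min_origin_spacing = 50000, gene_length = 8000,
                        h33_weights = c(0.5, 1, 2, 4)) {
  n_chroms <- assert_count(n_chroms, "n_chroms", min = 1L)
  n_origins <- assert_count(n_origins, "n_origins")
  n_genes <- assert_count(n_genes, "n_genes")
  if (chrom_length <= 0) abort("`chrom_length` must be positive.")
  if (length(h33_weights) != 4L || any(h33_weights < 0) ||
      is.unsorted(h33_weights)) {
    abort("`h33_weights` must be 4 nonnegative nondecreasing values (Q1..Q4).")
  }

  chroms <- tibble(
    chrom = paste0("chr", seq_len(n_chroms)),
    length = as.numeric(chrom_length)
  )

  withr::local_seed(child_seed(seed, "genome"))

  origins <- tibble(chrom = character(), position = numeric(),
                    efficiency = numeric(), origin_id = character())
  if (n_origins > 0) {
    per_chrom <- table(factor(rep(chroms$chrom, length.out = n_origins),
                              levels = chroms$chrom))
    placed <- imap(as.list(per_chrom), function(k, cn) {
      k <- as.integer(k)
      if (k == 0L) return(NULL)
      spacing <- chrom_length / (k + 1)
      if (spacing < min_origin_spacing) {
        abort(sprintf(
          "Cannot place %d origins on a %g bp chromosome at >= %g bp spacing.",
          k, chrom_length, min_origin_spacing), class = "parenthist_capacity")
      }
      jitter <- runif(k, -0.05, 0.05) * spacing
      tibble(chrom = cn,
             position = round(seq_len(k) * spacing + jitter))
    })
    origins <- list_rbind(placed)
    # efficiencies span (0, 1]; the permutation (not the set) is random
    origins$efficiency <- sample(seq_len(n_origins) / n_origins)
    origins <- arrange(origins, .data$chrom, .data$position)
    origins$origin_id <- sprintf("ori%03d", seq_len(nrow(origins)))
  }

  genes <- tibble(gene_id = character(), chrom = character(),
                  start = numeric(), end = numeric(), strand = character(),
                  quartile = integer(), h33_weight = numeric())
  if (n_genes > 0) {
    per_chrom <- table(factor(rep(chroms$chrom, length.out = n_genes),
                              levels = chroms$chrom))
    placed <- imap(as.list(per_chrom), function(k, cn) {
      k <- as.integer(k)
      if (k == 0L) return(NULL)
      slot <- chrom_length / k
      if (slot < 1.5 * gene_length) {
        abort(sprintf(
          "Cannot place %d genes of ~%g bp on a %g bp chromosome.",
          k, gene_length, chrom_length), class = "parenthist_capacity")
      }
      len <- round(gene_length * runif(k, 0.6, 1.4))
      center <- (seq_len(k) - 0.5) * slot
      tibble(chrom = cn,
             start = pmax(0, round(center - len / 2)),
             end = pmin(chrom_length, round(center + len / 2)),
             strand = sample(c("+", "-"), k, replace = TRUE))
    })
    genes <- list_rbind(placed)
    genes$quartile <- sample(rep(1:4, length.out = n_genes))
    genes$h33_weight <- h33_weights[genes$quartile]
    genes <- arrange(genes, .data$chrom, .data$start)
    genes$gene_id <- sprintf("gene%04d", seq_len(nrow(genes)))
    genes <- select(genes, "gene_id", "chrom", "start", "end", "strand",
                    "quartile", "h33_weight")
  }

  h33 <- genes |>
    filter(.data$quartile >= 3L) |>
    mutate(start = pmax(0, .data$start - 1000),
           end = pmin(chrom_length, .data$end + 1000)) |>
    select("chrom", "start", "end")

  structure(
    list(chromosomes = chroms, origins = origins, genes = genes,
         h33_regions = h33),
    class = "genome_model")
}

#' @export
print.genome_model <- function(x, ...) {
  cat("<genome_model>\n")
  cat(sprintf("  %d chromosome(s), %s bp total\n",
              nrow(x$chromosomes), format(sum(x$chromosomes$length),
                                          big.mark = ",")))
  cat(sprintf("  %d origins, %d genes, %d H3.3 regions\n",
              nrow(x$origins), nrow(x$genes), nrow(x$h33_regions)))
  invisible(x)
}

# Bin grid tiled from coordinate 0 for every chromosome (half-open bins;
# the last bin is truncated at the chromosome end).
genome_bins <- function(genome, bin_width) {
  if (bin_width <= 0) abort("`bin_width` must be positive.")
  genome$chromosomes |>
    mutate(bins = map(.data$length, function(L) {
      starts <- (seq_len(ceiling(L / bin_width)) - 1) * bin_width
      tibble(start = starts, end = pmin(starts + bin_width, L))
    })) |>
    select("chrom", "bins") |>
    tidyr::unnest("bins")
}
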