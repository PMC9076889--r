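# File I/O: BED6, bedGraph and TSV readers/writers. All coordinates
# 0-based half-open; Watson reads are written as '+' and Crick as '-'.

#' Read and write BED6 files
#'
#' `read_bed()` parses a tab-separated BED file (3 to 6 columns) into a
#' tibble, validating coordinates line by line; `write_bed()` writes a
#' read or region tibble as BED6. For stranded reads, strand `W` maps to
#' `+` and `C` to `-` on disk.
#'
#' @param path File path.
#' @return `read_bed()`: tibble (chrom, start, end, name, score, strand)
#'   with strand translated back to `W`/`C` where `+`/`-`.
#' @examples
#' tf <- tempfile(fileext = ".bed")
#' write_bed(tibble::tibble(chrom = "chr1", start = 0, end = 100,
#'                          strand = "W", assay = "espan"), tf)
#' read_bed(tf)
#' @export
read_bed <- function(path) {
  raw <- readr::read_tsv(path, col_names = FALSE, col_types = readr::cols(
    .default = readr::col_character()), progress = FALSE)
  if (ncol(raw) < 3) abort("BED needs at least 3 columns.")
  names(raw)[1:3] <- c("chrom", "start", "end")
  start <- suppressWarnings(as.numeric(raw$start))
  end <- suppressWarnings(as.numeric(raw$end))
  bad <- which(is.na(start) | is.na(end) | start != floor(start) |
                 end != floor(end) | start < 0 | start >= end)
  if (length(bad) > 0) {
    abort(sprintf("Malformed BED line(s): %s (need integer 0 <= start < end).",
                  paste(head(bad, 5), collapse = ", ")))
  }
  out <- tibble(chrom = raw$chrom, start = start, end = end,
                name = if (ncol(raw) >= 4) raw[[4]] else ".",
                score = if (ncol(raw) >= 5)
                  suppressWarnings(as.numeric(raw[[5]])) else 0,
                strand = if (ncol(raw) >= 6) raw[[6]] else ".")
  badstr <- which(!out$strand %in% c("+", "-", "."))
  if (length(badstr) > 0) {
    abort(sprintf("Unknown strand on line(s): %s.",
                  paste(head(badstr, 5), collapse = ", ")))
  }
  out$strand <- unname(c(`+` = "W", `-` = "C", `.` = NA_character_)[out$strand])
  out
}

#' @rdname read_bed
#' @param records Tibble with chrom, start, end and optionally strand
#'   (`W`/`C`), assay (used as the BED name) and score.
#' @export
write_bed <- function(records, path) {
  strand <- if ("strand" %in% names(records)) {
    unname(ifelse(is.na(records$strand), ".",
                  c(W = "+", C = "-")[records$strand]))
  } else "."
  bed <- tibble(chrom = records$chrom,
                start = format(records$start, scientific = FALSE, trim = TRUE),
                end = format(records$end, scientific = FALSE, trim = TRUE),
                name = if ("assay" %in% names(records)) records$assay
                       else if ("name" %in% names(records)) records$name
                       else ".",
                score = if ("score" %in% names(records)) records$score else 0,
                strand = strand)
  readr::write_tsv(bed, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read and write bedGraph tracks
#'
#' `write_bedgraph()` writes a bias or density track omitting masked
#' (`NA`) bins; `read_bedgraph()` re-reads one against a known genome and
#' bin width, restoring omitted bins as masked.
#'
#' @param track A `bias_track` or `density_track`.
#' @param path File path.
#' @export
write_bedgraph <- function(track, path) {
  col <- if ("bias" %in% names(track)) "bias" else "density"
  keep <- !is.na(track[[col]])
  readr::write_tsv(
    tibble(chrom = track$chrom[keep],
           start = format(track$start[keep], scientific = FALSE, trim = TRUE),
           end = format(track$end[keep], scientific = FALSE, trim = TRUE),
           value = track[[col]][keep]),
    path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' @rdname write_bedgraph
#' @param genome A `genome_model` defining the full bin grid.
#' @param bin_width Bin width the track was written at.
#' @return `read_bedgraph()`: a `bias_track` covering every genome bin,
#'   `NA` where the file had no line.
#' @export
read_bedgraph <- function(path, genome, bin_width) {
  raw <- readr::read_tsv(path, col_names = c("chrom", "start", "end", "value"),
                         col_types = "cddd", progress = FALSE)
  grid <- genome_bins(genome, bin_width)
  out <- grid |>
    left_join(raw |> select("chrom", "start", bias = "value"),
              by = c("chrom", "start"))
  out$n_reads <- NA_integer_
  structure(out, bin_width = bin_width, min_reads = NA,
            provenance = "file", class = c("bias_track", class(grid)))
}

#' Read live-cell traces from TSV
#'
#' Expects columns cell_id, parent_id, time_h, signal and optionally
#' geminin; empty parent_id marks mother cells.
#'
#' @param path File path.
#' @return A trace tibble suitable for [call_phases()].
#' @export
read_traces <- function(path) {
  tr <- readr::read_tsv(path, col_types = readr::cols(
    cell_id = readr::col_character(), parent_id = readr::col_character(),
    .default = readr::col_double()), progress = FALSE)
  need <- c("cell_id", "parent_id", "time_h", "signal")
  miss <- setdiff(need, names(tr))
  if (length(miss) > 0) abort(sprintf("Trace file missing column(s): %s.",
                                      paste(miss, collapse = ", ")))
  if (any(tr$signal < 0, na.rm = TRUE)) abort("Signals must be nonnegative.")
  tr
}

#' @rdname read_traces
#' @param traces Trace tibble.
#' @export
write_traces <- function(traces, path) {
  readr::write_tsv(as_tibble(traces), path, progress = FALSE)
  invisible(path)
}
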