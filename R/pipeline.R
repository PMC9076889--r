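#' Assemble a full run configuration
#'
#' Bundles every parameter of an end-to-end run. Defaults are the
#' analysis constants of the method: 5 kb bias bins, 4-read mask, five
#' flanking smoothing bins, 50 kb correlation windows, 11 h / 1 h / 1 h
#' phase offsets, 40 min pulse, 20% spike-in. Unknown arguments are
#' rejected (the formals are the schema), and a run is reproducible from
#' the configuration alone.
#'
#' @param seed Root seed.
#' @param genotype Preset name (see [genotype_presets()]).
#' @param out_dir Output directory.
#' @param n_chroms,chrom_length,n_origins,n_genes Genome layout.
#' @param n_cells_espan Cell-equivalents for the eSPAN simulator.
#' @param n_reads_cutrun Reads per CUT&RUN time point.
#' @param n_cells_live Mother cells for the live-cell simulator.
#' @param bin_width,min_reads,flank_bins,flank_bp Bias-stage parameters.
#' @param window_bp Correlation window (bp).
#' @param normalization `"rpm"`, `"spikein"` or `"both"`.
#' @param live_mode Phase-calling mode, `"offset"` or `"geminin"`.
#' @param g1s_offset_hours G1/S offset for offset mode (11; 12 for the
#'   double mutant preset).
#' @return A validated `run_config` list.
#' @export
run_config <- function(seed = 1L, genotype = "WT",
                       out_dir = tempfile("parenthist_run_"),
                       n_chroms = 2L, chrom_length = 1e6,
                       n_origins = 10L, n_genes = 40L,
                       n_cells_espan = 10L, n_reads_cutrun = 100000L,
                       n_cells_live = 50L,
                       bin_width = 5000, min_reads = 4, flank_bins = 5,
                       flank_bp = 50000, window_bp = 50000,
                       normalization = "both",
                       live_mode = "offset",
                       g1s_offset_hours = if (genotype == "Mcm2-2A+Pole4KO") 12 else 11) {
  if (!normalization %in% c("rpm", "spikein", "both")) {
    abort("`normalization` must be 'rpm', 'spikein' or 'both'.")
  }
  if (!live_mode %in% c("offset", "geminin")) {
    abort("`live_mode` must be 'offset' or 'geminin'.")
  }
  cfg <- list(seed = assert_count(seed, "seed"), genotype = genotype,
              out_dir = out_dir, n_chroms = n_chroms,
              chrom_length = chrom_length, n_origins = n_origins,
              n_genes = n_genes, n_cells_espan = n_cells_espan,
              n_reads_cutrun = n_reads_cutrun, n_cells_live = n_cells_live,
              bin_width = bin_width, min_reads = min_reads,
              flank_bins = flank_bins, flank_bp = flank_bp,
              window_bp = window_bp, normalization = normalization,
              live_mode = live_mode, g1s_offset_hours = g1s_offset_hours)
  structure(cfg, class = "run_config")
}

#' Load a run configuration from a YAML file
#'
#' Unknown keys are rejected rather than silently ignored.
#'
#' @param path YAML file whose keys are [run_config()] arguments.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0) {
    abort(sprintf("Unknown configuration key(s): %s.",
                  paste(unknown, collapse = ", ")))
  }
  do.call(run_config, vals)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("Pipeline stage '%s' failed: %s", name, conditionMessage(e)),
          parent = e)
  })
}

#' Run the full simulate-and-analyze pipeline
#'
#' Executes simulate -> count -> bias -> normalize -> smooth -> aggregate
#' for the eSPAN arm, RPM and spike-in density analysis for the CUT&RUN
#' arm, and phase calling plus inheritance quantification for the
#' live-cell arm, writing every intermediate (BED6, bedGraph, TSV), a
#' YAML copy of the configuration, a log, and a checksum manifest.
#' Identical configurations (including seed) produce identical file
#' checksums.
#'
#' @param config A `run_config`.
#' @return Invisibly, a list with `manifest` (tibble file, md5, bytes),
#'   `score` (the leading-strand bias score), `stats` (inheritance
#'   summary) and `out_dir`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  logf <- out("run.log")
  logline <- function(...) {
    msg <- sprintf(...)
    cat(msg, "\n", file = logf, append = TRUE, sep = "")
    inform(msg)
  }
  cat(sprintf("parenthist %s | seed %d | genotype %s\n",
              as.character(utils::packageVersion("parenthist")),
              config$seed, config$genotype), file = logf)

  params <- transfer_params(config$genotype)
  scfg <- sim_config(seed = config$seed, n_cells = config$n_cells_espan,
                     n_reads = config$n_reads_cutrun)

  genome <- stage("genome", make_genome(
    n_chroms = config$n_chroms, chrom_length = config$chrom_length,
    n_origins = config$n_origins, n_genes = config$n_genes,
    seed = config$seed))
  write_bed(genome$origins |>
              mutate(start = .data$position, end = .data$position + 1,
                     name = .data$origin_id, score = .data$efficiency),
            out("origins.bed"))
  readr::write_tsv(genome$genes, out("genes.tsv"), progress = FALSE)
  write_bed(genome$h33_regions, out("h33_regions.bed"))
  logline("genome: %d origins, %d genes", nrow(genome$origins),
          nrow(genome$genes))

  # --- eSPAN arm -----------------------------------------------------
  sim <- stage("simulate_espan", simulate_espan(genome, params, scfg))
  write_bed(sim$espan, out("espan_reads.bed"))
  write_bed(sim$brdu, out("brdu_reads.bed"))
  espan_bias <- stage("bias", {
    et <- count_stranded_reads(sim$espan, genome, config$bin_width)
    bt <- count_stranded_reads(sim$brdu, genome, config$bin_width)
    eb <- compute_bias(et, config$min_reads)
    cb <- compute_bias(bt, config$min_reads)
    smooth_bias(normalize_bias(eb, cb), config$flank_bins)
  })
  write_bedgraph(espan_bias, out("espan_bias_smoothed.bedgraph"))
  profile <- stage("aggregate_origins",
                   aggregate_origins(espan_bias, genome$origins,
                                     config$flank_bp))
  readr::write_tsv(tidy(profile), out("origin_profile.tsv"), progress = FALSE)
  readr::write_tsv(as_tibble(profile$matrix, rownames = "origin_id"),
                   out("origin_matrix.tsv"), progress = FALSE)
  score <- leading_bias_score(profile)
  logline("eSPAN: %d reads, leading_bias_score %.4f", nrow(sim$espan), score)

  # --- CUT&RUN coverage arm ------------------------------------------
  tc <- stage("simulate_cutrun",
              simulate_cutrun_timecourse(genome, config = scfg))
  readr::write_tsv(tc$libraries, out("library_sizes.tsv"), progress = FALSE)
  dens <- stage("coverage", {
    map(seq_len(nrow(tc$libraries)), function(i) {
      t <- tc$libraries$time_h[i]
      ct <- bin_coverage(tc$reads |> filter(.data$time_h == t),
                         genome, config$bin_width)
      d <- list()
      if (config$normalization %in% c("rpm", "both")) {
        d$rpm <- rpm_normalize(ct, tc$libraries$mouse_reads[i])
      }
      if (config$normalization %in% c("spikein", "both")) {
        d$spikein <- spikein_normalize(ct, tc$libraries$human_reads[i])
      }
      d
    }) |> setNames(paste0("T", tc$libraries$time_h))
  })
  for (tn in names(dens)) for (nm in names(dens[[tn]])) {
    write_bedgraph(dens[[tn]][[nm]], out(sprintf("density_%s_%s.bedgraph", tn, nm)))
  }
  first_norm <- names(dens[[1]])[1]
  regions <- stage("region_density", {
    map(names(dens), function(tn) {
      region_density(dens[[tn]][[first_norm]], genome$h33_regions) |>
        mutate(time = tn)
    }) |> list_rbind()
  })
  readr::write_tsv(regions, out("region_density.tsv"), progress = FALSE)
  mg <- stage("metagene", metagene_profile(dens[[1]][[first_norm]], genome$genes))
  readr::write_tsv(as_tibble(mg), out("metagene_T0.tsv"), progress = FALSE)
  cm <- stage("correlation", {
    trks <- map(dens, function(d) d[[first_norm]])
    correlation_matrix(trks, config$window_bp)
  })
  readr::write_tsv(as_tibble(cm, rownames = "track"),
                   out("correlation_matrix.tsv"), progress = FALSE)
  logline("coverage: %d time points (%s normalization)", length(dens),
          config$normalization)

  # --- live-cell arm -------------------------------------------------
  traces <- stage("simulate_live_cell",
                  simulate_live_cell(params, n_cells = config$n_cells_live,
                                     seed = config$seed,
                                     cycle_hours = config$g1s_offset_hours))
  write_traces(traces, out("traces.tsv"))
  calls <- stage("call_phases",
                 call_phases(traces, mode = config$live_mode,
                             g1s_offset_hours = config$g1s_offset_hours))
  readr::write_tsv(calls, out("phase_calls.tsv"), progress = FALSE)
  stats <- stage("quantify_inheritance", quantify_inheritance(traces, calls))
  readr::write_tsv(stats$cells, out("inheritance_cells.tsv"), progress = FALSE)
  readr::write_tsv(stats$summary, out("inheritance_summary.tsv"), progress = FALSE)
  logline("live-cell: %d cells, mean G2/G1S %.3f", nrow(stats$cells),
          stats$summary$mean[stats$summary$quantity == "rel_g2"])

  # out_dir excluded so identical runs give identical checksums
  yaml::write_yaml(unclass(config)[setdiff(names(config), "out_dir")],
                   out("config.yaml"))
  files <- setdiff(list.files(config$out_dir), c("manifest.tsv", "run.log"))
  manifest <- tibble(
    file = files,
    md5 = unname(tools::md5sum(file.path(config$out_dir, files))),
    bytes = file.size(file.path(config$out_dir, files)))
  readr::write_tsv(manifest, out("manifest.tsv"), progress = FALSE)

  invisible(list(manifest = manifest, score = score, stats = stats,
                 out_dir = config$out_dir))
}
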