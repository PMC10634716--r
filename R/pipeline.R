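#' Run the full synthetic-data analysis pipeline
#'
#' Wires the stages in dependency order: simulate contacts with planted
#' truth, build the multinomial null table, call peaks, compute the
#' stratified cohesin footprint, and compute the extrusion estimates.
#' All outputs plus a machine-readable manifest (resolved configuration,
#' seed, file md5 hashes, stage status) are written under `outdir`.
#' Reruns with the same seed produce identical manifest hashes.
#'
#' @param config [sim_config()] for the generator stage.
#' @param outdir Output directory (created if needed).
#' @param null_reps Monte-Carlo reps per read count for the null table.
#' @param n_max Largest tabulated read count (read counts above reuse it).
#' @param cparams [class_params()].
#' @param callp [caller_params()].
#' @param eparams [extrusion_params()].
#' @return Invisibly, a list with the manifest and the in-memory stage
#'   results (`sim`, `table`, `peaks`, `motif_q`, `footprint`,
#'   `extrusion`).
#' @export
run_pipeline <- function(config = sim_config(), outdir = tempfile("ffrun"),
                         null_reps = 2e5, n_max = 500L,
                         cparams = class_params(),
                         callp = caller_params(),
                         eparams = extrusion_params()) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = config$seed, stages = list(), files = list())
  t0 <- Sys.time()

  sim <- simulate_dataset(config)
  pairs_path <- file.path(outdir, "contacts.pairs")
  write_contacts(sim$contacts, pairs_path)
  write_bed(sim$truth$bound_motifs, file.path(outdir, "bound_motifs.bed"))
  write_bed(sim$truth$decoy_motifs, file.path(outdir, "decoy_motifs.bed"))
  manifest$stages$simulate <- "ok"

  table <- build_null_table(n_min = callp$min_reads, n_max = n_max,
                            reps = null_reps, seed = config$seed)
  table_path <- file.path(outdir, "null_table.tsv")
  write_null_table(table, table_path)
  manifest$stages$null_table <- "ok"

  peaks <- call_peaks(sim$contacts, table, callp)
  write_bed(peaks[, .(chrom, start, end, name = sprintf("peak_%04d", .I),
                      score = stat, strand = ".", summit, pvalue, qvalue)],
            file.path(outdir, "peaks.bed"),
            extra_cols = c("summit", "pvalue", "qvalue"))
  windows <- scan_windows(sim$contacts, table, callp)
  motif_q <- assign_motif_qvalues(sim$truth$motifs, windows)
  fwrite(motif_q, file.path(outdir, "motif_qvalues.tsv"), sep = "\t")
  manifest$stages$call_peaks <- "ok"

  strata <- stratify_rad21(sim$truth$motifs, sim$truth$rad21_peaks)
  fp <- cohesin_footprint(sim$contacts, sim$truth$motifs, strata, cparams)
  if (nrow(fp$coverage)) {
    fwrite(fp$coverage, file.path(outdir, "footprint_coverage.tsv"),
           sep = "\t")
    fwrite(fp$difference, file.path(outdir, "footprint_difference.tsv"),
           sep = "\t")
  }
  manifest$stages$footprint <- "ok"

  sig_cbs <- motif_q[pvalue < callp$p_threshold]
  ext <- NULL
  if (nrow(sig_cbs)) {
    ext <- tryCatch(
      fully_extruded_fraction(sim$contacts, sig_cbs, sim$truth$motifs,
                              cparams, eparams),
      error = function(e) NULL)
  }
  ls_strata <- setNames(sim$truth$motifs$group, NULL)
  ls_strata[!sim$truth$motifs$bound] <- NA
  loop_sizes <- loop_size_by_stratum(sim$contacts, sim$truth$motifs,
                                     ls_strata, cparams)
  ext_out <- list(
    fully_extruded = if (!is.null(ext)) {
      list(point_pct = ext$point, range_lo_pct = ext$range_lo,
           range_hi_pct = ext$range_hi, n_fragments = ext$n_fragments)
    } else NULL,
    loop_size_by_group = loop_sizes
  )
  jsonlite::write_json(ext_out, file.path(outdir, "extrusion.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  manifest$stages$extrusion <- "ok"

  outfiles <- list.files(outdir, full.names = TRUE)
  outfiles <- setdiff(outfiles, file.path(outdir, "manifest.json"))
  manifest$files <- as.list(tools::md5sum(outfiles))
  names(manifest$files) <- basename(outfiles)
  manifest$elapsed_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  manifest$config <- config[setdiff(names(config), "probs")]
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(list(manifest = manifest, sim = sim, table = table,
                 peaks = peaks, motif_q = motif_q, footprint = fp,
                 extrusion = ext_out))
}
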