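#' Analyze one SNP-array sample end to end
#'
#' Runs the per-sample chain: logR segmentation, BAF mirroring and
#' segmentation, breakpoint integration, centralization, purity/ploidy/ASCN
#' fitting and event calling.
#'
#' @param sample probe data frame (`chrom`, `pos`, `logR`, `BAF`).
#' @param alpha change-point significance level.
#' @param min_markers,min_het_markers,hom_exclusion_band segmentation
#'   parameters (see [segment_logr()], [segment_baf()], [mirror_baf()]).
#' @param nperm permutations per split test.
#' @param seed seed for the permutation tests.
#' @param ... passed to [gap_fit()].
#' @return list with `segments` (integrated, centralized), `fit`
#'   (a [gap_fit()]) and `profile` (the fit's segments with event calls).
#' @export
analyze_sample <- function(sample, alpha = 0.001, min_markers = 5,
                           min_het_markers = 10, hom_exclusion_band = 0.05,
                           nperm = 999, seed = NULL, ...) {
  lseg <- segment_logr(sample, alpha = alpha, min_markers = min_markers,
                       nperm = nperm, seed = seed)
  mb <- mirror_baf(sample, hom_exclusion_band)
  bseg <- segment_baf(mb, alpha = alpha, min_markers = min_markers,
                      min_het_markers = min_het_markers, nperm = nperm,
                      seed = if (is.null(seed)) NULL else seed + 1L)
  iseg <- integrate_segments(lseg, bseg, sample, hom_exclusion_band)
  iseg <- centralize(iseg)
  fit <- gap_fit(iseg, sample = sample, ...)
  list(segments = iseg, fit = fit, profile = event_profile(fit))
}

#' Write a SEG-like segment table
#'
#' Tab-separated columns `sample`, `chrom`, `start`, `end`, `n_markers`,
#' `mean_logr`, `mean_mbaf` (plus any extra columns present).
#'
#' @param segments segment data frame.
#' @param sample_id sample label for the first column.
#' @param path file path; gzip for `.gz`.
#' @export
write_seg_table <- function(segments, sample_id, path) {
  out <- cbind(sample = sample_id, segments)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a BED-like track
#'
#' @param track data frame with `chrom`, `pos` (probe centers) and a value
#'   column; probes are expanded to their covering grid intervals.
#' @param genome the [genome_model()] defining probe spacing.
#' @param path file path.
#' @param value value column name (default `"frequency"`).
#' @export
write_track <- function(track, genome, path, value = "frequency") {
  half <- genome$probe_spacing / 2
  out <- data.frame(chrom = track$chrom,
                    start = track$pos - half + 1,
                    end = track$pos + half)
  out[[value]] <- track[[value]]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full pipeline on a simulated or provided cohort
#'
#' Simulates a cohort (or reads probe tables), analyzes every sample with
#' [analyze_sample()], and writes segment tables, per-sample fit and FGA
#' summaries, subclonality calls, amplicon tables, event-frequency tracks,
#' recurrent-region tables and a run log into `outdir`. Identical
#' configuration and seed give identical outputs.
#'
#' @param outdir output directory (created if missing).
#' @param designs list of cohort designs: each element a list with `purity`
#'   and `clones` (see [clone_spec()]); alternatively `probe_files`, a
#'   character vector of probe-table paths.
#' @param genome the [genome_model()] shared by the cohort.
#' @param seed master seed; per-sample seeds are derived from it.
#' @param n_perm permutations for the recurrence null.
#' @param probe_files optional input probe tables instead of `designs`.
#' @param ... passed to [analyze_sample()].
#' @return invisibly, a list with per-sample results and cohort summaries.
#' @export
run_pipeline <- function(outdir, designs = NULL, genome = default_genome(),
                         seed = 1, n_perm = 1000, probe_files = NULL, ...) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(outdir, "run_log.txt")
  logf <- function(...) cat(sprintf(...), "\n", file = log_path, append = TRUE)
  cat("", file = log_path)
  logf("ascnpipe %s | seed %d | %d-probe genome",
       as.character(utils::packageVersion("ascnpipe")), seed,
       nrow(genome$probes))
  samples <- list()
  if (!is.null(probe_files)) {
    for (f in probe_files) samples[[basename(f)]] <- read_probe_table(f)
  } else {
    stopifnot(length(designs) >= 1)
    for (i in seq_along(designs)) {
      d <- designs[[i]]
      id <- if (!is.null(d$id)) d$id else sprintf("sim%02d", i)
      sim <- simulate_tumor(d$purity, d$clones, genome,
                            seed = seed + i, sample_id = id)
      samples[[id]] <- sim$sample
      logf("simulated %s: purity %.2f true ploidy %.3f", id,
           d$purity, sim$truth$psi)
    }
  }
  results <- list()
  profiles <- list()
  seg_list <- list()
  fit_rows <- fga_rows <- list()
  for (id in names(samples)) {
    res <- analyze_sample(samples[[id]], seed = seed, ...)
    results[[id]] <- res
    profiles[[id]] <- res$profile
    seg_list[[id]] <- res$segments
    write_seg_table(res$profile, id,
                    file.path(outdir, paste0(id, "_segments.tsv")))
    fit_rows[[id]] <- data.frame(sample = id, purity = res$fit$purity,
                                 ploidy = res$fit$psi,
                                 score = res$fit$fit_score,
                                 degenerate = res$fit$degenerate)
    fga_rows[[id]] <- data.frame(sample = id, t(fga(res$profile)))
    logf("fit %s: purity %s ploidy %.3f", id,
         format(res$fit$purity), res$fit$psi)
  }
  utils::write.table(do.call(rbind, fit_rows), file.path(outdir, "fits.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(do.call(rbind, fga_rows), file.path(outdir, "fga.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  sub_tab <- subclonal_table(profiles)
  utils::write.table(sub_tab, file.path(outdir, "subclonal.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (ev in c("gain", "loss", "loh", "cnnai")) {
    tr <- cohort_frequency(profiles, genome, ev)
    write_track(tr, genome, file.path(outdir, paste0("freq_", ev, ".tsv")))
  }
  write_track(combined_loss_cnnai_frequency(profiles, genome), genome,
              file.path(outdir, "freq_loss_or_cnnai.tsv"))
  amp_rows <- list()
  for (id in names(results)) {
    foc <- focal_amplicons(results[[id]]$segments)
    if (nrow(foc)) amp_rows[[paste0(id, "_f")]] <- cbind(sample = id, foc)
    br <- broad_amplified_events(results[[id]]$profile, results[[id]]$fit$psi)
    if (nrow(br)) {
      common <- c("chrom", "start", "end", "n_markers", "mean_logr", "kind")
      amp_rows[[paste0(id, "_b")]] <- cbind(sample = id, br[, common])
    }
  }
  if (length(amp_rows)) {
    common <- c("sample", "chrom", "start", "end", "n_markers", "mean_logr",
                "kind")
    amps <- do.call(rbind, lapply(amp_rows, function(x) x[, common]))
    utils::write.table(amps, file.path(outdir, "amplicons.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  grid_mat <- vapply(seg_list, to_grid, numeric(nrow(genome$probes)),
                     genome = genome)
  regions <- list()
  for (dir in c("gain", "loss")) {
    null <- permutation_null(grid_mat, n_perm = n_perm, seed = seed,
                             direction = dir)
    regions[[dir]] <- significant_regions(grid_mat, genome, null,
                                          direction = dir)
  }
  regions <- do.call(rbind, regions)
  utils::write.table(regions, file.path(outdir, "recurrent_regions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  rec_amp <- recurrent_amplicons(seg_list, genome)
  utils::write.table(rec_amp, file.path(outdir, "recurrent_amplicons.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  logf("wrote %d recurrent regions, %d recurrent amplicons",
       nrow(regions), nrow(rec_amp))
  invisible(list(results = results, subclonal = sub_tab,
                 regions = regions, recurrent_amplicons = rec_amp))
}
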