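#' Pipeline run configuration
#'
#' A single nested list (JSON-serializable) parameterizes every stage of
#' a run; together with the master `seed` it reproduces a run exactly.
#' `defaultConfig()` holds the full-scale study conditions (8 subjects
#' per group, three tasks, 20 trials at 1,000 Hz downsampled to 500 Hz,
#' four bands, 7 sparsity levels, 100 random-reference realizations).
#' `demoConfig()` is a reduced configuration (one task, fewer trials,
#' 250 Hz, alpha+beta, 20 realizations) sized for quick desk runs and
#' continuous testing.
#'
#' @param seed master seed; all stage seeds derive from it.
#' @return Nested configuration list.
#' @export
defaultConfig <- function(seed = 1) {
  list(
    seed = seed,
    simulation = list(
      n_per_group = 8, patient_attenuation = 0.3, n_trials = 20,
      fs = 1000, pre_s = 1, post_s = 4, gap_s = 1,
      tasks = c("fist", "elbow", "wrist"),
      coupled_bands = c("alpha", "beta"), noise_sd = 2,
      mixing_strength = 0.2, right_fraction = 1 / 8),
    preprocess = list(bandpass = c(0.1, 45), notch = c(49, 51),
                      transition_hz = 1, resample_to = 500),
    connectivity = list(bands = c("delta", "theta", "alpha", "beta"),
                        window_s = 0.4, hop_s = 0.2, pool_windows = TRUE),
    network = list(profile = thresholdProfile(), n_realizations = 100),
    stats = list(gate_alpha = 0.05, fdr_scope = "run",
                 mas_column = "mas_upper"))
}

#' @rdname defaultConfig
#' @export
demoConfig <- function(seed = 1) {
  cfg <- defaultConfig(seed)
  cfg$simulation$n_trials <- 8
  cfg$simulation$fs <- 500
  cfg$simulation$gap_s <- 0.5
  cfg$simulation$tasks <- "fist"
  cfg$preprocess$bandpass <- c(1, 45)
  cfg$preprocess$transition_hz <- 2
  cfg$preprocess$resample_to <- 250
  cfg$connectivity$bands <- c("alpha", "beta")
  cfg$network$n_realizations <- 20
  cfg
}

validateConfig <- function(cfg) {
  need <- c("seed", "simulation", "preprocess", "connectivity", "network",
            "stats")
  miss <- setdiff(need, names(cfg))
  if (length(miss))
    stop("config is missing block(s): ", paste(miss, collapse = ", "))
  known <- names(standardBands())
  badb <- setdiff(cfg$connectivity$bands, known)
  if (length(badb))
    stop("unknown band name in config: ", paste(badb, collapse = ", "))
  badc <- setdiff(cfg$simulation$coupled_bands, known)
  if (length(badc))
    stop("unknown band name in config: ", paste(badc, collapse = ", "))
  if (cfg$simulation$n_per_group < 2)
    stop("simulation.n_per_group must be >= 2")
  pr <- cfg$network$profile
  if (is.unsorted(pr, strictly = TRUE) || any(pr <= 0 | pr >= 1))
    stop("network.profile must be strictly increasing within (0, 1)")
  invisible(TRUE)
}

## preprocess one simulated subject into per-task baseline-corrected,
## (optionally mirrored) epochs over the 19 montage nodes
preprocessSubject <- function(subject, cfg, montage = standardMontage()) {
  pp <- cfg$preprocess
  rec <- subject$recording
  rec <- notchFilter(rec, pp$notch[1], pp$notch[2],
                     transition_hz = pp$transition_hz)
  rec <- bandpassFilter(rec, pp$bandpass[1], pp$bandpass[2],
                        transition_hz = pp$transition_hz)
  if (pp$resample_to < samplingRate(rec))
    rec <- resampleRecording(rec, pp$resample_to)
  rec <- rereferenceLinkedEars(rec)
  eps <- lapply(cfg$simulation$tasks, function(tk) {
    ep <- epochRecording(rec, tk, cfg$simulation$pre_s,
                         cfg$simulation$post_s)
    ep <- baselineCorrect(ep)
    if (identical(subject$group, "patient") &&
        identical(subject$affected_side, "right"))
      ep <- mirrorLateral(ep, montage)
    ep
  })
  names(eps) <- cfg$simulation$tasks
  eps
}

#' Aggregate metric table for a cohort
#'
#' One row per subject x task x band x sparsity level, plus an
#' `"aggregate"` row per subject x task x band holding the mean across
#' levels; columns `cc`, `le`, `ge`, `path_length`, `sw`.
#'
#' @param metric_list nested list
#'   `metric_list[[subject]][[task]][[band]]` of `ThresholdMetrics`.
#' @return data.frame.
#' @export
cohortMetricTable <- function(metric_list) {
  rows <- list()
  for (sid in names(metric_list)) {
    for (tk in names(metric_list[[sid]])) {
      for (bd in names(metric_list[[sid]][[tk]])) {
        tm <- metric_list[[sid]][[tk]][[bd]]
        lv <- tm$levels
        rows[[length(rows) + 1L]] <- data.frame(
          subject_id = sid, task = tk, band = bd,
          sparsity = c(sprintf("%.2f", lv$sparsity), "aggregate"),
          cc = c(lv$cc, tm$aggregate[["cc"]]),
          le = c(lv$le, tm$aggregate[["le"]]),
          ge = c(lv$ge, tm$aggregate[["ge"]]),
          path_length = c(lv$path_length, tm$aggregate[["path_length"]]),
          sw = c(lv$sw, tm$aggregate[["sw"]]),
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Run the full pipeline
#'
#' Simulate a cohort (or reuse intermediates), preprocess, estimate
#' per-band wPLI connectivity, compute thresholded network metrics, and
#' run the group statistics, writing every artifact under `out_dir`:
#' `manifest.csv`, `conn/<subject>_<task>_<band>.csv`, `metrics.csv`,
#' `comparisons.csv`, `correlations.csv`, and a machine-readable
#' `run_manifest.json` (package version, seed, config and its hash).
#' With the same configuration and seed the metric and statistics CSVs
#' are byte-identical across runs.
#'
#' @param cfg configuration list from [defaultConfig()]/[demoConfig()],
#'   or a path to a JSON file with the same structure.
#' @param out_dir output directory (created if needed).
#' @param resume if `TRUE`, stages whose outputs already exist are
#'   skipped (connectivity matrices are re-read from `conn/`).
#' @return Invisibly, a list with `manifest`, `metric_table`,
#'   `comparisons`, `correlations`, and `out_dir`.
#' @export
runPipeline <- function(cfg = demoConfig(), out_dir, resume = FALSE) {
  if (is.character(cfg)) cfg <- readConfig(cfg)
  validateConfig(cfg)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  conn_dir <- file.path(out_dir, "conn")
  dir.create(conn_dir, showWarnings = FALSE)
  sim <- cfg$simulation
  montage <- standardMontage()
  coupling <- defaultCoupling(bands = sim$coupled_bands,
                              noise_sd = sim$noise_sd,
                              mixing_strength = sim$mixing_strength)
  stage_seeds <- deriveSeeds(cfg$seed, 2L)

  cohort <- generateCohort(
    n_per_group = sim$n_per_group, base_coupling = coupling,
    patient_attenuation = sim$patient_attenuation,
    right_fraction = sim$right_fraction, n_trials = sim$n_trials,
    fs = sim$fs, pre_s = sim$pre_s, post_s = sim$post_s,
    gap_s = sim$gap_s, tasks = sim$tasks, seed = stage_seeds[1])
  manifest <- cohortManifest(cohort)
  write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)

  bands <- cfg$connectivity$bands
  conn <- list()
  for (s in cohort) {
    sid <- s$subject_id
    paths <- outer(sim$tasks, bands, function(tk, bd)
      file.path(conn_dir, paste0(sid, "_", tk, "_", bd, ".csv")))
    if (resume && all(file.exists(paths))) {
      conn[[sid]] <- lapply(stats::setNames(sim$tasks, sim$tasks),
        function(tk) lapply(stats::setNames(bands, bands), function(bd)
          readConnectivityCSV(file.path(conn_dir,
            paste0(sid, "_", tk, "_", bd, ".csv")), band = bd)))
      next
    }
    eps <- preprocessSubject(s, cfg, montage)
    conn[[sid]] <- lapply(stats::setNames(sim$tasks, sim$tasks),
      function(tk) {
        sp <- stftEpochs(eps[[tk]], window_s = cfg$connectivity$window_s,
                         hop_s = cfg$connectivity$hop_s)
        out <- lapply(stats::setNames(bands, bands), function(bd)
          bandWpli(sp, bd, pool_windows = cfg$connectivity$pool_windows))
        for (bd in bands)
          writeConnectivityCSV(out[[bd]], file.path(conn_dir,
            paste0(sid, "_", tk, "_", bd, ".csv")))
        out
      })
  }

  nw <- cfg$network
  metric_list <- lapply(conn, function(bytask)
    lapply(bytask, function(byband)
      lapply(byband, function(cm)
        metricsOverThresholds(cm, profile = nw$profile,
                              n_realizations = nw$n_realizations,
                              seed = stage_seeds[2]))))
  metric_table <- cohortMetricTable(metric_list)
  write.csv(metric_table, file.path(out_dir, "metrics.csv"),
            row.names = FALSE)

  agg <- metric_table[metric_table$sparsity == "aggregate", ]
  comparisons <- compareCohortMetrics(
    agg, manifest, gate_alpha = cfg$stats$gate_alpha,
    fdr_scope = cfg$stats$fdr_scope)
  write.csv(comparisons, file.path(out_dir, "comparisons.csv"),
            row.names = FALSE)
  correlations <- correlateWithMas(agg, manifest,
                                   mas_column = cfg$stats$mas_column)
  write.csv(correlations, file.path(out_dir, "correlations.csv"),
            row.names = FALSE)

  writeRunManifest(cfg, out_dir)
  invisible(list(manifest = manifest, metric_table = metric_table,
                 comparisons = comparisons, correlations = correlations,
                 out_dir = out_dir))
}

#' Read / write a pipeline configuration as JSON
#'
#' @param path JSON file path.
#' @return For `readConfig`, the configuration list.
#' @export
readConfig <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  validateConfig(cfg)
  cfg
}

#' @rdname readConfig
#' @param cfg configuration list.
#' @export
writeConfig <- function(cfg, path) {
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

writeRunManifest <- function(cfg, out_dir) {
  cfg_path <- file.path(out_dir, "config.json")
  writeConfig(cfg, cfg_path)
  manifest <- list(
    package = "wpliNet",
    version = as.character(utils::packageVersion("wpliNet")),
    seed = cfg$seed,
    config_md5 = unname(tools::md5sum(cfg_path)),
    outputs = c("manifest.csv", "metrics.csv", "comparisons.csv",
                "correlations.csv", "conn/"))
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Summarize a finished run
#'
#' Prints group means and SDs per metric, task and band (aggregate
#' sparsity) and lists the FDR-significant comparisons; a pure function
#' of the CSV artifacts on disk.
#'
#' @param out_dir run directory written by [runPipeline()].
#' @param alpha significance level on the FDR-adjusted p (default 0.05).
#' @return Invisibly, a list with `summary` and `significant`
#'   data.frames.
#' @export
reportRun <- function(out_dir, alpha = 0.05) {
  cmp <- read.csv(file.path(out_dir, "comparisons.csv"))
  cat("Group means +/- SD (aggregate across sparsity levels)\n")
  for (r in seq_len(nrow(cmp))) {
    cat(sprintf("  %-4s %-6s %-12s patient %.3f +/- %.3f | control %.3f +/- %.3f\n",
                toupper(cmp$metric[r]), cmp$task[r], cmp$band[r],
                cmp$patient_mean[r], cmp$patient_sd[r],
                cmp$control_mean[r], cmp$control_sd[r]))
  }
  sig <- cmp[!is.na(cmp$p_fdr) & cmp$p_fdr < alpha, ]
  if (nrow(sig)) {
    cat("\nFDR-significant comparisons (adjusted p <", alpha, ")\n")
    for (r in seq_len(nrow(sig))) {
      df_txt <- if (is.na(sig$df[r])) "" else sprintf("(%g)", sig$df[r])
      cat(sprintf("  %-4s %-6s %-12s %s%s = %.3f, p_fdr = %.4g, d = %.2f\n",
                  toupper(sig$metric[r]), sig$task[r], sig$band[r],
                  sig$test[r], df_txt, sig$statistic[r], sig$p_fdr[r],
                  sig$cohens_d[r]))
    }
  } else {
    cat("\nno significant comparisons\n")
  }
  invisible(list(summary = cmp, significant = sig))
}
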