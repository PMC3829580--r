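#' Read and validate a pipeline run configuration
#'
#' Flat key/value YAML mirroring the arguments of the simulation and
#' analysis stages. Unknown keys are rejected; every effective value
#' (defaults included) is recorded in the manifest written by
#' [run_simulate()].
#'
#' @param path YAML file path, or `NULL` to use pure defaults.
#' @param overrides named list overriding file values (e.g. from a driver
#'   script).
#' @return Validated named list of class `run_config`.
#' @export
read_run_config <- function(path = NULL, overrides = list()) {
  defaults <- list(
    preset = "25uM", n_cells = 100, n_experiments = 5,
    protocol = "standard", alpha = 0.05, window_length = 10, seed = 1,
    out_dir = "sperca_run",
    make_stack = FALSE, stack_cells = 4,
    ramp_factor = 2.16, ramp_cells = 5, ramp_noise_sd = 5,
    ramp_factor_sd = 0.22,
    endpoint_replicates = 5)
  cfg <- defaults
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    unknown <- setdiff(names(user), names(defaults))
    if (length(unknown))
      stop_sperca("unknown config keys: ", paste(unknown, collapse = ", "))
    cfg[names(user)] <- user
  }
  cfg[names(overrides)] <- overrides
  if (!cfg$preset %in% c("1pM", "1nM", "25uM", "50uM", "25uM_lowCa",
                         "25uM_mibefradil"))
    stop_sperca("unknown preset '", cfg$preset, "'")
  if (!cfg$protocol %in% c("standard", "inhibitor"))
    stop_sperca("protocol must be 'standard' or 'inhibitor'")
  stopifnot(cfg$n_cells >= 1, cfg$n_experiments >= 1,
            cfg$alpha > 0, cfg$alpha < 1, cfg$window_length >= 2)
  structure(cfg, class = "run_config")
}

config_protocol <- function(cfg) {
  if (cfg$protocol == "inhibitor") protocol_inhibitor() else protocol_standard()
}

#' Generate a complete fixture set on disk
#'
#' Writes, under `cfg$out_dir`: per-experiment trace files with ground-truth
#' JSON sidecars, optionally an image stack + ROI masks (TIFF) for the first
#' cells of experiment 1, a family of ramp recordings, an endpoint count
#' table, and `manifest.json` listing every effective parameter and the
#' seed. Regenerating with the same config is byte-identical.
#'
#' @param cfg a `run_config` (see [read_run_config()]).
#' @return Invisibly, the manifest list.
#' @export
run_simulate <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  preset <- dde_preset(cfg$preset)
  protocol <- config_protocol(cfg)
  bundles <- simulate_cohort(preset, cfg$n_cells, cfg$n_experiments,
                             protocol = protocol, seed = cfg$seed,
                             alpha = cfg$alpha)
  trace_files <- character(0)
  for (b in bundles) {
    f <- file.path(cfg$out_dir, sprintf("traces_exp%02d.tsv", b$experiment))
    write_traces(b, f)
    trace_files <- c(trace_files, f)
  }
  stack_files <- character(0)
  if (isTRUE(cfg$make_stack)) {
    sim <- simulate_image_stack(bundles[[1]],
                                seed = child_seed(cfg$seed, 101))
    keep <- min(cfg$stack_cells, nrow(sim$positions))
    f_stack <- file.path(cfg$out_dir, "stack_exp01.tif")
    write_stack_tiff(sim$stack, f_stack)
    f_mask <- file.path(cfg$out_dir, "stack_exp01_masks.tif")
    write_mask_tiff(sim$masks, f_mask)
    stack_files <- c(f_stack, f_mask)
  }
  recs <- simulate_ramp_family(
    conductance_scale = c(DVF = 1, `DVF+drug` = cfg$ramp_factor),
    n_cells = cfg$ramp_cells, noise_sd = cfg$ramp_noise_sd,
    factor_sd = cfg$ramp_factor_sd, seed = child_seed(cfg$seed, 202))
  ramp_files <- vapply(recs, function(r) {
    f <- file.path(cfg$out_dir,
                   sprintf("ramp_%s_%s.tsv", r$cell_id,
                           gsub("[^A-Za-z0-9]", "", r$condition)))
    write_ramp(r, f)
    f
  }, character(1))
  endpoints <- simulate_endpoint_table(n_replicates = cfg$endpoint_replicates,
                                       seed = child_seed(cfg$seed, 303))
  f_end <- file.path(cfg$out_dir, "endpoints.csv")
  utils::write.csv(endpoints, f_end, row.names = FALSE)
  manifest <- c(unclass(cfg),
                list(trace_files = basename(trace_files),
                     stack_files = basename(stack_files),
                     ramp_files = basename(ramp_files),
                     endpoint_file = basename(f_end),
                     package_version = as.character(
                       utils::packageVersion("sperca"))))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Analyze a fixture set on disk
#'
#' Reads the files produced by [run_simulate()] (or equivalently formatted
#' real exports) from `cfg$out_dir` and writes: `per_cell.csv`
#' (CellResults, or ReversalResults under the inhibitor protocol),
#' `per_experiment.csv`, `per_dose.csv`, `ramp_summary.csv`,
#' `endpoint_stats.csv` and a `report.json` with the headline numbers.
#' Re-running on the same inputs is deterministic.
#'
#' @param cfg a `run_config`.
#' @return Invisibly, the report list.
#' @export
run_analyze <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  trace_files <- sort(Sys.glob(file.path(cfg$out_dir, "traces_exp*.tsv")))
  if (!length(trace_files))
    stop_sperca("no trace files found under ", cfg$out_dir)
  bundles <- lapply(trace_files, read_traces)
  inhibitor <- !is.na(event_time(bundles[[1]]$protocol, "inhibitor_on"))
  report <- list(preset = cfg$preset, n_experiments = length(bundles))
  if (inhibitor) {
    cells <- do.call(rbind, lapply(bundles, analyze_bundle_reversal,
                                   alpha = cfg$alpha,
                                   window_length = cfg$window_length))
    utils::write.csv(cells, file.path(cfg$out_dir, "per_cell.csv"),
                     row.names = FALSE)
    corr <- rise_fall_correlation(cells)
    report$percent_reversed <- 100 * mean(cells$reversed)
    report$spearman_rho <- corr$rho
    report$spearman_p <- corr$p_value
  } else {
    cells <- do.call(rbind, lapply(bundles, analyze_bundle,
                                   alpha = cfg$alpha,
                                   window_length = cfg$window_length))
    utils::write.csv(cells, file.path(cfg$out_dir, "per_cell.csv"),
                     row.names = FALSE)
    experiments <- do.call(rbind, lapply(split(cells, cells$experiment),
      function(g) summarize_experiment(g, dose_label = g$dose_label[1])))
    dose <- aggregate_doses(experiments)
    utils::write.csv(experiments, file.path(cfg$out_dir, "per_experiment.csv"),
                     row.names = FALSE)
    utils::write.csv(dose, file.path(cfg$out_dir, "per_dose.csv"),
                     row.names = FALSE)
    report$mean_percent_responsive <- dose$mean_percent_responsive
    report$mean_amplitude <- dose$mean_amplitude
  }
  ramp_files <- sort(Sys.glob(file.path(cfg$out_dir, "ramp_*.tsv")))
  if (length(ramp_files)) {
    parse <- function(f) {
      parts <- strsplit(sub("\\.tsv$", "", basename(f)), "_")[[1]]
      read_ramp(f, condition = parts[3], cell_id = parts[2])
    }
    recs <- lapply(ramp_files, parse)
    ramp_tab <- do.call(rbind, lapply(recs, function(r)
      data.frame(cell_id = r$cell_id, condition = r$condition,
                 amplitude_pA = ramp_amplitude(r),
                 reversal_mV = reversal_potential(r),
                 rectification = rectification_index(r))))
    utils::write.csv(ramp_tab, file.path(cfg$out_dir, "ramp_summary.csv"),
                     row.names = FALSE)
    wide <- split(ramp_tab, ramp_tab$cell_id)
    pct <- vapply(wide, function(g) {
      b <- g$amplitude_pA[g$condition == "DVF"]
      a <- g$amplitude_pA[g$condition != "DVF"][1]
      if (length(b) && b > 0) percent_increase(b, a) else NA_real_
    }, numeric(1))
    report$ramp_mean_percent_increase <- mean(pct, na.rm = TRUE)
  }
  f_end <- file.path(cfg$out_dir, "endpoints.csv")
  if (file.exists(f_end)) {
    endpoints <- utils::read.csv(f_end)
    stats_v <- compare_conditions(endpoints, "viability")
    stats_a <- compare_conditions(endpoints, "acrosome")
    out <- rbind(cbind(endpoint = "viability", stats_v$per_condition),
                 cbind(endpoint = "acrosome", stats_a$per_condition))
    utils::write.csv(out, file.path(cfg$out_dir, "endpoint_stats.csv"),
                     row.names = FALSE)
    report$endpoint_significant <- sum(out$significant)
  }
  jsonlite::write_json(report, file.path(cfg$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}

#' Compare pipeline estimates against simulation ground truth
#'
#' For a fixture set with ground-truth sidecars, recomputes the headline
#' quantities and tabulates generating value, recovered value, tolerance and
#' pass/fail. Tolerances are 3 standard errors of the corresponding
#' estimator under the generating preset (binomial for prevalences,
#' window-mean for amplitudes).
#'
#' @param cfg a `run_config` whose `out_dir` holds [run_simulate()] output
#'   that [run_analyze()] has processed (it is invoked if its outputs are
#'   missing).
#' @return data.frame with one row per recovered quantity; also written to
#'   `recovery.csv`.
#' @export
run_recover <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  per_cell_f <- file.path(cfg$out_dir, "per_cell.csv")
  if (!file.exists(per_cell_f)) run_analyze(cfg)
  trace_files <- sort(Sys.glob(file.path(cfg$out_dir, "traces_exp*.tsv")))
  bundles <- lapply(trace_files, read_traces)
  gt <- do.call(rbind, lapply(bundles, function(b) b$ground_truth))
  if (is.null(gt)) stop_sperca("no ground truth sidecars under ", cfg$out_dir)
  cells <- utils::read.csv(per_cell_f)
  preset <- dde_preset(cfg$preset)
  rows <- list()
  add <- function(quantity, generating, recovered, tol)
    rows[[length(rows) + 1L]] <<- data.frame(
      quantity = quantity, generating = generating, recovered = recovered,
      tolerance = tol, pass = abs(recovered - generating) <= tol)
  n_total <- nrow(gt)
  if ("responsive" %in% names(cells)) {
    p <- preset$detected_prevalence
    add("percent_responsive", 100 * p,
        100 * mean(cells$responsive),
        tol = 3 * 100 * sqrt(max(p * (1 - p), 0.25 / n_total) / n_total))
    resp <- cells$responsive & gt$is_responder
    if (any(resp)) {
      se <- sqrt(2 / cfg$window_length) * preset$noise_sd / sqrt(sum(resp))
      add("mean_true_responder_amplitude", mean(gt$true_amplitude[resp]),
          mean(cells$amplitude[resp]), tol = 3 * se + 1e-6)
    }
  }
  if ("rise_amplitude" %in% names(cells)) {
    keep <- gt$is_responder & gt$true_amplitude > 0
    se <- sqrt(2 / cfg$window_length) * preset$noise_sd / sqrt(sum(keep))
    add("mean_rise_amplitude", mean(gt$true_amplitude[keep]),
        mean(cells$rise_amplitude[keep]), tol = 3 * se + 1e-6)
  }
  out <- do.call(rbind, rows)
  utils::write.csv(out, file.path(cfg$out_dir, "recovery.csv"),
                   row.names = FALSE)
  out
}
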