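#' Run the full per-cell pipeline on one simulated (or loaded) bundle
#'
#' For every cell: build the raw trace, subtract the cell-free background
#' trace, normalize to dF % over the pre-stimulus basal window, and apply
#' the windowed responder classification. Window placement comes from the
#' bundle's protocol (control = last 10 samples before agonist application;
#' test = last 10 samples of the exposure period).
#'
#' @param bundle a `trace_bundle`.
#' @param alpha per-cell significance level.
#' @param window_length samples per classification window.
#' @return data.frame of CellResults with `dose_label` and `experiment`
#'   columns appended.
#' @export
analyze_bundle <- function(bundle, alpha = 0.05, window_length = 10) {
  stopifnot(inherits(bundle, "trace_bundle"))
  protocol <- bundle$protocol
  times <- protocol_times(protocol)
  w <- protocol_windows(protocol, n = window_length)
  t_ag <- event_time(protocol, "agonist_on")
  res <- lapply(seq_len(ncol(bundle$raw_traces)), function(i) {
    tr <- ca_trace(times, bundle$raw_traces[, i],
                   cell_id = bundle$ground_truth$cell_id[i], stage = "raw")
    tr <- background_correct(tr, bundle$background_trace)
    tr <- normalize_trace(tr, basal_window = w$control, stimulus_onset = t_ag)
    classify_response(tr, w$control, w$test, alpha = alpha,
                      window_length = window_length)
  })
  out <- do.call(rbind, res)
  out$dose_label <- bundle$preset_label
  out$experiment <- bundle$experiment %||% 1L
  out
}

#' Reversal analysis of one inhibitor-protocol bundle
#'
#' Normalizes every trace and quantifies inhibitor reversal per cell.
#'
#' @inheritParams analyze_bundle
#' @param skip_margin seconds after inhibitor application excluded from the
#'   residual window.
#' @return data.frame of ReversalResults with bundle metadata appended.
#' @export
analyze_bundle_reversal <- function(bundle, alpha = 0.05, window_length = 10,
                                    skip_margin = 30) {
  stopifnot(inherits(bundle, "trace_bundle"))
  protocol <- bundle$protocol
  times <- protocol_times(protocol)
  t_ag <- event_time(protocol, "agonist_on")
  basal <- window_before(times, t_ag, window_length)
  res <- lapply(seq_len(ncol(bundle$raw_traces)), function(i) {
    tr <- ca_trace(times, bundle$raw_traces[, i],
                   cell_id = bundle$ground_truth$cell_id[i], stage = "raw")
    tr <- background_correct(tr, bundle$background_trace)
    tr <- normalize_trace(tr, basal_window = basal, stimulus_onset = t_ag)
    classify_reversal(tr, protocol, alpha = alpha,
                      window_length = window_length,
                      skip_margin = skip_margin)
  })
  out <- do.call(rbind, res)
  out$dose_label <- bundle$preset_label
  out$experiment <- bundle$experiment %||% 1L
  out
}

#' Simulate and analyze a dose cohort end to end
#'
#' Convenience wrapper: [simulate_cohort()] then [analyze_bundle()],
#' [summarize_experiment()] per experiment and [aggregate_doses()] across
#' experiments — the workflow behind the dose-response figures.
#'
#' @inheritParams simulate_cohort
#' @param alpha per-cell significance level.
#' @return List: `cells` (pooled CellResults), `experiments` (one summary
#'   row per experiment), `dose` (across-experiment mean +/- SEM), and
#'   `bundles` (the simulated data, for recovery checks).
#' @export
run_cohort_analysis <- function(preset, n_cells = 100, n_experiments = 5,
                                protocol = protocol_standard(), seed = 1,
                                alpha = 0.05) {
  bundles <- simulate_cohort(preset, n_cells, n_experiments,
                             protocol = protocol, seed = seed, alpha = alpha)
  cells <- do.call(rbind, lapply(bundles, analyze_bundle, alpha = alpha))
  experiments <- do.call(rbind, lapply(split(cells, cells$experiment),
    function(g) summarize_experiment(g, dose_label = g$dose_label[1])))
  rownames(experiments) <- NULL
  list(cells = cells, experiments = experiments,
       dose = aggregate_doses(experiments), bundles = bundles)
}

#' Simulate and analyze an inhibitor-reversal cohort
#'
#' Responsive cells (prevalence forced to 1, as in the published per-cell
#' reversal analysis, which conditions on a preceding agonist rise) are
#' simulated under the inhibitor protocol and quantified with
#' [classify_reversal()]; the per-cell rise/fall rank correlation is
#' computed over cells with a positive rise.
#'
#' @param preset a reversal-capable `dose_preset`
#'   (default `dde_preset("25uM_mibefradil")`).
#' @param n_cells cells in the cohort.
#' @param seed integer seed.
#' @param protocol inhibitor protocol.
#' @param alpha per-cell significance level.
#' @return List: `results` (ReversalResults), `percent_reversed` (% of
#'   analyzed cells with `reversed = TRUE`), `correlation`
#'   (from [rise_fall_correlation()]), `n_excluded` (cells without a
#'   positive rise, logged for denominator bookkeeping).
#' @export
run_reversal_study <- function(preset = dde_preset("25uM_mibefradil"),
                               n_cells = 60, seed = 1,
                               protocol = protocol_inhibitor(),
                               alpha = 0.05) {
  stopifnot(inherits(preset, "dose_preset"))
  if (is.null(preset$reversal))
    stop_sperca("preset has no reversal block")
  preset$detected_prevalence <- 1  # condition on responding cells
  bundle <- simulate_cohort(preset, n_cells, 1, protocol = protocol,
                            seed = seed, alpha = alpha)[[1]]
  results <- analyze_bundle_reversal(bundle, alpha = alpha)
  list(results = results,
       percent_reversed = 100 * mean(results$reversed),
       correlation = rise_fall_correlation(results),
       n_excluded = sum(results$rise_amplitude <= 0),
       bundle = bundle)
}

#' Simulate and quantify a voltage-ramp drug study
#'
#' A family of paired baseline/drug ramp recordings is simulated and each
#' cell's current amplitude quantified over the 77-80 mV window; the
#' per-cell percent increase, reversal potentials and rectification indices
#' are returned.
#'
#' @param drug_factor conductance factor of the drug condition
#'   (default 2.16).
#' @param n_cells number of cells (default 5).
#' @param noise_sd current noise, pA.
#' @param factor_sd per-cell sd of the drug factor (default 0.22,
#'   reproducing the published spread of the percent increase at n = 5).
#' @param seed integer seed.
#' @param ... further arguments to [simulate_ramp_family()].
#' @return List: `per_cell` data.frame (baseline/drug amplitudes, percent
#'   increase, reversal potentials, rectification indices) and
#'   `mean_percent_increase`, `sem_percent_increase`.
#' @export
run_ramp_study <- function(drug_factor = 2.16, n_cells = 5, noise_sd = 5,
                           factor_sd = 0.22, seed = 1, ...) {
  recs <- simulate_ramp_family(
    conductance_scale = c(DVF = 1, `DVF+drug` = drug_factor),
    n_cells = n_cells, noise_sd = noise_sd, factor_sd = factor_sd,
    seed = seed, ...)
  cells <- unique(vapply(recs, function(r) r$cell_id, character(1)))
  per_cell <- do.call(rbind, lapply(cells, function(cid) {
    mine <- Filter(function(r) r$cell_id == cid, recs)
    cond <- vapply(mine, function(r) r$condition, character(1))
    before <- mine[[which(cond == "DVF")]]
    after <- mine[[which(cond == "DVF+drug")]]
    a0 <- ramp_amplitude(before); a1 <- ramp_amplitude(after)
    data.frame(cell_id = cid, amp_baseline = a0, amp_drug = a1,
               percent_increase = percent_increase(a0, a1),
               erev_baseline = reversal_potential(before),
               erev_drug = reversal_potential(after),
               rect_baseline = rectification_index(before),
               rect_drug = rectification_index(after))
  }))
  list(per_cell = per_cell,
       mean_percent_increase = mean(per_cell$percent_increase),
       sem_percent_increase = stats::sd(per_cell$percent_increase) /
         sqrt(nrow(per_cell)),
       recordings = recs)
}
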