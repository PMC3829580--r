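#' Default response kinetics for simulated traces
#'
#' Published recordings show the trace *shapes* (mono-exponential rise to a
#' sustained plateau, decay on washout, a brief fluorescence bump on
#' inhibitor application) without parameterizing them; these defaults are
#' package choices, overridable everywhere a `kinetics` argument appears.
#'
#' @param tau_rise agonist rise time constant, s.
#' @param tau_decay washout/inhibitor decay time constant, s.
#' @param bump_amplitude inhibitor transient bump height, dF %.
#' @param bump_width inhibitor bump full width at half maximum, s.
#' @param bump_delay bump centre relative to inhibitor application, s.
#' @param pc_amplitude positive-control (progesterone) transient peak, dF %.
#' @param pc_tau_rise,pc_tau_decay positive-control transient time constants, s.
#' @return Named list of kinetic constants.
#' @export
trace_kinetics <- function(tau_rise = 20, tau_decay = 30,
                           bump_amplitude = 10, bump_width = 15,
                           bump_delay = 7.5,
                           pc_amplitude = 80, pc_tau_rise = 5,
                           pc_tau_decay = 20) {
  list(tau_rise = tau_rise, tau_decay = tau_decay,
       bump_amplitude = bump_amplitude, bump_width = bump_width,
       bump_delay = bump_delay, pc_amplitude = pc_amplitude,
       pc_tau_rise = pc_tau_rise, pc_tau_decay = pc_tau_decay)
}

# Deterministic dF(t) profile (in %) for one cell: piecewise exponential
# segments joined continuously at the protocol events. Non-responders have
# amplitude 0 but still show the inhibitor bump and the positive-control
# transient (both occur in solvent controls too).
delta_f_profile <- function(protocol, amplitude = 0, reversal_fraction = 0,
                            kinetics = trace_kinetics()) {
  times <- protocol_times(protocol)
  df <- numeric(length(times))
  ev <- protocol$events
  bounds <- c(ev, end_of_rec = protocol$total_duration + protocol$sampling_interval)
  level <- 0  # dF level carried into each segment
  for (i in seq_along(ev)) {
    lab <- names(ev)[i]
    t0 <- ev[[i]]
    t1 <- if (i < length(ev)) ev[[i + 1]] else bounds[["end_of_rec"]]
    sel <- times >= t0 & times < t1
    dt <- times[sel] - t0
    seg <- switch(lab,
      baseline_start = rep(0, sum(sel)),
      agonist_on = amplitude + (level - amplitude) * exp(-dt / kinetics$tau_rise),
      inhibitor_on = {
        target <- amplitude * (1 - reversal_fraction)
        base <- target + (level - target) * exp(-dt / kinetics$tau_decay)
        bsd <- kinetics$bump_width / (2 * sqrt(2 * log(2)))
        base + kinetics$bump_amplitude *
          exp(-0.5 * ((dt - kinetics$bump_delay) / bsd)^2)
      },
      washout = level * exp(-dt / kinetics$tau_decay),
      positive_control_on = {
        carrier <- level * exp(-dt / kinetics$tau_decay)
        shape <- (1 - exp(-dt / kinetics$pc_tau_rise)) *
          exp(-dt / kinetics$pc_tau_decay)
        tpk <- kinetics$pc_tau_rise *
          log1p(kinetics$pc_tau_decay / kinetics$pc_tau_rise)
        peak <- (1 - exp(-tpk / kinetics$pc_tau_rise)) *
          exp(-tpk / kinetics$pc_tau_decay)
        carrier + kinetics$pc_amplitude * shape / peak
      },
      end = rep(level, sum(sel)))
    df[sel] <- seg
    if (sum(sel)) {
      # continuity: carry the segment's closing value (noise-free) forward
      dt_end <- t1 - t0
      level <- switch(lab,
        baseline_start = 0,
        agonist_on = amplitude + (level - amplitude) * exp(-dt_end / kinetics$tau_rise),
        inhibitor_on = {
          target <- amplitude * (1 - reversal_fraction)
          target + (level - target) * exp(-dt_end / kinetics$tau_decay)
        },
        washout = level * exp(-dt_end / kinetics$tau_decay),
        positive_control_on = level * exp(-dt_end / kinetics$tau_decay),
        end = level)
    }
  }
  df
}

#' Simulate one raw fluorescence trace
#'
#' Builds the deterministic dF(t) profile for a cell (flat noisy baseline;
#' on agonist application responders rise mono-exponentially to a plateau at
#' the assigned true amplitude; on washout the signal decays back to
#' baseline; on inhibitor application a brief transient bump is followed by
#' decay to `baseline + amplitude * (1 - reversal_fraction)`; the positive
#' control evokes a transient peak in every cell) and converts it
#' multiplicatively to raw fluorescence units with a positive basal level,
#' linear drift and per-sample Gaussian noise.
#'
#' @param preset a `dose_preset` supplying `noise_sd` and `drift_rate`.
#' @param protocol a `ca_protocol`.
#' @param cell_truth list with `is_responder` (logical), `true_amplitude`
#'   (dF %) and optionally `true_reversal_fraction`.
#' @param seed optional integer; same seed and inputs give a bit-identical
#'   trace.
#' @param basal basal fluorescence in arbitrary units (must be positive).
#' @param kinetics see [trace_kinetics()].
#' @return Numeric vector of raw fluorescence, one value per frame.
#' @examples
#' pre <- dde_preset("25uM")
#' tr <- simulate_trace(pre, protocol_standard(),
#'                      list(is_responder = TRUE, true_amplitude = 50),
#'                      seed = 1)
#' @export
simulate_trace <- function(preset, protocol, cell_truth, seed = NULL,
                           basal = 1000, kinetics = trace_kinetics()) {
  stopifnot(inherits(preset, "dose_preset"), inherits(protocol, "ca_protocol"))
  if (!is_scalar_number(basal) || basal <= 0)
    stop_sperca("basal fluorescence must be positive")
  amp <- if (isTRUE(cell_truth$is_responder)) cell_truth$true_amplitude else 0
  rf <- cell_truth$true_reversal_fraction %||% 0
  df <- delta_f_profile(protocol, amp, rf, kinetics)
  times <- protocol_times(protocol)
  with_seed(seed, {
    noise <- if (preset$noise_sd > 0)
      stats::rnorm(length(df), 0, preset$noise_sd) else 0
    basal * (1 + (df + preset$drift_rate * times / 60 + noise) / 100)
  })
}

#' Simulate a cohort of imaging experiments
#'
#' Generates `n_experiments` independent experiments of `n_cells` cells each.
#' Ground-truth responder labels are drawn Bernoulli at the preset's true
#' prevalence (see [true_prevalence()]); responder amplitudes come from the
#' preset's truncated amplitude mixture, so classification power is ~1 by
#' design; reversal fractions (when the preset carries a `reversal` block and
#' the protocol has an inhibitor event) are uniform over the preset range
#' plus residual scatter.
#'
#' @param preset a `dose_preset`.
#' @param n_cells cells per experiment (>= 1).
#' @param n_experiments number of independent experiments (>= 1).
#' @param protocol a `ca_protocol`.
#' @param seed integer seed; experiment `e` uses a child seed derived from it.
#' @param alpha per-cell significance used when inverting detected prevalence.
#' @param basal basal fluorescence, AU.
#' @param background constant background fluorescence added to every cell
#'   trace (a cell-free region records this level), AU.
#' @param kinetics see [trace_kinetics()].
#' @return List of `trace_bundle` objects, one per experiment. Each bundle
#'   holds `raw_traces` (time x cells matrix, background included),
#'   `background_trace`, `ground_truth` (data.frame with `cell_id`,
#'   `is_responder`, `true_amplitude`, `true_reversal_fraction`), `protocol`,
#'   `preset_label` and `seed`.
#' @export
simulate_cohort <- function(preset, n_cells, n_experiments,
                            protocol = protocol_standard(), seed = 1,
                            alpha = 0.05, basal = 1000, background = 100,
                            kinetics = trace_kinetics()) {
  stopifnot(inherits(preset, "dose_preset"), inherits(protocol, "ca_protocol"))
  if (!is_scalar_number(n_cells) || n_cells < 1)
    stop_sperca("n_cells must be >= 1")
  if (!is_scalar_number(n_experiments) || n_experiments < 1)
    stop_sperca("n_experiments must be >= 1")
  p_true <- true_prevalence(preset, alpha)
  has_inh <- !is.na(event_time(protocol, "inhibitor_on")) &&
    !is.null(preset$reversal)
  lapply(seq_len(n_experiments), function(e) {
    eseed <- child_seed(seed, e)
    with_seed(eseed, {
      is_resp <- stats::runif(n_cells) < p_true
      amp <- numeric(n_cells)
      amp[is_resp] <- sample_amplitudes(preset, sum(is_resp))
      rf <- numeric(n_cells)
      if (has_inh && any(is_resp)) {
        fr <- preset$reversal$fraction_range
        eta <- stats::rnorm(sum(is_resp), 0, preset$reversal$residual_noise_sd)
        rf[is_resp] <- stats::runif(sum(is_resp), fr[1], fr[2]) +
          eta / amp[is_resp]
      }
      raw <- vapply(seq_len(n_cells), function(i) {
        simulate_trace(preset, protocol,
                       list(is_responder = is_resp[i], true_amplitude = amp[i],
                            true_reversal_fraction = rf[i]),
                       seed = NULL, basal = basal, kinetics = kinetics) +
          background
      }, numeric(length(protocol_times(protocol))))
      structure(
        list(raw_traces = raw,
             background_trace = rep(background, nrow(raw)),
             ground_truth = data.frame(
               cell_id = sprintf("exp%02d_cell%03d", e, seq_len(n_cells)),
               is_responder = is_resp, true_amplitude = amp,
               true_reversal_fraction = rf),
             protocol = protocol, preset_label = preset$label,
             experiment = e, seed = eseed),
        class = "trace_bundle")
    })
  })
}

#' @export
print.trace_bundle <- function(x, ...) {
  cat("trace bundle: ", ncol(x$raw_traces), " cells x ", nrow(x$raw_traces),
      " frames ('", x$preset_label, "', experiment ", x$experiment, ")\n",
      sep = "")
  cat("  true responders:", sum(x$ground_truth$is_responder), "\n")
  invisible(x)
}
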