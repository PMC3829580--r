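#' Whole-cell voltage-ramp recording
#'
#' Current response to a 1 s voltage ramp from -80 to +80 mV, the protocol
#' under which divalent-free monovalent CatSper currents are quantified.
#'
#' @param voltage command voltage in mV, strictly increasing, spanning
#'   approximately -80 to +80 mV.
#' @param current recorded current in pA (same length).
#' @param condition recording condition label, e.g. `"DVF"`, `"DVF+drug"`.
#' @param cell_id cell identifier.
#' @return An object of class `ramp_recording`.
#' @export
ramp_recording <- function(voltage, current, condition = "DVF",
                           cell_id = "cell") {
  voltage <- as.numeric(voltage); current <- as.numeric(current)
  if (length(voltage) != length(current))
    stop_sperca("voltage and current must have equal length")
  if (any(diff(voltage) <= 0))
    stop_sperca("ramp voltage must be strictly increasing")
  if (min(voltage) > -79.5 || max(voltage) < 79.5)
    stop_sperca("ramp must span -80..+80 mV (within tolerance)")
  structure(list(voltage = voltage, current = current,
                 condition = condition, cell_id = cell_id),
            class = "ramp_recording")
}

#' @export
print.ramp_recording <- function(x, ...) {
  cat("ramp recording '", x$cell_id, "' (", x$condition, "): ",
      length(x$voltage), " samples, ", round(min(x$voltage)), "..",
      round(max(x$voltage)), " mV\n", sep = "")
  invisible(x)
}

#' Ramp current amplitude over a voltage window
#'
#' Mean current over the closed voltage window, by default the last 3 mV of
#' the ramp (77-80 mV) — the quantification rule used for monovalent CatSper
#' currents.
#'
#' @param rec a `ramp_recording`.
#' @param window closed voltage window in mV (default `c(77, 80)`).
#' @return Amplitude in pA.
#' @export
ramp_amplitude <- function(rec, window = c(77, 80)) {
  stopifnot(inherits(rec, "ramp_recording"), length(window) == 2)
  sel <- rec$voltage >= window[1] & rec$voltage <= window[2]
  if (sum(sel) < 2)
    stop_sperca("fewer than 2 samples in the ", window[1], "-", window[2],
                " mV window")
  mean(rec$current[sel])
}

#' Percent increase of current amplitude between two conditions
#'
#' @param before amplitude before drug application, pA; must be positive
#'   (an outward current at +77..80 mV — a non-positive value signals a bad
#'   seal or quantification failure).
#' @param after amplitude after drug application, pA.
#' @return `100 * (after - before) / before`.
#' @export
percent_increase <- function(before, after) {
  if (!is_scalar_number(before) || before <= 0)
    stop_sperca("baseline amplitude must be positive")
  100 * (after - before) / before
}

#' Reversal potential of a ramp recording
#'
#' Voltage at which the current crosses zero, by linear interpolation
#' between the bracketing samples. With several crossings (noise around the
#' reversal), the one nearest 0 mV is taken.
#'
#' @param rec a `ramp_recording`.
#' @return Reversal potential in mV, or `NA` when the current never changes
#'   sign.
#' @export
reversal_potential <- function(rec) {
  stopifnot(inherits(rec, "ramp_recording"))
  i <- rec$current; v <- rec$voltage
  s <- sign(i)
  cross <- which(s[-length(s)] * s[-1] < 0)
  exact <- which(i == 0)
  cand <- c(v[exact],
            vapply(cross, function(k) {
              v[k] + (v[k + 1] - v[k]) * (0 - i[k]) / (i[k + 1] - i[k])
            }, numeric(1)))
  if (!length(cand)) return(NA_real_)
  cand[which.min(abs(cand))]
}

#' Outward rectification index
#'
#' Ratio of the mean absolute current over the top of the ramp (77..80 mV)
#' to the mean absolute current over the bottom (-80..-77 mV). Values above
#' 1 indicate outward rectification, the signature of CatSper currents.
#'
#' @param rec a `ramp_recording`.
#' @return Dimensionless index; `NA` when the inward-limb current is zero.
#' @export
rectification_index <- function(rec) {
  stopifnot(inherits(rec, "ramp_recording"))
  hi <- rec$voltage >= 77 & rec$voltage <= 80
  lo <- rec$voltage >= -80 & rec$voltage <= -77
  if (!any(hi) || !any(lo))
    stop_sperca("ramp does not sample both voltage extremes")
  denom <- abs(mean(rec$current[lo]))
  if (denom == 0) return(NA_real_)
  abs(mean(rec$current[hi])) / denom
}

# CatSper-like outwardly rectifying IV shape with zero-crossing at 0 mV,
# scaled so the 77-80 mV windowed mean equals `amp_77_80`.
catsper_iv <- function(voltage, amp_77_80 = 50) {
  shape <- voltage / (1 + exp(-voltage / 25))
  win <- voltage >= 77 & voltage <= 80
  amp_77_80 * shape / mean(shape[win])
}

#' Simulate a family of voltage-ramp recordings
#'
#' Per cell, a baseline outwardly rectifying IV curve with reversal
#' potential at 0 mV (divalent-free symmetric Cs+ conditions) is scaled by a
#' per-condition conductance factor and overlaid with Gaussian current
#' noise. Drug application scales the current without changing the reversal
#' potential or the rectification shape. Cell-to-cell variability enters
#' through a lognormal baseline conductance (`cell_cv`) and, for non-unit
#' factors, Gaussian jitter of the condition factor (`factor_sd`) emulating
#' variable agonist efficacy.
#'
#' @param conductance_scale named positive factors, one per condition; the
#'   reference condition should have factor 1.
#' @param n_cells number of cells.
#' @param noise_sd current noise per sample, pA (default 5).
#' @param factor_sd per-cell sd of each non-unit condition factor
#'   (default 0).
#' @param baseline_pA mean baseline amplitude over 77-80 mV, pA.
#' @param cell_cv lognormal coefficient of variation of the per-cell
#'   baseline conductance (default 0.2).
#' @param voltage command voltage grid (default 1 kHz over the 1 s ramp).
#' @param seed integer seed.
#' @return List of `ramp_recording` objects (cells x conditions), with the
#'   per-cell true factors in attribute `"true_factors"`.
#' @export
simulate_ramp_family <- function(conductance_scale = c(DVF = 1,
                                                       `DVF+drug` = 2.16),
                                 n_cells = 5, noise_sd = 5, factor_sd = 0,
                                 baseline_pA = 50, cell_cv = 0.2,
                                 voltage = seq(-80, 80, length.out = 1000),
                                 seed = 1) {
  if (any(conductance_scale <= 0))
    stop_sperca("conductance factors must be positive")
  if (is.null(names(conductance_scale)))
    names(conductance_scale) <- paste0("cond", seq_along(conductance_scale))
  with_seed(seed, {
    sdlog <- sqrt(log1p(cell_cv^2))
    base_amp <- baseline_pA * stats::rlnorm(n_cells, -sdlog^2 / 2, sdlog)
    true_factors <- matrix(rep(conductance_scale, each = n_cells),
                           nrow = n_cells,
                           dimnames = list(NULL, names(conductance_scale)))
    if (factor_sd > 0) {
      jitter_cols <- which(conductance_scale != 1)
      for (j in jitter_cols)
        true_factors[, j] <- pmax(0.01,
          stats::rnorm(n_cells, conductance_scale[j], factor_sd))
    }
    recs <- list()
    for (i in seq_len(n_cells)) {
      iv0 <- catsper_iv(voltage, base_amp[i])
      for (j in seq_along(conductance_scale)) {
        cur <- iv0 * true_factors[i, j]
        if (noise_sd > 0) cur <- cur + stats::rnorm(length(cur), 0, noise_sd)
        recs[[length(recs) + 1L]] <- ramp_recording(
          voltage, cur, condition = names(conductance_scale)[j],
          cell_id = sprintf("cell%02d", i))
      }
    }
    attr(recs, "true_factors") <- true_factors
    recs
  })
}
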