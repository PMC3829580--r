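#' Dose preset: generator parameters for one exposure condition
#'
#' A preset bundles everything the synthetic-trace generator needs to emulate
#' one agonist concentration/medium condition: the fraction of cells the
#' responder classifier should flag, the mixture from which responder dF
#' amplitudes are drawn, the recording medium, and the per-sample noise and
#' drift levels.
#'
#' Amplitude-mixture components are parameterized by their *realized*
#' (truncated) mean: the underlying normal location is solved internally so
#' that the mean of the truncated component equals `mean`. This lets presets
#' encode published summary amplitudes exactly.
#'
#' @param label condition label, e.g. `"25 uM"`.
#' @param detected_prevalence fraction of cells the classifier should flag as
#'   responsive under this condition, in `[0, 1]`.
#' @param amplitude_mixture data.frame with columns `weight`, `mean`, `sd`,
#'   `lo`, `hi`: mixture weights (must sum to 1), target truncated means and
#'   spreads in dF %, and truncation bounds. Lower bounds are raised to the
#'   detectability floor (see [amplitude_floor()]) at construction.
#' @param medium `"standard"` or `"low_calcium"`.
#' @param noise_sd per-sample Gaussian noise, dF % units (default 2).
#' @param drift_rate linear baseline drift, dF % per minute (default 0).
#' @param reversal optional list describing inhibitor reversal behaviour:
#'   `fraction_range` (uniform bounds for the per-cell reversal fraction) and
#'   `residual_noise_sd` (dF %, cell-to-cell scatter of the post-inhibitor
#'   residual, calibrated against the published rise/fall correlation).
#' @return An object of class `dose_preset`.
#' @seealso [dde_preset()] for the calibrated catalog.
#' @export
dose_preset <- function(label, detected_prevalence, amplitude_mixture,
                        medium = c("standard", "low_calcium"),
                        noise_sd = 2, drift_rate = 0, reversal = NULL) {
  medium <- match.arg(medium)
  if (!is_scalar_number(detected_prevalence) ||
      detected_prevalence < 0 || detected_prevalence > 1)
    stop_sperca("detected_prevalence must be in [0, 1]")
  m <- as.data.frame(amplitude_mixture)
  need <- c("weight", "mean", "sd", "lo", "hi")
  if (!all(need %in% names(m)))
    stop_sperca("amplitude_mixture needs columns: ", paste(need, collapse = ", "))
  if (abs(sum(m$weight) - 1) > 1e-8) stop_sperca("mixture weights must sum to 1")
  if (any(m$sd < 0)) stop_sperca("mixture sds must be >= 0")
  if (!is_scalar_number(noise_sd) || noise_sd < 0)
    stop_sperca("noise_sd must be a non-negative number")
  floor_amp <- amplitude_floor(noise_sd)
  m$lo <- pmax(m$lo, floor_amp)
  if (any(m$hi <= m$lo)) stop_sperca("mixture upper bounds must exceed lower bounds")
  if (any(m$mean <= m$lo | m$mean >= m$hi))
    stop_sperca("mixture target means must lie inside their truncation bounds")
  # solve each component's normal location for the requested truncated mean
  m$mu <- mapply(tnorm_solve_location, m$mean, m$sd, m$lo, m$hi)
  structure(list(label = label, detected_prevalence = detected_prevalence,
                 amplitude_mixture = m, medium = medium, noise_sd = noise_sd,
                 drift_rate = drift_rate, reversal = reversal),
            class = "dose_preset")
}

#' @export
print.dose_preset <- function(x, ...) {
  cat("dose preset '", x$label, "' (", x$medium, " medium)\n", sep = "")
  cat("  detected prevalence:", x$detected_prevalence,
      " noise sd:", x$noise_sd, "dF%  drift:", x$drift_rate, "dF%/min\n")
  cat("  amplitude mixture (target truncated means, dF%):\n")
  print(x$amplitude_mixture[c("weight", "mean", "sd", "lo", "hi")],
        row.names = FALSE)
  if (!is.null(x$reversal))
    cat("  reversal fraction ~ U(", x$reversal$fraction_range[1], ", ",
        x$reversal$fraction_range[2], "), residual noise sd ",
        x$reversal$residual_noise_sd, " dF%\n", sep = "")
  invisible(x)
}

#' Detectability floor for responder amplitudes
#'
#' Smallest true amplitude the generator assigns to a responder: `k` times
#' the standard error of an `n`-sample window mean at the given noise level.
#' Keeping simulated responder amplitudes above this floor makes the
#' classifier's power effectively 1, so prevalence-recovery checks probe the
#' classification rule rather than borderline detectability.
#'
#' @param noise_sd per-sample noise, dF %.
#' @param n window length (default 10).
#' @param k multiple of the window-mean standard error (default 4).
#' @return Amplitude floor in dF %.
#' @export
amplitude_floor <- function(noise_sd, n = 10, k = 4) k * noise_sd / sqrt(n)

#' Calibrated dose presets
#'
#' Catalog of generator presets encoding the published summary statistics of
#' the conditions this package emulates: percentage of responsive cells and
#' mean responder amplitude at 1 pM, 1 nM, 25 uM and 50 uM agonist in
#' standard medium, the near-abolished response at 25 uM in low-Ca2+ medium
#' (where ~72% of the remaining responders fall in the lowest amplitude bin),
#' and the mibefradil-reversal condition whose per-cell reversal fractions
#' and residual scatter reproduce the published >90% reversal rate and
#' rise/fall rank correlation.
#'
#' @param name one of `"1pM"`, `"1nM"`, `"25uM"`, `"50uM"`, `"25uM_lowCa"`,
#'   `"25uM_mibefradil"`.
#' @return A `dose_preset`.
#' @examples
#' dde_preset("25uM")
#' @export
dde_preset <- function(name = c("1pM", "1nM", "25uM", "50uM", "25uM_lowCa",
                                "25uM_mibefradil")) {
  name <- match.arg(name)
  mix1 <- function(mean, sd = 3.5)           # single low-amplitude component
    data.frame(weight = 1, mean = mean, sd = sd, lo = 0, hi = 20)
  # high-dose shape: bulk 20-100% with a minor 100-200% component; the main
  # component's mean is set so the mixture mean equals the published value
  mix_high <- function(total_mean, minor_mean = 125) {
    w2 <- 0.06
    data.frame(weight = c(1 - w2, w2),
               mean = c((total_mean - w2 * minor_mean) / (1 - w2), minor_mean),
               sd = c(16, 25), lo = c(20, 100), hi = c(100, 200))
  }
  switch(name,
    "1pM" = dose_preset("1 pM", 0.211, mix1(16.7)),
    "1nM" = dose_preset("1 nM", 0.280, mix1(15.4)),
    "25uM" = dose_preset("25 uM", 0.919, mix_high(55.6)),
    "50uM" = dose_preset("50 uM", 0.919, mix_high(55.5)),
    "25uM_lowCa" = {
      w1 <- 0.722                            # published share in the (0,20] bin
      total <- 22.8
      m1 <- 13
      dose_preset("25 uM low-Ca", 0.02,
        data.frame(weight = c(w1, 1 - w1),
                   mean = c(m1, (total - w1 * m1) / (1 - w1)),
                   sd = c(3.5, 10), lo = c(0, 20), hi = c(20, 100)),
        medium = "low_calcium")
    },
    "25uM_mibefradil" = dose_preset("25 uM + mibefradil", 0.919,
      mix_high(55.6),
      reversal = list(fraction_range = c(0.9, 1.1), residual_noise_sd = 11.7)))
}

#' True responder prevalence behind a detected prevalence
#'
#' The classifier flags a fraction `alpha/2` of genuinely unresponsive cells
#' (significant *increases* at per-cell significance `alpha`). Since
#' simulated responder amplitudes sit above the detectability floor (power
#' ~1), the expected flagged fraction is `p_true + (1 - p_true) * alpha/2`.
#' This helper inverts that relation so that cohorts generated from a preset
#' are *detected* at the preset's prevalence. When the target prevalence is
#' below the false-positive floor the inversion has no solution and the
#' target itself is used as the true rate (the detected fraction then
#' exceeds the target; see the methods vignette).
#'
#' @param preset a `dose_preset` (or a prevalence in `[0,1]`).
#' @param alpha per-cell significance level of the classifier.
#' @return True Bernoulli rate used for ground-truth responder labels.
#' @export
true_prevalence <- function(preset, alpha = 0.05) {
  p <- if (inherits(preset, "dose_preset")) preset$detected_prevalence
       else preset
  stopifnot(is_scalar_number(p), p >= 0, p <= 1)
  fp <- alpha / 2
  if (p < fp) p else min(1, (p - fp) / (1 - fp))
}

#' Draw responder amplitudes from a preset's mixture
#'
#' @param preset a `dose_preset`.
#' @param n number of amplitudes.
#' @return Numeric vector of true dF % amplitudes (all above the
#'   detectability floor).
#' @export
sample_amplitudes <- function(preset, n) {
  stopifnot(inherits(preset, "dose_preset"))
  if (n == 0) return(numeric(0))
  m <- preset$amplitude_mixture
  comp <- sample.int(nrow(m), n, replace = TRUE, prob = m$weight)
  rtnorm(n, m$mu[comp], m$sd[comp], m$lo[comp], m$hi[comp])
}

# --- truncated normal helpers -------------------------------------------

tnorm_mean <- function(mu, sd, lo, hi) {
  if (sd == 0) return(mu)
  a <- (lo - mu) / sd; b <- (hi - mu) / sd
  mu + sd * (stats::dnorm(a) - stats::dnorm(b)) /
    (stats::pnorm(b) - stats::pnorm(a))
}

# location parameter giving a requested truncated mean
tnorm_solve_location <- function(target, sd, lo, hi) {
  if (sd == 0) return(target)
  stats::uniroot(function(m) tnorm_mean(m, sd, lo, hi) - target,
                 c(lo - 2 * sd, hi + 2 * sd), tol = 1e-10)$root
}

# inverse-CDF sampler; vectorized over mu/sd/lo/hi
rtnorm <- function(n, mu, sd, lo, hi) {
  plo <- stats::pnorm((lo - mu) / sd)
  phi <- stats::pnorm((hi - mu) / sd)
  mu + sd * stats::qnorm(stats::runif(n, plo, phi))
}
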