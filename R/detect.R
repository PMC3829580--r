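#' Amplitude bin labels used for response histograms
#'
#' Half-open bins `(0,20]`, `(20,100]`, `(100,200]`, `>200` (dF %). The
#' boundary convention is closed on the right, so an amplitude of exactly
#' 20% falls in the lowest bin.
#' @export
AMPLITUDE_BINS <- c("(0,20]", "(20,100]", "(100,200]", ">200")

#' Assign a response amplitude to its histogram bin
#'
#' @param amplitude dF % amplitude(s); finite.
#' @return Factor with levels [AMPLITUDE_BINS]; `NA` for non-positive
#'   amplitudes (a cell with no rise has no bin).
#' @examples
#' bin_amplitude(c(10, 20, 55.6, 150, 250, -3))
#' @export
bin_amplitude <- function(amplitude) {
  stopifnot(is.numeric(amplitude), all(is.finite(amplitude) | is.na(amplitude)))
  cut(amplitude, breaks = c(0, 20, 100, 200, Inf), labels = AMPLITUDE_BINS,
      right = TRUE)
}

# shared window validation for the detector ops
check_windows <- function(trace, control_window, test_window,
                          window_length = 10) {
  stopifnot(inherits(trace, "ca_trace"))
  if (trace$stage != "normalized")
    stop_sperca("classification expects a normalized trace")
  cw <- as.integer(control_window); tw <- as.integer(test_window)
  if (length(cw) != window_length || length(tw) != window_length)
    stop_sperca("control and test windows must each have exactly ",
                window_length, " samples")
  n <- length(trace$values)
  if (any(c(cw, tw) < 1L) || any(c(cw, tw) > n))
    stop_sperca("window indices outside the trace")
  if (length(intersect(cw, tw)))
    stop_sperca("control and test windows overlap")
  list(control = cw, test = tw)
}

# Welch two-sample p-value robust to zero-variance windows
welch_p <- function(x, y) {
  tol <- 1e-12 * max(1, abs(mean(x)), abs(mean(y)))
  if (stats::sd(x) < tol && stats::sd(y) < tol) {
    return(if (abs(mean(x) - mean(y)) < tol) 1 else 0)
  }
  stats::t.test(x, y, var.equal = FALSE)$p.value
}

#' Classify a cell as responsive from two 10-sample windows
#'
#' Implements the per-cell responder criterion: the mean of `window_length`
#' determinations of normalized fluorescence at the end of the exposure
#' period is compared with the mean of `window_length` determinations during
#' the preceding control period by a two-sided Welch two-sample t-test. A
#' cell is scored responsive when the windows differ significantly at
#' per-cell level `alpha` *and* the change is a rise (positive amplitude) —
#' responders are cells with elevated Ca2+, and only positive amplitudes are
#' binned. No multiplicity correction is applied across cells.
#'
#' @param trace a normalized `ca_trace`.
#' @param control_window,test_window disjoint integer index vectors of
#'   exactly `window_length` samples; the control window must precede the
#'   exposure.
#' @param alpha per-cell significance level (default 0.05).
#' @param window_length number of determinations per window (default 10).
#' @return One-row data.frame (a CellResult): `cell_id`, `responsive`,
#'   `p_value`, `amplitude` (test mean minus control mean, dF %; may be
#'   negative) and `amplitude_bin` (`NA` unless responsive).
#' @export
classify_response <- function(trace, control_window, test_window,
                              alpha = 0.05, window_length = 10) {
  w <- check_windows(trace, control_window, test_window, window_length)
  ctrl <- trace$values[w$control]; test <- trace$values[w$test]
  p <- welch_p(test, ctrl)
  amp <- mean(test) - mean(ctrl)
  responsive <- is.finite(p) && p < alpha && amp > 0
  data.frame(cell_id = trace$cell_id, responsive = responsive, p_value = p,
             amplitude = amp,
             amplitude_bin = if (responsive) bin_amplitude(amp)
                             else factor(NA, levels = AMPLITUDE_BINS))
}

#' Response amplitude of a cell
#'
#' Difference between the test-window mean and the control-window mean of a
#' normalized trace (dF %). Reported for every cell regardless of the
#' responder verdict and never clamped, so washout/inhibitor undershoots
#' keep their sign.
#'
#' @inheritParams classify_response
#' @return Amplitude in dF %.
#' @export
response_amplitude <- function(trace, control_window, test_window,
                               window_length = 10) {
  w <- check_windows(trace, control_window, test_window, window_length)
  mean(trace$values[w$test]) - mean(trace$values[w$control])
}
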