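#' Percent reversal of an agonist-induced rise by an inhibitor
#'
#' `100 * (rise - residual) / rise`, both amplitudes referenced to the
#' pre-agonist baseline. Values above 100% occur when the inhibitor drives
#' Ca2+ below the original baseline (seen with mibefradil at low agonist
#' doses). Cells without a preceding rise carry no defined reversal: they
#' yield `NA` with a warning rather than an error, so cohort processing can
#' log and continue.
#'
#' @param rise_amplitude agonist-window minus baseline-window dF %.
#' @param residual_amplitude post-inhibitor stable window minus baseline
#'   window, dF %.
#' @return Percent reversal (vectorized); `NA` where `rise_amplitude <= 0`.
#' @examples
#' percent_reversal(50, 0)    # full reversal
#' percent_reversal(50, -10)  # undershoot below baseline: 120%
#' @export
percent_reversal <- function(rise_amplitude, residual_amplitude) {
  stopifnot(length(rise_amplitude) == length(residual_amplitude))
  out <- 100 * (rise_amplitude - residual_amplitude) / rise_amplitude
  bad <- !is.na(rise_amplitude) & rise_amplitude <= 0
  if (any(bad)) {
    warning(sum(bad), " cell(s) without a preceding rise excluded from ",
            "percent reversal", call. = FALSE)
    out[bad] <- NA_real_
  }
  out
}

#' Quantify inhibitor reversal for one cell
#'
#' Windows taken from the protocol: baseline = last `window_length` samples
#' before agonist application; agonist plateau = last `window_length` samples
#' before inhibitor application (the protocol leaves 2.5 min for the plateau
#' to stabilize); post-inhibitor stable level = last `window_length` samples
#' before the next event (washout or positive control), which also skips the
#' documented transient fluorescence bump right after inhibitor application
#' (`skip_margin` guards the degenerate case of a very short inhibitor
#' period). A cell is `reversed` when the post-inhibitor window lies
#' significantly below the agonist window under the same Welch test as the
#' responder criterion.
#'
#' @param trace a normalized `ca_trace`.
#' @param protocol a `ca_protocol` containing `agonist_on` and `inhibitor_on`.
#' @param alpha per-cell significance level.
#' @param window_length samples per window (default 10).
#' @param skip_margin seconds after inhibitor application that may never
#'   enter the residual window (default 30).
#' @return One-row data.frame (a ReversalResult): `cell_id`,
#'   `rise_amplitude`, `residual_amplitude`, `percent_reversal`, `reversed`,
#'   `p_value`.
#' @export
classify_reversal <- function(trace, protocol, alpha = 0.05,
                              window_length = 10, skip_margin = 30) {
  stopifnot(inherits(trace, "ca_trace"), inherits(protocol, "ca_protocol"))
  if (trace$stage != "normalized")
    stop_sperca("classify_reversal expects a normalized trace")
  t_ag <- event_time(protocol, "agonist_on")
  t_inh <- event_time(protocol, "inhibitor_on")
  if (is.na(t_ag) || is.na(t_inh))
    stop_sperca("protocol must contain agonist_on and inhibitor_on events")
  after <- protocol$events[protocol$events > t_inh]
  t_stop <- if (length(after)) min(after) else protocol$total_duration
  times <- trace$time
  w_base <- window_before(times, t_ag, window_length)
  w_plat <- window_before(times, t_inh, window_length)
  w_post <- window_before(times, t_stop, window_length)
  if (min(times[w_post]) < t_inh + skip_margin)
    stop_sperca("inhibitor period too short: residual window would overlap ",
                "the post-inhibitor transient")
  base <- trace$values[w_base]; plat <- trace$values[w_plat]
  post <- trace$values[w_post]
  rise <- mean(plat) - mean(base)
  residual <- mean(post) - mean(base)
  p <- welch_p(post, plat)
  reversed <- is.finite(p) && p < alpha && mean(post) < mean(plat)
  pr <- if (rise > 0) 100 * (rise - residual) / rise else NA_real_
  data.frame(cell_id = trace$cell_id, rise_amplitude = rise,
             residual_amplitude = residual, percent_reversal = pr,
             reversed = reversed, p_value = p)
}

#' Rank correlation between agonist rise and inhibitor-induced fall
#'
#' Spearman correlation (midranks for ties, two-sided p) between each cell's
#' rise amplitude and the subsequent fall, operationalized as
#' `rise - residual` (both baseline-referenced). Only cells with a positive
#' rise enter, matching the gating used for the published per-cell scatter.
#'
#' @param results data.frame of ReversalResults ([classify_reversal()] rows).
#' @param min_cells minimum number of cells with a positive rise (default 5).
#' @return List with `rho`, `p_value` and `n` (cells used); `rho` is `NA`
#'   when every value is tied.
#' @export
rise_fall_correlation <- function(results, min_cells = 5) {
  results <- as.data.frame(results)
  keep <- !is.na(results$rise_amplitude) & results$rise_amplitude > 0
  rise <- results$rise_amplitude[keep]
  fall <- rise - results$residual_amplitude[keep]
  if (length(rise) < min_cells)
    stop_sperca("need at least ", min_cells, " cells with a positive rise")
  if (stats::sd(rise) == 0 || stats::sd(fall) == 0)
    return(list(rho = NA_real_, p_value = NA_real_, n = length(rise)))
  ct <- suppressWarnings(
    stats::cor.test(rise, fall, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = length(rise))
}
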