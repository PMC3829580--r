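bin_fraction_cols <- c("(0,20]" = "pct_bin_0_20", "(20,100]" = "pct_bin_20_100",
                       "(100,200]" = "pct_bin_100_200", ">200" = "pct_bin_gt200")

#' Summarize one imaging experiment
#'
#' Per-experiment dose summary: percentage of responsive cells, mean
#' amplitude over responders only, and amplitude-bin fractions over
#' responders only (summing to 100 when any responder exists).
#'
#' @param cells data.frame of CellResults ([classify_response()] rows).
#' @param dose_label condition label attached to the summary.
#' @return One-row data.frame: `dose_label`, `n_cells`, `n_responsive`,
#'   `percent_responsive`, `mean_amplitude` (`NA` when no responders) and one
#'   `pct_bin_*` column per amplitude bin.
#' @export
summarize_experiment <- function(cells, dose_label = "dose") {
  cells <- as.data.frame(cells)
  if (!nrow(cells)) stop_sperca("no cells to summarize")
  stopifnot(all(c("responsive", "amplitude") %in% names(cells)))
  n <- nrow(cells)
  resp <- cells[cells$responsive, , drop = FALSE]
  out <- data.frame(dose_label = dose_label, n_cells = n,
                    n_responsive = nrow(resp),
                    percent_responsive = 100 * nrow(resp) / n,
                    mean_amplitude = if (nrow(resp)) mean(resp$amplitude)
                                     else NA_real_)
  bins <- bin_amplitude(resp$amplitude)
  fr <- if (nrow(resp)) 100 * as.numeric(table(bins)) / sum(!is.na(bins))
        else rep(NA_real_, length(AMPLITUDE_BINS))
  out[bin_fraction_cols] <- as.list(fr)
  out
}

#' Aggregate per-experiment summaries into per-dose statistics
#'
#' Mean and standard error across experiments, each experiment counting as
#' one observation (the publication convention: "mean percentage +/- SEM
#' from N independent experiments"). SEM is `sd / sqrt(n)` and is reported
#' missing for a single experiment.
#'
#' @param summaries data.frame of rows from [summarize_experiment()]; may
#'   contain several doses (grouped by `dose_label`).
#' @return data.frame per dose: `n_experiments`, `mean_percent_responsive`,
#'   `sem_percent_responsive`, `mean_amplitude`, `sem_amplitude` (amplitude
#'   averaged over experiments that had responders).
#' @export
aggregate_doses <- function(summaries) {
  summaries <- as.data.frame(summaries)
  if (!nrow(summaries)) stop_sperca("no experiment summaries to aggregate")
  sem <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 2) NA_real_ else stats::sd(x) / sqrt(length(x))
  }
  res <- lapply(split(summaries, summaries$dose_label), function(g) {
    amp <- g$mean_amplitude[!is.na(g$mean_amplitude)]
    data.frame(dose_label = g$dose_label[1], n_experiments = nrow(g),
               mean_percent_responsive = mean(g$percent_responsive),
               sem_percent_responsive = sem(g$percent_responsive),
               mean_amplitude = if (length(amp)) mean(amp) else NA_real_,
               sem_amplitude = sem(g$mean_amplitude))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out[match(unique(summaries$dose_label), out$dose_label), , drop = FALSE]
}

#' Amplitude histogram over pooled responsive cells
#'
#' Fractions of responsive cells per amplitude bin, per dose when a
#' `dose_label` column is present; fractions sum to 100 within each dose.
#'
#' @param cells data.frame of CellResults, pooled across experiments.
#' @return data.frame with `dose_label`, `bin`, `percent`.
#' @export
amplitude_histogram <- function(cells) {
  cells <- as.data.frame(cells)
  resp <- cells[cells$responsive, , drop = FALSE]
  if (!nrow(resp)) stop_sperca("no responsive cells to histogram")
  if (!"dose_label" %in% names(resp)) resp$dose_label <- "all"
  out <- do.call(rbind, lapply(split(resp, resp$dose_label), function(g) {
    bins <- bin_amplitude(g$amplitude)
    data.frame(dose_label = g$dose_label[1], bin = AMPLITUDE_BINS,
               percent = 100 * as.numeric(table(bins)) / sum(!is.na(bins)))
  }))
  rownames(out) <- NULL
  out
}
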