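#' Per-cell fluorescence trace
#'
#' Container for one cell's fluorescence time series with an explicit
#' processing stage: `raw` (ROI mean intensity, AU), `corrected` (background
#' subtracted, AU) or `normalized` (dF in %, with the basal fluorescence that
#' anchored the normalization recorded in `basal_value`).
#'
#' @param time sample times in seconds, strictly increasing with constant step.
#' @param values fluorescence values (AU, or dF % once normalized).
#' @param cell_id cell identifier.
#' @param stage one of `"raw"`, `"corrected"`, `"normalized"`.
#' @param basal_value mean basal fluorescence (AU); set by [normalize_trace()].
#' @return An object of class `ca_trace`.
#' @export
ca_trace <- function(time, values, cell_id = "cell",
                     stage = c("raw", "corrected", "normalized"),
                     basal_value = NA_real_) {
  stage <- match.arg(stage)
  time <- as.numeric(time); values <- as.numeric(values)
  if (length(time) != length(values))
    stop_sperca("time and values must have equal length")
  if (length(time) < 2) stop_sperca("a trace needs at least 2 samples")
  steps <- diff(time)
  if (any(steps <= 0)) stop_sperca("trace time must be strictly increasing")
  if (diff(range(steps)) > 1e-6 * mean(steps))
    stop_sperca("trace sampling interval must be constant")
  if (stage != "normalized" && any(!is.finite(values)))
    stop_sperca("raw/corrected trace values must be finite")
  structure(list(time = time, values = values, cell_id = cell_id,
                 stage = stage, basal_value = basal_value),
            class = "ca_trace")
}

#' @export
print.ca_trace <- function(x, ...) {
  cat("ca_trace '", x$cell_id, "' (", x$stage, "): ", length(x$values),
      " samples @ ", diff(x$time[1:2]), " s\n", sep = "")
  invisible(x)
}

#' Extract the mean-intensity trace of a region of interest
#'
#' Per-frame mean pixel intensity over a mask, the standard readout for
#' single-sperm recordings where the ROI is drawn around the posterior head
#' and neck region.
#'
#' @param stack numeric array `frames x rows x cols` (as produced by
#'   [simulate_image_stack()] or [read_stack_tiff()]).
#' @param roi logical matrix (`rows x cols`), or an integer label matrix
#'   together with `label`.
#' @param label which label to extract when `roi` is a label matrix.
#' @param sampling_interval frame interval in seconds.
#' @param cell_id identifier for the resulting trace.
#' @return A raw-stage [ca_trace()].
#' @export
extract_roi_trace <- function(stack, roi, label = NULL,
                              sampling_interval = 2.5, cell_id = "cell") {
  if (length(dim(stack)) != 3L) stop_sperca("stack must be a 3-d array")
  if (!is.null(label)) roi <- roi == label
  if (!is.logical(roi)) roi <- roi > 0
  if (!all(dim(roi) == dim(stack)[2:3]))
    stop_sperca("ROI mask dimensions must match the stack frames")
  if (!any(roi)) stop_sperca("ROI mask is empty")
  vals <- apply(stack, 1, function(fr) mean(fr[roi]))
  ca_trace(seq(0, by = sampling_interval, length.out = dim(stack)[1]),
           vals, cell_id = cell_id, stage = "raw")
}

#' Subtract the cell-free background trace
#'
#' Pointwise subtraction of a background ROI trace from a cell trace. The
#' result is not clipped: the whole point of doing this *before*
#' normalization is that dF/F is offset-sensitive, so any residual additive
#' term must be removed first.
#'
#' @param trace a raw-stage `ca_trace`.
#' @param background a raw-stage `ca_trace` from a cell-free ROI (equal
#'   length and time axis), or a single constant level.
#' @return A corrected-stage `ca_trace`.
#' @export
background_correct <- function(trace, background) {
  stopifnot(inherits(trace, "ca_trace"))
  if (trace$stage != "raw")
    stop_sperca("background_correct expects a raw trace, got '", trace$stage, "'")
  bg <- if (inherits(background, "ca_trace")) {
    if (length(background$values) != length(trace$values))
      stop_sperca("trace and background lengths differ")
    if (max(abs(background$time - trace$time)) > 1e-8)
      stop_sperca("trace and background time axes differ")
    background$values
  } else if (is.numeric(background) &&
             length(background) %in% c(1L, length(trace$values))) {
    background
  } else stop_sperca("background must be a ca_trace, a constant or a vector")
  ca_trace(trace$time, trace$values - bg, cell_id = trace$cell_id,
           stage = "corrected")
}

#' Normalize a trace to percent change over basal fluorescence
#'
#' Computes `dF(t) = 100 * (F(t) - F_basal) / F_basal`, with `F_basal` the
#' mean fluorescence over a basal window recorded before any stimulus.
#'
#' @param trace a corrected-stage `ca_trace` (a raw trace is accepted when no
#'   background correction is needed). Re-normalizing an already normalized
#'   trace is an error, not a silent recompute.
#' @param basal_window integer vector of sample indices defining the basal
#'   period (default: the 10 samples before `stimulus_onset`, or the first 10
#'   samples when no onset is given).
#' @param stimulus_onset optional time (s) of the first stimulus; the basal
#'   window must end before it.
#' @return A normalized-stage `ca_trace` in dF % with `basal_value` recorded.
#' @export
normalize_trace <- function(trace, basal_window = NULL, stimulus_onset = NULL) {
  stopifnot(inherits(trace, "ca_trace"))
  if (trace$stage == "normalized")
    stop_sperca("trace is already normalized")
  if (is.null(basal_window)) {
    basal_window <- if (is.null(stimulus_onset)) 1:10
      else window_before(trace$time, stimulus_onset, 10)
  }
  basal_window <- as.integer(basal_window)
  if (any(basal_window < 1L | basal_window > length(trace$values)))
    stop_sperca("basal_window out of range")
  if (!is.null(stimulus_onset) &&
      max(trace$time[basal_window]) >= stimulus_onset)
    stop_sperca("basal window overlaps the stimulus period")
  f_basal <- mean(trace$values[basal_window])
  if (!is.finite(f_basal) || f_basal <= 0)
    stop_sperca("mean basal fluorescence is not positive; ",
                "check loading and background correction")
  ca_trace(trace$time, 100 * (trace$values - f_basal) / f_basal,
           cell_id = trace$cell_id, stage = "normalized",
           basal_value = f_basal)
}
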