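#' Perfusion protocol for a single-cell Ca2+ imaging recording
#'
#' A protocol is the ordered list of timed perfusion events of one imaging
#' run: start of the baseline period, agonist application, optional CatSper
#' inhibitor application, washout, optional positive control (progesterone)
#' and end of recording. Frames are acquired at a fixed sampling interval
#' (2.5 s in the recordings this package emulates).
#'
#' @param events named numeric vector of event times in seconds. Names must
#'   be drawn from `baseline_start`, `agonist_on`, `inhibitor_on`, `washout`,
#'   `positive_control_on`, `end`; times must be strictly increasing and
#'   `baseline_start` must precede `agonist_on` by at least 10 samples so a
#'   pre-stimulus control window exists.
#' @param sampling_interval frame interval in seconds (default 2.5).
#' @param total_duration recording length in seconds; defaults to the last
#'   event time. Must not be shorter than the last event.
#' @return An object of class `ca_protocol`.
#' @examples
#' p <- ca_protocol(c(baseline_start = 0, agonist_on = 360, washout = 540,
#'                    end = 660))
#' event_time(p, "agonist_on")
#' @export
ca_protocol <- function(events, sampling_interval = 2.5, total_duration = NULL) {
  allowed <- c("baseline_start", "agonist_on", "inhibitor_on", "washout",
               "positive_control_on", "end")
  if (is.null(names(events)) || !all(names(events) %in% allowed))
    stop_sperca("protocol events must be named with: ",
                paste(allowed, collapse = ", "))
  if (anyDuplicated(names(events)))
    stop_sperca("duplicated protocol event labels")
  if (!is_scalar_number(sampling_interval) || sampling_interval <= 0)
    stop_sperca("sampling_interval must be a positive number")
  times <- as.numeric(events)
  if (any(diff(times) <= 0))
    stop_sperca("protocol event times must be strictly increasing")
  if (!"baseline_start" %in% names(events) || !"agonist_on" %in% names(events))
    stop_sperca("protocol needs at least baseline_start and agonist_on events")
  if (events[["agonist_on"]] - events[["baseline_start"]] <
      10 * sampling_interval)
    stop_sperca("baseline_start must precede agonist_on by >= 10 samples")
  total_duration <- total_duration %||% max(times)
  if (total_duration < max(times))
    stop_sperca("total_duration is shorter than the last protocol event")
  structure(
    list(events = times[order(times)] |> stats::setNames(names(events)[order(times)]),
         sampling_interval = sampling_interval,
         total_duration = total_duration),
    class = "ca_protocol")
}

#' @export
print.ca_protocol <- function(x, ...) {
  cat("Ca2+ imaging protocol (", x$sampling_interval, " s sampling, ",
      x$total_duration, " s total)\n", sep = "")
  for (i in seq_along(x$events))
    cat(sprintf("  %6.1f s  %s\n", x$events[i], names(x$events)[i]))
  invisible(x)
}

#' Standard agonist/washout imaging protocol
#'
#' Six minutes of baseline perfusion, three minutes of agonist exposure,
#' washout with fresh medium, then a progesterone positive control before the
#' end of the recording.
#'
#' @param sampling_interval frame interval in seconds.
#' @return A `ca_protocol`.
#' @export
protocol_standard <- function(sampling_interval = 2.5) {
  ca_protocol(c(baseline_start = 0, agonist_on = 360, washout = 540,
                positive_control_on = 600, end = 690),
              sampling_interval = sampling_interval)
}

#' Agonist/inhibitor imaging protocol
#'
#' Three minutes of baseline, agonist application, CatSper inhibitor
#' (mibefradil or NNC 55-0396) added 2.5 min later once the agonist plateau
#' has stabilized, then washout and progesterone positive control.
#'
#' @param sampling_interval frame interval in seconds.
#' @return A `ca_protocol`.
#' @export
protocol_inhibitor <- function(sampling_interval = 2.5) {
  ca_protocol(c(baseline_start = 0, agonist_on = 180, inhibitor_on = 330,
                washout = 630, positive_control_on = 690, end = 780),
              sampling_interval = sampling_interval)
}

#' Time of a protocol event
#'
#' @param protocol a `ca_protocol`.
#' @param label event label.
#' @return Event time in seconds, or `NA` if the event is absent.
#' @export
event_time <- function(protocol, label) {
  stopifnot(inherits(protocol, "ca_protocol"))
  if (label %in% names(protocol$events)) protocol$events[[label]] else NA_real_
}

#' Frame acquisition times of a protocol
#'
#' @param protocol a `ca_protocol`.
#' @return Numeric vector of sample times in seconds, starting at 0.
#' @export
protocol_times <- function(protocol) {
  stopifnot(inherits(protocol, "ca_protocol"))
  seq(0, protocol$total_duration, by = protocol$sampling_interval)
}

# first event that terminates the agonist exposure period
exposure_end_time <- function(protocol) {
  after <- protocol$events[protocol$events > event_time(protocol, "agonist_on")]
  stoppers <- after[names(after) %in%
                      c("inhibitor_on", "washout", "positive_control_on", "end")]
  if (!length(stoppers)) protocol$total_duration else min(stoppers)
}

# last `n` sample indices strictly before time `t`
window_before <- function(times, t, n) {
  idx <- which(times < t)
  if (length(idx) < n)
    stop_sperca("fewer than ", n, " samples available before t = ", t, " s")
  idx[(length(idx) - n + 1L):length(idx)]
}

#' Control and test windows implied by a protocol
#'
#' The responder criterion compares the mean of `n` determinations of
#' normalized fluorescence at the end of the agonist exposure against the
#' mean of `n` determinations immediately before agonist application.
#'
#' @param protocol a `ca_protocol`.
#' @param n window length in samples (default 10).
#' @return List with integer index vectors `control` and `test`.
#' @export
protocol_windows <- function(protocol, n = 10) {
  times <- protocol_times(protocol)
  list(control = window_before(times, event_time(protocol, "agonist_on"), n),
       test = window_before(times, exposure_end_time(protocol), n))
}
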