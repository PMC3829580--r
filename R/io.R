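#' Write a trace bundle as delimited text with a JSON sidecar
#'
#' Traces go to a tab-delimited file (column 1 = time in seconds, one column
#' per cell, header row of cell ids, plus a `background` column); protocol,
#' ground truth, preset label and seed go to `<path>.json`.
#'
#' @param bundle a `trace_bundle`.
#' @param path output file path (e.g. `traces_exp01.tsv`).
#' @return `path`, invisibly.
#' @export
write_traces <- function(bundle, path) {
  stopifnot(inherits(bundle, "trace_bundle"))
  times <- protocol_times(bundle$protocol)
  df <- data.frame(time_s = times, bundle$raw_traces,
                   background = bundle$background_trace,
                   check.names = FALSE)
  names(df) <- c("time_s", bundle$ground_truth$cell_id, "background")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(
    stage = "raw",
    preset_label = bundle$preset_label,
    experiment = bundle$experiment,
    seed = bundle$seed,
    protocol = list(events = as.list(bundle$protocol$events),
                    sampling_interval = bundle$protocol$sampling_interval,
                    total_duration = bundle$protocol$total_duration),
    ground_truth = bundle$ground_truth)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  invisible(path)
}

#' Read a trace bundle written by [write_traces()]
#'
#' @param path trace file path; `<path>.json` must exist alongside.
#' @return A `trace_bundle`.
#' @export
read_traces <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  protocol <- ca_protocol(unlist(meta$protocol$events),
                          sampling_interval = meta$protocol$sampling_interval,
                          total_duration = meta$protocol$total_duration)
  cell_cols <- setdiff(names(df), c("time_s", "background"))
  gt <- as.data.frame(meta$ground_truth)
  structure(
    list(raw_traces = as.matrix(df[cell_cols]),
         background_trace = df$background,
         ground_truth = gt, protocol = protocol,
         preset_label = meta$preset_label, experiment = meta$experiment,
         seed = meta$seed),
    class = "trace_bundle")
}

#' Write a ramp recording as two-column delimited text
#'
#' @param rec a `ramp_recording`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ramp <- function(rec, path) {
  stopifnot(inherits(rec, "ramp_recording"))
  utils::write.table(
    data.frame(voltage_mV = rec$voltage, current_pA = rec$current),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a two-column (mV, pA) ramp file
#'
#' @param path file path.
#' @param condition,cell_id labels for the resulting recording.
#' @return A `ramp_recording`.
#' @export
read_ramp <- function(path, condition = "DVF", cell_id = "cell") {
  df <- utils::read.table(path, sep = "\t", header = TRUE)
  ramp_recording(df[[1]], df[[2]], condition = condition, cell_id = cell_id)
}

#' Write an image stack as multi-page TIFF
#'
#' Intensities are stored as 16-bit (scaled by the recorded `scale` factor
#' so the round trip is exact to 1/65535 of the dynamic range).
#'
#' @param stack frames x rows x cols array.
#' @param path output TIFF path.
#' @return The scale factor used, invisibly.
#' @export
write_stack_tiff <- function(stack, path) {
  stopifnot(length(dim(stack)) == 3L)
  hi <- max(stack, 1e-9)
  pages <- lapply(seq_len(dim(stack)[1]), function(t) stack[t, , ] / hi)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  scale_path <- paste0(path, ".json")
  jsonlite::write_json(list(scale = hi), scale_path, auto_unbox = TRUE,
                       digits = NA)
  invisible(hi)
}

#' Read a multi-page TIFF stack written by [write_stack_tiff()]
#'
#' @param path TIFF path (with its `.json` scale sidecar).
#' @return frames x rows x cols array in original intensity units.
#' @export
read_stack_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  scale <- jsonlite::read_json(paste0(path, ".json"),
                               simplifyVector = TRUE)$scale
  arr <- array(0, dim = c(length(pages), dim(pages[[1]])[1],
                          dim(pages[[1]])[2]))
  for (t in seq_along(pages)) arr[t, , ] <- pages[[t]] * scale
  arr
}

#' Write a label-mask image as single-page TIFF
#'
#' @param masks integer label matrix (0 = background).
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_mask_tiff <- function(masks, path) {
  tiff::writeTIFF(masks / 255, path, bits.per.sample = 8L)
  invisible(path)
}

#' Read a label-mask TIFF written by [write_mask_tiff()]
#'
#' @param path TIFF path.
#' @return Integer label matrix.
#' @export
read_mask_tiff <- function(path) {
  m <- tiff::readTIFF(path)
  storage.mode(m) <- "double"
  round(m * 255)
}
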