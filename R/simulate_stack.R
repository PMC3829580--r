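#' Simulate a time-lapse image stack from a trace bundle
#'
#' Renders each frame as an additive scene background plus one 2-D Gaussian
#' spot per cell whose integrated intensity follows that cell's
#' background-free fluorescence signal (`raw_traces` minus the bundle's
#' background trace), with optional Gaussian or Poisson pixel noise. Circular
#' ROI masks around each spot and a cell-free background ROI are returned so
#' the extraction pathway can be exercised end to end.
#'
#' @param bundle a `trace_bundle` (its first `n` cells are rendered, where
#'   `n = nrow(cell_positions)`).
#' @param frame_shape `c(rows, cols)` in pixels.
#' @param cell_positions matrix/data.frame of `(row, col)` centres, one per
#'   rendered cell; defaults to a grid with generous spacing. ROIs must not
#'   overlap and must lie inside the frame.
#' @param spot_sigma Gaussian spot width, pixels.
#' @param roi_radius ROI disc radius, pixels.
#' @param background_level additive scene background, AU/pixel.
#' @param noise `"none"`, `"gaussian"` or `"poisson"`.
#' @param noise_sd pixel noise sd for `"gaussian"`.
#' @param seed integer seed for the pixel noise.
#' @return List: `stack` (frames x rows x cols array), `masks` (integer
#'   label matrix, cell `i` labelled `i`), `background_mask` (logical
#'   matrix), `positions`.
#' @export
simulate_image_stack <- function(bundle, frame_shape = c(48, 48),
                                 cell_positions = NULL, spot_sigma = 1.8,
                                 roi_radius = 4, background_level = 50,
                                 noise = c("none", "gaussian", "poisson"),
                                 noise_sd = 2, seed = 1) {
  stopifnot(inherits(bundle, "trace_bundle"))
  noise <- match.arg(noise)
  nr <- frame_shape[1]; nc <- frame_shape[2]
  n_avail <- ncol(bundle$raw_traces)
  if (is.null(cell_positions)) {
    step <- 2 * roi_radius + 4
    rows <- seq(roi_radius + 3, nr - roi_radius - 2, by = step)
    cols <- seq(roi_radius + 3, nc - roi_radius - 2, by = step)
    grid <- expand.grid(row = rows, col = cols)
    cell_positions <- as.matrix(grid[seq_len(min(nrow(grid), n_avail)), ])
  }
  cell_positions <- as.matrix(cell_positions)
  n_cells <- nrow(cell_positions)
  if (n_cells > n_avail)
    stop_sperca("more positions than cells in the bundle")
  if (any(cell_positions[, 1] < roi_radius + 1) ||
      any(cell_positions[, 1] > nr - roi_radius) ||
      any(cell_positions[, 2] < roi_radius + 1) ||
      any(cell_positions[, 2] > nc - roi_radius))
    stop_sperca("cell positions (with ROI radius) must lie inside the frame")
  if (n_cells > 1) {
    d <- as.matrix(stats::dist(cell_positions))
    diag(d) <- Inf
    if (min(d) <= 2 * roi_radius)
      stop_sperca("overlapping ROIs: cell spacing must exceed 2 * roi_radius")
  }
  signal <- bundle$raw_traces[, seq_len(n_cells), drop = FALSE] -
    bundle$background_trace
  n_frames <- nrow(signal)
  rr <- matrix(seq_len(nr), nr, nc)
  cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  spots <- lapply(seq_len(n_cells), function(i) {
    g <- exp(-((rr - cell_positions[i, 1])^2 +
                 (cc - cell_positions[i, 2])^2) / (2 * spot_sigma^2))
    g / sum(g)  # unit integrated intensity
  })
  masks <- matrix(0L, nr, nc)
  for (i in seq_len(n_cells)) {
    disc <- (rr - cell_positions[i, 1])^2 +
      (cc - cell_positions[i, 2])^2 <= roi_radius^2
    masks[disc] <- i
  }
  # background ROI: the square patch farthest from every cell
  dist_min <- Reduce(pmin, lapply(seq_len(n_cells), function(i)
    sqrt((rr - cell_positions[i, 1])^2 + (cc - cell_positions[i, 2])^2)))
  far <- which(dist_min == max(dist_min), arr.ind = TRUE)[1, ]
  bg_mask <- (rr - far[1])^2 + (cc - far[2])^2 <= roi_radius^2
  bg_mask <- bg_mask & masks == 0L
  stack <- array(background_level, dim = c(n_frames, nr, nc))
  for (t in seq_len(n_frames)) {
    fr <- matrix(background_level, nr, nc)
    for (i in seq_len(n_cells)) fr <- fr + signal[t, i] * spots[[i]]
    stack[t, , ] <- fr
  }
  if (noise != "none") {
    with_seed(seed, {
      if (noise == "gaussian")
        stack <- stack + stats::rnorm(length(stack), 0, noise_sd)
      else
        stack[] <- stats::rpois(length(stack), pmax(stack, 0))
    })
  }
  list(stack = stack, masks = masks, background_mask = bg_mask,
       positions = cell_positions)
}
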