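small_bundle <- function(n_cells = 3, noiseless_traces = TRUE, seed = 71) {
  pre <- dde_preset("25uM")
  if (noiseless_traces) pre$noise_sd <- 0
  pre$detected_prevalence <- 1
  simulate_cohort(pre, n_cells, 1, protocol = protocol_plain(),
                  seed = seed)[[1]]
}

test_that("noise-free stack round-trips the generating trace", {
  b <- small_bundle()
  sim <- simulate_image_stack(b, noise = "none")
  times <- protocol_times(b$protocol)
  for (i in seq_len(nrow(sim$positions))) {
    tr <- extract_roi_trace(sim$stack, sim$masks, label = i,
                            sampling_interval = 2.5)
    # proportional (up to the captured fraction) plus the scene background
    signal <- b$raw_traces[, i] - b$background_trace
    fit <- coef(lm(tr$values ~ signal))
    expect_equal(unname(fit[1]), 50, tolerance = 1e-4)  # background level
    # (neighbouring spots leak a vanishing amount into the ROI)
    expect_gt(fit[2], 0)
    expect_equal(cor(tr$values, signal), 1, tolerance = 1e-12)
    # full pathway: extract -> background-correct -> normalize == true dF
    bg <- extract_roi_trace(sim$stack, sim$background_mask)
    w <- protocol_windows(b$protocol)
    norm <- normalize_trace(background_correct(tr, bg),
                            basal_window = w$control, stimulus_onset = 360)
    amp <- response_amplitude(norm, w$control, w$test)
    expect_equal(amp, b$ground_truth$true_amplitude[i], tolerance = 1e-3)
  }
})

test_that("a cell-free ROI reads back the background level", {
  sim <- simulate_image_stack(small_bundle(), background_level = 80,
                              noise = "none")
  bg <- extract_roi_trace(sim$stack, sim$background_mask)
  expect_equal(bg$values, rep(80, length(bg$values)), tolerance = 1e-9)
})

test_that("extraction from a noisy stack still tracks the generating trace", {
  b <- small_bundle(noiseless_traces = FALSE)
  sim <- simulate_image_stack(b, noise = "gaussian", noise_sd = 2, seed = 72)
  tr <- extract_roi_trace(sim$stack, sim$masks, label = 1)
  signal <- b$raw_traces[, 1] - b$background_trace
  expect_gt(cor(tr$values, signal), 0.99)
})

test_that("overlapping or out-of-frame ROIs are rejected", {
  b <- small_bundle(2)
  expect_error(simulate_image_stack(b, cell_positions = rbind(c(20, 20),
                                                              c(22, 21))),
               "overlapping")
  expect_error(simulate_image_stack(b, cell_positions = rbind(c(2, 2))),
               "inside the frame")
})

test_that("stacks and masks survive the TIFF round trip", {
  b <- small_bundle(2)
  sim <- simulate_image_stack(b, frame_shape = c(24, 24),
                              cell_positions = rbind(c(8, 8), c(8, 17)))
  dir <- withr::local_tempdir()
  f <- file.path(dir, "stack.tif")
  write_stack_tiff(sim$stack, f)
  back <- read_stack_tiff(f)
  expect_equal(dim(back), dim(sim$stack))
  # 16-bit quantization of the recorded dynamic range
  expect_lt(max(abs(back - sim$stack)), max(sim$stack) / 65535 + 1e-9)
  fm <- file.path(dir, "masks.tif")
  write_mask_tiff(sim$masks, fm)
  expect_equal(read_mask_tiff(fm), sim$masks, ignore_attr = TRUE)
})
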