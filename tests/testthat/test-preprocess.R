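test_that("normalization follows the dF = (F - F_basal)/F_basal * 100 rule", {
  # direct arithmetic oracle: basal mean 100 over first three samples
  tr <- normalize_trace(raw_trace(c(100, 100, 100, 150)), basal_window = 1:3)
  expect_equal(tr$values, c(0, 0, 0, 50))
  expect_equal(tr$basal_value, 100)
  expect_identical(tr$stage, "normalized")
  # doubling over basal is +100%
  tr2 <- normalize_trace(raw_trace(c(50, 50, 100)), basal_window = 1:2)
  expect_equal(tr2$values[3], 100)
  # constant trace at basal is identically zero
  tr3 <- normalize_trace(raw_trace(rep(400, 20)), basal_window = 1:10)
  expect_equal(tr3$values, rep(0, 20))
})

test_that("background correction is pointwise and unclipped", {
  tr <- raw_trace(rep(110, 12))
  bg <- raw_trace(rep(10, 12))
  expect_equal(background_correct(tr, bg)$values, rep(100, 12))
  expect_equal(background_correct(tr, 0)$values, tr$values)  # identity
  # results may go negative (never clipped)
  expect_equal(background_correct(raw_trace(rep(5, 12)), bg)$values,
               rep(-5, 12))
  expect_error(background_correct(tr, raw_trace(rep(10, 9))), "length")
})

test_that("dF is gain-invariant but offset-sensitive", {
  set.seed(21)
  vals <- 500 + cumsum(rnorm(40, 0, 2)) + c(rep(0, 20), rep(80, 20))
  base <- normalize_trace(raw_trace(vals), basal_window = 1:10)
  for (c in c(0.5, 3, 117)) {
    scaled <- normalize_trace(raw_trace(c * vals), basal_window = 1:10)
    expect_equal(scaled$values, base$values, tolerance = 1e-12)
  }
  # an additive offset changes dF: this is why background subtraction
  # must precede normalization
  shifted <- normalize_trace(raw_trace(vals + 200), basal_window = 1:10)
  expect_gt(max(abs(shifted$values - base$values)), 1)
})

test_that("stage checks block re-normalization and bad basal windows", {
  tr <- normalize_trace(raw_trace(rep(100, 20)), basal_window = 1:10)
  expect_error(normalize_trace(tr), "already normalized")
  expect_error(normalize_trace(raw_trace(rep(0, 20)), basal_window = 1:10),
               "not positive")
  expect_error(normalize_trace(raw_trace(rep(100, 30)), basal_window = 15:24,
                               stimulus_onset = 25), "overlaps")
  expect_error(normalize_trace(raw_trace(rep(100, 20)), basal_window = 30:39),
               "out of range")
  expect_error(background_correct(tr, 0), "raw trace")
})

test_that("ROI extraction averages exactly the masked pixels", {
  # 2-frame 2x2 stack, hand-computed means over a 2-pixel mask
  stack <- array(0, dim = c(2, 2, 2))
  stack[1, , ] <- matrix(c(1, 2, 3, 4), 2, 2)   # column-major
  stack[2, , ] <- matrix(c(5, 6, 7, 8), 2, 2)
  mask <- matrix(c(TRUE, FALSE, TRUE, FALSE), 2, 2)  # pixels (1,1), (1,2)
  tr <- extract_roi_trace(stack, mask, sampling_interval = 2.5)
  expect_equal(tr$values, c(mean(c(1, 3)), mean(c(5, 7))))
  expect_equal(tr$time, c(0, 2.5))
  # constant stack gives a constant trace whatever the mask
  const <- array(7, dim = c(3, 4, 4))
  expect_equal(extract_roi_trace(const, matrix(TRUE, 4, 4))$values,
               rep(7, 3))
  expect_error(extract_roi_trace(stack, matrix(FALSE, 2, 2)), "empty")
  expect_error(extract_roi_trace(stack, matrix(TRUE, 3, 3)), "dimensions")
})

test_that("trace construction validates its time axis", {
  expect_error(ca_trace(c(0, 1, 1.5), rep(1, 3)), "constant")
  expect_error(ca_trace(c(0, -1, -2), rep(1, 3)), "increasing")
  expect_error(ca_trace(0:3, c(1, NA, 2, 3)), "finite")
})
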