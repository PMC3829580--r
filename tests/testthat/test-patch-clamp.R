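linear_ramp <- function(g = 1, erev = 0, n = 1000, condition = "DVF") {
  v <- seq(-80, 80, length.out = n)
  ramp_recording(v, g * (v - erev), condition = condition)
}

test_that("ramp amplitude is the windowed mean current, linear in current", {
  rec <- linear_ramp()
  # dense uniform grid: mean voltage in [77, 80] is ~78.5 (within one step)
  step <- 160 / 999
  expect_equal(ramp_amplitude(rec), 78.5, tolerance = step)
  zero <- ramp_recording(rec$voltage, rep(0, 1000))
  expect_equal(ramp_amplitude(zero), 0)
  scaled <- ramp_recording(rec$voltage, 3.7 * rec$current)
  expect_equal(ramp_amplitude(scaled), 3.7 * ramp_amplitude(rec))
  expect_error(ramp_amplitude(rec, window = c(90, 95)), "fewer than 2")
})

test_that("percent increase follows the published quantification", {
  expect_equal(percent_increase(50, 50), 0)
  expect_equal(percent_increase(50, 100), 100)
  expect_equal(percent_increase(50, 50 * 2.16), 116)
  expect_error(percent_increase(0, 10), "positive")
  expect_error(percent_increase(-5, 10), "positive")
})

test_that("reversal potential interpolates the zero crossing", {
  expect_equal(reversal_potential(linear_ramp()), 0, tolerance = 1e-10)
  step <- 160 / 999
  expect_equal(reversal_potential(linear_ramp(erev = 10)), 10,
               tolerance = step)
  # no sign change -> missing
  allpos <- ramp_recording(seq(-80, 80, length.out = 500),
                           rep(5, 500))
  expect_true(is.na(reversal_potential(allpos)))
  # with noise-induced multiple crossings, the one nearest 0 mV wins
  set.seed(61)
  v <- seq(-80, 80, length.out = 1000)
  i <- sperca:::catsper_iv(v, 50) + rnorm(1000, 0, 2)
  expect_lt(abs(reversal_potential(ramp_recording(v, i))), 5)
})

test_that("rectification index flags outward rectification, scale-free", {
  expect_equal(rectification_index(linear_ramp()), 1, tolerance = 0.05)
  v <- seq(-80, 80, length.out = 1000)
  cs <- ramp_recording(v, sperca:::catsper_iv(v, 50))
  expect_gt(rectification_index(cs), 5)
  scaled <- ramp_recording(v, 4 * cs$current)
  expect_equal(rectification_index(scaled), rectification_index(cs))
})

test_that("ramp family construction honours its factors exactly when clean", {
  fam <- simulate_ramp_family(c(DVF = 1, `DVF+drug` = 1),
                              n_cells = 1, noise_sd = 0, seed = 62)
  expect_equal(fam[[1]]$current, fam[[2]]$current)
  fam2 <- simulate_ramp_family(c(DVF = 1, `DVF+drug` = 2.16),
                               n_cells = 3, noise_sd = 0, seed = 62)
  for (i in c(1, 3, 5)) {
    a0 <- ramp_amplitude(fam2[[i]]); a1 <- ramp_amplitude(fam2[[i + 1]])
    expect_equal(percent_increase(a0, a1), 116, tolerance = 1e-10)
  }
  expect_error(simulate_ramp_family(c(DVF = 1, bad = -2)), "positive")
})

test_that("drug scaling preserves reversal potential and rectification", {
  fam <- simulate_ramp_family(c(DVF = 1, `DVF+drug` = 2.16),
                              n_cells = 4, noise_sd = 3, seed = 63)
  step <- 160 / 999
  for (i in seq(1, 7, by = 2)) {
    base <- fam[[i]]; drug <- fam[[i + 1]]
    expect_lt(abs(reversal_potential(base)), 5)
    expect_lt(abs(reversal_potential(drug)), 5)
    expect_gt(rectification_index(drug), 5)
    # amplitude grows by ~ the factor; shape quantities stay put
    expect_equal(ramp_amplitude(drug) / ramp_amplitude(base), 2.16,
                 tolerance = 0.1)
  }
})

test_that("ramp recordings validate their voltage axis", {
  expect_error(ramp_recording(c(-80, -10, -10, 80), rep(0, 4)), "increasing")
  expect_error(ramp_recording(seq(-50, 80, length.out = 100), rep(0, 100)),
               "span")
  expect_error(ramp_recording(seq(-80, 80, length.out = 10), rep(0, 9)),
               "equal length")
})
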