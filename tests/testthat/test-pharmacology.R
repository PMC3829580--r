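test_that("percent reversal arithmetic, including >100% undershoots", {
  expect_equal(percent_reversal(50, 0), 100)    # full reversal
  expect_equal(percent_reversal(50, 50), 0)     # no reversal
  expect_equal(percent_reversal(50, -10), 120)  # fall below baseline
  expect_warning(pr <- percent_reversal(c(50, -2, 0), c(10, 1, 1)),
                 "without a preceding rise")
  expect_equal(pr, c(80, NA, NA))
})

test_that("noiseless reversal fractions are recovered exactly", {
  pre <- noiseless(dde_preset("25uM_mibefradil"))
  prot <- protocol_inhibitor()
  times <- protocol_times(prot)
  run_one <- function(rf, amp = 60) {
    raw <- simulate_trace(pre, prot,
                          list(is_responder = TRUE, true_amplitude = amp,
                               true_reversal_fraction = rf))
    tr <- normalize_trace(
      ca_trace(times, raw, stage = "raw"),
      basal_window = sperca:::window_before(times, 180, 10),
      stimulus_onset = 180)
    classify_reversal(tr, prot)
  }
  full <- run_one(1)
  expect_true(full$reversed)
  expect_equal(full$percent_reversal, 100, tolerance = 1e-3)
  none <- run_one(0)
  expect_false(none$reversed)
  expect_equal(none$percent_reversal, 0, tolerance = 0.2)
  over <- run_one(1.2)
  expect_equal(over$percent_reversal, 120, tolerance = 1e-2)
})

test_that("near-complete reversal cohorts are recognized as reversed", {
  pre <- dde_preset("25uM_mibefradil")
  pre$reversal$residual_noise_sd <- 0  # fractions ~ U(0.9, 1.1) alone
  study <- run_reversal_study(pre, n_cells = 80, seed = 51)
  expect_gt(study$percent_reversed, 90)
  expect_equal(study$n_excluded, 0)
})

test_that("rise/fall correlation is a tie-aware Spearman", {
  rise <- c(10, 25, 40, 55, 70, 90)
  perfect <- rise_fall_correlation(reversal_rows(rise, residual = rep(0, 6)))
  expect_equal(perfect$rho, 1)
  # rank invariance: monotone transform of the fall leaves rho unchanged
  res <- reversal_rows(rise, residual = rise - c(8, 20, 45, 50, 75, 85))
  fall <- rise - res$residual_amplitude
  cubed <- res
  cubed$residual_amplitude <- rise - fall^3 / max(fall)^2
  expect_equal(rise_fall_correlation(res)$rho,
               rise_fall_correlation(cubed)$rho)
  # independence: rho near zero for unrelated rise and fall
  set.seed(52)
  rise_n <- runif(1000, 20, 100)
  fall_n <- runif(1000, 20, 100)  # independent of the rise
  null <- reversal_rows(rise_n, residual = rise_n - fall_n)
  expect_lt(abs(rise_fall_correlation(null)$rho), 0.1)
  # all tied -> undefined, reported missing
  tied <- rise_fall_correlation(reversal_rows(rep(50, 6), rep(10, 6)))
  expect_true(is.na(tied$rho))
  expect_error(rise_fall_correlation(reversal_rows(c(10, 20), c(0, 0))),
               "at least 5")
})

test_that("reversal noise degrades the estimated correlation monotonically", {
  set.seed(53)
  rho <- vapply(c(0, 15, 60), function(s) {
    rise <- runif(400, 20, 100)
    fall <- 0.9 * rise + rnorm(400, 0, s)
    rise_fall_correlation(reversal_rows(rise, rise - fall))$rho
  }, numeric(1))
  expect_true(all(diff(rho) < 0))
  expect_equal(rho[1], 1)
})

test_that("the inhibitor transient bump never enters the residual window", {
  pre <- noiseless(dde_preset("25uM_mibefradil"))
  prot <- protocol_inhibitor()
  times <- protocol_times(prot)
  kin_big_bump <- trace_kinetics(bump_amplitude = 200)
  res <- lapply(list(trace_kinetics(), kin_big_bump), function(k) {
    raw <- simulate_trace(pre, prot,
                          list(is_responder = TRUE, true_amplitude = 50,
                               true_reversal_fraction = 0.8),
                          kinetics = k)
    tr <- normalize_trace(ca_trace(times, raw, stage = "raw"),
                          basal_window = sperca:::window_before(times, 180, 10),
                          stimulus_onset = 180)
    classify_reversal(tr, prot)
  })
  expect_equal(res[[1]]$residual_amplitude, res[[2]]$residual_amplitude,
               tolerance = 1e-6)
})

test_that("reversal quantities are invariant to a constant trace offset", {
  pre <- noiseless(dde_preset("25uM_mibefradil"))
  prot <- protocol_inhibitor()
  times <- protocol_times(prot)
  raw <- simulate_trace(pre, prot,
                        list(is_responder = TRUE, true_amplitude = 40,
                             true_reversal_fraction = 0.6))
  bw <- sperca:::window_before(times, 180, 10)
  tr <- normalize_trace(ca_trace(times, raw, stage = "raw"),
                        basal_window = bw, stimulus_onset = 180)
  shifted <- tr
  shifted$values <- tr$values + 37
  a <- classify_reversal(tr, prot)
  b <- classify_reversal(shifted, prot)
  expect_equal(a$rise_amplitude, b$rise_amplitude)
  expect_equal(a$percent_reversal, b$percent_reversal)
})

test_that("missing protocol events are an error", {
  tr <- norm_trace(rnorm(300))
  expect_error(classify_reversal(tr, protocol_standard()), "inhibitor_on")
})
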