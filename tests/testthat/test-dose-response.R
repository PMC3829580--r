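cells_df <- function(responsive, amplitude, dose = "d", experiment = 1) {
  data.frame(cell_id = sprintf("c%03d", seq_along(responsive)),
             responsive = responsive, p_value = ifelse(responsive, 0.001, 0.5),
             amplitude = amplitude,
             amplitude_bin = ifelse(responsive, as.character(
               bin_amplitude(amplitude)), NA),
             dose_label = dose, experiment = experiment)
}

test_that("experiment summaries count responders and average them only", {
  cells <- cells_df(c(rep(TRUE, 92), rep(FALSE, 8)),
                    c(rep(50, 92), rep(0.5, 8)))
  s <- summarize_experiment(cells, "25 uM")
  expect_equal(s$percent_responsive, 92)
  expect_equal(s$mean_amplitude, 50)       # non-responders excluded
  expect_equal(s$pct_bin_20_100, 100)
  none <- summarize_experiment(cells_df(rep(FALSE, 10), rep(0.1, 10)))
  expect_equal(none$percent_responsive, 0)
  expect_true(is.na(none$mean_amplitude))
  expect_error(summarize_experiment(cells[0, ]), "no cells")
})

test_that("across-experiment aggregation uses the n-experiment SEM convention", {
  s <- do.call(rbind, lapply(c(90, 92, 94), function(p)
    summarize_experiment(cells_df(c(rep(TRUE, p), rep(FALSE, 100 - p)),
                                  rep(30, 100)), "dose A")))
  agg <- aggregate_doses(s)
  expect_equal(agg$mean_percent_responsive, 92)
  expect_equal(agg$sem_percent_responsive, sd(c(90, 92, 94)) / sqrt(3))
  expect_equal(agg$sem_percent_responsive, 1.1547, tolerance = 1e-4)
  # single experiment: mean reported, SEM missing
  one <- aggregate_doses(s[1, ])
  expect_equal(one$mean_percent_responsive, 90)
  expect_true(is.na(one$sem_percent_responsive))
  # identical experiments: SEM exactly zero
  same <- aggregate_doses(s[c(2, 2, 2), ])
  expect_equal(same$sem_percent_responsive, 0)
})

test_that("pooled prevalence equals the cell-weighted mean across experiments", {
  set.seed(41)
  all_cells <- do.call(rbind, lapply(1:4, function(e) {
    n <- sample(50:150, 1)
    cells_df(runif(n) < 0.4, runif(n, 5, 80), experiment = e)
  }))
  per_exp <- do.call(rbind, lapply(split(all_cells, all_cells$experiment),
                                   summarize_experiment))
  pooled <- 100 * mean(all_cells$responsive)
  weighted <- sum(per_exp$percent_responsive * per_exp$n_cells) /
    sum(per_exp$n_cells)
  expect_equal(weighted, pooled)
  # aggregation is permutation-invariant across experiments
  perm <- per_exp[sample(nrow(per_exp)), ]
  expect_equal(aggregate_doses(perm)$mean_percent_responsive,
               aggregate_doses(per_exp)$mean_percent_responsive)
})

test_that("amplitude histograms sum to 100 over responsive cells", {
  cells <- cells_df(rep(TRUE, 3), c(10, 50, 150))
  h <- amplitude_histogram(cells)
  expect_equal(h$percent, c(100, 100, 100, 0) / 3, tolerance = 1e-10)
  expect_equal(sum(h$percent), 100)
  all_low <- amplitude_histogram(cells_df(rep(TRUE, 5), rep(10, 5)))
  expect_equal(all_low$percent[all_low$bin == "(0,20]"], 100)
  expect_error(amplitude_histogram(cells_df(FALSE, 5)), "no responsive")
})
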