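endpoint_rows <- function(values, condition, day = 1,
                          reps = sprintf("donor%02d", seq_along(values))) {
  data.frame(day = day, condition = condition, replicate = reps,
             percent_live = values, percent_acrosome_intact = values)
}

test_that("relative percentage is plain control scaling", {
  expect_equal(relative_percentage(80, 80), 100)
  expect_equal(relative_percentage(40, 80), 50)
  expect_equal(relative_percentage(90, 75), 120)
  # scale-free in the raw counts behind the percentages
  expect_equal(relative_percentage(30, 60), relative_percentage(15, 30))
  expect_error(relative_percentage(10, 0), "positive")
})

test_that("a condition identical to control is declared no different", {
  tab <- rbind(endpoint_rows(c(80, 75, 82, 78, 81), "DMSO"),
               endpoint_rows(c(80, 75, 82, 78, 81), "50 uM"))
  res <- compare_conditions(tab, "viability")
  expect_equal(res$per_condition$p_paired_t, 1)
  expect_false(res$per_condition$significant)
  expect_equal(res$per_condition$mean_percent_of_control, 100)
})

test_that("a 30% deficit with small noise is detected at n = 5", {
  # power oracle: differences ~ N(-24, 2) on an 80% control -> huge effect
  set.seed(81)
  control <- 80 + rnorm(5, 0, 2)
  treated <- 0.7 * control + rnorm(5, 0, 2)
  tab <- rbind(endpoint_rows(control, "DMSO"),
               endpoint_rows(treated, "50 uM"))
  res <- compare_conditions(tab, "viability")
  expect_lt(res$per_condition$p_paired_t, 0.05)
  expect_true(res$per_condition$significant)
  expect_equal(res$per_condition$mean_percent_of_control, 70, tolerance = 0.1)
})

test_that("statistics are invariant to row order", {
  set.seed(82)
  tab <- simulate_endpoint_table(n_replicates = 5, seed = 9)
  res1 <- compare_conditions(tab, "acrosome")
  perm <- tab[sample(nrow(tab)), ]
  res2 <- compare_conditions(perm, "acrosome")
  o <- function(d) d[order(d$day, d$condition), ]
  expect_equal(o(res1$per_condition), o(res2$per_condition),
               ignore_attr = TRUE)
  expect_equal(res1$anova, res2$anova, tolerance = 1e-12)
})

test_that("a missing control pairing is an error", {
  tab <- endpoint_rows(c(70, 72, 71), "25 uM")
  expect_error(compare_conditions(tab, "viability"), "control")
})

test_that("the endpoint generator matches the scoring design", {
  tab <- simulate_endpoint_table(n_replicates = 6, seed = 10)
  expect_equal(nrow(tab), 6 * 5 * 3)
  expect_true(all(tab$percent_live >= 0 & tab$percent_live <= 100))
  # every (day, replicate) block carries a solvent control row
  blocks <- split(tab, interaction(tab$day, tab$replicate))
  expect_true(all(vapply(blocks, function(b) "DMSO" %in% b$condition,
                         logical(1))))
  # 50 uM acrosome deliberately unscored on day 3 (viability collapse)
  d3 <- tab[tab$day == 3 & tab$condition == "50 uM", ]
  expect_true(all(is.na(d3$percent_acrosome_intact)))
  expect_true(all(!is.na(d3$percent_live)))
  # percentages are multiples of 1/200 scored cells
  expect_true(all(abs(tab$percent_live * 2 -
                        round(tab$percent_live * 2)) < 1e-9))
})
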