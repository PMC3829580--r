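#' Simulate a viability/acrosome endpoint count table
#'
#' Scored endpoint counts for a 3-day continuous-exposure experiment:
#' each (day, condition, donor) cell is Binomial(`n_scored`, p) with a
#' donor-level random effect on the logit scale, so paired comparisons
#' against the solvent control are meaningful. The default success
#' probabilities emulate the published pattern qualitatively: viability
#' unaffected except at the highest dose on day 3; acrosomal integrity
#' reduced at 25/50 uM from day 2 and additionally at 10 uM on day 3 (the
#' 50 uM acrosome score is not recorded on day 3, when viability has
#' collapsed).
#'
#' @param n_replicates donors (default 5).
#' @param n_scored spermatozoa scored per slide (default 200).
#' @param seed integer seed.
#' @param donor_sd sd of the donor random effect, logit scale.
#' @return data.frame (an EndpointTable): `day`, `condition`, `replicate`,
#'   `percent_live`, `percent_acrosome_intact` (`NA` where not scored).
#' @export
simulate_endpoint_table <- function(n_replicates = 5, n_scored = 200,
                                    seed = 1, donor_sd = 0.25) {
  conditions <- c("DMSO", "1 uM", "10 uM", "25 uM", "50 uM")
  viability_p <- rbind(
    `1` = c(0.85, 0.85, 0.85, 0.84, 0.83),
    `2` = c(0.80, 0.80, 0.79, 0.78, 0.75),
    `3` = c(0.74, 0.73, 0.72, 0.71, 0.45))
  acrosome_p <- rbind(
    `1` = c(0.80, 0.80, 0.79, 0.78, 0.78),
    `2` = c(0.78, 0.77, 0.74, 0.62, 0.64),
    `3` = c(0.75, 0.73, 0.63, 0.55, NA))
  colnames(viability_p) <- colnames(acrosome_p) <- conditions
  logit <- function(p) log(p / (1 - p))
  inv_logit <- function(x) 1 / (1 + exp(-x))
  with_seed(seed, {
    donor_eff <- stats::rnorm(n_replicates, 0, donor_sd)
    rows <- expand.grid(replicate = seq_len(n_replicates),
                        condition = conditions, day = 1:3,
                        stringsAsFactors = FALSE)
    draw <- function(ptab) {
      p <- ptab[cbind(as.character(rows$day), rows$condition)]
      p_rep <- inv_logit(logit(p) + donor_eff[rows$replicate])
      out <- rep(NA_real_, nrow(rows))
      ok <- !is.na(p_rep)  # 50 uM acrosome not scored on day 3
      out[ok] <- 100 * stats::rbinom(sum(ok), n_scored, p_rep[ok]) / n_scored
      out
    }
    data.frame(day = rows$day, condition = rows$condition,
               replicate = sprintf("donor%02d", rows$replicate),
               percent_live = draw(viability_p),
               percent_acrosome_intact = draw(acrosome_p))
  })
}

#' Percentage relative to the control condition
#'
#' `100 * value / control`, the convention used to report viability and
#' acrosomal integrity relative to the solvent control. Scale-free:
#' multiplying both raw counts by a constant leaves it unchanged.
#'
#' @param value endpoint percentage for a condition.
#' @param control endpoint percentage for the paired control; must be
#'   positive.
#' @return Percent of control (vectorized).
#' @export
relative_percentage <- function(value, control) {
  if (any(!is.na(control) & control <= 0))
    stop_sperca("control percentage must be positive")
  100 * value / control
}

#' Compare endpoint conditions against the solvent control
#'
#' Per day and condition: a paired two-sided t-test against the control
#' (paired by donor), mean +/- SEM of the donor-wise percentages relative to
#' control, and a Shapiro-Wilk normality check of the paired differences
#' (logged, not acted upon). Per day, a one-way ANOVA across all conditions.
#' No multiplicity correction is applied across days or conditions,
#' mirroring the published analysis.
#'
#' @param table an EndpointTable ([simulate_endpoint_table()] layout).
#' @param endpoint `"viability"` or `"acrosome"`.
#' @param control control condition label (default `"DMSO"`).
#' @param alpha significance level used for the `significant` flag.
#' @return List with `per_condition` (day, condition, n, mean/SEM of percent
#'   of control, paired t p-value, normality p-value, significance flag) and
#'   `anova` (day, F, p) data.frames.
#' @export
compare_conditions <- function(table, endpoint = c("viability", "acrosome"),
                               control = "DMSO", alpha = 0.05) {
  endpoint <- match.arg(endpoint)
  col <- if (endpoint == "viability") "percent_live" else "percent_acrosome_intact"
  table <- as.data.frame(table)
  stopifnot(all(c("day", "condition", "replicate", col) %in% names(table)))
  per_cond <- list(); anova_rows <- list()
  for (d in sort(unique(table$day))) {
    dtab <- table[table$day == d & !is.na(table[[col]]), ]
    ctab <- dtab[dtab$condition == control, ]
    if (!nrow(ctab))
      stop_sperca("no control ('", control, "') rows for day ", d)
    if (any(!is.finite(ctab[[col]])) || any(ctab[[col]] <= 0))
      stop_sperca("control percentages must be positive on day ", d)
    for (cond in setdiff(unique(dtab$condition), control)) {
      xt <- dtab[dtab$condition == cond, ]
      common <- intersect(xt$replicate, ctab$replicate)
      if (length(common) < 2)
        stop_sperca("need >= 2 paired replicates for ", cond, " on day ", d)
      x <- xt[[col]][match(common, xt$replicate)]
      y <- ctab[[col]][match(common, ctab$replicate)]
      diffs <- x - y
      p_t <- if (stats::sd(diffs) == 0) {
        if (all(diffs == 0)) 1 else 0  # identical conditions: no difference
      } else stats::t.test(x, y, paired = TRUE)$p.value
      p_norm <- if (length(diffs) >= 3 && stats::sd(diffs) > 0)
        stats::shapiro.test(diffs)$p.value else NA_real_
      rel <- relative_percentage(x, y)
      per_cond[[length(per_cond) + 1L]] <- data.frame(
        day = d, condition = cond, n = length(common),
        mean_percent_of_control = mean(rel),
        sem_percent_of_control = stats::sd(rel) / sqrt(length(rel)),
        p_paired_t = p_t, p_normality = p_norm,
        significant = is.finite(p_t) && p_t < alpha)
    }
    if (length(unique(dtab$condition)) > 1 && stats::sd(dtab[[col]]) > 0) {
      fit <- stats::aov(dtab[[col]] ~ factor(dtab$condition))
      s <- summary(fit)[[1]]
      anova_rows[[length(anova_rows) + 1L]] <- data.frame(
        day = d, f_value = s$`F value`[1], p_anova = s$`Pr(>F)`[1])
    }
  }
  list(per_condition = do.call(rbind, per_cond),
       anova = if (length(anova_rows)) do.call(rbind, anova_rows) else NULL)
}
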