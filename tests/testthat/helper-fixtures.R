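# shared fixture builders (all data generated in code)

# normalized trace straight from a value vector (2.5 s sampling)
norm_trace <- function(values, cell_id = "cell") {
  ca_trace(seq(0, by = 2.5, length.out = length(values)), values,
           cell_id = cell_id, stage = "normalized", basal_value = 1000)
}

# raw trace from a value vector
raw_trace <- function(values, cell_id = "cell") {
  ca_trace(seq(0, by = 2.5, length.out = length(values)), values,
           cell_id = cell_id, stage = "raw")
}

# step trace: `n_base` samples at 0 then `n_step` samples at `level`
step_trace <- function(level, n_base = 10, n_step = 10, noise_sd = 0,
                       seed = NULL) {
  vals <- c(rep(0, n_base), rep(level, n_step))
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    vals <- vals + rnorm(length(vals), 0, noise_sd)
  }
  norm_trace(vals)
}

# protocol without a positive-control event (keeps non-responders flat)
protocol_plain <- function() {
  ca_protocol(c(baseline_start = 0, agonist_on = 360, washout = 540,
                end = 660))
}

# noiseless preset clone
noiseless <- function(preset) {
  preset$noise_sd <- 0
  preset
}

# manual ReversalResult rows for correlation tests
reversal_rows <- function(rise, residual) {
  data.frame(cell_id = sprintf("c%04d", seq_along(rise)),
             rise_amplitude = rise, residual_amplitude = residual,
             percent_reversal = 100 * (rise - residual) / rise,
             reversed = TRUE, p_value = 0)
}
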