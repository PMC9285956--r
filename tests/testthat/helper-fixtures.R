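# Small configurations shared by tests. Kept tiny so individual tests stay
# fast; the full-size replicate study lives in the acceptance suite.

tiny_config <- function(..., seed = 42L) {
  sim_config(n_hc = 2, n_ald = 2, n_channels = 5, fs = 250,
             n_single = 4, n_paired = 4, seed = seed, ...)
}

# noise-free single-edge configuration used for exact-recovery checks
clean_edge_config <- function(gain = 1, lag_ms = 30, fs = 1000, n_channels = 3) {
  sim_config(
    n_hc = 1, n_ald = 0, n_channels = n_channels, fs = fs,
    n_single = 2, n_paired = 2,
    coupling = tibble::tibble(src = 1L, dst = 2L, gain = gain, lag_ms = lag_ms),
    noise_sd = 0, coherence_sd = 0, seed = 5L
  )
}

# balanced random cohort metric table (metric-level, no signal simulation)
random_metric_table <- function(n_per_group, sd = 1, shift_cell = NULL,
                                shift = 0) {
  grid <- expand.grid(
    participant = sprintf("S%02d", seq_len(2 * n_per_group)),
    pulse = c("single", "paired"), side = c("left", "right"),
    stringsAsFactors = FALSE
  )
  grid$group <- ifelse(as.integer(sub("S", "", grid$participant)) <= n_per_group,
                       "HC", "ALD")
  subj_eff <- stats::rnorm(2 * n_per_group, 0, 0.5)
  names(subj_eff) <- sprintf("S%02d", seq_len(2 * n_per_group))
  grid$value <- 10 + subj_eff[grid$participant] + stats::rnorm(nrow(grid), 0, sd)
  if (!is.null(shift_cell)) {
    hit <- grid$group == shift_cell[1] & grid$side == shift_cell[2] &
      grid$pulse == shift_cell[3]
    grid$value[hit] <- grid$value[hit] + shift
  }
  tibble::as_tibble(grid)
}
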