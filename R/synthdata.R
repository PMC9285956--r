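#' Synthetic TMS-EEG cohorts with planted lagged coupling
#'
#' The generator emulates a paired-pulse TMS-EEG study: two groups (healthy
#' controls, `"HC"`, and alcohol-dependent participants in early recovery,
#' `"ALD"`), two stimulation sites (`"left"`/`"right"` prefrontal cortex) and
#' two pulse types (`"single"`/`"paired"`). Every channel carries a damped
#' oscillatory evoked response; a planted directed coupling network mixes
#' lag-shifted copies of source channels into target channels so that the
#' downstream lag-maximised cross-correlation analysis has a known ground
#' truth. Paired-pulse trials are scaled by a suppression factor (< 1 means
#' cortical inhibition), and coupling gains are degraded by
#' `ald_coupling_factor` only in the ALD x paired x left cell, planting a
#' localised group-by-pulse-by-side effect.
#'
#' @name synthdata
NULL

# ---- evoked templates -------------------------------------------------------

# Draw the parameters of a damped-oscillation evoked waveform: 2-3 decaying
# sinusoids with frequencies in 4-40 Hz. The waveform is zero before t = 0
# (the test pulse) and is normalised to unit RMS over 0-350 ms so that
# amplitudes and noise SDs are on a common microvolt scale.
evoked_params <- function(seed, n_range = 2:3, freq_range = c(4, 40),
                          decay_range = c(40, 120)) {
  local_seed_eval(seed, {
    n_comp <- if (length(n_range) == 1L) n_range else sample(n_range, 1L)
    p <- list(
      freq_hz  = runif(n_comp, freq_range[1], freq_range[2]),
      phase    = runif(n_comp, 0, 2 * pi),
      decay_ms = runif(n_comp, decay_range[1], decay_range[2]),
      amp      = runif(n_comp, 0.5, 1),
      scale    = 1
    )
    t_ref <- seq(0, 350, by = 1)
    p$scale <- 1 / sqrt(mean(evoked_eval(p, t_ref)^2))
    p
  })
}

# Channel background templates for the cohort generator use a richer damped
# mixture (about ten components, 4-60 Hz, decays up to 300 ms) than the
# classic 2-3 component evoked waveform: with only 2-3 smooth components,
# two *independent* 300 ms traces already reach lag-maximised correlations
# near the 0.6 edge threshold, which would saturate every graph. The richer
# mixture keeps the chance (null) correlation between uncoupled channels
# well below the threshold while remaining a phase-locked oscillatory
# evoked response.
channel_params <- function(seed) {
  evoked_params(seed, n_range = 8:12, freq_range = c(4, 60),
                decay_range = c(40, 300))
}

# Evaluate the waveform at arbitrary times (ms relative to the test pulse).
# Analytic evaluation keeps lag-shifted copies exact on any sampling grid.
evoked_eval <- function(params, t_ms) {
  out <- numeric(length(t_ms))
  pos <- t_ms >= 0
  if (any(pos)) {
    tp <- t_ms[pos]
    acc <- 0
    for (k in seq_along(params$freq_hz)) {
      acc <- acc + params$amp[k] * exp(-tp / params$decay_ms[k]) *
        sin(2 * pi * params$freq_hz[k] * tp / 1000 + params$phase[k])
    }
    out[pos] <- acc * params$scale
  }
  out
}

#' Generate a damped-oscillation evoked waveform
#'
#' Returns a template TMS-evoked potential: a sum of 2-3 exponentially
#' decaying sinusoids (4-40 Hz) that is zero before the pulse at `t = 0`,
#' sampled at `fs` from 0 to `duration_ms`, normalised to unit RMS over
#' 0-350 ms and scaled by `amplitude`. Deterministic given `seed`.
#'
#' @param fs Sampling rate in Hz.
#' @param duration_ms Duration in ms; must be at least 350.
#' @param amplitude Peak scale in microvolts (RMS over 0-350 ms); must be
#'   non-negative.
#' @param seed Integer seed selecting the waveform morphology.
#' @return Numeric vector of length `round(duration_ms * fs / 1000)`.
#' @examples
#' w <- generate_evoked_template(fs = 1000, duration_ms = 500, amplitude = 10, seed = 1)
#' @export
generate_evoked_template <- function(fs, duration_ms, amplitude, seed) {
  check_scalar_number(fs, "fs", positive = TRUE)
  check_scalar_number(duration_ms, "duration_ms")
  if (duration_ms <= 0) stop_invalid("`duration_ms` must be positive.")
  if (duration_ms < 350) stop_invalid("`duration_ms` must be at least 350 ms.")
  check_scalar_number(amplitude, "amplitude")
  if (amplitude < 0) stop_invalid("`amplitude` must be non-negative.")
  n <- ms_to_samples(duration_ms, fs)
  t_ms <- (seq_len(n) - 1) * 1000 / fs
  amplitude * evoked_eval(evoked_params(seed), t_ms)
}

# ---- configuration ----------------------------------------------------------

#' Default planted coupling network
#'
#' A hub layout: channel 1 drives every other channel with gains spread over
#' `gain_range` and lags on a 4 ms grid (so they sit on the sample grid at
#' both 1000 Hz and 250 Hz). With unit-variance mixing the planted gain of an
#' edge equals its noise-free maximal cross-correlation, and two driven
#' channels i, j correlate at `gain_i * gain_j`, which yields dense graphs at
#' a 0.6 absolute threshold, in the range reported for TMS-evoked scalp
#' networks.
#'
#' @param n_channels Number of EEG channels (>= 2).
#' @param gain_range Range of coupling gains assigned to the driven channels.
#' @return A tibble with columns `src`, `dst`, `gain`, `lag_ms`.
#' @export
default_coupling <- function(n_channels = 20, gain_range = c(0.70, 0.99)) {
  if (n_channels < 2) stop_invalid("`n_channels` must be >= 2.")
  dst <- 2:n_channels
  lags <- 4 * (((seq_along(dst) - 1) %% 19) + 1) # 4, 8, ..., 76 ms
  tibble::tibble(
    src = 1L,
    dst = as.integer(dst),
    gain = seq(gain_range[2], gain_range[1], length.out = length(dst)),
    lag_ms = lags
  )
}

#' Simulation configuration
#'
#' Bundles every tunable of the synthetic cohort. Defaults mirror the study
#' design being emulated: 16 controls vs 11 patients, 20 referenced channels,
#' 75 single- and 75 paired-pulse trials per stimulation site, a 100 ms
#' conditioning-test interval paradigm in which the paired-pulse evoked
#' response of controls is suppressed to half amplitude, and a coupling
#' degradation applied only in the ALD x paired-pulse x left-PFC cell.
#'
#' @param n_hc,n_ald Group sizes (HC and ALD).
#' @param n_channels Number of channels (>= 2).
#' @param fs Sampling rate in Hz.
#' @param n_single,n_paired Trials per pulse type and site.
#' @param coupling Planted coupling table (`src`, `dst`, `gain`, `lag_ms`);
#'   must be acyclic, with gains in `[0, 1]`, lags in `[0, 150]` ms, and the
#'   sum of squared gains into any one node at most 1 (unit-variance mixing).
#' @param noise_sd White measurement-noise SD in microvolts.
#' @param evoked_amplitude RMS amplitude of the evoked response in microvolts.
#' @param suppression_hc,suppression_ald Multiplicative factor on the
#'   paired-pulse evoked amplitude for each group; `< 1` is inhibition,
#'   `> 1` facilitation. Both must be positive (0 is allowed and yields a
#'   fully suppressed response).
#' @param ald_coupling_factor Multiplier applied to coupling gains only for
#'   ALD participants in the paired-pulse left-PFC cell (`1` plants no group
#'   effect).
#' @param coherence_sd SD of the log-normal per-participant jitter applied to
#'   all coupling gains; this is the between-subject variance source and, in
#'   the ALD group, the individual coupling level that the synthetic SADQ
#'   score is (negatively) linked to.
#' @param seed Integer master seed.
#' @return A `tep_sim_config` list.
#' @export
sim_config <- function(n_hc = 16, n_ald = 11, n_channels = 20, fs = 1000,
                       n_single = 75, n_paired = 75,
                       coupling = default_coupling(n_channels),
                       noise_sd = 5, evoked_amplitude = 10,
                       suppression_hc = 0.5, suppression_ald = 0.8,
                       ald_coupling_factor = 0.75,
                       coherence_sd = 0.08, seed = 1L) {
  if (n_hc < 0 || n_ald < 0) stop_invalid("Group sizes must be non-negative.")
  if (n_channels < 2) stop_invalid("`n_channels` must be >= 2.")
  check_scalar_number(fs, "fs", positive = TRUE)
  if (n_single < 1 || n_paired < 1) stop_invalid("Trial counts must be >= 1.")
  check_scalar_number(noise_sd, "noise_sd")
  if (noise_sd < 0) stop_invalid("`noise_sd` must be non-negative.")
  check_scalar_number(evoked_amplitude, "evoked_amplitude", positive = TRUE)
  if (suppression_hc < 0) stop_invalid("`suppression_hc` must be >= 0.")
  if (suppression_ald < 0) stop_invalid("`suppression_ald` must be >= 0.")
  check_scalar_number(ald_coupling_factor, "ald_coupling_factor", positive = TRUE)
  if (coherence_sd < 0) stop_invalid("`coherence_sd` must be >= 0.")
  coupling <- validate_coupling(coupling, n_channels)
  structure(
    list(
      n_hc = as.integer(n_hc), n_ald = as.integer(n_ald),
      n_channels = as.integer(n_channels), fs = fs,
      n_single = as.integer(n_single), n_paired = as.integer(n_paired),
      coupling = coupling, noise_sd = noise_sd,
      evoked_amplitude = evoked_amplitude,
      suppression_hc = suppression_hc, suppression_ald = suppression_ald,
      ald_coupling_factor = ald_coupling_factor,
      coherence_sd = coherence_sd, seed = as.integer(seed)
    ),
    class = "tep_sim_config"
  )
}

validate_coupling <- function(coupling, n_channels) {
  coupling <- tibble::as_tibble(coupling)
  need <- c("src", "dst", "gain", "lag_ms")
  if (!all(need %in% names(coupling))) {
    stop_invalid("`coupling` needs columns src, dst, gain, lag_ms.")
  }
  if (nrow(coupling) == 0) return(coupling)
  if (any(coupling$src < 1 | coupling$src > n_channels) ||
      any(coupling$dst < 1 | coupling$dst > n_channels)) {
    stop_invalid("Coupling endpoints must index channels 1..n_channels.")
  }
  if (any(coupling$src == coupling$dst)) {
    stop_invalid("Self-coupling is not allowed.")
  }
  if (any(coupling$gain < 0 | coupling$gain > 1)) {
    stop_invalid("Coupling gains must lie in [0, 1].")
  }
  if (any(coupling$lag_ms < 0 | coupling$lag_ms > 150)) {
    stop_invalid("Coupling lags must lie in [0, 150] ms.")
  }
  ss <- tapply(coupling$gain^2, coupling$dst, sum)
  if (any(ss > 1 + 1e-12)) {
    stop_invalid("Sum of squared gains into a node must not exceed 1.")
  }
  if (is.null(topological_order(coupling, n_channels))) {
    stop_invalid("`coupling` must be acyclic (a DAG).")
  }
  coupling
}

# Kahn's algorithm; NULL if the edge set has a cycle.
topological_order <- function(coupling, n_channels) {
  indeg <- integer(n_channels)
  if (nrow(coupling)) {
    tab <- table(factor(coupling$dst, levels = seq_len(n_channels)))
    indeg <- as.integer(tab)
  }
  queue <- which(indeg == 0L)
  order <- integer(0)
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    order <- c(order, v)
    out <- coupling$dst[coupling$src == v]
    for (w in out) {
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) queue <- c(queue, w)
    }
  }
  if (length(order) < n_channels) NULL else order
}

# ---- epoch generation -------------------------------------------------------

# Symbolic noise-free channel signals: each channel is a linear combination of
# lag-shifted channel templates, built by walking the coupling DAG. Mixing is
# unit-variance: sqrt(1 - sum g^2) * own template + sum g * shifted source, so
# a planted gain equals the planted noise-free correlation.
signal_terms <- function(coupling, n_channels) {
  order <- topological_order(coupling, n_channels)
  terms <- vector("list", n_channels)
  src_v <- coupling$src
  dst_v <- coupling$dst
  gain_v <- coupling$gain
  lag_v <- coupling$lag_ms
  for (ch in order) {
    inc <- which(dst_v == ch)
    tpl <- ch
    shift_ms <- 0
    coef <- sqrt(max(0, 1 - sum(gain_v[inc]^2)))
    for (k in inc) {
      st <- terms[[src_v[k]]]
      tpl <- c(tpl, st$tpl)
      shift_ms <- c(shift_ms, st$shift_ms + lag_v[k])
      coef <- c(coef, st$coef * gain_v[k])
    }
    terms[[ch]] <- list(tpl = tpl, shift_ms = shift_ms, coef = coef)
  }
  terms
}

participant_coherence <- function(config, participant_seed) {
  if (config$coherence_sd == 0) return(1)
  local_seed_eval(derive_seed(participant_seed, 55L),
                  exp(rnorm(1, 0, config$coherence_sd)))
}

# Apply per-participant coherence (and, in the affected cell, the ALD factor)
# to the planted gains, keeping the unit-variance constraint.
effective_coupling <- function(config, group, side, pulse, kappa) {
  cp <- config$coupling
  if (nrow(cp) == 0) return(cp)
  cp$gain <- pmin(cp$gain * kappa, 1)
  if (group == "ALD" && pulse == "paired" && side == "left") {
    cp$gain <- cp$gain * config$ald_coupling_factor
    cp$gain <- pmin(cp$gain, 1)
  }
  ss <- rowsum(cp$gain^2, cp$dst)
  bad <- as.integer(rownames(ss)[ss[, 1] > 1])
  for (d in bad) {
    idx <- cp$dst == d
    cp$gain[idx] <- cp$gain[idx] * sqrt(0.999 / sum(cp$gain[idx]^2))
  }
  cp
}

#' Generate one condition cell of synthetic post-pulse epochs
#'
#' Builds the stack of post-test-pulse epochs (50-1000 ms) for one participant
#' in one condition cell. Each channel is its own evoked template mixed with
#' lag-shifted source templates according to the planted coupling network,
#' scaled by the group's suppression factor when `pulse = "paired"`, plus
#' white noise. Coupling gains are multiplied by `ald_coupling_factor` if and
#' only if `group = "ALD"`, `pulse = "paired"` and `side = "left"`.
#'
#' @param config A [sim_config()].
#' @param group `"HC"` or `"ALD"`.
#' @param side `"left"` or `"right"` (stimulation site).
#' @param pulse `"single"` or `"paired"`.
#' @param participant_seed Integer seed identifying the participant.
#' @param .tpl_cache Optional environment used to memoise per-participant
#'   channel templates across condition cells (internal use).
#' @return A `tep_epochs` object (see [epoch_set()]); its `ground_truth`
#'   attribute holds the planted edges with their condition-effective gains.
#' @export
generate_epoch_set <- function(config, group, side, pulse, participant_seed,
                               .tpl_cache = NULL) {
  stopifnot(inherits(config, "tep_sim_config"))
  group <- match_enum(group, "group", c("HC", "ALD"))
  side <- match_enum(side, "side", c("left", "right"))
  pulse <- match_enum(pulse, "pulse", c("single", "paired"))

  nch <- config$n_channels
  fs <- config$fs
  side_idx <- if (side == "left") 1L else 2L
  cache_key <- sprintf("tpl_%d_%d", participant_seed, side_idx)
  tpl <- if (!is.null(.tpl_cache) && !is.null(.tpl_cache[[cache_key]])) {
    .tpl_cache[[cache_key]]
  } else {
    lapply(seq_len(nch), function(ch) {
      channel_params(derive_seed(participant_seed, side_idx * 7L, ch))
    })
  }
  if (!is.null(.tpl_cache)) .tpl_cache[[cache_key]] <- tpl
  variant0 <- if (group == "ALD" && pulse == "paired" && side == "left") "ald" else "base"
  cp_key <- sprintf("cp_%d_%s", participant_seed, variant0)
  cp <- if (!is.null(.tpl_cache) && !is.null(.tpl_cache[[cp_key]])) {
    .tpl_cache[[cp_key]]
  } else {
    kappa <- participant_coherence(config, participant_seed)
    effective_coupling(config, group, side, pulse, kappa)
  }
  if (!is.null(.tpl_cache)) .tpl_cache[[cp_key]] <- cp

  window_ms <- c(50, 1000)
  n_time <- ms_to_samples(window_ms[2] - window_ms[1], fs)
  t_ms <- window_ms[1] + (seq_len(n_time) - 1) * 1000 / fs

  supp <- if (pulse == "paired") {
    if (group == "HC") config$suppression_hc else config$suppression_ald
  } else 1
  amp <- config$evoked_amplitude * supp

  # unit-amplitude clean signals depend only on (participant, side) and on
  # whether the ALD degradation applies; memoise them across pulse cells
  variant <- if (group == "ALD" && pulse == "paired" && side == "left") "ald" else "base"
  sig_key <- sprintf("sig_%d_%d_%s", participant_seed, side_idx, variant)
  unit <- if (!is.null(.tpl_cache) && !is.null(.tpl_cache[[sig_key]])) {
    .tpl_cache[[sig_key]]
  } else {
    terms <- signal_terms(cp, nch)
    u <- matrix(0, nrow = nch, ncol = n_time)
    for (ch in seq_len(nch)) {
      tm <- terms[[ch]]
      sig <- numeric(n_time)
      for (k in seq_along(tm$coef)) {
        if (tm$coef[k] != 0) {
          sig <- sig + tm$coef[k] * evoked_eval(tpl[[tm$tpl[k]]], t_ms - tm$shift_ms[k])
        }
      }
      u[ch, ] <- sig
    }
    u
  }
  if (!is.null(.tpl_cache)) .tpl_cache[[sig_key]] <- unit
  clean <- amp * unit

  n_trials <- if (pulse == "single") config$n_single else config$n_paired
  noise_seed <- derive_seed(participant_seed, side_idx, if (pulse == "single") 3L else 4L)
  data <- local_seed_eval(noise_seed, {
    # epochs x channels x time layout filled without transposition: the
    # (epoch, channel, time) element sits at epoch + (ch-1)*n_trials + ...,
    # which matches a trials x (channels*time) matrix plus the clean signal
    # repeated each = n_trials
    base <- if (config$noise_sd > 0) {
      matrix(rnorm(n_trials * nch * n_time, 0, config$noise_sd), n_trials)
    } else {
      matrix(0, n_trials, nch * n_time)
    }
    base <- base + rep(as.vector(clean), each = n_trials)
    dim(base) <- c(n_trials, nch, n_time)
    base
  })

  es <- epoch_set(data, fs = fs, window_ms = window_ms,
                  site = side, pulse = pulse,
                  labels = sprintf("ch%02d", seq_len(nch)))
  attr(es, "ground_truth") <- tibble::new_tibble(list(
    src = cp$src, dst = cp$dst,
    gain = config$coupling$gain, gain_effective = cp$gain,
    lag_ms = cp$lag_ms
  ), nrow = nrow(cp))
  es
}

# ---- cohorts ----------------------------------------------------------------

participant_frame <- function(config) {
  n <- config$n_hc + config$n_ald
  if (n < 1) stop_invalid("The cohort must contain at least one participant.")
  tibble::tibble(
    participant = sprintf("P%02d", seq_len(n)),
    group = c(rep("HC", config$n_hc), rep("ALD", config$n_ald)),
    participant_seed = vapply(seq_len(n), function(i) derive_seed(config$seed, 17L, i), 1L)
  )
}

# Synthetic clinical scores. SADQ for controls sits near zero; for ALD it is a
# decreasing linear function of the participant's coupling coherence (plus
# noise), planting the negative SADQ <-> connectivity association.
clinical_scores <- function(config, participants) {
  kappa <- vapply(participants$participant_seed,
                  function(s) participant_coherence(config, s), 1.0)
  local_seed_eval(derive_seed(config$seed, 29L), {
    n <- nrow(participants)
    ald <- participants$group == "ALD"
    sadq <- numeric(n); bdi <- numeric(n); ocds <- numeric(n)
    sadq[!ald] <- abs(rnorm(sum(!ald), 0, 1.5))
    sadq[ald] <- pmax(0, 25 - 150 * log(kappa[ald]) + rnorm(sum(ald), 0, 3))
    bdi[!ald] <- abs(rnorm(sum(!ald), 2, 2))
    bdi[ald] <- pmax(0, rnorm(sum(ald), 14, 6))
    ocds[!ald] <- abs(rnorm(sum(!ald), 1, 1.5))
    ocds[ald] <- pmax(0, rnorm(sum(ald), 18, 7))
    tibble::tibble(
      participant = participants$participant, group = participants$group,
      SADQ = round(sadq, 1), BDI = round(bdi, 1), OCDS = round(ocds, 1),
      coherence = kappa
    )
  })
}

#' Generate a raw synthetic cohort
#'
#' Produces the full factorial design: every participant contributes four
#' condition cells (left/right site x single/paired pulse) of raw epochs,
#' together with synthetic clinical scores and the planted ground truth.
#' Deterministic for a fixed `config$seed`.
#'
#' @param config A [sim_config()].
#' @return A list with `participants` (clinical table), `epochs` (tibble with
#'   one row per participant x side x pulse and a list-column of `tep_epochs`)
#'   and `ground_truth` (planted coupling plus `true_group_effect`).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "tep_sim_config"))
  participants <- participant_frame(config)
  clin <- clinical_scores(config, participants)
  grid <- tidyr::expand_grid(
    participants[, c("participant", "group", "participant_seed")],
    side = c("left", "right"), pulse = c("single", "paired")
  )
  grid$epochs <- purrr::pmap(
    grid[, c("group", "side", "pulse", "participant_seed")],
    function(group, side, pulse, participant_seed) {
      generate_epoch_set(config, group, side, pulse, participant_seed)
    }
  )
  list(
    participants = clin[, c("participant", "group", "SADQ", "BDI", "OCDS")],
    epochs = grid[, c("participant", "group", "side", "pulse", "epochs")],
    ground_truth = list(
      coupling = config$coupling,
      true_group_effect = config$ald_coupling_factor,
      coherence = clin[, c("participant", "coherence")]
    )
  )
}
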