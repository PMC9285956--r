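# Replicate runner for the effect-locality study: simulates one full cohort
# through the complete pipeline and summarises the planted-effect signature.
#
# Simulation problem sizes (fs = 250 Hz, 8 trials per condition cell) are the
# package's replicate-study defaults; the methods vignette discusses the
# choice. The null configuration sets the coupling degradation to 1 AND
# equalises the suppression factors, which makes the two groups statistically
# exchangeable.

derive_seed_for_test <- function(seed, i) seed * 1000L + i

signature_replicate <- function(seed, null = FALSE, n_trials = 8) {
  cfg <- sim_config(
    n_hc = 16, n_ald = 11, fs = 250,
    n_single = n_trials, n_paired = n_trials,
    ald_coupling_factor = if (null) 1 else formals(sim_config)$ald_coupling_factor,
    suppression_ald = if (null) formals(sim_config)$suppression_hc else
      formals(sim_config)$suppression_ald,
    seed = seed
  )
  st <- simulate_study(cfg)
  m <- st$metrics
  mets <- c("mean_degree", "mean_clustering", "local_efficiency",
            "global_efficiency")
  cellmean <- function(g, s, p, col) {
    mean(m[[col]][m$group == g & m$side == s & m$pulse == p])
  }

  lower_pl <- all(vapply(mets, function(mc) {
    cellmean("ALD", "left", "paired", mc) < cellmean("HC", "left", "paired", mc)
  }, logical(1)))

  cells <- list(c("left", "paired"), c("left", "single"),
                c("right", "paired"), c("right", "single"))
  local_only <- all(vapply(mets, function(mc) {
    gaps <- vapply(cells, function(cs) {
      cellmean("ALD", cs[1], cs[2], mc) - cellmean("HC", cs[1], cs[2], mc)
    }, numeric(1))
    which.min(gaps) == 1L
  }, logical(1)))

  an <- mixed_anova(m, "mean_degree")
  p_interaction <- an$table$p[an$table$effect == "group x pulse"]

  roc <- study_roc(st)
  # directional AUC for the study hypothesis: lower network metric -> ALD
  roc$dir_auc <- 1 - roc$auc_raw
  auc_ok <- all(vapply(mets, function(mc) {
    sub <- roc[roc$metric == mc, ]
    pl <- sub$dir_auc[sub$side == "left" & sub$pulse == "paired"]
    all(pl > sub$dir_auc[sub$pulse == "single"])
  }, logical(1)))

  hc <- m$mean_degree[m$group == "HC" & m$side == "left" & m$pulse == "paired"]
  al <- m$mean_degree[m$group == "ALD" & m$side == "left" & m$pulse == "paired"]
  pooled_sd <- sqrt(((length(hc) - 1) * var(hc) + (length(al) - 1) * var(al)) /
                      (length(hc) + length(al) - 2))
  list(
    lower = lower_pl, local = local_only,
    interaction_sig = p_interaction < 0.05,
    p_interaction = p_interaction,
    auc_ok = auc_ok,
    effect_size_sd = (mean(hc) - mean(al)) / pooled_sd
  )
}
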