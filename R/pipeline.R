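#' From epochs to the four global network metrics
#'
#' One condition cell's full analysis: amplitude-based epoch rejection,
#' whole-epoch de-meaning, averaging to the ERP, re-cutting to the network
#' analysis window, lag-maximised connectivity, direction resolution with the
#' absolute threshold, and the four global graph metrics.
#'
#' @param epochs A `tep_epochs`.
#' @param threshold Absolute correlation threshold (default 0.6).
#' @param max_lag_ms Maximal delay for the lag scan (default 150 ms).
#' @param analysis_window Network-analysis window in ms (default 50-350).
#' @param reject_uv Artifact-rejection threshold in microvolts; `NULL`
#'   disables rejection.
#' @param per_epoch Use per-epoch connectivity matrices averaged, instead of
#'   the averaged-ERP trace.
#' @return A list with `metrics` (`tep_metrics`), `graph` (`tep_graph`),
#'   `connectivity` (`tep_connectivity`) and `n_kept`.
#' @export
analyze_epochs <- function(epochs, threshold = 0.6, max_lag_ms = 150,
                           analysis_window = c(50, 350), reject_uv = 200,
                           per_epoch = FALSE) {
  stopifnot(inherits(epochs, "tep_epochs"))
  if (!is.null(reject_uv)) epochs <- reject_artifacts(epochs, reject_uv)
  epochs <- demean_epochs(epochs)
  cropped <- crop_epochs(epochs, analysis_window)
  conn <- build_connectivity(cropped, max_lag_ms = max_lag_ms,
                             per_epoch = per_epoch)
  graph <- direct_and_threshold(conn, threshold)
  list(
    metrics = network_metrics(graph),
    graph = graph,
    connectivity = conn,
    n_kept = sum(epochs$kept_mask)
  )
}

#' Simulate and analyse a full synthetic study
#'
#' Generates a synthetic cohort cell by cell and runs the complete pipeline on
#' each: rejection, de-meaning, ERP averaging, the LICI inhibition statistic
#' per stimulation site, and the thresholded directed network metrics per
#' site x pulse cell. Raw epochs are discarded as soon as a cell is analysed,
#' so large cohorts stay within memory.
#'
#' @param config A [sim_config()].
#' @inheritParams analyze_epochs
#' @param lici_window Integration window for the inhibition statistic (ms).
#' @return A `tep_study` list: `cohort` (wide per-participant tibble with
#'   clinical scores, LICI per side and the 16 metric x condition columns),
#'   `metrics` (long tibble for the ANOVA layer), `lici`, `ground_truth`,
#'   `config`.
#' @export
simulate_study <- function(config, threshold = 0.6, max_lag_ms = 150,
                           analysis_window = c(50, 350),
                           lici_window = c(50, 150), reject_uv = 200,
                           per_epoch = FALSE) {
  stopifnot(inherits(config, "tep_sim_config"))
  participants <- participant_frame(config)
  clin <- clinical_scores(config, participants)

  n_cells <- nrow(participants) * 4L
  mr <- list(participant = character(n_cells), group = character(n_cells),
             side = character(n_cells), pulse = character(n_cells),
             mean_degree = numeric(n_cells), mean_clustering = numeric(n_cells),
             local_efficiency = numeric(n_cells),
             global_efficiency = numeric(n_cells), n_kept = integer(n_cells))
  n_li <- nrow(participants) * 2L
  li <- list(participant = character(n_li), group = character(n_li),
             side = character(n_li), auc_single = numeric(n_li),
             auc_paired = numeric(n_li), lici_percent = numeric(n_li))
  tpl_cache <- new.env(parent = emptyenv())
  cell_i <- 0L
  lici_i <- 0L
  for (i in seq_len(nrow(participants))) {
    p <- participants[i, ]
    for (side in c("left", "right")) {
      erps <- list()
      for (pulse in c("single", "paired")) {
        ep <- generate_epoch_set(config, p$group, side, pulse,
                                 p$participant_seed, .tpl_cache = tpl_cache)
        if (!is.null(reject_uv)) ep <- reject_artifacts(ep, reject_uv)
        ep <- demean_epochs(ep)
        erps[[pulse]] <- average_erp(ep)
        cell <- analyze_epochs(ep, threshold = threshold,
                               max_lag_ms = max_lag_ms,
                               analysis_window = analysis_window,
                               reject_uv = NULL, per_epoch = per_epoch)
        m <- cell$metrics
        cell_i <- cell_i + 1L
        mr$participant[cell_i] <- p$participant
        mr$group[cell_i] <- p$group
        mr$side[cell_i] <- side
        mr$pulse[cell_i] <- pulse
        mr$mean_degree[cell_i] <- m$mean_degree
        mr$mean_clustering[cell_i] <- m$mean_clustering
        mr$local_efficiency[cell_i] <- m$local_efficiency
        mr$global_efficiency[cell_i] <- m$global_efficiency
        mr$n_kept[cell_i] <- cell$n_kept
      }
      auc_s <- rectified_auc(erps$single, lici_window[1], lici_window[2])$mean
      auc_p <- rectified_auc(erps$paired, lici_window[1], lici_window[2])$mean
      lici_i <- lici_i + 1L
      li$participant[lici_i] <- p$participant
      li$group[lici_i] <- p$group
      li$side[lici_i] <- side
      li$auc_single[lici_i] <- auc_s
      li$auc_paired[lici_i] <- auc_p
      li$lici_percent[lici_i] <- lici_percent(auc_p, auc_s)
    }
  }
  metrics <- tibble::new_tibble(mr, nrow = n_cells)
  lici <- tibble::new_tibble(li, nrow = n_li)

  cohort <- cohort_table(metrics, lici,
                         clin[, c("participant", "group", "SADQ", "BDI", "OCDS")])
  structure(
    list(cohort = cohort, metrics = metrics, lici = lici,
         ground_truth = list(coupling = config$coupling,
                             true_group_effect = config$ald_coupling_factor,
                             coherence = clin[, c("participant", "coherence")]),
         config = config),
    class = "tep_study"
  )
}

#' Wide per-participant cohort table
#'
#' Joins clinical scores, per-site LICI values and the four network metrics
#' of the four condition cells into one row per participant, with metric
#' columns named `<metric>_<side>_<pulse>`.
#'
#' @param metrics Long metric tibble (as in `tep_study$metrics`).
#' @param lici LICI tibble (as in `tep_study$lici`); optional.
#' @param participants Per-participant table with at least `participant` and
#'   `group`; optional.
#' @return A wide tibble, one row per participant.
#' @export
cohort_table <- function(metrics, lici = NULL, participants = NULL) {
  wide <- metrics |>
    dplyr::select(-dplyr::any_of("n_kept")) |>
    tidyr::pivot_longer(
      cols = c("mean_degree", "mean_clustering",
               "local_efficiency", "global_efficiency"),
      names_to = "metric", values_to = "value"
    ) |>
    tidyr::pivot_wider(names_from = c("metric", "side", "pulse"),
                       values_from = "value", names_sep = "_")
  if (!is.null(lici)) {
    lw <- tidyr::pivot_wider(
      lici[, c("participant", "side", "lici_percent")],
      names_from = "side", values_from = "lici_percent",
      names_prefix = "lici_"
    )
    wide <- dplyr::left_join(wide, lw, by = "participant")
  }
  if (!is.null(participants)) {
    wide <- dplyr::left_join(wide, participants,
                             by = intersect(c("participant", "group"),
                                            names(participants)))
    wide <- dplyr::relocate(wide, dplyr::any_of(c("participant", "group",
                                                  "SADQ", "BDI", "OCDS")))
  }
  wide
}

#' @export
print.tep_study <- function(x, ...) {
  cat(sprintf("<tep_study> %d participants (%d HC, %d ALD), %d channels @ %g Hz\n",
              nrow(x$cohort), x$config$n_hc, x$config$n_ald,
              x$config$n_channels, x$config$fs))
  invisible(x)
}

#' ROC discrimination of all metric-condition columns
#'
#' Computes the (orientation-corrected) ROC AUC of every
#' `<metric>_<side>_<pulse>` column of a study's cohort table for
#' discriminating the two groups.
#'
#' @param study A `tep_study` (or a cohort tibble with a `group` column).
#' @return A tibble: `metric`, `side`, `pulse`, `auc`, `ci_low`, `ci_high`.
#' @export
study_roc <- function(study) {
  cohort <- if (inherits(study, "tep_study")) study$cohort else study
  cols <- tidyr::expand_grid(
    metric = c("mean_degree", "mean_clustering",
               "local_efficiency", "global_efficiency"),
    side = c("left", "right"), pulse = c("single", "paired")
  )
  purrr::pmap_dfr(cols, function(metric, side, pulse) {
    col <- paste(metric, side, pulse, sep = "_")
    r <- roc_auc(cohort[[col]], cohort$group)
    tibble::tibble(metric = metric, side = side, pulse = pulse,
                   auc = r$auc, auc_raw = r$auc_raw,
                   ci_low = r$ci_low, ci_high = r$ci_high)
  })
}

#' Write the group-level statistical tables of a study
#'
#' Runs the statistical layer on a simulated (or assembled) study and writes
#' tidy TSVs: `anova.tsv` (all four metrics), `logistic.tsv` (standardised
#' local efficiency model, one row per term), `roc.tsv`, `correlations.tsv`
#' (SADQ vs metrics within the ALD group) and `lici.tsv`.
#'
#' @param study A `tep_study`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_study_stats <- function(study, dir) {
  stopifnot(inherits(study, "tep_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  metrics <- c("mean_degree", "mean_clustering",
               "local_efficiency", "global_efficiency")

  anova_tab <- purrr::map_dfr(metrics, function(mc) {
    dplyr::mutate(tidy(mixed_anova(study$metrics, mc)), metric = mc,
                  .before = 1)
  })
  readr::write_tsv(anova_tab, file.path(dir, "anova.tsv"))

  le_cols <- paste0("local_efficiency_", c("left_single", "left_paired",
                                           "right_single", "right_paired"))
  logit <- logistic_group_model(study$cohort, le_cols)
  readr::write_tsv(tidy(logit), file.path(dir, "logistic.tsv"))

  readr::write_tsv(study_roc(study), file.path(dir, "roc.tsv"))

  cor_cols <- as.vector(outer(metrics, c("left_single", "left_paired",
                                         "right_single", "right_paired"),
                              paste, sep = "_"))
  cors <- clinical_correlations(study$cohort, cor_cols)
  readr::write_tsv(cors, file.path(dir, "correlations.tsv"))

  readr::write_tsv(study$lici, file.path(dir, "lici.tsv"))
  invisible(dir)
}
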