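#' Three-way mixed ANOVA (group x pulse x side)
#'
#' Fits the 2x2x2 mixed design with one between-subject factor (`group`) and
#' two within-subject factors (`pulse`, `side`) on one network metric, via the
#' classical sums-of-squares decomposition with separate error strata
#' (subjects, subjects-by-pulse, subjects-by-side, subjects-by-pulse-by-side).
#' Participants with incomplete cells are dropped listwise. Partial eta
#' squared is `SS_effect / (SS_effect + SS_error)` with the error term of the
#' effect's own stratum.
#'
#' @param data A long tibble with columns `participant`, `group` (`"HC"` /
#'   `"ALD"`), `pulse` (`"single"`/`"paired"`), `side` (`"left"`/`"right"`)
#'   and the metric column.
#' @param metric Name of the metric column (string).
#' @return A `tep_anova` object; `tidy()` returns the effect table
#'   (`effect`, `df1`, `df2`, `ss`, `ss_error`, `F`, `p`, `partial_eta_sq`).
#' @export
mixed_anova <- function(data, metric) {
  d <- prepare_anova_data(data, metric)
  n_per_group <- table(unique(d[, c("participant", "group")])$group)
  if (length(n_per_group) < 2 || any(n_per_group < 2)) {
    stop_invalid("The mixed ANOVA needs at least 2 complete participants per group.")
  }
  fit <- stats::aov(
    value ~ group * pulse * side + Error(participant / (pulse * side)),
    data = d
  )
  tab <- extract_aov_table(fit)
  structure(
    list(table = tab, n = length(unique(d$participant)),
         n_per_group = as.list(n_per_group), metric = metric, data = d),
    class = "tep_anova"
  )
}

prepare_anova_data <- function(data, metric) {
  need <- c("participant", "group", "pulse", "side", metric)
  if (!all(need %in% names(data))) {
    stop_invalid(sprintf("`data` needs columns %s.", paste(need, collapse = ", ")))
  }
  d <- data[, need]
  names(d)[5] <- "value"
  d <- d[stats::complete.cases(d), ]
  # listwise deletion: keep only participants with all 4 cells
  cnt <- tapply(d$value, d$participant, length)
  keep <- names(cnt)[cnt == 4L]
  d <- d[d$participant %in% keep, ]
  if (nrow(d) == 0) stop_invalid("No participant has complete cells.")
  d$participant <- factor(d$participant)
  d$group <- factor(d$group)
  d$pulse <- factor(d$pulse)
  d$side <- factor(d$side)
  d
}

extract_aov_table <- function(fit) {
  sm <- summary(fit)
  rows <- list()
  for (stratum in names(sm)) {
    tb <- sm[[stratum]][[1]]
    terms <- trimws(rownames(tb))
    resid <- terms == "Residuals"
    if (!any(resid)) next
    ss_err <- tb[resid, "Sum Sq"]
    df_err <- tb[resid, "Df"]
    for (k in which(!resid)) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        effect = gsub(":", " x ", terms[k]),
        df1 = tb[k, "Df"], df2 = df_err,
        ss = tb[k, "Sum Sq"], ss_error = ss_err,
        F = tb[k, "F value"], p = tb[k, "Pr(>F)"],
        partial_eta_sq = tb[k, "Sum Sq"] / (tb[k, "Sum Sq"] + ss_err)
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' @export
print.tep_anova <- function(x, ...) {
  cat(sprintf("<tep_anova> metric: %s, n = %d complete participants\n",
              x$metric, x$n))
  print(as.data.frame(x$table), digits = 4)
  invisible(x)
}

#' Sidak-adjusted simple effects
#'
#' Tests the effect of one factor at each fixed level of another, after
#' collapsing (averaging) the remaining within-subject factor per
#' participant. A between-subject effect (`effect = "group"`) is tested by a
#' one-way ANOVA on participant means; a within-subject effect at a group
#' level by the paired contrast. Pairwise p-values are Sidak-adjusted within
#' each simple-effect family (`p_adj = 1 - (1 - p)^m` with `m` the number of
#' pairwise comparisons in the family).
#'
#' @inheritParams mixed_anova
#' @param effect Factor whose effect is tested (`"group"`, `"pulse"` or
#'   `"side"`).
#' @param at Factor whose levels define the simple-effect families.
#' @return A tibble with one row per family level and comparison: estimated
#'   marginal means, standard errors, mean difference with 95 percent CI,
#'   `F`, `p` and `p_sidak`.
#' @export
simple_effects <- function(data, metric, effect = "group", at = "pulse") {
  d <- prepare_anova_data(data, metric)
  if (effect == at) stop_invalid("`effect` and `at` must differ.")
  fams <- levels(d[[at]])
  out <- lapply(fams, function(lv) {
    sub <- d[d[[at]] == lv, ]
    agg <- stats::aggregate(value ~ participant + group + 0, data = sub,
                            FUN = mean)
    if (effect == "group") {
      simple_between(agg, lv, at)
    } else {
      simple_within(sub, d, effect, lv, at)
    }
  })
  res <- dplyr::bind_rows(out)
  m <- nrow(res) / length(fams) # comparisons per family
  res$p_sidak <- 1 - (1 - res$p)^m
  res
}

simple_between <- function(agg, level, at) {
  fit <- stats::aov(value ~ group, data = agg)
  tb <- summary(fit)[[1]]
  mse <- tb["Residuals", "Mean Sq"]
  df2 <- tb["Residuals", "Df"]
  means <- tapply(agg$value, agg$group, mean)
  ns <- tapply(agg$value, agg$group, length)
  gl <- names(means)
  diff <- means[gl[1]] - means[gl[2]]
  se_diff <- sqrt(mse * (1 / ns[gl[1]] + 1 / ns[gl[2]]))
  tcrit <- stats::qt(0.975, df2)
  tibble::tibble(
    at = at, level = level,
    comparison = paste(gl[1], "-", gl[2]),
    em_1 = means[gl[1]], se_1 = sqrt(mse / ns[gl[1]]),
    em_2 = means[gl[2]], se_2 = sqrt(mse / ns[gl[2]]),
    mean_diff = unname(diff),
    ci_low = unname(diff - tcrit * se_diff),
    ci_high = unname(diff + tcrit * se_diff),
    F = tb["group", "F value"], df1 = tb["group", "Df"], df2 = df2,
    p = tb["group", "Pr(>F)"]
  )
}

simple_within <- function(sub, full, effect, level, at) {
  # average over the remaining factor, then a paired contrast between the
  # two levels of `effect`
  eff_levels <- levels(full[[effect]])
  agg <- stats::aggregate(
    value ~ participant + sub[[effect]], data = sub, FUN = mean
  )
  names(agg)[2] <- "eff"
  w <- tidyr::pivot_wider(tibble::as_tibble(agg), names_from = "eff",
                          values_from = "value")
  a <- w[[eff_levels[1]]]
  b <- w[[eff_levels[2]]]
  tt <- stats::t.test(a, b, paired = TRUE)
  diff <- mean(a - b)
  tibble::tibble(
    at = at, level = level,
    comparison = paste(eff_levels[1], "-", eff_levels[2]),
    em_1 = mean(a), se_1 = sd(a) / sqrt(length(a)),
    em_2 = mean(b), se_2 = sd(b) / sqrt(length(b)),
    mean_diff = diff,
    ci_low = tt$conf.int[1], ci_high = tt$conf.int[2],
    F = unname(tt$statistic)^2, df1 = 1, df2 = unname(tt$parameter),
    p = tt$p.value
  )
}

#' Standardise a numeric vector (z-scores)
#'
#' Subtracts the mean and divides by the sample (n - 1) standard deviation.
#'
#' @param values Numeric vector with positive SD.
#' @return The standardised vector (mean 0, SD 1).
#' @export
zscore <- function(values) {
  if (!is.numeric(values)) stop_invalid("`values` must be numeric.")
  s <- sd(values)
  if (!is.finite(s) || s == 0) {
    stop_invalid("Cannot z-score a constant (zero-SD) vector.")
  }
  (values - mean(values)) / s
}

#' Binomial logistic regression for group membership
#'
#' Fits `P(group = ALD)` on z-scored predictors by maximum likelihood (IRLS
#' via [stats::glm()]). Reports, per predictor, the coefficient, its SE, the
#' Wald statistic `(B / SE)^2`, the inverted odds ratio `exp(-B)` with its
#' inverted 95 percent Wald CI (so that a unit *decrease* of the predictor
#' maps to the reported odds multiplier), plus model-level Nagelkerke R
#' squared and the 0.5-cutoff classification table. Quasi-separated fits are
#' flagged as non-converged.
#'
#' @param data A tibble with one row per participant.
#' @param predictors Character vector of numeric predictor columns.
#' @param outcome Name of the group column (default `"group"`); the positive
#'   class is `"ALD"`.
#' @param standardize Z-score the predictors first (default `TRUE`).
#' @return A `tep_logistic` object; `tidy()` gives the coefficient table,
#'   `glance()` the model summary.
#' @export
logistic_group_model <- function(data, predictors, outcome = "group",
                                 standardize = TRUE) {
  if (!all(predictors %in% names(data))) {
    stop_invalid("All `predictors` must be columns of `data`.")
  }
  y <- as.integer(data[[outcome]] == "ALD")
  if (length(unique(y)) < 2) {
    stop_invalid("Both groups must be present in the outcome.")
  }
  X <- data[, predictors, drop = FALSE]
  X <- as.data.frame(lapply(X, function(col) if (standardize) zscore(col) else col))
  df <- cbind(data.frame(.y = y), X)

  separated <- FALSE
  fit <- withCallingHandlers(
    stats::glm(.y ~ ., data = df, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        separated <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  converged <- fit$converged && !separated && all(abs(stats::coef(fit)) < 20)

  cf <- summary(fit)$coefficients
  b <- cf[, "Estimate"]; se <- cf[, "Std. Error"]
  z975 <- stats::qnorm(0.975)
  or <- exp(b)
  inv_lo <- exp(-(b + z975 * se))
  inv_hi <- exp(-(b - z975 * se))
  coef_tab <- tibble::tibble(
    term = rownames(cf),
    B = unname(b), SE = unname(se),
    wald = unname((b / se)^2), df = 1,
    p = unname(cf[, "Pr(>|z|)"]),
    odds_ratio = unname(or),
    inverted_odds_ratio = unname(exp(-b)),
    inv_or_ci_low = unname(pmin(inv_lo, inv_hi)),
    inv_or_ci_high = unname(pmax(inv_lo, inv_hi))
  )

  n <- length(y)
  ll1 <- as.numeric(stats::logLik(fit))
  ll0 <- as.numeric(stats::logLik(stats::glm(.y ~ 1, data = df,
                                             family = stats::binomial())))
  nagelkerke <- (1 - exp(2 * (ll0 - ll1) / n)) / (1 - exp(2 * ll0 / n))
  chisq <- 2 * (ll1 - ll0)
  chisq_df <- length(predictors)
  chisq_p <- stats::pchisq(chisq, chisq_df, lower.tail = FALSE)

  pred <- as.integer(stats::fitted(fit) >= 0.5)
  tp <- sum(pred == 1 & y == 1); tn <- sum(pred == 0 & y == 0)
  fp <- sum(pred == 1 & y == 0); fn <- sum(pred == 0 & y == 1)
  cls <- tibble::tibble(
    sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
    ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_,
    accuracy = (tp + tn) / n
  )

  structure(
    list(coefficients = coef_tab, nagelkerke_r2 = nagelkerke,
         model_chisq = chisq, model_df = chisq_df, model_p = chisq_p,
         classification = cls, converged = converged, n = n, fit = fit),
    class = "tep_logistic"
  )
}

#' @export
print.tep_logistic <- function(x, ...) {
  cat(sprintf("<tep_logistic> n = %d, Nagelkerke R2 = %.3f, accuracy = %.2f%s\n",
              x$n, x$nagelkerke_r2, x$classification$accuracy,
              if (x$converged) "" else " [non-converged / separation]"))
  print(as.data.frame(x$coefficients), digits = 3)
  invisible(x)
}

#' ROC area under the curve with Hanley-McNeil confidence interval
#'
#' AUC computed as the Mann-Whitney probability that a randomly chosen
#' positive-class score ranks above a randomly chosen negative-class score
#' (ties count one half), via midranks. If the raw AUC falls below 0.5 the
#' reported AUC is `1 - AUC` and the orientation notes that lower scores
#' indicate the positive class. The 95 percent CI uses the Hanley-McNeil
#' variance approximation, clipped to `[0, 1]`.
#'
#' @param scores Numeric classifier scores (e.g. a network metric).
#' @param labels Class labels; `positive` marks the positive class.
#' @param positive Positive-class label (default `"ALD"`).
#' @return A `tep_roc` list: `auc`, `auc_raw`, `direction`, `ci_low`,
#'   `ci_high`, `se`, `n_pos`, `n_neg`.
#' @export
roc_auc <- function(scores, labels, positive = "ALD") {
  ok <- is.finite(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  pos <- labels == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) {
    stop_invalid("Both classes must be present to compute an AUC.")
  }
  r <- rank(scores, ties.method = "average")
  auc_raw <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  direction <- if (auc_raw >= 0.5) "higher scores -> positive class"
               else "lower scores -> positive class"
  auc <- max(auc_raw, 1 - auc_raw)
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  se <- sqrt((auc * (1 - auc) + (n1 - 1) * (q1 - auc^2) +
                (n0 - 1) * (q2 - auc^2)) / (n1 * n0))
  z <- stats::qnorm(0.975)
  structure(
    list(auc = auc, auc_raw = auc_raw, direction = direction,
         ci_low = max(0, auc - z * se), ci_high = min(1, auc + z * se),
         se = se, n_pos = n1, n_neg = n0),
    class = "tep_roc"
  )
}

#' @export
print.tep_roc <- function(x, ...) {
  cat(sprintf("<tep_roc> AUC = %.3f (95%% CI %.3f-%.3f), %s\n",
              x$auc, x$ci_low, x$ci_high, x$direction))
  invisible(x)
}

#' Pearson correlations of network metrics with a clinical score
#'
#' Within one group (default the patient group), correlates each metric
#' column with a clinical score, returning `r`, `n` and the two-sided p-value
#' per metric. Metrics with fewer than 3 complete pairs are skipped with a
#' warning.
#'
#' @param data A per-participant tibble.
#' @param metric_columns Character vector of metric column names.
#' @param clinical Clinical score column (default `"SADQ"`).
#' @param group Group to restrict to (default `"ALD"`); `NULL` uses all rows.
#' @return A tibble with columns `metric`, `r`, `n`, `p`.
#' @export
clinical_correlations <- function(data, metric_columns, clinical = "SADQ",
                                  group = "ALD") {
  if (!is.null(group)) data <- data[data$group == group, ]
  rows <- lapply(metric_columns, function(mc) {
    x <- data[[mc]]; y <- data[[clinical]]
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < 3) {
      warn(sprintf("Skipping `%s`: fewer than 3 complete pairs.", mc))
      return(NULL)
    }
    ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
    tibble::tibble(metric = mc, r = unname(ct$estimate), n = sum(ok),
                   p = ct$p.value)
  })
  dplyr::bind_rows(rows)
}
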