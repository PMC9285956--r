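test_that("effects with zero contrast means give F = 0 with positive error", {
  # orthogonal construction: subject offsets and subject-specific contrast
  # loadings are +-1 balanced within each group, so every effect's cell-mean
  # contrast is exactly zero while every error stratum keeps variance
  subj <- sprintf("S%d", 1:8)
  group <- rep(c("HC", "ALD"), each = 4)
  a_s <- rep(c(1, -1), 4)
  z1 <- rep(c(1, -1, -1, 1), 2)
  z2 <- rep(c(1, 1, -1, -1), 2)
  z3 <- rep(c(-1, 1, 1, -1), 2)
  rows <- list()
  for (i in seq_along(subj)) {
    for (p in c(-1, 1)) for (s in c(-1, 1)) {
      rows[[length(rows) + 1]] <- data.frame(
        participant = subj[i], group = group[i],
        pulse = ifelse(p < 0, "single", "paired"),
        side = ifelse(s < 0, "left", "right"),
        value = 10 + a_s[i] + z1[i] * p + z2[i] * s + z3[i] * p * s
      )
    }
  }
  d <- dplyr::bind_rows(rows)
  fit <- mixed_anova(d, "value")
  expect_true(all(abs(fit$table$F) < 1e-12))
  expect_true(all(fit$table$ss_error > 0))
})

test_that("the sums of squares add up to the total on random data", {
  withr::with_seed(21, {
    d <- random_metric_table(6)
  })
  fit <- mixed_anova(d, "value")
  # total SS decomposes into every effect SS plus the four distinct error SS
  ss_total <- sum((d$value - mean(d$value))^2)
  errs <- unique(fit$table$ss_error)
  expect_equal(ss_total, sum(fit$table$ss) + sum(errs), tolerance = 1e-9)
})

test_that("mixed ANOVA matches the explicit balanced sums-of-squares oracle", {
  withr::with_seed(22, {
    for (k in 1:5) {
      d <- random_metric_table(5)
      fit <- mixed_anova(d, "value")
      oracle <- oracle_mixed_anova_balanced(d)
      tab <- fit$table
      pick <- function(name) tab[tab$effect == name, ]
      expect_equal(pick("group")$F, oracle$group$F, tolerance = 1e-9)
      expect_equal(pick("pulse")$F, oracle$pulse$F, tolerance = 1e-9)
      expect_equal(pick("group x pulse")$F, oracle$group_pulse$F, tolerance = 1e-9)
      expect_equal(pick("side")$F, oracle$side$F, tolerance = 1e-9)
      expect_equal(pick("group x side")$F, oracle$group_side$F, tolerance = 1e-9)
      expect_equal(pick("pulse x side")$F, oracle$pulse_side$F, tolerance = 1e-9)
      expect_equal(pick("group x pulse x side")$F, oracle$group_pulse_side$F,
                   tolerance = 1e-9)
      expect_equal(pick("group x pulse")$partial_eta_sq,
                   oracle$group_pulse$pes, tolerance = 1e-9)
      expect_equal(pick("group x pulse")$p, oracle$group_pulse$p, tolerance = 1e-9)
    }
  })
})

test_that("listwise deletion drops participants with incomplete cells", {
  withr::with_seed(23, d <- random_metric_table(5))
  d2 <- d[!(d$participant == "S01" & d$pulse == "paired" & d$side == "left"), ]
  fit <- mixed_anova(d2, "value")
  expect_equal(fit$n, 9)
})

test_that("a planted single-cell deficit powers the pulse-by-group interaction", {
  withr::with_seed(24, {
    hits <- vapply(1:120, function(i) {
      d <- random_metric_table(12, sd = 1, shift_cell = c("ALD", "left", "paired"),
                               shift = -3)
      fit <- mixed_anova(d, "value")
      fit$table$p[fit$table$effect == "group x pulse"] < 0.05
    }, logical(1))
  })
  expect_gte(mean(hits), 0.9)
})

test_that("the interaction test is calibrated under the null", {
  withr::with_seed(25, {
    ps <- vapply(1:400, function(i) {
      d <- random_metric_table(10)
      fit <- mixed_anova(d, "value")
      fit$table$p[fit$table$effect == "group x pulse"]
    }, numeric(1))
  })
  rate <- mean(ps < 0.05)
  ci_half <- 1.96 * sqrt(0.05 * 0.95 / 400)
  expect_lte(abs(rate - 0.05), ci_half + 1e-9)
})

test_that("simple effects recover a group difference only where planted", {
  withr::with_seed(26, {
    d <- random_metric_table(10, sd = 0.8, shift_cell = c("ALD", "left", "paired"),
                             shift = -3)
    d2 <- d
    d2$value[d2$group == "ALD" & d2$side == "right" & d2$pulse == "paired"] <-
      d2$value[d2$group == "ALD" & d2$side == "right" & d2$pulse == "paired"] - 3
  })
  se <- simple_effects(d2, "value", effect = "group", at = "pulse")
  expect_equal(nrow(se), 2)
  p_paired <- se$p[se$level == "paired"]
  p_single <- se$p[se$level == "single"]
  expect_lt(p_paired, 0.05)
  expect_gt(p_single, 0.05)
  expect_true(all(se$p_sidak >= se$p - 1e-12))

  sw <- simple_effects(d2, "value", effect = "pulse", at = "group")
  expect_lt(sw$p_sidak[sw$level == "ALD"], 0.05)
})

test_that("z-scores use the sample-SD convention", {
  expect_equal(zscore(c(1, 2, 3)), c(-1, 0, 1))
  expect_error(zscore(rep(4, 5)), class = "tepnet_invalid_argument")
  withr::with_seed(27, v <- rnorm(40, 5, 3))
  z <- zscore(v)
  expect_lt(abs(mean(z)), 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
})

test_that("logistic MLE matches an exhaustive grid search", {
  withr::with_seed(28, {
    x <- rnorm(24)
    y <- rbinom(24, 1, plogis(0.4 - 1.1 * x))
  })
  d <- tibble::tibble(group = ifelse(y == 1, "ALD", "HC"), pred = x)
  fit <- logistic_group_model(d, "pred", standardize = FALSE)
  oracle <- oracle_logistic_grid(y, x)
  ll_fit <- as.numeric(stats::logLik(fit$fit))
  expect_lt(abs(ll_fit - oracle$loglik), 1e-4)
  expect_equal(unname(fit$coefficients$B), oracle$coef, tolerance = 1e-2)
})

test_that("inverted odds ratios and their CIs follow the reporting convention", {
  withr::with_seed(29, {
    x <- rnorm(40)
    y <- rbinom(40, 1, plogis(-0.8 * x))
  })
  d <- tibble::tibble(group = ifelse(y == 1, "ALD", "HC"), pred = x)
  fit <- logistic_group_model(d, "pred")
  tab <- tidy(fit)
  b <- tab$B[tab$term == "pred"]
  se <- tab$SE[tab$term == "pred"]
  expect_equal(tab$inverted_odds_ratio[tab$term == "pred"], exp(-b), tolerance = 1e-12)
  lo <- exp(-(b + 1.96 * se)); hi <- exp(-(b - 1.96 * se))
  expect_equal(tab$inv_or_ci_low[tab$term == "pred"], min(lo, hi), tolerance = 1e-3)
  expect_equal(tab$wald[tab$term == "pred"], (b / se)^2, tolerance = 1e-12)
})

test_that("Nagelkerke R2 is 0 for a null model and approaches 1 under separation", {
  withr::with_seed(30, {
    x <- rnorm(30)
    ynull <- rbinom(30, 1, 0.5)
  })
  d0 <- tibble::tibble(group = ifelse(ynull == 1, "ALD", "HC"), pred = 0 * x + rnorm(30))
  f0 <- logistic_group_model(d0, "pred")
  expect_lt(f0$nagelkerke_r2, 0.3)
  expect_gte(f0$nagelkerke_r2, 0)

  dsep <- tibble::tibble(group = rep(c("HC", "ALD"), each = 10),
                         pred = c(rnorm(10, -3), rnorm(10, 3)))
  fsep <- logistic_group_model(dsep, "pred")
  expect_false(fsep$converged)
  expect_gt(fsep$nagelkerke_r2, 0.9)
})

test_that("the classification table is computed at the 0.5 cut", {
  d <- tibble::tibble(group = rep(c("HC", "ALD"), each = 6),
                      pred = c(rnorm(6, -1.2, 0.3), rnorm(6, 1.2, 0.3)))
  fit <- logistic_group_model(d, "pred")
  cls <- glance(fit)
  pred <- as.integer(fitted(fit$fit) >= 0.5)
  y <- as.integer(d$group == "ALD")
  expect_equal(cls$accuracy, mean(pred == y))
  expect_equal(cls$sensitivity, sum(pred == 1 & y == 1) / sum(y == 1))
  expect_equal(cls$specificity, sum(pred == 0 & y == 0) / sum(y == 0))
})

test_that("a planted deficit yields a negative logistic coefficient in most runs", {
  withr::with_seed(31, {
    signs <- vapply(1:100, function(i) {
      le_hc <- rnorm(16, 0.66, 0.06)
      le_ald <- rnorm(11, 0.59, 0.11)
      d <- tibble::tibble(group = c(rep("HC", 16), rep("ALD", 11)),
                          le = c(le_hc, le_ald))
      fit <- logistic_group_model(d, "le")
      tidy(fit)$B[2] < 0
    }, logical(1))
  })
  expect_gte(mean(signs), 0.9)
})

test_that("AUC equals all-pairs counting, with ties at one half", {
  expect_equal(roc_auc(c(1, 2, 3, 10, 11, 12), rep(c("HC", "ALD"), each = 3))$auc, 1)
  withr::with_seed(32, {
    for (k in 1:5) {
      sc <- sample(1:8, 30, replace = TRUE) # many ties
      lab <- sample(c("HC", "ALD"), 30, replace = TRUE, prob = c(0.6, 0.4))
      if (length(unique(lab)) < 2) next
      r <- roc_auc(sc, lab)
      expect_equal(r$auc_raw, oracle_auc_pairs(sc, lab, "ALD"), tolerance = 1e-12)
    }
  })
  expect_error(roc_auc(1:5, rep("ALD", 5)), class = "tepnet_invalid_argument")
})

test_that("AUC is near one half for random labels and invariant to monotone maps", {
  withr::with_seed(33, {
    sc <- rnorm(2000)
    lab <- sample(c("HC", "ALD"), 2000, replace = TRUE)
  })
  r <- roc_auc(sc, lab)
  expect_lt(abs(r$auc_raw - 0.5), 0.04)
  r2 <- roc_auc(exp(3 * sc), lab)
  expect_equal(r2$auc_raw, r$auc_raw, tolerance = 1e-12)
  expect_true(r$ci_low <= r$auc && r$auc <= r$ci_high)
})

test_that("clinical correlations recover exact and null relations", {
  d <- tibble::tibble(group = "ALD", SADQ = 1:10, m1 = 1:10,
                      m2 = residuals(lm(rnorm(10) ~ seq(1, 10))))
  res <- clinical_correlations(d, c("m1", "m2"))
  expect_equal(res$r[res$metric == "m1"], 1, tolerance = 1e-12)
  expect_lt(abs(res$r[res$metric == "m2"]), 1e-8)
  expect_equal(res$n, c(10, 10))

  small <- tibble::tibble(group = "ALD", SADQ = c(1, 2), m1 = c(3, 4))
  expect_warning(out <- clinical_correlations(small, "m1"), "fewer than 3")
  expect_equal(nrow(out), 0)
})

test_that("planted SADQ-coupling links are recovered with a negative sign", {
  withr::with_seed(34, {
    hits <- vapply(1:100, function(i) {
      coupling <- rnorm(11, 1, 0.1)
      sadq <- 25 - 20 * (coupling - 1) + rnorm(11, 0, 1.5)
      md <- 14 + 5 * (coupling - 1) + rnorm(11, 0, 0.3)
      d <- tibble::tibble(group = "ALD", SADQ = sadq, md = md)
      res <- clinical_correlations(d, "md")
      res$r < 0
    }, logical(1))
  })
  expect_gte(mean(hits), 0.9)
})
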