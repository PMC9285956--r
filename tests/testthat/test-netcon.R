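test_that("an exact shift is recovered with correlation 1 at its lag", {
  fs <- 1000
  tpl <- generate_evoked_template(fs, 600, 5, seed = 14)
  x <- tpl[101:400]
  y <- tpl[71:370] # y[t] = x[t - 30 ms]
  res <- lagged_crosscorr(x, y, fs)
  expect_equal(res$c_max, 1, tolerance = 1e-12)
  expect_equal(res$tau_ms, 30)

  res0 <- lagged_crosscorr(x, x, fs)
  expect_equal(res0$c_max, 1, tolerance = 1e-12)
  expect_equal(res0$tau_ms, 0)
})

test_that("the lag scan equals the brute-force oracle on random signals", {
  withr::with_seed(8, {
    for (k in 1:5) {
      x <- rnorm(260) + 2
      y <- 0.3 * c(rep(0, 40), x[1:220]) + rnorm(260)
      got <- lagged_crosscorr(x, y, fs = 1000, max_lag_ms = 100)
      want <- oracle_lag_scan(x, y, fs = 1000, max_lag_ms = 100)
      expect_equal(got$c_max, want$c_max, tolerance = 1e-12)
      expect_equal(got$tau_samples, want$tau_samples)
    }
  })
})

test_that("ties break toward the smaller lag and short signals error", {
  x <- rep(c(1, -1), 50) # period-2 signal: equal correlation at lags 0, 2, 4...
  res <- lagged_crosscorr(x, x, fs = 1000, max_lag_ms = 10)
  expect_equal(res$tau_samples, 0L)
  expect_error(lagged_crosscorr(rnorm(10), rnorm(10), fs = 1000, max_lag_ms = 150),
               class = "tepnet_invalid_argument")
  expect_error(lagged_crosscorr(rep(1, 300), rnorm(300), fs = 1000),
               class = "tepnet_undefined_correlation")
})

test_that("pairwise connectivity equals the per-pair oracle and flags constants", {
  withr::with_seed(9, {
    X <- matrix(rnorm(200 * 4), 200, 4)
  })
  conn <- build_connectivity(t(X), fs = 1000, max_lag_ms = 60)
  want <- oracle_connectivity(X, fs = 1000, max_lag_ms = 60)
  expect_equal(unname(conn$weights), want$weights, tolerance = 1e-12)
  expect_equal(unname(conn$lags_ms), want$lags_ms)

  Xc <- cbind(X[, 1:2], rep(2, 200))
  expect_warning(connc <- build_connectivity(t(Xc), fs = 1000, max_lag_ms = 60),
                 "constant")
  expect_equal(connc$weights[1, 3], 0)
  expect_equal(connc$weights[3, 2], 0)
})

test_that("a planted chain is recovered with its lags and directions", {
  cfg <- sim_config(
    n_hc = 1, n_ald = 0, n_channels = 3, fs = 1000, n_single = 2, n_paired = 2,
    coupling = tibble::tibble(src = c(1L, 2L), dst = c(2L, 3L),
                              gain = c(1, 1), lag_ms = c(20, 20)),
    noise_sd = 0, coherence_sd = 0, seed = 10
  )
  ep <- generate_epoch_set(cfg, "HC", "left", "single", 31)
  erp <- average_erp(crop_epochs(demean_epochs(ep), c(50, 350)))
  conn <- build_connectivity(erp)
  expect_equal(conn$lags_ms[1, 2], 20)
  expect_equal(conn$lags_ms[2, 3], 20)
  g <- direct_and_threshold(conn, 0.6)
  expect_equal(g$adjacency[1, 2], 1L)
  expect_equal(g$adjacency[2, 3], 1L)
  expect_equal(g$adjacency[2, 1], 0L)
})

test_that("identical channels give weight 1 at lag 0 and a lower-index tournament", {
  withr::with_seed(12, x <- rnorm(300))
  X <- rbind(x, x, x)
  conn <- build_connectivity(X, fs = 1000)
  off <- conn$weights[upper.tri(conn$weights) | lower.tri(conn$weights)]
  expect_equal(off, rep(1, 6), tolerance = 1e-12)
  expect_true(all(conn$lags_ms == 0))
  g <- direct_and_threshold(conn, 0.6)
  expect_equal(g$adjacency[upper.tri(g$adjacency)], rep(1L, 3))
  expect_equal(g$adjacency[lower.tri(g$adjacency)], rep(0L, 3))
})

test_that("direction and threshold rules match their literal application", {
  w <- matrix(0, 3, 3)
  w[1, 2] <- 0.9; w[2, 1] <- 0.8 # keep 1 -> 2
  w[1, 3] <- 0.5; w[3, 1] <- 0.5 # tie below threshold
  w[2, 3] <- 0.7; w[3, 2] <- 0.7 # tie at/above threshold -> lower index leads
  conn <- structure(
    list(weights = w, lags_ms = matrix(0, 3, 3), n_samples = 100, fs = 1000,
         labels = c("a", "b", "c"), max_lag_ms = 150),
    class = "tep_connectivity"
  )
  g <- direct_and_threshold(conn, 0.6)
  expect_equal(unname(g$adjacency),
               matrix(c(0L, 0L, 0L, 1L, 0L, 0L, 0L, 1L, 0L), 3, 3))
  expect_equal(g$weights[1, 2], 0.9)

  withr::with_seed(13, {
    for (k in 1:10) {
      wr <- matrix(runif(36), 6, 6); diag(wr) <- 0
      connr <- conn
      connr$weights <- wr
      connr$lags_ms <- matrix(0, 6, 6)
      connr$labels <- letters[1:6]
      gg <- direct_and_threshold(connr, 0.6)
      expect_equal(unname(gg$adjacency), oracle_direct_threshold(wr, 0.6))
    }
  })
})

test_that("thresholded graphs are antisymmetric with bounded edge counts", {
  cfg <- tiny_config(seed = 19)
  ep <- generate_epoch_set(cfg, "HC", "left", "single", 3)
  conn <- build_connectivity(crop_epochs(demean_epochs(ep), c(50, 350)))
  for (thr in c(0.5, 0.7, 0.9)) {
    g <- direct_and_threshold(conn, thr)
    expect_true(all(g$adjacency * t(g$adjacency) == 0))
    expect_lte(sum(g$adjacency), 5 * 4 / 2)
    expect_true(all(g$weights[g$adjacency == 1] >= thr))
  }
})

test_that("raising the threshold only removes edges", {
  cfg <- tiny_config(seed = 23)
  ep <- generate_epoch_set(cfg, "ALD", "left", "paired", 13)
  conn <- build_connectivity(crop_epochs(demean_epochs(ep), c(50, 350)))
  prev <- NULL
  for (thr in c(0.5, 0.6, 0.7, 0.8, 0.9)) {
    g <- direct_and_threshold(conn, thr)
    if (!is.null(prev)) expect_true(all(g$adjacency <= prev))
    prev <- g$adjacency
  }
})

test_that("independent white-noise channels stay far below the 0.6 threshold", {
  withr::with_seed(31, {
    X <- matrix(rnorm(300 * 6), 300, 6)
  })
  conn <- build_connectivity(t(X), fs = 1000, max_lag_ms = 150)
  off <- abs(conn$weights[upper.tri(conn$weights) | lower.tri(conn$weights)])
  expect_true(all(off < 0.6))
})

test_that("per-epoch connectivity averages the per-epoch matrices", {
  cfg <- tiny_config(seed = 29)
  ep <- demean_epochs(generate_epoch_set(cfg, "HC", "right", "single", 17))
  cr <- crop_epochs(ep, c(50, 350))
  got <- build_connectivity(cr, per_epoch = TRUE)
  mats <- lapply(seq_len(dim(cr$data)[1]), function(k) {
    build_connectivity(cr$data[k, , ], fs = cr$fs)$weights
  })
  expect_equal(got$weights, Reduce(`+`, mats) / length(mats), tolerance = 1e-12)
})
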