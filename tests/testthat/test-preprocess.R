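make_recording <- function(signal_fun, fs = 500, dur_s = 10, nch = 2,
                           events = NULL) {
  t <- seq(0, dur_s - 1 / fs, by = 1 / fs)
  data <- t(vapply(seq_len(nch), function(ch) signal_fun(t, ch),
                   numeric(length(t))))
  eeg_recording(data, fs = fs, events = events)
}

interior <- function(x, frac = 0.2) {
  n <- length(x)
  x[ceiling(n * frac):floor(n * (1 - frac))]
}

test_that("the 50 Hz notch removes mains while the passband is preserved", {
  rec <- make_recording(function(t, ch) sin(2 * pi * 50 * t), fs = 500, dur_s = 20)
  out <- bandpass_notch(rec)
  expect_lt(sqrt(mean(interior(out$data[1, ])^2)),
            0.01 * sqrt(mean(interior(rec$data[1, ])^2)))

  rec10 <- make_recording(function(t, ch) sin(2 * pi * 10 * t), fs = 500, dur_s = 20)
  out10 <- bandpass_notch(rec10)
  ratio <- sqrt(mean(interior(out10$data[1, ])^2)) /
    sqrt(mean(interior(rec10$data[1, ])^2))
  expect_gt(ratio, 0.95)
  expect_lt(ratio, 1.05)
})

test_that("filtering suppresses DC and out-of-band noise power", {
  rec_dc <- make_recording(function(t, ch) rep(5, length(t)), fs = 500, dur_s = 20)
  out_dc <- bandpass_notch(rec_dc)
  expect_lt(sqrt(mean(interior(out_dc$data[1, ])^2)), 0.05) # < -40 dB re 5 uV

  withr::with_seed(11, {
    rec_wn <- make_recording(function(t, ch) rnorm(length(t)), fs = 500, dur_s = 20)
  })
  out_wn <- bandpass_notch(rec_wn)
  sp <- stats::spec.pgram(interior(out_wn$data[1, ]), taper = 0, plot = FALSE)
  freq_hz <- sp$freq * 500
  p_high <- sum(sp$spec[freq_hz > 85])
  expect_lt(p_high, 0.01 * sum(sp$spec))
})

test_that("filter argument validation", {
  rec <- make_recording(function(t, ch) sin(2 * pi * 10 * t), fs = 500)
  expect_error(bandpass_notch(rec, high_hz = 300), class = "tepnet_invalid_argument")
  expect_error(bandpass_notch(rec, low_hz = 0), class = "tepnet_invalid_argument")
})

test_that("epoching cuts one epoch per matching event with the right length", {
  fs <- 1000
  n_ev <- 75
  ev_samples <- seq(2000, by = 1100, length.out = n_ev)
  events <- tibble::tibble(sample_index = as.integer(ev_samples),
                           pulse_type = "single", site = "left")
  dur <- (max(ev_samples) + 1500) / fs
  rec <- make_recording(function(t, ch) sin(2 * pi * 7 * t), fs = fs,
                        dur_s = dur, nch = 1, events = events)
  eps <- epoch_recording(rec, c(50, 1000))
  expect_equal(nrow(eps), 1)
  expect_equal(eps$n_epochs, n_ev)
  expect_equal(dim(eps$epochs[[1]]$data), c(n_ev, 1, 950))
})

test_that("epoch windows outside the recording raise a named error", {
  fs <- 500
  events <- tibble::tibble(sample_index = c(100L, 4900L),
                           pulse_type = "single", site = "left")
  rec <- make_recording(function(t, ch) sin(t), fs = fs, dur_s = 10, nch = 1,
                        events = events)
  expect_error(epoch_recording(rec, c(50, 1000)), "event")
})

test_that("an empty event list yields an empty epoch table without error", {
  rec <- make_recording(function(t, ch) sin(t), fs = 500, dur_s = 2, nch = 1)
  eps <- epoch_recording(rec)
  expect_equal(nrow(eps), 0)
})

test_that("windows must start at or after 50 ms post-stimulus", {
  rec <- make_recording(function(t, ch) sin(t), fs = 500, dur_s = 2, nch = 1)
  expect_error(epoch_recording(rec, c(0, 500)), class = "tepnet_invalid_argument")
})

test_that("de-meaning zeroes epoch means, preserves variance, and is idempotent", {
  cfg <- tiny_config()
  ep <- generate_epoch_set(cfg, "HC", "left", "single", 5)
  dm <- demean_epochs(ep)
  means <- apply(dm$data, c(1, 2), mean)
  expect_lt(max(abs(means)), 1e-9)
  expect_equal(apply(dm$data, c(1, 2), var), apply(ep$data, c(1, 2), var),
               tolerance = 1e-12)
  dm2 <- demean_epochs(dm)
  expect_equal(dm2$data, dm$data, tolerance = 1e-12)

  const <- epoch_set(array(3, dim = c(1, 2, 250)), fs = 1000,
                     window_ms = c(50, 300), site = "left", pulse = "single")
  expect_true(all(demean_epochs(const)$data == 0))
})

test_that("amplitude rejection masks spiking epochs and keeps order", {
  cfg <- tiny_config()
  ep <- generate_epoch_set(cfg, "HC", "left", "single", 6)
  base_peak <- max(abs(ep$data))
  ep$data[2, 1, 10] <- 10 * base_peak
  rej <- reject_artifacts(ep, 5 * base_peak)
  expect_identical(rej$kept_mask, c(TRUE, FALSE, TRUE, TRUE))

  all_kept <- reject_artifacts(ep, Inf)
  expect_true(all(all_kept$kept_mask))

  expect_error(reject_artifacts(ep, 1e-9), class = "tepnet_no_epochs")
})

test_that("filtering commutes with epoching away from segment edges", {
  fs <- 500
  events <- tibble::tibble(sample_index = 2500L, pulse_type = "single",
                           site = "left")
  withr::with_seed(4, {
    rec <- make_recording(function(t, ch) {
      sin(2 * pi * 9 * t) + 0.5 * rnorm(length(t))
    }, fs = fs, dur_s = 12, nch = 1, events = events)
  })
  filtered <- bandpass_notch(rec, order = 300)
  ep_filtered <- epoch_recording(filtered, c(50, 400))$epochs[[1]]

  # filter only a generous window around the event, then cut the same epoch
  seg_idx <- 1500:3500
  seg <- eeg_recording(rec$data[, seg_idx, drop = FALSE], fs = fs,
                       events = tibble::tibble(sample_index = 1001L,
                                               pulse_type = "single",
                                               site = "left"))
  seg_f <- bandpass_notch(seg, order = 300)
  ep_seg <- epoch_recording(seg_f, c(50, 400))$epochs[[1]]
  expect_equal(ep_seg$data[1, 1, ], ep_filtered$data[1, 1, ], tolerance = 1e-3)
})

test_that("cropping re-cuts the analysis window exactly", {
  cfg <- tiny_config()
  ep <- generate_epoch_set(cfg, "HC", "left", "single", 5)
  cr <- crop_epochs(ep, c(50, 350))
  expect_equal(dim(cr$data)[3], round(300 * 250 / 1000))
  expect_equal(cr$data[1, 1, ], ep$data[1, 1, 1:75])
  expect_error(crop_epochs(ep, c(40, 300)), class = "tepnet_invalid_argument")
})
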