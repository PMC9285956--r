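#' Containers for continuous and epoched EEG
#'
#' `eeg_recording()` wraps a channels-by-samples matrix (microvolts) with its
#' sampling rate, channel labels and a pulse-event table. Event markers refer
#' to the TEST pulse; for paired-pulse events the conditioning pulse precedes
#' the marker by the inter-stimulus interval. `epoch_set()` wraps an
#' epochs-by-channels-by-time array cut relative to the test pulse, for one
#' (site, pulse) condition cell.
#'
#' @param data For `eeg_recording()`, a channels x samples numeric matrix; for
#'   `epoch_set()`, an epochs x channels x time numeric array.
#' @param fs Sampling rate in Hz.
#' @param events Data frame with columns `sample_index`, `pulse_type`
#'   (`"single"`/`"paired"`) and `site` (`"left"`/`"right"`).
#' @param labels Channel labels; defaults to `ch01`, `ch02`, ...
#' @param window_ms Length-2 numeric, epoch window relative to the test pulse
#'   (ms); the window must start at or after 50 ms so that only post-stimulus
#'   (artifact-free) data enter the analysis.
#' @param site,pulse Condition of the epoch set.
#' @param kept_mask Logical per-epoch mask of epochs surviving rejection.
#' @return An object of class `tep_recording` or `tep_epochs`.
#' @export
eeg_recording <- function(data, fs, events = NULL, labels = NULL) {
  if (!is.matrix(data) || !is.numeric(data)) {
    stop_invalid("`data` must be a numeric channels x samples matrix.")
  }
  check_scalar_number(fs, "fs", positive = TRUE)
  if (is.null(labels)) labels <- sprintf("ch%02d", seq_len(nrow(data)))
  if (length(labels) != nrow(data)) {
    stop_invalid("`labels` must have one entry per channel (row of `data`).")
  }
  if (is.null(events)) {
    events <- tibble::tibble(sample_index = integer(), pulse_type = character(),
                             site = character())
  }
  events <- tibble::as_tibble(events)
  need <- c("sample_index", "pulse_type", "site")
  if (!all(need %in% names(events))) {
    stop_invalid("`events` needs columns sample_index, pulse_type, site.")
  }
  if (nrow(events)) {
    if (any(events$sample_index < 1 | events$sample_index > ncol(data))) {
      stop_invalid("Event sample indices must lie within the recording.")
    }
    if (!all(events$pulse_type %in% c("single", "paired"))) {
      stop_invalid('`events$pulse_type` must be "single" or "paired".')
    }
    if (!all(events$site %in% c("left", "right"))) {
      stop_invalid('`events$site` must be "left" or "right".')
    }
  }
  structure(list(data = data, fs = fs, labels = labels, events = events),
            class = "tep_recording")
}

#' @rdname eeg_recording
#' @export
epoch_set <- function(data, fs, window_ms, site, pulse,
                      labels = NULL, kept_mask = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop_invalid("`data` must be an epochs x channels x time array.")
  }
  check_scalar_number(fs, "fs", positive = TRUE)
  if (length(window_ms) != 2L || window_ms[1] >= window_ms[2]) {
    stop_invalid("`window_ms` must be an increasing (start, end) pair.")
  }
  if (window_ms[1] < 50) {
    stop_invalid("Epoch windows must start at or after 50 ms post-stimulus.")
  }
  site <- match_enum(site, "site", c("left", "right"))
  pulse <- match_enum(pulse, "pulse", c("single", "paired"))
  n_expected <- ms_to_samples(window_ms[2] - window_ms[1], fs)
  if (dim(data)[3] != n_expected) {
    stop_invalid(sprintf(
      "Time axis has %d samples but the window implies %d.",
      dim(data)[3], n_expected
    ))
  }
  if (is.null(labels)) labels <- sprintf("ch%02d", seq_len(dim(data)[2]))
  if (is.null(kept_mask)) kept_mask <- rep(TRUE, dim(data)[1])
  if (length(kept_mask) != dim(data)[1]) {
    stop_invalid("`kept_mask` must have one entry per epoch.")
  }
  structure(
    list(data = data, fs = fs, window_ms = as.numeric(window_ms),
         condition = list(site = site, pulse = pulse),
         labels = labels, kept_mask = kept_mask),
    class = "tep_epochs"
  )
}

#' @export
print.tep_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<tep_epochs> %d epochs (%d kept) x %d channels x %d samples, %g-%g ms @ %g Hz, %s/%s\n",
    d[1], sum(x$kept_mask), d[2], d[3], x$window_ms[1], x$window_ms[2],
    x$fs, x$condition$site, x$condition$pulse
  ))
  invisible(x)
}

# ---- filtering --------------------------------------------------------------

#' Zero-phase FIR bandpass and notch filtering
#'
#' Applies a linear-phase FIR bandpass (default 1-80 Hz) followed by a band-stop
#' notch (default 50 Hz mains) to every channel, each run forward and backward
#' (`signal::filtfilt`) so the net filter is zero-phase and evoked-potential
#' latencies — which the lag analysis depends on — are preserved. The bandpass
#' removes the DC component.
#'
#' @param recording A [eeg_recording()].
#' @param low_hz,high_hz Passband edges in Hz; `0 < low < high < fs/2`.
#' @param notch_hz Mains frequency to suppress; `NULL` disables the notch.
#' @param notch_halfwidth_hz Half-width of the stop band around `notch_hz`.
#' @param order Bandpass FIR order in samples. The default is three periods of
#'   the lowest passband frequency (`3 * fs / low_hz`), capped by the data
#'   length so the forward-backward pass remains feasible.
#' @return The filtered `tep_recording` (same shape, same events).
#' @export
bandpass_notch <- function(recording, low_hz = 1, high_hz = 80, notch_hz = 50,
                           notch_halfwidth_hz = 4, order = NULL) {
  stopifnot(inherits(recording, "tep_recording"))
  fs <- recording$fs
  nyq <- fs / 2
  if (low_hz <= 0 || high_hz <= low_hz) {
    stop_invalid("Need 0 < low_hz < high_hz.")
  }
  if (high_hz >= nyq) {
    stop_invalid("`high_hz` must be below the Nyquist frequency fs/2.")
  }
  n_samp <- ncol(recording$data)
  if (is.null(order)) order <- round(3 * fs / low_hz)
  order <- min(order, floor((n_samp - 4) / 4))
  order <- max(2L, as.integer(order) %/% 2L * 2L) # even order, type-I FIR
  bp <- signal::fir1(order, c(low_hz, high_hz) / nyq, type = "pass")

  use_notch <- !is.null(notch_hz)
  if (use_notch) {
    if (notch_hz - notch_halfwidth_hz <= 0 || notch_hz + notch_halfwidth_hz >= nyq) {
      stop_invalid("The notch stop band must lie strictly inside (0, fs/2).")
    }
    n_order <- max(2L, min(as.integer(round(fs)), floor((n_samp - 4) / 4)))
    n_order <- n_order %/% 2L * 2L
    nf <- signal::fir1(n_order,
                       c(notch_hz - notch_halfwidth_hz,
                         notch_hz + notch_halfwidth_hz) / nyq,
                       type = "stop")
  }

  out <- recording$data
  for (ch in seq_len(nrow(out))) {
    x <- signal::filtfilt(bp, out[ch, ])
    if (use_notch) x <- signal::filtfilt(nf, x)
    out[ch, ] <- x
  }
  recording$data <- out
  recording
}

# ---- epoching ---------------------------------------------------------------

#' Cut a continuous recording into per-condition epoch sets
#'
#' Epochs are time-locked to the test-pulse markers; single- and paired-pulse
#' conditions are cut separately for each stimulation site. The number of
#' epochs in each cell equals the number of matching events.
#'
#' @param recording A [eeg_recording()] with events.
#' @param window_ms Epoch window (start, end) in ms relative to the test
#'   pulse; start must be >= 50 ms.
#' @return A tibble with columns `site`, `pulse`, `n_epochs` and a list-column
#'   `epochs` of `tep_epochs`, one row per condition present in the events.
#' @export
epoch_recording <- function(recording, window_ms = c(50, 1000)) {
  stopifnot(inherits(recording, "tep_recording"))
  if (window_ms[1] < 50) {
    stop_invalid("Epoch windows must start at or after 50 ms post-stimulus.")
  }
  fs <- recording$fs
  n_time <- ms_to_samples(window_ms[2] - window_ms[1], fs)
  offset <- ms_to_samples(window_ms[1], fs)
  ev <- recording$events
  cells <- unique(ev[, c("site", "pulse_type")])
  rows <- purrr::pmap(cells, function(site, pulse_type) {
    idx <- which(ev$site == site & ev$pulse_type == pulse_type)
    arr <- array(0, dim = c(length(idx), nrow(recording$data), n_time))
    for (k in seq_along(idx)) {
      start <- ev$sample_index[idx[k]] + offset
      stop_ <- start + n_time - 1L
      if (start < 1L || stop_ > ncol(recording$data)) {
        stop_invalid(sprintf(
          "Epoch window for event %d (sample %d, %s/%s) exceeds the recording.",
          idx[k], ev$sample_index[idx[k]], site, pulse_type
        ))
      }
      arr[k, , ] <- recording$data[, start:stop_]
    }
    tibble::tibble(
      site = site, pulse = pulse_type, n_epochs = length(idx),
      epochs = list(epoch_set(arr, fs = fs, window_ms = window_ms,
                              site = site, pulse = pulse_type,
                              labels = recording$labels))
    )
  })
  if (!length(rows)) {
    return(tibble::tibble(site = character(), pulse = character(),
                          n_epochs = integer(), epochs = list()))
  }
  dplyr::bind_rows(rows)
}

#' Re-cut an epoch set to a narrower analysis window
#'
#' The network analysis uses 50-350 ms post-pulse while the inhibition
#' statistic uses the full 50-1000 ms epoch; `crop_epochs()` extracts the
#' sub-window without re-touching the continuous data.
#'
#' @param epochs A `tep_epochs`.
#' @param window_ms Target (start, end) in ms; must be inside the current
#'   window.
#' @return A `tep_epochs` over the narrower window.
#' @export
crop_epochs <- function(epochs, window_ms = c(50, 350)) {
  stopifnot(inherits(epochs, "tep_epochs"))
  if (window_ms[1] < epochs$window_ms[1] - 1e-9 ||
      window_ms[2] > epochs$window_ms[2] + 1e-9) {
    stop_invalid("`window_ms` must lie inside the epoch window.")
  }
  fs <- epochs$fs
  from <- ms_to_samples(window_ms[1] - epochs$window_ms[1], fs) + 1L
  n <- ms_to_samples(window_ms[2] - window_ms[1], fs)
  out <- epochs
  out$data <- epochs$data[, , from:(from + n - 1L), drop = FALSE]
  out$window_ms <- as.numeric(window_ms)
  out
}

# ---- de-meaning and artifact rejection -------------------------------------

#' Subtract the whole-epoch mean from every channel trace
#'
#' For each epoch and channel, the average over the epoch's full time axis is
#' subtracted from every time point, attenuating DC offsets. Idempotent and
#' variance-preserving.
#'
#' @param epochs A `tep_epochs` with at least one epoch.
#' @return The de-meaned `tep_epochs`.
#' @export
demean_epochs <- function(epochs) {
  stopifnot(inherits(epochs, "tep_epochs"))
  d <- dim(epochs$data)
  if (d[1] == 0) stop_invalid("`epochs` contains no epochs.")
  m <- rowMeans(epochs$data, dims = 2) # epochs x channels means
  epochs$data <- epochs$data - as.vector(m) # recycles over the time axis
  epochs
}

#' Amplitude-based automatic epoch rejection
#'
#' An epoch is kept iff its maximum absolute amplitude over all channels stays
#' below `abs_threshold_uv`. This is a reproducible automatic proxy for manual
#' artifact screening and ICA component removal; it never reorders surviving
#' epochs.
#'
#' @param epochs A `tep_epochs`.
#' @param abs_threshold_uv Positive rejection threshold in microvolts.
#' @return The `tep_epochs` with an updated `kept_mask`.
#' @export
reject_artifacts <- function(epochs, abs_threshold_uv = 200) {
  stopifnot(inherits(epochs, "tep_epochs"))
  if (!is.numeric(abs_threshold_uv) || length(abs_threshold_uv) != 1L ||
      is.na(abs_threshold_uv) || abs_threshold_uv <= 0) {
    stop_invalid("`abs_threshold_uv` must be a single positive value (Inf keeps all).")
  }
  peak <- apply(abs(epochs$data), 1, max)
  keep <- peak < abs_threshold_uv
  if (!any(keep)) {
    abort("No usable epochs: every epoch exceeds the rejection threshold.",
          class = "tepnet_no_epochs")
  }
  epochs$kept_mask <- keep
  epochs
}
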