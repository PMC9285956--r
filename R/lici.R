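#' Average evoked potential over kept epochs
#'
#' Pointwise mean over the epochs whose `kept_mask` is `TRUE`, yielding the
#' averaged event-related potential (ERP) for one condition cell.
#'
#' @param epochs A `tep_epochs` with at least one kept epoch.
#' @return A `tep_erp`: channels x time matrix plus window/condition metadata.
#' @export
average_erp <- function(epochs) {
  stopifnot(inherits(epochs, "tep_epochs"))
  keep <- which(epochs$kept_mask)
  if (!length(keep)) {
    abort("Cannot average: no kept epochs.", class = "tepnet_no_epochs")
  }
  sub <- epochs$data[keep, , , drop = FALSE]
  erp <- colMeans(sub, dims = 1) # channels x time
  structure(
    list(data = erp, fs = epochs$fs, window_ms = epochs$window_ms,
         condition = epochs$condition, labels = epochs$labels,
         n_epochs = length(keep)),
    class = "tep_erp"
  )
}

#' @export
print.tep_erp <- function(x, ...) {
  cat(sprintf(
    "<tep_erp> %d channels x %d samples, %g-%g ms @ %g Hz, %s/%s (%d epochs)\n",
    nrow(x$data), ncol(x$data), x$window_ms[1], x$window_ms[2], x$fs,
    x$condition$site, x$condition$pulse, x$n_epochs
  ))
  invisible(x)
}

erp_times_ms <- function(erp) {
  erp$window_ms[1] + (seq_len(ncol(erp$data)) - 1) * 1000 / erp$fs
}

#' Rectified area under the averaged evoked potential
#'
#' Trapezoidal integral of the absolute ERP over `[t0_ms, t1_ms]` (default
#' 50-150 ms post pulse, the window in which the conditioning pulse expresses
#' its suppression), per channel, in microvolt-milliseconds. The channel mean
#' is the scalar used by the inhibition statistic; the per-channel values and
#' the channel sum are also returned since published pipelines are ambiguous
#' about the aggregation.
#'
#' @param erp A `tep_erp`.
#' @param t0_ms,t1_ms Integration bounds (ms); must lie inside the ERP window.
#' @return A list with `per_channel` (named numeric), `mean` and `sum`.
#' @export
rectified_auc <- function(erp, t0_ms = 50, t1_ms = 150) {
  stopifnot(inherits(erp, "tep_erp"))
  if (t0_ms >= t1_ms) stop_invalid("Need t0_ms < t1_ms.")
  t <- erp_times_ms(erp)
  if (t0_ms < t[1] - 1e-9 || t1_ms > t[length(t)] + 1e-9) {
    stop_invalid("The integration window must lie inside the ERP window.")
  }
  sel <- which(t >= t0_ms - 1e-9 & t <= t1_ms + 1e-9)
  ts <- t[sel]
  per <- apply(abs(erp$data[, sel, drop = FALSE]), 1, function(y) {
    sum((y[-1] + y[-length(y)]) / 2 * diff(ts))
  })
  names(per) <- erp$labels
  list(per_channel = per, mean = mean(per), sum = sum(per))
}

#' Long-interval cortical inhibition percentage
#'
#' `(1 - conditioned / unconditioned) * 100`: the fractional reduction of the
#' rectified evoked area caused by the conditioning pulse. Positive values
#' mean inhibition (100 is maximal, the conditioned response fully
#' suppressed); negative values mean facilitation. Scale-invariant: a common
#' gain on both ERPs cancels.
#'
#' @param auc_conditioned Rectified AUC of the paired-pulse (conditioned) ERP.
#' @param auc_unconditioned Rectified AUC of the single-pulse (test-alone)
#'   ERP; must be positive.
#' @return The inhibition percentage.
#' @export
lici_percent <- function(auc_conditioned, auc_unconditioned) {
  check_scalar_number(auc_conditioned, "auc_conditioned")
  check_scalar_number(auc_unconditioned, "auc_unconditioned")
  if (auc_conditioned < 0 || auc_unconditioned < 0) {
    stop_invalid("Rectified AUCs cannot be negative.")
  }
  if (auc_unconditioned == 0) {
    abort("Undefined inhibition ratio: the unconditioned AUC is zero.",
          class = "tepnet_undefined_ratio")
  }
  (1 - auc_conditioned / auc_unconditioned) * 100
}

#' LICI from a pair of condition cells
#'
#' Convenience wrapper: averages the single- and paired-pulse epoch sets of
#' one stimulation site, integrates the rectified ERPs over `[t0_ms, t1_ms]`
#' and returns the inhibition statistic.
#'
#' @param epochs_single,epochs_paired `tep_epochs` for the two pulse types.
#' @param t0_ms,t1_ms Integration window (ms post pulse).
#' @return A one-row tibble: `auc_single`, `auc_paired`, `lici_percent`.
#' @export
lici_from_epochs <- function(epochs_single, epochs_paired,
                             t0_ms = 50, t1_ms = 150) {
  auc_s <- rectified_auc(average_erp(epochs_single), t0_ms, t1_ms)$mean
  auc_p <- rectified_auc(average_erp(epochs_paired), t0_ms, t1_ms)$mean
  tibble::tibble(
    auc_single = auc_s, auc_paired = auc_p,
    lici_percent = lici_percent(auc_p, auc_s)
  )
}
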