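#' Lag-maximised Pearson cross-correlation of two signals
#'
#' For every integer-sample delay `tau` from 0 to `max_lag_ms`, computes the
#' Pearson correlation between `x` and a copy of `y` delayed by `tau` — i.e.
#' `cor(x[1:(T-tau)], y[(tau+1):T])`, with means and SDs taken on the
#' overlapping segment so the coefficient stays in `[-1, 1]` for every lag.
#' Returns the signed maximum and its delay; at a positive maximising delay
#' `y` is a delayed copy of `x` (x leads y). Ties are broken toward the
#' smaller delay.
#'
#' @param x,y Numeric signals of equal length `T`; `T` must exceed the lag
#'   span by more than 3 samples and neither signal may be constant on any
#'   evaluated overlap.
#' @param fs Sampling rate in Hz.
#' @param max_lag_ms Maximal delay considered, in ms (default 150, matching
#'   cross-cortical conduction times).
#' @return A list with `c_max`, `tau_ms`, `tau_samples` and the full profile
#'   `c_tau`.
#' @export
lagged_crosscorr <- function(x, y, fs, max_lag_ms = 150) {
  if (length(x) != length(y)) stop_invalid("`x` and `y` must have equal length.")
  check_scalar_number(fs, "fs", positive = TRUE)
  n <- length(x)
  max_lag <- ms_to_samples(max_lag_ms, fs)
  if (max_lag < 0) stop_invalid("`max_lag_ms` must be non-negative.")
  if (n <= max_lag + 3) {
    stop_invalid("Signals are too short for the requested lag span.")
  }
  r <- numeric(max_lag + 1L)
  for (tau in 0:max_lag) {
    xs <- x[1:(n - tau)]
    ys <- y[(tau + 1L):n]
    if (sd(xs) == 0 || sd(ys) == 0) {
      abort(sprintf("Undefined correlation: constant segment at lag %d samples.", tau),
            class = "tepnet_undefined_correlation")
    }
    r[tau + 1L] <- cor(xs, ys)
  }
  best <- which.max(r) # first maximum = smallest tau on ties
  list(
    c_max = r[best],
    tau_ms = (best - 1L) * 1000 / fs,
    tau_samples = best - 1L,
    c_tau = r
  )
}

#' Pairwise connectivity from lag-maximised cross-correlations
#'
#' Computes, for every ordered channel pair `(i, j)`, the maximum over delays
#' of the Pearson correlation between channel `i` and channel `j` delayed —
#' so `weights[i, j]` peaking at a positive lag marks `i` as leading `j` and
#' is the candidate directed edge `i -> j`. Both ordered pairs are computed;
#' direction is resolved later by [direct_and_threshold()]. By default the
#' correlation is computed on the condition-averaged ERP trace; with
#' `per_epoch = TRUE` a weight/lag matrix is computed for each kept epoch and
#' the matrices averaged.
#'
#' Pairs whose overlap is constant at some lag have no defined correlation;
#' they are reported via a warning and their weight set to 0.
#'
#' @param x A `tep_erp`, a `tep_epochs`, or a channels x time numeric matrix.
#' @param fs Sampling rate in Hz (taken from the object when available).
#' @param max_lag_ms Maximal delay in ms.
#' @param per_epoch Average per-epoch connectivity matrices instead of
#'   correlating the averaged ERP.
#' @return A `tep_connectivity`: `weights` and `lags_ms` N x N matrices
#'   (diagonal 0), `n_samples`, `fs`, `labels`.
#' @export
build_connectivity <- function(x, fs = NULL, max_lag_ms = 150,
                               per_epoch = FALSE) {
  if (inherits(x, "tep_epochs")) {
    if (per_epoch) {
      keep <- which(x$kept_mask)
      mats <- lapply(keep, function(ep) {
        connectivity_matrix(t(x$data[ep, , ]), x$fs, max_lag_ms)
      })
      w <- Reduce(`+`, lapply(mats, `[[`, "weights")) / length(mats)
      l <- Reduce(`+`, lapply(mats, `[[`, "lags_ms")) / length(mats)
      return(new_connectivity(w, l, mats[[1]]$n_samples, x$fs, x$labels,
                              max_lag_ms))
    }
    x <- average_erp(x)
  }
  if (inherits(x, "tep_erp")) {
    mat <- t(x$data) # time x channels
    fs <- x$fs
    labels <- x$labels
  } else if (is.matrix(x)) {
    if (is.null(fs)) stop_invalid("`fs` is required for a plain matrix input.")
    mat <- t(x)
    labels <- rownames(x) %||% sprintf("ch%02d", seq_len(ncol(mat)))
  } else {
    stop_invalid("`x` must be a tep_erp, tep_epochs or channels x time matrix.")
  }
  if (ncol(mat) < 2) stop_invalid("Connectivity needs at least 2 channels.")
  res <- connectivity_matrix(mat, fs, max_lag_ms)
  new_connectivity(res$weights, res$lags_ms, res$n_samples, fs, labels,
                   max_lag_ms)
}

# Core scan, vectorised over channel pairs: one cor() call per lag gives the
# full matrix cor(x_i[1:(T-tau)], x_j[(tau+1):T]) for all ordered pairs.
connectivity_matrix <- function(mat, fs, max_lag_ms) {
  n_time <- nrow(mat)
  nch <- ncol(mat)
  max_lag <- ms_to_samples(max_lag_ms, fs)
  if (n_time <= max_lag + 3) {
    stop_invalid("Analysis window too short for the requested lag span.")
  }
  w <- matrix(-Inf, nch, nch)
  lg <- matrix(0L, nch, nch)
  undefined <- matrix(FALSE, nch, nch)
  # prefix sums give the overlap means and variances of every head/tail
  # segment in O(1); only the cross-products are recomputed per lag
  cs <- apply(mat, 2, cumsum)
  cs2 <- apply(mat * mat, 2, cumsum)
  for (tau in 0:max_lag) {
    m <- n_time - tau
    sa <- cs[m, ]                    # head segment sums, x[1:m]
    sa2 <- cs2[m, ]
    sb <- cs[n_time, ] - if (tau > 0) cs[tau, ] else 0 # tail sums, y[(tau+1):T]
    sb2 <- cs2[n_time, ] - if (tau > 0) cs2[tau, ] else 0
    va <- sa2 / m - (sa / m)^2
    vb <- sb2 / m - (sb / m)^2
    # rounding can leave a constant segment with a tiny spurious variance;
    # snap it to zero so the pair is flagged undefined rather than garbage
    va[va < 1e-13 * pmax(sa2 / m, 1e-300)] <- 0
    vb[vb < 1e-13 * pmax(sb2 / m, 1e-300)] <- 0
    cab <- crossprod(mat[1:m, , drop = FALSE],
                     mat[(tau + 1L):n_time, , drop = FALSE]) / m -
      tcrossprod(sa / m, sb / m)
    denom <- sqrt(tcrossprod(pmax(va, 0), pmax(vb, 0)))
    r <- cab / denom
    bad <- !is.finite(r)
    undefined <- undefined | bad
    r[bad] <- -Inf
    r[r > 1] <- 1
    r[r < -1] <- -1
    upd <- r > w
    lg[upd] <- tau
    w[upd] <- r[upd]
  }
  if (any(undefined[upper.tri(undefined) | lower.tri(undefined)])) {
    warn("Some channel pairs had constant overlaps; their weights were set to 0.")
  }
  w[!is.finite(w)] <- 0
  w[undefined] <- 0
  diag(w) <- 0
  diag(lg) <- 0L
  list(weights = w, lags_ms = lg * 1000 / fs, n_samples = n_time)
}

new_connectivity <- function(weights, lags_ms, n_samples, fs, labels,
                             max_lag_ms) {
  dimnames(weights) <- dimnames(lags_ms) <- list(labels, labels)
  structure(
    list(weights = weights, lags_ms = lags_ms, n_samples = n_samples,
         fs = fs, labels = labels, max_lag_ms = max_lag_ms),
    class = "tep_connectivity"
  )
}

#' @export
print.tep_connectivity <- function(x, ...) {
  cat(sprintf("<tep_connectivity> %d channels, T = %d samples @ %g Hz, lags 0-%g ms\n",
              length(x$labels), x$n_samples, x$fs, x$max_lag_ms))
  invisible(x)
}

#' Resolve edge direction and apply the absolute threshold
#'
#' For each unordered channel pair, only the larger of the two directed
#' weights is kept (edges point from the leading to the lagging signal); on
#' an exact tie — always the case for zero-lag maxima, where the correlation
#' is symmetric — the edge whose leading node has the lower channel index is
#' kept. Kept edges whose weight falls below the absolute `threshold` are then
#' removed (the comparison is non-strict: a weight exactly at the threshold
#' survives). The result is a directed graph with at most one edge per pair,
#' hence at most `N (N - 1) / 2` edges.
#'
#' @param conn A `tep_connectivity`.
#' @param threshold Absolute correlation cutoff in `(0, 1)`; default 0.6.
#' @return A `tep_graph`: binary `adjacency` (rows = source), `weights` and
#'   `lags_ms` of retained edges (0 where no edge), `threshold`, `labels`.
#' @export
direct_and_threshold <- function(conn, threshold = 0.6) {
  stopifnot(inherits(conn, "tep_connectivity"))
  check_scalar_number(threshold, "threshold")
  if (threshold <= 0 || threshold >= 1) {
    stop_invalid("`threshold` must lie in (0, 1).")
  }
  w <- conn$weights
  n <- nrow(w)
  adj <- matrix(0L, n, n)
  kw <- matrix(0, n, n)
  kl <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      wij <- w[i, j] # candidate edge i -> j (i leads)
      wji <- w[j, i] # candidate edge j -> i
      if (wij >= wji) { # tie -> lower-index leader, i.e. i -> j
        src <- i; dst <- j; ww <- wij
      } else {
        src <- j; dst <- i; ww <- wji
      }
      if (ww >= threshold) {
        adj[src, dst] <- 1L
        kw[src, dst] <- ww
        kl[src, dst] <- conn$lags_ms[src, dst]
      }
    }
  }
  dimnames(adj) <- dimnames(kw) <- dimnames(kl) <-
    list(conn$labels, conn$labels)
  structure(
    list(adjacency = adj, weights = kw, lags_ms = kl,
         threshold = threshold, labels = conn$labels),
    class = "tep_graph"
  )
}

#' @export
print.tep_graph <- function(x, ...) {
  cat(sprintf("<tep_graph> %d nodes, %d directed edges (threshold %g)\n",
              nrow(x$adjacency), sum(x$adjacency), x$threshold))
  invisible(x)
}

#' Edge list of a thresholded graph
#'
#' @param graph A `tep_graph`.
#' @return A tibble with columns `src`, `dst`, `weight`, `lag_ms`.
#' @export
graph_edges <- function(graph) {
  stopifnot(inherits(graph, "tep_graph"))
  idx <- which(graph$adjacency == 1L, arr.ind = TRUE)
  tibble::tibble(
    src = graph$labels[idx[, 1]],
    dst = graph$labels[idx[, 2]],
    weight = graph$weights[idx],
    lag_ms = graph$lags_ms[idx]
  ) |> dplyr::arrange(.data$src, .data$dst)
}
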