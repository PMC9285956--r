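# Independent brute-force oracles used across the suite. These deliberately
# re-derive every quantity from first principles (exhaustive scans, explicit
# formulas) and share no code with the package internals they check.

# ---- lagged cross-correlation -----------------------------------------------

oracle_lag_scan <- function(x, y, fs, max_lag_ms = 150) {
  T <- length(x)
  L <- round(max_lag_ms * fs / 1000)
  r <- sapply(0:L, function(tau) cor(x[1:(T - tau)], y[(tau + 1):T]))
  best <- which.max(r)
  list(c_max = r[best], tau_samples = best - 1L, tau_ms = (best - 1L) * 1000 / fs)
}

oracle_connectivity <- function(X, fs, max_lag_ms = 150) {
  n <- ncol(X)
  w <- matrix(0, n, n)
  lg <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) {
    if (i == j) next
    res <- oracle_lag_scan(X[, i], X[, j], fs, max_lag_ms)
    w[i, j] <- res$c_max
    lg[i, j] <- res$tau_ms
  }
  list(weights = w, lags_ms = lg)
}

# Direction + threshold rule applied literally
oracle_direct_threshold <- function(w, threshold) {
  n <- nrow(w)
  adj <- matrix(0L, n, n)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (w[i, j] >= w[j, i]) { src <- i; dst <- j; ww <- w[i, j] }
    else { src <- j; dst <- i; ww <- w[j, i] }
    if (ww >= threshold) adj[src, dst] <- 1L
  }
  adj
}

# ---- graph metrics ----------------------------------------------------------

oracle_fw_distances <- function(a) {
  n <- nrow(a)
  d <- matrix(Inf, n, n)
  d[a != 0] <- 1
  diag(d) <- 0
  for (k in 1:n) for (i in 1:n) {
    d[i, ] <- pmin(d[i, ], d[i, k] + d[k, ])
  }
  d
}

oracle_mean_degree <- function(a) {
  u <- (a | t(a)) * 1
  diag(u) <- 0
  mean(rowSums(u))
}

oracle_clustering <- function(a) {
  u <- (a | t(a)) * 1
  diag(u) <- 0
  n <- nrow(a)
  ci <- numeric(n)
  for (i in 1:n) {
    nb <- which(u[i, ] == 1)
    k <- length(nb)
    if (k < 2) next
    t_i <- 0
    for (x in 1:(k - 1)) for (y in (x + 1):k) {
      if (u[nb[x], nb[y]] == 1) t_i <- t_i + 1
    }
    ci[i] <- 2 * t_i / (k * (k - 1))
  }
  mean(ci)
}

oracle_global_eff <- function(a) {
  n <- nrow(a)
  if (n < 2) return(0)
  d <- oracle_fw_distances(a)
  inv <- 1 / d
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

oracle_local_eff <- function(a) {
  u <- (a | t(a)) * 1
  diag(u) <- 0
  n <- nrow(a)
  le <- numeric(n)
  for (i in 1:n) {
    nb <- which(u[i, ] == 1)
    if (length(nb) >= 2) le[i] <- oracle_global_eff(a[nb, nb, drop = FALSE])
  }
  mean(le)
}

random_digraph <- function(n, density) {
  a <- matrix(as.integer(runif(n * n) < density), n, n)
  diag(a) <- 0L
  a
}

# random directed graph with at most one direction per pair (the domain the
# thresholding rule produces)
random_oriented_graph <- function(n, density) {
  a <- matrix(0L, n, n)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (runif(1) < density) {
      if (runif(1) < 0.5) a[i, j] <- 1L else a[j, i] <- 1L
    }
  }
  a
}

# ---- mixed ANOVA (balanced, explicit cell-mean sums of squares) -------------

# y: data frame with participant, group, pulse, side, value; groups balanced.
oracle_mixed_anova_balanced <- function(d) {
  d$participant <- as.character(d$participant)
  subj <- sort(unique(d$participant))
  groups <- sort(unique(d$group))
  n_per <- length(subj) / 2
  N <- length(subj)
  gm <- mean(d$value)

  msub <- c(tapply(d$value, d$participant, mean)[subj])
  mg <- tapply(d$value, d$group, mean)
  mp <- tapply(d$value, d$pulse, mean)
  ms <- tapply(d$value, d$side, mean)
  mgp <- tapply(d$value, list(d$group, d$pulse), mean)
  mgs <- tapply(d$value, list(d$group, d$side), mean)
  mps <- tapply(d$value, list(d$pulse, d$side), mean)
  mgps <- tapply(d$value, list(d$group, d$pulse, d$side), mean)
  msp <- tapply(d$value, list(d$participant, d$pulse), mean)[subj, ]
  mss <- tapply(d$value, list(d$participant, d$side), mean)[subj, ]

  ss_between <- 4 * sum((msub - gm)^2)
  ss_g <- 4 * n_per * sum((mg - gm)^2)
  ss_subj <- ss_between - ss_g

  ss_p <- 4 * n_per * sum((mp - gm)^2)
  ss_gp <- 2 * n_per * sum((sweep(sweep(mgp, 1, mg), 2, mp) + gm)^2)
  ss_p_tot <- 2 * sum((msp - msub)^2)
  ss_p_err <- ss_p_tot - ss_p - ss_gp

  ss_s <- 4 * n_per * sum((ms - gm)^2)
  ss_gs <- 2 * n_per * sum((sweep(sweep(mgs, 1, mg), 2, ms) + gm)^2)
  ss_s_tot <- 2 * sum((mss - msub)^2)
  ss_s_err <- ss_s_tot - ss_s - ss_gs

  ss_ps <- 2 * n_per * sum((sweep(sweep(mps, 1, mp), 2, ms) + gm)^2)
  dev3 <- array(0, dim = dim(mgps))
  for (gi in seq_along(dimnames(mgps)[[1]])) {
    for (pi in seq_along(dimnames(mgps)[[2]])) {
      for (si in seq_along(dimnames(mgps)[[3]])) {
        dev3[gi, pi, si] <- mgps[gi, pi, si] -
          mgp[gi, pi] - mgs[gi, si] - mps[pi, si] +
          mg[gi] + mp[pi] + ms[si] - gm
      }
    }
  }
  ss_gps <- n_per * sum(dev3^2)
  resid3 <- 0
  for (r in seq_len(nrow(d))) {
    s <- d$participant[r]
    resid3 <- resid3 + (d$value[r] - msp[s, d$pulse[r]] - mss[s, d$side[r]] + msub[s])^2
  }
  ss_3_err <- resid3 - ss_ps - ss_gps

  df_err <- N - 2
  mk <- function(ss, ss_err) {
    f <- (ss / 1) / (ss_err / df_err)
    data.frame(F = f, p = pf(f, 1, df_err, lower.tail = FALSE),
               pes = ss / (ss + ss_err))
  }
  list(
    group = mk(ss_g, ss_subj),
    pulse = mk(ss_p, ss_p_err),
    group_pulse = mk(ss_gp, ss_p_err),
    side = mk(ss_s, ss_s_err),
    group_side = mk(ss_gs, ss_s_err),
    pulse_side = mk(ss_ps, ss_3_err),
    group_pulse_side = mk(ss_gps, ss_3_err)
  )
}

# ---- logistic regression grid-search MLE ------------------------------------

oracle_logistic_loglik <- function(y, x, b0, b1) {
  eta <- b0 + b1 * x
  sum(y * eta - log1p(exp(eta)))
}

oracle_logistic_grid <- function(y, x) {
  best <- c(0, 0)
  best_ll <- -Inf
  for (b0 in seq(-5, 5, by = 0.1)) for (b1 in seq(-5, 5, by = 0.1)) {
    ll <- oracle_logistic_loglik(y, x, b0, b1)
    if (ll > best_ll) { best_ll <- ll; best <- c(b0, b1) }
  }
  for (round in 1:3) {
    step <- 0.1 / 10^round
    grid0 <- seq(best[1] - 12 * step * 10, best[1] + 12 * step * 10, by = step * 10)
    grid1 <- seq(best[2] - 12 * step * 10, best[2] + 12 * step * 10, by = step * 10)
    for (b0 in grid0) for (b1 in grid1) {
      ll <- oracle_logistic_loglik(y, x, b0, b1)
      if (ll > best_ll) { best_ll <- ll; best <- c(b0, b1) }
    }
  }
  list(coef = best, loglik = best_ll)
}

# ---- ROC AUC all-pairs counting ---------------------------------------------

oracle_auc_pairs <- function(scores, labels, positive) {
  sp <- scores[labels == positive]
  sn <- scores[labels != positive]
  tot <- 0
  for (a in sp) for (b in sn) {
    tot <- tot + (a > b) + 0.5 * (a == b)
  }
  tot / (length(sp) * length(sn))
}
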