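# Internal helpers shared across modules.

#' @importFrom rlang %||% .data abort warn
#' @importFrom stats cor rnorm runif sd
NULL

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG state.
local_seed_eval <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  force(expr)
}

# Deterministic sub-seed derivation; keeps results < 2^31 - 1 so they remain
# valid R integer seeds whatever small integer the user supplies.
derive_seed <- function(seed, ...) {
  idx <- c(...)
  m <- 2147483647
  s <- as.numeric(seed) %% m
  for (k in seq_along(idx)) {
    s <- (s * 48271 + as.numeric(idx[k]) * 30269 + k) %% m
  }
  as.integer(s)
}

stop_invalid <- function(msg) {
  abort(msg, class = "tepnet_invalid_argument")
}

check_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_invalid(sprintf("`%s` must be a single finite number.", name))
  }
  if (positive && x <= 0) {
    stop_invalid(sprintf("`%s` must be > 0.", name))
  }
  invisible(x)
}

match_enum <- function(x, name, choices) {
  if (!is.character(x) || length(x) != 1L || !(x %in% choices)) {
    stop_invalid(sprintf(
      "`%s` must be one of %s.", name,
      paste(sprintf('"%s"', choices), collapse = ", ")
    ))
  }
  x
}

ms_to_samples <- function(ms, fs) as.integer(round(ms * fs / 1000))
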