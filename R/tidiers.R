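#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy and glance methods for fitted tepnet objects
#'
#' `tidy()` returns the per-term / per-node table of a result; `glance()` a
#' one-row model summary, following the broom conventions.
#'
#' @param x A `tep_anova`, `tep_logistic`, `tep_roc` or `tep_metrics` object.
#' @param ... Unused.
#' @return A tibble.
#' @name tepnet-tidiers
NULL

#' @rdname tepnet-tidiers
#' @export
tidy.tep_anova <- function(x, ...) x$table

#' @rdname tepnet-tidiers
#' @export
glance.tep_anova <- function(x, ...) {
  tibble::tibble(metric = x$metric, n = x$n,
                 n_hc = x$n_per_group$HC %||% NA_integer_,
                 n_ald = x$n_per_group$ALD %||% NA_integer_)
}

#' @rdname tepnet-tidiers
#' @export
tidy.tep_logistic <- function(x, ...) x$coefficients

#' @rdname tepnet-tidiers
#' @export
glance.tep_logistic <- function(x, ...) {
  tibble::tibble(
    n = x$n, nagelkerke_r2 = x$nagelkerke_r2,
    model_chisq = x$model_chisq, model_df = x$model_df, model_p = x$model_p,
    accuracy = x$classification$accuracy,
    sensitivity = x$classification$sensitivity,
    specificity = x$classification$specificity,
    ppv = x$classification$ppv, npv = x$classification$npv,
    converged = x$converged
  )
}

#' @rdname tepnet-tidiers
#' @export
tidy.tep_roc <- function(x, ...) {
  tibble::tibble(auc = x$auc, auc_raw = x$auc_raw, se = x$se,
                 ci_low = x$ci_low, ci_high = x$ci_high,
                 direction = x$direction, n_pos = x$n_pos, n_neg = x$n_neg)
}

#' @rdname tepnet-tidiers
#' @export
tidy.tep_metrics <- function(x, ...) x$per_node

#' @rdname tepnet-tidiers
#' @export
glance.tep_metrics <- function(x, ...) {
  tibble::tibble(
    mean_degree = x$mean_degree,
    mean_clustering = x$mean_clustering,
    local_efficiency = x$local_efficiency,
    global_efficiency = x$global_efficiency
  )
}
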