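#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a hypothesis-test result
#'
#' @param x A `gw_htest`.
#' @param ... Unused.
#' @return One-row tibble with `statistic`, `p.value`, `effect.size`,
#'   `estimate`, `n`, `alternative`, `method`.
#' @method tidy gw_htest
#' @export
tidy.gw_htest <- function(x, ...) {
  tibble::tibble(method = x$name, statistic = x$statistic,
                 p.value = x$p_value, effect.size = x$effect_size,
                 estimate = x$estimate, n = x$n, alternative = x$sidedness)
}

#' @rdname tidy.gw_htest
#' @method glance gw_htest
#' @export
glance.gw_htest <- function(x, ...) tidy.gw_htest(x, ...)

#' Tidy a Huber line fit
#'
#' @param x A `gw_huber_fit`.
#' @param ... Unused.
#' @return Tibble with one row per term (`(Intercept)`, `slope`).
#' @method tidy gw_huber_fit
#' @export
tidy.gw_huber_fit <- function(x, ...) {
  tibble::tibble(term = c("(Intercept)", "slope"),
                 estimate = c(x$intercept, x$slope))
}

#' @rdname tidy.gw_huber_fit
#' @method glance gw_huber_fit
#' @export
glance.gw_huber_fit <- function(x, ...) {
  tibble::tibble(intercept = x$intercept, slope = x$slope, nobs = x$n)
}

#' Tidy pooled amplitude correlations
#'
#' @param x A `gw_cor_pool` from [amplitude_correlations()].
#' @param ... Unused.
#' @return `tidy()`: the per-participant table; `glance()`: one row with
#'   the Fisher-z pooled coefficients.
#' @method tidy gw_cor_pool
#' @export
tidy.gw_cor_pool <- function(x, ...) x$per_participant

#' @rdname tidy.gw_cor_pool
#' @method glance gw_cor_pool
#' @export
glance.gw_cor_pool <- function(x, ...) {
  tibble::tibble(pooled_rho_amplitude = x$pooled_rho_amplitude,
                 pooled_rho_landing = x$pooled_rho_landing,
                 n_participants = nrow(x$per_participant),
                 n_excluded = x$n_excluded)
}

#' Tidy a speed-condition summary
#'
#' @param x A `gw_exp1_summary` from [summarize_exp1()].
#' @param ... Unused.
#' @return `tidy()`: per participant x speed medians; `glance()`: one row
#'   with the per-condition means and the speed correlations.
#' @method tidy gw_exp1_summary
#' @export
tidy.gw_exp1_summary <- function(x, ...) x$cells

#' @rdname tidy.gw_exp1_summary
#' @method glance gw_exp1_summary
#' @export
glance.gw_exp1_summary <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(n_conditions = nrow(x$by_speed)),
    tibble::as_tibble(x$correlations))
}
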