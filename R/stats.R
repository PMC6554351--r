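new_htest <- function(name, statistic, p_value, effect_size = NA_real_,
                      estimate = NA_real_, n = NA_integer_,
                      sidedness = "two.sided") {
  structure(list(name = name, statistic = statistic, p_value = p_value,
                 effect_size = effect_size, estimate = estimate, n = n,
                 sidedness = sidedness),
            class = "gw_htest")
}

#' @export
print.gw_htest <- function(x, ...) {
  cat(sprintf("<gw_htest> %s: stat = %.4g, p = %.4g, d = %.3g, n = %d (%s)\n",
              x$name, x$statistic, x$p_value, x$effect_size, x$n, x$sidedness))
  invisible(x)
}

#' Paired t-test on per-participant differences with Cohen's d
#'
#' @param differences Vector of per-participant paired differences.
#' @return A `gw_htest` with the t statistic, p value, Cohen's
#'   `d = mean(differences) / sd(differences)` and the mean difference as
#'   estimate.
#' @export
paired_t <- function(differences) {
  differences <- differences[is.finite(differences)]
  if (length(differences) < 2) abort("need >= 2 paired differences")
  if (sd(differences) == 0) {
    return(new_htest("paired_t", 0, 1, effect_size = 0,
                     estimate = mean(differences),
                     n = length(differences)))
  }
  tt <- t.test(differences)
  new_htest("paired_t", unname(tt$statistic), tt$p.value,
            effect_size = cohens_d(differences),
            estimate = mean(differences), n = length(differences))
}

#' Cohen's d for paired differences
#'
#' `d = mean(differences) / sd(differences)`, the within-participant
#' effect-size convention.
#'
#' @param differences Vector of paired differences.
#' @return Numeric effect size (0 when all differences are zero).
#' @export
cohens_d <- function(differences) {
  differences <- differences[is.finite(differences)]
  s <- sd(differences)
  if (s == 0) return(0)
  mean(differences) / s
}

#' Exact binomial test
#'
#' @param k Number of successes.
#' @param n Number of trials.
#' @param p0 Null success probability.
#' @param sidedness `"two.sided"`, `"greater"` or `"less"`.
#' @return A `gw_htest`; the statistic is `k`.
#' @examples
#' binomial_test(11, 12)$p_value  # ~0.006
#' @export
binomial_test <- function(k, n, p0 = 0.5,
                          sidedness = c("two.sided", "greater", "less")) {
  sidedness <- match.arg(sidedness)
  bt <- binom.test(k, n, p0, alternative = sidedness)
  new_htest("binomial", k, bt$p.value, estimate = k / n, n = n,
            sidedness = sidedness)
}

#' Pool correlation coefficients via Fisher's z transformation
#'
#' `tanh(mean(atanh(rho)))`: coefficients are averaged on the
#' approximately normal z scale and transformed back. Non-finite and
#' degenerate (|rho| = 1 within machine tolerance is retained; `NA` from
#' constant inputs is dropped) coefficients are excluded, with a count of
#' exclusions attached.
#'
#' @param rhos Correlation coefficients in (-1, 1).
#' @return Pooled coefficient with attribute `n_excluded`.
#' @export
fisher_z_mean <- function(rhos) {
  ok <- is.finite(rhos) & abs(rhos) < 1
  out <- tanh(mean(atanh(rhos[ok])))
  attr(out, "n_excluded") <- sum(!ok)
  out
}

#' Spearman / Pearson correlation helpers
#'
#' Thin wrappers over [stats::cor()] that return `NA` (rather than error)
#' for constant input, as degenerate participants are excluded from
#' pooling.
#'
#' @param x,y Numeric vectors.
#' @return Correlation coefficient or `NA`.
#' @export
spearman_rho <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3 || sd(x[ok]) == 0 || sd(y[ok]) == 0) return(NA_real_)
  cor(x[ok], y[ok], method = "spearman")
}

#' @rdname spearman_rho
#' @export
pearson_r <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3 || sd(x[ok]) == 0 || sd(y[ok]) == 0) return(NA_real_)
  cor(x[ok], y[ok])
}

#' Robust line fit with the Huber loss
#'
#' Iteratively reweighted least squares with the Huber psi function
#' (delta = 1.345 on standardized residuals, the conventional
#' 95%-efficiency constant), via [MASS::rlm()]. When the residual scale is
#' numerically zero (noiseless data) or every residual lies within delta,
#' the fit coincides with ordinary least squares, which is returned
#' directly in the noiseless case.
#'
#' @param x,y Numeric vectors.
#' @param delta Huber tuning constant (standardized residuals).
#' @return A `gw_huber_fit` list: `slope`, `intercept`, `n`.
#' @export
huber_fit <- function(x, y, delta = 1.345) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2) abort("need >= 2 points for a line fit")
  ls <- lm(y ~ x)
  if (sd(stats::residuals(ls)) < 1e-10) {
    cf <- coef(ls)
  } else {
    fit <- MASS::rlm(y ~ x, psi = MASS::psi.huber, k = delta, maxit = 100)
    cf <- coef(fit)
  }
  structure(list(slope = unname(cf[2]), intercept = unname(cf[1]),
                 n = length(x)),
            class = "gw_huber_fit")
}

#' @export
print.gw_huber_fit <- function(x, ...) {
  cat(sprintf("<gw_huber_fit> slope = %.4g, intercept = %.4g (n = %d)\n",
              x$slope, x$intercept, x$n))
  invisible(x)
}
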