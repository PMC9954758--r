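#' Small-sample adjustment of a standard error
#'
#' Inflates a standard error by the factor `1 + 20 / df^2`. This is the
#' published correction for approximating a Student-t likelihood by a normal
#' likelihood in Bayes-factor calculations at small degrees of freedom: the
#' factor fattens the normal to mimic the t's heavier tails, and vanishes as
#' `df` grows. At `df = 51` the factor is 1.008.
#'
#' @param se Raw standard error (strictly positive).
#' @param df Residual degrees of freedom (>= 1).
#' @return The adjusted standard error, `se * (1 + 20 / df^2)`.
#' @export
#' @examples
#' adjust_se(0.277, 51)  # 0.279
adjust_se <- function(se, df) {
  if (!is.numeric(se) || any(se <= 0)) stop("se must be strictly positive")
  if (!is.numeric(df) || any(df < 1)) stop("df must be >= 1")
  se * (1 + 20 / df^2)
}

#' Uniform-prior Bayes factor for a coefficient estimate
#'
#' Evidence for a directional alternative against the point null at zero.
#' The likelihood of a parameter value \eqn{\theta} is the normal density of
#' the observed estimate with mean \eqn{\theta} and standard deviation
#' `se` (use the small-sample-adjusted SE from [adjust_se()]); under H1 the
#' parameter is uniform on `(lower, upper)`, under H0 it is exactly zero:
#' \deqn{BF_{10} = \frac{\frac{1}{u-l}\left[\Phi\!\left(\frac{u-\hat b}{se}\right)
#'   - \Phi\!\left(\frac{l-\hat b}{se}\right)\right]}{\phi(\hat b;\,0,\,se)}.}
#' The closed form above is exact; no numerical integration is involved.
#'
#' @param estimate Observed coefficient estimate.
#' @param se Standard deviation of the (normal) likelihood, usually the
#'   adjusted standard error. Strictly positive.
#' @param prior_lower,prior_upper Endpoints of the uniform H1 prior, with
#'   `prior_lower < prior_upper`. For the amplification prediction the
#'   interval is `[lower, 0]` with `lower < 0`.
#' @return An object of class `mfi_bf`: a list with `estimate`, `se`,
#'   `prior_lower`, `prior_upper`, `bf10` and `category` (see
#'   [classify_evidence()]).
#' @export
#' @examples
#' bf_uniform(-0.5298, 0.185, -0.93, 0)  # BF10 ~ 29.58, strong
bf_uniform <- function(estimate, se, prior_lower, prior_upper) {
  if (!is.numeric(se) || se <= 0) stop("se must be strictly positive")
  if (!(prior_lower < prior_upper)) {
    stop("degenerate prior: need prior_lower < prior_upper")
  }
  mean_lik <- (stats::pnorm((prior_upper - estimate) / se) -
                 stats::pnorm((prior_lower - estimate) / se)) /
    (prior_upper - prior_lower)
  null_lik <- stats::dnorm(estimate, mean = 0, sd = se)
  bf10 <- mean_lik / null_lik
  structure(list(estimate = estimate, se = se,
                 prior_lower = prior_lower, prior_upper = prior_upper,
                 bf10 = bf10, category = classify_evidence(bf10)),
            class = "mfi_bf")
}

#' Conventional evidence category for a Bayes factor
#'
#' Fixed bands: `bf10 < 1/3` is evidence for the null; `[1/3, 3]` is
#' inconclusive; `(3, 10]` moderate evidence for H1; `(10, 30]` strong; and
#' `> 30` very strong (the last band is an extension beyond the
#' moderate/strong convention, for completeness).
#'
#' @param bf10 Positive Bayes factor (vectorized).
#' @return Character vector of categories: `"evidence_for_null"`,
#'   `"inconclusive"`, `"moderate"`, `"strong"`, `"very_strong"`.
#' @export
#' @examples
#' classify_evidence(c(0.2, 0.457, 7.6, 29.579, 40))
classify_evidence <- function(bf10) {
  if (!is.numeric(bf10) || any(bf10 <= 0)) stop("bf10 must be positive")
  out <- character(length(bf10))
  out[bf10 < 1 / 3] <- "evidence_for_null"
  out[bf10 >= 1 / 3 & bf10 <= 3] <- "inconclusive"
  out[bf10 > 3 & bf10 <= 10] <- "moderate"
  out[bf10 > 10 & bf10 <= 30] <- "strong"
  out[bf10 > 30] <- "very_strong"
  out
}

#' @export
print.mfi_bf <- function(x, digits = 3, ...) {
  cat(sprintf(
    "BF10 = %.*f (%s)\n  estimate %.4g, likelihood SD %.4g, uniform H1 prior [%.4g, %.4g]\n",
    digits, x$bf10, x$category, x$estimate, x$se, x$prior_lower,
    x$prior_upper))
  invisible(x)
}

#' @export
format.mfi_bf <- function(x, digits = 3, ...) {
  sprintf("%.*f (%s)", digits, x$bf10, x$category)
}
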