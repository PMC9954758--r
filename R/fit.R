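#' Fit the predictor-by-OF interaction model
#'
#' Ordinary least squares for the moderation model
#' \deqn{y = b_0 + b_1 x + b_2 \cdot OF + b_3 (x \cdot OF) + \varepsilon,}
#' where `y` is a composite reading z-score, `x` the singled-out cognitive
#' predictor and `OF` the correlation-weighted index of the other
#' predictors. The scientific prediction is a *negative* interaction
#' (`b3 < 0`): the lower the aggregate efficiency of the other factors, the
#' steeper the effect of the singled-out predictor. Inference on `b3` is
#' therefore one-tailed in that direction by default.
#'
#' Children with a missing value in any of `y`, `x`, `of` are dropped
#' (listwise). Variables are not centered before the product is formed: all
#' inputs are z-scores or weighted sums of z-scores, and interpretation at
#' fixed moderator levels is delegated to [simple_slopes()].
#'
#' @param y Numeric outcome vector (composite reading z-score).
#' @param x Numeric vector, the singled-out predictor.
#' @param of Numeric vector, the other-factors index (see [of_index()]).
#' @param predictor,outcome Optional labels carried into print/summary.
#' @param direction Direction of the one-tailed test on the interaction:
#'   `"negative"` (default, the amplification prediction) or `"positive"`.
#' @return An object of class `mfi_fit` with components `coefficients`
#'   (b0..b3), `se`, `df` (residual degrees of freedom, n - 4), `n`,
#'   `t_interaction`, `p_one_tailed`, `sigma`, `direction`, `model` (the
#'   complete-case model frame), plus `fitted.values` and `residuals`.
#' @seealso [one_tailed_t()], [simple_slopes()], [mfi_analysis()]
#' @export
#' @examples
#' set.seed(1)
#' x <- rnorm(60); of <- rnorm(60)
#' y <- 1 + 0.5 * x + 0.8 * of - 0.4 * x * of + rnorm(60, sd = 0.3)
#' fit <- fit_interaction(y, x, of)
#' coef(fit)
fit_interaction <- function(y, x, of, predictor = "x", outcome = "y",
                            direction = c("negative", "positive")) {
  direction <- match.arg(direction)
  stopifnot(length(y) == length(x), length(x) == length(of))
  ok <- stats::complete.cases(y, x, of)
  n <- sum(ok)
  if (n <= 4) {
    stop("need at least 5 complete cases to fit the interaction model, got ",
         n)
  }
  dat <- data.frame(y = y[ok], x = x[ok], of = of[ok])
  fit <- stats::lm(y ~ x * of, data = dat)
  if (fit$rank < 4) {
    stop("rank-deficient design: predictor, OF index and their product ",
         "are collinear")
  }
  sm <- summary(fit)
  cf <- stats::coef(fit)
  se <- sm$coefficients[, "Std. Error"]
  names(cf) <- names(se) <- c("b0", "b1_x", "b2_of", "b3_xof")
  tt <- one_tailed_t(cf[["b3_xof"]], se[["b3_xof"]], fit$df.residual,
                     direction = direction)
  structure(list(
    coefficients = cf,
    se = se,
    df = fit$df.residual,
    n = n,
    t_interaction = tt$t,
    p_one_tailed = tt$p,
    sigma = sm$sigma,
    direction = direction,
    predictor = predictor,
    outcome = outcome,
    model = dat,
    fitted.values = stats::fitted(fit),
    residuals = stats::residuals(fit)
  ), class = "mfi_fit")
}

#' One-tailed t test for a directional coefficient
#'
#' Computes `t = estimate / se` and the one-tailed p value under a Student t
#' distribution with `df` degrees of freedom. With `direction = "negative"`
#' (the amplification prediction) the p value is the lower-tail probability
#' `P(T <= t)`; with `"positive"` it is the upper tail.
#'
#' @param estimate Coefficient estimate (vectorized).
#' @param se Standard error (strictly positive, vectorized).
#' @param df Residual degrees of freedom (positive integer, vectorized).
#' @param direction `"negative"` or `"positive"`.
#' @return List with elements `t` and `p`.
#' @export
#' @examples
#' one_tailed_t(-0.611, 0.277, 51)  # t ~ -2.21, p ~ 0.016
one_tailed_t <- function(estimate, se, df,
                         direction = c("negative", "positive")) {
  direction <- match.arg(direction)
  if (!is.numeric(se) || any(se <= 0)) stop("se must be strictly positive")
  if (any(df < 1)) stop("df must be a positive integer")
  t <- estimate / se
  p <- stats::pt(t, df, lower.tail = (direction == "negative"))
  list(t = t, p = p)
}

#' Count significant directional interactions
#'
#' Number of fits whose one-tailed p value is below `alpha`. No
#' multiple-comparison correction is applied: the interaction is predicted
#' in every test, not merely in at least one, so the family-wise framing
#' does not apply.
#'
#' @param fits A list of `mfi_fit` objects, or a numeric vector of
#'   one-tailed p values.
#' @param alpha Significance threshold (default 0.05).
#' @return Integer count.
#' @export
count_significant <- function(fits, alpha = 0.05) {
  if (is.numeric(fits)) {
    p <- fits
  } else {
    stopifnot(length(fits) >= 1,
              all(vapply(fits, inherits, logical(1), "mfi_fit")))
    p <- vapply(fits, function(f) f$p_one_tailed, numeric(1))
  }
  sum(p < alpha)
}

#' Simple slopes of the outcome on the OF index at fixed predictor levels
#'
#' For a fitted interaction model, the regression of the outcome on the OF
#' index at a fixed level `L` of the singled-out predictor has intercept
#' `b0 + b1 L` and slope `b2 + b3 L`. Levels are taken at the predictor's
#' mean and one standard deviation either side, the conventional display
#' for a moderated regression.
#'
#' @param fit An `mfi_fit` object.
#' @param x_mean Level center; defaults to the sample mean of the predictor
#'   in the fitted data.
#' @param x_sd Level spread; defaults to the sample standard deviation.
#'   Must be strictly positive.
#' @return A `data.frame` of class `simple_slopes` with columns `level`
#'   (labelled `mean-sd`, `mean`, `mean+sd`), `x`, `intercept`, `slope`.
#' @export
simple_slopes <- function(fit, x_mean = NULL, x_sd = NULL) {
  stopifnot(inherits(fit, "mfi_fit"))
  if (is.null(x_mean)) x_mean <- mean(fit$model$x)
  if (is.null(x_sd)) x_sd <- stats::sd(fit$model$x)
  if (!is.numeric(x_sd) || x_sd <= 0) stop("x_sd must be strictly positive")
  cf <- fit$coefficients
  levels <- c(x_mean - x_sd, x_mean, x_mean + x_sd)
  out <- data.frame(
    level = c("mean-sd", "mean", "mean+sd"),
    x = levels,
    intercept = cf[["b0"]] + cf[["b1_x"]] * levels,
    slope = cf[["b2_of"]] + cf[["b3_xof"]] * levels,
    stringsAsFactors = FALSE
  )
  class(out) <- c("simple_slopes", "data.frame")
  out
}

#' @export
print.mfi_fit <- function(x, digits = 4, ...) {
  cat("Predictor-by-OF interaction model (OLS)\n")
  cat(sprintf("  outcome: %s   predictor: %s   n = %d, df = %d\n",
              x$outcome, x$predictor, x$n, x$df))
  cat("  coefficients:\n")
  print(round(x$coefficients, digits))
  cat(sprintf("  interaction: b3 = %.*f (SE %.*f), t(%d) = %.*f, one-tailed p = %.*f [%s]\n",
              digits, x$coefficients[["b3_xof"]], digits, x$se[["b3_xof"]],
              x$df, digits, x$t_interaction, digits, x$p_one_tailed,
              x$direction))
  invisible(x)
}

#' @export
summary.mfi_fit <- function(object, ...) {
  tab <- data.frame(
    estimate = object$coefficients,
    se = object$se,
    t = object$coefficients / object$se,
    row.names = names(object$coefficients)
  )
  out <- list(coefficients = tab, n = object$n, df = object$df,
              sigma = object$sigma,
              t_interaction = object$t_interaction,
              p_one_tailed = object$p_one_tailed,
              direction = object$direction,
              predictor = object$predictor, outcome = object$outcome)
  class(out) <- "summary.mfi_fit"
  out
}

#' @export
print.summary.mfi_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Interaction model: %s ~ %s * OF   (n = %d, residual df = %d)\n",
              x$outcome, x$predictor, x$n, x$df))
  print(round(x$coefficients, digits))
  cat(sprintf("residual sigma = %.*f\n", digits, x$sigma))
  cat(sprintf("one-tailed (%s) interaction test: t(%d) = %.*f, p = %.*f\n",
              x$direction, x$df, digits, x$t_interaction, digits,
              x$p_one_tailed))
  invisible(x)
}

#' @export
coef.mfi_fit <- function(object, ...) object$coefficients

#' @export
residuals.mfi_fit <- function(object, ...) object$residuals

#' @export
fitted.mfi_fit <- function(object, ...) object$fitted.values

#' Predict from a fitted interaction model
#'
#' @param object An `mfi_fit` object.
#' @param newdata Optional `data.frame` with columns `x` and `of`; defaults
#'   to the fitted model frame.
#' @param ... Unused.
#' @return Numeric vector of predicted outcome values.
#' @export
predict.mfi_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- object$model
  stopifnot(all(c("x", "of") %in% names(newdata)))
  cf <- object$coefficients
  cf[["b0"]] + cf[["b1_x"]] * newdata$x + cf[["b2_of"]] * newdata$of +
    cf[["b3_xof"]] * newdata$x * newdata$of
}

#' Simulate outcome vectors from a fitted interaction model
#'
#' Parametric simulation: new outcome vectors are drawn as the fitted mean
#' plus Gaussian noise with the residual standard deviation, at the observed
#' design points.
#'
#' @param object An `mfi_fit` object.
#' @param nsim Number of simulated response vectors.
#' @param seed Optional integer seed.
#' @param ... Unused.
#' @return A `data.frame` with `nsim` columns, one simulated outcome vector
#'   per column.
#' @export
simulate.mfi_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- object$fitted.values
  out <- as.data.frame(replicate(nsim, mu + stats::rnorm(length(mu),
                                                         sd = object$sigma)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Plot a fitted interaction as simple-slopes lines
#'
#' Draws the observed outcome against the OF index and overlays the
#' regression lines at the predictor's mean and +/- 1 SD, the standard
#' moderation display: a fan of lines whose spread widens where the
#' interaction amplifies the predictor's effect.
#'
#' @param x An `mfi_fit` object.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, the [simple_slopes()] table that was drawn.
#' @export
plot.mfi_fit <- function(x, ...) {
  ss <- simple_slopes(x)
  cols <- c("steelblue", "gray40", "goldenrod")
  graphics::plot(x$model$of, x$model$y,
                 xlab = "OF index", ylab = x$outcome,
                 main = sprintf("%s moderated by %s", x$outcome, x$predictor),
                 pch = 16, col = "gray70", ...)
  for (i in 1:3) {
    graphics::abline(ss$intercept[i], ss$slope[i], col = cols[i], lwd = 2)
  }
  graphics::legend("topleft", bty = "n", lwd = 2, col = cols,
                   legend = sprintf("%s at %s", x$predictor, ss$level))
  invisible(ss)
}
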