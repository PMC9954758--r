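test_that("noiseless interactive data are interpolated exactly", {
  set.seed(3)
  x <- rnorm(30); of <- rnorm(30)
  y <- 1 + 2 * x + 3 * of - 0.5 * x * of
  fit <- suppressWarnings(fit_interaction(y, x, of))  # perfect-fit warning
  expect_equal(unname(coef(fit)), c(1, 2, 3, -0.5), tolerance = 1e-10)
  expect_lt(fit$sigma, 1e-10)
  expect_equal(fit$df, 26)
  expect_equal(fit$n, 30)
})

test_that("coefficients and SEs equal the normal-equations oracle", {
  tab <- make_fixed_table(20)
  w <- of_weights(tab, predictor_names, "reading_accuracy")
  of <- of_index(tab, w, "memory")
  y <- tab$reading_accuracy
  x <- tab$memory
  fit <- fit_interaction(y, x, of)
  oracle <- ols_normal_equations(y, x, of)
  expect_equal(unname(coef(fit)), oracle$beta, tolerance = 1e-10)
  expect_equal(unname(fit$se), unname(oracle$se), tolerance = 1e-10)
  expect_equal(fit$t_interaction, unname(oracle$beta[4] / oracle$se[4]),
               tolerance = 1e-12)
  expect_equal(fit$df, 16)
})

test_that("listwise deletion, rank deficiency and tiny-n are handled", {
  set.seed(4)
  x <- rnorm(12); of <- rnorm(12)
  y <- x + of + rnorm(12, sd = 0.1)
  y[3] <- NA; x[7] <- NA; of[9] <- NA
  fit <- fit_interaction(y, x, of)
  expect_equal(fit$n, 9)
  expect_equal(fit$df, 5)

  expect_error(fit_interaction(y, x, x), "rank-deficient")
  expect_error(fit_interaction(y[1:4], x[1:4], of[1:4]),
               "at least 5 complete cases")
})

test_that("one_tailed_t computes the directional tail probability", {
  r <- one_tailed_t(0, 1, 51)
  expect_equal(r$t, 0)
  expect_equal(r$p, 0.5)   # symmetry of the t distribution

  r2 <- one_tailed_t(-0.611, 0.277, 51)
  expect_equal(r2$t, -0.611 / 0.277, tolerance = 1e-12)
  expect_equal(r2$p, pt(-0.611 / 0.277, 51), tolerance = 1e-12)

  # flipping the declared direction mirrors the tail
  r3 <- one_tailed_t(0.5, 0.2, 20, direction = "positive")
  r4 <- one_tailed_t(-0.5, 0.2, 20, direction = "negative")
  expect_equal(r3$p, r4$p, tolerance = 1e-12)

  expect_error(one_tailed_t(1, 0, 51), "strictly positive")
  expect_error(one_tailed_t(1, -1, 51), "strictly positive")
  expect_error(one_tailed_t(1, 1, 0), "positive integer")
})

test_that("count_significant counts below alpha, monotonically in alpha", {
  expect_equal(count_significant(rep(0.5, 8), 0.05), 0)
  p <- c(0.001, 0.01, 0.04, 0.049, 0.05, 0.2)
  expect_equal(count_significant(p, 0.05), 4)   # strict inequality
  expect_lte(count_significant(p, 0.01), count_significant(p, 0.05))

  set.seed(5)
  fits <- lapply(1:3, function(i) {
    x <- rnorm(20); of <- rnorm(20)
    fit_interaction(x + of + rnorm(20), x, of)
  })
  expect_equal(count_significant(fits, 1), 3)
  expect_error(count_significant(list()), "length")
})

test_that("simple slopes follow the moderation algebra", {
  set.seed(6)
  x <- rnorm(40); of <- rnorm(40)
  y <- 0.3 + 0.7 * x + 1.1 * of - 0.4 * x * of + rnorm(40, sd = 0.2)
  fit <- fit_interaction(y, x, of)
  cf <- coef(fit)
  ss <- simple_slopes(fit, x_mean = 0.2, x_sd = 0.6)
  expect_equal(ss$x, c(-0.4, 0.2, 0.8))
  expect_equal(ss$intercept, cf[["b0"]] + cf[["b1_x"]] * ss$x,
               tolerance = 1e-12)
  expect_equal(ss$slope, cf[["b2_of"]] + cf[["b3_xof"]] * ss$x,
               tolerance = 1e-12)
  # at the predictor's mean the slope is b2 + b3 * mean
  expect_equal(ss$slope[2], cf[["b2_of"]] + cf[["b3_xof"]] * 0.2,
               tolerance = 1e-12)

  # without moderation all three slopes collapse to b2
  y0 <- 0.3 + 0.7 * x + 1.1 * of
  fit0 <- suppressWarnings(fit_interaction(y0, x, of))  # perfect fit
  ss0 <- simple_slopes(fit0, x_mean = 0, x_sd = 1)
  expect_equal(ss0$slope, rep(coef(fit0)[["b2_of"]], 3), tolerance = 1e-8)

  # gap between the +1 SD and -1 SD lines at OF = c is 2 sd (b1 + b3 c)
  sd_ <- 0.6
  for (cpt in c(-1, 0, 2)) {
    hi <- ss$intercept[3] + ss$slope[3] * cpt
    lo <- ss$intercept[1] + ss$slope[1] * cpt
    expect_equal(hi - lo, 2 * sd_ * (cf[["b1_x"]] + cf[["b3_xof"]] * cpt),
                 tolerance = 1e-10)
  }

  expect_error(simple_slopes(fit, x_mean = 0, x_sd = 0),
               "strictly positive")
})

test_that("OLS invariants: residual orthogonality, row-order invariance, amplification", {
  set.seed(7)
  for (rep in 1:5) {
    n <- 50
    x <- rnorm(n); of <- rnorm(n)
    y <- 0.2 * x + 0.5 * of - 0.6 * x * of + rnorm(n)
    fit <- fit_interaction(y, x, of)
    X <- cbind(1, scale(x), scale(of), scale(x * of))
    expect_lt(max(abs(t(X) %*% residuals(fit))), 1e-8)

    perm <- sample(n)
    fit_p <- fit_interaction(y[perm], x[perm], of[perm])
    expect_equal(coef(fit_p), coef(fit), tolerance = 1e-10)

    # with b3 < 0 the fitted x-effect b1 + b3 * of decreases in of
    cf <- coef(fit)
    if (cf[["b3_xof"]] < 0) {
      of_grid <- c(-1, 0, 1)
      eff <- cf[["b1_x"]] + cf[["b3_xof"]] * of_grid
      expect_true(all(diff(eff) < 0))
    }
  }
})

test_that("mfi_fit methods: predict, residuals, simulate, print, plot", {
  set.seed(8)
  x <- rnorm(25); of <- rnorm(25)
  y <- 1 + x - 0.3 * x * of + rnorm(25, sd = 0.4)
  fit <- fit_interaction(y, x, of, predictor = "iq",
                         outcome = "reading_accuracy")
  expect_equal(predict(fit), unname(fitted(fit)), tolerance = 1e-12)
  nd <- data.frame(x = c(0, 1), of = c(0, 0))
  cf <- coef(fit)
  expect_equal(predict(fit, nd), c(cf[["b0"]], cf[["b0"]] + cf[["b1_x"]]),
               tolerance = 1e-12)
  expect_equal(unname(residuals(fit)), y - predict(fit), tolerance = 1e-12)

  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_equal(dim(sims), c(25, 3))
  expect_identical(sims, simulate(fit, nsim = 3, seed = 1))

  expect_output(print(fit), "one-tailed p")
  expect_output(print(summary(fit)), "residual sigma")
  pdf(NULL)
  on.exit(dev.off())
  expect_invisible(plot(fit))
})
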