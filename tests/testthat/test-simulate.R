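test_that("cohort_config validates its inputs", {
  cfg <- cohort_config()
  expect_s3_class(cfg, "cohort_config")
  expect_equal(cfg$n_total, 266)
  expect_equal(cfg$n_complete, 55)
  expect_equal(unname(diag(cfg$factor_correlation)), rep(1, 5))

  bad <- matrix(0.99, 5, 5); diag(bad) <- 1; bad[1, 2] <- bad[2, 1] <- -0.99
  expect_error(cohort_config(factor_correlation = bad),
               "not positive definite")
  expect_error(cohort_config(n_complete = 300))
  expect_error(cohort_config(true_weights = c(1, 2)))
  expect_error(cohort_config(gamma = -1))
  expect_output(print(cfg), "threshold model")
})

test_that("sample_factors draws the configured correlation structure", {
  # identity correlation: empirical pairwise correlations near zero
  cfg_id <- cohort_config(factor_correlation = diag(5), seed = 21)
  f <- sample_factors(cfg_id, n = 10000)
  cors <- cor(f)
  expect_lt(max(abs(cors[upper.tri(cors)])), 0.05)
  expect_lt(max(abs(colMeans(f))), 0.05)

  # strong correlation survives sampling
  R <- diag(5); R[1, 2] <- R[2, 1] <- 0.99
  cfg_hi <- cohort_config(factor_correlation = R, seed = 22)
  f2 <- sample_factors(cfg_hi, n = 1000)
  expect_gt(cor(f2[, 1], f2[, 2]), 0.9)

  # fixed seed: bit-identical repeat
  expect_identical(sample_factors(cfg_id, n = 50),
                   sample_factors(cfg_id, n = 50))
})

test_that("reading_from_factors implements the hinge threshold law", {
  # additive degenerate case: gamma = 0, no noise, weight only on factor 1
  cfg <- cohort_config(true_weights = c(1, 0, 0, 0, 0), gamma = 0,
                       noise_sd = 0, component_sd = 0, seed = 23)
  f <- sample_factors(cfg, n = 40)
  comp <- reading_from_factors(f, cfg)
  for (col in names(comp)) expect_equal(comp[[col]], unname(f[, "iq"]))
  expect_equal(attr(comp, "mfi"), unname(f[, "iq"]))

  # at the threshold the amplification term is zero regardless of gamma
  w <- cohort_config()$true_weights
  f_at_tau <- matrix(0.5 / sum(w), 3, 5,
                     dimnames = list(NULL, names(w)))  # MFi = tau = 0.5
  cfg0 <- cohort_config(gamma = 0, noise_sd = 0, component_sd = 0, seed = 1)
  cfg5 <- cohort_config(gamma = 5, noise_sd = 0, component_sd = 0, seed = 1)
  expect_equal(reading_from_factors(f_at_tau, cfg0)$text_acc,
               reading_from_factors(f_at_tau, cfg5)$text_acc,
               tolerance = 1e-12)

  # below threshold the gap is amplified by exactly (1 + gamma)
  f_low <- matrix(-1 / sum(w), 1, 5, dimnames = list(NULL, names(w)))
  r <- reading_from_factors(f_low, cfg5)
  expect_equal(r$text_acc, -1 + 5 * (-1 - 0.5), tolerance = 1e-12)
})

test_that("the population interaction coefficient is negative under amplification", {
  cfg <- cohort_config(seed = 24)   # gamma = 1.5 default
  n <- 50000
  f <- sample_factors(cfg, n = n)
  comp <- reading_from_factors(f, cfg)
  tab <- data.frame(as.data.frame(f), comp)
  tab <- composite_score(tab, "reading_accuracy",
                         c("text_acc", "word_acc", "nonword_acc"))
  w <- of_weights(tab, predictor_names, "reading_accuracy")
  of <- of_index(tab, w, "phon_awareness")
  # brute-force population regression via the normal equations
  oracle <- ols_normal_equations(tab$reading_accuracy, tab$phon_awareness,
                                 of)
  expect_lt(oracle$beta[4], 0)
  # and the packaged fit agrees
  fit <- fit_interaction(tab$reading_accuracy, tab$phon_awareness, of)
  expect_equal(unname(coef(fit)), oracle$beta, tolerance = 1e-8)
})

test_that("the diagnosis filter retains exactly the children meeting the cutoff", {
  tab <- data.frame(text_acc = c(0, -2.5, -1), word_acc = c(0, 0, -2),
                    nonword_acc = 0, text_speed = 0, word_speed = 0,
                    nonword_speed = 0)
  kept <- apply_diagnosis_filter(tab, cutoff = -2)
  expect_equal(nrow(kept), 2)        # all-zero child excluded
  expect_true(all(apply(kept, 1, min) <= -2))

  expect_error(apply_diagnosis_filter(tab[, 1:2, drop = FALSE]),
               "reading column")

  # retained fraction strictly between 0 and 1 at scale
  cfg <- cohort_config(seed = 25)
  f <- sample_factors(cfg, n = 10000)
  comp <- reading_from_factors(f, cfg)
  kept2 <- apply_diagnosis_filter(comp, cfg$diagnosis_cutoff)
  frac <- nrow(kept2) / nrow(comp)
  expect_gt(frac, 0)
  expect_lt(frac, 1)
})

test_that("missingness injection leaves exactly n_complete complete cases", {
  tab <- make_fixed_table(30)
  out <- inject_missingness(tab, 12, predictor_names, seed = 26)
  cc <- complete.cases(out[, predictor_names])
  expect_equal(sum(cc), 12)
  # incomplete children lose a nonempty predictor subset, reading untouched
  expect_true(all(rowSums(is.na(out[!cc, predictor_names])) >= 1))
  expect_false(anyNA(out$reading_accuracy))
  expect_false(anyNA(out$reading_speed))

  # n_complete equal to cohort size: no missingness introduced
  expect_identical(inject_missingness(tab, 30, predictor_names, seed = 26),
                   tab)
  # deterministic under a fixed seed
  expect_identical(out, inject_missingness(tab, 12, predictor_names,
                                           seed = 26))
  expect_error(inject_missingness(tab, 31, predictor_names, seed = 1),
               "exceeds cohort size")
})

test_that("simulate_cohort composes the stages deterministically", {
  cfg <- cohort_config(seed = 27)
  coh <- simulate_cohort(cfg)
  expect_s3_class(coh, "synthetic_cohort")
  tab <- coh$table
  analysis_cols <- c(predictor_names, "reading_accuracy", "reading_speed")
  expect_true(all(analysis_cols %in% names(tab)))
  expect_equal(sum(complete.cases(tab[, analysis_cols])), cfg$n_complete)
  expect_equal(length(coh$mfi), nrow(tab))
  # ascertainment: no retained child violates the cutoff rule
  rc <- c("text_acc", "word_acc", "nonword_acc",
          "text_speed", "word_speed", "nonword_speed")
  expect_true(all(apply(tab[, rc], 1, min) <= cfg$diagnosis_cutoff))
  # same seed twice: identical cohort
  expect_identical(simulate_cohort(cfg)$table, tab)
  # different seed: different cohort
  expect_false(identical(simulate_cohort(cohort_config(seed = 28))$table,
                         tab))
  expect_output(print(coh), "ascertained children")
})

test_that("interaction_power recovers the amplification sign at modest scale", {
  pw <- interaction_power(gammas = c(0, 1.5), n = 300, replicates = 25,
                          seed = 29)
  expect_equal(nrow(pw), 2)
  expect_lt(pw$mean_b3[pw$gamma == 1.5], 0)
  expect_gt(pw$rejection_rate[pw$gamma == 1.5],
            pw$rejection_rate[pw$gamma == 0])
  det <- attr(pw, "replicates")
  expect_equal(nrow(det), 50)
  expect_true(all(det$p > 0 & det$p < 1))
})
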