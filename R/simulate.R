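# Deterministic substream seed: every stage of the generator draws from its
# own named stream derived from the master seed, so stages are individually
# reproducible and inserting a stage never perturbs the others.
substream <- function(seed, name) {
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 31 + ch) %% 97561
  as.integer((abs(as.double(seed)) %% 21473) * 97561 + h)
}

#' Configuration for the synthetic dyslexia cohort generator
#'
#' Bundles the generative parameters of the threshold model of reading used
#' by [simulate_cohort()]. Defaults emulate the structure of a clinical
#' dyslexia database: 266 referred children, of whom 55 carry all five
#' cognitive predictors plus both reading composites; five positively
#' correlated z-scored predictors; reading produced by a weighted factor sum
#' with below-threshold amplification; and ascertainment by at least one
#' reading z-score at or below -2.
#'
#' The defaults are illustrative of that structure, not estimates of any
#' study population: exchangeable factor correlation 0.3; true weights
#' ranking phonological awareness above RAN, visual search, then IQ and
#' memory; threshold `tau = 0.5` (most referred children sit below the
#' efficiency threshold); amplification `gamma = 1.5`; latent noise SD 0.5;
#' per-component measurement noise SD 0.3.
#'
#' @param n_total Number of children sampled before ascertainment.
#' @param n_complete Number of children left with all predictors after
#'   missingness injection.
#' @param factor_names Names of the cognitive predictors.
#' @param factor_correlation Symmetric positive-definite correlation matrix
#'   (unit diagonal) of the predictors.
#' @param true_weights Nonnegative generative weights of the predictors in
#'   the latent multifactor index.
#' @param tau Efficiency threshold of the reading model.
#' @param gamma Nonnegative amplification of the below-threshold gap;
#'   `gamma = 0` recovers a purely additive model.
#' @param noise_sd SD of the latent reading noise (per outcome dimension);
#'   may be 0 for a deterministic reading law.
#' @param component_sd SD of the independent measurement noise added to each
#'   of the three observed components per outcome.
#' @param diagnosis_cutoff Ascertainment cutoff on the minimum reading
#'   component z-score (default -2).
#' @param seed Master integer seed; all stages derive named substreams.
#' @return An object of class `cohort_config` (a validated list).
#' @export
cohort_config <- function(n_total = 266,
                          n_complete = 55,
                          factor_names = c("iq", "phon_awareness",
                                           "ran_speed",
                                           "visual_search_speed", "memory"),
                          factor_correlation = NULL,
                          true_weights = c(0.20, 0.35, 0.30, 0.25, 0.20),
                          tau = 0.5,
                          gamma = 1.5,
                          noise_sd = 0.5,
                          component_sd = 0.3,
                          diagnosis_cutoff = -2,
                          seed = 1L) {
  k <- length(factor_names)
  if (is.null(factor_correlation)) {
    factor_correlation <- matrix(0.3, k, k)
    diag(factor_correlation) <- 1
  }
  stopifnot(n_total >= 1, n_complete >= 1, n_complete <= n_total,
            length(true_weights) == k,
            all(true_weights >= 0),
            gamma >= 0, noise_sd >= 0, component_sd >= 0)
  if (!isTRUE(all.equal(dim(factor_correlation), c(k, k))) ||
      !isTRUE(all.equal(as.vector(diag(factor_correlation)), rep(1, k))) ||
      !isSymmetric(unname(factor_correlation))) {
    stop("factor_correlation must be a symmetric ", k, "x", k,
         " matrix with unit diagonal")
  }
  if (min(eigen(factor_correlation, symmetric = TRUE,
                only.values = TRUE)$values) <= 0) {
    stop("factor_correlation is not positive definite")
  }
  dimnames(factor_correlation) <- list(factor_names, factor_names)
  names(true_weights) <- factor_names
  structure(list(n_total = n_total, n_complete = n_complete,
                 factor_names = factor_names,
                 factor_correlation = factor_correlation,
                 true_weights = true_weights, tau = tau, gamma = gamma,
                 noise_sd = noise_sd, component_sd = component_sd,
                 diagnosis_cutoff = diagnosis_cutoff,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat(sprintf("  n_total = %d, n_complete = %d, seed = %d\n",
              x$n_total, x$n_complete, x$seed))
  cat("  factors:", paste(x$factor_names, collapse = ", "), "\n")
  cat(sprintf("  threshold model: tau = %.3g, gamma = %.3g, noise_sd = %.3g, component_sd = %.3g\n",
              x$tau, x$gamma, x$noise_sd, x$component_sd))
  cat(sprintf("  ascertainment: min reading component <= %.3g\n",
              x$diagnosis_cutoff))
  invisible(x)
}

#' Sample correlated cognitive factor z-scores
#'
#' Draws `n_total` children from a zero-mean multivariate normal with the
#' configured factor correlation matrix, the stand-in for age-normed
#' z-scores on the cognitive test battery.
#'
#' @param config A [cohort_config()] object.
#' @param n Number of children (default `config$n_total`).
#' @param seed Master seed (default `config$seed`); the draw uses the
#'   `"factors"` substream.
#' @return Numeric matrix, `n` rows by one column per factor.
#' @export
sample_factors <- function(config, n = config$n_total, seed = config$seed) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(substream(seed, "factors"))
  f <- MASS::mvrnorm(n, mu = rep(0, length(config$factor_names)),
                     Sigma = config$factor_correlation)
  f <- matrix(f, nrow = n, dimnames = list(NULL, config$factor_names))
  f
}

#' Generate observed reading components from the threshold model
#'
#' Per child, the latent multifactor index is `MFi = sum_i w_i f_i`. Latent
#' reading in each outcome dimension (accuracy, speed) is
#' `MFi + gamma * min(0, MFi - tau)` plus Gaussian noise: above the
#' threshold `tau` reading is (noisily) proportional to aggregate
#' efficiency, below it the shortfall is amplified by `1 + gamma` -- the
#' hinge is the minimal form of "difficulty proportional to the gap below
#' threshold". Each outcome dimension is observed through three components
#' (text, word, nonword) carrying independent measurement noise.
#'
#' @param factors Matrix from [sample_factors()].
#' @param config A [cohort_config()] object.
#' @param seed Master seed (default `config$seed`); noise uses the
#'   `"reading_noise"` and `"component_noise"` substreams.
#' @return A `data.frame` with six component columns (`text_acc`,
#'   `word_acc`, `nonword_acc`, `text_speed`, `word_speed`,
#'   `nonword_speed`); the per-child latent MFi is attached as attribute
#'   `"mfi"`.
#' @export
reading_from_factors <- function(factors, config, seed = config$seed) {
  stopifnot(inherits(config, "cohort_config"),
            is.matrix(factors),
            identical(colnames(factors), config$factor_names))
  n <- nrow(factors)
  mfi <- as.vector(factors %*% config$true_weights)
  ability <- mfi + config$gamma * pmin(0, mfi - config$tau)
  set.seed(substream(seed, "reading_noise"))
  latent <- list(acc = ability + stats::rnorm(n, sd = config$noise_sd),
                 speed = ability + stats::rnorm(n, sd = config$noise_sd))
  set.seed(substream(seed, "component_noise"))
  out <- data.frame(row.names = seq_len(n))
  for (dim_name in c("acc", "speed")) {
    for (comp in c("text", "word", "nonword")) {
      out[[paste(comp, dim_name, sep = "_")]] <-
        latent[[dim_name]] + stats::rnorm(n, sd = config$component_sd)
    }
  }
  attr(out, "mfi") <- mfi
  out
}

#' Ascertain a cohort on poor reading performance
#'
#' Clinical ascertainment: a child enters the database only if at least one
#' reading z-score falls at or below the diagnostic cutoff. Effect
#' magnitudes estimated on such a sample are distorted relative to the
#' population; the direction of the interaction is not.
#'
#' @param table Cohort `data.frame` containing the reading component
#'   columns.
#' @param cutoff Diagnostic cutoff (default -2).
#' @param reading_cols Names of the reading z-score columns to scan;
#'   defaults to the six component columns produced by
#'   [reading_from_factors()].
#' @return The subset of `table` meeting the criterion.
#' @export
apply_diagnosis_filter <- function(table, cutoff = -2, reading_cols = NULL) {
  if (is.null(reading_cols)) {
    reading_cols <- c("text_acc", "word_acc", "nonword_acc",
                      "text_speed", "word_speed", "nonword_speed")
  }
  missing_cols <- setdiff(reading_cols, names(table))
  if (length(missing_cols)) {
    stop("reading column(s) not in table: ",
         paste(missing_cols, collapse = ", "))
  }
  m <- as.matrix(table[, reading_cols, drop = FALSE])
  keep <- apply(m, 1, min) <= cutoff
  table[keep, , drop = FALSE]
}

#' Inject test-availability missingness into the predictor columns
#'
#' Emulates a retrospective database in which only a subgroup of children
#' received every test: a random subset of `n_complete` children keeps all
#' predictors; every other child loses a random nonempty subset of
#' predictor columns. Reading columns are never touched. Missingness is
#' completely at random.
#'
#' @param table Cohort `data.frame`.
#' @param n_complete Number of children to leave fully observed.
#' @param predictor_cols Names of the predictor columns subject to deletion.
#' @param seed Master seed; uses the `"missingness"` substream.
#' @return `table` with `NA`s injected.
#' @export
inject_missingness <- function(table, n_complete, predictor_cols, seed = 1L) {
  stopifnot(is.data.frame(table),
            all(predictor_cols %in% names(table)))
  n <- nrow(table)
  if (n_complete > n) {
    stop("n_complete (", n_complete, ") exceeds cohort size after ",
         "filtering (", n, ")")
  }
  set.seed(substream(seed, "missingness"))
  complete_rows <- sort(sample.int(n, n_complete))
  k <- length(predictor_cols)
  for (i in setdiff(seq_len(n), complete_rows)) {
    n_drop <- sample.int(k, 1)
    drop_cols <- predictor_cols[sample.int(k, n_drop)]
    table[i, drop_cols] <- NA_real_
  }
  table
}

#' Generate a full synthetic cohort
#'
#' Composes the generator stages: sample correlated factors, produce
#' reading components from the threshold model, add the composite reading
#' scores, ascertain on poor reading, and inject test-availability
#' missingness. Regenerating with the same config (and seed) yields an
#' identical cohort.
#'
#' @param config A [cohort_config()] object.
#' @return An object of class `synthetic_cohort`: a list with `table` (the
#'   cohort `data.frame`, including `reading_accuracy` and `reading_speed`
#'   composites), `config`, and `mfi` (latent per-child multifactor index of
#'   the retained children).
#' @export
#' @examples
#' coh <- simulate_cohort(cohort_config(seed = 7))
#' coh
simulate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  f <- sample_factors(config)
  comp <- reading_from_factors(f, config)
  mfi <- attr(comp, "mfi")
  tab <- data.frame(child_id = sprintf("c%04d", seq_len(config$n_total)),
                    as.data.frame(f), comp,
                    stringsAsFactors = FALSE)
  tab <- composite_score(tab, "reading_accuracy",
                         c("text_acc", "word_acc", "nonword_acc"))
  tab <- composite_score(tab, "reading_speed",
                         c("text_speed", "word_speed", "nonword_speed"))
  keep <- apply_diagnosis_filter(tab, config$diagnosis_cutoff)
  mfi <- mfi[match(keep$child_id, tab$child_id)]
  out <- inject_missingness(keep, config$n_complete, config$factor_names,
                            seed = config$seed)
  rownames(out) <- NULL
  structure(list(table = out, config = config, mfi = mfi),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  tab <- x$table
  complete <- sum(stats::complete.cases(tab[, x$config$factor_names]))
  cat(sprintf(
    "Synthetic dyslexia cohort: %d ascertained children (of %d sampled), %d with all predictors\n",
    nrow(tab), x$config$n_total, complete))
  cat(sprintf("  threshold model: tau = %.3g, gamma = %.3g; seed = %d\n",
              x$config$tau, x$config$gamma, x$config$seed))
  invisible(x)
}

#' Rejection rates of the one-tailed interaction test under the generator
#'
#' Simulation study over a grid of amplification strengths `gamma`: for each
#' replicate a cohort of `n` children is generated (optionally ascertained),
#' correlation weights are estimated on it, the OF index excluding
#' `predictor` is built, the interaction model is fitted, and the one-tailed
#' test at level `alpha` is recorded. With `gamma = 0` the generative model
#' is purely additive and the rejection rate estimates the type-I error;
#' with `gamma > 0` it estimates power, and the mean fitted interaction
#' coefficient estimates the (ascertainment-distorted) effect.
#'
#' @param gammas Numeric vector of amplification values.
#' @param n Children per simulated cohort.
#' @param replicates Replicates per `gamma`.
#' @param alpha One-tailed significance level.
#' @param predictor Singled-out predictor for the fitted model.
#' @param outcome Reading outcome (`"reading_accuracy"` or
#'   `"reading_speed"`).
#' @param config Template [cohort_config()]; `gamma`, sample size and seed
#'   are overridden per replicate.
#' @param ascertain Apply the diagnosis filter before fitting? Default
#'   `FALSE` (population calibration).
#' @param seed Master seed; replicate `r` at gamma index `g` uses the
#'   `"power:<g>:<r>"` substream.
#' @return A `data.frame` with one row per `gamma`: `gamma`, `replicates`,
#'   `rejection_rate`, `mean_b3`. Per-replicate interaction estimates and
#'   p values are attached as attribute `"replicates"`.
#' @export
interaction_power <- function(gammas = c(0, 1.5), n = 500, replicates = 200,
                              alpha = 0.05, predictor = "iq",
                              outcome = "reading_accuracy",
                              config = cohort_config(),
                              ascertain = FALSE, seed = 1L) {
  stopifnot(inherits(config, "cohort_config"),
            predictor %in% config$factor_names,
            outcome %in% c("reading_accuracy", "reading_speed"))
  detail <- data.frame()
  summary_rows <- data.frame()
  for (g in seq_along(gammas)) {
    cfg <- config
    cfg$gamma <- gammas[g]
    p_vals <- b3 <- numeric(replicates)
    for (r in seq_len(replicates)) {
      rep_seed <- substream(seed, sprintf("power:%d:%d", g, r))
      f <- sample_factors(cfg, n = n, seed = rep_seed)
      comp <- reading_from_factors(f, cfg, seed = rep_seed)
      tab <- data.frame(as.data.frame(f), comp)
      tab <- composite_score(tab, "reading_accuracy",
                             c("text_acc", "word_acc", "nonword_acc"))
      tab <- composite_score(tab, "reading_speed",
                             c("text_speed", "word_speed", "nonword_speed"))
      if (ascertain) {
        tab <- apply_diagnosis_filter(tab, cfg$diagnosis_cutoff)
      }
      w <- of_weights(tab, cfg$factor_names, outcome)
      of <- of_index(tab, w, singled_out = predictor)
      fit <- fit_interaction(tab[[outcome]], tab[[predictor]], of,
                             predictor = predictor, outcome = outcome)
      p_vals[r] <- fit$p_one_tailed
      b3[r] <- fit$coefficients[["b3_xof"]]
    }
    detail <- rbind(detail, data.frame(gamma = gammas[g],
                                       rep = seq_len(replicates),
                                       b3 = b3, p = p_vals))
    summary_rows <- rbind(summary_rows, data.frame(
      gamma = gammas[g], replicates = replicates,
      rejection_rate = mean(p_vals < alpha), mean_b3 = mean(b3)))
  }
  attr(summary_rows, "replicates") <- detail
  summary_rows
}
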