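# Independent Pearson correlation oracle: raw sums formula, no stats::cor.
pearson_sums <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
  num / den
}

# Independent OLS oracle: explicit 4x4 normal-equations solve with SEs from
# the unbiased residual variance and the inverse cross-product matrix.
ols_normal_equations <- function(y, x, of) {
  X <- cbind(1, x, of, x * of)
  XtX <- t(X) %*% X
  beta <- solve(XtX, t(X) %*% y)
  resid <- y - X %*% beta
  sigma2 <- sum(resid^2) / (length(y) - 4)
  se <- sqrt(sigma2 * diag(solve(XtX)))
  list(beta = as.vector(beta), se = se, sigma2 = sigma2)
}

# Fixed deterministic cohort-like table (no RNG): 20 children, 5 predictors
# with mild mutual structure plus two reading outcomes.
make_fixed_table <- function(n = 20) {
  i <- seq_len(n)
  base <- sin(i) + cos(2 * i) / 2
  tab <- data.frame(
    child_id = sprintf("k%02d", i),
    iq = round(base + sin(3 * i) / 3, 6),
    phon_awareness = round(base / 2 + cos(5 * i) / 2, 6),
    ran_speed = round(sin(i + 1) + sin(7 * i) / 4, 6),
    visual_search_speed = round(cos(i) / 2 + sin(11 * i) / 3, 6),
    memory = round(base / 3 + cos(13 * i) / 2, 6),
    stringsAsFactors = FALSE
  )
  preds <- c("iq", "phon_awareness", "ran_speed", "visual_search_speed",
             "memory")
  tab$reading_accuracy <- round(rowSums(tab[preds]) / 3 + sin(17 * i) / 2, 6)
  tab$reading_speed <- round(rowSums(tab[preds]) / 4 + cos(19 * i) / 2, 6)
  tab
}

predictor_names <- c("iq", "phon_awareness", "ran_speed",
                     "visual_search_speed", "memory")
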