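#' Correlation weights for the multifactor index
#'
#' Computes one Pearson correlation per predictor against a single reading
#' outcome, over pairwise-complete children. These correlations are the
#' weights of the multifactor (MFi) index and of every "other factors" (OF)
#' index derived from it; they are deliberately computed on the largest
#' available sample (the full clinical database), which is typically wider
#' than the complete-case subsample the interaction models are fitted on.
#' Weights are not renormalized.
#'
#' @param weighting_table Cohort `data.frame` used to estimate the weights
#'   (usually the full database, not the complete-case subset).
#' @param predictors Character vector of predictor column names.
#' @param outcome Name of the reading outcome column the weights target.
#' @return An object of class `of_weights`: a list with elements `outcome`
#'   and `weights` (named numeric vector of correlations).
#' @export
#' @examples
#' tab <- data.frame(child_id = letters[1:6], p = c(1, 2, 3, 4, 5, 6),
#'                   y = c(1.2, 1.9, 3.1, 4.2, 4.8, 6.1))
#' of_weights(tab, "p", "y")
of_weights <- function(weighting_table, predictors, outcome) {
  stopifnot(is.data.frame(weighting_table), length(predictors) >= 1)
  missing_cols <- setdiff(c(predictors, outcome), names(weighting_table))
  if (length(missing_cols)) {
    stop("column(s) not in weighting table: ",
         paste(missing_cols, collapse = ", "))
  }
  y <- weighting_table[[outcome]]
  w <- vapply(predictors, function(p) {
    x <- weighting_table[[p]]
    ok <- stats::complete.cases(x, y)
    if (stats::var(x[ok]) == 0) {
      stop("predictor '", p, "' has zero variance on the weighting sample")
    }
    stats::cor(x[ok], y[ok])
  }, numeric(1))
  structure(list(outcome = outcome, weights = w), class = "of_weights")
}

#' @export
print.of_weights <- function(x, digits = 3, ...) {
  cat("Correlation weights against outcome '", x$outcome, "':\n", sep = "")
  print(round(x$weights, digits))
  invisible(x)
}

#' Export correlation weights as a two-column csv
#'
#' @param x An `of_weights` object.
#' @param path Destination path.
#' @return Invisibly, `path`.
#' @export
write_weights <- function(x, path) {
  stopifnot(inherits(x, "of_weights"))
  utils::write.table(
    data.frame(predictor = names(x$weights), weight = x$weights),
    path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Other-factors (OF) index: weighted sum of the remaining predictors
#'
#' For each child, the OF index relative to a singled-out predictor is the
#' sum of `weight * z-score` over every predictor except the singled-out
#' one. With `singled_out = NULL` no predictor is excluded and the function
#' returns the full multifactor (MFi) index, the aggregate efficiency score
#' the threshold model is built on. The value is missing for any child
#' missing a contributing predictor.
#'
#' @param table Cohort `data.frame` holding the predictor columns.
#' @param weights An `of_weights` object (see [of_weights()]).
#' @param singled_out Name of the predictor to exclude, or `NULL` for the
#'   full MFi index.
#' @return Numeric vector, one value per row of `table`.
#' @export
of_index <- function(table, weights, singled_out = NULL) {
  stopifnot(is.data.frame(table), inherits(weights, "of_weights"))
  w <- weights$weights
  if (!is.null(singled_out)) {
    if (!singled_out %in% names(w)) {
      stop("singled-out predictor '", singled_out,
           "' is not among the weighted predictors")
    }
    w <- w[setdiff(names(w), singled_out)]
  }
  missing_cols <- setdiff(names(w), names(table))
  if (length(missing_cols)) {
    stop("column(s) not in table: ", paste(missing_cols, collapse = ", "))
  }
  z <- as.matrix(table[, names(w), drop = FALSE])
  as.vector(z %*% w)   # NA propagates if any contributor is NA
}
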