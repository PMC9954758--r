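#' Read a per-child cohort table of z-scored measures
#'
#' Reads a comma-separated table with one row per child, a header row, an
#' identifier column, and numeric z-score columns for every measure. Missing
#' measurements must be encoded explicitly with `missing_token`; any other
#' non-numeric cell is an error. All measures are assumed oriented so that a
#' higher z-score means better performance (speed measures included) -- the
#' non-negative-correlation predictor screen in [screen_predictors()] relies
#' on this orientation, which is the data preparer's contract.
#'
#' @param path Path to a comma-separated text file.
#' @param missing_token Character token encoding missing cells (default
#'   `"NA"`).
#' @param id_col Name of the child-identifier column (default `"child_id"`).
#' @return A `data.frame` with the identifier column as character and every
#'   other column numeric (`NA` where the cell held `missing_token`).
#' @seealso [write_cohort()] for the inverse operation.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' writeLines(c("child_id,iq,memory", "c1,0.5,NA", "c2,-1.2,0.3"), tf)
#' read_cohort(tf)
read_cohort <- function(path, missing_token = "NA", id_col = "child_id") {
  if (!file.exists(path)) {
    stop("cohort file not found: ", path)
  }
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, strip.white = TRUE,
                         na.strings = character(0))
  if (!id_col %in% names(raw)) {
    stop("identifier column '", id_col, "' not found in ", path)
  }
  ids <- raw[[id_col]]
  if (anyDuplicated(ids)) {
    stop("duplicate child_id values: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  out <- raw
  for (col in setdiff(names(raw), id_col)) {
    cell <- raw[[col]]
    is_missing <- is.na(cell) | cell == missing_token | cell == ""
    parsed <- suppressWarnings(as.numeric(cell))
    bad <- !is_missing & is.na(parsed)
    if (any(bad)) {
      stop(sprintf("unparseable cell in column '%s', row %d: '%s'",
                   col, which(bad)[1], cell[which(bad)[1]]))
    }
    parsed[is_missing] <- NA_real_
    if (any(!is.finite(parsed) & !is.na(parsed))) {
      stop("non-finite value in column '", col, "'")
    }
    out[[col]] <- parsed
  }
  out[[id_col]] <- ids
  rownames(out) <- NULL
  out
}

#' Write a cohort table to comma-separated text
#'
#' Inverse of [read_cohort()]: missing values are serialized as
#' `missing_token` and column order is preserved, so a written table re-reads
#' to an identical object (values round-trip losslessly at 15 significant
#' digits).
#'
#' @param table Cohort `data.frame`.
#' @param path Destination path.
#' @inheritParams read_cohort
#' @return Invisibly, `path`.
#' @export
write_cohort <- function(table, path, missing_token = "NA") {
  stopifnot(is.data.frame(table))
  out <- table
  for (col in names(out)) {
    if (is.numeric(out[[col]])) {
      out[[col]] <- ifelse(is.na(out[[col]]), missing_token,
                           formatC(out[[col]], digits = 15, format = "g"))
    }
  }
  ok <- tryCatch({
    utils::write.table(out, path, sep = ",", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write cohort table to ", path, ": ",
                        conditionMessage(ok))
  invisible(path)
}

#' Add a composite score column (mean of component z-scores)
#'
#' Composite reading accuracy and speed are defined as the arithmetic mean of
#' the text, word and nonword component z-scores; the memory composite is the
#' mean of forward and backward letter span. If any component is missing the
#' composite is missing -- complete-case selection is deferred to the model
#' fit, mirroring how a clinical database reduces to its complete-case
#' subsample.
#'
#' @param table Cohort `data.frame`.
#' @param name Name of the new composite column.
#' @param components Character vector of component column names (non-empty).
#' @return `table` with one added numeric column `name`.
#' @export
#' @examples
#' tab <- data.frame(child_id = "c1", a = -3, b = -2, c = -1)
#' composite_score(tab, "reading", c("a", "b", "c"))$reading  # -2
composite_score <- function(table, name, components) {
  stopifnot(is.data.frame(table), length(components) >= 1)
  unknown <- setdiff(components, names(table))
  if (length(unknown)) {
    stop("unknown component column(s): ", paste(unknown, collapse = ", "))
  }
  m <- as.matrix(table[, components, drop = FALSE])
  table[[name]] <- rowMeans(m)   # NA if any component NA, by design
  table
}

#' Screen candidate predictors by their correlation with reading
#'
#' A candidate predictor is retained only if its Pearson correlation with
#' both composite reading outcomes (accuracy and speed) is non-negative,
#' computed over pairwise-complete children. Within a declared group of
#' alternative measures for the same construct, only the measure maximizing
#' the summed correlation `r_accuracy + r_speed` is retained; exact ties are
#' reported unresolved (no member selected) so the analyst must choose
#' explicitly. Candidates with fewer than 3 pairwise-complete observations
#' against either outcome are flagged unevaluable.
#'
#' @param table Cohort `data.frame`.
#' @param candidates Character vector of candidate predictor columns.
#' @param acc_col,speed_col Names of the reading accuracy and speed columns.
#' @param groups Optional named list of character vectors; each element
#'   declares a set of alternative measures for one construct. Candidates not
#'   listed in any group form singleton groups.
#' @return A `data.frame` with one row per candidate: `candidate`,
#'   `r_accuracy`, `r_speed`, `selected`, `reason`.
#' @export
screen_predictors <- function(table, candidates, acc_col, speed_col,
                              groups = NULL) {
  stopifnot(is.data.frame(table), length(candidates) >= 1)
  missing_cols <- setdiff(c(candidates, acc_col, speed_col), names(table))
  if (length(missing_cols)) {
    stop("column(s) not in table: ", paste(missing_cols, collapse = ", "))
  }
  pair_cor <- function(x, y) {
    ok <- stats::complete.cases(x, y)
    if (sum(ok) < 3) return(NA_real_)
    stats::cor(x[ok], y[ok])
  }
  rep <- data.frame(candidate = candidates,
                    r_accuracy = NA_real_, r_speed = NA_real_,
                    selected = FALSE, reason = "",
                    stringsAsFactors = FALSE)
  for (i in seq_along(candidates)) {
    rep$r_accuracy[i] <- pair_cor(table[[candidates[i]]], table[[acc_col]])
    rep$r_speed[i] <- pair_cor(table[[candidates[i]]], table[[speed_col]])
  }
  unevaluable <- is.na(rep$r_accuracy) | is.na(rep$r_speed)
  negative <- !unevaluable & (rep$r_accuracy < 0 | rep$r_speed < 0)
  rep$selected <- !unevaluable & !negative
  rep$reason[unevaluable] <- "unevaluable: fewer than 3 pairwise-complete observations"
  rep$reason[negative] <- "negative correlation with a reading outcome"
  rep$reason[rep$selected] <- "non-negative correlations with both outcomes"

  # within each construct group keep only the maximizer of r_acc + r_speed
  grouped <- unlist(groups, use.names = FALSE)
  singletons <- setdiff(candidates, grouped)
  all_groups <- c(groups, as.list(singletons))
  for (g in all_groups) {
    idx <- match(intersect(g, candidates), rep$candidate)
    idx <- idx[rep$selected[idx]]
    if (length(idx) <= 1) next
    score <- rep$r_accuracy[idx] + rep$r_speed[idx]
    best <- which(score == max(score))
    if (length(best) > 1) {
      rep$selected[idx] <- FALSE
      rep$reason[idx] <- "tie within construct group: explicit choice required"
    } else {
      drop <- idx[-best]
      rep$selected[drop] <- FALSE
      rep$reason[drop] <- "dominated within construct group (smaller summed correlation)"
      rep$reason[idx[best]] <- "maximizes summed correlation within construct group"
    }
  }
  rep
}
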