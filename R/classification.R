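#' Predict a contrast from one row of similarity scores
#'
#' The predicted target is the comparable entry with the greatest absolute
#' score (scores ranked by |value| descending). Not-comparable (`NA`)
#' entries rank below every comparable entry; if every entry is
#' not-comparable the result is no-prediction (`NA_integer_`). Exact ties on
#' |value| break deterministically to the lowest column index, and a tie is
#' flagged via the `"tie"` attribute.
#'
#' @param scores numeric vector of similarity scores (`NA` = not comparable).
#' @return integer column index of the prediction, or `NA_integer_` for
#'   no-prediction; attribute `tie` is `TRUE` if the top |score| was tied.
#' @export
predict_contrast <- function(scores) {
  stopifnot(length(scores) >= 1L)
  a <- abs(scores)
  if (all(is.na(a))) return(structure(NA_integer_, tie = FALSE))
  top <- max(a, na.rm = TRUE)
  hits <- which(!is.na(a) & a == top)
  structure(hits[1L], tie = length(hits) > 1L)
}

#' Evaluate one subsample's score matrix
#'
#' Rows are query contrasts (group A, unthresholded), columns are target
#' contrasts (group B). A row is correct when its predicted column matches
#' its own contrast; no-prediction rows count as incorrect.
#'
#' @param score_matrix square numeric matrix with identical, consistently
#'   ordered row and column contrast labels (`NA` = not comparable).
#' @return list with `predicted` (integer vector, `NA` = no prediction),
#'   `correct` (logical vector named by contrast), and `accuracy` (mean of
#'   `correct`).
#' @export
evaluate_subsample <- function(score_matrix) {
  stopifnot(is.matrix(score_matrix), nrow(score_matrix) == ncol(score_matrix))
  if (!is.null(rownames(score_matrix)) &&
      !identical(rownames(score_matrix), colnames(score_matrix)))
    stop("row and column contrast labels must match")
  n <- nrow(score_matrix)
  predicted <- vapply(seq_len(n),
                      function(i) as.integer(predict_contrast(score_matrix[i, ])),
                      integer(1))
  correct <- !is.na(predicted) & predicted == seq_len(n)
  names(correct) <- rownames(score_matrix)
  list(predicted = predicted, correct = correct, accuracy = mean(correct))
}

#' Aggregate accuracy across subsamples
#'
#' Pools per-subsample classification results for one analysis condition
#' into an overall mean accuracy with a 95% normal-approximation interval
#' (`mean +/- 1.96 * sd / sqrt(n_subsamples)`), per-contrast mean/sd of the
#' correctness indicators, and a confusion matrix of counts (true contrast
#' by predicted contrast, with a final `"<none>"` column for no-prediction
#' rows so that every row sums to `n_subsamples`).
#'
#' @param correct logical matrix, contrasts x subsamples.
#' @param predicted integer matrix, contrasts x subsamples (`NA` = none).
#' @param contrast_ids character vector of contrast labels (row order).
#' @param condition optional named list describing the analysis condition
#'   (threshold, direction, strategy, metric); carried on the outputs.
#' @return list with `summary` (class `accuracy_summary`) and `confusion`
#'   (class `confusion_matrix`).
#' @export
aggregate_results <- function(correct, predicted, contrast_ids,
                              condition = list()) {
  stopifnot(is.matrix(correct), is.matrix(predicted),
            identical(dim(correct), dim(predicted)),
            nrow(correct) == length(contrast_ids))
  n_sub <- ncol(correct)
  acc <- colMeans(correct)
  overall <- mean(acc)
  if (n_sub >= 2L) {
    s <- stats::sd(acc)
    half <- 1.96 * s / sqrt(n_sub)
    ci <- c(overall - half, overall + half)
  } else {
    warning("single subsample: interval is degenerate")
    s <- NA_real_
    ci <- c(overall, overall)
  }
  per_contrast <- data.frame(
    contrast_id = contrast_ids,
    mean = rowMeans(correct),
    sd = apply(correct, 1L, stats::sd),
    stringsAsFactors = FALSE)

  n_c <- length(contrast_ids)
  conf <- matrix(0L, nrow = n_c, ncol = n_c + 1L,
                 dimnames = list(contrast_ids, c(contrast_ids, "<none>")))
  for (s_i in seq_len(n_sub)) {
    p <- predicted[, s_i]
    p[is.na(p)] <- n_c + 1L
    for (i in seq_len(n_c)) conf[i, p[i]] <- conf[i, p[i]] + 1L
  }

  summary <- structure(
    list(condition = condition, overall_mean = overall, sd = s,
         ci_low = ci[1L], ci_high = ci[2L], n_subsamples = n_sub,
         per_contrast = per_contrast),
    class = "accuracy_summary")
  confusion <- structure(conf, condition = condition,
                         class = c("confusion_matrix", "matrix", "array"))
  list(summary = summary, confusion = confusion)
}

#' @export
print.accuracy_summary <- function(x, ...) {
  cond <- if (length(x$condition))
    paste0(" [", paste(names(x$condition), unlist(x$condition),
                       sep = "=", collapse = ", "), "]") else ""
  cat(sprintf("<accuracy_summary>%s mean accuracy %.3f (95%% CI %.3f-%.3f) over %d subsamples\n",
              cond, x$overall_mean, x$ci_low, x$ci_high, x$n_subsamples))
  invisible(x)
}
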