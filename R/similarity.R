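#' Build the paired comparison vectors for two maps
#'
#' Assembles the voxel vectors that a similarity metric will see, under one
#' of two empty-voxel strategies:
#'
#' * `"cca"` (complete case analysis): the comparison set is the
#'   intersection of voxels that are non-empty, finite and non-zero in
#'   *both* maps, inside the mask.
#' * `"svi"` (single-value imputation): the comparison universe is the whole
#'   brain mask; empty/`NA` values are replaced with 0 in both vectors.
#'
#' Under `direction = "positive"` the positive-only filter is applied to
#' *both* images before set construction — including the unthresholded
#' query, whose negatives and zeros become empty. Directionality is treated
#' as a property of the analysis, not of a single image (see the methods
#' vignette for discussion of this choice).
#'
#' @param mapA the query `zstat_map` (unthresholded).
#' @param mapB the target `zstat_map` (possibly thresholded).
#' @param strategy `"cca"` or `"svi"`.
#' @param mask a [brain_mask()].
#' @param direction `"both"` or `"positive"`.
#' @return list with numeric vectors `x` (query), `y` (target), their common
#'   length `n`, and `index` (linear voxel indices used).
#' @export
build_comparison_set <- function(mapA, mapB, strategy = c("cca", "svi"),
                                 mask, direction = c("both", "positive")) {
  strategy <- match.arg(strategy)
  direction <- match.arg(direction)
  stopifnot(inherits(mapA, "zstat_map"), inherits(mapB, "zstat_map"),
            inherits(mask, "brain_mask"))
  check_same_grid(mapA$volume, mapB$volume, "query and target")
  check_same_grid(mapA$volume, mask$volume, "maps and mask")
  idx <- which(mask$volume)
  x <- mapA$volume[idx]
  y <- mapB$volume[idx]
  if (direction == "positive") {
    x[!is.na(x) & x <= 0] <- NA_real_
    y[!is.na(y) & y <= 0] <- NA_real_
  }
  if (strategy == "cca") {
    keep <- !is.na(x) & !is.na(y) & is.finite(x) & is.finite(y) & x != 0 & y != 0
    list(x = x[keep], y = y[keep], n = sum(keep), index = idx[keep])
  } else {
    x[!is.finite(x)] <- 0
    y[!is.finite(y)] <- 0
    list(x = x, y = y, n = length(idx), index = idx)
  }
}

#' Pearson correlation with degenerate-input policy
#'
#' Sample product-moment correlation of two equal-length vectors. Returns
#' `NA` (not comparable) when fewer than 3 paired values are available or
#' when either vector has zero variance, rather than erroring — a full
#' query-by-target sweep must keep its shape even when individual pairs
#' cannot be scored.
#'
#' @param x,y numeric vectors of equal length.
#' @return correlation in `[-1, 1]`, or `NA` if not comparable.
#' @export
pearson_score <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3L) return(NA_real_)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y, method = "pearson")
}

#' Spearman rank correlation with degenerate-input policy
#'
#' Pearson correlation of average ranks (ties receive average ranks). Same
#' not-comparable policy as [pearson_score()].
#'
#' @inheritParams pearson_score
#' @return correlation in `[-1, 1]`, or `NA` if not comparable.
#' @export
spearman_score <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3L) return(NA_real_)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y, method = "spearman")
}

# Shared scoring core used by compare_maps() and the pipeline's matrix
# sweep: takes pre-masked (and direction-filtered, for the query) vectors.
score_pair <- function(x, y, strategy, metric) {
  if (strategy == "cca") {
    keep <- !is.na(x) & !is.na(y) & is.finite(x) & is.finite(y) & x != 0 & y != 0
    x <- x[keep]; y <- y[keep]
  } else {
    x[!is.finite(x)] <- 0
    y[!is.finite(y)] <- 0
  }
  value <- if (metric == "pearson") pearson_score(x, y) else spearman_score(x, y)
  list(value = value, n = length(x))
}

#' Compare two statistical maps
#'
#' Scores the similarity of an unthresholded query map against a (possibly
#' thresholded) target map under a given empty-voxel strategy, metric and
#' directionality. Returns a not-comparable score (`NA`) when no voxels
#' survive thresholding, no overlapping finite values exist, or fewer than
#' three voxels remain to compute a score from.
#'
#' @param mapA query `zstat_map`; must be unthresholded.
#' @param mapB target `zstat_map`.
#' @param strategy `"cca"` or `"svi"`.
#' @param metric `"pearson"` or `"spearman"`.
#' @param mask a [brain_mask()].
#' @param direction `"both"` or `"positive"`.
#' @return object of class `similarity_score` with fields `value` (`NA` when
#'   not comparable), `metric`, `strategy`, `direction`, `n_voxels`,
#'   `query_contrast`, `target_contrast`.
#' @export
compare_maps <- function(mapA, mapB, strategy = c("cca", "svi"),
                         metric = c("pearson", "spearman"),
                         mask, direction = c("both", "positive")) {
  strategy <- match.arg(strategy)
  metric <- match.arg(metric)
  direction <- match.arg(direction)
  if (!is.null(mapA$threshold) &&
      !(mapA$threshold$level == 0 && mapA$threshold$direction == "both"))
    stop("query map must be unthresholded")
  set <- build_comparison_set(mapA, mapB, strategy, mask, direction)
  value <- if (metric == "pearson") pearson_score(set$x, set$y)
           else spearman_score(set$x, set$y)
  structure(list(value = value, metric = metric, strategy = strategy,
                 direction = direction, n_voxels = set$n,
                 query_contrast = mapA$contrast_id,
                 target_contrast = mapB$contrast_id),
            class = "similarity_score")
}

#' @export
print.similarity_score <- function(x, ...) {
  val <- if (is.na(x$value)) "not comparable" else sprintf("%.4f", x$value)
  cat(sprintf("<similarity_score> %s vs %s: %s (%s/%s/%s, %d voxels)\n",
              x$query_contrast, x$target_contrast, val,
              x$metric, x$strategy, x$direction, x$n_voxels))
  invisible(x)
}
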