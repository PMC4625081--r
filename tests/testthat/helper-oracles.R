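# Independent oracles and small fixtures, implemented without touching the
# code paths they check.

# Pearson correlation by the direct sum formula.
pearson_bf <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  num <- sum((x - mx) * (y - my))
  den <- sqrt(sum((x - mx)^2)) * sqrt(sum((y - my)^2))
  num / den
}

# Average ranks assigned by explicit counting (ties get the mean of the
# positions they would occupy).
avg_ranks_bf <- function(v) {
  vapply(seq_along(v), function(i)
    sum(v < v[i]) + (sum(v == v[i]) + 1) / 2, numeric(1))
}

spearman_bf <- function(x, y) pearson_bf(avg_ranks_bf(x), avg_ranks_bf(y))

# Naive linear-probability-space t -> Z (unstable in far tails; used only
# where it is numerically safe).
naive_z <- function(t, df) stats::qnorm(stats::pt(t, df))

# One-sample t by direct arithmetic.
t_bf <- function(x) {
  n <- length(x)
  m <- sum(x) / n
  s <- sqrt(sum((x - m)^2) / (n - 1))
  m / (s / sqrt(n))
}

# A zstat_map filled with given values (recycled) over the whole grid.
toy_zmap <- function(values, dims = NULL, contrast_id = "c1", group = "A") {
  if (is.null(dims)) dims <- c(length(values), 1L, 1L)
  threshsim:::zstat_map(array(values, dim = dims), contrast_id, group)
}

full_mask <- function(dims) brain_mask(array(TRUE, dim = dims))

# Small but placeable cohort configuration for fast end-to-end tests.
small_cohort_config <- function(...) {
  cohort_config(n_subjects = 8, n_families = 4, n_tasks = 2,
                contrasts_per_task = 2, grid_shape = c(16L, 16L, 16L),
                group_size = 2, ...)
}

# Random unthresholded zstat maps on a shared grid (for property tests).
random_zmap <- function(dims, mask = NULL, sd = 2) {
  vol <- array(stats::rnorm(prod(dims), sd = sd), dim = dims)
  if (!is.null(mask)) vol[!mask$volume] <- NA_real_
  threshsim:::zstat_map(vol, "rnd", "A")
}
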