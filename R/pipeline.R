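#' Experiment configuration
#'
#' Describes a full thresholding-vs-classification experiment: the synthetic
#' cohort, the threshold sweep, the directionalities, empty-voxel strategies
#' and similarity metrics to cross, and the number of repeated group
#' subsamples.
#'
#' Defaults give the package's desk-scale study (see the methods vignette):
#' thresholds Z = 0..6 in steps of 1, both directionalities, CCA and SVI,
#' Pearson and Spearman, 20 subsamples. The original large-cohort design
#' (47 contrasts, thresholds 0..13, 500 subsamples) is accepted by the same
#' configuration surface.
#'
#' @param cohort a [cohort_config()].
#' @param thresholds numeric vector of Z threshold levels, all `>= 0`.
#' @param directions subset of `c("both", "positive")`.
#' @param strategies subset of `c("cca", "svi")`.
#' @param metrics subset of `c("pearson", "spearman")`.
#' @param n_subsamples number of independent group-pair draws, `>= 1`.
#' @param out_dir optional output directory for CSV/JSON result files.
#' @param seed master seed; every random stage derives its own substream
#'   from it via [substream_seed()].
#' @param store_scores keep (and write) the long-format pairwise score table.
#' @param log_level `"quiet"`, `"info"` or `"debug"`.
#' @return object of class `experiment_config`.
#' @export
experiment_config <- function(cohort = cohort_config(),
                              thresholds = 0:6,
                              directions = c("both", "positive"),
                              strategies = c("cca", "svi"),
                              metrics = c("pearson", "spearman"),
                              n_subsamples = 20,
                              out_dir = NULL,
                              seed = 1L,
                              store_scores = TRUE,
                              log_level = "info") {
  cfg <- structure(list(cohort = cohort,
                        thresholds = as.numeric(thresholds),
                        directions = directions,
                        strategies = strategies,
                        metrics = metrics,
                        n_subsamples = as.integer(n_subsamples),
                        out_dir = out_dir,
                        seed = as.integer(seed),
                        store_scores = isTRUE(store_scores),
                        log_level = log_level),
                   class = "experiment_config")
  validate_experiment_config(cfg)
  cfg
}

validate_experiment_config <- function(cfg) {
  stopifnot(inherits(cfg$cohort, "cohort_config"))
  if (length(cfg$thresholds) == 0L || any(cfg$thresholds < 0))
    stop("thresholds must be a nonempty vector of levels >= 0")
  if (length(cfg$directions) == 0L ||
      !all(cfg$directions %in% c("both", "positive")))
    stop("directions must be a nonempty subset of {both, positive}")
  if (length(cfg$strategies) == 0L || !all(cfg$strategies %in% c("cca", "svi")))
    stop("strategies must be a nonempty subset of {cca, svi}")
  if (length(cfg$metrics) == 0L ||
      !all(cfg$metrics %in% c("pearson", "spearman")))
    stop("metrics must be a nonempty subset of {pearson, spearman}")
  if (cfg$n_subsamples < 1L) stop("n_subsamples must be >= 1")
  if (!cfg$log_level %in% c("quiet", "info", "debug"))
    stop("log_level must be quiet, info or debug")
  invisible(cfg)
}

#' Read an experiment configuration from YAML
#'
#' Strict parse: unknown keys (top-level or inside `cohort:`) are errors, so
#' typos fail loudly instead of silently running defaults.
#'
#' @param path YAML file path.
#' @param seed optional seed overriding the file's `seed:` entry.
#' @param out_dir optional output directory overriding the file's entry.
#' @return an [experiment_config()].
#' @export
read_experiment_config <- function(path, seed = NULL, out_dir = NULL) {
  raw <- yaml::read_yaml(path)
  top_known <- c("cohort", "thresholds", "directions", "strategies", "metrics",
                 "n_subsamples", "out_dir", "seed", "store_scores", "log_level")
  unknown <- setdiff(names(raw), top_known)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  co_raw <- raw$cohort %||% list()
  co_known <- names(formals(cohort_config))
  unknown <- setdiff(names(co_raw), co_known)
  if (length(unknown))
    stop("unknown cohort config keys: ", paste(unknown, collapse = ", "))
  cohort <- do.call(cohort_config, co_raw)
  args <- raw[setdiff(names(raw), "cohort")]
  args$cohort <- cohort
  if (!is.null(seed)) args$seed <- seed
  if (!is.null(out_dir)) args$out_dir <- out_dir
  do.call(experiment_config, args)
}

# Threshold a masked Z vector (same semantics as apply_threshold()).
threshold_masked <- function(y, level, direction) {
  if (direction == "both") {
    if (level > 0) y[!is.na(y) & y <= level & y >= -level] <- NA_real_
  } else {
    y[!is.na(y) & y <= level] <- NA_real_
  }
  y
}

condition_key <- function(threshold, direction, strategy, metric) {
  sprintf("T%g_%s_%s_%s", threshold, direction, strategy, metric)
}

exp_log <- function(cfg, level, ...) {
  lv <- c(quiet = 0L, info = 1L, debug = 2L)
  if (lv[[cfg$log_level]] >= lv[[level]])
    message(sprintf("[threshsim] %s", sprintf(...)))
}

#' Run the full thresholding experiment
#'
#' Orchestrates every stage: simulate the cohort, then for each subsample
#' draw two family-disjoint groups, build each group's one-sample-t Z maps
#' for every contrast, sweep the (threshold, direction, strategy, metric)
#' grid scoring every unthresholded group-A map against every thresholded
#' group-B map, classify each query by maximum absolute score, and finally
#' aggregate accuracies, intervals and confusion matrices per condition.
#'
#' Group Z maps are computed once per subsample and thresholded lazily per
#' condition. All randomness derives from `config$seed` through fixed
#' substreams, so reruns with the same configuration and seed reproduce
#' identical numeric output.
#'
#' @param config an [experiment_config()].
#' @return (invisibly) a list with elements `accuracy` (data.frame, one row
#'   per condition), `per_contrast` (data.frame), `confusion` (named list of
#'   confusion matrices), `summaries` (named list of `accuracy_summary`),
#'   `scores` (long data.frame or `NULL`), `contrast_ids`, `max_abs_z`, and
#'   `manifest`. When `config$out_dir` is set the same results are written
#'   as CSV/JSON files.
#' @export
run_experiment <- function(config) {
  validate_experiment_config(config)
  t_start <- Sys.time()
  seed <- config$seed

  # cohort generation is re-seeded from the experiment master seed so that
  # `--seed` alone controls the whole run
  co <- config$cohort
  co$seed <- substream_seed(seed, 0L)

  exp_log(config, "info", "building %d-task contrast battery",
          co$n_tasks)
  specs <- build_contrast_specs(co)
  contrast_ids <- vapply(specs, `[[`, "", "contrast_id")
  n_c <- length(contrast_ids)
  records <- make_subject_records(co$n_subjects, co$n_families)
  exp_log(config, "info", "simulating %d subjects x %d contrasts",
          co$n_subjects, n_c)
  cohort <- simulate_subject_maps(specs, records, co)
  mask <- cohort$mask
  mask_idx <- which(mask$volume)

  conditions <- expand.grid(threshold = config$thresholds,
                            direction = config$directions,
                            strategy = config$strategies,
                            metric = config$metrics,
                            stringsAsFactors = FALSE,
                            KEEP.OUT.ATTRS = FALSE)
  keys <- with(conditions, condition_key(threshold, direction, strategy, metric))
  n_sub <- config$n_subsamples

  correct <- lapply(keys, function(k)
    matrix(NA, nrow = n_c, ncol = n_sub, dimnames = list(contrast_ids, NULL)))
  predicted <- lapply(keys, function(k)
    matrix(NA_integer_, nrow = n_c, ncol = n_sub,
           dimnames = list(contrast_ids, NULL)))
  names(correct) <- names(predicted) <- keys
  score_rows <- if (config$store_scores) vector("list", n_sub * nrow(conditions))
  score_i <- 0L
  max_abs_z <- 0

  group_z <- function(ids, label) {
    z <- matrix(NA_real_, nrow = length(mask_idx), ncol = n_c,
                dimnames = list(NULL, contrast_ids))
    for (cid in contrast_ids) {
      tm <- one_sample_t(cohort$data[[cid]][, ids, drop = FALSE], mask,
                         contrast_id = cid, group_label = label)
      zm <- t_to_z(tm)
      z[, cid] <- zm$volume[mask_idx]
    }
    z
  }

  for (s in seq_len(n_sub)) {
    groups <- draw_groups_with_retry(records, co$group_size, seed, s)
    zA <- group_z(groups$ids_A, "A")
    zB <- group_z(groups$ids_B, "B")
    max_abs_z <- max(max_abs_z, abs(zA), abs(zB), na.rm = TRUE)

    for (dir in config$directions) {
      qA <- zA
      if (dir == "positive") qA[!is.na(qA) & qA <= 0] <- NA_real_
      for (th in config$thresholds) {
        tB <- zB
        tB[] <- apply(zB, 2L, threshold_masked, level = th, direction = dir)
        for (strat in config$strategies) for (met in config$metrics) {
          key <- condition_key(th, dir, strat, met)
          sm <- matrix(NA_real_, n_c, n_c,
                       dimnames = list(contrast_ids, contrast_ids))
          nv <- matrix(0L, n_c, n_c)
          for (i in seq_len(n_c)) for (j in seq_len(n_c)) {
            sc <- score_pair(qA[, i], tB[, j], strat, met)
            sm[i, j] <- sc$value
            nv[i, j] <- sc$n
          }
          ev <- evaluate_subsample(sm)
          correct[[key]][, s] <- ev$correct
          predicted[[key]][, s] <- ev$predicted
          if (config$store_scores) {
            score_i <- score_i + 1L
            score_rows[[score_i]] <- data.frame(
              subsample = s, threshold = th, direction = dir,
              strategy = strat, metric = met,
              query_contrast = rep(contrast_ids, times = n_c),
              target_contrast = rep(contrast_ids, each = n_c),
              score = as.vector(sm), n_voxels = as.vector(nv),
              stringsAsFactors = FALSE)
          }
        }
      }
    }
    exp_log(config, "info", "subsample %d/%d done", s, n_sub)
  }

  summaries <- vector("list", length(keys))
  confusion <- vector("list", length(keys))
  names(summaries) <- names(confusion) <- keys
  acc_rows <- pc_rows <- vector("list", length(keys))
  for (k in seq_along(keys)) {
    cond <- as.list(conditions[k, ])
    agg <- aggregate_results(correct[[keys[k]]] == 1 | correct[[keys[k]]] == TRUE,
                             predicted[[keys[k]]], contrast_ids, cond)
    summaries[[k]] <- agg$summary
    confusion[[k]] <- agg$confusion
    acc_rows[[k]] <- data.frame(
      threshold = cond$threshold, direction = cond$direction,
      strategy = cond$strategy, metric = cond$metric,
      mean_accuracy = agg$summary$overall_mean, sd = agg$summary$sd,
      ci_low = agg$summary$ci_low, ci_high = agg$summary$ci_high,
      n_subsamples = agg$summary$n_subsamples, stringsAsFactors = FALSE)
    pc_rows[[k]] <- cbind(acc_rows[[k]][rep(1L, n_c),
                                        c("threshold", "direction", "strategy", "metric")],
                          agg$summary$per_contrast, row.names = NULL)
  }
  accuracy <- do.call(rbind, acc_rows)
  per_contrast <- do.call(rbind, pc_rows)
  scores <- if (config$store_scores) do.call(rbind, score_rows[seq_len(score_i)])

  manifest <- list(
    package = "threshsim",
    version = as.character(utils::packageVersion("threshsim")),
    seed = seed,
    n_subsamples = n_sub,
    n_contrasts = n_c,
    contrast_ids = contrast_ids,
    thresholds = config$thresholds,
    directions = config$directions,
    strategies = config$strategies,
    metrics = config$metrics,
    cohort = unclass(co),
    max_abs_z = max_abs_z,
    started = format(t_start, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    complete = TRUE)

  result <- list(accuracy = accuracy, per_contrast = per_contrast,
                 confusion = confusion, summaries = summaries,
                 scores = scores, contrast_ids = contrast_ids,
                 max_abs_z = max_abs_z, config = config, manifest = manifest)

  if (!is.null(config$out_dir)) write_experiment_outputs(result, config$out_dir)
  invisible(result)
}

# Redraw the two groups with fresh substreams if a draw is infeasible
# (possible in principle for tiny cohorts with large families).
draw_groups_with_retry <- function(records, group_size, seed, s,
                                   max_retries = 5L) {
  for (r in 0:(max_retries - 1L)) {
    g <- tryCatch(
      with_seed(substream_seed(seed, 10L + 8L * s + r),
                sample_unrelated_groups(records, group_size)),
      threshsim_sampling_infeasible = function(e) NULL)
    if (!is.null(g)) return(g)
  }
  stop("group subsampling failed repeatedly: cohort has too few unrelated subjects")
}

write_experiment_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(result$accuracy, file.path(out_dir, "accuracy.csv"),
                   row.names = FALSE)
  utils::write.csv(result$per_contrast,
                   file.path(out_dir, "accuracy_per_contrast.csv"),
                   row.names = FALSE)
  conf_dir <- file.path(out_dir, "confusion")
  dir.create(conf_dir, showWarnings = FALSE)
  for (k in names(result$confusion)) {
    m <- result$confusion[[k]]
    df <- data.frame(true_contrast = rownames(m),
                     as.data.frame(unclass(m)[, , drop = FALSE]),
                     check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.csv(df, file.path(conf_dir, paste0("confusion_", k, ".csv")),
                     row.names = FALSE)
  }
  if (!is.null(result$scores))
    utils::write.csv(result$scores, file.path(out_dir, "scores.csv"),
                     row.names = FALSE)
  summary_json <- list(
    accuracy = result$accuracy,
    per_contrast = result$per_contrast,
    max_abs_z = result$max_abs_z)
  jsonlite::write_json(summary_json, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  jsonlite::write_json(result$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Re-evaluate classification from a long score table
#'
#' Rebuilds per-condition, per-subsample score matrices from the long-format
#' pairwise score table (as written to `scores.csv`) and recomputes
#' accuracies and confusion matrices. This is the resumable `evaluate`
#' stage: it must agree exactly with the in-memory evaluation of
#' [run_experiment()].
#'
#' @param scores data.frame with columns `subsample`, `threshold`,
#'   `direction`, `strategy`, `metric`, `query_contrast`, `target_contrast`,
#'   `score` (and optionally `n_voxels`).
#' @return list of `accuracy` / `per_contrast` data.frames and `confusion`
#'   list, as in [run_experiment()].
#' @export
evaluate_scores <- function(scores) {
  need <- c("subsample", "threshold", "direction", "strategy", "metric",
            "query_contrast", "target_contrast", "score")
  if (!all(need %in% names(scores)))
    stop("scores table must have columns: ", paste(need, collapse = ", "))
  contrast_ids <- sort(unique(scores$query_contrast))
  n_c <- length(contrast_ids)
  conditions <- unique(scores[, c("threshold", "direction", "strategy", "metric")])
  rownames(conditions) <- NULL
  subs <- sort(unique(scores$subsample))

  acc_rows <- pc_rows <- vector("list", nrow(conditions))
  confusion <- list()
  for (k in seq_len(nrow(conditions))) {
    cond <- as.list(conditions[k, ])
    sel <- scores$threshold == cond$threshold &
      scores$direction == cond$direction &
      scores$strategy == cond$strategy &
      scores$metric == cond$metric
    sc <- scores[sel, , drop = FALSE]
    correct <- matrix(NA, n_c, length(subs), dimnames = list(contrast_ids, NULL))
    predicted <- matrix(NA_integer_, n_c, length(subs),
                        dimnames = list(contrast_ids, NULL))
    for (si in seq_along(subs)) {
      ss <- sc[sc$subsample == subs[si], , drop = FALSE]
      m <- matrix(NA_real_, n_c, n_c, dimnames = list(contrast_ids, contrast_ids))
      m[cbind(match(ss$query_contrast, contrast_ids),
              match(ss$target_contrast, contrast_ids))] <- ss$score
      ev <- evaluate_subsample(m)
      correct[, si] <- ev$correct
      predicted[, si] <- ev$predicted
    }
    agg <- aggregate_results(correct == TRUE, predicted, contrast_ids, cond)
    key <- condition_key(cond$threshold, cond$direction, cond$strategy, cond$metric)
    confusion[[key]] <- agg$confusion
    acc_rows[[k]] <- data.frame(
      threshold = cond$threshold, direction = cond$direction,
      strategy = cond$strategy, metric = cond$metric,
      mean_accuracy = agg$summary$overall_mean, sd = agg$summary$sd,
      ci_low = agg$summary$ci_low, ci_high = agg$summary$ci_high,
      n_subsamples = agg$summary$n_subsamples, stringsAsFactors = FALSE)
    pc_rows[[k]] <- cbind(acc_rows[[k]][rep(1L, n_c),
                                        c("threshold", "direction", "strategy", "metric")],
                          agg$summary$per_contrast, row.names = NULL)
  }
  list(accuracy = do.call(rbind, acc_rows),
       per_contrast = do.call(rbind, pc_rows),
       confusion = confusion)
}
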