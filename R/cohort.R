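#' Cohort simulation configuration
#'
#' Bundles every knob of the synthetic cohort generator: cohort size and
#' family structure, the contrast battery layout, grid geometry, and the
#' variance components of the generative model for subject-level effect maps.
#'
#' The generative model for subject s, family f(s), contrast c at voxel v is
#'
#'   y(s, c, v) = A * template_c(v) + F_{f(s),c}(v) + E_{s,c}(v) + B(v)
#'
#' where `A = effect_amplitude`, `F` is a smooth family-level field drawn once
#' per family per contrast (sd `family_noise_sd`), `E` is smooth subject-level
#' noise (sd `subject_noise_sd`), and `B` is a weak smooth background field
#' drawn once per cohort and shared by every subject and contrast
#' (sd `background_shared_sd`). The shared background gives statistically
#' unrelated contrasts a faint common structure, so that near-zero voxels act
#' as correlated "noise" between otherwise independent maps, as they do in
#' real group statistical maps. All noise fields are Gaussian white noise
#' smoothed to `smoothing_fwhm_vox` voxels FWHM.
#'
#' Defaults describe the package's desk-scale study: 12 contrasts over 4
#' tasks on a 24^3 grid, 48 subjects in 24 families of two, and group size
#' 12, with an amplitude chosen so that group-level peak |Z| lands around
#' 4-5 at n = 12 (see the methods vignette).
#'
#' @param n_subjects number of subjects in the cohort.
#' @param n_families number of families; subjects are assigned round-robin.
#' @param n_tasks number of tasks.
#' @param contrasts_per_task scalar or length-`n_tasks` vector of contrast
#'   counts per task.
#' @param grid_shape integer vector of 3 grid dimensions.
#' @param effect_amplitude scale applied to each contrast's signal template
#'   (arbitrary effect units).
#' @param subject_noise_sd sd of the smooth per-subject noise field.
#' @param family_noise_sd sd of the smooth per-family shared field.
#' @param smoothing_fwhm_vox FWHM of the Gaussian smoother, in voxels.
#' @param background_shared_sd sd of the contrast-independent shared
#'   background field.
#' @param group_size subjects per group in the two-group subsampling.
#' @param overlap_frac minimum fraction of nonzero template support that two
#'   contrasts in one overlap group must share.
#' @param n_overlap_pairs number of engineered overlapping contrast pairs
#'   (at most one per task with >= 2 contrasts); default one per eligible
#'   task.
#' @param seed integer seed controlling template and map generation.
#' @return an object of class `cohort_config` (a validated list).
#' @export
cohort_config <- function(n_subjects = 48,
                          n_families = 24,
                          n_tasks = 4,
                          contrasts_per_task = 3,
                          grid_shape = c(24L, 24L, 24L),
                          effect_amplitude = 0.85,
                          subject_noise_sd = 0.4,
                          family_noise_sd = 0.15,
                          smoothing_fwhm_vox = 3,
                          background_shared_sd = 0.05,
                          group_size = 12,
                          overlap_frac = 0.5,
                          n_overlap_pairs = NULL,
                          seed = 1L) {
  cfg <- list(n_subjects = as.integer(n_subjects),
              n_families = as.integer(n_families),
              n_tasks = as.integer(n_tasks),
              contrasts_per_task = as.integer(contrasts_per_task),
              grid_shape = as.integer(grid_shape),
              effect_amplitude = effect_amplitude,
              subject_noise_sd = subject_noise_sd,
              family_noise_sd = family_noise_sd,
              smoothing_fwhm_vox = smoothing_fwhm_vox,
              background_shared_sd = background_shared_sd,
              group_size = as.integer(group_size),
              overlap_frac = overlap_frac,
              n_overlap_pairs = if (is.null(n_overlap_pairs)) NULL else as.integer(n_overlap_pairs),
              seed = as.integer(seed))
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  stopifnot(cfg$n_subjects >= 1, cfg$n_families >= 1, cfg$n_tasks >= 1)
  if (cfg$n_families > cfg$n_subjects)
    stop("n_families must not exceed n_subjects")
  if (2L * cfg$group_size > cfg$n_subjects)
    stop("need group_size * 2 <= n_subjects to draw two disjoint groups")
  if (!(length(cfg$contrasts_per_task) %in% c(1L, cfg$n_tasks)))
    stop("contrasts_per_task must be scalar or one value per task")
  if (any(cfg$contrasts_per_task < 1)) stop("contrasts_per_task must be >= 1")
  if (length(cfg$grid_shape) != 3L || any(cfg$grid_shape < 3))
    stop("grid_shape must be 3 dimensions, each >= 3")
  sds <- c(cfg$subject_noise_sd, cfg$family_noise_sd, cfg$background_shared_sd)
  if (any(sds < 0)) stop("noise sds must be >= 0")
  if (cfg$smoothing_fwhm_vox < 0) stop("smoothing_fwhm_vox must be >= 0")
  if (cfg$overlap_frac < 0 || cfg$overlap_frac > 1)
    stop("overlap_frac must be in [0, 1]")
  invisible(cfg)
}

#' @export
print.cohort_config <- function(x, ...) {
  cpt <- rep_len(x$contrasts_per_task, x$n_tasks)
  cat(sprintf(paste0("<cohort_config> %d subjects / %d families, %d tasks ",
                     "(%d contrasts), grid %s, group size %d, seed %d\n"),
              x$n_subjects, x$n_families, x$n_tasks, sum(cpt),
              paste(x$grid_shape, collapse = "x"), x$group_size, x$seed))
  invisible(x)
}

#' Subject metadata table
#'
#' Builds the subject table (one row per subject, with a family identifier)
#' used by the family-constrained group subsampling. Families are assigned
#' round-robin so family sizes differ by at most one.
#'
#' @param n_subjects,n_families counts, `n_families <= n_subjects`.
#' @return data.frame with columns `subject_id`, `family_id`.
#' @export
make_subject_records <- function(n_subjects, n_families) {
  stopifnot(n_families >= 1, n_families <= n_subjects)
  data.frame(
    subject_id = sprintf("sub%04d", seq_len(n_subjects)),
    family_id = sprintf("fam%03d", rep_len(seq_len(n_families), n_subjects)),
    stringsAsFactors = FALSE)
}

# ---- contrast templates ----------------------------------------------------

# A template is a sum of smooth positive and negative Gaussian blobs.
# Internal layout constants (not config): 5 positive + 4 negative blobs,
# blob sigma scaled to the grid, centers kept apart so peaks do not stack
# (stacked peaks would push group |Z| far beyond the intended range).
TEMPLATE_N_POS <- 5L
TEMPLATE_N_NEG <- 4L

template_geometry <- function(grid_shape) {
  sigma <- max(1.5, min(grid_shape) / 10)
  list(sigma = sigma,
       min_sep = 2.2 * sigma,
       center_frac = 0.63) # centers restricted to this ellipsoid fraction
}

gaussian_blob <- function(grid_shape, center, sigma, amplitude) {
  ax <- lapply(1:3, function(d) exp(-((seq_len(grid_shape[d]) - center[d])^2) /
                                      (2 * sigma^2)))
  amplitude * (ax[[1L]] %o% ax[[2L]] %o% ax[[3L]])
}

# Rejection-sample `n` blob centers inside the central ellipsoid, pairwise
# at least `min_sep` apart from each other and from `fixed` centers.
place_blob_centers <- function(n, grid_shape, geom, fixed = NULL,
                               max_attempts = 500L) {
  ctr <- (grid_shape + 1) / 2
  semi <- geom$center_frac * grid_shape / 2
  centers <- fixed
  placed <- list()
  for (i in seq_len(n)) {
    ok <- FALSE
    for (a in seq_len(max_attempts)) {
      u <- stats::runif(3, -1, 1)
      if (sum(u^2) > 1) next
      cand <- ctr + u * semi
      if (length(centers) == 0L ||
          all(vapply(centers, function(p) sqrt(sum((p - cand)^2)), 0) >= geom$min_sep)) {
        ok <- TRUE
        break
      }
    }
    if (!ok)
      stop("grid too small to place requested blobs: increase grid_shape ",
           "or reduce the number of contrasts")
    centers <- c(centers, list(cand))
    placed <- c(placed, list(cand))
  }
  placed
}

blob_sum <- function(blobs, grid_shape, sigma) {
  vol <- array(0, dim = grid_shape)
  for (b in blobs)
    vol <- vol + gaussian_blob(grid_shape, b$center, sigma, b$amplitude)
  vol
}

template_support <- function(template) {
  m <- max(abs(template))
  if (m == 0) return(array(FALSE, dim = dim(template)))
  abs(template) > 0.01 * m
}

support_overlap_frac <- function(t1, t2) {
  s1 <- template_support(t1); s2 <- template_support(t2)
  denom <- min(sum(s1), sum(s2))
  if (denom == 0) return(0)
  sum(s1 & s2) / denom
}

#' Build the contrast battery
#'
#' Generates one signal template per contrast: a sum of smooth positive and
#' negative blobs on the cohort grid. Tasks partition the contrasts; within
#' each eligible task one pair of contrasts is engineered to share a fraction
#' of its blob layout (an "overlap group"), emulating redundant task
#' contrasts such as a condition and its generalization.
#'
#' Templates are deterministic given `config$seed`.
#'
#' @param config a [cohort_config()].
#' @return list of `contrast_spec` objects, each with fields `contrast_id`,
#'   `task_id`, `template` (3D array), `overlap_group` (string or `NA`).
#' @export
build_contrast_specs <- function(config) {
  validate_cohort_config(config)
  with_seed(substream_seed(config$seed, 1L), build_contrast_specs_impl(config))
}

build_contrast_specs_impl <- function(config) {
  gs <- config$grid_shape
  geom <- template_geometry(gs)
  cpt <- rep_len(config$contrasts_per_task, config$n_tasks)
  eligible <- which(cpt >= 2L)
  n_ovl <- config$n_overlap_pairs %||% length(eligible)
  if (n_ovl > length(eligible))
    stop("n_overlap_pairs exceeds the number of tasks with >= 2 contrasts")
  ovl_tasks <- eligible[seq_len(n_ovl)]

  n_blobs <- TEMPLATE_N_POS + TEMPLATE_N_NEG
  shared_n <- max(1L, ceiling(config$overlap_frac * n_blobs))
  amp_signs <- c(rep(1, TEMPLATE_N_POS), rep(-1, TEMPLATE_N_NEG))

  new_blobs <- function(n, fixed_centers = NULL, signs = amp_signs[seq_len(n)]) {
    ctrs <- place_blob_centers(n, gs, geom, fixed = fixed_centers)
    mapply(function(center, s) list(center = center, amplitude = s),
           ctrs, signs, SIMPLIFY = FALSE)
  }

  specs <- list()
  for (task in seq_len(config$n_tasks)) {
    task_id <- sprintf("task%02d", task)
    base_blobs <- NULL
    for (con in seq_len(cpt[task])) {
      contrast_id <- sprintf("%s_con%02d", task_id, con)
      in_pair <- task %in% ovl_tasks && con <= 2L
      overlap_group <- if (in_pair) sprintf("%s_ovl", task_id) else NA_character_
      if (in_pair && con == 1L) {
        blobs <- new_blobs(n_blobs)
        base_blobs <- blobs
      } else if (in_pair && con == 2L) {
        shared <- base_blobs[seq_len(shared_n)]
        fresh <- new_blobs(n_blobs - shared_n,
                           fixed_centers = lapply(shared, `[[`, "center"),
                           signs = amp_signs[(shared_n + 1L):n_blobs])
        blobs <- c(shared, fresh)
      } else {
        blobs <- new_blobs(n_blobs)
      }
      template <- blob_sum(blobs, gs, geom$sigma)
      specs[[contrast_id]] <- structure(
        list(contrast_id = contrast_id, task_id = task_id,
             template = template, overlap_group = overlap_group),
        class = "contrast_spec")
    }
    if (task %in% ovl_tasks) {
      ids <- sprintf("%s_con%02d", task_id, 1:2)
      frac <- support_overlap_frac(specs[[ids[1L]]]$template,
                                   specs[[ids[2L]]]$template)
      if (frac < config$overlap_frac)
        stop(sprintf("engineered overlap pair %s shares only %.2f of support (< %.2f)",
                     task_id, frac, config$overlap_frac))
    }
  }
  unname(specs)
}

# ---- subject map simulation ------------------------------------------------

#' Simulate subject-level contrast maps for a cohort
#'
#' Draws every subject's effect map for every contrast from the generative
#' model documented in [cohort_config()]: amplitude-scaled template, plus a
#' smooth family field (shared by family members), smooth subject noise, and
#' a weak background field shared across the whole cohort and all contrasts.
#'
#' @param specs contrast specs from [build_contrast_specs()].
#' @param records subject table from [make_subject_records()].
#' @param config the [cohort_config()].
#' @param mask optional [brain_mask()]; defaults to an ellipsoid in the grid.
#' @return an object of class `subject_cohort` holding, per contrast, a
#'   `voxels x subjects` matrix of map values, plus the records, specs,
#'   mask and config. Use [subject_map()] to extract one subject's volume.
#' @export
simulate_subject_maps <- function(specs, records, config, mask = NULL) {
  validate_cohort_config(config)
  stopifnot(is.data.frame(records),
            all(c("subject_id", "family_id") %in% names(records)))
  if (anyDuplicated(records$subject_id))
    stop("subject_id must be unique within a cohort")
  if (nrow(records) != config$n_subjects)
    stop("records must cover exactly n_subjects subjects")
  gs <- config$grid_shape
  if (is.null(mask)) mask <- ellipsoid_mask(gs)
  check_same_grid(mask$volume, array(0, dim = gs), "mask and cohort grid")

  with_seed(substream_seed(config$seed, 2L), {
    nvox <- prod(gs)
    n_sub <- nrow(records)
    fam_ids <- unique(records$family_id)
    background <- smooth_noise_field(gs, config$background_shared_sd,
                                     config$smoothing_fwhm_vox)
    data <- list()
    for (spec in specs) {
      signal <- config$effect_amplitude * spec$template + background
      m <- matrix(0, nrow = nvox, ncol = n_sub,
                  dimnames = list(NULL, records$subject_id))
      fam_fields <- lapply(fam_ids, function(f)
        smooth_noise_field(gs, config$family_noise_sd, config$smoothing_fwhm_vox))
      names(fam_fields) <- fam_ids
      for (i in seq_len(n_sub)) {
        vol <- signal + fam_fields[[records$family_id[i]]] +
          smooth_noise_field(gs, config$subject_noise_sd, config$smoothing_fwhm_vox)
        m[, i] <- as.vector(vol)
      }
      data[[spec$contrast_id]] <- m
    }
    structure(list(data = data, records = records, specs = specs,
                   config = config, mask = mask, affine = mask$affine),
              class = "subject_cohort")
  })
}

#' @export
print.subject_cohort <- function(x, ...) {
  cat(sprintf("<subject_cohort> %d subjects x %d contrasts on a %s grid\n",
              nrow(x$records), length(x$data),
              paste(x$config$grid_shape, collapse = "x")))
  invisible(x)
}

#' Extract one subject's contrast map
#'
#' @param cohort a `subject_cohort` from [simulate_subject_maps()].
#' @param subject_id,contrast_id identifiers present in the cohort.
#' @return object of class `subject_map`: list with `volume` (3D array),
#'   `subject_id`, `contrast_id`, `affine`.
#' @export
subject_map <- function(cohort, subject_id, contrast_id) {
  stopifnot(inherits(cohort, "subject_cohort"))
  m <- cohort$data[[contrast_id]]
  if (is.null(m)) stop("unknown contrast_id: ", contrast_id)
  if (!subject_id %in% colnames(m)) stop("unknown subject_id: ", subject_id)
  structure(list(volume = array(m[, subject_id], dim = cohort$config$grid_shape),
                 subject_id = subject_id, contrast_id = contrast_id,
                 affine = cohort$affine),
            class = "subject_map")
}

# ---- family-constrained group subsampling ---------------------------------

#' Draw two family-disjoint subject groups
#'
#' Mirrors the two-group subsampling used for repeated group-map comparison:
#' group A is a uniform random sample without replacement; candidates for
#' group B are then drawn from the remaining subjects and admitted only if
#' their family has no member in group A, until B is full. Relatives *within*
#' a group are permitted; only between-group relatedness is excluded.
#'
#' @param records subject table with `subject_id` and `family_id`.
#' @param group_size subjects per group.
#' @param max_attempts cap on candidate draws for group B; exceeding it (or
#'   exhausting the eligible pool) raises an error of class
#'   `threshsim_sampling_infeasible`, signalling that the cohort has too few
#'   subjects unrelated to group A.
#' @return list with character vectors `ids_A` and `ids_B`.
#' @export
sample_unrelated_groups <- function(records, group_size,
                                    max_attempts = 10L * nrow(records)) {
  stopifnot(is.data.frame(records), nrow(records) >= 1, group_size >= 1)
  if (2L * group_size > nrow(records))
    stop("need at least 2 * group_size subjects")
  ids_A <- sample(records$subject_id, group_size)
  fams_A <- unique(records$family_id[records$subject_id %in% ids_A])
  pool <- records[!(records$subject_id %in% ids_A), , drop = FALSE]
  candidates <- pool[sample.int(nrow(pool)), , drop = FALSE]
  ids_B <- character(0)
  attempts <- 0L
  for (i in seq_len(nrow(candidates))) {
    if (length(ids_B) == group_size) break
    attempts <- attempts + 1L
    if (attempts > max_attempts) break
    if (!(candidates$family_id[i] %in% fams_A))
      ids_B <- c(ids_B, candidates$subject_id[i])
  }
  if (length(ids_B) < group_size) {
    cond <- structure(
      class = c("threshsim_sampling_infeasible", "error", "condition"),
      list(message = sprintf(
        "could not assemble group B (%d of %d) unrelated to group A within %d attempts",
        length(ids_B), group_size, attempts),
        call = sys.call(-1)))
    stop(cond)
  }
  list(ids_A = ids_A, ids_B = ids_B)
}
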