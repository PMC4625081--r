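test_that("contrast battery has the configured layout, overlap pairs and determinism", {
  co <- cohort_config(n_tasks = 7, contrasts_per_task = c(3, 19, 3, 3, 3, 3, 13),
                      seed = 11)
  specs <- build_contrast_specs(co)
  expect_length(specs, 47L)
  tasks <- vapply(specs, `[[`, "", "task_id")
  expect_equal(unname(c(table(tasks)[sprintf("task%02d", 1:7)])),
               c(3, 19, 3, 3, 3, 3, 13))
  # every task contributes an engineered overlap pair by default
  ovl <- vapply(specs, `[[`, "", "overlap_group")
  expect_equal(sum(!is.na(ovl)), 14L)
  for (g in unique(ovl[!is.na(ovl)])) {
    pair <- specs[which(ovl == g)]
    frac <- threshsim:::support_overlap_frac(pair[[1]]$template,
                                             pair[[2]]$template)
    expect_gte(frac, co$overlap_frac)
  }
  # non-overlap contrasts share much less support than the engineered pair
  t1 <- specs[[1]]$template
  t3 <- specs[[3]]$template
  expect_lt(threshsim:::support_overlap_frac(t1, t3),
            threshsim:::support_overlap_frac(t1, specs[[2]]$template))

  specs2 <- build_contrast_specs(co)
  expect_identical(specs, specs2)

  one <- build_contrast_specs(cohort_config(n_tasks = 1, contrasts_per_task = 1,
                                            n_subjects = 2, n_families = 2,
                                            group_size = 1, seed = 5))
  expect_length(one, 1L)
  expect_true(is.na(one[[1]]$overlap_group))
})

test_that("templates are sums of localized positive and negative blobs", {
  specs <- build_contrast_specs(small_cohort_config(seed = 4))
  tpl <- specs[[1]]$template
  expect_identical(dim(tpl), c(16L, 16L, 16L))
  expect_gt(max(tpl), 0.9)   # positive blobs peak near +1
  expect_lt(min(tpl), -0.9)  # negative blobs peak near -1
  expect_lt(mean(threshsim:::template_support(tpl)), 1) # localized support
})

test_that("grid too small for the blob layout is a configuration error", {
  co <- cohort_config(grid_shape = c(8, 8, 8), n_subjects = 8, n_families = 4,
                      group_size = 2, seed = 1)
  expect_error(build_contrast_specs(co), "grid too small")
})

test_that("noise-free cohort reproduces amplitude * template exactly", {
  co <- small_cohort_config(subject_noise_sd = 0, family_noise_sd = 0,
                            background_shared_sd = 0, effect_amplitude = 2,
                            seed = 7)
  specs <- build_contrast_specs(co)
  recs <- make_subject_records(co$n_subjects, co$n_families)
  coh <- simulate_subject_maps(specs, recs, co)
  for (k in seq_along(specs)) {
    m <- coh$data[[specs[[k]]$contrast_id]]
    expect_equal(max(abs(m - as.vector(2 * specs[[k]]$template))), 0)
    # all subjects identical in the noise-free limit
    expect_equal(max(abs(m - m[, 1])), 0)
  }
})

test_that("zero-signal cohort has voxelwise mean near zero across many subjects", {
  co <- cohort_config(n_subjects = 150, n_families = 75, n_tasks = 1,
                      contrasts_per_task = 1, grid_shape = c(16L, 16L, 16L),
                      group_size = 2, effect_amplitude = 0,
                      background_shared_sd = 0, seed = 9)
  specs <- build_contrast_specs(co)
  recs <- make_subject_records(co$n_subjects, co$n_families)
  coh <- simulate_subject_maps(specs, recs, co)
  mu <- rowMeans(coh$data[[1]])
  # per-voxel sd of the mean is sqrt(0.4^2 + 0.15^2)/sqrt(150) ~ 0.035
  expect_lt(max(abs(mu)), 0.2)
})

test_that("simulated cohort is deterministic given its seed and exposes subject maps", {
  co <- small_cohort_config(seed = 21)
  specs <- build_contrast_specs(co)
  recs <- make_subject_records(co$n_subjects, co$n_families)
  a <- simulate_subject_maps(specs, recs, co)
  b <- simulate_subject_maps(specs, recs, co)
  expect_identical(a$data, b$data)

  sm <- subject_map(a, recs$subject_id[3], specs[[2]]$contrast_id)
  expect_s3_class(sm, "subject_map")
  expect_identical(dim(sm$volume), co$grid_shape)
  expect_identical(as.vector(sm$volume),
                   unname(a$data[[specs[[2]]$contrast_id]][, 3]))
  expect_true(all(is.finite(sm$volume)))
})

test_that("one-sample t on the cohort matches direct per-voxel arithmetic and Z range is plausible", {
  co <- cohort_config(seed = 31)
  specs <- build_contrast_specs(co)
  recs <- make_subject_records(co$n_subjects, co$n_families)
  coh <- simulate_subject_maps(specs, recs, co)
  ids <- recs$subject_id[1:12]
  tm <- one_sample_t(coh$data[[1]][, ids], coh$mask,
                     specs[[1]]$contrast_id, "A")
  idx <- which(coh$mask$volume)
  # independent oracle: direct arithmetic at a sample of voxels
  for (v in idx[seq(1, length(idx), length.out = 25)]) {
    expect_equal(tm$volume[v], t_bf(coh$data[[1]][v, ids]), tolerance = 1e-12)
  }
  z <- t_to_z(tm)$volume[idx]
  expect_true(all(is.finite(z)))
  expect_gt(max(abs(z)), 3)  # group maps carry strong signal at n = 12
  expect_lt(max(abs(z)), 8)
})

test_that("group subsampling is family-disjoint, uniform for A, and mirrors the admit/skip loop", {
  recs <- make_subject_records(465, 232)
  set.seed(1)
  for (i in 1:100) {
    g <- sample_unrelated_groups(recs, 46)
    expect_length(g$ids_A, 46L)
    expect_length(g$ids_B, 46L)
    expect_length(intersect(g$ids_A, g$ids_B), 0L)
    famA <- recs$family_id[recs$subject_id %in% g$ids_A]
    famB <- recs$family_id[recs$subject_id %in% g$ids_B]
    expect_length(intersect(famA, famB), 0L)
  }

  # with singleton families any disjoint split is valid
  singles <- data.frame(subject_id = letters[1:4], family_id = LETTERS[1:4])
  set.seed(2)
  g <- sample_unrelated_groups(singles, 2)
  expect_length(intersect(g$ids_A, g$ids_B), 0L)

  # 2 families of 2, group size 2: brute-force enumeration shows the only
  # admissible splits put one whole family in each group
  fam2 <- data.frame(subject_id = c("s1", "s2", "s3", "s4"),
                     family_id = c("f1", "f1", "f2", "f2"))
  set.seed(3)
  successes <- 0
  for (i in 1:60) {
    g <- tryCatch(sample_unrelated_groups(fam2, 2),
                  threshsim_sampling_infeasible = function(e) NULL)
    if (is.null(g)) next
    successes <- successes + 1
    famA <- unique(fam2$family_id[fam2$subject_id %in% g$ids_A])
    famB <- unique(fam2$family_id[fam2$subject_id %in% g$ids_B])
    expect_length(famA, 1L)
    expect_length(famB, 1L)
    expect_false(famA == famB)
  }
  expect_gt(successes, 5)

  # infeasible when everyone is related to group A
  onefam <- data.frame(subject_id = c("s1", "s2", "s3", "s4"),
                       family_id = "f1")
  set.seed(4)
  expect_error(sample_unrelated_groups(onefam, 2),
               class = "threshsim_sampling_infeasible")
})

test_that("inclusion in group A is uniform across subjects", {
  recs <- make_subject_records(100, 100)
  counts <- integer(100)
  names(counts) <- recs$subject_id
  set.seed(5)
  n_draws <- 500
  for (i in seq_len(n_draws)) {
    g <- sample_unrelated_groups(recs, 10)
    counts[g$ids_A] <- counts[g$ids_A] + 1L
  }
  p <- 10 / 100
  expected <- n_draws * p
  tol <- 5 * sqrt(n_draws * p * (1 - p)) # 5 sigma binomial tolerance
  expect_true(all(abs(counts - expected) < tol))
})

test_that("cohort configuration invariants are enforced", {
  expect_error(cohort_config(n_subjects = 4, n_families = 6, group_size = 1),
               "n_families")
  expect_error(cohort_config(n_subjects = 10, n_families = 5, group_size = 6),
               "group_size")
  expect_error(cohort_config(subject_noise_sd = -1), "sds")
  expect_error(cohort_config(n_tasks = 3, contrasts_per_task = c(2, 2)),
               "contrasts_per_task")
})
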