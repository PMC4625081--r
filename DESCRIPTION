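Package: threshsim
Title: Thresholding Effects on Statistical Brain Map Similarity and Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates multi-subject cohorts of 3D task-contrast effect maps with
    family structure and overlapping contrast signal, computes group-level
    statistical maps (voxelwise one-sample t converted to Z scores with a
    tail-precise log-space transform), applies two-sided or positive-only
    Z thresholds, scores pairwise map similarity (Pearson or Spearman) under
    complete-case analysis or zero imputation of empty voxels, and evaluates
    contrast classification accuracy by maximum absolute correlation across
    repeated family-disjoint group subsamples. Reads and writes NIfTI-1
    volumes and exports long-format scores, accuracy summaries and confusion
    matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
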