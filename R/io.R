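# NIfTI-1, TSV and JSON manifest I/O.
#
# Dialect note: in memory, empty voxels are NA; NIfTI files cannot carry
# that distinction portably, so exports write 0 at empty voxels and rely on
# the mask (stored alongside) plus the JSON sidecar to recover semantics.
# On import, a 0 inside the mask is therefore read back as empty.

write_nifti_volume <- function(vol, path, affine = default_affine()) {
  img <- RNifti::asNifti(vol)
  RNifti::`sform<-`(img, structure(affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

read_nifti_volume <- function(path) {
  img <- RNifti::readNifti(path)
  list(volume = as.array(img), affine = unclass(RNifti::xform(img)))
}

#' Write a Z-statistic map as NIfTI-1 with a JSON sidecar
#'
#' Empty voxels are written as 0; the sidecar (`<path minus extensions>.json`)
#' records contrast, group, degrees of freedom and any applied threshold so
#' the map is self-describing on disk.
#'
#' @param zmap a `zstat_map`.
#' @param path output `.nii.gz` path.
#' @param df optional degrees of freedom to record.
#' @param affine 4x4 transform for the file header.
#' @return the path, invisibly.
#' @export
write_zstat_map <- function(zmap, path, df = NULL, affine = default_affine()) {
  stopifnot(inherits(zmap, "zstat_map"))
  vol <- zmap$volume
  vol[is.na(vol)] <- 0
  write_nifti_volume(vol, path, affine)
  sidecar <- list(contrast_id = zmap$contrast_id,
                  group_label = zmap$group_label,
                  df = df,
                  threshold = if (!is.null(zmap$threshold))
                    list(level = zmap$threshold$level,
                         direction = zmap$threshold$direction))
  jsonlite::write_json(sidecar, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a Z-statistic map written by [write_zstat_map()]
#'
#' @param path the `.nii.gz` path.
#' @param mask a [brain_mask()]; voxels outside it, and exact zeros inside
#'   it, are restored as empty.
#' @return a list with the `zstat_map` (element `zmap`) and the sidecar
#'   `df` (may be `NULL`).
#' @export
read_zstat_map <- function(path, mask) {
  stopifnot(inherits(mask, "brain_mask"))
  nii <- read_nifti_volume(path)
  vol <- nii$volume
  check_same_grid(vol, mask$volume, "map file and mask")
  vol[!mask$volume] <- NA_real_
  vol[!is.na(vol) & vol == 0] <- NA_real_
  side <- sidecar_path(path)
  meta <- if (file.exists(side)) jsonlite::read_json(side) else list()
  thr <- if (!is.null(meta$threshold))
    threshold_spec(meta$threshold$level, meta$threshold$direction)
  list(zmap = zstat_map(vol,
                        contrast_id = meta$contrast_id %||% NA_character_,
                        group_label = meta$group_label %||% NA_character_,
                        threshold = thr),
       df = meta$df)
}

sidecar_path <- function(path) {
  sub("\\.nii(\\.gz)?$", ".json", path)
}

#' Write / read the subject metadata table
#'
#' Tab-separated, header `subject_id<TAB>family_id`.
#'
#' @param records data.frame with `subject_id`, `family_id`.
#' @param path TSV path.
#' @return `write_subject_tsv`: the path, invisibly. `read_subject_tsv`:
#'   the records data.frame.
#' @export
write_subject_tsv <- function(records, path) {
  stopifnot(all(c("subject_id", "family_id") %in% names(records)))
  utils::write.table(records[, c("subject_id", "family_id")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_subject_tsv
#' @export
read_subject_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    colClasses = "character", stringsAsFactors = FALSE)
}

#' Export a simulated cohort to disk
#'
#' Writes one NIfTI-1 file per subject per contrast
#' (`{subject_id}_{contrast_id}.nii.gz`), the subject TSV, the binary brain
#' mask, and a JSON contrast manifest (`contrast_id`, `task_id`,
#' `overlap_group`).
#'
#' @param cohort a `subject_cohort`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "subject_cohort"))
  dir.create(file.path(dir, "maps"), recursive = TRUE, showWarnings = FALSE)
  write_subject_tsv(cohort$records, file.path(dir, "subjects.tsv"))
  write_nifti_volume(cohort$mask$volume + 0, file.path(dir, "mask.nii.gz"),
                     cohort$affine)
  manifest <- lapply(cohort$specs, function(s)
    list(contrast_id = s$contrast_id, task_id = s$task_id,
         overlap_group = if (is.na(s$overlap_group)) NULL else s$overlap_group))
  jsonlite::write_json(manifest, file.path(dir, "contrasts.json"),
                       auto_unbox = TRUE, null = "null")
  gs <- cohort$config$grid_shape
  for (cid in names(cohort$data)) {
    m <- cohort$data[[cid]]
    for (sid in colnames(m)) {
      write_nifti_volume(array(m[, sid], dim = gs),
                         file.path(dir, "maps",
                                   sprintf("%s_%s.nii.gz", sid, cid)),
                         cohort$affine)
    }
  }
  jsonlite::write_json(unclass(cohort$config),
                       file.path(dir, "cohort_config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Load a cohort exported with [write_cohort()]
#'
#' @param dir cohort directory.
#' @return a `subject_cohort` (templates in `specs` are not restored; only
#'   identifiers, task and overlap-group metadata round-trip).
#' @export
read_cohort <- function(dir) {
  cfg_raw <- jsonlite::read_json(file.path(dir, "cohort_config.json"),
                                 simplifyVector = TRUE)
  cfg_raw <- cfg_raw[names(cfg_raw) %in% names(formals(cohort_config))]
  config <- do.call(cohort_config, cfg_raw)
  records <- read_subject_tsv(file.path(dir, "subjects.tsv"))
  msk <- read_nifti_volume(file.path(dir, "mask.nii.gz"))
  mask <- brain_mask(msk$volume != 0, msk$affine)
  contrasts <- jsonlite::read_json(file.path(dir, "contrasts.json"))
  gs <- config$grid_shape
  data <- list()
  specs <- list()
  for (con in contrasts) {
    cid <- con$contrast_id
    m <- matrix(NA_real_, nrow = prod(gs), ncol = nrow(records),
                dimnames = list(NULL, records$subject_id))
    for (sid in records$subject_id) {
      f <- file.path(dir, "maps", sprintf("%s_%s.nii.gz", sid, cid))
      m[, sid] <- as.vector(read_nifti_volume(f)$volume)
    }
    data[[cid]] <- m
    specs[[length(specs) + 1L]] <- structure(
      list(contrast_id = cid, task_id = con$task_id, template = NULL,
           overlap_group = con$overlap_group %||% NA_character_),
      class = "contrast_spec")
  }
  structure(list(data = data, records = records, specs = specs,
                 config = config, mask = mask, affine = mask$affine),
            class = "subject_cohort")
}
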