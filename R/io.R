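#' Read a two-channel volumetric patch from NIfTI files
#'
#' Loads per-channel volumes (e.g. T2W-like and ADC-like) sharing one voxel
#' grid and optionally crops them to the tight bounding box of a lesion
#' mask, dilated by `margin` voxels per side and clipped to the volume.
#' Without a mask the whole volume becomes the patch. Coordinates are
#' treated as (i, j, k) = (row, column, slice).
#'
#' @param t2w_path,adc_path Paths to the channel volumes.
#' @param mask_path Optional path to a binary lesion mask on the same grid.
#' @param margin Dilation of the mask bounding box, in voxels (default 2).
#' @param lesion_id Identifier stored on the patch.
#' @return A `vt_patch` (list with 3D arrays `t2w`, `adc` and `lesion_id`).
#' @export
read_patch_nifti <- function(t2w_path, adc_path, mask_path = NULL, margin = 2L,
                             lesion_id = NULL) {
  t2w <- as.array(RNifti::readNifti(t2w_path))
  adc <- as.array(RNifti::readNifti(adc_path))
  if (!identical(dim(t2w), dim(adc))) abort("channel volumes are on different grids")
  if (!is.null(mask_path)) {
    mask <- as.array(RNifti::readNifti(mask_path))
    if (!identical(dim(mask), dim(t2w))) abort("mask is on a different grid")
    if (!any(mask > 0)) abort("mask is empty")
    idx <- which(mask > 0, arr.ind = TRUE)
    lo <- pmax(apply(idx, 2, min) - margin, 1)
    hi <- pmin(apply(idx, 2, max) + margin, dim(t2w))
    t2w <- t2w[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
    adc <- adc[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  }
  structure(list(t2w = t2w, adc = adc,
                 lesion_id = lesion_id %||% basename(t2w_path)),
            class = "vt_patch")
}

#' Export a cohort's patches as NIfTI volumes
#'
#' Writes one file per lesion per channel
#' (`<lesion_id>_<channel>.nii.gz`) for interoperability with imaging tools.
#'
#' @param cohort A `vt_cohort`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
write_cohort_nifti <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (p in cohort$patches) {
    for (ch in c("t2w", "adc")) {
      f <- file.path(dir, sprintf("%s_%s.nii.gz", p$lesion_id, ch))
      RNifti::writeNifti(RNifti::asNifti(p[[ch]]), f)
      paths <- c(paths, f)
    }
  }
  invisible(paths)
}

#' Save / load a cohort archive
#'
#' The archive is one serialized container holding all patches plus the
#' records as CSV alongside, with a JSON sidecar recording the generator
#' configuration hash and seed for provenance.
#'
#' @param cohort A `vt_cohort`.
#' @param dir Archive directory.
#' @param config Optional configuration recorded in the sidecar.
#' @return `write_cohort()` the directory, invisibly; `read_cohort()` a
#'   `vt_cohort`.
#' @export
write_cohort <- function(cohort, dir, config = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  saveRDS(cohort$patches, file.path(dir, "patches.rds"))
  readr::write_csv(cohort$records, file.path(dir, "records.csv"))
  write_sidecar(file.path(dir, "cohort.json"), config)
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  patches_f <- file.path(dir, "patches.rds")
  records_f <- file.path(dir, "records.csv")
  for (f in c(patches_f, records_f))
    if (!file.exists(f)) abort(sprintf("missing artifact: %s", f))
  records <- readr::read_csv(records_f, show_col_types = FALSE)
  structure(list(patches = readRDS(patches_f), records = records),
            class = "vt_cohort")
}

# provenance sidecar: config hash + seed so a rerun with the same hash
# reproduces the artifact exactly
write_sidecar <- function(path, config) {
  payload <- list(created_by = "voltexture",
                  config_hash = config_hash(config),
                  seed = config$seed)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, null = "null",
                       pretty = TRUE)
  invisible(path)
}

#' MD5 hash of a configuration object
#'
#' Canonical hash of the JSON serialization, used in artifact sidecars.
#'
#' @param config Any list-like configuration (NULL hashes to the string
#'   "none").
#' @return Character hash.
#' @export
config_hash <- function(config) {
  if (is.null(config)) return("none")
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tmp))
}

#' Write an evaluation report as JSON
#'
#' Serializes the evaluation tibble (plus its ROC curves) deterministically:
#' identical inputs produce byte-identical files.
#'
#' @param eval A `vt_eval` from [evaluate_models()].
#' @param path Output path.
#' @param config Optional run configuration recorded alongside (as a hash).
#' @return The path, invisibly.
#' @export
write_eval_json <- function(eval, path, config = NULL) {
  payload <- list(baseline = attr(eval, "baseline"),
                  config_hash = config_hash(config),
                  results = as.data.frame(eval),
                  roc = lapply(attr(eval, "roc"), as.data.frame))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null", null = "null", pretty = TRUE)
  invisible(path)
}
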