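#' 4D dynamic PET image
#'
#' Carrier for a dynamic acquisition: a 4D voxel array (x, y, z, frame) of
#' activity concentrations in kBq/mL, a voxel-to-world affine (mm), and the
#' frame schedule. Voxel indices are 0-based when mapped through the affine;
#' world coordinates are in mm.
#'
#' @param voxels 4D numeric array (x, y, z, frame), kBq/mL.
#' @param affine 4x4 invertible voxel-to-world transform (mm).
#' @param schedule A [frame_schedule]; its length must equal `dim(voxels)[4]`.
#' @return An object of class `dynamic_image`.
#' @export
dynamic_image <- function(voxels, affine, schedule) {
  if (length(dim(voxels)) != 4L)
    stop("voxels must be a 4D array (x, y, z, frame)")
  stopifnot(inherits(schedule, "frame_schedule"))
  if (dim(voxels)[4] != n_frames(schedule))
    stop(sprintf("schedule mismatch: image has %d frames but schedule has %d",
                 dim(voxels)[4], n_frames(schedule)))
  affine <- check_affine(affine)
  structure(list(voxels = voxels, affine = affine, schedule = schedule),
            class = "dynamic_image")
}

check_affine <- function(affine) {
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4, 4)) || !all(is.finite(affine)))
    stop("affine must be a finite 4x4 matrix")
  if (abs(det(affine)) < 1e-12)
    stop("affine must be invertible")
  matrix(as.numeric(affine), 4, 4)  # strip NIfTI header attributes
}

voxel_volume_mm3 <- function(affine) abs(det(affine[1:3, 1:3]))

# World-space coordinates (mm) of 0-based voxel indices (n x 3 matrix).
voxel_to_world <- function(affine, ijk) {
  ijk <- matrix(ijk, ncol = 3)
  t(affine %*% rbind(t(ijk), 1))[, 1:3, drop = FALSE]
}

sidecar_path <- function(path) paste0(sub("\\.nii(\\.gz)?$", "", path), ".json")

#' Write / read a dynamic image as NIfTI plus a frame-schedule sidecar
#'
#' The image is written as NIfTI-1 with the affine in the sform; the frame
#' schedule (minutes) and units are written to a JSON sidecar next to the
#' image. The round trip through [read_dynamic_image()] is lossless.
#'
#' @param image A [dynamic_image].
#' @param path Output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_dynamic_image <- function(image, path) {
  stopifnot(inherits(image, "dynamic_image"))
  if (anyNA(image$voxels))
    warning("image contains NaN/NA voxels; values are preserved on disk")
  nii <- RNifti::asNifti(image$voxels)
  RNifti::sform(nii) <- structure(image$affine, code = 2L)
  RNifti::writeNifti(nii, path)
  jsonlite::write_json(
    list(frame_start = image$schedule$start, frame_end = image$schedule$end,
         time_unit = "min", value_unit = "kBq/mL"),
    sidecar_path(path), digits = NA)
  invisible(path)
}

#' @rdname write_dynamic_image
#' @param sidecar Path to the frame-schedule JSON; defaults to the sidecar
#'   written by [write_dynamic_image()].
#' @export
read_dynamic_image <- function(path, sidecar = sidecar_path(path)) {
  if (!file.exists(path)) stop("no such image file: ", path)
  if (!file.exists(sidecar))
    stop("missing metadata: frame-schedule sidecar not found at ", sidecar)
  nii <- RNifti::readNifti(path)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  sched <- frame_schedule(meta$frame_start, meta$frame_end)
  arr <- as.array(nii)
  arr <- array(as.numeric(arr), dim(arr))  # plain array, no header attributes
  if (length(dim(arr)) == 3L && n_frames(sched) == 1L)
    dim(arr) <- c(dim(arr), 1L)  # NIfTI drops a trailing singleton frame
  if (length(dim(arr)) != 4L)
    stop("expected a 4D NIfTI image, got ", length(dim(arr)), " dimensions")
  if (dim(arr)[4] != n_frames(sched))
    stop(sprintf("schedule mismatch: image has %d frames but sidecar lists %d",
                 dim(arr)[4], n_frames(sched)))
  dynamic_image(arr, RNifti::xform(nii, useQuaternionFirst = FALSE), sched)
}

#' Labelled volume-of-interest atlas
#'
#' An integer label image on the same grid as the dynamic data, with a name
#' map from region name to label value. 0 is background. The map must be
#' injective and every named label must occur in the array.
#'
#' @param labels 3D integer array of region labels (0 = background).
#' @param name_map Named integer vector: region name -> label value.
#' @param affine 4x4 voxel-to-world transform, as for [dynamic_image()].
#' @return An object of class `voi_atlas`.
#' @export
voi_atlas <- function(labels, name_map, affine) {
  if (length(dim(labels)) != 3L) stop("labels must be a 3D array")
  name_map <- unlist(name_map)
  if (is.null(names(name_map)) || any(!nzchar(names(name_map))))
    stop("name_map must be a named vector")
  if (anyDuplicated(name_map) || anyDuplicated(names(name_map)))
    stop("name_map must be injective (unique names and unique labels)")
  if (any(name_map == 0)) stop("label 0 is reserved for background")
  present <- unique(as.vector(labels))
  missing <- setdiff(name_map, present)
  if (length(missing))
    stop("labels named in name_map but absent from the array: ",
         paste(names(name_map)[name_map %in% missing], collapse = ", "))
  structure(list(labels = labels, name_map = name_map,
                 affine = check_affine(affine)),
            class = "voi_atlas")
}

#' @rdname voi_atlas
#' @param atlas A `voi_atlas`.
#' @param region Region name present in the atlas name map.
#' @return `atlas_mask()`: logical 3D array selecting the region's voxels.
#' @export
atlas_mask <- function(atlas, region) {
  stopifnot(inherits(atlas, "voi_atlas"))
  if (!region %in% names(atlas$name_map))
    stop("region not in atlas: ", region)
  atlas$labels == atlas$name_map[[region]]
}

#' @rdname voi_atlas
#' @export
atlas_regions <- function(atlas) names(atlas$name_map)

#' @rdname voi_atlas
#' @param path Output path for the label NIfTI; name map goes to a JSON sidecar.
#' @export
write_voi_atlas <- function(atlas, path) {
  stopifnot(inherits(atlas, "voi_atlas"))
  nii <- RNifti::asNifti(atlas$labels)
  RNifti::sform(nii) <- structure(atlas$affine, code = 2L)
  RNifti::writeNifti(nii, path, datatype = "int16")
  jsonlite::write_json(as.list(atlas$name_map), sidecar_path(path),
                       auto_unbox = TRUE)
  invisible(path)
}

#' @rdname voi_atlas
#' @param sidecar Path to the name-map JSON.
#' @export
read_voi_atlas <- function(path, sidecar = sidecar_path(path)) {
  if (!file.exists(sidecar)) stop("missing metadata: name-map sidecar not found")
  nii <- RNifti::readNifti(path)
  nm <- unlist(jsonlite::read_json(sidecar, simplifyVector = TRUE))
  arr <- as.array(nii)
  arr <- array(as.integer(round(arr)), dim(arr))
  voi_atlas(arr, nm, RNifti::xform(nii, useQuaternionFirst = FALSE))
}

tci_trait_names <- function() {
  paste0("tci_", c("novelty_seeking", "harm_avoidance", "reward_dependence",
                   "persistence", "self_directedness", "cooperativeness",
                   "self_transcendence"))
}

cohort_required_columns <- function() {
  c("id", "sex", "age", "baq_total", tci_trait_names(), "arterial_sampled")
}

#' Read / write a cohort covariate table
#'
#' The cohort table holds one row per subject: id, sex (F/M), age (years),
#' BAQ total aggression score, the 7 TCI trait scores, and whether arterial
#' blood was sampled. Extra columns (e.g. plasma hormone levels) pass through
#' untouched.
#'
#' @param path CSV file path.
#' @return A data frame with one row per subject, sex as a factor with
#'   levels F, M.
#' @export
read_cohort_table <- function(path) {
  if (!file.exists(path)) stop("no such cohort table: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(cohort_required_columns(), names(df))
  if (length(missing))
    stop("cohort table schema error; missing columns: ",
         paste(missing, collapse = ", "))
  if (nrow(df) == 0L) {
    df$sex <- factor(df$sex, levels = c("F", "M"))
    return(df)
  }
  if (!all(df$sex %in% c("F", "M")))
    stop("parse error: sex must be 'F' or 'M', got: ",
         paste(unique(setdiff(df$sex, c("F", "M"))), collapse = ", "))
  df$sex <- factor(df$sex, levels = c("F", "M"))
  score_cols <- c("age", "baq_total", tci_trait_names())
  for (cl in score_cols) {
    v <- suppressWarnings(as.numeric(df[[cl]]))
    if (anyNA(v)) stop("parse error: non-numeric values in column ", cl)
    df[[cl]] <- v
  }
  df$arterial_sampled <- as.logical(df$arterial_sampled)
  df
}

#' @rdname read_cohort_table
#' @param cohort Data frame as returned by [read_cohort_table()] or
#'   [generate_cohort()].
#' @export
write_cohort_table <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}
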