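# NIfTI-1 readers and writers. Scalar volumes are 3D images; vector fields
# (SVFs, displacement fields) are 4D images with a trailing vector dimension
# of size 3 written with the NIfTI vector intent code. Axis order is fixed:
# array index order (x, y, z[, component]). Values round-trip bit-exact as
# double precision.

#' Read a 3D scalar volume from NIfTI
#'
#' @param path path to a `.nii` / `.nii.gz` file with exactly 3 dimensions.
#' @return A [scalar_volume()] with spacing from the file header.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3)
    stop(sprintf("read_volume: expected a 3D image, got %dD (%s)",
                 length(d), path))
  scalar_volume(as.array(img), spacing = abs(RNifti::pixdim(img)[1:3]))
}

#' Write a scalar volume to NIfTI
#'
#' @param vol a [scalar_volume()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return The path, invisibly.
#' @export
write_volume <- function(vol, path) {
  vol <- as_volume(vol)
  img <- RNifti::asNifti(unclass(vol) + 0)
  RNifti::pixdim(img) <- voxel_spacing(vol)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a 3-vector field from NIfTI
#'
#' Accepts 4D images whose last dimension has size 3 (vector intent or
#' plain 4D).
#'
#' @param path path to the file.
#' @param what `"velocity"` (default) or `"deformation"` — the class to
#'   construct.
#' @return A [velocity_field()] or [deformation_field()].
#' @export
read_field <- function(path, what = c("velocity", "deformation")) {
  what <- match.arg(what)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4 || d[4] != 3)
    stop(sprintf("read_field: expected a 4D image with 3 components, got [%s] (%s)",
                 paste(d, collapse = ", "), path))
  spacing <- abs(RNifti::pixdim(img)[1:3])
  if (what == "velocity") velocity_field(as.array(img), spacing)
  else deformation_field(as.array(img), spacing)
}

#' Write a 3-vector field to NIfTI
#'
#' Written as a 4D image with the NIfTI vector intent code (1007).
#'
#' @param field a [velocity_field()] or [deformation_field()].
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_field <- function(field, path) {
  if (!(inherits(field, "velocity_field") || inherits(field, "deformation_field")))
    stop("write_field: expected a velocity_field or deformation_field")
  img <- RNifti::asNifti(unclass(field) + 0,
                         reference = list(intent_code = 1007L))
  RNifti::pixdim(img) <- c(voxel_spacing(field), 1)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a cohort manifest
#'
#' CSV with columns `subject_id`, `baseline_path`, `followup_path`, `label`
#' (labels `MCIc` for converters, `MCIs` for stable subjects). Paths are
#' interpreted relative to the manifest's directory; rows are returned sorted
#' by `subject_id` so that feature-matrix row order is reproducible.
#'
#' @param path path to the CSV file.
#' @return Data frame with absolute paths.
#' @export
read_manifest <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "baseline_path", "followup_path", "label")
  missing <- setdiff(need, names(m))
  if (length(missing) > 0)
    stop("read_manifest: missing columns: ", paste(missing, collapse = ", "))
  if (!all(m$label %in% c("MCIc", "MCIs")))
    stop("read_manifest: labels must be 'MCIc' or 'MCIs'")
  base <- dirname(normalizePath(path))
  fix <- function(p) ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(base, p))
  m$baseline_path <- fix(m$baseline_path)
  m$followup_path <- fix(m$followup_path)
  m[order(m$subject_id), , drop = FALSE]
}
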