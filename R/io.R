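#' Read a NIfTI volume
#'
#' Loads a `.nii`/`.nii.gz` file into an [image_volume] or, for
#' `type = "labels"`, a [label_volume] validated against the label
#' vocabulary. Spacing is taken from the NIfTI pixdim and the origin
#' from the stored transform's translation; anisotropic spacings are
#' preserved verbatim.
#'
#' @param path File path.
#' @param type "image" or "labels".
#' @return An [image_volume] or [label_volume].
#' @export
read_volume <- function(path, type = c("image", "labels")) {
  type <- match.arg(type)
  if (!file.exists(path)) stopf("file not found: %s", path)
  nii <- RNifti::readNifti(path)
  dat <- array(as.numeric(nii), dim = dim(nii))
  sp <- attr(nii, "pixdim")
  if (is.null(sp)) sp <- RNifti::pixdim(nii)
  sp <- abs(sp[1:3])
  xf <- try(RNifti::xform(nii), silent = TRUE)
  origin <- if (!inherits(xf, "try-error") && is.matrix(xf)) xf[1:3, 4L]
            else c(0, 0, 0)
  if (type == "labels") {
    ints <- round(dat)
    if (max(abs(dat - ints)) > 1e-6)
      stopf("label file contains non-integer values")
    label_volume(array(as.integer(ints), dim = dim(dat)), sp, origin)
  } else {
    image_volume(dat, sp, origin)
  }
}

#' Write a volume to NIfTI
#'
#' @param vol An [image_volume] or [label_volume].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  dat <- vol$data
  if (inherits(vol, "label_volume")) storage.mode(dat) <- "integer"
  affine <- diag(4)
  affine[1:3, 1:3] <- diag(vol$spacing_mm)
  affine[1:3, 4L] <- vol$origin_mm
  nii <- RNifti::asNifti(dat)
  RNifti::pixdim(nii) <- vol$spacing_mm
  RNifti::qform(nii) <- structure(affine, code = 2L)
  RNifti::sform(nii) <- structure(affine, code = 2L)
  RNifti::writeNifti(nii, path)
  invisible(path)
}

#' Write a phantom cohort to disk
#'
#' Emits paired NIfTI files `case_####_img.nii.gz` /
#' `case_####_lab.nii.gz` plus `manifest.csv` describing each case's
#' spec.
#'
#' @param cohort Output of [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return The manifest data.frame, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (case in cohort$cases) {
    write_volume(case$image, file.path(dir, paste0(case$id, "_img.nii.gz")))
    write_volume(case$labels, file.path(dir, paste0(case$id, "_lab.nii.gz")))
  }
  utils::write.csv(cohort$manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(cohort$manifest)
}
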