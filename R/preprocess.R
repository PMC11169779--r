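#' Preprocessing configuration
#'
#' Parameters of the CTA preprocessing chain: isotropic resampling
#' target, intensity clip window, patch edge for cubic patch extraction
#' and the body-cropping threshold.
#'
#' @param target_spacing_mm Isotropic target voxel size (mm, default 0.5).
#' @param clip_low,clip_high Intensity clip window in HU (default 0 and
#'   1200).
#' @param patch_edge Cubic patch edge in voxels (default 256; reduce for
#'   small volumes).
#' @param body_threshold Intensity (HU) above which a voxel counts as
#'   body for cropping (default 0).
#' @return A `preprocess_config` list.
#' @export
preprocess_config <- function(target_spacing_mm = 0.5, clip_low = 0,
                              clip_high = 1200, patch_edge = 256L,
                              body_threshold = 0) {
  if (target_spacing_mm <= 0) stopf("'target_spacing_mm' must be > 0")
  if (clip_low >= clip_high) stopf("'clip_low' must be < 'clip_high'")
  if (patch_edge < 16L) stopf("'patch_edge' must be >= 16")
  structure(list(target_spacing_mm = target_spacing_mm, clip_low = clip_low,
                 clip_high = clip_high, patch_edge = as.integer(patch_edge),
                 body_threshold = body_threshold),
            class = "preprocess_config")
}

# Shared resampling grid: voxel centres of the output grid expressed as
# fractional input indices. Edges of the world extent are preserved: the
# output grid covers [origin - spacing/2, origin + (n-1+1/2)*spacing] on
# each axis, with the half-voxel origin shift handled explicitly.
resample_grid <- function(vol, target_spacing_mm) {
  if (target_spacing_mm <= 0) stopf("'target_spacing_mm' must be > 0")
  d <- dim(vol$data); sp <- vol$spacing_mm
  new_d <- pmax(1L, as.integer(round(d * sp / target_spacing_mm)))
  new_origin <- vol$origin_mm - sp / 2 + target_spacing_mm / 2
  centers <- lapply(1:3, function(ax) {
    (new_origin[ax] + (seq_len(new_d[ax]) - 1) * target_spacing_mm -
       vol$origin_mm[ax]) / sp[ax] + 1
  })
  idx <- cbind(
    rep(centers[[1L]], times = new_d[2L] * new_d[3L]),
    rep(rep(centers[[2L]], each = new_d[1L]), times = new_d[3L]),
    rep(centers[[3L]], each = new_d[1L] * new_d[2L]))
  list(new_dim = new_d, new_origin = new_origin, idx = idx)
}

#' Resample an image volume to isotropic spacing
#'
#' Trilinear interpolation onto an isotropic grid covering the same
#' world extent (within one voxel). Output shape per axis is
#' `round(extent_mm / target_spacing_mm)`.
#'
#' @param image An [image_volume].
#' @param target_spacing_mm Target isotropic voxel size (mm).
#' @return Resampled [image_volume].
#' @export
resample_image <- function(image, target_spacing_mm = 0.5) {
  g <- resample_grid(image, target_spacing_mm)
  # clamp to the input centre range: edge output voxels sit half an input
  # voxel outside the outermost centres and take the edge value
  d <- dim(image$data)
  for (ax in 1:3) g$idx[, ax] <- pmin(pmax(g$idx[, ax], 1), d[ax])
  vals <- sample_trilinear(image$data, g$idx)
  image_volume(array(vals, dim = g$new_dim), rep(target_spacing_mm, 3),
               g$new_origin, image$orientation)
}

#' Resample a label volume to isotropic spacing
#'
#' Nearest-neighbour interpolation on the same grid convention as
#' [resample_image()]; the output label set is a subset of the input's.
#'
#' @param labels A [label_volume].
#' @inheritParams resample_image
#' @return Resampled [label_volume].
#' @export
resample_labels <- function(labels, target_spacing_mm = 0.5) {
  g <- resample_grid(labels, target_spacing_mm)
  d <- dim(labels$data)
  for (ax in 1:3) g$idx[, ax] <- pmin(pmax(g$idx[, ax], 1), d[ax])
  vals <- sample_nearest(labels$data, g$idx)
  label_volume(array(as.integer(vals), dim = g$new_dim),
               rep(target_spacing_mm, 3), g$new_origin, labels$orientation)
}

#' Clip intensities and normalize to the unit interval
#'
#' Values are clipped to `[clip_low, clip_high]` and then mapped
#' affinely onto the unit interval. With the default HU window, -100 maps to 0 and
#' 1500 maps to 1.
#'
#' @param image An [image_volume] on the HU scale.
#' @param clip_low,clip_high Clip window; `clip_low < clip_high`.
#' @return Normalized [image_volume] with values in 0..1.
#' @export
clip_and_normalize <- function(image, clip_low = 0, clip_high = 1200) {
  if (clip_low >= clip_high) stopf("'clip_low' must be < 'clip_high'")
  v <- pmin(pmax(image$data, clip_low), clip_high)
  v <- (v - clip_low) / (clip_high - clip_low)
  image_volume(array(v, dim = dim(image$data)), image$spacing_mm,
               image$origin_mm, image$orientation)
}

#' Crop a volume to its body region
#'
#' Returns the tight bounding box (plus a fixed 2-voxel margin, clamped
#' at the grid) of voxels above `body_threshold`, together with the
#' 0-based voxel offset of the crop so that a paired label volume can be
#' cropped congruently via [crop_with_offset()].
#'
#' @param image An [image_volume].
#' @param body_threshold Intensity cutoff defining body voxels.
#' @return List with `image` (cropped volume) and `offset` (0-based
#'   voxel triple of the crop's lower corner).
#' @export
crop_to_body <- function(image, body_threshold = 0) {
  fg <- which(image$data > body_threshold, arr.ind = TRUE)
  if (nrow(fg) == 0L) stopf("empty body region: no voxel above threshold")
  lo <- pmax(apply(fg, 2L, min) - 2L, 1L)
  hi <- pmin(apply(fg, 2L, max) + 2L, dim(image$data))
  cropped <- image$data[lo[1L]:hi[1L], lo[2L]:hi[2L], lo[3L]:hi[3L],
                        drop = FALSE]
  new_origin <- image$origin_mm + (lo - 1L) * image$spacing_mm
  list(image = image_volume(cropped, image$spacing_mm, new_origin,
                            image$orientation),
       offset = as.integer(lo - 1L))
}

#' Crop a paired volume congruently with a previous crop
#'
#' @param vol An [image_volume] or [label_volume] on the pre-crop grid.
#' @param offset 0-based voxel triple returned by [crop_to_body()].
#' @param shape Shape of the cropped grid.
#' @return Cropped volume of the same class.
#' @export
crop_with_offset <- function(vol, offset, shape) {
  lo <- offset + 1L
  hi <- offset + shape
  if (any(hi > dim(vol$data))) stopf("crop window exceeds volume")
  cropped <- vol$data[lo[1L]:hi[1L], lo[2L]:hi[2L], lo[3L]:hi[3L],
                      drop = FALSE]
  new_origin <- vol$origin_mm + offset * vol$spacing_mm
  if (inherits(vol, "label_volume"))
    label_volume(cropped, vol$spacing_mm, new_origin, vol$orientation)
  else
    image_volume(cropped, vol$spacing_mm, new_origin, vol$orientation)
}

#' Extract a cubic patch
#'
#' Cuts a cubic patch of edge `patch_edge` centred on voxel `center`
#' (1-based integer triple); the patch covers indices
#' `center - floor(edge/2) + (0 : edge-1)` on each axis and is
#' zero-padded where it exceeds the volume.
#'
#' @param image An [image_volume].
#' @param patch_edge Patch edge in voxels (>= 16).
#' @param center 1-based voxel triple inside the volume.
#' @return [image_volume] of shape `patch_edge^3`.
#' @export
extract_patch <- function(image, patch_edge, center) {
  if (patch_edge < 16L) stopf("'patch_edge' must be >= 16")
  d <- dim(image$data)
  center <- as.integer(center)
  if (any(center < 1L) || any(center > d))
    stopf("'center' outside the volume")
  start <- center - patch_edge %/% 2L
  out <- array(0, dim = rep(as.integer(patch_edge), 3L))
  src_lo <- pmax(start, 1L)
  src_hi <- pmin(start + patch_edge - 1L, d)
  if (all(src_lo <= src_hi)) {
    dst_lo <- src_lo - start + 1L
    dst_hi <- src_hi - start + 1L
    out[dst_lo[1L]:dst_hi[1L], dst_lo[2L]:dst_hi[2L], dst_lo[3L]:dst_hi[3L]] <-
      image$data[src_lo[1L]:src_hi[1L], src_lo[2L]:src_hi[2L],
                 src_lo[3L]:src_hi[3L]]
  }
  new_origin <- image$origin_mm + (start - 1L) * image$spacing_mm
  image_volume(out, image$spacing_mm, new_origin, image$orientation)
}

#' Augmentation parameters
#'
#' Rigid 3-D rotation (each axis within +/-20 degrees), isotropic zoom
#' (0.85-1.15), plus optional Gaussian noise and artifacts applied to
#' the image only. Out-of-range values are rejected.
#'
#' @param rotation_deg Three rotation angles (degrees), each within -20..20 degrees,
#'   applied about the x, y and z axes (in that order) around the volume
#'   centre.
#' @param zoom Isotropic zoom factor within 0.85..1.15.
#' @param noise_sigma Gaussian noise level on the normalized scale (>= 0).
#' @param artifact_strength Artifact amplitude (>= 0).
#' @param seed Integer seed.
#' @return An `augment_params` list.
#' @export
augment_params <- function(rotation_deg = c(0, 0, 0), zoom = 1,
                           noise_sigma = 0, artifact_strength = 0,
                           seed = 1L) {
  if (length(rotation_deg) != 3L || any(abs(rotation_deg) > 20))
    stopf("'rotation_deg' must be 3 angles within +/-20 degrees")
  if (zoom < 0.85 || zoom > 1.15)
    stopf("'zoom' must be within [0.85, 1.15]")
  if (noise_sigma < 0 || artifact_strength < 0)
    stopf("'noise_sigma' and 'artifact_strength' must be >= 0")
  structure(list(rotation_deg = as.numeric(rotation_deg), zoom = zoom,
                 noise_sigma = noise_sigma,
                 artifact_strength = artifact_strength,
                 seed = as.integer(seed)),
            class = "augment_params")
}

rotation_matrix <- function(deg) {
  a <- deg * pi / 180
  rx <- rbind(c(1, 0, 0), c(0, cos(a[1L]), -sin(a[1L])),
              c(0, sin(a[1L]), cos(a[1L])))
  ry <- rbind(c(cos(a[2L]), 0, sin(a[2L])), c(0, 1, 0),
              c(-sin(a[2L]), 0, cos(a[2L])))
  rz <- rbind(c(cos(a[3L]), -sin(a[3L]), 0),
              c(sin(a[3L]), cos(a[3L]), 0), c(0, 0, 1))
  rz %*% ry %*% rx
}

#' Augment a paired image/label volume
#'
#' Applies the same rigid rotation and isotropic zoom to the image
#' (trilinear interpolation) and labels (nearest-neighbour), about the
#' volume centre in world coordinates, then adds noise/artifacts to the
#' image only. Fully determined by `params$seed`. Out-of-field regions
#' take `fill` for the image and background for the labels.
#'
#' @param image An [image_volume] (HU scale).
#' @param labels The paired [label_volume].
#' @param params An [augment_params()].
#' @param fill Image fill value for out-of-field voxels (default 0 HU,
#'   the lower clip bound).
#' @return List with augmented `image` and `labels` on the input grid.
#' @export
augment <- function(image, labels, params, fill = 0) {
  stopifnot(inherits(params, "augment_params"))
  stop_if_not_congruent(image, labels)
  d <- dim(image$data); sp <- image$spacing_mm
  rot <- rotation_matrix(params$rotation_deg)
  ctr <- image$origin_mm + (d - 1) * sp / 2
  identity_geom <- all(params$rotation_deg == 0) && params$zoom == 1
  if (identity_geom) {
    img_out <- image$data
    lab_out <- labels$data
  } else {
    # inverse map: output world -> rotate back & unzoom -> input world
    xs <- image$origin_mm[1L] + (seq_len(d[1L]) - 1) * sp[1L]
    ys <- image$origin_mm[2L] + (seq_len(d[2L]) - 1) * sp[2L]
    zs <- image$origin_mm[3L] + (seq_len(d[3L]) - 1) * sp[3L]
    W <- cbind(
      rep(xs, times = d[2L] * d[3L]),
      rep(rep(ys, each = d[1L]), times = d[3L]),
      rep(zs, each = d[1L] * d[2L]))
    Wc <- sweep(W, 2L, ctr, "-")
    src <- sweep(Wc %*% rot, 2L, params$zoom, "/")  # t(t(rot) %*% t(Wc)) / zoom
    src <- sweep(src, 2L, ctr, "+")
    idx <- world_to_voxel(image, src)
    img_out <- array(sample_trilinear(image$data, idx, fill = fill), dim = d)
    lab_out <- array(sample_nearest(labels$data, idx, fill = 0L), dim = d)
  }
  img <- image_volume(img_out, sp, image$origin_mm, image$orientation)
  if (params$noise_sigma > 0 || params$artifact_strength > 0)
    img <- degrade_image(img, params$noise_sigma, params$artifact_strength,
                         seed = params$seed)
  list(image = img,
       labels = label_volume(lab_out, sp, labels$origin_mm,
                             labels$orientation))
}
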