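#' @useDynLib aortaseg, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Label vocabulary of aortic-root segmentations
#'
#' Integer codes used throughout the package for multi-class label
#' volumes: 0 background, 1 ascending aorta (AA), 2 left ventricle (LV),
#' 3 valve leaflet, 4 calcification.
#'
#' @format Named integer vector of length 5.
#' @export
LABEL_VOCAB <- c(background = 0L, AA = 1L, LV = 2L, leaflet = 3L,
                 calcification = 4L)

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_len3_positive <- function(x, name) {
  if (length(x) != 3L || !is.numeric(x) || any(!is.finite(x)) || any(x <= 0))
    stopf("'%s' must be 3 positive finite numbers", name)
  as.numeric(x)
}

#' Construct a 3-D image volume
#'
#' A dense scalar intensity grid (Hounsfield-unit-like, or normalized
#' after [clip_and_normalize()]) with voxel spacing in millimetres.
#' The world coordinate of voxel centre `(i, j, k)` (1-based) is
#' `origin_mm + (c(i, j, k) - 1) * spacing_mm`, axes ordered
#' right/anterior/superior (RAS-like).
#'
#' @param data Numeric 3-D array.
#' @param spacing_mm Per-axis voxel size in mm (3 positive numbers).
#' @param origin_mm World coordinate of the centre of voxel (1,1,1).
#' @param orientation Axis convention tag; only "RAS" is produced by
#'   this package.
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(data, spacing_mm, origin_mm = c(0, 0, 0),
                         orientation = "RAS") {
  if (!is.array(data) || length(dim(data)) != 3L)
    stopf("'data' must be a 3-D array")
  spacing_mm <- check_len3_positive(spacing_mm, "spacing_mm")
  if (length(origin_mm) != 3L || any(!is.finite(origin_mm)))
    stopf("'origin_mm' must be 3 finite numbers")
  structure(list(data = data, spacing_mm = spacing_mm,
                 origin_mm = as.numeric(origin_mm),
                 orientation = orientation),
            class = "image_volume")
}

#' Construct a 3-D label volume
#'
#' Integer grid on the same geometry as its paired image. Values must
#' belong to [LABEL_VOCAB].
#'
#' @inheritParams image_volume
#' @param data Integer-valued 3-D array over the label vocabulary.
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(data, spacing_mm, origin_mm = c(0, 0, 0),
                         orientation = "RAS") {
  if (!is.array(data) || length(dim(data)) != 3L)
    stopf("'data' must be a 3-D array")
  storage.mode(data) <- "integer"
  bad <- setdiff(unique(as.vector(data)), unname(LABEL_VOCAB))
  if (length(bad))
    stopf("label values outside vocabulary {0,1,2,3,4}: %s",
          paste(bad, collapse = ", "))
  vol <- image_volume(data, spacing_mm, origin_mm, orientation)
  class(vol) <- c("label_volume", "image_volume")
  vol
}

#' @export
print.image_volume <- function(x, ...) {
  kind <- if (inherits(x, "label_volume")) "label_volume" else "image_volume"
  cat(sprintf("<%s> %s voxels, spacing %s mm, origin (%s), %s\n",
              kind, paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing_mm, 4), collapse = "x"),
              paste(signif(x$origin_mm, 4), collapse = ", "),
              x$orientation))
  if (inherits(x, "label_volume")) {
    tab <- table(factor(as.vector(x$data), levels = unname(LABEL_VOCAB),
                        labels = names(LABEL_VOCAB)))
    cat("  labels:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "),
        "\n")
  }
  invisible(x)
}

#' Test geometric congruence of two volumes
#'
#' Two volumes are congruent when their grid shapes, spacings and
#' origins agree (spacing/origin to 1e-6 mm).
#'
#' @param a,b `image_volume` or `label_volume` objects.
#' @return Logical scalar.
#' @export
same_geometry <- function(a, b) {
  identical(dim(a$data), dim(b$data)) &&
    all(abs(a$spacing_mm - b$spacing_mm) < 1e-6) &&
    all(abs(a$origin_mm - b$origin_mm) < 1e-6)
}

stop_if_not_congruent <- function(a, b) {
  if (!same_geometry(a, b)) stopf("volumes are not geometrically congruent")
  invisible(TRUE)
}

#' World coordinates of voxels
#'
#' Converts 1-based voxel indices to world millimetre coordinates under
#' the volume's centre convention.
#'
#' @param vol An `image_volume`.
#' @param idx n x 3 matrix of 1-based voxel indices (may be fractional).
#' @return n x 3 matrix of mm coordinates.
#' @export
voxel_to_world <- function(vol, idx) {
  idx <- matrix(as.numeric(idx), ncol = 3L)
  sweep(sweep(idx - 1, 2L, vol$spacing_mm, "*"), 2L, vol$origin_mm, "+")
}

#' @rdname voxel_to_world
#' @param xyz n x 3 matrix of mm coordinates.
#' @export
world_to_voxel <- function(vol, xyz) {
  xyz <- matrix(as.numeric(xyz), ncol = 3L)
  sweep(sweep(xyz, 2L, vol$origin_mm, "-"), 2L, vol$spacing_mm, "/") + 1
}

#' Coordinates of foreground voxels in mm
#'
#' @param mask Logical/0-1 3-D array.
#' @param spacing_mm Per-axis voxel size.
#' @param origin_mm World coordinate of voxel (1,1,1); default 0.
#' @return n x 3 matrix of world coordinates of TRUE voxels.
#' @export
mask_coords_mm <- function(mask, spacing_mm, origin_mm = c(0, 0, 0)) {
  idx <- which(mask != 0, arr.ind = TRUE)
  sweep(sweep(matrix(as.numeric(idx), ncol = 3L) - 1, 2L,
              as.numeric(spacing_mm), "*"),
        2L, as.numeric(origin_mm), "+")
}

# Trilinear sampling of `arr` at fractional 1-based voxel indices.
# Points outside the grid (beyond the outermost voxel centres) get `fill`.
sample_trilinear <- function(arr, idx, fill = 0) {
  d <- dim(arr)
  i <- idx[, 1L]; j <- idx[, 2L]; k <- idx[, 3L]
  inside <- i >= 1 & i <= d[1L] & j >= 1 & j <= d[2L] & k >= 1 & k <= d[3L]
  out <- rep(as.numeric(fill), length(i))
  if (!any(inside)) return(out)
  i <- i[inside]; j <- j[inside]; k <- k[inside]
  i0 <- pmin(pmax(floor(i), 1), d[1L] - 1L); fi <- i - i0
  j0 <- pmin(pmax(floor(j), 1), d[2L] - 1L); fj <- j - j0
  k0 <- pmin(pmax(floor(k), 1), d[3L] - 1L); fk <- k - k0
  if (d[1L] == 1L) { i0 <- rep(1, length(i)); fi <- 0 }
  if (d[2L] == 1L) { j0 <- rep(1, length(j)); fj <- 0 }
  if (d[3L] == 1L) { k0 <- rep(1, length(k)); fk <- 0 }
  at <- function(ii, jj, kk) arr[cbind(ii, jj, kk)]
  i1 <- pmin(i0 + 1L, d[1L]); j1 <- pmin(j0 + 1L, d[2L]); k1 <- pmin(k0 + 1L, d[3L])
  v <- at(i0, j0, k0) * (1 - fi) * (1 - fj) * (1 - fk) +
       at(i1, j0, k0) * fi       * (1 - fj) * (1 - fk) +
       at(i0, j1, k0) * (1 - fi) * fj       * (1 - fk) +
       at(i1, j1, k0) * fi       * fj       * (1 - fk) +
       at(i0, j0, k1) * (1 - fi) * (1 - fj) * fk       +
       at(i1, j0, k1) * fi       * (1 - fj) * fk       +
       at(i0, j1, k1) * (1 - fi) * fj       * fk       +
       at(i1, j1, k1) * fi       * fj       * fk
  out[inside] <- v
  out
}

# Nearest-neighbour sampling at fractional 1-based indices; ties at the
# half-voxel boundary round half up (floor(x + 0.5)).
sample_nearest <- function(arr, idx, fill = 0L) {
  d <- dim(arr)
  i <- floor(idx[, 1L] + 0.5); j <- floor(idx[, 2L] + 0.5)
  k <- floor(idx[, 3L] + 0.5)
  inside <- i >= 1 & i <= d[1L] & j >= 1 & j <= d[2L] & k >= 1 & k <= d[3L]
  out <- rep(fill, nrow(idx))
  out[inside] <- arr[cbind(i[inside], j[inside], k[inside])]
  out
}
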