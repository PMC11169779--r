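#' Specification of a synthetic aortic-root phantom
#'
#' Describes one synthetic contrast-CTA-like case: a bright tubular
#' ascending aorta (AA) standing on an annular plane, a left-ventricle
#' (LV) ellipsoid capping it from below, and 2 or 3 thin curved leaflet
#' sheets spanning the annulus, separated at the commissures, with an
#' optional raphe ridge (Sievers type-1 bicuspid morphology) and
#' calcific nodules on the leaflet surfaces.
#'
#' Valve types follow the Sievers vocabulary restricted to the classes
#' this package models: `"TAV"` (tricuspid), `"BAV0"` (bicuspid, no
#' raphe) and `"BAV1"` (bicuspid, one raphe). `raphe` is forced `TRUE`
#' for BAV1 and `FALSE` otherwise.
#'
#' @param valve_type One of "TAV", "BAV0", "BAV1".
#' @param grid_shape Voxels per axis (each >= 32).
#' @param spacing_mm Per-axis voxel size in mm.
#' @param annulus_radius_mm Radius of the aortic annulus (mm).
#' @param aorta_length_mm Length of the ascending-aorta tube above the
#'   annular plane (mm).
#' @param leaflet_thickness_mm Leaflet sheet thickness (mm); must be
#'   smaller than the annulus radius.
#' @param cusp_gap_deg Angular width of the commissural gap between
#'   adjacent cusps, measured at the aortic wall (degrees).
#' @param n_calcifications Number of calcific nodules to place on the
#'   leaflet surfaces.
#' @param calcification_radius_mm Nodule radius (mm).
#' @param noise_sigma Gaussian noise level on the normalized 0-1
#'   intensity scale (0 = noiseless).
#' @param seed Integer seed; the phantom is a pure function of the spec.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(valve_type = c("TAV", "BAV0", "BAV1"),
                         grid_shape = c(64L, 64L, 64L),
                         spacing_mm = c(0.7, 0.7, 0.7),
                         annulus_radius_mm = 12,
                         aorta_length_mm = 20,
                         leaflet_thickness_mm = 1.8,
                         cusp_gap_deg = 14,
                         n_calcifications = 4L,
                         calcification_radius_mm = 1.5,
                         noise_sigma = 0,
                         seed = 1L) {
  valve_type <- match.arg(valve_type)
  spec <- structure(list(
    valve_type = valve_type,
    grid_shape = as.integer(grid_shape),
    spacing_mm = as.numeric(spacing_mm),
    annulus_radius_mm = annulus_radius_mm,
    aorta_length_mm = aorta_length_mm,
    leaflet_thickness_mm = leaflet_thickness_mm,
    cusp_gap_deg = cusp_gap_deg,
    raphe = identical(valve_type, "BAV1"),
    n_calcifications = as.integer(n_calcifications),
    calcification_radius_mm = calcification_radius_mm,
    noise_sigma = noise_sigma,
    seed = as.integer(seed)), class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  if (!inherits(spec, "phantom_spec")) stopf("not a phantom_spec")
  with(spec, {
    if (!valve_type %in% c("TAV", "BAV0", "BAV1"))
      stopf("invalid field 'valve_type': %s", valve_type)
    if (raphe != identical(valve_type, "BAV1"))
      stopf("invalid field 'raphe': must be TRUE iff valve_type is BAV1")
    if (length(grid_shape) != 3L || any(grid_shape < 32L))
      stopf("invalid field 'grid_shape': each axis must be >= 32")
    check_len3_positive(spacing_mm, "spacing_mm")
    for (f in c("annulus_radius_mm", "aorta_length_mm",
                "leaflet_thickness_mm", "calcification_radius_mm")) {
      v <- spec[[f]]
      if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
        stopf("invalid field '%s': must be a positive number", f)
    }
    if (leaflet_thickness_mm >= annulus_radius_mm)
      stopf("invalid field 'leaflet_thickness_mm': must be < annulus_radius_mm")
    if (cusp_gap_deg <= 0 || cusp_gap_deg >= 60)
      stopf("invalid field 'cusp_gap_deg': must be in (0, 60)")
    if (n_calcifications < 0L)
      stopf("invalid field 'n_calcifications': must be >= 0")
    if (noise_sigma < 0)
      stopf("invalid field 'noise_sigma': must be >= 0")
  })
  invisible(spec)
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf(
    "<phantom_spec> %s, grid %s @ %s mm, annulus R=%.1f mm, %d calc, noise %.3f, seed %d\n",
    x$valve_type, paste(x$grid_shape, collapse = "x"),
    paste(signif(x$spacing_mm, 3), collapse = "x"),
    x$annulus_radius_mm, x$n_calcifications, x$noise_sigma, x$seed))
  invisible(x)
}

# Canonical cusp layout: angle measured in the annular plane from +x
# (patient right) toward +y (anterior), degrees. The conventions here
# define the ground-truth naming the analysis stage must recover.
cusp_layout <- function(valve_type) {
  if (valve_type == "TAV") {
    list(names = c("right-coronary", "left-coronary", "non-coronary"),
         center_deg = c(90, 210, 330), width_deg = c(120, 120, 120))
  } else if (valve_type == "BAV0") {
    list(names = c("anterior", "posterior"),
         center_deg = c(90, 270), width_deg = c(180, 180))
  } else {
    # BAV1: the anterior cusp is the conjoint (fused) cusp carrying the
    # raphe, hence wider than its partner.
    list(names = c("anterior", "posterior"),
         center_deg = c(90, 280), width_deg = c(200, 160))
  }
}

ang_diff_deg <- function(a, b) {
  d <- (a - b) %% 360
  pmin(d, 360 - d)
}

#' Generate a synthetic aortic-root phantom
#'
#' Builds a paired image/label volume from a [phantom_spec()]. The label
#' volume contains exactly one connected AA component (a tube along the
#' z axis), one LV component (an ellipsoid below the annular plane), `k`
#' leaflet sheets (3 for TAV, 2 for BAV0/BAV1) as thin cup-shaped wedges
#' separated by commissural gaps of at least two voxels, BAV1's raphe as
#' a thin leaflet-labelled fin on the conjoint cusp, and calcific
#' nodules on the leaflet surfaces. Pre-noise intensities: blood pool
#' 400 HU, leaflets 150 HU, calcification 1000 HU, background -50 HU.
#'
#' The generator is a pure function of the spec: the same spec always
#' yields bit-identical volumes.
#'
#' @param spec A [phantom_spec()].
#' @return List with elements `image` ([image_volume]), `labels`
#'   ([label_volume]) and `meta` (ground-truth geometry: cusp names and
#'   centre angles, annular plane height, long axis, raphe angle).
#' @export
generate_phantom <- function(spec) {
  validate_phantom_spec(spec)
  d <- spec$grid_shape; sp <- spec$spacing_mm
  ext <- (d - 1L) * sp
  cx <- ext[1L] / 2; cy <- ext[2L] / 2
  R <- spec$annulus_radius_mm
  t2 <- spec$leaflet_thickness_mm / 2
  z0 <- 0.45 * ext[3L]                       # annular plane height
  z_top <- min(z0 + spec$aorta_length_mm, ext[3L] - sp[3L])
  gap_half <- R * spec$cusp_gap_deg * pi / 180 / 2  # gap half-width, mm
  cup_depth <- min(4, 0.35 * R)
  # central coaptation hole: minimal, as closed leaflets meet centrally;
  # inter-cusp separation is guaranteed by the constant-width gap bands
  r_hole <- max(1, gap_half)

  xs <- (seq_len(d[1L]) - 1) * sp[1L] - cx
  ys <- (seq_len(d[2L]) - 1) * sp[2L] - cy
  zs <- (seq_len(d[3L]) - 1) * sp[3L]
  X <- array(rep(xs, times = d[2L] * d[3L]), dim = d)
  Y <- array(rep(rep(ys, each = d[1L]), times = d[3L]), dim = d)
  Z <- array(rep(zs, each = d[1L] * d[2L]), dim = d)
  Rxy <- sqrt(X^2 + Y^2)
  theta <- (atan2(Y, X) * 180 / pi) %% 360

  lab <- array(0L, dim = d)

  # ascending aorta: blood-filled tube above the annular plane
  aa <- Rxy <= R & Z >= z0 & Z <= z_top
  lab[aa] <- LABEL_VOCAB[["AA"]]

  # left ventricle: ellipsoid body plus a cylindrical outflow tract of
  # annular caliber reaching the annular plane, so the leaflets sit on
  # blood (as over the real LVOT), not on background
  az <- min(10, (z0 - 2) / 2) * 2
  lv_sxy <- min(1.35 * R, cx - 2, cy - 2)
  lv_cz <- z0 - az / 2 - 2
  lv <- (((X / lv_sxy)^2 + (Y / lv_sxy)^2 +
            ((Z - lv_cz) / (az / 2))^2) <= 1 |
           (Rxy <= R & Z >= z0 - 6)) & Z < z0
  lab[lv] <- LABEL_VOCAB[["LV"]]

  # leaflets: thin cup-shaped sheets z_s(r) = z0 + cup_depth*(1-(r/R)^2),
  # one per cusp sector, with constant-width commissural gap bands
  layout <- cusp_layout(spec$valve_type)
  k <- length(layout$names)
  zsurf <- z0 + cup_depth * (1 - (Rxy / R)^2)
  sheet <- Rxy >= r_hole & Rxy <= R & abs(Z - zsurf) <= t2
  # distance to a boundary ray at angle a (degrees): |p x u| where the
  # projection on the ray is positive, else distance to the origin
  ray_dist <- function(a) {
    u <- c(cos(a * pi / 180), sin(a * pi / 180))
    along <- X * u[1L] + Y * u[2L]
    perp <- abs(X * u[2L] - Y * u[1L])
    ifelse(along > 0, perp, Rxy)
  }
  bounds <- sort(unique((layout$center_deg + layout$width_deg / 2) %% 360))
  in_gap <- array(FALSE, dim = d)
  for (b in bounds) in_gap <- in_gap | (ray_dist(b) < gap_half)
  leaflet <- sheet & !in_gap
  lab[leaflet] <- LABEL_VOCAB[["leaflet"]]

  # raphe: thin fin standing on the conjoint cusp, mid-sector, running
  # from near the free edge to the wall
  raphe_deg <- NA_real_
  if (spec$raphe) {
    raphe_deg <- layout$center_deg[1L]
    fin_h <- min(3.5, 2.5 * spec$leaflet_thickness_mm)
    fin <- ray_dist(raphe_deg) <= t2 & Rxy >= max(r_hole, 0.25 * R) &
      Rxy <= R & Z >= zsurf - t2 & Z <= zsurf + fin_h
    lab[fin] <- LABEL_VOCAB[["leaflet"]]
  }

  # calcific nodules on the leaflet surfaces, non-overlapping, clear of
  # the commissural gaps and the raphe
  calc_centers <- NULL
  if (spec$n_calcifications > 0L) {
    rc <- spec$calcification_radius_mm
    centers <- withr::with_seed(spec$seed, {
      acc <- matrix(numeric(0), ncol = 3L)
      tries <- 0L
      while (nrow(acc) < spec$n_calcifications && tries < 2000L) {
        tries <- tries + 1L
        ci <- sample.int(k, 1L)
        half <- layout$width_deg[ci] / 2
        marg_deg <- (gap_half + rc + max(sp)) / (0.45 * R) * 180 / pi
        if (2 * (half - marg_deg) <= 0) next
        a <- (layout$center_deg[ci] +
                stats::runif(1, -half + marg_deg, half - marg_deg)) %% 360
        if (spec$raphe && ci == 1L &&
            ang_diff_deg(a, raphe_deg) < (rc + 2 * t2) / (0.45 * R) * 180 / pi)
          next
        rr <- stats::runif(1, 0.45 * R, 0.85 * R)
        p <- c(rr * cos(a * pi / 180), rr * sin(a * pi / 180),
               z0 + cup_depth * (1 - (rr / R)^2))
        if (nrow(acc) &&
            min(sqrt(colSums((t(acc) - p)^2))) < 2 * rc + 2 * max(sp)) next
        acc <- rbind(acc, p)
      }
      if (nrow(acc) < spec$n_calcifications)
        stopf("invalid field 'n_calcifications': cannot place %d non-overlapping nodules",
              spec$n_calcifications)
      acc
    })
    for (i in seq_len(nrow(centers))) {
      p <- centers[i, ]
      speck <- (X - p[1L])^2 + (Y - p[2L])^2 + (Z - p[3L])^2 <= rc^2
      lab[speck] <- LABEL_VOCAB[["calcification"]]
    }
    calc_centers <- centers
  }

  hu <- array(-50, dim = d)
  hu[lab == LABEL_VOCAB[["AA"]] | lab == LABEL_VOCAB[["LV"]]] <- 400
  hu[lab == LABEL_VOCAB[["leaflet"]]] <- 150
  hu[lab == LABEL_VOCAB[["calcification"]]] <- 1000

  img <- image_volume(hu, sp)
  if (spec$noise_sigma > 0)
    img <- degrade_image(img, noise_sigma = spec$noise_sigma,
                         artifact_strength = 0, seed = spec$seed)

  list(image = img,
       labels = label_volume(lab, sp),
       meta = list(valve_type = spec$valve_type,
                   cusp_names = layout$names,
                   cusp_center_deg = layout$center_deg,
                   annulus_z_mm = z0, center_xy_mm = c(cx, cy),
                   axis = c(0, 0, 1), raphe_deg = raphe_deg,
                   calc_centers_mm = calc_centers))
}

#' Generate a balanced phantom cohort
#'
#' Produces `3 * n_per_class` cases, equally many TAV, BAV0 and BAV1,
#' each with a distinct derived seed and geometric parameters jittered
#' by up to +/-10% of the base spec's lengths.
#'
#' @param n_per_class Cases per valve class (>= 1).
#' @param base_spec Base [phantom_spec()]; its `valve_type` is ignored.
#' @param seed Integer seed driving the per-case seeds and jitter.
#' @return List with `cases` (list of `generate_phantom()` outputs, each
#'   also carrying its `spec`) and `manifest` (data.frame: case id,
#'   valve class, seed, jittered spec fields).
#' @export
generate_cohort <- function(n_per_class, base_spec = phantom_spec(),
                            seed = 1L) {
  if (n_per_class < 1L) stopf("'n_per_class' must be >= 1")
  classes <- rep(c("TAV", "BAV0", "BAV1"), each = n_per_class)
  n <- length(classes)
  rand <- withr::with_seed(seed, list(
    seeds = sample.int(.Machine$integer.max - 1L, n),
    jitter = matrix(stats::runif(n * 4L, 0.9, 1.1), ncol = 4L)))
  cases <- vector("list", n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    sp_i <- phantom_spec(
      valve_type = classes[i],
      grid_shape = base_spec$grid_shape,
      spacing_mm = base_spec$spacing_mm,
      annulus_radius_mm = base_spec$annulus_radius_mm * rand$jitter[i, 1L],
      aorta_length_mm = base_spec$aorta_length_mm * rand$jitter[i, 2L],
      leaflet_thickness_mm = base_spec$leaflet_thickness_mm * rand$jitter[i, 3L],
      cusp_gap_deg = base_spec$cusp_gap_deg,
      n_calcifications = base_spec$n_calcifications,
      calcification_radius_mm = base_spec$calcification_radius_mm *
        rand$jitter[i, 4L],
      noise_sigma = base_spec$noise_sigma,
      seed = rand$seeds[i])
    ph <- generate_phantom(sp_i)
    ph$spec <- sp_i
    ph$id <- sprintf("case_%04d", i)
    cases[[i]] <- ph
    rows[[i]] <- data.frame(
      case_id = ph$id, valve_class = classes[i], seed = rand$seeds[i],
      annulus_radius_mm = sp_i$annulus_radius_mm,
      aorta_length_mm = sp_i$aorta_length_mm,
      leaflet_thickness_mm = sp_i$leaflet_thickness_mm,
      cusp_gap_deg = sp_i$cusp_gap_deg,
      n_calcifications = sp_i$n_calcifications,
      calcification_radius_mm = sp_i$calcification_radius_mm,
      noise_sigma = sp_i$noise_sigma, stringsAsFactors = FALSE)
  }
  list(cases = cases, manifest = do.call(rbind, rows))
}

#' Degrade an image with noise and low-frequency artifacts
#'
#' Adds seeded Gaussian noise (standard deviation `noise_sigma` on the
#' normalized 0-1 scale, i.e. `noise_sigma * 1200` HU) and, when
#' `artifact_strength > 0`, additive low-frequency bias fields and
#' planar streaks mimicking compromised imaging quality. Geometry is
#' unchanged; with both parameters zero the input is returned exactly.
#'
#' @param image An [image_volume] on the HU scale.
#' @param noise_sigma Gaussian noise level on the normalized scale (>= 0).
#' @param artifact_strength Artifact amplitude on the normalized scale
#'   (>= 0).
#' @param seed Integer seed.
#' @return Degraded [image_volume].
#' @export
degrade_image <- function(image, noise_sigma, artifact_strength = 0,
                          seed = 1L) {
  if (noise_sigma < 0) stopf("'noise_sigma' must be >= 0")
  if (artifact_strength < 0) stopf("'artifact_strength' must be >= 0")
  if (noise_sigma == 0 && artifact_strength == 0) return(image)
  d <- dim(image$data)
  out <- image$data
  withr::with_seed(seed, {
    if (noise_sigma > 0)
      out <- out + array(stats::rnorm(prod(d), 0, noise_sigma * 1200), dim = d)
    if (artifact_strength > 0) {
      xs <- seq(0, 1, length.out = d[1L])
      ys <- seq(0, 1, length.out = d[2L])
      zs <- seq(0, 1, length.out = d[3L])
      bias <- array(0, dim = d)
      for (m in 1:3) {
        f <- stats::runif(3, 0.5, 2); ph <- stats::runif(3, 0, 2 * pi)
        amp <- artifact_strength * 1200 / 3
        bias <- bias + amp *
          outer(outer(cos(2 * pi * f[1L] * xs + ph[1L]),
                      cos(2 * pi * f[2L] * ys + ph[2L])),
                cos(2 * pi * f[3L] * zs + ph[3L]))
      }
      # two planar streaks with a Gaussian cross-profile
      X <- array(rep(xs, times = d[2L] * d[3L]), dim = d)
      Y <- array(rep(rep(ys, each = d[1L]), times = d[3L]), dim = d)
      Z <- array(rep(zs, each = d[1L] * d[2L]), dim = d)
      for (s in 1:2) {
        nrm <- stats::rnorm(3); nrm <- nrm / sqrt(sum(nrm^2))
        off <- stats::runif(1, 0.2, 0.8)
        amp <- artifact_strength * 1200 * sample(c(-1, 1), 1)
        dist <- X * nrm[1L] + Y * nrm[2L] + Z * nrm[3L] - off
        bias <- bias + amp * exp(-(dist / 0.03)^2 / 2)
      }
      out <- out + bias
    }
  })
  image_volume(out, image$spacing_mm, image$origin_mm, image$orientation)
}
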