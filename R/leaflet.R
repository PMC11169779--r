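#' Label connected components of a binary 3-D mask
#'
#' @param mask Logical or 0/1 3-D array.
#' @param connectivity 6 (faces) or 26 (faces, edges and corners;
#'   default — thin oblique leaflet sheets fragment under 6-connectivity).
#' @return Integer array of component labels (0 = background), numbered
#'   in column-major scan order of each component's first voxel.
#' @export
label_components <- function(mask, connectivity = 26L) {
  if (!connectivity %in% c(6L, 26L)) stopf("connectivity must be 6 or 26")
  d <- dim(mask)
  if (length(d) != 3L) stopf("'mask' must be a 3-D array")
  lab <- cpp_label_components(as.integer(mask != 0), as.integer(d),
                              as.integer(connectivity))
  array(lab, dim = d)
}

#' Keep only the largest connected component
#'
#' Removes scattered segmentation pieces by retaining the
#' maximum-cardinality connected component. Size ties are broken in
#' favour of the component containing the lexicographically smallest
#' voxel index (i, then j, then k).
#'
#' @inheritParams label_components
#' @return Logical 3-D array containing only the winning component.
#' @export
keep_largest_component <- function(mask, connectivity = 26L) {
  lab <- label_components(mask, connectivity)
  if (!any(lab > 0L)) stopf("empty structure: mask has no foreground voxel")
  sizes <- tabulate(lab)
  winners <- which(sizes == max(sizes))
  if (length(winners) > 1L) {
    # lexicographic (i, j, k) order of each candidate's smallest voxel
    key <- vapply(winners, function(w) {
      ijk <- which(lab == w, arr.ind = TRUE)
      ijk <- ijk[order(ijk[, 1L], ijk[, 2L], ijk[, 3L]), , drop = FALSE]
      sum(ijk[1L, ] * c(1e12, 1e6, 1))
    }, numeric(1L))
    winners <- winners[which.min(key)]
  }
  lab == winners[1L]
}

#' Drop small connected components
#'
#' Keeps every component whose voxel count is at least `min_voxels` and
#' at least `min_fraction` of the mask's total foreground. Used for
#' structures that are legitimately multi-component (leaflets,
#' calcification), where strict largest-component filtering would delete
#' true anatomy.
#'
#' @inheritParams label_components
#' @param min_voxels Absolute size floor (voxels).
#' @param min_fraction Relative size floor (fraction of foreground).
#' @return Logical 3-D array.
#' @export
filter_small_components <- function(mask, connectivity = 26L,
                                    min_voxels = 1L, min_fraction = 0) {
  lab <- label_components(mask, connectivity)
  if (!any(lab > 0L)) return(array(FALSE, dim = dim(mask)))
  sizes <- tabulate(lab)
  keep <- which(sizes >= max(min_voxels, min_fraction * sum(sizes)))
  array(lab %in% keep & lab > 0L, dim = dim(mask))
}

mean_silhouette <- function(coords, cl) {
  s <- cluster::silhouette(cl, stats::dist(coords))
  mean(s[, "sil_width"])
}

# logical array marking leaflet voxels with a 26-neighbour assigned to a
# different cluster (the cluster "cut" surface)
cluster_disagreement <- function(mask, assignment) {
  d <- dim(mask)
  asg <- array(0L, dim = d)
  asg[which(mask != 0)] <- as.integer(assignment)
  offs <- neighbor_offsets(26L)
  bad <- array(FALSE, dim = d)
  for (r in seq_len(nrow(offs))) {
    o <- offs[r, ]
    sh <- array(0L, dim = d)
    src <- lapply(1:3, function(ax)
      max(1L, 1L - o[ax]):min(d[ax], d[ax] - o[ax]))
    dst <- lapply(1:3, function(ax) src[[ax]] + o[ax])
    sh[dst[[1L]], dst[[2L]], dst[[3L]]] <- asg[src[[1L]], src[[2L]], src[[3L]]]
    bad <- bad | (asg > 0L & sh > 0L & sh != asg)
  }
  bad
}

#' Determine the number of valve cusps by clustering
#'
#' Runs seeded K-means (10 restarts) on the world coordinates (mm) of
#' the leaflet voxels for k = 2 and k = 3 and picks the k whose cluster
#' boundaries coincide with real commissural gaps: for the correct k
#' the K-means partition separates along the gaps and almost no leaflet
#' voxel touches a differently-assigned 26-neighbour, while the wrong k
#' must cut through a continuous cusp sheet. The k with the smaller
#' boundary-cut fraction wins; when the two fractions are within
#' `cut_tol` of each other (e.g. a single merged leaflet mass) the mean
#' silhouette coefficient decides, with silhouette ties going to k = 3,
#' the prevalent tricuspid morphology. Silhouettes are evaluated on a
#' seeded subsample of at most `max_silhouette_points` voxels shared
#' between the two candidate partitions, and are always reported.
#'
#' @param leaflet_mask Logical/0-1 3-D array of leaflet voxels.
#' @param spacing_mm Voxel size triple (mm).
#' @param seed Integer seed; the result is deterministic given the seed.
#' @param min_voxels Minimum leaflet voxel count (default 200).
#' @param cut_tol Boundary-cut fraction difference below which the
#'   silhouette fallback decides (default 0.01).
#' @param tie_tol Silhouette difference below which k = 3 wins in the
#'   fallback (default 0.005).
#' @param max_silhouette_points Subsample cap for silhouette evaluation.
#' @return List: `k` (2 or 3), `assignment` (integer 1..k per leaflet
#'   voxel, in column-major order of `which(leaflet_mask)`),
#'   `silhouettes` and `cut_fractions` (named vectors for k2/k3),
#'   `coords_mm`.
#' @export
determine_cuspid_number <- function(leaflet_mask, spacing_mm, seed = 1L,
                                    min_voxels = 200L, cut_tol = 0.01,
                                    tie_tol = 0.005,
                                    max_silhouette_points = 1500L) {
  coords <- mask_coords_mm(leaflet_mask, spacing_mm)
  n <- nrow(coords)
  if (n < min_voxels)
    stopf("insufficient leaflet volume: %d voxels (< %d)", n, min_voxels)
  res <- withr::with_seed(seed, {
    # empty-cluster warnings are routine when k exceeds the natural
    # cluster count (e.g. k = 3 fitted to a bicuspid valve)
    fits <- lapply(c(2L, 3L), function(k)
      suppressWarnings(
        stats::kmeans(coords, centers = k, nstart = 10L, iter.max = 200L,
                      algorithm = "Lloyd")))
    sub <- if (n > max_silhouette_points)
      sort(sample.int(n, max_silhouette_points)) else seq_len(n)
    sils <- vapply(fits, function(f)
      mean_silhouette(coords[sub, , drop = FALSE], f$cluster[sub]),
      numeric(1L))
    list(fits = fits, sils = sils)
  })
  cuts <- stats::setNames(vapply(res$fits, function(f)
    sum(cluster_disagreement(leaflet_mask, f$cluster)) / n, numeric(1L)),
    c("k2", "k3"))
  sils <- stats::setNames(res$sils, c("k2", "k3"))
  pick <- if (abs(cuts[["k2"]] - cuts[["k3"]]) >= cut_tol)
    which.min(cuts)
  else if (abs(sils[["k2"]] - sils[["k3"]]) < tie_tol) 2L
  else which.max(sils)
  fit <- res$fits[[pick]]
  # stable cluster numbering: order clusters by centroid (x, then y, z)
  ord <- order(fit$centers[, 1L], fit$centers[, 2L], fit$centers[, 3L])
  relabel <- match(seq_len(nrow(fit$centers)), ord)
  list(k = c(2L, 3L)[pick],
       assignment = as.integer(relabel[fit$cluster]),
       silhouettes = sils, cut_fractions = cuts,
       coords_mm = coords)
}

# 26-neighbourhood offsets as an integer matrix
neighbor_offsets <- function(connectivity = 26L) {
  g <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  if (connectivity == 6L) g <- g[rowSums(abs(g)) == 1L, , drop = FALSE]
  g
}

#' Refine the inter-leaflet boundary by K-nearest-neighbour voting
#'
#' Voxels in the boundary band — leaflet voxels with at least one
#' 26-neighbour assigned to a different cluster, dilated by one voxel —
#' are re-labelled by the majority vote of their `n_neighbors` nearest
#' leaflet voxels outside the band (world coordinates, mm). Ties go to
#' the lower cluster index. Interior voxels are untouched; the voxel set
#' itself never changes.
#'
#' @param leaflet_mask Logical/0-1 3-D array.
#' @param assignment Integer cluster per leaflet voxel (column-major
#'   order), from [determine_cuspid_number()].
#' @param n_neighbors Odd neighbour count (default 15).
#' @param spacing_mm Voxel size triple (mm).
#' @return Refined integer assignment of the same length.
#' @export
refine_leaflet_boundary <- function(leaflet_mask, assignment,
                                    n_neighbors = 15L, spacing_mm) {
  idx <- which(leaflet_mask != 0)
  if (length(idx) != length(assignment))
    stopf("assignment length does not match leaflet voxel count")
  d <- dim(leaflet_mask)
  asg <- array(0L, dim = d)
  asg[idx] <- as.integer(assignment)
  offs <- neighbor_offsets(26L)
  shift_arr <- function(a, o) {
    out <- array(0L, dim = d)
    src <- lapply(1:3, function(ax)
      max(1L, 1L - o[ax]):min(d[ax], d[ax] - o[ax]))
    dst <- lapply(1:3, function(ax) src[[ax]] + o[ax])
    out[dst[[1L]], dst[[2L]], dst[[3L]]] <- a[src[[1L]], src[[2L]], src[[3L]]]
    out
  }
  disagree <- cluster_disagreement(leaflet_mask, assignment)
  # dilate the band by one voxel (within the mask)
  band <- disagree
  for (r in seq_len(nrow(offs)))
    band <- band | (shift_arr(array(as.integer(disagree), dim = d),
                              offs[r, ]) > 0L & asg > 0L)
  band_idx <- which(band)
  if (length(band_idx) == 0L) return(as.integer(assignment))
  ref_idx <- setdiff(idx, band_idx)
  if (length(ref_idx) < n_neighbors)
    stopf("n_neighbors (%d) exceeds available reference voxels (%d)",
          n_neighbors, length(ref_idx))
  to_mm <- function(ii) {
    ijk <- arrayInd(ii, d)
    sweep(matrix(as.numeric(ijk), ncol = 3L) - 1, 2L,
          as.numeric(spacing_mm), "*")
  }
  k <- max(assignment)
  votes <- cpp_knn_vote(to_mm(band_idx), to_mm(ref_idx),
                        asg[ref_idx] - 1L, as.integer(n_neighbors),
                        as.integer(k))
  asg[band_idx] <- votes + 1L
  as.integer(asg[idx])
}

#' Name the leaflets by anatomical position
#'
#' Estimates the valve's long axis from the ascending-aorta and
#' left-ventricle centroids in the label volume, projects the cluster
#' centroids onto the annular plane, and names clusters by angular
#' position. Angles are measured in the annular plane from +x (patient
#' right) toward +y (anterior). Convention: for k = 3 the canonical
#' centre angles are right-coronary 90, left-coronary 210 and
#' non-coronary 330 degrees, and names are matched to centroids by the
#' permutation minimizing total angular discrepancy; for k = 2 the
#' cluster with the more anterior (larger +y) centroid is "anterior",
#' the other "posterior".
#'
#' @param assignment Integer cluster per leaflet voxel (column-major).
#' @param leaflet_mask Logical/0-1 3-D array.
#' @param labels [label_volume] providing AA and LV voxels for the axis.
#' @return Character vector of length k: name of each cluster index.
#' @export
name_leaflets <- function(assignment, leaflet_mask, labels) {
  sp <- labels$spacing_mm
  aa <- labels$data == LABEL_VOCAB[["AA"]]
  lv <- labels$data == LABEL_VOCAB[["LV"]]
  if (!any(aa) || !any(lv))
    stopf("degenerate geometry: AA or LV absent from label volume")
  c_aa <- colMeans(mask_coords_mm(aa, sp))
  c_lv <- colMeans(mask_coords_mm(lv, sp))
  axis <- c_aa - c_lv
  nrm <- sqrt(sum(axis^2))
  if (nrm < 1e-6) stopf("degenerate geometry: AA and LV centroids coincide")
  axis <- axis / nrm
  # in-plane frame anchored to the world axes
  e1 <- c(1, 0, 0) - sum(c(1, 0, 0) * axis) * axis
  if (sqrt(sum(e1^2)) < 1e-6) e1 <- c(0, 1, 0) - sum(c(0, 1, 0) * axis) * axis
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(axis[2L] * e1[3L] - axis[3L] * e1[2L],
          axis[3L] * e1[1L] - axis[1L] * e1[3L],
          axis[1L] * e1[2L] - axis[2L] * e1[1L])
  coords <- mask_coords_mm(leaflet_mask, sp)
  k <- max(assignment)
  ctr <- colMeans(coords)
  ang <- vapply(seq_len(k), function(ci) {
    p <- colMeans(coords[assignment == ci, , drop = FALSE]) - ctr
    (atan2(sum(p * e2), sum(p * e1)) * 180 / pi) %% 360
  }, numeric(1L))
  if (k == 3L) {
    canon <- c("right-coronary" = 90, "left-coronary" = 210,
               "non-coronary" = 330)
    perms <- list(1:3, c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2),
                  c(3, 2, 1))
    cost <- vapply(perms, function(p)
      sum(ang_diff_deg(ang, canon[p])), numeric(1L))
    best <- perms[[which.min(cost)]]
    names(canon)[best]
  } else if (k == 2L) {
    anterior_first <- ang_diff_deg(ang[1L], 90) < ang_diff_deg(ang[2L], 90)
    if (anterior_first) c("anterior", "posterior")
    else c("posterior", "anterior")
  } else stopf("k must be 2 or 3")
}

#' Classify the valve and detect a raphe
#'
#' Three clusters imply a tricuspid valve (TAV). Two clusters imply a
#' bicuspid valve, subtyped by a raphe detector: the leaflet voxel cloud
#' is expressed in its own principal frame (sheet normal = smallest
#' principal axis), the radial height profile of the cusp surfaces is
#' removed, and a raphe is declared when a ridge of voxels stands
#' clear of the sheets — angularly concentrated and spanning radially
#' from the free-edge region toward the wall. Found: Sievers type 1
#' (BAV1); otherwise type 0 (BAV0).
#'
#' @param k Cluster count from [determine_cuspid_number()] (2 or 3).
#' @param leaflet_mask Logical/0-1 3-D array.
#' @param spacing_mm Voxel size triple (mm).
#' @param assignment Integer cluster per leaflet voxel (unused by the
#'   detector but part of the stage contract).
#' @param image Optional [image_volume]; reserved for intensity-aware
#'   detection, unused by the geometric detector.
#' @return List: `valve_class` ("TAV", "BAV0" or "BAV1") and
#'   `raphe_detected` (logical).
#' @export
classify_valve <- function(k, leaflet_mask, spacing_mm, assignment = NULL,
                           image = NULL) {
  if (!k %in% c(2L, 3L)) stopf("k must be 2 or 3")
  if (k == 3L)
    return(list(valve_class = "TAV", raphe_detected = FALSE))
  raphe <- detect_raphe(leaflet_mask, spacing_mm)
  list(valve_class = if (raphe) "BAV1" else "BAV0", raphe_detected = raphe)
}

# Geometric raphe detector; see classify_valve().
#
# The leaflet voxel cloud is expressed in its principal frame (sheet
# normal = smallest principal axis) and the shared radial height
# profile of the cusp surfaces is subtracted. A raphe ridge stands
# proud of the sheets, so its voxels carry height residuals well above
# the sheet thickness, concentrated in a narrow angular sector and
# spanning radially from the free-edge region toward the wall. Evidence
# is integrated per 10-degree angular bin as the mean residual excess
# over `resid_floor_mm`, smoothed over 3 adjacent bins; a raphe is
# declared when the peak window carries absolute evidence >=
# `peak_min_mm`, dominates the angular background by `peak_ratio`, and
# its ridge voxels span >= `radial_span_frac` of the valve radius.
detect_raphe <- function(leaflet_mask, spacing_mm,
                         resid_floor_mm = 1.2, peak_min_mm = 0.10,
                         peak_ratio = 3, radial_span_frac = 0.35) {
  coords <- mask_coords_mm(leaflet_mask, spacing_mm)
  if (nrow(coords) < 50L) return(FALSE)
  ctr <- colMeans(coords)
  cc <- sweep(coords, 2L, ctr)
  ev <- eigen(stats::cov(cc), symmetric = TRUE)
  h <- cc %*% ev$vectors[, 3L]
  p1 <- cc %*% ev$vectors[, 1L]; p2 <- cc %*% ev$vectors[, 2L]
  r <- sqrt(p1^2 + p2^2)
  th <- (atan2(p2, p1) * 180 / pi) %% 360
  rmax <- stats::quantile(r, 0.98, names = FALSE)
  nb <- 12L
  bin <- pmin(pmax(ceiling(r / rmax * nb), 1L), nb)
  base <- vapply(seq_len(nb), function(b)
    if (any(bin == b)) stats::median(h[bin == b]) else 0, numeric(1L))
  resid <- abs(h - base[bin])
  sel <- r > 0.25 * rmax & r < 0.95 * rmax
  ab <- pmin(pmax(ceiling(th / 10), 1L), 36L)
  e <- vapply(1:36, function(b) {
    i <- sel & ab == b
    if (sum(i) < 5L) 0 else mean(pmax(resid[i] - resid_floor_mm, 0))
  }, numeric(1L))
  w <- vapply(1:36, function(b) mean(e[((b - 2):b - 1) %% 36 + 1]),
              numeric(1L))
  peak <- which.max(w)
  if (w[peak] < peak_min_mm) return(FALSE)
  if (w[peak] < peak_ratio * (stats::median(w) + 0.02)) return(FALSE)
  # ridge voxels in the peak window must span the radius like a raphe
  win_bins <- ((peak - 2):peak - 1) %% 36 + 1
  ridge <- sel & ab %in% win_bins & resid > resid_floor_mm
  if (sum(ridge) < 8L) return(FALSE)
  diff(range(r[ridge])) >= radial_span_frac * rmax
}

#' Confusion matrix and overall accuracy
#'
#' Cross-tabulates expert (rows) against predicted (columns) valve
#' classes; accuracy is the trace over the total.
#'
#' @param predicted,expert Equal-length non-empty class vectors.
#' @param classes Class vocabulary (default: TAV, BAV0, BAV1).
#' @return A `confusion_matrix` object: `classes`, `counts` (square
#'   table, rows = expert), `accuracy`.
#' @export
confusion_and_accuracy <- function(predicted, expert,
                                   classes = c("TAV", "BAV0", "BAV1")) {
  if (length(predicted) == 0L || length(expert) == 0L)
    stopf("class lists must be non-empty")
  if (length(predicted) != length(expert))
    stopf("predicted and expert lists differ in length")
  bad <- setdiff(unique(c(predicted, expert)), classes)
  if (length(bad))
    stopf("unknown class value(s): %s", paste(bad, collapse = ", "))
  counts <- table(factor(expert, levels = classes),
                  factor(predicted, levels = classes))
  structure(list(classes = classes,
                 counts = unclass(counts),
                 accuracy = sum(diag(counts)) / sum(counts)),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("<confusion_matrix> rows = expert, columns = predicted\n")
  print(x$counts)
  cat(sprintf("accuracy: %.4f\n", x$accuracy))
  invisible(x)
}
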