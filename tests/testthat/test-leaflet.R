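test_that("keep_largest_component matches the flood-fill oracle", {
  m <- array(FALSE, dim = c(16L, 16L, 16L))
  m[2:6, 2:6, 2:5] <- TRUE        # 100 voxels
  m[12:12, 12:16, 12:12] <- TRUE  # 5 voxels
  kept <- keep_largest_component(m)
  lab <- flood_fill_components(m)
  big <- which.max(tabulate(lab))
  expect_identical(kept, lab == big)
  expect_equal(sum(kept), 100L, ignore_attr = TRUE)
  # single component: identity
  s <- array(FALSE, dim = c(8L, 8L, 8L)); s[3:5, 3:5, 3:5] <- TRUE
  expect_identical(keep_largest_component(s), s)
  expect_error(keep_largest_component(array(FALSE, dim = c(4L, 4L, 4L))),
               "empty structure")
})

test_that("equal-size ties go to the lexicographically smallest voxel", {
  m <- array(FALSE, dim = c(12L, 12L, 12L))
  m[8:9, 8:9, 1:2] <- TRUE   # earlier in k, later in (i,j,k) lex order
  m[2:3, 2:3, 8:9] <- TRUE   # smaller (i,j) => lex winner
  expect_equal(sum(m), 16L, ignore_attr = TRUE)
  kept <- keep_largest_component(m)
  expect_true(all(kept[2:3, 2:3, 8:9]))
  expect_false(any(kept[8:9, 8:9, 1:2]))
})

make_clouds <- function(k, n_each = 60L, radius_deg = c(90, 210, 330)) {
  set.seed(10L + k)
  do.call(rbind, lapply(seq_len(k), function(i) {
    a <- radius_deg[i] * pi / 180
    cbind(10 * cos(a) + rnorm(n_each, 0, 0.8),
          10 * sin(a) + rnorm(n_each, 0, 0.8),
          rnorm(n_each, 0, 0.8))
  }))
}

cloud_mask <- function(pts, spacing = 1) {
  ijk <- round(sweep(pts, 2L, apply(pts, 2L, min) - 3, "-")) + 1L
  d <- apply(ijk, 2L, max) + 2L
  m <- array(FALSE, dim = d)
  m[ijk] <- TRUE
  m
}

test_that("cuspid number is recovered for separated cloud geometries", {
  for (k_true in c(2L, 3L)) {
    pts <- make_clouds(k_true)
    m <- cloud_mask(pts)
    res <- determine_cuspid_number(m, c(1, 1, 1), seed = 1L,
                                   min_voxels = 50L)
    expect_equal(res$k, k_true)
    # the chosen partition agrees with an independently computed
    # silhouette ranking on the same voxel cloud
    co <- mask_coords_mm(m, c(1, 1, 1))
    set.seed(1)
    s2 <- brute_mean_silhouette(co, stats::kmeans(co, 2, nstart = 5)$cluster)
    s3 <- brute_mean_silhouette(co, stats::kmeans(co, 3, nstart = 5)$cluster)
    expect_equal(res$k, if (s2 > s3) 2L else 3L)
  }
})

test_that("cuspid determination is deterministic and validates input", {
  ph <- generate_phantom(small_spec("TAV", seed = 6L))
  leaf <- ph$labels$data == 3L
  a <- determine_cuspid_number(leaf, sp07, seed = 9L)
  b <- determine_cuspid_number(leaf, sp07, seed = 9L)
  expect_identical(a$k, b$k)
  expect_identical(a$assignment, b$assignment)
  tiny <- array(FALSE, dim = c(36L, 36L, 36L)); tiny[1:3, 1:3, 1:3] <- TRUE
  expect_error(determine_cuspid_number(tiny, sp07),
               "insufficient leaflet volume")
})

test_that("silhouettes are reported alongside the boundary-cut choice", {
  ph <- generate_phantom(small_spec("BAV0", seed = 2L))
  res <- determine_cuspid_number(ph$labels$data == 3L, sp07, seed = 1L)
  expect_equal(res$k, 2L)
  expect_true(all(res$silhouettes >= -1 & res$silhouettes <= 1))
  expect_true(all(res$cut_fractions >= 0 & res$cut_fractions <= 1))
  expect_lt(res$cut_fractions[["k2"]], res$cut_fractions[["k3"]])
})

test_that("KNN refinement fixes isolated mislabels and keeps the voxel set", {
  m <- array(FALSE, dim = c(24L, 24L, 12L))
  m[3:10, 3:10, 4:7] <- TRUE
  m[15:22, 15:22, 4:7] <- TRUE
  idx <- which(m)
  asg <- ifelse(arrayInd(idx, dim(m))[, 1L] <= 12L, 1L, 2L)
  # coherent assignment: unchanged
  expect_identical(refine_leaflet_boundary(m, asg, 15L, c(1, 1, 1)), asg)
  # flip one voxel deep inside cluster 1
  bad <- asg
  deep <- which(arrayInd(idx, dim(m))[, 1L] == 6 &
                  arrayInd(idx, dim(m))[, 2L] == 6 &
                  arrayInd(idx, dim(m))[, 3L] == 5)
  bad[deep] <- 2L
  fixed <- refine_leaflet_boundary(m, bad, 15L, c(1, 1, 1))
  expect_identical(fixed, asg)
  expect_length(fixed, length(asg))
  expect_error(refine_leaflet_boundary(m, bad, 99999L, c(1, 1, 1)),
               "n_neighbors")
})

test_that("tied KNN votes go to the lower cluster index", {
  ref <- rbind(c(0, 0, 0), c(2, 0, 0), c(0, 2, 0), c(2, 2, 0))
  votes <- aortaseg:::cpp_knn_vote(matrix(c(1, 1, 0), 1L), ref,
                                   c(0L, 0L, 1L, 1L), 4L, 2L)
  expect_equal(votes, 0L)
})

test_that("leaflet names match the phantom construction", {
  for (vt in c("TAV", "BAV0")) {
    ph <- generate_phantom(small_spec(vt, seed = 8L))
    leaf <- ph$labels$data == 3L
    res <- determine_cuspid_number(leaf, sp07, seed = 1L)
    nms <- name_leaflets(res$assignment, leaf, ph$labels)
    expect_setequal(nms, ph$meta$cusp_names)
    # each cluster's angular position matches the named wedge
    co <- mask_coords_mm(leaf, sp07)
    ctr <- c(ph$meta$center_xy_mm, 0)
    for (ci in seq_len(res$k)) {
      p <- colMeans(co[res$assignment == ci, , drop = FALSE]) - ctr
      ang <- (atan2(p[2L], p[1L]) * 180 / pi) %% 360
      true_name <- ph$meta$cusp_names[
        which.min(pmin(abs(ph$meta$cusp_center_deg - ang),
                       360 - abs(ph$meta$cusp_center_deg - ang)))]
      expect_equal(nms[ci], true_name)
    }
  }
})

test_that("naming is stable under a 10-degree axial rotation", {
  ph <- generate_phantom(small_spec("TAV", seed = 12L))
  rot <- augment(ph$image, ph$labels,
                 augment_params(rotation_deg = c(0, 0, 10)))
  leaf <- rot$labels$data == 3L
  res <- determine_cuspid_number(leaf, sp07, seed = 1L)
  nms <- name_leaflets(res$assignment, leaf, rot$labels)
  expect_setequal(nms, c("right-coronary", "left-coronary", "non-coronary"))
  co <- mask_coords_mm(leaf, sp07)
  ctr <- c(ph$meta$center_xy_mm, 0)
  for (ci in seq_len(res$k)) {
    p <- colMeans(co[res$assignment == ci, , drop = FALSE]) - ctr
    ang <- (atan2(p[2L], p[1L]) * 180 / pi - 10) %% 360  # undo the rotation
    true_name <- ph$meta$cusp_names[
      which.min(pmin(abs(ph$meta$cusp_center_deg - ang),
                     360 - abs(ph$meta$cusp_center_deg - ang)))]
    expect_equal(nms[ci], true_name)
  }
})

test_that("naming requires a resolvable AA-LV axis", {
  ph <- generate_phantom(small_spec("TAV", seed = 1L))
  leaf <- ph$labels$data == 3L
  res <- determine_cuspid_number(leaf, sp07, seed = 1L)
  no_lv <- ph$labels$data
  no_lv[no_lv == 2L] <- 0L
  broken <- label_volume(no_lv, sp07)
  expect_error(name_leaflets(res$assignment, leaf, broken),
               "degenerate geometry")
})

test_that("valve classification recovers all three phantom classes", {
  expect_equal(classify_valve(3L, NULL, sp07)$valve_class, "TAV")
  ph1 <- generate_phantom(small_spec("BAV1", seed = 3L))
  cl1 <- classify_valve(2L, ph1$labels$data == 3L, sp07)
  expect_equal(cl1$valve_class, "BAV1")
  expect_true(cl1$raphe_detected)
  ph0 <- generate_phantom(small_spec("BAV0", seed = 3L))
  cl0 <- classify_valve(2L, ph0$labels$data == 3L, sp07)
  expect_equal(cl0$valve_class, "BAV0")
  expect_false(cl0$raphe_detected)
  expect_error(classify_valve(4L, NULL, sp07), "k must be 2 or 3")
})

test_that("confusion matrix counts and accuracy follow their definitions", {
  perfect <- confusion_and_accuracy(rep(c("TAV", "BAV0"), 10L),
                                    rep(c("TAV", "BAV0"), 10L))
  expect_equal(perfect$accuracy, 1)
  expect_true(all(perfect$counts[upper.tri(perfect$counts)] == 0))
  pred <- c(rep("TAV", 9L), "BAV0", rep("BAV0", 10L))
  expert <- c(rep("TAV", 10L), rep("BAV0", 10L))
  cm <- confusion_and_accuracy(pred, expert, classes = c("TAV", "BAV0"))
  expect_equal(unname(cm$counts), rbind(c(9, 1), c(0, 10)))
  expect_equal(cm$accuracy, 0.95)
  expect_error(confusion_and_accuracy(character(0), character(0)),
               "non-empty")
  expect_error(confusion_and_accuracy(c("TAV"), c("TAV", "BAV0")), "length")
  expect_error(confusion_and_accuracy("TAV", "quad"), "unknown class")
})
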