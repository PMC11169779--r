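test_that("resampling preserves constants and world extent", {
  v <- image_volume(array(7.5, c(20L, 24L, 16L)), c(1.0, 0.8, 1.2))
  r <- resample_image(v, 0.5)
  expect_equal(range(r$data), c(7.5, 7.5), tolerance = 1e-6)
  expect_equal(dim(r$data), c(40L, 38L, 38L))
  v64 <- image_volume(array(0, c(64L, 64L, 64L)), c(1, 1, 1))
  expect_equal(dim(resample_image(v64, 0.5)$data), rep(128L, 3L))
})

test_that("trilinear resampling is exact on an affine intensity field", {
  d <- c(32L, 32L, 32L)
  ramp <- array(rep(seq_len(d[1L]), times = prod(d[2:3])), dim = d)
  v <- image_volume(ramp, c(1, 1, 1), origin_mm = c(5, 0, 0))
  r <- resample_image(v, 0.5)
  # analytic: value equals the (fractional) input index at each output centre
  xs_mm <- r$origin_mm[1L] + (seq_len(dim(r$data)[1L]) - 1L) * 0.5
  expected <- pmin(pmax((xs_mm - v$origin_mm[1L]) / 1 + 1, 1), d[1L])
  expect_equal(r$data[, 16L, 16L], expected, tolerance = 1e-6)
})

test_that("label resampling is nearest-neighbour and closed over labels", {
  lab <- array(3L, dim = c(20L, 20L, 20L))
  lv <- label_volume(lab, c(1, 1, 1))
  r <- resample_labels(lv, 0.7)
  expect_setequal(unique(as.vector(r$data)), 3L)
  # checkerboard downsampling agrees with a brute-force nearest lookup
  d <- c(16L, 16L, 16L)
  ijk <- arrayInd(seq_len(prod(d)), d)
  cb <- array(ifelse(rowSums(ijk) %% 2L == 0L, 0L, 3L), dim = d)
  cv <- label_volume(cb, c(1, 1, 1))
  r2 <- resample_labels(cv, 2)
  d2 <- dim(r2$data)
  for (v in seq_len(prod(d2))) {
    out_ijk <- arrayInd(v, d2)
    mm <- r2$origin_mm + (out_ijk - 1L) * 2
    src <- pmin(pmax(floor((mm - cv$origin_mm) / 1 + 1 + 0.5), 1L), d)
    expect_identical(r2$data[v], cb[src[1L], src[2L], src[3L]])
  }
  expect_true(all(unique(as.vector(r2$data)) %in% c(0L, 3L)))
})

test_that("round-trip resampling at the native spacing is stable", {
  ph <- generate_phantom(small_spec("TAV", seed = 3L))
  r <- resample_image(ph$image, 0.7)
  expect_equal(dim(r$data), dim(ph$image$data))
  expect_lt(max(abs(r$data - ph$image$data)), 1e-6)
})

test_that("clip_and_normalize maps the clip window onto [0,1]", {
  v <- image_volume(array(c(-100, 1500, 600, 0, 1200, 300),
                          dim = c(6L, 1L, 1L)), c(1, 1, 1))
  n <- clip_and_normalize(v, 0, 1200)
  expect_equal(as.vector(n$data)[1:5], c(0, 1, 0.5, 0, 1))
  rnd <- image_volume(array(stats::rnorm(1000, 300, 800),
                            dim = c(10L, 10L, 10L)), c(1, 1, 1))
  nn <- clip_and_normalize(rnd)
  expect_gte(min(nn$data), 0)
  expect_lte(max(nn$data), 1)
  expect_error(clip_and_normalize(v, 10, 10), "clip_low")
})

test_that("crop_to_body finds the margin-padded bounding box", {
  a <- array(-100, dim = c(30L, 30L, 30L))
  a[10:14, 12:16, 5:9] <- 500
  v <- image_volume(a, c(1, 1, 1))
  cr <- crop_to_body(v, body_threshold = 0)
  expect_equal(cr$offset, c(7L, 9L, 2L))
  expect_equal(dim(cr$image$data), c(9L, 9L, 9L))
  # congruent crop of a paired volume
  lab <- label_volume(array(0L, dim = c(30L, 30L, 30L)), c(1, 1, 1))
  lc <- crop_with_offset(lab, cr$offset, dim(cr$image$data))
  expect_true(same_geometry(cr$image, lc))
  # corner foreground clamps at the grid edge
  b <- array(-100, dim = c(20L, 20L, 20L)); b[1:3, 1:3, 1:3] <- 500
  cb <- crop_to_body(image_volume(b, c(1, 1, 1)), 0)
  expect_equal(cb$offset, c(0L, 0L, 0L))
  expect_error(crop_to_body(image_volume(array(-100, dim = c(8L, 8L, 8L)),
                                         c(1, 1, 1)), 0), "empty body")
})

test_that("extract_patch is identity at full size and zero-pads outside", {
  a <- array(stats::rnorm(32^3), dim = c(32L, 32L, 32L))
  v <- image_volume(a, c(1, 1, 1))
  p <- extract_patch(v, 32L, c(17L, 17L, 17L))
  expect_equal(p$data, a)
  ph <- extract_patch(v, 32L, c(1L, 17L, 17L))
  expect_true(all(ph$data[1:15, , ] == 0))
  expect_equal(sum(ph$data), sum(a[1:16, , ]))
  expect_error(extract_patch(v, 32L, c(0L, 1L, 1L)), "center")
})

test_that("augment parameters are validated and identity is exact", {
  expect_error(augment_params(rotation_deg = c(25, 0, 0)), "rotation")
  expect_error(augment_params(zoom = 1.3), "zoom")
  ph <- generate_phantom(small_spec("BAV0", seed = 4L))
  id <- augment(ph$image, ph$labels, augment_params())
  expect_equal(id$image$data, ph$image$data, tolerance = 1e-6)
  expect_identical(id$labels$data, ph$labels$data)
})

test_that("augment is deterministic and geometry-congruent", {
  ph <- generate_phantom(small_spec("TAV", seed = 5L))
  prm <- augment_params(rotation_deg = c(10, -5, 15), zoom = 0.9,
                        noise_sigma = 0.03, seed = 21L)
  a <- augment(ph$image, ph$labels, prm)
  b <- augment(ph$image, ph$labels, prm)
  expect_identical(a$image$data, b$image$data)
  expect_identical(a$labels$data, b$labels$data)
  expect_true(same_geometry(a$image, a$labels))
  expect_true(all(unique(as.vector(a$labels$data)) %in% 0:4))
})

test_that("isotropic zoom scales foreground volume as zoom cubed", {
  d <- c(48L, 48L, 48L)
  ijk <- arrayInd(seq_len(prod(d)), d)
  ctr <- (d + 1) / 2
  sph <- array(0, dim = d)
  sph[rowSums(sweep(ijk, 2L, ctr)^2) <= 10^2] <- 400
  iv <- image_volume(sph, c(1, 1, 1))
  lv <- label_volume(array(0L, dim = d), c(1, 1, 1))
  zoomed <- augment(iv, lv, augment_params(zoom = 1.15))
  r0 <- (sum(sph > 200) * 3 / (4 * pi))^(1 / 3)
  r1 <- (sum(zoomed$image$data > 200) * 3 / (4 * pi))^(1 / 3)
  expect_equal(r1 / r0, 1.15, tolerance = 0.03)
})
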