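test_that("overlap metrics follow their definitions and conventions", {
  m <- array(FALSE, dim = c(8L, 8L, 8L)); m[2:3, 2:3, 2:3] <- TRUE
  self <- overlap_metrics(m, m)
  expect_equal(self[c("dsc", "precision", "recall")],
               list(dsc = 1, precision = 1, recall = 1))
  other <- array(FALSE, dim = c(8L, 8L, 8L)); other[6:7, 6:7, 6:7] <- TRUE
  disj <- overlap_metrics(m, other)
  expect_equal(disj[c("dsc", "precision", "recall")],
               list(dsc = 0, precision = 0, recall = 0))
  # |P|=8, |G|=8, |P.G|=4
  p <- array(FALSE, dim = c(8L, 8L, 8L)); p[1:8, 1L, 1L] <- TRUE
  g <- array(FALSE, dim = c(8L, 8L, 8L)); g[5:8, 1L, 1L] <- TRUE
  g[5:8, 2L, 1L] <- TRUE
  half <- overlap_metrics(p, g)
  expect_equal(half[c("dsc", "precision", "recall")],
               list(dsc = 0.5, precision = 0.5, recall = 0.5))
  # empty-mask conventions
  e <- array(FALSE, dim = dim(m))
  both <- overlap_metrics(e, e)
  expect_equal(both$dsc, 1)
  expect_true(both$degenerate)
  one <- overlap_metrics(e, m)
  expect_equal(one$dsc, 0)
  expect_true(one$degenerate)
})

test_that("surface extraction matches direct enumeration", {
  single <- array(FALSE, dim = c(5L, 5L, 5L)); single[3L, 3L, 3L] <- TRUE
  expect_identical(surface_extract(single), single)
  cube <- array(FALSE, dim = c(7L, 7L, 7L)); cube[3:5, 3:5, 3:5] <- TRUE
  s <- surface_extract(cube)
  expect_equal(sum(s), 26L, ignore_attr = TRUE)
  expect_false(s[4L, 4L, 4L])
  # grid edge counts as outside: a full volume keeps only its shell
  full <- array(TRUE, dim = c(4L, 4L, 4L))
  sf <- surface_extract(full)
  expect_true(all(sf[c(1L, 4L), , ]) && all(sf[, c(1L, 4L), ]) &&
                all(sf[, , c(1L, 4L)]))
  expect_false(any(sf[2:3, 2:3, 2:3]))
  expect_error(surface_extract(array(FALSE, dim = c(3L, 3L, 3L))),
               "empty structure")
})

test_that("hd95 and assd match elementary cases", {
  m <- array(FALSE, dim = c(10L, 10L, 10L)); m[3:5, 3:5, 3:5] <- TRUE
  expect_equal(hd95(m, m, c(0.5, 0.5, 0.5)), 0)
  expect_equal(assd(m, m, c(0.5, 0.5, 0.5)), 0)
  a <- array(FALSE, dim = c(10L, 10L, 10L)); a[2L, 2L, 2L] <- TRUE
  b <- array(FALSE, dim = c(10L, 10L, 10L)); b[6L, 2L, 2L] <- TRUE
  expect_equal(hd95(a, b, c(0.5, 0.5, 0.5)), 2.0)
  expect_error(hd95(a, array(FALSE, dim = c(10L, 10L, 10L)), c(1, 1, 1)),
               "empty structure")
})

test_that("surface distances equal the all-pairs brute-force oracle", {
  set.seed(31L)
  for (i in 1:8) {
    p <- random_blob_mask(); g <- random_blob_mask()
    if (!any(p) || !any(g)) next
    sp <- c(0.6, 0.8, 1.1)
    expect_equal(hd95(p, g, sp), brute_hd95(p, g, sp), tolerance = 1e-9)
    expect_equal(assd(p, g, sp), brute_assd(p, g, sp), tolerance = 1e-9)
    expect_equal(assd(p, g, sp), assd(g, p, sp))
    expect_gte(hd95(p, g, sp),
               stats::median(brute_pooled_dists(p, g, sp)))
  }
})

test_that("metrics are translation-invariant and scale with spacing", {
  set.seed(7L)
  p <- random_blob_mask(c(18L, 18L, 18L)); g <- random_blob_mask(c(18L, 18L, 18L))
  shift <- function(m) {
    out <- array(FALSE, dim = dim(m) + 4L)
    out[3:(dim(m)[1L] + 2L), 3:(dim(m)[2L] + 2L), 3:(dim(m)[3L] + 2L)] <- m
    out
  }
  expect_equal(overlap_metrics(p, g)$dsc, overlap_metrics(shift(p), shift(g))$dsc)
  expect_equal(hd95(p, g, c(1, 1, 1)), hd95(shift(p), shift(g), c(1, 1, 1)))
  expect_equal(hd95(p, g, c(2, 2, 2)), 2 * hd95(p, g, c(1, 1, 1)))
  expect_equal(assd(p, g, c(3, 3, 3)), 3 * assd(p, g, c(1, 1, 1)))
})

test_that("dsc equals the harmonic mean of precision and recall when |P|=|G|", {
  set.seed(13L)
  for (i in 1:10) {
    d <- c(12L, 12L, 12L)
    idx <- sample(prod(d), 100L)
    p <- array(FALSE, dim = d); p[idx] <- TRUE
    g <- array(FALSE, dim = d); g[sample(prod(d), 100L)] <- TRUE
    m <- overlap_metrics(p, g)
    if (m$precision + m$recall > 0)
      expect_equal(2 * m$precision * m$recall / (m$precision + m$recall),
                   m$dsc)
  }
})

test_that("evaluate_case reports per-structure metrics with absent markers", {
  # thicker leaflets so that erosion leaves a non-empty interior
  ph <- generate_phantom(small_spec("TAV", n_calcifications = 2L,
                                    leaflet_thickness_mm = 3.5, seed = 4L))
  rep0 <- evaluate_case(ph$labels, ph$labels, case_id = "self")
  expect_equal(rep0$structures$dsc, rep(1, 4L))
  expect_equal(rep0$structures$hd95_mm, rep(0, 4L))
  # erode the leaflet mask: recall drops, precision stays 1
  lab <- ph$labels$data
  leaf <- lab == 3L
  er <- leaf & !surface_extract(leaf)
  lab2 <- lab; lab2[leaf & !er] <- 0L
  rep1 <- evaluate_case(label_volume(lab2, sp07), ph$labels)
  lrow <- rep1$structures[rep1$structures$structure == "leaflet", ]
  expect_equal(lrow$precision, 1)
  expect_lt(lrow$recall, 1)
  # absent structure flagged, not zeroed
  no_calc <- lab; no_calc[no_calc == 4L] <- 0L
  rep2 <- evaluate_case(label_volume(no_calc, sp07),
                        label_volume(no_calc, sp07))
  expect_true(rep2$structures$absent[rep2$structures$structure ==
                                       "calcification"])
  expect_error(evaluate_case(ph$labels,
                             label_volume(lab[1:40, 1:48, 1:48],
                                          sp07)),
               "congruent")
})

test_that("dice_focal_loss has the stated closed-form limits", {
  onehot <- cbind(c(1, 0, 1, 0), c(0, 1, 0, 1))
  expect_lt(dice_focal_loss(onehot, onehot), 1e-5)
  unif <- matrix(0.5, nrow = 4L, ncol = 2L)
  expect_equal(dice_focal_loss(unif, onehot, lambda_mix = 0, gamma = 0,
                               alpha = 1), log(2))
  expect_gte(dice_focal_loss(unif, onehot), 0)
  expect_error(dice_focal_loss(matrix(c(0.9, 0.3, 0.5, 0.5), 2L), onehot[1:2, ]),
               "probabilities")
})

test_that("loss decreases as probability mass moves toward the truth", {
  set.seed(3L)
  n <- 50L
  gt <- t(vapply(sample(1:3, n, TRUE), function(c)
    as.numeric(1:3 == c), numeric(3L)))
  start <- matrix(1 / 3, n, 3L)
  losses <- vapply(seq(0, 1, length.out = 10L), function(t)
    dice_focal_loss(start * (1 - t) + gt * t, gt), numeric(1L))
  expect_true(all(diff(losses) < 0))
})
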