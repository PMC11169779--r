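as_mask_array <- function(x) {
  if (inherits(x, "image_volume")) x <- x$data
  if (!is.array(x) || length(dim(x)) != 3L) stopf("expected a 3-D mask")
  x != 0
}

#' Voxel-overlap metrics
#'
#' Dice similarity coefficient, precision and recall between a predicted
#' and a ground-truth binary mask:
#' `dsc = 2|P&G| / (|P|+|G|)`, `precision = |P&G|/|P|`,
#' `recall = |P&G|/|G|`. When both masks are empty the agreement is
#' perfect by convention (all three 1.0, flagged); when exactly one is
#' empty the undefined ratios are reported as 0, flagged.
#'
#' @param pred,gt Same-shape binary 3-D arrays (or volumes).
#' @return List: `dsc`, `precision`, `recall`, `degenerate` (logical
#'   flag for the empty-mask conventions).
#' @export
overlap_metrics <- function(pred, gt) {
  p <- as_mask_array(pred); g <- as_mask_array(gt)
  if (!identical(dim(p), dim(g))) stopf("mask shapes differ")
  np <- sum(p); ng <- sum(g)
  if (np == 0 && ng == 0)
    return(list(dsc = 1, precision = 1, recall = 1, degenerate = TRUE))
  inter <- sum(p & g)
  list(dsc = 2 * inter / (np + ng),
       precision = if (np > 0) inter / np else 0,
       recall = if (ng > 0) inter / ng else 0,
       degenerate = (np == 0 || ng == 0))
}

#' Extract the surface voxels of a mask
#'
#' A mask voxel is a surface voxel when at least one of its six
#' face-adjacent neighbours lies outside the mask; the grid edge counts
#' as outside.
#'
#' @param mask Binary 3-D array (or volume).
#' @return Logical 3-D array of surface voxels.
#' @export
surface_extract <- function(mask) {
  m <- as_mask_array(mask)
  if (!any(m)) stopf("empty structure: cannot extract surface")
  d <- dim(m)
  pad <- array(FALSE, dim = d + 2L)
  pad[2:(d[1L] + 1L), 2:(d[2L] + 1L), 2:(d[3L] + 1L)] <- m
  i <- 2:(d[1L] + 1L); j <- 2:(d[2L] + 1L); k <- 2:(d[3L] + 1L)
  interior <- pad[i - 1L, j, k] & pad[i + 1L, j, k] &
    pad[i, j - 1L, k] & pad[i, j + 1L, k] &
    pad[i, j, k - 1L] & pad[i, j, k + 1L]
  m & !interior
}

surface_coords_mm <- function(mask, spacing_mm) {
  mask_coords_mm(surface_extract(mask), spacing_mm)
}

pooled_surface_distances <- function(pred, gt, spacing_mm) {
  p <- as_mask_array(pred); g <- as_mask_array(gt)
  if (!identical(dim(p), dim(g))) stopf("mask shapes differ")
  if (!any(p) || !any(g)) stopf("empty structure: surface distance undefined")
  a <- surface_coords_mm(p, spacing_mm)
  b <- surface_coords_mm(g, spacing_mm)
  c(cpp_min_dists(a, b), cpp_min_dists(b, a))
}

#' 95th-percentile Hausdorff distance
#'
#' The 95th percentile (default R quantile, type 7) of the pooled set of
#' nearest-surface distances in both directions between the two mask
#' surfaces, in millimetres. `variant = "max"` gives the classical
#' (maximum) Hausdorff distance.
#'
#' @param pred,gt Non-empty same-shape binary 3-D arrays.
#' @param spacing_mm Voxel size triple (mm).
#' @param variant "hd95" (default) or "max".
#' @return Length in mm.
#' @export
hd95 <- function(pred, gt, spacing_mm, variant = c("hd95", "max")) {
  variant <- match.arg(variant)
  dists <- pooled_surface_distances(pred, gt, spacing_mm)
  if (variant == "max") max(dists)
  else stats::quantile(dists, 0.95, names = FALSE)
}

#' Average symmetric surface distance
#'
#' Mean of the pooled nearest-surface distances in both directions, mm.
#'
#' @inheritParams hd95
#' @return Length in mm.
#' @export
assd <- function(pred, gt, spacing_mm) {
  mean(pooled_surface_distances(pred, gt, spacing_mm))
}

#' Evaluate a predicted label volume against ground truth
#'
#' One-vs-rest metrics (DSC, precision, recall, HD95, ASSD) for each of
#' the four structures (AA, LV, leaflet, calcification). Structures
#' absent from both volumes are flagged absent rather than zeroed;
#' structures empty on exactly one side get overlap metrics under the
#' empty-mask conventions and NA distances.
#'
#' @param pred,gt Congruent [label_volume]s.
#' @param case_id Case identifier recorded in the report.
#' @param hd_variant Passed to [hd95()].
#' @param provenance Optional named list recorded verbatim.
#' @return A `case_report`: `structures` data.frame (one row per
#'   structure), `case_id`, `provenance`.
#' @export
evaluate_case <- function(pred, gt, case_id = "case",
                          hd_variant = c("hd95", "max"),
                          provenance = list()) {
  hd_variant <- match.arg(hd_variant)
  stop_if_not_congruent(pred, gt)
  structs <- names(LABEL_VOCAB)[-1L]
  rows <- lapply(structs, function(s) {
    code <- LABEL_VOCAB[[s]]
    p <- pred$data == code; g <- gt$data == code
    if (!any(p) && !any(g))
      return(data.frame(structure = s, dsc = NA_real_, precision = NA_real_,
                        recall = NA_real_, hd95_mm = NA_real_,
                        assd_mm = NA_real_, absent = TRUE,
                        degenerate = FALSE, stringsAsFactors = FALSE))
    ov <- overlap_metrics(p, g)
    if (any(p) && any(g)) {
      hv <- hd95(p, g, pred$spacing_mm, variant = hd_variant)
      av <- assd(p, g, pred$spacing_mm)
    } else {
      hv <- NA_real_; av <- NA_real_
    }
    data.frame(structure = s, dsc = ov$dsc, precision = ov$precision,
               recall = ov$recall, hd95_mm = hv, assd_mm = av,
               absent = FALSE, degenerate = ov$degenerate,
               stringsAsFactors = FALSE)
  })
  structure(list(structures = do.call(rbind, rows), case_id = case_id,
                 provenance = provenance),
            class = "case_report")
}

#' @export
print.case_report <- function(x, ...) {
  cat(sprintf("<case_report> %s\n", x$case_id))
  print(x$structures, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Combined Dice + focal loss
#'
#' `lambda_mix * (1 - soft Dice) + (1 - lambda_mix) * focal loss`, where
#' the soft Dice is averaged over classes and the focal term is the mean
#' over voxels of `-alpha * (1 - p_t)^gamma * log(p_t)` with `p_t` the
#' predicted probability of the true class, clamped to
#' `[1e-7, 1 - 1e-7]`. Dice supervises large structures (blood pool)
#' well; the focal term keeps gradients informative for small
#' structures (leaflets, calcification).
#'
#' @param prob Numeric matrix (voxels x classes) or array whose last
#'   dimension indexes classes; rows must be probabilities summing to 1.
#' @param gt_onehot One-hot ground truth of the same shape.
#' @param lambda_mix Mixing weight between 0 and 1 (default 0.5).
#' @param gamma Focal exponent (default 2).
#' @param alpha Focal weight (default 0.25).
#' @return Finite non-negative scalar.
#' @export
dice_focal_loss <- function(prob, gt_onehot, lambda_mix = 0.5, gamma = 2,
                            alpha = 0.25) {
  flatten <- function(x) {
    d <- dim(x)
    if (is.null(d) || length(d) < 2L) stopf("'prob' must have a class dimension")
    matrix(x, ncol = d[length(d)])
  }
  p <- flatten(prob); g <- flatten(gt_onehot)
  if (!identical(dim(p), dim(g))) stopf("prob and gt_onehot shapes differ")
  if (lambda_mix < 0 || lambda_mix > 1) stopf("'lambda_mix' must be in [0,1]")
  if (any(p < -1e-9) || any(p > 1 + 1e-9) ||
      any(abs(rowSums(p) - 1) > 1e-6))
    stopf("invalid probabilities: rows must lie in [0,1] and sum to 1")
  if (any(abs(rowSums(g) - 1) > 1e-6) || !all(g %in% c(0, 1)))
    stopf("'gt_onehot' must be one-hot")
  # soft Dice averaged over classes (empty classes count as perfect)
  num <- 2 * colSums(p * g)
  den <- colSums(p) + colSums(g)
  dice <- ifelse(den > 0, num / den, 1)
  dice_loss <- 1 - mean(dice)
  pt <- pmin(pmax(rowSums(p * g), 1e-7), 1 - 1e-7)
  focal <- mean(-alpha * (1 - pt)^gamma * log(pt))
  lambda_mix * dice_loss + (1 - lambda_mix) * focal
}
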