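# Separable FFT Gaussian smoothing. The volume is zero-padded by 4 sigma
# before the transform so the periodic boundary cannot leak intensity
# across opposite faces.
gaussian_smooth3 <- function(arr, sigma_vox) {
  if (sigma_vox <= 0) return(arr)
  pad <- as.integer(ceiling(4 * sigma_vox))
  d0 <- dim(arr)
  big <- array(0, dim = d0 + 2L * pad)
  big[pad + seq_len(d0[1L]), pad + seq_len(d0[2L]), pad + seq_len(d0[3L])] <-
    arr
  arr <- big
  d <- dim(arr)
  kern1 <- function(n) {
    x <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1))
    k <- exp(-x^2 / (2 * sigma_vox^2))
    k / sum(k)
  }
  f <- stats::fft(arr)
  broadcast <- function(v, ax) {
    each <- if (ax == 1L) 1L else prod(d[seq_len(ax - 1L)])
    array(rep(v, each = each), dim = d)
  }
  for (ax in 1:3)
    f <- f * broadcast(stats::fft(kern1(d[ax])), ax)
  sm <- Re(stats::fft(f, inverse = TRUE)) / prod(d)
  sm[pad + seq_len(d0[1L]), pad + seq_len(d0[2L]), pad + seq_len(d0[3L])]
}

#' Reference phantom segmenter
#'
#' A deterministic threshold-and-geometry segmenter standing in for the
#' learned segmentation stage, so that the downstream post-processing
#' pipeline can be exercised on phantoms with known truth. Expects a
#' normalized 0-1 image (the phantom palette maps to background ~0,
#' leaflet ~0.125, blood ~0.333, calcification ~0.833).
#'
#' Steps: optional edge-preserving 3x3x3 median denoising (triggered
#' when a robust noise estimate exceeds `noise_gate`; a Gaussian blur
#' would erase the thin leaflet sheets); intensity banding into
#' calcification / blood / leaflet; leaflet candidates restricted to the
#' blood-pool neighbourhood; the blood pool split into AA and LV at the
#' basal leaflet plane along the pool's principal axis, with the wider
#' side (the ventricle) below; largest-component cleanup for AA/LV and
#' small-piece removal for leaflets and calcification.
#'
#' @param image Normalized [image_volume].
#' @param params Optional list overriding thresholds: `calc_low`,
#'   `blood_low`, `leaflet_low`, `denoise` (NA = auto, TRUE, FALSE),
#'   `noise_gate`.
#' @return [label_volume] on the image geometry.
#' @export
reference_segmenter <- function(image, params = list()) {
  p <- utils::modifyList(list(calc_low = 0.58, blood_low = 0.235,
                              leaflet_low = 0.065, denoise = NA,
                              noise_gate = 0.015), params)
  v <- image$data
  d <- dim(v)
  # robust noise estimate from adjacent-voxel differences along x,
  # restricted to non-clipped foreground (the clipped background is
  # mostly constant and would mask the noise)
  dv <- v[-1L, , ] - v[-d[1L], , ]
  fg <- v[-1L, , ] > 0.08 & v[-d[1L], , ] > 0.08
  noise <- if (any(fg)) stats::mad(dv[fg]) / sqrt(2) else 0
  do_dn <- if (is.na(p$denoise)) noise > p$noise_gate else isTRUE(p$denoise)
  if (do_dn) v <- median_filter3(v)

  calc <- v >= p$calc_low
  blood <- v >= p$blood_low & v < p$calc_low
  leaf <- v >= p$leaflet_low & v < p$blood_low

  lab <- array(0L, dim = d)
  if (!any(blood)) {
    if (any(calc)) lab[calc] <- LABEL_VOCAB[["calcification"]]
    return(label_volume(lab, image$spacing_mm, image$origin_mm,
                        image$orientation))
  }
  blood <- filter_small_components(blood, min_fraction = 0.05)
  # leaflet candidates must lie interior to the (morphologically closed)
  # blood pool: the partial-volume shell where background meets the pool
  # also lands in the mid-intensity band, but it sits just outside the
  # pool surface, while true leaflets are slits within it
  leaf <- leaf & close26(blood, 3L)
  leaf <- filter_small_components(leaf, min_voxels = 20L,
                                  min_fraction = 0.02)

  sp <- image$spacing_mm
  bc <- mask_coords_mm(blood, sp)
  ctr <- colMeans(bc)
  ax <- eigen(stats::cov(sweep(bc, 2L, ctr)), symmetric = TRUE)$vectors[, 1L]
  hb <- as.vector(sweep(bc, 2L, ctr) %*% ax)
  # orient the axis so the wider (ventricular) side is negative
  radial <- sqrt(rowSums((sweep(bc, 2L, ctr) - outer(hb, ax))^2))
  hi <- hb > stats::median(hb)
  if (stats::quantile(radial[hi], 0.9) >
      stats::quantile(radial[!hi], 0.9)) {
    ax <- -ax; hb <- -hb
  }
  if (any(leaf)) {
    lc <- mask_coords_mm(leaf, sp)
    hl <- as.vector(sweep(lc, 2L, ctr) %*% ax)
    h_split <- stats::quantile(hl, 0.02, names = FALSE) - 0.25 * max(sp)
  } else {
    h_split <- 0
  }
  bidx <- which(blood)
  aa_mask <- array(FALSE, dim = d); lv_mask <- array(FALSE, dim = d)
  aa_mask[bidx[hb >= h_split]] <- TRUE
  lv_mask[bidx[hb < h_split]] <- TRUE
  if (any(aa_mask)) aa_mask <- keep_largest_component(aa_mask)
  if (any(lv_mask)) lv_mask <- keep_largest_component(lv_mask)
  calc <- filter_small_components(calc, min_voxels = 3L)

  lab[aa_mask] <- LABEL_VOCAB[["AA"]]
  lab[lv_mask] <- LABEL_VOCAB[["LV"]]
  lab[leaf] <- LABEL_VOCAB[["leaflet"]]
  lab[calc] <- LABEL_VOCAB[["calcification"]]
  label_volume(lab, sp, image$origin_mm, image$orientation)
}

# 3x3x3 median filter (edge-replicated)
median_filter3 <- function(arr) {
  array(cpp_median_filter3(as.numeric(arr), as.integer(dim(arr))),
        dim = dim(arr))
}

# binary erosion; out-of-grid counts as background
erode26 <- function(mask, iter = 1L) {
  m <- mask != 0
  d <- dim(m)
  for (it in seq_len(iter)) {
    pad <- array(FALSE, dim = d + 2L)
    pad[2:(d[1L] + 1L), 2:(d[2L] + 1L), 2:(d[3L] + 1L)] <- m
    acc <- array(TRUE, dim = d)
    for (di in -1:1) for (dj in -1:1) for (dk in -1:1)
      acc <- acc & pad[(2:(d[1L] + 1L)) + di, (2:(d[2L] + 1L)) + dj,
                       (2:(d[3L] + 1L)) + dk]
    m <- acc
  }
  m
}

# binary closing: dilation then erosion, 26-neighbourhood
close26 <- function(mask, iter = 1L) {
  erode26(dilate26(mask, iter), iter)
}

# binary dilation by `iter` steps of the 26-neighbourhood
dilate26 <- function(mask, iter = 1L) {
  m <- mask != 0
  d <- dim(m)
  for (it in seq_len(iter)) {
    pad <- array(FALSE, dim = d + 2L)
    pad[2:(d[1L] + 1L), 2:(d[2L] + 1L), 2:(d[3L] + 1L)] <- m
    acc <- array(FALSE, dim = d)
    for (di in -1:1) for (dj in -1:1) for (dk in -1:1)
      acc <- acc | pad[(2:(d[1L] + 1L)) + di, (2:(d[2L] + 1L)) + dj,
                       (2:(d[3L] + 1L)) + dk]
    m <- acc
  }
  m
}

#' Post-process a predicted label volume
#'
#' Scattered-piece removal per structure: the AA and LV keep only their
#' largest connected component; leaflets and calcification — structures
#' that are legitimately multi-component — instead drop components
#' below a size floor.
#'
#' @param labels A [label_volume].
#' @param connectivity Component connectivity (default 26).
#' @return Cleaned [label_volume].
#' @export
postprocess_labels <- function(labels, connectivity = 26L) {
  lab <- labels$data
  out <- array(0L, dim = dim(lab))
  for (s in c("AA", "LV")) {
    m <- lab == LABEL_VOCAB[[s]]
    if (any(m)) out[keep_largest_component(m, connectivity)] <- LABEL_VOCAB[[s]]
  }
  m <- lab == LABEL_VOCAB[["leaflet"]]
  if (any(m))
    out[filter_small_components(m, connectivity, min_voxels = 20L,
                                min_fraction = 0.02)] <- LABEL_VOCAB[["leaflet"]]
  m <- lab == LABEL_VOCAB[["calcification"]]
  if (any(m))
    out[filter_small_components(m, connectivity,
                                min_voxels = 3L)] <- LABEL_VOCAB[["calcification"]]
  label_volume(out, labels$spacing_mm, labels$origin_mm, labels$orientation)
}

#' Pipeline configuration
#'
#' Bundles the stage parameters of [run_pipeline()]. Unknown keys in
#' the overriding lists are rejected.
#'
#' @param preprocess A [preprocess_config()].
#' @param leaflet Named list: `seed`, `n_neighbors`, `min_voxels`, `cut_tol`,
#'   `tie_tol`.
#' @param metrics Named list: `hd_variant` ("hd95" or "max").
#' @param segmenter Named list: `name` ("reference" or "identity") and
#'   `params`; "identity" expects each case to carry predicted labels.
#' @param resample Logical: resample cases to the target spacing first.
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(preprocess = preprocess_config(),
                            leaflet = list(), metrics = list(),
                            segmenter = list(), resample = FALSE) {
  merge_strict <- function(defaults, user, what) {
    bad <- setdiff(names(user), names(defaults))
    if (length(bad)) stopf("unknown %s key(s): %s", what,
                           paste(bad, collapse = ", "))
    utils::modifyList(defaults, user)
  }
  cfg <- structure(list(
    preprocess = preprocess,
    leaflet = merge_strict(list(seed = 1L, n_neighbors = 15L,
                                min_voxels = 200L, cut_tol = 0.01,
                                tie_tol = 0.005),
                           leaflet, "leaflet"),
    metrics = merge_strict(list(hd_variant = "hd95"), metrics, "metrics"),
    segmenter = merge_strict(list(name = "reference", params = list()),
                             segmenter, "segmenter"),
    resample = isTRUE(resample)), class = "pipeline_config")
  if (!cfg$segmenter$name %in% c("reference", "identity"))
    stopf("unknown segmenter '%s'", cfg$segmenter$name)
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose top-level keys mirror the arguments of
#'   [pipeline_config()].
#' @return A `pipeline_config` object.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  bad <- setdiff(names(y), c("preprocess", "leaflet", "metrics",
                             "segmenter", "resample"))
  if (length(bad)) stopf("unknown config key(s): %s",
                         paste(bad, collapse = ", "))
  pp <- do.call(preprocess_config, if (is.null(y$preprocess)) list()
                else y$preprocess)
  pipeline_config(preprocess = pp,
                  leaflet = if (is.null(y$leaflet)) list() else y$leaflet,
                  metrics = if (is.null(y$metrics)) list() else y$metrics,
                  segmenter = if (is.null(y$segmenter)) list() else y$segmenter,
                  resample = isTRUE(y$resample))
}

config_hash <- function(config) {
  f <- tempfile(fileext = ".yaml")
  on.exit(unlink(f))
  yaml::write_yaml(unclass_deep(config), f)
  unname(tools::md5sum(f))
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}

#' Run the aortic-root analysis pipeline on a cohort
#'
#' Per case: preprocessing (optional isotropic resampling, intensity
#' clip + normalization), segmentation via the configured plugin,
#' scattered-piece removal, cuspid-number determination, KNN boundary
#' refinement, leaflet naming, valve classification, and — when ground
#' truth labels are supplied — the per-structure metric report. A
#' failing stage marks that case failed and the pipeline continues;
#' ground-truth valve classes, when present, yield a cohort confusion
#' matrix over the successful cases.
#'
#' @param config A [pipeline_config()].
#' @param cases List of cases; each a list with `image` ([image_volume],
#'   HU scale), optional `labels` (ground-truth [label_volume]),
#'   optional `gt_class`, optional `id`, and — for the "identity"
#'   segmenter — `pred_labels`.
#' @return List: `cases` (per-case results: `cuspid`, `names`,
#'   `valve_class`, `report`, or `error`), `confusion`
#'   (a [confusion_and_accuracy()] object or NULL), `config_hash`.
#' @export
run_pipeline <- function(config, cases) {
  stopifnot(inherits(config, "pipeline_config"))
  if (length(cases) < 1L) stopf("at least one case required")
  pp <- config$preprocess
  lf <- config$leaflet
  results <- vector("list", length(cases))
  for (ci in seq_along(cases)) {
    case <- cases[[ci]]
    id <- if (is.null(case$id)) sprintf("case_%04d", ci) else case$id
    results[[ci]] <- tryCatch({
      img <- case$image
      gt <- case$labels
      if (config$resample) {
        img <- resample_image(img, pp$target_spacing_mm)
        if (!is.null(gt)) gt <- resample_labels(gt, pp$target_spacing_mm)
      }
      norm <- clip_and_normalize(img, pp$clip_low, pp$clip_high)
      pred <- switch(config$segmenter$name,
        reference = reference_segmenter(norm, config$segmenter$params),
        identity = {
          if (is.null(case$pred_labels))
            stopf("identity segmenter requires case$pred_labels")
          case$pred_labels
        })
      pred <- postprocess_labels(pred)
      leaf <- pred$data == LABEL_VOCAB[["leaflet"]]
      cusp <- determine_cuspid_number(leaf, pred$spacing_mm,
                                      seed = lf$seed,
                                      min_voxels = lf$min_voxels,
                                      cut_tol = lf$cut_tol,
                                      tie_tol = lf$tie_tol)
      cusp$assignment <- refine_leaflet_boundary(leaf, cusp$assignment,
                                                 n_neighbors = lf$n_neighbors,
                                                 spacing_mm = pred$spacing_mm)
      nms <- tryCatch(name_leaflets(cusp$assignment, leaf, pred),
                      error = function(e) rep(NA_character_, cusp$k))
      cls <- classify_valve(cusp$k, leaf, pred$spacing_mm,
                            assignment = cusp$assignment, image = norm)
      report <- NULL
      if (!is.null(gt))
        report <- evaluate_case(pred, gt, case_id = id,
                                hd_variant = config$metrics$hd_variant,
                                provenance = list(
                                  segmenter = config$segmenter$name,
                                  seed = lf$seed))
      list(id = id, ok = TRUE, k = cusp$k,
           silhouettes = cusp$silhouettes, leaflet_names = nms,
           valve_class = cls$valve_class,
           raphe_detected = cls$raphe_detected,
           gt_class = case$gt_class, report = report, pred = pred)
    }, error = function(e) {
      list(id = id, ok = FALSE, error = conditionMessage(e),
           gt_class = case$gt_class)
    })
  }
  ok <- vapply(results, function(r) isTRUE(r$ok), logical(1L))
  has_gt <- ok & vapply(results, function(r) !is.null(r$gt_class), logical(1L))
  confusion <- NULL
  if (any(has_gt))
    confusion <- confusion_and_accuracy(
      vapply(results[has_gt], `[[`, character(1L), "valve_class"),
      vapply(results[has_gt], `[[`, character(1L), "gt_class"))
  list(cases = results, confusion = confusion,
       config_hash = config_hash(config))
}

#' Write pipeline reports to disk
#'
#' Emits `metrics.csv` (one row per case x structure, stable column
#' order) and `cohort.json` (valve-class calls, confusion matrix,
#' accuracy, config hash).
#'
#' @param run Output of [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return Invisible list of the two file paths.
#' @export
write_report <- function(run, dir) {
  if (length(run$cases) < 1L) stopf("no reports to write")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (r in run$cases) {
    if (isTRUE(r$ok) && !is.null(r$report))
      rows[[length(rows) + 1L]] <-
        cbind(case_id = r$report$case_id, r$report$structures)
  }
  csv_path <- file.path(dir, "metrics.csv")
  if (length(rows))
    utils::write.csv(do.call(rbind, rows), csv_path, row.names = FALSE)
  cohort <- list(
    cases = lapply(run$cases, function(r) {
      if (isTRUE(r$ok))
        list(id = r$id, ok = TRUE, k = r$k, valve_class = r$valve_class,
             raphe_detected = r$raphe_detected,
             leaflet_names = as.list(r$leaflet_names),
             gt_class = r$gt_class)
      else list(id = r$id, ok = FALSE, error = r$error)
    }),
    confusion = if (!is.null(run$confusion))
      list(classes = run$confusion$classes,
           counts = unname(apply(run$confusion$counts, 1L, as.list)),
           accuracy = run$confusion$accuracy),
    config_hash = run$config_hash)
  json_path <- file.path(dir, "cohort.json")
  jsonlite::write_json(cohort, json_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(list(csv = csv_path, json = json_path))
}
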