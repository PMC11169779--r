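# Independent brute-force oracles and small fixture builders. These are
# deliberately naive implementations kept free of the package's code
# paths so they can arbitrate correctness.

# flood-fill connected-component labelling, plain R BFS
flood_fill_components <- function(mask, connectivity = 26L) {
  d <- dim(mask)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  if (connectivity == 6L) offs <- offs[rowSums(abs(offs)) == 1L, , drop = FALSE]
  lab <- array(0L, dim = d)
  cur <- 0L
  for (v in which(mask != 0)) {
    if (lab[v] != 0L) next
    cur <- cur + 1L
    queue <- v
    lab[v] <- cur
    while (length(queue)) {
      x <- queue[[1L]]; queue <- queue[-1L]
      ijk <- arrayInd(x, d)
      for (r in seq_len(nrow(offs))) {
        n <- ijk + offs[r, ]
        if (any(n < 1L) || any(n > d)) next
        ni <- n[1L] + (n[2L] - 1L) * d[1L] + (n[3L] - 1L) * d[1L] * d[2L]
        if (mask[ni] != 0 && lab[ni] == 0L) {
          lab[ni] <- cur
          queue <- c(queue, ni)
        }
      }
    }
  }
  lab
}

# surface voxels by direct 6-neighbour check (grid edge = outside)
brute_surface <- function(mask) {
  d <- dim(mask)
  idx <- which(mask != 0, arr.ind = TRUE)
  keep <- logical(nrow(idx))
  for (r in seq_len(nrow(idx))) {
    p <- idx[r, ]
    on_surface <- FALSE
    for (ax in 1:3) for (s in c(-1L, 1L)) {
      q <- p; q[ax] <- q[ax] + s
      if (any(q < 1L) || any(q > d) || mask[q[1L], q[2L], q[3L]] == 0)
        on_surface <- TRUE
    }
    keep[r] <- on_surface
  }
  idx[keep, , drop = FALSE]
}

# pooled symmetric nearest-surface distances by all-pairs computation
brute_pooled_dists <- function(pred, gt, spacing_mm) {
  a <- sweep(brute_surface(pred) - 1, 2L, spacing_mm, "*")
  b <- sweep(brute_surface(gt) - 1, 2L, spacing_mm, "*")
  dmat <- sqrt(outer(a[, 1L], b[, 1L], "-")^2 +
                 outer(a[, 2L], b[, 2L], "-")^2 +
                 outer(a[, 3L], b[, 3L], "-")^2)
  c(apply(dmat, 1L, min), apply(dmat, 2L, min))
}

brute_hd95 <- function(pred, gt, spacing_mm)
  stats::quantile(brute_pooled_dists(pred, gt, spacing_mm), 0.95,
                  names = FALSE)

brute_assd <- function(pred, gt, spacing_mm)
  mean(brute_pooled_dists(pred, gt, spacing_mm))

# plain mean-silhouette from first principles (all-pairs distances)
brute_mean_silhouette <- function(coords, cl) {
  n <- nrow(coords)
  dmat <- as.matrix(stats::dist(coords))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- cl == cl[i]
    a <- if (sum(own) > 1L) sum(dmat[i, own]) / (sum(own) - 1L) else 0
    b <- min(vapply(setdiff(unique(cl), cl[i]), function(c2)
      mean(dmat[i, cl == c2]), numeric(1L)))
    s[i] <- if (sum(own) > 1L) (b - a) / max(a, b) else 0
  }
  mean(s)
}

# random blobby mask: union of a few random balls in a small grid
random_blob_mask <- function(d = c(20L, 20L, 20L), n_balls = 2L,
                             r_range = c(2, 4)) {
  m <- array(FALSE, dim = d)
  ijk <- arrayInd(seq_len(prod(d)), d)
  for (b in seq_len(n_balls)) {
    ctr <- runif(3, 4, d - 3)
    rad <- runif(1, r_range[1L], r_range[2L])
    m[rowSums(sweep(ijk, 2L, ctr)^2) <= rad^2] <- TRUE
  }
  m
}

# compact phantom spec for fast unit tests
small_spec <- function(valve_type = "TAV", ...) {
  phantom_spec(valve_type, grid_shape = c(48L, 48L, 48L), ...)
}

sp07 <- c(0.7, 0.7, 0.7)
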