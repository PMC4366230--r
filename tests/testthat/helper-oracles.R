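# independent brute-force oracles used across test files

# per-pixel windowed population SD with mirror-at-edge reflection,
# computed by an explicit double loop (no shared code with the package)
bf_window_sd <- function(img, r) {
  n1 <- nrow(img); n2 <- ncol(img)
  refl <- function(k, n) ifelse(k < 1, 2 - k, ifelse(k > n, 2 * n - k, k))
  out <- matrix(0, n1, n2)
  for (i in seq_len(n1)) {
    for (j in seq_len(n2)) {
      vals <- numeric((2 * r + 1)^2)
      q <- 1L
      for (di in -r:r) {
        for (dj in -r:r) {
          vals[q] <- img[refl(i + di, n1), refl(j + dj, n2)]
          q <- q + 1L
        }
      }
      m <- mean(vals)
      out[i, j] <- sqrt(mean((vals - m)^2))
    }
  }
  out
}

# exhaustive between-class-variance threshold search over fixed bin edges
bf_otsu <- function(values, n_bins = 256) {
  lo <- min(values); hi <- max(values)
  edges <- seq(lo, hi, length.out = n_bins + 1)
  best <- -Inf; best_thr <- lo
  for (b in 2:n_bins) {
    thr <- edges[b]
    g0 <- values[values <= thr]; g1 <- values[values > thr]
    if (!length(g0) || !length(g1)) next
    bcv <- length(g0) * length(g1) * (mean(g0) - mean(g1))^2
    if (bcv > best) { best <- bcv; best_thr <- thr }
  }
  best_thr
}

# optimal 1:1 assignment by total centroid distance, by enumerating all
# bijections (tiny n only)
bf_assignment <- function(ca, cb) {
  n <- nrow(ca)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    }
    out
  }
  best <- NULL; best_cost <- Inf
  for (p in perms(seq_len(n))) {
    cost <- sum(sqrt(rowSums((ca - cb[p, , drop = FALSE])^2)))
    if (cost < best_cost) { best_cost <- cost; best <- p }
  }
  best
}

# voxelize a sphere on an anisotropic grid; returns a voxel_object
voxel_sphere <- function(radius = 50, voxel = c(2, 2, 10),
                         center = NULL, margin = 2) {
  nx <- ceiling(2 * (radius + margin * voxel[1]) / voxel[1])
  ny <- ceiling(2 * (radius + margin * voxel[2]) / voxel[2])
  nz <- ceiling(2 * (radius + margin * voxel[3]) / voxel[3])
  if (is.null(center)) {
    center <- c(nx * voxel[1], ny * voxel[2], nz * voxel[3]) / 2
  }
  occ <- array(FALSE, c(ny, nx, nz))
  xc <- (seq_len(nx) - 0.5) * voxel[1]
  yc <- (seq_len(ny) - 0.5) * voxel[2]
  for (k in seq_len(nz)) {
    zc <- (k - 0.5) * voxel[3]
    d2 <- outer((yc - center[2])^2, (xc - center[1])^2, "+") +
      (zc - center[3])^2
    occ[, , k] <- d2 <= radius^2
  }
  voxel_object(which(occ), dim(occ), voxel)
}
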