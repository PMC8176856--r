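# Independent brute-force oracles: plain triple loops over voxel centres,
# written without reference to the package's vectorized implementations.

oracle_count_at_threshold <- function(values, mask, t) {
  d <- dim(values)
  n <- 0L
  for (i in seq_len(d[1]))
    for (j in seq_len(d[2]))
      for (k in seq_len(d[3]))
        if (mask[i, j, k] && values[i, j, k] >= t) n <- n + 1L
  n
}

oracle_rasterize_ellipsoid <- function(vol, center, semi_axes) {
  d <- dim(vol$values)
  m <- array(FALSE, d)
  for (i in seq_len(d[1]))
    for (j in seq_len(d[2]))
      for (k in seq_len(d[3])) {
        w <- vol$origin + vol$spacing * (c(i, j, k) - 1)
        m[i, j, k] <- sum(((w - center) / semi_axes)^2) <= 1
      }
  m
}

oracle_rasterize_box <- function(vol, center, edges) {
  d <- dim(vol$values)
  m <- array(FALSE, d)
  for (i in seq_len(d[1]))
    for (j in seq_len(d[2]))
      for (k in seq_len(d[3])) {
        w <- vol$origin + vol$spacing * (c(i, j, k) - 1)
        m[i, j, k] <- all(abs(w - center) <= edges / 2)
      }
  m
}

oracle_rasterize_disc <- function(vol, center, diameter) {
  d <- dim(vol$values)
  zc <- vol$origin[3] + vol$spacing[3] * (seq_len(d[3]) - 1)
  kbest <- which.min(abs(zc - center[3]))
  m <- array(FALSE, d)
  for (i in seq_len(d[1]))
    for (j in seq_len(d[2])) {
      w <- vol$origin[1:2] + vol$spacing[1:2] * (c(i, j) - 1)
      m[i, j, kbest] <- sum((w - center[1:2])^2) <= (diameter / 2)^2
    }
  m
}

# Hand computation of the Kruskal-Wallis H with tie correction.
oracle_kruskal_h <- function(groups) {
  x <- unlist(groups)
  g <- rep(seq_along(groups), lengths(groups))
  n <- length(x)
  r <- rank(x)
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, g, function(ri) length(ri) * mean(ri)^2)) - 3 * (n + 1)
  ties <- table(x)
  h / (1 - sum(ties^3 - ties) / (n^3 - n))
}

# A small random image + VOI for segmentation oracle checks. Values are a
# noisy blob so that thresholds cut through a range of volumes.
random_grid_case <- function(seed) {
  set.seed(seed)
  d <- sample(6:20, 3, replace = TRUE)
  sp <- runif(3, 1, 4)
  vol <- scalar_volume(array(runif(prod(d), 0, 10), d), spacing = sp)
  center <- vol$origin + sp * (d - 1) / 2
  semi <- sp * d / 2  # covers most of the grid; always >= 1 voxel centre
  list(vol = vol, voi = ellipsoid_voi(center, semi))
}

# world coordinates of voxel centres along one axis (local re-derivation)
axis_coords_for_test <- function(vol, ax)
  vol$origin[ax] + vol$spacing[ax] * (seq_len(dim(vol$values)[ax]) - 1)
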