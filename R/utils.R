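# Internal helpers shared across modules.

# Voxel-center coordinate vector for n voxels of edge h, grid centred on the
# origin. n is kept odd by the phantom builder so that the mid-sagittal plane
# x = 0 passes through a voxel-center column and mirror symmetry is exact.
grid_coords <- function(n, h) (seq_len(n) - (n + 1) / 2) * h

# Full 3-D coordinate arrays (mm) for a grid; varying dimension 1 = x (right),
# 2 = y (anterior), 3 = z (superior).
coord_arrays <- function(dims, h) {
  x <- grid_coords(dims[1], h)
  y <- grid_coords(dims[2], h)
  z <- grid_coords(dims[3], h)
  list(
    X = array(rep(x, times = dims[2] * dims[3]), dims),
    Y = array(rep(rep(y, each = dims[1]), times = dims[3]), dims),
    Z = array(rep(z, each = dims[1] * dims[2]), dims)
  )
}

# Linear-index stride for a face normal axis.
axis_stride <- function(dims, axis) switch(axis, 1L, dims[1], dims[1] * dims[2])

# Quasi-uniform unit directions on the sphere (Fibonacci lattice).
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

# Trilinear interpolation of a 3-D array at points (mm, head frame).
# Points must lie strictly inside the voxel-center hull.
trilinear <- function(arr, points, spacing_mm) {
  dims <- dim(arr)
  out <- numeric(nrow(points))
  for (ax in 1:3) {
    # continuous voxel coordinate (1-based)
    points[, ax] <- points[, ax] / spacing_mm + (dims[ax] + 1) / 2
  }
  i0 <- floor(points)
  f <- points - i0
  if (any(i0 < 1 | i0 + 1 > matrix(dims, nrow(points), 3, byrow = TRUE)))
    stop("interpolation point outside the grid")
  idx <- function(di) {
    ii <- i0 + matrix(di, nrow(points), 3, byrow = TRUE)
    ii[, 1] + dims[1] * (ii[, 2] - 1) + dims[1] * dims[2] * (ii[, 3] - 1)
  }
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (dx * f[, 1] + (1 - dx) * (1 - f[, 1])) *
      (dy * f[, 2] + (1 - dy) * (1 - f[, 2])) *
      (dz * f[, 3] + (1 - dz) * (1 - f[, 3]))
    out <- out + w * arr[idx(c(dx, dy, dz))]
  }
  out
}

# Run code with a private RNG stream, restoring the caller's state.
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
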