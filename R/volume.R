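#' Density volume container
#'
#' A 3D scalar grid with physical voxel size. Data are stored as an R array
#' with dims (nx, ny, nz), x fastest, which matches the MRC section layout.
#' The physical position of voxel (i, j, k) (1-based R indices) is
#' `origin + (c(i, j, k) - 1) * voxel_size` nm. Internal contrast convention
#' is protein-positive (protein = high values); [write_mrc()] can invert at
#' the boundary for EM-convention output.
#'
#' @param data numeric 3D array
#' @param voxel_size voxel edge length in nm (> 0)
#' @param origin physical position of voxel (1,1,1), nm (length-3)
#' @return an object of class `volume`
#' @export
volume <- function(data, voxel_size = 1, origin = c(0, 0, 0)) {
  stopifnot(is.array(data), length(dim(data)) == 3)
  if (!is.numeric(voxel_size) || length(voxel_size) != 1 || voxel_size <= 0)
    stop("voxel_size must be a single positive number")
  if (any(!is.finite(data))) stop("volume data must be finite")
  structure(list(data = data, voxel_size = voxel_size,
                 origin = as.numeric(origin)),
            class = "volume")
}

#' @export
print.volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume> %d x %d x %d voxels, %.3f nm/voxel, range [%.3g, %.3g]\n",
              d[1], d[2], d[3], x$voxel_size, min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.volume <- function(x) dim(x$data)

is_volume <- function(x) inherits(x, "volume")

#' Sum of central slices (projection image)
#'
#' Sums `n_slices` central slices perpendicular to the given axis, the
#' standard way cross-sections of subtomogram averages are displayed (five
#' summed slices by default in this package's classification stages).
#'
#' @param vol a [volume()] or 3D array
#' @param n_slices number of central slices to sum (<= extent along axis)
#' @param axis one of "x", "y", "z": the axis perpendicular to the slices
#' @return 2D matrix; for axis "z" the result is indexed (x, y)
#' @export
project <- function(vol, n_slices = 5, axis = c("z", "x", "y")) {
  axis <- match.arg(axis)
  a <- if (is_volume(vol)) vol$data else vol
  ax <- match(axis, c("x", "y", "z"))
  n <- dim(a)[ax]
  if (n_slices > n) stop("n_slices exceeds volume extent along axis")
  mid <- (n + 1) / 2
  idx <- seq(floor(mid - (n_slices - 1) / 2), length.out = n_slices)
  sl <- switch(axis,
    x = a[idx, , , drop = FALSE],
    y = a[, idx, , drop = FALSE],
    z = a[, , idx, drop = FALSE]
  )
  apply(sl, setdiff(1:3, ax), sum)
}

# frequency coordinates (cycles per nm) along one axis of length n
freq_axis <- function(n, voxel) {
  k <- c(0:floor((n - 1) / 2), -(ceiling((n - 1) / 2):1))
  k / (n * voxel)
}

# binary missing-wedge mask in Fourier space for a volume of dims d;
# tilt axis y, beam along z: region |atan2(|kz|, |kx|)| > tilt_range is unmeasured
wedge_mask <- function(d, tilt_range) {
  kx <- abs(freq_axis(d[1], 1))
  kz <- abs(freq_axis(d[3], 1))
  ang <- outer(kx, kz, function(x, z) atan2(z, x) * 180 / pi)
  inside <- ang <= tilt_range        # measured region
  inside[1, 1] <- TRUE               # keep the DC/equatorial line
  aperm(array(rep(inside, d[2]), dim = c(d[1], d[3], d[2])), c(1, 3, 2))
}

#' Trilinear interpolation of a volume at arbitrary points
#'
#' @param vol a [volume()]
#' @param pts n x 3 matrix of physical positions, nm
#' @return numeric vector (0 outside the grid)
#' @export
sample_volume <- function(vol, pts) {
  d <- dim(vol$data)
  p <- sweep(as.matrix(pts), 2, vol$origin) / vol$voxel_size + 1  # 1-based
  out <- numeric(nrow(p))
  ok <- p[, 1] >= 1 & p[, 2] >= 1 & p[, 3] >= 1 &
    p[, 1] <= d[1] & p[, 2] <= d[2] & p[, 3] <= d[3]
  if (!any(ok)) return(out)
  p <- pmin(p[ok, , drop = FALSE],
            matrix(d - 1e-9, sum(ok), 3, byrow = TRUE))
  i0 <- pmin(floor(p[, 1]), d[1] - 1); fx <- p[, 1] - i0
  j0 <- pmin(floor(p[, 2]), d[2] - 1); fy <- p[, 2] - j0
  k0 <- pmin(floor(p[, 3]), d[3] - 1); fz <- p[, 3] - k0
  v <- vol$data
  idx <- function(i, j, k) v[cbind(i, j, k)]
  out[ok] <-
    idx(i0, j0, k0) * (1 - fx) * (1 - fy) * (1 - fz) +
    idx(i0 + 1, j0, k0) * fx * (1 - fy) * (1 - fz) +
    idx(i0, j0 + 1, k0) * (1 - fx) * fy * (1 - fz) +
    idx(i0, j0, k0 + 1) * (1 - fx) * (1 - fy) * fz +
    idx(i0 + 1, j0 + 1, k0) * fx * fy * (1 - fz) +
    idx(i0 + 1, j0, k0 + 1) * fx * (1 - fy) * fz +
    idx(i0, j0 + 1, k0 + 1) * (1 - fx) * fy * fz +
    idx(i0 + 1, j0 + 1, k0 + 1) * fx * fy * fz
  out
}
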