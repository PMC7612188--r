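# Constrained subtomogram alignment, cleaning, symmetry expansion, averaging,
# projections and FSC.
#
# Alignment model: each particle carries an orientation R (Euler angles,
# box -> tomogram) and a position. The cropped box differs from the common
# (reference) frame by a residual transform (dR, ds) expressed in the box
# frame; alignment searches a discrete grid of residuals within stated
# limits, maximizing masked normalized cross-correlation, and composes the
# winning residual into the table: R' = R dR, pos' = pos + R ds.

#' Alignment search limits
#'
#' @param max_inplane maximum in-plane (spin) rotation, degrees
#' @param max_axial_shift maximum shift along the filament/box z axis, nm
#' @param max_lateral_shift maximum shift perpendicular to the axis, nm
#' @param cone maximum tilt of the box axis, degrees (0 = axis locked,
#'   180 = free orientation search)
#' @param inplane_step,shift_step,cone_step search grid steps (degrees, nm,
#'   degrees); shift_step defaults to half a voxel at alignment time if NA
#' @param mask mask specification: `list(type = "gaussian_tube", radius =, sigma =)`,
#'   `list(type = "gaussian_sphere", radius =, sigma =)`, or `list(type = "none")`
#' @return object of class `alignment_limits`
#' @export
alignment_limits <- function(max_inplane = 28, max_axial_shift = 2.2,
                             max_lateral_shift = 0, cone = 0,
                             inplane_step = 2, shift_step = NA,
                             cone_step = 30,
                             mask = list(type = "gaussian_tube",
                                         radius = 10.6, sigma = 3)) {
  if (any(c(max_inplane, max_axial_shift, max_lateral_shift, cone) < 0))
    stop("alignment limits must be >= 0")
  structure(list(max_inplane = max_inplane, max_axial_shift = max_axial_shift,
                 max_lateral_shift = max_lateral_shift, cone = cone,
                 inplane_step = inplane_step, shift_step = shift_step,
                 cone_step = cone_step, mask = mask),
            class = "alignment_limits")
}

#' Soft masks for alignment and classification
#'
#' `mask_volume` builds the mask described by a limits mask spec on a cubic
#' box grid: a gaussian tube (soft annulus centered on the wall radius,
#' used to align on the MT wall and ignore luminal densities), a gaussian
#' sphere (1 inside `radius`, gaussian falloff of width `sigma` outside), or
#' no mask.
#'
#' @param spec mask specification list (see [alignment_limits()])
#' @param box_size box edge, voxels (odd)
#' @param voxel_size nm per voxel
#' @return numeric array of weights in `[0, 1]`
#' @export
mask_volume <- function(spec, box_size, voxel_size) {
  c0 <- (box_size - 1) / 2
  ax <- (seq_len(box_size) - 1 - c0) * voxel_size
  if (is.null(spec) || identical(spec$type, "none"))
    return(array(1, rep(box_size, 3)))
  if (spec$type == "gaussian_tube") {
    r2 <- outer(ax^2, ax^2, "+")              # x-y radial distance^2
    r <- sqrt(r2)
    m2 <- exp(-(r - spec$radius)^2 / (2 * spec$sigma^2))
    return(array(rep(m2, box_size), rep(box_size, 3)))
  }
  if (spec$type == "gaussian_sphere") {
    r <- sqrt(outer(outer(ax^2, ax^2, "+"), ax^2, "+"))
    m <- ifelse(r <= spec$radius, 1,
                exp(-(r - spec$radius)^2 / (2 * spec$sigma^2)))
    return(array(m, rep(box_size, 3)))
  }
  stop("unknown mask type: ", spec$type)
}

# soft cosine taper that down-weights the box faces a shifted/rotated
# reference cannot fill (margin in nm per axis); keeps edge zero-fill from
# biasing the shift search
edge_taper <- function(box_size, voxel_size, margin) {
  half <- (box_size - 1) / 2 * voxel_size
  w_axis <- function(m) {
    if (m <= 0) return(rep(1, box_size))
    z <- abs((seq_len(box_size) - 1 - (box_size - 1) / 2) * voxel_size)
    w <- rep(1, box_size)
    roll <- z > half - m
    w[roll] <- 0.5 + 0.5 * cos(pi * (z[roll] - (half - m)) / m)
    w
  }
  wx <- w_axis(margin[1]); wy <- w_axis(margin[2]); wz <- w_axis(margin[3])
  outer(outer(wx, wy), wz)
}

# small Gaussian low-pass (sigma in voxels) applied before correlation
# scoring: trilinear resampling smooths fractional-grid bank entries but not
# the identity entry; band-limiting both sides first removes that bias
lowpass_box <- function(arr, sigma_vox = 0.6) {
  cpp_lowpass3(arr, sigma_vox)
}

# weighted centering + unit norm per column; returns list(mat, ok)
normalize_cols <- function(mat, w) {
  sw <- sum(w)
  mu <- colSums(mat * w) / sw
  ctr <- sweep(mat, 2, mu) * sqrt(w)
  nrm <- sqrt(colSums(ctr^2))
  ok <- nrm > 1e-12
  ctr[, ok] <- sweep(ctr[, ok, drop = FALSE], 2, nrm[ok], "/")
  list(mat = ctr, ok = ok)
}

# residual search grid within limits: one row per (rotation, shift)
residual_grid <- function(limits, voxel_size) {
  sstep <- limits$shift_step
  if (is.na(sstep)) sstep <- voxel_size / 2
  dpsi <- if (limits$max_inplane > 0)
    seq(-limits$max_inplane, limits$max_inplane, by = limits$inplane_step)
  else 0
  if (limits$max_inplane >= 180) dpsi <- dpsi[dpsi > -180]   # avoid double cover
  sym_seq <- function(lim, step) {
    if (lim <= 0) return(0)
    half <- seq(0, lim, by = step)
    sort(unique(c(-half, half)))
  }
  sz <- sym_seq(limits$max_axial_shift, sstep)
  sxy <- sym_seq(limits$max_lateral_shift, sstep)
  cone <- expand.grid(tilt = 0, az = 0)
  if (limits$cone > 0) {
    tilts <- seq(limits$cone_step, limits$cone, by = limits$cone_step)
    cone <- rbind(cone, do.call(rbind, lapply(tilts, function(tt) {
      n_az <- max(1, ceiling(360 * sin(deg2rad(min(tt, 90))) / limits$cone_step))
      data.frame(tilt = tt, az = seq(0, 360 - 360 / n_az, by = 360 / n_az))
    })))
  }
  g <- expand.grid(ci = seq_len(nrow(cone)), dpsi = dpsi,
                   sx = sxy, sy = sxy, sz = sz)
  data.frame(tilt = cone$tilt[g$ci], az = cone$az[g$ci], dpsi = g$dpsi,
             sx = g$sx, sy = g$sy, sz = g$sz)
}

grid_rotation <- function(row) {
  Rc <- if (row$tilt != 0)
    rot_z(row$az) %*% rot_x(row$tilt) %*% rot_z(-row$az) else diag(3)
  Rc %*% rot_z(row$dpsi)
}

# bank of transformed, masked, normalized reference vectors (nvox x G)
reference_bank <- function(reference, grid, mask_arr, voxel_size) {
  ref <- if (is_volume(reference)) reference$data else reference
  mvec <- as.numeric(mask_arr)
  bank <- matrix(0, length(ref), nrow(grid))
  for (g in seq_len(nrow(grid))) {
    dR <- grid_rotation(grid[g, ])
    ds <- c(grid$sx[g], grid$sy[g], grid$sz[g])
    A <- t(dR)
    s <- -as.numeric(A %*% ds)
    bank[, g] <- cpp_transform_box(ref, as.numeric(A), s, voxel_size)
  }
  normalize_cols(bank, mvec)
}

# residual transform taking the cropped box into the current table frame
residual_from_tables <- function(stack, table, i) {
  ids <- if (!is.null(table$source_id)) table$source_id else table$particle_id
  j <- match(ids[i], stack$table$particle_id)
  R0 <- eul2rot(stack$table$phi[j], stack$table$theta[j], stack$table$psi[j])
  R1 <- eul2rot(table$phi[i], table$theta[i], table$psi[i])
  dR <- t(R0) %*% R1
  ds <- as.numeric(t(R0) %*% (c(table$x[i], table$y[i], table$z[i]) -
                              c(stack$table$x[j], stack$table$y[j], stack$table$z[j])))
  list(dR = dR, ds = ds)
}

# boxes resampled into the frame described by `table` (matrix nvox x N,
# one column per table row, matched to stack columns by particle_id)
aligned_boxes <- function(stack, table = stack$table) {
  ids <- if (!is.null(table$source_id)) table$source_id else table$particle_id
  j <- match(ids, stack$table$particle_id)
  if (anyNA(j)) stop("table contains particles absent from the stack")
  out <- stack$boxes[, j, drop = FALSE]
  for (i in seq_len(nrow(table))) {
    r <- residual_from_tables(stack, table, i)
    if (max(abs(r$dR - diag(3))) > 1e-9 || max(abs(r$ds)) > 1e-9)
      out[, i] <- cpp_transform_box(stack_box(stack, j[i]), as.numeric(r$dR),
                                    r$ds, stack$voxel_size)
  }
  out
}

#' Align particles against a reference
#'
#' Grid search over residual rotations and shifts within `limits`,
#' maximizing masked normalized cross-correlation. Updates are cumulative
#' across iterations (each iteration recenters the search on the current
#' estimate). All-zero boxes get `cc_score = -1` and are flagged.
#'
#' @param stack a [subtomogram_stack()]
#' @param reference a [volume()] or array of the same box size
#' @param limits an [alignment_limits()]
#' @param iterations number of grid search passes
#' @param table optional current table (defaults to the stack's)
#' @return updated [particle_table()] with angles, positions and cc_score
#' @export
align <- function(stack, reference, limits = alignment_limits(),
                  iterations = 1, table = stack$table) {
  ref <- if (is_volume(reference)) reference$data else reference
  if (!all(dim(ref) == rep(stack$box_size, 3)))
    stop("reference and boxes must have the same size")
  mask_arr <- mask_volume(limits$mask, stack$box_size, stack$voxel_size)
  lat_m <- limits$max_lateral_shift + stack$voxel_size
  mask_arr <- mask_arr * edge_taper(stack$box_size, stack$voxel_size,
                                    c(lat_m, lat_m,
                                      limits$max_axial_shift + stack$voxel_size))
  mvec <- as.numeric(mask_arr)
  grid <- residual_grid(limits, stack$voxel_size)
  ref_lp <- lowpass_box(ref)
  # score the grid in chunks so the transformed-reference bank stays small
  chunk_size <- max(1L, as.integer(2e7 / length(ref)))
  chunks <- split(seq_len(nrow(grid)),
                  ceiling(seq_len(nrow(grid)) / chunk_size))
  tb <- table
  for (it in seq_len(iterations)) {
    M <- aligned_boxes(stack, tb)
    d3 <- rep(stack$box_size, 3)
    for (i in seq_len(ncol(M)))
      M[, i] <- lowpass_box(array(M[, i], d3))
    P <- normalize_cols(M, mvec)
    best <- rep(1L, ncol(P$mat))
    best_cc <- rep(-Inf, ncol(P$mat))
    for (ch in chunks) {
      bank <- reference_bank(ref_lp, grid[ch, , drop = FALSE], mask_arr,
                             stack$voxel_size)
      ccc <- crossprod(bank$mat, P$mat)       # chunk x N
      top <- max.col(t(ccc), ties.method = "first")
      val <- ccc[cbind(top, seq_along(top))]
      upd <- val > best_cc
      best[upd] <- ch[top[upd]]
      best_cc[upd] <- val[upd]
    }
    for (i in seq_len(nrow(tb))) {
      if (!P$ok[i]) {
        tb$cc_score[i] <- -1
        tb$keep_flag[i] <- FALSE
        next
      }
      g <- best[i]
      dR <- grid_rotation(grid[g, ])
      ds <- c(grid$sx[g], grid$sy[g], grid$sz[g])
      R <- eul2rot(tb$phi[i], tb$theta[i], tb$psi[i])
      Rn <- R %*% dR
      e <- rot2eul(Rn)
      tb$phi[i] <- e[1]; tb$theta[i] <- e[2]; tb$psi[i] <- e[3]
      pos <- c(tb$x[i], tb$y[i], tb$z[i]) + as.numeric(R %*% ds)
      tb$x[i] <- pos[1]; tb$y[i] <- pos[2]; tb$z[i] <- pos[3]
      tb$cc_score[i] <- max(min(best_cc[i], 1), -1)
    }
  }
  tb
}

#' Keep the best-correlating fraction of particles per filament
#'
#' Within each filament, retains the `ceiling(fraction * n)` highest
#' cc_score particles (score ties are kept).
#'
#' @param table a [particle_table()] with cc scores
#' @param fraction fraction to retain (0.8 = remove the worst 20%)
#' @param group_by grouping column (default filament_id)
#' @return filtered table
#' @export
cc_clean <- function(table, fraction = 0.8, group_by = "filament_id") {
  stopifnot(fraction > 0, fraction <= 1)
  keep <- logical(nrow(table))
  for (g in unique(table[[group_by]])) {
    idx <- which(table[[group_by]] == g & table$keep_flag)
    if (!length(idx)) next
    sc <- table$cc_score[idx]
    k <- ceiling(fraction * length(idx))
    thr <- sort(sc, decreasing = TRUE)[k]
    keep[idx[sc >= thr]] <- TRUE
  }
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Remove near-duplicate particles
#'
#' Among particle pairs that are BOTH closer than `min_dist` and differ in
#' in-plane angle by less than `min_angle`, the lower-scoring particle is
#' removed (greedy from the highest score down). Pairs failing either
#' condition are kept: the test is conjunctive.
#'
#' @param table a [particle_table()]
#' @param min_dist minimum center distance, nm
#' @param min_angle minimum in-plane angular difference, degrees
#' @return filtered table
#' @export
distance_clean <- function(table, min_dist = 3.5, min_angle = 25) {
  n <- nrow(table)
  if (n < 2) return(table)
  ord <- order(-table$cc_score)
  removed <- logical(n)
  pos <- as.matrix(table[, c("x", "y", "z")])
  for (oi in seq_len(n)) {
    i <- ord[oi]
    if (removed[i]) next
    d <- sqrt(colSums((t(pos) - pos[i, ])^2))
    dpsi <- abs(wrap180(table$psi - table$psi[i]))
    viol <- which(d < min_dist & dpsi < min_angle & seq_len(n) != i & !removed)
    removed[viol] <- TRUE
  }
  out <- table[!removed, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Helical symmetry expansion
#'
#' Appends `copies` symmetry-related copies of each particle: copy k is
#' rotated k*rot about the filament axis and shifted k*rise along it. The
#' defaults are the 13-protofilament helical parameters (27.69 degrees,
#' 0.92 nm) applied cumulatively 12 times, so each input particle yields
#' 13 rows.
#'
#' @param table a [particle_table()]
#' @param rot in-plane rotation per copy, degrees
#' @param rise axial shift per copy, nm
#' @param copies number of copies to append
#' @return expanded table (rows ordered original first, then copies)
#' @export
symmetry_expand <- function(table, rot = 27.69, rise = 0.92, copies = 12) {
  out <- vector("list", copies + 1)
  out[[1]] <- cbind(as.data.frame(table), expand_copy = 0L)
  for (k in seq_len(copies)) {
    tb <- as.data.frame(table)
    for (i in seq_len(nrow(tb))) {
      R <- eul2rot(tb$phi[i], tb$theta[i], tb$psi[i])
      pos <- c(tb$x[i], tb$y[i], tb$z[i]) + as.numeric(R %*% c(0, 0, k * rise))
      tb$x[i] <- pos[1]; tb$y[i] <- pos[2]; tb$z[i] <- pos[3]
    }
    tb$psi <- wrap180(tb$psi + k * rot)
    tb$expand_copy <- k
    out[[k + 1]] <- tb
  }
  res <- do.call(rbind, out)
  src <- res$particle_id
  res$particle_id <- seq_len(nrow(res)) - 1L
  rownames(res) <- NULL
  ec <- res$expand_copy
  res <- as_particle_table(res)
  res$expand_copy <- ec
  res$source_id <- src       # crop-time identity of each symmetry copy
  res
}

#' Average a subtomogram stack
#'
#' Resamples each kept particle into the common frame by the inverse of its
#' residual transform and averages. With `wedge_compensation`, the Fourier
#' sum is divided per voxel by the summed missing-wedge coverage of the
#' contributing particles (floored at 10% of its maximum to avoid
#' amplifying unmeasured regions).
#'
#' @param stack a [subtomogram_stack()]
#' @param table current table (kept rows are averaged)
#' @param wedge_compensation logical
#' @param tilt_range wedge half-range used when compensating, degrees
#' @return a [volume()]
#' @export
average <- function(stack, table = stack$table, wedge_compensation = FALSE,
                    tilt_range = 60) {
  tb <- table[table$keep_flag, , drop = FALSE]
  if (nrow(tb) == 0) stop("no kept particles to average")
  M <- aligned_boxes(stack, tb)
  s <- array(rowMeans(M), rep(stack$box_size, 3))
  if (!wedge_compensation)
    return(volume(s, voxel_size = stack$voxel_size))
  d <- rep(stack$box_size, 3)
  kx <- freq_axis(d[1], 1); ky <- freq_axis(d[2], 1); kz <- freq_axis(d[3], 1)
  kg <- cbind(rep(kx, times = d[2] * d[3]),
              rep(rep(ky, each = d[1]), times = d[3]),
              rep(kz, each = d[1] * d[2]))
  cov <- numeric(prod(d))
  for (i in seq_len(nrow(tb))) {
    R <- eul2rot(tb$phi[i], tb$theta[i], tb$psi[i])
    kw <- kg %*% t(R)          # box-frame freq -> world frame
    ang <- atan2(abs(kw[, 3]), abs(kw[, 1])) * 180 / pi
    cov <- cov + as.numeric(ang <= tilt_range)
  }
  cov[1] <- nrow(tb)           # DC always measured
  flo <- 0.1 * max(cov)
  F <- fft(array(rowSums(M), d)) / pmax(cov, flo)
  s <- Re(fft(array(F, d), inverse = TRUE)) / prod(d)
  volume(array(s, d), voxel_size = stack$voxel_size)
}

#' Fourier shell correlation between two volumes
#'
#' @param vol_a,vol_b volumes or arrays of identical (cubic) dimensions
#' @param mask optional real-space mask applied to both
#' @param voxel_size nm per voxel (taken from `vol_a` if it is a volume)
#' @return data.frame with shell index, frequency (1/nm) and correlation
#' @export
fsc <- function(vol_a, vol_b, mask = NULL, voxel_size = NULL) {
  a <- if (is_volume(vol_a)) vol_a$data else vol_a
  b <- if (is_volume(vol_b)) vol_b$data else vol_b
  if (is.null(voxel_size))
    voxel_size <- if (is_volume(vol_a)) vol_a$voxel_size else 1
  if (!all(dim(a) == dim(b))) stop("volumes must have equal shapes")
  if (!is.null(mask)) {
    m <- if (is_volume(mask)) mask$data else mask
    a <- a * m; b <- b * m
  }
  d <- dim(a)
  Fa <- fft(a); Fb <- fft(b)
  ix <- c(0:floor((d[1] - 1) / 2), -(ceiling((d[1] - 1) / 2):1)) / d[1]
  iy <- c(0:floor((d[2] - 1) / 2), -(ceiling((d[2] - 1) / 2):1)) / d[2]
  iz <- c(0:floor((d[3] - 1) / 2), -(ceiling((d[3] - 1) / 2):1)) / d[3]
  r <- sqrt(outer(outer(ix^2, iy^2, "+"), iz^2, "+"))   # cycles/voxel
  n_shell <- floor(min(d) / 2)
  shell <- pmin(round(r * min(d)), n_shell)
  num <- Re(tapply(Fa * Conj(Fb), shell, sum))
  da <- tapply(abs(Fa)^2, shell, sum)
  db <- tapply(abs(Fb)^2, shell, sum)
  sh <- as.integer(names(num))
  corr <- num / sqrt(da * db)
  corr[!is.finite(corr)] <- 0
  keep <- sh <= n_shell
  data.frame(shell = sh[keep],
             freq = sh[keep] / (min(d) * voxel_size),
             fsc = corr[keep])
}

#' Resolution at an FSC threshold
#'
#' Frequency of the first crossing below `threshold` (linear interpolation),
#' reported as a real-space resolution in Angstrom. If the curve never
#' crosses, the Nyquist bound is returned with attribute `crossed = FALSE`.
#'
#' @param curve data.frame from [fsc()]
#' @param threshold FSC cutoff (0.143 gold-standard, 0.5 conservative)
#' @param voxel_size nm per voxel (for the Nyquist bound if needed)
#' @return resolution in Angstrom
#' @export
resolution_at <- function(curve, threshold = 0.143, voxel_size = 1) {
  f <- curve$fsc; q <- curve$freq
  below <- which(f < threshold & q > 0)
  if (!length(below)) {
    res <- 2 * voxel_size * 10
    attr(res, "crossed") <- FALSE
    return(res)
  }
  i <- below[1]
  if (i == 1) {
    fr <- q[1]
  } else {
    t <- (f[i - 1] - threshold) / (f[i - 1] - f[i])
    fr <- q[i - 1] + t * (q[i] - q[i - 1])
  }
  res <- 10 / fr          # 1/nm -> Angstrom
  attr(res, "crossed") <- TRUE
  res
}

#' Write an FSC curve as TSV (shell, frequency in 1/Angstrom, correlation)
#' @param curve data.frame from [fsc()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_fsc <- function(curve, path) {
  out <- data.frame(shell = curve$shell,
                    freq_inv_angstrom = sprintf("%.6f", curve$freq / 10),
                    fsc = sprintf("%.6f", curve$fsc))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#shell\tfreq_inv_angstrom\tfsc", con)
  writeLines(paste(out$shell, out$freq_inv_angstrom, out$fsc, sep = "\t"), con)
  invisible(path)
}
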