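# Microtubule lattice geometry
#
# A microtubule is modeled as pf_number protofilaments on a cylinder of
# radius wall_radius around the picking path. Each dimer layer advances
# dimer_rise (8 nm) along the axis; protofilament j sits at angle
# phase0 + j * skew_per_pf and is raised by j * rise_per_pf, where
# rise_per_pf = 1.5 * dimer_rise / pf_number (the 3-start helical rise,
# 0.92 nm for 13 pfs), which also produces the lattice seam. The beta
# monomer of each dimer is offset along the axis by monomer_offset and, to
# encode the polarity cue ("slew"), displaced tangentially (sign set by
# polarity) and radially outward by monomer_offset * sin(slew_tilt). In
# cross-section projections this shears the outer wall against the inner
# wall, the automatable equivalent of the clockwise/anti-clockwise tubulin
# slew used to read microtubule polarity.

#' Microtubule lattice parameters
#'
#' @param pf_number protofilament count (11-15; 13 for mammalian neurons)
#' @param wall_radius distance from the axis to the pf centerline, nm. The
#'   default NULL scales the canonical 13-pf radius (10.6 nm) by
#'   pf_number/13 so the inter-pf spacing stays constant.
#' @param dimer_rise axial repeat per tubulin dimer, nm
#' @param monomer_offset beta relative to alpha monomer, nm
#' @param skew_per_pf lattice rotation per protofilament, degrees
#'   (default 360/pf_number: zero supertwist)
#' @param monomer_sigma Gaussian blob width of one monomer, nm
#' @param slew_tilt tilt of the monomer pair producing the projection slew,
#'   degrees
#' @return object of class `lattice_spec`
#' @export
lattice_spec <- function(pf_number = 13L, wall_radius = NULL,
                         dimer_rise = 8, monomer_offset = 4,
                         skew_per_pf = 360 / pf_number,
                         monomer_sigma = 2, slew_tilt = 15) {
  pf_number <- as.integer(pf_number)
  if (!pf_number %in% 11:15) stop("pf_number must be in 11..15")
  if (is.null(wall_radius)) wall_radius <- 10.6 * pf_number / 13
  if (wall_radius <= 0 || dimer_rise <= 0) stop("wall_radius and dimer_rise must be > 0")
  if (pf_number == 13L && abs(skew_per_pf * pf_number - 360) > 0.5)
    stop("13-pf lattice must have zero supertwist (skew_per_pf * 13 within 0.5 deg of 360)")
  structure(list(pf_number = pf_number, wall_radius = wall_radius,
                 dimer_rise = dimer_rise, monomer_offset = monomer_offset,
                 skew_per_pf = skew_per_pf, monomer_sigma = monomer_sigma,
                 slew_tilt = slew_tilt),
            class = "lattice_spec")
}

#' Ground-truth filament specification
#'
#' @param path n x 3 matrix of ordered 3D points, nm
#' @param polarity "plus_along_path" (plus end at the path end) or
#'   "minus_along_path"
#' @param pf_segments data.frame with columns s0, s1, pf tiling
#'   `[0, length]`: protofilament number per arclength interval
#' @param break_intervals data.frame with columns s0, s1 (nm): lattice breaks
#' @param end_taper list(start =, end =): per-pf terminal arclengths at each
#'   end; at the path start, pf j carries no monomers below
#'   `end_taper$start[j]`, and symmetrically at the path end. Taper length is
#'   max - min of the terminal arclengths.
#' @param mip_rate luminal particle rate, count per micrometer
#' @param kind filament type
#' @param phase0 lattice phase (rotation of pf 0 about the axis), degrees
#' @return object of class `filament_spec`
#' @export
filament_spec <- function(path, polarity = c("plus_along_path", "minus_along_path"),
                          pf_segments = NULL, break_intervals = NULL,
                          end_taper = NULL, mip_rate = 0,
                          kind = c("MT", "actin", "thick", "thin"),
                          phase0 = 0) {
  polarity <- match.arg(polarity)
  kind <- match.arg(kind)
  path <- as.matrix(path)
  stopifnot(ncol(path) == 3)
  seg <- sqrt(rowSums((path[-1, , drop = FALSE] - path[-nrow(path), , drop = FALSE])^2))
  if (any(seg == 0)) stop("degenerate path: repeated consecutive points")
  len <- sum(seg)
  if (is.null(pf_segments)) pf_segments <- data.frame(s0 = 0, s1 = len, pf = 13L)
  pf_segments <- pf_segments[order(pf_segments$s0), , drop = FALSE]
  if (abs(pf_segments$s0[1]) > 1e-6 ||
      abs(pf_segments$s1[nrow(pf_segments)] - len) > 1e-6 ||
      (nrow(pf_segments) > 1 &&
       any(abs(pf_segments$s1[-nrow(pf_segments)] - pf_segments$s0[-1]) > 1e-6)))
    stop("pf_segments must tile [0, length] without overlap")
  if (is.null(break_intervals))
    break_intervals <- data.frame(s0 = numeric(0), s1 = numeric(0))
  if (nrow(break_intervals) &&
      (any(break_intervals$s0 < 0) || any(break_intervals$s1 > len)))
    stop("break intervals must lie inside the path")
  if (is.null(end_taper)) end_taper <- list(start = 0, end = 0)
  if (mip_rate < 0) stop("mip_rate must be >= 0")
  structure(list(path = path, polarity = polarity, pf_segments = pf_segments,
                 break_intervals = break_intervals, end_taper = end_taper,
                 mip_rate = mip_rate, kind = kind, phase0 = phase0,
                 length = len),
            class = "filament_spec")
}

# Frames along a polyline by parallel transport: returns, for each requested
# arclength, the position and a rotation matrix whose 3rd column is the local
# tangent. Twist-free (rotation-minimizing) so the lattice phase is stable.
path_frames <- function(path, s_values) {
  cl <- polyline_cumlen(path)
  n <- nrow(path)
  tang <- function(i) {
    if (i == 1) d <- path[2, ] - path[1, ]
    else if (i == n) d <- path[n, ] - path[n - 1, ]
    else d <- path[i + 1, ] - path[i - 1, ]
    d / sqrt(sum(d^2))
  }
  # transport frame along vertices
  frames <- vector("list", n)
  frames[[1]] <- frame_from_tangent(tang(1))
  for (i in 2:n) {
    t_old <- frames[[i - 1]][, 3]
    t_new <- tang(i)
    v <- c(t_old[2] * t_new[3] - t_old[3] * t_new[2],
           t_old[3] * t_new[1] - t_old[1] * t_new[3],
           t_old[1] * t_new[2] - t_old[2] * t_new[1])
    s <- sqrt(sum(v^2))
    co <- sum(t_old * t_new)
    if (s < 1e-12) {
      R <- diag(3)
    } else {
      vx <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
      R <- diag(3) + vx + vx %*% vx * ((1 - co) / s^2)
    }
    frames[[i]] <- R %*% frames[[i - 1]]
  }
  ord <- order(s_values)
  pos <- polyline_point(path, s_values)
  idx <- findInterval(s_values, cl, rightmost.closed = TRUE)
  idx <- pmin(pmax(idx, 1), n - 1)
  out <- vector("list", length(s_values))
  for (k in seq_along(s_values)) {
    # blend between vertex frames by transporting the lower frame onto the
    # interpolated tangent
    i <- idx[k]
    f <- (s_values[k] - cl[i]) / max(cl[i + 1] - cl[i], .Machine$double.eps)
    tz <- (1 - f) * frames[[i]][, 3] + f * frames[[i + 1]][, 3]
    tz <- tz / sqrt(sum(tz^2))
    base <- frames[[i]]
    t_old <- base[, 3]
    v <- c(t_old[2] * tz[3] - t_old[3] * tz[2],
           t_old[3] * tz[1] - t_old[1] * tz[3],
           t_old[1] * tz[2] - t_old[2] * tz[1])
    s2 <- sqrt(sum(v^2))
    co <- sum(t_old * tz)
    if (s2 < 1e-12) R <- diag(3)
    else {
      vx <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
      R <- diag(3) + vx + vx %*% vx * ((1 - co) / s2^2)
    }
    out[[k]] <- list(pos = pos[k, ], rot = R %*% base)
  }
  out
}

#' Build oriented monomer positions for a microtubule lattice
#'
#' Places alpha and beta tubulin monomer centers on the lattice defined by
#' `spec` along the path of `filament`, honoring protofilament-number
#' segments, lattice breaks and per-pf end tapers. A dimer layer is emitted
#' only where the complete layer (all protofilaments, including the helical
#' rise and the beta offset) fits inside its pf segment.
#'
#' @param spec a [lattice_spec()]; its pf_number is overridden per segment by
#'   the filament's pf_segments
#' @param filament a [filament_spec()]
#' @return data.frame with monomer centers (x, y, z nm), pf index, layer,
#'   monomer ("alpha"/"beta"), arclength, and the dimer-axis unit vector
#'   (ax, ay, az) encoding the slew tilt
#' @export
build_lattice_points <- function(spec, filament) {
  if (filament$length < spec$dimer_rise)
    stop("path shorter than one dimer rise")
  h <- if (filament$polarity == "plus_along_path") 1 else -1
  tilt <- deg2rad(spec$slew_tilt)
  rows <- list()
  for (si in seq_len(nrow(filament$pf_segments))) {
    s0 <- filament$pf_segments$s0[si]
    s1 <- filament$pf_segments$s1[si]
    P <- filament$pf_segments$pf[si]
    wr <- spec$wall_radius * P / spec$pf_number
    skew <- 360 / P
    rise_pf <- 1.5 * spec$dimer_rise / P
    beta_ds <- spec$monomer_offset * cos(tilt)
    layer_extent <- (P - 1) * rise_pf + beta_ds
    n_layers <- floor((s1 - s0 - layer_extent) / spec$dimer_rise) + 1
    if (n_layers < 1) next
    j <- rep(0:(P - 1), times = n_layers)
    L <- rep(0:(n_layers - 1), each = P)
    s_alpha <- s0 + L * spec$dimer_rise + j * rise_pf
    s_beta <- s_alpha + beta_ds
    ang <- filament$phase0 + j * skew
    # symmetric radial/angular shear of the monomer pair about the wall
    # radius: preserves the mean wall radius (peak-to-peak diameter) while
    # encoding the polarity handedness
    dr <- 2 * spec$monomer_offset * sin(tilt)
    dphi <- rad2deg(h * 2 * spec$monomer_offset * sin(tilt) / wr)
    rows[[length(rows) + 1]] <- data.frame(
      pf = c(j, j), layer = c(L, L),
      monomer = rep(c("alpha", "beta"), each = length(j)),
      arclength = c(s_alpha, s_beta),
      angle = c(ang - dphi / 2, ang + dphi / 2),
      radius = c(rep(wr - dr / 2, length(j)), rep(wr + dr / 2, length(j))),
      seg_pf = P)
  }
  if (!length(rows)) stop("no complete dimer layer fits the path")
  pts <- do.call(rbind, rows)

  # breaks: drop monomers inside break intervals
  if (nrow(filament$break_intervals)) {
    for (bi in seq_len(nrow(filament$break_intervals))) {
      b <- filament$break_intervals[bi, ]
      pts <- pts[!(pts$arclength > b$s0 & pts$arclength < b$s1), , drop = FALSE]
    }
  }
  # end tapers: per-pf terminal arclengths
  ts <- rep_len(filament$end_taper$start, max(pts$pf) + 1)
  te <- rep_len(filament$end_taper$end, max(pts$pf) + 1)
  keep <- pts$arclength >= ts[pts$pf + 1] &
          pts$arclength <= (filament$length - te[pts$pf + 1])
  pts <- pts[keep, , drop = FALSE]
  if (!nrow(pts)) stop("taper/breaks removed every monomer")

  fr <- path_frames(filament$path, pts$arclength)
  a <- deg2rad(pts$angle)
  xyz <- t(vapply(seq_len(nrow(pts)), function(i) {
    f <- fr[[i]]
    radial <- f$rot[, 1] * cos(a[i]) + f$rot[, 2] * sin(a[i])
    f$pos + radial * pts$radius[i]
  }, numeric(3)))
  # dimer axis: tangent tilted tangentially by slew_tilt (handedness h)
  axis <- t(vapply(seq_len(nrow(pts)), function(i) {
    f <- fr[[i]]
    tangential <- -f$rot[, 1] * sin(a[i]) + f$rot[, 2] * cos(a[i])
    v <- f$rot[, 3] * cos(tilt) + tangential * (h * sin(tilt))
    v / sqrt(sum(v^2))
  }, numeric(3)))
  data.frame(x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             pf = pts$pf, layer = pts$layer, monomer = pts$monomer,
             arclength = pts$arclength, seg_pf = pts$seg_pf,
             ax = axis[, 1], ay = axis[, 2], az = axis[, 3])
}

# run code with a local RNG state derived from seed
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  force(code)
}

#' Place luminal particles (MIPs) along a filament
#'
#' Draws the particle count from a Poisson distribution at `mip_rate` per
#' micrometer of filament, then places that many positions uniformly under a
#' hard-core (minimum spacing) constraint, so the realized density matches
#' the nominal rate while respecting the particle diameter. If the drawn
#' count cannot be packed at the minimum spacing it is truncated with a
#' warning.
#'
#' @param filament a [filament_spec()]
#' @param seed integer seed (reproducible placement)
#' @param min_spacing minimum center-to-center distance, nm (the MIP diameter)
#' @return sorted numeric vector of arclengths, nm
#' @export
place_mips <- function(filament, seed, min_spacing = 9) {
  rate <- filament$mip_rate
  if (rate < 0) stop("mip_rate must be >= 0")
  if (rate == 0) return(numeric(0))
  L <- filament$length
  with_seed(seed, {
    n <- rpois(1, rate * L / 1000)
    n_max <- floor(L / min_spacing) + 1
    if (n > n_max) {
      warning(sprintf("mip_rate too high: %d of %d draws cannot be packed at %.1f nm spacing",
                      n - n_max, n, min_spacing))
      n <- n_max
    }
    if (n == 0) {
      numeric(0)
    } else if (n == 1) {
      runif(1, 0, L)
    } else {
      slack <- L - (n - 1) * min_spacing
      u <- sort(runif(n, 0, slack))
      sort(u + (seq_len(n) - 1) * min_spacing)
    }
  })
}
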