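# Synthetic tomogram scenes with ground truth
#
# A scene manifest lists filament specifications together with the lattice
# parameters, realized luminal-particle (MIP) positions, the noise level and
# missing-wedge geometry, and the seed. Rendering is deterministic given the
# manifest, so every downstream measurement can be checked against the
# manifest as a recovery oracle.

#' Ground-truth scene manifest
#'
#' @param filaments list of [filament_spec()]
#' @param lattice a [lattice_spec()] used for MT-kind filaments
#' @param snr signal-to-noise ratio (signal variance over the signal support
#'   mask / noise variance); Inf for noiseless
#' @param tilt_range half-range of the tilt series, degrees (60 = +/-60
#'   wedge); 90 disables the wedge
#' @param seed integer seed controlling MIP placement, MIP ring orientations
#'   and the noise realization
#' @return object of class `scene_manifest` (with realized `mip_positions`)
#' @export
scene_manifest <- function(filaments, lattice = lattice_spec(), snr = Inf,
                           tilt_range = 90, seed = 1L) {
  if (inherits(filaments, "filament_spec")) filaments <- list(filaments)
  if (!is.numeric(snr) || snr <= 0) stop("snr must be > 0 (Inf for noiseless)")
  if (tilt_range <= 0 || tilt_range > 90) stop("tilt_range must be in (0, 90]")
  mip_positions <- lapply(seq_along(filaments), function(i)
    place_mips(filaments[[i]], seed = seed * 1000L + i))
  structure(list(filaments = filaments, lattice = lattice,
                 mip_positions = mip_positions, snr = snr,
                 tilt_range = tilt_range, seed = as.integer(seed)),
            class = "scene_manifest")
}

#' @export
print.scene_manifest <- function(x, ...) {
  cat(sprintf("<scene_manifest> %d filament(s), snr %s, tilt +/-%g deg, seed %d\n",
              length(x$filaments), format(x$snr), x$tilt_range, x$seed))
  invisible(x)
}

# ring motif for one MIP: n_blob blobs on a ring (central pore), randomly
# oriented plane
mip_ring_points <- function(center, axis_frame, n_blob = 6, ring_radius = 3.2) {
  ang <- seq(0, 360 - 360 / n_blob, by = 360 / n_blob) + runif(1, 0, 360)
  a <- deg2rad(ang)
  # random ring orientation: random rotation applied to the local frame
  u <- rnorm(3); u <- u / sqrt(sum(u^2))
  th <- runif(1, 0, 2 * pi)
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  Rr <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
  fr <- Rr %*% axis_frame
  t(center + fr[, 1] %o% (ring_radius * cos(a)) + fr[, 2] %o% (ring_radius * sin(a)))
}

#' Render a scene manifest into a density volume
#'
#' Sums isotropic Gaussian blobs for tubulin monomers, ring-of-blobs MIP
#' motifs (6 blobs on a 3.2-nm ring: ~9 nm outer diameter with a central
#' pore), 6-nm-repeat zig-zag chains for actin, hollow tubes for thick
#' filaments and thin blob chains for thin filaments. Density is
#' protein-positive and >= 0; no noise or wedge is applied here (see
#' [corrupt()]).
#'
#' @param manifest a [scene_manifest()]
#' @param dim integer length-3 grid dimensions (nx, ny, nz)
#' @param voxel_size nm per voxel (must not exceed the monomer blob sigma)
#' @param origin physical position of voxel (1,1,1), nm
#' @return a [volume()]
#' @export
render_scene <- function(manifest, dim, voxel_size = 1, origin = c(0, 0, 0)) {
  if (voxel_size > manifest$lattice$monomer_sigma)
    stop("voxel_size exceeds monomer_sigma: lattice would be undersampled")
  dim <- as.integer(dim)
  upper <- origin + (dim - 1) * voxel_size
  centers <- list(); amps <- list(); sigmas <- list()
  add <- function(xyz, amp, sigma) {
    centers[[length(centers) + 1]] <<- xyz
    amps[[length(amps) + 1]] <<- rep(amp, nrow(xyz))
    sigmas[[length(sigmas) + 1]] <<- rep(sigma, nrow(xyz))
  }
  for (i in seq_along(manifest$filaments)) {
    fl <- manifest$filaments[[i]]
    if (any(t(fl$path) < origin) || any(t(fl$path) > upper))
      stop("filament ", i, " path outside the rendering grid")
    if (fl$kind == "MT") {
      pts <- build_lattice_points(manifest$lattice, fl)
      # alpha/beta contrast difference: lets the axial register (which
      # monomer sits where) be identifiable, as it is for real tubulin
      for (mm in c("alpha", "beta")) {
        sel <- pts$monomer == mm
        add(as.matrix(pts[sel, c("x", "y", "z")]),
            if (mm == "alpha") 1.12 else 0.88,
            manifest$lattice$monomer_sigma)
      }
      mp <- manifest$mip_positions[[i]]
      if (length(mp)) {
        with_seed(manifest$seed * 1000L + i, {
          fr <- path_frames(fl$path, mp)
          for (k in seq_along(mp))
            add(mip_ring_points(fr[[k]]$pos, fr[[k]]$rot), 1, 1.3)
        })
      }
    } else if (fl$kind == "actin") {
      s <- seq(0, fl$length, by = 3)            # monomer every 3 nm
      fr <- path_frames(fl$path, s)
      xyz <- t(vapply(seq_along(s), function(k) {
        side <- if (k %% 2 == 0) 1 else -1      # 6-nm lateral repeat
        tz <- fr[[k]]$rot[, 3]
        # zig-zag in the tomogram plane (perpendicular to the beam), where
        # it is visible in projections and slices
        u <- c(-tz[2], tz[1], 0)
        nu <- sqrt(sum(u^2))
        u <- if (nu > 0.05) u / nu else fr[[k]]$rot[, 1]
        fr[[k]]$pos + side * 1.8 * u
      }, numeric(3)))
      add(xyz, 1, 1.5)
    } else if (fl$kind == "thick") {
      s <- seq(0, fl$length, by = 2)
      fr <- path_frames(fl$path, s)
      xyz <- do.call(rbind, lapply(seq_along(s), function(k) {
        a <- deg2rad(seq(0, 315, by = 45))
        t(fr[[k]]$pos + fr[[k]]$rot[, 1] %o% (4.25 * cos(a)) +
            fr[[k]]$rot[, 2] %o% (4.25 * sin(a)))
      }))
      add(xyz, 0.5, 1.5)
    } else {                                     # thin
      s <- seq(0, fl$length, by = 2)
      add(polyline_point(fl$path, s), 0.7, 1.4)
    }
  }
  if (!length(centers)) {
    return(volume(array(0, dim), voxel_size = voxel_size, origin = origin))
  }
  dat <- cpp_render_blobs(dim, voxel_size, origin,
                          do.call(rbind, centers), unlist(amps), unlist(sigmas))
  volume(dat, voxel_size = voxel_size, origin = origin)
}

#' Corrupt a volume with noise and a missing wedge
#'
#' Adds white Gaussian noise scaled so that the signal variance over the
#' signal support mask (voxels with noiseless density > 10% of the maximum)
#' divided by the noise variance equals `snr`, then zeroes Fourier amplitudes
#' inside the missing wedge (tilt axis y, beam z: the region
#' `|atan2(|kz|, |kx|)| > tilt_range`). Reproducible given `seed`.
#'
#' @param vol a [volume()] (noiseless render)
#' @param snr target signal-to-noise ratio; Inf adds no noise
#' @param tilt_range tilt half-range in degrees; 90 applies no wedge
#' @param seed integer seed for the noise realization
#' @return corrupted [volume()]
#' @export
corrupt <- function(vol, snr, tilt_range = 60, seed = 1L) {
  stopifnot(is_volume(vol))
  if (!is.numeric(snr) || snr <= 0) stop("snr must be > 0")
  if (tilt_range <= 0 || tilt_range > 90) stop("tilt_range must be in (0, 90]")
  dat <- vol$data
  if (is.finite(snr)) {
    mask <- dat > 0.1 * max(dat)
    if (!any(mask)) stop("volume has no signal support; cannot scale noise")
    sig_var <- stats::var(dat[mask])
    noise_sd <- sqrt(sig_var / snr)
    dat <- dat + with_seed(seed, array(rnorm(length(dat), sd = noise_sd), dim(dat)))
  }
  if (tilt_range < 90) {
    w <- wedge_mask(dim(dat), tilt_range)
    F <- fft(dat)
    F[!w] <- 0
    dat <- Re(fft(F, inverse = TRUE)) / length(dat)
  }
  volume(dat, voxel_size = vol$voxel_size, origin = vol$origin)
}

#' Serialize a scene manifest to JSON
#' @param manifest a [scene_manifest()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_manifest <- function(manifest, path) {
  fl <- lapply(manifest$filaments, function(f) list(
    path = f$path, polarity = f$polarity,
    pf_segments = as.list(f$pf_segments),
    break_intervals = as.list(f$break_intervals),
    end_taper = f$end_taper, mip_rate = f$mip_rate, kind = f$kind,
    phase0 = f$phase0))
  obj <- list(filaments = fl,
              lattice = unclass(manifest$lattice),
              mip_positions = manifest$mip_positions,
              snr = if (is.finite(manifest$snr)) manifest$snr else "Inf",
              tilt_range = manifest$tilt_range, seed = manifest$seed)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a scene manifest from JSON
#' @param path file path
#' @return a [scene_manifest()]
#' @export
read_manifest <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  lat <- do.call(lattice_spec, lapply(obj$lattice, function(x) x))
  fl <- lapply(obj$filaments, function(f) {
    seg <- f$pf_segments
    pf_segments <- data.frame(
      s0 = vapply(seg$s0, as.numeric, numeric(1)),
      s1 = vapply(seg$s1, as.numeric, numeric(1)),
      pf = vapply(seg$pf, as.integer, integer(1)))
    br <- f$break_intervals
    break_intervals <- if (is.null(br$s0) || !length(br$s0))
      data.frame(s0 = numeric(0), s1 = numeric(0))
    else data.frame(s0 = vapply(br$s0, as.numeric, numeric(1)),
                    s1 = vapply(br$s1, as.numeric, numeric(1)))
    filament_spec(path = matrix(unlist(f$path), ncol = 3, byrow = TRUE),
                  polarity = f$polarity, pf_segments = pf_segments,
                  break_intervals = break_intervals,
                  end_taper = list(start = unlist(f$end_taper$start),
                                   end = unlist(f$end_taper$end)),
                  mip_rate = f$mip_rate, kind = f$kind, phase0 = f$phase0)
  })
  mips <- lapply(obj$mip_positions, function(p)
    if (is.null(p) || !length(p)) numeric(0) else unlist(p))
  if (!length(mips)) mips <- rep(list(numeric(0)), length(fl))
  structure(list(filaments = fl, lattice = lat, mip_positions = mips,
                 snr = if (identical(obj$snr, "Inf")) Inf else obj$snr,
                 tilt_range = obj$tilt_range, seed = as.integer(obj$seed)),
            class = "scene_manifest")
}

#' Convenience constructor: one straight microtubule in its own volume
#'
#' Builds a single-MT scene along a given direction, renders it and corrupts
#' it, returning everything downstream stages need. The default geometry
#' (wall radius 10.6 nm, 1-nm voxels) gives the ~21-nm peak-to-peak wall
#' diameter of mammalian axonal MTs.
#'
#' @param length_nm MT length
#' @param direction axis direction (default +y, the tilt axis, the favorable
#'   orientation in single-axis tomography); normalized internally
#' @param pf_segments protofilament segments (default uniform 13)
#' @param polarity filament polarity along the path
#' @param snr,tilt_range,seed corruption parameters (see [corrupt()])
#' @param mip_rate luminal particle rate per micrometer
#' @param break_intervals lattice break intervals (data.frame s0, s1)
#' @param end_taper per-pf terminal arclengths (list(start=, end=))
#' @param phase0 lattice phase, degrees; NA draws it uniformly from the seed
#' @param lattice a [lattice_spec()]
#' @param voxel_size nm per voxel
#' @param pad margin around the MT bounding box, nm
#' @return list with `manifest`, `volume` (corrupted), `clean` (noiseless),
#'   `model` ([filament_model()] of the picking path)
#' @export
make_mt_scene <- function(length_nm = 300, direction = c(0, 1, 0),
                          pf_segments = NULL,
                          polarity = "plus_along_path",
                          snr = Inf, tilt_range = 90, seed = 1L,
                          mip_rate = 0, break_intervals = NULL,
                          end_taper = NULL, phase0 = NA,
                          lattice = lattice_spec(), voxel_size = 1,
                          pad = 26) {
  u <- direction / sqrt(sum(direction^2))
  if (is.na(phase0)) phase0 <- with_seed(seed + 7L, runif(1, 0, 360))
  n_pts <- max(2, ceiling(length_nm / 40))
  s <- seq(0, length_nm, length.out = n_pts)
  path0 <- t(vapply(s, function(si) si * u, numeric(3)))
  lo <- apply(path0, 2, min) - pad
  path <- sweep(path0, 2, lo)
  extent <- apply(path, 2, max) + pad
  d <- vapply(extent / voxel_size + 1, good_fft_size, numeric(1))
  fl <- filament_spec(path, polarity = polarity, pf_segments = pf_segments,
                      break_intervals = break_intervals, end_taper = end_taper,
                      mip_rate = mip_rate, phase0 = phase0)
  man <- scene_manifest(list(fl), lattice = lattice, snr = snr,
                        tilt_range = tilt_range, seed = seed)
  clean <- render_scene(man, dim = d, voxel_size = voxel_size)
  vol <- corrupt(clean, snr = snr, tilt_range = tilt_range, seed = seed)
  list(manifest = man, volume = vol, clean = clean,
       model = filament_model(path, filament_id = 0L, kind = "MT"))
}

# smallest integer >= n with prime factors in {2,3,5,7} (fast FFT sizes)
good_fft_size <- function(n) {
  n <- ceiling(n)
  repeat {
    m <- n
    for (p in c(2, 3, 5, 7)) while (m %% p == 0) m <- m / p
    if (m == 1) return(n)
    n <- n + 1
  }
}
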