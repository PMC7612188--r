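# Particle extraction: filament models -> oriented positions -> subtomogram stack

#' Evenly spaced oriented frames along a filament
#'
#' Positions at arclengths 0, spacing, 2*spacing, ... <= total length
#' (inclusive endpoints: both filament ends are sampled). Euler angles orient
#' the box z axis along the local tangent (parallel-transported frames,
#' central differences); the in-plane angle is 0.
#'
#' @param model a [filament_model()]
#' @param spacing nm between particles (8 nm = tubulin dimer, 4 nm = monomer)
#' @param tomogram_id integer id recorded in the table
#' @param id_offset first particle_id to assign
#' @return a [particle_table()]
#' @export
frames_along_filament <- function(model, spacing = 8, tomogram_id = 0L,
                                  id_offset = 0L) {
  stopifnot(spacing > 0)
  L <- visible_length(model)
  if (spacing > L) {
    warning("spacing exceeds filament length; single frame at start")
    s <- 0
  } else {
    s <- seq(0, L, by = spacing)
  }
  fr <- path_frames(model$points, s)
  # tomogram-referenced roll: box x horizontal (beam cross tangent), box y
  # toward the beam, so the missing-wedge sector sits at a fixed in-plane
  # angle for every particle (near-vertical tangents fall back to the
  # transported frame)
  beam_frame <- function(R) {
    tz <- R[, 3]
    hx <- c(-tz[2], tz[1], 0)
    nh <- sqrt(sum(hx^2))
    if (nh < 0.05) return(R)
    hx <- hx / nh
    hy <- c(tz[2] * hx[3] - tz[3] * hx[2],
            tz[3] * hx[1] - tz[1] * hx[3],
            tz[1] * hx[2] - tz[2] * hx[1])
    cbind(hx, hy, tz, deparse.level = 0)
  }
  eul <- t(vapply(fr, function(f) rot2eul(beam_frame(f$rot)), numeric(3)))
  pos <- t(vapply(fr, function(f) f$pos, numeric(3)))
  particle_table(
    particle_id = id_offset + seq_along(s) - 1L,
    filament_id = model$filament_id,
    tomogram_id = as.integer(tomogram_id),
    x = pos[, 1], y = pos[, 2], z = pos[, 3],
    phi = eul[, 1], theta = eul[, 2], psi = eul[, 3],
    arclength = s)
}

#' Subtomogram stack
#'
#' Cropped cubic boxes stored as a voxel-by-particle matrix (for fast
#' correlation scoring) together with the particle table at crop time. The
#' crop-time orientations are kept so that later angle/shift updates can be
#' expressed as residual transforms of the fixed boxes.
#'
#' @param boxes numeric matrix, `box_size^3` x N
#' @param box_size box edge in voxels (odd)
#' @param voxel_size nm per voxel
#' @param table the [particle_table()] the boxes were cropped with
#' @return object of class `subtomogram_stack`
#' @export
subtomogram_stack <- function(boxes, box_size, voxel_size, table) {
  stopifnot(ncol(boxes) == nrow(table))
  if (box_size %% 2 == 0) stop("box_size must be odd (unambiguous center)")
  structure(list(boxes = boxes, box_size = as.integer(box_size),
                 voxel_size = voxel_size, table = table),
            class = "subtomogram_stack")
}

#' @export
print.subtomogram_stack <- function(x, ...) {
  cat(sprintf("<subtomogram_stack> %d boxes of %d^3 voxels, %.2f nm/voxel\n",
              ncol(x$boxes), x$box_size, x$voxel_size))
  invisible(x)
}

# i-th box as a 3D array
stack_box <- function(stack, i) {
  array(stack$boxes[, i], rep(stack$box_size, 3))
}

#' Crop oriented subtomograms from a volume
#'
#' Boxes are sampled by trilinear interpolation at rotated sample points,
#' centered on the table positions with box z along the particle orientation
#' (Euler angles in the table). Particles whose sampling region leaves the
#' volume are flagged (`keep_flag = FALSE`), never silently zero-padded.
#'
#' @param vol a [volume()]
#' @param table a [particle_table()]
#' @param box_size box edge in voxels (odd)
#' @return a [subtomogram_stack()]
#' @export
crop <- function(vol, table, box_size) {
  stopifnot(is_volume(vol))
  if (box_size %% 2 == 0) stop("box_size must be odd")
  n <- nrow(table)
  boxes <- matrix(0, box_size^3, max(n, 0))
  keep <- table$keep_flag
  for (i in seq_len(n)) {
    R <- eul2rot(table$phi[i], table$theta[i], table$psi[i])
    res <- cpp_crop(vol$data, dim(vol$data), vol$voxel_size, vol$origin,
                    c(table$x[i], table$y[i], table$z[i]), as.numeric(R),
                    as.integer(box_size))
    boxes[, i] <- res$data
    if (res$n_outside > 0) keep[i] <- FALSE
  }
  tb <- table
  tb$keep_flag <- keep
  subtomogram_stack(boxes, box_size, vol$voxel_size, tb)
}

#' Randomize in-plane (spin) angles
#'
#' Adds Uniform(-180, 180] spin to psi (the rotation about the filament
#' axis), leaving phi and theta untouched. Averaging particles after this
#' randomization yields the rotationally smeared tube used as an unbiased
#' initial alignment reference.
#'
#' @param table a [particle_table()]
#' @param seed integer seed
#' @return updated table
#' @export
randomize_inplane <- function(table, seed = 1L) {
  tb <- table
  tb$psi <- wrap180(tb$psi + with_seed(seed, runif(nrow(tb), -180, 180)))
  tb
}
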