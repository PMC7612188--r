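test_that("aligning a stack against its own average gives cc ~ 1, zero shift", {
  fx <- fx_clean_mt()
  lim <- alignment_limits(max_inplane = 0, max_axial_shift = 0,
                          mask = list(type = "none"))
  ta <- align(fx$stack, fx$avg, lim)
  expect_gt(max(ta$cc_score), 0.99)
  expect_equal(ta$x, fx$table$x)
  expect_equal(ta$psi, fx$table$psi)
})

test_that("a planted axial offset is recovered within half a grid step", {
  sc <- make_mt_scene(length_nm = 120, seed = 2)
  tb <- frames_along_filament(sc$model, 8)
  ref <- average(crop(sc$volume, tb, 33))
  tb_off <- tb
  tb_off$y <- tb_off$y + 1.5            # path along +y: axial offset
  st <- crop(sc$volume, tb_off, 33)
  lim <- alignment_limits(max_inplane = 0, max_axial_shift = 2.2,
                          shift_step = 0.5,
                          mask = list(type = "gaussian_tube",
                                      radius = 10.6, sigma = 4))
  ta <- align(st, ref, lim)
  expect_lt(abs(mean(ta$y - tb_off$y) - (-1.5)), 0.5)
})

test_that("recovered shifts never exceed the stated limit", {
  sc <- make_mt_scene(length_nm = 120, seed = 2)
  tb <- frames_along_filament(sc$model, 8)
  ref <- average(crop(sc$volume, tb, 33))
  tb5 <- tb; tb5$y <- tb5$y + 5
  st <- crop(sc$volume, tb5, 33)
  lim <- alignment_limits(max_inplane = 0, max_axial_shift = 2.2,
                          shift_step = 0.5,
                          mask = list(type = "gaussian_tube",
                                      radius = 10.6, sigma = 4))
  ta <- align(st, ref, lim)
  expect_lte(max(abs(ta$y - tb5$y)), 2.2 + 1e-9)
})

test_that("all-zero boxes are flagged with score -1", {
  v <- volume(array(0, c(20, 20, 20)))
  tb <- particle_table(particle_id = 0L, filament_id = 0L, tomogram_id = 0L,
                       x = 9, y = 9, z = 9, phi = 0, theta = 0, psi = 0)
  st <- crop(v, tb, 9)
  ta <- align(st, array(rnorm(9^3), rep(9, 3)),
              alignment_limits(max_inplane = 0, max_axial_shift = 0,
                               mask = list(type = "none")))
  expect_equal(ta$cc_score, -1)
  expect_false(ta$keep_flag)
})

test_that("cc cleaning keeps the best fraction per filament, ties kept", {
  tb <- particle_table(particle_id = 0:9, filament_id = 0L, tomogram_id = 0L,
                       x = 0, y = 0, z = 0, phi = 0, theta = 0, psi = 0,
                       cc_score = seq(0.1, 1.0, by = 0.1))
  out <- cc_clean(tb, 0.8)
  expect_equal(nrow(out), 8)
  expect_equal(min(out$cc_score), 0.3)
  expect_equal(nrow(cc_clean(tb, 1)), 10)
  tb5 <- tb[1:5, ]
  expect_equal(nrow(cc_clean(tb5, 0.8)), 4)     # ceiling(4.0)
})

test_that("distance cleaning is conjunctive and greedy by score", {
  mk <- function(dy, dpsi, cc2 = 0.6) particle_table(
    particle_id = 0:1, filament_id = 0L, tomogram_id = 0L,
    x = 0, y = c(0, dy), z = 0, phi = 0, theta = 0, psi = c(0, dpsi),
    cc_score = c(0.8, cc2))
  out1 <- distance_clean(mk(2, 10))
  expect_equal(out1$cc_score, 0.8)             # both violated: lower removed
  expect_equal(nrow(distance_clean(mk(2, 30))), 2)   # angle ok: kept
  expect_equal(nrow(distance_clean(mk(5, 10))), 2)   # distance ok: kept
})

test_that("helical expansion appends 12 cumulative copies", {
  tb <- particle_table(particle_id = 0L, filament_id = 0L, tomogram_id = 0L,
                       x = 0, y = 0, z = 0, phi = 0, theta = 0, psi = 0)
  ex <- symmetry_expand(tb)
  expect_equal(nrow(ex), 13)
  expect_equal(ex$psi[13], axonmt:::wrap180(12 * 27.69))
  expect_equal(ex$z, 0.92 * (0:12), tolerance = 1e-9)
})

test_that("expanding a 13-fold symmetric particle leaves the average unchanged", {
  # symmetric phantom: achiral lattice with exactly 360/13 skew, no seam
  lat <- lattice_spec(slew_tilt = 0)
  ref <- render_mt_reference(13, 33, 1, lat)
  st <- subtomogram_stack(matrix(as.numeric(ref$data), ncol = 1), 33L, 1,
                          particle_table(particle_id = 0L, filament_id = 0L,
                                         tomogram_id = 0L, x = 0, y = 0,
                                         z = 0, phi = 0, theta = 0, psi = 0))
  ex <- symmetry_expand(st$table, rot = 360 / 13, rise = 0)
  a0 <- average(st)
  aex <- average(st, ex)
  core <- axonmt:::mask_volume(list(type = "gaussian_tube", radius = 10.6,
                                    sigma = 3), 33, 1) > 0.5
  core[, , c(1:6, 28:33)] <- FALSE    # ignore resampling edge voxels
  # compare band-limited volumes: trilinear resampling of the symmetry
  # copies adds high-frequency interpolation error that is not structure
  s0 <- axonmt:::lowpass_box(a0$data, 1)
  sx <- axonmt:::lowpass_box(aex$data, 1)
  relerr <- sqrt(mean((sx[core] - s0[core])^2)) / max(s0)
  expect_lt(relerr, 0.03)
})

test_that("averaging identical copies reproduces the box; empty input errors", {
  fx <- fx_clean_mt()
  one <- fx$stack$table[3, ]
  st3 <- subtomogram_stack(fx$stack$boxes[, c(3, 3, 3)], 33L, 1,
                           particle_table(particle_id = 0:2,
                                          filament_id = 0L, tomogram_id = 0L,
                                          x = one$x, y = one$y, z = one$z,
                                          phi = one$phi, theta = one$theta,
                                          psi = one$psi))
  expect_equal(average(st3)$data,
               array(fx$stack$boxes[, 3], rep(33, 3)), tolerance = 1e-12)
  bad <- fx$stack$table
  bad$keep_flag <- FALSE
  expect_error(average(fx$stack, bad), "no kept particles")
})

test_that("wedge compensation improves two orthogonally-tilted copies", {
  set.seed(9)
  blobs <- cbind(runif(8, -10, 10), runif(8, -10, 10), runif(8, -10, 10))
  P <- array(axonmt:::cpp_render_blobs(rep(33L, 3), 1, rep(-16, 3), blobs,
                                       rep(1, 8), rep(1.8, 8)), rep(33, 3))
  Q <- matrix(c(0, 0, -1, 0, 1, 0, 1, 0, 0), 3, 3)     # +90 about tilt axis y
  # tomogram A holds the phantom in canonical pose; tomogram B holds it
  # rotated by Q; each is wedge-corrupted in the world frame, then the
  # particle is cropped along its own pose axes
  tomoA <- volume(P, 1)
  VB <- array(axonmt:::cpp_transform_box(P, as.numeric(t(Q)), c(0, 0, 0), 1),
              rep(33, 3))
  tomoB <- volume(VB, 1)
  wA <- corrupt(tomoA, Inf, 60, 1)$data
  wBv <- corrupt(tomoB, Inf, 60, 1)$data
  boxB <- array(axonmt:::cpp_transform_box(wBv, as.numeric(Q), c(0, 0, 0), 1),
                rep(33, 3))
  eB <- rot2eul(Q)
  tb <- particle_table(particle_id = 0:1, filament_id = 0:1, tomogram_id = 0:1,
                       x = 0, y = 0, z = 0,
                       phi = c(0, eB[1]), theta = c(0, eB[2]),
                       psi = c(0, eB[3]))
  st <- subtomogram_stack(cbind(as.numeric(wA), as.numeric(boxB)), 33L, 1, tb)
  naive <- average(st)
  comp <- average(st, wedge_compensation = TRUE, tilt_range = 60)
  core <- as.logical(axonmt:::mask_volume(list(type = "gaussian_sphere",
                                               radius = 12, sigma = 1),
                                          33, 1) > 0.5)
  cc <- function(a) cor(as.numeric(a$data[core]), as.numeric(P[core]))
  expect_gt(cc(comp), cc(naive))
})

test_that("projections sum central slices", {
  v <- volume(array(seq_len(5^3), rep(5, 3)))
  expect_equal(project(v, 1, "z"), v$data[, , 3])
  expect_equal(project(v, 5, "z"), apply(v$data, 1:2, sum))
})

test_that("FSC is exactly 1 for identical volumes and noise-like for noise", {
  ref <- render_mt_reference(13, 33, 1)
  f <- fsc(ref, ref)
  expect_true(all(abs(f$fsc - 1) < 1e-9))
  expect_false(attr(resolution_at(f, 0.143, 1), "crossed"))
  set.seed(1)
  f2 <- fsc(volume(array(rnorm(33^3), rep(33, 3))),
            volume(array(rnorm(33^3), rep(33, 3))))
  expect_lt(max(abs(f2$fsc[f2$shell > 3])), 0.1)
})

test_that("a band-limited phantom pair crosses 0.143 at its band limit", {
  lp <- function(v, res_nm) {
    F <- fft(v$data); d <- dim(v$data)
    fx <- axonmt:::freq_axis(d[1], 1)
    r <- sqrt(outer(outer(fx^2, fx^2, "+"), fx^2, "+"))
    F[r > 1 / res_nm] <- 0
    volume(Re(fft(F, inverse = TRUE)) / prod(d))
  }
  set.seed(2)
  base <- volume(array(rnorm(33^3), rep(33, 3)))
  a <- lp(base, 2)
  b <- lp(base, 2)
  b$data <- b$data + array(rnorm(33^3, sd = 1e-3), rep(33, 3))
  res <- resolution_at(fsc(a, b), 0.143, 1)
  shell_nm <- 33 / (33 / 2)       # one-shell width at the band limit, nm
  expect_lt(abs(as.numeric(res) - 20), 10 * shell_nm)
})
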