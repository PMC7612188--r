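test_that("picking frames are evenly spaced with inclusive endpoints", {
  m80 <- filament_model(rbind(c(0, 0, 0), c(0, 80, 0)))
  expect_equal(nrow(frames_along_filament(m80, 8)), 11)
  m75 <- filament_model(rbind(c(0, 0, 0), c(0, 75, 0)))
  expect_equal(nrow(frames_along_filament(m75, 8)), 10)
})

test_that("a straight +z model gives identity frames", {
  m <- filament_model(rbind(c(0, 0, 0), c(0, 0, 50)))
  tb <- frames_along_filament(m, 10)
  expect_equal(tb$phi, rep(0, 6))
  expect_equal(tb$theta, rep(0, 6))
  expect_equal(tb$psi, rep(0, 6))
})

test_that("frames orient the box z axis along the local tangent", {
  m <- filament_model(rbind(c(0, 0, 0), c(30, 40, 0)))
  tb <- frames_along_filament(m, 10)
  R <- eul2rot(tb$phi[2], tb$theta[2], tb$psi[2])
  expect_equal(as.numeric(R[, 3]), c(0.6, 0.8, 0), tolerance = 1e-9)
})

test_that("over-long spacing degrades to a single warned frame", {
  m <- filament_model(rbind(c(0, 0, 0), c(0, 20, 0)))
  expect_warning(tb <- frames_along_filament(m, 50), "single frame")
  expect_equal(nrow(tb), 1)
})

test_that("identity crops equal the direct sub-array", {
  set.seed(7)
  v <- volume(array(rnorm(40^3), rep(40, 3)), voxel_size = 1)
  tb <- particle_table(particle_id = 0L, filament_id = 0L, tomogram_id = 0L,
                       x = 19, y = 19, z = 19, phi = 0, theta = 0, psi = 0)
  st <- crop(v, tb, 9)
  direct <- v$data[16:24, 16:24, 16:24]
  expect_equal(array(st$boxes[, 1], c(9, 9, 9)), direct, tolerance = 1e-12)
})

test_that("out-of-volume positions are flagged, never zero-padded silently", {
  v <- volume(array(1, c(20, 20, 20)))
  tb <- particle_table(particle_id = 0:1, filament_id = 0L, tomogram_id = 0L,
                       x = c(9, 18), y = 9, z = 9,
                       phi = 0, theta = 0, psi = 0)
  st <- crop(v, tb, 9)
  expect_true(st$table$keep_flag[1])
  expect_false(st$table$keep_flag[2])
})

test_that("a 90-degree table rotation rotates the cropped content", {
  v <- volume(array(0, c(31, 31, 31)))
  v$data[21, 16, 16] <- 1            # blob at +x from center
  tb0 <- particle_table(particle_id = 0L, filament_id = 0L, tomogram_id = 0L,
                        x = 15, y = 15, z = 15, phi = 0, theta = 0, psi = 0)
  tb90 <- tb0; tb90$psi <- 90
  b0 <- array(crop(v, tb0, 15)$boxes[, 1], c(15, 15, 15))
  b90 <- array(crop(v, tb90, 15)$boxes[, 1], c(15, 15, 15))
  # psi=90: box x axis points along world y, so the +x blob appears at -y...
  expect_equal(which(b0 == max(b0), arr.ind = TRUE)[1, ], c(13, 8, 8),
               ignore_attr = TRUE)
  i90 <- which(b90 == max(b90), arr.ind = TRUE)[1, ]
  expect_equal(sort(abs(i90 - 8)), c(0, 0, 5), ignore_attr = TRUE)
  expect_equal(max(b90), max(b0), tolerance = 1e-9)
})

test_that("in-plane randomization only touches the spin angle", {
  fx <- fx_clean_mt()
  tb <- fx$table
  r1 <- randomize_inplane(tb, seed = 5)
  r2 <- randomize_inplane(tb, seed = 5)
  expect_identical(r1$psi, r2$psi)
  expect_identical(r1$phi, tb$phi)
  expect_identical(r1$theta, tb$theta)
  big <- randomize_inplane(do.call(rbind, rep(list(as.data.frame(tb)), 700)),
                           seed = 8)
  expect_lt(abs(mean(axonmt:::wrap180(big$psi - rep(tb$psi, 700)))),
            3 * 104 / sqrt(nrow(big)))
})

test_that("randomized-spin averages approach a rotationally smeared tube", {
  fx <- fx_clean_mt()
  st <- fx$stack
  aligned_img <- project(average(st), 9, "z")
  tbr <- randomize_inplane(fx$table, seed = 3)
  smeared_img <- project(average(st, tbr), 9, "z")
  pow13 <- function(img) {
    cnt <- count_pfs(img, r_wall = 10.6)
    attr(cnt, "power")[["13"]]
  }
  expect_lt(pow13(smeared_img), pow13(aligned_img) / 10)
})
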