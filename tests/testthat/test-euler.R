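test_that("Euler angles round-trip through rotation matrices", {
  set.seed(1)
  for (i in 1:50) {
    e <- c(runif(1, -179, 180), runif(1, 1, 179), runif(1, -179, 180))
    R <- eul2rot(e[1], e[2], e[3])
    expect_equal(det(R), 1, tolerance = 1e-10)
    expect_equal(crossprod(R), diag(3), tolerance = 1e-10,
                 ignore_attr = TRUE)
    e2 <- rot2eul(R)
    expect_equal(eul2rot(e2[1], e2[2], e2[3]), R, tolerance = 1e-8)
  }
})

test_that("gimbal-degenerate orientations recompose correctly", {
  for (psi in c(-90, 0, 45, 180)) {
    R <- eul2rot(30, 0, psi)     # theta 0: only phi+psi matters
    e <- rot2eul(R)
    expect_equal(eul2rot(e[1], e[2], e[3]), R, tolerance = 1e-8)
  }
})

test_that("wrap180 maps angles into (-180, 180]", {
  expect_equal(wrap180(c(190, -190, 360, 180, -180)),
               c(-170, 170, 0, 180, 180))
})
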