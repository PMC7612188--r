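test_that("straight contours yield empty deviation paths", {
  ec <- make_end_contours(n_pf = 5, straight_lengths = 30, flare_radii = 0)
  paths <- pf_deviation_paths(ec$end)
  expect_true(all(vapply(paths, nrow, integer(1)) == 0))
})

test_that("a quarter-circle flare of radius 20 ends near (20, 20)", {
  ec <- make_end_contours(n_pf = 13, straight_lengths = 24, flare_radii = 20,
                          arc_degrees = 90, point_spacing = 2)
  paths <- pf_deviation_paths(ec$end)
  ends <- t(vapply(paths, function(p) as.numeric(p[nrow(p), ]), numeric(2)))
  expect_true(all(abs(ends[, 1] - 20) < 1))
  expect_true(all(abs(ends[, 2] - 20) < 1))
})

test_that("deviation paths recover the generator's flare radius within 10%", {
  ec <- make_end_contours(n_pf = 13, straight_lengths = 30,
                          flare_radii = 25, arc_degrees = 80,
                          point_spacing = 2)
  paths <- pf_deviation_paths(ec$end, threshold = 2)
  # circle fit: for an arc leaving the wall tangentially, s^2 + (rho-d)^2 = rho^2
  rho_hat <- unlist(lapply(paths, function(p) (p$s^2 + p$d^2) / (2 * p$d)))
  expect_lt(abs(median(rho_hat) - 25) / 25, 0.1)
})

test_that("taper length is the axial spread of terminal points", {
  mk3 <- function(lens) make_end_contours(n_pf = 3, straight_lengths = lens,
                                          flare_radii = 0)$end
  expect_equal(taper_length(mk3(c(10, 18, 30))), 20)
  expect_equal(taper_length(mk3(c(25, 25, 25))), 0)
  one <- end_contours(list(rbind(c(10.6, 0, 0), c(10.6, 0, 20))))
  expect_error(taper_length(one), "single contour")
})

test_that("a generated 46-nm taper is measured back within 1 nm", {
  lens <- seq(10, 56, length.out = 13)      # max - min = 46
  ec <- make_end_contours(n_pf = 13, straight_lengths = lens,
                          flare_radii = 12, arc_degrees = 45)
  truth <- max(ec$truth$terminal_axial) - min(ec$truth$terminal_axial)
  expect_lt(abs(taper_length(ec$end) - truth), 1)
})

test_that("taper length is invariant under rigid-body transforms", {
  set.seed(61)
  base <- make_end_contours(n_pf = 13,
                            straight_lengths = runif(13, 15, 60),
                            flare_radii = 18, arc_degrees = 70)
  t0 <- taper_length(base$end)
  for (i in 1:5) {
    e <- c(runif(1, -180, 180), runif(1, 0, 180), runif(1, -180, 180))
    R <- eul2rot(e[1], e[2], e[3])
    tr <- runif(3, -100, 100)
    contours <- lapply(base$end$contours, function(p)
      t(R %*% t(p)) + matrix(tr, nrow(p), 3, byrow = TRUE))
    me <- end_contours(contours)
    expect_lt(abs(taper_length(me) - t0), 1e-6)
  }
})

test_that("the end census combines side and filament polarity", {
  e1 <- make_end_contours(n_pf = 5, end_side = "path_end", end_id = 1,
                          filament_id = 0)$end
  e2 <- make_end_contours(n_pf = 5, end_side = "path_start", end_id = 2,
                          filament_id = 0)$end
  e3 <- make_end_contours(n_pf = 5, end_side = "path_end", end_id = 3,
                          filament_id = 1)$end
  pol <- data.frame(filament_id = c(0, 1), assignment = c("plus", "unclear"))
  cen <- end_census(list(e1, e2, e3), pol)
  expect_equal(cen$census$polarity_label, c("plus", "minus", "ND"))
  e4 <- make_end_contours(n_pf = 5, end_side = "path_end", end_id = 4,
                          filament_id = 9)$end
  expect_warning(end_census(list(e4), pol), "absent")
})

test_that("the census t-test has power at a planted taper difference", {
  set.seed(62)
  detected <- replicate(100, {
    plus <- rnorm(11, 120, 40)
    minus <- rnorm(11, 46, 25)
    ttest(pmax(plus, 1), pmax(minus, 1))$p < 0.05
  })
  expect_gte(mean(detected), 0.8)
})
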