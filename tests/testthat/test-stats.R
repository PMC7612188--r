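test_that("summary statistics match a two-pass oracle", {
  set.seed(71)
  for (i in 1:20) {
    x <- rnorm(sample(2:200, 1), sd = runif(1, 0.1, 50))
    s <- summary_stat(x)
    mu <- sum(x) / length(x)
    expect_equal(s$mean, mu, tolerance = 1e-12)
    expect_equal(s$sd, sqrt(sum((x - mu)^2) / (length(x) - 1)),
                 tolerance = 1e-12)
  }
})

test_that("peak-to-peak diameters interpolate to sub-voxel accuracy", {
  x <- seq(0, 30, by = 1)
  prof <- exp(-(x - 2.0)^2 / 2) + exp(-(x - 23.2)^2 / 2)
  expect_lt(abs(diameter_peak_to_peak(prof, 1) - 21.2), 0.05)
  expect_error(diameter_peak_to_peak(rep(1, 30), 1), "peaks")
})

test_that("visible length is the polyline arclength", {
  expect_equal(visible_length(rbind(c(0, 0, 0), c(0, 100, 0))), 100)
  sq <- rbind(c(0, 0, 0), c(10, 0, 0), c(10, 10, 0), c(0, 10, 0), c(0, 0, 0))
  expect_equal(visible_length(sq), 40)
  expect_error(visible_length(rbind(c(0, 0, 0))), "2 points")
})

test_that("layer-line spacing is unit-consistent and silent on noise", {
  fl <- filament_spec(rbind(c(24, 10, 24), c(24, 210, 24)), kind = "actin",
                      pf_segments = data.frame(s0 = 0, s1 = 200, pf = 13L))
  man <- scene_manifest(list(fl))
  vol <- render_scene(man, dim = c(48, 224, 48), voxel_size = 1)
  img <- t(project(vol, n_slices = 15, axis = "z"))
  s1 <- layer_line_spectrum(img, voxel_size = 1)$spacing_nm
  # doubling the nominal pixel size (and the physical search window with
  # it) doubles the reported nm spacing: the frequency axis is in physical
  # units
  s2 <- layer_line_spectrum(img, voxel_size = 2, min_spacing = 7,
                            max_spacing = 40)$spacing_nm
  expect_equal(s2, 2 * s1, tolerance = 1e-9)
  set.seed(72)
  noise <- matrix(rnorm(224 * 48), 224, 48)
  expect_false(layer_line_spectrum(noise, 1)$significant)
})

test_that("plus-end density arithmetic and scale consistency hold", {
  d <- densities(11, 75, 0.3)
  expect_equal(unname(d$report["per_um"]), 0.15)
  expect_equal(unname(d$report["per_um2"]), 0.49)
  expect_equal(unname(round(d$per_um2 / 0.065)), 8)   # ~7.5x literature
  d2 <- densities(22, 150, 0.3)
  expect_equal(d2$per_um, d$per_um)
})

test_that("the pooled t-test matches the closed form and its symmetries", {
  tt <- ttest(c(1, 2, 3, 4, 5), c(2, 3, 4, 5, 6))
  expect_equal(abs(tt$t), 1, tolerance = 1e-12)
  expect_equal(tt$df, 8)
  sw <- ttest(c(2, 3, 4, 5, 6), c(1, 2, 3, 4, 5))
  expect_equal(sw$t, -tt$t)
  expect_equal(sw$p, tt$p)
  same <- ttest(c(1, 2, 3), c(1, 2, 3), mode = "paired")
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_true(same$flagged)
})

test_that("wall-thickness ratios recover a planted twofold difference", {
  w <- wall_thickness_ratio(2.4, 5.9)
  expect_equal(round(w$ratios, 2), 0.41)
  ident <- wall_thickness_ratio(c(3, 3), c(3, 3))
  expect_equal(ident$mean_ratio, 1)
  expect_equal(ident$test$p, 1)
  set.seed(73)
  est <- replicate(200, {
    b <- runif(6, 4, 7)
    a <- 0.5 * b * exp(rnorm(6, 0, 0.05))
    wall_thickness_ratio(a, b)$mean_ratio
  })
  expect_lt(abs(mean(est) - 0.5), 3 * sd(est) / sqrt(200))
})

test_that("census percentages come from counts at the report layer", {
  pc <- pf_census(c("12" = 134, "13" = 101, "ND" = 21))
  expect_equal(pc$percent[pc$class == "12"], 52)
  expect_equal(pc$percent[pc$class == "13"], 39)
})

test_that("neurite census separates mixed, consistent and undetermined", {
  df <- data.frame(neurite_id = c(1, 1, 2, 2, 3, 3, 4),
                   pf = c(12, 13, 13, 13, 13, NA, 12))
  cen <- neurite_census(df)
  expect_equal(cen$call[cen$neurite_id == 1], "mixed")
  expect_equal(cen$call[cen$neurite_id == 2], "all_13")
  expect_equal(cen$call[cen$neurite_id == 3], "ND")
  expect_equal(cen$call[cen$neurite_id == 4], "all_12")
})
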