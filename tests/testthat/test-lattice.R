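test_that("a 16-nm 13-pf path yields one complete dimer layer", {
  spec <- lattice_spec(slew_tilt = 0)
  fl <- filament_spec(rbind(c(0, 0, 0), c(0, 0, 16)),
                      pf_segments = data.frame(s0 = 0, s1 = 16, pf = 13L))
  pts <- build_lattice_points(spec, fl)
  expect_equal(nrow(pts), 26)
  ang <- sort(unique(round(atan2(pts$y, pts$x) * 180 / pi, 4)))
  expect_length(ang, 13)
  expect_equal(diff(ang), rep(360 / 13, 12), tolerance = 1e-6)
})

test_that("pf segments change the cross-section symmetry at the boundary", {
  spec <- lattice_spec(slew_tilt = 0)
  fl <- filament_spec(rbind(c(0, 0, 0), c(0, 0, 1000)),
                      pf_segments = data.frame(s0 = c(0, 500),
                                               s1 = c(500, 1000),
                                               pf = c(12L, 13L)))
  pts <- build_lattice_points(spec, fl)
  before <- pts[pts$arclength < 480, ]
  after <- pts[pts$arclength > 520, ]
  expect_length(unique(before$pf), 12)
  expect_length(unique(after$pf), 13)
  expect_true(all(before$seg_pf == 12))
  expect_true(all(after$seg_pf == 13))
})

test_that("break intervals remove monomers only inside the break", {
  spec <- lattice_spec()
  mk <- function(breaks) {
    fl <- filament_spec(rbind(c(0, 0, 0), c(0, 0, 400)),
                        pf_segments = data.frame(s0 = 0, s1 = 400, pf = 13L),
                        break_intervals = breaks)
    build_lattice_points(spec, fl)
  }
  full <- mk(NULL)
  broken <- mk(data.frame(s0 = 100, s1 = 150))
  expect_equal(sum(broken$arclength > 100 & broken$arclength < 150), 0)
  keep <- full$arclength <= 100 | full$arclength >= 150
  expect_equal(broken$x, full$x[keep])
})

test_that("degenerate paths are rejected", {
  expect_error(filament_spec(rbind(c(0, 0, 0), c(0, 0, 0), c(0, 0, 10))),
               "degenerate")
})

test_that("the 13-pf lattice carries the 13-fold screw symmetry", {
  # one step of the helical symmetry: rotate by 360/13 about the axis and
  # advance by the 3-start rise; pf j maps onto pf j+1 (the seam excluded)
  spec <- lattice_spec(slew_tilt = 0)
  fl <- filament_spec(rbind(c(0, 0, 0), c(0, 0, 40)),
                      pf_segments = data.frame(s0 = 0, s1 = 40, pf = 13L))
  pts <- build_lattice_points(spec, fl)
  one <- pts[pts$layer == 0 & pts$monomer == "alpha", ]
  one <- one[order(one$pf), ]
  th <- 2 * pi / 13
  rise <- 1.5 * spec$dimer_rise / 13
  src <- one[one$pf < 12, ]
  screw <- cbind(src$x * cos(th) - src$y * sin(th),
                 src$x * sin(th) + src$y * cos(th), src$z + rise)
  tgt <- one[one$pf >= 1, c("x", "y", "z")]
  d <- sqrt(rowSums((screw - as.matrix(tgt))^2))
  expect_lt(max(d), 1e-6)
})

test_that("polarity flips the tangential handedness of the dimer axis", {
  spec <- lattice_spec()
  mk <- function(pol) {
    fl <- filament_spec(rbind(c(0, 0, 0), c(0, 0, 40)), polarity = pol,
                        pf_segments = data.frame(s0 = 0, s1 = 40, pf = 13L))
    build_lattice_points(spec, fl)
  }
  p <- mk("plus_along_path"); m <- mk("minus_along_path")
  # tangential component of the dimer axis: sign must flip with polarity
  tang <- function(pts) {
    phi <- atan2(pts$y, pts$x)
    -sin(phi) * pts$ax + cos(phi) * pts$ay
  }
  expect_true(all(tang(p) * tang(m) < 0))
  # radial positions identical: mirror-related lattices
  expect_equal(sqrt(p$x^2 + p$y^2), sqrt(m$x^2 + m$y^2), tolerance = 1e-9)
})

test_that("luminal particle placement is Poisson at the nominal rate", {
  fl <- filament_spec(rbind(c(0, 0, 0), c(0, 0, 1000)), mip_rate = 72,
                      pf_segments = data.frame(s0 = 0, s1 = 1000, pf = 13L))
  counts <- vapply(1:1000, function(s) length(place_mips(fl, s)), numeric(1))
  se <- sqrt(72 / 1000)      # Poisson SE of the mean count over 1000 draws
  expect_lt(abs(mean(counts) - 72), 3 * se)
  # minimum spacing enforced
  gaps <- unlist(lapply(1:50, function(s) diff(place_mips(fl, s))))
  expect_gte(min(gaps), 9 - 1e-9)
})

test_that("placement is deterministic and empty at rate zero", {
  fl0 <- filament_spec(rbind(c(0, 0, 0), c(0, 0, 500)), mip_rate = 0,
                       pf_segments = data.frame(s0 = 0, s1 = 500, pf = 13L))
  expect_length(place_mips(fl0, 1), 0)
  fl <- filament_spec(rbind(c(0, 0, 0), c(0, 0, 500)), mip_rate = 60,
                      pf_segments = data.frame(s0 = 0, s1 = 500, pf = 13L))
  expect_identical(place_mips(fl, 7), place_mips(fl, 7))
})
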