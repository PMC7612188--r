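test_that("an empty manifest renders to an all-zero volume", {
  man <- scene_manifest(list())
  v <- render_scene(man, dim = c(16, 16, 16), voxel_size = 1)
  expect_true(all(v$data == 0))
})

test_that("rendered 13-pf MTs have the canonical ~21-nm wall diameter", {
  fx <- fx_clean_mt()
  img <- project(fx$avg, n_slices = 9, axis = "z")
  mid <- (ncol(img) + 1) / 2
  d <- diameter_peak_to_peak(img[, mid], voxel_size = 1)
  expect_lt(abs(d - 2 * lattice_spec()$wall_radius), 1.0)
})

test_that("rendered actin shows a 6-nm layer line", {
  fl <- filament_spec(rbind(c(24, 10, 24), c(24, 210, 24)), kind = "actin",
                      pf_segments = data.frame(s0 = 0, s1 = 200, pf = 13L))
  man <- scene_manifest(list(fl))
  vol <- render_scene(man, dim = c(48, 224, 48), voxel_size = 1)
  img <- t(project(vol, n_slices = 15, axis = "z"))
  lls <- layer_line_spectrum(img, 1)
  expect_true(lls$significant)
  expect_lt(abs(lls$spacing_nm - 6), 0.3)
})

test_that("undersampled rendering is refused", {
  man <- scene_manifest(list())
  expect_error(render_scene(man, c(8, 8, 8), voxel_size = 3), "undersampled")
})

test_that("corrupt with snr=Inf and full tilt range is the identity", {
  fx <- fx_clean_mt()
  out <- corrupt(fx$scene$clean, snr = Inf, tilt_range = 90, seed = 1)
  expect_identical(out$data, fx$scene$clean$data)
})

test_that("the missing wedge is zeroed in Fourier space", {
  fx <- fx_clean_mt()
  out <- corrupt(fx$scene$clean, snr = Inf, tilt_range = 60, seed = 1)
  F <- fft(out$data)
  d <- dim(out$data)
  w <- axonmt:::wedge_mask(d, 60)
  expect_lt(mean(Mod(F[!w])), 1e-6 * mean(Mod(F[w])))
})

test_that("corruption is reproducible given the seed and hits the target SNR", {
  fx <- fx_clean_mt()
  a <- corrupt(fx$scene$clean, snr = 0.5, tilt_range = 90, seed = 3)
  b <- corrupt(fx$scene$clean, snr = 0.5, tilt_range = 90, seed = 3)
  expect_identical(a$data, b$data)
  noise <- a$data - fx$scene$clean$data
  sig <- fx$scene$clean$data
  mask <- sig > 0.1 * max(sig)
  expect_lt(abs(var(sig[mask]) / var(as.numeric(noise)) - 0.5), 0.05)
})

test_that("manifests round-trip losslessly through JSON", {
  sc <- make_mt_scene(length_nm = 120, mip_rate = 50, seed = 5,
                      break_intervals = data.frame(s0 = 40, s1 = 60),
                      end_taper = list(start = seq(0, 12, length.out = 13),
                                       end = 0))
  path <- tempfile(fileext = ".json")
  write_manifest(sc$manifest, path)
  m2 <- read_manifest(path)
  expect_equal(m2$mip_positions, sc$manifest$mip_positions,
               tolerance = 1e-12)
  expect_equal(m2$filaments[[1]]$path, sc$manifest$filaments[[1]]$path,
               tolerance = 1e-12, ignore_attr = TRUE)
  v2 <- render_scene(m2, dim(sc$clean$data), sc$clean$voxel_size)
  expect_equal(v2$data, sc$clean$data, tolerance = 1e-12)
})
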