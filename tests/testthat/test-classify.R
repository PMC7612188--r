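test_that("MSA of identical boxes has near-zero eigenvalues, orthonormal components", {
  fx <- fx_clean_mt()
  one <- fx$stack$boxes[, rep(4, 8)]
  tb <- particle_table(particle_id = 0:7, filament_id = 0L, tomogram_id = 0L,
                       x = 0, y = 0, z = 0, phi = 0, theta = 0, psi = 0)
  st <- subtomogram_stack(one, 33L, 1, tb)
  expect_warning(dec <- msa(st, n_components = 10), "rank")
  expect_lt(max(dec$eigenvalues), 1e-12 * sum(one[, 1]^2))
  fxdec <- msa(fx$stack, n_components = 5,
               mask = list(type = "gaussian_tube", radius = 10.6, sigma = 4))
  G <- crossprod(fxdec$components)
  expect_lt(max(abs(G - diag(ncol(G)))), 1e-6)
})

test_that("slew handedness flips under mirror reflection and is silent on noise", {
  fx <- fx_clean_mt()
  img <- axonmt:::slew_image(fx$avg)
  s1 <- slew_sign(img, 9, 12.5)
  s2 <- slew_sign(img[nrow(img):1, ], 9, 12.5)     # mirror through a plane
  expect_true(s1$sign %in% c("cw", "ccw"))
  expect_true(s2$sign %in% c("cw", "ccw"))
  expect_true(s1$sign != s2$sign)
  expect_equal(s1$score, -s2$score, tolerance = 0.2)
  set.seed(5)
  noise <- matrix(rnorm(33^2), 33, 33)
  expect_equal(slew_sign(noise, 9, 12.5)$sign, "undetermined")
})

test_that("per-MT averages of known polarity read the expected slew", {
  for (pol in c("plus_along_path", "minus_along_path")) {
    sc <- make_mt_scene(length_nm = 160, polarity = pol, seed = 3,
                        phase0 = 15)
    st <- crop(sc$volume, frames_along_filament(sc$model, 8), 33)
    res <- mt_polarity_by_slew(st)
    expect_equal(res$assignment,
                 if (pol == "plus_along_path") "plus" else "minus")
  }
})

test_that("pf counting reads 13 and 12 from noiseless averages, ND from noise", {
  fx <- fx_clean_mt()
  expect_equal(as.integer(count_pfs(fx$avg)), 13L)
  sc12 <- make_mt_scene(length_nm = 160,
                        pf_segments = data.frame(s0 = 0, s1 = 160, pf = 12L),
                        seed = 4)
  st12 <- crop(sc12$volume, frames_along_filament(sc12$model, 8), 33)
  expect_equal(as.integer(count_pfs(average(st12))), 12L)
  set.seed(6)
  noise <- volume(array(rnorm(33^3), rep(33, 3)))
  expect_true(is.na(count_pfs(noise)))
})

test_that("a single-polarity stack has no polarity eigenvector", {
  sc <- make_mt_scene(length_nm = 240, seed = 8, snr = 2, tilt_range = 60)
  st <- crop(sc$volume, frames_along_filament(sc$model, 8), 33)
  dec <- msa(st, n_components = 10,
             mask = list(type = "gaussian_tube", radius = 10.6, sigma = 4),
             tilt_range = 60)
  expect_error(find_polarity_eigenvector(dec,
                                         filament_id = st$table$filament_id,
                                         n_scan = 8),
               "not found")
})

test_that("MRA assigns a particle identical to a reference to that class", {
  fx <- fx_clean_mt()
  refA <- fx$avg$data
  refB <- array(rev(refA), rep(33, 3))
  one <- fx$stack$table[5, , drop = FALSE]
  st <- subtomogram_stack(matrix(refA, ncol = 1), 33L, 1,
                          particle_table(particle_id = 0L, filament_id = 0L,
                                         tomogram_id = 0L, x = 0, y = 0,
                                         z = 0, phi = 0, theta = 0, psi = 0))
  res <- suppressWarnings(mra(st, list(refA, refB), rounds = 1,
             limits = alignment_limits(max_inplane = 0, max_axial_shift = 0,
                                       mask = list(type = "none"))))
  expect_equal(res$table$class_label, 1L)
  expect_gt(res$table$cc_score, 0.99)
})

test_that("noiseless 12-pf particles all classify as 12 against 12/13 references", {
  sc <- make_mt_scene(length_nm = 240,
                      pf_segments = data.frame(s0 = 0, s1 = 240, pf = 12L),
                      seed = 10)
  st <- crop(sc$volume, frames_along_filament(sc$model, 8), 33)
  res <- suppressWarnings(detect_pf_transitions(st))
  expect_equal(res$assignments$assignment, "12")
  expect_true(all(res$table$class_label == 1L))
})

test_that("the polarity vote is strict at 70% and unclear when empty", {
  tb <- particle_table(particle_id = 0:9, filament_id = 0L, tomogram_id = 0L,
                       x = 0, y = 0, z = 0, phi = 0, theta = 0, psi = 0,
                       cc_score = 0.5, class_label = c(rep(1L, 8), 2L, 2L))
  v <- vote_polarity(tb, c("plus", "minus"), pre_clean = 1)
  expect_equal(v$assignment, "plus")                 # 0.8 > 0.7
  tb2 <- tb; tb2$class_label <- c(rep(1L, 7), rep(2L, 3))
  expect_equal(vote_polarity(tb2, c("plus", "minus"),
                             pre_clean = 1)$assignment, "unclear")  # exactly 70%
  tb3 <- tb; tb3$keep_flag <- FALSE
  expect_equal(vote_polarity(tb3, c("plus", "minus"))$assignment, "unclear")
})

test_that("pf assignment follows the 95% / patch rules on constructed labels", {
  sc <- make_mt_scene(length_nm = 500, seed = 12)    # pure 13-pf data
  st <- crop(sc$volume, frames_along_filament(sc$model, 8), 33)
  n <- nrow(st$table)
  tb <- st$table
  tb$cc_score <- 0.9
  # 97% one class: automatic assignment
  tb$class_label <- c(rep(1L, 2), rep(2L, n - 2))
  res97 <- assign_pf(list(table = tb), st, class_pf = c(12, 13))
  expect_equal(res97$assignment, "13")
  expect_true(is.na(res97$transition_nm))
  # 15 + 48 runs: the short run fails the >20-particle rule and its class
  # average (13-pf data labeled 12) fails the quality gate: assigned 13
  tb$class_label <- c(rep(1L, 15), rep(2L, n - 15))
  res15 <- assign_pf(list(table = tb), st, class_pf = c(12, 13))
  expect_equal(res15$assignment, "13")
})

test_that("a constructed 30/30 split on matching data localizes the boundary", {
  L <- 520
  s_tr <- 260
  sc <- make_mt_scene(length_nm = L,
                      pf_segments = data.frame(s0 = c(0, s_tr),
                                               s1 = c(s_tr, L),
                                               pf = c(12L, 13L)),
                      seed = 13)
  st <- crop(sc$volume, frames_along_filament(sc$model, 8), 33)
  res <- detect_pf_transitions(st)
  expect_equal(res$assignments$assignment, "transition")
  expect_lt(abs(res$assignments$transition_nm - s_tr), 12)
})
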