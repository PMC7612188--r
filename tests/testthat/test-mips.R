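test_that("noiseless planted particles are each recovered within 2 nm", {
  sc <- make_mt_scene(length_nm = 400, mip_rate = 25, seed = 21)
  mp <- sc$manifest$mip_positions[[1]]
  cand <- detect_mips(sc$volume, sc$model)
  cl <- cluster_clean(cand, radius = 5, min_size = 2)
  expect_gte(nrow(cl), length(mp))
  d <- abs(outer(mp, cl$arclength, "-"))
  expect_lt(max(apply(d, 1, min)), 2)
})

test_that("empty lumens yield zero detections after cleaning", {
  sc <- make_mt_scene(length_nm = 300, mip_rate = 0, seed = 22)
  expect_equal(nrow(cluster_clean(detect_mips(sc$volume, sc$model), 5, 2)), 0)
  scn <- make_mt_scene(length_nm = 300, mip_rate = 0, snr = 1,
                       tilt_range = 60, seed = 23)
  expect_equal(nrow(cluster_clean(detect_mips(scn$volume, scn$model), 5, 2)), 0)
})

test_that("a lumen radius at or beyond the wall is refused", {
  sc <- make_mt_scene(length_nm = 120, seed = 24)
  expect_error(detect_mips(sc$volume, sc$model, lumen_radius = 11),
               "smaller than the wall")
})

test_that("cluster cleaning follows the pairwise-radius rule", {
  mk <- function(y, cc) particle_table(
    particle_id = seq_along(y) - 1L, filament_id = 0L, tomogram_id = 0L,
    x = 0, y = y, z = 0, phi = 0, theta = 0, psi = 0, cc_score = cc,
    arclength = y)
  two <- cluster_clean(mk(c(0, 4), c(0.9, 0.7)), 5, 2)
  expect_equal(nrow(two), 1)
  expect_equal(two$cc_score, 0.9)
  expect_equal(nrow(cluster_clean(mk(5, 0.8), 5, 2)), 0)       # singleton
  expect_equal(nrow(cluster_clean(mk(c(0, 6, 12), c(0.9, 0.8, 0.7)), 5, 2)), 0)
})

test_that("single-linkage cleaning matches a brute-force all-pairs oracle", {
  set.seed(31)
  for (rep in 1:5) {
    n <- sample(10:50, 1)
    tb <- particle_table(particle_id = seq_len(n) - 1L, filament_id = 0L,
                         tomogram_id = 0L,
                         x = runif(n, 0, 40), y = runif(n, 0, 40),
                         z = runif(n, 0, 40), phi = 0, theta = 0, psi = 0,
                         cc_score = runif(n))
    got <- cluster_clean(tb, radius = 6, min_size = 2)
    # oracle: transitive closure of the all-pairs within-radius relation
    pos <- as.matrix(tb[, c("x", "y", "z")])
    adj <- as.matrix(dist(pos)) <= 6
    reach <- adj
    for (k in 1:n) reach <- reach | (reach %*% reach > 0)
    comp <- match(apply(reach, 1, function(r) min(which(r))),
                  unique(apply(reach, 1, function(r) min(which(r)))))
    keep <- unlist(lapply(split(seq_len(n), comp), function(m) {
      if (length(m) >= 2) m[which.max(tb$cc_score[m])] else integer(0)
    }))
    expect_setequal(got$particle_id, tb$particle_id[sort(keep)])
  }
})

test_that("per-MT density arithmetic is exact and robust to zero counts", {
  tb <- particle_table(particle_id = 0:35, filament_id = 0L, tomogram_id = 0L,
                       x = 0, y = seq(0, 490, length.out = 36), z = 0,
                       phi = 0, theta = 0, psi = 0,
                       arclength = seq(0, 490, length.out = 36))
  d <- mip_density(tb, c("0" = 500))
  expect_equal(d$per_mt$density_per_um, 72)
  d0 <- mip_density(tb[0, ], c("0" = 500))
  expect_equal(d0$per_mt$density_per_um, 0)
})

test_that("break/end windows produce the documented arithmetic", {
  # MT of 1000 nm with 69 MIPs/um overall; a 100-nm adjacent window holding
  # 9 MIPs reads 90/um for that side
  arc <- c(seq(5, 595, length.out = 41), seq(601, 699, length.out = 9),
           seq(815, 995, length.out = 19))
  tb <- particle_table(particle_id = seq_along(arc) - 1L, filament_id = 0L,
                       tomogram_id = 0L, x = 0, y = arc, z = 0,
                       phi = 0, theta = 0, psi = 0, arclength = arc)
  res <- break_end_mip_stats(tb, c("0" = 1000),
                             breaks = data.frame(filament_id = 0, s0 = 700,
                                                 s1 = 810))
  expect_equal(res$breaks$expected, 69)
  expect_equal(res$breaks$observed_within, 0)
  # left window (600-700) holds 9 MIPs -> 90/um; right (810-910) holds 10
  expect_equal(res$breaks$observed_adjacent, mean(c(90, 100)))
  # zero-length break flagged
  res0 <- break_end_mip_stats(tb, c("0" = 1000),
                              breaks = data.frame(filament_id = 0, s0 = 700,
                                                  s1 = 700))
  expect_true(res0$breaks$flagged)
  expect_true(is.na(res0$breaks$observed_within))
})

test_that("the paired break test is calibrated under the uniform null", {
  set.seed(41)
  pvals <- replicate(40, {
    rows <- lapply(1:12, function(f) {
      n <- rpois(1, 60)
      arc <- sort(runif(n, 0, 1000))
      data.frame(filament_id = f, arclength = arc)
    })
    tab <- do.call(rbind, rows)
    tab$particle_id <- seq_len(nrow(tab)) - 1L
    tab$x <- 0; tab$y <- tab$arclength; tab$z <- 0
    tab$tomogram_id <- 0L; tab$phi <- 0; tab$theta <- 0; tab$psi <- 0
    tab$cc_score <- NA_real_; tab$class_label <- NA_integer_
    tab$keep_flag <- TRUE
    tab <- axonmt:::as_particle_table(tab[axonmt:::PARTICLE_COLS])
    lens <- setNames(rep(1000, 12), as.character(1:12))
    br <- data.frame(filament_id = 1:12, s0 = 400, s1 = 520)
    break_end_mip_stats(tab, lens, breaks = br)$tests$within_break$p
  })
  expect_gt(suppressWarnings(ks.test(pvals, "punif"))$p.value, 0.01)
})

test_that("free-angle averaging recovers the ring phantom's central pore", {
  set.seed(51)
  n <- 60
  boxes <- matrix(0, 15^3, n)
  for (i in 1:n) {
    pts <- axonmt:::with_seed(100 + i,
      axonmt:::mip_ring_points(rep(7, 3), diag(3)))
    clean <- axonmt:::cpp_render_blobs(rep(15L, 3), 1, c(0, 0, 0), pts,
                                       rep(1, 6), rep(1.3, 6))
    boxes[, i] <- clean + rnorm(15^3, sd = sd(clean))
  }
  tb <- particle_table(particle_id = seq_len(n) - 1L,
                       filament_id = rep(0:5, each = 10), tomogram_id = 0L,
                       x = 0, y = 0, z = 0, phi = 0, theta = 0, psi = 0)
  st <- subtomogram_stack(boxes, 15L, 1, tb)
  res <- average_mips(st, rounds = 2, min_particles = 50)
  avg <- res$average$data
  ctr <- avg[8, 8, 8]
  ring <- mean(c(avg[8 + 3, 8, 8], avg[8 - 3, 8, 8], avg[8, 8 + 3, 8]))
  expect_lt(ctr, ring)
  expect_false(is.null(res$fsc))
  # identical particles: average equals the particle
  st1 <- subtomogram_stack(boxes[, c(1, 1)], 15L, 1, tb[1:2, ])
  expect_equal(average(st1)$data, array(boxes[, 1], rep(15, 3)),
               tolerance = 1e-12)
})
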