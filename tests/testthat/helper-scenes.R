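# Shared fixtures, built in code and cached for the session.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, builder(), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# small noiseless 13-pf MT scene along +y with its 8-nm particle stack
fx_clean_mt <- function() fixture("clean_mt", function() {
  sc <- make_mt_scene(length_nm = 160, seed = 11, phase0 = 20)
  tb <- frames_along_filament(sc$model, 8)
  st <- crop(sc$volume, tb, 33)
  list(scene = sc, table = tb, stack = st, avg = average(st))
})

# mixed-polarity noisy cohort used by the classification unit tests
fx_polarity_cohort <- function(n = 6, length_nm = 280, snr = 0.5) {
  build <- function() {
    set.seed(42)
    stacks <- vector("list", n)
    truth <- character(n)
    for (i in seq_len(n)) {
      pol <- if (i %% 2 == 1) "plus_along_path" else "minus_along_path"
      truth[i] <- if (pol == "plus_along_path") "plus" else "minus"
      th <- runif(1, -10, 10) * pi / 180
      ph <- runif(1, 0, 2 * pi)
      dirv <- c(sin(th) * cos(ph), cos(th), sin(th) * sin(ph))
      sc <- make_mt_scene(length_nm = length_nm, direction = dirv,
                          polarity = pol, snr = snr, tilt_range = 60,
                          seed = 100 + i)
      sc$model$filament_id <- i - 1L
      tb <- frames_along_filament(sc$model, 8, tomogram_id = i - 1L)
      stacks[[i]] <- crop(sc$volume, tb, 33)
    }
    list(stack = pool_stacks(stacks), truth = truth)
  }
  if (n > 10) return(build())          # large cohorts are not cached
  fixture(sprintf("polcohort_%d_%d", n, length_nm), build)
}

expect_polarity_match <- function(assignment, truth) {
  ok <- assignment == truth
  wrong <- assignment != "unclear" & !ok
  list(correct = sum(ok), unclear = sum(assignment == "unclear"),
       wrong = sum(wrong))
}
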