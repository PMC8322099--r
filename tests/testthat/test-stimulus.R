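test_that("harmonic stacks contain every integer multiple up to fmax", {
  s <- make_harmonic_stack(4000, 40000)
  expect_equal(nrow(s$components), 10)
  expect_equal(s$components$frequency, seq(4000, 40000, by = 4000))
  expect_true(all(s$components$onset == 0))

  expect_equal(nrow(make_harmonic_stack(8000, 8000)$components), 1)
  expect_equal(nrow(make_harmonic_stack(2000, 40000)$components), 20)
  # exact integer-multiple invariant across several F0s
  for (f0 in c(2000, 2800, 4000, 5700, 8000)) {
    s <- make_harmonic_stack(f0, 40000)
    expect_identical(s$components$frequency,
                     seq_len(floor(40000 / f0)) * f0)
  }
  expect_error(make_harmonic_stack(-1, 40000))
  expect_error(make_harmonic_stack(8000, 4000))
})

test_that("onset shifts move the designated group and invert cleanly", {
  st <- make_harmonic_stack(4000, 40000)
  s <- apply_onset_shift(st, -45, "lower_half")
  expect_equal(s$components$onset, c(rep(-45, 5), rep(0, 5)))
  expect_equal(s$delta_onset, -45)

  s0 <- apply_onset_shift(st, 0, "lower_half")
  expect_equal(s0$components$onset, rep(0, 10))

  three <- make_harmonic_stack(4000, 12000)
  sf <- apply_onset_shift(three, -100, "fundamental")
  expect_equal(sf$components$onset[sf$components$frequency == 4000], -100)
  expect_equal(sf$components$onset[sf$components$frequency != 4000], c(0, 0))

  # involution on the shifted group
  for (d in c(-45, -15, 30)) {
    back <- apply_onset_shift(apply_onset_shift(st, d, "lower_half"),
                              -d, "lower_half")
    expect_equal(back$components$onset, rep(0, 10))
  }
  # odd component count: floor(n/2) lowest shifted
  five <- make_harmonic_stack(4000, 20000)
  s5 <- apply_onset_shift(five, 15, "lower_half")
  expect_equal(sum(s5$components$onset == 15), 2)

  jit <- make_jittered(st, 2000, seed = 1)
  expect_error(apply_onset_shift(jit, 15, "fundamental"))
})

test_that("frequency jitter is uniform, seeded, and count-preserving", {
  st <- make_harmonic_stack(4000, 40000)
  expect_equal(make_jittered(st, 0, seed = 5)$components$frequency,
               st$components$frequency)
  j1 <- make_jittered(st, 2000, seed = 42)
  j2 <- make_jittered(st, 2000, seed = 42)
  expect_identical(j1$components$frequency, j2$components$frequency)
  expect_false(identical(j1$components$frequency,
                         make_jittered(st, 2000, seed = 43)$components$frequency))

  # law-of-large-numbers check on the stated uniform
  dev <- unlist(lapply(1:1000, function(s) {
    sort(make_jittered(st, 2000, seed = s)$components$frequency) -
      st$components$frequency
  }))
  expect_true(all(abs(dev) <= 2000))
  expect_lt(abs(mean(dev)), 30)
  expect_gt(max(dev), 1800)  # jitter actually reaches the stated range
  expect_lt(min(dev), -1800)

  # non-positive draws are redrawn, preserving the component count
  low <- make_harmonic_stack(500, 2000)
  jl <- make_jittered(low, 499.9, seed = 7)
  expect_equal(nrow(jl$components), 4)
  expect_true(all(jl$components$frequency > 0))
})

test_that("pure-tone sets are log-spaced with inclusive endpoints", {
  specs <- make_pure_tone_set(4000, 64000, 17, c(30, 50, 70))
  expect_length(specs, 51)
  freqs <- sort(unique(vapply(specs, function(s) s$components$frequency,
                              numeric(1))))
  expect_length(freqs, 17)
  expect_equal(freqs[1], 4000)
  expect_equal(freqs[17], 64000)
  ratios <- freqs[-1] / freqs[-17]
  expect_equal(ratios, rep(2^(4 / 16), 16), tolerance = 1e-12)

  two <- make_pure_tone_set(4000, 64000, 2, 70)
  expect_equal(vapply(two, function(s) s$components$frequency, numeric(1)),
               c(4000, 64000))
  expect_error(make_pure_tone_set(-4000, 64000, 17, 70))
})

test_that("waveform synthesis ramps, sums coherently, and hits the RMS form", {
  sr <- 192000
  spec <- stimulus_spec(tone_component(4000, duration = 100, ramp = 5))
  x <- synthesize_waveform(spec, sr)
  expect_equal(length(x), 0.1 * sr)
  t <- (seq_along(x) - 1) / sr
  # linear rise/fall envelope: |x| bounded by the ramp line, and close to
  # it at the sine peaks
  rise <- t < 0.005
  expect_true(all(abs(x[rise]) <= t[rise] / 0.005 + 1e-9))
  fall <- t >= 0.095
  expect_true(all(abs(x[fall]) <= (0.1 - t[fall]) / 0.005 + 1e-9))
  expect_gt(max(abs(x[t > 0.004 & t < 0.005])), 0.75)

  # empty component list
  empty <- stimulus_spec(data.frame(frequency = numeric(0),
                                    onset = numeric(0), duration = numeric(0),
                                    level = numeric(0), ramp = numeric(0)))
  expect_length(synthesize_waveform(empty, sr), 0)

  # coherent summation: two identical components at doubled total amplitude
  # give exactly twice the single-component waveform
  one <- stimulus_spec(tone_component(4000, duration = 50, ramp = 0))
  two <- stimulus_spec(rbind(tone_component(4000, duration = 50, ramp = 0),
                             tone_component(4000, duration = 50, ramp = 0)))
  x1 <- synthesize_waveform(one, sr, peak_amplitude = 1)
  x2 <- synthesize_waveform(two, sr, peak_amplitude = 2)
  expect_equal(max(abs(x2 - 2 * x1)), 0, tolerance = 1e-9)

  # full-scale single tone, no ramps: RMS = A / sqrt(2) within 0.1%
  full <- stimulus_spec(tone_component(4000, duration = 100, ramp = 0))
  xf <- synthesize_waveform(full, sr)
  expect_equal(sqrt(mean(xf^2)), 1 / sqrt(2), tolerance = 1e-3)

  expect_error(synthesize_waveform(full, 7000))  # component at/above Nyquist
})

test_that("schedules are seeded block permutations of the stimulus set", {
  ids <- seq_len(35)
  sch <- build_schedule(ids, n_blocks = 5, seed = 9)
  expect_equal(nrow(sch), 175)
  expect_true(all(table(sch$stim_id) == 5))
  for (b in 1:5) {
    expect_setequal(sch$stim_id[sch$block == b], ids)
  }
  expect_identical(build_schedule(ids, 5, seed = 9), sch)

  one <- build_schedule("a", n_blocks = 3, seed = 1)
  expect_equal(one$stim_id, rep("a", 3))

  # different seeds give different permutations essentially always
  perms <- vapply(1:100, function(s) {
    paste(build_schedule(ids, 1, seed = s)$stim_id, collapse = ",")
  }, character(1))
  expect_gt(length(unique(perms)), 95)
  expect_error(build_schedule(character(0), 5, 1))
})

test_that("WAV files round-trip through the codec", {
  sr <- 48000
  x <- synthesize_waveform(
    stimulus_spec(tone_component(1000, duration = 20)), sr)
  f32 <- tempfile(fileext = ".wav")
  write_wav(x, f32, bit_depth = 32)
  y <- read_wav(f32)
  expect_equal(attr(y, "sample_rate"), sr)
  expect_equal(as.numeric(y), as.numeric(x), tolerance = 1e-7)

  f16 <- tempfile(fileext = ".wav")
  write_wav(x, f16, bit_depth = 16)
  y16 <- read_wav(f16)
  expect_equal(as.numeric(y16), as.numeric(x), tolerance = 1e-4)
  unlink(c(f16, f32))
})

test_that("stimulus tables serialize the stimulus metadata", {
  specs <- list(make_harmonic_stack(4000),
                make_jittered(make_harmonic_stack(4000), 2000, seed = 3))
  path <- tempfile(fileext = ".csv")
  tab <- write_stimulus_table(specs, path)
  back <- read.csv(path)
  expect_equal(nrow(back), 2)
  expect_equal(back$F0_Hz[1], 4000)
  expect_equal(back$jitter_seed[2], 3)
  expect_equal(length(strsplit(back$component_freqs[1], ";")[[1]]), 10)
  unlink(path)
})
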