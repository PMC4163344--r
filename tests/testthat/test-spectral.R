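cfg_bin <- spectral_config(refine_peak = FALSE)

test_that("windowed spectrum matches a direct DFT oracle", {
  win <- cosine_window(1.5, 1, Tw = 3)
  sp <- window_and_spectrum(win, cfg_bin)
  # bin spacing fs / n_fft
  expect_equal(sp$df, 100 / 2048)
  # magnitude peak lands on bin 31 (1.513672 Hz), per the brute-force DFT
  mags <- Mod(sp$spectrum)
  expect_equal(which.max(mags) - 1L, 31L)
  expect_equal(sp$freq[which.max(mags)], 31 * 100 / 2048)
  # value agrees with the independent definition-level DFT at that bin
  expect_equal(mags[32], oracle_dft_mag(win$samples, 31), tolerance = 1e-9)
  # amplitude correction by the coherent gain recovers ~1 within 3%
  expect_equal(2 * mags[32] / sp$coherent_sum, 1, tolerance = 0.03)
  # mean removal: constant segment gives a null spectrum
  spc <- window_and_spectrum(analysis_window(rep(5, 300), 100), cfg_bin)
  expect_lt(max(Mod(spc$spectrum)), 1e-9)
  # over-long windows are rejected with advice
  expect_error(
    window_and_spectrum(analysis_window(rnorm(3000), 100), cfg_bin),
    "n_fft")
})

test_that("fundamental estimation picks the right bin and survives strong harmonics", {
  sp <- window_and_spectrum(cosine_window(2, 1, Tw = 3), cfg_bin)
  expect_equal(estimate_fundamental(sp, cfg_bin), 41 * 100 / 2048) # 2.00195 Hz
  # refined estimate is within 0.3 min^-1 of the true rate
  cfg_ref <- spectral_config(refine_peak = TRUE)
  expect_lt(abs(60 * estimate_fundamental(sp, cfg_ref) - 120), 0.3)
  # 2nd harmonic stronger than the fundamental: subharmonic check wins
  sp2 <- window_and_spectrum(
    cosine_window(c(1.4, 2.8), c(1, 1.8), Tw = 3), cfg_bin)
  expect_equal(estimate_fundamental(sp2, cfg_bin), 1.4, tolerance = 0.03)
  # pure noise carries no periodicity
  set.seed(4)
  spn <- window_and_spectrum(analysis_window(rnorm(300), 100), cfg_bin)
  expect_error(estimate_fundamental(spn, cfg_bin),
               class = "cpr_no_periodicity")
})

test_that("displacement harmonics follow the second-derivative relation", {
  h <- harmonic_set(fcc = 2, A = 1, theta = 0)
  expect_equal(h$S[1], 1000 / (2 * pi * 2)^2)   # 6.3326 mm
  expect_equal(h$S[1], 6.3326, tolerance = 1e-4)
  expect_equal(h$phi[1], pi)                     # theta + pi
  h2 <- harmonic_set(2, c(1, 0.5, 0.2), c(0.3, -2, 5))
  k <- 1:3
  expect_equal(h2$S, 1000 * h2$A / (2 * pi * k * 2)^2)
  expect_equal(h2$phi, (h2$theta + pi) %% (2 * pi))
  # round trip: differentiating each displacement harmonic twice returns
  # the acceleration amplitude to machine precision
  expect_equal(h2$S / 1000 * (2 * pi * k * h2$fcc)^2, h2$A, tolerance = 1e-12)
  # harmonic estimation zeroes absent harmonics
  sp <- window_and_spectrum(cosine_window(2, 1, Tw = 3), cfg_bin)
  hs <- estimate_harmonics(sp, estimate_fundamental(sp, cfg_bin), cfg_bin)
  expect_equal(hs$A[2:3], c(0, 0))
  expect_equal(hs$A[1], 1, tolerance = 0.03)
})

test_that("cycle reconstruction reproduces hand-computed peak-to-peak values", {
  h1 <- harmonic_set(2, 25 / 1000 * (2 * pi * 2)^2, 0)  # S1 = 25 mm
  cyc <- reconstruct_cycle(h1)
  expect_equal(max(cyc) - min(cyc), 50, tolerance = 1e-3)
  # two-harmonic case: S = (20, 5), phi = (0, 0) -> max 25, min -15
  h2 <- harmonic_set(2, c(20, 5, 0) / 1000 * (2 * pi * 1:3 * 2)^2,
                     c(-pi, -pi, 0))  # theta = phi - pi
  cyc2 <- reconstruct_cycle(h2, samples_per_cycle = 4096)
  dense <- sapply(seq(0, 1, length.out = 20001)[-20001], function(u)
    20 * cos(2 * pi * u) + 5 * cos(4 * pi * u))
  expect_equal(max(cyc2) - min(cyc2), max(dense) - min(dense),
               tolerance = 1e-4)
  expect_equal(max(cyc2) - min(cyc2), 40, tolerance = 1e-4)
  # all-zero harmonics give a flat zero cycle
  h0 <- harmonic_set(2, c(0, 0, 0), c(0, 0, 0))
  expect_equal(max(reconstruct_cycle(h0)) - min(reconstruct_cycle(h0)), 0)
})

test_that("axis projection is rotation-invariant and flags dead windows", {
  acc <- sinusoid_accel(100, 50, duration = 10)
  w <- project_axes(acc, 2, 3, mode = "principal")
  wz <- acc$samples[201:500, 3] - mean(acc$samples[201:500, 3])
  # single-axis signal: principal projection equals the mean-removed axis
  expect_equal(abs(w$samples), abs(wz), tolerance = 1e-9)
  # rigid 18-degree rotation leaves the projection unchanged (up to sign)
  wrot <- project_axes(rotate_record(acc, 18), 2, 3, mode = "principal")
  expect_equal(abs(wrot$samples), abs(w$samples), tolerance = 1e-6)
  # fixed-axis mode picks the requested channel
  wfz <- project_axes(acc, 2, 3, mode = "z")
  expect_equal(wfz$samples, wz, ignore_attr = TRUE)
  # all-zero window -> no activity
  flat <- accel_record(matrix(0, 1000, 3), fs = 100)
  expect_error(project_axes(flat, 0, 3), class = "cpr_no_activity")
  expect_error(project_axes(acc, 9, 3), "bounds")
})

test_that("the full chain recovers rate and depth from analytic sinusoids", {
  # closed-form: (2*pi*100/60)^2 * 0.025 = 2.742 m/s^2 drives a 50 mm,
  # 100 min^-1 sinusoidal displacement
  acc <- sinusoid_accel(100, 50, duration = 12)
  expect_equal((2 * pi * 100 / 60)^2 * 0.025, 2.742, tolerance = 1e-3)
  w <- project_axes(acc, 3, 3)
  est <- feedback_from_window(w, cfg_bin)
  expect_equal(est$rate, 100, tolerance = 1.5 / 100)
  expect_equal(est$depth, 50, tolerance = 1 / 50)
  # rate = 60 * fcc scaling
  sp <- window_and_spectrum(cosine_window(2, 1, Tw = 3), cfg_bin)
  fcc <- estimate_fundamental(sp, cfg_bin)
  expect_equal(feedback_from_window(cosine_window(2, 1, Tw = 3), cfg_bin)$rate,
               60 * fcc)
  # zero-ish input propagates the no-activity error
  expect_error(feedback_from_window(analysis_window(rep(0, 300) + 1e-300, 100),
                                    cfg_bin),
               class = "cpr_no_periodicity")
})

test_that("closed-form recovery holds across the whole rate/depth grid", {
  bin_rate <- 60 * 100 / 2048
  for (rate in c(80, 100, 120, 140)) {
    for (depth in c(30, 50)) {
      acc <- sinusoid_accel(rate, depth, duration = 9)
      est <- feedback_from_window(project_axes(acc, 3, 3), cfg_bin)
      expect_lt(abs(est$rate - rate), bin_rate)
      expect_lt(abs(est$depth - depth) / depth, 0.03)
      # refined fundamental is within 0.3 min^-1
      estr <- feedback_from_window(project_axes(acc, 3, 3),
                                   spectral_config(refine_peak = TRUE))
      expect_lt(abs(estr$rate - rate), 0.3)
    }
  }
})

test_that("estimates are offset-invariant, scale-equivariant and drift-free", {
  acc <- sinusoid_accel(112, 42, duration = 9, gravity = 0)
  base <- feedback_from_window(project_axes(acc, 3, 3))
  # adding a constant (gravity-sized) offset changes nothing materially
  accg <- acc; accg$samples <- accg$samples + 9.81
  offs <- feedback_from_window(project_axes(accg, 3, 3))
  expect_lt(abs(offs$rate - base$rate) / base$rate, 0.001)
  expect_lt(abs(offs$depth - base$depth) / base$depth, 0.001)
  # scaling acceleration by c scales depth by c exactly, rate unchanged
  accs <- acc; accs$samples <- accs$samples * 1.37
  scl <- feedback_from_window(project_axes(accs, 3, 3))
  expect_equal(scl$rate, base$rate)
  expect_equal(scl$depth, base$depth * 1.37, tolerance = 1e-9)
  # no drift: a window's estimate ignores everything before it
  acc2 <- acc
  acc2$samples[1:300, ] <- acc2$samples[1:300, ] + 50  # corrupt earlier data
  late <- feedback_from_window(project_axes(acc2, 6, 3))
  ref <- feedback_from_window(project_axes(acc, 6, 3))
  expect_equal(late$rate, ref$rate)
  expect_equal(late$depth, ref$depth, tolerance = 1e-12)
})

test_that("session analysis windows the record on the floor rule with gap markers", {
  acc <- sinusoid_accel(100, 50, duration = 60)
  expect_equal(nrow(analyze_session(acc, 3)), 20)
  expect_equal(nrow(analyze_session(acc, 7)), 8)   # last 4 s discarded
  expect_error(analyze_session(acc, 61), "shorter")
  # silent middle third yields gap markers, not values
  accq <- acc
  accq$samples[2001:4000, ] <- 9.81 + 1e-6
  res <- analyze_session(accq, 3)
  mid <- res$window_start >= 21 & res$window_start < 39
  expect_true(all(res$status[mid] != "ok"))
  expect_true(all(is.na(res$rate[mid])))
  expect_true(all(res$status[res$window_start < 18] == "ok"))
})
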