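test_that("jitter-free generation is exactly periodic with the target depth", {
  cfg <- simulation_config(target_rate = 100, target_depth = 50,
                           duration = 12, rate_jitter_cv = 0,
                           depth_jitter_cv = 0, duty_cycle = 1,
                           noise_std = 0, seed = 1)
  gen <- generate_displacement(cfg)
  expect_true(all(abs(gen$truth$period - 0.6) < 1e-12))
  expect_true(all(abs(gen$truth$depth - 50) < 1e-12))
  expect_equal(max(gen$cd$samples), 50, tolerance = 1e-4)
  expect_equal(min(gen$cd$samples), 0)
  # one cycle, sampled at the period, repeats exactly
  s <- gen$cd$samples
  expect_equal(s[1:300], s[301:600], tolerance = 1e-9)
})

test_that("reduced duty cycle introduces harmonic structure", {
  cfg <- simulation_config(100, 50, duration = 30, rate_jitter_cv = 0,
                           depth_jitter_cv = 0, duty_cycle = 0.7,
                           noise_std = 0, seed = 1)
  gen <- generate_displacement(cfg)
  n <- 300  # one 0.6 s cycle at 500 Hz
  X <- stats::fft(gen$cd$samples[1:n]) / n
  expect_gt(Mod(X[3]) / Mod(X[2]), 0.05)  # 2nd harmonic > 5% of fundamental
})

test_that("generation is seed-deterministic", {
  cfg <- simulation_config(120, 30, duration = 10, seed = 33)
  a <- generate_session(cfg)
  b <- generate_session(cfg)
  expect_identical(a$accel$samples, b$accel$samples)
  expect_identical(a$truth, b$truth)
  cfg2 <- simulation_config(120, 30, duration = 10, seed = 34)
  expect_false(identical(generate_session(cfg2)$truth, a$truth))
})

test_that("acceleration follows the closed-form second derivative", {
  # 50 mm peak-to-peak sinusoid at 2 Hz -> peak acceleration 3.948 m/s^2
  fs <- 500
  tt <- (0:(10 * fs - 1)) / fs
  cd <- disp_record(25 * sin(2 * pi * 2 * tt) + 25, fs)
  cfg <- simulation_config(120, 50, noise_std = 0, gravity = 0, seed = 1)
  acc <- displacement_to_acceleration(cd, cfg)
  pk <- max(abs(acc$samples[100:4900, 3]))
  expect_equal(pk, (2 * pi * 2)^2 * 0.025, tolerance = 0.005)
  expect_equal((2 * pi * 2)^2 * 0.025, 3.948, tolerance = 1e-3)
  # x and y stay silent without tilt or noise
  expect_equal(max(abs(acc$samples[, 1:2])), 0)
  expect_error(displacement_to_acceleration(disp_record(c(1, 2), fs), cfg),
               "3 displacement samples")
})

test_that("tilt rotates the compression axis into the x channel", {
  fs <- 500
  tt <- (0:(10 * fs - 1)) / fs
  cd <- disp_record(25 * sin(2 * pi * 2 * tt) + 25, fs)
  cfg0 <- simulation_config(120, 50, noise_std = 0, gravity = 0,
                            tilt_deg = 0, seed = 1)
  cfg18 <- simulation_config(120, 50, noise_std = 0, gravity = 0,
                             tilt_deg = 18, seed = 1)
  a0 <- displacement_to_acceleration(cd, cfg0)
  a18 <- displacement_to_acceleration(cd, cfg18)
  expect_equal(a18$samples[, 3], a0$samples[, 3] * cos(18 * pi / 180),
               tolerance = 1e-9)
  expect_equal(a18$samples[, 1], a0$samples[, 3] * sin(18 * pi / 180),
               tolerance = 1e-9)
  # zero displacement, gravity on: constant (0, 0, 9.81)
  cfgg <- simulation_config(120, 50, noise_std = 0, gravity = 9.81, seed = 1)
  ag <- displacement_to_acceleration(disp_record(rep(0, 100), fs), cfgg)
  expect_true(all(abs(sweep(ag$samples, 2, c(0, 0, 9.81))) < 1e-12))
})

test_that("double integration of clean compression-axis acceleration recovers the displacement", {
  cfg <- simulation_config(100, 50, duration = 12, noise_std = 0,
                           gravity = 0, tilt_deg = 0, seed = 9)
  ses <- generate_session(cfg)
  az <- ses$accel$samples[, 3]
  fs <- ses$accel$fs
  # integrate over 3 s spans with the true initial position and velocity
  # (central difference of the displacement at the span start)
  cd <- ses$cd$samples
  for (st in ses$truth$cycle_start[c(2, 8, 14)]) {
    i0 <- round(st * fs) + 1L
    idx <- i0:(i0 + 3 * fs - 1L)
    tt <- (seq_along(idx) - 1) / fs
    v0 <- (cd[i0 + 1L] - cd[i0 - 1L]) * fs / 2   # mm/s
    v <- pracma::cumtrapz(tt, az[idx])
    s <- pracma::cumtrapz(tt, as.numeric(v)) * 1000 + v0 * tt + cd[i0]
    expect_lt(max(abs(s - cd[idx])), 1)
  }
})

test_that("the benchmark design spans the full study grid", {
  des <- benchmark_design(seed = 1)
  expect_equal(nrow(des), 320)  # 20 rescuers x 4 rates x 2 depths x 2 kinds
  expect_equal(length(unique(des$rescuer_id)), 20)
  expect_setequal(unique(des$target_rate), c(80, 100, 120, 140))
  expect_setequal(unique(des$session_kind), c("regular", "tilt"))
  expect_true(all(des$tilt_deg[des$session_kind == "tilt"] == 18))
  # the programme implies ~35,000 compressions in total
  expect_equal(sum(des$duration * des$target_rate / 60), 35200)
  # per-rescuer skills are constant within rescuer, different across
  sk <- unique(des[, c("rescuer_id", "rate_jitter_cv", "depth_jitter_cv")])
  expect_equal(nrow(sk), 20)
  # determinism of the design under a fixed master seed
  expect_identical(des, benchmark_design(seed = 1))
  # a 1 x 1 x 1 grid yields a single record, and it materializes
  one <- benchmark_design(n_rescuers = 1, rates = 100, depths = 50,
                          sessions = "regular", duration = 8, seed = 2)
  expect_equal(nrow(one), 1)
  ses <- generate_benchmark(one)
  expect_length(ses, 1)
  expect_s3_class(ses[[1]]$accel, "accel_record")
  expect_equal(record_duration(ses[[1]]$accel), 8)
})
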