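test_that("sv_total is the per-sample Euclidean magnitude", {
  expect_equal(sv_total(static_trace(10)), rep(1, 10))
  tr <- accel_trace(0.6, 0.8, 0, fs = 200)
  expect_equal(sv_total(tr), 1)
  set.seed(11)
  rt <- random_trace(1000)
  expect_equal(sv_total(rt), sqrt(rt$ax^2 + rt$ay^2 + rt$az^2),
               tolerance = 1e-12)
})

test_that("cv_fast matches the brute-force sliding-window oracle", {
  # constant trace: no change anywhere
  expect_equal(cv_fast(static_trace(50)), rep(0, 50))
  # single-axis step of height delta: delta while the step straddles the
  # window, 0 before and after
  z <- c(rep(1, 40), rep(1.5, 40))
  tr <- accel_trace(rep(0, 80), rep(0, 80), z, fs = 200)
  cv <- cv_fast(tr, window_s = 0.1)   # 20-sample window
  expect_equal(cv[1:40], rep(0, 40))
  expect_equal(cv[41:59], rep(0.5, 19))
  expect_equal(cv[60:80], rep(0, 21))
  # random traces vs O(n*w) recomputation
  set.seed(21)
  for (rep_i in 1:10) {
    rt <- random_trace(300)
    w <- sample(2:40, 1)
    got <- cv_fast(rt, window_s = w / 200)
    want <- sqrt(naive_sliding_range(rt$ax, w)^2 +
                   naive_sliding_range(rt$ay, w)^2 +
                   naive_sliding_range(rt$az, w)^2)
    expect_equal(got, want, tolerance = 1e-12)
  }
  expect_error(cv_fast(static_trace(10), window_s = 0.004), "2 samples")
})

test_that("sv_d removes gravity and passes 5 Hz dynamics", {
  n <- 2000
  expect_lt(max(sv_d(static_trace(n))[600:n]), 0.01)
  t <- (0:(n - 1)) / 200
  for (a in c(0.1, 0.4, 0.8)) {
    tr <- accel_trace(rep(0, n), rep(0, n), 1 + a * sin(2 * pi * 5 * t),
                      fs = 200)
    expect_lt(abs(max(sv_d(tr)[600:n]) - a), 0.05 * a + 0.001)
  }
  expect_error(sv_d(static_trace(10), hp_cutoff_hz = 100), "cutoff")
})

test_that("vertical acceleration identities hold", {
  expect_equal(vertical_acceleration(1, 0), 0)
  expect_equal(vertical_acceleration(0, 0), -0.5)
  for (a in seq(0.1, 1, by = 0.1))
    expect_equal(vertical_acceleration(1 + a, a), a, tolerance = 1e-12)
  expect_error(vertical_acceleration(1:3, 1:2), "mismatch")
})

test_that("posture angle hits the canonical orientations and bounds", {
  n <- 1500
  expect_equal(posture_angle(static_trace(n))[n], 0, tolerance = 1e-6)
  lying <- static_trace(n, axis = c(1, 0, 0))
  expect_equal(posture_angle(lying)[n], 90, tolerance = 1e-6)
  inverted <- static_trace(n, axis = c(0, 0, -1))
  expect_equal(posture_angle(inverted)[n], 180, tolerance = 1e-6)
  # bounds on noisy random traces
  set.seed(31)
  for (i in 1:5) {
    ang <- posture_angle(random_trace(400))
    expect_true(all(ang >= 0 & ang <= 180))
  }
})

test_that("posture angle responds monotonically to a slow tilt", {
  fs <- 200
  n <- fs * 20
  th <- c(rep(0, fs * 5), seq(0, pi / 2, length.out = fs * 10),
          rep(pi / 2, fs * 5))
  tr <- accel_trace(sin(th), rep(0, n), cos(th), fs = fs)
  ang <- posture_angle(tr)
  idx <- seq(fs * 6, n, by = fs)        # after initial settle, 1 s apart
  expect_true(all(diff(ang[idx]) > -1))  # monotone up to filter lag wiggle
  expect_equal(ang[n], 90, tolerance = 3)
})

test_that("extract_features composes and preserves length", {
  tr <- static_trace(900, noise = 0.005)
  f <- extract_features(tr)
  expect_equal(nrow(f), 900)
  tail_i <- 700:900
  expect_equal(mean(f$sv_total[tail_i]), 1, tolerance = 0.01)
  expect_lt(max(f$cv_fast[tail_i]), 0.1)
  expect_lt(max(abs(f$va[tail_i])), 0.05)
  expect_lt(max(f$phi_z[tail_i]), 2)
  expect_equal(nrow(extract_features(accel_trace(numeric(0), numeric(0),
                                                 numeric(0)))), 0)
})

test_that("free-fall segments show the expected signature", {
  g <- generate_trial(3, seed = 99)
  f <- extract_features(g$trace)
  drop_i <- which(f$t >= g$annotation$start_s + 0.2 &
                    f$t <= g$annotation$start_s + 0.35)
  expect_lt(min(f$sv_total[drop_i]), 0.5)
  expect_lt(min(f$va[drop_i]), -0.25)
})

test_that("features are translation-invariant in time", {
  set.seed(41)
  n <- 800
  k <- 100
  base <- cbind(rnorm(n, 0, 0.1), rnorm(n, 0, 0.1), rnorm(n, 1, 0.1))
  shifted <- rbind(matrix(rep(base[1, ], k), k, byrow = TRUE), base)
  t1 <- accel_trace(base[, 1], base[, 2], base[, 3], fs = 200)
  t2 <- accel_trace(shifted[, 1], shifted[, 2], shifted[, 3], fs = 200)
  f1 <- extract_features(t1)
  f2 <- extract_features(t2)
  core <- 300:n    # outside edge windows and filter memory of the pad
  expect_equal(f2$cv_fast[core + k], f1$cv_fast[core], tolerance = 1e-9)
  expect_equal(f2$sv_total[core + k], f1$sv_total[core], tolerance = 1e-9)
  expect_equal(f2$va[core + k], f1$va[core], tolerance = 0.02)
  expect_equal(f2$phi_z[core + k], f1$phi_z[core], tolerance = 0.5)
})
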