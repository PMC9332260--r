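test_that("generators are reproducible: same seed and parameters, same output", {
  a <- sim_flash_trace(1, 10, 0.5, noise_sd = 0.05, dt = 0.01, duration = 5,
                       seed = 7)
  b <- sim_flash_trace(1, 10, 0.5, noise_sd = 0.05, dt = 0.01, duration = 5,
                       seed = 7)
  expect_identical(a$intensities, b$intensities)
  c <- sim_flash_trace(1, 10, 0.5, noise_sd = 0.05, dt = 0.01, duration = 5,
                       seed = 8)
  expect_false(identical(a$intensities, c$intensities))

  s1 <- sim_inactivation_series(k = 1, noise_sd = 0.02, seed = 3)
  s2 <- sim_inactivation_series(k = 1, noise_sd = 0.02, seed = 3)
  expect_identical(s1$R, s2$R)

  t1 <- sim_thermogram(320, 500, 600, noise_sd = 1, seed = 5)
  t2 <- sim_thermogram(320, 500, 600, noise_sd = 1, seed = 5)
  expect_identical(t1$Cp, t2$Cp)

  st <- toy_structure(10)
  tr1 <- sim_trajectory(st, 1, n_frames = 5, rigid_motion = TRUE, seed = 2)
  tr2 <- sim_trajectory(st, 1, n_frames = 5, rigid_motion = TRUE, seed = 2)
  expect_identical(tr1$frames, tr2$frames)
})

test_that("generators leave the caller's RNG stream untouched", {
  set.seed(123); r1 <- runif(1)
  set.seed(123)
  invisible(sim_flash_trace(1, 10, 0.5, noise_sd = 0.05, seed = 42))
  expect_identical(runif(1), r1)
})

test_that("flash trace has the closed-form peak and integral", {
  tr <- sim_flash_trace(1, 10, 0.5, noise_sd = 0, dt = 0.001, duration = 30)
  t_pk <- log(10 / 0.5) / (10 - 0.5)
  expect_equal(t_pk, 0.3153, tolerance = 1e-3)
  i <- which.max(tr$intensities)
  expect_equal(tr$times[i], t_pk, tolerance = 2e-3)
  expect_equal(max(tr$intensities), 0.8114, tolerance = 1e-3)
  expect_true(all(tr$intensities >= -1e-12))
  # single interior maximum: intensity increases before, decreases after
  expect_true(all(diff(tr$intensities[1:i]) > 0))
  expect_true(all(diff(tr$intensities[i:length(tr$times)]) < 0))
  # integral = amplitude (1/k_decay - 1/k_rise)
  expect_equal(pracma::trapz(tr$times, tr$intensities), 1 / 0.5 - 1 / 10,
               tolerance = 1e-3)
})

test_that("flash generator flags degenerate and trivial parameter sets", {
  expect_error(sim_flash_trace(1, 0.5, 10), "k_rise")
  z <- sim_flash_trace(0, 10, 0.5, noise_sd = 0, dt = 0.01, duration = 2)
  expect_true(all(z$intensities == 0))
})

test_that("noise-free flash tail log-slope equals -k_decay", {
  for (kd in c(0.32, 0.21)) {
    tr <- sim_flash_trace(1, 10, kd, noise_sd = 0, dt = 0.01, duration = 40)
    tail_idx <- tr$times > 5 & tr$intensities > 0
    sl <- coef(lm(log(tr$intensities[tail_idx]) ~ tr$times[tail_idx]))[2]
    expect_equal(unname(sl), -kd, tolerance = 1e-6)
  }
})

test_that("inactivation series honours lag, half-life and plateau", {
  s <- sim_inactivation_series(k = 0.693, t_lag = 2, noise_sd = 0,
                               times = c(0, 1, 2, 3, 4))
  expect_equal(s$R[1], 100)
  expect_true(all(s$R[s$times <= 2] == 100))
  expect_equal(s$R[s$times == 3], 50, tolerance = 1e-3)  # one half-life past lag
  expect_true(all(diff(s$R) <= 0))
  expect_error(sim_inactivation_series(k = 1, times = numeric(0)), "empty")
  expect_error(sim_inactivation_series(k = -1), "positive")
  expect_error(sim_inactivation_series(k = 1, plateau_frac = 1), "plateau")
})

test_that("thermogram excess term integrates to dH_cal and alpha(T_m) = 1/2", {
  Tg <- seq(280, 360, 0.02)
  ts <- two_state_excess_cp(Tg, 320.1, 552, 700)
  expect_equal(pracma::trapz(Tg, ts$Cp_exc), 552, tolerance = 0.5 / 552)
  expect_equal(approx(Tg, ts$alpha, xout = 320.1)$y, 0.5, tolerance = 1e-6)
  # area is invariant to the baseline choice (baselines add on top)
  tg1 <- sim_thermogram(320.1, 552, 700, native_baseline = c(0, 0),
                        denatured_baseline = c(0, 0), noise_sd = 0,
                        T_grid = Tg)
  tg2 <- sim_thermogram(320.1, 552, 700, native_baseline = c(40, 0.1),
                        denatured_baseline = c(55, 0.05), noise_sd = 0,
                        T_grid = Tg)
  bn <- 40 + 0.1 * (Tg - 320.1); bd <- 55 + 0.05 * (Tg - 320.1)
  blend <- (1 - ts$alpha) * bn + ts$alpha * bd
  expect_equal(tg2$Cp - blend, tg1$Cp, tolerance = 1e-8)
})

test_that("larger van't Hoff enthalpy sharpens and heightens the peak", {
  Tg <- seq(300, 340, 0.01)
  w <- sapply(c(400, 800), function(h) {
    y <- two_state_excess_cp(Tg, 320, 500, h)$Cp_exc
    half <- max(y) / 2
    rng <- range(Tg[y >= half])
    c(width = diff(rng), height = max(y))
  })
  expect_lt(w["width", 2], w["width", 1])
  expect_gt(w["height", 2], w["height", 1])
})

test_that("thermogram generator warns when the grid truncates the peak", {
  expect_warning(sim_thermogram(400, 500, 600, T_grid = seq(290, 350, 0.1)),
                 "truncated")
})

test_that("zero-amplitude trajectories are exact copies or rigid transforms", {
  st <- toy_structure(12)
  tr <- sim_trajectory(st, 0, n_frames = 4, rigid_motion = FALSE, seed = 1)
  for (f in tr$frames) expect_equal(f, coords(st), tolerance = 1e-12)
  trr <- sim_trajectory(st, 0, n_frames = 4, rigid_motion = TRUE, seed = 1)
  for (f in trr$frames) {
    expect_lt(kabsch_superpose(f, coords(st))$rmsd, 1e-9)
    expect_gt(sqrt(mean(rowSums((f - coords(st))^2))), 0.1)  # actually moved
  }
})

test_that("trajectory generator invariants are enforced", {
  st <- toy_structure(5)
  expect_error(sim_trajectory(st, -1), "non-negative")
  expect_error(sim_trajectory(st, 1, n_frames = 1), "2 frames")
  expect_error(sim_solvated_trajectory(st, cosolvent_count = 0), "positive")
  expect_error(sim_solvated_trajectory(st, cosolvent_count = 10, box = 3),
               "box too small")
  expect_error(sim_solvated_trajectory(st, cosolvent_count = 10,
                                       enrichment = c("3" = 0.5)), ">= 1")
})
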