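test_that("fixed seed gives bit-identical simulator output", {
  p <- study_params()
  a <- simulate_end_dynamics(p, duration = 50, seed = 99)
  b <- simulate_end_dynamics(p, duration = 50, seed = 99)
  expect_identical(a$frames, b$frames)
  expect_identical(a$events, b$events)
  ta <- render_intensity_trace(a, seed = 7)
  tb <- render_intensity_trace(b, seed = 7)
  expect_identical(ta$intensity_au, tb$intensity_au)
  va <- simulate_velocity_dataset(c(1e-8, 1e-7), study_mm(), seed = 3)
  vb <- simulate_velocity_dataset(c(1e-8, 1e-7), study_mm(), seed = 3)
  expect_identical(va, vb)
})

test_that("dwell and gap statistics match the generative rate constants", {
  # long run at 83 nM: >= 5000 events
  p <- study_params()
  traj <- simulate_end_dynamics(p, duration = 20000, noise_sd = 0, seed = 12)
  ev <- traj$events
  expect_gt(nrow(ev), 5000)
  dwell <- ev$unbind_time_s - ev$bind_time_s
  dwell <- dwell[-nrow(ev)]  # last may be censored at duration
  expect_lt(abs(mean(dwell) - 1 / 0.45), 3 * sd(dwell) / sqrt(length(dwell)))
  gaps <- ev$bind_time_s[-1] - ev$unbind_time_s[-nrow(ev)]
  m_true <- 1 / (1.1e7 * 83e-9)
  expect_lt(abs(mean(gaps) - m_true), 3 * sd(gaps) / sqrt(length(gaps)))
  # bind/unbind strictly interleaved within the record
  expect_true(all(ev$bind_time_s < ev$unbind_time_s))
  expect_true(all(diff(as.vector(rbind(ev$bind_time_s, ev$unbind_time_s))) > 0))
})

test_that("ergodic mean velocity matches the closed-form prediction", {
  p <- study_params(productive_fraction = 0.8)
  traj <- simulate_end_dynamics(p, duration = 10000, noise_sd = 0, seed = 21)
  fr <- traj$frames
  v_emp <- (fr$length_true[1] - fr$length_true[nrow(fr)]) /
    (fr$time_s[nrow(fr)] - fr$time_s[1])
  # SE of the time-averaged rate: Poisson count noise plus state switching;
  # bound below by the Poisson term, use 3x a generous switching-aware SE
  removed <- fr$length_true[1] - fr$length_true[nrow(fr)]
  se <- sqrt(removed) / 10000 + 53 * sqrt(2 * 2.2 * 0.67 * 0.33 / 10000)
  expect_lt(abs(v_emp - predicted_mean_velocity(p)), 3 * se)
})

test_that("degenerate simulator inputs behave as promised", {
  # c = 0: permanently unbound, control-rate depolymerization
  p0 <- kinetic_params(1.1e7, 0.45, 0, v_bound = 53, v_unbound = 0.14)
  traj <- simulate_end_dynamics(p0, duration = 10000, noise_sd = 0, seed = 2)
  expect_identical(nrow(traj$events), 0L)
  expect_false(any(traj$frames$bound_truth))
  v <- (traj$frames$length_true[1] - utils::tail(traj$frames$length_true, 1)) / 10000
  expect_equal(v, 0.14, tolerance = 0.1)
  # both velocities zero: constant length
  pz <- kinetic_params(1.1e7, 0.45, 83e-9, v_bound = 0, v_unbound = 0)
  tz <- simulate_end_dynamics(pz, duration = 100, noise_sd = 0, seed = 3)
  expect_true(all(tz$frames$length_true == tz$frames$length_true[1]))
  # length_true never increases
  p <- study_params()
  tr <- simulate_end_dynamics(p, duration = 200, seed = 4)
  expect_true(all(diff(tr$frames$length_true) <= 0))
  # observation noise is zero-mean at the configured sd
  resid <- tr$frames$length_observed - tr$frames$length_true
  expect_lt(abs(mean(resid)), 3 * 10 / sqrt(length(resid)))
  expect_equal(sd(resid), 10, tolerance = 0.1)
})

test_that("rendered traces expose only labeled events, at fraction f", {
  p <- study_params()
  lab <- labeling_model(f = 0.779)
  traj <- simulate_end_dynamics(p, duration = 12000, labeling = lab,
                                noise_sd = 0, seed = 31)
  ev <- traj$events
  expect_gt(nrow(ev), 2000)
  vis <- mean(ev$n_dyes > 0)
  se <- sqrt(0.779 * 0.221 / nrow(ev))
  expect_lt(abs(vis - 0.779), 3 * se)
  # noiseless, bleach-free render is a staircase matching truth exactly
  short <- simulate_end_dynamics(p, duration = 60, labeling = lab,
                                 noise_sd = 0, seed = 32)
  tr <- render_intensity_trace(short, unit_intensity = 100, k_bleach = 0,
                               noise_sd = 0, seed = 33)
  expect_true(all(tr$intensity_au[!tr$truth_occupied] == 0))
  expect_true(all(tr$intensity_au[tr$truth_occupied] >= 100))
  expect_true(all(tr$intensity_au %% 100 == 0))
  # zero-dye-only events give a pure-noise trace
  lab0 <- labeling_model(p_site = 0)
  t0 <- simulate_end_dynamics(p, duration = 60, labeling = lab0,
                              noise_sd = 0, seed = 34)
  r0 <- render_intensity_trace(t0, unit_intensity = 100, k_bleach = 0,
                               noise_sd = 5, seed = 35)
  expect_false(any(r0$truth_occupied))
  expect_lt(max(abs(r0$intensity_au)), 5 * 5)
  expect_error(render_intensity_trace(short, noise_sd = -1), "nonnegative")
})

test_that("photobleach staircases have zero-truncated binomial dye counts", {
  lab <- labeling_model(f = 0.779)
  traces <- simulate_photobleach_traces(2000, lab, seed = 41)
  counts <- vapply(traces, attr, 0L, "true_steps")
  expect_true(all(counts >= 1 & counts <= 6))
  # exact enumeration oracle for the zero-truncated Binomial(6, p)
  k <- 1:6
  expected <- dbinom(k, 6, lab$p_site) / (1 - dbinom(0, 6, lab$p_site))
  obs <- tabulate(counts, 6)
  expect_gt(suppressWarnings(chisq.test(obs, p = expected)$p.value), 0.001)
  expect_equal(dye_count_distribution(lab)$prob, expected)
  # p_site = 1: all six dyes, six steps
  all6 <- simulate_photobleach_traces(10, labeling_model(p_site = 1), seed = 5)
  expect_true(all(vapply(all6, attr, 0L, "true_steps") == 6L))
  # modal dye count at the study labeling level is 1 (most have 1-2 dyes)
  expect_equal(which.max(expected), 1L)
  expect_gt(sum(expected[1:2]), 0.75)
})

test_that("velocity datasets follow the saturation curve", {
  fit <- study_mm()
  # zero noise: exact curve
  v0 <- simulate_velocity_dataset(c(10, 150, 500) * 1e-9, fit, noise_cv = 0,
                                  n_per_c = 2, seed = 6)
  expect_equal(v0$velocity_subunits_per_s,
               mm_velocity(v0$conc_M, fit), tolerance = 1e-12)
  # closed-form mean at 150 nM is ~39.8
  expect_equal(mm_velocity(150e-9, fit), 39.75)
  vn <- simulate_velocity_dataset(150e-9, fit, noise_cv = 0.15,
                                  n_per_c = 400, seed = 7)
  expect_equal(mean(vn$velocity_subunits_per_s), 39.75, tolerance = 0.03)
  # saturation: mean -> k_cat
  vs <- simulate_velocity_dataset(1e-4, fit, noise_cv = 0.05, n_per_c = 200,
                                  seed = 8)
  expect_equal(mean(vs$velocity_subunits_per_s), 53, tolerance = 0.02)
  expect_error(simulate_velocity_dataset(numeric(0), fit), "nonempty")
})

test_that("rendered movies track the pointed end at the right pixel rate", {
  # static filament, no noise: identical frames
  pz <- kinetic_params(0, 0.45, 0, v_bound = 0, v_unbound = 0)
  tz <- simulate_end_dynamics(pz, duration = 2, noise_sd = 0, length0 = 300,
                              seed = 51)
  mz <- render_movie(tz, frame_stride = 10, shot_noise = FALSE, seed = 52)
  expect_true(all(mz$actin[, , 1] == mz$actin[, , dim(mz$actin)[3]]))
  # 43.9 subunits/s -> 43.9 * 2.7 / 130 ~ 0.91 px/s of end regression
  expect_equal(43.9 * 2.7 / 130, 0.912, tolerance = 1e-3)
  p <- kinetic_params(1e9, 1e-9, 1e-3, v_bound = 43.9, v_unbound = 0)
  tr <- simulate_end_dynamics(p, duration = 15, noise_sd = 0, length0 = 1200,
                              labeling = labeling_model(p_site = 1), seed = 53)
  mv <- render_movie(tr, frame_stride = 10, seed = 54)
  px_rate <- coef(lm(x_px ~ time_s, mv$end_track))[2]
  realized <- fit_trajectory_velocity(tr)$velocity_subunits_per_s
  expect_equal(unname(px_rate), realized * 2.7 / 130, tolerance = 0.02)
  # empty (fully depolymerized) trajectory renders background only
  t0 <- simulate_end_dynamics(pz, duration = 1, noise_sd = 0, length0 = 1,
                              seed = 55)
  m0 <- render_movie(t0, shot_noise = FALSE, seed = 56)
  expect_lt(max(m0$spot), 10 + 1e-9)
})
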