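test_that("spot extraction removes flat background exactly and finds spots", {
  # uniform image: 5x5 sum minus 25 x perimeter median is exactly zero
  st <- array(13.7, dim = c(25, 40, 4))
  pos <- data.frame(frame = 1:4, x_px = 20, y_px = 13)
  tr <- extract_spot_intensity(st, pos, frame_interval_s = 0.5)
  expect_equal(tr$intensity_au, rep(0, 4))
  expect_equal(frame_interval(tr), 0.5)

  # forward-rendered Gaussian spot of known integrated signal on background
  sig <- 1; amp <- 500
  g <- outer(1:25, 1:40, function(y, x) {
    amp * exp(-((y - 13)^2 + (x - 20)^2) / (2 * sig^2))
  })
  total <- sum(g[11:15, 18:22])
  st2 <- array(rep(g + 50, 2), dim = c(25, 40, 2))
  tr2 <- extract_spot_intensity(st2, data.frame(frame = 1:2, x_px = 20, y_px = 13))
  expect_equal(tr2$intensity_au[1], total, tolerance = 0.01)

  # spot at the frame edge: missing value, not an exception
  pos_edge <- data.frame(frame = 1:2, x_px = c(20, 3), y_px = 13)
  expect_message(tr3 <- extract_spot_intensity(st2, pos_edge), "NA")
  expect_false(is.na(tr3$intensity_au[1]))
  expect_true(is.na(tr3$intensity_au[2]))
})

test_that("Savitzky-Golay smoothing preserves polynomials and damps noise", {
  n <- 400
  const <- capdep:::new_intensity_trace((0:(n - 1)) * 0.065, rep(5, n), 0.065)
  expect_equal(smooth_trace(const)$intensity_au, rep(5, n))
  ramp <- capdep:::new_intensity_trace((0:(n - 1)) * 0.065, seq(0, 10, length.out = n), 0.065)
  sm <- smooth_trace(ramp)
  inner <- 6:(n - 5)
  expect_equal(sm$intensity_au[inner], ramp$intensity_au[inner], tolerance = 1e-8)

  # window: 0.71 s at 0.065 s/frame is 11 frames; variance reduction equals
  # the sum of squared central filter weights (direct convolution oracle)
  expect_identical(capdep:::sg_window_frames(0.71, 0.065), 11L)
  w <- signal::sgolay(p = 2, n = 11)[6, ]
  noise <- withr::with_seed(8, rnorm(20000))
  tr <- capdep:::new_intensity_trace(seq_along(noise) * 0.065, noise, 0.065)
  ratio <- var(smooth_trace(tr)$intensity_au[100:19900]) / var(noise)
  expect_equal(ratio, sum(w^2), tolerance = 0.05)

  short <- capdep:::new_intensity_trace((0:5) * 0.065, rnorm(6), 0.065)
  expect_error(smooth_trace(short), "shorter")
})

test_that("dwell detection is exact on noiseless staircases", {
  # one 50-frame plateau
  lev <- c(rep(0, 40), rep(1, 50), rep(0, 40))
  dw <- detect_dwells(staircase_trace(lev))
  expect_identical(nrow(dw$dwells), 1L)
  expect_equal(dw$dwells$duration_s, 50 * 0.065)
  expect_equal(dw$dwells$start_s, 40 * 0.065)

  # boundary contract of the "> four frames" filter
  four <- c(rep(0, 30), rep(1, 4), rep(0, 30))
  expect_identical(nrow(detect_dwells(staircase_trace(four))$dwells), 0L)
  five <- c(rep(0, 30), rep(1, 5), rep(0, 30))
  expect_identical(nrow(detect_dwells(staircase_trace(five))$dwells), 1L)

  # multi-level events (different dye counts) both detected, boundaries exact
  lev2 <- c(rep(0, 30), rep(3, 20), rep(0, 25), rep(1, 12), rep(0, 30))
  dw2 <- detect_dwells(staircase_trace(lev2))
  expect_identical(nrow(dw2$dwells), 2L)
  expect_equal(dw2$dwells$duration_s, c(20, 12) * 0.065)
  expect_equal(dw2$gaps, 25 * 0.065)

  # censored runs at the trace ends are not counted
  lev3 <- c(rep(1, 20), rep(0, 40), rep(1, 10), rep(0, 40), rep(1, 20))
  dw3 <- detect_dwells(staircase_trace(lev3))
  expect_identical(nrow(dw3$dwells), 1L)

  # constant trace: zero dwells with a warning
  expect_warning(d0 <- detect_dwells(staircase_trace(rep(1, 100))), "Degenerate")
  expect_identical(nrow(d0$dwells), 0L)
})

test_that("detection is invariant to a constant intensity offset", {
  p <- study_params()
  traj <- simulate_end_dynamics(p, duration = 150, seed = 61)
  tr <- render_intensity_trace(traj, seed = 62)
  sm <- smooth_trace(tr)
  shifted <- sm
  shifted$intensity_au <- sm$intensity_au + 5000
  a <- detect_dwells(sm); b <- detect_dwells(shifted)
  expect_identical(a$dwells, b$dwells)
  expect_identical(a$gaps, b$gaps)
})

test_that("detected dwell boundaries track ground truth on clean renders", {
  p <- study_params(c = 8.3e-9)  # sparse events, no merging ambiguity
  lab <- labeling_model(p_site = 0.999999)
  traj <- simulate_end_dynamics(p, duration = 400, labeling = lab, seed = 63)
  tr <- render_intensity_trace(traj, k_bleach = 0, noise_sd = 2, seed = 64)
  dw <- detect_dwells(smooth_trace(tr))
  ev <- traj$events
  dt <- traj$frame_interval
  # every long *isolated* interior event (no neighbor within one smoothing
  # window, so no merging ambiguity) must be found with boundaries within a
  # couple of frames; every detected dwell must overlap a real event
  gap_prev <- c(Inf, ev$bind_time_s[-1] - ev$unbind_time_s[-nrow(ev)])
  gap_next <- c(ev$bind_time_s[-1] - ev$unbind_time_s[-nrow(ev)], Inf)
  long <- ev[ev$unbind_time_s - ev$bind_time_s >= 7 * dt &
             ev$unbind_time_s < 400 - dt & ev$bind_time_s > dt &
             gap_prev > 1 & gap_next > 1, ]
  match_err <- vapply(seq_len(nrow(long)), function(j) {
    ds <- abs(dw$dwells$start_s - long$bind_time_s[j])
    de <- abs(dw$dwells$end_s - long$unbind_time_s[j])
    min(ds + de)
  }, numeric(1))
  expect_true(all(match_err < 2 * 2.5 * dt))
  matched_ev <- vapply(seq_len(nrow(dw$dwells)), function(j) {
    any(dw$dwells$start_s[j] < ev$unbind_time_s &
        dw$dwells$end_s[j] > ev$bind_time_s)
  }, logical(1))
  expect_true(all(matched_ev))
  expect_gte(nrow(dw$dwells), nrow(long))
})

test_that("k_off estimation recovers the dissociation rate from dwells", {
  # exact inputs: all dwells equal tau gives k_off = 1/tau with zero SE
  mk <- function(durations, gaps = numeric(0)) {
    ds <- list(dwells = tibble::tibble(
      start_s = cumsum(c(0, utils::head(durations, -1) + 1)),
      end_s = cumsum(c(0, utils::head(durations, -1) + 1)) + durations,
      duration_s = durations),
      gaps = gaps, mean_dwell = mean(durations),
      m_prime = if (length(gaps)) mean(gaps) else NA_real_,
      n_censored = 0L, min_frames = 4L, frame_interval = 0.065,
      policy = NULL)
    class(ds) <- "dwell_set"
    ds
  }
  est <- estimate_koff(mk(rep(2.5, 10)))
  expect_equal(est$k_off, 1 / 2.5)
  expect_equal(est$se, 0)
  expect_equal(est$k_off_ml, 1 / 2.5, tolerance = 1e-6)

  # pooled mean of 2.2 s gives the printed 0.45 /s
  d <- withr::with_seed(9, rexp(126, 0.45))
  d <- d * 2.2 / mean(d)
  expect_equal(estimate_koff(mk(d))$k_off, 0.4545, tolerance = 1e-3)

  # sampling oracle at n = 126
  d2 <- withr::with_seed(10, rexp(126, 0.45))
  expect_lt(abs(estimate_koff(mk(d2))$k_off - 0.45), 3 * 0.45 / sqrt(126))
  expect_error(estimate_koff(mk(numeric(0))), "2 pooled")

  # simulated traces at high SNR: mean dwell within 3 SE of 1/0.45 after
  # accounting for the detector's lower cutoff
  p <- study_params()
  dws <- lapply(1:3, function(i) {
    traj <- simulate_end_dynamics(p, duration = 400, seed = 70 + i)
    tr <- render_intensity_trace(traj, k_bleach = 0, noise_sd = 5,
                                 seed = 80 + i)
    detect_dwells(smooth_trace(tr))
  })
  est2 <- estimate_koff(dws, min_dwell_s = 4 * 0.065)
  expect_lt(abs(est2$k_off - 0.45), 3 * est2$se + 0.45 * 0.1)
})

test_that("k_on estimation applies the labeling correction correctly", {
  gaps <- withr::with_seed(11, rexp(300, 1))
  gaps <- gaps * 2.0365 / mean(gaps)
  ds <- list(dwells = tibble::tibble(start_s = seq_along(gaps) * 10,
                                     end_s = seq_along(gaps) * 10 + 2,
                                     duration_s = rep(2, length(gaps))),
             gaps = gaps, mean_dwell = 2, m_prime = mean(gaps),
             n_censored = 0L, min_frames = 4L, frame_interval = 0.065,
             policy = NULL)
  class(ds) <- "dwell_set"
  est <- estimate_kon(ds, f = 0.779, k_off = 0.45, c = 83e-9)
  expect_equal(est$k_on, 1.1e7, tolerance = 1e-3)
  # f = 1 reduces to 1/(m' c)
  est1 <- estimate_kon(ds, f = 1, k_off = 0.45, c = 83e-9)
  expect_equal(est1$k_on, 1 / (mean(gaps) * 83e-9))
  expect_error(estimate_kon(ds, f = 0.2, k_off = 0.1, c = 83e-9),
               "Inconsistent")
})

test_that("estimator chain converges to generative constants as noise drops", {
  # full simulate -> render -> detect -> estimate at three noise levels,
  # with near-complete labeling; recovered k_on approaches truth
  p <- study_params()
  lab <- labeling_model(f = 0.9999)
  err <- vapply(c(40, 10, 2), function(ns) {
    dws <- lapply(1:2, function(i) {
      traj <- simulate_end_dynamics(p, duration = 600, labeling = lab,
                                    seed = 100 + i)
      tr <- render_intensity_trace(traj, k_bleach = 0, noise_sd = ns,
                                   seed = 120 + i)
      detect_dwells(smooth_trace(tr))
    })
    est <- estimate_kon(dws, f = lab$f, k_off = 0.45, c = 83e-9,
                        min_dwell_s = 4 * 0.065)
    abs(est$k_on - 1.1e7) / 1.1e7
  }, numeric(1))
  expect_lt(err[3], 0.25)
  # and at the lowest noise the full-chain k_on is within 3 SE of truth
  dws <- lapply(1:4, function(i) {
    traj <- simulate_end_dynamics(p, duration = 600, labeling = lab,
                                  seed = 140 + i)
    tr <- render_intensity_trace(traj, k_bleach = 0, noise_sd = 2,
                                 seed = 160 + i)
    detect_dwells(smooth_trace(tr))
  })
  est <- estimate_kon(dws, f = lab$f, k_off = 0.45, c = 83e-9,
                      min_dwell_s = 4 * 0.065)
  expect_lt(abs(est$k_on - 1.1e7), 3 * est$se + 0.1 * 1.1e7)
})

test_that("the labeling correction removes the incomplete-labeling bias", {
  # 20 seeded replicates of the thinned-gap process: uncorrected 1/(m'c)
  # underestimates k_on by the predicted factor; corrected mean is unbiased
  k_on <- 1.1e7; c <- 83e-9; k_off <- 0.45; f <- 0.779
  m <- 1 / (k_on * c)
  m_prime_expected <- (m + (1 - f) / k_off) / f
  reps <- vapply(1:20, function(r) {
    obs <- simulate_thinned_gaps(1200, k_on, c, k_off, f, seed = 200 + r)
    c(mean(obs), correct_interevent_time(mean(obs), f, k_off))
  }, numeric(2))
  # uncorrected estimate biased low by the predicted factor m/m'
  kon_uncorr <- 1 / (mean(reps[1, ]) * c)
  expect_equal(kon_uncorr / k_on, m / m_prime_expected, tolerance = 0.05)
  # corrected estimate unbiased within 3 SE of the replicate mean
  se_rep <- sd(reps[2, ]) / sqrt(20)
  expect_lt(abs(mean(reps[2, ]) - m), 3 * se_rep)
})
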