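# Shared fixtures, all built in code.

study_params <- function(c = 83e-9, v_bound = 53, v_unbound = 0.43,
                         productive_fraction = 1) {
  kinetic_params(k_on = 1.1e7, k_off = 0.45, c = c, v_bound = v_bound,
                 v_unbound = v_unbound,
                 productive_fraction = productive_fraction)
}

study_mm <- function() mm_params(k_cat = 53, K_M = 50e-9,
                                 se_k_cat = 8, se_K_M = 10e-9)

# a noiseless intensity trace from frame-level occupancy
staircase_trace <- function(levels, frame_interval = 0.065, unit = 200) {
  capdep:::new_intensity_trace(
    time_s = (seq_along(levels) - 1) * frame_interval,
    intensity_au = levels * unit,
    frame_interval = frame_interval,
    unit_intensity = unit
  )
}

# alternating exponential binding/unbinding schedule with label thinning;
# independent brute-force oracle for the inter-event-gap correction
simulate_thinned_gaps <- function(n_events, k_on, c, k_off, f, seed) {
  withr::with_seed(seed, {
    gaps <- rexp(n_events, k_on * c)
    dwells <- rexp(n_events, k_off)
    visible <- runif(n_events) < f
    # observed gap between consecutive visible events: sum of skipped
    # (gap + dwell) pairs plus the final gap
    obs <- numeric(0)
    acc <- 0
    started <- FALSE
    for (i in seq_len(n_events)) {
      acc <- acc + gaps[i]
      if (visible[i]) {
        if (started) obs <- c(obs, acc)
        acc <- 0
        started <- TRUE
      } else {
        acc <- acc + dwells[i]
      }
    }
    obs
  })
}
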