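#' Extract a background-corrected spot intensity trace from an image stack
#'
#' Per frame, sums pixel intensities in a 5 x 5 box centred on the tracked
#' pointed-end position and subtracts an equal-area local background: 25
#' times the median of the 72 pixels on the perimeter of a 19 x 19 square
#' centred on the same position. Positions closer than 9 pixels to any
#' image edge give a missing value for that frame (not an error).
#'
#' @param stack numeric array (ny, nx, n_frames) or a `rendered_movie`
#'   channel; if a `rendered_movie` is given its `spot` channel is used.
#' @param positions tibble/data frame with one row per frame: `frame`,
#'   `x_px`, `y_px` (positions rounded to the nearest pixel). Defaults to a
#'   movie's own `end_track`.
#' @param frame_interval_s frame time; taken from the movie when available.
#' @param box half-widths are fixed by the measurement design (5 x 5 signal
#'   box inside a 19 x 19 background square); exposed for completeness.
#' @param bg_box side of the background square.
#'
#' @return An `intensity_trace` with `NA` intensity at out-of-bounds frames.
#' @export
extract_spot_intensity <- function(stack, positions = NULL,
                                   frame_interval_s = NULL,
                                   box = 5L, bg_box = 19L) {
  if (inherits(stack, "rendered_movie")) {
    if (is.null(positions)) positions <- stack$end_track
    if (is.null(frame_interval_s)) frame_interval_s <- stack$frame_interval_s
    stack <- stack$spot
  }
  stopifnot(is.array(stack), length(dim(stack)) == 3L, !is.null(positions))
  if (is.null(frame_interval_s)) frame_interval_s <- 1
  ny <- dim(stack)[1]; nx <- dim(stack)[2]; nfr <- dim(stack)[3]
  hw <- box %/% 2L          # 2 for 5x5
  bhw <- bg_box %/% 2L      # 9 for 19x19

  n_missing <- 0L
  vals <- vapply(seq_len(nfr), function(i) {
    row <- positions[positions$frame == i, , drop = FALSE]
    if (nrow(row) == 0) return(NA_real_)
    x <- round(row$x_px[1]); y <- round(row$y_px[1])
    if (x - bhw < 1 || x + bhw > nx || y - bhw < 1 || y + bhw > ny) {
      n_missing <<- n_missing + 1L
      return(NA_real_)
    }
    frame <- stack[, , i]
    sig <- sum(frame[(y - hw):(y + hw), (x - hw):(x + hw)])
    ring <- frame[(y - bhw):(y + bhw), (x - bhw):(x + bhw)]
    perim <- c(ring[1, ], ring[nrow(ring), ],
               ring[2:(nrow(ring) - 1), 1], ring[2:(nrow(ring) - 1), ncol(ring)])
    sig - box^2 * stats::median(perim)
  }, numeric(1))
  if (n_missing > 0) {
    message(n_missing, " frame(s) too close to the image edge; set to NA.")
  }
  times <- (seq_len(nfr) - 1L) * frame_interval_s
  new_intensity_trace(times, vals, frame_interval_s)
}

#' Savitzky-Golay smoothing of an intensity trace
#'
#' Polynomial moving-window smoothing with a window of `window_s` seconds,
#' converted to the nearest odd frame count (11 frames for 0.71 s at
#' 0.065 s/frame). A second-order filter reproduces constants and linear
#' ramps exactly while attenuating white noise by the sum of squared filter
#' weights.
#'
#' @param trace an `intensity_trace`.
#' @param window_s smoothing window in seconds.
#' @param order polynomial order (default 2).
#'
#' @return The smoothed `intensity_trace` (same grid).
#' @export
smooth_trace <- function(trace, window_s = 0.71, order = 2L) {
  fi <- frame_interval(trace)
  nwin <- sg_window_frames(window_s, fi)
  if (nwin < order + 2) {
    stop("Smoothing window must cover at least order + 2 frames.", call. = FALSE)
  }
  x <- trace$intensity_au
  if (length(x) < nwin) {
    stop("Trace shorter than the smoothing window.", call. = FALSE)
  }
  sm <- signal::sgolayfilt(x, p = order, n = nwin)
  out <- trace
  out$intensity_au <- sm
  out
}

# nearest odd frame count to window_s / frame_interval
sg_window_frames <- function(window_s, frame_interval) {
  n <- round(window_s / frame_interval)
  n <- max(n, 1)
  if (n %% 2 == 0) {
    # of the two flanking odd counts, pick the closer to the exact ratio
    lo <- n - 1; hi <- n + 1
    n <- if (abs(lo - window_s / frame_interval) <=
             abs(hi - window_s / frame_interval)) lo else hi
  }
  as.integer(max(n, 3))
}

#' Threshold policy for dwell detection
#'
#' The detector calls a frame "occupied" once the (smoothed) intensity rises
#' above `background + enter_sd * background_sd` and keeps the dwell open
#' until it falls below `background + exit_sd * background_sd` (hysteresis).
#' The background level and spread are estimated per trace from the lowest
#' mode of the intensity density (the occupied state is itself multimodal,
#' 1-6 dyes, so a two-cluster model would misplace the background); this
#' works for traces that spend a detectable fraction of frames unoccupied.
#' A trace whose maximum stays within what the extreme-value statistics of
#' pure background noise would produce (`sqrt(2 log n)` plus
#' `min_separation_sd` background sds) is declared featureless and yields
#' no dwells.
#'
#' @param enter_sd,exit_sd entry/exit thresholds in background sd units.
#' @param min_separation_sd extra signal margin, in background sds, a trace
#'   maximum must clear beyond the expected background extreme before any
#'   dwell is called.
#' @param refine_half_amplitude logical; after hysteresis detection, refine
#'   each dwell boundary to the half-amplitude crossing, which removes the
#'   asymmetric edge dilation the smoothing window would otherwise cause.
#' @return A `dwell_threshold_policy` list.
#' @export
dwell_threshold <- function(enter_sd = 3, exit_sd = 1.5,
                            min_separation_sd = 4,
                            refine_half_amplitude = TRUE) {
  structure(list(enter_sd = enter_sd, exit_sd = exit_sd,
                 min_separation_sd = min_separation_sd,
                 refine_half_amplitude = refine_half_amplitude),
            class = "dwell_threshold_policy")
}

#' Detect single-molecule dwells in a (smoothed) intensity trace
#'
#' Groups supra-threshold frames into maximal runs with hysteresis, bridges
#' up to `na_tolerance` consecutive missing frames inside a run, optionally
#' refines boundaries to half-amplitude crossings, and keeps only runs
#' strictly longer than `min_frames` frames as true binding events (the
#' "> four frames" filter; a 4-frame run is rejected, a 5-frame run kept).
#' Runs touching the first or last frame are censored: they are excluded
#' from the mean dwell, and only gaps between two complete interior dwells
#' enter the gap statistics.
#'
#' @param trace an `intensity_trace` (smooth first with [smooth_trace()]).
#' @param threshold_policy a [dwell_threshold()] policy, or a single numeric
#'   intensity threshold (then used for both entry and exit).
#' @param min_frames dwell-length cutoff in frames; runs must exceed this.
#' @param na_tolerance maximum consecutive missing frames bridged inside a
#'   dwell before the run is split.
#'
#' @return A `dwell_set`: list with `dwells` (tibble `start_s`, `end_s`,
#'   `duration_s`), `gaps` (seconds), `mean_dwell`, `m_prime`, counts of
#'   censored dwells, and the detection settings.
#' @export
detect_dwells <- function(trace, threshold_policy = dwell_threshold(),
                          min_frames = 4L, na_tolerance = 2L) {
  x <- trace$intensity_au
  t <- trace$time_s
  fi <- frame_interval(trace)
  n <- length(x)
  ok <- is.finite(x)

  if (!any(ok) || stats::sd(x[ok]) == 0) {
    warning("Degenerate (constant or empty) trace; no dwells called.")
    return(new_dwell_set(tibble::tibble(start_s = numeric(0), end_s = numeric(0),
                                        duration_s = numeric(0)),
                         gaps = numeric(0), n_censored = 0L,
                         min_frames = min_frames, frame_interval = fi))
  }

  if (is.numeric(threshold_policy)) {
    enter <- exit <- threshold_policy[1]
    bg_level <- NA_real_
  } else {
    bg <- estimate_background(x[ok], threshold_policy$min_separation_sd)
    if (is.null(bg)) {
      return(new_dwell_set(tibble::tibble(start_s = numeric(0), end_s = numeric(0),
                                          duration_s = numeric(0)),
                           gaps = numeric(0), n_censored = 0L,
                           min_frames = min_frames, frame_interval = fi,
                           policy = threshold_policy))
    }
    sd_floor <- max(bg$sd, 1e-3 * max(abs(bg$sep), 1e-12))
    enter <- bg$mean + threshold_policy$enter_sd * sd_floor
    exit <- bg$mean + threshold_policy$exit_sd * sd_floor
    bg_level <- bg$mean
  }

  runs <- hysteresis_runs(x, enter, exit, na_tolerance)
  if (!is.numeric(threshold_policy) &&
      isTRUE(threshold_policy$refine_half_amplitude)) {
    runs <- refine_runs_half_amplitude(runs, x, bg_level)
  }

  if (nrow(runs)) {
    len <- runs$end - runs$start + 1L
    censored <- runs$start == 1L | runs$end == n
    keep <- len > min_frames & !censored
    n_censored <- sum(censored & len > min_frames)
    kept <- runs[keep, , drop = FALSE]
  } else {
    kept <- runs
    n_censored <- 0L
  }

  dwells <- tibble::tibble(
    start_s = t[kept$start],
    end_s = t[kept$end] + fi,
    duration_s = (kept$end - kept$start + 1L) * fi
  )
  gaps <- if (nrow(dwells) >= 2) {
    dwells$start_s[-1] - dwells$end_s[-nrow(dwells)]
  } else numeric(0)

  new_dwell_set(dwells, gaps, n_censored, min_frames, fi,
                policy = threshold_policy)
}

# Background level/spread from the lowest intensity mode. The occupied-state
# intensity is itself multimodal (1..6 dyes), so a two-cluster split is the
# wrong model; the background is simply the leftmost mode of the intensity
# density, provided the trace spends some time unoccupied. Returns NULL when
# the trace has no signal clearly above what the extreme value statistics of
# pure background noise would produce.
estimate_background <- function(x, min_separation_sd = 4) {
  n <- length(x)
  dens <- stats::density(x, n = 512)
  y <- dens$y
  is_peak <- c(FALSE, y[2:(length(y) - 1)] > y[1:(length(y) - 2)] &
                      y[2:(length(y) - 1)] >= y[3:length(y)], FALSE)
  is_peak <- is_peak & y > 0.05 * max(y)
  bg0 <- if (any(is_peak)) dens$x[which(is_peak)[1]] else stats::median(x)

  # robust spread from the left flank of the background mode
  left_dev <- bg0 - x[x <= bg0]
  s0 <- 1.4826 * stats::median(left_dev)
  if (!is.finite(s0) || s0 == 0) s0 <- stats::mad(x)
  if (!is.finite(s0) || s0 == 0) s0 <- stats::sd(x) / 10
  bgpts <- x[abs(x - bg0) <= 3 * s0]
  if (length(bgpts) < 2) bgpts <- x[x <= bg0]
  bg_mean <- mean(bgpts)
  bg_sd <- stats::sd(bgpts)
  if (!is.finite(bg_sd)) bg_sd <- 0

  # featureless guard: is the maximum beyond what n background draws give?
  margin <- (sqrt(2 * log(n)) + min_separation_sd) * bg_sd
  if (max(x) - bg_mean <= margin) return(NULL)
  list(mean = bg_mean, sd = bg_sd, sep = max(x) - bg_mean)
}

# state machine: start a run when x > enter, keep it while x > exit;
# NA frames bridged up to na_tol inside a run
hysteresis_runs <- function(x, enter, exit, na_tol) {
  n <- length(x)
  starts <- integer(0); ends <- integer(0)
  in_run <- FALSE; run_start <- 0L; na_count <- 0L; last_good <- 0L
  for (i in seq_len(n)) {
    xi <- x[i]
    if (!is.finite(xi)) {
      if (in_run) {
        na_count <- na_count + 1L
        if (na_count > na_tol) {
          starts <- c(starts, run_start); ends <- c(ends, last_good)
          in_run <- FALSE; na_count <- 0L
        }
      }
      next
    }
    if (!in_run) {
      if (xi > enter) { in_run <- TRUE; run_start <- i; last_good <- i; na_count <- 0L }
    } else {
      if (xi > exit) { last_good <- i; na_count <- 0L }
      else { starts <- c(starts, run_start); ends <- c(ends, last_good); in_run <- FALSE; na_count <- 0L }
    }
  }
  if (in_run) { starts <- c(starts, run_start); ends <- c(ends, last_good) }
  # backward extension: the run actually began where x last crossed `exit`
  if (length(starts)) {
    for (j in seq_along(starts)) {
      i <- starts[j]
      while (i > 1 && is.finite(x[i - 1]) && x[i - 1] > exit &&
             (j == 1 || i - 1 > ends[j - 1])) i <- i - 1L
      starts[j] <- i
    }
  }
  data.frame(start = starts, end = ends)
}

# Move each boundary to the nearest half-amplitude crossing so smoothing-
# induced edge ramps do not dilate the dwell asymmetrically. The amplitude is
# per run (dwells carry 1..6 dyes, so a global half-level would be wrong).
refine_runs_half_amplitude <- function(runs, x, bg) {
  if (!nrow(runs)) return(runs)
  n <- length(x)
  for (j in seq_len(nrow(runs))) {
    s <- runs$start[j]; e <- runs$end[j]
    amp <- stats::median(x[s:e], na.rm = TRUE)
    half <- bg + 0.5 * (amp - bg)
    while (s <= e && is.finite(x[s]) && x[s] < half) s <- s + 1L
    while (s > 1 && is.finite(x[s - 1]) && x[s - 1] >= half &&
           (j == 1 || s - 1 > runs$end[j - 1])) s <- s - 1L
    while (e >= s && is.finite(x[e]) && x[e] < half) e <- e - 1L
    while (e < n && is.finite(x[e + 1]) && x[e + 1] >= half &&
           (j == nrow(runs) || e + 1 < runs$start[j + 1])) e <- e + 1L
    runs$start[j] <- s; runs$end[j] <- e
  }
  runs[runs$start <= runs$end, , drop = FALSE]
}

new_dwell_set <- function(dwells, gaps, n_censored, min_frames,
                          frame_interval, policy = NULL) {
  structure(
    list(dwells = dwells,
         gaps = gaps,
         mean_dwell = if (nrow(dwells)) mean(dwells$duration_s) else NA_real_,
         m_prime = if (length(gaps)) mean(gaps) else NA_real_,
         n_censored = n_censored,
         min_frames = min_frames,
         frame_interval = frame_interval,
         policy = policy),
    class = "dwell_set"
  )
}

#' @export
print.dwell_set <- function(x, ...) {
  cat(sprintf("<dwell_set> %d dwells (mean %.3f s), %d gaps (mean %.3f s), %d censored\n",
              nrow(x$dwells), x$mean_dwell, length(x$gaps), x$m_prime,
              x$n_censored))
  invisible(x)
}

pool_dwellsets <- function(dwellsets) {
  if (inherits(dwellsets, "dwell_set")) dwellsets <- list(dwellsets)
  list(
    dwells = unlist(lapply(dwellsets, function(d) d$dwells$duration_s)),
    gaps = unlist(lapply(dwellsets, function(d) d$gaps)),
    min_frames = max(vapply(dwellsets, function(d) d$min_frames, numeric(1))),
    frame_interval = stats::median(vapply(dwellsets,
                                          function(d) d$frame_interval,
                                          numeric(1)))
  )
}

#' Dissociation rate constant from pooled dwell times
#'
#' Pools dwell durations across filaments (each dwell weighted equally),
#' reports the mean dwell with its standard error, and converts to
#' k_off = 1/mean with a delta-method SE. An exponential maximum-likelihood
#' fit is reported alongside as a cross-check. If `min_dwell_s > 0` is
#' supplied, the memorylessness of the exponential is used to undo the
#' left truncation imposed by the dwell-length filter
#' (k_off = 1/(mean - min_dwell_s)); by default no correction is applied.
#'
#' @param dwellsets a `dwell_set` or list of them (one per filament/trace).
#' @param min_dwell_s detection cutoff to subtract from the mean dwell
#'   before inversion (0 = plain reciprocal mean).
#'
#' @return A `koff_estimate`: tibble row with `k_off`, `se`, `mean_dwell_s`,
#'   `se_mean`, `n`, `k_off_ml`.
#' @export
estimate_koff <- function(dwellsets, min_dwell_s = 0) {
  pooled <- pool_dwellsets(dwellsets)
  d <- pooled$dwells
  if (length(d) < 2) stop("Need at least 2 pooled dwells.", call. = FALSE)
  m <- mean(d)
  se_m <- stats::sd(d) / sqrt(length(d))
  m_eff <- m - min_dwell_s
  if (m_eff <= 0) stop("Truncation correction exceeds the mean dwell.",
                       call. = FALSE)
  k <- 1 / m_eff
  se_k <- se_m / m_eff^2
  k_ml <- if (requireNamespace("fitdistrplus", quietly = TRUE)) {
    unname(fitdistrplus::fitdist(as.numeric(d), "exp")$estimate)
  } else 1 / m
  out <- tibble::tibble(k_off = k, se = se_k, mean_dwell_s = m,
                        se_mean = se_m, n = length(d), k_off_ml = k_ml)
  class(out) <- c("koff_estimate", class(out))
  out
}

#' Association rate constant from pooled inter-event gaps
#'
#' Pools the observed gaps between consecutive visible dwells, applies the
#' incomplete-labeling correction, and converts the corrected mean gap to
#' k_on = 1/(m c). Uncertainty comes from the delta method on the SE of the
#' pooled mean gap.
#'
#' With `min_dwell_s = 0` (default) the correction is exactly
#' [correct_interevent_time()]: m = f m' - (1 - f)/k_off. A positive
#' `min_dwell_s` additionally accounts for *labeled* events dropped by the
#' dwell-length filter, which also merge gaps but insert much shorter dwells
#' than 1/k_off: the generalized correction is m = q m' - (1 - q) delta,
#' where q = f exp(-k_off t_min) is the probability an event is visible and
#' survives the filter, and delta is the mean dwell of a skipped event
#' (mixture of unlabeled events, mean 1/k_off, and short labeled events,
#' mean E\[T | T < t_min\]).
#'
#' @param dwellsets a `dwell_set` or list of them.
#' @param f labeled fraction, in (0, 1].
#' @param k_off dissociation rate constant (per second).
#' @param c hexamer concentration (molar).
#' @param min_dwell_s dwell-filter cutoff in seconds (0 disables the
#'   filter-loss term).
#'
#' @return A `kon_estimate`: tibble row with `k_on`, `se`, `m_prime_s`,
#'   `m_s`, `n_gaps`.
#' @export
estimate_kon <- function(dwellsets, f, k_off, c, min_dwell_s = 0) {
  stopifnot(f > 0, f <= 1, k_off > 0, c > 0, min_dwell_s >= 0)
  pooled <- pool_dwellsets(dwellsets)
  g <- pooled$gaps
  if (length(g) < 2) stop("Need at least 2 pooled gaps.", call. = FALSE)
  m_prime <- mean(g)
  se_mp <- stats::sd(g) / sqrt(length(g))

  if (min_dwell_s > 0) {
    p_short <- stats::pexp(min_dwell_s, k_off)
    q <- f * (1 - p_short)
    # mean dwell of an exponential conditioned on T < t_min
    e_short <- 1 / k_off - min_dwell_s * exp(-k_off * min_dwell_s) / p_short
    delta <- ((1 - f) / k_off + f * p_short * e_short) / (1 - q)
    m <- q * m_prime - (1 - q) * delta
    slope <- q
  } else {
    m <- f * m_prime - (1 - f) / k_off
    slope <- f
  }
  if (m <= 0) {
    stop("Inconsistent inputs: corrected mean gap is nonpositive.",
         call. = FALSE)
  }
  k_on <- 1 / (m * c)
  se_kon <- slope * se_mp / (m^2 * c)
  out <- tibble::tibble(k_on = k_on, se = se_kon, m_prime_s = m_prime,
                        se_m_prime = se_mp, m_s = m, n_gaps = length(g))
  class(out) <- c("kon_estimate", class(out))
  out
}
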