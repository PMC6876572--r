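#' Depolymerization velocity of a length-vs-time trajectory
#'
#' Ordinary least-squares slope of filament length against time, negated so
#' that depolymerization (shrinkage) is reported as a positive rate —
#' the field's convention. Lengths in nanometers are converted at 2.7 nm
#' per actin subunit.
#'
#' @param traj a data frame with a time column and a length column, or a
#'   `filament_trajectory` (then `length_observed` is used).
#' @param interval optional `c(t0, t1)` window in seconds; only frames
#'   inside it are fitted.
#' @param time_col,length_col column names.
#' @param length_unit `"subunits"` or `"nm"`.
#' @param subunit_nm nm of filament length per subunit.
#'
#' @return One-row tibble: `velocity_subunits_per_s`, `se`, `n_frames`.
#' @examples
#' df <- data.frame(time_s = 0:20, length_subunits = 1000 - 43.9 * 0:20)
#' fit_trajectory_velocity(df)
#' @export
fit_trajectory_velocity <- function(traj, interval = NULL,
                                    time_col = "time_s",
                                    length_col = "length_subunits",
                                    length_unit = c("subunits", "nm"),
                                    subunit_nm = 2.7) {
  length_unit <- match.arg(length_unit)
  if (inherits(traj, "filament_trajectory")) {
    df <- data.frame(time_s = traj$frames$time_s,
                     length_subunits = traj$frames$length_observed)
    time_col <- "time_s"; length_col <- "length_subunits"
  } else {
    df <- as.data.frame(traj)
  }
  t <- df[[time_col]]; y <- df[[length_col]]
  if (is.null(t) || is.null(y)) {
    stop("Columns `", time_col, "` and `", length_col, "` are required.",
         call. = FALSE)
  }
  if (!is.null(interval)) {
    keep <- t >= interval[1] & t <= interval[2]
    t <- t[keep]; y <- y[keep]
  }
  ok <- is.finite(t) & is.finite(y)
  t <- t[ok]; y <- y[ok]
  if (length(t) < 3) stop("Need at least 3 points to fit a velocity.",
                          call. = FALSE)
  if (length_unit == "nm") y <- y / subunit_nm
  fit <- stats::lm(y ~ t)
  # noiseless fixtures trigger a benign "perfect fit" note from summary.lm
  sm <- suppressWarnings(summary(fit))$coefficients
  tibble::tibble(velocity_subunits_per_s = -unname(sm["t", "Estimate"]),
                 se = unname(sm["t", "Std. Error"]),
                 n_frames = length(t))
}

#' Depolymerization velocity from a kymograph
#'
#' Locates the pointed-end edge in each time row of a space-time image by
#' thresholding (edge = outermost pixel above background + `edge_frac` of
#' the dynamic range, on the side given by `end`), fits end position
#' against time, and converts the slope from pixels/frame to subunits/s via
#' the pixel size and the 2.7 nm subunit length.
#'
#' @param kymo numeric matrix, rows = frames, columns = position; e.g. from
#'   [movie_kymograph()].
#' @param geometry an [imaging_geometry()] giving `pixel_nm` and
#'   `subunit_nm`; defaults to the matrix's `pixel_nm` attribute if set.
#' @param frame_interval_s time per kymograph row (seconds). No default when
#'   it cannot be read from the matrix attributes: the acquisition interval
#'   must be supplied.
#' @param end which side the pointed end is on: `"left"` (edge moves right
#'   as the filament shrinks) or `"right"`.
#' @param edge_frac threshold fraction of the background-to-peak range.
#' @param robust use a robust M-estimator (`MASS::rlm`) instead of OLS for
#'   the slope, to resist edge-detection outliers.
#' @param max_missing_frac error if more than this fraction of rows has no
#'   detectable edge.
#'
#' @return One-row tibble: `velocity_subunits_per_s`, `se`, `n_rows`.
#' @export
kymograph_slope <- function(kymo, geometry = NULL, frame_interval_s = NULL,
                            end = c("left", "right"), edge_frac = 0.4,
                            robust = FALSE, max_missing_frac = 0.2) {
  end <- match.arg(end)
  if (is.null(frame_interval_s)) {
    frame_interval_s <- attr(kymo, "frame_interval_s")
    if (is.null(frame_interval_s)) {
      stop("`frame_interval_s` is required (no default).", call. = FALSE)
    }
  }
  pixel_nm <- if (!is.null(geometry)) geometry$pixel_nm else attr(kymo, "pixel_nm")
  subunit_nm <- if (!is.null(geometry)) geometry$subunit_nm else 2.7
  if (is.null(pixel_nm)) stop("Pixel size unknown; supply `geometry`.",
                              call. = FALSE)

  # the filament may fill most of the field, so take the background from the
  # dim tail and the signal level from the bright tail
  bg <- stats::quantile(kymo, 0.02, names = FALSE)
  peak <- stats::quantile(kymo, 0.98, names = FALSE)
  thr <- bg + edge_frac * (peak - bg)
  edge <- apply(kymo, 1, function(row) {
    above <- which(row > thr)
    if (!length(above)) return(NA_real_)
    if (end == "left") {
      i <- min(above)
      if (i > 1 && row[i] > row[i - 1]) {
        # subpixel: linear interpolation of the threshold crossing
        i - (row[i] - thr) / (row[i] - row[i - 1])
      } else as.numeric(i)
    } else {
      i <- max(above)
      if (i < length(row) && row[i] > row[i + 1]) {
        i + (row[i] - thr) / (row[i] - row[i + 1])
      } else as.numeric(i)
    }
  })
  missing <- mean(!is.finite(edge))
  if (missing > max_missing_frac) {
    stop(sprintf("No edge found in %.0f%% of kymograph rows.", 100 * missing),
         call. = FALSE)
  }
  tt <- (seq_len(nrow(kymo)) - 1) * frame_interval_s
  ok <- is.finite(edge)
  fit <- if (robust) {
    MASS::rlm(edge[ok] ~ tt[ok], maxit = 100)
  } else {
    stats::lm(edge[ok] ~ tt[ok])
  }
  sm <- suppressWarnings(summary(fit))$coefficients
  slope_px_s <- unname(sm[2, 1])    # px per second of end motion
  se_px_s <- unname(sm[2, 2])
  # shrinkage moves a left pointed end to the right (+), a right one left (-)
  sgn <- if (end == "left") 1 else -1
  conv <- pixel_nm / subunit_nm
  tibble::tibble(velocity_subunits_per_s = sgn * slope_px_s * conv,
                 se = se_px_s * conv,
                 n_rows = sum(ok))
}

#' Per-interval velocities split by end occupancy
#'
#' Fits a linear velocity to the observed filament length inside each
#' detected dwell (bound intervals) and inside each complementary interval
#' between dwells (unbound), mirroring the segmented velocimetry used to
#' show that rapid shrinkage coincides with depolymerase residence at the
#' end. Intervals covering fewer than 3 frames are skipped and counted.
#'
#' @param traj a `filament_trajectory` or data frame with `time_s` and
#'   `length_subunits` columns.
#' @param dwells a `dwell_set` (e.g. from [detect_dwells()] on the matched
#'   intensity trace).
#'
#' @return Tibble with one row per interval: `state` ("bound"/"unbound"),
#'   `start_s`, `end_s`, `n_frames`, `velocity_subunits_per_s`, `se`.
#'   Attribute `n_skipped` counts intervals with too few frames.
#' @export
segment_velocities <- function(traj, dwells) {
  if (inherits(traj, "filament_trajectory")) {
    df <- data.frame(time_s = traj$frames$time_s,
                     length_subunits = traj$frames$length_observed)
  } else {
    df <- as.data.frame(traj)
  }
  dw <- dwells$dwells
  tmin <- min(df$time_s); tmax <- max(df$time_s)

  intervals <- tibble::tibble(start_s = numeric(0), end_s = numeric(0),
                              state = character(0))
  if (nrow(dw)) {
    intervals <- dplyr::bind_rows(
      tibble::tibble(start_s = dw$start_s, end_s = dw$end_s, state = "bound"),
      tibble::tibble(
        start_s = c(tmin, dw$end_s),
        end_s = c(dw$start_s, tmax),
        state = "unbound"
      )
    )
    intervals <- intervals[intervals$end_s - intervals$start_s > 0, ]
  } else {
    intervals <- tibble::tibble(start_s = tmin, end_s = tmax,
                                state = "unbound")
  }

  n_skipped <- 0L
  rows <- purrr::pmap_dfr(intervals, function(start_s, end_s, state) {
    sel <- df$time_s >= start_s & df$time_s < end_s
    if (sum(sel) < 3) {
      n_skipped <<- n_skipped + 1L
      return(NULL)
    }
    v <- fit_trajectory_velocity(df[sel, ])
    tibble::tibble(state = state, start_s = start_s, end_s = end_s,
                   n_frames = v$n_frames,
                   velocity_subunits_per_s = v$velocity_subunits_per_s,
                   se = v$se)
  })
  if (nrow(rows) == 0) {
    rows <- tibble::tibble(state = character(0), start_s = numeric(0),
                           end_s = numeric(0), n_frames = integer(0),
                           velocity_subunits_per_s = numeric(0),
                           se = numeric(0))
  }
  rows <- dplyr::arrange(rows, .data$start_s)
  attr(rows, "n_skipped") <- n_skipped
  rows
}

#' Fit the Michaelis-Menten saturation curve to velocity data
#'
#' Nonlinear least squares of v = k_cat c / (K_M + c) on per-filament
#' velocities, initialized at K_M = median concentration and k_cat = maximum
#' velocity. Standard errors come from the fit covariance; an optional
#' 1/sd^2 weighting by per-concentration spread is available, but the
#' default is unweighted.
#'
#' @param velocities data frame with concentration and velocity columns,
#'   e.g. from [simulate_velocity_dataset()].
#' @param conc_col,velocity_col column names (molar, subunits/s).
#' @param weighted logical; weight each point by 1/sd^2 of its
#'   concentration group.
#'
#' @return An `mm_fit` object (also an [mm_params()]): the fitted `k_cat`,
#'   `K_M` with SEs, plus `fit` (the `nls` object), `n_points`, and the
#'   data. Methods: [tidy.mm_fit()], [glance.mm_fit()], `autoplot`.
#' @examples
#' d <- simulate_velocity_dataset(c(10, 25, 50, 100, 150, 300, 500) * 1e-9,
#'                                mm_params(53, 50e-9), seed = 1)
#' fit_mm(d)
#' @export
fit_mm <- function(velocities, conc_col = "conc_M",
                   velocity_col = "velocity_subunits_per_s",
                   weighted = FALSE) {
  df <- as.data.frame(velocities)
  cc <- df[[conc_col]]; v <- df[[velocity_col]]
  if (is.null(cc) || is.null(v)) {
    stop("Columns `", conc_col, "` and `", velocity_col, "` are required.",
         call. = FALSE)
  }
  if (length(unique(cc)) < 3) {
    stop("Need at least 3 distinct concentrations.", call. = FALSE)
  }
  w <- rep(1, length(v))
  if (weighted) {
    sds <- tapply(v, cc, stats::sd)
    w <- 1 / (sds[as.character(cc)]^2)
    w[!is.finite(w)] <- max(w[is.finite(w)], 1)
  }
  dat <- data.frame(c = cc, v = v, w = w)
  start <- list(k_cat = max(v), K_M = stats::median(cc))
  fit <- tryCatch(
    minpack.lm::nlsLM(v ~ k_cat * c / (K_M + c), data = dat, start = start,
                      weights = dat$w,
                      lower = c(k_cat = 1e-12, K_M = 1e-15),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("Michaelis-Menten fit did not converge: ",
                             conditionMessage(e), call. = FALSE)
  )
  est <- summary(fit)$coefficients
  out <- mm_params(k_cat = est["k_cat", "Estimate"],
                   K_M = est["K_M", "Estimate"],
                   se_k_cat = est["k_cat", "Std. Error"],
                   se_K_M = est["K_M", "Std. Error"],
                   n_points = nrow(dat))
  out$fit <- fit
  out$data <- tibble::as_tibble(dat[c("c", "v")])
  class(out) <- c("mm_fit", class(out))
  out
}

#' 95% confidence intervals of a Michaelis-Menten fit
#'
#' t-based Wald intervals from the fit covariance.
#'
#' @param fit an `mm_fit`.
#' @param level confidence level.
#' @return Tibble with `term`, `estimate`, `conf_low`, `conf_high`.
#' @export
mm_confint <- function(fit, level = 0.95) {
  df_resid <- fit$n_points - 2
  tq <- stats::qt(1 - (1 - level) / 2, df_resid)
  tibble::tibble(
    term = c("k_cat", "K_M"),
    estimate = c(fit$k_cat, fit$K_M),
    conf_low = c(fit$k_cat - tq * fit$se_k_cat, fit$K_M - tq * fit$se_K_M),
    conf_high = c(fit$k_cat + tq * fit$se_k_cat, fit$K_M + tq * fit$se_K_M)
  )
}

#' Occupancy-versus-velocity comparison table
#'
#' For each concentration, the predicted equilibrium end occupancy
#' c K_A / (1 + c K_A) from the single-molecule rate constants, next to the
#' fraction of saturating velocity c / (c + K_M) from the bulk saturation
#' fit. Parallel columns support the model in which the end depolymerizes
#' rapidly exactly while a hexamer occupies it.
#'
#' @param params a [kinetic_params()] (supplies `k_on`, `k_off`).
#' @param fit an [mm_params()] or `mm_fit` (supplies `K_M`).
#' @param concentrations hexamer concentrations (molar).
#'
#' @return Tibble with `conc_M`, `occupancy_fraction`, `velocity_fraction`,
#'   both in \[0, 1\] and monotone in concentration.
#' @examples
#' occupancy_velocity_table(kinetic_params(1.1e7, 0.45, 83e-9),
#'                          mm_params(53, 50e-9), c(8.3e-9, 83e-9))
#' @export
occupancy_velocity_table <- function(params, fit, concentrations) {
  stopifnot(inherits(params, "kinetic_params"))
  tibble::tibble(
    conc_M = concentrations,
    occupancy_fraction = occupancy(concentrations, params$k_on, params$k_off),
    velocity_fraction = concentrations / (concentrations + fit$K_M)
  )
}
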