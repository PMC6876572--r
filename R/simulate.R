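#' Imaging geometry for rendered data
#'
#' @param pixel_nm nanometers per pixel (130 for the single-molecule setup,
#'   143 for mf-TIRF).
#' @param subunit_nm filament length contributed by one actin subunit
#'   (2.7 nm).
#' @param actin_label_fraction fraction of actin subunits carrying a
#'   fluorophore (0.10 in the experiments emulated here).
#' @param psf_sigma_px Gaussian point-spread-function sigma in pixels.
#'
#' @return An `imaging_geometry` object.
#' @export
imaging_geometry <- function(pixel_nm = 130, subunit_nm = 2.7,
                             actin_label_fraction = 0.10,
                             psf_sigma_px = 1.0) {
  stopifnot(pixel_nm > 0, subunit_nm > 0, psf_sigma_px > 0,
            actin_label_fraction > 0, actin_label_fraction <= 1)
  structure(list(pixel_nm = pixel_nm, subunit_nm = subunit_nm,
                 actin_label_fraction = actin_label_fraction,
                 psf_sigma_px = psf_sigma_px),
            class = "imaging_geometry")
}

with_seed_maybe <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(seed, code)
}

#' Simulate filament pointed-end dynamics under the two-state model
#'
#' Event-driven (exact exponential sampling) simulation of a filament end
#' alternating between unbound intervals (rate `k_on * c`) and bound dwells
#' (rate `k_off`). Each binding event is independently productive with
#' probability `productive_fraction` and carries `n_dyes ~ Binomial(n_sites,
#' p_site)` fluorophores. While the end is occupied by a productive hexamer,
#' subunits are removed as a Poisson process at `v_bound`; otherwise at
#' `v_unbound`. The event schedule is then discretized to a uniform frame
#' grid; no fixed-timestep approximation enters the kinetics.
#'
#' @param params a [kinetic_params()] object (the ground truth).
#' @param duration simulated time (seconds).
#' @param labeling a [labeling_model()] for the dye counts of binding events.
#' @param frame_interval camera frame time in seconds (0.065 by default).
#' @param noise_sd per-frame Gaussian length-measurement noise (subunits),
#'   standing in for filament Brownian motion and the sparse (10%) actin
#'   labeling that limit length precision.
#' @param length0 initial filament length (subunits); defaults to 1.25 x the
#'   expected loss over `duration` plus 500 so the filament never runs out.
#' @param seed integer seed; `NULL` leaves the RNG state alone.
#'
#' @return A `filament_trajectory` object: list with `frames` (tibble:
#'   `time_s`, `length_true`, `length_observed`, `bound_truth`), `events`
#'   (tibble: `bind_time_s`, `unbind_time_s`, `productive`, `n_dyes`),
#'   `params`, `frame_interval`.
#' @examples
#' p <- kinetic_params(1.1e7, 0.45, 83e-9)
#' traj <- simulate_end_dynamics(p, duration = 30, seed = 1)
#' head(traj$frames)
#' @export
simulate_end_dynamics <- function(params, duration,
                                  labeling = labeling_model(f = 0.779),
                                  frame_interval = 0.065,
                                  noise_sd = 10,
                                  length0 = NULL,
                                  seed = NULL) {
  stopifnot(inherits(params, "kinetic_params"), duration > 0,
            frame_interval > 0, noise_sd >= 0)
  with_seed_maybe(seed, {
    rate_bind <- params$k_on * params$c

    # alternating exponential schedule, starting unbound at t = 0
    bind <- numeric(0); unbind <- numeric(0)
    t <- 0
    if (rate_bind > 0) {
      repeat {
        t_b <- t + stats::rexp(1, rate_bind)
        if (t_b >= duration) break
        t_u <- if (params$k_off > 0) t_b + stats::rexp(1, params$k_off) else Inf
        bind <- c(bind, t_b)
        unbind <- c(unbind, min(t_u, duration))
        if (t_u >= duration) break
        t <- t_u
      }
    }
    n_ev <- length(bind)
    productive <- if (n_ev) stats::runif(n_ev) < params$productive_fraction else logical(0)
    n_dyes <- if (n_ev) stats::rbinom(n_ev, labeling$n_sites, labeling$p_site) else integer(0)

    events <- tibble::tibble(
      bind_time_s = bind, unbind_time_s = unbind,
      productive = productive, n_dyes = n_dyes
    )

    times <- seq(0, duration, by = frame_interval)
    nf <- length(times)

    # per-frame expected removal = overlap-weighted velocity; Poisson
    # increments per frame are a valid discretization of the removal process
    fast_frac <- rep(0, nf - 1L)
    if (n_ev) {
      fs <- times[-nf]; fe <- times[-1L]
      for (j in which(productive)) {
        # only frames the event can overlap
        i0 <- max(1L, floor(bind[j] / frame_interval) + 1L)
        i1 <- min(nf - 1L, ceiling(unbind[j] / frame_interval))
        if (i1 < i0) next
        idx <- i0:i1
        ov <- pmax(0, pmin(fe[idx], unbind[j]) - pmax(fs[idx], bind[j]))
        fast_frac[idx] <- fast_frac[idx] + ov
      }
      fast_frac <- fast_frac / frame_interval
    }
    mean_removed <- frame_interval *
      (fast_frac * params$v_bound + (1 - fast_frac) * params$v_unbound)
    removed <- stats::rpois(nf - 1L, pmax(mean_removed, 0))

    if (is.null(length0)) {
      length0 <- ceiling(1.25 * predicted_mean_velocity(params) * duration) + 500
    }
    length_true <- length0 - c(0, cumsum(removed))
    length_obs <- length_true + stats::rnorm(nf, 0, noise_sd)

    bound_truth <- rep(FALSE, nf)
    if (n_ev) {
      for (j in seq_len(n_ev)) {
        i0 <- max(1L, ceiling(bind[j] / frame_interval) + 1L)
        i1 <- min(nf, floor(unbind[j] / frame_interval - 1e-12) + 1L)
        if (i1 >= i0) bound_truth[i0:i1] <- TRUE
      }
    }

    structure(
      list(frames = tibble::tibble(time_s = times,
                                   length_true = length_true,
                                   length_observed = length_obs,
                                   bound_truth = bound_truth),
           events = events,
           params = params,
           labeling = labeling,
           frame_interval = frame_interval),
      class = "filament_trajectory"
    )
  })
}

#' @export
print.filament_trajectory <- function(x, ...) {
  cat(sprintf("<filament_trajectory> %d frames @ %.3f s, %d binding events\n",
              nrow(x$frames), x$frame_interval, nrow(x$events)))
  invisible(x)
}

#' Render the pointed-end fluorescence intensity trace of a trajectory
#'
#' Converts the binding-event schedule of a simulated trajectory into the
#' fluorescence intensity a camera would record at the pointed end. Each
#' bound hexamer contributes `unit_intensity` per surviving dye; dyes bleach
#' independently at `k_bleach` while the molecule is at the end; Gaussian
#' camera noise is added per frame. Hexamers with zero dyes contribute
#' nothing and are invisible, which is exactly the bias the inter-event-gap
#' correction removes downstream.
#'
#' @param traj a `filament_trajectory` from [simulate_end_dynamics()].
#' @param unit_intensity intensity per dye (a.u.).
#' @param k_bleach per-dye bleaching rate (per second); keep at or below
#'   0.05/s so dwell truncation bias stays well under 10% of 1/k_off.
#' @param noise_sd Gaussian camera noise sd (a.u.), nonnegative.
#' @param seed integer seed or `NULL`.
#'
#' @return An `intensity_trace`: tibble with `time_s`, `intensity_au`,
#'   `truth_occupied` (end occupied by a molecule with >= 1 surviving dye at
#'   bind time), plus attributes `frame_interval` and `unit_intensity`.
#' @export
render_intensity_trace <- function(traj, unit_intensity = 200,
                                   k_bleach = 0.02, noise_sd = 20,
                                   seed = NULL) {
  stopifnot(inherits(traj, "filament_trajectory"))
  if (noise_sd < 0) stop("`noise_sd` must be nonnegative.", call. = FALSE)
  with_seed_maybe(seed, {
    times <- traj$frames$time_s
    nf <- length(times)
    signal <- rep(0, nf)
    visible <- rep(FALSE, nf)
    ev <- traj$events
    dt <- traj$frame_interval
    for (j in seq_len(nrow(ev))) {
      nd <- ev$n_dyes[j]
      if (nd == 0) next
      i0 <- max(1L, ceiling(ev$bind_time_s[j] / dt) + 1L)
      i1 <- min(nf, floor(ev$unbind_time_s[j] / dt - 1e-12) + 1L)
      if (i1 < i0) next
      idx <- i0:i1
      bleach_at <- if (k_bleach > 0) stats::rexp(nd, k_bleach) else rep(Inf, nd)
      el <- times[idx] - ev$bind_time_s[j]
      surviving <- vapply(el, function(tt) sum(bleach_at > tt), numeric(1))
      signal[idx] <- signal[idx] + surviving * unit_intensity
      visible[idx] <- visible[idx] | surviving > 0
    }
    intensity <- signal + if (noise_sd > 0) stats::rnorm(nf, 0, noise_sd) else 0
    new_intensity_trace(times, intensity, traj$frame_interval,
                        truth_occupied = visible,
                        unit_intensity = unit_intensity)
  })
}

new_intensity_trace <- function(time_s, intensity_au, frame_interval,
                                truth_occupied = NULL, unit_intensity = NA_real_) {
  out <- tibble::tibble(time_s = time_s, intensity_au = intensity_au)
  if (!is.null(truth_occupied)) out$truth_occupied <- truth_occupied
  structure(out, frame_interval = frame_interval,
            unit_intensity = unit_intensity,
            class = c("intensity_trace", class(out)))
}

#' Frame interval of an intensity trace
#' @param trace an `intensity_trace`.
#' @return Frame interval in seconds.
#' @export
frame_interval <- function(trace) {
  fi <- attr(trace, "frame_interval")
  if (is.null(fi)) stats::median(diff(trace$time_s)) else fi
}

#' Simulate surface-immobilized photobleaching staircases
#'
#' Generates `n` traces of visible (>= 1 dye) surface-adsorbed molecules.
#' Dye counts follow the zero-truncated Binomial(n_sites, p_site) implied by
#' `labeling` (zero-dye molecules never make it into the dataset because
#' they cannot be seen). Each dye bleaches at an independent exponential
#' time, dropping the intensity by one `unit_intensity`.
#'
#' @param n number of traces (> 0).
#' @param labeling a [labeling_model()].
#' @param unit_intensity intensity per dye (a.u.).
#' @param k_bleach per-dye bleaching rate (per second).
#' @param noise_sd Gaussian camera noise sd (a.u.). `unit_intensity /
#'   noise_sd` is the step signal-to-noise ratio.
#' @param frame_interval frame time in seconds.
#' @param seed integer seed or `NULL`.
#'
#' @return A list of `intensity_trace` objects, each carrying attribute
#'   `true_steps` (its dye count).
#' @examples
#' tr <- simulate_photobleach_traces(3, labeling_model(f = 0.779), seed = 1)
#' attr(tr[[1]], "true_steps")
#' @export
simulate_photobleach_traces <- function(n, labeling = labeling_model(f = 0.779),
                                        unit_intensity = 1, k_bleach = 0.05,
                                        noise_sd = 0.2, frame_interval = 0.1,
                                        seed = NULL) {
  stopifnot(n > 0, inherits(labeling, "labeling_model"),
            unit_intensity > 0, k_bleach > 0, noise_sd >= 0)
  with_seed_maybe(seed, {
    dyes <- rtruncbinom(n, labeling$n_sites, labeling$p_site)
    lapply(dyes, function(nd) {
      bleach_at <- sort(stats::rexp(nd, k_bleach))
      duration <- max(bleach_at) * 1.3 + 20 * frame_interval
      times <- seq(0, duration, by = frame_interval)
      surviving <- vapply(times, function(tt) sum(bleach_at > tt), numeric(1))
      intensity <- surviving * unit_intensity +
        if (noise_sd > 0) stats::rnorm(length(times), 0, noise_sd) else 0
      tr <- new_intensity_trace(times, intensity, frame_interval,
                                unit_intensity = unit_intensity)
      attr(tr, "true_steps") <- nd
      tr
    })
  })
}

# zero-truncated binomial sampler (visible molecules only)
rtruncbinom <- function(n, size, prob) {
  if (prob <= 0) stop("`prob` must be positive for a visible molecule.",
                      call. = FALSE)
  k <- seq_len(size)
  w <- stats::dbinom(k, size, prob)
  sample(k, n, replace = TRUE, prob = w / sum(w))
}

#' Probability mass of the zero-truncated binomial dye-count distribution
#'
#' @param labeling a [labeling_model()].
#' @return Tibble with `n_dyes` (1..n_sites) and `prob`.
#' @export
dye_count_distribution <- function(labeling) {
  k <- seq_len(labeling$n_sites)
  w <- stats::dbinom(k, labeling$n_sites, labeling$p_site)
  tibble::tibble(n_dyes = k, prob = w / sum(w))
}

#' Simulate a per-filament velocity dataset along a saturation curve
#'
#' Emulates a concentration series: at each concentration, per-filament
#' depolymerization velocities are drawn from a normal distribution centred
#' on the Michaelis-Menten curve with coefficient of variation `noise_cv`,
#' truncated at zero (negative draws resampled).
#'
#' @param concentrations vector of hexamer concentrations (molar), nonempty.
#' @param fit an [mm_params()] ground truth.
#' @param noise_cv coefficient of variation of per-filament velocities.
#' @param n_per_c filaments per concentration (>= 1).
#' @param seed integer seed or `NULL`.
#'
#' @return Tibble with `conc_M`, `filament`, `velocity_subunits_per_s`.
#' @examples
#' simulate_velocity_dataset(c(10, 50, 150) * 1e-9,
#'                           mm_params(53, 50e-9), n_per_c = 3, seed = 1)
#' @export
simulate_velocity_dataset <- function(concentrations, fit = mm_params(53, 50e-9),
                                      noise_cv = 0.15, n_per_c = 30,
                                      seed = NULL) {
  if (length(concentrations) == 0) {
    stop("`concentrations` must be nonempty.", call. = FALSE)
  }
  stopifnot(all(concentrations >= 0), n_per_c >= 1, noise_cv >= 0)
  with_seed_maybe(seed, {
    purrr::map_dfr(concentrations, function(cc) {
      mu <- mm_velocity(cc, fit)
      v <- stats::rnorm(n_per_c, mu, noise_cv * mu)
      while (any(bad <- v < 0)) v[bad] <- stats::rnorm(sum(bad), mu, noise_cv * mu)
      tibble::tibble(conc_M = cc, filament = seq_len(n_per_c),
                     velocity_subunits_per_s = v)
    })
  })
}

#' Render a two-channel synthetic movie of a depolymerizing filament
#'
#' Channel 1 (actin): the filament as a line of Gaussian-PSF spots at the
#' positions of its sparsely labeled subunits, anchored at the barbed end on
#' the right and shrinking from the pointed end on the left. Channel 2
#' (depolymerase): a PSF spot at the pointed-end position whenever a dye-
#' carrying hexamer is bound. Poisson shot noise on top of a constant
#' background in both channels.
#'
#' @param traj a `filament_trajectory`.
#' @param geometry an [imaging_geometry()].
#' @param frame_stride render every `frame_stride`-th trajectory frame.
#' @param background mean background photon count per pixel.
#' @param amplitude peak PSF photon count per emitter.
#' @param ny image height in pixels (>= 19 so the background annulus of the
#'   spot-extraction stage fits).
#' @param shot_noise logical; apply Poisson noise.
#' @param seed integer seed or `NULL`.
#'
#' @return A `rendered_movie`: list with `actin` and `spot` arrays of
#'   dimension (ny, nx, n_frames), `end_track` tibble (`frame`, `time_s`,
#'   `x_px`, `y_px`), `geometry`, `frame_interval_s`.
#' @export
render_movie <- function(traj, geometry = imaging_geometry(),
                         frame_stride = 1L, background = 10,
                         amplitude = 150, ny = 25L, shot_noise = TRUE,
                         seed = NULL) {
  stopifnot(inherits(traj, "filament_trajectory"),
            inherits(geometry, "imaging_geometry"), ny >= 19L)
  with_seed_maybe(seed, {
    fr <- traj$frames
    keep <- seq(1L, nrow(fr), by = frame_stride)
    times <- fr$time_s[keep]
    L <- fr$length_true[keep]
    L0 <- fr$length_true[1]

    su_px <- geometry$subunit_nm / geometry$pixel_nm  # pixels per subunit
    margin <- 12L
    nx <- as.integer(ceiling(L0 * su_px) + 2L * margin)
    if (nx > 4096L) {
      warning("Trajectory longer than field of view; truncating to 4096 px.")
      nx <- 4096L
    }
    x_barbed <- nx - margin
    y0 <- (ny + 1) / 2

    # labeled subunits, indexed from the barbed end, fixed in the lab frame
    labeled <- which(stats::runif(L0) < geometry$actin_label_fraction)
    x_labeled <- x_barbed - labeled * su_px

    sig <- geometry$psf_sigma_px
    xs <- seq_len(nx); ys <- seq_len(ny)
    psf_y <- exp(-(ys - y0)^2 / (2 * sig^2))

    bound_vis <- rep(FALSE, nrow(fr))
    ev <- traj$events
    for (j in seq_len(nrow(ev))) {
      if (ev$n_dyes[j] > 0) {
        bound_vis[fr$time_s >= ev$bind_time_s[j] &
                  fr$time_s < ev$unbind_time_s[j]] <- TRUE
      }
    }
    bound_vis <- bound_vis[keep]

    nfr <- length(keep)
    actin <- array(background, dim = c(ny, nx, nfr))
    spot <- array(background, dim = c(ny, nx, nfr))
    x_end <- x_barbed - L * su_px

    for (i in seq_len(nfr)) {
      vis <- x_labeled >= x_end[i] - 1e-9
      if (any(vis)) {
        prof <- rep(0, nx)
        for (xl in x_labeled[vis]) {
          lo <- max(1L, floor(xl - 4 * sig)); hi <- min(nx, ceiling(xl + 4 * sig))
          prof[lo:hi] <- prof[lo:hi] + exp(-(xs[lo:hi] - xl)^2 / (2 * sig^2))
        }
        actin[, , i] <- actin[, , i] + amplitude * outer(psf_y, prof)
      }
      if (bound_vis[i]) {
        prof <- exp(-(xs - x_end[i])^2 / (2 * sig^2))
        spot[, , i] <- spot[, , i] + amplitude * outer(psf_y, prof)
      }
    }
    if (shot_noise) {
      actin[] <- stats::rpois(length(actin), actin)
      spot[] <- stats::rpois(length(spot), spot)
    }
    structure(
      list(actin = actin, spot = spot,
           end_track = tibble::tibble(frame = seq_len(nfr), time_s = times,
                                      x_px = x_end, y_px = y0),
           geometry = geometry,
           frame_interval_s = traj$frame_interval * frame_stride),
      class = "rendered_movie"
    )
  })
}

#' Collapse a movie channel into a kymograph
#'
#' Maximum projection across the short image axis, yielding a space-time
#' matrix (rows = frames, columns = pixels along the filament) on which edge
#' velocimetry can be run.
#'
#' @param movie a `rendered_movie`.
#' @param channel `"actin"` or `"spot"`.
#' @return Numeric matrix (n_frames x nx) with attributes `pixel_nm` and
#'   `frame_interval_s`.
#' @export
movie_kymograph <- function(movie, channel = c("actin", "spot")) {
  channel <- match.arg(channel)
  arr <- movie[[channel]]
  kymo <- t(apply(arr, 3, function(m) apply(m, 2, max)))
  attr(kymo, "pixel_nm") <- movie$geometry$pixel_nm
  attr(kymo, "frame_interval_s") <- movie$frame_interval_s
  kymo
}

#' Write a trajectory's frame table to TSV
#'
#' Unit-suffixed headers (`time_s`, `length_subunits`, ...) so files are
#' self-describing.
#'
#' @param traj a `filament_trajectory`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory_tsv <- function(traj, path) {
  df <- traj$frames
  out <- data.frame(time_s = df$time_s,
                    length_subunits = df$length_observed,
                    length_true_subunits = df$length_true,
                    bound_truth = as.integer(df$bound_truth))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an intensity trace to TSV
#' @param trace an `intensity_trace`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trace_tsv <- function(trace, path) {
  out <- data.frame(time_s = trace$time_s, intensity_au = trace$intensity_au)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an intensity trace from TSV
#' @param path TSV with columns `time_s`, `intensity_au`.
#' @return An `intensity_trace`.
#' @export
read_trace_tsv <- function(path) {
  df <- utils::read.delim(path)
  stopifnot(all(c("time_s", "intensity_au") %in% names(df)))
  new_intensity_trace(df$time_s, df$intensity_au,
                      stats::median(diff(df$time_s)))
}
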