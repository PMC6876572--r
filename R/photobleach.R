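#' Optimal piecewise-constant segmentation by penalized least squares
#'
#' Exact dynamic-programming partitioning of a 1-D signal into constant
#' segments, minimizing total within-segment sum of squares plus
#' `penalty` per changepoint. Segment costs are O(1) via cumulative sums,
#' so the whole solve is O(n^2) — fine for photobleaching traces of a few
#' thousand frames.
#'
#' @param x numeric signal.
#' @param penalty per-changepoint penalty; default `2 * sigma^2 * log(n)`
#'   (BIC-like) with sigma estimated robustly from first differences,
#'   `mad(diff(x)) / sqrt(2)`.
#' @param min_seg minimum segment length in frames.
#'
#' @return Tibble with one row per segment: `start`, `end`, `mean`.
#' @export
segment_piecewise_constant <- function(x, penalty = NULL, min_seg = 2L) {
  n <- length(x)
  stopifnot(n >= 1)
  if (is.null(penalty)) {
    sigma <- stats::mad(diff(x)) / sqrt(2)
    if (!is.finite(sigma) || sigma == 0) sigma <- stats::sd(x) / 10
    if (!is.finite(sigma) || sigma == 0) sigma <- 1e-12
    penalty <- 2 * sigma^2 * log(n)
  }
  cs <- c(0, cumsum(x))
  cs2 <- c(0, cumsum(x^2))
  segcost_to <- function(t, s) {
    # cost of segments (s+1):t for a vector of starts s
    len <- t - s
    (cs2[t + 1] - cs2[s + 1]) - (cs[t + 1] - cs[s + 1])^2 / len
  }
  F <- rep(Inf, n + 1); F[1] <- -penalty
  back <- integer(n)
  for (t in seq_len(n)) {
    s <- 0:(t - 1)
    s <- s[t - s >= min_seg | s == 0]
    if (!length(s)) s <- 0L
    cand <- F[s + 1] + penalty + segcost_to(t, s)
    j <- which.min(cand)
    F[t + 1] <- cand[j]
    back[t] <- s[j]
  }
  ends <- integer(0); t <- n
  while (t > 0) { ends <- c(t, ends); t <- back[t] }
  starts <- c(1L, utils::head(ends, -1) + 1L)
  tibble::tibble(
    start = starts, end = ends,
    mean = (cs[ends + 1] - cs[starts]) / (ends - starts + 1)
  )
}

#' Count photobleaching steps in a surface-immobilized molecule trace
#'
#' Fits a piecewise-constant model to the trace by penalized changepoint
#' segmentation and counts downward level transitions. Adjacent segments
#' whose level difference is smaller than `min_step_frac * unit_intensity`
#' are merged first (spurious sub-step splits), so only full fluorophore
#' losses are counted. A trace whose final level does not return to within
#' half a unit of background is flagged censored (the molecule had unbleached
#' dyes when the recording ended) and should be excluded from labeling fits.
#'
#' @param trace an `intensity_trace` (or bare numeric vector).
#' @param unit_intensity intensity of a single-dye step; defaults to the
#'   trace's `unit_intensity` attribute, else the median absolute level
#'   drop between fitted segments.
#' @param penalty changepoint penalty passed to
#'   [segment_piecewise_constant()]; `NULL` for the robust default.
#' @param min_step_frac steps smaller than this fraction of
#'   `unit_intensity` are merged away.
#' @param background expected background level (0 for a background-
#'   subtracted trace).
#'
#' @return A one-row tibble: `n_steps`, `censored`, `unit_intensity`,
#'   `n_segments`.
#' @examples
#' tr <- simulate_photobleach_traces(1, labeling_model(f = 0.779), seed = 4)[[1]]
#' count_steps(tr)
#' @export
count_steps <- function(trace, unit_intensity = NULL, penalty = NULL,
                        min_step_frac = 0.5, background = 0) {
  x <- if (is.numeric(trace)) trace else trace$intensity_au
  if (is.null(unit_intensity) && !is.numeric(trace)) {
    unit_intensity <- attr(trace, "unit_intensity")
    if (!is.null(unit_intensity) && is.na(unit_intensity)) unit_intensity <- NULL
  }
  seg <- segment_piecewise_constant(x, penalty = penalty)

  if (is.null(unit_intensity)) {
    drops <- abs(diff(seg$mean))
    unit_intensity <- if (length(drops)) stats::median(drops) else
      max(abs(x - background))
  }

  # merge level changes too small to be a single-dye loss
  repeat {
    if (nrow(seg) < 2) break
    d <- abs(diff(seg$mean))
    j <- which.min(d)
    if (d[j] >= min_step_frac * unit_intensity) break
    merged_start <- seg$start[j]
    merged_end <- seg$end[j + 1]
    merged_mean <- stats::weighted.mean(
      seg$mean[j:(j + 1)],
      w = seg$end[j:(j + 1)] - seg$start[j:(j + 1)] + 1
    )
    seg <- seg[-(j + 1), , drop = FALSE]
    seg$start[j] <- merged_start; seg$end[j] <- merged_end
    seg$mean[j] <- merged_mean
  }

  n_steps <- sum(diff(seg$mean) < 0)
  censored <- abs(seg$mean[nrow(seg)] - background) > 0.5 * unit_intensity
  tibble::tibble(n_steps = as.integer(n_steps), censored = censored,
                 unit_intensity = unit_intensity, n_segments = nrow(seg))
}

#' Count steps across a list of photobleaching traces
#'
#' @param traces list of `intensity_trace` objects.
#' @param ... passed to [count_steps()].
#' @return Tibble with one row per trace (`trace`, `n_steps`, `censored`,
#'   ...).
#' @export
count_steps_all <- function(traces, ...) {
  purrr::imap_dfr(traces, function(tr, i) {
    dplyr::mutate(count_steps(tr, ...), trace = i, .before = 1)
  })
}

# zero-truncated binomial log-likelihood for a step-count histogram
ztb_loglik <- function(p, counts, n_sites) {
  k <- which(counts > 0)  # empty bins contribute nothing (avoid 0 * -Inf)
  logp <- stats::dbinom(k, n_sites, p, log = TRUE) -
    log1p(-(1 - p)^n_sites)
  sum(counts[k] * logp)
}

#' Fit the labeling model to a photobleaching step-count histogram
#'
#' Maximum-likelihood estimate of the per-site labeling probability under a
#' zero-truncated Binomial(n_sites, p): molecules with zero dyes are never
#' observed, so the zero class is conditioned away. The labeled fraction is
#' `f = 1 - (1 - p)^n_sites`. A profile-likelihood confidence interval for
#' `p` is mapped through the same monotone transform to give the interval
#' for `f`; an observed-information standard error is reported alongside
#' (the printed +/- on a labeled fraction can be read either way, so both
#' are labelled explicitly).
#'
#' @param counts step-count histogram: either a numeric vector whose k-th
#'   element is the number of traces with k steps (k = 1..n_sites), or the
#'   tibble from [count_steps_all()] (censored traces are dropped).
#' @param n_sites dye sites per molecule.
#' @param conf_level confidence level for the profile interval.
#'
#' @return A `labeling_fit`: list with `labeling` (a [labeling_model()] at
#'   the MLE), `summary` (tibble: `p_site_hat`, `f_hat`, `se_f`, `ci_f_lo`,
#'   `ci_f_hi`, `n_traces`), and the histogram.
#' @examples
#' fit_labeling(c(`1` = 120, `2` = 100, `3` = 55, `4` = 20, `5` = 4, `6` = 1))
#' @export
fit_labeling <- function(counts, n_sites = 6L, conf_level = 0.95) {
  if (is.data.frame(counts)) {
    cc <- counts[!counts$censored & counts$n_steps >= 1, ]
    counts <- tabulate(cc$n_steps, nbins = n_sites)
  }
  counts <- as.numeric(counts)
  if (length(counts) < n_sites) counts <- c(counts, rep(0, n_sites - length(counts)))
  if (length(counts) > n_sites) {
    stop("Histogram has more bins than dye sites.", call. = FALSE)
  }
  n <- sum(counts)
  if (n < 1 || all(counts == 0)) {
    stop("Step-count histogram is empty.", call. = FALSE)
  }

  if (counts[n_sites] == n) {
    p_hat <- 1
  } else {
    p_hat <- stats::optimize(ztb_loglik, c(1e-6, 1 - 1e-9), counts = counts,
                             n_sites = n_sites, maximum = TRUE,
                             tol = 1e-10)$maximum
  }
  f_hat <- 1 - (1 - p_hat)^n_sites

  # profile-likelihood CI on p, mapped to f (monotone)
  ll_max <- ztb_loglik(min(p_hat, 1 - 1e-12), counts, n_sites)
  crit <- stats::qchisq(conf_level, df = 1) / 2
  inside <- function(p) ztb_loglik(p, counts, n_sites) >= ll_max - crit
  lo <- if (inside(1e-9)) 0 else
    stats::uniroot(function(p) ztb_loglik(p, counts, n_sites) - (ll_max - crit),
                   c(1e-9, p_hat), tol = 1e-10)$root
  hi <- if (p_hat >= 1 - 1e-9 || inside(1 - 1e-9)) 1 else
    stats::uniroot(function(p) ztb_loglik(p, counts, n_sites) - (ll_max - crit),
                   c(p_hat, 1 - 1e-9), tol = 1e-10)$root

  # observed-information SE on p, delta-method to f
  se_f <- if (p_hat > 1e-6 && p_hat < 1 - 1e-6) {
    h <- 1e-5
    d2 <- (ztb_loglik(p_hat + h, counts, n_sites) -
           2 * ztb_loglik(p_hat, counts, n_sites) +
           ztb_loglik(p_hat - h, counts, n_sites)) / h^2
    se_p <- if (d2 < 0) sqrt(-1 / d2) else NA_real_
    abs(n_sites * (1 - p_hat)^(n_sites - 1)) * se_p
  } else NA_real_

  structure(
    list(labeling = labeling_model(p_site = p_hat, n_sites = n_sites),
         summary = tibble::tibble(
           p_site_hat = p_hat, f_hat = f_hat, se_f = se_f,
           ci_f_lo = 1 - (1 - lo)^n_sites, ci_f_hi = 1 - (1 - hi)^n_sites,
           conf_level = conf_level, n_traces = n),
         counts = stats::setNames(counts, seq_len(n_sites))),
    class = "labeling_fit"
  )
}

#' @export
print.labeling_fit <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<labeling_fit> p_site = %.4f, f = %.3f (SE %.3f, %d%% CI %.3f-%.3f), n = %d\n",
              s$p_site_hat, s$f_hat, s$se_f, round(100 * s$conf_level),
              s$ci_f_lo, s$ci_f_hi, s$n_traces))
  invisible(x)
}

#' Predicted spot-intensity distribution of single labeled molecules
#'
#' The intensity of one molecule is (number of dyes) x `unit_intensity`
#' plus Gaussian noise, with dye counts following the zero-truncated
#' binomial of the labeling model. Used to test whether filament-end-bound
#' spots are single hexamers: their intensity sample should be consistent
#' with this mixture.
#'
#' @param labeling a [labeling_model()].
#' @param unit_intensity intensity per dye (a.u.).
#' @param noise_sd Gaussian measurement noise sd (a.u.).
#'
#' @return An `intensity_mixture`: list with `components` (tibble `n_dyes`,
#'   `mean`, `weight`), and functions `pdf(x)`, `cdf(x)`, `sample(n)`.
#' @export
predicted_intensity_distribution <- function(labeling, unit_intensity = 200,
                                             noise_sd = 20) {
  stopifnot(inherits(labeling, "labeling_model"), unit_intensity > 0,
            noise_sd >= 0)
  comp <- dye_count_distribution(labeling)
  comp$mean <- comp$n_dyes * unit_intensity
  sd_eff <- max(noise_sd, 1e-12)
  pdf <- function(x) {
    rowSums(outer(x, seq_len(nrow(comp)), function(xx, j) {
      comp$prob[j] * stats::dnorm(xx, comp$mean[j], sd_eff)
    }))
  }
  cdf <- function(x) {
    rowSums(outer(x, seq_len(nrow(comp)), function(xx, j) {
      comp$prob[j] * stats::pnorm(xx, comp$mean[j], sd_eff)
    }))
  }
  smp <- function(n) {
    k <- sample(comp$n_dyes, n, replace = TRUE, prob = comp$prob)
    k * unit_intensity + stats::rnorm(n, 0, noise_sd)
  }
  components <- tibble::tibble(n_dyes = comp$n_dyes, mean = comp$mean,
                               weight = comp$prob)
  structure(list(components = components,
                 pdf = pdf, cdf = cdf, sample = smp,
                 unit_intensity = unit_intensity, noise_sd = noise_sd),
            class = "intensity_mixture")
}

#' Compare observed spot intensities with the predicted mixture
#'
#' One-sample Kolmogorov-Smirnov test of observed intensities against the
#' mixture CDF implied by the labeling model. A non-significant statistic is
#' consistent with end-bound spots being single molecules.
#'
#' @param intensities numeric vector of observed spot intensities.
#' @param mixture from [predicted_intensity_distribution()].
#' @return Tibble with `statistic` and `p_value`.
#' @export
compare_intensity_distribution <- function(intensities, mixture) {
  ks <- suppressWarnings(stats::ks.test(intensities, mixture$cdf))
  tibble::tibble(statistic = unname(ks$statistic), p_value = ks$p.value)
}
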