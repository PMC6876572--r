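#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL

#' Tidy a Michaelis-Menten fit
#'
#' @param x an `mm_fit` from [fit_mm()].
#' @param ... unused.
#' @return Tibble with one row per parameter: `term`, `estimate`,
#'   `std.error`, `conf.low`, `conf.high`.
#' @method tidy mm_fit
#' @export
tidy.mm_fit <- function(x, ...) {
  ci <- mm_confint(x)
  tibble::tibble(term = ci$term, estimate = ci$estimate,
                 std.error = c(x$se_k_cat, x$se_K_M),
                 conf.low = ci$conf_low, conf.high = ci$conf_high)
}

#' One-row summary of a Michaelis-Menten fit
#'
#' @param x an `mm_fit`.
#' @param ... unused.
#' @return Tibble with `k_cat`, `K_M_nM`, `sigma`, `n_points`,
#'   `catalytic_efficiency`.
#' @method glance mm_fit
#' @export
glance.mm_fit <- function(x, ...) {
  tibble::tibble(
    k_cat = x$k_cat, K_M_nM = x$K_M * 1e9,
    sigma = if (!is.null(x$fit)) summary(x$fit)$sigma else NA_real_,
    n_points = x$n_points,
    catalytic_efficiency = x$k_cat / x$K_M
  )
}

#' Tidy a labeling-model fit
#'
#' @param x a `labeling_fit` from [fit_labeling()].
#' @param ... unused.
#' @return One-row tibble with the estimated per-site probability and
#'   labeled fraction with uncertainty.
#' @method tidy labeling_fit
#' @export
tidy.labeling_fit <- function(x, ...) x$summary

#' Tidy a dwell set
#'
#' @param x a `dwell_set` from [detect_dwells()].
#' @param ... unused.
#' @return The dwell table (`start_s`, `end_s`, `duration_s`).
#' @method tidy dwell_set
#' @export
tidy.dwell_set <- function(x, ...) x$dwells

#' One-row summary of a dwell set
#'
#' @param x a `dwell_set`.
#' @param ... unused.
#' @return Tibble with dwell/gap counts and means.
#' @method glance dwell_set
#' @export
glance.dwell_set <- function(x, ...) {
  tibble::tibble(n_dwells = nrow(x$dwells), mean_dwell_s = x$mean_dwell,
                 n_gaps = length(x$gaps), m_prime_s = x$m_prime,
                 n_censored = x$n_censored)
}

#' Tidy a pipeline result
#'
#' @param x a `pipeline_result` from [run_pipeline()].
#' @param ... unused.
#' @return The estimates tibble.
#' @method tidy pipeline_result
#' @export
tidy.pipeline_result <- function(x, ...) x$estimates

#' Plot a filament length trajectory with bound intervals shaded
#'
#' @param object a `filament_trajectory`.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot filament_trajectory
#' @export
autoplot.filament_trajectory <- function(object, ...) {
  fr <- object$frames
  ev <- object$events
  p <- ggplot2::ggplot(fr, ggplot2::aes(x = .data$time_s)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$length_observed),
                       colour = "grey60", linewidth = 0.3) +
    ggplot2::geom_line(ggplot2::aes(y = .data$length_true),
                       colour = "black") +
    ggplot2::labs(x = "Time (s)", y = "Filament length (subunits)") +
    ggplot2::theme_minimal()
  if (nrow(ev)) {
    p <- p + ggplot2::geom_rect(
      data = ev,
      ggplot2::aes(xmin = .data$bind_time_s, xmax = .data$unbind_time_s),
      ymin = -Inf, ymax = Inf, inherit.aes = FALSE,
      fill = "steelblue", alpha = 0.2
    )
  }
  p
}

#' Plot an intensity trace
#'
#' @param object an `intensity_trace`.
#' @param dwells optional `dwell_set` whose intervals are shaded.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot intensity_trace
#' @export
autoplot.intensity_trace <- function(object, dwells = NULL, ...) {
  df <- tibble::tibble(time_s = object$time_s,
                       intensity_au = object$intensity_au)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$time_s, .data$intensity_au)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "Time (s)", y = "Intensity (a.u.)") +
    ggplot2::theme_minimal()
  if (!is.null(dwells) && nrow(dwells$dwells)) {
    p <- p + ggplot2::geom_rect(
      data = dwells$dwells,
      ggplot2::aes(xmin = .data$start_s, xmax = .data$end_s),
      ymin = -Inf, ymax = Inf, inherit.aes = FALSE,
      fill = "darkgreen", alpha = 0.15
    )
  }
  p
}

#' Plot a Michaelis-Menten fit over its data
#'
#' @param object an `mm_fit`.
#' @param ... unused.
#' @return A ggplot with per-filament points and the fitted curve.
#' @method autoplot mm_fit
#' @export
autoplot.mm_fit <- function(object, ...) {
  dat <- object$data
  grid <- tibble::tibble(c = seq(0, max(dat$c) * 1.05, length.out = 200))
  grid$v <- mm_velocity(grid$c, object)
  ggplot2::ggplot(dat, ggplot2::aes(.data$c * 1e9, .data$v)) +
    ggplot2::geom_point(alpha = 0.4, size = 1) +
    ggplot2::geom_line(data = grid, colour = "red") +
    ggplot2::labs(x = "Hexamer concentration (nM)",
                  y = "Depolymerization velocity (subunits/s)") +
    ggplot2::theme_minimal()
}

#' Histogram of dwell (residence) times
#'
#' @param object a `dwell_set`.
#' @param binwidth histogram bin width in seconds.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot dwell_set
#' @export
autoplot.dwell_set <- function(object, binwidth = 0.5, ...) {
  ggplot2::ggplot(object$dwells, ggplot2::aes(.data$duration_s)) +
    ggplot2::geom_histogram(binwidth = binwidth, fill = "darkgreen",
                            colour = "white", boundary = 0) +
    ggplot2::labs(x = "Residence time (s)", y = "Count") +
    ggplot2::theme_minimal()
}
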