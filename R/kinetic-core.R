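#' Ground-truth / estimated rate constants of the two-state end-occupancy model
#'
#' Bundles the kinetic constants describing a depolymerase that binds the
#' pointed end of a cofilin-decorated actin filament (association rate
#' `k_on`, dissociation rate `k_off`, free hexamer concentration `c`) together
#' with the depolymerization velocities in the end-occupied and end-free
#' states. The end is modelled as a two-state (bound/unbound) Markov switch;
#' while bound *and* productive, subunits leave at `v_bound`, otherwise at
#' `v_unbound`.
#'
#' All concentrations are molar and all times are seconds internally;
#' nanomolar appears only at I/O boundaries, which avoids silent 1e9-scale
#' unit errors in `k_on`.
#'
#' @param k_on second-order association rate constant (per molar per second).
#' @param k_off dissociation rate constant (per second).
#' @param c depolymerase hexamer concentration (molar).
#' @param v_bound depolymerization velocity while the end is occupied and the
#'   event is productive (subunits/s).
#' @param v_unbound velocity while the end is unoccupied (subunits/s).
#' @param productive_fraction probability that a binding event is
#'   depolymerization-competent, in \[0, 1\]. Defaults to 1; exposed because
#'   some observed binding events are not accompanied by rapid
#'   depolymerization.
#'
#' @return An object of class `kinetic_params` (a named list).
#' @examples
#' kinetic_params(k_on = 1.1e7, k_off = 0.45, c = 83e-9,
#'                v_bound = 53, v_unbound = 0.43)
#' @export
kinetic_params <- function(k_on, k_off, c, v_bound = 53, v_unbound = 0.43,
                           productive_fraction = 1) {
  stopifnot(
    is.numeric(k_on), length(k_on) == 1L, k_on >= 0,
    is.numeric(k_off), length(k_off) == 1L, k_off >= 0,
    is.numeric(c), length(c) == 1L, c >= 0,
    is.numeric(v_bound), length(v_bound) == 1L,
    is.numeric(v_unbound), length(v_unbound) == 1L
  )
  if (!is.numeric(productive_fraction) || productive_fraction < 0 ||
      productive_fraction > 1) {
    stop("`productive_fraction` must be a probability in [0, 1].",
         call. = FALSE)
  }
  structure(
    list(k_on = k_on, k_off = k_off, c = c,
         v_bound = v_bound, v_unbound = v_unbound,
         productive_fraction = productive_fraction),
    class = "kinetic_params"
  )
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("<kinetic_params>\n")
  cat(sprintf("  k_on  = %.4g /M/s   k_off = %.4g /s   c = %.4g M\n",
              x$k_on, x$k_off, x$c))
  cat(sprintf("  v_bound = %.4g subunits/s   v_unbound = %.4g subunits/s   phi = %.3g\n",
              x$v_bound, x$v_unbound, x$productive_fraction))
  if (x$k_off > 0) {
    cat(sprintf("  K_A = k_on/k_off = %.4g /M   occupancy at c = %.3f\n",
                x$k_on / x$k_off, occupancy(x$c, x$k_on, x$k_off)))
  }
  invisible(x)
}

#' Michaelis-Menten saturation parameters for end depolymerization
#'
#' Container for a saturation-kinetics description of pointed-end
#' depolymerization velocity versus depolymerase concentration,
#' v(c) = k_cat c / (K_M + c).
#'
#' @param k_cat maximal depolymerization velocity (subunits/s).
#' @param K_M half-saturation concentration (molar).
#' @param se_k_cat,se_K_M standard errors (same units); `NA` when unknown.
#' @param n_points number of fitted observations; `NA` for a hand-specified
#'   parameter set.
#'
#' @return An object of class `mm_params` (a named list).
#' @examples
#' mm_params(k_cat = 53, K_M = 50e-9, se_k_cat = 8, se_K_M = 10e-9)
#' @export
mm_params <- function(k_cat, K_M, se_k_cat = NA_real_, se_K_M = NA_real_,
                      n_points = NA_integer_) {
  stopifnot(is.numeric(k_cat), k_cat > 0, is.numeric(K_M), K_M > 0)
  if (!is.na(se_k_cat) && se_k_cat < 0) stop("`se_k_cat` must be nonnegative.")
  if (!is.na(se_K_M) && se_K_M < 0) stop("`se_K_M` must be nonnegative.")
  structure(
    list(k_cat = k_cat, K_M = K_M,
         se_k_cat = as.numeric(se_k_cat), se_K_M = as.numeric(se_K_M),
         n_points = n_points),
    class = "mm_params"
  )
}

#' @export
print.mm_params <- function(x, ...) {
  cat("<mm_params>\n")
  cat(sprintf("  k_cat = %.4g +/- %.3g subunits/s\n", x$k_cat, x$se_k_cat))
  cat(sprintf("  K_M   = %.4g +/- %.3g M (%.3g nM)\n",
              x$K_M, x$se_K_M, x$K_M * 1e9))
  invisible(x)
}

#' Incomplete-labeling model for a multimeric fluorescent molecule
#'
#' A hexamer carries up to `n_sites` dyes, each site labeled independently
#' with probability `p_site`; molecules with zero dyes are invisible. The
#' observable fraction is `f = 1 - (1 - p_site)^n_sites`. Provide either
#' `p_site` or `f`; the other is derived.
#'
#' @param p_site per-site labeling probability in \[0, 1\].
#' @param f fraction of molecules carrying at least one dye.
#' @param n_sites number of dye sites per molecule (6 for a hexamer with one
#'   labelable cysteine per monomer).
#'
#' @return An object of class `labeling_model` with fields `n_sites`,
#'   `p_site` and `f`.
#' @examples
#' labeling_model(f = 0.779)       # the measured labeled-hexamer fraction
#' labeling_model(p_site = 0.2223)
#' @export
labeling_model <- function(p_site = NULL, f = NULL, n_sites = 6L) {
  stopifnot(is.numeric(n_sites), n_sites >= 1)
  n_sites <- as.integer(n_sites)
  if (is.null(p_site) == is.null(f)) {
    stop("Supply exactly one of `p_site` or `f`.", call. = FALSE)
  }
  if (is.null(p_site)) {
    stopifnot(is.numeric(f), f >= 0, f <= 1)
    p_site <- 1 - (1 - f)^(1 / n_sites)
  } else {
    stopifnot(is.numeric(p_site), p_site >= 0, p_site <= 1)
    f <- 1 - (1 - p_site)^n_sites
  }
  structure(list(n_sites = n_sites, p_site = p_site, f = f),
            class = "labeling_model")
}

#' @export
print.labeling_model <- function(x, ...) {
  cat(sprintf("<labeling_model> %d sites, p_site = %.4f, f = %.4f\n",
              x$n_sites, x$p_site, x$f))
  invisible(x)
}

#' Equilibrium occupancy of the filament end
#'
#' Fraction of time the pointed end is occupied by a depolymerase hexamer at
#' free concentration `c`, from the binding isotherm
#' occ = c K_A / (1 + c K_A) with K_A = k_on / k_off.
#'
#' @param c hexamer concentration (molar); vectorised.
#' @param k_on association rate constant (per molar per second).
#' @param k_off dissociation rate constant (per second); must be positive.
#'
#' @return Occupancy fraction(s) in \[0, 1\], monotone nondecreasing in `c`.
#' @examples
#' occupancy(83e-9, k_on = 1.1e7, k_off = 0.45)  # ~0.67
#' @export
occupancy <- function(c, k_on, k_off) {
  if (any(k_off <= 0)) stop("`k_off` must be positive.", call. = FALSE)
  if (any(c < 0) || any(k_on < 0)) {
    stop("`c` and `k_on` must be nonnegative.", call. = FALSE)
  }
  cKA <- c * (k_on / k_off)
  cKA / (1 + cKA)
}

#' Michaelis-Menten velocity at a given concentration
#'
#' @param c hexamer concentration (molar); vectorised.
#' @param fit an [mm_params()] (or fitted `mm_fit`) object, or `NULL` when
#'   `k_cat` and `K_M` are given directly.
#' @param k_cat,K_M saturation parameters, used when `fit` is `NULL`.
#'
#' @return Velocity k_cat c / (K_M + c) in subunits/s, bounded above by
#'   `k_cat`.
#' @examples
#' mm_velocity(83e-9, k_cat = 53, K_M = 50e-9)  # ~33.1 subunits/s
#' @export
mm_velocity <- function(c, fit = NULL, k_cat = NULL, K_M = NULL) {
  if (!is.null(fit)) {
    k_cat <- fit$k_cat
    K_M <- fit$K_M
  }
  stopifnot(is.numeric(k_cat), is.numeric(K_M), K_M > 0)
  if (any(c < 0)) stop("`c` must be nonnegative.", call. = FALSE)
  k_cat * c / (K_M + c)
}

#' Catalytic efficiency k_cat / K_M with propagated uncertainty
#'
#' The ratio k_cat/K_M (subunits per second per molar) equals the mean number
#' of subunits removed per binding event multiplied by the association rate
#' constant, which is what makes it the bridge between bulk saturation
#' kinetics and single-molecule association measurements. The standard error
#' is propagated to first order (delta method), treating the two estimates as
#' independent: rel.se = sqrt((se_kcat/kcat)^2 + (se_KM/KM)^2).
#'
#' @param fit an [mm_params()] or fitted `mm_fit` object.
#'
#' @return A tibble with columns `efficiency` (subunits/s/M), `se` and
#'   `rel_se`. `se` is `NA` when the fit carries no uncertainties.
#' @examples
#' catalytic_efficiency(mm_params(53, 50e-9, 8, 10e-9))  # ~1.06e9 +/- 0.27e9
#' @export
catalytic_efficiency <- function(fit) {
  stopifnot(is.numeric(fit$k_cat), is.numeric(fit$K_M))
  if (fit$K_M <= 0) stop("`K_M` must be positive.", call. = FALSE)
  eff <- fit$k_cat / fit$K_M
  rel <- sqrt((fit$se_k_cat / fit$k_cat)^2 + (fit$se_K_M / fit$K_M)^2)
  tibble::tibble(efficiency = eff, se = eff * rel, rel_se = rel)
}

#' Mean subunits removed per binding event
#'
#' Processivity of the depolymerase: (k_cat/K_M) / k_on, the mean number of
#' actin subunits removed from the pointed end during a single hexamer
#' binding event. When standard errors are supplied the uncertainty is
#' propagated to first order assuming independence.
#'
#' @param efficiency catalytic efficiency k_cat/K_M (subunits/s/M).
#' @param k_on association rate constant (per molar per second); positive.
#' @param se_efficiency,se_k_on optional standard errors.
#'
#' @return A tibble with columns `subunits_per_event` and `se`.
#' @examples
#' subunits_per_event(1.06e9, 1.1e7)  # ~96 subunits
#' @export
subunits_per_event <- function(efficiency, k_on,
                               se_efficiency = NA_real_, se_k_on = NA_real_) {
  if (any(k_on <= 0)) stop("`k_on` must be positive.", call. = FALSE)
  n <- efficiency / k_on
  rel <- sqrt((se_efficiency / efficiency)^2 + (se_k_on / k_on)^2)
  tibble::tibble(subunits_per_event = n, se = abs(n) * rel)
}

#' Correct the observed mean inter-event gap for incomplete labeling
#'
#' With only a fraction `f` of hexamers visible, runs of invisible binding
#' events merge the true gaps flanking them, so the observed mean time `m'`
#' between consecutive *visible* dwells overestimates the true mean gap `m`.
#' Each invisible event inserts, on average, one dwell (1/k_off) into the
#' observed gap, giving the exact correction
#'
#'   m = f m' - (1 - f) / k_off.
#'
#' @param m_prime observed mean time between consecutive visible dwells (s).
#' @param f fraction of molecules carrying at least one dye, in (0, 1\].
#' @param k_off dissociation rate constant (per second), positive.
#'
#' @return Corrected mean gap `m` in seconds.
#' @examples
#' correct_interevent_time(2.0365, f = 0.779, k_off = 0.45)  # ~1.095 s
#' @export
correct_interevent_time <- function(m_prime, f, k_off) {
  stopifnot(is.numeric(m_prime), is.numeric(f), is.numeric(k_off))
  if (any(f <= 0) || any(f > 1)) stop("`f` must be in (0, 1].", call. = FALSE)
  if (any(m_prime <= 0)) stop("`m_prime` must be positive.", call. = FALSE)
  if (any(k_off <= 0)) stop("`k_off` must be positive.", call. = FALSE)
  m <- f * m_prime - (1 - f) / k_off
  if (any(m <= 0)) {
    stop("Inconsistent inputs: labeling correction exceeds the observed ",
         "mean gap (corrected m <= 0).", call. = FALSE)
  }
  m
}

#' Association rate constant from the corrected mean gap
#'
#' Binding is pseudo-first-order at free concentration `c`, so the mean wait
#' between events is 1/(k_on c) and k_on = 1 / (m c).
#'
#' @param m corrected mean inter-event gap (seconds), positive.
#' @param c hexamer concentration (molar), positive.
#'
#' @return k_on in per molar per second.
#' @examples
#' kon_from_mean_gap(1.0953, 83e-9)  # ~1.1e7 /M/s
#' @export
kon_from_mean_gap <- function(m, c) {
  if (any(m <= 0) || any(c <= 0)) {
    stop("`m` and `c` must be positive.", call. = FALSE)
  }
  1 / (m * c)
}

#' Dissociation rate constant from the mean dwell time
#'
#' For a single-exponential residence-time distribution the maximum-likelihood
#' rate is simply the reciprocal mean dwell.
#'
#' @param mean_dwell mean residence time (seconds), positive.
#'
#' @return k_off in per second.
#' @examples
#' koff_from_mean_dwell(2.2)  # 0.4545 /s, printed as 0.45
#' @export
koff_from_mean_dwell <- function(mean_dwell) {
  if (any(mean_dwell <= 0)) stop("`mean_dwell` must be positive.", call. = FALSE)
  1 / mean_dwell
}

#' Closed-form mean depolymerization velocity of the two-state model
#'
#' The long-run time-averaged velocity implied by [kinetic_params()]:
#' a fraction occ * phi of the time the end is occupied by a productive
#' hexamer and loses subunits at `v_bound`; the rest of the time it loses
#' them at `v_unbound`:
#'
#'   v = occ phi v_bound + (1 - occ phi) v_unbound.
#'
#' This is the ergodic oracle against which the stochastic simulator is
#' tested.
#'
#' @param params a [kinetic_params()] object.
#'
#' @return Mean velocity in subunits/s.
#' @examples
#' p <- kinetic_params(1.1e7, 0.45, 83e-9, v_bound = 53, v_unbound = 0.43)
#' predicted_mean_velocity(p)  # ~35.6 subunits/s
#' @export
predicted_mean_velocity <- function(params) {
  stopifnot(inherits(params, "kinetic_params"))
  occ <- if (params$c == 0 || params$k_on == 0) 0 else {
    occupancy(params$c, params$k_on, params$k_off)
  }
  w <- occ * params$productive_fraction
  w * params$v_bound + (1 - w) * params$v_unbound
}
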