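#' Observable relaxation parameters of the double Kelvin-Voigt recoil model
#'
#' Container for the four parameters that are identifiable from a single
#' post-ablation displacement trace: the long-time displacements of the fast
#' and slow Kelvin-Voigt elements (\eqn{X_f}, \eqn{X_s}, in micrometres) and
#' their relaxation timescales (\eqn{\tau_f}, \eqn{\tau_s}, in seconds).
#' The model is symmetric under exchange of the two elements, so parameters
#' are stored in the canonical order \eqn{\tau_f \le \tau_s}: if the
#' arguments violate it, the (X, tau) pairs are swapped together.
#'
#' @param X_f,X_s long-time displacements of the fast and slow elements (um),
#'   strictly positive.
#' @param tau_f,tau_s relaxation timescales of the fast and slow elements (s),
#'   strictly positive.
#' @return An object of class `relaxation_params`: a named list with fields
#'   `X_f`, `X_s`, `tau_f`, `tau_s`.
#' @seealso [displacement()], [fit_relaxation()], [relaxation_from_mechanics()]
#' @examples
#' p <- relaxation_params(X_f = 2.2, X_s = 7.0, tau_f = 0.65, tau_s = 20)
#' displacement(c(0, 0.65, 5), p)
#' @export
relaxation_params <- function(X_f, X_s, tau_f, tau_s) {
  stopifnot_scalar(X_f, "X_f", positive = TRUE)
  stopifnot_scalar(X_s, "X_s", positive = TRUE)
  stopifnot_scalar(tau_f, "tau_f", positive = TRUE)
  stopifnot_scalar(tau_s, "tau_s", positive = TRUE)
  if (tau_f > tau_s) {  # canonical ordering: fast element first
    tmp <- tau_f; tau_f <- tau_s; tau_s <- tmp
    tmp <- X_f; X_f <- X_s; X_s <- tmp
  }
  structure(list(X_f = unname(X_f), X_s = unname(X_s),
                 tau_f = unname(tau_f), tau_s = unname(tau_s)),
            class = "relaxation_params")
}

#' @export
print.relaxation_params <- function(x, digits = 4, ...) {
  cat("Double Kelvin-Voigt relaxation parameters:\n")
  cat(sprintf("  fast: X_f = %.*g um, tau_f = %.*g s\n",
              digits, x$X_f, digits, x$tau_f))
  cat(sprintf("  slow: X_s = %.*g um, tau_s = %.*g s\n",
              digits, x$X_s, digits, x$tau_s))
  invisible(x)
}

#' Mechanical (circuit) parameters of the pre-ablation tissue model
#'
#' The pre-ablation state is a spring `k` (the cell patch that will be
#' ablated) in parallel with two Kelvin-Voigt elements in series (springs
#' `kf`, `ks`; dashpots `eta_f`, `eta_s`), all under a constant stress
#' `sigma`. Derived quantities: the series elasticity
#' \eqn{\bar k = k_f k_s / (k_f + k_s)}, the ablated elastic fraction
#' \eqn{\kappa = k / (k + \bar k) \in (0, 1)}, and the pre-ablation end-point
#' distance \eqn{x(0) = \sigma / (k + \bar k)}. Units are arbitrary but must
#' be consistent; only ratios are observable.
#'
#' @param sigma constant tissue stress (arbitrary force units).
#' @param k elastic constant of the ablated-cell spring.
#' @param kf,ks elastic constants of the fast and slow Kelvin-Voigt elements.
#' @param eta_f,eta_s viscosities of the fast and slow elements (force * time).
#' @return An object of class `mechanical_params` with fields `sigma`, `k`,
#'   `kf`, `ks`, `eta_f`, `eta_s` and derived `kbar`, `kappa`, `x0`.
#' @seealso [relaxation_from_mechanics()]
#' @export
mechanical_params <- function(sigma, k, kf, ks, eta_f, eta_s) {
  for (nm in c("sigma", "k", "kf", "ks", "eta_f", "eta_s"))
    stopifnot_scalar(get(nm), nm, positive = TRUE)
  kbar <- kf * ks / (kf + ks)
  kappa <- k / (k + kbar)
  stopifnot(kbar < min(kf, ks), kappa > 0, kappa < 1)
  structure(list(sigma = sigma, k = k, kf = kf, ks = ks,
                 eta_f = eta_f, eta_s = eta_s,
                 kbar = kbar, kappa = kappa, x0 = sigma / (k + kbar)),
            class = "mechanical_params")
}

#' @export
print.mechanical_params <- function(x, digits = 4, ...) {
  cat("Pre-ablation mechanical parameters (arbitrary units):\n")
  cat(sprintf("  sigma = %.*g, k = %.*g, kf = %.*g, ks = %.*g\n",
              digits, x$sigma, digits, x$k, digits, x$kf, digits, x$ks))
  cat(sprintf("  eta_f = %.*g, eta_s = %.*g\n", digits, x$eta_f, digits, x$eta_s))
  cat(sprintf("  derived: kbar = %.*g, kappa = %.*g, x(0) = %.*g\n",
              digits, x$kbar, digits, x$kappa, digits, x$x0))
  invisible(x)
}

#' Closed-form post-ablation membrane displacement
#'
#' Evaluates the double-exponential recoil
#' \eqn{\Delta x(t) = X_f(1 - e^{-t/\tau_f}) + X_s(1 - e^{-t/\tau_s})},
#' the solution of the two Kelvin-Voigt force-balance equations after the
#' ablated spring is removed. Non-negative, non-decreasing in `t`, saturating
#' at \eqn{X_f + X_s}.
#'
#' @param t time since ablation (s); vectorised, all values must be >= 0.
#' @param params a [relaxation_params()] object.
#' @return Displacement in micrometres, same length as `t`.
#' @export
displacement <- function(t, params) {
  stopifnot(inherits(params, "relaxation_params"))
  if (!is.numeric(t) || any(!is.finite(t)) || any(t < 0))
    stop("`t` must be finite and non-negative", call. = FALSE)
  params$X_f * (1 - exp(-t / params$tau_f)) +
    params$X_s * (1 - exp(-t / params$tau_s))
}

#' Map mechanical circuit parameters to observable relaxation parameters
#'
#' Computes \eqn{X_{f,s} = \sigma \kappa / k_{f,s}} and
#' \eqn{\tau_{f,s} = \eta_{f,s} / k_{f,s}} from the six circuit parameters.
#' The identity \eqn{X_f + X_s = \sigma/\bar k - \sigma/(k + \bar k)}
#' (new minus old equilibrium length) is verified on every call.
#'
#' @param mech a [mechanical_params()] object.
#' @return A [relaxation_params()] object with attributes `kappa`, `kbar`
#'   and `x0` carrying the mechanical derivation.
#' @export
relaxation_from_mechanics <- function(mech) {
  stopifnot(inherits(mech, "mechanical_params"))
  X_f <- mech$sigma * mech$kappa / mech$kf
  X_s <- mech$sigma * mech$kappa / mech$ks
  tau_f <- mech$eta_f / mech$kf
  tau_s <- mech$eta_s / mech$ks
  # new minus old equilibrium length; sigma*kappa/kbar is the cancellation-
  # free form of sigma/kbar - sigma/(k + kbar)
  total <- mech$sigma * mech$kappa / mech$kbar
  if (abs((X_f + X_s) - total) > 1e-10 * abs(total))
    stop("internal inconsistency: X_f + X_s != sigma*kappa/kbar")
  out <- relaxation_params(X_f = X_f, X_s = X_s, tau_f = tau_f, tau_s = tau_s)
  attr(out, "kappa") <- mech$kappa
  attr(out, "kbar") <- mech$kbar
  attr(out, "x0") <- mech$x0
  out
}

#' Initial recoil velocity over the dark ablation interval
#'
#' The mean recoil velocity over the first `delta_t` seconds (the unobserved
#' interval while the cutting laser fires):
#' \eqn{v = \Delta x(\delta t) / \delta t}. With the observed parameter
#' ranges this proxy is dominated by the fast mode.
#'
#' @param params a [relaxation_params()] object.
#' @param delta_t averaging interval in seconds (> 0); default 0.65, the
#'   first observed timepoint after a linear ablation.
#' @return Velocity in um/s.
#' @export
initial_recoil_velocity <- function(params, delta_t = 0.65) {
  stopifnot_scalar(delta_t, "delta_t", positive = TRUE)
  displacement(delta_t, params) / delta_t
}

#' Fast-mode share of the initial recoil velocity
#'
#' Fraction of the displacement accrued during `delta_t` that comes from the
#' fast Kelvin-Voigt element:
#' \eqn{X_f(1-e^{-\delta t/\tau_f}) / \Delta x(\delta t)}. Lies in (0, 1);
#' close to 1 when \eqn{\tau_f \approx \delta t \ll \tau_s} and
#' \eqn{X_s/\tau_s \ll X_f/\tau_f}.
#'
#' @inheritParams initial_recoil_velocity
#' @return Dimensionless fraction in (0, 1).
#' @export
fast_fraction <- function(params, delta_t = 0.65) {
  stopifnot(inherits(params, "relaxation_params"))
  stopifnot_scalar(delta_t, "delta_t", positive = TRUE)
  fast <- params$X_f * (1 - exp(-delta_t / params$tau_f))
  slow <- params$X_s * (1 - exp(-delta_t / params$tau_s))
  if (fast + slow <= 0)
    stop("both relaxed displacements are zero; fraction undefined", call. = FALSE)
  fast / (fast + slow)
}

#' Fraction of a mode's long-time displacement relaxed after a given time
#'
#' Returns \eqn{1 - e^{-\delta t/\tau}}, the share of a single exponential
#' mode's asymptotic displacement reached after `delta_t` seconds. Equals
#' about 0.63 at `delta_t = tau` and stays below 0.05 when
#' `delta_t <= tau/19`.
#'
#' @param tau relaxation timescale (s, > 0).
#' @param delta_t elapsed time (s, >= 0); vectorised.
#' @return Dimensionless fraction in \[0, 1).
#' @export
relaxed_fraction <- function(tau, delta_t) {
  stopifnot_scalar(tau, "tau", positive = TRUE)
  if (!is.numeric(delta_t) || any(!is.finite(delta_t)) || any(delta_t < 0))
    stop("`delta_t` must be finite and non-negative", call. = FALSE)
  1 - exp(-delta_t / tau)
}

#' Orientation difference of initial recoil velocities
#'
#' Signed difference \eqn{\delta v = v_{PD} - v_{AP}} between recoil
#' velocities measured with cuts perpendicular to the proximal-distal and
#' anterior-posterior axes; proportional to the shear stress along the PD
#' axis under the series-circuit model.
#'
#' @param v_pd,v_ap initial recoil velocities (um/s).
#' @return Signed difference in um/s (vectorised).
#' @export
recoil_anisotropy <- function(v_pd, v_ap) {
  stopifnot(is.numeric(v_pd), is.numeric(v_ap),
            all(is.finite(v_pd)), all(is.finite(v_ap)))
  v_pd - v_ap
}

#' Normalized active anisotropic stress from the constitutive relation
#'
#' Under the linear constitutive relation \eqn{\tilde\sigma = 2KQ + \zeta},
#' the active stress component normalized by the shear modulus is
#' \eqn{\zeta/2K = \tilde\sigma/2K - Q}. The normalized shear stress
#' \eqn{\tilde\sigma/2K} is an external measurement (e.g. from circular
#' ablation); `Q` is the PD component of mean cell elongation.
#'
#' @param normalized_shear_stress \eqn{\tilde\sigma/2K}, dimensionless.
#' @param Q mean PD cell elongation, dimensionless.
#' @return \eqn{\zeta/2K}, dimensionless (vectorised).
#' @export
active_stress <- function(normalized_shear_stress, Q) {
  stopifnot(is.numeric(normalized_shear_stress), is.numeric(Q),
            all(is.finite(normalized_shear_stress)), all(is.finite(Q)))
  normalized_shear_stress - Q
}
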