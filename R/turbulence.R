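# Lagrangian turbulence corrections: the K41 velocity-space analogue of the
# macroquantum machinery, where velocity increments scale as |dt|^(1/2) and
# the constant D_v = C0*eps/2 plays the role of D in velocity space.

#' Turbulence parameter set (K41 regime)
#'
#' Consistency relations `2 D_v = C0 * eps_diss` and `D_v = sigma_v^2 / T_L`
#' are checked when both sides are supplied.
#'
#' @param C0 Kolmogorov constant (literature range 4-9).
#' @param eps_diss energy dissipation rate per unit mass.
#' @param D_v velocity-space constant (defaults to `C0*eps_diss/2`).
#' @param sigma_v velocity dispersion.
#' @param T_L Lagrangian integral time.
#' @param L_int Lagrangian length scale.
#' @param sigma_a acceleration dispersion.
#' @param a0_dns,a0_exp normalized acceleration-variance constants.
#' @param nu_visc kinematic viscosity.
#' @return Object of class `turbulence_params`.
#' @export
turbulence_params <- function(C0 = 6, eps_diss = 1, D_v = NULL,
                              sigma_v = NULL, T_L = NULL, L_int = NULL,
                              sigma_a = NULL, a0_dns = NULL, a0_exp = NULL,
                              nu_visc = NULL) {
  stopifnot_positive(C0, "C0"); stopifnot_positive(eps_diss, "eps_diss")
  if (is.null(D_v)) D_v <- C0 * eps_diss / 2
  if (abs(2 * D_v - C0 * eps_diss) > 1e-9 * abs(C0 * eps_diss)) {
    stop("inconsistent parameters: 2*D_v must equal C0*eps_diss", call. = FALSE)
  }
  if (!is.null(sigma_v) && !is.null(T_L)) {
    if (abs(D_v - sigma_v^2 / T_L) > 1e-6 * D_v) {
      stop("inconsistent parameters: D_v must equal sigma_v^2/T_L", call. = FALSE)
    }
  }
  structure(list(C0 = C0, eps_diss = eps_diss, D_v = D_v, sigma_v = sigma_v,
                 T_L = T_L, L_int = L_int, sigma_a = sigma_a,
                 a0_dns = a0_dns, a0_exp = a0_exp, nu_visc = nu_visc),
            class = "turbulence_params")
}

#' Velocity-space constant from the K41 relation
#'
#' `D_v = C0 * eps / 2`.
#' @param C0 Kolmogorov constant, > 0.
#' @param eps_diss dissipation rate, > 0.
#' @export
dv_from_k41 <- function(C0, eps_diss) {
  stopifnot_positive(C0, "C0"); stopifnot_positive(eps_diss, "eps_diss")
  C0 * eps_diss / 2
}

#' Velocity-space quantum potential (Gaussian velocity PDF)
#'
#' For a centred 3D Maxwellian velocity distribution of dispersion
#' `sigma_v` per axis: `Q_v = -D_v^2 (v^2 - 6 sigma_v^2) / (2 sigma_v^4)`.
#' @param v speed (modulus of the velocity vector).
#' @param sigma_v velocity dispersion, > 0.
#' @param D_v velocity-space constant.
#' @export
velocity_quantum_potential <- function(v, sigma_v, D_v) {
  stopifnot_positive(sigma_v, "sigma_v")
  -D_v^2 * (v^2 - 6 * sigma_v^2) / (2 * sigma_v^4)
}

#' Repulsive position-space quantum force
#'
#' Time integral of the velocity-space quantum force:
#' `F_Qx = (D_v^2 / sigma_v^4) x`, a repulsive harmonic-oscillator force.
#' @param x position.
#' @param D_v velocity-space constant.
#' @param sigma_v velocity dispersion, > 0.
#' @export
position_quantum_force <- function(x, D_v, sigma_v) {
  stopifnot_positive(sigma_v, "sigma_v")
  (D_v^2 / sigma_v^4) * x
}

#' Total acceleration variance with the geometric correction
#'
#' `sigma_a^2 = (sigma_a)_cl^2 + (D_v^4 / sigma_v^8) sigma_x^2`.
#' @param sigma_a_cl classical acceleration dispersion.
#' @param D_v velocity-space constant (0 switches the correction off).
#' @param sigma_v velocity dispersion.
#' @param sigma_x positional dispersion (about the Lagrangian length `L`).
#' @return Total variance `sigma_a^2`.
#' @export
acceleration_variance_total <- function(sigma_a_cl, D_v, sigma_v, sigma_x) {
  stopifnot_positive(sigma_v, "sigma_v")
  sigma_a_cl^2 + (D_v^4 / sigma_v^8) * sigma_x^2
}

#' Classical fraction of the acceleration variance
#'
#' `(sigma_a)_cl^2 / sigma_a^2 = 1 - L^2 / (sigma_a^2 T_L^4)`; the companion
#' `intermediate` value is `L / (sigma_a T_L^2)`.  For the printed van Karman
#' experiment (sigma_a = 87 m/s^2, L = 0.071 m, T_L = 39 ms) the intermediate
#' ratio is 0.54 and the fraction about 2/3.
#'
#' @param L_int Lagrangian length scale.
#' @param sigma_a total acceleration dispersion.
#' @param T_L Lagrangian integral time.
#' @return list with `fraction` and `intermediate`.
#' @export
#' @examples
#' classical_fraction(0.071, 87, 0.039)$intermediate   # 0.54
classical_fraction <- function(L_int, sigma_a, T_L) {
  stopifnot_positive(sigma_a, "sigma_a"); stopifnot_positive(T_L, "T_L")
  if (L_int < 0) stop("L_int must be >= 0", call. = FALSE)
  r <- L_int / (sigma_a * T_L^2)
  if (r > 1) {
    stop("regime error: the geometric correction exceeds the total variance",
         call. = FALSE)
  }
  list(fraction = 1 - r^2, intermediate = r)
}

#' Geometric correction inferred from a0 constants
#'
#' `sqrt(1 - a0_dns / a0_exp)`: the fraction of the acceleration dispersion
#' attributable to the velocity-space quantum force, from the normalized
#' acceleration-variance constants of simulations vs experiment.
#' @param a0_dns simulation value (no quantum correction), > 0.
#' @param a0_exp experimental value, >= a0_dns.
#' @export
#' @examples
#' a0_geometric_correction(4.5, 6.2)   # about 0.52
a0_geometric_correction <- function(a0_dns, a0_exp) {
  stopifnot_positive(a0_dns, "a0_dns"); stopifnot_positive(a0_exp, "a0_exp")
  if (a0_dns > a0_exp) {
    stop("regime error: a0_dns must not exceed a0_exp", call. = FALSE)
  }
  sqrt(1 - a0_dns / a0_exp)
}

#' Lagrangian velocity-path simulator (K41 fluctuations)
#'
#' Simulates velocity paths `dV = dupsilon + zeta sqrt(2 D_v) |dt|^(1/2)`
#' (optionally with a linear Langevin friction `dupsilon = -V/T_fric dt`) and
#' reports: the log-log scaling exponent of the second-order structure
#' function over `lags`, the empirical `<dv^2>/dt` at the sampling
#' resolution, the empirical acceleration and acceleration-increment
#' dispersions, and the forward/backward derivative pair of the two-valued
#' velocity derivative.
#'
#' @param D_v velocity-space constant, > 0.
#' @param dt sampling step.
#' @param n_steps steps per path.
#' @param n_paths independent paths.
#' @param friction optional Langevin time constant `T_fric` (NULL: off).
#' @param seed RNG seed.
#' @param lags integration lags (in steps) for the structure function.
#' @return list with `paths`, `exponent`, `msd_rate`, `sigma_a`, `sigma_da`,
#'   `deriv_forward`, `deriv_backward`, `lag_dt`, `structure_fn`.
#' @export
lagrangian_velocity_simulator <- function(D_v, dt, n_steps, n_paths = 1,
                                          friction = NULL, seed = 1,
                                          lags = 2^(0:6)) {
  stopifnot_positive(D_v, "D_v"); stopifnot_positive(dt, "dt")
  V <- with_seed(seed, {
    zeta <- matrix(stats::rnorm(n_steps * n_paths), n_steps, n_paths)
    dxi <- zeta * sqrt(2 * D_v * dt)
    if (is.null(friction)) {
      rbind(0, apply(dxi, 2, cumsum))
    } else {
      out <- matrix(0, n_steps + 1, n_paths)
      for (s in seq_len(n_steps)) {
        out[s + 1, ] <- out[s, ] - out[s, ] / friction * dt + dxi[s, ]
      }
      out
    }
  })
  lags <- lags[lags < n_steps]
  sf <- vapply(lags, function(L) {
    dv <- V[-seq_len(L), , drop = FALSE] -
      V[seq_len(nrow(V) - L), , drop = FALSE]
    mean(dv^2)
  }, numeric(1))
  fit <- stats::lm(log(sf) ~ log(lags * dt))
  a <- diff(V) / dt                      # one-sided derivative samples
  da <- diff(a)
  # at interior sample s: forward uses (V[s+1]-V[s]), backward (V[s]-V[s-1]);
  # their difference is the second-difference X'' * |dt| of the Taylor pair
  list(paths = V,
       exponent = unname(stats::coef(fit)[2]),
       msd_rate = sf[1] / (lags[1] * dt),
       sigma_a = stats::sd(as.vector(a)),
       sigma_da = stats::sd(as.vector(da)),
       deriv_forward = a[-1, , drop = FALSE],
       deriv_backward = a[-nrow(a), , drop = FALSE],
       lag_dt = lags * dt, structure_fn = sf)
}
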