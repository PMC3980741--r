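#' Macroquantum parameters
#'
#' The self-organization constant `D` (dimension length^2/time) replaces
#' `hbar/2m` of standard quantum mechanics; together with the inertial
#' parameter `m` it fixes the action constant `S0 = 2*m*D`.  Setting
#' `D = hbar/(2*m)` recovers ordinary quantum mechanics exactly.
#'
#' @param D macroquantum constant, > 0.
#' @param m inertial parameter (mass), > 0.
#' @return Object of class `macro_params` with fields `D`, `m`, `S0`.
#' @export
#' @examples
#' p <- macro_params(D = 0.5, m = 1)
#' p$S0   # 1
macro_params <- function(D, m = 1) {
  stopifnot_positive(D, "D")
  stopifnot_positive(m, "m")
  structure(list(D = D, m = m, S0 = 2 * m * D), class = "macro_params")
}

#' @export
print.macro_params <- function(x, ...) {
  cat(sprintf("<macro_params> D = %g, m = %g, S0 = 2mD = %g\n", x$D, x$m, x$S0))
  invisible(x)
}

#' Generalized Compton length
#'
#' `lambda_C = 2*D/c`; with `S0 = hbar` this is the usual `hbar/(m*c)`.
#'
#' @param params a [macro_params()] object.
#' @param c_vel velocity scale, > 0.
#' @export
compton_length <- function(params, c_vel) {
  stopifnot_positive(c_vel, "c_vel")
  2 * params$D / c_vel
}

#' Exterior potential specification
#'
#' Either a named analytic generator or a custom field sampled on the grid.
#' `beta` is the coefficient of the optional Ginzburg-Landau cubic term
#' `2*m*beta*|psi|^2*psi` (beta = c_s^2 / (2 rho_0) in the acoustic
#' derivation); it must be >= 0.
#'
#' @param kind `"box"` (phi = 0, confinement from the Dirichlet walls),
#'   `"harmonic"` (phi = m/2 * sum_k omega_k^2 (x_k - center_k)^2) or
#'   `"custom"`.
#' @param omega angular frequency (scalar or per axis), harmonic case.
#' @param center trap centre (harmonic case), default mid-domain.
#' @param phi field array matching the grid (custom case).
#' @param beta nonlinear coefficient, >= 0.
#' @return Object of class `potential_spec`.
#' @export
potential_spec <- function(kind = c("box", "harmonic", "custom"),
                           omega = 1, center = NULL, phi = NULL, beta = 0) {
  kind <- match.arg(kind)
  if (beta < 0) stop("beta must be >= 0", call. = FALSE)
  if (kind == "custom" && is.null(phi)) {
    stop("custom potential needs `phi`", call. = FALSE)
  }
  structure(list(kind = kind, omega = omega, center = center,
                 phi = phi, beta = beta),
            class = "potential_spec")
}

#' Sample a potential on a grid
#'
#' @param pot a [potential_spec()].
#' @param grid an [grid_spec()] grid.
#' @param params [macro_params()] (the harmonic potential scales with `m`).
#' @return Array of potential energies over the grid.
#' @export
potential_field <- function(pot, grid, params) {
  if (pot$kind == "box") {
    return(as_field_array(rep(0, grid_npoints(grid)), grid))
  }
  if (pot$kind == "custom") {
    phi <- pot$phi
    if (length(phi) != grid_npoints(grid)) {
      stop("custom phi does not match the grid", call. = FALSE)
    }
    if (any(!is.finite(phi))) stop("phi must be finite", call. = FALSE)
    return(as_field_array(phi, grid))
  }
  omega <- rep_len(pot$omega, grid$ndim)
  center <- if (is.null(pot$center)) {
    grid$origin + grid$extent / 2
  } else rep_len(pot$center, grid$ndim)
  co <- grid_coords(grid)
  out <- 0
  for (k in seq_len(grid$ndim)) {
    out <- out + 0.5 * params$m * omega[k]^2 * (co[[k]] - center[k])^2
  }
  as_field_array(out, grid)
}

#' Complex wave field on a grid
#'
#' @param psi complex values over the grid (any shape of the right length).
#' @param grid [grid_spec()] grid.
#' @param params [macro_params()].
#' @param t time stamp.
#' @param normalize renormalize so that `sum(|psi|^2) * dV = 1`.
#' @return Object of class `wave_field` with fields `psi`, `grid`, `params`, `t`.
#' @export
wave_field <- function(psi, grid, params, t = 0, normalize = TRUE) {
  if (length(psi) != grid_npoints(grid)) {
    stop("psi length does not match the grid", call. = FALSE)
  }
  if (any(!is.finite(Re(psi))) || any(!is.finite(Im(psi)))) {
    stop("psi must be finite", call. = FALSE)
  }
  psi <- as_field_array(as.complex(psi), grid)
  if (normalize) {
    nrm <- sqrt(cell_integral(Mod(psi)^2, grid))
    if (nrm == 0) stop("cannot normalize the zero field", call. = FALSE)
    psi <- psi / nrm
  }
  structure(list(psi = psi, grid = grid, params = params, t = t),
            class = "wave_field")
}

#' @export
print.wave_field <- function(x, ...) {
  cat(sprintf("<wave_field> t = %g, norm = %.8f on ", x$t,
              cell_integral(Mod(x$psi)^2, x$grid)))
  print(x$grid)
  invisible(x)
}

#' Squared-modulus density of a wave field
#' @param w a [wave_field()].
#' @export
density_of <- function(w) Mod(w$psi)^2
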