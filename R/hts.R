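# Dopant-trap model of high-Tc superconductivity: the static dopant charge
# density n_d creates a microscopic quantum potential Q_d in which the
# superfluid fraction of carriers is trapped and paired.  This branch runs
# in ordinary quantum units: D = hbar/(2 m_e), so 2 m D^2 = hbar^2/(2 m_e).

#' Dopant charge-density model
#'
#' @param n_d static dopant-charge density field (>= 0, not identically 0).
#' @param grid [grid_spec()] grid.
#' @param hbar action constant (default 1, natural units).
#' @param m_e carrier mass.
#' @param phi_ext optional external potential array (default 0).
#' @return Object of class `dopant_model`.
#' @export
dopant_model <- function(n_d, grid, hbar = 1, m_e = 1, phi_ext = NULL) {
  n_d <- as_field_array(n_d, grid)
  if (any(n_d < 0)) stop("n_d must be >= 0", call. = FALSE)
  if (all(n_d == 0)) stop("n_d is identically zero", call. = FALSE)
  stopifnot_positive(hbar, "hbar"); stopifnot_positive(m_e, "m_e")
  phi_ext <- if (is.null(phi_ext)) as_field_array(0 * n_d, grid)
  else as_field_array(phi_ext, grid)
  structure(list(n_d = n_d, grid = grid, hbar = hbar, m_e = m_e,
                 phi_ext = phi_ext,
                 params = macro_params(D = hbar / (2 * m_e), m = m_e)),
            class = "dopant_model")
}

#' Quantum potential of the dopant charge density
#'
#' `Q_d = -(hbar^2 / 2 m_e) Lap(sqrt n_d)/sqrt(n_d)`: local density minima
#' (the dopant sites) generate potential wells for the superfluid carriers.
#' @param model a [dopant_model()].
#' @param floor_frac density floor.
#' @return Energy field (NA on masked cells).
#' @export
dopant_quantum_potential <- function(model, floor_frac = 1e-12) {
  Qd <- quantum_potential(model$n_d, model$grid, model$params, floor_frac)
  if (model$grid$ndim == 1 && model$grid$boundary == "box") {
    # n_d does not vanish at the walls, so the Dirichlet ghost cells distort
    # Lap(sqrt n_d) in the two border cells; continue from the interior
    n <- length(Qd)
    Qd[1] <- Qd[2]; Qd[n] <- Qd[n - 1]
  }
  Qd
}

#' Bound states in the dopant-induced well
#'
#' Solves the stationary problem in the total potential
#' `phi_ext + Q_d` with the microscopic constants and counts states bound
#' below the asymptotic (boundary) potential level.  An empty result is a
#' valid outcome (no trapping).
#'
#' @param model a [dopant_model()].
#' @param n_states eigenpairs to compute.
#' @return list with `solution` ([stationary_states()] output), `n_bound`,
#'   `asymptote` (boundary potential level).
#' @export
dopant_bound_states <- function(model, n_states = 4) {
  Qd <- dopant_quantum_potential(model)
  Qd[is.na(Qd)] <- 0
  Vtot <- model$phi_ext + Qd
  asym <- if (model$grid$ndim == 1) {
    k <- max(2L, length(Vtot) %/% 10)
    mean(Vtot[c(k, length(Vtot) - k + 1L)])
  } else {
    mean(Vtot[slice.index(Vtot, 1) %in% c(2, dim(Vtot)[1] - 1)])
  }
  pot <- potential_spec("custom", phi = Vtot)
  sol <- stationary_states(pot, model$grid, model$params, n_states)
  list(solution = sol, n_bound = sum(sol$energies < asym - 1e-10 * max(abs(Vtot), 1)),
       asymptote = asym)
}

#' Superfluid fraction from charge counting
#'
#' `n_s / n_n = n_paired / (n_total_charges + n_paired)`: with the optimal
#' configuration of 4 dopant defects bringing 8 charges and one trapped
#' pair, 2/(8+2) = 0.2, the observed optimal-doping value.
#' @param n_paired paired carriers per well, >= 0.
#' @param n_total_charges doping-induced charges per well, > 0.
#' @export
#' @examples
#' superfluid_fraction(2, 8)   # 0.2
superfluid_fraction <- function(n_paired, n_total_charges) {
  stopifnot_positive(n_total_charges, "n_total_charges")
  if (n_paired < 0 || n_paired > n_total_charges + n_paired) {
    stop("need 0 <= n_paired", call. = FALSE)
  }
  n_paired / (n_total_charges + n_paired)
}

#' Side length of a dopant potential well
#'
#' The `n_charges` doping charges at doping fraction `p` occupy
#' `n_charges / p` lattice cells, i.e. a square of side
#' `sqrt(n_charges / p) * d_unit`.  At optimal doping `p = 1/6.5` with 8-10
#' charges and `d_unit` = 3.9 Angstroms this gives the observed 28-32
#' Angstrom wells.
#' @param p_doping doping fraction in (0, 1].
#' @param n_charges charges per well, > 0.
#' @param d_unit lattice constant (default 1: result in lattice units).
#' @export
#' @examples
#' well_side_length(1/6.5, 8)        # sqrt(52) = 7.2 lattice units
#' well_side_length(1/6.5, 8, 3.9)   # about 28 Angstroms
well_side_length <- function(p_doping, n_charges, d_unit = 1) {
  if (p_doping <= 0 || p_doping > 1) {
    stop("p_doping must lie in (0, 1]", call. = FALSE)
  }
  stopifnot_positive(n_charges, "n_charges")
  stopifnot_positive(d_unit, "d_unit")
  sqrt(n_charges / p_doping) * d_unit
}
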