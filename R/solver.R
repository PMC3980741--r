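#' Discretized Hamiltonian matrix
#'
#' Builds the dense symmetric operator `H = -(S0^2/2m) Lap + phi` =
#' `-2 m D^2 Lap + phi` on the grid (second-order central Laplacian,
#' Dirichlet or periodic closure).  Symmetry is exact by construction and is
#' asserted before the matrix is returned.
#'
#' @param pot a [potential_spec()].
#' @param grid an [grid_spec()] grid.
#' @param params [macro_params()].
#' @return Dense symmetric matrix of size `prod(grid$n)`.
#' @export
hamiltonian_matrix <- function(pot, grid, params) {
  ntot <- grid_npoints(grid)
  if (ntot > 4096) {
    stop("dense Hamiltonian limited to 4096 grid points; coarsen the grid",
         call. = FALSE)
  }
  H <- -(params$S0^2 / (2 * params$m)) * laplacian_matrix(grid)
  phi <- as.vector(potential_field(pot, grid, params))
  diag(H) <- diag(H) + phi
  if (max(abs(H - t(H))) != 0) {
    stop("internal error: discretized Hamiltonian is not symmetric",
         call. = FALSE)
  }
  H
}

#' Stationary states of the generalized Schrodinger equation
#'
#' Lowest eigenpairs of `-2 m D^2 Lap psi + phi psi = E psi`.  With
#' `S0 = 2mD` set to `hbar` this is the ordinary time-independent
#' Schrodinger problem; for a harmonic trap the spectrum is
#' `E_n = 2 m D omega (n + 1/2)` and for a Dirichlet box of width `a`,
#' `E_n = 2 m D^2 pi^2 n^2 / a^2`.
#'
#' @inheritParams hamiltonian_matrix
#' @param n_states number of eigenpairs to return (>= 1).
#' @return Object of class `eigen_solution`: list with `energies` (ascending)
#'   and `states` (list of normalized [wave_field()]s).
#' @export
#' @examples
#' g <- grid_spec(200, extent = 20, origin = -10)
#' p <- macro_params(D = 0.5)
#' sol <- stationary_states(potential_spec("harmonic", omega = 1), g, p, 3)
#' sol$energies          # close to (0.5, 1.5, 2.5)
stationary_states <- function(pot, grid, params, n_states = 1) {
  if (n_states < 1) stop("n_states must be >= 1", call. = FALSE)
  H <- hamiltonian_matrix(pot, grid, params)
  es <- eigen(H, symmetric = TRUE)
  ntot <- nrow(H)
  idx <- ntot:(ntot - n_states + 1)          # eigen() sorts descending
  energies <- es$values[idx]
  states <- lapply(seq_len(n_states), function(j) {
    v <- es$vectors[, idx[j]]
    # fix sign convention: positive lobe first
    k <- which(abs(v) > 1e-3 * max(abs(v)))[1]
    if (v[k] < 0) v <- -v
    wave_field(v, grid, params, t = 0, normalize = TRUE)
  })
  structure(list(energies = energies, states = states,
                 n_states = n_states, grid = grid, params = params),
            class = "eigen_solution")
}

#' @export
print.eigen_solution <- function(x, ...) {
  cat(sprintf("<eigen_solution> %d states, E = %s\n", x$n_states,
              paste(signif(x$energies, 6), collapse = ", ")))
  invisible(x)
}

#' Unitary time evolution (Crank-Nicolson / implicit midpoint)
#'
#' Integrates `i S0 dpsi/dt = -2 m D^2 Lap psi + phi psi +
#' 2 m beta |psi|^2 psi`.  The linear part uses the Cayley propagator
#' `(1 + i dt H / 2 S0)^-1 (1 - i dt H / 2 S0)`, which is exactly unitary;
#' a nonlinear `beta > 0` term is handled by Strang splitting with a local
#' phase rotation, which conserves the norm as well.
#'
#' @param w initial [wave_field()].
#' @param pot [potential_spec()] (its `beta` activates the cubic term).
#' @param dt time step (> 0).  A warning is issued above the resolution
#'   bound `h^2/(2 D)`.
#' @param n_steps number of steps.
#' @return Evolved [wave_field()] with `t` advanced by `n_steps * dt`.
#' @export
evolve <- function(w, pot, dt, n_steps) {
  if (!is.numeric(dt) || !is.finite(dt) || dt == 0) {
    stop("`dt` must be finite and non-zero (negative steps run backwards)",
         call. = FALSE)
  }
  grid <- w$grid; params <- w$params
  if (abs(dt) > min(grid$spacing)^2 / (2 * params$D)) {
    warning("dt exceeds h^2/(2D); phase accuracy may be poor", call. = FALSE)
  }
  H <- hamiltonian_matrix(pot, grid, params)
  ntot <- nrow(H)
  A <- diag(ntot) + (1i * dt / (2 * params$S0)) * H
  B <- diag(ntot) - (1i * dt / (2 * params$S0)) * H
  U <- solve(A, B)
  psi <- as.vector(w$psi)
  beta <- pot$beta
  half_nl <- function(psi) {
    if (beta == 0) return(psi)
    psi * exp(-1i * (2 * params$m * beta) * Mod(psi)^2 * dt / (2 * params$S0))
  }
  for (s in seq_len(n_steps)) {
    psi <- half_nl(psi)
    psi <- U %*% psi
    psi <- half_nl(psi)
    if (any(!is.finite(Re(psi)))) {
      stop("numerical blow-up at step ", s, call. = FALSE)
    }
  }
  wave_field(as.vector(psi), grid, params, t = w$t + n_steps * dt,
             normalize = FALSE)
}

#' Explicit fractal solution in a 1D box
#'
#' Partial sum `psi(x,t) = (1/pi) * sum_{n=-N}^{N} (-1)^n (n+1/2)^{-1}
#' exp{i pi [2 x (n+1/2) - t (n+1/2)^2]}`, a solution of
#' `i dpsi/dt = -(1/(4 pi)) d2psi/dx2` whose density develops structure on
#' all scales down to `~1/N`.  The 2D product form `psi(x) psi(y)` is
#' available via `product_2d`.
#'
#' @param N truncation order, >= 1.
#' @param t dimensionless time.
#' @param x positions in `[0, 1]`.
#' @param y optional second coordinate; if given, returns the outer product
#'   field `psi(x) psi(y)` as a matrix.
#' @return Complex vector (or matrix for the 2D product form).
#' @export
#' @examples
#' psi0 <- fractal_box_solution(1000, 0, 0.25)
#' Mod(psi0)^2     # close to 1 away from x = 1/2
fractal_box_solution <- function(N, t, x, y = NULL) {
  if (N < 1) stop("N must be >= 1", call. = FALSE)
  nn <- seq(-N, N)
  coef <- (-1)^nn / (nn + 0.5)
  eval_1d <- function(x) {
    M <- exp(1i * pi * (outer(2 * x, nn + 0.5) -
                          matrix(t * (nn + 0.5)^2, length(x), length(nn),
                                 byrow = TRUE)))
    as.vector(M %*% coef) / pi
  }
  px <- eval_1d(x)
  if (is.null(y)) return(px)
  outer(px, eval_1d(y))
}
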