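# Direct integration of the fluid representations: continuity + Euler with
# the macroquantum potential (Madelung route), its sign-reversed diffusive
# twin, and the Fokker-Planck equation of the (P, v+) representation.

#' Evolve the hydrodynamic representation (continuity + Euler)
#'
#' Integrates the continuity + Euler system with the macroquantum potential
#' by the Lagrangian quantum-trajectory method: the grid nodes become fluid
#' particles `X(t)` carrying the initial density, `dX/dt = V`,
#' `m dV/dt = -grad(phi) - grad(Q)`, and the density follows from the
#' deformation Jacobian `P = P0 / J`.  In the co-moving frame the amplitude
#' retains full relative precision at any tail depth, which makes the
#' quantum force well conditioned without density floors (an Eulerian
#' finite-difference Madelung scheme loses the Schrodinger-Madelung
#' cancellation at grid scale in low-density regions).  One dimensional;
#' the flow must be nodeless (the potential-flow description fails on
#' nodes, which are genuine caustics of the trajectory fluid).
#'
#' `quantum = "off"` drops Q (classical pressureless flow);
#' `quantum = "reversed"` flips its sign, which turns the dynamics into the
#' hydrodynamical form of a standard diffusion process.
#'
#' Validity notes.  Like every direct discretization of the Madelung
#' system, the scheme is accurate while the density contrast across the
#' domain stays bounded: relative perturbations in the hydrodynamic
#' variables amplify like the inverse amplitude as they travel down a
#' density slope, so flows with very deep tails (a Gaussian wave packet on
#' a wide domain has contrasts beyond 1e12) lose the two-route
#' Schrodinger-Madelung agreement over long horizons and eventually trip
#' the caustic detector.  Periodic nodeless flows of order-unity contrast
#' are unconditionally comfortable.  The reversed branch is ill-posed off
#' the diffusion manifold (spurious modes grow like a backward heat
#' equation at grid scale): it is meant for short-horizon diagnostics.
#'
#' @param h initial [hydro_field()] (1D, nodeless density).
#' @param pot [potential_spec()] exterior potential.
#' @param dt time step.
#' @param n_steps number of steps.
#' @param quantum `"on"`, `"off"` or `"reversed"`.
#' @param j_min Jacobian floor: a trajectory-crossing (caustic) diagnostic
#'   is raised when the local Jacobian falls below it.
#' @return Evolved [hydro_field()] (densities re-interpolated to the
#'   grid, with constant continuation at the ends of the particle span).
#' @export
evolve_hydro <- function(h, pot, dt, n_steps,
                         quantum = c("on", "off", "reversed"),
                         j_min = 0.05) {
  quantum <- match.arg(quantum)
  stopifnot_positive(dt, "dt")
  grid <- h$grid; params <- h$params
  if (grid$ndim != 1) {
    stop("evolve_hydro integrates 1D flows", call. = FALSE)
  }
  sgn <- switch(quantum, on = 1, off = 0, reversed = -1)
  h0 <- grid$spacing[1]
  X0 <- grid$axes[[1]]
  phi_grid <- potential_field(pot, grid, params)
  phix_fun <- if (pot$kind == "harmonic") {
    omega <- rep_len(pot$omega, 1)
    center <- if (is.null(pot$center)) grid$origin + grid$extent / 2 else pot$center
    function(x) params$m * omega^2 * (x - center)
  } else if (pot$kind == "box") {
    function(x) 0 * x
  } else {
    dfun <- stats::splinefun(X0, phi_grid)
    function(x) dfun(x, deriv = 1)
  }
  a0 <- sqrt(pmax(h$P, 0))
  if (min(h$P) <= 0) {
    stop("evolve_hydro needs a strictly positive (nodeless) density",
         call. = FALSE)
  }
  periodic <- grid$boundary == "periodic"
  # uniform central differences in the reference coordinate X0
  d0 <- if (periodic) {
    function(f) {
      n <- length(f)
      (f[c(2:n, 1)] - f[c(n, 1:(n - 1))]) / (2 * h0)
    }
  } else {
    function(f) {
      n <- length(f)
      c(-1.5 * f[1] + 2 * f[2] - 0.5 * f[3],
        (f[3:n] - f[1:(n - 2)]) / 2,
        1.5 * f[n] - 2 * f[n - 1] + 0.5 * f[n - 2]) / h0
    }
  }
  dd0 <- if (periodic) {
    function(f) {
      n <- length(f)
      (f[c(2:n, 1)] - 2 * f + f[c(n, 1:(n - 1))]) / h0^2
    }
  } else {
    function(f) {
      n <- length(f)
      c(2 * f[1] - 5 * f[2] + 4 * f[3] - f[4],
        f[3:n] - 2 * f[2:(n - 1)] + f[1:(n - 2)],
        2 * f[n] - 5 * f[n - 1] + 4 * f[n - 2] - f[n - 3]) / h0^2
    }
  }
  la0 <- log(a0)
  jac <- function(X) {
    if (periodic) 1 + d0(X - X0) else d0(X)
  }
  rhs <- function(X, V) {
    J <- jac(X)
    if (min(J) < j_min) {
      stop("caustic detected: fluid trajectories cross (Jacobian below ",
           j_min, "); the potential-flow description fails", call. = FALSE)
    }
    dV <- -phix_fun(X) / params$m
    if (sgn != 0) {
      # Q/m = -2 D^2 (d2a/dx2)/a via log-amplitude in the reference frame:
      # ln a = ln a0 - ln(J)/2 keeps relative precision at any tail depth
      la <- la0 - 0.5 * log(J)
      lap <- d0(la); lapp <- dd0(la)
      # (a''/a) in x: ((la'' + la'^2) - la' J'/J) / J^2   (' = d/dX0)
      Jp <- d0(J)
      ratio <- (lapp + lap^2 - lap * Jp / J) / J^2
      Q_over_m <- -2 * params$D^2 * ratio
      dV <- dV - sgn * d0(Q_over_m) / J
    }
    list(dX = V, dV = dV)
  }
  X <- X0
  V <- h$V[[1]]; V[is.na(V)] <- 0
  for (s in seq_len(n_steps)) {
    k1 <- rhs(X, V)
    k2 <- rhs(X + dt / 2 * k1$dX, V + dt / 2 * k1$dV)
    k3 <- rhs(X + dt / 2 * k2$dX, V + dt / 2 * k2$dV)
    k4 <- rhs(X + dt * k3$dX, V + dt * k3$dV)
    X <- X + dt / 6 * (k1$dX + 2 * k2$dX + 2 * k3$dX + k4$dX)
    V <- V + dt / 6 * (k1$dV + 2 * k2$dV + 2 * k3$dV + k4$dV)
    if (any(!is.finite(X)) || any(!is.finite(V))) {
      stop("numerical blow-up at step ", s, call. = FALSE)
    }
  }
  J <- jac(X)
  if (min(J) < j_min) {
    stop("caustic detected: fluid trajectories cross at the final state",
         call. = FALSE)
  }
  P_part <- h$P / J
  # back to the Eulerian grid (log-linear interpolation preserves the tails)
  if (periodic) {
    L <- grid$extent[1]
    Xw <- ((X - grid$origin[1]) %% L) + grid$origin[1]
    ord <- order(Xw)
    Xs <- Xw[ord]; Ps <- P_part[ord]; Vs <- V[ord]
    Xe <- c(Xs[length(Xs)] - L, Xs, Xs[1] + L)
    lp_fun <- stats::approxfun(Xe, log(c(Ps[length(Ps)], Ps, Ps[1])))
    v_fun <- stats::approxfun(Xe, c(Vs[length(Vs)], Vs, Vs[1]))
  } else {
    lp_fun <- stats::approxfun(X, log(P_part), rule = 2)
    v_fun <- stats::approxfun(X, V, rule = 2)
  }
  lp <- lp_fun(X0)
  P_grid <- ifelse(is.na(lp), 0, exp(lp))
  hydro_field(P_grid, list(v_fun(X0)), grid, params, t = h$t + n_steps * dt,
              normalize = FALSE)
}

#' Evolve the diffusive (Fokker-Planck) representation
#'
#' Forward: `dP/dt + div(P v+) = +D Lap P`.  The backward equation
#' `dP/dt + div(P v-) = -D Lap P` is only integrated in paired mode
#' (`paired = TRUE`), with `v- = v+ - 2 D grad(ln P)` slaved to the current
#' density: it is a consequence of the dynamics, not a founding equation of
#' any classical process, and both modes then propagate the same density.
#'
#' @param d initial [diffusive_field()].
#' @param dt time step.
#' @param n_steps steps.
#' @param sign `"forward"` or `"backward"`.
#' @param paired required for `"backward"`.
#' @param positivity_tol largest tolerated negative excursion of `P`
#'   (fraction of `max(P)`).
#' @return Evolved [diffusive_field()].
#' @export
evolve_fokker_planck <- function(d, dt, n_steps,
                                 sign = c("forward", "backward"),
                                 paired = FALSE, positivity_tol = 1e-8) {
  sign <- match.arg(sign)
  stopifnot_positive(dt, "dt")
  if (sign == "backward" && !paired) {
    stop("the backward equation is only integrated in paired mode",
         call. = FALSE)
  }
  grid <- d$grid; params <- d$params
  vp <- lapply(d$v_plus, function(v) { v[is.na(v)] <- 0; v })
  rhs <- function(P) {
    if (sign == "forward") {
      PV <- lapply(vp, function(v) P * v)
      -fd_divergence(PV, grid) + params$D * fd_laplacian(P, grid)
    } else {
      # backward equation with v- slaved to v+ - 2 D grad(ln P).  Staggered
      # half-point fluxes keep the discrete cancellation against the
      # anti-diffusive -D Lap P term exact at every wavenumber (a centred
      # 2h stencil would leave grid-scale modes fully anti-diffused).
      per <- grid$boundary == "periodic"
      lp <- log(pmax(P, .Machine$double.xmin))
      out <- -params$D * fd_laplacian(P, grid)
      for (k in seq_along(vp)) {
        hk <- grid$spacing[k]
        Pface <- (P + shift_array(P, 1L, k, per)) / 2
        vface <- (vp[[k]] + shift_array(vp[[k]], 1L, k, per)) / 2
        dlp <- (shift_array(lp, 1L, k, per) - lp) / hk
        flux <- Pface * (vface - 2 * params$D * dlp)
        out <- out - (flux - shift_array(flux, -1L, k, per)) / hk
      }
      out
    }
  }
  P <- d$P
  for (s in seq_len(n_steps)) {
    k1 <- rhs(P); k2 <- rhs(P + dt / 2 * k1)
    k3 <- rhs(P + dt / 2 * k2); k4 <- rhs(P + dt * k3)
    P <- P + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (min(P) < -positivity_tol * max(P)) {
      stop("density lost positivity at step ", s, call. = FALSE)
    }
    P[P < 0] <- 0
    if (any(!is.finite(P))) stop("numerical blow-up at step ", s, call. = FALSE)
  }
  diffusive_field(P, d$v_plus, grid, params, t = d$t + n_steps * dt,
                  normalize = FALSE)
}

#' Gibbs entropy of a density
#'
#' `S = -integral P ln(P) dV`, with `P ln P -> 0` at vanishing density.
#' Strictly increasing along a diffusive flow.
#' @param P density array (or [hydro_field()]/[diffusive_field()]).
#' @param grid grid (unless carried by `P`).
#' @export
gibbs_entropy <- function(P, grid = NULL) {
  if (inherits(P, "hydro_field") || inherits(P, "diffusive_field")) {
    grid <- P$grid; P <- P$P
  }
  integrand <- ifelse(P > 0, P * log(P), 0)
  -cell_integral(integrand, grid)
}
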