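# Interconversion among the equivalent representations of the macroquantum
# dynamics: wave psi, hydrodynamic (P, V) with quantum potential Q, two-fluid
# (V, U), and diffusive (P, v+) with Q+.  All logarithmic/ratio quantities
# are masked (NA) where P falls below a floor fraction of its maximum: the
# continuum formulas are singular on the zero-density "walls".

node_mask <- function(P, floor_frac = 1e-12) P > floor_frac * max(P)

mask_na <- function(f, mask) { f[!mask] <- NA_real_; f }

#' Hydrodynamic field (P, V)
#'
#' @param P probability density (unit integral after normalization).
#' @param V velocity field: list of component arrays, one per axis (a single
#'   array is accepted in 1D).
#' @param grid [grid_spec()] grid.
#' @param params [macro_params()].
#' @param t time stamp.
#' @param normalize renormalize `P` to unit integral.
#' @export
hydro_field <- function(P, V, grid, params, t = 0, normalize = TRUE) {
  P <- as_field_array(P, grid)
  if (any(P < -1e-12 * max(abs(P)))) stop("P must be >= 0", call. = FALSE)
  P[P < 0] <- 0
  if (normalize) P <- P / cell_integral(P, grid)
  if (!is.list(V)) V <- list(V)
  if (length(V) != grid$ndim) stop("V needs one component per axis", call. = FALSE)
  V <- lapply(V, as_field_array, grid = grid)
  structure(list(P = P, V = V, grid = grid, params = params, t = t),
            class = "hydro_field")
}

#' Diffusive field (P, v+)
#'
#' @param P probability density.
#' @param v_plus forward drift velocity field (list of component arrays).
#' @inheritParams hydro_field
#' @export
diffusive_field <- function(P, v_plus, grid, params, t = 0, normalize = TRUE) {
  P <- as_field_array(P, grid)
  if (any(P < -1e-12 * max(abs(P)))) stop("P must be >= 0", call. = FALSE)
  P[P < 0] <- 0
  if (normalize) P <- P / cell_integral(P, grid)
  if (!is.list(v_plus)) v_plus <- list(v_plus)
  if (length(v_plus) != grid$ndim) {
    stop("v_plus needs one component per axis", call. = FALSE)
  }
  v_plus <- lapply(v_plus, as_field_array, grid = grid)
  structure(list(P = P, v_plus = v_plus, grid = grid, params = params, t = t),
            class = "diffusive_field")
}

#' Wave to hydrodynamic representation
#'
#' `P = |psi|^2`, `V = 2 D grad(theta)` computed through the node-robust
#' identity `V = 2 D Im(conj(psi) grad psi) / |psi|^2`; `V` is masked (NA)
#' where `P` is below the node floor.
#'
#' @param w a [wave_field()].
#' @param floor_frac node floor as fraction of `max(P)`.
#' @return A [hydro_field()].
#' @export
wave_to_hydro <- function(w, floor_frac = 1e-12) {
  P <- density_of(w)
  mask <- node_mask(P, floor_frac)
  g <- fd_gradient(w$psi, w$grid)
  V <- lapply(g, function(gk) {
    mask_na(2 * w$params$D * Im(Conj(w$psi) * gk) / pmax(P, .Machine$double.xmin),
            mask)
  })
  hydro_field(P, V, w$grid, w$params, t = w$t, normalize = FALSE)
}

# Integrate a velocity field / (2D) into a phase along a spanning tree
# (first axis line, then the remaining axes), trapezoid rule.  1D/2D only.
integrate_phase <- function(V, grid, params) {
  f <- lapply(V, function(v) { v[is.na(v)] <- 0; v / (2 * params$D) })
  h <- grid$spacing
  if (grid$ndim == 1) {
    fx <- f[[1]]
    th <- c(0, cumsum(0.5 * (fx[-length(fx)] + fx[-1]) * h[1]))
    return(th)
  }
  if (grid$ndim == 2) {
    n1 <- grid$n[1]; n2 <- grid$n[2]
    th <- matrix(0, n1, n2)
    fx <- f[[1]][, 1]
    th[, 1] <- c(0, cumsum(0.5 * (fx[-n1] + fx[-1]) * h[1]))
    fy <- f[[2]]
    incr <- 0.5 * (fy[, -n2, drop = FALSE] + fy[, -1, drop = FALSE]) * h[2]
    th[, -1] <- th[, 1] + t(apply(incr, 1, cumsum))
    return(th)
  }
  stop("phase reconstruction supports 1D and 2D grids", call. = FALSE)
}

# Maximal elementary-loop circulation of V/(2D), in radians (2D grids).
loop_residual <- function(V, grid, params) {
  if (grid$ndim == 1) return(0)
  if (grid$ndim != 2) stop("loop check supports 1D and 2D grids", call. = FALSE)
  fx <- V[[1]] / (2 * params$D); fy <- V[[2]] / (2 * params$D)
  fx[is.na(fx)] <- 0; fy[is.na(fy)] <- 0
  n1 <- grid$n[1]; n2 <- grid$n[2]; h <- grid$spacing
  i <- 1:(n1 - 1); j <- 1:(n2 - 1)
  circ <- 0.5 * (fx[i, j] + fx[i + 1, j]) * h[1] +
    0.5 * (fy[i + 1, j] + fy[i + 1, j + 1]) * h[2] -
    0.5 * (fx[i, j + 1] + fx[i + 1, j + 1]) * h[1] -
    0.5 * (fy[i, j] + fy[i, j + 1]) * h[2]
  max(abs(circ))
}

#' Hydrodynamic to wave representation
#'
#' `psi = sqrt(P) * exp(i theta)` with the phase integrated along a spanning
#' tree from the first grid node.  Only potential (curl-free) flows are
#' admissible: if any elementary loop circulation of `V/(2D)` exceeds
#' `loop_tol` radians, a typed error (`mq_nonpotential`) is raised.  The
#' result is defined up to one global phase.
#'
#' @param h a [hydro_field()].
#' @param loop_tol loop-circulation tolerance in radians.
#' @return A [wave_field()].
#' @export
hydro_to_wave <- function(h, loop_tol = 1e-6) {
  res <- loop_residual(h$V, h$grid, h$params)
  if (res > loop_tol) {
    stop(structure(class = c("mq_nonpotential", "error", "condition"),
                   list(message = sprintf(
                     "velocity field is not potential flow (loop residual %.3g rad)",
                     res), call = sys.call(-1))))
  }
  theta <- integrate_phase(h$V, h$grid, h$params)
  wave_field(sqrt(h$P) * exp(1i * theta), h$grid, h$params, t = h$t,
             normalize = FALSE)
}

laplacian_sqrt_ratio <- function(P, grid, floor_frac = 1e-12) {
  mask <- node_mask(P, floor_frac)
  s <- sqrt(pmax(P, 0))
  mask_na(fd_laplacian(s, grid) / pmax(s, .Machine$double.xmin), mask)
}

#' Macroquantum potential Q from a density
#'
#' `Q = -2 m D^2 Lap(sqrt P)/sqrt P`, the potential-energy term through which
#' the fractality of the medium acts on the mean flow.  Masked (NA) below the
#' density floor.
#'
#' @param P density array, a [hydro_field()] or a [wave_field()].
#' @param grid grid (not needed when `P` carries one).
#' @param params [macro_params()] (idem).
#' @param floor_frac density floor as a fraction of `max(P)`.
#' @return Energy field, NA on masked nodes.
#' @export
#' @examples
#' g <- grid_spec(64, extent = 12, origin = -6)
#' P <- dnorm(g$axes[[1]])
#' Q <- quantum_potential(P, g, macro_params(1))
quantum_potential <- function(P, grid = NULL, params = NULL,
                              floor_frac = 1e-12) {
  if (inherits(P, "wave_field")) { grid <- P$grid; params <- P$params; P <- density_of(P) }
  if (inherits(P, "hydro_field")) { grid <- P$grid; params <- P$params; P <- P$P }
  if (all(P == 0)) stop("density is identically zero", call. = FALSE)
  -2 * params$m * params$D^2 * laplacian_sqrt_ratio(P, grid, floor_frac)
}

#' Macroquantum potential, logarithmic form
#'
#' `Q = -m D^2 {Lap(ln P) + (1/2) (grad ln P)^2}`, algebraically identical to
#' [quantum_potential()] in the continuum; agreement on a grid is limited by
#' discretization error only.
#' @inheritParams quantum_potential
#' @export
quantum_potential_log_form <- function(P, grid = NULL, params = NULL,
                                       floor_frac = 1e-12) {
  if (inherits(P, "wave_field")) { grid <- P$grid; params <- P$params; P <- density_of(P) }
  if (inherits(P, "hydro_field")) { grid <- P$grid; params <- P$params; P <- P$P }
  if (all(P == 0)) stop("density is identically zero", call. = FALSE)
  mask <- node_mask(P, floor_frac)
  lp <- log(pmax(P, .Machine$double.xmin))
  g <- fd_gradient(lp, grid)
  g2 <- Reduce(`+`, lapply(g, function(x) x^2))
  mask_na(-params$m * params$D^2 * (fd_laplacian(lp, grid) + 0.5 * g2), mask)
}

#' Diffusion potential (sign-reversed Q)
#'
#' `+2 m D^2 Lap(sqrt P)/sqrt P = -Q`: the potential governing the
#' hydrodynamical form of a classical diffusion process.  Its appearance in
#' the Euler equation turns self-organization into entropy-increasing
#' spreading.
#' @inheritParams quantum_potential
#' @export
diffusion_potential <- function(P, grid = NULL, params = NULL,
                                floor_frac = 1e-12) {
  -quantum_potential(P, grid, params, floor_frac)
}

#' Map a classical diffusive state to hydrodynamic variables
#'
#' The change of variables `V = upsilon - D grad(ln P)` under which a
#' Fokker-Planck drift `upsilon` becomes the velocity of a continuity +
#' Euler system driven by the diffusion potential.
#'
#' @param P density array.
#' @param upsilon drift velocity (list of arrays, or one array in 1D).
#' @param grid,params grid and constants.
#' @return A [hydro_field()].
#' @export
classical_to_hydro <- function(P, upsilon, grid, params) {
  if (!is.list(upsilon)) upsilon <- list(upsilon)
  mask <- node_mask(P)
  lp <- log(pmax(P, .Machine$double.xmin))
  g <- fd_gradient(lp, grid)
  V <- lapply(seq_along(g), function(k) {
    mask_na(upsilon[[k]] - params$D * g[[k]], mask)
  })
  hydro_field(P, V, grid, params, normalize = FALSE)
}

#' Wave to diffusive representation
#'
#' `v+ = V + D grad(ln P)` (and `v- = v+ - 2 D grad(ln P)`); the inverse map
#' is [diffusive_to_wave()], implementing `psi = P^((1-i)/2) e^{i theta+}`
#' with `v+ = 2 D grad(theta+)`.
#'
#' @param w a [wave_field()].
#' @param floor_frac node floor.
#' @return A [diffusive_field()]; the backward drift is attached as `v_minus`.
#' @export
wave_to_diffusive <- function(w, floor_frac = 1e-12) {
  h <- wave_to_hydro(w, floor_frac)
  mask <- node_mask(h$P, floor_frac)
  lp <- log(pmax(h$P, .Machine$double.xmin))
  g <- fd_gradient(lp, w$grid)
  v_plus <- lapply(seq_along(g), function(k) {
    mask_na(h$V[[k]] + w$params$D * g[[k]], mask)
  })
  v_minus <- lapply(seq_along(g), function(k) {
    mask_na(v_plus[[k]] - 2 * w$params$D * g[[k]], mask)
  })
  d <- diffusive_field(h$P, v_plus, w$grid, w$params, t = w$t, normalize = FALSE)
  d$v_minus <- v_minus
  d
}

#' Diffusive to wave representation
#'
#' Reconstructs `psi = P^((1-i)/2) * exp(i theta+)` with `theta+` integrated
#' from `v+/(2D)` along a spanning tree; defined up to one global phase.
#' @param d a [diffusive_field()].
#' @param loop_tol loop tolerance in radians for the potential-flow check.
#' @export
diffusive_to_wave <- function(d, loop_tol = 1e-6) {
  res <- loop_residual(d$v_plus, d$grid, d$params)
  if (res > loop_tol) {
    stop(structure(class = c("mq_nonpotential", "error", "condition"),
                   list(message = sprintf(
                     "v+ is not potential flow (loop residual %.3g rad)", res),
                     call = sys.call(-1))))
  }
  theta_p <- integrate_phase(d$v_plus, d$grid, d$params)
  lp <- log(pmax(d$P, .Machine$double.xmin))
  psi <- exp(0.5 * (1 - 1i) * lp + 1i * theta_p)
  wave_field(psi, d$grid, d$params, t = d$t, normalize = FALSE)
}

#' Velocity-dependent quantum potential Q+
#'
#' `Q+ = -m D (v+ . grad(ln P) + D Lap(ln P))`: the form the fractal
#' potential takes in the diffusive (P, v+) representation, where part of Q
#' is compensated by the kinetic term of the forward drift.  The energy
#' bookkeeping `m v+^2/2 + phi + Q+ = m V^2/2 + phi + Q` holds pointwise.
#'
#' @param d a [diffusive_field()].
#' @param floor_frac node floor.
#' @return Energy field, NA on masked nodes.
#' @export
quantum_potential_plus <- function(d, floor_frac = 1e-12) {
  mask <- node_mask(d$P, floor_frac)
  lp <- log(pmax(d$P, .Machine$double.xmin))
  g <- fd_gradient(lp, d$grid)
  adv <- Reduce(`+`, lapply(seq_along(g), function(k) d$v_plus[[k]] * g[[k]]))
  mask_na(-d$params$m * d$params$D *
            (adv + d$params$D * fd_laplacian(lp, d$grid)), mask)
}

#' Two-fluid representation and its dynamical residuals
#'
#' Splits the complex velocity `V - iU` of a wave field into the coupled
#' fluids `V` and `U = D grad(ln P)`, and (when a potential is supplied)
#' evaluates the finite-difference residuals of the two coupled Euler-type
#' equations: `(dt + V.grad)V = (U.grad + D Lap)U - grad(phi/m)` and
#' `(dt + V.grad)U = -(U.grad + D Lap)V`.  Time derivatives are computed by
#' a centred step of the wave evolution when `dt` is given; a stationary
#' state may be checked with `dt = NULL` (time terms zero).
#'
#' @param w a [wave_field()].
#' @param pot optional [potential_spec()] for the residual evaluation.
#' @param dt optional time step for centred time differences.
#' @param floor_frac node floor; masked cells are excluded from norms.
#' @return list with `V`, `U`, and (when `pot` is given) `res30`, `res31`
#'   (residual fields by component) and `rel30`, `rel31` (relative L2 norms).
#' @export
two_fluid <- function(w, pot = NULL, dt = NULL, floor_frac = 1e-10) {
  h <- wave_to_hydro(w, floor_frac)
  mask <- node_mask(h$P, floor_frac)
  lp <- log(pmax(h$P, .Machine$double.xmin))
  U <- lapply(fd_gradient(lp, w$grid), function(g) {
    mask_na(w$params$D * g, mask)
  })
  out <- list(V = h$V, U = U)
  if (is.null(pot)) return(out)

  fields_of <- function(wf) {
    hh <- wave_to_hydro(wf, floor_frac)
    UU <- lapply(fd_gradient(log(pmax(hh$P, .Machine$double.xmin)), wf$grid),
                 function(g) wf$params$D * g)
    list(V = lapply(hh$V, function(v) { v[is.na(v)] <- 0; v }), U = UU)
  }
  if (is.null(dt)) {
    dV <- lapply(h$V, function(v) 0 * v)
    dU <- dV
  } else {
    fp <- fields_of(evolve(w, pot, dt, 1))
    fm <- fields_of(evolve(w, pot, -dt, 1))
    dV <- lapply(seq_len(w$grid$ndim), function(k) (fp$V[[k]] - fm$V[[k]]) / (2 * dt))
    dU <- lapply(seq_len(w$grid$ndim), function(k) (fp$U[[k]] - fm$U[[k]]) / (2 * dt))
  }
  V0 <- lapply(h$V, function(v) { v[is.na(v)] <- 0; v })
  U0 <- lapply(U, function(u) { u[is.na(u)] <- 0; u })
  phi <- potential_field(pot, w$grid, w$params)
  gphi <- fd_gradient(phi / w$params$m, w$grid)
  D <- w$params$D
  adv <- function(A, f) Reduce(`+`, lapply(seq_along(A), function(k) {
    A[[k]] * fd_gradient(f, w$grid)[[k]]
  }))
  # erode the mask so that FD stencils never straddle masked cells
  core <- erode_mask(mask, w$grid, 3L)
  res30 <- list(); res31 <- list()
  sc30 <- 0; sc31 <- 0; n30 <- 0; n31 <- 0
  for (k in seq_len(w$grid$ndim)) {
    r30 <- dV[[k]] + adv(V0, V0[[k]]) -
      (adv(U0, U0[[k]]) + D * fd_laplacian(U0[[k]], w$grid)) + gphi[[k]]
    r31 <- dU[[k]] + adv(V0, U0[[k]]) +
      (adv(U0, V0[[k]]) + D * fd_laplacian(V0[[k]], w$grid))
    res30[[k]] <- mask_na(r30, core)
    res31[[k]] <- mask_na(r31, core)
    s30 <- max(abs(gphi[[k]][core]), abs((adv(U0, U0[[k]]) +
             D * fd_laplacian(U0[[k]], w$grid))[core]), 1e-300)
    s31 <- max(abs((adv(U0, V0[[k]]) + D * fd_laplacian(V0[[k]], w$grid))[core]),
               abs(dU[[k]][core]), 1e-300)
    n30 <- n30 + sum(r30[core]^2); sc30 <- max(sc30, s30)
    n31 <- n31 + sum(r31[core]^2); sc31 <- max(sc31, s31)
  }
  npts <- sum(core)
  # characteristic dynamical scale so the ratios stay meaningful for free
  # flows, where every term vanishes identically
  vscale <- max(vapply(c(V0, U0), function(v) max(abs(v[core])), numeric(1)))
  base <- max(vscale^2 / max(w$grid$extent), 1e-300)
  out$res30 <- res30; out$res31 <- res31
  out$rel30 <- sqrt(n30 / npts) / max(sc30, base)
  out$rel31 <- sqrt(n31 / npts) / max(sc31, base)
  out
}

# shrink a logical mask by `cells` grid cells in every direction
erode_mask <- function(mask, grid, cells = 2L) {
  m <- mask
  for (r in seq_len(cells)) {
    acc <- m
    for (k in seq_len(grid$ndim)) {
      acc <- acc & shift_array(m, 1L, k, grid$boundary == "periodic") &
        shift_array(m, -1L, k, grid$boundary == "periodic")
    }
    m <- acc & !is.na(acc)
    m[is.na(m)] <- FALSE
  }
  m
}

#' Residual of the geodesic equation for an evolving wave field
#'
#' Evaluates `m (dt + Vc.grad - i D Lap) Vc + grad(phi)` with the complex
#' velocity `Vc = -2 i D grad(ln psi)` by central finite differences in space
#' and (optionally) time; for a solution of the dynamics this vanishes up to
#' discretization error.
#'
#' @param w a [wave_field()].
#' @param pot the [potential_spec()] under which `w` evolves.
#' @param dt optional centred time step (NULL: stationary state assumed, the
#'   time term of `Vc` is zero).
#' @param floor_frac node floor; masked cells excluded from the norm.
#' @return list with `residual` (complex field components) and `rel_norm`.
#' @export
geodesic_residual <- function(w, pot, dt = NULL, floor_frac = 1e-10) {
  grid <- w$grid; params <- w$params
  P <- density_of(w)
  mask <- node_mask(P, floor_frac)
  core <- erode_mask(mask, grid, 3L)
  # node-robust complex log-gradient: grad(ln psi) = grad(psi)/psi
  vc_of <- function(wf) {
    g <- fd_gradient(wf$psi, grid)
    lapply(g, function(gk) -2i * params$D * gk / wf$psi)
  }
  Vc <- vc_of(w)
  dVc <- if (is.null(dt)) {
    lapply(Vc, function(v) 0 * v)
  } else {
    vp <- vc_of(evolve(w, pot, dt, 1))
    vm <- vc_of(evolve(w, pot, -dt, 1))
    lapply(seq_len(grid$ndim), function(k) (vp[[k]] - vm[[k]]) / (2 * dt))
  }
  phi <- potential_field(pot, grid, params)
  gphi <- fd_gradient(phi, grid)
  resid <- list(); num <- 0; scale <- 0
  for (k in seq_len(grid$ndim)) {
    advk <- Reduce(`+`, lapply(seq_len(grid$ndim), function(j) {
      Vc[[j]] * fd_gradient(Vc[[k]], grid)[[j]]
    }))
    term <- params$m * (dVc[[k]] + advk - 1i * params$D * fd_laplacian(Vc[[k]], grid))
    rk <- term + gphi[[k]]
    resid[[k]] <- mask_na(Re(rk), core) + 1i * mask_na(Im(rk), core)
    num <- num + sum(Mod(rk[core])^2)
    scale <- max(scale, max(Mod(term[core])), max(abs(gphi[[k]][core])))
  }
  # characteristic dynamical scale keeps the ratio meaningful for free
  # motion, where every individual term vanishes identically
  vmax <- max(vapply(Vc, function(v) max(Mod(v[core])), numeric(1)))
  scale <- max(scale, params$m * vmax^2 / max(grid$extent), 1e-300)
  list(residual = resid, rel_norm = sqrt(num / sum(core)) / scale)
}

#' Sample fractal paths with D_F = 2 fluctuations
#'
#' Elementary displacements `dX = upsilon dt + zeta sqrt(2 D) |dt|^(1/2)`
#' with `<zeta> = 0`, `<zeta^2> = 1` (Gaussian), the Markovian regime of
#' critical fractal dimension 2.
#'
#' @param params [macro_params()] or any list with a `D` field (`D = 0`
#'   gives deterministic straight paths).
#' @param dt time step.
#' @param n_steps steps per path.
#' @param n_paths number of independent paths.
#' @param seed RNG seed.
#' @param upsilon constant drift velocity.
#' @return list with `paths` (matrix, (n_steps+1) x n_paths), `t`,
#'   `zeta_mean`, `msd_rate` (empirical `<d_xi^2>/dt`).
#' @export
make_fractal_paths <- function(params, dt, n_steps, n_paths = 1, seed = 1,
                               upsilon = 0) {
  stopifnot_positive(dt, "dt")
  D <- params$D
  if (D < 0) stop("D must be >= 0", call. = FALSE)
  zeta <- if (D == 0) {
    matrix(0, n_steps, n_paths)
  } else {
    with_seed(seed, matrix(stats::rnorm(n_steps * n_paths), n_steps, n_paths))
  }
  dxi <- zeta * sqrt(2 * D) * sqrt(dt)
  steps <- upsilon * dt + dxi
  paths <- rbind(0, apply(steps, 2, cumsum))
  list(paths = paths, t = seq(0, n_steps) * dt,
       zeta_mean = mean(zeta),
       msd_rate = mean(dxi^2) / dt)
}
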