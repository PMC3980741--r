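# Growth-from-centre morphologies: angular probability densities of central
# potentials (spherical harmonics), petal-shaped ridge curves, duplication
# between quantized levels, and hierarchy modes in the space of scales.

#' Morphology specification
#'
#' @param l angular momentum quantum number, >= 0.
#' @param m_q magnetic quantum number, |m_q| <= l.
#' @param k petal quantization integer, >= 1 (azimuthal multiplicity).
#' @param tension constant transverse force magnitude bending the petals.
#' @param axis growth axis (3-vector), default z.
#' @return Object of class `morphology_spec`.
#' @export
morphology_spec <- function(l = 5, m_q = 0, k = 5, tension = 0.3,
                            axis = c(0, 0, 1)) {
  if (l < 0 || l != round(l)) stop("l must be a nonnegative integer", call. = FALSE)
  if (abs(m_q) > l || m_q != round(m_q)) {
    stop("|m_q| must be <= l and integer", call. = FALSE)
  }
  if (k < 1 || k != round(k)) stop("k must be a positive integer", call. = FALSE)
  structure(list(l = as.integer(l), m_q = as.integer(m_q), k = as.integer(k),
                 tension = tension, axis = axis / sqrt(sum(axis^2))),
            class = "morphology_spec")
}

# normalized associated Legendre part of |Y_lm|^2 as a function of theta
ylm2_theta <- function(l, m, theta) {
  m <- abs(m)
  x <- cos(theta)
  Pl <- if (l == 0) matrix(1, 1, length(x)) else pracma::legendre(l, x)
  Plm <- Pl[m + 1, ]
  norm2 <- (2 * l + 1) / (4 * pi) * exp(lgamma(l - m + 1) - lgamma(l + m + 1))
  norm2 * Plm^2
}

#' Angular probability density of a growth mode
#'
#' `P(theta, phi) = |Y_lm(theta, phi)|^2`: the angular distribution of the
#' outgoing probability flow for a central potential, whose maxima select the
#' directions along which matter is preferentially sent.
#'
#' @param spec a [morphology_spec()].
#' @param theta polar angle(s) in `[0, pi]`.
#' @param phi azimuthal angle(s) (the density does not depend on it).
#' @return Density values; integrates to 1 over the sphere.
#' @export
angular_density <- function(spec, theta, phi = 0) {
  ylm2_theta(spec$l, spec$m_q, theta) + 0 * phi
}

#' Polar angles of maximal angular probability
#'
#' Locates the local maxima of `|Y_lm|^2(theta)` on `[0, pi]` by dense grid
#' search refined with golden-section optimization; for `m = 0` there are
#' `l + 1` of them (poles included).
#'
#' @param spec a [morphology_spec()].
#' @param n_grid search grid size.
#' @return Sorted vector of theta values.
#' @export
maximal_angles <- function(spec, n_grid = 4096) {
  th <- seq(0, pi, length.out = n_grid)
  f <- ylm2_theta(spec$l, spec$m_q, th)
  if (diff(range(f)) < 1e-12 * max(f)) {
    return(pi / 2)            # isotropic density: every direction is maximal
  }
  idx <- peaks1d(f, min_prom = 1e-9 * max(f))
  out <- vapply(idx, function(i) {
    lo <- th[max(1, i - 2)]; hi <- th[min(n_grid, i + 2)]
    stats::optimize(function(t) ylm2_theta(spec$l, spec$m_q, t),
                    c(lo, hi), maximum = TRUE, tol = 1e-10)$maximum
  }, numeric(1))
  # boundary maxima (the poles) are not interior sign changes
  if (f[1] > f[2]) out <- c(0, out)
  if (f[n_grid] > f[n_grid - 1]) out <- c(out, pi)
  sort(out)
}

#' Flower-shaped ridge curves along maximal angles
#'
#' For each non-polar band of maximal probability, emits `k` azimuthally
#' equispaced curves launched along `(theta_max, phi_j = 2 pi j / k)` and
#' bent by a constant-magnitude tension force transverse to the launch ray
#' (in the plane containing the growth axis), integrated into quadratic
#' curves.  Polar bands yield a single axial curve each ("stamen" near
#' theta = 0, "sepal" analogue near theta = pi).
#'
#' @param spec a [morphology_spec()].
#' @param n_points samples per curve.
#' @param length_scale curve length.
#' @return list of curves; each a list with `role` ("petal", "stamen" or
#'   "sepal"), `theta`, `phi`, and `xyz` (n_points x 3 matrix).
#' @export
flower_shape <- function(spec, n_points = 50, length_scale = 1) {
  th_max <- maximal_angles(spec)
  s <- seq(0, length_scale, length.out = n_points)
  curves <- list()
  for (th in th_max) {
    polar <- th < 1e-8 || th > pi - 1e-8
    phis <- if (polar) 0 else 2 * pi * (seq_len(spec$k) - 1) / spec$k
    role <- if (th < 1e-8) "stamen" else if (th > pi - 1e-8) "sepal" else "petal"
    for (ph in phis) {
      u <- c(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
      # transverse direction in the (axis, u) plane
      tv <- spec$axis - sum(spec$axis * u) * u
      nt <- sqrt(sum(tv^2))
      tv <- if (nt < 1e-12) c(0, 0, 0) else tv / nt
      xyz <- outer(s, u) + 0.5 * spec$tension * outer(s^2, tv)
      curves[[length(curves) + 1]] <-
        list(role = role, theta = th, phi = ph, xyz = xyz)
    }
  }
  curves
}

#' Duplication: transition from single to binary structure
#'
#' Renders the passage from the fundamental to the first excited level of a
#' confining potential as the normalized interpolation
#' `psi(s) = cos(pi s / 2) psi_0 + sin(pi s / 2) psi_1`.  The endpoints are
#' the stationary quantized morphologies (one peak, then two); intermediate
#' frames are transitory (not stationary: Q + phi is not constant).  The
#' path itself is illustrative; the testable content is the endpoint
#' stationarity and peak counts.
#'
#' @param pot confining [potential_spec()].
#' @param grid [grid_spec()] grid (1D or 2D).
#' @param params [macro_params()].
#' @param schedule interpolation parameter values in `[0, 1]`.
#' @param degeneracy_tol relative gap below which E0, E1 are considered
#'   degenerate (non-generic potential error).
#' @return list with `frames` (list of [wave_field()]), `peak_counts`,
#'   `energies` (E0, E1), `schedule`.
#' @export
duplication_simulation <- function(pot, grid, params,
                                   schedule = seq(0, 1, length.out = 5),
                                   degeneracy_tol = 1e-6) {
  sol <- stationary_states(pot, grid, params, n_states = 3)
  E <- sol$energies
  if (abs(E[2] - E[1]) <= degeneracy_tol * max(abs(E))) {
    stop("non-generic potential: E0 and E1 are degenerate", call. = FALSE)
  }
  if (abs(E[3] - E[2]) <= degeneracy_tol * max(abs(E))) {
    stop("non-generic potential: the first excited level is degenerate, ",
         "psi_1 is not unique", call. = FALSE)
  }
  psi0 <- sol$states[[1]]$psi; psi1 <- sol$states[[2]]$psi
  frames <- lapply(schedule, function(s) {
    wave_field(cos(pi * s / 2) * psi0 + sin(pi * s / 2) * psi1,
               grid, params, t = 0, normalize = TRUE)
  })
  peak_counts <- vapply(frames, function(w) count_peaks(density_of(w)),
                        integer(1))
  list(frames = frames, peak_counts = peak_counts, energies = E,
       schedule = schedule)
}

#' Scale hierarchy specification
#'
#' @param lam_min,lam_max extreme scales (0 < lam_min < lam_max): the walls
#'   of the "box" in `ln(scale)`.
#' @param n_mode excitation index >= 0; mode n describes n+1 embedded
#'   hierarchical levels.
#' @export
scale_hierarchy_spec <- function(lam_min, lam_max, n_mode = 0) {
  stopifnot_positive(lam_min, "lam_min")
  stopifnot_positive(lam_max, "lam_max")
  if (lam_min >= lam_max) stop("need lam_min < lam_max", call. = FALSE)
  if (n_mode < 0 || n_mode != round(n_mode)) {
    stop("n_mode must be a nonnegative integer", call. = FALSE)
  }
  structure(list(lam_min = lam_min, lam_max = lam_max,
                 n_mode = as.integer(n_mode)),
            class = "scale_hierarchy_spec")
}

#' Hierarchy modes in the space of scales
#'
#' Particle-in-a-box eigenmode `n` over `x = ln(scale)` between the walls
#' `ln(lam_min)` and `ln(lam_max)`: density proportional to
#' `sin^2((n+1) pi (x - x_min)/(x_max - x_min))`.  Mode n has n+1 probability
#' peaks, i.e., n+1 embedded levels of organization; the fundamental peaks at
#' the geometric mean of the walls.
#'
#' @param spec a [scale_hierarchy_spec()].
#' @param n_grid evaluation grid size over `ln(scale)`.
#' @return list with `scale` (grid), `density` (normalized in `ln(scale)`),
#'   `peak_scales` (the n+1 antinode scales).
#' @export
hierarchy_modes <- function(spec, n_grid = 1024) {
  x0 <- log(spec$lam_min); x1 <- log(spec$lam_max)
  x <- seq(x0, x1, length.out = n_grid)
  nq <- spec$n_mode + 1L
  dens <- 2 / (x1 - x0) * sin(nq * pi * (x - x0) / (x1 - x0))^2
  peaks_x <- x0 + (2 * seq_len(nq) - 1) / (2 * nq) * (x1 - x0)
  list(scale = exp(x), density = dens, peak_scales = exp(peaks_x))
}

#' Geometric mid-scale of two extreme scales
#'
#' `sqrt(lam_min * lam_max)`: the peak of the fundamental hierarchy mode.
#' With the Planck and cosmic scales (ratio 5.3e60) this lands at 2.3e30
#' Planck lengths, about 40 micrometres — the same value obtained from the
#' biological extremes 0.5 Angstrom and 30 m.
#'
#' @param lam_min,lam_max positive scales.
#' @export
#' @examples
#' mid_scale(1, 5.3e60)             # 2.3e30 (Planck units)
#' mid_scale(0.5e-10, 30) * 1e6     # about 40 (micrometres)
mid_scale <- function(lam_min, lam_max) {
  stopifnot_positive(lam_min, "lam_min")
  stopifnot_positive(lam_max, "lam_max")
  sqrt(lam_min * lam_max)
}

#' Complementary density concentrated on the walls
#'
#' Given a density `P` with peaks in the "cells", builds the normalized
#' density of a complementary fluid supported where `P < threshold * max(P)`
#' (the zero-density "walls"), lightly smoothed.  The two high-probability
#' supports are disjoint at the stated threshold.
#'
#' @param P density (vector, or [wave_field()]).
#' @param grid grid (unless carried by `P`).
#' @param threshold wall threshold in (0, 1).
#' @param smooth half-width (cells) of the smoothing window.
#' @return Normalized complementary density array.
#' @export
complementary_density <- function(P, grid = NULL, threshold = 0.1,
                                  smooth = 3L) {
  if (inherits(P, "wave_field")) { grid <- P$grid; P <- density_of(P) }
  if (threshold <= 0 || threshold >= 1) {
    stop("threshold must be inside (0, 1)", call. = FALSE)
  }
  w <- as.numeric(P < threshold * max(P))
  if (all(w == 0)) {
    stop("no walls: the density never falls below the threshold", call. = FALSE)
  }
  if (!is.null(dim(P))) w <- array(w, dim = dim(P))
  if (smooth > 0) {
    # separable moving-average smoothing (zero fill at the borders)
    naxes <- if (is.null(dim(P))) 1L else length(dim(P))
    for (ax in seq_len(naxes)) {
      acc <- 0 * w
      for (d in -smooth:smooth) acc <- acc + shift_array(w, d, ax, FALSE)
      w <- acc / (2 * smooth + 1)
    }
  }
  w / cell_integral(w, grid)
}
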