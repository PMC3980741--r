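test_that("wave_to_hydro extracts P and the phase-gradient velocity", {
  p <- std_params()
  g <- grid_spec(128, extent = 16, boundary = "periodic")
  k <- 2 * pi * 3 / 16
  w <- wave_field(exp(1i * k * g$axes[[1]]), g, p)
  h <- wave_to_hydro(w)
  # the discrete phase gradient is sin(k h)/h: uniform, equal to k to O(h^2)
  expect_lt(diff(range(h$V[[1]])), 1e-12)
  expect_equal(mean(h$V[[1]]), 2 * p$D * sin(k * g$spacing) / g$spacing,
               tolerance = 1e-12)
  expect_equal(mean(h$V[[1]]), 2 * p$D * k, tolerance = 0.01)
  expect_lt(diff(range(h$P)), 1e-12)
  # any real psi has V = 0
  g2 <- grid_spec(128, extent = 12, origin = -6)
  w2 <- wave_field(exp(-g2$axes[[1]]^2), g2, p)
  h2 <- wave_to_hydro(w2)
  expect_lt(max(abs(h2$V[[1]]), na.rm = TRUE), 1e-12)
})

test_that("hydro and diffusive representations round-trip to the wave field", {
  p <- std_params()
  g <- osc_grid(300)
  sol <- stationary_states(osc_pot(), g, p, 1)
  w0 <- sol$states[[1]]
  # ground state and a displaced complex (nodeless) packet
  x <- g$axes[[1]]
  wmv <- wave_field(exp(-(x - 0.4)^2 / 2 + 0.7i * x), g, p)
  for (w in list(w0, wmv)) {
    h <- wave_to_hydro(w)
    wh <- hydro_to_wave(h)
    expect_gt(abs(sum(Conj(w$psi) * wh$psi)) * g$spacing, 1 - 1e-6)
    expect_lt(max(abs(h$P - density_of(wh))), 1e-8)
    d <- wave_to_diffusive(w)
    wd <- diffusive_to_wave(d)
    expect_gt(abs(sum(Conj(w$psi) * wd$psi)) * g$spacing, 1 - 1e-6)
  }
  # 2D round trip on a seeded curl-free flow
  g2 <- grid_spec(c(48, 48), extent = c(6, 6), origin = c(-3, -3))
  co <- grid_coords(g2)
  chi <- sin(co[[1]]) * cos(0.7 * co[[2]]) * 0.2       # smooth flow potential
  V2 <- list(2 * p$D * 0.2 * cos(co[[1]]) * cos(0.7 * co[[2]]),
             -2 * p$D * 0.14 * sin(co[[1]]) * sin(0.7 * co[[2]]))
  P2 <- exp(-(co[[1]]^2 + co[[2]]^2) / 4)
  h2 <- hydro_field(P2, V2, g2, p)
  w2 <- hydro_to_wave(h2, loop_tol = 0.05)
  h2b <- wave_to_hydro(w2)
  expect_lt(max(abs(h2b$P - h2$P)), 1e-8)
  # compare velocities away from the Dirichlet border ring, where the
  # zero-ghost gradient of either route is not meaningful
  interior <- matrix(FALSE, 48, 48); interior[5:44, 5:44] <- TRUE
  core <- h2$P > 1e-3 * max(h2$P) & interior
  expect_lt(max(abs(h2b$V[[1]] - h2$V[[1]])[core]), 1e-2)
})

test_that("rotational flows are rejected as non-potential", {
  vx <- generate_fixture(fixture_spec("vortex_velocity"), params = std_params())
  expect_error(hydro_to_wave(vx), class = "mq_nonpotential")
})

test_that("the quantum potential matches Gaussian closed forms", {
  p1 <- macro_params(D = 1, m = 1)
  # 1D: Q(0) = m D^2 / sigma^2
  g <- grid_spec(400, extent = 16, origin = -8)
  x <- g$axes[[1]]
  s2 <- 1.3
  Q <- quantum_potential(exp(-x^2 / (2 * s2)), g, p1)
  expect_equal(Q[which.min(abs(x))], 1 / s2, tolerance = 0.01)
  # uniform density: Q = 0
  gp <- grid_spec(64, extent = 8, boundary = "periodic")
  expect_lt(max(abs(quantum_potential(rep(1, 64), gp, p1))), 1e-12)
  # 3D isotropic Gaussian: Q(r) = -D^2 (r^2 - 6 sigma^2) / (2 sigma^4)
  g3 <- grid_spec(c(48, 48, 48), extent = 12, origin = -6)
  co <- grid_coords(g3)
  r2 <- co[[1]]^2 + co[[2]]^2 + co[[3]]^2
  Q3 <- quantum_potential(exp(-r2 / 2), g3, p1)
  Qex <- -(r2 - 6) / 2
  reg <- r2 < 9
  expect_lt(max(abs(Q3[reg] - Qex[reg])) / max(abs(Qex[reg])), 0.01)
  # logarithmic form agrees on a seeded smooth density
  set.seed(7)
  Ps <- exp(-x^2 / 3) * (1 + 0.2 * sin(x))
  Qa <- quantum_potential(Ps, g, p1)
  Qb <- quantum_potential_log_form(Ps, g, p1)
  core <- Ps > 1e-4 * max(Ps)
  expect_lt(max(abs(Qa - Qb)[core]) / max(abs(Qa[core])), 1e-3)
  expect_lt(max(abs(quantum_potential_log_form(rep(1, 64), gp, p1))), 1e-12)
})

test_that("the diffusive representation carries v+ = V + D grad ln P", {
  p <- std_params()
  g <- osc_grid(400)
  x <- g$axes[[1]]
  sol <- stationary_states(osc_pot(), g, p, 1)
  d <- wave_to_diffusive(sol$states[[1]])
  # real stationary state: v+ = D grad ln P = -D x / sigma^2 and v- = -v+
  core <- density_of(sol$states[[1]]) > 1e-3 * max(density_of(sol$states[[1]]))
  expect_lt(max(abs(d$v_plus[[1]] + p$D * x / 0.5)[core]), 0.02)
  expect_lt(max(abs(d$v_minus[[1]] + d$v_plus[[1]])[core]), 1e-10)
  # (v+ + v-)/2 recovers the hydrodynamic V
  h <- wave_to_hydro(sol$states[[1]])
  expect_lt(max(abs((d$v_plus[[1]] + d$v_minus[[1]]) / 2 - h$V[[1]])[core]), 1e-10)
})

test_that("Q+ satisfies its closed form and the energy identity", {
  p <- std_params()
  # closed form: Gaussian P with v+ = -D x / sigma^2 gives
  # Q+ = -m D^2 (x^2 / sigma^4 - 1 / sigma^2)
  g <- grid_spec(500, extent = 12, origin = -6)
  x <- g$axes[[1]]
  s2 <- 0.8
  P <- exp(-x^2 / (2 * s2))
  d <- diffusive_field(P, list(-p$D * x / s2), g, p, normalize = FALSE)
  Qp <- quantum_potential_plus(d)
  Qex <- -p$m * p$D^2 * (x^2 / s2^2 - 1 / s2)
  core <- P > 1e-3 * max(P)
  expect_lt(max(abs(Qp - Qex)[core]) / max(abs(Qex[core])), 0.01)
  # uniform P with v+ = 0: Q+ = 0
  gp <- grid_spec(64, extent = 8, boundary = "periodic")
  d0 <- diffusive_field(rep(1, 64), list(rep(0, 64)), gp, p)
  expect_lt(max(abs(quantum_potential_plus(d0))), 1e-12)
  # energy bookkeeping on the oscillator ground state:
  # E = m v+^2/2 + phi + Q+ is constant and equals E0; and it agrees
  # pointwise with m V^2/2 + phi + Q
  go <- grid_spec(480, extent = 12, origin = -6)
  sol <- stationary_states(osc_pot(), go, p, 1)
  w0 <- sol$states[[1]]
  dd <- wave_to_diffusive(w0)
  h <- wave_to_hydro(w0)
  phi <- potential_field(osc_pot(), go, p)
  E40 <- 0.5 * p$m * dd$v_plus[[1]]^2 + phi + quantum_potential_plus(dd)
  E36 <- 0.5 * p$m * ifelse(is.na(h$V[[1]]), 0, h$V[[1]])^2 + phi +
    quantum_potential(h$P, go, p)
  core <- density_of(w0) > 1e-3 * max(density_of(w0))
  expect_lt(stats::sd(E40[core]) / abs(mean(E40[core])), 1e-3)
  expect_equal(mean(E40[core]), sol$energies[1], tolerance = 1e-3)
  expect_lt(max(abs(E36 - E40)[core]) / abs(mean(E40[core])), 1e-3)
})

test_that("the diffusion potential is minus the quantum potential", {
  p <- std_params()
  g <- grid_spec(256, extent = 16, origin = -8)
  P <- exp(-g$axes[[1]]^2 / 2)
  s <- quantum_potential(P, g, p) + diffusion_potential(P, g, p)
  expect_lt(max(abs(s), na.rm = TRUE), 1e-12)
})

test_that("the mapped free-diffusion Gaussian solves the reversed Euler equation", {
  p <- std_params()
  g <- grid_spec(1024, extent = 40, origin = -20)
  x <- g$axes[[1]]
  for (s2 in c(1, 2, 4, 10)) {          # a decade of spreading
    P <- exp(-x^2 / (2 * s2)) / sqrt(2 * pi * s2)
    V <- p$D * x / s2                    # Eq-map of upsilon = 0
    dVdt <- -p$D * x * (2 * p$D) / s2^2
    adv <- V * fd_gradient(V, g)[[1]]
    dpot <- diffusion_potential(P, g, p)
    Fx <- -fd_gradient(dpot, g)[[1]] / p$m
    core <- P > 1e-6 * max(P) & !is.na(dpot)
    res <- (dVdt + adv - Fx)[core]
    expect_lt(sqrt(mean(res^2)) / max(abs(Fx[core])), 1e-3)
  }
})

test_that("entropy increases strictly along the diffusive flow", {
  p <- std_params()
  g <- grid_spec(256, extent = 20, origin = -10)
  P <- gaussian_density_on(g, sigma2 = 0.5)
  d <- diffusive_field(P, list(rep(0, 256)), g, p, normalize = FALSE)
  S <- gibbs_entropy(d)
  for (i in 1:6) {
    d <- evolve_fokker_planck(d, dt = 1e-3, n_steps = 100)
    S2 <- gibbs_entropy(d)
    expect_gt(S2, S)
    S <- S2
  }
})

test_that("two-fluid residuals vanish for free and stationary flows", {
  p <- std_params()
  # plane wave: U = 0, V uniform, residuals at machine level
  gp <- grid_spec(128, extent = 16, boundary = "periodic")
  k <- 2 * pi * 3 / 16
  wp <- wave_field(exp(1i * k * gp$axes[[1]]), gp, p)
  tf0 <- two_fluid(wp, potential_spec("box"))
  expect_lt(max(abs(tf0$U[[1]]), na.rm = TRUE), 1e-10)
  expect_lt(tf0$rel30, 1e-8)
  # stationary eigenstate: (U.grad + D Lap) U balances grad(phi/m)
  g <- grid_spec(480, extent = 12, origin = -6)
  sol <- stationary_states(osc_pot(), g, p, 1)
  tf <- two_fluid(sol$states[[1]], osc_pot())
  expect_lt(tf$rel30, 1e-3)
  expect_lt(tf$rel31, 1e-3)
  # time-dependent consistency: displaced packet over a fraction of a period
  x <- g$axes[[1]]
  wc <- wave_field(exp(-(x - 0.5)^2 / (4 * 0.5)), g, p)
  tfc <- two_fluid(wc, osc_pot(), dt = 5e-4)
  expect_lt(tfc$rel30, 1e-2)
  expect_lt(tfc$rel31, 1e-2)
})

test_that("the geodesic-equation residual separates solutions from corrupted fields", {
  p <- std_params()
  gp <- grid_spec(128, extent = 16, boundary = "periodic")
  k <- 2 * pi * 3 / 16
  wp <- wave_field(exp(1i * k * gp$axes[[1]]), gp, p)
  expect_lt(geodesic_residual(wp, potential_spec("box"))$rel_norm, 1e-10)
  g <- grid_spec(480, extent = 12, origin = -6)
  sol <- stationary_states(osc_pot(), g, p, 1)
  clean <- geodesic_residual(sol$states[[1]], osc_pot())$rel_norm
  expect_lt(clean, 1e-2)
  set.seed(1)
  wbad <- wave_field(sol$states[[1]]$psi *
                       exp(1i * 0.1 * rnorm(480)), g, p, normalize = FALSE)
  expect_gt(geodesic_residual(wbad, osc_pot())$rel_norm, 10 * clean)
})

test_that("Fokker-Planck evolution spreads, rests and pairs correctly", {
  p <- std_params()
  g <- grid_spec(256, extent = 20, origin = -10)
  x <- g$axes[[1]]
  # free diffusion: variance grows as sigma0^2 + 2 D t
  P <- gaussian_density_on(g, sigma2 = 1)
  d <- diffusive_field(P, list(rep(0, 256)), g, p, normalize = FALSE)
  dT <- evolve_fokker_planck(d, dt = 1e-3, n_steps = 1000)
  v2 <- sum(dT$P * x^2) / sum(dT$P)
  expect_equal(v2, 1 + 2 * p$D, tolerance = 0.01)
  # v+ = D grad ln P is the stationary drift (periodic, bounded contrast)
  gf <- grid_spec(1024, extent = 8, boundary = "periodic")
  xf <- gf$axes[[1]]
  Pf <- 1 + 0.5 * cos(2 * pi * xf / 8); Pf <- Pf / (sum(Pf) * gf$spacing)
  vst <- p$D * fd_gradient(log(Pf), gf)[[1]]
  dst <- evolve_fokker_planck(diffusive_field(Pf, list(vst), gf, p,
                                              normalize = FALSE),
                              dt = 1e-5, n_steps = 1000)
  expect_lt(max(abs(dst$P - Pf)) / max(Pf), 1e-6)
  # paired backward propagates the same density as forward
  gp <- grid_spec(128, extent = 8, boundary = "periodic")
  xp <- gp$axes[[1]]
  Pp <- 1 + 0.5 * cos(2 * pi * xp / 8); Pp <- Pp / (sum(Pp) * gp$spacing)
  dp <- diffusive_field(Pp, list(0.3 + 0 * xp), gp, p, normalize = FALSE)
  dF <- evolve_fokker_planck(dp, 5e-4, 600, "forward")
  dB <- evolve_fokker_planck(dp, 5e-4, 600, "backward", paired = TRUE)
  expect_lt(max(abs(dF$P - dB$P)) / max(dF$P), 1e-4)
  expect_error(evolve_fokker_planck(dp, 5e-4, 10, "backward"), "paired")
})

test_that("fractal paths have D_F = 2 statistics", {
  p <- std_params()
  fp <- make_fractal_paths(p, dt = 0.01, n_steps = 100, n_paths = 2000, seed = 7)
  expect_lt(abs(fp$zeta_mean), 3 / sqrt(100 * 2000))
  expect_equal(fp$msd_rate, 2 * p$D, tolerance = 0.05)
  # <X^2(t)> = 2 D t at the end of the paths
  expect_equal(mean(fp$paths[101, ]^2), 2 * p$D * 1, tolerance = 0.05)
  # scaling exponent of <dX^2> vs dt over the path
  lags <- c(1, 2, 4, 8, 16, 32)
  msd <- vapply(lags, function(L) {
    dx <- fp$paths[-(1:L), ] - fp$paths[1:(101 - L), ]
    mean(dx^2)
  }, numeric(1))
  slope <- coef(lm(log(msd) ~ log(lags * 0.01)))[2]
  expect_equal(unname(slope), 1, tolerance = 0.05)
  # D = 0: deterministic straight paths
  fp0 <- make_fractal_paths(list(D = 0), dt = 0.1, n_steps = 10, n_paths = 3,
                            seed = 1, upsilon = 2)
  expect_equal(fp0$paths[11, ], rep(2, 3), tolerance = 1e-12)
})
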