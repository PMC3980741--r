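test_that("macro parameters enforce S0 = 2 m D and the Compton relation", {
  p <- macro_params(D = 0.5, m = 2)
  expect_equal(p$S0, 2)
  expect_error(macro_params(D = -1), "D")
  expect_equal(compton_length(macro_params(D = 3), 2), 3)
  expect_equal(compton_length(macro_params(D = 0.5, m = 1), 1), 1)
  # hbar branch: lambda_C * m * c = hbar
  hbar <- 1.054571817e-34; me <- 9.1093837e-31
  pm <- macro_params(D = hbar / (2 * me), m = me)
  expect_equal(compton_length(pm, 3e8) * me * 3e8, hbar, tolerance = 1e-12)
})

test_that("the discretized Hamiltonian is exactly symmetric", {
  p <- std_params()
  for (bnd in c("box", "periodic")) {
    g <- grid_spec(32, extent = 4, boundary = bnd)
    H <- hamiltonian_matrix(osc_pot(), g, p)
    expect_identical(max(abs(H - t(H))), 0)
  }
  g2 <- grid_spec(c(10, 12), extent = c(2, 3))
  H2 <- hamiltonian_matrix(potential_spec("box"), g2, p)
  expect_identical(max(abs(H2 - t(H2))), 0)
})

test_that("oscillator and box spectra match the closed forms with hbar -> 2mD", {
  p <- std_params()
  sol <- stationary_states(osc_pot(), osc_grid(600), p, 3)
  E_exact <- p$S0 * 1 * (0:2 + 0.5)
  expect_lt(max(abs(sol$energies - E_exact) / E_exact), 1e-4)
  gb <- grid_spec(400, extent = 1)
  solb <- stationary_states(potential_spec("box"), gb, p, 3)
  Eb <- 2 * p$m * p$D^2 * pi^2 * (1:3)^2
  expect_lt(max(abs(solb$energies - Eb) / Eb), 1e-4)
  expect_true(all(diff(sol$energies) > 0))
})

test_that("setting S0 to hbar reproduces standard quantum mechanics", {
  hbar <- 1.054571817e-34; me <- 9.1093837e-31
  pm <- macro_params(D = hbar / (2 * me), m = me)
  om <- 1e15
  sig <- sqrt(hbar / (2 * me * om))
  g <- grid_spec(600, extent = 20 * sig, origin = -10 * sig)
  sol <- stationary_states(potential_spec("harmonic", omega = om, center = 0),
                           g, pm, 2)
  E_qm <- hbar * om * (0:1 + 0.5)
  expect_lt(max(abs(sol$energies - E_qm) / E_qm), 1e-4)
})

test_that("eigenvalue error decreases by >= 3x under grid doubling", {
  p <- std_params()
  E1 <- stationary_states(osc_pot(), osc_grid(150, 14 / sqrt(0.5)), p, 1)$energies
  E2 <- stationary_states(osc_pot(), osc_grid(300, 14 / sqrt(0.5)), p, 1)$energies
  expect_gt(abs(E1 - 0.5) / abs(E2 - 0.5), 3)
})

test_that("the node theorem holds across trap shapes for n <= 8", {
  p <- std_params()
  sol <- stationary_states(osc_pot(), osc_grid(500), p, 9)
  expect_identical(vapply(sol$states, count_nodes, integer(1)), 0:8)
  gb <- grid_spec(400, extent = 1)
  solb <- stationary_states(potential_spec("box"), gb, p, 9)
  expect_identical(vapply(solb$states, count_nodes, integer(1)), 0:8)
  gq <- grid_spec(400, extent = 12, origin = -6)
  solq <- stationary_states(potential_spec("custom", phi = 0.1 * gq$axes[[1]]^4),
                            gq, p, 9)
  expect_identical(vapply(solq$states, count_nodes, integer(1)), 0:8)
})

test_that("node and peak counters behave on explicit profiles", {
  p <- std_params()
  gb <- grid_spec(300, extent = 1)
  expect_identical(count_nodes(sin(3 * pi * gb$axes[[1]])), 2L)
  sol <- stationary_states(osc_pot(), osc_grid(300), p, 2)
  expect_identical(count_peaks(density_of(sol$states[[1]])), 1L)
  expect_identical(count_peaks(density_of(sol$states[[2]])), 2L)
  solb <- stationary_states(potential_spec("box"), gb, p, 4)
  expect_identical(vapply(solb$states, function(w) count_peaks(density_of(w)),
                          integer(1)), 1:4)
  # a profile with no global phase that makes it real is rejected
  expect_error(count_nodes(wave_field(exp(10i * gb$axes[[1]]) *
                                        sin(pi * gb$axes[[1]]), gb, p)),
               "complex")
  expect_error(count_peaks(rep(0, 10)), "zero")
})

test_that("Cayley evolution is unitary and keeps eigenstates stationary", {
  p <- std_params()
  g <- osc_grid(400)
  sol <- stationary_states(osc_pot(), g, p, 1)
  w0 <- sol$states[[1]]
  w1 <- evolve(w0, osc_pot(), dt = 0.001, n_steps = 1500)
  expect_lt(abs(cell_integral(Mod(w1$psi)^2, g) - 1), 1e-8)
  expect_lt(max(abs(density_of(w1) - density_of(w0))), 1e-6)
  # accumulated phase e^{-i E t / S0}
  ph <- Arg(sum(Conj(w0$psi) * w1$psi))
  target <- -sol$energies[1] * 1.5 / p$S0
  expect_lt(abs(((ph - target + pi) %% (2 * pi)) - pi), 1e-4)
})

test_that("a free Gaussian packet disperses by sigma2(t) = sigma0^2 + (D t / sigma0)^2", {
  p <- std_params()
  g <- grid_spec(512, extent = 40, origin = -20, boundary = "periodic")
  x <- g$axes[[1]]
  w <- wave_field(exp(-x^2 / 4), g, p)          # sigma0^2 = 1 in density
  wf <- suppressWarnings(evolve(w, potential_spec("box"), dt = 0.005,
                                n_steps = 800))
  P <- density_of(wf)
  s2 <- cell_integral(P * x^2, g) / cell_integral(P, g)
  expect_equal(s2, 1 + (p$D * 4)^2, tolerance = 0.01)
})

test_that("a constant potential only shifts the global phase", {
  p <- std_params()
  g <- grid_spec(200, extent = 14, origin = -7)
  w <- wave_field(exp(-g$axes[[1]]^2 / 2), g, p)
  wa <- suppressWarnings(evolve(w, potential_spec("box"), dt = 1e-3, n_steps = 200))
  wb <- suppressWarnings(evolve(w, potential_spec("custom", phi = rep(2.5, 200)),
                                dt = 1e-3, n_steps = 200))
  expect_lt(max(abs(density_of(wa) - density_of(wb))), 1e-6)
  rel <- Arg(sum(Conj(wa$psi) * wb$psi))
  expect_lt(abs(((rel + 2.5 * 0.2 / p$S0 + pi) %% (2 * pi)) - pi), 1e-6)
})

test_that("the cubic Ginzburg-Landau term conserves the norm", {
  p <- std_params()
  g <- grid_spec(128, extent = 16, boundary = "periodic")
  w <- wave_field(exp(-g$axes[[1]]^2 / 2), g, p)
  wb <- suppressWarnings(evolve(w, potential_spec("box", beta = 0.5),
                                dt = 5e-4, n_steps = 400))
  expect_lt(abs(cell_integral(Mod(wb$psi)^2, g) - 1), 1e-8)
  # beta really acts: density differs from the linear evolution
  wl <- suppressWarnings(evolve(w, potential_spec("box"), dt = 5e-4, n_steps = 400))
  expect_gt(max(abs(density_of(wb) - density_of(wl))), 1e-4)
})

test_that("evolve warns above the resolution bound on dt", {
  p <- std_params()
  g <- grid_spec(64, extent = 8, origin = -4)
  w <- wave_field(exp(-g$axes[[1]]^2), g, p)
  expect_warning(evolve(w, potential_spec("box"),
                        dt = 1.1 * g$spacing^2 / (2 * p$D), n_steps = 1),
                 "h\\^2")
})

test_that("the explicit fractal box solution solves its Schrodinger equation", {
  # i dpsi/dt = -(1/4pi) d2psi/dx2, term by term
  N <- 20; tt <- 0.3; dx <- 2e-4; dtt <- 1e-5
  for (x0 in c(0.3, 0.61)) {
    dpsidt <- (fractal_box_solution(N, tt + dtt, x0) -
                 fractal_box_solution(N, tt - dtt, x0)) / (2 * dtt)
    d2 <- (fractal_box_solution(N, tt, x0 + dx) -
             2 * fractal_box_solution(N, tt, x0) +
             fractal_box_solution(N, tt, x0 - dx)) / dx^2
    expect_lt(Mod(1i * dpsidt + d2 / (4 * pi)) / Mod(dpsidt), 1e-3)
  }
  # t = 0: |psi|^2 -> 1 away from x = 1/2 (Fourier series of the square wave)
  expect_equal(Mod(fractal_box_solution(1e4, 0, 0.25))^2, 1, tolerance = 1e-2)
  # the 2D product form
  z <- fractal_box_solution(5, 0.1, c(0.2, 0.4), y = c(0.3, 0.7))
  expect_identical(dim(z), c(2L, 2L))
  expect_equal(z[1, 2], fractal_box_solution(5, 0.1, 0.2) *
                 fractal_box_solution(5, 0.1, 0.7))
  # higher truncation orders resolve ever finer density structure
  x <- seq(0, 1, length.out = 2048)
  P100 <- Mod(fractal_box_solution(100, 0.551, x))^2
  P10 <- Mod(fractal_box_solution(10, 0.551, x))^2
  expect_gt(count_peaks(P100, prominence = 0.02),
            2 * count_peaks(P10, prominence = 0.02))
  expect_gt(count_peaks(P100, prominence = 0.02), 15)
})
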