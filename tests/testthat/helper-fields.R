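# shared builders for the numerical tests; everything is generated in code

std_params <- function() macro_params(D = 0.5, m = 1)   # S0 = 1

osc_pot <- function(omega = 1) potential_spec("harmonic", omega = omega, center = 0)

# oscillator test grid: 20 sigma wide, converged for the first few states
osc_grid <- function(n = 500, nsig = 20) {
  sig <- sqrt(0.5)                      # sigma_P for D = 0.5, omega = m = 1
  grid_spec(n, extent = nsig * sig, origin = -nsig * sig / 2)
}

gaussian_density_on <- function(grid, sigma2 = 0.5, center = 0) {
  x <- grid$axes[[1]]
  P <- exp(-(x - center)^2 / (2 * sigma2))
  P / (sum(P) * grid$spacing)
}

l2_rel <- function(a, b) sqrt(sum((a - b)^2) / sum(b^2))
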