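# Seeded synthetic-fixture generators: every module of the package can be
# exercised without any external data.

#' Fixture specification
#'
#' @param kind one of `"gaussian_density"`, `"smooth_random_potential"`,
#'   `"logperiodic_series"`, `"vortex_velocity"`, `"gaussian_dip_density"`.
#' @param ... kind-specific parameters (see [generate_fixture()]).
#' @param seed RNG seed for the stochastic kinds.
#' @return Object of class `fixture_spec`.
#' @export
fixture_spec <- function(kind = c("gaussian_density", "smooth_random_potential",
                                  "logperiodic_series", "vortex_velocity",
                                  "gaussian_dip_density"),
                         ..., seed = 1) {
  kind <- match.arg(kind)
  structure(c(list(kind = kind, seed = as.integer(seed)), list(...)),
            class = "fixture_spec")
}

fx_default <- function(spec, name, default) {
  if (is.null(spec[[name]])) default else spec[[name]]
}

#' Generate a synthetic fixture
#'
#' Deterministic under the spec's seed.  Kinds and their parameters:
#' \describe{
#'   \item{gaussian_density}{`n`, `extent`, `origin`, `sigma`, `center`,
#'     `ndim`; a normalized Gaussian [hydro_field()] with `V = 0`.}
#'   \item{smooth_random_potential}{`n`, `extent`, `origin`, `n_modes`,
#'     `amplitude`; a seeded low-order Fourier potential as a
#'     [potential_spec()] (attribute `grid` carries the grid).}
#'   \item{logperiodic_series}{`a`, `nu`, `b`, `omega`, `noise`
#'     (multiplicative, relative), `n`, `eps_min`, `eps_max`; a data frame
#'     with columns `eps`, `value` on a log-spaced grid.}
#'   \item{vortex_velocity}{`n`, `extent`, `circulation`; a 2D
#'     [hydro_field()] with uniform density and a solid-body vortex flow
#'     (non-potential by construction).}
#'   \item{gaussian_dip_density}{`n`, `extent`, `origin`, `n0`, `depth`,
#'     `sigma`, `center`; a density with a Gaussian dip, for dopant models.}
#' }
#'
#' @param spec a [fixture_spec()].
#' @param params [macro_params()] used for field-typed fixtures.
#' @return The generated object (see above).
#' @export
generate_fixture <- function(spec, params = macro_params(D = 0.5, m = 1)) {
  switch(spec$kind,
    gaussian_density = {
      ndim <- fx_default(spec, "ndim", 1L)
      n <- rep_len(fx_default(spec, "n", 256L), ndim)
      extent <- rep_len(fx_default(spec, "extent", 16), ndim)
      origin <- rep_len(fx_default(spec, "origin", -extent[1] / 2), ndim)
      sigma <- rep_len(fx_default(spec, "sigma", 1), ndim)
      center <- rep_len(fx_default(spec, "center", 0), ndim)
      g <- grid_spec(n, extent, origin)
      co <- grid_coords(g)
      q <- 0
      for (k in seq_len(ndim)) q <- q + (co[[k]] - center[k])^2 / (2 * sigma[k]^2)
      P <- exp(-q)
      hydro_field(P, lapply(seq_len(ndim), function(k) 0 * P), g, params,
                  normalize = TRUE)
    },
    smooth_random_potential = {
      n <- fx_default(spec, "n", 128L)
      extent <- fx_default(spec, "extent", 16)
      origin <- fx_default(spec, "origin", -extent / 2)
      n_modes <- fx_default(spec, "n_modes", 4L)
      amp <- fx_default(spec, "amplitude", 1)
      g <- grid_spec(n, extent, origin)
      x <- g$axes[[1]]
      phi <- with_seed(spec$seed, {
        co <- stats::rnorm(n_modes) * amp / seq_len(n_modes)
        si <- stats::rnorm(n_modes) * amp / seq_len(n_modes)
        out <- 0 * x
        for (j in seq_len(n_modes)) {
          out <- out + co[j] * cos(2 * pi * j * (x - origin) / extent) +
            si[j] * sin(2 * pi * j * (x - origin) / extent)
        }
        out
      })
      pot <- potential_spec("custom", phi = phi)
      attr(pot, "grid") <- g
      pot
    },
    logperiodic_series = {
      a <- fx_default(spec, "a", 1); nu <- fx_default(spec, "nu", 0.5)
      b <- fx_default(spec, "b", 0.3); omega <- fx_default(spec, "omega", 6)
      noise <- fx_default(spec, "noise", 0.01)
      n <- fx_default(spec, "n", 50L)
      eps_min <- fx_default(spec, "eps_min", 0.01)
      eps_max <- fx_default(spec, "eps_max", 10)
      eps <- exp(seq(log(eps_min), log(eps_max), length.out = n))
      value <- a * eps^nu * (1 + b * cos(omega * log(eps)))
      if (noise > 0) {
        value <- value * with_seed(spec$seed, 1 + noise * stats::rnorm(n))
      }
      data.frame(eps = eps, value = value)
    },
    vortex_velocity = {
      n <- rep_len(fx_default(spec, "n", 32L), 2)
      extent <- rep_len(fx_default(spec, "extent", 8), 2)
      circ <- fx_default(spec, "circulation", 1)
      g <- grid_spec(n, extent, origin = -extent / 2)
      co <- grid_coords(g)
      # solid-body rotation: curl = 2*circ everywhere, never potential flow
      Vx <- -circ * co[[2]]
      Vy <- circ * co[[1]]
      P <- 1 + 0 * Vx
      hydro_field(P, list(Vx, Vy), g, params, normalize = TRUE)
    },
    gaussian_dip_density = {
      ndim <- fx_default(spec, "ndim", 1L)
      n <- rep_len(fx_default(spec, "n", 256L), ndim)
      extent <- rep_len(fx_default(spec, "extent", 20), ndim)
      origin <- rep_len(fx_default(spec, "origin", -extent[1] / 2), ndim)
      n0 <- fx_default(spec, "n0", 1)
      depth <- fx_default(spec, "depth", 0.5)
      sigma <- fx_default(spec, "sigma", 1)
      center <- rep_len(fx_default(spec, "center", 0), ndim)
      if (depth >= n0) stop("depth must be < n0 (density stays positive)",
                            call. = FALSE)
      g <- grid_spec(n, extent, origin)
      co <- grid_coords(g)
      q <- 0
      for (k in seq_len(ndim)) q <- q + (co[[k]] - center[k])^2 / (2 * sigma^2)
      nd <- n0 - depth * exp(-q)
      attr(nd, "grid") <- g
      nd
    }
  )
}
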