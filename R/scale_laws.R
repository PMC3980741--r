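#' Scale-law parameter set
#'
#' Parameters of the scale differential equations in the space of resolutions
#' `ln(eps)`: the first-order broken-scale-invariance law, its log-periodic
#' correction, the constant scale-force ("scale dynamics") law, the scale
#' harmonic oscillator with an impassable wall `lam1`, and the limiting-scale
#' law with invariant scale `lamH`.
#'
#' Conventions: `tau_F = D_F - 1` (dimensionless "djinn") and `tau_F = -b_coef`
#' where `b_coef` is the linear coefficient of the first-order law; the
#' inhomogeneous coefficient is `a_coef = tau_F * L0`.
#'
#' @param L0 reference length, > 0.
#' @param lam fractal/non-fractal transition scale, > 0.
#' @param tau_F djinn, >= 0.
#' @param G scale-growth coefficient of the constant scale-force law.
#' @param lam0 reference scale of the second-order laws.
#' @param lam1 wall scale of the scale oscillator (interior branch: eps < lam1).
#' @param tau0 asymptotic djinn of the second-order laws.
#' @param lamH limiting (impassable) scale of the special scale-relativity law.
#' @param a_lp,nu,b_lp,omega log-periodic law `a * eps^nu * (1 + b*cos(omega*ln eps))`.
#' @return Object of class `scale_law_params`.
#' @export
scale_law_params <- function(L0 = 1, lam = 1, tau_F = 1,
                             G = 1, lam0 = 1, lam1 = NULL, tau0 = 1,
                             lamH = NULL,
                             a_lp = 1, nu = 0, b_lp = 0, omega = 2 * pi) {
  for (nm in c("L0", "lam", "lam0", "tau0")) {
    stopifnot_positive(get(nm), nm)
  }
  if (!is.null(lam1)) stopifnot_positive(lam1, "lam1")
  if (!is.null(lamH)) stopifnot_positive(lamH, "lamH")
  if (tau_F < 0) stop("tau_F must be >= 0", call. = FALSE)
  structure(list(L0 = L0, lam = lam, tau_F = tau_F,
                 a_coef = tau_F * L0, b_coef = -tau_F,
                 G = G, lam0 = lam0, lam1 = lam1, tau0 = tau0, lamH = lamH,
                 a_lp = a_lp, nu = nu, b_lp = b_lp, omega = omega),
            class = "scale_law_params")
}

check_eps <- function(eps) {
  if (any(!is.finite(eps)) || any(eps <= 0)) {
    stop("resolution `eps` must be finite and > 0", call. = FALSE)
  }
  eps
}

#' Fractal length with scale-invariance breaking
#'
#' `L(eps) = L0 * (1 + (lam/eps)^tau_F)`: power-law fractal part below the
#' transition `lam`, scale-independent part above it.
#'
#' @param eps resolution(s), > 0.
#' @param params [scale_law_params()].
#' @export
#' @examples
#' p <- scale_law_params(L0 = 1, lam = 1, tau_F = 1)
#' fractal_length(0.1, p)   # 11
fractal_length <- function(eps, params) {
  check_eps(eps)
  params$L0 * (1 + (params$lam / eps)^params$tau_F)
}

#' Ratio of fractal parts at two resolutions
#'
#' Depends only on `eps2/eps1` (relativity of scales): equals
#' `(eps2/eps1)^tau_F`.
#' @param eps1,eps2 resolutions, > 0.
#' @inheritParams fractal_length
#' @export
fractal_part_ratio <- function(eps1, eps2, params) {
  check_eps(eps1); check_eps(eps2)
  (eps2 / eps1)^params$tau_F
}

#' Log-periodic scale law
#'
#' `L(eps) = a * eps^nu * (1 + b * cos(omega * ln eps))`: discrete scale
#' invariance, periodic in `ln eps` with period `2*pi/omega`.
#' @inheritParams fractal_length
#' @export
log_periodic_length <- function(eps, params) {
  check_eps(eps)
  params$a_lp * eps^params$nu *
    (1 + params$b_lp * cos(params$omega * log(eps)))
}

#' Constant scale-force law
#'
#' Variable fractal dimension `tau_F(eps) = ln(lam0/eps)/G`, linear in
#' `ln(1/eps)`, and `ln(L/L0) = ln^2(lam0/eps)/(2G)`.
#' @inheritParams fractal_length
#' @return list with `tau_F` and `log_length` (= ln(L/L0)), each along `eps`.
#' @export
scale_dynamics_length <- function(eps, params) {
  check_eps(eps)
  if (params$G == 0) stop("degenerate parameter: G must be non-zero", call. = FALSE)
  u <- log(params$lam0 / eps)
  list(tau_F = u / params$G, log_length = u^2 / (2 * params$G))
}

#' Scale harmonic oscillator (interior branch)
#'
#' `ln(L/L0) = tau0 * sqrt(ln^2(lam0/eps) - ln^2(lam0/lam1))` for resolutions
#' inside the wall (`eps <= lam1 < lam0`).  Resolutions between `lam1` and the
#' mirror scale are forbidden: the argument of the square root is negative
#' there and a typed error (`mq_forbidden_scale`) is raised.
#' @inheritParams fractal_length
#' @export
scale_oscillator_length <- function(eps, params) {
  check_eps(eps)
  if (is.null(params$lam1)) stop("params$lam1 is required", call. = FALSE)
  arg <- log(params$lam0 / eps)^2 - log(params$lam0 / params$lam1)^2
  if (any(arg < 0)) {
    stop(structure(class = c("mq_forbidden_scale", "error", "condition"),
                   list(message = paste0(
                     "resolution inside the forbidden band at the wall lam1 = ",
                     format(params$lam1)), call = sys.call(-1))))
  }
  params$tau0 * sqrt(arg)
}

#' Special scale-relativity law (limiting scale)
#'
#' Log-Lorentzian djinn `tau_F(eps) = tau0 / sqrt(1 - ln^2(lam0/eps)/
#' ln^2(lam0/lamH))` and the matching `ln(L/L0)`; the scale `lamH` is
#' impassable and resolutions at or beyond it raise a typed error
#' (`mq_limiting_scale`).
#' @inheritParams fractal_length
#' @return list with `tau_F` and `log_length`.
#' @export
special_relativity_djinn <- function(eps, params) {
  check_eps(eps)
  if (is.null(params$lamH)) stop("params$lamH is required", call. = FALSE)
  num <- log(params$lam0 / eps)
  den <- log(params$lam0 / params$lamH)
  ratio2 <- num^2 / den^2
  if (any(ratio2 >= 1)) {
    stop(structure(class = c("mq_limiting_scale", "error", "condition"),
                   list(message = paste0(
                     "resolution at or beyond the limiting scale lamH = ",
                     format(params$lamH)), call = sys.call(-1))))
  }
  g <- 1 / sqrt(1 - ratio2)
  list(tau_F = params$tau0 * g, log_length = params$tau0 * num * g)
}

#' Effective fractal-dimension profile of a wall ("cell wall" model)
#'
#' Radial profile of the effective fractal dimension produced by a repulsive
#' harmonic oscillator in scale space: a constant dimension `1 + tau0` deep in
#' the inner region, a divergence on approaching the inner wall `lam1`, a
#' formally infinite dimension across the wall band, and a constant outer
#' dimension beyond the outer edge.  The local dimension on each branch is
#' `1 + |d ln L / d ln(1/eps)|` of the scale-oscillator solution.
#'
#' @param r radial scale variable(s), > 0.
#' @param params_inner [scale_law_params()] with `lam0`, `lam1`, `tau0` for the
#'   interior branch (`lam1 < lam0`).
#' @param params_outer same for the exterior branch; its wall edge
#'   `lam0^2/lam1` must not lie below the inner wall (overlap is a
#'   configuration error).  `NULL` reuses the mirror branch of `params_inner`.
#' @return Effective dimension; `Inf` inside the wall band.
#' @export
wall_dimension_profile <- function(r, params_inner, params_outer = NULL) {
  check_eps(r)
  if (is.null(params_outer)) params_outer <- params_inner
  pin <- params_inner; pout <- params_outer
  if (is.null(pin$lam1) || pin$lam1 >= pin$lam0) {
    stop("inner branch needs lam1 < lam0", call. = FALSE)
  }
  r_in <- pin$lam1
  r_out <- pout$lam0^2 / pout$lam1          # mirror wall of the outer branch
  if (r_out < r_in) {
    stop("inner and outer wall domains overlap", call. = FALSE)
  }
  dim_branch <- function(r, p) {
    u <- log(p$lam0 / r)
    c2 <- log(p$lam0 / p$lam1)^2
    # |d lnL / d ln(1/eps)| = tau0 |u| / sqrt(u^2 - c2)
    1 + p$tau0 * abs(u) / sqrt(pmax(u^2 - c2, 0))
  }
  out <- numeric(length(r))
  inner <- r < r_in
  outer <- r > r_out
  out[inner] <- dim_branch(r[inner], pin)
  out[outer] <- dim_branch(r[outer], pout)
  out[!inner & !outer] <- Inf
  out
}

#' Fit the log-periodic scale law to a series
#'
#' Least-squares fit of `value = a * eps^nu * (1 + b*cos(omega*ln(eps) + phase))`
#' by a grid search over `omega` with `(ln a, nu, b*cos, b*sin)` profiled
#' linearly on `ln(value)`, followed by Levenberg-Marquardt refinement of the
#' full nonlinear model.  Significance of the log-periodic component is scored
#' by permutation: the detrended residuals are shuffled `n_perm` times and the
#' maximal RSS reduction over the omega grid is recompared to the observed one.
#'
#' @param series data frame with columns `eps` and `value` (>= 8 points
#'   spanning at least one decade in `eps`).
#' @param omega_grid candidate angular log-frequencies.
#' @param n_perm permutations for the significance score.
#' @param seed RNG seed for the permutations.
#' @return list with `params` (fitted [scale_law_params()]), `omega`, `nu`,
#'   `a`, `b`, `phase`, `residual_norm`, `p_value`.
#' @export
#' @examples
#' s <- generate_fixture(fixture_spec("logperiodic_series", nu = 0.5, b = 0.3,
#'                                    omega = 6, noise = 0.01, n = 50, seed = 1))
#' fit <- fit_log_periodic(s)
#' fit$omega
fit_log_periodic <- function(series, omega_grid = seq(0.5, 20, by = 0.05),
                             n_perm = 200, seed = 1) {
  eps <- series$eps
  y <- series$value
  if (length(eps) < 8) stop("need at least 8 samples", call. = FALSE)
  check_eps(eps)
  if (diff(range(log10(eps))) < 1) {
    stop("series must span at least one decade in eps", call. = FALSE)
  }
  if (any(y <= 0) || stats::sd(y) == 0) {
    stop("degenerate series: values must be positive and non-constant",
         call. = FALSE)
  }
  le <- log(eps); ly <- log(y)

  rss_for <- function(ly) {
    # profiled linear fit per candidate omega (small-b log linearization)
    base <- cbind(1, le)
    rss0 <- sum(stats::lsfit(base, ly, intercept = FALSE)$residuals^2)
    rss <- vapply(omega_grid, function(w) {
      X <- cbind(base, cos(w * le), sin(w * le))
      sum(stats::lsfit(X, ly, intercept = FALSE)$residuals^2)
    }, numeric(1))
    list(rss0 = rss0, rss = rss)
  }

  obs <- rss_for(ly)
  k <- which.min(obs$rss)
  w0 <- omega_grid[k]
  X <- cbind(1, le, cos(w0 * le), sin(w0 * le))
  beta <- stats::lsfit(X, ly, intercept = FALSE)$coefficients
  beta <- unname(beta)
  start <- c(lna = beta[1], nu = beta[2],
             b = sqrt(beta[3]^2 + beta[4]^2),
             phase = atan2(-beta[4], beta[3]), omega = w0)
  model_fn <- function(par) {
    exp(par[["lna"]]) * eps^par[["nu"]] *
      (1 + par[["b"]] * cos(par[["omega"]] * le + par[["phase"]]))
  }
  jac_fn <- function(par) {
    A <- exp(par[["lna"]]) * eps^par[["nu"]]
    th <- par[["omega"]] * le + par[["phase"]]
    m <- A * (1 + par[["b"]] * cos(th))
    -cbind(lna = m, nu = m * le, b = A * cos(th),
           phase = -A * par[["b"]] * sin(th),
           omega = -A * par[["b"]] * sin(th) * le)
  }
  lm_ctrl <- minpack.lm::nls.lm.control(maxiter = 1000, ftol = 1e-18,
                                        ptol = 1e-15, maxfev = 10000)
  fit <- try(minpack.lm::nls.lm(par = start,
                                fn = function(par) y - model_fn(par),
                                jac = jac_fn, control = lm_ctrl),
             silent = TRUE)
  if (inherits(fit, "try-error")) {
    co <- start
    resid_norm <- sqrt(obs$rss[k])
  } else {
    co <- fit$par
    resid_norm <- sqrt(sum(fit$fvec^2))
  }
  b_hat <- abs(co[["b"]])
  ph <- co[["phase"]] + if (co[["b"]] < 0) pi else 0

  # permutation score on the RSS reduction of the oscillatory component
  trend <- stats::lsfit(cbind(1, le), ly, intercept = FALSE)
  det_res <- trend$residuals
  trend_fit <- ly - det_res
  obs_gain <- obs$rss0 - min(obs$rss)
  perm_gain <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    lyp <- trend_fit + sample(det_res)
    rp <- rss_for(lyp)
    rp$rss0 - min(rp$rss)
  }, numeric(1)))
  p_value <- (1 + sum(perm_gain >= obs_gain)) / (1 + n_perm)

  params <- scale_law_params(a_lp = exp(co[["lna"]]), nu = co[["nu"]],
                             b_lp = b_hat, omega = abs(co[["omega"]]))
  list(params = params, omega = abs(co[["omega"]]), nu = co[["nu"]],
       a = exp(co[["lna"]]), b = b_hat, phase = ph,
       residual_norm = resid_norm, p_value = p_value)
}
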