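# Internal numerical helpers shared across modules.

#' Evaluate code under a fixed RNG seed, restoring the caller's RNG state
#' @noRd
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

stopifnot_positive <- function(x, name = deparse(substitute(x))) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0)) {
    stop("`", name, "` must be finite and strictly positive", call. = FALSE)
  }
  invisible(x)
}

#' Shift an array along one dimension (zero or wrap fill)
#'
#' Used to build central-difference stencils without explicit loops.
#' @noRd
shift_array <- function(x, by, axis, periodic = FALSE) {
  d <- dim(x)
  if (is.null(d)) {             # plain vector
    n <- length(x)
    idx <- seq_len(n) + by
    if (periodic) {
      idx <- ((idx - 1L) %% n) + 1L
      return(x[idx])
    }
    out <- rep(0 * x[1], n)     # keeps complex/double type
    keep <- idx >= 1L & idx <= n
    out[keep] <- x[idx[keep]]
    return(out)
  }
  n <- d[axis]
  idx <- seq_len(n) + by
  args <- rep(list(quote(expr = )), length(d))
  if (periodic) {
    args[[axis]] <- ((idx - 1L) %% n) + 1L
    return(do.call(`[`, c(list(x), args, list(drop = FALSE))))
  }
  keep <- idx >= 1L & idx <= n
  out <- array(0 * x[1], dim = d)
  src <- args; src[[axis]] <- idx[keep]
  dst <- args; dst[[axis]] <- seq_len(n)[keep]
  out_sub <- do.call(`[`, c(list(x), src, list(drop = FALSE)))
  out <- do.call(`[<-`, c(list(out), dst, list(value = out_sub)))
  out
}

#' Local maxima of a 1D profile with topographic prominence
#'
#' Returns indices of strict local maxima whose prominence (height above the
#' highest saddle separating them from any higher peak) is at least
#' `min_prom`.  Plateaus are collapsed to their centre point.
#' @noRd
peaks1d <- function(y, min_prom = 0) {
  n <- length(y)
  if (n < 3) return(integer(0))
  # collapse exact plateaus so strict comparisons work
  cand <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    if (y[i] > y[i - 1L]) {
      j <- i
      while (j < n && y[j + 1L] == y[j]) j <- j + 1L
      if (j <= n - 1L && y[j + 1L] < y[j]) {
        cand <- c(cand, as.integer(round((i + j) / 2)))
      }
      i <- j + 1L
    } else i <- i + 1L
  }
  if (!length(cand)) return(integer(0))
  prom <- vapply(cand, function(p) {
    h <- y[p]
    # walk left until a higher point; track the minimum en route
    lmin <- h
    k <- p
    while (k > 1L) {
      k <- k - 1L
      if (y[k] > h) break
      lmin <- min(lmin, y[k])
    }
    if (y[k] <= h) lmin <- min(lmin, y[k])  # reached the border
    rmin <- h
    k <- p
    while (k < n) {
      k <- k + 1L
      if (y[k] > h) break
      rmin <- min(rmin, y[k])
    }
    if (y[k] <= h) rmin <- min(rmin, y[k])
    h - max(lmin, rmin)
  }, numeric(1))
  cand[prom >= min_prom]
}

#' Trapezoid-free integral on a uniform grid (cell-sum quadrature)
#' @noRd
cell_integral <- function(f, grid) {
  sum(f) * prod(grid$spacing)
}

fmt_num <- function(x) sprintf("%.17g", x)
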