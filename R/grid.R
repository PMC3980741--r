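#' Uniform computational grid
#'
#' Defines a uniform grid on a rectangular domain in 1, 2 or 3 dimensions.
#' With `boundary = "box"` the field satisfies Dirichlet conditions
#' (psi = 0 on the walls) and the stored points are the interior nodes
#' `origin + i*h`, `i = 1..n`, with `h = extent/(n+1)`.  With
#' `boundary = "periodic"` the points are `origin + (i-1)*h`, `h = extent/n`,
#' and the domain is the half-open interval `[origin, origin + extent)`.
#'
#' @param n integer vector, points per axis (>= 8 each).
#' @param extent numeric vector, domain length per axis.
#' @param origin numeric vector, lower domain edge per axis (default 0).
#' @param boundary `"box"` (Dirichlet) or `"periodic"`.
#' @return An object of class `mq_grid` with fields `ndim`, `n`, `extent`,
#'   `origin`, `boundary`, `spacing` and per-axis coordinates `axes`.
#' @export
#' @examples
#' g <- grid_spec(128, extent = 16, origin = -8)
#' range(g$axes[[1]])
grid_spec <- function(n, extent, origin = 0, boundary = c("box", "periodic")) {
  boundary <- match.arg(boundary)
  n <- as.integer(n)
  ndim <- length(n)
  if (!ndim %in% 1:3) stop("grid must be 1, 2 or 3 dimensional", call. = FALSE)
  if (any(n < 8)) stop("need at least 8 points per axis", call. = FALSE)
  extent <- rep_len(as.numeric(extent), ndim)
  origin <- rep_len(as.numeric(origin), ndim)
  stopifnot_positive(extent, "extent")
  spacing <- if (boundary == "box") extent / (n + 1) else extent / n
  axes <- lapply(seq_len(ndim), function(k) {
    if (boundary == "box") origin[k] + seq_len(n[k]) * spacing[k]
    else origin[k] + (seq_len(n[k]) - 1L) * spacing[k]
  })
  structure(
    list(ndim = ndim, n = n, extent = extent, origin = origin,
         boundary = boundary, spacing = spacing, axes = axes),
    class = "mq_grid"
  )
}

#' @export
print.mq_grid <- function(x, ...) {
  cat(sprintf("<mq_grid> %dD %s, n = %s, extent = %s, h = %s\n",
              x$ndim, x$boundary, paste(x$n, collapse = "x"),
              paste(signif(x$extent, 4), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = ", ")))
  invisible(x)
}

grid_npoints <- function(grid) prod(grid$n)

#' Coordinate arrays of a grid
#'
#' @param grid an `mq_grid`.
#' @return A list of arrays (one per axis), each of the full grid shape,
#'   giving the coordinate value of every node.
#' @export
grid_coords <- function(grid) {
  if (grid$ndim == 1) return(list(grid$axes[[1]]))
  tmpl <- array(0L, dim = grid$n)
  lapply(seq_len(grid$ndim), function(k) {
    array(grid$axes[[k]][slice.index(tmpl, k)], dim = grid$n)
  })
}

as_field_array <- function(x, grid) {
  if (grid$ndim == 1) as.vector(x) else array(x, dim = grid$n)
}

#' Central-difference gradient of a scalar field
#'
#' Second-order central differences; Dirichlet grids use zero ghost nodes,
#' periodic grids wrap.
#' @param f scalar field (vector/matrix/array matching `grid`).
#' @param grid an `mq_grid`.
#' @return list of arrays, one component per axis.
#' @export
fd_gradient <- function(f, grid) {
  per <- grid$boundary == "periodic"
  lapply(seq_len(grid$ndim), function(k) {
    (shift_array(f, 1L, k, per) - shift_array(f, -1L, k, per)) /
      (2 * grid$spacing[k])
  })
}

#' Central-difference Laplacian of a scalar field
#' @inheritParams fd_gradient
#' @return array of the same shape as `f`.
#' @export
fd_laplacian <- function(f, grid) {
  per <- grid$boundary == "periodic"
  out <- 0 * f
  for (k in seq_len(grid$ndim)) {
    out <- out + (shift_array(f, 1L, k, per) + shift_array(f, -1L, k, per) -
                    2 * f) / grid$spacing[k]^2
  }
  out
}

#' Divergence of a vector field
#' @param v list of component arrays (one per axis).
#' @inheritParams fd_gradient
#' @export
fd_divergence <- function(v, grid) {
  per <- grid$boundary == "periodic"
  out <- 0 * v[[1]]
  for (k in seq_len(grid$ndim)) {
    out <- out + (shift_array(v[[k]], 1L, k, per) -
                    shift_array(v[[k]], -1L, k, per)) / (2 * grid$spacing[k])
  }
  out
}

# 1D second-difference matrix (dense) for the chosen boundary
second_diff_matrix <- function(n, h, boundary) {
  M <- diag(-2, n)
  idx <- seq_len(n - 1)
  M[cbind(idx, idx + 1)] <- 1
  M[cbind(idx + 1, idx)] <- 1
  if (boundary == "periodic") {
    M[1, n] <- 1
    M[n, 1] <- 1
  }
  M / h^2
}

# Discrete Laplacian as a dense matrix over all grid points (column-major
# flattening, axis 1 fastest), built from Kronecker products.
laplacian_matrix <- function(grid) {
  mats <- lapply(seq_len(grid$ndim), function(k) {
    second_diff_matrix(grid$n[k], grid$spacing[k], grid$boundary)
  })
  eyes <- lapply(grid$n, diag)
  out <- NULL
  for (k in seq_len(grid$ndim)) {
    term <- 1
    for (j in seq_len(grid$ndim)) {
      m <- if (j == k) mats[[j]] else eyes[[j]]
      term <- if (identical(term, 1)) m else kronecker(m, term)
    }
    out <- if (is.null(out)) term else out + term
  }
  out
}
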