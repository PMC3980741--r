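#' Count interior nodes of an essentially real 1D state
#'
#' Removes the global phase (phase at the point of maximal amplitude), checks
#' that the remaining profile is real within tolerance, and counts sign
#' changes of the real part above the amplitude floor
#' `1e-6 * max|psi|`.  By the oscillation theorem the (n+1)-th eigenstate of a
#' 1D confining problem has exactly n such nodes.
#'
#' @param state a 1D [wave_field()] (or a numeric/complex vector).
#' @param floor_frac amplitude floor as a fraction of `max|psi|`.
#' @return Integer node count.
#' @export
count_nodes <- function(state, floor_frac = 1e-6) {
  psi <- if (inherits(state, "wave_field")) {
    if (state$grid$ndim != 1) stop("count_nodes is 1D only", call. = FALSE)
    as.vector(state$psi)
  } else as.complex(state)
  k <- which.max(Mod(psi))
  psi <- psi * exp(-1i * Arg(psi[k]))
  if (max(abs(Im(psi))) > 1e-6 * max(Mod(psi))) {
    stop("state is genuinely complex; no global phase makes it real",
         call. = FALSE)
  }
  v <- Re(psi)
  v <- v[abs(v) > floor_frac * max(abs(v))]
  sum(diff(sign(v)) != 0)
}

#' Count prominent peaks of a nonnegative field
#'
#' 1D fields use topographic prominence; 2D fields count strict local maxima
#' (8-neighbourhood) above the prominence threshold, which is adequate for
#' the well-separated density lobes this package produces.
#'
#' @param P nonnegative field (vector or matrix), not identically zero.
#' @param prominence minimal prominence as a fraction of `max(P)`.
#' @return Integer peak count.
#' @export
count_peaks <- function(P, prominence = 0.1) {
  if (inherits(P, "wave_field")) P <- density_of(P)
  if (all(P == 0)) stop("field is identically zero", call. = FALSE)
  if (any(P < 0)) stop("field must be nonnegative", call. = FALSE)
  if (is.null(dim(P)) || length(dim(P)) == 1) {
    return(length(peaks1d(as.vector(P), min_prom = prominence * max(P))))
  }
  if (length(dim(P)) != 2) stop("count_peaks supports 1D and 2D fields",
                                call. = FALSE)
  nr <- nrow(P); nc <- ncol(P)
  pad <- matrix(-Inf, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- P
  ismax <- matrix(TRUE, nr, nc)
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    ismax <- ismax & (P > pad[(2:(nr + 1)) + di, (2:(nc + 1)) + dj])
  }
  sum(ismax & P >= prominence * max(P))
}
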