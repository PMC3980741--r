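# Plain-text field container: '#'-prefixed key-value header carrying the
# grid and macroquantum attributes, followed by a CSV body at full double
# precision (17 significant digits), so write-read round-trips are testable.

field_columns <- function(field) {
  g <- field$grid
  co <- grid_coords(g)
  cols <- stats::setNames(lapply(co, as.vector),
                          paste0("x", seq_len(g$ndim)))
  if (inherits(field, "wave_field")) {
    cols$re <- as.vector(Re(field$psi))
    cols$im <- as.vector(Im(field$psi))
  } else if (inherits(field, "hydro_field")) {
    cols$P <- as.vector(field$P)
    for (k in seq_len(g$ndim)) cols[[paste0("V", k)]] <- as.vector(field$V[[k]])
  } else if (inherits(field, "diffusive_field")) {
    cols$P <- as.vector(field$P)
    for (k in seq_len(g$ndim)) {
      cols[[paste0("v_plus", k)]] <- as.vector(field$v_plus[[k]])
    }
  } else stop("unsupported field class", call. = FALSE)
  cols
}

#' Write a field to the plain-text container
#'
#' @param field a [wave_field()], [hydro_field()] or [diffusive_field()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_field <- function(field, path) {
  g <- field$grid
  hdr <- c("# macroquant-field v1",
           paste0("# class: ", class(field)[1]),
           paste0("# ndim: ", g$ndim),
           paste0("# n: ", paste(g$n, collapse = " ")),
           paste0("# extent: ", paste(fmt_num(g$extent), collapse = " ")),
           paste0("# origin: ", paste(fmt_num(g$origin), collapse = " ")),
           paste0("# boundary: ", g$boundary),
           paste0("# D: ", fmt_num(field$params$D)),
           paste0("# m: ", fmt_num(field$params$m)),
           paste0("# t: ", fmt_num(field$t)))
  cols <- field_columns(field)
  body <- do.call(paste, c(lapply(cols, function(v) {
    ifelse(is.na(v), "NA", sprintf("%.17g", v))
  }), list(sep = ",")))
  writeLines(c(hdr, paste(names(cols), collapse = ","), body), path)
  invisible(path)
}

#' Read a field from the plain-text container
#'
#' @param path input file path.
#' @return The reconstructed field object.
#' @export
read_field <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || lines[1] != "# macroquant-field v1") {
    stop("format error: not a macroquant-field container", call. = FALSE)
  }
  hdr_idx <- grep("^#", lines)
  hdr <- lines[hdr_idx][-1]
  kv <- list()
  for (l in hdr) {
    m <- regmatches(l, regexec("^# ([a-zA-Z_]+): (.*)$", l))[[1]]
    if (length(m) == 3) kv[[m[2]]] <- m[3]
  }
  for (need in c("class", "ndim", "n", "extent", "origin", "boundary",
                 "D", "m", "t")) {
    if (is.null(kv[[need]])) {
      stop("format error: missing attribute `", need, "`", call. = FALSE)
    }
  }
  num <- function(x) as.numeric(strsplit(x, " ")[[1]])
  grid <- grid_spec(num(kv$n), num(kv$extent), num(kv$origin), kv$boundary)
  params <- macro_params(D = as.numeric(kv$D), m = as.numeric(kv$m))
  t0 <- as.numeric(kv$t)
  body <- lines[-seq_len(max(hdr_idx))]
  col_names <- strsplit(body[1], ",")[[1]]
  dat <- utils::read.csv(text = paste(body, collapse = "\n"))
  names(dat) <- col_names
  cls <- kv$class
  ndim <- grid$ndim
  if (cls == "wave_field") {
    if (!all(c("re", "im") %in% col_names)) {
      stop("format error: missing dataset `re`/`im`", call. = FALSE)
    }
    wave_field(complex(real = dat$re, imaginary = dat$im), grid, params,
               t = t0, normalize = FALSE)
  } else if (cls == "hydro_field") {
    V <- lapply(seq_len(ndim), function(k) {
      nm <- paste0("V", k)
      if (!nm %in% col_names) stop("format error: missing dataset `", nm, "`",
                                   call. = FALSE)
      as_field_array(dat[[nm]], grid)
    })
    hydro_field(dat$P, V, grid, params, t = t0, normalize = FALSE)
  } else if (cls == "diffusive_field") {
    vp <- lapply(seq_len(ndim), function(k) {
      nm <- paste0("v_plus", k)
      if (!nm %in% col_names) stop("format error: missing dataset `", nm, "`",
                                   call. = FALSE)
      as_field_array(dat[[nm]], grid)
    })
    diffusive_field(dat$P, vp, grid, params, t = t0, normalize = FALSE)
  } else stop("format error: unknown class `", cls, "`", call. = FALSE)
}
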