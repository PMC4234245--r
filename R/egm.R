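#' Extracellular unipolar electrograms at every node
#'
#' Forward-models the extracellular potential by inverse-distance
#' superposition of tissue sources:
#' \deqn{u_{i,j}(t) = c \sum_{k,l} S_{k,l}(t) / r_{k,l}}
#' with `c = 1` and `r` the 3-D distance from the electrode (elevated
#' `h` node spacings above the sheet) to node (k, l). The source `S` is
#' either the negated discrete Laplacian of the transmembrane voltage
#' (`source_mode = "laplacian"`, the standard current-source
#' approximation) or the voltage itself (`"voltage"`, the literal
#' inverse-distance sum of v). Both modes are kept because published
#' mapping work uses either convention; entropy-at-pivot conclusions
#' hold for both.
#'
#' The double sum is evaluated exactly via FFT convolution; the kernel
#' is the full-grid 1/r stencil (no truncation).
#'
#' @param movie a `voltage_movie`.
#' @param h electrode elevation above the sheet in node-spacing units
#'   (> 0; regularizes the self-term).
#' @param source_mode `"laplacian"` (default) or `"voltage"`.
#' @param window optional fraction window `c(lo, hi)` of frames to use
#'   (see [movie_window()]).
#' @return object of class `egm_field` with `data` (`nx` x `ny` x `n_t`),
#'   `fs` (Hz, taking the model time unit as ms), `sites_x`, `sites_y`
#'   (node coordinates), `kind = "unipolar"`, `h`, `source_mode`.
#' @export
unipolar_field <- function(movie, h = 1,
                           source_mode = c("laplacian", "voltage"),
                           window = NULL) {
  stopifnot(inherits(movie, "voltage_movie"))
  source_mode <- match.arg(source_mode)
  if (h <= 0) stop("electrode height h must be > 0 (self-term singularity)")
  if (!is.null(window)) movie <- movie_window(movie, window)
  fr <- movie$frames
  nx <- dim(fr)[1]; ny <- dim(fr)[2]; nt <- dim(fr)[3]
  dx <- movie$grid$dx
  # 1/r kernel over all integer offsets, wrap-around layout for padded FFT
  P <- nextn(2 * nx - 1, c(2, 3, 5))
  Q <- nextn(2 * ny - 1, c(2, 3, 5))
  K <- matrix(0, P, Q)
  ki <- c(seq_len(nx), P - rev(seq_len(nx - 1)) + 1)
  kj <- c(seq_len(ny), Q - rev(seq_len(ny - 1)) + 1)
  vi <- c(0:(nx - 1), (nx - 1):1)
  vj <- c(0:(ny - 1), (ny - 1):1)
  K[ki, kj] <- 1 / (dx * sqrt(outer(vi^2, vj^2, "+") + h^2))
  Kf <- fft(K)
  u <- array(NA_real_, c(nx, ny, nt))
  Sp <- matrix(0, P, Q)
  for (k in seq_len(nt)) {
    S <- if (source_mode == "laplacian") {
      -discrete_laplacian(fr[, , k], dx)
    } else {
      fr[, , k]
    }
    Sp[seq_len(nx), seq_len(ny)] <- S
    conv <- Re(fft(fft(Sp) * Kf, inverse = TRUE)) / (P * Q)
    u[, , k] <- conv[seq_len(nx), seq_len(ny)]
  }
  structure(list(data = u, fs = 1000 / movie$dt_sample,
                 t = movie$t, dt_sample = movie$dt_sample,
                 sites_x = seq_len(nx), sites_y = seq_len(ny),
                 kind = "unipolar", h = h, source_mode = source_mode,
                 spacing = NA_integer_, orientation = NA_character_,
                 grid = movie$grid, model_tag = movie$model_tag),
            class = "egm_field")
}

#' Discrete 5-point Laplacian with mirror (no-flux) boundaries
#' @param z matrix; @param dx node spacing.
#' @return matrix of the same shape, units z / dx^2.
#' @export
discrete_laplacian <- function(z, dx = 1) {
  nx <- nrow(z); ny <- ncol(z)
  im <- c(2L, seq_len(nx - 1)); ip <- c(seq_len(nx)[-1], nx - 1L)
  jm <- c(2L, seq_len(ny - 1)); jp <- c(seq_len(ny)[-1], ny - 1L)
  (z[im, ] + z[ip, ] + z[, jm] + z[, jp] - 4 * z) / dx^2
}

#' Bipolar electrograms as spaced differences of unipolar signals
#'
#' \deqn{w_{i,j}(t) = u_{i,j}(t) - u_{i+s,j}(t)} for horizontal bipoles
#' (difference along x), or the analogous difference along y for
#' vertical ones. The output grid is cropped by `s` along the bipole
#' axis and each bipole site is registered at the midpoint of its two
#' poles, so maps at different spacings stay co-registered.
#'
#' @param ufield a unipolar `egm_field`.
#' @param s inter-electrode spacing in mesh nodes (>= 0; `s = 0` gives
#'   an identically zero field).
#' @param orientation `"horizontal"` (along x) or `"vertical"`.
#' @return a bipolar `egm_field`.
#' @export
bipolar_field <- function(ufield, s,
                          orientation = c("horizontal", "vertical")) {
  stopifnot(inherits(ufield, "egm_field"), ufield$kind == "unipolar")
  orientation <- match.arg(orientation)
  s <- as.integer(s)
  if (s < 0) stop("spacing s must be >= 0")
  u <- ufield$data
  nx <- dim(u)[1]; ny <- dim(u)[2]
  out <- ufield
  if (orientation == "horizontal") {
    if (s >= nx) stop("spacing s = ", s, " exceeds the grid (nx = ", nx, ")")
    keep <- seq_len(nx - s)
    out$data <- u[keep, , , drop = FALSE] - u[keep + s, , , drop = FALSE]
    out$sites_x <- ufield$sites_x[keep] + s / 2
  } else {
    if (s >= ny) stop("spacing s = ", s, " exceeds the grid (ny = ", ny, ")")
    keep <- seq_len(ny - s)
    out$data <- u[, keep, , drop = FALSE] - u[, keep + s, , drop = FALSE]
    out$sites_y <- ufield$sites_y[keep] + s / 2
  }
  out$kind <- "bipolar"
  out$spacing <- s
  out$orientation <- orientation
  out
}

#' @export
print.egm_field <- function(x, ...) {
  d <- dim(x$data)
  cat("<egm_field>", x$kind,
      if (x$kind == "bipolar")
        paste0("(s = ", x$spacing, ", ", x$orientation, ")"),
      ":", d[1], "x", d[2], "sites,", d[3], "samples @", x$fs, "Hz\n")
  invisible(x)
}

#' Extract a single electrode trace from an EGM field
#'
#' @param field an `egm_field`.
#' @param i,j site indices into the field arrays.
#' @return object of class `egm_trace`: `samples`, `fs`, `kind`,
#'   `config` (site coordinates, spacing, orientation, height, source
#'   mode).
#' @export
egm_trace <- function(field, i, j) {
  stopifnot(inherits(field, "egm_field"))
  structure(list(samples = as.numeric(field$data[i, j, ]),
                 t = field$t, fs = field$fs, kind = field$kind,
                 config = list(position = c(x = field$sites_x[i],
                                            y = field$sites_y[j]),
                               spacing_s = field$spacing,
                               orientation = field$orientation,
                               height_h = field$h,
                               source_mode = field$source_mode)),
            class = "egm_trace")
}

#' @export
print.egm_trace <- function(x, ...) {
  cat("<egm_trace>", x$kind, "at (",
      paste(signif(x$config$position, 4), collapse = ", "), "),",
      length(x$samples), "samples @", x$fs, "Hz\n")
  invisible(x)
}

#' Site nearest to given node coordinates
#' @param field an `egm_field`.
#' @param x,y node coordinates.
#' @return integer site indices `c(i, j)`.
#' @export
nearest_site <- function(field, x, y) {
  c(which.min(abs(field$sites_x - x)), which.min(abs(field$sites_y - y)))
}
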