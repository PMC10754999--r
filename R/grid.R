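#' Wavenumber grid
#'
#' A regular wavenumber axis for FTIR absorbance spectra, stored ascending.
#' The default grid covers the mid-infrared window used for serum spectra:
#' 700--4000 cm\eqn{^{-1}} sampled every 4 cm\eqn{^{-1}}, i.e. 826 points.
#'
#' @param start First wavenumber (cm^-1).
#' @param stop Last wavenumber (cm^-1); must exceed `start` and be reachable
#'   from `start` in whole steps.
#' @param step Grid spacing (cm^-1), positive.
#'
#' @return An object of class `wn_grid`: a list with elements `start`, `stop`,
#'   `step`, `n_points` and the full `wavenumbers` vector.
#' @examples
#' g <- wn_grid()
#' g$n_points # 826
#' @export
wn_grid <- function(start = 700, stop = 4000, step = 4) {
  if (!is.numeric(start) || !is.numeric(stop) || !is.numeric(step)) {
    rlang::abort("grid bounds and step must be numeric", class = "spectranet_config_error")
  }
  if (start >= stop) {
    rlang::abort("grid start must be below stop", class = "spectranet_config_error")
  }
  if (step <= 0) {
    rlang::abort("grid step must be positive", class = "spectranet_config_error")
  }
  n_points <- floor((stop - start) / step) + 1L
  wn <- start + step * (seq_len(n_points) - 1L)
  structure(
    list(start = start, stop = stop, step = step,
         n_points = as.integer(n_points), wavenumbers = wn),
    class = "wn_grid"
  )
}

#' @export
print.wn_grid <- function(x, ...) {
  cat(sprintf("<wn_grid> %g-%g cm^-1, step %g, %d points\n",
              x$start, x$stop, x$step, x$n_points))
  invisible(x)
}

#' @export
format.wn_grid <- function(x, ...) {
  sprintf("%g:%g:%g", x$start, x$stop, x$step)
}

# Build a grid from an observed (possibly irregular-looking) axis vector.
# The axis must be strictly monotone and evenly spaced to within `tol`.
grid_from_axis <- function(wavenumbers, tol = 1e-6) {
  wn <- as.numeric(wavenumbers)
  if (length(wn) < 2) {
    rlang::abort("a wavenumber axis needs at least two points",
                 class = "spectranet_parse_error")
  }
  descending <- wn[1] > wn[length(wn)]
  if (descending) wn <- rev(wn)
  d <- diff(wn)
  if (any(d <= 0)) {
    rlang::abort("wavenumber axis is not strictly monotone",
                 class = "spectranet_parse_error")
  }
  if (max(d) - min(d) > tol * max(abs(wn))) {
    rlang::abort("wavenumber axis is not evenly spaced",
                 class = "spectranet_parse_error")
  }
  g <- wn_grid(start = wn[1], stop = wn[length(wn)], step = mean(d))
  # guard against floor() dropping the final point through rounding
  g$n_points <- length(wn)
  g$wavenumbers <- wn
  attr(g, "was_descending") <- descending
  g
}

grids_equal <- function(a, b, tol = 1e-8) {
  a$n_points == b$n_points &&
    abs(a$start - b$start) <= tol &&
    abs(a$step - b$step) <= tol
}
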