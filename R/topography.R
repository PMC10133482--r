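#' Periodic surface topography
#'
#' Describes the height field \eqn{h(x, y)} of the wall surface about its
#' mid-plane \eqn{z = 0}. Four families are supported, all bounded by
#' \eqn{-A \le h \le A}:
#' \describe{
#'   \item{\code{flat}}{\eqn{h \equiv 0} (any amplitude).}
#'   \item{\code{sin1d}}{singly periodic sinusoid \eqn{h = A \sin(kx)}.}
#'   \item{\code{sin2d}}{doubly periodic sinusoid
#'     \eqn{h = A \sin(kx)\sin(ky)}.}
#'   \item{\code{peaks2d}}{doubly periodic peaks
#'     \eqn{h = A(2\sin^2(kx)\sin^2(ky) - 1)}; because the sinusoids are
#'     squared the inter-peak wavelength is \eqn{\lambda/2}, half the
#'     nominal wave parameter.}
#' }
#' Lengths are measured in squirmer radii; \eqn{k = 2\pi/\lambda}.
#'
#' @param kind topography family.
#' @param amplitude peak height \eqn{A \ge 0} (squirmer radii).
#' @param wavelength wave parameter \eqn{\lambda > 0} (squirmer radii).
#' @return An object of class \code{"topography"}.
#' @examples
#' topo <- topography("sin1d", amplitude = 0.1, wavelength = 4)
#' topo_height(topo, x = 1, y = 0)   # crest: +A
#' @export
topography <- function(kind = c("flat", "sin1d", "sin2d", "peaks2d"),
                       amplitude = 0, wavelength = 1) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(amplitude), length(amplitude) == 1L, amplitude >= 0,
            is.numeric(wavelength), length(wavelength) == 1L, wavelength > 0)
  structure(list(kind = kind, amplitude = amplitude,
                 wavelength = wavelength, k = 2 * pi / wavelength),
            class = "topography")
}

#' @export
print.topography <- function(x, ...) {
  cat(sprintf("<topography> kind=%s  A=%g  lambda=%g\n",
              x$kind, x$amplitude, x$wavelength))
  invisible(x)
}

#' Topography height
#'
#' Evaluates \eqn{h(x, y)} for a [topography()]. Vectorised over `x`, `y`.
#'
#' @param topo a [topography()].
#' @param x,y horizontal coordinates (squirmer radii), recycled to a common
#'   length.
#' @return Numeric vector of heights.
#' @export
topo_height <- function(topo, x, y) {
  stopifnot(inherits(topo, "topography"))
  A <- topo$amplitude; k <- topo$k
  switch(topo$kind,
    flat    = rep(0, max(length(x), length(y))),
    sin1d   = A * sin(k * x) + 0 * y,
    sin2d   = A * sin(k * x) * sin(k * y),
    peaks2d = A * (2 * sin(k * x)^2 * sin(k * y)^2 - 1))
}

#' Topography gradient
#'
#' Analytic horizontal gradient \eqn{(\partial h/\partial x,
#' \partial h/\partial y)}, used for the surface area metric
#' \eqn{\sqrt{1 + |\nabla h|^2}} and clearance computations.
#'
#' @inheritParams topo_height
#' @return A two-column matrix `(dhdx, dhdy)`.
#' @export
topo_gradient <- function(topo, x, y) {
  stopifnot(inherits(topo, "topography"))
  A <- topo$amplitude; k <- topo$k
  n <- max(length(x), length(y))
  x <- rep_len(x, n); y <- rep_len(y, n)
  g <- switch(topo$kind,
    flat    = cbind(rep(0, n), rep(0, n)),
    sin1d   = cbind(A * k * cos(k * x), rep(0, n)),
    sin2d   = cbind(A * k * cos(k * x) * sin(k * y),
                    A * k * sin(k * x) * cos(k * y)),
    peaks2d = cbind(4 * A * k * sin(k * x) * cos(k * x) * sin(k * y)^2,
                    4 * A * k * sin(k * x)^2 * sin(k * y) * cos(k * y)))
  colnames(g) <- c("dhdx", "dhdy")
  g
}

#' Minimum squirmer--wall clearance
#'
#' Smallest distance between the squirmer surface and the wall surface:
#' \eqn{\min_{(x,y)} |p(x,y) - X| - 1} with \eqn{p = (x, y, h(x, y))}.
#' Used for the stopping rule that halts a trajectory just before
#' unresolved short-range surface dynamics would matter. Non-positive
#' values signal contact/overlap rather than raising an error.
#'
#' For a flat wall the closed form \eqn{z - 1} is returned. Otherwise a
#' coarse grid search over a window beneath the centre (half-width
#' \eqn{1.5\lambda}, capped at 4 radii since \eqn{|h| \le A \ll 1} keeps
#' the minimiser nearly under the centre) seeds a Nelder--Mead refinement
#' with relative tolerance 1e-6.
#'
#' @param state a [squirmer()] state.
#' @param topo a [topography()].
#' @return Scalar clearance (squirmer radii).
#' @export
min_clearance <- function(state, topo) {
  stopifnot(inherits(state, "squirmer_state"), inherits(topo, "topography"))
  X <- state$centre
  if (topo$kind == "flat" || topo$amplitude == 0) return(X[3] - 1)
  half <- max(1, min(1.5 * topo$wavelength, 4))
  gx <- seq(X[1] - half, X[1] + half, length.out = 61)
  gy <- seq(X[2] - half, X[2] + half, length.out = 61)
  gr <- expand.grid(x = gx, y = gy)
  d2 <- (gr$x - X[1])^2 + (gr$y - X[2])^2 +
    (topo_height(topo, gr$x, gr$y) - X[3])^2
  p0 <- c(gr$x[which.min(d2)], gr$y[which.min(d2)])
  obj <- function(p)
    sqrt((p[1] - X[1])^2 + (p[2] - X[2])^2 +
           (topo_height(topo, p[1], p[2]) - X[3])^2)
  opt <- stats::optim(p0, obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-10, maxit = 500))
  opt$value - 1
}
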