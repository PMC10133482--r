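## The spherical tangential squirmer: state, orientation conventions, and
## the prescribed surface slip.
##
## Angle conventions (used consistently for all I/O): theta = asin(n_z) is
## the pitch relative to the wall mid-plane; phi = atan2(n_x, n_y) is the
## heading of the horizontal projection of n measured from the +y axis,
## positive toward +x.

#' Squirmer state
#'
#' The moving rigid body: centre position, unit orientation vector, and the
#' two retained slip modes. The radius is fixed at \eqn{a = 1}; all lengths
#' are in squirmer radii. `B1` sets the free-space speed
#' (\eqn{|U| = 2B_1/3}); `beta` \eqn{= B_2/B_1} is the squirmer parameter
#' (pusher < 0, puller > 0, neutral = 0).
#'
#' @param centre centre position (3-vector).
#' @param orientation unit orientation vector; if `NULL`, built from
#'   `theta`, `phi`.
#' @param theta,phi pitch and heading angles (radians), used when
#'   `orientation` is `NULL`.
#' @param B1 first slip mode amplitude.
#' @param beta squirmer parameter \eqn{B_2/B_1}.
#' @return An object of class `"squirmer_state"`.
#' @examples
#' s <- squirmer(c(0, 0, 1.2), theta = -0.17 * pi, phi = 0.5 * pi, beta = 7)
#' @export
squirmer <- function(centre = c(0, 0, 1.2), orientation = NULL,
                     theta = 0, phi = 0, B1 = 1.5, beta = 0) {
  stopifnot(length(centre) == 3, is.numeric(B1), is.numeric(beta))
  n <- if (is.null(orientation)) orientation_from_angles(theta, phi)
       else as.numeric(orientation)
  stopifnot(length(n) == 3)
  nn <- sqrt(sum(n^2))
  if (abs(nn - 1) > 1e-6)
    stop("orientation must be a unit vector", call. = FALSE)
  structure(list(centre = as.numeric(centre), orientation = n / nn,
                 B1 = B1, beta = beta),
            class = "squirmer_state")
}

#' @export
print.squirmer_state <- function(x, ...) {
  a <- orientation_angles(x$orientation)
  cat(sprintf(
    "<squirmer> X=(%.4g, %.4g, %.4g)  theta=%.4g  phi=%.4g  B1=%g beta=%g\n",
    x$centre[1], x$centre[2], x$centre[3], a$theta, a$phi, x$B1, x$beta))
  invisible(x)
}

#' Orientation vector from pitch and heading angles
#'
#' \eqn{n = (\cos\theta \sin\varphi,\; \cos\theta \cos\varphi,\;
#' \sin\theta)}: `theta` is the angle to the horizontal mid-plane and `phi`
#' the heading measured from the +y axis toward +x, so `(0, 0)` points
#' along +y and `theta = pi/2` straight up.
#'
#' @param theta pitch in \eqn{[-\pi/2, \pi/2]}.
#' @param phi heading (radians).
#' @return Unit 3-vector.
#' @export
orientation_from_angles <- function(theta, phi) {
  c(cos(theta) * sin(phi), cos(theta) * cos(phi), sin(theta))
}

#' Pitch and heading angles of an orientation vector
#'
#' Inverse of [orientation_from_angles()]: `theta = asin(n_z)`,
#' `phi = atan2(n_x, n_y)`. At the poles (`n = c(0, 0, +/-1)`) the heading
#' is undefined; it is set to 0 and flagged.
#'
#' @param n unit 3-vector.
#' @return List with `theta`, `phi`, and logical `degenerate`.
#' @export
orientation_angles <- function(n) {
  stopifnot(length(n) == 3)
  nz <- min(1, max(-1, n[3]))
  degen <- (n[1]^2 + n[2]^2) < 1e-24
  list(theta = asin(nz),
       phi = if (degen) 0 else atan2(n[1], n[2]),
       degenerate = degen)
}

# general-mode slip magnitude divided by sin(Theta):
#   u_s / sin(Theta) = sum_n B_n * 2 P'_n(ct) / (n (n+1)),   ct = cos(Theta)
# P'_n via the derivative recurrence; smooth at the poles, which makes the
# tangential slip vector polynomial in ct.
slip_speed_modes_over_sin <- function(ct, B) {
  ct <- pmin(1, pmax(-1, ct))
  out <- 0
  P_prev <- rep(1, length(ct))   # P_0
  P_cur <- ct                    # P_1
  dP_cur <- rep(1, length(ct))   # P_1'
  for (n in seq_along(B)) {
    if (n > 1) {
      P_next <- ((2 * n - 1) * ct * P_cur - (n - 1) * P_prev) / n
      dP_next <- dP_cur * ct + n * P_cur   # P'_{n} from P'_{n-1}, P_{n-1}
      P_prev <- P_cur; P_cur <- P_next; dP_cur <- dP_next
    }
    out <- out + B[n] * 2 * dP_cur / (n * (n + 1))
  }
  out
}

#' Tangential slip speed
#'
#' The axisymmetric surface slip of the two-mode tangential squirmer at
#' polar angle \eqn{\Theta} from the orientation axis,
#' \deqn{u_s(\Theta) = B_1 \sin\Theta + B_1 \beta \sin\Theta \cos\Theta,}
#' i.e. the general mode expansion \eqn{\sum_n B_n V_n(\cos\Theta)} with
#' \eqn{V_n(x) = \frac{2\sqrt{1-x^2}}{n(n+1)} P'_n(x)} truncated at the
#' second mode (`B2 = beta * B1`, higher modes zero). Positive values point
#' in the direction of increasing \eqn{\Theta} (front pole to rear pole).
#'
#' @param Theta polar angle(s) in \eqn{[0, \pi]}.
#' @param B1 first mode amplitude.
#' @param beta squirmer parameter.
#' @return Numeric vector of slip speeds.
#' @export
slip_speed <- function(Theta, B1 = 1.5, beta = 0) {
  stopifnot(all(Theta >= -1e-12 & Theta <= pi + 1e-12))
  sin(Theta) * slip_speed_modes_over_sin(cos(Theta), c(B1, B1 * beta))
}

#' Slip velocity vectors on the squirmer surface
#'
#' Evaluates the tangential slip velocity at points on the unit sphere
#' about the squirmer centre. With radial unit vector \eqn{m} and
#' \eqn{\cos\Theta = n \cdot m}, the slip is
#' \eqn{u_s(\Theta)\,\hat t} where
#' \eqn{\hat t = (\cos\Theta\, m - n)/\sin\Theta} is the unit tangent of
#' increasing \eqn{\Theta}; the product is polynomial in \eqn{\cos\Theta},
#' so the poles evaluate cleanly to the zero vector. The result is tangent
#' to the sphere at every node.
#'
#' @param points matrix (m x 3) of surface points, each at unit distance
#'   from the centre (tolerance 1e-8).
#' @param state a [squirmer()] state.
#' @return Matrix (m x 3) of slip velocities.
#' @export
slip_velocity <- function(points, state) {
  stopifnot(inherits(state, "squirmer_state"))
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  m <- sweep(points, 2, state$centre)
  r <- sqrt(rowSums(m^2))
  if (any(abs(r - 1) > 1e-8))
    stop("slip_velocity: points are not on the unit sphere about the centre",
         call. = FALSE)
  m <- m / r
  n <- state$orientation
  ct <- as.vector(m %*% n)
  f <- slip_speed_modes_over_sin(ct, c(state$B1, state$B1 * state$beta))
  f * (ct * m - matrix(n, nrow(m), 3, byrow = TRUE))
}

#' Free-space swimming velocity
#'
#' The closed-form swimming velocity of the tangential squirmer in
#' unbounded fluid, \eqn{U = \tfrac23 B_1 n}; only the first slip mode
#' contributes. With the conventional \eqn{B_1 = 3/2} the free-space speed
#' is exactly 1.
#'
#' @param state a [squirmer()] state.
#' @return 3-vector.
#' @export
free_space_velocity <- function(state) {
  stopifnot(inherits(state, "squirmer_state"))
  (2 / 3) * state$B1 * state$orientation
}
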