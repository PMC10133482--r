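## Regularised fundamental solutions. Kernels carry no -1/(8*pi) prefactor;
## that constant is applied once in the boundary-integral assembly.

#' Kernel specification
#'
#' Selects the fundamental solution used by the mobility solver:
#' `"reg_stokeslet"` (free space, also used with an explicitly discretised
#' wall) or `"reg_blakelet"` (half-space image system enforcing no slip on
#' the plane `z = wall_height`). `epsilon` is the regularisation (blob)
#' width in squirmer radii.
#'
#' @param kind kernel family.
#' @param epsilon regularisation parameter, > 0.
#' @param wall_height wall plane height (Blakelet only).
#' @return An object of class `"kernel_spec"`.
#' @export
kernel_spec <- function(kind = c("reg_stokeslet", "reg_blakelet"),
                        epsilon = 1e-3, wall_height = 0) {
  kind <- match.arg(kind)
  if (!is.numeric(epsilon) || length(epsilon) != 1L || epsilon <= 0)
    stop("epsilon must be a positive scalar", call. = FALSE)
  structure(list(kind = kind, epsilon = epsilon, wall_height = wall_height),
            class = "kernel_spec")
}

#' Regularised Stokeslet
#'
#' The Cortez-blob regularised Stokeslet
#' \deqn{S^\epsilon_{ij} = \frac{(r^2 + 2\epsilon^2)\,\delta_{ij} +
#'   r_i r_j}{(r^2 + \epsilon^2)^{3/2}}, \qquad r = x - y,}
#' the exact (divergence-free) Stokes solution for a spatially smoothed
#' point force. Finite for all separations including \eqn{r = 0}, where it
#' equals \eqn{(2/\epsilon)\,\delta_{ij}}; symmetric in \eqn{(i, j)} and in
#' swapping `x` and `y`.
#'
#' @param x evaluation point (3-vector).
#' @param y force location (3-vector).
#' @param epsilon regularisation parameter, > 0.
#' @return A 3x3 matrix.
#' @export
reg_stokeslet <- function(x, y, epsilon) {
  if (!is.numeric(epsilon) || length(epsilon) != 1L || epsilon <= 0)
    stop("epsilon must be a positive scalar", call. = FALSE)
  stopifnot(length(x) == 3, length(y) == 3)
  cpp_kernel(as.numeric(x), as.numeric(y), epsilon, 0L, 0)
}

#' Regularised Blakelet
#'
#' Image-system kernel for a regularised point force above the no-slip
#' plane `z = wall_height`: the free-space regularised Stokeslet plus its
#' mirror image and the potential-dipole and Stokeslet-doublet corrections
#' of Blake's image system, with every inverse power of the image distance
#' regularised by the same blob width. The construction cancels the wall
#' velocity per power of the image distance, so the no-slip plane condition
#' holds to rounding for every `epsilon`, and the kernel converges to the
#' classical singular Blake tensor as \eqn{\epsilon \to 0}. Far from the
#' wall the image contributions decay and the kernel approaches
#' [reg_stokeslet()].
#'
#' @inheritParams reg_stokeslet
#' @param wall_height height of the no-slip plane; the source `y` must lie
#'   strictly above it and the evaluation point `x` must not lie below it
#'   (evaluation exactly on the plane is allowed -- that is where the
#'   no-slip property is checked).
#' @return A 3x3 matrix.
#' @export
reg_blakelet <- function(x, y, epsilon, wall_height = 0) {
  if (!is.numeric(epsilon) || length(epsilon) != 1L || epsilon <= 0)
    stop("epsilon must be a positive scalar", call. = FALSE)
  stopifnot(length(x) == 3, length(y) == 3)
  if (x[3] < wall_height || y[3] <= wall_height)
    stop("reg_blakelet: points must lie above the wall plane",
         call. = FALSE)
  cpp_kernel(as.numeric(x), as.numeric(y), epsilon, 1L, wall_height)
}
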