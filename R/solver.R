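## Discretised single-layer boundary-integral mobility/resistance solver.
##
## Collocation of u_j(x) = -1/(8*pi) * int S^eps_jk(x, y) f_k(y) dS(y) at the
## coarse nodes, with the integral evaluated on the fine nodes and the
## traction interpolated through the nearest-neighbour matrix, gives the
## square system of 3N + 6 equations for the N coarse tractions plus the
## rigid-body velocities (U, Omega); the six extra rows are the discrete
## force and torque balances over the swimmer surface.

skew <- function(v) {
  rbind(c(0, -v[3], v[2]),
        c(v[3], 0, -v[1]),
        c(-v[2], v[1], 0))
}

#' Nearest-neighbour interpolation matrix
#'
#' The sparse 0/1 matrix \eqn{\nu[q, n]} linking each fine quadrature node
#' to its nearest coarse traction node of the same body: row q has exactly
#' one 1, at the arg-min of the distance over coarse nodes with matching
#' body label; cross-body entries are zero. Ties are broken by the lowest
#' coarse index, deterministically.
#'
#' @param coarse,fine `node_set` objects (or lists of them, one per body).
#' @return A sparse `Matrix` of dimension Q x N.
#' @export
nearest_neighbour_matrix <- function(coarse, fine) {
  if (inherits(coarse, "node_set")) coarse <- list(coarse)
  if (inherits(fine, "node_set")) fine <- list(fine)
  if (!length(coarse) || !any(vapply(coarse, function(s) s$count, 1L) > 0))
    stop("assembly error: empty coarse node set", call. = FALSE)
  Ns <- vapply(coarse, function(s) s$count, 1L)
  Qs <- vapply(fine, function(s) s$count, 1L)
  cbody <- vapply(coarse, function(s) s$body, "")
  fbody <- vapply(fine, function(s) s$body, "")
  coff <- c(0, cumsum(Ns))
  foff <- c(0, cumsum(Qs))
  i <- integer(0); j <- integer(0)
  for (b in seq_along(fine)) {
    cb <- match(fbody[b], cbody)
    if (is.na(cb))
      stop("assembly error: fine body '", fbody[b],
           "' has no coarse counterpart", call. = FALSE)
    idx <- cpp_nearest(fine[[b]]$positions, coarse[[cb]]$positions)
    i <- c(i, foff[b] + seq_len(Qs[b]))
    j <- c(j, coff[cb] + idx)
  }
  Matrix::sparseMatrix(i = i, j = j, x = 1, dims = c(sum(Qs), sum(Ns)))
}

#' Mobility problem definition
#'
#' Bundles the squirmer state, kernel, wall representation and
#' discretisation into the instantaneous rigid-body mobility problem.
#' Three wall modes are supported:
#' \describe{
#'   \item{`"free"`}{unbounded fluid, regularised Stokeslet kernel.}
#'   \item{`"blakelet"`}{flat wall at `z = 0` through the regularised image
#'     system; no wall nodes, so the system stays at `3 * 6 n_s^2 + 6`.}
#'   \item{`"patch"`}{explicitly discretised wall patch carrying the
#'     topography, centred under the squirmer; wall tractions join the
#'     unknowns.}
#' }
#'
#' @param state a [squirmer()] state.
#' @param wall wall representation (see Details).
#' @param topo a [topography()] (patch mode; must be flat for blakelet).
#' @param wall_spec a [wall_patch_spec()] (patch mode). Its `centre_xy` is
#'   overridden by the horizontal projection of the squirmer centre.
#' @param epsilon regularisation parameter.
#' @param n_s,N_s coarse and fine sphere refinements (nodes per cube-face
#'   side); the sphere carries `6 n_s^2` traction and `6 N_s^2` quadrature
#'   nodes.
#' @return An object of class `"mobility_problem"`.
#' @export
mobility_problem <- function(state, wall = c("free", "blakelet", "patch"),
                             topo = topography("flat"),
                             wall_spec = wall_patch_spec(),
                             epsilon = 1e-3, n_s = 4, N_s = 18) {
  wall <- match.arg(wall)
  stopifnot(inherits(state, "squirmer_state"))
  if (wall == "blakelet" && !(topo$kind == "flat" || topo$amplitude == 0))
    stop("blakelet mode requires a flat wall", call. = FALSE)
  kernel <- kernel_spec(if (wall == "blakelet") "reg_blakelet"
                        else "reg_stokeslet", epsilon)
  sc <- sphere_nodes(n_s, state$centre, "coarse")
  sf <- sphere_nodes(N_s, state$centre, "fine")
  # sphere nn depends only on the (cached) templates
  snn <- cache_get(paste0("snn_", n_s, "_", N_s), function()
    cpp_nearest(sphere_template(N_s)$x, sphere_template(n_s)$x))
  wc <- wf <- NULL
  wnn <- integer(0)
  if (wall == "patch") {
    wall_spec$centre_xy <- state$centre[1:2]
    wc <- wall_nodes(wall_spec, topo, "coarse")
    wf <- wall_nodes(wall_spec, topo, "fine")
    # wall nn from the flat grid template: identical to the 3-D assignment
    # away from near-ties (|h| <= A << spacing) and smooth in time as the
    # patch re-centres
    wnn <- cache_get(
      paste0("wnn_", wall_spec$coarse_per_side, "_",
             wall_spec$fine_per_side, "_", wall_spec$rescale),
      function() {
        tc <- wall_template(wall_spec$coarse_per_side, wall_spec$rescale)
        tf <- wall_template(wall_spec$fine_per_side, wall_spec$rescale)
        cpp_nearest(cbind(tf$px, tf$py, 0), cbind(tc$px, tc$py, 0))
      })
  }
  structure(list(state = state, wall = wall, topo = topo,
                 wall_spec = wall_spec, kernel = kernel,
                 n_s = n_s, N_s = N_s,
                 swimmer_coarse = sc, swimmer_fine = sf,
                 wall_coarse = wc, wall_fine = wf,
                 sphere_nn = snn, wall_nn = wnn),
            class = "mobility_problem")
}

# stack node sets and nn indices into assembly inputs
problem_arrays <- function(prob) {
  colloc <- prob$swimmer_coarse$positions
  fine <- prob$swimmer_fine$positions
  fw <- prob$swimmer_fine$weights
  nn <- prob$sphere_nn
  n_sw <- prob$swimmer_coarse$count
  if (prob$wall == "patch") {
    colloc <- rbind(colloc, prob$wall_coarse$positions)
    fine <- rbind(fine, prob$wall_fine$positions)
    fw <- c(fw, prob$wall_fine$weights)
    nn <- c(nn, prob$wall_nn + n_sw)
  }
  if (anyDuplicated(colloc))
    stop("singular-system error: duplicate collocation points",
         call. = FALSE)
  list(colloc = colloc, fine = fine, fw = fw, nn = as.integer(nn),
       n_swimmer = n_sw, N = nrow(colloc), Q = nrow(fine))
}

#' Assemble the discrete mobility system
#'
#' Builds the dense linear system of size \eqn{3N + 6} for the unknown
#' coarse tractions and rigid-body velocities: the first \eqn{3N} rows are
#' the collocated boundary-integral equations with boundary velocity
#' \eqn{U + \Omega \times (x - X) + u_s} on the swimmer and 0 on the wall;
#' the last 6 rows impose zero net force and torque on the swimmer (or the
#' prescribed external force/torque), aggregated through the same fine
#' quadrature and nearest-neighbour interpolation as the kernel integrals.
#'
#' @param problem a [mobility_problem()].
#' @param external_force,external_torque applied force/torque on the
#'   swimmer entering the balance rows (defaults zero: force- and
#'   torque-free swimming).
#' @return List with the system matrix `A`, right-hand side `b`, and the
#'   aggregated areas/moments used by the balance rows.
#' @export
assemble_mobility_system <- function(problem,
                                     external_force = c(0, 0, 0),
                                     external_torque = c(0, 0, 0)) {
  stopifnot(inherits(problem, "mobility_problem"))
  pa <- problem_arrays(problem)
  N <- pa$N
  X <- problem$state$centre
  agg <- cpp_assemble_nn(pa$colloc, pa$fine, pa$nn, pa$fw,
                         problem$kernel$epsilon,
                         if (problem$kernel$kind == "reg_blakelet") 1L else 0L,
                         problem$kernel$wall_height)
  agg$area <- as.vector(agg$area)
  dim <- 3 * N + 6
  A <- matrix(0, dim, dim)
  A[1:(3 * N), 1:(3 * N)] <- -agg$K / (8 * pi)
  b <- numeric(dim)
  n_sw <- pa$n_swimmer
  us <- slip_velocity(problem$swimmer_coarse$positions, problem$state)
  # swimmer collocation rows: -(1/8pi) K g - U - Omega x (x_m - X) = u_s
  for (m in seq_len(n_sw)) {
    r <- 3 * (m - 1)
    A[r + 1:3, 3 * N + 1:3] <- -diag(3)
    A[r + 1:3, 3 * N + 4:6] <- skew(pa$colloc[m, ] - X)
    b[r + 1:3] <- us[m, ]
  }
  # balance rows over the swimmer: sum_n A~[n] g[n] = -F_ext,
  # sum_n (M~[n] - A~[n] X) x g[n] = -T_ext
  for (m in seq_len(n_sw)) {
    cix <- 3 * (m - 1) + 1:3
    A[3 * N + 1:3, cix] <- agg$area[m] * diag(3)
    A[3 * N + 4:6, cix] <- skew(agg$moment[m, ] - agg$area[m] * X)
  }
  b[3 * N + 1:3] <- -external_force
  b[3 * N + 4:6] <- -external_torque
  list(A = A, b = b, area = agg$area, moment = agg$moment,
       n_swimmer = n_sw, N = N, Q = pa$Q)
}

#' Solve the rigid-body mobility problem
#'
#' Direct (LU) solution of the assembled system: returns the rigid-body
#' translational and angular velocities, the coarse-node tractions, and the
#' force/torque balance residuals recomputed a posteriori from the returned
#' tractions. With `diagnostics = TRUE` a reciprocal condition estimate of
#' the system matrix is included (costs an extra factorisation).
#'
#' @inheritParams assemble_mobility_system
#' @param diagnostics also estimate the condition number.
#' @return An object of class `"mobility_solution"` with fields `U`,
#'   `Omega`, `tractions` (N x 3), `force_residual`, `torque_residual`,
#'   `rcond`, `N`, `Q`.
#' @examples
#' \donttest{
#' prob <- mobility_problem(squirmer(c(0, 0, 0), theta = pi / 2))
#' sol <- solve_mobility(prob)
#' sqrt(sum(sol$U^2))   # ~ 1: free-space speed for B1 = 3/2
#' }
#' @export
solve_mobility <- function(problem, external_force = c(0, 0, 0),
                           external_torque = c(0, 0, 0),
                           diagnostics = FALSE) {
  sys <- assemble_mobility_system(problem, external_force, external_torque)
  N <- sys$N
  z <- tryCatch(solve(sys$A, sys$b), error = function(e)
    stop(sprintf("solver error: %s (rcond ~ %.3g)", conditionMessage(e),
                 rcond(sys$A)), call. = FALSE))
  g <- matrix(z[1:(3 * N)], ncol = 3, byrow = TRUE)
  sw <- seq_len(sys$n_swimmer)
  X <- problem$state$centre
  fres <- colSums(sys$area[sw] * g[sw, , drop = FALSE]) + external_force
  arm <- sys$moment[sw, , drop = FALSE] -
    outer(sys$area[sw], X)
  tres <- colSums(cross_rows(arm, g[sw, , drop = FALSE])) + external_torque
  structure(list(
    U = z[3 * N + 1:3], Omega = z[3 * N + 4:6], tractions = g,
    force_residual = fres, torque_residual = tres,
    traction_scale = sum(sys$area[sw] * sqrt(rowSums(g[sw, , drop = FALSE]^2))),
    rcond = if (diagnostics) rcond(sys$A) else NA_real_,
    N = N, Q = sys$Q, dim = 3 * N + 6),
    class = "mobility_solution")
}

cross_rows <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

#' @export
print.mobility_solution <- function(x, ...) {
  cat(sprintf("<mobility_solution> |U|=%.6g  |Omega|=%.3g  N=%d Q=%d\n",
              sqrt(sum(x$U^2)), sqrt(sum(x$Omega^2)), x$N, x$Q))
  cat(sprintf("  residuals: force %.2e  torque %.2e\n",
              max(abs(x$force_residual)), max(abs(x$torque_residual))))
  invisible(x)
}

#' Solve the resistance problem
#'
#' Companion validation solve: the rigid-body motion `(U, Omega)` is
#' prescribed (slip disabled, so the state must have `B1 = 0`), the coarse
#' tractions are the only unknowns, and the net force and torque the body
#' must exert on the fluid (equal to minus the fluid drag on the body) are
#' returned. For a unit-speed translating sphere in free space the force
#' magnitude approaches the Stokes drag \eqn{6\pi\mu a U}; for unit
#' rotation, the torque approaches \eqn{8\pi\mu a^3 \Omega}.
#'
#' @param problem a [mobility_problem()] whose state has `B1 = 0`.
#' @param U_given,Omega_given prescribed translational/angular velocity.
#' @return List with `force`, `torque` (3-vectors) and `tractions`.
#' @export
solve_resistance <- function(problem, U_given, Omega_given = c(0, 0, 0)) {
  stopifnot(inherits(problem, "mobility_problem"))
  if (problem$state$B1 != 0)
    stop("solve_resistance requires slip disabled (B1 = 0)", call. = FALSE)
  pa <- problem_arrays(problem)
  N <- pa$N
  X <- problem$state$centre
  agg <- cpp_assemble_nn(pa$colloc, pa$fine, pa$nn, pa$fw,
                         problem$kernel$epsilon,
                         if (problem$kernel$kind == "reg_blakelet") 1L else 0L,
                         problem$kernel$wall_height)
  agg$area <- as.vector(agg$area)
  A <- -agg$K / (8 * pi)
  b <- numeric(3 * N)
  for (m in seq_len(pa$n_swimmer)) {
    d <- pa$colloc[m, ] - X
    b[3 * (m - 1) + 1:3] <- U_given + c(
      Omega_given[2] * d[3] - Omega_given[3] * d[2],
      Omega_given[3] * d[1] - Omega_given[1] * d[3],
      Omega_given[1] * d[2] - Omega_given[2] * d[1])
  }
  g <- matrix(solve(A, b), ncol = 3, byrow = TRUE)
  sw <- seq_len(pa$n_swimmer)
  arm <- agg$moment[sw, , drop = FALSE] - outer(agg$area[sw], X)
  list(force = -colSums(agg$area[sw] * g[sw, , drop = FALSE]),
       torque = -colSums(cross_rows(arm, g[sw, , drop = FALSE])),
       tractions = g)
}
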