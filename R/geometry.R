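## Quadrature node sets: cube-projected sphere meshes and rescaled,
## topography-conforming wall patches.

new_node_set <- function(positions, weights, body, level) {
  structure(list(positions = positions, weights = weights,
                 body = body, level = level, count = nrow(positions)),
            class = "node_set")
}

#' @export
print.node_set <- function(x, ...) {
  cat(sprintf("<node_set> %s/%s  %d nodes  total area %.6g\n",
              x$body, x$level, x$count, sum(x$weights)))
  invisible(x)
}

#' Sphere surface quadrature nodes
#'
#' Builds the \eqn{6n^2}-node quadrature mesh of the unit sphere used for
#' both the coarse (traction) and fine (kernel quadrature) levels: each face
#' of the circumscribing cube is divided into \eqn{n \times n} equal cells,
#' one node is placed at each cell centre and projected radially onto the
#' sphere, and the node weight is the exact spherical area (solid angle) of
#' the projected cell, computed from the closed-form solid angle of a plane
#' rectangle. Weights therefore sum to \eqn{4\pi} to rounding, and no two
#' nodes coincide. Coarse and fine meshes at refinements whose ratio has an
#' even numerator (e.g. 4 and 18) share no nodes, which keeps the two-level
#' quadrature accurate at small regularisation.
#'
#' @param n nodes per cube-face side (refinement); the mesh has `6 * n^2`
#'   nodes. Must be at least 2.
#' @param centre sphere centre (3-vector).
#' @param level `"coarse"` or `"fine"` label carried by the node set.
#' @return A `node_set` with `positions`, `weights`, `body = "swimmer"`.
#' @examples
#' ns <- sphere_nodes(4)
#' ns$count                 # 96
#' sum(ns$weights) - 4 * pi # ~ 0
#' @export
sphere_nodes <- function(n, centre = c(0, 0, 0), level = "coarse") {
  if (!is.numeric(n) || length(n) != 1L || n != round(n) || n < 2)
    stop("invalid refinement: 'n' must be an integer >= 2", call. = FALSE)
  stopifnot(length(centre) == 3)
  tmpl <- cache_get(paste0("sphere_", n), function() sphere_template(n))
  new_node_set(sweep(tmpl$x, 2, centre, "+"), tmpl$w, "swimmer", level)
}

# unit sphere mesh template (centred at origin); cached
sphere_template <- function(n) {
  u <- -1 + (2 * seq_len(n) - 1) / n      # cell centres on the face
  e <- -1 + 2 * (0:n) / n                 # cell edges
  sa <- function(u, v) atan(u * v / sqrt(1 + u^2 + v^2))
  W <- outer(seq_len(n), seq_len(n), function(i, j)
    sa(e[i + 1], e[j + 1]) - sa(e[i], e[j + 1]) -
      sa(e[i + 1], e[j]) + sa(e[i], e[j]))
  g <- expand.grid(u = u, v = u)
  faces <- list(
    function(u, v) cbind(u, v, 1), function(u, v) cbind(u, v, -1),
    function(u, v) cbind(1, u, v), function(u, v) cbind(-1, u, v),
    function(u, v) cbind(u, 1, v), function(u, v) cbind(u, -1, v))
  P <- do.call(rbind, lapply(faces, function(f) f(g$u, g$v)))
  w <- rep(as.vector(W), 6L)
  P <- P / sqrt(rowSums(P^2))
  dimnames(P) <- NULL
  list(x = P, w = w)
}

#' Arctangent grid-stretching map
#'
#' The odd, strictly increasing bijection of \eqn{[-1/2, 1/2]} onto itself,
#' \deqn{f(x) = \tfrac12 \tan(\pi x / 2),}
#' used to concentrate wall-patch nodes beneath the squirmer: an equally
#' spaced grid on the unit square is mapped componentwise by `f` before
#' dilation, so the central cells shrink by a factor \eqn{f'(0) = \pi/4}
#' while the patch still tiles the full square.
#'
#' @param x numeric vector in \eqn{[-1/2, 1/2]}.
#' @return `0.5 * tan(pi * x / 2)`.
#' @export
rescale_map <- function(x) {
  if (any(abs(x) > 0.5 + 1e-12))
    stop("rescale_map: input outside [-1/2, 1/2]", call. = FALSE)
  0.5 * tan(pi * pmin(pmax(x, -0.5), 0.5) / 2)
}

#' Wall patch specification
#'
#' Geometry of the truncated square wall patch that stands in for the
#' infinite wall: side length `L`, nodes per side at the coarse (traction)
#' and fine (quadrature) levels, the horizontal centre (which tracks the
#' projection of the squirmer centre during a simulation), and whether the
#' grid-stretching [rescale_map()] is applied.
#'
#' The defaults `side_length = 8`, `coarse_per_side = 20`,
#' `fine_per_side = 80` give a central coarse spacing (~0.31) slightly
#' finer than the sphere's coarse spacing and resolve the near-gap wall
#' traction well enough for the flat-wall stable swimming height to match
#' the half-space (Blakelet) reference; the even fine/coarse ratio also
#' guarantees the two cell-centred grids share no node (an odd ratio such
#' as 48/16 = 3 makes every coarse node coincide with a fine node and
#' spoils the local quadrature when the regularisation is far below the
#' node spacing).
#'
#' @param side_length patch side `L` (squirmer radii).
#' @param coarse_per_side,fine_per_side nodes per side, fine > coarse.
#' @param centre_xy horizontal patch centre.
#' @param rescale apply the arctangent stretching (recommended).
#' @return An object of class `"wall_patch_spec"`.
#' @export
wall_patch_spec <- function(side_length = 8, coarse_per_side = 20,
                            fine_per_side = 80, centre_xy = c(0, 0),
                            rescale = TRUE) {
  stopifnot(side_length > 0, coarse_per_side >= 2,
            fine_per_side > coarse_per_side, length(centre_xy) == 2)
  structure(list(side_length = side_length,
                 coarse_per_side = as.integer(coarse_per_side),
                 fine_per_side = as.integer(fine_per_side),
                 centre_xy = as.numeric(centre_xy),
                 rescale = isTRUE(rescale)),
            class = "wall_patch_spec")
}

# unit-square grid template for one level: node coordinates u (cell
# centres), per-node 1-D mapped cell lengths, and the flattened 2-D layout.
wall_template <- function(m, rescale) {
  key <- paste0("wall_", m, "_", rescale)
  cache_get(key, function() {
    u <- -0.5 + (seq_len(m) - 0.5) / m
    e <- -0.5 + (0:m) / m
    if (rescale) {
      pos <- rescale_map(u)
      len <- diff(rescale_map(e))
    } else {
      pos <- u
      len <- diff(e)
    }
    g <- expand.grid(i = seq_len(m), j = seq_len(m))
    list(px = pos[g$i], py = pos[g$j], area = len[g$i] * len[g$j])
  })
}

#' Wall patch quadrature nodes
#'
#' Generates the coarse or fine node set of the wall patch: an equally
#' spaced cell-centred grid on the unit square is mapped componentwise by
#' [rescale_map()] (if enabled), dilated by the side length, translated to
#' the patch centre, and lifted onto the topography, \eqn{z = h(x, y)}.
#' Each node's weight is its mapped cell area times the surface metric
#' \eqn{\sqrt{1 + |\nabla h|^2}}, so for a flat wall the weights sum to
#' exactly \eqn{L^2}.
#'
#' @param spec a [wall_patch_spec()].
#' @param topo a [topography()].
#' @param level `"coarse"` (traction grid) or `"fine"` (quadrature grid).
#' @return A `node_set` with `body = "wall"`.
#' @export
wall_nodes <- function(spec, topo, level = c("coarse", "fine")) {
  stopifnot(inherits(spec, "wall_patch_spec"), inherits(topo, "topography"))
  level <- match.arg(level)
  m <- if (level == "coarse") spec$coarse_per_side else spec$fine_per_side
  t <- wall_template(m, spec$rescale)
  L <- spec$side_length
  x <- L * t$px + spec$centre_xy[1]
  y <- L * t$py + spec$centre_xy[2]
  z <- topo_height(topo, x, y)
  gr <- topo_gradient(topo, x, y)
  metric <- sqrt(1 + gr[, 1]^2 + gr[, 2]^2)
  new_node_set(cbind(x, y, z, deparse.level = 0),
               L^2 * t$area * metric, "wall", level)
}

#' Export a node set as a plain-text table
#'
#' Writes a four-column whitespace-separated table (x, y, z, weight) with a
#' single `#` header comment, for debugging and external visualisation.
#'
#' @param ns a `node_set`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_node_set <- function(ns, path) {
  stopifnot(inherits(ns, "node_set"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# node_set body=%s level=%s count=%d  (x y z weight)",
                     ns$body, ns$level, ns$count), con)
  utils::write.table(
    data.frame(ns$positions, w = ns$weights), con,
    row.names = FALSE, col.names = FALSE)
  invisible(path)
}
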