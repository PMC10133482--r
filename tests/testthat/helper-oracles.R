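# Independent oracles used across test files. These deliberately avoid the
# package's own code paths.

# classical (singular or naively regularised) Blake image system, direct
# R transcription of the image-singularity expansion
blake_oracle <- function(x, y, eps = 0, wall = 0) {
  h <- y[3] - wall
  ystar <- c(y[1], y[2], 2 * wall - y[3])
  r <- x - y; R <- x - ystar
  r2 <- sum(r^2); R2 <- sum(R^2)
  re3 <- (r2 + eps^2)^(-1.5)
  Re3 <- (R2 + eps^2)^(-1.5); Re5 <- (R2 + eps^2)^(-2.5)
  S <- diag(3) * (r2 + 2 * eps^2) * re3 + outer(r, r) * re3
  SI <- diag(3) * (R2 + 2 * eps^2) * Re3 + outer(R, R) * Re3
  PD <- diag(3) * Re3 - 3 * outer(R, R) * Re5
  e3 <- c(0, 0, 1)
  SD <- -outer(e3, R) * Re3 + diag(3) * R[3] * Re3 + outer(R, e3) * Re3 -
    3 * R[3] * outer(R, R) * Re5
  S - SI + (2 * h * (h * PD - SD)) %*% diag(c(1, 1, -1))
}

# singular free-space Stokeslet
stokeslet_singular <- function(x, y) {
  r <- x - y; rn <- sqrt(sum(r^2))
  diag(3) / rn + outer(r, r) / rn^3
}

# slip speed through the textbook mode functions V_n(x) =
# 2 sqrt(1-x^2) P'_n(x) / (n(n+1)), with explicit Legendre derivatives
slip_oracle <- function(Theta, B) {
  x <- cos(Theta)
  dP <- list(function(x) rep(1, length(x)),        # P1'
             function(x) 3 * x,                    # P2'
             function(x) (15 * x^2 - 3) / 2,       # P3'
             function(x) (35 * x^3 - 15 * x) / 2)  # P4'
  out <- 0
  for (n in seq_along(B))
    out <- out + B[n] * 2 * sqrt(pmax(0, 1 - x^2)) * dP[[n]](x) / (n * (n + 1))
  out
}

# central-difference divergence of the flow u_i(x) = S_ij(x, y) f_j
numeric_divergence <- function(kernel_fn, x, y, f, h = 1e-5) {
  div <- 0
  for (i in 1:3) {
    e <- numeric(3); e[i] <- h
    up <- kernel_fn(x + e, y) %*% f
    dn <- kernel_fn(x - e, y) %*% f
    div <- div + (up[i] - dn[i]) / (2 * h)
  }
  div
}

# reduced-cost simulation configuration for symmetry/regression properties
# that hold at any resolution (sizes chosen so coarse and fine grids never
# coincide and a short run stays in budget)
fast_config <- function(topo, ...) {
  simulation_config(topo = topo, wall = "patch",
                    wall_spec = wall_patch_spec(6, 10, 32),
                    n_s = 3, N_s = 8, rtol = 1e-5, atol = 1e-7,
                    output_stride = 0.1, ...)
}

# share expensive full-resolution runs across test files within one session
shared_run <- function(key, build) {
  cache <- squirmtopo:::.cache
  if (is.null(cache[[key]])) assign(key, build(), envir = cache)
  cache[[key]]
}

default_start <- function(phi, beta = 7, y0 = 0, z0 = 1.2)
  squirmer(c(0, y0, z0), theta = -0.17 * pi, phi = phi, beta = beta)
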