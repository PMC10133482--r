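test_that("free-space kinematics: unit speed along n, no rotation", {
  cfg <- simulation_config(wall = "free", n_s = 4, N_s = 18, max_time = 1)
  st <- squirmer(c(0, 0, 0), theta = 0.3, phi = 1.2, beta = 7)
  d <- rhs(st, cfg)
  expect_equal(d$dcentre, st$orientation, tolerance = 0.02)
  expect_lt(sqrt(sum(d$dorientation^2)), 1e-6)
  # dn/dt is always orthogonal to n
  expect_lt(abs(sum(d$dorientation * st$orientation)), 1e-12)
})

test_that("flat-wall mirror symmetry keeps motion in the vertical plane", {
  # with n in the y-z plane the configuration is mirror symmetric in x,
  # so Omega must be along x and the centre velocity in the y-z plane
  cfg <- fast_config(topography("flat"))
  st <- default_start(phi = 0)
  d <- rhs(st, cfg)
  expect_lt(abs(d$dcentre[1]), 1e-10)
  expect_lt(abs(d$dorientation[1]), 1e-10)
})

test_that("zero-amplitude topography reproduces the flat-wall trajectory", {
  st <- default_start(phi = 0.3)
  t_flat <- simulate_squirmer(st, fast_config(topography("flat"),
                                              max_time = 1.5))
  t_a0 <- simulate_squirmer(st, fast_config(topography("sin1d", 0, 2),
                                            max_time = 1.5))
  expect_equal(t_a0$data, t_flat$data, tolerance = 1e-10)
})

test_that("flat-wall dynamics are invariant under the initial heading", {
  # the half-space image kernel is exactly rotation-invariant about z, so
  # blakelet trajectories must agree to integrator tolerance
  cfgb <- simulation_config(topo = topography("flat"), wall = "blakelet",
                            n_s = 3, N_s = 8, rtol = 1e-6, atol = 1e-8,
                            max_time = 2)
  b0 <- simulate_squirmer(default_start(phi = 0), cfgb)
  b1 <- simulate_squirmer(default_start(phi = 1.1), cfgb)
  expect_equal(b1$data$z, b0$data$z, tolerance = 1e-6)
  expect_equal(b1$data$theta, b0$data$theta, tolerance = 1e-6)
  # the square wall patch breaks exact rotational symmetry of the
  # discretisation; the residual anisotropy stays at the quadrature-error
  # scale, well below the physical signal
  t0 <- simulate_squirmer(default_start(phi = 0),
                          fast_config(topography("flat"), max_time = 1.5))
  t1 <- simulate_squirmer(default_start(phi = 1.1),
                          fast_config(topography("flat"), max_time = 1.5))
  expect_equal(t1$data$z, t0$data$z, tolerance = 1e-3)
  expect_equal(t1$data$theta, t0$data$theta, tolerance = 1e-3)
})

test_that("sin2d diagonal release stays on the diagonal", {
  topo <- topography("sin2d", amplitude = 0.1, wavelength = 2)
  tr <- simulate_squirmer(default_start(phi = pi / 4),
                          fast_config(topo, max_time = 1.5))
  expect_equal(tr$data$x, tr$data$y, tolerance = 1e-8)
  # orientation stays diagonal too
  expect_equal(tr$data$nx, tr$data$ny, tolerance = 1e-8)
})

test_that("repeated runs are bit-identical", {
  topo <- topography("sin1d", amplitude = 0.1, wavelength = 2)
  a <- simulate_squirmer(default_start(phi = 0.4),
                         fast_config(topo, max_time = 1))
  b <- simulate_squirmer(default_start(phi = 0.4),
                         fast_config(topo, max_time = 1))
  expect_identical(a$data, b$data)
  expect_identical(a$termination, b$termination)
})

test_that("trajectory bookkeeping: unit orientation, increasing times", {
  tr <- simulate_squirmer(default_start(phi = 0.2),
                          fast_config(topography("flat"), max_time = 1))
  nn <- with(tr$data, cbind(nx, ny, nz))
  expect_equal(rowSums(nn^2), rep(1, nrow(nn)), tolerance = 1e-10)
  expect_true(all(diff(tr$data$t) > 0))
})

test_that("clearance stopping halts the run before contact", {
  # steep downward release dives into the wall; the run must stop at the
  # clearance threshold, not crash through it
  st <- squirmer(c(0, 0, 1.4), theta = -0.45 * pi, phi = 0, beta = 7)
  cfg <- fast_config(topography("flat"), max_time = 6, stop_clearance = 0.1)
  tr <- simulate_squirmer(st, cfg)
  expect_equal(tr$termination$kind, "contact_stop")
  expect_equal(min(tr$data$clearance), 0.1, tolerance = 5e-3)
  expect_lt(tr$termination$time, 6)
  # starting below the threshold is rejected
  low <- squirmer(c(0, 0, 1.02), theta = 0, beta = 7)
  expect_error(simulate_squirmer(low, cfg), "stop_clearance")
})

test_that("integrator tolerances control the flat-wall trajectory", {
  st <- default_start(phi = 0, z0 = 1.15)
  base <- simulation_config(topo = topography("flat"), wall = "blakelet",
                            max_time = 10)
  tight <- simulation_config(topo = topography("flat"), wall = "blakelet",
                             max_time = 10, rtol = 5e-7, atol = 5e-9)
  a <- simulate_squirmer(st, base)
  b <- simulate_squirmer(st, tight)
  pa <- unlist(a$data[nrow(a$data), c("x", "y", "z")])
  pb <- unlist(b$data[nrow(b$data), c("x", "y", "z")])
  expect_lt(sqrt(sum((pa - pb)^2)), 1e-3)
})

test_that("oscillation metrics recover constructed signals", {
  mk_traj <- function(x, z) {
    df <- data.frame(t = x, x = x, y = 0, z = z, nx = 0, ny = 1, nz = 0,
                     theta = 0, phi = 0, clearance = z - 1)
    structure(list(data = df,
                   termination = list(kind = "max_time", time = max(x))),
              class = "trajectory")
  }
  x <- seq(0, 40, by = 0.05)
  m <- oscillation_metrics(mk_traj(x, 1.15 + 0.03 * sin(2 * pi * x / 8)), 30)
  expect_equal(m$z_amplitude, 0.03, tolerance = 1e-3)
  expect_equal(m$z_wavelength, 8, tolerance = 0.01)
  flat <- oscillation_metrics(mk_traj(x, rep(1.15, length(x))), 30)
  expect_equal(flat$z_amplitude, 0)
  expect_true(is.na(flat$z_wavelength))
  expect_equal(flat$flag, "constant")
  expect_error(oscillation_metrics(mk_traj(x, x), 100), "window")
})

test_that("trajectories round-trip through CSV with a JSON sidecar", {
  tr <- simulate_squirmer(default_start(phi = 0.2),
                          fast_config(topography("flat"), max_time = 0.5))
  path <- tempfile(fileext = ".csv")
  write_trajectory(tr, path)
  back <- read.csv(path)
  expect_equal(back$z, tr$data$z, tolerance = 1e-12)
  meta <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(meta$termination$kind, tr$termination$kind)
  expect_equal(meta$config$wall, "patch")
  unlink(c(path, paste0(path, ".json")))
})
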