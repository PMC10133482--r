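test_that("orientation angle conventions and round trips", {
  expect_equal(orientation_from_angles(0, 0), c(0, 1, 0))
  expect_equal(orientation_from_angles(pi / 2, 1.3), c(0, 0, 1),
               tolerance = 1e-15)
  # default release attitude used throughout the wall studies
  expect_equal(orientation_from_angles(-0.17 * pi, 0.5 * pi),
               c(0.8607, 0, -0.5090), tolerance = 1e-4)
  a <- orientation_angles(c(0, 1, 0))
  expect_equal(c(a$theta, a$phi), c(0, 0))
  expect_equal(orientation_angles(c(1, 0, 0))$phi, pi / 2)
  # pole: heading degenerate, set to 0 by convention
  p <- orientation_angles(c(0, 0, -1))
  expect_equal(p$theta, -pi / 2)
  expect_equal(p$phi, 0)
  expect_true(p$degenerate)
  # round trip away from the poles
  set.seed(21)
  for (i in 1:25) {
    th <- runif(1, -1.4, 1.4); ph <- runif(1, -pi, pi)
    n <- orientation_from_angles(th, ph)
    b <- orientation_angles(n)
    expect_equal(c(b$theta, b$phi), c(th, ph), tolerance = 1e-10)
    expect_equal(sum(n^2), 1, tolerance = 1e-14)
  }
})

test_that("slip speed follows the two-mode truncation", {
  expect_equal(slip_speed(0, 1.5, 7), 0)
  expect_lt(abs(slip_speed(pi, 1.5, 7)), 1e-12)
  # equator: only the first mode survives
  expect_equal(slip_speed(pi / 2, 1.5, 7), 1.5)
  # mid-latitude value: B1 sin(pi/4) (1 + beta cos(pi/4))
  expect_equal(slip_speed(pi / 4, 1.5, 7),
               1.5 * sqrt(2) / 2 * (1 + 7 * sqrt(2) / 2), tolerance = 1e-12)
  expect_equal(slip_speed(pi / 4, 1.5, 7), 6.3103, tolerance = 1e-4)
  # neutral squirmer slip is fore-aft symmetric
  th <- seq(0, pi, length.out = 41)
  expect_equal(slip_speed(th, 2, 0), slip_speed(pi - th, 2, 0),
               tolerance = 1e-12)
  # the internal evaluator accepts general mode lists; check against the
  # explicit Legendre-polynomial oracle through mode 4
  B <- c(1.5, 3, -0.7, 0.2)
  mine <- sin(th) * squirmtopo:::slip_speed_modes_over_sin(cos(th), B)
  expect_equal(mine, slip_oracle(th, B), tolerance = 1e-10)
})

test_that("slip velocity is tangential and correctly oriented", {
  st <- squirmer(c(1, 1, 5), theta = 0.3, phi = 1.1, B1 = 1.5, beta = 7)
  nodes <- sphere_nodes(6, centre = st$centre)
  u <- slip_velocity(nodes$positions, st)
  m <- sweep(nodes$positions, 2, st$centre)
  # tangency at every node
  expect_lt(max(abs(rowSums(u * m))), 1e-10)
  # front pole: zero slip
  expect_equal(as.vector(slip_velocity(
    matrix(st$centre + st$orientation, 1), st)), c(0, 0, 0),
    tolerance = 1e-12)
  # equatorial point, beta = 0: slip of magnitude B1 along -n
  st0 <- squirmer(c(0, 0, 0), orientation = c(0, 0, 1), B1 = 1.5)
  eq <- matrix(c(1, 0, 0), 1)
  expect_equal(as.vector(slip_velocity(eq, st0)), c(0, 0, -1.5),
               tolerance = 1e-12)
  expect_error(slip_velocity(matrix(c(0, 0, 1.5), 1), st0), "sphere")
})

test_that("surface-averaged slip equals minus the free-space velocity", {
  # classical tangential-squirmer identity, checked on the fine mesh
  st <- squirmer(c(0, 0, 0), theta = 0.4, phi = -0.8, B1 = 1.5, beta = 7)
  f <- sphere_nodes(18, centre = st$centre, level = "fine")
  u <- slip_velocity(f$positions, st)
  avg <- colSums(u * f$weights) / sum(f$weights)
  U <- free_space_velocity(st)
  expect_equal(avg, -U, tolerance = 0.01)
  expect_equal(sqrt(sum(U^2)), 1)          # B1 = 3/2 normalisation
  expect_equal(free_space_velocity(squirmer(B1 = 0))[1:3], c(0, 0, 0))
  expect_equal(free_space_velocity(
    squirmer(orientation = c(0, 0, 1), B1 = 3)), c(0, 0, 2))
})
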