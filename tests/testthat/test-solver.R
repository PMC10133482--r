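test_that("nearest-neighbour matrix selects the closest same-body node", {
  # coarse identical to fine: identity
  co <- sphere_nodes(3)
  nu <- nearest_neighbour_matrix(co, co)
  expect_equal(as.matrix(nu), diag(54), ignore_attr = TRUE)
  # 1-D example, brute-force verified: fine at 0.1, 0.4, 0.9 pick (1, 1, 2)
  mk <- function(x, body) squirmtopo:::new_node_set(
    cbind(x, 0, 0, deparse.level = 0), rep(1, length(x)), body, "coarse")
  nu2 <- nearest_neighbour_matrix(mk(c(0, 1), "wall"),
                                  mk(c(0.1, 0.4, 0.9), "wall"))
  expect_equal(as.matrix(nu2),
               rbind(c(1, 0), c(1, 0), c(0, 1)), ignore_attr = TRUE)
  # every fine row sums to exactly one, cross-body entries zero
  fi <- sphere_nodes(7, level = "fine")
  wc <- wall_nodes(wall_patch_spec(4, 4, 12), topography("flat"), "coarse")
  wf <- wall_nodes(wall_patch_spec(4, 4, 12), topography("flat"), "fine")
  nu3 <- nearest_neighbour_matrix(list(co, wc), list(fi, wf))
  expect_equal(Matrix::rowSums(nu3), rep(1, fi$count + wf$count),
               ignore_attr = TRUE)
  expect_equal(sum(nu3[seq_len(fi$count), co$count + seq_len(wc$count)]), 0)
  expect_equal(sum(nu3[fi$count + seq_len(wf$count), seq_len(co$count)]), 0)
  # ties break to the lowest coarse index
  nu4 <- nearest_neighbour_matrix(mk(c(0, 1), "wall"), mk(0.5, "wall"))
  expect_equal(as.matrix(nu4), matrix(c(1, 0), 1), ignore_attr = TRUE)
  expect_error(nearest_neighbour_matrix(list(), list()), "empty")
})

test_that("system dimensions follow 3N + 6", {
  st <- squirmer(c(0, 0, 0), theta = pi / 2)
  sys <- assemble_mobility_system(mobility_problem(st, wall = "free"))
  expect_equal(dim(sys$A), c(294, 294))     # 3 * 96 + 6
  stw <- squirmer(c(0, 0, 1.2), theta = -0.17 * pi, beta = 7)
  sysw <- assemble_mobility_system(mobility_problem(
    stw, wall = "patch", topo = topography("flat"),
    wall_spec = wall_patch_spec(8, 16, 50)))
  expect_equal(dim(sysw$A), c(3 * (96 + 256) + 6, 3 * (96 + 256) + 6))
})

test_that("balance rows aggregate to total area and zero moment", {
  st <- squirmer(c(0, 0, 0), theta = pi / 2)
  sys <- assemble_mobility_system(mobility_problem(st, wall = "free"))
  # constant unit traction: force rows give total area, torque rows vanish
  expect_equal(sum(sys$area), 4 * pi, tolerance = 1e-12)
  arm <- sys$moment - sys$area %o% st$centre
  expect_lt(max(abs(colSums(arm))), 1e-12)
})

test_that("free-space mobility reproduces the analytic swimming velocity", {
  st <- squirmer(c(0, 0, 0), theta = pi / 2, B1 = 1.5, beta = 0)
  sol <- solve_mobility(mobility_problem(st, wall = "free"))
  expect_equal(sqrt(sum(sol$U^2)), 1, tolerance = 0.01)
  expect_lt(sqrt(sum(sol$Omega^2)), 1e-6)
  # U parallel to n (axisymmetry)
  expect_equal(sol$U / sqrt(sum(sol$U^2)), st$orientation,
               tolerance = 1e-6)
  # balance residuals recomputed from the tractions are tiny
  expect_lt(max(abs(sol$force_residual)),
            1e-8 * max(1, sol$traction_scale))
  expect_lt(max(abs(sol$torque_residual)),
            1e-8 * max(1, sol$traction_scale))
  # beta does not change the free-space speed
  st7 <- squirmer(c(0, 0, 0), theta = pi / 2, B1 = 1.5, beta = 7)
  sol7 <- solve_mobility(mobility_problem(st7, wall = "free"))
  expect_equal(sqrt(sum(sol7$U^2)), sqrt(sum(sol$U^2)), tolerance = 1e-3)
})

test_that("regularisation convergence: speed changes < 0.5% from 1e-2 to 1e-3", {
  st <- squirmer(c(0, 0, 0), theta = pi / 2)
  s2 <- solve_mobility(mobility_problem(st, wall = "free", epsilon = 1e-2))
  s3 <- solve_mobility(mobility_problem(st, wall = "free", epsilon = 1e-3))
  expect_lt(abs(sqrt(sum(s2$U^2)) - sqrt(sum(s3$U^2))) / sqrt(sum(s3$U^2)),
            0.005)
})

test_that("resistance solve recovers Stokes drag and rotation torque", {
  st <- squirmer(c(0, 0, 0), B1 = 0)
  prob <- mobility_problem(st, wall = "free")
  tr <- solve_resistance(prob, U_given = c(0, 0, 1))
  expect_equal(sqrt(sum(tr$force^2)), 6 * pi, tolerance = 0.02 * 6 * pi)
  expect_equal(tr$force / sqrt(sum(tr$force^2)), c(0, 0, 1),
               tolerance = 1e-10)
  rot <- solve_resistance(prob, U_given = c(0, 0, 0),
                          Omega_given = c(0, 0, 1))
  expect_equal(sqrt(sum(rot$torque^2)), 8 * pi, tolerance = 0.02 * 8 * pi)
  zero <- solve_resistance(prob, c(0, 0, 0), c(0, 0, 0))
  expect_equal(max(abs(c(zero$force, zero$torque))), 0, tolerance = 1e-12)
  expect_error(solve_resistance(mobility_problem(
    squirmer(B1 = 1.5), wall = "free"), c(0, 0, 1)), "B1 = 0")
})

test_that("mobility and resistance are reciprocal for the towed sphere", {
  st <- squirmer(c(0, 0, 0), B1 = 0)
  prob <- mobility_problem(st, wall = "free")
  F <- c(0, 0, 6 * pi)
  sol <- solve_mobility(prob, external_force = F)
  expect_equal(sol$U, F / (6 * pi), tolerance = 0.02)
  expect_lt(sqrt(sum(sol$Omega^2)), 1e-8)
})

test_that("traction gauge shift leaves the balance quantities unchanged", {
  # f -> f + c * m changes the discrete force integral by c * sum A~ m and
  # the torque analogue; both vanish by the mesh's reflection symmetry
  st <- squirmer(c(0, 0, 0), theta = pi / 2, beta = 7)
  prob <- mobility_problem(st, wall = "free")
  sys <- assemble_mobility_system(prob)
  m <- sphere_nodes(4, centre = st$centre)$positions  # outward normals
  cshift <- 3.7
  dF <- cshift * colSums(sys$area * m)
  arm <- sys$moment - sys$area %o% st$centre
  dT <- cshift * colSums(squirmtopo:::cross_rows(arm, m))
  expect_lt(max(abs(dF)), 1e-8)
  expect_lt(max(abs(dT)), 1e-8)
})

test_that("duplicate collocation points are rejected", {
  st <- squirmer(c(0, 0, 1.2))
  prob <- mobility_problem(st, wall = "free")
  prob$swimmer_coarse$positions[2, ] <- prob$swimmer_coarse$positions[1, ]
  expect_error(assemble_mobility_system(prob), "duplicate collocation")
})
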