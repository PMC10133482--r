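## Rigid-body trajectory integration above a wall: adaptive Dormand-Prince
## 5(4) with orientation renormalisation after every accepted step, wall
## patch re-centring at every right-hand-side evaluation, and physically
## motivated stopping events (clearance threshold, escape, settling).

#' Simulation configuration
#'
#' Collects everything that defines a trajectory run apart from the initial
#' state: the surface, the wall representation, discretisation, integrator
#' controls and stopping rules. Times are in units of \eqn{a/U} (radius over
#' free-space speed).
#'
#' @param topo a [topography()].
#' @param wall `"patch"` (discretised, topography-carrying wall),
#'   `"blakelet"` (flat half-space image system) or `"free"`.
#' @param wall_spec a [wall_patch_spec()]; its centre tracks the squirmer.
#' @param epsilon regularisation parameter.
#' @param n_s,N_s sphere coarse/fine refinements.
#' @param rtol,atol integrator relative/absolute tolerances.
#' @param max_time integration horizon.
#' @param stop_clearance clearance (squirmer radii) at which the run halts,
#'   just before unresolved short-range surface physics would matter.
#'   Default 0.05: above the regularisation and mesh scales, below the
#'   stable swimming gaps (~0.15) seen in practice.
#' @param output_stride sampling interval of the returned trajectory.
#' @param max_step upper bound on the adaptive step.
#' @param escape_height if the centre exceeds this height the run stops
#'   with termination `"escaped"` (default `Inf`: disabled).
#' @return An object of class `"simulation_config"`.
#' @export
simulation_config <- function(topo = topography("flat"),
                              wall = c("patch", "blakelet", "free"),
                              wall_spec = wall_patch_spec(),
                              epsilon = 1e-3, n_s = 4, N_s = 18,
                              rtol = 1e-6, atol = 1e-8,
                              max_time = 30, stop_clearance = 0.05,
                              output_stride = 0.1, max_step = 0.5,
                              escape_height = Inf) {
  wall <- match.arg(wall)
  stopifnot(max_time > 0, stop_clearance >= 0, output_stride > 0,
            rtol > 0, atol > 0, max_step > 0)
  structure(list(topo = topo, wall = wall, wall_spec = wall_spec,
                 epsilon = epsilon, n_s = n_s, N_s = N_s,
                 rtol = rtol, atol = atol, max_time = max_time,
                 stop_clearance = stop_clearance,
                 output_stride = output_stride, max_step = max_step,
                 escape_height = escape_height),
            class = "simulation_config")
}

state_from_vec <- function(y, proto) {
  n <- y[4:6]
  squirmer(y[1:3], orientation = n / sqrt(sum(n^2)),
           B1 = proto$B1, beta = proto$beta)
}

#' Instantaneous equations of motion
#'
#' One right-hand-side evaluation of the trajectory ODE: the wall patch (if
#' any) is re-centred under the current squirmer centre, the mobility
#' problem is solved, and the rigid-body kinematics
#' \eqn{dX/dt = U}, \eqn{dn/dt = \Omega \times n} are returned along with
#' the full mobility solution.
#'
#' @param state a [squirmer()] state.
#' @param config a [simulation_config()].
#' @return List with `dcentre`, `dorientation`, and `solution`.
#' @export
rhs <- function(state, config) {
  stopifnot(inherits(config, "simulation_config"))
  prob <- mobility_problem(state, wall = config$wall, topo = config$topo,
                           wall_spec = config$wall_spec,
                           epsilon = config$epsilon,
                           n_s = config$n_s, N_s = config$N_s)
  sol <- solve_mobility(prob)
  n <- state$orientation
  list(dcentre = sol$U,
       dorientation = c(sol$Omega[2] * n[3] - sol$Omega[3] * n[2],
                        sol$Omega[3] * n[1] - sol$Omega[1] * n[3],
                        sol$Omega[1] * n[2] - sol$Omega[2] * n[1]),
       solution = sol)
}

# Dormand-Prince 5(4) coefficients
.dp <- list(
  c = c(0, 1/5, 3/10, 4/5, 8/9, 1, 1),
  a = list(
    c(1/5),
    c(3/40, 9/40),
    c(44/45, -56/15, 32/9),
    c(19372/6561, -25360/2187, 64448/6561, -212/729),
    c(9017/3168, -355/33, 46732/5247, 49/176, -5103/18656),
    c(35/384, 0, 500/1113, 125/192, -2187/6784, 11/84)),
  b5 = c(35/384, 0, 500/1113, 125/192, -2187/6784, 11/84, 0),
  b4 = c(5179/57600, 0, 7571/16695, 393/640, -92097/339200, 187/2100, 1/40))

# cubic Hermite interpolation of one step
hermite <- function(t, t0, t1, y0, y1, f0, f1) {
  h <- t1 - t0
  s <- (t - t0) / h
  h00 <- (1 + 2 * s) * (1 - s)^2
  h10 <- s * (1 - s)^2
  h01 <- s^2 * (3 - 2 * s)
  h11 <- s^2 * (s - 1)
  h00 * y0 + h10 * h * f0 + h01 * y1 + h11 * h * f1
}

#' Integrate a squirmer trajectory
#'
#' Adaptive Dormand--Prince 5(4) integration of [rhs()] from an initial
#' state. The orientation is renormalised after every accepted step. The
#' run terminates at `max_time`, when the squirmer--wall clearance drops to
#' `stop_clearance` (event time refined by bisection on the dense output),
#' when the centre exceeds `escape_height`, or when a user-supplied
#' `monitor` requests a stop (used e.g. for settling detection).
#'
#' @param state0 initial [squirmer()] state.
#' @param config a [simulation_config()].
#' @param monitor optional `function(t, state, deriv)` called after every
#'   accepted step; return `NULL` to continue or a string naming the
#'   termination kind to stop.
#' @return An object of class `"trajectory"`: a data frame of samples at
#'   `output_stride` spacing (columns `t, x, y, z, nx, ny, nz, theta, phi,
#'   clearance`), the termination record, the accepted-step count, and the
#'   final state.
#' @export
simulate_squirmer <- function(state0, config, monitor = NULL) {
  stopifnot(inherits(state0, "squirmer_state"),
            inherits(config, "simulation_config"))
  check_clearance <- config$wall != "free"
  if (check_clearance) {
    cl0 <- min_clearance(state0, config$topo)
    if (cl0 <= config$stop_clearance)
      stop("initial clearance is at or below stop_clearance", call. = FALSE)
  }
  fvec <- function(y) {
    d <- rhs(state_from_vec(y, state0), config)
    c(d$dcentre, d$dorientation)
  }
  clear_of <- function(y) min_clearance(state_from_vec(y, state0),
                                        config$topo)
  t <- 0
  y <- c(state0$centre, state0$orientation)
  k1 <- fvec(y)
  h <- min(config$max_step, config$output_stride)
  ts <- t; Y <- matrix(y, 1); Fd <- matrix(k1, 1)
  termination <- list(kind = "max_time", time = config$max_time)
  n_acc <- 0L
  K <- matrix(0, 7, 6)
  repeat {
    if (t >= config$max_time - 1e-12) break
    h <- min(h, config$max_time - t)
    K[1, ] <- k1
    for (s in 2:6) {
      acc <- .dp$a[[s - 1]]
      K[s, ] <- fvec(y + h * colSums(acc * K[seq_along(acc), , drop = FALSE]))
    }
    y5 <- y + h * colSums(.dp$a[[6]] * K[1:6, ])
    K[7, ] <- fvec(y5)
    err_vec <- h * colSums((.dp$b5 - .dp$b4) * K)
    sc <- config$atol + config$rtol * pmax(abs(y), abs(y5))
    err <- sqrt(mean((err_vec / sc)^2))
    if (err <= 1) {
      t_new <- t + h
      # renormalise orientation (keeps |n| = 1 to rounding)
      y5[4:6] <- y5[4:6] / sqrt(sum(y5[4:6]^2))
      k7 <- K[7, ]
      n_acc <- n_acc + 1L
      stop_now <- NULL
      t_ev <- t_new; y_ev <- y5
      if (check_clearance && clear_of(y5) <= config$stop_clearance) {
        # bisect the dense output for the crossing time
        lo <- t; hi <- t_new
        for (i in 1:40) {
          mid <- (lo + hi) / 2
          ym <- hermite(mid, t, t_new, y, y5, k1, k7)
          if (clear_of(ym) <= config$stop_clearance) hi <- mid else lo <- mid
          if (hi - lo < 1e-8) break
        }
        t_ev <- hi
        y_ev <- hermite(hi, t, t_new, y, y5, k1, k7)
        y_ev[4:6] <- y_ev[4:6] / sqrt(sum(y_ev[4:6]^2))
        stop_now <- "contact_stop"
      } else if (y5[3] > config$escape_height) {
        stop_now <- "escaped"
      } else if (!is.null(monitor)) {
        stop_now <- monitor(t_new, state_from_vec(y5, state0), k7)
      }
      t <- t_ev; y <- y_ev
      ts <- c(ts, t); Y <- rbind(Y, y)
      Fd <- rbind(Fd, if (identical(t, t_new)) k7 else fvec(y))
      k1 <- Fd[nrow(Fd), ]
      if (!is.null(stop_now)) {
        termination <- list(kind = stop_now, time = t)
        break
      }
      h <- min(config$max_step, h * min(5, max(0.2, 0.9 * err^(-0.2))))
    } else {
      h <- h * max(0.2, 0.9 * err^(-0.2))
      if (h < 1e-10)
        stop(sprintf(
          "integration error: step size underflow at t = %.6g (z = %.6g)",
          t, y[3]), call. = FALSE)
    }
  }
  if (termination$kind == "max_time") termination$time <- t
  build_trajectory(ts, Y, Fd, termination, state0, config, n_acc)
}

build_trajectory <- function(ts, Y, Fd, termination, state0, config, n_acc) {
  t_out <- unique(c(seq(0, max(ts), by = config$output_stride), max(ts)))
  samp <- matrix(NA_real_, length(t_out), 6)
  idx <- findInterval(t_out, ts, rightmost.closed = TRUE)
  idx[idx >= length(ts)] <- length(ts) - 1L
  if (length(ts) == 1L) {
    samp <- matrix(Y[1, ], length(t_out), 6, byrow = TRUE)
  } else {
    for (r in seq_along(t_out)) {
      i <- idx[r]
      samp[r, ] <- hermite(t_out[r], ts[i], ts[i + 1],
                           Y[i, ], Y[i + 1, ], Fd[i, ], Fd[i + 1, ])
    }
  }
  nn <- samp[, 4:6] / sqrt(rowSums(samp[, 4:6, drop = FALSE]^2))
  cl <- if (config$wall == "free") rep(NA_real_, length(t_out))
  else vapply(seq_along(t_out), function(r)
    min_clearance(squirmer(samp[r, 1:3], orientation = nn[r, ],
                           B1 = state0$B1, beta = state0$beta),
                  config$topo), 0)
  df <- data.frame(t = t_out, x = samp[, 1], y = samp[, 2], z = samp[, 3],
                   nx = nn[, 1], ny = nn[, 2], nz = nn[, 3],
                   theta = asin(pmin(1, pmax(-1, nn[, 3]))),
                   phi = atan2(nn[, 1], nn[, 2]),
                   clearance = cl)
  structure(list(data = df, termination = termination,
                 state0 = state0, config = config,
                 final_state = state_from_vec(
                   c(Y[nrow(Y), 1:3], Y[nrow(Y), 4:6]), state0),
                 n_steps = n_acc),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  d <- x$data
  cat(sprintf(
    "<trajectory> %d samples to t=%.4g  (%d steps)  termination: %s\n",
    nrow(d), max(d$t), x$n_steps, x$termination$kind))
  cat(sprintf("  final: x=(%.4g, %.4g, %.4g)  theta=%.4g  phi=%.4g\n",
              d$x[nrow(d)], d$y[nrow(d)], d$z[nrow(d)],
              d$theta[nrow(d)], d$phi[nrow(d)]))
  invisible(x)
}

#' Steady-oscillation diagnostics
#'
#' Measures the vertical oscillation over the final time window of a
#' trajectory: the amplitude is half the peak-to-peak range of `z`, and the
#' spatial wavelength is the mean spacing, in horizontal arc length, of
#' consecutive local maxima of `z` (peak positions refined by local
#' quadratic interpolation). A constant `z` yields amplitude 0 and an
#' undefined (flagged, `NA`) wavelength.
#'
#' @param traj a [simulate_squirmer()] trajectory.
#' @param window length of the final time window to analyse.
#' @return List with `z_amplitude`, `z_wavelength`, `n_peaks`, `flag`
#'   (`"ok"`, `"constant"` or `"too_few_peaks"`).
#' @export
oscillation_metrics <- function(traj, window) {
  stopifnot(inherits(traj, "trajectory"), window > 0)
  d <- traj$data
  t_end <- max(d$t)
  if (window > t_end)
    stop("analysis error: window longer than the trajectory", call. = FALSE)
  d <- d[d$t >= t_end - window, ]
  z <- d$z
  amp <- (max(z) - min(z)) / 2
  s <- c(0, cumsum(sqrt(diff(d$x)^2 + diff(d$y)^2)))
  if (amp < 1e-6)
    return(list(z_amplitude = amp, z_wavelength = NA_real_,
                n_peaks = 0L, flag = "constant"))
  m <- length(z)
  pk <- which(z[2:(m - 1)] > z[1:(m - 2)] & z[2:(m - 1)] >= z[3:m]) + 1L
  # ignore peaks shallower than 10% of the range (sampling noise)
  pk <- pk[z[pk] > min(z) + 0.2 * amp]
  if (length(pk) < 2)
    return(list(z_amplitude = amp, z_wavelength = NA_real_,
                n_peaks = length(pk), flag = "too_few_peaks"))
  s_pk <- vapply(pk, function(i) {
    # quadratic refinement through the three points around the peak
    si <- s[(i - 1):(i + 1)]; zi <- z[(i - 1):(i + 1)]
    den <- (si[1] - si[2]) * (si[1] - si[3]) * (si[2] - si[3])
    a <- (si[3] * (zi[2] - zi[1]) + si[2] * (zi[1] - zi[3]) +
            si[1] * (zi[3] - zi[2])) / den
    b <- (si[3]^2 * (zi[1] - zi[2]) + si[2]^2 * (zi[3] - zi[1]) +
            si[1]^2 * (zi[2] - zi[3])) / den
    if (abs(a) < 1e-12) si[2] else -b / (2 * a)
  }, 0)
  list(z_amplitude = amp, z_wavelength = mean(diff(s_pk)),
       n_peaks = length(pk), flag = "ok")
}

#' Write a trajectory to CSV with a JSON sidecar
#'
#' The sample table goes to `path` as CSV (columns `t, x, y, z, nx, ny, nz,
#' theta, phi, clearance`); run metadata (configuration, initial state,
#' termination record, package version) goes to `paste0(path, ".json")`.
#'
#' @param traj a trajectory.
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  utils::write.csv(traj$data, path, row.names = FALSE)
  cfg <- traj$config
  meta <- list(
    package = "squirmtopo",
    version = as.character(utils::packageVersion("squirmtopo")),
    termination = traj$termination,
    n_steps = traj$n_steps,
    initial_state = list(centre = traj$state0$centre,
                         orientation = traj$state0$orientation,
                         B1 = traj$state0$B1, beta = traj$state0$beta),
    config = list(
      topography = unclass(cfg$topo), wall = cfg$wall,
      wall_spec = unclass(cfg$wall_spec), epsilon = cfg$epsilon,
      n_s = cfg$n_s, N_s = cfg$N_s, rtol = cfg$rtol, atol = cfg$atol,
      max_time = cfg$max_time, stop_clearance = cfg$stop_clearance,
      output_stride = cfg$output_stride, max_step = cfg$max_step))
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
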