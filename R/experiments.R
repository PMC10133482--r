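## Scenario runner: free-space speed table, flat-wall validation, and
## topography sweeps. Default parameters follow the study conditions:
## B1 = 3/2 (unit free-space speed), puller beta = 7, topography amplitude
## A = 0.1, start X = (0, y0, 1.2) with attack angle theta = -0.17*pi.

#' Free-space swimming speed table
#'
#' One free-space mobility solve per (`n_s`, `N_s`) grid entry, tabulating
#' the numerical swimming speed against the closed-form value
#' \eqn{|U| = 2B_1/3} (= 1 for the default \eqn{B_1 = 3/2}).
#'
#' @param epsilon regularisation parameter.
#' @param grid data frame with columns `n_s`, `N_s`; the default is the
#'   standard refinement grid used for validation.
#' @param B1,beta squirmer parameters.
#' @return Data frame with columns `n_s`, `N_s`, `epsilon`, `speed`,
#'   `rel_error` (relative to the closed form).
#' @export
run_speed_table <- function(epsilon = 1e-3,
                            grid = data.frame(
                              n_s = c(4, 4, 4, 4, 4, 5, 5, 5, 5),
                              N_s = c(10, 12, 14, 16, 18, 10, 12, 14, 16)),
                            B1 = 1.5, beta = 0) {
  stopifnot(nrow(grid) > 0, all(c("n_s", "N_s") %in% names(grid)))
  exact <- abs(2 * B1 / 3)
  speed <- vapply(seq_len(nrow(grid)), function(i) {
    st <- squirmer(c(0, 0, 0), theta = pi / 2, B1 = B1, beta = beta)
    sol <- solve_mobility(mobility_problem(
      st, wall = "free", epsilon = epsilon,
      n_s = grid$n_s[i], N_s = grid$N_s[i]))
    sqrt(sum(sol$U^2))
  }, 0)
  data.frame(n_s = grid$n_s, N_s = grid$N_s, epsilon = epsilon,
             speed = speed,
             rel_error = if (exact > 0) (speed - exact) / exact
                         else NA_real_)
}

#' Flat-wall stable swimming height
#'
#' Integrates a puller squirmer released above a flat wall until the
#' vertical dynamics settle: the run stops once \eqn{|dz/dt|} has stayed
#' below `settle_tol` throughout a trailing window of length
#' `settle_window`, and the settled height and pitch are reported. Strong
#' pullers (\eqn{\beta \gtrsim 5}) are hydrodynamically attracted to a
#' stable height and pitch; this run is the standard validation of the
#' wall-bounded solver.
#'
#' @param mode `"blakelet"` (half-space image system) or `"patch"`
#'   (discretised flat wall).
#' @param beta squirmer parameter (default 7, a strong puller).
#' @param z0 release height.
#' @param theta0,phi0 initial pitch and heading.
#' @param settle_tol,settle_window settling criterion (see above).
#' @param max_time integration horizon.
#' @param ... further arguments passed to [simulation_config()].
#' @return List with `z_star`, `theta_star`, `settled` (logical),
#'   `trajectory`.
#' @export
run_flat_wall_validation <- function(mode = c("blakelet", "patch"),
                                     beta = 7, z0 = 1.15,
                                     theta0 = -0.17 * pi, phi0 = 0,
                                     settle_tol = 1e-4, settle_window = 1,
                                     max_time = 150, ...) {
  mode <- match.arg(mode)
  cfg <- simulation_config(topo = topography("flat"), wall = mode,
                           max_time = max_time, ...)
  st0 <- squirmer(c(0, 0, z0), theta = theta0, phi = phi0, beta = beta)
  hist_t <- numeric(0); hist_v <- numeric(0)
  monitor <- function(t, state, deriv) {
    hist_t <<- c(hist_t, t); hist_v <<- c(hist_v, abs(deriv[3]))
    keep <- hist_t >= t - settle_window
    hist_t <<- hist_t[keep]; hist_v <<- hist_v[keep]
    if (t >= settle_window && max(hist_v) < settle_tol) "settled" else NULL
  }
  traj <- simulate_squirmer(st0, cfg, monitor = monitor)
  fin <- traj$final_state
  list(z_star = fin$centre[3],
       theta_star = orientation_angles(fin$orientation)$theta,
       settled = traj$termination$kind == "settled",
       trajectory = traj)
}

#' Define a topography scenario
#'
#' A named sweep of trajectory runs over a parameter grid. Each sweep row
#' defines one run: topography wavelength and amplitude, initial heading
#' `phi`, and initial lateral offset `y0`. Remaining conditions follow the
#' study defaults (start `(0, y0, 1.2)`, `theta0 = -0.17*pi`, `B1 = 3/2`,
#' `beta = 7`).
#'
#' @param name scenario identifier (used in artefact file names).
#' @param kind topography family passed to [topography()].
#' @param sweep data frame with any of the columns `lambda`, `A`, `phi`,
#'   `y0` (missing columns take the defaults `lambda = 2`, `A = 0.1`,
#'   `phi = 0`, `y0 = 0`).
#' @param beta,B1 squirmer parameters.
#' @param theta0 initial attack angle.
#' @param z0 initial height.
#' @param t_max integration horizon per run.
#' @param config_args list of overrides for [simulation_config()].
#' @return An object of class `"scenario"`.
#' @export
scenario <- function(name, kind, sweep, beta = 7, B1 = 1.5,
                     theta0 = -0.17 * pi, z0 = 1.2, t_max = 30,
                     config_args = list()) {
  stopifnot(is.character(name), is.data.frame(sweep))
  for (col in c("lambda", "A", "phi", "y0")) {
    if (is.null(sweep[[col]]))
      sweep[[col]] <- rep(c(lambda = 2, A = 0.1, phi = 0, y0 = 0)[[col]],
                          nrow(sweep))
  }
  structure(list(name = name, kind = kind, sweep = sweep, beta = beta,
                 B1 = B1, theta0 = theta0, z0 = z0, t_max = t_max,
                 config_args = config_args),
            class = "scenario")
}

#' Canonical scenario registry
#'
#' The named scenarios used for validation and the topography sweeps:
#' \describe{
#'   \item{`speed_table`}{free-space refinement study
#'     ([run_speed_table()]).}
#'   \item{`flat_wall`}{flat-wall stable-height validation
#'     ([run_flat_wall_validation()]).}
#'   \item{`sin1d_head_on`}{singly periodic sinusoid, heading along the
#'     wave vector (`phi = pi/2`), wavelengths 1, 2, 4, 8.}
#'   \item{`sin1d_phi_sweep`, `sin2d_phi_sweep`}{heading sweeps
#'     `phi = 0, 0.05*pi, ..., 0.5*pi` for each wavelength 1, 2, 4, 8.}
#'   \item{`peaks_phi_sweep`}{doubly periodic peaks; wave parameters
#'     2, 4, 8, 16 (inter-peak wavelengths 1, 2, 4, 8).}
#' }
#'
#' @return Named list; entries are [scenario()] objects or descriptors with
#'   a `type` field for the two validation entries.
#' @export
scenario_registry <- function() {
  phis <- seq(0, 0.5 * pi, by = 0.05 * pi)
  list(
    speed_table = list(type = "speed_table", name = "speed_table"),
    flat_wall = list(type = "flat_wall", name = "flat_wall"),
    sin1d_head_on = scenario(
      "sin1d_head_on", "sin1d",
      expand.grid(lambda = c(1, 2, 4, 8), phi = 0.5 * pi)),
    sin1d_phi_sweep = scenario(
      "sin1d_phi_sweep", "sin1d",
      expand.grid(lambda = c(1, 2, 4, 8), phi = phis)),
    sin2d_phi_sweep = scenario(
      "sin2d_phi_sweep", "sin2d",
      expand.grid(lambda = c(1, 2, 4, 8), phi = phis)),
    peaks_phi_sweep = scenario(
      "peaks_phi_sweep", "peaks2d",
      expand.grid(lambda = c(2, 4, 8, 16), phi = phis)))
}

#' Run a topography scenario
#'
#' Executes every sweep row of a [scenario()], optionally writing each
#' trajectory (CSV + JSON sidecar) to `outdir`, and returns a summary table
#' with, per run: the termination record, final heading `phi`, the drift
#' angle (unsigned angle between the horizontal displacement over the final
#' window and the horizontal projection of the orientation), and the steady
#' vertical oscillation amplitude and wavelength from
#' [oscillation_metrics()]. Individual run failures are recorded in the
#' summary and do not abort the sweep.
#'
#' @param sc a [scenario()].
#' @param outdir optional output directory for trajectory artefacts.
#' @param window final time window for the steady metrics.
#' @param quiet suppress per-run progress messages.
#' @return Data frame, one row per sweep entry.
#' @export
run_topography_scenario <- function(sc, outdir = NULL, window = 10,
                                    quiet = FALSE) {
  stopifnot(inherits(sc, "scenario"))
  if (!is.null(outdir) && !dir.exists(outdir))
    dir.create(outdir, recursive = TRUE)
  if (nrow(sc$sweep) == 0L)
    return(data.frame(run = character(0), lambda = numeric(0),
                      A = numeric(0), phi0 = numeric(0), y0 = numeric(0),
                      termination = character(0), t_end = numeric(0),
                      phi_final = numeric(0), theta_final = numeric(0),
                      z_final = numeric(0), drift_angle = numeric(0),
                      z_amplitude = numeric(0), z_wavelength = numeric(0),
                      n_steps = integer(0), error = character(0)))
  rows <- lapply(seq_len(nrow(sc$sweep)), function(i) {
    p <- sc$sweep[i, ]
    run_name <- sprintf("%s_run%03d_lam%g_A%g_phi%.4g",
                        sc$name, i, p$lambda, p$A, p$phi)
    base <- data.frame(run = run_name, lambda = p$lambda, A = p$A,
                       phi0 = p$phi, y0 = p$y0)
    out <- tryCatch({
      topo <- topography(sc$kind, amplitude = p$A, wavelength = p$lambda)
      cfg <- do.call(simulation_config, c(
        list(topo = topo, wall = "patch", max_time = sc$t_max),
        sc$config_args))
      st0 <- squirmer(c(0, p$y0, sc$z0), theta = sc$theta0, phi = p$phi,
                      B1 = sc$B1, beta = sc$beta)
      tm0 <- Sys.time()
      traj <- simulate_squirmer(st0, cfg)
      dt <- as.numeric(difftime(Sys.time(), tm0, units = "secs"))
      if (!quiet)
        message(sprintf("[%s] %s in %.1fs (%d steps)", run_name,
                        traj$termination$kind, dt, traj$n_steps))
      if (!is.null(outdir))
        write_trajectory(traj, file.path(outdir, paste0(run_name, ".csv")))
      d <- traj$data
      w <- min(window, max(d$t) * 0.5)
      met <- oscillation_metrics(traj, w)
      fin <- d[d$t >= max(d$t) - w, ]
      disp <- c(fin$x[nrow(fin)] - fin$x[1], fin$y[nrow(fin)] - fin$y[1])
      head_xy <- c(fin$nx[nrow(fin)], fin$ny[nrow(fin)])
      drift <- if (sqrt(sum(disp^2)) < 1e-8) NA_real_ else
        acos(min(1, max(-1, sum(disp * head_xy) /
                          (sqrt(sum(disp^2)) * sqrt(sum(head_xy^2))))))
      cbind(base, data.frame(
        termination = traj$termination$kind,
        t_end = traj$termination$time,
        phi_final = d$phi[nrow(d)],
        theta_final = d$theta[nrow(d)],
        z_final = d$z[nrow(d)],
        drift_angle = drift,
        z_amplitude = met$z_amplitude,
        z_wavelength = met$z_wavelength,
        n_steps = traj$n_steps, error = NA_character_))
    }, error = function(e) {
      if (!quiet) message(sprintf("[%s] FAILED: %s", run_name,
                                  conditionMessage(e)))
      cbind(base, data.frame(
        termination = "error", t_end = NA_real_, phi_final = NA_real_,
        theta_final = NA_real_, z_final = NA_real_, drift_angle = NA_real_,
        z_amplitude = NA_real_, z_wavelength = NA_real_,
        n_steps = NA_integer_, error = conditionMessage(e)))
    })
    out
  })
  do.call(rbind, rows)
}
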