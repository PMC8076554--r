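#' Oculomotor plant parameters
#'
#' The eyes are modelled as a single conjugate second-order plant (one
#' equation drives both eyes). `J` is the moment of inertia of the eyeball,
#' `kappa` the damping constant of the restoring torque, and `omega` the
#' convergence angle that offsets the two eyes' heading proprioception by
#' `+/- omega/2`. `Pi_f` and `Pi_g` are diagonal precisions (inverse
#' variances) of the process and sensory noise. Defaults `J = 1`,
#' `kappa = 2` put the plant exactly at critical damping, so saccades land
#' without oscillating around the target.
#'
#' @param J moment of inertia, > 0 (arbitrary units).
#' @param kappa damping constant, >= 0.
#' @param omega convergence angle in radians, >= 0.
#' @param Pi_f length-2 process-noise precision (heading, elevation rows of
#'   the velocity dynamics).
#' @param Pi_g sensory-noise precision applied to every afferent channel.
#' @return An object of class `plant_params`.
#' @export
plant_params <- function(J = 1, kappa = 2, omega = 0,
                         Pi_f = c(1e4, 1e4), Pi_g = 1e4) {
  if (!is.finite(J) || J <= 0) stop_invalid("`J` must be > 0")
  if (!is.finite(kappa) || kappa < 0) stop_invalid("`kappa` must be >= 0")
  if (!is.finite(omega) || omega < 0) stop_invalid("`omega` must be >= 0")
  if (length(Pi_f) == 1) Pi_f <- rep(Pi_f, 2)
  if (any(!is.finite(Pi_f)) || any(Pi_f <= 0) || !is.finite(Pi_g) ||
      Pi_g <= 0) {
    stop_invalid("precisions must be strictly positive")
  }
  structure(list(J = J, kappa = kappa, omega = omega,
                 Pi_f = as.numeric(Pi_f), Pi_g = Pi_g),
            class = "plant_params")
}

#' Gaze state and motor command
#'
#' `oculo_state()` stacks the gaze angles `(heading, elevation)` and their
#' time derivatives; `motor_command()` holds the equilibrium point `phi`
#' toward which the plant relaxes -- the setpoint of the equilibrium-point
#' reading of motor control.
#'
#' @param theta length-2 `(heading, elevation)` in radians.
#' @param theta_dot length-2 angular velocity in rad/s.
#' @return `oculo_state()` returns an `oculo_state`; `motor_command()` a
#'   `motor_command`.
#' @export
oculo_state <- function(theta = c(0, 0), theta_dot = c(0, 0)) {
  check_finite(theta, "theta")
  check_finite(theta_dot, "theta_dot")
  structure(list(theta = as.numeric(theta),
                 theta_dot = as.numeric(theta_dot)),
            class = "oculo_state")
}

#' @rdname oculo_state
#' @param phi length-2 equilibrium gaze `(heading, elevation)` in radians.
#' @export
motor_command <- function(phi = c(0, 0)) {
  check_finite(phi, "phi")
  structure(list(phi = as.numeric(phi)), class = "motor_command")
}

#' Restoring torque
#'
#' The pendulum-like torque `tau = phi - theta - kappa * theta_dot` per
#' axis: a spring toward the setpoint plus viscous damping.
#'
#' @param command a `motor_command`.
#' @param state an `oculo_state`.
#' @param kappa damping constant.
#' @return Length-2 `(heading, elevation)` torque.
#' @export
torque <- function(command, state, kappa) {
  command$phi - state$theta - kappa * state$theta_dot
}

#' Equations of motion of the eye
#'
#' `d(theta)/dt = theta_dot`; `d(theta_dot)/dt = tau / J`.
#'
#' @param state an `oculo_state`.
#' @param command a `motor_command`.
#' @param params a `plant_params`.
#' @return List with `dtheta` and `dtheta_dot` (each length 2).
#' @export
flow <- function(state, command, params) {
  list(dtheta = state$theta_dot,
       dtheta_dot = torque(command, state, params$kappa) / params$J)
}

#' Closed-form solution of the saccadic plant
#'
#' The plant is a linear damped oscillator per axis,
#' `J y'' + kappa y' + y = 0` in the error `y = theta - phi`, solved exactly
#' through its characteristic roots in the under-, over- and critically
#' damped regimes. Serves as the independent oracle for the numerical
#' integrator.
#'
#' @param state0 initial `oculo_state`.
#' @param command a `motor_command`.
#' @param params a `plant_params`.
#' @param t time in seconds, >= 0.
#' @return The exact `oculo_state` at time `t`.
#' @export
closed_form_state <- function(state0, command, params, t) {
  if (!is.finite(t) || t < 0) stop_invalid("`t` must be >= 0")
  J <- params$J; kap <- params$kappa
  disc <- kap^2 - 4 * J
  y0 <- state0$theta - command$phi
  v0 <- state0$theta_dot
  if (abs(disc) < 1e-12) {
    r <- -kap / (2 * J)
    B <- v0 - r * y0
    y <- (y0 + B * t) * exp(r * t)
    yd <- (B + r * (y0 + B * t)) * exp(r * t)
  } else if (disc > 0) {
    s <- sqrt(disc)
    r1 <- (-kap + s) / (2 * J)
    r2 <- (-kap - s) / (2 * J)
    A <- (v0 - r2 * y0) / (r1 - r2)
    B <- y0 - A
    y <- A * exp(r1 * t) + B * exp(r2 * t)
    yd <- A * r1 * exp(r1 * t) + B * r2 * exp(r2 * t)
  } else {
    mu <- -kap / (2 * J)
    wd <- sqrt(-disc) / (2 * J)
    A <- y0
    B <- (v0 - mu * y0) / wd
    e <- exp(mu * t)
    y <- e * (A * cos(wd * t) + B * sin(wd * t))
    yd <- e * ((mu * A + wd * B) * cos(wd * t) +
                 (mu * B - wd * A) * sin(wd * t))
  }
  oculo_state(theta = command$phi + y, theta_dot = yd)
}

#' Proprioceptive read-out
#'
#' Maps the conjugate gaze state to per-eye II (position) and Ia (velocity)
#' afferents. Heading II channels are offset by the convergence angle --
#' left eye `theta - omega/2`, right eye `theta + omega/2` -- while
#' elevation channels are identical across eyes (eye movements are
#' congruent; only heading carries the convergence discrepancy). Optional
#' iid Gaussian sensory noise at precision `Pi_g` on every channel.
#'
#' @param state an `oculo_state`.
#' @param params a `plant_params` (supplies `omega` and `Pi_g`).
#' @param seed integer to seed sensory noise, or `NULL` for the noiseless
#'   read-out.
#' @return Named numeric vector with channels `II_left_h`, `Ia_left_h`,
#'   `II_right_h`, `Ia_right_h`, `II_left_e`, `Ia_left_e`, `II_right_e`,
#'   `Ia_right_e` (radians and rad/s, arbitrary units).
#' @export
observe_proprio <- function(state, params, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  s <- proprio_channels(state, params)
  if (!is.null(seed)) {
    s <- s + stats::rnorm(length(s), 0, 1 / sqrt(params$Pi_g))
  }
  s
}

proprio_channels <- function(state, params) {
  w <- params$omega
  c(II_left_h = state$theta[1] - w / 2, Ia_left_h = state$theta_dot[1],
    II_right_h = state$theta[1] + w / 2, Ia_right_h = state$theta_dot[1],
    II_left_e = state$theta[2], Ia_left_e = state$theta_dot[2],
    II_right_e = state$theta[2], Ia_right_e = state$theta_dot[2])
}

#' Simulate a saccade
#'
#' Fixed-step RK4 integration of the plant from `state0` toward the
#' equilibrium point, sampling the proprioceptive read-out on the same time
#' grid. With a seed, zero-mean Gaussian process noise of covariance
#' `Pi_f^-1 * dt` is added to the velocity rows after each step and sensory
#' noise of covariance `Pi_g^-1` to every afferent sample; the same seed
#' reproduces the trajectory exactly. Without a seed the simulation is
#' noiseless and bit-reproducible.
#'
#' @param state0 initial `oculo_state`.
#' @param command a `motor_command`.
#' @param params a `plant_params`.
#' @param dt integration step in seconds, > 0.
#' @param T total duration in seconds, >= dt.
#' @param seed integer seed for the noisy variant, or `NULL` (noiseless).
#' @return A `saccade_trajectory` data frame with columns `time`,
#'   `theta_h`, `theta_e`, `dtheta_h`, `dtheta_e` and the eight afferent
#'   channels of [observe_proprio()].
#' @export
integrate_saccade <- function(state0, command, params, dt = 1e-3, T = 1,
                              seed = NULL) {
  if (!is.finite(dt) || dt <= 0) stop_invalid("`dt` must be > 0")
  if (!is.finite(T) || T < dt) stop_invalid("`T` must be >= dt")
  n <- as.integer(round(T / dt))
  noisy <- !is.null(seed)
  if (noisy) set.seed(seed)
  sd_proc <- sqrt(dt / params$Pi_f)
  sd_sens <- 1 / sqrt(params$Pi_g)
  deriv <- function(x) {
    tau <- command$phi - x[1:2] - params$kappa * x[3:4]
    c(x[3:4], tau / params$J)
  }
  x <- c(state0$theta, state0$theta_dot)
  states <- matrix(NA_real_, n + 1, 4)
  proprio <- matrix(NA_real_, n + 1, 8)
  states[1, ] <- x
  sample_proprio <- function(x) {
    s <- proprio_channels(oculo_state(x[1:2], x[3:4]), params)
    if (noisy) s <- s + stats::rnorm(8, 0, sd_sens)
    s
  }
  proprio[1, ] <- sample_proprio(x)
  for (i in seq_len(n)) {
    k1 <- deriv(x)
    k2 <- deriv(x + dt / 2 * k1)
    k3 <- deriv(x + dt / 2 * k2)
    k4 <- deriv(x + dt * k3)
    x <- x + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (noisy) x[3:4] <- x[3:4] + stats::rnorm(2, 0, sd_proc)
    if (any(!is.finite(x))) {
      stop_invalid(sprintf("integration blew up at step %d (t = %g s)", i,
                           i * dt),
                   class = "activevision_integration_error")
    }
    states[i + 1, ] <- x
    proprio[i + 1, ] <- sample_proprio(x)
  }
  out <- data.frame(time = (0:n) * dt,
                    theta_h = states[, 1], theta_e = states[, 2],
                    dtheta_h = states[, 3], dtheta_e = states[, 4])
  colnames(proprio) <- names(proprio_channels(state0, params))
  out <- cbind(out, as.data.frame(proprio))
  class(out) <- c("saccade_trajectory", "data.frame")
  out
}

#' Export a trajectory as CSV
#'
#' Writes the standard column layout `time, theta_h, theta_e, dtheta_h,
#' dtheta_e, II_left_h, Ia_left_h, II_right_h, Ia_right_h, II_elev,
#' Ia_elev`; the shared elevation channels are taken from the left eye
#' (identical across eyes in the noiseless plant).
#'
#' @param trajectory a `saccade_trajectory`.
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
write_trajectory_csv <- function(trajectory, path) {
  df <- data.frame(
    time = trajectory$time,
    theta_h = trajectory$theta_h, theta_e = trajectory$theta_e,
    dtheta_h = trajectory$dtheta_h, dtheta_e = trajectory$dtheta_e,
    II_left_h = trajectory$II_left_h, Ia_left_h = trajectory$Ia_left_h,
    II_right_h = trajectory$II_right_h, Ia_right_h = trajectory$Ia_right_h,
    II_elev = trajectory$II_left_e, Ia_elev = trajectory$Ia_left_e
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
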