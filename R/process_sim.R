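# Stirred-tank process simulator: batch phase, optional semi-continuous
# phase with a fresh-mass-triggered feed and periodic drains, and peak-yield
# extraction from the resulting trajectory.

#' Feed medium composition
#'
#' Concentrations of the six nutrients in the feed medium [g/L]. The
#' standard feed mirrors the batch medium but with 59 mM instead of 88 mM
#' sucrose.
#'
#' @param S,F,G,A,N,P Feed concentrations [g/L], >= 0.
#' @return Named numeric vector over [NUTRIENT_IDS].
#' @examples
#' standard_feed <- medium_composition(
#'   S = to_internal(59, "S"), A = to_internal(21, "A"),
#'   N = to_internal(39, "N"), P = to_internal(2.7, "P"))
#' @export
medium_composition <- function(S = 0, F = 0, G = 0, A = 0, N = 0, P = 0) {
  m <- c(S = S, F = F, G = G, A = A, N = N, P = P)
  if (any(m < 0) || any(!is.finite(m))) {
    stop("feed concentrations must be finite and non-negative")
  }
  m
}

#' Feed and drain policy
#'
#' In `semi_continuous` mode the feed engages once the fresh mass
#' (`(Xa + Xd) * fm_per_dm`) reaches `trigger_FM`; from then on the feed
#' rate is chosen to hold the dry mass at the setpoint
#' `trigger_FM / fm_per_dm` (a setpoint-holding abstraction of the
#' capacitance-probe control loop: `Ft = mu * Xa * V / X_set`, floored at
#' zero). Broth is drained back to the starting volume every
#' `drain_interval` hours (22-26 h window; drains are instantaneous and
#' well-mixed, so concentrations are continuous across them).
#'
#' @param mode `"batch_only"` or `"semi_continuous"`.
#' @param trigger_FM Fresh-mass setpoint [g/L] (default 100).
#' @param fm_per_dm Fresh-to-dry mass ratio [g/g] (default 20).
#' @param drain_interval Hours between drains (default 24, allowed 22-26).
#' @param feed_medium Feed composition, see [medium_composition()].
#' @param V_max Hard volume ceiling [L]; feed stops when reached.
#' @return Object of class `by2_feed_policy`.
#' @export
feed_policy <- function(mode = c("batch_only", "semi_continuous"),
                        trigger_FM = 100, fm_per_dm = 20,
                        drain_interval = 24,
                        feed_medium = medium_composition(),
                        V_max = Inf) {
  mode <- match.arg(mode)
  if (trigger_FM <= 0 || fm_per_dm <= 0) {
    stop("trigger_FM and fm_per_dm must be positive")
  }
  if (mode == "semi_continuous" &&
      (drain_interval < 22 || drain_interval > 26)) {
    stop("drain_interval must lie in [22, 26] h")
  }
  structure(list(mode = mode, trigger_FM = trigger_FM,
                 fm_per_dm = fm_per_dm, drain_interval = drain_interval,
                 feed_medium = feed_medium, V_max = V_max),
            class = "by2_feed_policy")
}

#' Experiment design
#'
#' Bundles everything needed to simulate one fermentation run: initial
#' state, feed policy, duration and offline sampling grid. The inoculum is
#' assumed fully viable (`Xd = 0` at start).
#'
#' @param label Character run label.
#' @param state0 Initial state from [process_state()] (with `Xd = 0`).
#' @param duration Total simulated time [h].
#' @param policy [feed_policy()] (default batch only).
#' @param sampling_times Offline sampling times [h] within `[0, duration]`.
#' @return Object of class `by2_design`.
#' @export
experiment_design <- function(label, state0, duration,
                              policy = feed_policy("batch_only"),
                              sampling_times = seq(0, duration, by = 24)) {
  if (duration <= 0) stop("duration must be positive")
  if (state0[["Xd"]] != 0) stop("initial dead dry mass must be zero")
  sampling_times <- sort(unique(sampling_times))
  if (any(sampling_times < 0) || any(sampling_times > duration)) {
    stop("sampling times must lie within [0, duration]")
  }
  structure(list(label = label, state0 = state0, duration = duration,
                 policy = policy, sampling_times = sampling_times),
            class = "by2_design")
}

#' Solver options
#'
#' Integrator settings. Near-depletion nutrient dynamics are stiff, so the
#' default is a stiff-capable method at tight tolerances.
#'
#' @param rtol,atol Relative / absolute tolerance (1e-8 / 1e-10).
#' @param grid_dt Dense output step [h] (0.5).
#' @param method deSolve method (default `"lsoda"`).
#' @return List of options.
#' @export
solver_options <- function(rtol = 1e-8, atol = 1e-10, grid_dt = 0.5,
                           method = "lsoda") {
  list(rtol = rtol, atol = atol, grid_dt = grid_dt, method = method)
}

# deSolve-facing RHS wrappers ------------------------------------------------

.deriv_batch <- function(t, y, parms) {
  list(unname(.rhs(y, parms$params, Ft = 0, feed = parms$feed)))
}

.deriv_feed <- function(t, y, parms) {
  mu <- .growth_rate(y, parms$params)
  Ft <- max(mu * max(y[["Xa"]], 0) * y[["V"]] / parms$X_set, 0)
  if (y[["V"]] >= parms$V_max) Ft <- 0
  list(unname(.rhs(y, parms$params, Ft = Ft, feed = parms$feed)))
}

.integrate_window <- function(y0, times, deriv, parms, solver) {
  out <- deSolve::ode(y = y0, times = times, func = deriv, parms = parms,
                      method = solver$method,
                      rtol = solver$rtol, atol = solver$atol)
  if (attr(out, "istate")[1] < 0) {
    stop("ODE solver failure at t = ", max(out[, "time"]),
         "; last state: ",
         paste(sprintf("%s=%.4g", STATE_NAMES, out[nrow(out), STATE_NAMES]),
               collapse = ", "))
  }
  out
}

#' Simulate a fermentation run
#'
#' Integrates the chosen model through the batch phase and, for
#' semi-continuous designs, through feed/drain cycles: the batch phase runs
#' with zero feed until the fresh-mass trigger is crossed (event-detected),
#' after which the setpoint-holding feed law engages and the volume is
#' drained back to the starting volume every `drain_interval` hours.
#'
#' @param design [experiment_design()].
#' @param params `by2_params` object matching the design's model variant.
#' @param solver [solver_options()].
#' @return Object of class `by2_trajectory`: dense time grid, state matrix,
#'   event log, and the design/parameters used. Coerce with
#'   `as.data.frame()`.
#' @export
simulate_culture <- function(design, params, solver = solver_options()) {
  stopifnot(inherits(design, "by2_design"), inherits(params, "by2_params"))
  pol <- design$policy
  y0 <- design$state0
  grid <- sort(unique(c(seq(0, design$duration, by = solver$grid_dt),
                        design$duration, design$sampling_times)))
  parms <- list(params = params, feed = pol$feed_medium,
                X_set = pol$trigger_FM / pol$fm_per_dm, V_max = pol$V_max)
  events <- data.frame(time = numeric(0), event = character(0),
                       detail = numeric(0))

  if (pol$mode == "batch_only") {
    out <- .integrate_window(y0, grid, .deriv_batch, parms, solver)
    states <- out[, STATE_NAMES, drop = FALSE]
    times <- out[, "time"]
  } else {
    # batch phase with event detection on the fresh-mass trigger
    rootfun <- function(t, y, parms) {
      (y[["Xa"]] + y[["Xd"]]) * pol$fm_per_dm - pol$trigger_FM
    }
    if ((y0[["Xa"]] + y0[["Xd"]]) * pol$fm_per_dm >= pol$trigger_FM) {
      times <- 0; states <- matrix(y0, nrow = 1,
                                   dimnames = list(NULL, STATE_NAMES))
      t_feed <- 0
    } else {
      out <- deSolve::ode(y = y0, times = grid, func = .deriv_batch,
                          parms = parms, method = "lsodar",
                          rootfunc = rootfun,
                          rtol = solver$rtol, atol = solver$atol)
      times <- out[, "time"]
      states <- out[, STATE_NAMES, drop = FALSE]
      t_feed <- times[length(times)]
    }
    if (t_feed < design$duration) {  # trigger crossed: feed phase
      events <- rbind(events, data.frame(time = t_feed, event = "feed_start",
                                         detail = NA_real_))
      V_start <- y0[["V"]]
      t0 <- t_feed
      y <- states[nrow(states), ]
      while (t0 < design$duration - 1e-9) {
        t1 <- min(t0 + pol$drain_interval, design$duration)
        w_times <- sort(unique(c(t0, grid[grid > t0 & grid < t1], t1)))
        outw <- .integrate_window(y, w_times, .deriv_feed, parms, solver)
        times <- c(times, outw[-1, "time"])
        states <- rbind(states, outw[-1, STATE_NAMES, drop = FALSE])
        y <- states[nrow(states), ]
        if (t1 < design$duration && y[["V"]] > V_start) {
          events <- rbind(events,
                          data.frame(time = t1, event = "drain",
                                     detail = y[["V"]] - V_start))
          y[["V"]] <- V_start  # well-mixed removal: concentrations unchanged
          times <- c(times, t1)
          states <- rbind(states, y)
        }
        t0 <- t1
      }
    }
  }

  conc <- setdiff(STATE_NAMES, "V")
  states[, conc] <- pmax(states[, conc], 0)  # clip integrator undershoot
  rownames(states) <- NULL
  structure(list(times = unname(times), states = states, events = events,
                 design = design, params = params),
            class = "by2_trajectory")
}

#' @export
as.data.frame.by2_trajectory <- function(x, ...) {
  df <- as.data.frame(x$states)
  df$X <- df$Xa + df$Xd
  cbind(data.frame(time_h = x$times), df)
}

#' @export
print.by2_trajectory <- function(x, ...) {
  cat("by2_trajectory:", x$design$label, "|", length(x$times),
      "grid points over", max(x$times), "h |", nrow(x$events), "events\n")
  invisible(x)
}

#' Evaluate a trajectory at arbitrary times
#'
#' Linear interpolation of every state component onto `times`.
#'
#' @param traj A `by2_trajectory`.
#' @param times Times [h] within the simulated range.
#' @return Matrix with one row per time, columns as the state vector.
#' @export
interpolate_trajectory <- function(traj, times) {
  if (any(times < min(traj$times) - 1e-9) ||
      any(times > max(traj$times) + 1e-9)) {
    stop("interpolation times outside the simulated range")
  }
  out <- vapply(STATE_NAMES, function(nm) {
    stats::approx(traj$times, traj$states[, nm], xout = times,
                  ties = "ordered")$y
  }, numeric(length(times)))
  if (length(times) == 1L) out <- matrix(out, nrow = 1,
                                         dimnames = list(NULL, STATE_NAMES))
  out
}

#' Peak active-biomass yield of a trajectory
#'
#' Locates the first maximum of active dry mass on the dense grid, refines
#' it by a local quadratic through the three bracketing grid points, and
#' returns the peak time `t*` and the dimensionless yield
#' `Ya* = Xa(t*) / X0`. Active mass peaks because growth slows as nutrients
#' deplete while death continues; a trajectory still rising at its end has
#' no interior peak and raises an error.
#'
#' @param traj A `by2_trajectory`.
#' @param X0 Inoculum dry mass [g/L]; defaults to the initial `Xa`.
#' @return List with `t_star` [h], `Ya_star`, and `Xa_star` [g/L].
#' @export
peak_active_yield <- function(traj, X0 = NULL) {
  Xa <- traj$states[, "Xa"]
  tt <- traj$times
  if (is.null(X0)) X0 <- Xa[1]
  if (X0 <= 0) stop("X0 must be positive")
  i <- which.max(Xa)
  if (i == length(Xa)) {
    stop("active dry mass is still increasing at the end of the ",
         "trajectory: no interior peak (extend the duration)")
  }
  t_star <- tt[i]; Xa_star <- Xa[i]
  if (i > 1L) {  # quadratic refinement on the bracketing triple
    t3 <- tt[(i - 1):(i + 1)]; x3 <- Xa[(i - 1):(i + 1)]
    d1 <- (x3[2] - x3[1]) / (t3[2] - t3[1])
    d2 <- (x3[3] - x3[2]) / (t3[3] - t3[2])
    curv <- 2 * (d2 - d1) / (t3[3] - t3[1])
    if (is.finite(curv) && curv < 0) {
      tv <- (t3[1] + t3[2]) / 2 - d1 / curv  # vertex of the quadratic
      if (tv >= t3[1] && tv <= t3[3]) {
        t_star <- tv
        Xa_star <- .quad_eval(t3, x3, tv)
      }
    }
  }
  list(t_star = t_star, Ya_star = Xa_star / X0, Xa_star = Xa_star)
}

# Lagrange quadratic through three points, evaluated at x
.quad_eval <- function(xs, ys, x) {
  l1 <- (x - xs[2]) * (x - xs[3]) / ((xs[1] - xs[2]) * (xs[1] - xs[3]))
  l2 <- (x - xs[1]) * (x - xs[3]) / ((xs[2] - xs[1]) * (xs[2] - xs[3]))
  l3 <- (x - xs[1]) * (x - xs[2]) / ((xs[3] - xs[1]) * (xs[3] - xs[2]))
  ys[1] * l1 + ys[2] * l2 + ys[3] * l3
}
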