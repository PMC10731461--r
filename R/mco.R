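# Bi-criteria optimization of the batch process: maximize the dimensionless
# active-biomass yield Ya* = Xa(t*)/X0 and minimize the peak time t*, over
# the initial dry mass X0 and initial sucrose S0. The front is built in
# three stages: the two anchor points (max yield; earliest peak), a
# weighted-sum sweep for the convex part, and an epsilon-constraint pass on
# a uniform t* grid for the non-convex remainder.

#' Design space for the bi-criteria problem
#'
#' The degrees of freedom are the inoculum dry mass and the initial sucrose
#' concentration; the other initial conditions are pinned at the standard
#' MS-medium start.
#'
#' @param X0 Range of inoculum dry mass [g/L] (default 0.3-1.5).
#' @param S0_mM Range of initial sucrose [mM] (default 17-88).
#' @param A_mM,N_mM,P_mM Fixed initial ammonium/nitrate/phosphate [mM].
#' @param V Working volume [L].
#' @param duration Simulation horizon [h]; must cover the latest peak in
#'   the space (default 480).
#' @param mm Molar mass table.
#' @return Object of class `by2_design_space`.
#' @export
design_space <- function(X0 = c(0.3, 1.5), S0_mM = c(17, 88),
                         A_mM = 21, N_mM = 39, P_mM = 2.7,
                         V = 2, duration = 480, mm = molar_masses()) {
  stopifnot(length(X0) == 2, length(S0_mM) == 2,
            X0[1] > 0, X0[1] < X0[2], S0_mM[1] >= 0, S0_mM[1] < S0_mM[2])
  structure(list(X0 = X0, S0_mM = S0_mM, A_mM = A_mM, N_mM = N_mM,
                 P_mM = P_mM, V = V, duration = duration, mm = mm),
            class = "by2_design_space")
}

.space_design <- function(X0, S0_mM, space) {
  X0 <- as.numeric(X0)[1]; S0_mM <- as.numeric(S0_mM)[1]
  st <- process_state(V = space$V, Xa = X0, Xd = 0,
                      S = to_internal(S0_mM, "S", space$mm),
                      A = to_internal(space$A_mM, "A", space$mm),
                      N = to_internal(space$N_mM, "N", space$mm),
                      P = to_internal(space$P_mM, "P", space$mm))
  experiment_design(label = sprintf("X0=%.3g_S0=%.3g", X0, S0_mM),
                    state0 = st, duration = space$duration,
                    sampling_times = c(0, space$duration))
}

#' Evaluate the two objectives at one design
#'
#' Runs a batch simulation (the optimization varies only the starting
#' conditions; no feed) and extracts the peak of active dry mass.
#'
#' @param X0 Inoculum dry mass [g/L].
#' @param S0_mM Initial sucrose [mM].
#' @param params Kinetic parameters.
#' @param space [design_space()].
#' @param solver [solver_options()].
#' @return List with `t_star` [h], `Ya_star`, `Xa_star` [g/L], `feasible`
#'   (`FALSE` with `NA` objectives when no peak occurs within the horizon).
#' @export
mco_objectives <- function(X0, S0_mM, params, space = design_space(),
                           solver = solver_options(grid_dt = 1)) {
  des <- .space_design(X0, S0_mM, space)
  p <- .params_for_design(params, des)
  pk <- tryCatch({
    traj <- simulate_culture(des, p, solver)
    peak_active_yield(traj, X0 = X0)
  }, error = function(e) NULL)
  if (is.null(pk)) {
    return(list(t_star = NA_real_, Ya_star = NA_real_, Xa_star = NA_real_,
                feasible = FALSE))
  }
  c(pk, list(feasible = TRUE))
}

# bound-constrained minimization of f(X0, S0) over the space: a coarse grid
# scan (which covers the corners and the interior) followed by one local
# gradient polish from the best cell
.optim_2d <- function(f, space, n_grid = 5) {
  lo <- c(space$X0[1], space$S0_mM[1]); hi <- c(space$X0[2], space$S0_mM[2])
  g1 <- seq(lo[1], hi[1], length.out = n_grid)
  g2 <- seq(lo[2], hi[2], length.out = n_grid)
  grid <- as.matrix(expand.grid(g1, g2))
  vals <- apply(grid, 1, function(v) f(unname(v)))
  v0 <- unname(grid[which.min(vals), ])
  # nudge boundary starts inside so finite-difference gradients stay in-box
  eps <- 1e-3 * (hi - lo)
  v0 <- pmin(pmax(v0, lo + eps), hi - eps)
  run <- tryCatch(
    stats::optim(v0, f, method = "L-BFGS-B", lower = lo, upper = hi,
                 control = list(maxit = 50, factr = 1e9,
                                parscale = hi - lo)),
    error = function(e) list(value = Inf, par = v0)
  )
  if (min(vals) < run$value) {
    run <- list(value = min(vals), par = grid[which.min(vals), ])
  }
  run$par <- unname(run$par)
  run
}

#' Anchor points of the Pareto front
#'
#' Stage one of the front construction: the maximum-yield anchor
#' (`argmax Ya*`, recording its peak time) and the minimum-time anchor (the
#' earliest achievable peak of active dry mass over the design space).
#'
#' @param params Kinetic parameters.
#' @param space [design_space()].
#' @param solver [solver_options()].
#' @return List with elements `max_yield` and `min_time`, each a list
#'   `(X0, S0_mM, t_star, Ya_star)`.
#' @export
anchor_points <- function(params, space = design_space(),
                          solver = solver_options(grid_dt = 1)) {
  obj <- function(v, what) {
    o <- mco_objectives(v[1], v[2], params, space, solver)
    if (!o$feasible) return(1e10)
    if (what == "yield") -o$Ya_star else o$t_star
  }
  ry <- .optim_2d(function(v) obj(v, "yield"), space)
  rt <- .optim_2d(function(v) obj(v, "time"), space)
  oy <- mco_objectives(ry$par[1], ry$par[2], params, space, solver)
  ot <- mco_objectives(rt$par[1], rt$par[2], params, space, solver)
  list(
    max_yield = list(X0 = ry$par[1], S0_mM = ry$par[2],
                     t_star = oy$t_star, Ya_star = oy$Ya_star),
    min_time  = list(X0 = rt$par[1], S0_mM = rt$par[2],
                     t_star = ot$t_star, Ya_star = ot$Ya_star)
  )
}

#' Uniform peak-time grid for the epsilon-constraint stage
#'
#' @param t_min,t_max Grid end points [h].
#' @param step Step width [h] (default 3).
#' @return Numeric vector from `t_min` to `t_max`; the number of steps is
#'   `length(.) - 1`.
#' @export
epsilon_grid <- function(t_min, t_max, step = 3) {
  stopifnot(t_max > t_min, step > 0)
  seq(t_min, t_max, by = step)
}

#' Remove dominated points
#'
#' Keeps the non-dominated subset of a set of objective pairs: a point is
#' dominated when another point has a peak no later and a yield no smaller,
#' with at least one strict.
#'
#' @param points `data.frame` with columns `t_star` and `Ya_star`.
#' @return The non-dominated rows, sorted by `t_star`.
#' @export
nondominated <- function(points) {
  stopifnot(all(c("t_star", "Ya_star") %in% names(points)))
  pts <- points[is.finite(points$t_star) & is.finite(points$Ya_star), ]
  pts <- pts[!duplicated(pts[, c("t_star", "Ya_star")]), ]
  keep <- vapply(seq_len(nrow(pts)), function(i) {
    !any(pts$t_star <= pts$t_star[i] & pts$Ya_star >= pts$Ya_star[i] &
           (pts$t_star < pts$t_star[i] | pts$Ya_star > pts$Ya_star[i]))
  }, logical(1))
  out <- pts[keep, ]
  out[order(out$t_star), ]
}

# maximize Ya subject to t*(X0, S0) = t_target (within tol_t), by a nested
# solve: for each S0, the peak time is monotone decreasing in X0, so the
# equality is solved for X0 by root finding, and Ya is then maximized over
# S0 alone.
.eps_solve <- function(t_target, params, space, solver, tol_t = 0.5,
                       n_outer = 9) {
  f_S0 <- function(S0) {
    h <- function(X0) {
      o <- mco_objectives(X0, S0, params, space, solver)
      # no peak inside the horizon: the peak time exceeds the duration
      if (!o$feasible) return(space$duration - t_target)
      o$t_star - t_target
    }
    h_lo <- h(space$X0[1]); h_hi <- h(space$X0[2])
    X0 <- if (h_lo <= 0) {
      if (abs(h_lo) <= tol_t) space$X0[1] else return(NULL)
    } else if (h_hi >= 0) {
      if (abs(h_hi) <= tol_t) space$X0[2] else return(NULL)
    } else {
      stats::uniroot(h, lower = space$X0[1], upper = space$X0[2],
                     tol = 1e-3)$root
    }
    o <- mco_objectives(X0, S0, params, space, solver)
    if (!o$feasible || abs(o$t_star - t_target) > tol_t) return(NULL)
    list(X0 = X0, S0_mM = S0, t_star = o$t_star, Ya_star = o$Ya_star)
  }
  grid_S0 <- seq(space$S0_mM[1], space$S0_mM[2], length.out = n_outer)
  cand <- lapply(grid_S0, f_S0)
  ok <- !vapply(cand, is.null, logical(1))
  if (!any(ok)) return(NULL)
  ya <- rep(-Inf, n_outer)
  ya[ok] <- vapply(cand[ok], `[[`, numeric(1), "Ya_star")
  i <- which.max(ya)
  best <- cand[[i]]
  # local refinement of S0 around the best grid point
  lo <- grid_S0[max(i - 1, 1)]; hi <- grid_S0[min(i + 1, n_outer)]
  if (hi > lo) {
    opt <- stats::optimize(function(S0) {
      r <- f_S0(S0)
      if (is.null(r)) -1e10 else r$Ya_star
    }, lower = lo, upper = hi, maximum = TRUE, tol = 0.5)
    if (opt$objective > best$Ya_star) {
      r <- f_S0(opt$maximum)
      if (!is.null(r)) best <- r
    }
  }
  best
}

#' Construct the bi-criteria Pareto front
#'
#' Three-stage construction: (1) the two anchors; (2) a weighted-sum sweep
#' over normalized objectives, which recovers the convex portion of the
#' front; (3) an epsilon-constraint pass in which the peak time is held at
#' a uniform grid of values between the anchor times (default step 3 h),
#' recovering any non-convex section. The union is filtered to its
#' non-dominated subset.
#'
#' @param params Kinetic parameters.
#' @param space [design_space()].
#' @param t_step Peak-time grid step [h] (default 3).
#' @param n_weights Number of weighted-sum weights (default 9).
#' @param solver [solver_options()].
#' @param anchors Optional precomputed [anchor_points()] result.
#' @return `data.frame` of class `by2_pareto_front` with columns `X0_gL`,
#'   `S0_mM`, `t_star_h`, `Ya_star`, `method`; sorted by `t_star_h`.
#' @export
pareto_front <- function(params, space = design_space(), t_step = 3,
                         n_weights = 9,
                         solver = solver_options(grid_dt = 1),
                         anchors = NULL) {
  if (is.null(anchors)) anchors <- anchor_points(params, space, solver)
  pts <- data.frame(
    X0_gL = c(anchors$max_yield$X0, anchors$min_time$X0),
    S0_mM = c(anchors$max_yield$S0_mM, anchors$min_time$S0_mM),
    t_star = c(anchors$max_yield$t_star, anchors$min_time$t_star),
    Ya_star = c(anchors$max_yield$Ya_star, anchors$min_time$Ya_star),
    method = "anchor"
  )
  t_ref <- anchors$max_yield$t_star
  ya_ref <- anchors$max_yield$Ya_star

  # weighted-sum sweep (interior weights; the end weights are the anchors)
  ws <- seq(0, 1, length.out = n_weights + 2)[2:(n_weights + 1)]
  for (w in ws) {
    f <- function(v) {
      o <- mco_objectives(v[1], v[2], params, space, solver)
      if (!o$feasible) return(1e10)
      w * o$t_star / t_ref - (1 - w) * o$Ya_star / ya_ref
    }
    r <- .optim_2d(f, space)
    o <- mco_objectives(r$par[1], r$par[2], params, space, solver)
    if (o$feasible) {
      pts <- rbind(pts, data.frame(X0_gL = r$par[1], S0_mM = r$par[2],
                                   t_star = o$t_star, Ya_star = o$Ya_star,
                                   method = "weighted_sum"))
    }
  }

  # epsilon-constraint pass on the uniform peak-time grid
  tg <- epsilon_grid(anchors$min_time$t_star, anchors$max_yield$t_star,
                     step = t_step)
  tg <- tg[tg > anchors$min_time$t_star & tg < anchors$max_yield$t_star]
  for (t_target in tg) {
    r <- .eps_solve(t_target, params, space, solver)
    if (!is.null(r)) {
      pts <- rbind(pts, data.frame(X0_gL = r$X0, S0_mM = r$S0_mM,
                                   t_star = r$t_star, Ya_star = r$Ya_star,
                                   method = "eps_constraint"))
    }
  }

  nd <- nondominated(pts)
  out <- data.frame(X0_gL = nd$X0_gL, S0_mM = nd$S0_mM,
                    t_star_h = nd$t_star, Ya_star = nd$Ya_star,
                    method = nd$method)
  rownames(out) <- NULL
  class(out) <- c("by2_pareto_front", "data.frame")
  out
}
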