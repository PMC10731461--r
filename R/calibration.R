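# Parameter identification: weighted least-squares objective on relative
# residuals, bound-constrained multistart optimization with the KI >= K
# ordering enforced by reparameterization, residual-bootstrap confidence
# intervals, and the MAE family of fit-quality measures.

# simulate a design at params and return the response matrix g at `times`
# (improved-model growth offsets are re-derived from the design's start)
.params_for_design <- function(params, design) {
  if (inherits(params, "by2_params_improved")) {
    with_growth_offsets(params, design$state0)
  } else {
    params
  }
}

.predict_g <- function(params, design, times, solver = solver_options(),
                       responses = RESPONSES) {
  p <- .params_for_design(params, design)
  traj <- simulate_culture(design, p, solver)
  cols <- unique(c(if ("X" %in% responses) c("Xa", "Xd"),
                   intersect(responses, NUTRIENT_IDS)))
  sm <- vapply(cols, function(nm) {
    stats::approx(traj$times, traj$states[, nm], xout = times,
                  ties = "ordered")$y
  }, numeric(length(times)))
  if (length(times) == 1L) sm <- matrix(sm, nrow = 1,
                                        dimnames = list(NULL, cols))
  out <- if ("X" %in% responses) {
    cbind(X = sm[, "Xa"] + sm[, "Xd"],
          sm[, intersect(responses, NUTRIENT_IDS), drop = FALSE])
  } else {
    sm[, intersect(responses, NUTRIENT_IDS), drop = FALSE]
  }
  out
}

#' Define a parameter-identification problem
#'
#' @param datasets List of [ts_dataset()] objects, each carrying its design.
#' @param params0 Baseline `by2_params` object: starting point and the
#'   values at which non-fitted parameters are held fixed.
#' @param free Names of the parameters to fit (default: every identifiable
#'   parameter of the variant, see [param_bounds()]).
#' @param weights Named per-response weights in the objective (default all
#'   1, equal priority for every response).
#' @param value_floor Per-response floor below which observations are
#'   excluded from the relative-residual objective (it divides by the
#'   measured value, which is undefined at zero — late-time phosphate).
#'   Default: the response's constant uncertainty `u0` if positive, else
#'   1e-6.
#' @param bounds Identification box bounds (default [param_bounds()]).
#' @return Object of class `by2_fit_problem`.
#' @export
fit_problem <- function(datasets, params0, free = NULL, weights = NULL,
                        value_floor = NULL, bounds = NULL) {
  if (inherits(datasets, "by2_dataset")) datasets <- list(datasets)
  stopifnot(length(datasets) >= 1, inherits(params0, "by2_params"))
  for (d in datasets) {
    if (is.null(d$design)) stop("dataset '", d$label, "' carries no design")
  }
  variant <- model_variant(params0)
  if (is.null(bounds)) bounds <- param_bounds(variant)
  if (is.null(free)) free <- bounds$name
  if (!all(free %in% bounds$name)) {
    stop("unknown free parameter(s): ",
         paste(setdiff(free, bounds$name), collapse = ", "))
  }
  w <- stats::setNames(rep(1, length(RESPONSES)), RESPONSES)
  if (!is.null(weights)) {
    stopifnot(all(names(weights) %in% RESPONSES), all(weights >= 0))
    w[names(weights)] <- weights
  }
  fl <- vapply(RESPONSES, function(r) {
    u0 <- datasets[[1]]$noise$u0[[r]]
    if (u0 > 0) u0 else 1e-6
  }, numeric(1))
  if (!is.null(value_floor)) {
    stopifnot(all(names(value_floor) %in% RESPONSES))
    fl[names(value_floor)] <- value_floor
  }
  structure(list(datasets = datasets, params0 = params0, variant = variant,
                 free = free, weights = w, value_floor = fl,
                 bounds = bounds),
            class = "by2_fit_problem")
}

#' Weighted least-squares objective
#'
#' `Q(theta) = sum over experiments, times, responses of
#' w_r * (1 - g_r(theta) / y_obs)^2`, with observations below the
#' response's value floor excluded. A simulation failure at `theta` returns
#' a large finite penalty (1e10) rather than an error, so optimizers can
#' step past pathological parameter combinations.
#'
#' @param params `by2_params` object to evaluate.
#' @param problem [fit_problem()].
#' @param solver [solver_options()].
#' @return Scalar `Q >= 0` (attribute `"penalized"` set when simulation
#'   failed).
#' @export
objective_value <- function(params, problem, solver = solver_options()) {
  Q <- 0
  for (d in problem$datasets) {
    times <- sort(unique(d$data$time))
    g <- tryCatch(.predict_g(params, d$design, times, solver,
                             responses = unique(d$data$response)),
                  error = function(e) NULL)
    if (is.null(g)) {
      out <- 1e10
      attr(out, "penalized") <- TRUE
      return(out)
    }
    idx <- match(d$data$time, times)
    gv <- g[cbind(idx, match(d$data$response, colnames(g)))]
    keep <- d$data$value >= problem$value_floor[d$data$response]
    wv <- problem$weights[d$data$response]
    Q <- Q + sum(wv[keep] * (1 - gv[keep] / d$data$value[keep])^2)
  }
  Q
}

# --- free-vector <-> params mapping with KI >= K handled by shift ----------
# For a free inhibition constant whose saturation partner is also free, the
# optimizer works on the shift d = KI - K >= 0 (box [0, max_KI]); KI is then
# capped at its own upper bound. If only one of the pair is free, the
# partner's fixed value tightens the free one's box directly.
.vec_spec <- function(problem) {
  b <- problem$bounds
  pairs <- .KI_PAIRS[[problem$variant]]
  spec <- lapply(problem$free, function(nm) {
    lo <- b$min[b$name == nm]; hi <- b$max[b$name == nm]
    kind <- "plain"
    if (nm %in% names(pairs)) {                 # an inhibition constant
      partner <- pairs[[nm]]
      if (partner %in% problem$free) {
        kind <- "shift"; lo <- 0
      } else {
        lo <- max(lo, problem$params0[[partner]])
      }
    } else if (nm %in% pairs) {                 # a saturation constant
      ki <- names(pairs)[pairs == nm]
      if (!ki %in% problem$free) hi <- min(hi, problem$params0[[ki]])
    }
    list(name = nm, lower = lo, upper = hi, kind = kind)
  })
  names(spec) <- problem$free
  spec
}

.vec_to_params <- function(v, problem, spec) {
  p <- problem$params0
  pairs <- .KI_PAIRS[[problem$variant]]
  for (i in seq_along(spec)) {
    if (spec[[i]]$kind == "plain") p[[spec[[i]]$name]] <- unname(v[i])
  }
  for (i in seq_along(spec)) {
    if (spec[[i]]$kind == "shift") {
      nm <- spec[[i]]$name
      cap <- problem$bounds$max[problem$bounds$name == nm]
      p[[nm]] <- unname(min(p[[pairs[[nm]]]] + v[i], cap))
    }
  }
  class(p) <- class(problem$params0)
  p
}

.params_to_vec <- function(params, problem, spec) {
  pairs <- .KI_PAIRS[[problem$variant]]
  vapply(spec, function(s) {
    if (s$kind == "shift") {
      max(params[[s$name]] - params[[pairs[[s$name]]]], 0)
    } else {
      params[[s$name]]
    }
  }, numeric(1))
}

#' Fit a model by multistart bound-constrained least squares
#'
#' Minimizes [objective_value()] over the free parameters with `L-BFGS-B`
#' from `n_starts` Latin-hypercube starting points inside the bounds (plus
#' the baseline `params0` as an extra start). The `KI >= K` inequality of
#' every saturation/inhibition pair is built into the parameterization.
#'
#' @param problem [fit_problem()].
#' @param n_starts Number of Latin-hypercube starts (default 16; the
#'   objective is nonconvex).
#' @param seed Seed for the start design.
#' @param control Passed to [stats::optim()] (default `maxit = 200`).
#' @param solver [solver_options()].
#' @param diagnostics Compute the baseline objective and residual table
#'   (default `TRUE`; refits inside resampling loops skip them).
#' @return Object of class `by2_fit`: `params` (best fit), `Q`,
#'   `residuals` (per-observation table with predictions and measurement
#'   sigma), `starts` (per-start diagnostics), `constraint_active` (which
#'   KI sit on their K within 1%), `convergence`.
#' @export
fit_model <- function(problem, n_starts = 16, seed = 1,
                      control = list(maxit = 200),
                      solver = solver_options(), diagnostics = TRUE) {
  stopifnot(inherits(problem, "by2_fit_problem"))
  spec <- .vec_spec(problem)
  lower <- vapply(spec, `[[`, numeric(1), "lower")
  upper <- vapply(spec, `[[`, numeric(1), "upper")
  rng <- upper - lower
  act <- rng > 1e-12   # components with collapsed bounds are pinned
  # optimize in range-normalized coordinates so the finite-difference step
  # is relative to each parameter's identification range
  to_v <- function(z) {
    v <- lower
    v[act] <- lower[act] + z * rng[act]
    v
  }
  fn <- function(z) as.numeric(objective_value(
    .vec_to_params(to_v(z), problem, spec), problem, solver))
  ctl <- utils::modifyList(list(maxit = 200, factr = 1e7), control)
  ctl$ndeps <- rep(ctl$ndeps %||% 1e-6, sum(act))
  set.seed(seed)
  v0 <- pmin(pmax(.params_to_vec(problem$params0, problem, spec),
                  lower), upper)
  starts <- list(((v0 - lower) / ifelse(act, rng, 1))[act])
  if (n_starts > 1 && sum(act) > 0) {
    u <- lhs::randomLHS(n_starts - 1, sum(act))
    for (i in seq_len(nrow(u))) starts[[i + 1]] <- u[i, ]
  }
  runs <- lapply(starts, function(z0) {
    if (length(z0) == 0) {
      return(list(value = fn(numeric(0)), par = numeric(0),
                  convergence = 0L))
    }
    z0 <- pmin(pmax(z0, 0), 1)
    tryCatch(
      if (length(z0) == 1L) {
        # scalar problems: derivative-free bracketing beats FD gradients
        o <- stats::optim(z0, fn, method = "Brent", lower = 0, upper = 1,
                          control = list(reltol = ctl$reltol %||% 1e-9))
        s0 <- fn(z0)
        if (s0 < o$value) o <- list(par = z0, value = s0, convergence = 0L)
        o
      } else {
        stats::optim(z0, fn, method = "L-BFGS-B",
                     lower = rep(0, length(z0)), upper = rep(1, length(z0)),
                     control = ctl)
      },
      error = function(e) list(value = Inf, par = z0, convergence = -1L,
                               message = conditionMessage(e))
    )
  })
  vals <- vapply(runs, `[[`, numeric(1), "value")
  if (all(!is.finite(vals))) {
    stop("all optimization starts failed; per-start messages: ",
         paste(vapply(runs, function(r) r$message %||% "", ""), collapse = "; "))
  }
  best <- runs[[which.min(vals)]]
  pstar <- .vec_to_params(to_v(best$par), problem, spec)
  Q0 <- if (diagnostics) {
    as.numeric(objective_value(problem$params0, problem, solver))
  } else {
    NA_real_
  }
  resid <- if (diagnostics) .residual_table(pstar, problem, solver) else NULL
  pairs <- .KI_PAIRS[[problem$variant]]
  act <- vapply(names(pairs), function(ki) {
    k0 <- pstar[[pairs[[ki]]]]
    k0 > 0 && (pstar[[ki]] - k0) <= 0.01 * k0 + 1e-12
  }, logical(1))
  structure(list(params = pstar, Q = min(vals), Q_start = Q0,
                 residuals = resid,
                 starts = data.frame(start = seq_along(runs), Q = vals,
                                     convergence = vapply(runs, `[[`,
                                                          numeric(1),
                                                          "convergence")),
                 constraint_active = act,
                 convergence = best$convergence,
                 problem = problem),
            class = "by2_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.residual_table <- function(params, problem, solver) {
  do.call(rbind, lapply(problem$datasets, function(d) {
    times <- sort(unique(d$data$time))
    g <- .predict_g(params, d$design, times, solver,
                    responses = unique(d$data$response))
    gv <- g[cbind(match(d$data$time, times),
                  match(d$data$response, colnames(g)))]
    data.frame(experiment = d$label, time = d$data$time,
               response = d$data$response, y = d$data$value, g = gv,
               sigma = d$noise$u0[d$data$response] +
                 d$noise$upct[d$data$response] * d$data$value)
  }))
}

#' @export
print.by2_fit <- function(x, ...) {
  cat("by2_fit (", x$problem$variant, " model): Q = ",
      format(x$Q, digits = 6), " over ", nrow(x$residuals),
      " observations\n", sep = "")
  print(unlist(x$params[x$problem$free]))
  invisible(x)
}

#' Measurement-error matrix
#'
#' Per-observation measurement uncertainty `sigma = u0_r + upct_r * y`,
#' built from the uncertainty pair each dataset carries.
#'
#' @param datasets A [ts_dataset()] or list thereof.
#' @return `data.frame` with columns `experiment`, `time`, `response`, `y`,
#'   `sigma`.
#' @export
error_matrix <- function(datasets) {
  if (inherits(datasets, "by2_dataset")) datasets <- list(datasets)
  do.call(rbind, lapply(datasets, function(d) {
    data.frame(experiment = d$label, time = d$data$time,
               response = d$data$response, y = d$data$value,
               sigma = d$noise$u0[d$data$response] +
                 d$noise$upct[d$data$response] * d$data$value)
  }))
}

#' Residual-bootstrap confidence intervals
#'
#' Non-parametric bootstrap on the measurement-error scale, built from the
#' error matrix of per-observation uncertainties `sigma = u0 + upct * y`.
#' With `resample = "residual"` (default) the observed residuals are
#' standardized by their `sigma`, resampled with replacement within each
#' response, rescaled by the local `sigma`, and added back onto the model
#' predictions `g(theta*)`; this respects the strong heteroscedasticity of
#' proportional assay errors. `resample = "uncertainty"` instead resamples
#' the `sigma` magnitudes themselves and attaches them with random signs
#' (a coarser scheme that transplants the error scale across the
#' trajectory). Each synthetic dataset is refitted and the percentile
#' interval of the refitted parameters gives the CI (90% by default).
#' Deterministic under a fixed seed.
#'
#' @param fit A [fit_model()] result.
#' @param n_boot Number of bootstrap resamples (study-scale choice ~1000;
#'   use less for quick checks).
#' @param level CI level (default 0.9).
#' @param seed Integer seed.
#' @param n_starts Starts per refit (default 1, starting at `theta*`).
#' @param resample Resampling scheme, see above.
#' @param control,solver Passed to the refits.
#' @return `data.frame` with columns `parameter`, `estimate`, `lower`,
#'   `upper`, `half_width`; attributes `n_effective` (successful refits)
#'   and `level`.
#' @export
bootstrap_ci <- function(fit, n_boot = 1000, level = 0.9, seed = 1,
                         n_starts = 1,
                         resample = c("residual", "uncertainty"),
                         control = list(maxit = 200),
                         solver = solver_options()) {
  stopifnot(inherits(fit, "by2_fit"))
  resample <- match.arg(resample)
  problem <- fit$problem
  res <- fit$residuals
  set.seed(seed)
  draws <- vector("list", n_boot)
  for (b in seq_len(n_boot)) {
    synth <- res
    for (r in unique(res$response)) {
      i <- which(res$response == r)
      pick <- sample.int(length(i), length(i), replace = TRUE)
      if (resample == "residual") {
        e_std <- ifelse(res$sigma[i] > 0,
                        (res$y[i] - res$g[i]) / res$sigma[i], 0)
        # small-sample leverage correction: fitted residuals underestimate
        # the error scale by roughly sqrt((n - p) / n)
        infl <- sqrt(length(i) / max(length(i) - length(problem$free), 1))
        synth$y[i] <- pmax(0, res$g[i] + infl * e_std[pick] * res$sigma[i])
      } else {
        sig <- res$sigma[i][pick]
        sgn <- sample(c(-1, 1), length(i), replace = TRUE)
        synth$y[i] <- pmax(0, res$g[i] + sgn * sig)
      }
    }
    boot_ds <- lapply(problem$datasets, function(d) {
      rows <- synth[synth$experiment == d$label, ]
      ts_dataset(d$label,
                 data.frame(time = rows$time, response = rows$response,
                            value = rows$y),
                 noise = d$noise, design = d$design)
    })
    bp <- problem
    bp$datasets <- boot_ds
    refit <- tryCatch(
      fit_model(bp, n_starts = n_starts, seed = seed + b,
                control = control, solver = solver, diagnostics = FALSE),
      error = function(e) NULL
    )
    if (!is.null(refit)) {
      draws[[b]] <- unlist(refit$params[problem$free])
    }
  }
  ok <- !vapply(draws, is.null, logical(1))
  if (mean(ok) < 0.8) {
    warning("bootstrap refit failure rate above 20%: effective n = ",
            sum(ok), " of ", n_boot)
  }
  mat <- do.call(rbind, draws[ok])
  a <- (1 - level) / 2
  ci <- t(apply(mat, 2, stats::quantile, probs = c(a, 1 - a), names = FALSE))
  out <- data.frame(parameter = problem$free,
                    estimate = unlist(fit$params[problem$free]),
                    lower = ci[, 1], upper = ci[, 2])
  out$half_width <- (out$upper - out$lower) / 2
  rownames(out) <- NULL
  attr(out, "n_effective") <- sum(ok)
  attr(out, "level") <- level
  out
}

#' Mean absolute error of a fitted model on one dataset
#'
#' `MAE = mean |y - g(theta)|` over the observations of one response;
#' `nmae()` normalizes by the grand mean of that response over a
#' normalization set of datasets; [mae_subset()] pools observations across
#' several datasets.
#'
#' @param params `by2_params` object.
#' @param dataset A [ts_dataset()].
#' @param response One of `X, S, F, G, A, N, P`.
#' @param obs_filter Optional predicate on the observation table (columns
#'   `time`, `response`, `value`) restricting which observations count,
#'   e.g. `function(d) d$value > 8` for the high-density dry-mass regime.
#' @param solver [solver_options()].
#' @return Scalar MAE in the response's units.
#' @export
mae <- function(params, dataset, response, obs_filter = NULL,
                solver = solver_options()) {
  mae_subset(params, list(dataset), response, obs_filter, solver)
}

#' @rdname mae
#' @param datasets List of [ts_dataset()] objects whose observations are
#'   pooled.
#' @export
mae_subset <- function(params, datasets, response, obs_filter = NULL,
                       solver = solver_options()) {
  if (inherits(datasets, "by2_dataset")) datasets <- list(datasets)
  errs <- unlist(lapply(datasets, function(d) {
    rows <- d$data[d$data$response == response, ]
    if (!is.null(obs_filter)) rows <- rows[obs_filter(rows), ]
    if (nrow(rows) == 0) return(numeric(0))
    g <- .predict_g(params, d$design, rows$time, solver,
                    responses = response)[, response]
    abs(rows$value - g)
  }))
  if (length(errs) == 0) {
    stop("no observations of response '", response, "' after filtering")
  }
  mean(errs)
}

#' Grand mean of a response over a normalization set
#'
#' @param datasets List of [ts_dataset()] objects.
#' @param response Response id.
#' @return Mean measured value pooled over all observations.
#' @export
grand_mean <- function(datasets, response) {
  if (inherits(datasets, "by2_dataset")) datasets <- list(datasets)
  vals <- unlist(lapply(datasets, function(d) {
    d$data$value[d$data$response == response]
  }))
  if (!length(vals)) stop("no observations of response '", response, "'")
  mean(vals)
}

#' @rdname mae
#' @param norm_set Datasets defining the normalization grand mean
#'   (defaults to `dataset` itself).
#' @export
nmae <- function(params, dataset, response, norm_set = NULL,
                 obs_filter = NULL, solver = solver_options()) {
  if (is.null(norm_set)) norm_set <- list(dataset)
  mae(params, dataset, response, obs_filter, solver) /
    grand_mean(norm_set, response)
}
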