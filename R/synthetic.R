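# Synthetic-study generator: simulated trajectories sampled on an offline
# grid and perturbed with the constant-plus-proportional measurement-error
# structure of the dry-mass and nutrient assays.

RESPONSES <- c("X", "S", "F", "G", "A", "N", "P")

#' Measurement-noise specification
#'
#' Per-response constant (`u0`, response units) and proportional (`upct`,
#' fraction) uncertainty components. The standard deviation of a
#' measurement of true value `g` is `u0 + upct * g`. Defaults: no constant
#' component, 3% proportional for dry mass and 6% for every nutrient.
#'
#' @param u0 Named numeric over (a subset of) `X, S, F, G, A, N, P`.
#' @param upct Named numeric, same names, proportional fractions in [0, 1).
#' @return Object of class `by2_noise_spec` (list of two full named vectors).
#' @export
noise_spec <- function(u0 = NULL, upct = NULL) {
  base_u0 <- stats::setNames(rep(0, length(RESPONSES)), RESPONSES)
  base_up <- c(X = 0.03, S = 0.06, F = 0.06, G = 0.06,
               A = 0.06, N = 0.06, P = 0.06)
  if (!is.null(u0)) {
    stopifnot(all(names(u0) %in% RESPONSES))
    base_u0[names(u0)] <- u0
  }
  if (!is.null(upct)) {
    stopifnot(all(names(upct) %in% RESPONSES))
    base_up[names(upct)] <- upct
  }
  if (any(base_u0 < 0)) stop("u0 components must be non-negative")
  if (any(base_up < 0) || any(base_up >= 1)) stop("upct must lie in [0, 1)")
  structure(list(u0 = base_u0, upct = base_up), class = "by2_noise_spec")
}

#' In-study experiment presets
#'
#' The nine batch-start designs of the study: runs 1-3 (standard
#' conditions, 88 mM sucrose), 4-5 (Pareto-optimal, 67 mM), 6-7
#' (non-optimal comparators) and 8-9 (fructose or glucose as sole carbon
#' source, 151 mM). All share 21 mM ammonium, 39 mM nitrate and 2.7 mM
#' phosphate, with no initial dead mass.
#'
#' @return `data.frame` with columns `id`, `X0_gL`, `S0_mM`, `F0_mM`,
#'   `G0_mM`, `A0_mM`, `N0_mM`, `P0_mM`.
#' @export
study_presets <- function() {
  data.frame(
    id    = 1:9,
    X0_gL = c(0.68, 0.58, 1.00, 0.80, 0.56, 0.92, 1.25, 0.75, 0.75),
    S0_mM = c(88, 88, 88, 67, 67, 47, 87, 0, 0),
    F0_mM = c(0, 0, 0, 0, 0, 0, 0, 151, 0),
    G0_mM = c(0, 0, 0, 0, 0, 0, 0, 0, 151),
    A0_mM = 21, N0_mM = 39, P0_mM = 2.7
  )
}

#' Build an experiment design from a study preset
#'
#' @param id Preset id, 1-9 (see [study_presets()]).
#' @param duration Batch duration [h] (default 144 h: sucrose is depleted
#'   within about six days under these conditions).
#' @param sampling_times Offline sampling grid (default every 24 h).
#' @param V Working volume [L].
#' @param mm Molar mass table for the mM -> g/L conversion.
#' @return [experiment_design()] object (batch only).
#' @export
preset_design <- function(id, duration = 144,
                          sampling_times = seq(0, duration, by = 24),
                          V = 2, mm = molar_masses()) {
  pr <- study_presets()
  if (!id %in% pr$id) stop("unknown preset id: ", id)
  pr <- pr[pr$id == id, ]
  st <- process_state(V = V, Xa = pr$X0_gL, Xd = 0,
                      S = to_internal(pr$S0_mM, "S", mm),
                      F = to_internal(pr$F0_mM, "F", mm),
                      G = to_internal(pr$G0_mM, "G", mm),
                      A = to_internal(pr$A0_mM, "A", mm),
                      N = to_internal(pr$N0_mM, "N", mm),
                      P = to_internal(pr$P0_mM, "P", mm))
  experiment_design(label = paste0("preset_", id), state0 = st,
                    duration = duration, sampling_times = sampling_times)
}

#' Construct a measurement dataset
#'
#' Tidy long-format container for measured (or synthetic) offline data:
#' one row per (time, response) with values on the internal g/L scale (dry
#' mass included). The noise specification travels with the data so that
#' calibration can reconstruct the error matrix.
#'
#' @param label Experiment label.
#' @param data `data.frame` with columns `time`, `response`, `value`.
#' @param noise [noise_spec()].
#' @param design Optional [experiment_design()] the data belong to.
#' @return Object of class `by2_dataset`.
#' @export
ts_dataset <- function(label, data, noise = noise_spec(), design = NULL) {
  stopifnot(all(c("time", "response", "value") %in% names(data)))
  if (!all(data$response %in% RESPONSES)) {
    stop("unknown response(s): ",
         paste(setdiff(unique(data$response), RESPONSES), collapse = ", "))
  }
  if (any(data$value < 0)) stop("measured values must be non-negative")
  data <- data[order(data$response, data$time),
               c("time", "response", "value")]
  rownames(data) <- NULL
  structure(list(label = label, data = data, noise = noise, design = design),
            class = "by2_dataset")
}

#' @export
print.by2_dataset <- function(x, ...) {
  cat("by2_dataset:", x$label, "|", nrow(x$data), "observations,",
      length(unique(x$data$response)), "responses\n")
  invisible(x)
}

#' Generate one synthetic dataset from a model
#'
#' Simulates the design at `params`, samples the trajectory at the design's
#' sampling times, and perturbs each value with zero-truncated Gaussian
#' noise of standard deviation `u0 + upct * g` (the assay uncertainty
#' structure; the truncation keeps concentrations physical). With a fixed
#' seed the output is reproducible.
#'
#' @param design [experiment_design()].
#' @param params True kinetic parameters used to generate the data.
#' @param noise [noise_spec()].
#' @param seed Integer seed (optional; caller-managed RNG if `NULL`).
#' @param responses Responses to include (default all seven).
#' @param solver [solver_options()].
#' @return A [ts_dataset()] object.
#' @export
generate_dataset <- function(design, params, noise = noise_spec(),
                             seed = NULL, responses = RESPONSES,
                             solver = solver_options()) {
  if (!is.null(seed)) set.seed(seed)
  traj <- simulate_culture(design, params, solver)
  sm <- interpolate_trajectory(traj, design$sampling_times)
  g <- cbind(X = sm[, "Xa"] + sm[, "Xd"],
             sm[, c("S", "F", "G", "A", "N", "P")])
  rows <- do.call(rbind, lapply(responses, function(r) {
    gv <- g[, r]
    sdv <- noise$u0[[r]] + noise$upct[[r]] * gv
    y <- pmax(0, gv + stats::rnorm(length(gv), 0, sdv))
    data.frame(time = design$sampling_times, response = r, value = y)
  }))
  ts_dataset(design$label, rows, noise = noise, design = design)
}

#' Generate a multi-experiment synthetic study
#'
#' @param ids Preset ids (see [study_presets()]).
#' @param params True kinetic parameters. For the improved model the growth
#'   offsets are re-derived per design (10% of its starting ammonium and
#'   phosphate).
#' @param noise [noise_spec()].
#' @param seed Integer seed; experiment k uses `seed + k` so studies are
#'   reproducible element-wise.
#' @param solver [solver_options()] for the generating simulations.
#' @param ... Passed to [preset_design()].
#' @return Named list of [ts_dataset()] objects.
#' @export
make_study <- function(ids, params, noise = noise_spec(), seed = 1,
                       solver = solver_options(), ...) {
  out <- lapply(ids, function(id) {
    des <- preset_design(id, ...)
    p <- params
    if (inherits(p, "by2_params_improved")) {
      p <- with_growth_offsets(p, des$state0)
    }
    generate_dataset(des, p, noise = noise, seed = seed + id, solver = solver)
  })
  names(out) <- paste0("preset_", ids)
  out
}
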