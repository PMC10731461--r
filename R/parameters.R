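# Kinetic parameter containers for the two model variants. Both are plain
# named lists with a class attribute; constructors validate non-negativity,
# the KI >= K saturation/inhibition ordering, and the identification bounds.

.BOUNDS_INITIAL <- data.frame(
  name = c("kd", "mum", "KS", "KIS", "KA", "KIA", "KN", "KIN",
           "muS", "muA", "muN", "muP"),
  min  = 0,
  max  = c(0.1, 10, 100, 100, 1, 1, 5, 5, 1, 1, 1, 1),
  stringsAsFactors = FALSE
)

.BOUNDS_IMPROVED <- data.frame(
  name = c("kd", "mum", "mumA", "mumP",
           "KS", "KIS", "KA", "KIA", "KN", "KIN", "KF", "KIF", "KG", "KIG",
           "alpha", "muA", "muN", "muF", "muG", "muP"),
  min  = 0,
  max  = c(0.01, 10, 10, 10,
           100, 100, 1, 1, 5, 5, 30, 30, 30, 30,
           1, 1, 1, 1, 1, 1),
  stringsAsFactors = FALSE
)

# inhibition constant -> matching saturation constant, per variant
.KI_PAIRS <- list(
  initial  = c(KIS = "KS", KIA = "KA", KIN = "KN"),
  improved = c(KIS = "KS", KIA = "KA", KIN = "KN", KIF = "KF", KIG = "KG")
)

#' Identification bounds for a model variant
#'
#' Box bounds for every fitted parameter of the chosen variant. Saturation
#' and inhibition constants are in g L^-1, all rates in h^-1.
#'
#' @param model `"initial"` or `"improved"`.
#' @return `data.frame` with columns `name`, `min`, `max`.
#' @export
param_bounds <- function(model = c("initial", "improved")) {
  model <- match.arg(model)
  if (model == "initial") .BOUNDS_INITIAL else .BOUNDS_IMPROVED
}

.check_params <- function(p, model, check_bounds) {
  bounds <- param_bounds(model)
  vals <- unlist(p[bounds$name])
  if (any(!is.finite(vals))) stop("kinetic parameters must be finite")
  if (any(vals < 0)) stop("kinetic parameters must be non-negative")
  if (check_bounds) {
    lo <- vals < bounds$min - 1e-12
    hi <- vals > bounds$max + 1e-12
    if (any(lo | hi)) {
      stop("parameter(s) outside identification bounds: ",
           paste(bounds$name[lo | hi], collapse = ", "))
    }
  }
  pairs <- .KI_PAIRS[[model]]
  for (ki in names(pairs)) {
    if (p[[ki]] < p[[pairs[[ki]]]] - 1e-9) {
      stop(ki, " must be >= ", pairs[[ki]],
           " (inhibition constant below saturation constant)")
    }
  }
  invisible(p)
}

#' Kinetic parameters of the initial (sucrose-driven) model
#'
#' The 12 identifiable parameters of the initial model: death rate `kd`,
#' maximum specific growth rate `mum` [h^-1], saturation/inhibition constant
#' pairs for sucrose, ammonium and nitrate [g L^-1], and consumption rates
#' `muS`, `muA`, `muN`, `muP` [h^-1]. Phosphate has no Monod factor in this
#' model: it is consumed but does not modulate growth.
#'
#' @param kd,mum,KS,KIS,KA,KIA,KN,KIN,muS,muA,muN,muP Scalars, see above.
#' @param check_bounds Validate against [param_bounds()] (default `TRUE`).
#' @return Object of class `by2_params_initial`.
#' @export
params_initial <- function(kd, mum, KS, KIS, KA, KIA, KN, KIN,
                           muS, muA, muN, muP, check_bounds = TRUE) {
  p <- list(kd = kd, mum = mum, KS = KS, KIS = KIS, KA = KA, KIA = KIA,
            KN = KN, KIN = KIN, muS = muS, muA = muA, muN = muN, muP = muP)
  .check_params(p, "initial", check_bounds)
  structure(p, class = c("by2_params_initial", "by2_params"))
}

#' Kinetic parameters of the improved (hydrolysis) model
#'
#' The 20 identifiable parameters of the improved model, which adds external
#' sucrose hydrolysis into fructose and glucose (rate constant `alpha`),
#' Monod factors for the two hexoses, and additive ammonium/phosphate
#' contributions to the maximum specific growth rate (`mumA`, `mumP`). Two
#' quantities are fixed, never fitted: the hexose mass yields `mSF = mSG =
#' 0.526` g g^-1 (stoichiometry of sucrose hydrolysis) and the growth
#' offsets `deltaA`, `deltaP` [g L^-1], interpretable as the minimal
#' ammonium/phosphate level supporting growth, set to 10% of the starting
#' concentrations of the design being modelled (see [with_growth_offsets()]).
#'
#' @param kd,mum,mumA,mumP,KS,KIS,KA,KIA,KN,KIN,KF,KIF,KG,KIG,alpha,muA,muN,muF,muG,muP
#'   Scalars; rates in h^-1, K constants in g L^-1.
#' @param deltaA,deltaP Growth offsets [g L^-1], must be > 0.
#' @param mSF,mSG Hexose mass yields, fixed at 0.526 by default.
#' @param check_bounds Validate fitted entries against [param_bounds()].
#' @return Object of class `by2_params_improved`.
#' @export
params_improved <- function(kd, mum, mumA, mumP,
                            KS, KIS, KA, KIA, KN, KIN, KF, KIF, KG, KIG,
                            alpha, muA, muN, muF, muG, muP,
                            deltaA, deltaP, mSF = 0.526, mSG = 0.526,
                            check_bounds = TRUE) {
  p <- list(kd = kd, mum = mum, mumA = mumA, mumP = mumP,
            KS = KS, KIS = KIS, KA = KA, KIA = KIA, KN = KN, KIN = KIN,
            KF = KF, KIF = KIF, KG = KG, KIG = KIG,
            alpha = alpha, muA = muA, muN = muN, muF = muF, muG = muG,
            muP = muP, deltaA = deltaA, deltaP = deltaP,
            mSF = mSF, mSG = mSG)
  if (deltaA <= 0 || deltaP <= 0) stop("deltaA and deltaP must be positive")
  if (mSF < 0 || mSG < 0) stop("hexose yields must be non-negative")
  .check_params(p, "improved", check_bounds)
  structure(p, class = c("by2_params_improved", "by2_params"))
}

#' Set the growth offsets of an improved-model parameter set from a design
#'
#' `deltaA` and `deltaP` are defined as 10% of the starting ammonium and
#' phosphate concentrations of the experiment being modelled; this helper
#' stamps them onto an existing parameter object.
#'
#' @param params A `by2_params_improved` object.
#' @param state0 Initial process state (named vector with `A` and `P` in
#'   g L^-1), e.g. from [process_state()].
#' @param fraction Offset fraction of the starting concentration (0.1).
#' @return Updated parameter object.
#' @export
with_growth_offsets <- function(params, state0, fraction = 0.1) {
  stopifnot(inherits(params, "by2_params_improved"))
  params$deltaA <- fraction * state0[["A"]]
  params$deltaP <- fraction * state0[["P"]]
  if (params$deltaA <= 0 || params$deltaP <= 0) {
    stop("starting ammonium/phosphate must be positive to set growth offsets")
  }
  params
}

#' Reference identified parameter values, initial model
#'
#' The identified optimum of the initial model (weighted least squares on
#' the three standard-condition 5-L runs).
#'
#' @return `by2_params_initial` object.
#' @export
ref_params_initial <- function() {
  params_initial(
    kd = 6.62e-4, mum = 9.47,
    KS = 17.64, KIS = 17.64,
    KA = 0.796, KIA = 0.797,
    KN = 0.133, KIN = 0.135,
    muS = 2.235e-1, muA = 4.863e-3, muN = 3.013e-2, muP = 2.883e-2
  )
}

#' Reference identified parameter values, improved model
#'
#' The identified optimum of the improved (hydrolysis) model. Growth
#' offsets default to 10% of the standard MS-medium start (21 mM ammonium,
#' 2.7 mM phosphate); pass a design's own start through
#' [with_growth_offsets()] when modelling other media.
#'
#' @param deltaA,deltaP Growth offsets [g L^-1].
#' @return `by2_params_improved` object.
#' @export
ref_params_improved <- function(deltaA = 0.1 * to_internal(21, "A"),
                                deltaP = 0.1 * to_internal(2.7, "P")) {
  params_improved(
    kd = 5.44e-4, mum = 0.162, mumA = 0.578, mumP = 2.1e-5,
    KS = 72.53, KIS = 100.0,
    KA = 0.221, KIA = 0.221,
    KN = 0.835, KIN = 1.0,
    KF = 1.108, KIF = 1.404,
    KG = 18.0, KIG = 18.0,
    alpha = 0.396,
    muA = 6.9e-3, muN = 1.71e-2, muF = 8.34e-2, muG = 0.273, muP = 2.68e-2,
    deltaA = deltaA, deltaP = deltaP
  )
}

#' Model variant of a parameter object
#' @param params A `by2_params` object.
#' @return `"initial"` or `"improved"`.
#' @export
model_variant <- function(params) {
  if (inherits(params, "by2_params_initial")) return("initial")
  if (inherits(params, "by2_params_improved")) return("improved")
  stop("not a by2_params object")
}

#' @export
print.by2_params <- function(x, ...) {
  cat("Kinetic parameters (", model_variant(x), " model)\n", sep = "")
  nm <- param_bounds(model_variant(x))$name
  print(unlist(x[nm]))
  extra <- setdiff(names(x), nm)
  if (length(extra)) {
    cat("fixed:\n")
    print(unlist(x[extra]))
  }
  invisible(x)
}
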