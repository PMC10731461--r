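# Growth-rate kernels and ODE right-hand sides for both model variants.
#
# State vector convention (all concentrations in g L^-1):
#   V  broth volume [L]
#   Xa active dry mass, Xd dead dry mass
#   S sucrose, F fructose, G glucose, A ammonium, N nitrate, P phosphate
#
# The balances are written as d(C V)/dt = feed - consumption, so with
# dV/dt = Ft the concentration derivative is
#   dC/dt = Ft (Cf - C) / V - (consumption rate per volume).

STATE_NAMES <- c("V", "Xa", "Xd", "S", "F", "G", "A", "N", "P")

#' Construct a process state
#'
#' Instantaneous reactor state. Nutrients are given on the internal g L^-1
#' scale; use [to_internal()] to convert from mM. Total dry mass is
#' `X = Xa + Xd`.
#'
#' @param V Broth volume [L], > 0.
#' @param Xa Active dry mass [g/L], >= 0.
#' @param Xd Dead dry mass [g/L], >= 0 (0 at inoculation).
#' @param S,F,G,A,N,P Nutrient concentrations [g/L], >= 0.
#' @return Named numeric vector over `V, Xa, Xd, S, F, G, A, N, P`.
#' @examples
#' # standard MS-medium batch start at 0.75 g/L dry mass in 2 L
#' process_state(V = 2, Xa = 0.75,
#'               S = to_internal(88, "S"), A = to_internal(21, "A"),
#'               N = to_internal(39, "N"), P = to_internal(2.7, "P"))
#' @export
process_state <- function(V, Xa, Xd = 0, S = 0, F = 0, G = 0,
                          A = 0, N = 0, P = 0) {
  st <- c(V = V, Xa = Xa, Xd = Xd, S = S, F = F, G = G, A = A, N = N, P = P)
  if (!all(is.finite(st))) stop("process state must be finite")
  if (V <= 0) stop("volume must be positive")
  if (any(st[-1] < 0)) stop("state components must be non-negative")
  st
}

#' Monod saturation-inhibition factor
#'
#' The dimensionless kernel `(c/(c+K)) * (KI/(c+KI))` combining substrate
#' saturation with high-concentration inhibition. When `KI = K` its maximum
#' over `c` is 1/4 (at `c = K`); as `KI -> Inf` it reduces to plain Monod
#' saturation. Concentrations are clamped at zero before evaluation so that
#' small negative integrator excursions cannot produce negative factors.
#'
#' @param c Substrate concentration [g/L] (vectorised).
#' @param K Saturation constant [g/L].
#' @param KI Inhibition constant [g/L], `KI >= K` by convention.
#' @return Factor in `[0, 1]`.
#' @export
monod_factor <- function(c, K, KI) {
  if (any(c < 0) || K < 0 || KI < 0) {
    stop("monod_factor: negative input")
  }
  if (K == 0 && any(c == 0)) stop("monod_factor: c and K both zero")
  cc <- pmax(c, 0)
  (cc / (cc + K)) * (KI / (cc + KI))
}

# internal, clamping variant used inside the RHS (no error on tiny
# negatives; takes the K -> 0 limit value 1 for the saturation part when
# both c and K vanish)
.monod <- function(c, K, KI) {
  cc <- max(c, 0)
  if (cc + K <= 0) return(KI / (cc + KI))
  (cc / (cc + K)) * (KI / (cc + KI))
}

#' Specific growth rate, initial model
#'
#' `mu = mum * f(S) * f(A) * f(N)` with `f` the Monod saturation-inhibition
#' factor of each nutrient. Phosphate is deliberately absent: it is depleted
#' early in the batch and a multiplicative phosphate factor would wrongly
#' zero the growth from then on.
#'
#' @param state Named state vector, see [process_state()].
#' @param params `by2_params_initial` object.
#' @return Specific growth rate [h^-1].
#' @export
growth_rate_initial <- function(state, params) {
  p <- params
  p$mum *
    .monod(state[["S"]], p$KS, p$KIS) *
    .monod(state[["A"]], p$KA, p$KIA) *
    .monod(state[["N"]], p$KN, p$KIN)
}

#' Specific growth rate, improved model
#'
#' The carbon dependence moves from sucrose to its hydrolysis products:
#' `mu = (mum + mumA*A/(A+deltaA) + mumP*P/(P+deltaP)) * (f(G) + f(F)) * f(N)`.
#' Ammonium and phosphate enter as additive terms in the maximum rate so
#' that their depletion attenuates rather than abolishes growth; glucose
#' and fructose contribute an additive pair of Monod factors (no
#' renormalisation, maximum 0.5 when both sit at their K = KI optimum).
#'
#' @param state Named state vector.
#' @param params `by2_params_improved` object (with `deltaA`, `deltaP` set).
#' @return Specific growth rate [h^-1].
#' @export
growth_rate_improved <- function(state, params) {
  p <- params
  A <- max(state[["A"]], 0)
  P <- max(state[["P"]], 0)
  mumax <- p$mum + p$mumA * A / (A + p$deltaA) + p$mumP * P / (P + p$deltaP)
  carbon <- .monod(state[["G"]], p$KG, p$KIG) + .monod(state[["F"]], p$KF, p$KIF)
  mumax * carbon * .monod(state[["N"]], p$KN, p$KIN)
}

#' Time derivative of the process state, initial model
#'
#' Balances: active mass grows at `mu` and dies at `kd`; dead mass
#' accumulates the death flux; both are diluted by feed. Each nutrient is
#' fed at `Ft * Cf` and consumed at its own rate times its own Monod factor
#' times the active mass, except phosphate whose uptake `muP * P` is
#' independent of the biomass (its concentration is near zero for most of
#' the run, where a biomass-proportional term is numerically fragile and
#' adds an unidentifiable parameter).
#'
#' @param state Named state vector (see [process_state()]).
#' @param params `by2_params_initial` object.
#' @param Ft Feed rate [L/h], >= 0.
#' @param feed Feed medium composition, see [medium_composition()].
#' @return Named derivative vector over the state components.
#' @export
rhs_initial <- function(state, params, Ft = 0,
                        feed = medium_composition()) {
  if (any(state[c("Xa", "Xd", "S", "F", "G", "A", "N", "P")] < -1e-8) ||
      state[["V"]] <= 0) {
    stop("rhs_initial: invalid state")
  }
  if (Ft < 0) stop("feed rate must be non-negative")
  p <- params
  V <- state[["V"]]; Xa <- max(state[["Xa"]], 0)
  fS <- .monod(state[["S"]], p$KS, p$KIS)
  fA <- .monod(state[["A"]], p$KA, p$KIA)
  fN <- .monod(state[["N"]], p$KN, p$KIN)
  mu <- p$mum * fS * fA * fN
  dil <- Ft / V
  c(V  = Ft,
    Xa = (mu - p$kd) * Xa - dil * state[["Xa"]],
    Xd = p$kd * Xa - dil * state[["Xd"]],
    S  = dil * (feed[["S"]] - state[["S"]]) - p$muS * fS * Xa,
    F  = dil * (feed[["F"]] - state[["F"]]),
    G  = dil * (feed[["G"]] - state[["G"]]),
    A  = dil * (feed[["A"]] - state[["A"]]) - p$muA * fA * Xa,
    N  = dil * (feed[["N"]] - state[["N"]]) - p$muN * fN * Xa,
    P  = dil * (feed[["P"]] - state[["P"]]) - p$muP * max(state[["P"]], 0))
}

#' Time derivative of the process state, improved model
#'
#' As [rhs_initial()], but sucrose is consumed only by cell-wall invertase
#' hydrolysis (rate `alpha * f(S) * Xa`), each hydrolysed sucrose mass unit
#' yields `mSF` fructose and `mSG` glucose mass units (0.526 each from the
#' hydrolysis stoichiometry), the hexoses are taken up through their own
#' Monod factors, and growth follows [growth_rate_improved()].
#'
#' @inheritParams rhs_initial
#' @param params `by2_params_improved` object.
#' @return Named derivative vector.
#' @export
rhs_improved <- function(state, params, Ft = 0,
                         feed = medium_composition()) {
  if (any(state[c("Xa", "Xd", "S", "F", "G", "A", "N", "P")] < -1e-8) ||
      state[["V"]] <= 0) {
    stop("rhs_improved: invalid state")
  }
  if (Ft < 0) stop("feed rate must be non-negative")
  p <- params
  V <- state[["V"]]; Xa <- max(state[["Xa"]], 0)
  fS <- .monod(state[["S"]], p$KS, p$KIS)
  fF <- .monod(state[["F"]], p$KF, p$KIF)
  fG <- .monod(state[["G"]], p$KG, p$KIG)
  fA <- .monod(state[["A"]], p$KA, p$KIA)
  fN <- .monod(state[["N"]], p$KN, p$KIN)
  A <- max(state[["A"]], 0); P <- max(state[["P"]], 0)
  mumax <- p$mum + p$mumA * A / (A + p$deltaA) + p$mumP * P / (P + p$deltaP)
  mu <- mumax * (fG + fF) * fN
  hyd <- p$alpha * fS * Xa   # sucrose hydrolysis flux [g/L/h]
  dil <- Ft / V
  c(V  = Ft,
    Xa = (mu - p$kd) * Xa - dil * state[["Xa"]],
    Xd = p$kd * Xa - dil * state[["Xd"]],
    S  = dil * (feed[["S"]] - state[["S"]]) - hyd,
    F  = dil * (feed[["F"]] - state[["F"]]) + p$mSF * hyd - p$muF * fF * Xa,
    G  = dil * (feed[["G"]] - state[["G"]]) + p$mSG * hyd - p$muG * fG * Xa,
    A  = dil * (feed[["A"]] - state[["A"]]) - p$muA * fA * Xa,
    N  = dil * (feed[["N"]] - state[["N"]]) - p$muN * fN * Xa,
    P  = dil * (feed[["P"]] - state[["P"]]) - p$muP * P)
}

# dispatch helpers used by the simulator and calibration
.growth_rate <- function(state, params) {
  if (inherits(params, "by2_params_initial")) {
    growth_rate_initial(state, params)
  } else {
    growth_rate_improved(state, params)
  }
}

.rhs <- function(state, params, Ft, feed) {
  if (inherits(params, "by2_params_initial")) {
    rhs_initial(state, params, Ft, feed)
  } else {
    rhs_improved(state, params, Ft, feed)
  }
}
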