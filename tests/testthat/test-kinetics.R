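test_that("monod factor matches direct arithmetic and its bounds", {
  expect_equal(monod_factor(0, 1, 1), 0)
  expect_equal(monod_factor(17.64, 17.64, 17.64), 0.25)
  # frozen from (10/27.64) * (17.64/27.64)
  expect_equal(monod_factor(10, 17.64, 17.64), 0.230899239969758,
               tolerance = 1e-12)
  expect_error(monod_factor(-0.1, 1, 1), "negative")
  expect_error(monod_factor(0, 0, 1), "both zero")
  # bounded by 1 always, by 1/4 when KI = K
  set.seed(42)
  for (i in 1:50) {
    c <- runif(1, 0, 50); K <- runif(1, 0.01, 50); KI <- K + runif(1, 0, 50)
    expect_lte(monod_factor(c, K, KI), 1)
    expect_lte(monod_factor(c, K, K), 0.25 + 1e-12)
    expect_gte(monod_factor(c, K, KI), 0)
  }
})

test_that("initial-model growth rate follows the three-factor product", {
  p <- ref_params_initial()
  st0 <- process_state(V = 2, Xa = 1, S = 0, A = 1, N = 1, P = 0.2)
  expect_equal(growth_rate_initial(st0, p), 0)
  # all three nutrients at their K = KI point: mu = mum / 64
  pk <- params_initial(kd = 0, mum = 2, KS = 3, KIS = 3, KA = 0.5, KIA = 0.5,
                       KN = 0.2, KIN = 0.2, muS = 0, muA = 0, muN = 0,
                       muP = 0)
  stk <- process_state(V = 1, Xa = 1, S = 3, A = 0.5, N = 0.2)
  expect_equal(growth_rate_initial(stk, pk), 2 / 64)
  # reference optimum at the standard MS start, frozen arithmetic oracle
  st <- process_state(V = 2, Xa = 1, S = 30, A = 0.378, N = 2.418, P = 0.25)
  expect_equal(growth_rate_initial(st, p), 0.0241712582360511,
               tolerance = 1e-12)
})

test_that("improved-model growth rate has additive N/P terms and hexose sum", {
  p <- ref_params_improved(deltaA = 0.0378, deltaP = 0.0256)
  st0 <- process_state(V = 2, Xa = 1, S = 10, F = 0, G = 0, A = 1, N = 1,
                       P = 0.2)
  expect_equal(growth_rate_improved(st0, p), 0)
  # frozen arithmetic oracle at the reference optimum, G = F = 15 mM
  st <- process_state(V = 2, Xa = 1, S = 10, F = 2.7024, G = 2.7024,
                      A = 0.378, N = 2.418, P = 0.256)
  expect_equal(growth_rate_improved(st, p), 0.0532210123161539,
               tolerance = 1e-12)
  # with A = P = 0 the additive terms vanish; N at K = KI gives factor 1/4
  p2 <- params_improved(kd = 0, mum = 0.8, mumA = 0.5, mumP = 0.5,
                        KS = 1, KIS = 1, KA = 0.1, KIA = 0.1,
                        KN = 0.5, KIN = 0.5, KF = 2, KIF = 2, KG = 3, KIG = 3,
                        alpha = 0, muA = 0, muN = 0, muF = 0, muG = 0,
                        muP = 0, deltaA = 0.01, deltaP = 0.01)
  st2 <- process_state(V = 1, Xa = 1, F = 1, G = 1, A = 0, N = 0.5, P = 0)
  carbon <- monod_factor(1, 3, 3) + monod_factor(1, 2, 2)
  expect_equal(growth_rate_improved(st2, p2), 0.8 * carbon * 0.25)
  # with mumA = mumP = 0 and F = 0 the carbon structure reduces to the
  # initial model's single-substrate product (glucose in place of sucrose)
  p3 <- p2; p3$mumA <- 0; p3$mumP <- 0
  st3 <- process_state(V = 1, Xa = 1, F = 0, G = 1.7, A = 0.3, N = 0.9)
  expect_equal(growth_rate_improved(st3, p3),
               0.8 * monod_factor(1.7, 3, 3) * monod_factor(0.9, 0.5, 0.5))
})

# independent transcription of the initial-model balances, structured
# differently from the package implementation (total-mass form)
oracle_rhs_initial <- function(st, p, Ft, feed) {
  V <- st[["V"]]
  f <- function(c, K, KI) (c / (c + K)) * (KI / (c + KI))
  mu <- p$mum * f(st[["S"]], p$KS, p$KIS) * f(st[["A"]], p$KA, p$KIA) *
    f(st[["N"]], p$KN, p$KIN)
  dXa <- (mu * st[["Xa"]] * V - p$kd * st[["Xa"]] * V - st[["Xa"]] * Ft) / V
  dXd <- (p$kd * st[["Xa"]] * V - st[["Xd"]] * Ft) / V
  dS <- (Ft * feed[["S"]] - p$muS * f(st[["S"]], p$KS, p$KIS) * st[["Xa"]] * V -
           st[["S"]] * Ft) / V
  dA <- (Ft * feed[["A"]] - p$muA * f(st[["A"]], p$KA, p$KIA) * st[["Xa"]] * V -
           st[["A"]] * Ft) / V
  dN <- (Ft * feed[["N"]] - p$muN * f(st[["N"]], p$KN, p$KIN) * st[["Xa"]] * V -
           st[["N"]] * Ft) / V
  dP <- (Ft * feed[["P"]] - p$muP * st[["P"]] * V - st[["P"]] * Ft) / V
  dF <- (Ft * feed[["F"]] - st[["F"]] * Ft) / V
  dG <- (Ft * feed[["G"]] - st[["G"]] * Ft) / V
  c(V = Ft, Xa = dXa, Xd = dXd, S = dS, F = dF, G = dG, A = dA, N = dN,
    P = dP)
}

test_that("initial-model RHS agrees with an independent transcription", {
  p <- ref_params_initial()
  st <- process_state(V = 1.8, Xa = 2.3, Xd = 0.1, S = 12, F = 0.5, G = 1.1,
                      A = 0.2, N = 1.5, P = 0.05)
  feed <- medium_composition(S = to_internal(59, "S"), A = to_internal(21, "A"),
                             N = to_internal(39, "N"), P = to_internal(2.7, "P"))
  for (Ft in c(0, 0.03)) {
    got <- rhs_initial(st, p, Ft, feed)
    want <- oracle_rhs_initial(st, p, Ft, feed)
    expect_equal(got[names(want)], want, tolerance = 1e-12)
  }
  # no biomass: only phosphate moves in a batch
  st0 <- process_state(V = 2, Xa = 0, S = 10, A = 0.3, N = 2, P = 0.2)
  d <- rhs_initial(st0, p, 0, medium_composition())
  expect_equal(unname(d[c("V", "Xa", "Xd", "S", "A", "N")]), rep(0, 6))
  expect_equal(d[["P"]], -p$muP * 0.2)
  expect_error(rhs_initial(st, p, -1), "non-negative")
})

test_that("improved-model RHS conserves hydrolysis stoichiometry exactly", {
  p <- ref_params_improved()
  # no hexose uptake: every derivative of (F + G) comes from hydrolysis
  p$muF <- 0; p$muG <- 0
  st <- process_state(V = 2, Xa = 3, S = 20, F = 1, G = 2, A = 0.3, N = 2,
                      P = 0.2)
  d <- rhs_improved(st, p, 0, medium_composition())
  expect_equal((d[["F"]] + d[["G"]]) / (-d[["S"]]), p$mSF + p$mSG,
               tolerance = 1e-15)
  expect_equal(p$mSF + p$mSG, 1.052)
  # alpha = 0 removes hydrolysis production entirely
  p0 <- ref_params_improved(); p0$alpha <- 0
  d0 <- rhs_improved(st, p0, 0, medium_composition())
  expect_equal(d0[["S"]], 0)
  expect_lte(d0[["F"]], 0)
  expect_lte(d0[["G"]], 0)
})

test_that("hydrolysis bookkeeping holds along an integrated batch", {
  p <- ref_params_improved()
  p$muF <- 0; p$muG <- 0
  des <- ms_design(X0 = 0.75, duration = 120, sampling = c(0, 120))
  tr <- simulate_culture(des, with_growth_offsets(p, des$state0))
  df <- as.data.frame(tr)
  hexose_made <- (df$F + df$G) - (df$F[1] + df$G[1])
  sucrose_used <- df$S[1] - df$S
  expect_true(max(sucrose_used) > 1)  # the run actually hydrolyses sucrose
  expect_equal(hexose_made, 1.052 * sucrose_used, tolerance = 1e-7)
})

test_that("saturating nutrients give the closed-form exponential limit", {
  p <- saturating_params(mum = 0.05, kd = 0.01)
  des <- experiment_design("exp_limit", saturated_state(Xa = 0.5),
                           duration = 150, sampling_times = c(0, 150))
  tr <- simulate_culture(des, p)
  want <- 0.5 * exp((0.05 - 0.01) * tr$times)
  expect_equal(tr$states[, "Xa"], want, tolerance = 1e-6)
})

test_that("integrated concentrations never go negative", {
  # aggressive consumption rates drive nutrients into depletion
  p <- params_initial(kd = 1e-3, mum = 5, KS = 1, KIS = 5, KA = 0.05,
                      KIA = 0.1, KN = 0.05, KIN = 0.1, muS = 0.9, muA = 0.05,
                      muN = 0.08, muP = 0.5)
  des <- ms_design(X0 = 1.5, duration = 200, sampling = c(0, 200))
  tr <- simulate_culture(des, p)
  expect_true(all(tr$states >= 0))
})
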