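# calibration tests use noiseless synthetic data so that objective values
# and recovery targets have exact references
zero_noise <- function() {
  noise_spec(upct = c(X = 0, S = 0, F = 0, G = 0, A = 0, N = 0, P = 0))
}

noiseless_ds <- function(X0 = 0.75, duration = 120, sampling = seq(0, 120, 24),
                         params = ref_params_initial()) {
  des <- ms_design(X0 = X0, duration = duration, sampling = sampling)
  generate_dataset(des, params, noise = zero_noise(), seed = 1,
                   solver = fast_solver())
}

test_that("objective is zero at the generating parameters and scales as (1-g/y)^2", {
  ds <- noiseless_ds()
  prob <- fit_problem(ds, ref_params_initial(), free = c("mum", "muS"))
  expect_lt(objective_value(ref_params_initial(), prob, fast_solver()), 1e-10)
  # scale all measurements by 1/0.9: every ratio g/y becomes 0.9
  ds2 <- ds
  ds2$data$value <- ds$data$value / 0.9
  n_used <- sum(ds2$data$value >= 1e-6)
  prob2 <- fit_problem(ds2, ref_params_initial())
  expect_equal(objective_value(ref_params_initial(), prob2, fast_solver()),
               n_used * (1 - 0.9)^2, tolerance = 1e-6)
})

test_that("objective is invariant to observation order and additive over weights", {
  ds <- noiseless_ds()
  ds$data$value <- ds$data$value * 1.07  # imperfect fit, non-zero Q
  perm <- ds
  set.seed(3)
  perm$data <- perm$data[sample.int(nrow(perm$data)), ]
  perm <- ts_dataset(perm$label, perm$data, perm$noise, perm$design)
  p <- ref_params_initial()
  q1 <- objective_value(p, fit_problem(ds, p), fast_solver())
  expect_equal(objective_value(p, fit_problem(perm, p), fast_solver()), q1)
  # doubling a response weight exactly doubles its contribution
  q_w0 <- objective_value(p, fit_problem(ds, p, weights = c(X = 0)),
                          fast_solver())
  q_w2 <- objective_value(p, fit_problem(ds, p, weights = c(X = 2)),
                          fast_solver())
  expect_equal(q_w2 - q_w0, 2 * (q1 - q_w0), tolerance = 1e-9)
})

test_that("observations below the value floor are excluded, not divided by", {
  ds <- noiseless_ds()
  rows <- ds$data
  rows$value[rows$response == "P" & rows$time == 120] <- 0  # depleted assay
  dsz <- ts_dataset(ds$label, rows, ds$noise, ds$design)
  q <- objective_value(ref_params_initial(), fit_problem(dsz, ref_params_initial()),
                       fast_solver())
  expect_true(is.finite(q))
  # identical to dropping the zero observation entirely
  rows2 <- rows[!(rows$response == "P" & rows$time == 120), ]
  dsd <- ts_dataset(ds$label, rows2, ds$noise, ds$design)
  q2 <- objective_value(ref_params_initial(),
                        fit_problem(dsd, ref_params_initial()), fast_solver())
  expect_equal(q, q2)
})

test_that("simulation failure yields a large finite penalty", {
  ds <- noiseless_ds()
  prob <- fit_problem(ds, ref_params_initial())
  bad <- ref_params_initial()
  bad$mum <- NaN
  q <- objective_value(bad, prob, fast_solver())
  expect_true(is.finite(q) && q >= 1e9)
})

test_that("error matrix combines constant and proportional components", {
  ds <- noiseless_ds()
  ds$noise <- noise_spec(u0 = c(X = 0.1), upct = c(X = 0.06, S = 0.06))
  em <- error_matrix(ds)
  x10 <- em[em$response == "X", ][1, ]
  expect_equal(x10$sigma, 0.1 + 0.06 * x10$y)
  s <- em[em$response == "S", ]
  expect_equal(s$sigma, 0.06 * s$y)
  # defaults: 3% on dry mass, 6% per nutrient, no constant part
  ds_def <- noiseless_ds()
  ds_def$noise <- noise_spec()
  em2 <- error_matrix(ds_def)
  expect_equal(em2$sigma[em2$response == "X"],
               0.03 * em2$y[em2$response == "X"])
  expect_equal(em2$sigma[em2$response == "N"],
               0.06 * em2$y[em2$response == "N"])
})

test_that("collapsed bounds pin the fit to the only feasible point", {
  ds <- noiseless_ds()
  b <- param_bounds("initial")
  b$min <- b$max <- unlist(ref_params_initial()[b$name])
  prob <- fit_problem(ds, ref_params_initial(), free = c("mum", "kd"),
                      bounds = b)
  fit <- fit_model(prob, n_starts = 2, seed = 1, solver = fast_solver())
  expect_equal(fit$params$mum, 9.47)
  expect_equal(fit$params$kd, 6.62e-4)
})

test_that("a one-parameter fit matches a brute-force objective scan", {
  ds <- noiseless_ds(sampling = seq(0, 120, 12))
  truth <- ref_params_initial()
  start <- truth; start$muP <- 0.01
  prob <- fit_problem(ds, start, free = "muP")
  fit <- fit_model(prob, n_starts = 4, seed = 2, solver = fast_solver())
  # independent oracle: golden-section scan of the same objective
  scan <- stats::optimize(function(v) {
    p <- truth; p$muP <- v
    objective_value(p, prob, fast_solver())
  }, interval = c(0, 0.2), tol = 1e-7)
  expect_equal(fit$params$muP, scan$minimum, tolerance = 1e-3)
  expect_equal(fit$params$muP, truth$muP, tolerance = 1e-3)
  expect_lte(fit$Q, fit$Q_start)
})

test_that("noiseless multi-parameter recovery is within 1%", {
  ds <- list(noiseless_ds(X0 = 0.68), noiseless_ds(X0 = 1.0))
  truth <- ref_params_initial()
  start <- truth
  start$mum <- 5; start$muS <- 0.1; start$muA <- 0.002
  prob <- fit_problem(ds, start, free = c("mum", "muS", "muA"))
  fit <- fit_model(prob, n_starts = 1, seed = 1, solver = fast_solver(),
                   control = list(maxit = 300))
  for (nm in c("mum", "muS", "muA")) {
    expect_lt(abs(fit$params[[nm]] - truth[[nm]]) / truth[[nm]], 0.01)
  }
  # the KI >= K ordering survives fitting
  expect_true(fit$params$KIS >= fit$params$KS)
})

test_that("KI/K pairs can be fitted jointly without violating the ordering", {
  ds <- noiseless_ds(sampling = seq(0, 120, 12))
  start <- ref_params_initial()
  start$KS <- 10; start$KIS <- 30
  prob <- fit_problem(ds, start, free = c("KS", "KIS"))
  fit <- fit_model(prob, n_starts = 4, seed = 3, solver = fast_solver())
  expect_gte(fit$params$KIS, fit$params$KS)
  expect_lte(fit$Q, objective_value(start, prob, fast_solver()))
  # the generating values had KIS = KS: the constraint should be active
  expect_true(fit$constraint_active[["KIS"]])
})

test_that("zero measurement noise gives zero-width bootstrap intervals", {
  ds <- noiseless_ds()
  ds$noise <- noise_spec(u0 = c(X = 0, S = 0),
                         upct = c(X = 0, S = 0, F = 0, G = 0, A = 0, N = 0,
                                  P = 0))
  prob <- fit_problem(ds, ref_params_initial(), free = "muP")
  fit <- fit_model(prob, n_starts = 1, seed = 1, solver = fast_solver())
  ci <- bootstrap_ci(fit, n_boot = 3, seed = 4, solver = fast_solver())
  expect_equal(ci$half_width, 0, tolerance = 1e-8)
  expect_equal(attr(ci, "n_effective"), 3)
})

test_that("bootstrap intervals are deterministic under a fixed seed", {
  des <- ms_design(X0 = 0.75, duration = 120, sampling = seq(0, 120, 24))
  ds <- generate_dataset(des, ref_params_initial(), noise = noise_spec(),
                         seed = 21, solver = fast_solver())
  prob <- fit_problem(ds, ref_params_initial(), free = "muP")
  fit <- fit_model(prob, n_starts = 1, seed = 1, solver = fast_solver())
  ci1 <- bootstrap_ci(fit, n_boot = 5, seed = 10, solver = fast_solver(),
                      control = list(maxit = 50))
  ci2 <- bootstrap_ci(fit, n_boot = 5, seed = 10, solver = fast_solver(),
                      control = list(maxit = 50))
  expect_identical(ci1, ci2)
  expect_lt(ci1$lower, ci1$upper)
})

test_that("MAE family matches hand-computed shifts and pooling", {
  ds <- noiseless_ds()
  p <- ref_params_initial()
  expect_equal(mae(p, ds, "X", solver = fast_solver()), 0, tolerance = 1e-8)
  # shifting every dry-mass value by +0.5 shifts the MAE to exactly 0.5
  rows <- ds$data
  rows$value[rows$response == "X"] <- rows$value[rows$response == "X"] + 0.5
  ds5 <- ts_dataset(ds$label, rows, ds$noise, ds$design)
  expect_equal(mae(p, ds5, "X", solver = fast_solver()), 0.5,
               tolerance = 1e-8)
  # pooled MAE is the observation-weighted mean of the shifts
  dsA <- ds5                                    # 6 points shifted by 0.5
  rowsB <- ds$data
  rowsB$value[rowsB$response == "X"] <- rowsB$value[rowsB$response == "X"] + 2
  dsB <- ts_dataset("b", rowsB, ds$noise, ds$design)
  pooled <- mae_subset(p, list(dsA, dsB), "X", solver = fast_solver())
  expect_equal(pooled, (0.5 + 2) / 2, tolerance = 1e-8)
  # nMAE normalizes by the grand mean over the normalization set
  gm <- grand_mean(list(dsA, dsB), "X")
  expect_equal(nmae(p, dsA, "X", norm_set = list(dsA, dsB),
                    solver = fast_solver()),
               0.5 / gm, tolerance = 1e-8)
  # observation filters restrict the error set
  f <- function(d) d$time >= 96
  expect_equal(mae(p, ds5, "X", obs_filter = f, solver = fast_solver()), 0.5,
               tolerance = 1e-8)
  expect_error(mae(p, ds, "X", obs_filter = function(d) d$time > 999),
               "no observations")
})
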