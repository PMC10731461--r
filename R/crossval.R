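# K-fold cross-validation over whole experiments, for comparing the two
# model variants by average test-set MAE.

#' Compare models by leave-one-experiment-out cross-validation
#'
#' Folds are whole experiments (a time series is never split). For each
#' fold k, every candidate model is fitted on the remaining K-1 experiments
#' and scored by MAE per response on the held-out one. The report gives
#' `aMAE` (arithmetic mean of the K fold MAEs) and `anMAE = aMAE / ybar_r`
#' with `ybar_r` the grand mean of the response over all K experiments.
#' Optional observation filters add conditional columns (e.g. the MAE of
#' dry mass restricted to measured values above 8 g/L).
#'
#' @param datasets List of K >= 2 [ts_dataset()] objects.
#' @param models Named list of model specifications, each a list with
#'   `params0` (baseline `by2_params`, also the fixed values) and
#'   optionally `free` (parameters to fit; default all identifiable ones).
#' @param responses Responses to score (default `X`, `S`, `A`, `N`).
#' @param filters Named list of observation predicates (see [mae()]);
#'   each adds `aMAE`/`anMAE` columns per response suffixed by its name.
#' @param n_starts,seed,control,solver Passed to [fit_model()].
#' @return Object of class `by2_cv_report`: `summary` (one row per model x
#'   response with `aMAE`, `anMAE` and filtered variants), `folds`
#'   (per-fold MAE table), `assignments` (fold id per experiment).
#' @export
kfold_compare <- function(datasets, models,
                          responses = c("X", "S", "A", "N"),
                          filters = list(),
                          n_starts = 4, seed = 1,
                          control = list(maxit = 200),
                          solver = solver_options()) {
  K <- length(datasets)
  stopifnot(K >= 2, length(models) >= 1, !is.null(names(models)))
  labels <- vapply(datasets, `[[`, character(1), "label")
  for (mname in names(models)) {
    m <- models[[mname]]
    needed <- if (model_variant(m$params0) == "improved") {
      c("F", "G")
    } else {
      character(0)
    }
    for (d in datasets) {
      missing_r <- setdiff(needed, unique(d$data$response))
      if (length(missing_r)) {
        stop("model '", mname, "' requires response(s) ",
             paste(missing_r, collapse = ", "), " absent from dataset '",
             d$label, "'")
      }
    }
  }
  ybar <- vapply(responses, function(r) grand_mean(datasets, r), numeric(1))

  folds <- list()
  for (k in seq_len(K)) {
    train <- datasets[-k]
    test <- datasets[[k]]
    for (mname in names(models)) {
      m <- models[[mname]]
      prob <- fit_problem(train, m$params0, free = m$free)
      fit <- fit_model(prob, n_starts = n_starts, seed = seed + k,
                       control = control, solver = solver)
      row <- data.frame(fold = k, test_experiment = test$label,
                        model = mname, n_test = nrow(test$data))
      for (r in responses) {
        row[[paste0("MAE_", r)]] <- mae(fit$params, test, r, solver = solver)
        for (fname in names(filters)) {
          row[[paste0("MAE_", r, "_", fname)]] <-
            tryCatch(mae(fit$params, test, r, obs_filter = filters[[fname]],
                         solver = solver),
                     error = function(e) NA_real_)
        }
      }
      folds[[length(folds) + 1]] <- row
    }
  }
  folds <- do.call(rbind, folds)

  summ <- do.call(rbind, lapply(names(models), function(mname) {
    do.call(rbind, lapply(responses, function(r) {
      rows <- folds[folds$model == mname, ]
      out <- data.frame(model = mname, response = r,
                        aMAE = mean(rows[[paste0("MAE_", r)]]),
                        anMAE = mean(rows[[paste0("MAE_", r)]]) / ybar[[r]])
      for (fname in names(filters)) {
        v <- rows[[paste0("MAE_", r, "_", fname)]]
        out[[paste0("aMAE_", fname)]] <- mean(v, na.rm = TRUE)
        out[[paste0("anMAE_", fname)]] <- mean(v, na.rm = TRUE) / ybar[[r]]
      }
      out
    }))
  }))
  rownames(summ) <- NULL
  structure(list(summary = summ, folds = folds,
                 assignments = data.frame(experiment = labels,
                                          fold = seq_len(K))),
            class = "by2_cv_report")
}

#' @export
print.by2_cv_report <- function(x, ...) {
  cat("K-fold cross-validation report (K =", nrow(x$assignments), ")\n")
  print(x$summary, digits = 4)
  invisible(x)
}
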