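# Plain-text readers/writers: tidy dataset CSVs (values in both g/L and mM,
# uncertainty components inline), parameter tables mirroring the published
# layout, trajectory exports, fronts and CV reports. Every file starts with
# commented header lines recording package version and seed for
# reproducibility.

.write_header <- function(path, seed = NA) {
  ver <- as.character(utils::packageVersion("by2growth"))
  writeLines(c(sprintf("# by2growth %s", ver),
               sprintf("# seed: %s", seed),
               sprintf("# written: %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))),
             path)
}

.append_csv <- function(df, path) {
  con <- file(path, "a")
  on.exit(close(con))
  utils::write.table(df, con, sep = ",", row.names = FALSE,
                     col.names = TRUE, quote = FALSE)
}

#' Write / read a measurement dataset
#'
#' Tidy long CSV: one row per observation with the value on both scales
#' (`value_gL` authoritative; `value_mM` `NA` for dry mass) and the
#' response's uncertainty pair inline, so a file round-trips losslessly.
#' Design metadata (initial state, duration, sampling) is embedded in
#' commented header lines.
#'
#' @param ds A [ts_dataset()].
#' @param path Output CSV path.
#' @param seed Seed recorded in the header (provenance only).
#' @param mm Molar mass table for the mM column.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(ds, path, seed = NA, mm = molar_masses()) {
  stopifnot(inherits(ds, "by2_dataset"))
  .write_header(path, seed)
  con <- file(path, "a")
  on.exit(close(con))
  writeLines(sprintf("# label: %s", ds$label), con)
  if (!is.null(ds$design)) {
    st <- ds$design$state0
    writeLines(c(sprintf("# duration_h: %.10g", ds$design$duration),
                 sprintf("# sampling_h: %s",
                         paste(ds$design$sampling_times, collapse = ";")),
                 sprintf("# state0: %s",
                         paste(sprintf("%s=%.10g", names(st), st),
                               collapse = ";"))),
               con)
  }
  df <- ds$data
  df$value_mM <- vapply(seq_len(nrow(df)), function(i) {
    if (df$response[i] == "X") NA_real_
    else to_reported(df$value[i], df$response[i], mm)
  }, numeric(1))
  out <- data.frame(experiment = ds$label, time_h = df$time,
                    response = df$response, value_gL = df$value,
                    value_mM = df$value_mM,
                    u0 = ds$noise$u0[df$response],
                    upct = ds$noise$upct[df$response])
  utils::write.table(out, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_dataset
#' @return For `read_dataset()`: the reconstructed [ts_dataset()].
#' @export
read_dataset <- function(path) {
  hdr <- readLines(path, n = 50)
  hdr <- hdr[startsWith(hdr, "#")]
  getf <- function(key) {
    ln <- grep(paste0("^# ", key, ":"), hdr, value = TRUE)
    if (!length(ln)) return(NULL)
    trimws(sub(paste0("^# ", key, ":"), "", ln[1]))
  }
  df <- tryCatch(
    utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE),
    error = function(e) stop("cannot parse dataset file '", path, "': ",
                             conditionMessage(e))
  )
  need <- c("experiment", "time_h", "response", "value_gL", "u0", "upct")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("dataset file '", path, "' lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (!is.numeric(df$value_gL) || !is.numeric(df$time_h)) {
    stop("dataset file '", path,
         "': time_h and value_gL must be numeric columns")
  }
  u0 <- tapply(df$u0, df$response, `[`, 1)
  up <- tapply(df$upct, df$response, `[`, 1)
  ns <- noise_spec(u0 = u0, upct = up)
  design <- NULL
  st_line <- getf("state0")
  if (!is.null(st_line)) {
    kv <- strsplit(strsplit(st_line, ";")[[1]], "=")
    st <- stats::setNames(vapply(kv, function(x) as.numeric(x[2]), numeric(1)),
                          vapply(kv, `[`, character(1), 1))
    design <- experiment_design(
      label = getf("label"),
      state0 = do.call(process_state, as.list(st)),
      duration = as.numeric(getf("duration_h")),
      sampling_times = as.numeric(strsplit(getf("sampling_h"), ";")[[1]])
    )
  }
  ts_dataset(label = getf("label") %||% df$experiment[1],
             data = data.frame(time = df$time_h, response = df$response,
                               value = df$value_gL),
             noise = ns, design = design)
}

#' Write / read a kinetic-parameter table
#'
#' CSV with one row per parameter (`parameter`, `value`, `min`, `max`) plus
#' rows for the fixed improved-model quantities (`deltaA`, `deltaP`, `mSF`,
#' `mSG`, with `NA` bounds). A fit report additionally carries CI columns.
#'
#' @param params A `by2_params` object.
#' @param path CSV path.
#' @param ci Optional [bootstrap_ci()] table to merge in.
#' @param seed Seed recorded in the header.
#' @return `path` invisibly; for `read_params()`, the parameter object.
#' @export
write_params <- function(params, path, ci = NULL, seed = NA) {
  stopifnot(inherits(params, "by2_params"))
  variant <- model_variant(params)
  b <- param_bounds(variant)
  df <- data.frame(parameter = b$name,
                   value = unlist(params[b$name]),
                   min = b$min, max = b$max)
  fixed <- setdiff(names(params), b$name)
  if (length(fixed)) {
    df <- rbind(df, data.frame(parameter = fixed,
                               value = unlist(params[fixed]),
                               min = NA_real_, max = NA_real_))
  }
  if (!is.null(ci)) {
    df$ci_lower <- ci$lower[match(df$parameter, ci$parameter)]
    df$ci_upper <- ci$upper[match(df$parameter, ci$parameter)]
  }
  .write_header(path, seed)
  con <- file(path, "a")
  on.exit(close(con))
  writeLines(sprintf("# model: %s", variant), con)
  utils::write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  hdr <- readLines(path, n = 20)
  ln <- grep("^# model:", hdr, value = TRUE)
  if (!length(ln)) stop("parameter file '", path, "' lacks a '# model:' header")
  variant <- trimws(sub("^# model:", "", ln[1]))
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("parameter", "value") %in% names(df))) {
    stop("parameter file '", path, "' needs columns parameter, value")
  }
  if (!is.numeric(df$value)) {
    stop("parameter file '", path, "': value column is not numeric")
  }
  vals <- stats::setNames(as.list(df$value), df$parameter)
  ctor <- if (variant == "initial") params_initial else params_improved
  need <- setdiff(names(formals(ctor)), c("check_bounds", "mSF", "mSG",
                                          "deltaA", "deltaP"))
  missing_p <- setdiff(need, names(vals))
  if (length(missing_p)) {
    stop("parameter file '", path, "' lacks parameter(s): ",
         paste(missing_p, collapse = ", "))
  }
  do.call(ctor, vals[intersect(names(formals(ctor)), names(vals))])
}

#' Export a trajectory as tidy CSV
#'
#' One row per grid point with volume, active/dead/total dry mass and every
#' nutrient in both g/L and mM.
#'
#' @param traj A `by2_trajectory`.
#' @param path CSV path.
#' @param seed Seed recorded in the header.
#' @param mm Molar mass table.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path, seed = NA, mm = molar_masses()) {
  df <- as.data.frame(traj)
  for (n in NUTRIENT_IDS) {
    df[[paste0(n, "_mM")]] <- to_reported(df[[n]], n, mm)
  }
  names(df)[match(c("V", NUTRIENT_IDS), names(df))] <-
    c("volume_L", paste0(NUTRIENT_IDS, "_gL"))
  .write_header(path, seed)
  .append_csv(df, path)
  invisible(path)
}

#' Export a Pareto front or CV report as CSV
#'
#' @param x A `by2_pareto_front` or `by2_cv_report`.
#' @param path CSV path.
#' @param seed Seed recorded in the header.
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path, seed = NA) {
  .write_header(path, seed)
  df <- if (inherits(x, "by2_cv_report")) x$summary else as.data.frame(x)
  .append_csv(df, path)
  invisible(path)
}
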