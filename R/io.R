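# File interfaces: trial tables and trajectory tables as CSV (UTF-8, comma
# separated, '.' decimal, header mandatory), error maps as long CSV or JSON,
# run configurations as YAML.

trial_columns <- c("subject_id", "experiment", "session", "trial_index",
                   "target_row", "target_col", "target_x_mm", "target_y_mm",
                   "hand_x_mm", "hand_y_mm")
trajectory_columns <- c("subject_id", "session", "trial_index", "alpha", "beta",
                        "sample_index", "t_s", "x_mm", "y_mm", "valid")

check_schema <- function(df, required, numeric_cols, label) {
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop_("%s: missing column(s): %s", label, paste(missing, collapse = ", "))
  extra <- setdiff(names(df), required)
  if (length(extra))
    warning(sprintf("%s: unknown column(s) preserved and ignored: %s",
                    label, paste(extra, collapse = ", ")))
  for (col in numeric_cols) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (length(bad))
      stop_("%s: non-numeric value in column %s at row(s) %s", label, col,
            paste(utils::head(bad, 5), collapse = ", "))
    df[[col]] <- v
  }
  df
}

#' Write / read a matching-trial table
#'
#' CSV with the documented schema (`subject_id`, `experiment`, `session`,
#' `trial_index`, `target_row`, `target_col`, `target_x_mm`, `target_y_mm`,
#' `hand_x_mm`, `hand_y_mm`). Reading validates the schema, reports
#' non-numeric coordinates with row numbers, and rejects duplicate
#' (subject, session, target) combinations; unknown extra columns are kept
#' with a warning.
#'
#' @param trials matching-trial data frame.
#' @param path CSV file path.
#' @return `read_trials` returns the validated data frame; `write_trials`
#'   returns `path` invisibly.
#' @export
write_trials <- function(trials, path) {
  utils::write.csv(trials, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df <- check_schema(df, trial_columns,
                     c("target_row", "target_col", "target_x_mm", "target_y_mm",
                       "hand_x_mm", "hand_y_mm"),
                     "trial table")
  key <- paste(df$subject_id, df$session, df$target_row, df$target_col)
  if (anyDuplicated(key))
    stop_("trial table: duplicate (subject, session, target) at row(s) %s",
          paste(utils::head(which(duplicated(key)), 5), collapse = ", "))
  df
}

#' Write / read a trajectory-trial table
#'
#' @param trials trajectory-trial data frame (see
#'   [generate_trajectory_trials()] for the schema).
#' @param path CSV file path.
#' @return `read_trajectories` returns the validated data frame.
#' @export
write_trajectories <- function(trials, path) {
  utils::write.csv(trials, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectories
#' @export
read_trajectories <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_schema(df, trajectory_columns,
               c("alpha", "beta", "sample_index", "t_s", "x_mm", "y_mm"),
               "trajectory table")
}

#' Write / read error maps as long CSV
#'
#' One row per target and map: `subject_id`, `session`, `row`, `col`,
#' `x_e_cm`, `y_e_cm`.
#'
#' @param maps list of `error_map`s.
#' @param path CSV file path.
#' @return `read_error_maps` returns a list of `error_map`s.
#' @export
write_error_maps <- function(maps, path) {
  rows <- lapply(maps, function(m) {
    d <- dim(m$errors)
    g <- expand.grid(row = seq_len(d[2]), col = seq_len(d[3]))
    data.frame(subject_id = m$subject_id, session = m$session,
               row = g$row, col = g$col,
               x_e_cm = m$errors[cbind(1L, g$row, g$col)],
               y_e_cm = m$errors[cbind(2L, g$row, g$col)])
  })
  utils::write.csv(do.call(rbind, c(rows, list(make.row.names = FALSE))),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_error_maps
#' @export
read_error_maps <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "session", "row", "col", "x_e_cm", "y_e_cm")
  df <- check_schema(df, need, c("row", "col", "x_e_cm", "y_e_cm"), "error map table")
  pieces <- split(df, list(df$subject_id, df$session), drop = TRUE)
  maps <- lapply(pieces, function(p) {
    errs <- array(NA_real_, dim = c(2L, max(p$row), max(p$col)))
    errs[cbind(1L, p$row, p$col)] <- p$x_e_cm
    errs[cbind(2L, p$row, p$col)] <- p$y_e_cm
    error_map(errs, subject_id = as.character(p$subject_id[1]),
              session = p$session[1])
  })
  maps
}

#' Write / read a run configuration as YAML
#'
#' The YAML mirrors [cohort_config()] and [classifier_config()]
#' field-for-field under `cohort:` and `classifier:` keys, plus `protocols`,
#' `alpha`, `output_dir` and `log_level`.
#'
#' @param config a [run_config()].
#' @param path YAML file path.
#' @return `read_run_config` returns a `run_config`.
#' @export
write_run_config <- function(config, path) {
  co <- config$cohort
  cl <- config$classifier
  obj <- list(
    cohort = list(n_subjects = co$n_subjects, sessions = co$sessions,
                  learning_factors = co$learning_factors,
                  idio_scale = co$idio_scale, smoothness = co$smoothness,
                  noise_sd = co$noise_sd, group_bias = co$group_bias,
                  coupling = co$coupling, trajectory = co$trajectory,
                  geometry = unclass(co$geometry), seed = co$seed),
    classifier = unclass(cl),
    protocols = lapply(config$protocols, function(p)
      list(train = p$train, test = p$test)),
    alpha = config$alpha,
    output_dir = config$output_dir,
    log_level = config$log_level)
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  obj <- yaml::read_yaml(path)
  co <- obj$cohort %||% list()
  geom <- if (!is.null(co$geometry)) do.call(workspace_geometry, co$geometry)
          else workspace_geometry()
  co$geometry <- geom
  cohort <- do.call(cohort_config, co)
  classifier <- do.call(classifier_config, obj$classifier %||% list())
  run_config(cohort = cohort, classifier = classifier,
             protocols = lapply(obj$protocols %||% list(), function(p)
               list(train = unlist(p$train), test = p$test)),
             alpha = obj$alpha %||% 0.05,
             output_dir = obj$output_dir,
             log_level = obj$log_level %||% "info")
}
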