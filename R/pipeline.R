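# End-to-end pipeline: simulate -> error maps -> similarity -> person
# identification -> trajectory scoring -> report.

#' Pipeline run configuration
#'
#' @param cohort a [cohort_config()].
#' @param classifier a [classifier_config()].
#' @param protocols list of identification splits, each
#'   `list(train = <sessions>, test = <session>)`; may be empty.
#' @param alpha significance level used throughout reports.
#' @param output_dir optional directory where all artifacts are written.
#' @param log_level `"quiet"`, `"info"`, or `"debug"`.
#' @return an object of class `run_config`.
#' @export
run_config <- function(cohort = cohort_config(), classifier = classifier_config(),
                       protocols = list(list(train = c(1, 2), test = 3)),
                       alpha = 0.05, output_dir = NULL, log_level = "info") {
  if (alpha <= 0 || alpha >= 1) stop_("alpha must lie strictly in (0, 1)")
  for (p in protocols) {
    referenced <- c(p$train, p$test)
    missing <- setdiff(referenced, cohort$sessions)
    if (length(missing))
      stop_("protocol references session(s) absent from the cohort: %s",
            paste(missing, collapse = ", "))
  }
  structure(list(cohort = cohort, classifier = classifier, protocols = protocols,
                 alpha = alpha, output_dir = output_dir, log_level = log_level),
            class = "run_config")
}

pipeline_log <- function(config, level, fmt, ...) {
  levels <- c(quiet = 0, info = 1, debug = 2)
  if (levels[[config$log_level %||% "info"]] >= levels[[level]])
    message(sprintf(paste0("[propriomap] ", fmt), ...))
}

#' Run the full analysis pipeline
#'
#' Simulates a cohort (matching and trajectory trials), builds all error
#' maps, computes session summaries, regional contrasts, error reductions
#' and direction-bias tables, within/between-subject similarity for every
#' session pair (correlations and distances) plus the between-subject
#' distance trend, runs every configured identification protocol, and scores
#' the trajectory task with its motor-vs-localization analyses. Idempotent
#' under a fixed config: the same seeds yield an identical report.
#'
#' @param config a [run_config()].
#' @return an object of class `report_bundle`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  co <- config$cohort
  grid <- make_target_grid(co$geometry)
  t0 <- proc.time()[3]

  pipeline_log(config, "info", "simulate: %d subjects x %d sessions",
               co$n_subjects, length(co$sessions))
  trials <- generate_cohort(co)
  fields <- lapply(seq_len(co$n_subjects), sample_subject_field, config = co,
                   grid = grid)
  traj <- generate_trajectory_trials(co, fields = fields)

  pipeline_log(config, "info", "maps: building error maps")
  maps <- build_error_maps(trials, grid)
  subj <- vapply(maps, function(m) m$subject_id, character(1))
  sess <- vapply(maps, function(m) as.character(m$session), character(1))

  session_summaries <- lapply(co$sessions, function(s) {
    ms <- maps[sess == as.character(s)]
    per_subject <- vapply(ms, mean_error_magnitude, numeric(1))
    ci <- mean_ci(per_subject)
    regions <- lapply(ms, regional_errors)
    list(session = s,
         mean_error_cm = ci$mean, ci_lower = ci$lower, ci_upper = ci$upper,
         per_subject = unname(per_subject),
         regional = list(left = mean(vapply(regions, `[[`, numeric(1), "left")),
                         right = mean(vapply(regions, `[[`, numeric(1), "right")),
                         near = mean(vapply(regions, `[[`, numeric(1), "near")),
                         far = mean(vapply(regions, `[[`, numeric(1), "far"))))
  })
  names(session_summaries) <- paste0("session_", co$sessions)

  e1 <- session_summaries[[1]]$per_subject
  reductions <- lapply(seq_along(co$sessions)[-1], function(i) {
    ei <- session_summaries[[i]]$per_subject
    red <- error_reduction(e1, ei)
    ci <- mean_ci(red)
    list(session = co$sessions[i], mean_percent = ci$mean,
         ci_lower = ci$lower, ci_upper = ci$upper)
  })
  names(reductions) <- paste0("session_", co$sessions[-1])

  averaged <- lapply(sort(unique(subj)), function(id)
    average_subject_map(maps[subj == id]))
  direction_bias <- list(x = direction_bias_test(averaged, "x", config$alpha),
                         y = direction_bias_test(averaged, "y", config$alpha))

  pipeline_log(config, "info", "similarity: %d session pairs",
               choose(length(co$sessions), 2))
  pairs <- utils::combn(co$sessions, 2)
  similarity <- lapply(seq_len(ncol(pairs)), function(k) {
    sa <- pairs[1, k]; sb <- pairs[2, k]
    rset <- within_between_sets(maps, sa, sb, "correlation")
    dset <- within_between_sets(maps, sa, sb, "distance")
    list(session_a = sa, session_b = sb,
         correlation = list(sets = rset, test = compare_within_between(rset)),
         distance = list(sets = dset, test = compare_within_between(dset)))
  })
  names(similarity) <- paste0("s", pairs[1, ], "_s", pairs[2, ])
  trend <- distance_trend(between_subject_distances(maps, co$sessions))

  identification <- lapply(config$protocols, function(p) {
    pipeline_log(config, "info", "identify: train %s -> test %s",
                 paste(p$train, collapse = "+"), p$test)
    identification_protocol(maps, p$train, p$test, config$classifier)
  })

  pipeline_log(config, "info", "trajectory: scoring %d trials",
               length(unique(paste(traj$subject_id, traj$trial_index))))
  scores <- score_trajectories(traj, min_speed = 165)
  subj_rmse <- tapply(scores$rmse_cm, scores$subject_id, mean, na.rm = TRUE)
  s1_maps <- maps[sess == as.character(co$sessions[1])]
  s1_subj <- vapply(s1_maps, function(m) m$subject_id, character(1))
  s1_err <- vapply(s1_maps, mean_error_magnitude, numeric(1))[
    match(names(subj_rmse), s1_subj)]
  motor_cor <- motor_vs_localization_correlation(as.vector(subj_rmse), s1_err)
  # per-trial local localization error from the subject's session-1 map
  local_err <- mapply(function(id, a, b) {
    local_localization_error(s1_maps[[which(s1_subj == id)]],
                             make_template(a, b), grid)
  }, scores$subject_id, scores$alpha, scores$beta)
  valid <- scores$valid
  regression <- subject_dummy_regression(scores$rmse_cm[valid],
                                         local_err[valid],
                                         scores$subject_id[valid])
  rmse_beta <- stats::cor(abs(scores$beta[valid]), scores$rmse_cm[valid])

  bundle <- structure(list(
    config = config,
    seed = co$seed,
    grid = grid,
    session_summaries = session_summaries,
    error_reductions = reductions,
    direction_bias = direction_bias,
    similarity = similarity,
    distance_trend = trend,
    identification = identification,
    trajectory = list(scores = scores,
                      mean_rmse_cm = mean(scores$rmse_cm, na.rm = TRUE),
                      n_invalid = sum(!scores$valid),
                      rmse_curvature_correlation = rmse_beta,
                      motor_vs_localization = motor_cor,
                      local_error_regression = regression),
    elapsed_s = proc.time()[3] - t0), class = "report_bundle")

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    write_trials(trials, file.path(config$output_dir, "matching_trials.csv"))
    write_trajectories(traj, file.path(config$output_dir, "trajectory_trials.csv"))
    write_error_maps(maps, file.path(config$output_dir, "error_maps.csv"))
    writeLines(render_report(bundle, "json"),
               file.path(config$output_dir, "results.json"))
    writeLines(render_report(bundle, "markdown"),
               file.path(config$output_dir, "report.md"))
    pipeline_log(config, "info", "artifacts written to %s", config$output_dir)
  }
  pipeline_log(config, "info", "done in %.1f s", bundle$elapsed_s)
  bundle
}

#' Plain numeric payload of a report bundle
#'
#' Everything in the report, reduced to plain lists and numbers: the part of
#' the bundle that must be byte-stable under a fixed seed and round-trips
#' through JSON.
#'
#' @param bundle a `report_bundle`.
#' @return a nested list of plain numbers and strings.
#' @export
report_payload <- function(bundle) {
  sim <- lapply(bundle$similarity, function(s) list(
    session_a = s$session_a, session_b = s$session_b,
    within_mean_r = mean(s$correlation$sets$within),
    between_mean_r = mean(s$correlation$sets$between),
    correlation_t = s$correlation$test$statistic,
    correlation_p = s$correlation$test$p_value,
    within_mean_distance_cm = mean(s$distance$sets$within),
    between_mean_distance_cm = mean(s$distance$sets$between),
    distance_p = s$distance$test$p_value))
  ident <- lapply(bundle$identification, function(r) list(
    train = paste(r$split$train, collapse = "+"), test = r$split$test,
    accuracy = r$accuracy, n_correct = r$n_correct, n_test = r$n_test,
    chance = r$chance))
  list(
    seed = bundle$seed,
    sessions = lapply(bundle$session_summaries, function(s) list(
      session = s$session, mean_error_cm = s$mean_error_cm,
      ci_lower = s$ci_lower, ci_upper = s$ci_upper,
      regional = s$regional)),
    error_reductions = lapply(bundle$error_reductions, function(r) list(
      session = r$session, mean_percent = r$mean_percent,
      ci_lower = r$ci_lower, ci_upper = r$ci_upper)),
    direction_bias = list(
      x_significant_targets = sum(bundle$direction_bias$x$significant),
      y_significant_targets = sum(bundle$direction_bias$y$significant)),
    similarity = sim,
    distance_trend = list(W = bundle$distance_trend$W,
                          p_value = bundle$distance_trend$p_value),
    identification = ident,
    trajectory = list(
      mean_rmse_cm = bundle$trajectory$mean_rmse_cm,
      n_invalid = bundle$trajectory$n_invalid,
      rmse_curvature_correlation = bundle$trajectory$rmse_curvature_correlation,
      motor_vs_localization_r = bundle$trajectory$motor_vs_localization$estimate,
      motor_vs_localization_p = bundle$trajectory$motor_vs_localization$p_value,
      motor_vs_localization_method = bundle$trajectory$motor_vs_localization$method,
      regression_slope = bundle$trajectory$local_error_regression$slope,
      regression_p = bundle$trajectory$local_error_regression$p_value))
}

#' Render a report bundle
#'
#' @param bundle a `report_bundle`.
#' @param format `"markdown"` or `"json"`.
#' @return a character scalar (the document).
#' @export
render_report <- function(bundle, format = c("markdown", "json")) {
  format <- match.arg(format)
  required <- c("session_summaries", "error_reductions", "similarity",
                "distance_trend", "trajectory")
  missing <- required[!vapply(required, function(f)
    !is.null(bundle[[f]]), logical(1))]
  if (length(missing))
    stop_("partial bundle: missing section(s) %s", paste(missing, collapse = ", "))
  payload <- report_payload(bundle)
  if (format == "json")
    return(as.character(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA)))
  lines <- c("# Hand localization analysis report", "",
             sprintf("Seed: %d", payload$seed), "",
             "## Session error summaries", "")
  for (s in payload$sessions)
    lines <- c(lines, sprintf("- session %s: %s cm", s$session,
                              format_ci(s$mean_error_cm, s$ci_lower, s$ci_upper)))
  lines <- c(lines, "", "## Error reduction relative to session 1", "")
  for (r in payload$error_reductions)
    lines <- c(lines, sprintf("- session %s: %s %%", r$session,
                              format_ci(r$mean_percent, r$ci_lower, r$ci_upper, 1)))
  lines <- c(lines, "", "## Direction bias", "",
             sprintf("- x (rightward): %d/%d targets significantly biased",
                     payload$direction_bias$x_significant_targets,
                     nrow(bundle$direction_bias$x)),
             sprintf("- y (away from body): %d/%d targets significantly biased",
                     payload$direction_bias$y_significant_targets,
                     nrow(bundle$direction_bias$y)),
             "", "## Within- vs between-subject similarity", "")
  for (s in payload$similarity)
    lines <- c(lines, sprintf(
      "- sessions %s vs %s: within r %.3f, between r %.3f (Welch p = %.2g); within distance %.3f cm, between %.3f cm (Wilcoxon p = %.2g)",
      s$session_a, s$session_b, s$within_mean_r, s$between_mean_r,
      s$correlation_p, s$within_mean_distance_cm, s$between_mean_distance_cm,
      s$distance_p))
  lines <- c(lines, "", sprintf(
    "Between-subject distance trend: Kendall's W = %.3f, p = %.2g",
    payload$distance_trend$W, payload$distance_trend$p_value),
    "", "## Person identification", "")
  if (length(payload$identification) == 0) {
    lines <- c(lines, "Not run: no identification protocols were configured.")
  } else {
    for (r in payload$identification)
      lines <- c(lines, sprintf(
        "- train %s -> test %s: accuracy %.2f%% (%d/%d, chance %.2f%%)",
        r$train, r$test, 100 * r$accuracy, r$n_correct, r$n_test, 100 * r$chance))
  }
  tr <- payload$trajectory
  lines <- c(lines, "", "## Trajectory-matching task", "",
             sprintf("- mean motor error (RMSE): %.3f cm (%d invalid trials)",
                     tr$mean_rmse_cm, tr$n_invalid),
             sprintf("- RMSE vs template curvature |beta|: r = %.3f",
                     tr$rmse_curvature_correlation),
             sprintf("- subject-mean motor vs localization error: r = %.3f (p = %.3f, %s)",
                     tr$motor_vs_localization_r, tr$motor_vs_localization_p,
                     tr$motor_vs_localization_method),
             sprintf("- local localization error -> motor error slope: %.3f (p = %.3g)",
                     tr$regression_slope, tr$regression_p))
  paste(lines, collapse = "\n")
}

#' @export
print.report_bundle <- function(x, ...) {
  cat(render_report(x, "markdown"), "\n")
  invisible(x)
}
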