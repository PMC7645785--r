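# Trajectory-matching templates, trial validation, motor-error scoring, and
# the motor-vs-localization analyses.
#
# A template is the curve x = alpha * y + beta * sin(pi * y) with y in
# [0, 1], where one template unit corresponds to 211 mm of workspace depth.
# Motor error is the RMSE between the produced trace and the template at 30
# evenly spaced depth cut points: the trace's x is interpolated at
# y = k/30 (k = 1..30) and the score is the square root of the SUM of the 30
# squared deviations (no division by 30), in cm.

#' Create a trajectory template
#'
#' @param alpha slope of the template's main direction (unitless).
#' @param beta curvature amplitude (unitless); `abs(beta)` summarizes the
#'   template's curvature.
#' @param scale mm of workspace depth per template unit (default 211).
#' @return an object of class `trajectory_template`.
#' @examples
#' tpl <- make_template(0, 0.1)
#' template_x(tpl, 0.5) # 21.1 mm
#' @export
make_template <- function(alpha, beta, scale = 211) {
  structure(list(alpha = alpha, beta = beta, scale = scale),
            class = "trajectory_template")
}

#' Evaluate a template's x-coordinate (mm)
#'
#' @param template a [make_template()] template.
#' @param y depth in template units (0 at the start, 1 at the nominal end);
#'   the analytic formula extrapolates smoothly outside `[0, 1]`.
#' @return x in mm.
#' @export
template_x <- function(template, y) {
  template$scale * (template$alpha * y + template$beta * sin(pi * y))
}

#' The default 15-template set
#'
#' Fifteen `(alpha, beta)` pairs spanning alpha in [-1, 1] and beta in
#' [-0.9, 0.8]: the grid `alpha in {-1, -0.5, 0, 0.5, 1}` crossed with
#' `beta in {-0.9, -0.05, 0.8}`. The individual pairs of the original set
#' are not published, so this evenly spaced stand-in covers the stated
#' ranges; it excludes the familiarization template (0, 0.1). Fully
#' configurable — any list of [make_template()] objects can replace it.
#'
#' @param scale mm per template unit.
#' @return list of 15 `trajectory_template`s.
#' @export
default_template_set <- function(scale = 211) {
  g <- expand.grid(alpha = c(-1, -0.5, 0, 0.5, 1), beta = c(-0.9, -0.05, 0.8))
  lapply(seq_len(nrow(g)), function(i) make_template(g$alpha[i], g$beta[i], scale))
}

#' Generate a trace that follows a template exactly
#'
#' Constant depth-speed sampling of the template curve; useful as a
#' noise-free reference trace.
#'
#' @param template a template.
#' @param n_samples number of samples (default 157, i.e. 1.2 s at 130 Hz).
#' @param duration movement duration in s.
#' @return data frame `t_s`, `x_mm`, `y_mm`.
#' @export
template_trace <- function(template, n_samples = 157, duration = 1.2) {
  yu <- (seq_len(n_samples) - 1) / (n_samples - 1)
  data.frame(t_s = yu * duration,
             x_mm = template_x(template, yu),
             y_mm = yu * template$scale)
}

#' Validate a movement trace
#'
#' A trial is invalid if the mean movement speed (path length over elapsed
#' time) is below `min_speed`, if the trace ever moves backward toward the
#' body (a y decrement), or if movement samples precede the go cue (negative
#' time stamps).
#'
#' @param trace data frame with `t_s`, `x_mm`, `y_mm`.
#' @param min_speed lowest allowed mean speed in mm/s (default 165).
#' @return list with `valid` (logical) and `reasons` (character vector among
#'   `"slow"`, `"backward"`, `"early-start"`).
#' @export
validate_trial <- function(trace, min_speed = 165) {
  if (is.null(trace) || nrow(trace) < 2) stop_("trace must have at least 2 samples")
  reasons <- character(0)
  path <- sum(sqrt(diff(trace$x_mm)^2 + diff(trace$y_mm)^2))
  elapsed <- max(trace$t_s) - min(trace$t_s)
  if (elapsed <= 0 || path / elapsed < min_speed) reasons <- c(reasons, "slow")
  if (any(diff(trace$y_mm) < 0)) reasons <- c(reasons, "backward")
  if (any(trace$t_s < 0)) reasons <- c(reasons, "early-start")
  list(valid = length(reasons) == 0, reasons = reasons)
}

# x of the trace linearly interpolated at the depth cut points (mm)
interp_at_cuts <- function(trace, scale, n_segments = 30) {
  yu <- trace$y_mm / scale
  if (max(yu) < 1 - 1e-9) stop_("trace does not reach the end of the template (y = 1)")
  cuts <- seq_len(n_segments) / n_segments
  stats::approx(yu, trace$x_mm, xout = cuts, ties = mean)$y
}

#' Motor error (RMSE) of a trace against its template
#'
#' The movement is divided into 30 segments along the depth axis; the
#' trace's x is interpolated at the segment cut points `y = k/30`
#' (k = 1..30, including the endpoint) and compared with the template's x
#' there. The score is `sqrt(sum(deviations^2))` in cm — the square root of
#' the 30-term sum, with no division by 30. Set `normalized = TRUE` for the
#' per-point variant `sqrt(mean(deviations^2))`.
#'
#' @param trace data frame `t_s`, `x_mm`, `y_mm` spanning the template depth.
#' @param template a template.
#' @param n_segments number of depth segments (default 30).
#' @param normalized divide the sum by `n_segments` before the square root.
#' @return RMSE in cm.
#' @export
trajectory_rmse <- function(trace, template, n_segments = 30, normalized = FALSE) {
  cuts <- seq_len(n_segments) / n_segments
  xi <- interp_at_cuts(trace, template$scale, n_segments)
  dev_cm <- (xi - template_x(template, cuts)) / 10
  ss <- sum(dev_cm^2)
  if (normalized) sqrt(ss / n_segments) else sqrt(ss)
}

#' Endpoint error of a trace
#'
#' Absolute horizontal deviation between the trace and the template at the
#' final cut point (y = 1), in cm.
#'
#' @inheritParams trajectory_rmse
#' @return endpoint error in cm.
#' @export
endpoint_error <- function(trace, template) {
  xi <- interp_at_cuts(trace, template$scale, 30)
  abs(xi[30] - template_x(template, 1)) / 10
}

# two grid columns whose x bracket xt on a row; clamped to the two nearest
# edge columns when xt lies outside the column range
bracket_cols <- function(col_x, xt) {
  j <- findInterval(xt, col_x)
  j <- min(max(j, 1L), length(col_x) - 1L)
  c(j, j + 1L)
}

#' Trajectory-local localization error
#'
#' On each grid row, the template's x-position at that row's depth is
#' bracketed by two column targets (clamped to the two outermost columns
#' when the template exits the grid laterally); the result is the mean error
#' magnitude at the 2-per-row "sandwich" targets, in cm. Row depths are
#' taken relative to the movement start at the near workspace edge.
#'
#' @param map an `error_map` (cm).
#' @param template a template.
#' @param grid a [make_target_grid()] grid.
#' @return mean localization error magnitude (cm) at the 10 sandwich targets.
#' @export
local_localization_error <- function(map, template, grid = make_target_grid()) {
  geom <- attr(grid, "geometry")
  mags <- if (inherits(map, "error_map")) map_magnitudes(map)
          else sqrt(map[1, , ]^2 + map[2, , ]^2)
  col_x <- grid_col_x(grid)
  row_y <- grid_row_y(grid)
  sel <- numeric(0)
  for (r in seq_along(row_y)) {
    yt <- (row_y[r] - geom$body_offset) / template$scale
    cols <- bracket_cols(col_x, template_x(template, yt))
    sel <- c(sel, mags[r, cols])
  }
  mean(sel)
}

#' Endpoint-specific localization error
#'
#' Mean error magnitude at the two far-row targets bracketing the template's
#' endpoint x-position, in cm.
#'
#' @inheritParams local_localization_error
#' @return mean localization error magnitude (cm) at the 2 endpoint targets.
#' @export
endpoint_localization_error <- function(map, template, grid = make_target_grid()) {
  mags <- if (inherits(map, "error_map")) map_magnitudes(map)
          else sqrt(map[1, , ]^2 + map[2, , ]^2)
  col_x <- grid_col_x(grid)
  cols <- bracket_cols(col_x, template_x(template, 1))
  mean(mags[nrow(mags), cols])
}

#' Score all trials of a trajectory-trial table
#'
#' Validates each trial and computes its RMSE and endpoint error against its
#' own template; invalid trials get `NA` scores.
#'
#' @param trials long trajectory-trial table (see
#'   [generate_trajectory_trials()] for the schema).
#' @param scale mm per template unit.
#' @param min_speed validity speed threshold, mm/s.
#' @return data frame with one row per trial: `subject_id`, `session`,
#'   `trial_index`, `alpha`, `beta`, `valid`, `reasons`, `rmse_cm`,
#'   `endpoint_cm`.
#' @export
score_trajectories <- function(trials, scale = 211, min_speed = 165) {
  pieces <- split(trials, list(trials$subject_id, trials$trial_index), drop = TRUE)
  rows <- lapply(pieces, function(tr) {
    tr <- tr[order(tr$sample_index), ]
    tpl <- make_template(tr$alpha[1], tr$beta[1], scale)
    v <- validate_trial(tr, min_speed)
    data.frame(subject_id = tr$subject_id[1], session = tr$session[1],
               trial_index = tr$trial_index[1],
               alpha = tr$alpha[1], beta = tr$beta[1],
               valid = v$valid,
               reasons = paste(v$reasons, collapse = ";"),
               rmse_cm = if (v$valid) trajectory_rmse(tr, tpl) else NA_real_,
               endpoint_cm = if (v$valid) endpoint_error(tr, tpl) else NA_real_)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out[order(out$subject_id, out$trial_index), ]
}

#' Subject-dummy regression of motor error on localization error
#'
#' Linear model of per-trajectory motor error on per-trajectory localization
#' error with one dummy-coded intercept per subject and a common slope; the
#' fixed-effect slope tests whether trajectory-local localization error
#' predicts motor error across trajectories within subjects. The residual
#' degrees of freedom are `N - n_subjects - 1`.
#'
#' @param motor per-trajectory motor error (e.g. RMSE, cm).
#' @param localization per-trajectory localization error (cm).
#' @param subject subject identifier per observation.
#' @return list with `slope`, `ci` (95\%), `t`, `df`, `p_value`, `n`,
#'   `n_subjects`.
#' @export
subject_dummy_regression <- function(motor, localization, subject) {
  subject <- as.factor(subject)
  if (nlevels(subject) < 2) stop_("need at least 2 subjects")
  ok <- is.finite(motor) & is.finite(localization)
  motor <- motor[ok]; localization <- localization[ok]; subject <- droplevels(subject[ok])
  fit <- stats::lm(motor ~ localization + subject)
  if (anyNA(stats::coef(fit)))
    stop_("degenerate design: collinear predictors")
  sm <- summary(fit)$coefficients
  ci <- suppressMessages(stats::confint(fit, "localization", level = 0.95))
  list(slope = unname(stats::coef(fit)["localization"]),
       ci = c(ci[1], ci[2]),
       t = unname(sm["localization", "t value"]),
       df = stats::df.residual(fit),
       p_value = unname(sm["localization", "Pr(>|t|)"]),
       n = length(motor), n_subjects = nlevels(subject))
}

#' Correlation between subject-level motor and localization error
#'
#' Pearson correlation by default; Spearman's rho when a Shapiro-Wilk
#' normality pre-check fails (p < 0.05) for either variable.
#'
#' @param motor per-subject mean motor error.
#' @param localization per-subject mean localization error.
#' @param method `"auto"` (normality-checked), `"pearson"`, or `"spearman"`.
#' @return list with `estimate`, `p_value`, `method`, `n`.
#' @export
motor_vs_localization_correlation <- function(motor, localization,
                                              method = c("auto", "pearson", "spearman")) {
  method <- match.arg(method)
  if (length(motor) < 3) stop_("need at least 3 subjects")
  if (stats::sd(motor) == 0 || stats::sd(localization) == 0)
    stop_("correlation undefined for a constant vector")
  if (method == "auto") {
    p1 <- stats::shapiro.test(motor)$p.value
    p2 <- stats::shapiro.test(localization)$p.value
    method <- if (min(p1, p2) < 0.05) "spearman" else "pearson"
  }
  ct <- stats::cor.test(motor, localization, method = method, exact = FALSE)
  list(estimate = unname(ct$estimate), p_value = ct$p.value,
       method = method, n = length(motor))
}
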