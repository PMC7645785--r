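# Synthetic cohort generator.
#
# Emulates the statistical structure of multi-session visual-matching data:
# each subject carries a smooth idiosyncratic error vector field over the
# target grid, all subjects share a group bias field (rightward errors that
# grow with distance from the left shoulder, inflated in the far rows), a
# per-session learning factor shrinks the measured map, and i.i.d. noise is
# added per target. Trajectory-matching trials are generated alongside with
# template-dependent motor deviation that is, by default, independent of the
# localization field.

#' Configuration of a synthetic cohort
#'
#' Defaults are calibrated so that a simulated cohort reproduces the summary
#' structure of real multi-session visual-matching data: session-1 mean error
#' magnitude near 3 cm, within-subject map correlations near 0.45, and
#' between-subject correlations near 0.15.
#'
#' @param n_subjects number of subjects.
#' @param sessions session labels (integer vector).
#' @param learning_factors one multiplicative shrinkage factor per session;
#'   the default (1, 0.95, 0.78) concentrates improvement on the second day.
#' @param idio_scale RMS vector magnitude (mm) of the per-subject
#'   idiosyncratic field.
#' @param smoothness correlation length (mm) of the idiosyncratic field.
#' @param noise_sd per-target, per-component measurement noise SD in mm.
#' @param group_bias list with `drift_per_mm` (rightward x-error per mm of
#'   distance from the left shoulder), `shoulder_x` (shoulder x position, mm),
#'   `forward_bias` (constant y-error, mm), and `far_gain` (magnitude gain
#'   applied to the measured error in the two far rows — the
#'   distance-from-body effect).
#' @param coupling strength of the localization-field to motor-noise
#'   coupling in trajectory trials (0 = independent, the default).
#' @param trajectory list of trajectory-trial parameters: `b0` and `b1` set
#'   the motor deviation amplitude `b0 + b1 * abs(beta)` in mm, `duration` is
#'   the movement time in s, `sample_rate` in Hz, `n_repeats` the number of
#'   consecutive repetitions of each template.
#' @param geometry a [workspace_geometry()].
#' @param seed root RNG seed; per-subject streams are derived by fixed
#'   offsets so adding subjects does not perturb existing ones.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 26,
                          sessions = 1:3,
                          learning_factors = c(1, 0.95, 0.78),
                          idio_scale = 15,
                          smoothness = 60,
                          noise_sd = 13,
                          group_bias = list(drift_per_mm = 0.06, shoulder_x = -180,
                                            forward_bias = 4, far_gain = 1.5),
                          coupling = 0,
                          trajectory = list(b0 = 2.5, b1 = 3, duration = 1.2,
                                            sample_rate = 130, n_repeats = 2),
                          geometry = workspace_geometry(),
                          seed = 1L) {
  if (length(learning_factors) != length(sessions))
    stop_("need one learning factor per session")
  if (any(learning_factors <= 0 | learning_factors > 1.5))
    stop_("learning factors must lie in (0, 1.5]")
  if (noise_sd < 0) stop_("noise_sd must be non-negative")
  if (idio_scale < 0) stop_("idio_scale must be non-negative")
  gb <- utils::modifyList(list(drift_per_mm = 0.06, shoulder_x = -180,
                               forward_bias = 4, far_gain = 1.5), group_bias)
  tr <- utils::modifyList(list(b0 = 2.5, b1 = 3, duration = 1.2,
                               sample_rate = 130, n_repeats = 2), trajectory)
  structure(
    list(n_subjects = as.integer(n_subjects), sessions = as.integer(sessions),
         learning_factors = learning_factors, idio_scale = idio_scale,
         smoothness = smoothness, noise_sd = noise_sd, group_bias = gb,
         coupling = coupling, trajectory = tr, geometry = geometry,
         seed = as.integer(seed)),
    class = "cohort_config")
}

subject_ids <- function(config) sprintf("S%02d", seq_len(config$n_subjects))

# cache of field-normalization constants keyed by geometry + smoothness
.field_norm_cache <- new.env(parent = emptyenv())

# E[ sqrt(mean_i |f_i|^2) ] for f = K z with z ~ N(0, I), computed exactly
# from the eigenvalues of K K' via E[sqrt(Q)] =
# (2 sqrt(pi))^-1 int t^(-3/2) (1 - prod_j (1 + 2 t lambda_j / n)^-1) dt,
# since Q is a weighted sum of independent chi-square(2) variables.
expected_field_rms <- function(K, key) {
  if (!is.null(.field_norm_cache[[key]])) return(.field_norm_cache[[key]])
  n <- nrow(K)
  lambda <- eigen(tcrossprod(K), symmetric = TRUE, only.values = TRUE)$values
  lambda <- lambda[lambda > max(lambda) * 1e-12]
  integrand <- function(t)
    t^(-1.5) * (1 - vapply(t, function(tt)
      1 / prod(1 + 2 * tt * lambda / n), numeric(1)))
  val <- stats::integrate(integrand, 0, Inf, rel.tol = 1e-9)$value / (2 * sqrt(pi))
  .field_norm_cache[[key]] <- val
  val
}

# rows counted as "far" (away from the body): the last two of five by the
# regional convention, generalized as rows beyond 60% of the row count.
far_rows <- function(n_rows) which(seq_len(n_rows) > ceiling(0.6 * n_rows))

# per-row magnitude gain: 1 in the near rows, far_gain in the far rows
row_gain <- function(config, n_rows) {
  gain <- rep(1, n_rows)
  gain[far_rows(n_rows)] <- config$group_bias$far_gain
  gain
}

# apply the per-row gain to a c(2, n_rows, n_cols) field
apply_row_gain <- function(field, gain) {
  for (r in seq_along(gain)) field[, r, ] <- field[, r, ] * gain[r]
  field
}

#' Shared group bias field
#'
#' Rightward x-errors growing linearly with distance from the left shoulder
#' plus a small constant forward y-error, inflated by the far-region gain:
#' the error field a grand average over many subjects would show.
#'
#' @param config a [cohort_config()].
#' @param grid a [make_target_grid()] grid (defaults to the config geometry).
#' @return array `c(2, n_rows, n_cols)` of bias vectors in mm (component 1 =
#'   x, component 2 = y).
#' @export
group_bias_field <- function(config, grid = make_target_grid(config$geometry)) {
  geom <- attr(grid, "geometry")
  apply_row_gain(bias_core(config, grid), row_gain(config, geom$n_rows))
}

# the bias before the far-region magnitude gain
bias_core <- function(config, grid = make_target_grid(config$geometry)) {
  geom <- attr(grid, "geometry")
  gb <- config$group_bias
  bias <- array(0, dim = c(2L, geom$n_rows, geom$n_cols))
  for (i in seq_len(nrow(grid))) {
    r <- grid$row[i]; c <- grid$col[i]
    bias[1, r, c] <- gb$drift_per_mm * (grid$x_mm[i] - gb$shoulder_x)
    bias[2, r, c] <- gb$forward_bias
  }
  bias
}

#' Sample a subject's idiosyncratic error field
#'
#' White noise per target and component, smoothed with a Gaussian kernel of
#' correlation length `config$smoothness`, then rescaled so the RMS vector
#' magnitude over targets equals `config$idio_scale` in expectation (the
#' realized magnitude varies between subjects, as real idiosyncrasy does).
#' Deterministic given `(config$seed, subject_index)`.
#'
#' @param config a [cohort_config()].
#' @param subject_index 1-based subject index.
#' @param grid target grid (defaults to the config geometry).
#' @return an object of class `subject_field` holding the field array
#'   (`c(2, n_rows, n_cols)`, mm) and the generating parameters.
#' @export
sample_subject_field <- function(config, subject_index,
                                 grid = make_target_grid(config$geometry)) {
  geom <- attr(grid, "geometry")
  n <- nrow(grid)
  d2 <- outer(grid$x_mm, grid$x_mm, "-")^2 + outer(grid$y_mm, grid$y_mm, "-")^2
  K <- exp(-d2 / (2 * config$smoothness^2))
  z <- with_seed(derive_seed(config$seed, subject_index, purpose = 0),
                 matrix(stats::rnorm(2L * n), nrow = n, ncol = 2L))
  f <- K %*% z
  key <- paste(geom$width, geom$depth, geom$body_offset, geom$n_rows,
               geom$n_cols, config$smoothness, sep = "|")
  rms_expected <- expected_field_rms(K, key)
  f <- if (config$idio_scale == 0) f * 0 else f * (config$idio_scale / rms_expected)
  field <- array(0, dim = c(2L, geom$n_rows, geom$n_cols))
  for (i in seq_len(n)) {
    field[1, grid$row[i], grid$col[i]] <- f[i, 1]
    field[2, grid$row[i], grid$col[i]] <- f[i, 2]
  }
  structure(list(field = field, subject_index = as.integer(subject_index),
                 idio_scale = config$idio_scale, smoothness = config$smoothness),
            class = "subject_field")
}

#' Simulate one measured session map
#'
#' The measured map is `learning_factor x row_gain x (group bias +
#' idiosyncratic field + noise)`: the far-region gain inflates error
#' magnitudes in the rows away from the body (the distance-from-body effect
#' applies to the whole measured error, not just its shared component), and
#' the session factor shrinks the whole measured error — which keeps map
#' correlations scale-invariant across sessions while the mean error
#' magnitude shrinks in proportion, the pattern seen in repeated
#' visual-matching measurements.
#'
#' @param field a [sample_subject_field()] result.
#' @param session session label (must be one of `config$sessions`).
#' @param config a [cohort_config()].
#' @param grid target grid.
#' @param seed optional noise seed; by default derived from the config seed,
#'   the field's subject index and the session.
#' @return array `c(2, n_rows, n_cols)` of error vectors in mm.
#' @export
generate_session_map <- function(field, session, config,
                                 grid = make_target_grid(config$geometry),
                                 seed = NULL) {
  s_idx <- match(session, config$sessions)
  if (is.na(s_idx)) stop_("unknown session label '%s'", session)
  lf <- config$learning_factors[s_idx]
  geom <- attr(grid, "geometry")
  seed <- seed %||% derive_seed(config$seed, field$subject_index, s_idx, purpose = 1)
  noise <- with_seed(seed,
    array(stats::rnorm(2L * geom$n_rows * geom$n_cols, sd = config$noise_sd),
          dim = c(2L, geom$n_rows, geom$n_cols)))
  lf * apply_row_gain(bias_core(config, grid) + field$field + noise,
                      row_gain(config, geom$n_rows))
}

#' Generate a full matching-trial table
#'
#' One row per subject x session x target, with randomized target order per
#' session and hand positions equal to target + simulated error. Bit-identical
#' given the same config (including seed).
#'
#' @param config a [cohort_config()].
#' @return a data frame with columns `subject_id`, `experiment`, `session`,
#'   `trial_index`, `target_row`, `target_col`, `target_x_mm`, `target_y_mm`,
#'   `hand_x_mm`, `hand_y_mm`.
#' @export
generate_cohort <- function(config) {
  if (config$n_subjects < 2)
    stop_("n_subjects must be at least 2 (similarity analyses are undefined otherwise)")
  grid <- make_target_grid(config$geometry)
  n_t <- nrow(grid)
  ids <- subject_ids(config)
  out <- vector("list", config$n_subjects * length(config$sessions))
  k <- 0L
  for (i in seq_len(config$n_subjects)) {
    field <- sample_subject_field(config, i, grid)
    for (s_idx in seq_along(config$sessions)) {
      session <- config$sessions[s_idx]
      map <- generate_session_map(field, session, config, grid)
      err <- cbind(map[cbind(1L, grid$row, grid$col)],
                   map[cbind(2L, grid$row, grid$col)])
      ord <- with_seed(derive_seed(config$seed, i, s_idx, purpose = 2),
                       sample.int(n_t))
      k <- k + 1L
      out[[k]] <- data.frame(
        subject_id = ids[i], experiment = 1L, session = session,
        trial_index = seq_len(n_t),
        target_row = grid$row[ord], target_col = grid$col[ord],
        target_x_mm = grid$x_mm[ord], target_y_mm = grid$y_mm[ord],
        hand_x_mm = grid$x_mm[ord] + err[ord, 1],
        hand_y_mm = grid$y_mm[ord] + err[ord, 2])
    }
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

# expected squared magnitude of the deviation shape basis at the RMSE cut
# points, used to normalize so the deviation RMS equals the amplitude.
.dev_weights <- c(linear = 1, sin1 = 1, sin2 = 0.6)
.dev_norm <- function(n_cut = 30) {
  y <- seq_len(n_cut) / n_cut
  sqrt(.dev_weights[1]^2 * mean(y^2) +
       .dev_weights[2]^2 * mean(sin(pi * y)^2) +
       .dev_weights[3]^2 * mean(sin(2 * pi * y)^2))
}

#' Generate trajectory-matching trials
#'
#' Each subject performs every template `n_repeats` times in a row (template
#' order randomized per subject), producing constant-depth-speed movement
#' traces sampled at `sample_rate` Hz over `duration` s. The trace is the
#' template plus a smooth random deviation whose RMS amplitude is
#' `b0 + b1 * abs(beta) + coupling * local field magnitude`, so motor noise
#' grows with template curvature and is independent of the localization
#' field unless `coupling > 0`.
#'
#' @param config a [cohort_config()].
#' @param templates list of [make_template()] templates.
#' @param fields optional list of [sample_subject_field()] objects (one per
#'   subject), required when `config$coupling != 0`.
#' @param session session label recorded in the table (trajectory trials are
#'   performed once, on day 1).
#' @param prop_invalid proportion of trials injected with a validity defect
#'   (too slow or containing a backward step) for filter testing.
#' @return a long data frame with columns `subject_id`, `session`,
#'   `trial_index`, `alpha`, `beta`, `sample_index`, `t_s`, `x_mm`, `y_mm`,
#'   `valid`.
#' @export
generate_trajectory_trials <- function(config, templates = default_template_set(),
                                       fields = NULL, session = 1L,
                                       prop_invalid = 0) {
  if (length(templates) == 0) stop_("templates must be non-empty")
  if (config$coupling != 0 && is.null(fields))
    stop_("coupling is non-zero but no subject fields were supplied")
  tr <- config$trajectory
  grid <- make_target_grid(config$geometry)
  n_s <- as.integer(round(tr$duration * tr$sample_rate)) + 1L
  t_s <- (seq_len(n_s) - 1L) / tr$sample_rate
  yu <- (seq_len(n_s) - 1L) / (n_s - 1L)           # template units, 0..1
  scale <- templates[[1]]$scale
  norm <- .dev_norm()
  basis <- cbind(yu, sin(pi * yu), sin(2 * pi * yu)) %*% diag(.dev_weights / norm)
  ids <- subject_ids(config)
  n_trials <- length(templates) * tr$n_repeats
  out <- vector("list", config$n_subjects)
  for (i in seq_len(config$n_subjects)) {
    res <- with_seed(derive_seed(config$seed, i, purpose = 60013), {
      ord <- rep(sample.int(length(templates)), each = tr$n_repeats)
      xs <- matrix(0, n_s, n_trials)
      ys <- matrix(rep(yu * scale, n_trials), n_s, n_trials)
      tt <- matrix(rep(t_s, n_trials), n_s, n_trials)
      ab <- matrix(0, n_trials, 2)
      bad <- logical(n_trials)
      for (k in seq_len(n_trials)) {
        tpl <- templates[[ord[k]]]
        amp <- tr$b0 + tr$b1 * abs(tpl$beta)
        if (config$coupling != 0) {
          fmap <- fields[[i]]$field / 10  # cm, as error maps are reported
          amp <- amp + config$coupling *
            10 * local_localization_error(fmap, tpl, grid)
        }
        dev <- as.vector(basis %*% stats::rnorm(3)) * amp
        xs[, k] <- template_x(tpl, yu) + dev
        ab[k, ] <- c(tpl$alpha, tpl$beta)
        if (prop_invalid > 0 && stats::runif(1) < prop_invalid) {
          bad[k] <- TRUE
          if (stats::runif(1) < 0.5) {
            tt[, k] <- tt[, k] * 3          # too slow
          } else {
            j <- floor(n_s / 2)
            ys[j, k] <- ys[j - 2, k]        # backward step
          }
        }
      }
      list(ord = ord, xs = xs, ys = ys, tt = tt, ab = ab, bad = bad)
    })
    out[[i]] <- data.frame(
      subject_id = ids[i], session = as.integer(session),
      trial_index = rep(seq_len(n_trials), each = n_s),
      alpha = rep(res$ab[, 1], each = n_s),
      beta = rep(res$ab[, 2], each = n_s),
      sample_index = rep(seq_len(n_s), n_trials),
      t_s = as.vector(res$tt), x_mm = as.vector(res$xs), y_mm = as.vector(res$ys),
      valid = rep(!res$bad, each = n_s))
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf(paste0("cohort config: %d subjects, sessions %s ",
                     "(learning factors %s)\n  idio_scale %.1f mm, noise_sd %.1f mm, ",
                     "coupling %.2f, seed %d\n"),
              x$n_subjects, paste(x$sessions, collapse = ","),
              paste(x$learning_factors, collapse = ","),
              x$idio_scale, x$noise_sd, x$coupling, x$seed))
  invisible(x)
}
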