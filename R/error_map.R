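# Error-map construction and the regional / directional summaries.
#
# An error map is a 2 x n_rows x n_cols array of localization error vectors
# in cm: component 1 is the mediolateral error x_e, component 2 the depth
# error y_e, both defined as hand minus target (the vector's tail sits at
# the target, its head at the registered hand position). Internally the
# simulator works in mm; the conversion to cm happens once, here.

#' Construct an error map object
#'
#' @param errors array `c(2, n_rows, n_cols)` of error vectors in cm.
#' @param subject_id subject identifier.
#' @param session session label.
#' @return an object of class `error_map`.
#' @export
error_map <- function(errors, subject_id = NA_character_, session = NA) {
  if (!is.array(errors) || length(dim(errors)) != 3 || dim(errors)[1] != 2)
    stop_("errors must be a 2 x n_rows x n_cols array")
  if (!all(is.finite(errors))) stop_("error map contains non-finite values")
  structure(list(errors = errors, subject_id = subject_id, session = session),
            class = "error_map")
}

#' Build an error map from one subject-session block of matching trials
#'
#' Requires exactly one trial per grid target; the error vector at each
#' target is `hand - target`, converted from mm to cm.
#'
#' @param trials data frame of matching trials for a single subject and
#'   session (columns `target_row`, `target_col`, `target_x_mm`,
#'   `target_y_mm`, `hand_x_mm`, `hand_y_mm`).
#' @param grid a [make_target_grid()] grid.
#' @return an `error_map`.
#' @export
build_error_map <- function(trials, grid = make_target_grid()) {
  geom <- attr(grid, "geometry")
  if (length(unique(trials$subject_id %||% "x")) > 1 ||
      length(unique(trials$session %||% 1)) > 1)
    stop_("trials must come from a single subject and session")
  key <- paste(trials$target_row, trials$target_col)
  dup <- key[duplicated(key)]
  if (length(dup))
    stop_("incomplete error map: duplicate trial at target (row, col) = (%s)",
          dup[1])
  errs <- array(NA_real_, dim = c(2L, geom$n_rows, geom$n_cols))
  idx_r <- trials$target_row; idx_c <- trials$target_col
  errs[cbind(1L, idx_r, idx_c)] <- (trials$hand_x_mm - trials$target_x_mm) / 10
  errs[cbind(2L, idx_r, idx_c)] <- (trials$hand_y_mm - trials$target_y_mm) / 10
  if (anyNA(errs)) {
    miss <- which(is.na(errs[1, , ]), arr.ind = TRUE)
    stop_("incomplete error map: missing trial at target (row, col) = (%d, %d)",
          miss[1, 1], miss[1, 2])
  }
  error_map(errs,
            subject_id = as.character(trials$subject_id[1] %||% NA_character_),
            session = trials$session[1] %||% NA)
}

#' Build all error maps in a trial table
#'
#' @param trials full matching-trial table (see [generate_cohort()] for the
#'   schema).
#' @param grid a [make_target_grid()] grid.
#' @return a list of `error_map` objects named `"<subject_id>.<session>"`,
#'   with attributes `subjects` and `sessions`.
#' @export
build_error_maps <- function(trials, grid = make_target_grid()) {
  pieces <- split(trials, list(trials$subject_id, trials$session), drop = TRUE)
  maps <- lapply(pieces, build_error_map, grid = grid)
  structure(maps,
            subjects = sort(unique(trials$subject_id)),
            sessions = sort(unique(trials$session)))
}

# 5 x 20 matrix of vector magnitudes (cm)
map_magnitudes <- function(map) {
  sqrt(map$errors[1, , ]^2 + map$errors[2, , ]^2)
}

#' Mean error magnitude of a map
#'
#' Mean over all targets of the Euclidean length of the error vector, in cm.
#'
#' @param map an `error_map`.
#' @return scalar, cm.
#' @export
mean_error_magnitude <- function(map) {
  mean(map_magnitudes(map))
}

#' Regional error summary
#'
#' The workspace is split by the vertical midline into left/right halves
#' (10 columns each) and by depth into a near region (the three rows closest
#' to the body) and a far region (the remaining two rows).
#'
#' @param map an `error_map`.
#' @return a list with mean error magnitudes (cm) `left`, `right`, `near`,
#'   `far`, `overall`.
#' @export
regional_errors <- function(map) {
  m <- map_magnitudes(map)
  n_rows <- nrow(m); n_cols <- ncol(m)
  fr <- far_rows(n_rows)
  left_cols <- seq_len(n_cols %/% 2)
  list(left = mean(m[, left_cols]),
       right = mean(m[, setdiff(seq_len(n_cols), left_cols)]),
       near = mean(m[setdiff(seq_len(n_rows), fr), ]),
       far = mean(m[fr, ]),
       overall = mean(m))
}

#' Percentage error reduction relative to the first session
#'
#' `100 * (error_1 - error_i) / error_1`; positive values mean improvement.
#'
#' @param error_1 mean error magnitude of the reference (first) session, cm.
#' @param error_i mean error magnitude(s) of the compared session(s), cm.
#' @return signed percentage(s).
#' @export
error_reduction <- function(error_1, error_i) {
  if (any(error_1 <= 0)) stop_("error_1 must be positive")
  100 * (error_1 - error_i) / error_1
}

#' Average a subject's maps across sessions
#'
#' @param maps list of `error_map`s from the same subject.
#' @return an `error_map` of component-wise per-target means, with session
#'   label the concatenation of the inputs' sessions.
#' @export
average_subject_map <- function(maps) {
  if (length(maps) < 1) stop_("need at least one map")
  subj <- unique(vapply(maps, function(m) m$subject_id, character(1)))
  if (length(subj) > 1)
    stop_("cannot average maps across subjects (%s)", paste(subj, collapse = ", "))
  acc <- Reduce(`+`, lapply(maps, function(m) m$errors)) / length(maps)
  error_map(acc, subject_id = subj,
            session = paste(vapply(maps, function(m) as.character(m$session),
                                   character(1)), collapse = "+"))
}

#' Exact one-tailed binomial critical counts
#'
#' For `n` subjects and null proportion `p0`, the smallest count `upper`
#' with `P(X >= upper) < alpha` and the largest count `lower` with
#' `P(X <= lower) < alpha` under `X ~ Binomial(n, p0)`. For n = 26 at
#' alpha = 0.05 these are 18 and 8: at least 18 (or at most 8) subjects
#' biased to one side is significant. `NA` is returned for a tail where no
#' count attains `alpha`.
#'
#' @param n number of subjects.
#' @param p0 null proportion (default 0.5).
#' @param alpha one-tailed significance level.
#' @return integer vector `c(lower, upper)` (possibly `NA`).
#' @export
binomial_critical_counts <- function(n, p0 = 0.5, alpha = 0.05) {
  if (n < 1) stop_("n must be at least 1")
  if (alpha <= 0 || alpha >= 1) stop_("alpha must lie strictly between 0 and 1")
  k <- 0:n
  p_upper <- stats::pbinom(k - 1, n, p0, lower.tail = FALSE)  # P(X >= k)
  p_lower <- stats::pbinom(k, n, p0)                          # P(X <= k)
  up <- k[p_upper < alpha]
  lo <- k[p_lower < alpha]
  c(lower = if (length(lo)) max(lo) else NA_integer_,
    upper = if (length(up)) min(up) else NA_integer_)
}

#' Per-target direction-bias test
#'
#' For each target, counts the subjects whose (session-averaged) error
#' component is positive (rightward for x, away from the body for y) and
#' flags the targets where the count reaches the exact one-tailed binomial
#' critical counts at either tail. Components exactly 0 count as
#' not-positive.
#'
#' @param maps list of per-subject averaged `error_map`s (one per subject).
#' @param component `"x"` or `"y"`.
#' @param alpha one-tailed significance level per tail.
#' @return a data frame with one row per target: `row`, `col`, `n_positive`,
#'   `fraction`, `significant`; attribute `critical` holds the counts.
#' @export
direction_bias_test <- function(maps, component = c("x", "y"), alpha = 0.05) {
  component <- match.arg(component)
  if (length(maps) < 2) stop_("need at least 2 subjects")
  comp <- if (component == "x") 1L else 2L
  n <- length(maps)
  dims <- dim(maps[[1]]$errors)
  pos <- Reduce(`+`, lapply(maps, function(m) (m$errors[comp, , ] > 0) * 1L))
  crit <- binomial_critical_counts(n, 0.5, alpha)
  sig <- matrix(FALSE, dims[2], dims[3])
  if (!is.na(crit["upper"])) sig <- sig | (pos >= crit["upper"])
  if (!is.na(crit["lower"])) sig <- sig | (pos <= crit["lower"])
  g <- expand.grid(row = seq_len(dims[2]), col = seq_len(dims[3]))
  out <- data.frame(row = g$row, col = g$col,
                    n_positive = pos[cbind(g$row, g$col)],
                    fraction = pos[cbind(g$row, g$col)] / n,
                    significant = sig[cbind(g$row, g$col)])
  attr(out, "critical") <- crit
  attr(out, "n_subjects") <- n
  out
}

#' @export
print.error_map <- function(x, ...) {
  d <- dim(x$errors)
  cat(sprintf("error map: subject %s, session %s, %d x %d targets, mean error %.3f cm\n",
              x$subject_id, x$session, d[2], d[3], mean_error_magnitude(x)))
  invisible(x)
}

#' Quiver plot of an error map
#'
#' Draws each error vector with its tail at the target location (arrows are
#' drawn in workspace mm; errors are magnified by `magnify` for visibility).
#'
#' @param x an `error_map`.
#' @param grid a [make_target_grid()] grid.
#' @param magnify visual magnification of the error vectors.
#' @param ... passed to [graphics::plot()].
#' @export
plot.error_map <- function(x, grid = make_target_grid(), magnify = 3, ...) {
  graphics::plot(grid$x_mm, grid$y_mm, pch = 16, cex = 0.4, asp = 1,
                 xlab = "x (mm)", ylab = "y (mm)",
                 main = sprintf("subject %s, session %s", x$subject_id, x$session),
                 ...)
  dx <- x$errors[cbind(1L, grid$row, grid$col)] * 10 * magnify
  dy <- x$errors[cbind(2L, grid$row, grid$col)] * 10 * magnify
  graphics::arrows(grid$x_mm, grid$y_mm, grid$x_mm + dx, grid$y_mm + dy,
                   length = 0.03, col = "firebrick")
  invisible(x)
}
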