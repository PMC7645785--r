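# Trajectory templates, validity filtering, cut-point RMSE, endpoint error,
# sandwich target selection, and the motor-vs-localization analyses.

test_that("template curve obeys x = alpha*y + beta*sin(pi*y) on the 211 mm scale", {
  expect_equal(template_x(make_template(0.7, -0.4), 0), 0)
  expect_equal(template_x(make_template(0, 0.1), 0.5), 21.1)
  expect_equal(template_x(make_template(0.7, -0.4), 1), 0.7 * 211, tolerance = 1e-12)
})

test_that("default template set spans the stated ranges with 15 members", {
  tpls <- default_template_set()
  expect_length(tpls, 15)
  a <- sapply(tpls, `[[`, "alpha")
  b <- sapply(tpls, `[[`, "beta")
  expect_true(all(a >= -1 & a <= 1))
  expect_true(all(b >= -0.9 & b <= 0.8))
  expect_equal(range(a), c(-1, 1))
  expect_equal(range(b), c(-0.9, 0.8))
  expect_false(any(a == 0 & b == 0.1))  # familiarization template excluded
})

test_that("validity filter flags slow, backward, and premature movements", {
  tr <- template_trace(make_template(0.5, 0.3))  # 229 mm/s-ish over 1.2 s
  expect_true(validate_trial(tr)$valid)
  slow <- tr; slow$t_s <- tr$t_s * 3
  expect_equal(validate_trial(slow)$reasons, "slow")
  back <- tr; back$y_mm[80] <- back$y_mm[78]
  expect_true("backward" %in% validate_trial(back)$reasons)
  early <- tr; early$t_s <- tr$t_s - 0.05
  expect_true("early-start" %in% validate_trial(early)$reasons)
  expect_error(validate_trial(tr[1, ]), "at least 2")
})

test_that("RMSE is the square root of the 30-term cut-point sum", {
  tpl <- make_template(0.4, -0.6)
  exact <- template_trace(tpl, n_samples = 301)  # nodes include all k/30 cuts
  expect_equal(trajectory_rmse(exact, tpl), 0, tolerance = 1e-9)
  # constant offset d cm -> d * sqrt(30)
  off <- exact; off$x_mm <- off$x_mm + 12  # 1.2 cm
  expect_equal(trajectory_rmse(off, tpl), 1.2 * sqrt(30), tolerance = 1e-9)
  expect_equal(trajectory_rmse(off, tpl, normalized = TRUE), 1.2, tolerance = 1e-9)
  # beta-only deviation 0.1 against the straight template: 2.11 * sqrt(15)
  straight <- make_template(0, 0)
  curved <- template_trace(make_template(0, 0.1), n_samples = 301)
  expect_equal(trajectory_rmse(curved, straight), 2.11 * sqrt(15), tolerance = 1e-9)
  short <- exact[exact$y_mm < 200, ]
  expect_error(trajectory_rmse(short, tpl), "does not reach")
})

test_that("RMSE depends only on x at the cut points, not on timing", {
  tpl <- make_template(-0.5, 0.8)
  tr <- template_trace(tpl, n_samples = 301)
  tr$x_mm <- tr$x_mm + 5
  warped <- tr
  warped$t_s <- tr$t_s^2 / max(tr$t_s)  # nonuniform time reparameterization
  expect_equal(trajectory_rmse(warped, tpl), trajectory_rmse(tr, tpl),
               tolerance = 1e-12)
  # rmse^2 is at least the squared final-cut deviation
  dev_end <- (5 / 10)^2
  expect_gte(trajectory_rmse(tr, tpl)^2 + 1e-12, dev_end)
})

test_that("interpolated cut-point x matches a dense-resampling oracle", {
  tpl <- make_template(0.3, 0.5)
  trace <- template_trace(make_template(0.3, 0.5), n_samples = 30001)
  dev <- trajectory_rmse(trace, make_template(0, 0))
  # oracle: analytic evaluation at the 30 cut points
  cuts <- (1:30) / 30
  expected <- sqrt(sum((template_x(tpl, cuts) / 10)^2))
  expect_equal(dev, expected, tolerance = 1e-6)
})

test_that("endpoint error is the absolute x deviation at y = 1", {
  tpl <- make_template(0.2, -0.7)
  tr <- template_trace(tpl, n_samples = 301)
  expect_equal(endpoint_error(tr, tpl), 0, tolerance = 1e-12)
  off <- tr; off$x_mm <- off$x_mm + 10
  expect_equal(endpoint_error(off, tpl), 1, tolerance = 1e-9)
  # a beta-only perturbation vanishes at the endpoint (sin(pi) = 0)
  pert <- template_trace(make_template(0.2, 0.3), n_samples = 301)
  expect_equal(endpoint_error(pert, tpl), 0, tolerance = 1e-9)
})

test_that("sandwich targets bracket the trajectory on each row, clamped at edges", {
  grid <- make_target_grid()
  uni <- uniform_map(0.6, 0.8)
  expect_equal(local_localization_error(uni, make_template(0.4, -0.3), grid), 1)
  expect_equal(endpoint_localization_error(uni, make_template(0.4, -0.3), grid), 1)
  # straight midline template selects the two middle columns on every row
  m <- uniform_map(1, 0)
  m$errors[1, , 10] <- 2  # column at -12.19 mm
  m$errors[1, , 11] <- 4  # column at +12.19 mm
  expect_equal(local_localization_error(m, make_template(0, 0), grid), 3)
  expect_equal(endpoint_localization_error(m, make_template(0, 0), grid), 3)
  # template far right of the grid clamps to the two rightmost columns
  mr <- uniform_map(1, 0)
  mr$errors[1, , 19:20] <- 5
  far_right <- make_template(10, 0)  # x > 269 mm at every row depth
  expect_equal(local_localization_error(mr, far_right, grid), 5)
  expect_equal(endpoint_localization_error(mr, far_right, grid), 5)
})

test_that("subject-dummy regression recovers an exact common slope", {
  set.seed(1)
  subj <- rep(sprintf("S%02d", 1:26), each = 15)
  x <- runif(390)
  offs <- rep(rnorm(26), each = 15)
  y <- 2 * x + offs
  # perfect fit: lm warns that the summary may be unreliable, which is fine here
  fit <- suppressWarnings(subject_dummy_regression(y, x, subj))
  expect_equal(fit$slope, 2, tolerance = 1e-8)
  expect_lt(diff(fit$ci), 1e-6)
  expect_equal(fit$df, 390 - 26 - 1)   # N - n_subjects - 1
  expect_error(subject_dummy_regression(y, rep(1, 390), subj), "degenerate|undefined")
})

test_that("dummy-regression CI covers a null slope at the nominal rate", {
  set.seed(99)
  cover <- replicate(60, {
    subj <- rep(sprintf("S%02d", 1:8), each = 6)
    x <- rnorm(48)
    y <- rep(rnorm(8), each = 6) + rnorm(48)
    ci <- subject_dummy_regression(y, x, subj)$ci
    ci[1] <= 0 && 0 <= ci[2]
  })
  expect_gte(mean(cover), 0.85)
})

test_that("motor-localization correlation switches method on non-normal data", {
  x <- c(1, 2, 3, 4, 5, 6, 7, 8)
  expect_equal(motor_vs_localization_correlation(x, x, "pearson")$estimate, 1)
  set.seed(2)
  xs <- rnorm(30)
  skew <- exp(3 * xs) # grossly non-normal
  res <- motor_vs_localization_correlation(skew, xs + rnorm(30, sd = 0.1))
  expect_equal(res$method, "spearman")
  expect_error(motor_vs_localization_correlation(rep(1, 10), xs[1:10]), "constant")
  expect_error(motor_vs_localization_correlation(x[1:2], x[1:2]), "at least 3")
})

test_that("curvature-dependent motor noise yields positive RMSE-|beta| coupling", {
  co <- cohort_config(n_subjects = 10, seed = 77)
  sc <- score_trajectories(generate_trajectory_trials(co))
  per_subj <- sapply(split(sc, sc$subject_id), function(d)
    cor(abs(d$beta), d$rmse_cm))
  expect_gte(sum(per_subj > 0), 9)
})

test_that("strong field-motor coupling with low noise gives strong correlations", {
  # motor deviation driven almost entirely by the local localization field;
  # the correlation ceiling is < 1 because the 15 templates sample only part
  # of the workspace the whole-map error average covers
  rs <- sapply(1:6, function(s) {
    co <- cohort_config(n_subjects = 20, coupling = 10, noise_sd = 2,
                        group_bias = list(drift_per_mm = 0.01),
                        trajectory = list(b0 = 0.1, b1 = 0.1, n_repeats = 6),
                        seed = 600 + s)
    fields <- lapply(seq_len(co$n_subjects), sample_subject_field, config = co)
    sc <- score_trajectories(generate_trajectory_trials(co, fields = fields))
    maps <- build_error_maps(generate_cohort(co))
    sess <- sapply(maps, function(m) m$session)
    loc <- sapply(maps[sess == 1], mean_error_magnitude)
    rmse <- tapply(sc$rmse_cm, sc$subject_id, mean)
    cor(as.vector(rmse), loc)
  })
  expect_gt(median(rs), 0.6)
  expect_true(all(rs > 0.3))
})
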