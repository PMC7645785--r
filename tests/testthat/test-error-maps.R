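# Error-map construction, magnitudes, regional splits, error reduction,
# averaging, and the exact binomial direction-bias machinery.

make_trials <- function(grid, err_x_mm = 0, err_y_mm = 0, subject = "S01",
                        session = 1) {
  data.frame(subject_id = subject, session = session,
             trial_index = seq_len(nrow(grid)),
             target_row = grid$row, target_col = grid$col,
             target_x_mm = grid$x_mm, target_y_mm = grid$y_mm,
             hand_x_mm = grid$x_mm + err_x_mm, hand_y_mm = grid$y_mm + err_y_mm)
}

test_that("error vectors are hand minus target, converted to cm", {
  grid <- make_target_grid()
  trials <- make_trials(grid, err_x_mm = 10, err_y_mm = -5)
  map <- build_error_map(trials, grid)
  expect_equal(unique(as.vector(map$errors[1, , ])), 1.0)
  expect_equal(unique(as.vector(map$errors[2, , ])), -0.5)
  zero <- build_error_map(make_trials(grid), grid)
  expect_true(all(zero$errors == 0))
})

test_that("missing or duplicate targets are reported with their (row, col)", {
  grid <- make_target_grid()
  trials <- make_trials(grid)
  expect_error(build_error_map(trials[-7, ], grid), "missing trial.*\\(1, 7\\)")
  dup <- rbind(trials, trials[3, ])
  expect_error(build_error_map(dup, grid), "duplicate trial")
})

test_that("mean error magnitude averages per-target vector lengths", {
  m <- uniform_map(0.3, 0.4)  # 3-4-5 triangle in mm
  expect_equal(mean_error_magnitude(m), 0.5)
  expect_equal(mean_error_magnitude(uniform_map(0, 0)), 0)
})

test_that("mean error magnitude is invariant under global rotation", {
  m <- random_map(1)
  theta <- 0.73
  rot <- m
  rot$errors[1, , ] <- cos(theta) * m$errors[1, , ] - sin(theta) * m$errors[2, , ]
  rot$errors[2, , ] <- sin(theta) * m$errors[1, , ] + cos(theta) * m$errors[2, , ]
  expect_equal(mean_error_magnitude(rot), mean_error_magnitude(m), tolerance = 1e-12)
})

test_that("regional summaries partition the grid as 10/10 columns and 3/2 rows", {
  m <- uniform_map(1, 0)
  m$errors[1, , 11:20] <- 2
  reg <- regional_errors(m)
  expect_equal(reg$left, 1)
  expect_equal(reg$right, 2)
  expect_equal(reg$overall, 1.5)
  u <- regional_errors(uniform_map(0.6, 0.8))
  expect_equal(unlist(u), c(left = 1, right = 1, near = 1, far = 1, overall = 1))
  # overall is the row-count-weighted mean of near and far
  r <- regional_errors(random_map(2))
  expect_equal(r$overall, (3 * r$near + 2 * r$far) / 5, tolerance = 1e-12)
  expect_equal(r$overall, (r$left + r$right) / 2, tolerance = 1e-12)
})

test_that("error reduction is the signed percentage improvement", {
  expect_equal(error_reduction(2, 2), 0)
  expect_equal(error_reduction(2, 1), 50)
  expect_equal(error_reduction(2, 3), -50)
  expect_error(error_reduction(0, 1), "positive")
  # the published session means imply a 21.9% third-session reduction
  expect_equal(round(error_reduction(3.098, 2.420), 1), 21.9)
  # inverse identity: error_i = error_1 * (1 - reduction/100)
  e1 <- 3.2; ei <- 1.7
  expect_equal(e1 * (1 - error_reduction(e1, ei) / 100), ei, tolerance = 1e-12)
})

test_that("averaging maps is component-wise per target and subject-guarded", {
  m <- random_map(3)
  expect_equal(average_subject_map(list(m))$errors, m$errors)
  neg <- m; neg$errors <- -m$errors; neg$session <- 2
  expect_true(all(average_subject_map(list(m, neg))$errors == 0))
  a <- uniform_map(1, 0); b <- uniform_map(2, 0, session = 2)
  c3 <- uniform_map(3, 0, session = 3)
  expect_equal(unique(as.vector(average_subject_map(list(a, b, c3))$errors[1, , ])), 2)
  other <- random_map(4, subject = "S02")
  expect_error(average_subject_map(list(m, other)), "across subjects")
})

test_that("binomial critical counts match brute-force tail enumeration", {
  expect_identical(binomial_critical_counts(26),
                   c(lower = 8L, upper = 18L))
  # oracle: direct tail sums over all counts
  for (n in 2:30) {
    p_ge <- function(k) sum(choose(n, k:n)) / 2^n
    p_le <- function(k) sum(choose(n, 0:k)) / 2^n
    ups <- Filter(function(k) p_ge(k) < 0.05, 0:n)
    los <- Filter(function(k) p_le(k) < 0.05, 0:n)
    got <- binomial_critical_counts(n)
    expect_identical(got[["upper"]],
                     if (length(ups)) as.integer(min(ups)) else NA_integer_)
    expect_identical(got[["lower"]],
                     if (length(los)) as.integer(max(los)) else NA_integer_)
    # symmetry at p0 = 0.5
    if (!is.na(got[["upper"]])) expect_equal(got[["lower"]], n - got[["upper"]])
  }
  # n = 4: P(X >= 4) = 1/16 >= 0.05 at both tails -> sentinel
  expect_true(all(is.na(binomial_critical_counts(4))))
  expect_error(binomial_critical_counts(26, alpha = 0), "alpha")
})

test_that("direction-bias test counts positive components against the criticals", {
  pos <- lapply(1:26, function(i) uniform_map(1, 1, subject = sprintf("S%02d", i)))
  res <- direction_bias_test(pos, "x")
  expect_true(all(res$fraction == 1))
  expect_true(all(res$significant))
  # 13 of 26 positive: not significant; 18 of 26: significant
  mixed <- lapply(1:26, function(i)
    uniform_map(ifelse(i <= 13, 1, -1), 0, subject = sprintf("S%02d", i)))
  r13 <- direction_bias_test(mixed, "x")
  expect_true(all(r13$fraction == 0.5))
  expect_false(any(r13$significant))
  m18 <- lapply(1:26, function(i)
    uniform_map(ifelse(i <= 18, 1, -1), 0, subject = sprintf("S%02d", i)))
  r18 <- direction_bias_test(m18, "x")
  expect_true(all(r18$n_positive == 18))
  expect_true(all(r18$significant))
  expect_error(direction_bias_test(pos[1], "x"), "at least 2")
})

test_that("default generator inflates far-region errors in most subjects", {
  maps <- build_error_maps(generate_cohort(cohort_config(seed = 31)))
  sess1 <- maps[sapply(maps, function(m) m$session) == 1]
  regs <- lapply(sess1, regional_errors)
  frac_far <- mean(sapply(regs, function(r) r$far > r$near))
  expect_gte(frac_far, 0.9)
})
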