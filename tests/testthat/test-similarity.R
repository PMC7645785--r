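# Map similarity: correlations over jointly flattened components, scaled
# Euclidean distances, within/between pairing, Fisher's Z, Kendall's W.

test_that("map correlation is Pearson over the 200 flattened components", {
  m <- random_map(1)
  expect_equal(map_correlation(m, m), 1)
  neg <- m; neg$errors <- -m$errors
  expect_equal(map_correlation(m, neg), -1)
  # affine invariance of the correlation
  aff <- m; aff$errors <- 3 * m$errors + 0.7
  expect_equal(map_correlation(m, aff), 1, tolerance = 1e-12)
  expect_error(map_correlation(uniform_map(1, 1), m), "zero variance")
})

test_that("map distance is the 200-component L2 norm over 100", {
  m <- random_map(2)
  expect_equal(map_distance(m, m), 0)
  one <- m
  one$errors[1, 1, 1] <- one$errors[1, 1, 1] + 0.1
  expect_equal(map_distance(m, one), sqrt(0.01) / 100, tolerance = 1e-12)
  all_off <- m; all_off$errors <- m$errors + 0.1
  expect_equal(map_distance(m, all_off), sqrt(200 * 0.01) / 100, tolerance = 1e-12)
  # linear scaling with a common multiplicative factor
  a <- random_map(3); b <- random_map(4)
  a2 <- a; a2$errors <- 2 * a$errors
  b2 <- b; b2$errors <- 2 * b$errors
  expect_equal(map_distance(a2, b2), 2 * map_distance(a, b), tolerance = 1e-12)
})

test_that("fisher_z is atanh with a guarded domain", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), 0.5493, tolerance = 1e-4)
  expect_equal(fisher_z(-0.3), -fisher_z(0.3))
  expect_error(fisher_z(1), "\\|r\\| < 1")
})

test_that("within/between sets have n and n(n-1) values forming the full pairing", {
  maps <- unlist(lapply(1:26, function(i) lapply(1:2, function(s)
    random_map(100 * i + s, subject = sprintf("S%02d", i), session = s))),
    recursive = FALSE)
  res <- within_between_sets(maps, 1, 2)
  expect_equal(length(res$within), 26)
  expect_equal(length(res$between), 650)
  two <- within_between_sets(maps[1:4], 1, 2)
  expect_equal(length(two$within), 2)
  expect_equal(length(two$between), 2)
  # identical constant maps for everyone: correlation undefined, surfaced
  same <- unlist(lapply(1:3, function(i) lapply(1:2, function(s)
    uniform_map(1, 1, subject = sprintf("S%02d", i), session = s))),
    recursive = FALSE)
  expect_error(within_between_sets(same, 1, 2), "zero variance")
})

test_that("within/between sets match hand enumeration on a 3-subject toy case", {
  vals <- list(S1 = c(1, 2), S2 = c(3, 5), S3 = c(7, 11))
  maps <- unlist(lapply(names(vals), function(id) lapply(1:2, function(s) {
    m <- random_map(match(id, names(vals)) * 10 + s, subject = id, session = s,
                    n_rows = 2, n_cols = 2)
    m
  })), recursive = FALSE)
  res <- within_between_sets(maps, 1, 2, "distance")
  # oracle: direct evaluation of every ordered pairing
  get <- function(id, s) maps[[(match(id, names(vals)) - 1) * 2 + s]]
  ids <- names(vals)
  expected_within <- sapply(ids, function(i) map_distance(get(i, 1), get(i, 2)))
  expect_equal(unname(res$within), unname(expected_within))
  expected_between <- c()
  for (i in ids) for (j in ids) if (i != j)
    expected_between <- c(expected_between, map_distance(get(i, 1), get(j, 2)))
  expect_equal(unname(res$between), expected_between)
  # union covers the full n^2 pairing matrix
  expect_equal(length(res$within) + length(res$between), 9)
})

test_that("subjects missing a session are dropped with a warning", {
  maps <- unlist(lapply(1:3, function(i) lapply(1:2, function(s)
    random_map(10 * i + s, subject = sprintf("S%02d", i), session = s))),
    recursive = FALSE)
  expect_warning(res <- within_between_sets(maps[-2], 1, 2), "S01")
  expect_equal(res$n_subjects, 2)
})

test_that("clearly separated within/between sets test significant and directional", {
  maps <- unlist(lapply(1:8, function(i) lapply(1:2, function(s) {
    base <- random_map(i, subject = sprintf("S%02d", i), session = s)
    noise <- random_map(1000 + 16 * i + s, n_rows = 5, n_cols = 20, sd = 0.2)
    base$errors <- random_map(i)$errors + noise$errors
    base
  })), recursive = FALSE)
  res <- within_between_sets(maps, 1, 2)
  out <- compare_within_between(res)
  expect_lt(out$p_value, 0.001)
  expect_gt(out$statistic, 0)
  expect_gt(out$difference, 0)
  dist <- within_between_sets(maps, 1, 2, "distance")
  outd <- compare_within_between(dist)
  expect_equal(outd$method, "Wilcoxon rank-sum")
  expect_lt(outd$p_value, 0.001)
  expect_lt(outd$mean_within, outd$mean_between)
})

test_that("Kendall's W equals 1 for perfectly concordant rankings and matches friedman", {
  vals <- matrix(c(3, 2, 1,
                   30, 20, 10,
                   6, 5, 4), nrow = 3, byrow = TRUE,
                 dimnames = list(NULL, c("1", "2", "3")))
  res <- distance_trend(vals)
  expect_equal(res$W, 1)
  expect_equal(nrow(res$posthoc), 3)
  # cross-check with stats::friedman.test: chisq = m * (k - 1) * W
  set.seed(7)
  rnd <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("1", "2", "3")))
  got <- distance_trend(rnd)
  fr <- friedman.test(rnd)
  expect_equal(got$chisq, unname(fr$statistic), tolerance = 1e-10)
  expect_equal(got$p_value, fr$p.value, tolerance = 1e-10)
})

test_that("decreasing learning factors produce a detectable distance decline", {
  co <- cohort_config(n_subjects = 10, seed = 17)
  maps <- build_error_maps(generate_cohort(co))
  trend <- distance_trend(between_subject_distances(maps, 1:3))
  expect_lt(trend$p_value, 0.05)
  expect_true(all(diff(trend$mean_by_session) < 0))
})

test_that("within-subject similarity is monotone in measurement noise", {
  noise_levels <- c(0.5, 4, 10, 18, 28)
  within_r <- numeric(length(noise_levels))
  within_d <- numeric(length(noise_levels))
  for (i in seq_along(noise_levels)) {
    co <- cohort_config(n_subjects = 4, noise_sd = noise_levels[i], seed = 50)
    maps <- build_error_maps(generate_cohort(co))
    res_r <- within_between_sets(maps, 1, 2, "correlation")
    res_d <- within_between_sets(maps, 1, 2, "distance")
    within_r[i] <- mean(res_r$within)
    within_d[i] <- mean(res_d$within)
  }
  expect_true(all(diff(within_r) < 0))
  expect_true(all(diff(within_d) > 0))
  expect_gt(within_r[1], 0.95)
  expect_lt(within_d[1], 0.1)
})
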