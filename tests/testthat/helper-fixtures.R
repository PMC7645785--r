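# Fixtures built in code: tiny error maps and cohorts used across tests.

# an error map with constant error vector (x_cm, y_cm) at every target
uniform_map <- function(x_cm, y_cm, subject = "S01", session = 1,
                        n_rows = 5, n_cols = 20) {
  errs <- array(0, dim = c(2, n_rows, n_cols))
  errs[1, , ] <- x_cm
  errs[2, , ] <- y_cm
  error_map(errs, subject_id = subject, session = session)
}

# a reproducible random map
random_map <- function(seed, subject = "S01", session = 1,
                       n_rows = 5, n_cols = 20, sd = 1) {
  set.seed(seed)
  error_map(array(rnorm(2 * n_rows * n_cols, sd = sd), c(2, n_rows, n_cols)),
            subject_id = subject, session = session)
}

# a small calibrated cohort for fast end-to-end tests
small_cohort_config <- function(n_subjects = 6, seed = 42, ...) {
  cohort_config(n_subjects = n_subjects, seed = seed, ...)
}
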