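# Within- vs between-subject similarity of error maps.
#
# Two maps are compared either by the Pearson correlation of their 200
# jointly flattened components (x and y concatenated) or by the Euclidean
# norm of the 200-component difference divided by 100, the per-target-scaled
# map distance. Idiosyncrasy shows up as within-subject (same subject,
# different sessions) coefficients exceeding between-subject ones.

flatten_map <- function(map) as.vector(map$errors)

#' Pearson correlation between two error maps
#'
#' Computed over the 200 flattened components (both error components of all
#' targets jointly), yielding one coefficient per map pair.
#'
#' @param map_a,map_b `error_map`s on the same grid.
#' @return Pearson r.
#' @export
map_correlation <- function(map_a, map_b) {
  a <- flatten_map(map_a); b <- flatten_map(map_b)
  if (length(a) != length(b)) stop_("maps are not on the same grid")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop_("undefined correlation: a map has zero variance")
  stats::cor(a, b)
}

#' Scaled Euclidean distance between two error maps
#'
#' The Euclidean norm of the 200-component difference vector divided by 100
#' (the number of targets), in cm.
#'
#' @inheritParams map_correlation
#' @return distance in cm.
#' @export
map_distance <- function(map_a, map_b) {
  a <- flatten_map(map_a); b <- flatten_map(map_b)
  if (length(a) != length(b)) stop_("maps are not on the same grid")
  sqrt(sum((a - b)^2)) / (length(a) / 2)
}

#' Fisher's Z transformation
#'
#' @param r correlation coefficient(s), `abs(r) < 1`.
#' @return `atanh(r)`.
#' @export
fisher_z <- function(r) {
  if (any(abs(r) >= 1)) stop_("Fisher's Z requires |r| < 1")
  atanh(r)
}

map_key <- function(subject, session) paste(subject, session, sep = ".")

#' Within- and between-subject similarity sets for a session pair
#'
#' For `n` subjects measured in both sessions: the `n` within-subject values
#' compare each subject's session-A map with their own session-B map; the
#' `n * (n - 1)` between-subject values compare every subject's session-A map
#' with every other subject's session-B map (all ordered pairings). Subjects
#' missing either session are dropped with a warning.
#'
#' @param maps list of `error_map`s as returned by [build_error_maps()].
#' @param session_a,session_b the two session labels.
#' @param metric `"correlation"` or `"distance"`.
#' @return an object of class `session_pair_result` with elements `within`
#'   (length n), `between` (length n(n-1)), `metric`, `session_a`,
#'   `session_b`, `n_subjects`.
#' @export
within_between_sets <- function(maps, session_a, session_b,
                                metric = c("correlation", "distance")) {
  metric <- match.arg(metric)
  f <- if (metric == "correlation") map_correlation else map_distance
  subj <- vapply(maps, function(m) m$subject_id, character(1))
  sess <- vapply(maps, function(m) as.character(m$session), character(1))
  subjects <- sort(unique(subj))
  has_both <- vapply(subjects, function(s)
    any(subj == s & sess == as.character(session_a)) &&
    any(subj == s & sess == as.character(session_b)), logical(1))
  if (any(!has_both)) {
    warning(sprintf("dropping subjects missing a session: %s",
                    paste(subjects[!has_both], collapse = ", ")))
    subjects <- subjects[has_both]
  }
  if (length(subjects) < 2) stop_("need at least 2 subjects with both sessions")
  get_map <- function(s, session)
    maps[[which(subj == s & sess == as.character(session))[1]]]
  n <- length(subjects)
  within <- vapply(subjects, function(s)
    f(get_map(s, session_a), get_map(s, session_b)), numeric(1))
  between <- numeric(n * (n - 1))
  labs <- character(n * (n - 1))
  k <- 0L
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    k <- k + 1L
    between[k] <- f(get_map(subjects[i], session_a), get_map(subjects[j], session_b))
    labs[k] <- paste(subjects[i], subjects[j], sep = "->")
  }
  names(between) <- labs
  structure(list(within = within, between = between, metric = metric,
                 session_a = session_a, session_b = session_b, n_subjects = n),
            class = "session_pair_result")
}

#' Compare within- against between-subject similarity
#'
#' Correlations are Fisher-Z transformed by default and compared with
#' Welch's unequal-variance t-test; distances are compared with the Wilcoxon
#' rank-sum test. A positive direction means within-subject maps are more
#' similar (larger r, or smaller distance).
#'
#' @param result a [within_between_sets()] result.
#' @param transform `"fisher"` (default, correlations only) or `"none"`.
#' @param method `"welch"` or `"wilcoxon"`; defaults to Welch for
#'   correlations and Wilcoxon for distances.
#' @return list with `statistic`, `df` (Welch only), `p_value`, `method`,
#'   `mean_within`, `mean_between`, `difference`.
#' @export
compare_within_between <- function(result, transform = c("fisher", "none"),
                                   method = NULL) {
  transform <- match.arg(transform)
  stopifnot(inherits(result, "session_pair_result"))
  if (length(result$within) == 0 || length(result$between) == 0)
    stop_("both similarity sets must be non-empty")
  method <- method %||% if (result$metric == "correlation") "welch" else "wilcoxon"
  w <- result$within; b <- result$between
  if (result$metric == "correlation" && transform == "fisher") {
    w <- fisher_z(w); b <- fisher_z(b)
  }
  if (stats::sd(w) == 0 && stats::sd(b) == 0 && method == "welch")
    stop_("degenerate variance in both similarity sets")
  if (method == "welch") {
    tt <- stats::t.test(w, b, var.equal = FALSE)
    res <- list(statistic = unname(tt$statistic), df = unname(tt$parameter),
                p_value = tt$p.value, method = "Welch t")
  } else {
    wt <- stats::wilcox.test(w, b, exact = FALSE)
    res <- list(statistic = unname(wt$statistic), df = NA_real_,
                p_value = wt$p.value, method = "Wilcoxon rank-sum")
  }
  c(res, list(mean_within = mean(result$within),
              mean_between = mean(result$between),
              difference = mean(result$within) - mean(result$between)))
}

#' Between-subject distances within each session
#'
#' Distance between every unordered pair of subjects' maps, computed within
#' each session — the quantity whose decline across sessions indicates a
#' shrinking between-subject spread.
#'
#' @param maps list of `error_map`s.
#' @param sessions session labels (default: all in `maps`).
#' @return matrix of distances, one row per subject pair, one column per
#'   session.
#' @export
between_subject_distances <- function(maps, sessions = NULL) {
  subj <- vapply(maps, function(m) m$subject_id, character(1))
  sess <- vapply(maps, function(m) as.character(m$session), character(1))
  sessions <- as.character(sessions %||% sort(unique(sess)))
  subjects <- sort(unique(subj))
  pairs <- utils::combn(subjects, 2)
  out <- matrix(NA_real_, ncol(pairs), length(sessions),
                dimnames = list(paste(pairs[1, ], pairs[2, ], sep = "-"), sessions))
  for (s in seq_along(sessions)) {
    get_map <- function(id) maps[[which(subj == id & sess == sessions[s])[1]]]
    for (p in seq_len(ncol(pairs)))
      out[p, s] <- map_distance(get_map(pairs[1, p]), get_map(pairs[2, p]))
  }
  out
}

#' Kendall's W trend test across sessions
#'
#' Kendall's coefficient of concordance over the per-pair rankings of the
#' session values (tie-corrected), with its chi-square test, plus
#' Bonferroni-corrected pairwise Wilcoxon signed-rank post-hocs between
#' sessions.
#'
#' @param values matrix with one row per observational unit (e.g. subject
#'   pair) and one column per session, as from [between_subject_distances()].
#' @return list with `W`, `chisq`, `df`, `p_value`, `mean_by_session`, and a
#'   data frame `posthoc` of pairwise comparisons.
#' @export
distance_trend <- function(values) {
  if (!is.matrix(values) || ncol(values) < 2)
    stop_("values must be a matrix with at least 2 session columns")
  if (anyNA(values)) stop_("unequal pair sets across sessions (missing values)")
  m <- nrow(values); k <- ncol(values)
  ranks <- t(apply(values, 1, rank))
  R <- colSums(ranks)
  S <- sum((R - m * (k + 1) / 2)^2)
  ties <- sum(apply(values, 1, function(row) {
    t <- table(row); sum(t^3 - t)
  }))
  W <- 12 * S / (m^2 * (k^3 - k) - m * ties)
  chisq <- m * (k - 1) * W
  p <- stats::pchisq(chisq, df = k - 1, lower.tail = FALSE)
  combs <- utils::combn(k, 2)
  posthoc <- data.frame(
    session_a = colnames(values)[combs[1, ]],
    session_b = colnames(values)[combs[2, ]],
    p_value = apply(combs, 2, function(cc)
      stats::wilcox.test(values[, cc[1]], values[, cc[2]],
                         paired = TRUE, exact = FALSE)$p.value))
  posthoc$p_adjusted <- stats::p.adjust(posthoc$p_value, method = "bonferroni")
  list(W = W, chisq = chisq, df = k - 1, p_value = p,
       mean_by_session = colMeans(values), posthoc = posthoc)
}

#' @export
print.session_pair_result <- function(x, ...) {
  cat(sprintf(paste0("session pair %s vs %s (%s): %d within (mean %.3f), ",
                     "%d between (mean %.3f)\n"),
              x$session_a, x$session_b, x$metric,
              length(x$within), mean(x$within),
              length(x$between), mean(x$between)))
  invisible(x)
}
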