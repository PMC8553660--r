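# Statistical comparisons used on the promoter groups: normality screen,
# two-sample rank test, multi-group rank test. Backed by the base `stats`
# implementations; the contracts (exact small-sample p, tie handling, k=2
# Kruskal-Wallis equivalence) are pinned by the test suite.

new_test_result <- function(statistic, p_value, n_per_group, test_name) {
  stopifnot(p_value >= 0, p_value <= 1, all(n_per_group >= 1L))
  structure(list(statistic = unname(statistic), p_value = unname(p_value),
                 n_per_group = as.integer(n_per_group),
                 test_name = test_name),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("<%s> statistic = %.4g, p = %.4g (n = %s)\n", x$test_name,
              x$statistic, x$p_value, paste(x$n_per_group, collapse = ", ")))
  invisible(x)
}

#' Shapiro-Wilk normality screen
#'
#' Used to justify the nonparametric follow-up tests; rejection means the
#' rank tests are used for the group comparisons.
#'
#' @param sample Numeric vector, 3 <= n <= 5000, non-constant.
#' @return A `test_result` (statistic W, p value).
#' @export
normality_screen <- function(sample) {
  sample <- as.numeric(sample)
  n <- length(sample)
  if (n < 3L || n > 5000L) {
    stop("Shapiro-Wilk requires 3 <= n <= 5000 (got ", n, ")", call. = FALSE)
  }
  if (stats::var(sample) == 0) {
    stop("sample is constant; normality screen is degenerate", call. = FALSE)
  }
  res <- stats::shapiro.test(sample)
  new_test_result(res$statistic, res$p.value, n, "Shapiro-Wilk")
}

#' Two-sample rank-sum (Mann-Whitney U) test
#'
#' Two-sided. The exact permutation distribution is used when
#' `length(a) * length(b) <= 400` and there are no ties; otherwise the
#' normal approximation with tie correction (no continuity correction, so
#' the two-group Kruskal-Wallis test gives the same p in the tie-free
#' case).
#'
#' @param a,b Numeric samples (both nonempty).
#' @return A `test_result` with the U statistic of the first sample.
#' @export
rank_sum_test <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (!length(a) || !length(b)) {
    stop("both groups must be nonempty", call. = FALSE)
  }
  if (length(unique(c(a, b))) == 1L) {
    # every observation tied: U at its null center, no evidence either way
    return(new_test_result(length(a) * length(b) / 2, 1,
                           c(length(a), length(b)),
                           "Mann-Whitney U (degenerate: all tied)"))
  }
  ties <- anyDuplicated(c(a, b)) > 0L
  exact <- !ties && length(a) * length(b) <= 400L
  res <- suppressWarnings(
    stats::wilcox.test(a, b, alternative = "two.sided", exact = exact,
                       correct = FALSE))
  new_test_result(res$statistic, min(res$p.value, 1),
                  c(length(a), length(b)),
                  paste0("Mann-Whitney U (",
                         if (exact) "exact" else "normal approximation",
                         ")"))
}

#' Kruskal-Wallis rank test across k groups
#'
#' H statistic with tie correction; p from the chi-square distribution with
#' k - 1 degrees of freedom.
#'
#' @param groups List of >= 2 nonempty numeric vectors.
#' @return A `test_result`.
#' @export
kruskal_test <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) {
    stop("need at least two groups", call. = FALSE)
  }
  sizes <- lengths(groups)
  if (any(sizes == 0L)) stop("empty group", call. = FALSE)
  if (length(unique(unlist(groups))) == 1L) {
    return(new_test_result(0, 1, sizes, "Kruskal-Wallis (degenerate)"))
  }
  res <- stats::kruskal.test(lapply(groups, as.numeric))
  new_test_result(res$statistic, min(res$p.value, 1), sizes,
                  "Kruskal-Wallis")
}
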