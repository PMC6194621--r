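#' Two-sample Wilcoxon rank-sum test
#'
#' Rank-sum comparison of two samples with midranks for ties. The p-value
#' is exact (enumeration of rank assignments) when the combined sample size
#' is at most `exact_threshold` and the data are tie-free; otherwise the
#' normal approximation with tie correction and, by default, continuity
#' correction is used. The degenerate case of all pooled values identical
#' returns a two-sided p of 1: there is no separation to detect.
#'
#' @param x,y Non-empty numeric samples.
#' @param alternative `"two_sided"`, `"less"` or `"greater"`.
#' @param exact_threshold Largest combined sample size for which the exact
#'   null distribution is used (tie-free data only).
#' @param continuity Apply the continuity correction in the normal
#'   approximation.
#' @return An object of class `rank_test`: `statistic` (the Mann-Whitney U
#'   form of the rank-sum statistic), `p_value`, `method` (`"exact"` or
#'   `"normal_approx"`), `n1`, `n2`, `alternative`.
#' @examples
#' wilcoxon_rank_sum(c(1, 2), c(3, 4))$p_value # 1/3, exact
#' @export
wilcoxon_rank_sum <- function(x, y,
                              alternative = c("two_sided", "less", "greater"),
                              exact_threshold = 12, continuity = TRUE) {
  alternative <- match.arg(alternative)
  if (!length(x) || !length(y)) rlang::abort("samples must be non-empty")
  x <- as.numeric(x); y <- as.numeric(y)
  if (anyNA(c(x, y))) rlang::abort("samples must not contain NA")
  pooled <- c(x, y)
  if (length(unique(pooled)) == 1) {
    return(new_rank_test(statistic = length(x) * length(y) / 2, p_value = 1,
                         method = "normal_approx", sizes = c(length(x),
                                                             length(y)),
                         alternative = alternative))
  }
  ties <- anyDuplicated(pooled) > 0
  exact <- !ties && (length(x) + length(y)) <= exact_threshold
  alt <- c(two_sided = "two.sided", less = "less",
           greater = "greater")[alternative]
  ht <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = unname(alt), exact = exact,
                       correct = continuity)
  )
  p <- unname(ht$p.value)
  if (is.na(p)) p <- 1 # zero-variance tie structure: no evidence either way
  new_rank_test(statistic = unname(ht$statistic), p_value = p,
                method = if (exact) "exact" else "normal_approx",
                sizes = c(length(x), length(y)), alternative = alternative)
}

#' K-sample rank test (Kruskal-Wallis)
#'
#' Kruskal-Wallis H with tie correction against the chi-square reference
#' distribution with k-1 degrees of freedom. Used for the three-region
#' comparisons; with two groups its p-value coincides with the two-sided
#' Wilcoxon normal approximation without continuity correction. All pooled
#' values identical returns H = 0, p = 1.
#'
#' @param groups A list of two or more non-empty numeric samples.
#' @return An object of class `rank_test` with `statistic` (H), `p_value`,
#'   `df`, `method = "chi_square"`, and the group sizes.
#' @examples
#' k_sample_rank_test(list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)))
#' @export
k_sample_rank_test <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) {
    rlang::abort("need a list of at least two groups")
  }
  sizes <- vapply(groups, length, integer(1))
  if (any(sizes == 0)) rlang::abort("all groups must be non-empty")
  pooled <- unlist(groups, use.names = FALSE)
  if (anyNA(pooled)) rlang::abort("samples must not contain NA")
  if (length(unique(pooled)) == 1) {
    return(new_rank_test(statistic = 0, p_value = 1, method = "chi_square",
                         sizes = sizes, df = length(groups) - 1))
  }
  g <- factor(rep(seq_along(groups), sizes))
  ht <- stats::kruskal.test(pooled, g)
  new_rank_test(statistic = unname(ht$statistic),
                p_value = unname(ht$p.value), method = "chi_square",
                sizes = sizes, df = unname(ht$parameter))
}

#' @noRd
new_rank_test <- function(statistic, p_value, method, sizes,
                          alternative = NULL, df = NULL) {
  structure(
    list(statistic = statistic, p_value = p_value, method = method,
         n = sizes, alternative = alternative, df = df),
    class = "rank_test"
  )
}

#' @export
print.rank_test <- function(x, ...) {
  cat("<rank_test ", x$method, ">  statistic = ", signif(x$statistic, 6),
      ", p = ", signif(x$p_value, 4),
      ", n = (", paste(x$n, collapse = ", "), ")\n", sep = "")
  invisible(x)
}
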