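#' One-sided rank-sum (Mann-Whitney) test
#'
#' Tests the alternative that `x` is stochastically smaller than `y` (or
#' another direction via `alternative`). When both groups are small
#' (`max(n_x, n_y) <= exact_cutoff`) and the data are tie-free, the exact
#' null permutation distribution of the U statistic is used; otherwise the
#' tie-corrected normal approximation with continuity correction. This is
#' the comparison used three times per gene pair in the SC screen.
#'
#' @param x,y Numeric vectors, each non-empty and finite.
#' @param alternative `"less"` (default: x tends to be smaller), `"greater"`,
#'   or `"two.sided"`.
#' @param exact_cutoff Largest group size for which the exact branch is
#'   attempted.
#' @return A list of class `rank_sum_result` with `u_statistic`, `p_value`,
#'   `n_x`, `n_y`, `method` (`"exact"` or `"normal_approx"`) and
#'   `alternative`.
#' @examples
#' rank_sum_test(c(1, 2, 3), c(4, 5, 6))$p_value  # exactly 1/20
#' @export
rank_sum_test <- function(x, y, alternative = c("less", "greater", "two.sided"),
                          exact_cutoff = 25) {
  alternative <- match.arg(alternative)
  if (length(x) < 1L || length(y) < 1L)
    stop("both groups must be non-empty")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("rank-sum input must be finite")
  has_ties <- anyDuplicated(c(x, y)) > 0L
  use_exact <- max(length(x), length(y)) <= exact_cutoff && !has_ties
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = alternative,
                       exact = use_exact, correct = TRUE)
  )
  structure(list(u_statistic = unname(wt$statistic),
                 p_value = wt$p.value,
                 n_x = length(x), n_y = length(y),
                 method = if (use_exact) "exact" else "normal_approx",
                 alternative = alternative),
            class = "rank_sum_result")
}

#' @export
print.rank_sum_result <- function(x, ...) {
  cat("Rank-sum test (", x$method, ", alternative = ", x$alternative, "): U = ",
      format(x$u_statistic), ", p = ", format.pval(x$p_value),
      " (n = ", x$n_x, " vs ", x$n_y, ")\n", sep = "")
  invisible(x)
}

#' Kruskal-Wallis comparison across groups
#'
#' Tie-corrected Kruskal-Wallis H with a chi-square reference on k - 1
#' degrees of freedom; used to compare ln IC50 across SC-burden groups.
#'
#' @param groups A list of two or more non-empty numeric vectors, or a
#'   numeric vector plus a parallel grouping factor via `g`.
#' @param g Optional grouping factor when `groups` is a single vector.
#' @return A list of class `kruskal_wallis_result` with `h_statistic`, `df`,
#'   `p_value`, `group_sizes` and `group_medians`.
#' @export
kruskal_wallis <- function(groups, g = NULL) {
  if (!is.null(g)) groups <- split(as.numeric(groups), g)
  if (!is.list(groups) || length(groups) < 2L)
    stop("need at least two groups")
  sizes <- lengths(groups)
  if (any(sizes == 0L)) stop("every group must be non-empty")
  if (sum(sizes) < length(groups) + 1L)
    stop("too few observations for a Kruskal-Wallis test")
  kt <- stats::kruskal.test(groups)
  structure(list(h_statistic = unname(kt$statistic),
                 df = unname(kt$parameter),
                 p_value = kt$p.value,
                 group_sizes = sizes,
                 group_medians = vapply(groups, stats::median, numeric(1))),
            class = "kruskal_wallis_result")
}

#' @export
print.kruskal_wallis_result <- function(x, ...) {
  cat("Kruskal-Wallis: H = ", format(x$h_statistic, digits = 5), " on ",
      x$df, " df, p = ", format.pval(x$p_value), "\n", sep = "")
  cat("group medians:", paste(format(x$group_medians, digits = 4),
                              collapse = ", "), "\n")
  invisible(x)
}
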