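# Rank-based k-sample comparisons used throughout the results: the
# tie-corrected Kruskal-Wallis rank-sum test and Dunn's post-hoc z tests
# with Bonferroni adjustment. Implemented from the closed forms; the
# chi-square approximation is used for all sample sizes, matching standard
# reporting practice.

#' Midranks
#'
#' Ranks with tied values sharing the mean of their rank span, so the rank
#' sum is always N(N+1)/2.
#'
#' @param values Numeric vector, all finite.
#' @return Numeric rank vector.
#' @export
midranks <- function(values) {
  if (length(values) < 1) stop_mt("midranks needs at least one value")
  if (any(!is.finite(values))) stop_mt("midranks: values must be finite")
  rank(values, ties.method = "average")
}

as_group_list <- function(groups) {
  if (!is.list(groups)) stop_mt("groups must be a list of numeric vectors")
  if (length(groups) < 2) stop_mt("need at least 2 groups")
  if (any(vapply(groups, length, integer(1)) == 0))
    stop_mt("empty group supplied")
  if (any(!vapply(groups, is.numeric, logical(1))))
    stop_mt("groups must be numeric")
  if (is.null(names(groups)) || any(names(groups) == ""))
    names(groups) <- paste0("group", seq_along(groups))
  groups
}

tie_term <- function(pooled) {
  t <- table(pooled)
  sum(t^3 - t)
}

#' Kruskal-Wallis rank-sum test with tie correction
#'
#' \deqn{H = \left[\frac{12}{N(N+1)} \sum_i R_i^2/n_i - 3(N+1)\right] / C,
#'   \quad C = 1 - \frac{\sum_t (t^3 - t)}{N^3 - N}}
#' where \eqn{R_i} are group rank sums over the pooled midranks and the sum
#' in \eqn{C} runs over tie groups of size \eqn{t}. The p-value is the
#' chi-square upper tail with k-1 degrees of freedom. Fully tied input
#' (vanishing correction denominator) returns H = 0 by convention.
#'
#' @param groups List of k >= 2 non-empty numeric vectors (total N >= 3).
#' @return A `kw_result` list: `H`, `df`, `p_value`, `n` (group sizes),
#'   `tie_correction`.
#' @export
kruskal_wallis <- function(groups) {
  groups <- as_group_list(groups)
  pooled <- unlist(groups, use.names = FALSE)
  N <- length(pooled)
  if (N < 3) stop_mt("need at least 3 observations in total")
  r <- midranks(pooled)
  g <- rep(seq_along(groups), vapply(groups, length, integer(1)))
  Ri <- tapply(r, g, sum)
  ni <- tapply(r, g, length)
  H0 <- 12 / (N * (N + 1)) * sum(Ri^2 / ni) - 3 * (N + 1)
  C <- 1 - tie_term(pooled) / (N^3 - N)
  H <- if (C <= 0) 0 else H0 / C
  df <- length(groups) - 1L
  structure(list(
    H = unname(H), df = df,
    p_value = stats::pchisq(unname(H), df, lower.tail = FALSE),
    n = stats::setNames(as.integer(ni), names(groups)),
    tie_correction = unname(C)
  ), class = "kw_result")
}

#' @export
print.kw_result <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis rank-sum test: chi-squared = %.4g, df = %d, p = %.4g\n",
              x$H, x$df, x$p_value))
  cat("  group sizes:", paste(names(x$n), x$n, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Dunn post-hoc test with Bonferroni adjustment
#'
#' For each group pair,
#' \deqn{z_{ij} = \frac{\bar R_i - \bar R_j}{\sqrt{\left(\frac{N(N+1)}{12} -
#'   \frac{\sum_t (t^3-t)}{12(N-1)}\right)\left(\frac{1}{n_i}+\frac{1}{n_j}\right)}}}
#' with two-sided normal p-values, multiplied by the number of pairs
#' k(k-1)/2 and capped at 1.
#'
#' @param groups List of k >= 2 non-empty numeric vectors.
#' @return Tibble of class `dunn_result`: group_i, group_j, z, p_raw, p_adj.
#' @export
dunn_bonferroni <- function(groups) {
  groups <- as_group_list(groups)
  pooled <- unlist(groups, use.names = FALSE)
  N <- length(pooled)
  r <- midranks(pooled)
  g <- rep(seq_along(groups), vapply(groups, length, integer(1)))
  rbar <- tapply(r, g, mean)
  ni <- tapply(r, g, length)
  k <- length(groups)
  m <- k * (k - 1) / 2
  s2 <- N * (N + 1) / 12 - tie_term(pooled) / (12 * (N - 1))
  pairs <- utils::combn(k, 2)
  z <- (rbar[pairs[1, ]] - rbar[pairs[2, ]]) /
    sqrt(s2 * (1 / ni[pairs[1, ]] + 1 / ni[pairs[2, ]]))
  p_raw <- 2 * stats::pnorm(-abs(z))
  out <- tibble::tibble(
    group_i = names(groups)[pairs[1, ]],
    group_j = names(groups)[pairs[2, ]],
    z = unname(z),
    p_raw = unname(p_raw),
    p_adj = pmin(1, unname(p_raw) * m)
  )
  class(out) <- c("dunn_result", class(out))
  out
}

#' Compare a metric between groups (species or years)
#'
#' Runs one Kruskal-Wallis test of the metric across groups, attaching a
#' Dunn/Bonferroni post-hoc table when the omnibus test is significant and
#' more than two groups are present. Excluded calendar years (e.g. a year
#' kept in data summaries but dropped from statistics for limited sample
#' size) are honoured when the table has a `year` column.
#'
#' @param data Data frame holding the metric and grouping columns.
#' @param value_col Name of the metric column.
#' @param group_col Name of the grouping column (default `"species"`).
#' @param alpha Significance threshold gating the post-hoc test (default
#'   0.05).
#' @param exclude_years Calendar years to drop before testing.
#' @return List of class `metric_comparison`: `metric`, `grouping`, `kw`,
#'   `dunn` (NULL unless triggered), `n`.
#' @export
compare_species <- function(data, value_col, group_col = "species",
                            alpha = 0.05, exclude_years = NULL) {
  if (!value_col %in% names(data)) stop_mt("no column '", value_col, "'")
  if (!group_col %in% names(data)) stop_mt("no column '", group_col, "'")
  if (!is.null(exclude_years) && "year" %in% names(data)) {
    data <- data[!data$year %in% exclude_years, ]
  }
  data <- data[is.finite(data[[value_col]]), ]
  groups <- split(data[[value_col]], data[[group_col]], drop = TRUE)
  if (length(groups) < 2)
    stop_mt("fewer than 2 non-empty groups for '", value_col, "' by '",
            group_col, "'")
  kw <- kruskal_wallis(groups)
  dunn <- NULL
  if (kw$p_value < alpha && length(groups) > 2) {
    dunn <- dunn_bonferroni(groups)
  }
  structure(list(metric = value_col, grouping = group_col, kw = kw,
                 dunn = dunn, n = kw$n),
            class = "metric_comparison")
}

#' Tabulate a set of metric comparisons
#'
#' @param comparisons A list of `metric_comparison` objects.
#' @return Tibble with one row per comparison: metric, grouping, H, df,
#'   p_value, significant, and group sizes as a comma-separated string.
#' @export
comparison_table <- function(comparisons) {
  rows <- lapply(comparisons, function(cm) {
    tibble::tibble(
      metric = cm$metric,
      grouping = cm$grouping,
      H = cm$kw$H,
      df = cm$kw$df,
      p_value = cm$kw$p_value,
      significant = cm$kw$p_value < 0.05,
      n = paste(names(cm$n), cm$n, sep = "=", collapse = ",")
    )
  })
  dplyr::bind_rows(rows)
}
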