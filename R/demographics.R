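#' Chi-square test of independence on a contingency table
#'
#' Pearson chi-square without continuity correction:
#' `X2 = sum((O - E)^2 / E)` with expected counts from the product of the
#' margins, `df = (r - 1)(c - 1)`, and an upper-tail chi-square p-value.
#' This is the test applied to sex-by-subgroup counts in the cohort
#' demographics table.
#'
#' @param counts numeric matrix of non-negative counts, at least 2 x 2
#'   (rows = groups, columns = categories).
#' @return A one-row tibble: `statistic`, `df`, `p`.
#' @examples
#' sex <- rbind(c(112, 58), c(14, 11), c(107, 35), c(124, 72))
#' chi_square_independence(sex)
#' @export
chi_square_independence <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2 || ncol(counts) < 2) stop("need at least a 2x2 table")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    stop("zero row or column margin: expected counts undefined")
  }
  expected <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  stat <- sum((counts - expected)^2 / expected)
  df <- (nrow(counts) - 1) * (ncol(counts) - 1)
  tibble::tibble(
    statistic = stat, df = df,
    p = stats::pchisq(stat, df, lower.tail = FALSE)
  )
}

#' One-way ANOVA reconstructed from group summaries
#'
#' Rebuilds the between- and within-group sums of squares from per-group
#' (n, mean, sd) — `SSB = sum n_i (m_i - m)^2`,
#' `SSW = sum (n_i - 1) s_i^2` — giving `F = MSB / MSW` with
#' `df = (k - 1, N - k)`. This reproduces a raw-data one-way ANOVA exactly
#' whenever raw data matching the summaries exist; applied to summaries
#' printed at 1 decimal it agrees with the underlying raw-data F to within
#' rounding.
#'
#' @param n integer vector of group sizes (each >= 2).
#' @param mean numeric vector of group means.
#' @param sd numeric vector of group standard deviations (>= 0).
#' @return A one-row tibble: `statistic` (F), `df1`, `df2`, `p`.
#' @examples
#' oneway_anova_from_summary(
#'   n = c(170, 25, 142, 196),
#'   mean = c(101.98, 79.8, 94.93, 108.44),
#'   sd = c(18.8, 21.1, 20.8, 14.1)
#' )
#' @export
oneway_anova_from_summary <- function(n, mean, sd) {
  stopifnot(length(n) == length(mean), length(n) == length(sd))
  if (length(n) < 2) stop("need at least 2 groups")
  if (any(n < 2)) stop("every group needs n >= 2")
  if (any(sd < 0)) stop("sd must be >= 0")
  k <- length(n)
  N <- sum(n)
  gm <- sum(n * mean) / N
  ssb <- sum(n * (mean - gm)^2)
  ssw <- sum((n - 1) * sd^2)
  f <- (ssb / (k - 1)) / (ssw / (N - k))
  tibble::tibble(
    statistic = f, df1 = k - 1, df2 = N - k,
    p = stats::pf(f, k - 1, N - k, lower.tail = FALSE)
  )
}

#' Percentage of a count, reported at one decimal
#'
#' @param count numeric, `0 <= count <= total`.
#' @param total positive total.
#' @return `100 * count / total` rounded to 1 decimal.
#' @examples
#' percentage(107, 142) # 75.4
#' @export
percentage <- function(count, total) {
  if (total <= 0) stop("total must be > 0")
  if (count < 0 || count > total) stop("count must be in [0, total]")
  round(100 * count / total, 1)
}

#' Group-comparison statistics for a phenotype table
#'
#' Reproduces the demographics comparisons of the factorial cohort: a
#' chi-square test of independence on sex-by-group counts and unadjusted
#' one-way ANOVAs across the four subgroups for each continuous variable.
#'
#' @param subjects phenotype tibble with columns `group`, `sex`, and the
#'   continuous variables in `vars`.
#' @param vars continuous variables to compare (default `age`, `fsiq`,
#'   `global_measure` where present).
#' @return A tibble with one row per comparison: `variable`, `test`,
#'   `statistic`, `df1`, `df2` (NA for chi-square), `p`.
#' @export
compare_groups <- function(subjects, vars = NULL) {
  stopifnot(all(c("group", "sex") %in% names(subjects)))
  if (is.null(vars)) {
    vars <- intersect(c("age", "fsiq", "global_measure"), names(subjects))
  }
  sex_tab <- as.matrix(table(subjects$group, subjects$sex))
  chi <- chi_square_independence(sex_tab)
  rows <- list(tibble::tibble(
    variable = "sex", test = "chi-square",
    statistic = chi$statistic, df1 = chi$df, df2 = NA_real_, p = chi$p
  ))
  for (v in vars) {
    smry <- subjects |>
      dplyr::group_by(.data$group) |>
      dplyr::summarise(
        n = dplyr::n(),
        m = base::mean(.data[[v]]),
        s = stats::sd(.data[[v]]),
        .groups = "drop"
      )
    an <- oneway_anova_from_summary(smry$n, smry$m, smry$s)
    rows <- c(rows, list(tibble::tibble(
      variable = v, test = "oneway-anova",
      statistic = an$statistic, df1 = an$df1, df2 = an$df2, p = an$p
    )))
  }
  dplyr::bind_rows(rows)
}
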