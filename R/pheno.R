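# Descriptive phenotype statistics and the parental comparison.

#' Summary statistics of a trait vector
#'
#' Max, min, mean, and bias-corrected sample skewness and excess kurtosis
#' (the spreadsheet/SPSS convention, e1071 type 2):
#' \deqn{g_1' = \frac{n}{(n-1)(n-2)} \sum z_i^3, \qquad
#'   g_2' = \frac{n(n+1)}{(n-1)(n-2)(n-3)} \sum z_i^4 -
#'   \frac{3(n-1)^2}{(n-2)(n-3)}}
#' with \eqn{z_i = (x_i - \bar x)/s}. Simple moment estimators are available
#' with `bias_corrected = FALSE` (e1071 type 1). Skewness needs n >= 3,
#' kurtosis n >= 4; both are undefined (NA) for constant data.
#'
#' @param values Numeric vector (NAs dropped).
#' @param bias_corrected Use the bias-corrected formulas (default TRUE).
#' @return Tibble: `n`, `max`, `min`, `mean`, `skew`, `kurt`.
#' @export
#' @examples
#' pheno_summarize(c(4, 5, 6, 5))$skew  # 0
pheno_summarize <- function(values, bias_corrected = TRUE) {
  x <- values[!is.na(values)]
  n <- length(x)
  if (n == 0) {
    return(tibble(n = 0L, max = NA_real_, min = NA_real_, mean = NA_real_,
                  skew = NA_real_, kurt = NA_real_))
  }
  type <- if (bias_corrected) 2L else 1L
  skew <- if (n >= 3 && sd(x) > 0) e1071::skewness(x, type = type) else NA_real_
  kurt <- if (n >= 4 && sd(x) > 0) e1071::kurtosis(x, type = type) else NA_real_
  tibble(n = n, max = max(x), min = min(x), mean = mean(x),
         skew = skew, kurt = kurt)
}

#' Compare two parental groups by Welch's t-test
#'
#' Two-sample unequal-variance t-test with significance stars: `**` for
#' p < 0.01, `*` for p < 0.05. The degenerate all-constant case (zero
#' variance in both groups) yields p = 1 when the means are equal and p = 0
#' otherwise.
#'
#' @param group_a,group_b Numeric vectors, each with n >= 2.
#' @return Tibble: `t`, `df`, `p_value`, `stars`, `mean_a`, `mean_b`.
#' @export
#' @examples
#' compare_parents(c(5, 6, 7), c(5, 6, 7))$p_value  # 1
compare_parents <- function(group_a, group_b) {
  a <- group_a[!is.na(group_a)]
  b <- group_b[!is.na(group_b)]
  if (length(a) < 2 || length(b) < 2) {
    stop("both groups need at least 2 observations", call. = FALSE)
  }
  if (sd(a) == 0 && sd(b) == 0) {
    p <- if (mean(a) == mean(b)) 1 else 0
    t_stat <- if (mean(a) == mean(b)) 0 else Inf * sign(mean(a) - mean(b))
    df <- NA_real_
  } else {
    tt <- t.test(a, b, var.equal = FALSE)
    p <- tt$p.value
    t_stat <- unname(tt$statistic)
    df <- unname(tt$parameter)
  }
  tibble(t = t_stat, df = df, p_value = p,
         stars = if (p < 0.01) "**" else if (p < 0.05) "*" else "",
         mean_a = mean(a), mean_b = mean(b))
}

#' Per-group phenotype summary table
#'
#' One row per group with the descriptive statistics of
#' [pheno_summarize()] -- the layout of a parents/F1/segregating-populations
#' trait table.
#'
#' @param df Data frame with a grouping column and a value column.
#' @param group_col,value_col Column names.
#' @param bias_corrected See [pheno_summarize()].
#' @return Tibble: `group`, `n`, `max`, `min`, `mean`, `skew`, `kurt`.
#' @export
phenotype_summary_table <- function(df, group_col = "group",
                                    value_col = "nffb",
                                    bias_corrected = TRUE) {
  stopifnot(all(c(group_col, value_col) %in% names(df)))
  groups <- unique(df[[group_col]])
  rows <- lapply(groups, function(g) {
    s <- pheno_summarize(df[[value_col]][df[[group_col]] == g], bias_corrected)
    cbind(tibble(group = g), s)
  })
  as_tibble(do.call(rbind, rows))
}
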