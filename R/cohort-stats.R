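#' Unpaired two-sample t test from raw samples or summary statistics
#'
#' Pooled-variance (Student) two-sided t test by default, the historical
#' default of common desktop statistics software; set `var_equal = FALSE` for
#' the Welch test. Each group may be given either as a numeric vector of raw
#' samples or as a summary triplet `list(n =, mean =, sd =)` — published
#' group summaries can be tested directly, and by construction the two input
#' forms give identical results.
#'
#' If both groups have zero variance the test is degenerate: equal means
#' return `t = 0, p = 1` with a `"degenerate"` flag; unequal means are an
#' error (the pooled SD is 0).
#'
#' @param a,b numeric vector of samples, or `list(n, mean, sd)` (or a named
#'   numeric vector with those names). Each group needs `n >= 2`.
#' @param var_equal pooled-variance test if `TRUE` (default), Welch if
#'   `FALSE`.
#'
#' @return List: `t`, `df`, `p`, `method`, `flags`.
#'
#' @examples
#' unpaired_ttest(list(n = 27, mean = 16, sd = 4), list(n = 10, mean = 20, sd = 5))
#' @export
unpaired_ttest <- function(a, b, var_equal = TRUE) {
  a <- as_group_summary(a)
  b <- as_group_summary(b)
  flags <- character(0)
  if (a$sd == 0 && b$sd == 0) {
    if (isTRUE(all.equal(a$mean, b$mean))) {
      return(list(t = 0, df = a$n + b$n - 2, p = 1,
                  method = "pooled", flags = "degenerate"))
    }
    stop("both groups have zero variance with unequal means: t undefined")
  }
  if (var_equal) {
    df <- a$n + b$n - 2
    sp2 <- ((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / df
    se <- sqrt(sp2 * (1 / a$n + 1 / b$n))
    method <- "pooled"
  } else {
    va <- a$sd^2 / a$n
    vb <- b$sd^2 / b$n
    se <- sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (a$n - 1) + vb^2 / (b$n - 1))
    method <- "welch"
  }
  t <- (a$mean - b$mean) / se
  p <- 2 * pt(-abs(t), df)
  list(t = t, df = df, p = p, method = method, flags = flags)
}

as_group_summary <- function(x) {
  if (is.list(x) || (is.numeric(x) && !is.null(names(x)) &&
                     all(c("n", "mean", "sd") %in% names(x)))) {
    x <- as.list(x)
    if (!all(c("n", "mean", "sd") %in% names(x)))
      stop("summary input must provide n, mean and sd")
    out <- list(n = as.numeric(x$n), mean = as.numeric(x$mean),
                sd = as.numeric(x$sd))
  } else {
    x <- as.numeric(x[!is.na(x)])
    out <- list(n = length(x), mean = mean(x), sd = sd(x))
  }
  if (out$n < 2) stop("each group needs at least 2 observations")
  if (out$sd < 0) stop("sd must be non-negative")
  out
}

#' Pearson product-moment correlation with two-sided p value
#'
#' `r = cov(x, y) / (sd(x) sd(y))`, with the two-sided p value from the t
#' transform `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of
#' freedom. Pairs with a missing value in either variable are dropped
#' (pairwise-complete deletion); the effective `n` is reported.
#'
#' @param x,y numeric vectors of equal length, at least 3 complete pairs,
#'   nonzero variance in both.
#'
#' @return List: `r`, `p`, `n`, `df`, `t`.
#' @export
pearson_corr <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length")
  ok <- !is.na(x) & !is.na(y)
  x <- as.numeric(x[ok]); y <- as.numeric(y[ok])
  n <- length(x)
  if (n < 3) stop("Pearson correlation needs at least 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0)
    stop("correlation undefined: zero variance in x or y")
  r <- sum((x - mean(x)) * (y - mean(y))) / ((n - 1) * sd(x) * sd(y))
  r <- max(-1, min(1, r))
  df <- n - 2
  if (abs(r) == 1) {
    t <- sign(r) * Inf
    p <- 0
  } else {
    t <- r * sqrt(df / (1 - r^2))
    p <- 2 * pt(-abs(t), df)
  }
  list(r = r, p = p, n = n, df = df, t = t)
}

#' Interobserver variability of paired measurements
#'
#' For each pair the percent difference is taken relative to the pair mean,
#' `100 * (obs2 - obs1) / ((obs1 + obs2) / 2)` — symmetric in the two
#' observers — and summarised as mean +/- SD across pairs.
#'
#' @param obs1,obs2 numeric vectors of the two observers' measurements,
#'   equal length; pair means must be positive.
#'
#' @return List: `mean_pct`, `sd_pct`, `n`, `diff_pct` (per-pair values).
#' @export
interobserver_variability <- function(obs1, obs2) {
  if (length(obs1) != length(obs2))
    stop("observer vectors must have equal length")
  denom <- (obs1 + obs2) / 2
  if (any(!is.finite(denom)) || any(denom <= 0))
    stop("pair means must be positive")
  d <- 100 * (obs2 - obs1) / denom
  list(mean_pct = mean(d), sd_pct = sd(d), n = length(d), diff_pct = d)
}

#' Per-metric group summaries with unpaired t tests
#'
#' For each requested metric, reports per-group `n` (non-missing), mean and
#' SD — the "mean +/- SD" convention — together with the unpaired t test
#' between the two groups. Missing values are dropped per metric
#' (pairwise-complete), so the per-metric `n` can be smaller than the group
#' size, as when a covariate was only assessed in a subset of subjects.
#'
#' With `by`, the comparison is between the two levels of a boolean covariate
#' (e.g. presence of fibrosis on HRCT) instead of the patient/control split;
#' subjects with a missing `by` value are dropped.
#'
#' @param cohort a [cohort_table()] (or plain data frame with a `group`
#'   column).
#' @param metrics character vector of metric column names; unknown names are
#'   an error.
#' @param by optional name of a logical column used to split subjects instead
#'   of `group`.
#' @param var_equal passed to [unpaired_ttest()].
#'
#' @return A data frame with one row per metric: `metric`, `group1`, `n1`,
#'   `mean1`, `sd1`, `group2`, `n2`, `mean2`, `sd2`, `t`, `df`, `p`.
#' @export
summarize_groups <- function(cohort, metrics, by = NULL, var_equal = TRUE) {
  cohort <- as.data.frame(cohort)
  unknown <- setdiff(metrics, names(cohort))
  if (length(unknown))
    stop("unknown metric(s): ", paste(unknown, collapse = ", "))
  if (is.null(by)) {
    split_var <- as.character(cohort$group)
    levels <- c("patient", "control")
    if (!all(levels %in% split_var)) levels <- unique(split_var)
  } else {
    if (!by %in% names(cohort)) stop("unknown `by` column: ", by)
    split_var <- cohort[[by]]
    levels <- c(TRUE, FALSE)
  }
  if (length(unique(split_var[!is.na(split_var)])) != 2L)
    stop("grouping variable must have exactly 2 levels")
  rows <- lapply(metrics, function(m) {
    v1 <- cohort[[m]][!is.na(split_var) & split_var == levels[1]]
    v2 <- cohort[[m]][!is.na(split_var) & split_var == levels[2]]
    v1 <- v1[!is.na(v1)]; v2 <- v2[!is.na(v2)]
    # a metric whose test is undefined (e.g. zero variance in both groups
    # with unequal means) still gets its summary row, with NA test fields
    tt <- tryCatch(unpaired_ttest(v1, v2, var_equal = var_equal),
                   error = function(e) list(t = NA_real_, df = NA_real_,
                                            p = NA_real_))
    data.frame(
      metric = m,
      group1 = as.character(levels[1]), n1 = length(v1),
      mean1 = mean(v1), sd1 = sd(v1),
      group2 = as.character(levels[2]), n2 = length(v2),
      mean2 = mean(v2), sd2 = sd(v2),
      t = tt$t, df = tt$df, p = tt$p,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Cohort table of per-subject records
#'
#' A data frame of subject records with a `group` column (`"patient"` /
#' `"control"`) and one column per derived metric or covariate. Light
#' validation wrapper used by the cohort generator, readers and the batch
#' pipeline.
#'
#' @param df data frame with at least `id` and `group` columns.
#'
#' @return `df` with class `c("cohort_table", "data.frame")`.
#' @export
cohort_table <- function(df) {
  df <- as.data.frame(df)
  if (!all(c("id", "group") %in% names(df)))
    stop("a cohort table needs `id` and `group` columns")
  if (!all(df$group %in% c("patient", "control")))
    stop("`group` must be 'patient' or 'control'")
  tab <- table(df$group)
  if (length(tab) == 2L && any(tab < 2))
    warning("fewer than 2 subjects in a group: statistics unavailable")
  class(df) <- c("cohort_table", "data.frame")
  df
}
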