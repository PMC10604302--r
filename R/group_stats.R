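# Per-group descriptive statistics, Wilcoxon-Mann-Whitney tests, and the
# variance-standardised consistency measure used to rank indicators.

#' Per-group descriptive statistics
#'
#' Means, medians (midpoint convention for even n), and sample standard
#' deviations (n - 1 denominator) for the non-cardiac (0) and cardiac (1)
#' groups, after missing-value removal.
#'
#' @param values0,values1 Numeric vectors for groups 0 and 1.
#' @return Named list `mu0, mu1, m0, m1, s0, s1` plus group sizes `n0, n1`.
#' @export
summarize_groups <- function(values0, values1) {
  values0 <- values0[!is.na(values0)]
  values1 <- values1[!is.na(values1)]
  if (length(values0) == 0 || length(values1) == 0) {
    stop("degenerate group: empty after missing-value removal", call. = FALSE)
  }
  list(mu0 = mean(values0), mu1 = mean(values1),
       m0 = stats::median(values0), m1 = stats::median(values1),
       s0 = stats::sd(values0), s1 = stats::sd(values1),
       n0 = length(values0), n1 = length(values1))
}

#' Consistency measure between two groups
#'
#' Standardised distance between the group means,
#' `d = |mu0 - mu1| / sqrt(s0^2 + s1^2)`.  The denominator is the square root
#' of the summed group variances, which makes d invariant under swapping the
#' groups and under common positive rescaling of all values.  An indicator
#' with a larger d separates the cardiac and non-cardiac groups more cleanly
#' relative to its dispersion.
#'
#' @param mu0,mu1 Group means.
#' @param s0,s1 Group standard deviations (n - 1 denominator).
#' @return Non-negative scalar (vectorised over its arguments).
#' @examples
#' consistency_d(105.1306, 108.0998, 11.6754, 11.6864)  # 0.1797
#' @export
consistency_d <- function(mu0, mu1, s0, s1) {
  if (any(s0 < 0 | s1 < 0)) stop("standard deviations must be non-negative",
                                 call. = FALSE)
  denom2 <- s0^2 + s1^2
  if (any(denom2 == 0)) {
    stop("undefined consistency measure: both group SDs are zero",
         call. = FALSE)
  }
  abs(mu0 - mu1) / sqrt(denom2)
}

#' Two-sided Wilcoxon-Mann-Whitney p-value
#'
#' Exact enumeration when the combined sample is small (`n0 + n1 <=
#' exact_limit`) and untied; otherwise the normal approximation with
#' continuity and tie correction.
#'
#' @param values0,values1 Numeric vectors; missing values dropped.
#' @param exact_limit Combined-size threshold for the exact path (default 30).
#' @return Two-sided p-value.  If every value in both groups is identical the
#'   test is degenerate and `p = 1` is returned with a warning.
#' @export
wmw_pvalue <- function(values0, values1, exact_limit = 30) {
  values0 <- values0[!is.na(values0)]
  values1 <- values1[!is.na(values1)]
  if (length(values0) == 0 || length(values1) == 0) {
    stop("degenerate group: empty after missing-value removal", call. = FALSE)
  }
  all_vals <- c(values0, values1)
  if (length(unique(all_vals)) == 1) {
    warning("all values identical across both groups: p set to 1",
            call. = FALSE)
    return(1)
  }
  ties <- anyDuplicated(all_vals) > 0
  use_exact <- (length(all_vals) <= exact_limit) && !ties
  suppressWarnings(
    stats::wilcox.test(values0, values1, alternative = "two.sided",
                       exact = use_exact, correct = TRUE)$p.value)
}

#' Indicator-by-indicator group comparison report
#'
#' Computes, for each of the seven indicators in the fixed order alpha,
#' alpha2, HM, MAP, PBPI, PBPIRC, RC, the group means/medians/SDs, the
#' Wilcoxon-Mann-Whitney p-value and the consistency measure d between the
#' non-cardiac (y = 0) and cardiac (y = 1) groups.  Indicators whose groups
#' are degenerate (e.g. a single-class cohort) produce a row of missing values
#' with a note instead of aborting the report.
#'
#' @param cohort A `cs_cohort`; indicator columns are computed from the vitals
#'   if not already present.
#' @param conventions A [cs_conventions()] object.
#' @return A data frame of class `cs_group_report` with one row per indicator
#'   (`indicator`, `mu0`, `mu1`, `m0`, `m1`, `s0`, `s1`, `p_wmw`, `d`,
#'   `note`).
#' @export
indicator_report <- function(cohort, conventions = cs_conventions()) {
  if (!all(cs_indicator_names() %in% names(cohort))) {
    cohort <- add_indicators(cohort, conventions)
  }
  rows <- lapply(cs_indicator_names(), function(ind) {
    v0 <- cohort[[ind]][cohort$y == 0]
    v1 <- cohort[[ind]][cohort$y == 1]
    tryCatch({
      s <- summarize_groups(v0, v1)
      p <- suppressWarnings(wmw_pvalue(v0, v1))
      d <- consistency_d(s$mu0, s$mu1, s$s0, s$s1)
      data.frame(indicator = ind, mu0 = s$mu0, mu1 = s$mu1, m0 = s$m0,
                 m1 = s$m1, s0 = s$s0, s1 = s$s1, p_wmw = p, d = d,
                 note = "")
    }, error = function(e) {
      data.frame(indicator = ind, mu0 = NA_real_, mu1 = NA_real_,
                 m0 = NA_real_, m1 = NA_real_, s0 = NA_real_, s1 = NA_real_,
                 p_wmw = NA_real_, d = NA_real_, note = conditionMessage(e))
    })
  })
  out <- do.call(rbind, rows)
  class(out) <- c("cs_group_report", "data.frame")
  out
}

# significance stars: * at 10%, ** at 5%, *** at 1%
significance_stars <- function(p) {
  ifelse(is.na(p), "",
         ifelse(p < 0.01, "***", ifelse(p < 0.05, "**",
                                        ifelse(p < 0.10, "*", ""))))
}

#' @export
print.cs_group_report <- function(x, digits = 4, ...) {
  d <- as.data.frame(x)
  num <- c("mu0", "mu1", "m0", "m1", "s0", "s1", "p_wmw", "d")
  for (col in num) d[[col]] <- signif(d[[col]], digits)
  d$sig <- significance_stars(x$p_wmw)
  d$note <- NULL
  print.data.frame(d, row.names = FALSE)
  cat("Signif.: '*' 10%, '**' 5%, '***' 1%\n")
  invisible(x)
}

#' Render a group report as markdown or CSV text
#' @param x A `cs_group_report`.
#' @param format `"markdown"` or `"csv"`.
#' @param digits Significant digits.
#' @return Character vector of lines.
#' @export
format_group_report <- function(x, format = c("markdown", "csv"), digits = 4) {
  format <- match.arg(format)
  d <- as.data.frame(x)
  num <- c("mu0", "mu1", "m0", "m1", "s0", "s1", "p_wmw", "d")
  for (col in num) d[[col]] <- formatC(d[[col]], digits = digits,
                                       format = "f")
  d$sig <- significance_stars(x$p_wmw)
  d$note <- NULL
  if (format == "csv") {
    con <- textConnection("out", "w", local = TRUE)
    utils::write.csv(d, con, row.names = FALSE)
    close(con)
    return(out)
  }
  header <- paste0("| ", paste(names(d), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(d)), collapse = "|"), "|")
  body <- apply(d, 1, function(r) paste0("| ", paste(r, collapse = " | "),
                                         " |"))
  c(header, sep, body)
}

#' Consistency measures recomputed from published group statistics
#'
#' Applies [consistency_d()] to a table of per-indicator group means and SDs
#' (by default the shipped [reference_group_stats()]), returning the dataset by
#' indicator matrix of d values.
#'
#' @param stats Data frame with columns `dataset`, `indicator`, `mu0`, `mu1`,
#'   `s0`, `s1`.
#' @return Data frame with one row per (dataset, indicator) and a `d` column.
#' @export
consistency_from_stats <- function(stats = reference_group_stats()) {
  stats$d <- consistency_d(stats$mu0, stats$mu1, stats$s0, stats$s1)
  stats[, c("dataset", "indicator", "d")]
}
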