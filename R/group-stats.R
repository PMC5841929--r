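# Group comparison tests and the summary report.

#' Two-sided Mann-Whitney U test (Wilcoxon rank-sum)
#'
#' Exact when both samples have at most 20 observations and no ties;
#' normal approximation with continuity correction otherwise.
#'
#' @param a,b numeric samples for the two groups.
#' @return list with `statistic` (U for the first sample), `p`.
#' @export
mann_whitney <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (!length(a) || !length(b)) stop("both groups must be nonempty")
  exact <- length(a) <= 20 && length(b) <= 20 &&
    !anyDuplicated(c(a, b))
  w <- suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                           correct = TRUE))
  list(statistic = unname(w$statistic), p = w$p.value)
}

#' Pearson chi-square test for two proportions
#'
#' Chi-square test on the 2x2 table (k1, n1 - k1; k2, n2 - k2) with one
#' degree of freedom and no continuity correction.
#'
#' @param k1,n1 successes and total in group 1.
#' @param k2,n2 successes and total in group 2.
#' @return list with `statistic` (chi-square), `p`, `df`.
#' @export
chi_square_proportions <- function(k1, n1, k2, n2) {
  stopifnot(k1 >= 0, k2 >= 0, k1 <= n1, k2 <= n2)
  tab <- matrix(c(k1, n1 - k1, k2, n2 - k2), nrow = 2, byrow = TRUE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("degenerate 2x2 table (zero margin)")
  ct <- stats::chisq.test(tab, correct = FALSE)
  list(statistic = unname(ct$statistic), p = ct$p.value,
       df = unname(ct$parameter))
}

#' One-way ANOVA
#'
#' Standard fixed-effects one-way F test assuming equal variances, as
#' applied to per-animal means.
#'
#' @param groups list of numeric vectors, one per group (>= 2 groups,
#'   each with >= 2 values).
#' @return list with `statistic` (F), `p`, `df1`, `df2`; degenerate
#'   within-group variance gives `NA` with a warning.
#' @export
one_way_anova <- function(groups) {
  stopifnot(length(groups) >= 2L, all(lengths(groups) >= 2L))
  y <- unlist(groups)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  if (stats::var(y) == 0) {
    warning("degenerate variance: all observations identical")
    return(list(statistic = NA_real_, p = NA_real_,
                df1 = length(groups) - 1L, df2 = length(y) - length(groups)))
  }
  ot <- stats::oneway.test(y ~ g, var.equal = TRUE)
  list(statistic = unname(ot$statistic), p = ot$p.value,
       df1 = unname(ot$parameter[1]), df2 = unname(ot$parameter[2]))
}

#' Significance stars for a p-value
#'
#' Conventional star notation: `***` p < 0.001, `**` p < 0.01, `*`
#' p < 0.05, empty otherwise.
#'
#' @param p numeric p-value(s).
#' @return character vector of star strings.
#' @export
p_stars <- function(p) {
  vapply(p, function(pp) {
    if (is.na(pp)) "" else if (pp < 0.001) "***"
    else if (pp < 0.01) "**" else if (pp < 0.05) "*" else ""
  }, character(1))
}

#' Group-comparison report table
#'
#' Builds one row per metric with group means +/- SEM, the chosen test
#' and its p-value with significance stars. Per-unit metrics are
#' compared with the Mann-Whitney U test; per-animal metrics with
#' one-way ANOVA. Metrics present in only one group are omitted with a
#' warning. No multiple-testing correction is applied.
#'
#' @param metrics_a,metrics_b named lists of numeric vectors (metric
#'   name -> per-unit or per-animal samples) for the two groups.
#' @param test `"mwu"` or `"anova1"`, recycled over metrics.
#' @param group_names labels for the two groups.
#' @return data.frame: `metric`, `n_<a>`, `mean_<a>`, `sem_<a>`, same
#'   for group b, `test`, `statistic`, `p`, `stars`.
#' @export
build_report <- function(metrics_a, metrics_b, test = "mwu",
                         group_names = c("a", "b")) {
  common <- intersect(names(metrics_a), names(metrics_b))
  lost <- setdiff(union(names(metrics_a), names(metrics_b)), common)
  if (length(lost))
    warning("metrics missing in one group, omitted: ",
            paste(lost, collapse = ", "))
  test <- rep_len(test, length(common))
  sem <- function(x) stats::sd(x) / sqrt(length(x))
  rows <- lapply(seq_along(common), function(k) {
    m <- common[k]
    a <- metrics_a[[m]]; a <- a[!is.na(a)]
    b <- metrics_b[[m]]; b <- b[!is.na(b)]
    res <- if (test[k] == "anova1") one_way_anova(list(a, b))
           else mann_whitney(a, b)
    data.frame(metric = m, n_a = length(a), mean_a = mean(a), sem_a = sem(a),
               n_b = length(b), mean_b = mean(b), sem_b = sem(b),
               test = test[k], statistic = res$statistic, p = res$p,
               stars = p_stars(res$p), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  names(out) <- c("metric",
                  paste0(c("n_", "mean_", "sem_"), group_names[1]),
                  paste0(c("n_", "mean_", "sem_"), group_names[2]),
                  "test", "statistic", "p", "stars")
  out
}
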