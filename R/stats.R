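# ICEES-style interrogation of an integrated feature table: cohort
# selection, 2x2 feature-association tables, Pearson chi-square, and
# column-percent formatting.

# Comparable numeric view of a column: numerics pass through; binned range
# labels are ordered by their lower edge.
comparable_values <- function(x) {
  if (is.numeric(x)) return(x)
  parse_bin_lower(x)
}

#' Select a cohort from an integrated feature table
#'
#' @param table Tibble (an integrated feature table).
#' @param filters List of `list(variable, operator, value)` triples combined
#'   by conjunction.  Operators: `"="` (label or numeric equality), `"<"`,
#'   `">="` (numeric, or ordering of binned range labels by lower edge).
#' @return The filtered tibble.
#' @export
select_cohort <- function(table, filters = list()) {
  out <- table
  for (f in filters) {
    v <- f$variable %||% f[[1]]
    op <- f$operator %||% f[[2]]
    val <- f$value %||% f[[3]]
    if (!v %in% names(out)) {
      stop_clinexpo(sprintf("unknown variable '%s'", v), "query_error")
    }
    keep <- switch(
      op,
      "=" = out[[v]] == val,
      "<" = comparable_values(out[[v]]) < as.numeric(val),
      ">=" = , "≥" = comparable_values(out[[v]]) >= as.numeric(val),
      stop_clinexpo(sprintf("unsupported operator '%s'", op), "query_error")
    )
    out <- out[!is.na(keep) & keep, , drop = FALSE]
  }
  out
}

#' Build a 2x2 feature-by-outcome contingency table
#'
#' Dichotomizes a feature (at a level, or at a numeric cutpoint applied to
#' numeric values or to binned-label lower edges) against an outcome
#' dichotomized at a threshold (`< t` vs `>= t`, e.g. fewer than two vs two
#' or more annual ED/inpatient respiratory visits).  Rows missing either
#' variable are excluded and counted.
#'
#' @param cohort Tibble of cohort rows.
#' @param feature `list(variable =, level =)` or `list(variable =, cutpoint =)`.
#' @param outcome `list(variable =, threshold =)`.
#' @return A `contingency_2x2`: list with `counts` (2x2 integer matrix,
#'   feature levels as rows, outcome levels as columns), `cohort_n`,
#'   `n_excluded`, and the dichotomization descriptors.
#' @export
contingency_2x2 <- function(cohort, feature, outcome) {
  fv <- cohort[[feature$variable]]
  ov <- cohort[[outcome$variable]]
  if (is.null(fv) || is.null(ov)) {
    stop_clinexpo("feature or outcome variable not in table", "query_error")
  }
  if (!is.null(feature$level)) {
    fbin <- fv == feature$level
    row_labels <- c("No", "Yes")
  } else {
    fbin <- comparable_values(fv) >= as.numeric(feature$cutpoint)
    row_labels <- paste0(c("<", ">="), feature$cutpoint)
  }
  obin <- comparable_values(ov) >= as.numeric(outcome$threshold)
  col_labels <- paste0(c("<", ">="), outcome$threshold)

  ok <- !is.na(fbin) & !is.na(obin)
  counts <- matrix(
    c(sum(!fbin[ok] & !obin[ok]), sum(fbin[ok] & !obin[ok]),
      sum(!fbin[ok] & obin[ok]), sum(fbin[ok] & obin[ok])),
    nrow = 2, dimnames = list(row_labels, col_labels)
  )
  new_contingency_2x2(counts, n_excluded = sum(!ok),
                      feature = feature, outcome = outcome)
}

#' Construct a 2x2 contingency table from counts
#'
#' @param counts 2x2 non-negative integer matrix (rows = feature levels,
#'   columns = outcome levels); dimnames optional.
#' @param n_excluded Rows excluded for missingness.
#' @param feature,outcome Optional descriptors.
#' @return A `contingency_2x2`.
#' @export
new_contingency_2x2 <- function(counts, n_excluded = 0L,
                                feature = NULL, outcome = NULL) {
  counts <- matrix(as.integer(counts), nrow = 2, dimnames = dimnames(counts))
  stopifnot(all(counts >= 0))
  if (is.null(dimnames(counts))) {
    dimnames(counts) <- list(c("No", "Yes"), c("<2", ">=2"))
  }
  structure(
    list(counts = counts, cohort_n = sum(counts),
         n_excluded = as.integer(n_excluded),
         feature = feature, outcome = outcome),
    class = "contingency_2x2"
  )
}

#' @export
print.contingency_2x2 <- function(x, ...) {
  cat(sprintf("<contingency_2x2> N = %d (%d excluded for missingness)\n",
              x$cohort_n, x$n_excluded))
  print(x$counts)
  invisible(x)
}

#' Pearson chi-square test of a 2x2 table
#'
#' Pearson's statistic without continuity correction,
#' \eqn{\sum (O - E)^2 / E} with expected counts from the row/column
#' marginals, on 1 degree of freedom.  The statistic is reported rounded
#' half-up to 4 decimals (the convention of ICEES-style result tables);
#' degenerate tables (a zero marginal) are an error.
#'
#' @param t A `contingency_2x2` (or a bare 2x2 matrix of counts).
#' @return A `chisq_assoc`: list with `statistic` (4-decimal), `p_value`,
#'   `df`, `statistic_raw`, and the source `table`.
#' @export
chi_square <- function(t) {
  if (is.matrix(t)) t <- new_contingency_2x2(t)
  m <- t$counts
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    stop_clinexpo("chi-square undefined: zero marginal", "degenerate_table")
  }
  # nominal statistic and p-value are wanted even at small expected counts
  ht <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  structure(
    list(
      statistic = round_half_up(unname(ht$statistic), 4),
      statistic_raw = unname(ht$statistic),
      p_value = unname(ht$p.value),
      df = unname(ht$parameter),
      table = t
    ),
    class = "chisq_assoc"
  )
}

#' @export
print.chisq_assoc <- function(x, ...) {
  cat(sprintf("X^2 = %.4f, df = %d, P %s\n", x$statistic, x$df,
              if (x$p_value < 1e-4) "< 0.0001" else sprintf("= %.4f", x$p_value)))
  invisible(x)
}

#' Format a 2x2 table as column percentages
#'
#' Each cell becomes `"N (p%)"` with `p = 100 * cell / column sum`, rounded
#' half-up to 2 decimals, so each column's percentages sum to 100 within
#' rounding.
#'
#' @param t A `contingency_2x2` (or a 2x2 count matrix).
#' @return 2x2 character matrix with the source dimnames.
#' @export
column_percent <- function(t) {
  if (is.matrix(t)) t <- new_contingency_2x2(t)
  m <- t$counts
  cs <- colSums(m)
  if (any(cs == 0)) stop_clinexpo("column percent undefined: zero column sum", "degenerate_table")
  pct <- round_half_up(100 * sweep(m, 2, cs, "/"), 2)
  out <- matrix(
    sprintf("%s (%.2f%%)", format(m, big.mark = ",", trim = TRUE), pct),
    nrow = 2, dimnames = dimnames(m)
  )
  out
}

#' Run a cohort-association query against a feature table
#'
#' The query is a list (typically parsed from JSON): `cohort` filters,
#' `feature`, and `outcome` as accepted by [select_cohort()] and
#' [contingency_2x2()].
#'
#' @param table Integrated feature tibble.
#' @param query List with `cohort` (optional), `feature`, `outcome`.
#' @return List: `cohort_n`, `counts`, `formatted` (column percents),
#'   `chi_square`, `p_value`, `df`, `n_excluded`.
#' @export
run_query <- function(table, query) {
  cohort <- select_cohort(table, query$cohort %||% list())
  ct <- contingency_2x2(cohort, query$feature, query$outcome)
  ht <- chi_square(ct)
  list(
    cohort_n = ct$cohort_n,
    n_excluded = ct$n_excluded,
    row_labels = rownames(ct$counts),
    col_labels = colnames(ct$counts),
    counts = unclass(ct$counts),
    formatted = column_percent(ct),
    chi_square = ht$statistic,
    p_value = ht$p_value,
    df = ht$df
  )
}

#' @method tidy contingency_2x2
#' @export
tidy.contingency_2x2 <- function(x, ...) {
  m <- x$counts
  tibble::tibble(
    feature_level = rep(rownames(m), 2),
    outcome_level = rep(colnames(m), each = 2),
    n = as.integer(m),
    column_percent = as.numeric(round_half_up(100 * sweep(m, 2, colSums(m), "/"), 2))
  )
}

#' @method tidy chisq_assoc
#' @export
tidy.chisq_assoc <- function(x, ...) {
  tibble::tibble(
    statistic = x$statistic, p_value = x$p_value, df = x$df,
    method = "Pearson chi-square (no continuity correction)"
  )
}

#' @method glance chisq_assoc
#' @export
glance.chisq_assoc <- function(x, ...) {
  tibble::tibble(
    statistic = x$statistic, p_value = x$p_value, df = x$df,
    cohort_n = x$table$cohort_n, n_excluded = x$table$n_excluded
  )
}

#' @method autoplot contingency_2x2
#' @export
autoplot.contingency_2x2 <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data$outcome_level, y = .data$column_percent, fill = .data$feature_level
  )) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "outcome level", y = "% of column",
                  fill = "feature level") +
    ggplot2::theme_minimal()
}
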