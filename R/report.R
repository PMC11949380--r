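#' Assemble the period-by-subgroup metrics table
#'
#' Runs the matrix metric computations for every transition-probability
#' context and stacks the rows into one table keyed by (period, subgroup).
#'
#' @param probs_by_context list of `transition_probs`, each carrying its own
#'   period and subgroup metadata. Duplicate (period, subgroup) keys are an
#'   error.
#' @param start_age,cond_age passed to [multistate_metrics()].
#' @return A `metrics_table`: data frame of metrics rows.
#' @export
build_metrics_table <- function(probs_by_context, start_age = 480,
                                cond_age = 780) {
  if (inherits(probs_by_context, "transition_probs")) {
    probs_by_context <- list(probs_by_context)
  }
  keys <- vapply(probs_by_context, function(tp) {
    paste(tp$period, tp$subgroup, sep = "|")
  }, character(1))
  if (anyDuplicated(keys)) {
    stop("duplicate (period, subgroup) context: ", keys[duplicated(keys)][1])
  }
  rows <- lapply(probs_by_context, multistate_metrics,
                 start_age = start_age, cond_age = cond_age)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("metrics_table", "data.frame")
  out
}

#' @export
print.metrics_table <- function(x, digits = 2, ...) {
  cat("Multistate metrics by period and subgroup:\n")
  y <- as.data.frame(x)
  num <- vapply(y, is.numeric, logical(1))
  y[num] <- lapply(y[num], round, digits = digits)
  print(y, row.names = FALSE)
  invisible(x)
}

#' @export
plot.metrics_table <- function(x, metric = "e_free", ...) {
  df <- as.data.frame(x)
  if (!metric %in% names(df)) stop("unknown metric: ", metric)
  groups <- unique(df$subgroup)
  pers <- intersect(period_labels(), unique(as.character(df$period)))
  cols <- grDevices::hcl.colors(max(3L, length(groups)), "Dark 3")
  m <- sapply(groups, function(g) {
    df[match(paste(pers, g), paste(df$period, df$subgroup)), metric]
  })
  graphics::matplot(seq_along(pers), m, type = "b", pch = 19, lty = 1,
                    col = cols[seq_along(groups)], xaxt = "n",
                    xlab = "Period", ylab = metric, ...)
  graphics::axis(1, at = seq_along(pers), labels = pers, cex.axis = 0.8)
  graphics::legend("topleft", legend = groups, col = cols[seq_along(groups)],
                   lty = 1, pch = 19, bty = "n", cex = 0.8)
  invisible(x)
}

#' Look up one row of a metrics table
#'
#' @param table a `metrics_table`.
#' @param subgroup,period the row key.
#' @return The one-row data frame; an error if the row does not exist.
#' @export
metrics_lookup <- function(table, subgroup, period) {
  df <- as.data.frame(table)
  hit <- which(as.character(df$subgroup) == subgroup &
                 as.character(df$period) == period)
  if (length(hit) == 0L) {
    stop(sprintf("no metrics row for subgroup '%s' in period '%s'",
                 subgroup, period))
  }
  df[hit[1L], , drop = FALSE]
}

# metrics measured in percent are rounded to integers for display,
# metrics in years to one decimal
metric_is_percent <- function(metric) {
  metric %in% c("pct_free", "lifetime_risk_pct")
}

#' Between-group disparity in a metric
#'
#' Difference `metric(group_a) - metric(group_b)` within one period, on the
#' metric's native scale, with display rounding matching the conventions of
#' the reported tables: years to one decimal, percentage points to
#' integers.
#'
#' @param table a `metrics_table` (computed or reference).
#' @param metric a metric column name, e.g. `"tle"`, `"e_free"`, `"e_cvd"`,
#'   `"pct_free"`.
#' @param group_a,group_b subgroup labels.
#' @param period period label.
#' @return The rounded gap (group_a minus group_b).
#' @export
disparity_gap <- function(table, metric, group_a, group_b, period) {
  a <- metrics_lookup(table, group_a, period)[[metric]]
  b <- metrics_lookup(table, group_b, period)[[metric]]
  if (is.null(a) || is.null(b)) stop("unknown metric: ", metric)
  gap <- a - b
  if (metric_is_percent(metric)) round(gap) else round(gap, 1)
}

#' Disparity trends across all periods
#'
#' Per-period gaps for one metric and group pair, plus the change from
#' first to last period (last gap minus first gap).
#'
#' @inheritParams disparity_gap
#' @param periods the period labels to cover (default all present).
#' @return A list with the per-period `gaps` (named vector) and `change`.
#' @export
disparity_report <- function(table, metric, group_a, group_b,
                             periods = NULL) {
  df <- as.data.frame(table)
  if (is.null(periods)) {
    periods <- intersect(period_labels(), unique(as.character(df$period)))
  }
  gaps <- vapply(periods, function(p) {
    disparity_gap(table, metric, group_a, group_b, p)
  }, numeric(1))
  list(metric = metric, group_a = group_a, group_b = group_b,
       gaps = gaps, change = unname(gaps[length(gaps)] - gaps[1L]))
}

#' Decompose a life-expectancy gain into CVD-free and CVD years
#'
#' Differences in total, CVD-free and CVD life expectancy for one group
#' between two periods, and the share of the total gain that is CVD-free.
#' Differences are displayed to one decimal and the share to the nearest
#' percent (computed from the unrounded differences). A zero total change
#' leaves the share undefined (`NA` with a warning).
#'
#' @param table a `metrics_table` with `tle`, `e_free`, `e_cvd` columns.
#' @param group subgroup label.
#' @param first_period,last_period period labels to compare.
#' @return List with `d_tle`, `d_free`, `d_cvd` (years, 1 decimal) and
#'   `pct_free_of_gain` (integer percent or `NA`).
#' @export
decompose_tle_gain <- function(table, group, first_period, last_period) {
  r1 <- metrics_lookup(table, group, first_period)
  r2 <- metrics_lookup(table, group, last_period)
  d_tle <- r2$tle - r1$tle
  d_free <- r2$e_free - r1$e_free
  d_cvd <- r2$e_cvd - r1$e_cvd
  share <- if (d_tle == 0) {
    warning("total life expectancy did not change; share of gain undefined")
    NA_real_
  } else {
    round(100 * d_free / d_tle)
  }
  list(d_tle = round(d_tle, 1), d_free = round(d_free, 1),
       d_cvd = round(d_cvd, 1), pct_free_of_gain = share)
}

#' Percent of life expectancy spent disease-free
#'
#' `100 * e_free / tle`, rounded to the nearest integer for display; the
#' unrounded value is kept in the `"unrounded"` attribute.
#'
#' @param e_free disease-free expectancy (years).
#' @param tle total life expectancy (years, > 0).
#' @return Rounded integer percent with attribute `unrounded`.
#' @export
percent_cvd_free <- function(e_free, tle) {
  if (any(tle <= 0)) stop("tle must be positive")
  val <- 100 * e_free / tle
  structure(round(val), unrounded = val)
}

#' Published reference tables for Finland 1996-2020
#'
#' Loads the packaged reference tables of register-based estimates for the
#' Finnish population aged 40-100, 1996-2020: expectancies at age 40
#' (total life expectancy, CVD-free and CVD years, percent CVD-free) and
#' the lifetime risk of CVD at age 40 (percent), by period for the total
#' population, by gender, and by gender and education. They drive the
#' worked examples of the reporting operations.
#'
#' @return `reference_expectancies()`: a `metrics_table` with columns
#'   `period`, `subgroup`, `tle`, `e_free`, `e_cvd`, `pct_free`.
#'   `reference_lifetime_risk()`: same keys with `lifetime_risk_pct`.
#' @export
reference_expectancies <- function() {
  path <- system.file("extdata", "finland_cvd_expectancies_1996_2020.csv",
                      package = "msexpect", mustWork = TRUE)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  class(df) <- c("metrics_table", "data.frame")
  df
}

#' @rdname reference_expectancies
#' @export
reference_lifetime_risk <- function() {
  path <- system.file("extdata", "finland_cvd_lifetime_risk_1996_2020.csv",
                      package = "msexpect", mustWork = TRUE)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  class(df) <- c("metrics_table", "data.frame")
  df
}

#' Export a metrics table or long transition probabilities as CSV
#'
#' @param x a `metrics_table` or list of `transition_probs`.
#' @param path file path.
#' @return the path, invisibly.
#' @export
write_metrics_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_metrics_csv
#' @export
write_transition_probs_csv <- function(x, path) {
  utils::write.csv(transition_probs_table(x), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
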