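#' Round half away from zero
#'
#' Report tables use conventional half-up rounding (0.005 -> 0.01), not the
#' round-half-even rule of [round()]. Internal computations always stay at
#' full precision; rounding happens only at render time.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Mean score of one DMU across periods
#'
#' @param table long table with columns `dmu`, `period` and a value column.
#' @param dmu the DMU.
#' @param value_col name of the value column (default `"rho"`).
#' @return arithmetic mean over the DMU's periods.
#' @export
dmu_mean <- function(table, dmu, value_col = "rho") {
  stopifnot(value_col %in% names(table))
  sel <- table$dmu == dmu
  if (!any(sel)) stop(sprintf("unknown dmu '%s'", dmu), call. = FALSE)
  mean(table[[value_col]][sel])
}

#' Regional annual trajectories
#'
#' Unweighted mean of member DMUs per region per period (so each province
#' counts once regardless of size).
#'
#' @param table long table with columns `dmu`, `period` and a value column.
#' @param region_map data frame `dmu, region` (see [read_region_map()]).
#' @param value_col name of the value column (default `"rho"`).
#' @return data frame `region, period, mean`.
#' @export
regional_series <- function(table, region_map, value_col = "rho") {
  stopifnot(value_col %in% names(table))
  missing <- setdiff(unique(table$dmu), region_map$dmu)
  if (length(missing)) {
    stop("DMUs without region assignment: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  region <- region_map$region[match(table$dmu, region_map$dmu)]
  agg <- stats::aggregate(
    list(mean = table[[value_col]]),
    by = list(region = region, period = table$period), FUN = mean)
  agg[order(agg$region, agg$period), , drop = FALSE]
}

#' Render a DMU-by-period summary table with marginal means
#'
#' Pivots a long score table to DMUs-by-periods, appends an "Average"
#' column (per-DMU mean over periods) and an "Average" row (per-period mean
#' over DMUs). The grand-mean cell is the same whether computed row-wise or
#' column-wise; this consistency is asserted to 1e-12 before rounding.
#' Rounding is half-up at the requested number of decimals and applied only
#' to the returned `rounded` copy; the `full` copy keeps full precision.
#'
#' @param table long table with columns `dmu`, `period` and a value column;
#'   must be rectangular (every dmu observed in every period).
#' @param digits decimal places for the rounded copy (default 2).
#' @param value_col name of the value column (default `"rho"`).
#' @return list with elements `full` and `rounded`, each a data frame whose
#'   first column is `dmu` and remaining columns are the periods plus
#'   `Average`.
#' @export
render_summary <- function(table, digits = 2, value_col = "rho") {
  stopifnot(all(c("dmu", "period") %in% names(table)),
            value_col %in% names(table))
  dmus <- unique(table$dmu)
  periods <- sort(unique(table$period))
  m <- matrix(NA_real_, length(dmus), length(periods),
              dimnames = list(dmus, as.character(periods)))
  m[cbind(match(table$dmu, dmus), match(table$period, periods))] <-
    table[[value_col]]
  if (anyNA(m)) stop("table is ragged: not every dmu has every period",
                     call. = FALSE)
  row_avg <- rowMeans(m)
  col_avg <- colMeans(m)
  grand_by_rows <- mean(row_avg)
  grand_by_cols <- mean(col_avg)
  stopifnot(abs(grand_by_rows - grand_by_cols) <= 1e-12)
  full <- rbind(cbind(m, Average = row_avg),
                Average = c(col_avg, grand_by_rows))
  as_df <- function(x) {
    out <- data.frame(dmu = rownames(x), x, check.names = FALSE,
                      stringsAsFactors = FALSE)
    rownames(out) <- NULL
    out
  }
  list(full = as_df(full),
       rounded = as_df(round_half_up(full, digits)))
}
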