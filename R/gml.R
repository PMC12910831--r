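#' Global Malmquist-Luenberger productivity records for a panel
#'
#' For every DMU and every adjacent period pair (t, t+1) the index is built
#' from slacks-based directional distances:
#' \deqn{GML_{t}^{t+1} = \frac{1 + S^G(x_t, y_t, b_t)}{1 + S^G(x_{t+1},
#'   y_{t+1}, b_{t+1})}}
#' where \eqn{S^G} is the inefficiency against the global (pooled-period)
#' frontier. The index decomposes multiplicatively into efficiency change
#' (catch-up against the own-period contemporaneous frontier \eqn{S^t})
#' \deqn{GEC = \frac{1 + S^t(x_t, y_t, b_t)}{1 + S^{t+1}(x_{t+1}, y_{t+1},
#'   b_{t+1})}}
#' and technology change \eqn{GTC = GML / GEC} (the frontier-shift term;
#' because it is computed as a ratio, cross-period evaluations that could be
#' infeasible never need to be solved). Values above 1 signal improvement,
#' below 1 decline.
#'
#' Because the global frontier is common to all periods, the index is
#' circular: `GML(t, t+2) = GML(t, t+1) * GML(t+1, t+2)`.
#'
#' @inheritParams efficiency_matrix
#' @return data frame with one row per (dmu, t -> t+1): distance columns
#'   `S_G_t`, `S_G_t1` (global), `S_C_t`, `S_C_t1` (contemporaneous), and the
#'   indices `GML`, `GEC`, `GTC`.
#' @export
gml_panel <- function(panel, include_undesirable = TRUE, directions = NULL) {
  stopifnot(inherits(panel, "phc_panel"))
  if (length(panel$periods) < 2L) {
    stop("the GML index needs at least two periods", call. = FALSE)
  }
  glob <- efficiency_matrix(panel, frontier_scope("global"),
                            include_undesirable, directions)
  cont <- efficiency_matrix(panel, frontier_scope("contemporaneous"),
                            include_undesirable, directions)
  key <- function(d, p) paste(d, p, sep = "\r")
  sg <- stats::setNames(glob$S, key(glob$dmu, glob$period))
  sc <- stats::setNames(cont$S, key(cont$dmu, cont$period))

  periods <- panel$periods
  pairs <- data.frame(t = periods[-length(periods)], t_next = periods[-1L])
  rows <- lapply(panel$dmus, function(d) {
    data.frame(
      dmu = d, pairs,
      S_G_t = unname(sg[key(d, pairs$t)]),
      S_G_t1 = unname(sg[key(d, pairs$t_next)]),
      S_C_t = unname(sc[key(d, pairs$t)]),
      S_C_t1 = unname(sc[key(d, pairs$t_next)]),
      stringsAsFactors = FALSE)
  })
  rec <- do.call(rbind, rows)
  rec$GML <- (1 + rec$S_G_t) / (1 + rec$S_G_t1)
  rec$GEC <- (1 + rec$S_C_t) / (1 + rec$S_C_t1)
  rec$GTC <- rec$GML / rec$GEC
  rownames(rec) <- NULL
  rec
}

#' GML record for one DMU and one adjacent period pair
#'
#' Single-record form of [gml_panel()]: solves the four directional
#' distances (global and own-period contemporaneous at t and t+1) for one
#' unit.
#'
#' @inheritParams solve_sbm_ddf
#' @param t first period of the pair; `t+1` is the next period present in
#'   the panel and must be adjacent.
#' @return one-row data frame in the [gml_panel()] layout.
#' @export
compute_gml <- function(panel, dmu, t, include_undesirable = TRUE,
                        direction = NULL) {
  t <- as.integer(t)
  i <- match(t, panel$periods)
  if (is.na(i) || i == length(panel$periods)) {
    stop(sprintf("no period pair starting at %s", t), call. = FALSE)
  }
  t1 <- panel$periods[i + 1L]
  dist <- function(p, scope) {
    solve_sbm_ddf(panel, dmu, p, scope, direction, include_undesirable)$S
  }
  rec <- data.frame(
    dmu = dmu, t = t, t_next = t1,
    S_G_t = dist(t, frontier_scope("global")),
    S_G_t1 = dist(t1, frontier_scope("global")),
    S_C_t = dist(t, frontier_scope("contemporaneous")),
    S_C_t1 = dist(t1, frontier_scope("contemporaneous")),
    stringsAsFactors = FALSE)
  rec$GML <- (1 + rec$S_G_t) / (1 + rec$S_G_t1)
  rec$GEC <- (1 + rec$S_C_t) / (1 + rec$S_C_t1)
  rec$GTC <- rec$GML / rec$GEC
  rec
}

#' Cross-DMU means per period pair
#'
#' The "Average" row of a GML table: unweighted means of GML, GEC and GTC
#' over DMUs for each adjacent period pair.
#'
#' @param records table from [gml_panel()].
#' @return data frame `t, t_next, GML, GEC, GTC`.
#' @export
gml_averages <- function(records) {
  need <- c("t", "t_next", "GML", "GEC", "GTC")
  stopifnot(all(need %in% names(records)))
  agg <- stats::aggregate(records[c("GML", "GEC", "GTC")],
                          by = records[c("t", "t_next")], FUN = mean)
  agg[order(agg$t), , drop = FALSE]
}

#' Interpret a productivity index value
#'
#' @param index positive numeric vector of index values.
#' @param tol equality tolerance around 1.
#' @return character vector: `"improvement"` (> 1), `"decline"` (< 1) or
#'   `"stable"` (= 1 within `tol`).
#' @examples
#' interpret_index(c(1.02, 0.96, 1))
#' @export
interpret_index <- function(index, tol = 1e-9) {
  if (any(!is.finite(index) | index <= 0)) {
    stop("index values must be positive", call. = FALSE)
  }
  ifelse(abs(index - 1) <= tol, "stable",
         ifelse(index > 1, "improvement", "decline"))
}
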