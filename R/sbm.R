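#' Frontier scope: global or contemporaneous reference technology
#'
#' The global frontier pools every (dmu, period) observation, giving
#' intertemporally comparable distances (the property the GML index relies
#' on). A contemporaneous frontier is built from a single period's
#' observations.
#'
#' @param kind `"global"` or `"contemporaneous"`.
#' @param period reference period for a contemporaneous frontier. `NULL`
#'   (default) means "the evaluated observation's own period".
#' @return list of class `phc_scope`.
#' @export
frontier_scope <- function(kind = c("global", "contemporaneous"),
                           period = NULL) {
  kind <- match.arg(kind)
  if (kind == "global" && !is.null(period)) {
    stop("a global scope takes no reference period", call. = FALSE)
  }
  structure(list(kind = kind, period = if (is.null(period)) NULL
                 else as.integer(period)),
            class = "phc_scope")
}

# the (dmu, period) observation pool a scope implies
#' @keywords internal
#' @noRd
scope_pool <- function(panel, scope, eval_period) {
  if (scope$kind == "global") {
    expand.grid(dmu = panel$dmus, period = panel$periods,
                KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  } else {
    p <- if (is.null(scope$period)) eval_period else scope$period
    if (!p %in% panel$periods) {
      stop(sprintf("reference period %s not in panel", p), call. = FALSE)
    }
    data.frame(dmu = panel$dmus, period = rep(as.integer(p), length(panel$dmus)),
               stringsAsFactors = FALSE)
  }
}

# core LP on a prebuilt pool; works in direction-scaled units so every
# coefficient is O(1) regardless of the data's raw magnitudes
#' @keywords internal
#' @noRd
sbm_core <- function(mats, x0, y0, b0, direction, include_undesirable) {
  X <- mats$X / direction$g_x
  Y <- mats$Y / direction$g_y
  N <- nrow(X); M <- nrow(Y); K <- ncol(X)
  if (include_undesirable) {
    if (is.null(mats$B)) stop("panel has no undesirable outputs", call. = FALSE)
    B <- mats$B / direction$g_b
    I <- nrow(B)
  } else {
    B <- NULL
    I <- 0L
  }
  x0s <- x0 / direction$g_x
  y0s <- y0 / direction$g_y
  b0s <- if (I > 0) b0 / direction$g_b else numeric()

  nv <- K + N + M + I
  obj <- numeric(nv)
  obj[K + seq_len(N)] <- 0.5 / N
  obj[K + N + seq_len(M)] <- 0.5 / (M + I)
  if (I > 0) obj[K + N + M + seq_len(I)] <- 0.5 / (M + I)

  A <- matrix(0, N + M + I + 1L, nv)
  A[seq_len(N), seq_len(K)] <- X
  A[cbind(seq_len(N), K + seq_len(N))] <- 1          # input excess: Xw + s_x = x0
  A[N + seq_len(M), seq_len(K)] <- Y
  A[cbind(N + seq_len(M), K + N + seq_len(M))] <- -1 # output shortfall: Yw - s_y = y0
  if (I > 0) {
    A[N + M + seq_len(I), seq_len(K)] <- B
    A[cbind(N + M + seq_len(I), K + N + M + seq_len(I))] <- 1
  }
  A[N + M + I + 1L, seq_len(K)] <- 1                 # VRS: sum w = 1
  rhs <- c(x0s, y0s, b0s, 1)

  sol <- lp_max_eq(obj, A, rhs)
  if (sol$status != 0L) {
    stop("LP solver failed with status ", sol$status, call. = FALSE)
  }
  w <- sol$x[seq_len(K)]
  resid <- max(abs(A %*% sol$x - rhs))
  if (resid > 1e-7) {
    stop(sprintf("solution violates feasibility (residual %.2e)", resid),
         call. = FALSE)
  }
  list(
    S = sol$value,
    w = w,
    s_x = sol$x[K + seq_len(N)] * direction$g_x,
    s_y = sol$x[K + N + seq_len(M)] * direction$g_y,
    s_b = if (I > 0) sol$x[K + N + M + seq_len(I)] * direction$g_b else numeric(),
    residual = resid
  )
}

#' Solve the slacks-based directional distance model for one unit
#'
#' Maximizes the mean slack ratio
#' \deqn{S = \tfrac12\Big[\tfrac1N\sum_n \frac{s^x_n}{g^x_n} +
#'   \tfrac1{M+I}\Big(\sum_m \frac{s^y_m}{g^y_m} +
#'   \sum_i \frac{s^b_i}{g^b_i}\Big)\Big]}
#' subject to \eqn{\sum_j w_j x_j + s^x = x_0}, \eqn{\sum_j w_j y_j - s^y =
#' y_0}, \eqn{\sum_j w_j b_j + s^b = b_0}, \eqn{\sum_j w_j = 1} (variable
#' returns to scale), all variables non-negative, where the reference sums run
#' over the scope's observation pool. Efficiency is reported as
#' \eqn{\rho = 1 - S}; a unit on the frontier has \eqn{S = 0}, \eqn{\rho = 1}.
#'
#' When `include_undesirable = FALSE` all undesirable terms and constraints
#' are dropped and the output weight becomes `1/M`.
#'
#' The score `S` is the unique LP optimum; the slack vector and reference set
#' can be non-unique under alternate optima and are reported as returned by
#' the solver.
#'
#' @param panel a [panel_data()] object.
#' @param dmu,period the evaluated observation (must belong to the scope's
#'   pool).
#' @param scope a [frontier_scope()]; default global.
#' @param direction a [direction_vector()]; default is the unit's own
#'   observation ([default_direction()]).
#' @param include_undesirable treat the panel's undesirable outputs as
#'   contractible bads (`TRUE`) or ignore them entirely (`FALSE`).
#' @return list of class `phc_sbm_result`: `S`, `rho`, slack vectors `s_x`,
#'   `s_y`, `s_b` (original units), `weights` (intensity weights over the
#'   pool, summing to 1), `reference_set` (pool observations with positive
#'   weight), `status`.
#' @examples
#' d <- data.frame(dmu = rep(c("A", "B"), each = 2), period = 1,
#'                 variable = rep(c("x", "y"), 2), value = c(1, 2, 1, 1))
#' p <- panel_data(d, input = "x", desirable = "y")
#' r <- solve_sbm_ddf(p, "B", 1, direction = direction_vector(1, 1))
#' r$rho  # 0.5: B could produce one more unit of y at the same input
#' @export
solve_sbm_ddf <- function(panel, dmu, period,
                          scope = frontier_scope("global"),
                          direction = NULL, include_undesirable = TRUE) {
  stopifnot(inherits(panel, "phc_panel"))
  period <- as.integer(period)
  if (include_undesirable && !length(panel$undesirable_names)) {
    include_undesirable <- FALSE
  }
  pool <- scope_pool(panel, scope, period)
  if (!any(pool$dmu == dmu & pool$period == period)) {
    stop(sprintf("evaluated unit (%s, %s) is outside the reference pool",
                 dmu, period), call. = FALSE)
  }
  mats <- panel_matrices(panel, pool)
  obs <- panel_values(panel, dmu, period)
  if (is.null(direction)) direction <- default_direction(panel, dmu, period)
  check_direction(direction, panel, include_undesirable)

  core <- sbm_core(mats, obs$x, obs$y, obs$b, direction, include_undesirable)
  S <- core$S
  rho <- 1 - S
  if (rho < 0) {
    warning(sprintf("unit (%s, %s): S = %.4f > 1, efficiency reported negative",
                    dmu, period, S), call. = FALSE)
  }
  ref <- core$w > 1e-9
  structure(list(
    dmu = dmu, period = period,
    S = S, rho = rho,
    s_x = stats::setNames(core$s_x, panel$input_names),
    s_y = stats::setNames(core$s_y, panel$desirable_names),
    s_b = stats::setNames(core$s_b,
                          if (include_undesirable) panel$undesirable_names
                          else character()),
    weights = data.frame(pool, weight = core$w, stringsAsFactors = FALSE),
    reference_set = pool[ref, , drop = FALSE],
    include_undesirable = include_undesirable,
    status = "optimal"
  ), class = "phc_sbm_result")
}

#' @export
print.phc_sbm_result <- function(x, ...) {
  cat(sprintf("SBM-DDF result for (%s, %s): S = %.6f, rho = %.6f\n",
              x$dmu, x$period, x$S, x$rho))
  cat(sprintf("  reference set: %s\n",
              paste(sprintf("%s/%s", x$reference_set$dmu,
                            x$reference_set$period), collapse = ", ")))
  invisible(x)
}

#' @keywords internal
#' @noRd
check_direction <- function(direction, panel, include_undesirable) {
  if (!inherits(direction, "phc_direction")) {
    stop("direction must be a direction_vector()", call. = FALSE)
  }
  ok <- length(direction$g_x) == length(panel$input_names) &&
    length(direction$g_y) == length(panel$desirable_names) &&
    (!include_undesirable ||
       length(direction$g_b) == length(panel$undesirable_names))
  if (!ok) stop("direction dimensions do not match the panel", call. = FALSE)
}

#' Efficiency scores for every observation in a panel
#'
#' Batch form of [solve_sbm_ddf()]: one solve per (dmu, period). Results are
#' independent of DMU or period ordering.
#'
#' @inheritParams solve_sbm_ddf
#' @param directions `NULL` for the default self-observation direction, or a
#'   function `(panel, dmu, period) -> direction_vector` applied per unit.
#' @param slacks if `TRUE`, append one column per variable with the optimal
#'   slack.
#' @return data frame with columns `dmu`, `period`, `S`, `rho`, `status`
#'   (plus slack columns when requested).
#' @export
efficiency_matrix <- function(panel, scope = frontier_scope("global"),
                              include_undesirable = TRUE, directions = NULL,
                              slacks = FALSE) {
  stopifnot(inherits(panel, "phc_panel"))
  if (include_undesirable && !length(panel$undesirable_names)) {
    include_undesirable <- FALSE
  }
  grid <- expand.grid(dmu = panel$dmus, period = panel$periods,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[order(match(grid$dmu, panel$dmus), grid$period), , drop = FALSE]

  # prebuild pool matrices once per distinct reference pool
  pools <- new.env(parent = emptyenv())
  get_pool <- function(eval_period) {
    key <- if (scope$kind == "global") "global" else
      as.character(if (is.null(scope$period)) eval_period else scope$period)
    if (is.null(pools[[key]])) {
      pools[[key]] <- panel_matrices(panel, scope_pool(panel, scope, eval_period))
    }
    pools[[key]]
  }

  rows <- lapply(seq_len(nrow(grid)), function(i) {
    dmu <- grid$dmu[i]; period <- grid$period[i]
    obs <- panel_values(panel, dmu, period)
    dir <- if (is.null(directions)) default_direction(panel, dmu, period)
           else directions(panel, dmu, period)
    check_direction(dir, panel, include_undesirable)
    core <- tryCatch(
      sbm_core(get_pool(period), obs$x, obs$y, obs$b, dir, include_undesirable),
      error = function(e) stop(sprintf("solve failed for (%s, %s): %s",
                                       dmu, period, conditionMessage(e)),
                               call. = FALSE))
    out <- data.frame(dmu = dmu, period = period, S = core$S,
                      rho = 1 - core$S, status = "optimal",
                      stringsAsFactors = FALSE)
    if (slacks) {
      sl <- c(core$s_x, core$s_y, core$s_b)
      names(sl) <- paste0("s_", c(panel$input_names, panel$desirable_names,
                                  if (length(core$s_b)) panel$undesirable_names
                                  else character()))
      out <- cbind(out, as.data.frame(as.list(sl)))
    }
    out
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
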