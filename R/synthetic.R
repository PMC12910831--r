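#' Specification for a synthetic province-year panel
#'
#' The generator draws a panel around a known concave variable-returns
#' frontier so that true efficiencies are defined by construction and every
#' pipeline stage can be validated end-to-end without external data.
#'
#' Construction. Inputs are drawn positive; an aggregate input
#' \eqn{z = a'x} feeds concave increasing production rules
#' \eqn{f_m(z) = c_m z^{\gamma_m}} (\eqn{0 < \gamma_m < 1}) that define the
#' efficient output levels. Observed desirable outputs are
#' \eqn{y = u \cdot f(z)} with a true efficiency multiplier
#' \eqn{u \in (0, 1]}; because any convex combination of points on a concave
#' surface lies weakly below it, every unit with \eqn{u = 1} sits on the
#' pooled VRS frontier and scores \eqn{\rho = 1} in the noiseless panel.
#' The undesirable output grows with inefficiency:
#' \eqn{b = b_0 + b_{scale}(1/u - 1)\exp(\sigma\varepsilon)}, with a small
#' positive baseline \eqn{b_0} so that fully efficient units still emit a
#' strictly positive bad and the self-direction stays well defined.
#' A per-period technology factor `progress` scales the efficient outputs
#' geometrically across periods (1 = static technology).
#'
#' @param n_dmu,n_periods panel dimensions (defaults 30 x 13, the study
#'   design).
#' @param n_inputs,n_desirable variable counts (defaults 3 inputs, 2
#'   desirable outputs).
#' @param include_undesirable generate the undesirable output (default TRUE).
#' @param u optional `n_dmu x n_periods` matrix of true efficiency
#'   multipliers in (0, 1], at least one 1 per period; drawn uniformly on
#'   [0.6, 1] (forcing one exact 1 per period) when omitted.
#' @param noise multiplicative log-scale noise sd on observed outputs
#'   (default 0: exact frontier, exact recovery).
#' @param progress per-period geometric growth of the efficient frontier
#'   (default 1).
#' @param input_profile `"varied"` draws inputs independently per unit;
#'   `"common"` gives every unit the same input profile so the multiplier u
#'   is the only source of cross-unit variation (used for rank-recovery
#'   checks).
#' @param b_base,b_scale baseline and slope of the undesirable-output rule.
#' @param start_period first period label (default 2010).
#' @param seed integer; fixes the panel bit-exactly.
#' @return list of class `phc_synth_spec`.
#' @export
synthetic_spec <- function(n_dmu = 30L, n_periods = 13L, n_inputs = 3L,
                           n_desirable = 2L, include_undesirable = TRUE,
                           u = NULL, noise = 0, progress = 1,
                           input_profile = c("varied", "common"),
                           b_base = 50, b_scale = 400,
                           start_period = 2010L, seed = 1L) {
  input_profile <- match.arg(input_profile)
  stopifnot(n_dmu >= 1L, n_periods >= 1L, n_inputs >= 1L, n_desirable >= 1L,
            noise >= 0, progress > 0, b_base > 0, b_scale >= 0)
  if (!is.null(u)) {
    u <- as.matrix(u)
    if (!all(dim(u) == c(n_dmu, n_periods))) {
      stop("u must be an n_dmu x n_periods matrix", call. = FALSE)
    }
    if (any(u <= 0 | u > 1)) {
      stop("true efficiency multipliers must lie in (0, 1]", call. = FALSE)
    }
    if (!all(apply(u, 2, max) == 1)) {
      stop("each period needs at least one unit with u = 1", call. = FALSE)
    }
  }
  structure(list(n_dmu = as.integer(n_dmu), n_periods = as.integer(n_periods),
                 n_inputs = as.integer(n_inputs),
                 n_desirable = as.integer(n_desirable),
                 include_undesirable = isTRUE(include_undesirable),
                 u = u, noise = noise, progress = progress,
                 input_profile = input_profile,
                 b_base = b_base, b_scale = b_scale,
                 start_period = as.integer(start_period),
                 seed = as.integer(seed)),
            class = "phc_synth_spec")
}

#' Generate a synthetic panel with known true efficiencies
#'
#' @param spec a [synthetic_spec()].
#' @return list with elements `panel` (a [panel_data()] object), `truth`
#'   (data frame `dmu, period, u`) and `spec`.
#' @export
generate_panel <- function(spec) {
  stopifnot(inherits(spec, "phc_synth_spec"))
  set.seed(spec$seed)
  n <- spec$n_dmu; t <- spec$n_periods
  input_names <- c("institutions", "beds", "workers",
                   paste0("input", seq_len(max(0, spec$n_inputs - 3L)) + 3L))
  input_names <- input_names[seq_len(spec$n_inputs)]
  desirable_names <- c("visits", "admissions",
                       paste0("output", seq_len(max(0, spec$n_desirable - 2L)) + 2L))
  desirable_names <- desirable_names[seq_len(spec$n_desirable)]
  b_name <- "excess_admissions"

  dmus <- sprintf("DMU%02d", seq_len(n))
  periods <- spec$start_period + seq_len(t) - 1L

  # input scales loosely follow the study's magnitudes (institutions, beds,
  # workers as province-level counts); units are immaterial to the score
  scales <- c(900, 1500, 800, rep(500, max(0, spec$n_inputs - 3L)))[seq_len(spec$n_inputs)]
  a <- 1 / scales                                   # aggregation weights
  gam <- seq(0.55, 0.85, length.out = spec$n_desirable)
  cm <- c(4000, 400, rep(100, max(0, spec$n_desirable - 2L)))[seq_len(spec$n_desirable)]

  u <- spec$u
  if (is.null(u)) {
    u <- matrix(stats::runif(n * t, 0.6, 1), n, t)
    for (j in seq_len(t)) u[which.max(u[, j]), j] <- 1
  }

  if (spec$input_profile == "common") {
    base_x <- stats::runif(spec$n_inputs, 0.8, 1.2) * scales
    X <- array(rep(base_x, each = n * t), c(n, t, spec$n_inputs))
  } else {
    X <- array(stats::runif(n * t * spec$n_inputs, 0.5, 1.5), c(n, t, spec$n_inputs))
    for (k in seq_len(spec$n_inputs)) X[, , k] <- X[, , k] * scales[k]
  }

  rows <- vector("list", 0L)
  for (j in seq_len(t)) {
    z <- X[, j, , drop = FALSE]
    z <- apply(z, 1, function(x) sum(a * x))
    tech <- spec$progress^(j - 1L)
    for (m in seq_len(spec$n_desirable)) {
      y_eff <- tech * cm[m] * z^gam[m]
      eps <- if (spec$noise > 0) exp(spec$noise * stats::rnorm(n)) else 1
      rows[[length(rows) + 1L]] <- data.frame(
        dmu = dmus, period = periods[j], variable = desirable_names[m],
        value = u[, j] * y_eff * eps, stringsAsFactors = FALSE)
    }
    for (k in seq_len(spec$n_inputs)) {
      rows[[length(rows) + 1L]] <- data.frame(
        dmu = dmus, period = periods[j], variable = input_names[k],
        value = X[, j, k], stringsAsFactors = FALSE)
    }
    if (spec$include_undesirable) {
      eps <- if (spec$noise > 0) exp(spec$noise * stats::rnorm(n)) else 1
      b <- spec$b_base + spec$b_scale * (1 / u[, j] - 1) * eps
      rows[[length(rows) + 1L]] <- data.frame(
        dmu = dmus, period = periods[j], variable = b_name,
        value = b, stringsAsFactors = FALSE)
    }
  }
  panel <- panel_data(do.call(rbind, rows), input = input_names,
                      desirable = desirable_names,
                      undesirable = if (spec$include_undesirable) b_name
                      else character())
  truth <- expand.grid(dmu = dmus, period = periods, KEEP.OUT.ATTRS = FALSE,
                       stringsAsFactors = FALSE)
  truth$u <- as.vector(u[cbind(match(truth$dmu, dmus),
                               match(truth$period, periods))])
  list(panel = panel, truth = truth, spec = spec)
}

#' Generate a synthetic annual demand series
#'
#' Emulates a multi-decade annual patient-visit series (default length 33
#' years starting 1990) with a chosen trend shape plus iid gaussian noise.
#' Values are in hundreds of millions of visits.
#'
#' @param trend `"linear"`, `"logistic"` (S-shaped saturation) or
#'   `"plateau"` (saturating exponential).
#' @param n_years series length (>= 5).
#' @param noise additive gaussian noise sd (>= 0).
#' @param seed integer seed.
#' @param start_year first year (default 1990).
#' @return an [annual_series()].
#' @export
generate_series <- function(trend = c("linear", "logistic", "plateau"),
                            n_years = 33L, noise = 0, seed = 1L,
                            start_year = 1990L) {
  trend <- match.arg(trend)
  n_years <- as.integer(n_years)
  if (n_years < 5L) stop("n_years must be at least 5", call. = FALSE)
  if (noise < 0) stop("noise must be non-negative", call. = FALSE)
  set.seed(as.integer(seed))
  i <- seq_len(n_years)
  base <- switch(trend,
    linear = 4 + 0.2 * (i - 1),
    logistic = 4 + 8 / (1 + exp(-0.25 * (i - n_years / 2))),
    plateau = 4 + 7 * (1 - exp(-i / 8)))
  value <- base + if (noise > 0) stats::rnorm(n_years, sd = noise) else 0
  value <- pmax(value, 0.01)
  annual_series(start_year + i - 1L, value)
}
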