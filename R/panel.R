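#' Construct a validated province-by-year panel
#'
#' A `phc_panel` holds a DMU (decision-making unit) by period by variable
#' tensor of non-negative observations, with every variable assigned a role:
#' `input` (e.g. institutions, beds, healthcare workers), `desirable` output
#' (e.g. patient visits, admissions) or `undesirable` output (e.g. potentially
#' unreasonable admissions). The canonical internal layout is long format;
#' every downstream stage (frontier solver, severity decomposition, GML index,
#' reporting) consumes this object.
#'
#' @param data data frame in long layout with columns `dmu`, `period`,
#'   `variable`, `value`.
#' @param input,desirable,undesirable character vectors naming the variables
#'   in each role. `undesirable` may be empty.
#' @param strict if `TRUE` (default) every variable must have at least one
#'   strictly positive value in every period. Derived panels whose
#'   undesirable column is identically zero (all admissions judged
#'   reasonable) may be built with `strict = FALSE`; such panels need an
#'   explicit direction downstream.
#' @return An object of class `phc_panel` with elements `data` (long data
#'   frame, ordered), `dmus`, `periods`, `input_names`, `desirable_names`,
#'   `undesirable_names`.
#' @examples
#' d <- expand.grid(dmu = c("A", "B"), period = 1:2, variable = c("beds", "visits"))
#' d$value <- seq_len(nrow(d))
#' p <- panel_data(d, input = "beds", desirable = "visits")
#' p
#' @export
panel_data <- function(data, input, desirable, undesirable = character(),
                       strict = TRUE) {
  req <- c("dmu", "period", "variable", "value")
  if (!all(req %in% names(data))) {
    stop("long panel data must have columns dmu, period, variable, value",
         call. = FALSE)
  }
  data <- as.data.frame(data)[req]
  data$dmu <- as.character(data$dmu)
  data$variable <- as.character(data$variable)
  data$period <- as.integer(data$period)
  data$value <- as.numeric(data$value)

  input <- as.character(input)
  desirable <- as.character(desirable)
  undesirable <- as.character(undesirable)
  vars <- c(input, desirable, undesirable)
  if (length(input) < 1L || length(desirable) < 1L) {
    stop("need at least one input and one desirable output", call. = FALSE)
  }
  if (anyDuplicated(vars)) {
    stop("a variable may hold only one role", call. = FALSE)
  }
  missing_vars <- setdiff(vars, unique(data$variable))
  if (length(missing_vars)) {
    stop("variables absent from data: ", paste(missing_vars, collapse = ", "),
         call. = FALSE)
  }
  data <- data[data$variable %in% vars, , drop = FALSE]

  dmus <- unique(data$dmu)
  periods <- sort(unique(data$period))

  key <- paste(data$dmu, data$period, data$variable, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    stop("duplicate cells: ",
         paste(utils::head(gsub("\r", "/", key[dup]), 3L), collapse = "; "),
         call. = FALSE)
  }
  full <- expand.grid(dmu = dmus, period = periods, variable = vars,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  full_key <- paste(full$dmu, full$period, full$variable, sep = "\r")
  absent <- setdiff(full_key, key)
  if (length(absent)) {
    stop("missing cells (dmu/period/variable): ",
         paste(utils::head(gsub("\r", "/", absent), 3L), collapse = "; "),
         call. = FALSE)
  }
  bad <- !is.finite(data$value) | data$value < 0
  if (any(bad)) {
    i <- which(bad)[1L]
    stop(sprintf("non-finite or negative value at (%s, %s, %s)",
                 data$dmu[i], data$period[i], data$variable[i]), call. = FALSE)
  }
  # every variable must have at least one strictly positive value per period
  if (strict) for (v in vars) {
    for (p in periods) {
      sel <- data$variable == v & data$period == p
      if (!any(data$value[sel] > 0)) {
        stop(sprintf("variable '%s' is identically zero in period %s", v, p),
             call. = FALSE)
      }
    }
  }

  ord <- order(match(data$dmu, dmus), data$period, match(data$variable, vars))
  data <- data[ord, , drop = FALSE]
  rownames(data) <- NULL
  structure(
    list(data = data, dmus = dmus, periods = periods,
         input_names = input, desirable_names = desirable,
         undesirable_names = undesirable),
    class = "phc_panel"
  )
}

#' @export
print.phc_panel <- function(x, ...) {
  cat(sprintf(
    "phc_panel: %d DMUs x %d periods (%s-%s)\n", length(x$dmus),
    length(x$periods), min(x$periods), max(x$periods)))
  cat("  inputs:     ", paste(x$input_names, collapse = ", "), "\n")
  cat("  desirable:  ", paste(x$desirable_names, collapse = ", "), "\n")
  cat("  undesirable:",
      if (length(x$undesirable_names)) paste(x$undesirable_names, collapse = ", ")
      else "(none)", "\n")
  invisible(x)
}

#' Read a panel from CSV
#'
#' Long layout expects columns `dmu,period,variable,value`; wide layout
#' expects one row per (dmu, period) and one column per variable. Both
#' layouts produce identical panels; row and column order never affect
#' downstream numerics.
#'
#' @param path CSV file path.
#' @param layout `"long"` or `"wide"`.
#' @inheritParams panel_data
#' @return A [panel_data()] object.
#' @export
read_panel <- function(path, layout = c("long", "wide"), input, desirable,
                       undesirable = character()) {
  layout <- match.arg(layout)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (layout == "wide") {
    if (!all(c("dmu", "period") %in% names(raw))) {
      stop("wide panel CSV must have dmu and period columns", call. = FALSE)
    }
    vars <- setdiff(names(raw), c("dmu", "period"))
    raw <- stats::reshape(
      raw, direction = "long", varying = vars, v.names = "value",
      times = vars, timevar = "variable", idvar = c("dmu", "period"))
    rownames(raw) <- NULL
  }
  if (any(is.na(raw$value))) {
    i <- which(is.na(raw$value))[1L]
    stop(sprintf("blank cell at (%s, %s, %s)",
                 raw$dmu[i], raw$period[i], raw$variable[i]), call. = FALSE)
  }
  panel_data(raw, input = input, desirable = desirable,
             undesirable = undesirable)
}

#' Write a panel to CSV
#'
#' @param panel a [panel_data()] object.
#' @param path output CSV path.
#' @param layout `"long"` or `"wide"`.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path, layout = c("long", "wide")) {
  layout <- match.arg(layout)
  stopifnot(inherits(panel, "phc_panel"))
  d <- panel$data
  if (layout == "wide") {
    d <- stats::reshape(d, direction = "wide", idvar = c("dmu", "period"),
                        timevar = "variable")
    names(d) <- sub("^value\\.", "", names(d))
    for (v in setdiff(names(d), c("dmu", "period"))) {
      d[[v]] <- sprintf("%.17g", d[[v]])  # value-preserving decimal form
    }
  } else {
    d$value <- sprintf("%.17g", d$value)
  }
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a DMU-to-region map
#'
#' @param path two-column CSV `dmu,region`.
#' @param panel optional panel; if given, every panel DMU must be mapped.
#' @return data frame with columns `dmu`, `region` (class `phc_region_map`).
#' @export
read_region_map <- function(path, panel = NULL) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("dmu", "region") %in% names(m))) {
    stop("region map CSV must have columns dmu, region", call. = FALSE)
  }
  m <- m[c("dmu", "region")]
  m$dmu <- as.character(m$dmu)
  m$region <- as.character(m$region)
  dup <- m$dmu[duplicated(m$dmu)]
  if (length(dup)) {
    conflicting <- unique(dup[vapply(
      dup, function(d) length(unique(m$region[m$dmu == d])) > 1L, logical(1))])
    if (length(conflicting)) {
      stop("conflicting region assignments for: ",
           paste(conflicting, collapse = ", "), call. = FALSE)
    }
    m <- m[!duplicated(m$dmu), , drop = FALSE]
  }
  if (!is.null(panel)) {
    missing <- setdiff(panel$dmus, m$dmu)
    if (length(missing)) {
      stop("DMUs missing from region map: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  rownames(m) <- NULL
  class(m) <- c("phc_region_map", "data.frame")
  m
}

#' Direction vector for one evaluated unit
#'
#' The directional distance function measures feasible movement along a
#' direction `g = (g_x, g_y, g_b)`: contract inputs by `g_x`, expand
#' desirable outputs by `g_y`, contract undesirable outputs by `g_b`. The
#' default direction is the evaluated unit's own observation, which makes
#' each slack ratio `s/g` dimensionless and the inefficiency score
#' units-invariant.
#'
#' @param g_x,g_y,g_b strictly positive numeric vectors matching the panel's
#'   input / desirable / undesirable dimensions.
#' @return list of class `phc_direction`.
#' @export
direction_vector <- function(g_x, g_y, g_b = numeric()) {
  g_x <- as.numeric(g_x); g_y <- as.numeric(g_y); g_b <- as.numeric(g_b)
  if (any(c(g_x, g_y, g_b) <= 0) || anyNA(c(g_x, g_y, g_b))) {
    stop("all direction components must be strictly positive", call. = FALSE)
  }
  structure(list(g_x = g_x, g_y = g_y, g_b = g_b), class = "phc_direction")
}

#' Default (self-observation) direction for a unit
#'
#' @param panel a [panel_data()] object.
#' @param dmu,period the evaluated observation.
#' @param on_zero what to do when the unit observes a zero in some variable
#'   (a zero direction component is not allowed): `"error"` (default)
#'   instructs the caller to supply an explicit direction; `"mean"`
#'   substitutes the panel-wide mean of the affected variable, the natural
#'   fallback for derived panels whose undesirable column is zero for
#'   frontier units.
#' @return a [direction_vector()] equal to the unit's observed (x, y, b),
#'   with zero components substituted when `on_zero = "mean"`.
#' @export
default_direction <- function(panel, dmu, period,
                              on_zero = c("error", "mean")) {
  on_zero <- match.arg(on_zero)
  obs <- panel_values(panel, dmu, period)
  if (any(c(obs$x, obs$y, obs$b) <= 0)) {
    if (on_zero == "error") {
      stop(sprintf(
        "unit (%s, %s) has a zero observation; supply an explicit direction",
        dmu, period), call. = FALSE)
    }
    fill <- function(v, names) {
      if (!length(v)) return(v)
      zero <- v <= 0
      if (any(zero)) {
        means <- vapply(names[zero], function(nm)
          mean(panel$data$value[panel$data$variable == nm]), 0)
        if (any(means <= 0)) {
          stop("variable identically zero panel-wide; supply an explicit direction",
               call. = FALSE)
        }
        v[zero] <- means
      }
      v
    }
    obs$x <- fill(obs$x, panel$input_names)
    obs$y <- fill(obs$y, panel$desirable_names)
    obs$b <- fill(obs$b, panel$undesirable_names)
  }
  direction_vector(obs$x, obs$y, obs$b)
}

# observed (x, y, b) vectors for one (dmu, period)
#' @keywords internal
#' @noRd
panel_values <- function(panel, dmu, period) {
  d <- panel$data
  sel <- d$dmu == dmu & d$period == period
  if (!any(sel)) {
    stop(sprintf("observation (%s, %s) not in panel", dmu, period),
         call. = FALSE)
  }
  v <- stats::setNames(d$value[sel], d$variable[sel])
  list(x = unname(v[panel$input_names]),
       y = unname(v[panel$desirable_names]),
       b = unname(v[panel$undesirable_names]))
}

# observation pool as matrices: one column per (dmu, period) in `obs`
#' @keywords internal
#' @noRd
panel_matrices <- function(panel, obs) {
  d <- panel$data
  wide <- stats::reshape(d, direction = "wide", idvar = c("dmu", "period"),
                         timevar = "variable")
  names(wide) <- sub("^value\\.", "", names(wide))
  key <- paste(wide$dmu, wide$period, sep = "\r")
  idx <- match(paste(obs$dmu, obs$period, sep = "\r"), key)
  stopifnot(!anyNA(idx))
  w <- wide[idx, , drop = FALSE]
  list(
    X = t(as.matrix(w[panel$input_names])),
    Y = t(as.matrix(w[panel$desirable_names])),
    B = if (length(panel$undesirable_names))
      t(as.matrix(w[panel$undesirable_names])) else NULL,
    obs = obs
  )
}

#' Retrieve a single variable as a DMU-by-period matrix
#'
#' @param panel a [panel_data()] object.
#' @param variable variable name.
#' @return numeric matrix, DMUs in rows, periods in columns.
#' @export
panel_variable <- function(panel, variable) {
  stopifnot(variable %in% c(panel$input_names, panel$desirable_names,
                            panel$undesirable_names))
  d <- panel$data[panel$data$variable == variable, ]
  m <- matrix(NA_real_, length(panel$dmus), length(panel$periods),
              dimnames = list(panel$dmus, panel$periods))
  m[cbind(match(d$dmu, panel$dmus), match(d$period, panel$periods))] <- d$value
  m
}
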