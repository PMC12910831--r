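#' Benchmark efficiency without hospitalizations as an undesirable output
#'
#' Stage one of the two-stage decomposition: admissions are treated as an
#' ordinary desirable output and no undesirable output enters the model
#' (global frontier, default self-direction). The resulting score per
#' observation is the benchmark \eqn{\rho_1}.
#'
#' @param panel a [panel_data()] object whose desirable outputs include both
#'   visits and admissions (if `admissions` currently sits in the undesirable
#'   role it is moved to the desirable role first).
#' @param admissions name of the admissions variable.
#' @return efficiency table as from [efficiency_matrix()].
#' @seealso [run_rho2()], [severity()]
#' @export
run_rho1 <- function(panel, admissions = "admissions") {
  p <- set_admission_role(panel, admissions, "desirable")
  efficiency_matrix(p, frontier_scope("global"), include_undesirable = FALSE)
}

#' Efficiency with hospitalizations as an undesirable output
#'
#' Stage two: admissions move to the undesirable set (visits and any other
#' desirable outputs remain), so excess admissions count against a unit. The
#' resulting score is \eqn{\rho_2}; the drop \eqn{\rho_1 - \rho_2} is read as
#' the imprint of potentially unreasonable hospitalization.
#'
#' @inheritParams run_rho1
#' @return efficiency table as from [efficiency_matrix()].
#' @export
run_rho2 <- function(panel, admissions = "admissions") {
  p <- set_admission_role(panel, admissions, "undesirable")
  efficiency_matrix(p, frontier_scope("global"), include_undesirable = TRUE)
}

# move one variable between the desirable and undesirable roles
#' @keywords internal
#' @noRd
set_admission_role <- function(panel, admissions, role) {
  stopifnot(inherits(panel, "phc_panel"))
  all_vars <- c(panel$desirable_names, panel$undesirable_names)
  if (!admissions %in% all_vars) {
    stop(sprintf("variable '%s' is not an output of this panel", admissions),
         call. = FALSE)
  }
  des <- setdiff(panel$desirable_names, admissions)
  und <- setdiff(panel$undesirable_names, admissions)
  if (role == "desirable") des <- c(des, admissions) else und <- c(und, admissions)
  panel_data(panel$data, input = panel$input_names, desirable = des,
             undesirable = und)
}

#' Efficiency difference and severity of unreasonable hospitalization
#'
#' Given per-DMU mean efficiencies \eqn{\bar\rho_1} (admissions desirable)
#' and \eqn{\bar\rho_2} (admissions undesirable), computes the efficiency
#' difference \eqn{\bar\rho_1 - \bar\rho_2} and the severity percentage
#' \eqn{100 (\bar\rho_1 - \bar\rho_2) / \bar\rho_1}. A positive difference
#' means that accounting for hospitalization volume lowers measured
#' efficiency; a negative one means inpatient care contributes positively.
#'
#' @param mean_rho1,mean_rho2 numeric vectors of per-DMU period means.
#' @return data frame with columns `difference` and `severity_pct`
#'   (full precision; round at report time).
#' @examples
#' severity(0.91, 0.66)  # difference 0.25, severity 27.47...%
#' @export
severity <- function(mean_rho1, mean_rho2) {
  stopifnot(length(mean_rho1) == length(mean_rho2))
  if (any(mean_rho1 == 0)) {
    stop("severity ratio undefined where mean_rho1 = 0", call. = FALSE)
  }
  difference <- mean_rho1 - mean_rho2
  data.frame(difference = difference,
             severity_pct = 100 * difference / mean_rho1)
}

#' Per-DMU severity report
#'
#' Runs both model variants over the full panel, averages each DMU's scores
#' across periods, and applies [severity()]. Mirrors the headline
#' severity-of-unreasonable-hospitalization table.
#'
#' @inheritParams run_rho1
#' @param rho1,rho2 optional precomputed efficiency tables (as from
#'   [run_rho1()] / [run_rho2()]); computed from `panel` when omitted.
#' @return data frame `dmu, mean_rho1, mean_rho2, difference, severity_pct`.
#' @export
severity_report <- function(panel, admissions = "admissions",
                            rho1 = NULL, rho2 = NULL) {
  if (is.null(rho1)) rho1 <- run_rho1(panel, admissions)
  if (is.null(rho2)) rho2 <- run_rho2(panel, admissions)
  m1 <- tapply(rho1$rho, rho1$dmu, mean)
  m2 <- tapply(rho2$rho, rho2$dmu, mean)
  dmus <- unique(rho1$dmu)
  m1 <- m1[dmus]; m2 <- m2[dmus]
  out <- cbind(data.frame(dmu = dmus, mean_rho1 = unname(m1),
                          mean_rho2 = unname(m2), stringsAsFactors = FALSE),
               severity(unname(m1), unname(m2)))
  rownames(out) <- NULL
  out
}

#' Split observed admissions into reasonable and unreasonable components
#'
#' For each (dmu, period) the model is re-solved with admissions as the sole
#' desirable output (no undesirable outputs, global frontier), yielding a
#' single-output efficiency \eqn{\rho_{single}}. The unit's inefficiency
#' share is then read as the potentially unreasonable fraction:
#' `reasonable = rho_single * observed`, `unreasonable = (1 - rho_single) *
#' observed`. The split conserves admissions exactly and both components are
#' non-negative (`rho_single` is truncated to `[0, 1]` with a warning on
#' pathological data where the inefficiency score exceeds 1).
#'
#' @inheritParams run_rho1
#' @return data frame `dmu, period, observed, rho_single, reasonable,
#'   unreasonable`.
#' @export
decompose_admissions <- function(panel, admissions = "admissions") {
  p <- set_admission_role(panel, admissions, "desirable")
  keep <- c(p$input_names, admissions)
  single <- panel_data(p$data[p$data$variable %in% keep, , drop = FALSE],
                       input = p$input_names, desirable = admissions)
  eff <- efficiency_matrix(single, frontier_scope("global"),
                           include_undesirable = FALSE)
  obs_mat <- panel_variable(p, admissions)
  observed <- obs_mat[cbind(match(eff$dmu, p$dmus),
                            match(eff$period, p$periods))]
  rho <- eff$rho
  if (any(rho < 0)) {
    warning("single-output efficiency below 0 for some units; truncated for the split",
            call. = FALSE)
    rho <- pmax(rho, 0)
  }
  rho <- pmin(rho, 1)
  data.frame(dmu = eff$dmu, period = eff$period, observed = observed,
             rho_single = eff$rho, reasonable = rho * observed,
             unreasonable = (1 - rho) * observed, stringsAsFactors = FALSE)
}

#' Assemble the main-model panel from an admission split
#'
#' Builds the panel used by the static and dynamic headline analyses:
#' desirable outputs are the original desirable set with observed admissions
#' replaced by the reasonable component, and the unreasonable component
#' enters as the undesirable output.
#'
#' @inheritParams run_rho1
#' @param split the table returned by [decompose_admissions()], conforming to
#'   `panel`.
#' @return a [panel_data()] object with variables
#'   `reasonable_<admissions>` (desirable) and `unreasonable_<admissions>`
#'   (undesirable).
#' @export
build_main_panel <- function(panel, split, admissions = "admissions") {
  stopifnot(inherits(panel, "phc_panel"))
  need <- c("dmu", "period", "reasonable", "unreasonable")
  if (!all(need %in% names(split))) {
    stop("split must come from decompose_admissions()", call. = FALSE)
  }
  full <- expand.grid(dmu = panel$dmus, period = panel$periods,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  idx <- match(paste(full$dmu, full$period),
               paste(split$dmu, split$period))
  if (anyNA(idx)) {
    stop("split does not cover every (dmu, period) of the panel",
         call. = FALSE)
  }
  split <- split[idx, , drop = FALSE]
  reasonable_name <- paste0("reasonable_", admissions)
  unreasonable_name <- paste0("unreasonable_", admissions)
  keep_vars <- setdiff(c(panel$input_names, panel$desirable_names,
                         panel$undesirable_names), admissions)
  d <- panel$data[panel$data$variable %in% keep_vars, , drop = FALSE]
  d <- rbind(
    d,
    data.frame(dmu = full$dmu, period = full$period,
               variable = reasonable_name, value = split$reasonable,
               stringsAsFactors = FALSE),
    data.frame(dmu = full$dmu, period = full$period,
               variable = unreasonable_name, value = split$unreasonable,
               stringsAsFactors = FALSE))
  panel_data(d, input = panel$input_names,
             desirable = c(setdiff(panel$desirable_names, admissions),
                           reasonable_name),
             undesirable = c(setdiff(panel$undesirable_names, admissions),
                             unreasonable_name),
             strict = FALSE)
}
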