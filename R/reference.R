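#' Published reference tables for China's primary healthcare system
#'
#' The package ships the published province-level summary statistics of the
#' 2010-2022 national primary-healthcare efficiency analysis as plain-CSV
#' report-layer fixtures. The underlying raw yearbook panel is not
#' machine-readable, so these tables serve as inputs to the reporting and
#' severity arithmetic (not as solver outputs):
#'
#' * `"efficiency"` — main-model SBM-DDF efficiency scores (reasonable
#'   admissions desirable, unreasonable admissions undesirable) per province
#'   and year, 2010-2022; returned long with columns `dmu, period, rho`.
#' * `"rho_means"` — per-province 13-year mean efficiencies of the benchmark
#'   model (`mean_rho1`, admissions desirable) and the undesirable-output
#'   model (`mean_rho2`); the inputs of the severity table.
#' * `"gml"` — GML productivity index per province and adjacent year pair;
#'   returned long with columns `dmu, t, t_next, GML`.
#' * `"regions"` — the National Bureau of Statistics three-region
#'   classification (11 east, 8 central, 11 west provinces; Tibet, Hong
#'   Kong, Macao and Taiwan are outside the study sample), as a replaceable
#'   `dmu, region` map.
#'
#' @param name which table to load.
#' @return a data frame (see above for the layout per table).
#' @examples
#' eff <- reference_table("efficiency")
#' dmu_mean(eff, "Hebei")  # 0.7423...
#' @export
reference_table <- function(name = c("efficiency", "rho_means", "gml",
                                     "regions")) {
  name <- match.arg(name)
  file <- switch(name,
    efficiency = "china_phc_efficiency_2010_2022.csv",
    rho_means = "china_phc_rho_means.csv",
    gml = "china_phc_gml_2010_2022.csv",
    regions = "china_regions_nbs.csv")
  path <- system.file("extdata", file, package = "phcfrontier",
                      mustWork = TRUE)
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (name == "rho_means") return(raw)
  if (name == "regions") {
    class(raw) <- c("phc_region_map", "data.frame")
    return(raw)
  }
  years <- setdiff(names(raw), "dmu")
  long <- do.call(rbind, lapply(years, function(y) {
    data.frame(dmu = raw$dmu, period = as.integer(y), value = raw[[y]],
               stringsAsFactors = FALSE)
  }))
  long <- long[order(match(long$dmu, raw$dmu), long$period), , drop = FALSE]
  rownames(long) <- NULL
  if (name == "efficiency") {
    names(long)[names(long) == "value"] <- "rho"
  } else {
    names(long)[names(long) == "value"] <- "GML"
    long$t <- long$period
    long$t_next <- long$period + 1L
    long <- long[c("dmu", "t", "t_next", "GML")]
  }
  long
}
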