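# small panel with the study's variable roles: inputs + visits + admissions
hosp_panel <- function(K = 4, periods = 2, seed = 21, admissions = NULL) {
  set.seed(seed)
  dmus <- paste0("P", seq_len(K))
  d <- expand.grid(dmu = dmus, period = seq_len(periods),
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  long <- do.call(rbind, lapply(c("beds", "visits", "admissions"), function(v) {
    data.frame(d, variable = v, value = runif(nrow(d), 1, 4),
               stringsAsFactors = FALSE)
  }))
  if (!is.null(admissions)) {
    long$value[long$variable == "admissions"] <- admissions
  }
  panel_data(long, input = "beds", desirable = c("visits", "admissions"))
}

test_that("severity reproduces worked pairs and the identity case", {
  s <- severity(c(0.91, 0.95, 0.7), c(0.66, 0.52, 0.7))
  expect_equal(s$difference, c(0.25, 0.43, 0), tolerance = 1e-12)
  expect_equal(round_half_up(s$severity_pct, 2), c(27.47, 45.26, 0))
  expect_error(severity(0, 0.5), "undefined")
})

test_that("severity_pct carries the sign of the difference", {
  set.seed(1)
  r1 <- runif(50, 0.3, 1)
  r2 <- runif(50, 0.3, 1.2)
  s <- severity(r1, r2)
  expect_equal(s$difference, r1 - r2)
  expect_equal(sign(s$severity_pct), sign(s$difference))
})

test_that("rho1 equals the solver with no undesirable role (config equivalence)", {
  p <- hosp_panel()
  r1 <- run_rho1(p)
  direct <- efficiency_matrix(p, include_undesirable = FALSE)
  expect_equal(r1$rho, direct$rho, tolerance = 1e-9)
  # identical-DMU panel: everything efficient under both variants
  d <- p$data
  for (v in unique(d$variable)) d$value[d$variable == v] <- 2
  p_id <- panel_data(d, input = "beds", desirable = c("visits", "admissions"))
  expect_true(all(abs(run_rho1(p_id)$rho - 1) < 1e-9))
  expect_true(all(abs(run_rho2(p_id)$rho - 1) < 1e-9))
})

test_that("excess admissions depress rho2 but not rho1", {
  # three units identical except the third has double the admissions
  d <- expand.grid(dmu = c("P1", "P2", "P3"), period = 1L,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  long <- rbind(
    data.frame(d, variable = "beds", value = 2),
    data.frame(d, variable = "visits", value = 3),
    data.frame(d, variable = "admissions", value = c(1, 1, 2)))
  p <- panel_data(long, input = "beds", desirable = c("visits", "admissions"))
  r1 <- run_rho1(p); r2 <- run_rho2(p)
  expect_equal(r1$rho[r1$dmu == "P3"], 1, tolerance = 1e-9)
  expect_lt(r2$rho[r2$dmu == "P3"], 1)
  expect_equal(r2$rho[r2$dmu == "P1"], 1, tolerance = 1e-9)
})

test_that("admission decomposition conserves admissions and respects the frontier", {
  p <- hosp_panel(K = 5, periods = 3)
  sp <- suppressWarnings(decompose_admissions(p))  # random data can have S > 1
  expect_equal(sp$reasonable + sp$unreasonable, sp$observed, tolerance = 1e-9)
  expect_true(all(sp$reasonable >= 0 & sp$unreasonable >= 0))
  # frontier units keep all admissions as reasonable
  on_frontier <- abs(sp$rho_single - 1) < 1e-9
  expect_true(any(on_frontier))
  expect_equal(sp$unreasonable[on_frontier],
               rep(0, sum(on_frontier)), tolerance = 1e-9)
  # stated split rule: unreasonable fraction is the inefficiency share,
  # with the single-output score truncated to [0, 1]
  rho_clamped <- pmin(pmax(sp$rho_single, 0), 1)
  expect_equal(sp$unreasonable, (1 - rho_clamped) * sp$observed,
               tolerance = 1e-9)
})

test_that("the main-model panel conserves admissions and round-trips", {
  p <- hosp_panel(K = 4, periods = 2, seed = 9)
  sp <- suppressWarnings(decompose_admissions(p))
  main <- build_main_panel(p, sp)
  expect_setequal(main$desirable_names, c("visits", "reasonable_admissions"))
  expect_equal(main$undesirable_names, "unreasonable_admissions")
  tot <- panel_variable(main, "reasonable_admissions") +
    panel_variable(main, "unreasonable_admissions")
  expect_equal(tot, panel_variable(p, "admissions"), tolerance = 1e-9)

  f <- withr::local_tempfile(fileext = ".csv")
  write_panel(main, f, "long")
  back <- read_panel(f, "long", input = main$input_names,
                     desirable = main$desirable_names,
                     undesirable = main$undesirable_names)
  expect_equal(back$data$value, main$data$value)
})

test_that("an all-efficient split yields a zero undesirable column", {
  p <- hosp_panel(K = 3, periods = 1, seed = 2, admissions = c(2, 2, 2))
  # give all units identical inputs/outputs so each is fully efficient
  d <- p$data
  d$value[d$variable == "beds"] <- 1
  d$value[d$variable == "visits"] <- 2
  p <- panel_data(d, input = "beds", desirable = c("visits", "admissions"))
  sp <- decompose_admissions(p)
  expect_true(all(sp$unreasonable == 0))
  main <- build_main_panel(p, sp)
  expect_true(all(panel_variable(main, "unreasonable_admissions") == 0))
  expect_error(default_direction(main, "P1", 1), "zero observation")
})

test_that("severity_report mirrors per-DMU means of both model variants", {
  p <- hosp_panel(K = 4, periods = 3, seed = 33)
  rep_ <- severity_report(p)
  r1 <- run_rho1(p); r2 <- run_rho2(p)
  for (d in rep_$dmu) {
    expect_equal(rep_$mean_rho1[rep_$dmu == d], dmu_mean(r1, d),
                 tolerance = 1e-12)
    expect_equal(rep_$mean_rho2[rep_$dmu == d], dmu_mean(r2, d),
                 tolerance = 1e-12)
  }
  expect_equal(rep_$difference, rep_$mean_rho1 - rep_$mean_rho2)
})
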