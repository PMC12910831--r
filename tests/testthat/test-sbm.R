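test_that("a self-referencing unit has zero slack and efficiency 1", {
  p <- make_panel(X = matrix(3), Y = matrix(7))
  r <- solve_sbm_ddf(p, "U1", 1)
  expect_equal(r$S, 0, tolerance = 1e-9)
  expect_equal(r$rho, 1, tolerance = 1e-9)
  expect_equal(r$weights$weight, 1, tolerance = 1e-9)
})

test_that("two-unit worked instances match the vertex oracle values", {
  # A=(x=1,y=2), B=(x=1,y=1): evaluating B with g=(1,1) leaves a pure
  # output shortfall of 1, so S = 0.5
  p <- make_panel(X = matrix(c(1, 1), 1), Y = matrix(c(2, 1), 1))
  r <- solve_sbm_ddf(p, "U2", 1, direction = direction_vector(1, 1))
  expect_equal(r$S, 0.5, tolerance = 1e-9)
  expect_equal(r$rho, 0.5, tolerance = 1e-9)
  expect_equal(unname(r$s_x), 0, tolerance = 1e-9)
  expect_equal(unname(r$s_y), 1, tolerance = 1e-9)

  # undesirable case: B carries one excess unit of the bad, g = own obs
  p <- make_panel(X = matrix(c(1, 1), 1), Y = matrix(c(2, 2), 1),
                  B = matrix(c(1, 2), 1))
  r <- solve_sbm_ddf(p, "U2", 1)
  expect_equal(r$S, 0.125, tolerance = 1e-9)
  expect_equal(r$rho, 0.875, tolerance = 1e-9)
  expect_equal(unname(r$s_b), 1, tolerance = 1e-9)
})

test_that("LP optimum matches exhaustive vertex enumeration on random instances", {
  set.seed(42)
  for (rep in 1:40) {
    inst <- random_instance(K = sample(2:4, 1), N = sample(1:2, 1),
                            M = sample(1:2, 1), I = sample(0:2, 1))
    k <- sample(ncol(inst$X), 1)
    res <- both_ways(inst, k)
    expect_equal(res[["lp"]], res[["oracle"]], tolerance = 1e-8)
  }
})

test_that("score is invariant to variable rescaling and DMU order", {
  set.seed(11)
  inst <- random_instance(K = 4, N = 2, M = 2, I = 1)
  p <- make_panel(inst$X, inst$Y, inst$B)
  S0 <- solve_sbm_ddf(p, "U3", 1)$S

  # rescale one input and one output by arbitrary positive constants
  p2 <- make_panel(inst$X * c(100, 0.01), inst$Y * c(7, 1), inst$B)
  expect_equal(solve_sbm_ddf(p2, "U3", 1)$S, S0, tolerance = 1e-8)

  # permute unit order: same data, new labels
  perm <- c(4, 1, 3, 2)
  p3 <- make_panel(inst$X[, perm], inst$Y[, perm], inst$B[, perm, drop = FALSE])
  expect_equal(solve_sbm_ddf(p3, "U3", 1)$S,      # U3 now holds old unit 3
               S0, tolerance = 1e-8)
})

test_that("identical observations all sit on the frontier", {
  d <- expand.grid(dmu = paste0("U", 1:5), period = 1:2,
                   variable = c("x", "y"), KEEP.OUT.ATTRS = FALSE,
                   stringsAsFactors = FALSE)
  d$value <- ifelse(d$variable == "x", 2, 3)
  p <- panel_data(d, input = "x", desirable = "y")
  em <- efficiency_matrix(p)
  expect_true(all(abs(em$rho - 1) < 1e-9))
})

test_that("a dominating observation never raises another unit's efficiency", {
  set.seed(3)
  inst <- random_instance(K = 3, N = 1, M = 1, I = 0)
  p <- make_panel(inst$X, inst$Y)
  before <- vapply(paste0("U", 1:3),
                   function(d) solve_sbm_ddf(p, d, 1)$rho, 0)
  # add a unit that dominates everything: least input, most output
  X2 <- cbind(inst$X, min(inst$X) * 0.5)
  Y2 <- cbind(inst$Y, max(inst$Y) * 2)
  p2 <- make_panel(X2, Y2)
  after <- vapply(paste0("U", 1:3), function(d)
    suppressWarnings(solve_sbm_ddf(p2, d, 1))$rho, 0)
  expect_true(all(after <= before + 1e-9))
  # removing a non-referenced observation leaves scores unchanged
  r <- suppressWarnings(solve_sbm_ddf(p2, "U1", 1))
  unref <- setdiff(paste0("U", 1:4), c("U1", r$reference_set$dmu))
  if (length(unref)) {
    drop_k <- as.integer(sub("U", "", unref[1]))
    p3 <- make_panel(X2[, -drop_k, drop = FALSE], Y2[, -drop_k, drop = FALSE])
    # U1 keeps its label only if it precedes the dropped column
    if (drop_k > 1) {
      expect_equal(suppressWarnings(solve_sbm_ddf(p3, "U1", 1))$S, r$S,
                   tolerance = 1e-9)
    }
  }
})

test_that("global-frontier inefficiency is at least the contemporaneous one", {
  gen <- generate_panel(synthetic_spec(n_dmu = 6, n_periods = 3, seed = 5))
  glob <- efficiency_matrix(gen$panel, frontier_scope("global"))
  cont <- efficiency_matrix(gen$panel, frontier_scope("contemporaneous"))
  expect_true(all(glob$S >= cont$S - 1e-9))
})

test_that("with equal bads the two model variants rank 1x1 panels identically", {
  set.seed(8)
  X <- matrix(runif(5, 1, 3), 1)
  Y <- matrix(runif(5, 1, 3), 1)
  B <- matrix(rep(2, 5), 1)
  p <- make_panel(X, Y, B)
  with_b <- efficiency_matrix(p, include_undesirable = TRUE)
  without_b <- efficiency_matrix(p, include_undesirable = FALSE)
  expect_equal(order(with_b$rho), order(without_b$rho))
})

test_that("evaluating outside the reference pool is an error", {
  gen <- generate_panel(synthetic_spec(n_dmu = 3, n_periods = 2, seed = 2))
  expect_error(
    solve_sbm_ddf(gen$panel, "DMU01", 2011,
                  scope = frontier_scope("contemporaneous", period = 2010)),
    "outside the reference pool")
})
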