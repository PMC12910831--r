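# Independent oracle for small SBM-DDF instances: after eliminating the slack
# variables the model is max of a linear function of the intensity weights w
# over the polytope {w >= 0, sum(w) = 1, Xw <= x0, Yw >= y0, Bw <= b0}; the
# optimum sits at a vertex, and with K <= 4 weights every vertex can be
# enumerated as a K-subset of active constraints (the convexity equality plus
# K-1 inequalities).
oracle_sbm <- function(X, Y, B = NULL, x0, y0, b0 = NULL, gx, gy, gb = NULL) {
  X <- rbind(X); Y <- rbind(Y)
  K <- ncol(X); N <- nrow(X); M <- nrow(Y)
  I <- if (is.null(B)) 0L else nrow(rbind(B))
  if (I > 0) B <- rbind(B)

  obj <- function(w) {
    sx <- x0 - as.vector(X %*% w)
    sy <- as.vector(Y %*% w) - y0
    val <- mean(sx / gx) / 2 +
      (sum(sy / gy) + if (I > 0) sum((b0 - as.vector(B %*% w)) / gb) else 0) /
      (2 * (M + I))
    val
  }
  # inequality system A w <= cvec
  A <- rbind(X, -Y, if (I > 0) B, -diag(K))
  cvec <- c(x0, -y0, if (I > 0) b0, rep(0, K))
  feasible <- function(w) all(A %*% w <= cvec + 1e-9)

  best <- -Inf
  if (K == 1L) {
    w <- 1
    if (feasible(w)) best <- obj(w)
    return(best)
  }
  subsets <- utils::combn(nrow(A), K - 1L, simplify = FALSE)
  for (s in subsets) {
    Msys <- rbind(rep(1, K), A[s, , drop = FALSE])
    if (abs(det(Msys)) < 1e-12) next
    w <- tryCatch(solve(Msys, c(1, cvec[s])), error = function(e) NULL)
    if (is.null(w) || any(!is.finite(w))) next
    if (feasible(w)) best <- max(best, obj(w))
  }
  best
}

# single-period panel from unit columns; rows of X/Y/B are variables
make_panel <- function(X, Y, B = NULL, period = 1L) {
  X <- rbind(X); Y <- rbind(Y)
  K <- ncol(X)
  dmus <- paste0("U", seq_len(K))
  block <- function(mat, prefix) {
    do.call(rbind, lapply(seq_len(nrow(mat)), function(r) {
      data.frame(dmu = dmus, period = period,
                 variable = paste0(prefix, r), value = mat[r, ],
                 stringsAsFactors = FALSE)
    }))
  }
  d <- rbind(block(X, "x"), block(Y, "y"),
             if (!is.null(B)) block(rbind(B), "b"))
  panel_data(d,
             input = paste0("x", seq_len(nrow(X))),
             desirable = paste0("y", seq_len(nrow(Y))),
             undesirable = if (is.null(B)) character()
             else paste0("b", seq_len(nrow(rbind(B)))))
}

# random small instance: K units, N inputs, M desirable, I undesirable
random_instance <- function(K, N, M, I) {
  list(X = matrix(runif(N * K, 0.5, 5), N),
       Y = matrix(runif(M * K, 0.5, 5), M),
       B = if (I > 0) matrix(runif(I * K, 0.5, 5), I) else NULL)
}

# solve one unit of an instance both ways and return (lp, oracle)
both_ways <- function(inst, k) {
  X <- inst$X; Y <- inst$Y; B <- inst$B
  p <- make_panel(X, Y, B)
  dmu <- paste0("U", k)
  g <- default_direction(p, dmu, 1L)
  lp <- suppressWarnings(          # random instances can have S > 1
    solve_sbm_ddf(p, dmu, 1L, include_undesirable = !is.null(B)))$S
  or <- oracle_sbm(X, Y, B, X[, k], Y[, k], if (!is.null(B)) B[, k],
                   gx = g$g_x, gy = g$g_y, gb = g$g_b)
  c(lp = lp, oracle = or)
}
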