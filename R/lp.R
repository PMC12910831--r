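# Dense two-phase primal simplex for small equality-form linear programs.
#
# Solves  max c'v  s.t.  A v = b, v >= 0.
# The frontier models solved here have few constraint rows (one per
# input/output variable plus the VRS convexity row) and up to a few hundred
# columns (one intensity weight per pooled observation plus slacks), so a
# dense tableau is the right tool. DEA systems are routinely degenerate
# (the convexity row makes slack rows linearly dependent at vertices), so the
# pivot rule falls back to Bland's anti-cycling rule if Dantzig stalls.

#' @keywords internal
#' @noRd
lp_max_eq <- function(obj, A, b, tol = 1e-9, max_iter = NULL) {
  A <- as.matrix(A)
  m <- nrow(A)
  n <- ncol(A)
  stopifnot(length(obj) == n, length(b) == m)
  if (is.null(max_iter)) max_iter <- 50L * (m + n)

  # orient rows so b >= 0, then scale rows to O(1) for stable pivot tests
  for (i in seq_len(m)) {
    if (b[i] < 0) {
      A[i, ] <- -A[i, ]
      b[i] <- -b[i]
    }
    sc <- max(abs(A[i, ]), b[i])
    if (sc > 0) {
      A[i, ] <- A[i, ] / sc
      b[i] <- b[i] / sc
    }
  }

  # tableau columns: structural (n) + artificial (m); last col = rhs
  tab <- cbind(A, diag(m), b)
  basis <- n + seq_len(m)
  art <- n + seq_len(m)

  pivot <- function(tab, r, j) {
    tab[r, ] <- tab[r, ] / tab[r, j]
    other <- setdiff(seq_len(nrow(tab)), r)
    tab[other, ] <- tab[other, ] - outer(tab[other, j], tab[r, ])
    tab
  }

  run_phase <- function(tab, basis, cost, active_cols) {
    it <- 0L
    bland_after <- 20L * (m + 5L)
    repeat {
      it <- it + 1L
      if (it > max_iter) return(list(tab = tab, basis = basis, status = 2L))
      cb <- cost[basis]
      red <- cost[active_cols] - as.vector(cb %*% tab[, active_cols, drop = FALSE])
      cand <- which(red > tol)
      if (!length(cand)) return(list(tab = tab, basis = basis, status = 0L))
      j <- if (it > bland_after) {
        active_cols[cand[1L]]                       # Bland: smallest index
      } else {
        active_cols[cand[which.max(red[cand])]]     # Dantzig
      }
      col <- tab[, j]
      rhs <- tab[, ncol(tab)]
      rows <- which(col > tol)
      if (!length(rows)) return(list(tab = tab, basis = basis, status = 3L))
      ratio <- rhs[rows] / col[rows]
      rmin <- min(ratio)
      tie <- rows[ratio <= rmin + tol]
      r <- tie[which.min(basis[tie])]               # Bland tie-break on leaving var
      tab <- pivot(tab, r, j)
      basis[r] <- j
    }
  }

  # phase 1: drive out artificials
  cost1 <- c(rep(0, n), rep(-1, m), 0)
  ph1 <- run_phase(tab, basis, cost1, seq_len(n))
  if (ph1$status != 0L) {
    return(list(status = ph1$status, value = NA_real_, x = rep(NA_real_, n)))
  }
  tab <- ph1$tab
  basis <- ph1$basis
  infeas <- sum(tab[basis %in% art, ncol(tab)])
  if (infeas > 1e-7) {
    return(list(status = 1L, value = NA_real_, x = rep(NA_real_, n)))
  }
  # pivot remaining (degenerate) artificials out of the basis; drop truly
  # redundant rows
  keep <- rep(TRUE, m)
  for (r in seq_len(m)) {
    if (basis[r] %in% art) {
      j <- which(abs(tab[r, seq_len(n)]) > tol)[1L]
      if (is.na(j)) {
        keep[r] <- FALSE
      } else {
        tab <- pivot(tab, r, j)
        basis[r] <- j
      }
    }
  }
  if (!all(keep)) {
    tab <- tab[keep, , drop = FALSE]
    basis <- basis[keep]
  }

  # phase 2
  cost2 <- c(obj, rep(0, m), 0)
  ph2 <- run_phase(tab, basis, cost2, seq_len(n))
  if (ph2$status != 0L) {
    return(list(status = ph2$status, value = NA_real_, x = rep(NA_real_, n)))
  }
  tab <- ph2$tab
  basis <- ph2$basis
  x <- numeric(n)
  structural <- basis <= n
  x[basis[structural]] <- tab[structural, ncol(tab)]
  x[x < 0 & x > -1e-10] <- 0
  list(status = 0L, value = sum(obj * x), x = x)
}
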