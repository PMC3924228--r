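# Dense two-phase primal simplex with Bland's rule.
#
# All crowding-FBA problems in this package are small LPs (tens of
# variables), solved in the form
#   max/min  c'v   s.t.  Aeq v = beq,  Aub v <= bub,  lb <= v <= ub
# Bland's anti-cycling rule makes the solver deterministic on the highly
# degenerate bases that flux balance problems produce (zero-capacity
# exchanges, redundant mass balances). Infeasibility and unboundedness
# are reported as status values, never as errors.

# core: minimize c'x s.t. Ax = b (b >= 0), x >= 0
simplex_core <- function(A, b, cvec, tol = 1e-9, max_iter = 10000L) {
  m <- nrow(A); n <- ncol(A)
  flip <- b < 0
  A[flip, ] <- -A[flip, , drop = FALSE]
  b[flip] <- -b[flip]

  run_phase <- function(T_, basis, cost, n_real) {
    # T_: m x (n_real+1) tableau [A | b]; cost: length n_real
    m <- nrow(T_)
    cb <- cost[basis]
    iter <- 0L
    repeat {
      iter <- iter + 1L
      if (iter > max_iter) return(list(status = "maxiter"))
      # reduced costs
      y <- drop(cb %*% T_[, seq_len(n_real), drop = FALSE])
      red <- cost - y
      enter <- which(red < -tol)
      if (!length(enter)) {
        return(list(status = "optimal", T_ = T_, basis = basis))
      }
      j <- enter[1L]                      # Bland: smallest index
      col <- T_[, j]
      pos <- which(col > tol)
      if (!length(pos)) return(list(status = "unbounded"))
      ratio <- T_[pos, n_real + 1L] / col[pos]
      rmin <- min(ratio)
      cand <- pos[ratio <= rmin + tol]
      i <- cand[which.min(basis[cand])]   # Bland on leaving variable
      # pivot at (i, j)
      T_[i, ] <- T_[i, ] / T_[i, j]
      other <- setdiff(seq_len(m), i)
      T_[other, ] <- T_[other, ] - outer(T_[other, j], T_[i, ])
      basis[i] <- j
      cb <- cost[basis]
    }
  }

  # phase 1: artificial basis
  n1 <- n + m
  T_ <- cbind(A, diag(m), b)
  basis <- n + seq_len(m)
  cost1 <- c(rep(0, n), rep(1, m))
  p1 <- run_phase(T_, basis, cost1, n1)
  if (p1$status != "optimal") return(list(status = "infeasible"))
  obj1 <- sum(cost1[p1$basis] * p1$T_[, n1 + 1L])
  if (obj1 > 1e-7) return(list(status = "infeasible"))
  T_ <- p1$T_; basis <- p1$basis
  # drive remaining artificials out of the basis (degenerate rows)
  drop_rows <- integer()
  for (i in which(basis > n)) {
    piv <- which(abs(T_[i, seq_len(n)]) > tol)
    if (length(piv)) {
      j <- piv[1L]
      T_[i, ] <- T_[i, ] / T_[i, j]
      other <- setdiff(seq_len(nrow(T_)), i)
      T_[other, ] <- T_[other, ] - outer(T_[other, j], T_[i, ])
      basis[i] <- j
    } else drop_rows <- c(drop_rows, i)   # redundant constraint
  }
  if (length(drop_rows)) {
    T_ <- T_[-drop_rows, , drop = FALSE]
    basis <- basis[-drop_rows]
  }
  # phase 2 on real columns only
  T2 <- T_[, c(seq_len(n), n1 + 1L), drop = FALSE]
  p2 <- run_phase(T2, basis, cvec, n)
  if (p2$status == "unbounded") return(list(status = "unbounded"))
  if (p2$status != "optimal") return(list(status = "infeasible"))
  x <- numeric(n)
  x[p2$basis] <- p2$T_[, n + 1L]
  list(status = "optimal", x = x, value = sum(cvec * x))
}

solve_lp <- function(obj, A_eq = NULL, b_eq = NULL, A_ub = NULL, b_ub = NULL,
                     lb, ub, maximize = TRUE) {
  n <- length(obj)
  stopifnot(length(lb) == n, length(ub) == n)
  if (any(!is.finite(lb)))
    mc_stop("lp-bounds", "lower bounds must be finite (split the network first)")
  if (any(lb > ub + 1e-12))
    return(list(x = rep(NA_real_, n), value = NA_real_, status = "infeasible"))

  # shift x = v - lb so all variables are >= 0; add slacks for <= rows
  fin <- which(is.finite(ub) & ub - lb > 1e-12)
  fixed <- which(ub - lb <= 1e-12)        # variables pinned at lb
  rows_ub <- length(fin)
  A_in <- NULL; b_in <- NULL
  if (rows_ub) {
    A_in <- matrix(0, rows_ub, n)
    A_in[cbind(seq_len(rows_ub), fin)] <- 1
    b_in <- ub[fin] - lb[fin]
  }
  if (!is.null(A_ub) && nrow(A_ub) > 0) {
    A_in <- rbind(A_in, A_ub)
    b_in <- c(b_in, b_ub - as.numeric(A_ub %*% lb))
  }
  n_slack <- length(b_in)
  m_eq <- if (is.null(A_eq)) 0L else nrow(A_eq)
  A <- NULL; b <- NULL
  if (m_eq) {
    A <- cbind(A_eq, matrix(0, m_eq, n_slack))
    b <- b_eq - as.numeric(A_eq %*% lb)
  }
  if (n_slack) {
    A <- rbind(A, cbind(A_in, diag(n_slack)))
    b <- c(b, b_in)
  }
  if (length(fixed)) {   # pin x_i = 0 for fixed variables
    P <- matrix(0, length(fixed), n + n_slack)
    P[cbind(seq_along(fixed), fixed)] <- 1
    A <- rbind(A, P)
    b <- c(b, rep(0, length(fixed)))
  }
  cvec <- c(if (maximize) -obj else obj, rep(0, n_slack))
  res <- simplex_core(A, b, cvec)
  if (res$status == "maxiter")
    mc_stop("lp-failure", "simplex iteration limit reached")
  if (res$status != "optimal")
    return(list(x = rep(NA_real_, n),
                value = if (res$status == "unbounded")
                  (if (maximize) Inf else -Inf) else NA_real_,
                status = res$status))
  x <- res$x[seq_len(n)] + lb
  list(x = x, value = sum(obj * x), status = "optimal")
}
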