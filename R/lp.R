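# Bounded-variable two-phase primal simplex.
#
# Solves  min/max c'x  s.t.  A x = b,  l <= x <= u  with all bounds finite
# (flux models substitute a +-1000 sentinel before reaching this layer).
# Deterministic by construction: Dantzig pricing with lowest-index tie-break,
# switching to Bland's rule after a fixed iteration budget to rule out
# cycling. Dense LU via solve() each iteration; model sizes here (tens to a
# few hundred columns) never justify factor updates.

LP_TOL <- 1e-9

#' Solve a bounded linear program
#'
#' Minimises or maximises `obj %*% x` subject to `A %*% x == rhs` and
#' `lb <= x <= ub`. All bounds must be finite; callers substitute the
#' unconstrained-bound sentinel first.
#'
#' @param obj numeric objective coefficients (length n).
#' @param A constraint matrix (m x n), dense or `Matrix` sparse.
#' @param rhs right-hand side (length m).
#' @param lb,ub finite lower/upper variable bounds.
#' @param maximize logical; maximise instead of minimise.
#' @param tol feasibility/optimality tolerance.
#' @return list with `status` ("optimal" or "infeasible"), `objective`,
#'   and `x` (the primal solution, `NA` unless optimal).
#' @keywords internal
solve_lp <- function(obj, A, rhs, lb, ub, maximize = FALSE, tol = LP_TOL) {
  A <- as.matrix(A)
  m <- nrow(A); n <- ncol(A)
  stopifnot(length(obj) == n, length(rhs) == m,
            length(lb) == n, length(ub) == n)
  if (any(!is.finite(lb)) || any(!is.finite(ub)))
    stop("solve_lp requires finite bounds; substitute the bound sentinel first")
  if (any(lb > ub + tol))
    stop("lower bound exceeds upper bound")
  c0 <- if (maximize) -as.numeric(obj) else as.numeric(obj)

  # Phase 1: artificial columns carry the residual of a bound-nearest start.
  x <- ifelse(abs(lb) <= abs(ub), lb, ub)
  r <- as.numeric(rhs) - as.numeric(A %*% x)
  sg <- ifelse(r >= 0, 1, -1)
  Ax <- cbind(A, diag(sg, nrow = m, ncol = m))
  big <- sum(abs(r)) + 1
  lbx <- c(lb, rep(0, m)); ubx <- c(ub, rep(big, m))
  status <- c(ifelse(abs(lb) <= abs(ub), 1L, 2L), rep(0L, m)) # 1 at lb, 2 at ub, 0 basic
  basis <- n + seq_len(m)
  xx <- c(x, abs(r))
  ph1 <- c(rep(0, n), rep(1, m))

  res <- simplex_iterate(ph1, Ax, as.numeric(rhs), lbx, ubx, basis, status, xx, tol)
  if (res$objective > 1e-7)
    return(list(status = "infeasible", objective = NA_real_, x = rep(NA_real_, n)))
  basis <- res$basis; status <- res$status; xx <- res$x
  # Pin artificials so phase 2 cannot reuse them.
  ubx[(n + 1):(n + m)] <- 0
  xx[(n + 1):(n + m)] <- 0

  res <- simplex_iterate(c(c0, rep(0, m)), Ax, as.numeric(rhs), lbx, ubx, basis, status, xx, tol)
  xout <- res$x[seq_len(n)]
  val <- sum(c0 * xout)
  list(status = "optimal",
       objective = if (maximize) -val else val,
       x = xout)
}

# Core pivoting loop shared by both phases. `status`: 0 basic, 1 at lower,
# 2 at upper. Returns updated basis/status/x and the phase objective.
simplex_iterate <- function(cc, A, b, lb, ub, basis, status, x, tol) {
  m <- nrow(A); n <- ncol(A)
  bland_after <- 200L * (m + n)
  maxit <- 2000L * (m + n) + 10000L
  iter <- 0L
  repeat {
    iter <- iter + 1L
    if (iter > maxit) stop("simplex iteration limit exceeded")
    B <- A[, basis, drop = FALSE]
    Binv <- tryCatch(solve(B), error = function(e) NULL)
    if (is.null(Binv)) stop("singular basis encountered in simplex")
    # Recompute basic values from the nonbasic bounds (keeps drift bounded).
    nb <- which(status != 0L)
    xb <- as.numeric(Binv %*% (b - A[, nb, drop = FALSE] %*% x[nb]))
    x[basis] <- xb
    y <- as.numeric(crossprod(Binv, cc[basis]))
    d <- cc - as.numeric(crossprod(A, y))
    viol_l <- status == 1L & d < -tol
    viol_u <- status == 2L & d > tol
    cand <- which(viol_l | viol_u)
    if (!length(cand)) break
    if (iter <= bland_after) {
      score <- abs(d[cand])
      q <- cand[order(-score, cand)][1]
    } else q <- min(cand)

    enter_from_lower <- status[q] == 1L
    w <- as.numeric(Binv %*% A[, q])
    # t >= 0 measures movement of x_q away from its current bound.
    dir <- if (enter_from_lower) 1 else -1
    delta_b <- -dir * w
    t_best <- ub[q] - lb[q]      # bound flip
    leave <- 0L; leave_to <- 0L  # 1 -> leaves to lb, 2 -> to ub
    for (k in seq_len(m)) {
      dk <- delta_b[k]
      if (dk < -1e-10) {
        tk <- (x[basis[k]] - lb[basis[k]]) / (-dk)
        if (tk < t_best - 1e-12 ||
            (tk < t_best + 1e-12 && leave > 0L && basis[k] < basis[leave])) {
          t_best <- tk; leave <- k; leave_to <- 1L
        }
      } else if (dk > 1e-10) {
        tk <- (ub[basis[k]] - x[basis[k]]) / dk
        if (tk < t_best - 1e-12 ||
            (tk < t_best + 1e-12 && leave > 0L && basis[k] < basis[leave])) {
          t_best <- tk; leave <- k; leave_to <- 1L + 1L
        }
      }
    }
    if (t_best < 0) t_best <- 0
    x[basis] <- x[basis] + delta_b * t_best
    x[q] <- x[q] + dir * t_best
    if (leave == 0L) {
      # Bound flip: q moves across to its opposite bound, basis unchanged.
      status[q] <- if (enter_from_lower) 2L else 1L
      x[q] <- if (enter_from_lower) ub[q] else lb[q]
    } else {
      out <- basis[leave]
      status[out] <- leave_to
      x[out] <- if (leave_to == 1L) lb[out] else ub[out]
      basis[leave] <- q
      status[q] <- 0L
    }
  }
  list(basis = basis, status = status, x = x,
       objective = sum(cc * x))
}
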