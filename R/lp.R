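#' @include utils.R
NULL

## Dense two-phase primal simplex for
##     min c'x  s.t.  A x = b,  x >= 0
## with Bland's anti-cycling rule throughout (entering: smallest eligible
## column index; leaving: smallest basis index among minimal ratios).  Sized
## for the desk-scale systems this package targets; every optimization
## method goes through solveLP() below.

simplexPivot <- function(T, pr, pc) {
  T[pr, ] <- T[pr, ] / T[pr, pc]
  other <- setdiff(seq_len(nrow(T)), pr)
  fac <- T[other, pc]
  T[other, ] <- T[other, , drop = FALSE] - outer(fac, T[pr, ])
  T
}

simplexRun <- function(T, basis, cost, allowed, tol = 1e-9, max_iter = 20000L) {
  ncols <- length(cost)
  rhs_col <- ncols + 1L
  for (it in seq_len(max_iter)) {
    rc <- cost - as.vector(cost[basis] %*% T[, seq_len(ncols), drop = FALSE])
    cand <- which(allowed & rc < -tol)
    if (length(cand) == 0L)
      return(list(T = T, basis = basis, status = "optimal"))
    pc <- cand[1L]                              # Bland: smallest index
    col <- T[, pc]
    ok <- col > tol
    if (!any(ok)) return(list(T = T, basis = basis, status = "unbounded"))
    ratios <- rep(Inf, nrow(T))
    ratios[ok] <- T[ok, rhs_col] / col[ok]
    rmin <- min(ratios)
    ties <- which(ratios <= rmin + tol)
    pr <- ties[which.min(basis[ties])]          # Bland: smallest basis index
    T <- simplexPivot(T, pr, pc)
    basis[pr] <- pc
  }
  fkStop("numericalError", "simplex iteration limit reached")
}

## core: min c'x s.t. Ax = b, x >= 0
simplexCore <- function(cvec, A, b, tol = 1e-9) {
  m <- nrow(A); n <- ncol(A)
  neg <- b < 0
  A[neg, ] <- -A[neg, , drop = FALSE]
  b[neg] <- -b[neg]
  T <- cbind(A, diag(m), b, deparse.level = 0)
  basis <- n + seq_len(m)
  cost1 <- c(rep(0, n), rep(1, m))
  allowed1 <- rep(TRUE, n + m)
  r1 <- simplexRun(T, basis, cost1, allowed1, tol)
  T <- r1$T; basis <- r1$basis
  p1obj <- sum(cost1[basis] * T[, n + m + 1L])
  if (p1obj > 1e-7 * max(1, max(abs(b))))
    return(list(status = "infeasible"))

  ## drive surviving artificials out of the basis; drop redundant rows
  art <- which(basis > n)
  if (length(art)) {
    drop_rows <- integer()
    for (r in art) {
      j <- which(abs(T[r, seq_len(n)]) > tol)
      if (length(j)) {
        T <- simplexPivot(T, r, j[1L]); basis[r] <- j[1L]
      } else drop_rows <- c(drop_rows, r)
    }
    if (length(drop_rows)) {
      T <- T[-drop_rows, , drop = FALSE]
      basis <- basis[-drop_rows]
    }
  }

  cost2 <- c(cvec, rep(0, m))
  allowed2 <- c(rep(TRUE, n), rep(FALSE, m))
  r2 <- simplexRun(T, basis, cost2, allowed2, tol)
  if (r2$status == "unbounded") return(list(status = "unbounded"))
  T <- r2$T; basis <- r2$basis
  x <- numeric(n + m)
  x[basis] <- T[, n + m + 1L]
  list(status = "optimal", x = x[seq_len(n)],
       objective = sum(cvec * x[seq_len(n)]))
}

#' Solve a bounded linear program
#'
#' Solves `opt c'v` subject to `A v = b` and `lower <= v <= upper` with a
#' dense two-phase primal simplex (Bland's rule; deterministic).  Variables
#' are shifted to the nonnegative orthant and finite upper bounds become
#' explicit rows, so all bounds must be finite — infinite entries are capped
#' at `cap`.
#'
#' @param obj Objective coefficients (length n).
#' @param A Equality constraint matrix (m x n), dense or sparse.
#' @param b Right-hand side (length m).
#' @param lower,upper Variable bounds (length n).
#' @param maximize Maximize instead of minimize?
#' @param cap Magnitude replacing infinite lower bounds (shifting to the
#'   nonnegative orthant needs a finite lower end); infinite upper bounds
#'   stay free, so unboundedness is detected.
#' @return List with `status` (`"optimal"`, `"infeasible"`, `"unbounded"`),
#'   and for optimal solves `x` (length n) and `objective`.
#' @examples
#' # max x1 + x2 s.t. x1 + x2 = 2, 0 <= x <= 5:
#' solveLP(c(1, 1), matrix(c(1, 1), 1), 2, c(0, 0), c(5, 5), maximize = TRUE)
#' @export
solveLP <- function(obj, A, b, lower, upper, maximize = FALSE, cap = 1e7) {
  A <- asDense(A)
  n <- ncol(A)
  stopifnot(length(obj) == n, length(lower) == n, length(upper) == n,
            length(b) == nrow(A))
  lower <- pmax(lower, -cap)
  if (any(lower > upper + 1e-12)) return(list(status = "infeasible"))
  d <- upper - lower
  bdd <- which(is.finite(d))                  # upper-bound rows only where finite
  nb <- length(bdd)
  ## columns: y (shifted vars), s (upper-bound slacks)
  Aug <- rbind(cbind(A, matrix(0, nrow(A), nb)),
               cbind(diag(n)[bdd, , drop = FALSE], diag(nb)))
  rhs <- c(as.numeric(b - A %*% lower), d[bdd])
  cvec <- c(if (maximize) -obj else obj, rep(0, nb))
  res <- simplexCore(cvec, Aug, rhs)
  if (res$status != "optimal") return(list(status = res$status))
  v <- lower + res$x[seq_len(n)]
  names(v) <- colnames(A)
  list(status = "optimal", x = v, objective = sum(obj * v))
}
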