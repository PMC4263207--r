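#' @import methods
#' @importClassesFrom Matrix Matrix
#' @importFrom Matrix Matrix sparseMatrix t crossprod
#' @importFrom stats setNames
#' @importFrom utils read.csv write.csv head
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

## Classed conditions so callers can distinguish validation problems from
## infeasibility, unboundedness, method gating, etc.
fkStop <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "fluxkitError", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

fkWarn <- function(msg, ...) warning(sprintf(msg, ...), call. = FALSE)

#' Package-wide numerical defaults
#'
#' The magnitude standing in for "unbounded" in reaction bounds, the
#' feasibility tolerance used when checking steady state, bounds and ratio
#' rows, and the relative tolerance at which the parsimonious-FBA stage fixes
#' the primary objective.  All are configurable through the corresponding
#' arguments of the functions that use them; these are the defaults.
#'
#' @return A named list with elements `big_bound` (10000 mmol/gDW/hr),
#'   `feasibility_tol` (1e-6) and `optimality_tol` (1e-9).
#' @examples
#' fluxkitDefaults()
#' @export
fluxkitDefaults <- function() {
  list(big_bound = 1e4, feasibility_tol = 1e-6, optimality_tol = 1e-9)
}

FK_BIG <- 1e4
FK_FEAS_TOL <- 1e-6
FK_OPT_TOL <- 1e-9

## dense numeric matrix from possibly-sparse input
asDense <- function(x) {
  if (is(x, "Matrix")) as.matrix(x) else as.matrix(x)
}

## numerical rank via singular values, tol = max(m,n) * eps * sigma_max
svdRank <- function(A, tol = NULL) {
  A <- asDense(A)
  if (nrow(A) == 0L || ncol(A) == 0L) return(0L)
  sv <- svd(A, nu = 0, nv = 0)$d
  if (is.null(tol)) tol <- max(dim(A)) * .Machine$double.eps * max(sv, 0)
  sum(sv > tol)
}

## Moore-Penrose least-squares solve via SVD (minimum-norm solution)
pinvSolve <- function(A, b, tol = NULL) {
  A <- asDense(A)
  s <- svd(A)
  if (is.null(tol)) tol <- max(dim(A)) * .Machine$double.eps * max(s$d, 0)
  pos <- s$d > tol
  if (!any(pos)) return(numeric(ncol(A)))
  drop(s$v[, pos, drop = FALSE] %*%
         ((crossprod(s$u[, pos, drop = FALSE], b)) / s$d[pos]))
}

## orthonormal kernel basis of A (columns), via SVD
kernelBasis <- function(A, tol = NULL) {
  A <- asDense(A)
  n <- ncol(A)
  if (nrow(A) == 0L) return(diag(n))
  s <- svd(A, nu = 0, nv = n)
  d <- c(s$d, rep(0, n - length(s$d)))
  if (is.null(tol)) tol <- max(dim(A)) * .Machine$double.eps * max(d, 0)
  keep <- d <= tol
  s$v[, keep, drop = FALSE]
}
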