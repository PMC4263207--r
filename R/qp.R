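#' @include lp.R
NULL

## Primal active-set method for the convex box-constrained QP
##     min 1/2 v'Hv + g'v   s.t.  Aeq v = beq,  lower <= v <= upper
## with H positive SEMIdefinite (the measurement-fitting Hessian is diagonal
## with zeros on unmeasured fluxes).  Equality-constrained subproblems are
## reduced to the kernel of the working-set rows; flat directions take the
## minimum-norm step, so iterates are deterministic.

solveBoxQP <- function(H, g, Aeq, beq, lower, upper, tol = 1e-9,
                       max_iter = NULL) {
  Aeq <- asDense(Aeq)
  n <- length(g)
  max_iter <- max_iter %||% (50L + 10L * n)

  ## feasible start from a zero-objective LP
  lp <- solveLP(rep(0, n), Aeq, beq, lower, upper)
  if (lp$status != "optimal") return(list(status = lp$status))
  v <- unname(lp$x)

  at_lower <- function(v) abs(v - lower) < 1e-8
  at_upper <- function(v) abs(v - upper) < 1e-8
  W_lo <- which(at_lower(v))
  W_hi <- setdiff(which(at_upper(v)), W_lo)

  for (it in seq_len(max_iter)) {
    W <- c(W_lo, W_hi)
    if (length(W)) {
      E <- matrix(0, length(W), n)
      E[cbind(seq_along(W), W)] <- 1
      Aw <- rbind(Aeq, E)
    } else Aw <- Aeq
    N <- kernelBasis(Aw)
    grad <- as.numeric(H %*% v + g)
    p <- if (ncol(N)) as.numeric(N %*% pinvSolve(crossprod(N, H %*% N),
                                                 -crossprod(N, grad)))
         else numeric(n)

    if (max(abs(p)) < 1e-10) {
      ## multipliers of the working-set bound rows
      lam <- pinvSolve(t(Aw), grad)
      mu <- if (length(W)) lam[nrow(Aeq) + seq_along(W)] else numeric()
      rel_lo <- W_lo[lower[W_lo] < upper[W_lo] - 1e-12]
      rel_hi <- W_hi[lower[W_hi] < upper[W_hi] - 1e-12]
      viol <- c(-mu[match(rel_lo, W)], mu[match(rel_hi, W)])
      idx <- c(rel_lo, rel_hi)
      bad <- which(viol > 1e-7)
      if (length(bad) == 0L) {
        obj <- 0.5 * sum(v * as.numeric(H %*% v)) + sum(g * v)
        return(list(status = "optimal", x = v, objective = obj))
      }
      worst <- idx[bad[which.max(viol[bad])]]
      W_lo <- setdiff(W_lo, worst)
      W_hi <- setdiff(W_hi, worst)
      next
    }

    ## ratio test against the inactive bounds
    alpha <- 1; block <- NA_integer_; block_side <- NA_character_
    for (i in setdiff(seq_len(n), c(W_lo, W_hi))) {
      if (p[i] > tol) {
        a <- (upper[i] - v[i]) / p[i]
        if (a < alpha - 1e-12) { alpha <- a; block <- i; block_side <- "hi" }
      } else if (p[i] < -tol) {
        a <- (lower[i] - v[i]) / p[i]
        if (a < alpha - 1e-12) { alpha <- a; block <- i; block_side <- "lo" }
      }
    }
    v <- v + max(alpha, 0) * p
    v <- pmin(pmax(v, lower), upper)
    if (!is.na(block)) {
      if (block_side == "lo") W_lo <- sort(c(W_lo, block))
      else W_hi <- sort(c(W_hi, block))
    }
  }
  fkStop("numericalError", "active-set QP iteration limit reached")
}
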