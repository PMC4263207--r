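#' @include system-analysis.R
NULL

## bound-violation check shared by the algebraic solvers: the algebraic
## route has no mechanism to enforce inequalities, so violations are
## reported as warnings, never hidden.
warnBoundViolations <- function(v, bounds, tol = FK_FEAS_TOL) {
  lo <- bounds[, 1]; hi <- bounds[, 2]
  bad <- names(v)[v < lo - tol | v > hi + tol]
  if (length(bad))
    fkWarn("algebraic solution violates effective bounds for: %s",
           paste(bad, collapse = ", "))
  invisible(bad)
}

#' Solve a determined system directly
#'
#' For a system classified as determined, solves the combined equation
#' system (mass balances, ratio rows, measurement/knockout equalities) for
#' the unique flux vector, via an SVD pseudo-inverse for conditioning.
#' Solutions outside the effective inequality bounds are reported as
#' warnings — the algebraic route cannot enforce inequalities, and silent
#' failure would hide measurement problems.
#'
#' @param model A [MetabolicModel-class].
#' @param constraints An [EffectiveConstraints-class].
#' @param scope Balance-row scope (see [combinedEquationMatrix()]).
#' @param tol Consistency tolerance on the residual norm.
#' @return An [AlgebraicSolution-class] with `method = "direct"`.
#' @examples
#' m <- makeFixture("TOY-BR")
#' ec <- mergeConstraints(m,
#'   measurements = data.frame(reaction_id = "U", value = 10, stddev = NA),
#'   ratios = list(fluxRatio(c(R1 = 1), c(U = 1), 0.6)))
#' fluxes(solveDetermined(m, ec))  # U=10, R1=6, R2=4, E1=6, E2=4
#' @export
solveDetermined <- function(model, constraints, scope = "full_system",
                            tol = FK_FEAS_TOL) {
  cls <- classifySystem(model, constraints, scope = scope)
  if (cls@verdict != "determined")
    fkStop("methodNotApplicableError",
           "direct solve requires a determined system (this one is %s%s)",
           cls@verdict,
           if (cls@verdict == "overdetermined")
             "; use solveLeastSquares()" else "")
  ce <- combinedEquationMatrix(model, constraints, scope)
  v <- pinvSolve(ce$coefficients, ce$rhs)
  names(v) <- reactionIds(model)
  resid <- sqrt(sum((asDense(ce$coefficients) %*% v - ce$rhs)^2))
  if (resid > max(tol, tol * max(abs(ce$rhs))))
    fkStop("numericalError",
           "system classified determined but solve left residual %g (numerical degeneracy)",
           resid)
  warnBoundViolations(v, constraints@bounds)
  new("AlgebraicSolution", fluxes = v, residualNorm = resid,
      method = "direct", consistent = TRUE)
}

#' Least-squares flux fitting for (over-)determined systems
#'
#' Treats mass balances, ratio rows and knockout zeros as hard constraints
#' and the flux measurements as soft targets, minimizing the (optionally
#' weighted) squared measurement residual over the admissible space.  With
#' equal weights this is the regular least-squares fit; with
#' `weighted = TRUE` the weights default to 1/stddev^2 (inverse variance,
#' the standard metabolic-flux-analysis choice), unit weight when a
#' measurement carries no stddev.  For a consistent determined system the
#' result coincides with [solveDetermined()].
#'
#' @param model A [MetabolicModel-class].
#' @param constraints An [EffectiveConstraints-class]; merge measurements
#'   with `measurement_mode = "as_equation_rows"` so they stay soft here.
#' @param weights Optional named vector (reaction id -> positive weight)
#'   overriding the defaults.
#' @param weighted Use 1/stddev^2 weights from the measurements?
#' @param scope Balance-row scope.
#' @param tol Consistency tolerance on the residual norm.
#' @return An [AlgebraicSolution-class]; `residualNorm` is the square root
#'   of the attained weighted sum of squares, so users can judge measurement
#'   consistency.
#' @examples
#' m <- makeFixture("TOY-LIN")
#' ec <- mergeConstraints(m,
#'   measurements = data.frame(reaction_id = c("U", "E"),
#'                             value = c(10, 10.4), stddev = NA),
#'   measurement_mode = "as_equation_rows")
#' fluxes(solveLeastSquares(m, ec))["R"]  # 10.2
#' @export
solveLeastSquares <- function(model, constraints, weights = NULL,
                              weighted = FALSE, scope = "full_system",
                              tol = FK_FEAS_TOL) {
  cls <- classifySystem(model, constraints, scope = scope)
  if (cls@verdict == "underdetermined")
    fkStop("methodNotApplicableError",
           "least-squares fitting requires a determined or over-determined system")
  meas <- constraints@measurements
  if (nrow(meas) == 0L)
    fkStop("methodNotApplicableError", "no measurements to fit")
  rids <- reactionIds(model)
  n <- length(rids)

  ## hard part: balances + ratio rows + every fixed bound that is not a
  ## measurement (knockouts, model-fixed fluxes)
  S <- asDense(stoichiometricMatrix(model, scope))
  ratio_rows <- constraints@equalityOrigin == "ratio"
  hardA <- rbind(S, asDense(constraints@equalityCoef[ratio_rows, , drop = FALSE]))
  hardb <- c(rep(0, nrow(S)), constraints@equalityRhs[ratio_rows])
  b <- constraints@bounds
  fixed <- setdiff(rids[b[, 1] == b[, 2]], meas$reaction_id)
  if (length(fixed)) {
    U <- matrix(0, length(fixed), n)
    U[cbind(seq_along(fixed), match(fixed, rids))] <- 1
    hardA <- rbind(hardA, U)
    hardb <- c(hardb, unname(b[fixed, 1]))
  }

  ## soft part: measurement rows with weights
  w <- rep(1, nrow(meas))
  if (weighted) {
    ok <- !is.na(meas$stddev) & meas$stddev > 0
    w[ok] <- 1 / meas$stddev[ok]^2
  }
  if (!is.null(weights)) {
    hit <- match(meas$reaction_id, names(weights))
    w[!is.na(hit)] <- weights[hit[!is.na(hit)]]
    if (any(w <= 0)) fkStop("validationError", "weights must be positive")
  }
  M <- matrix(0, nrow(meas), n)
  M[cbind(seq_len(nrow(meas)), match(meas$reaction_id, rids))] <- 1

  vp <- pinvSolve(hardA, hardb)
  N <- kernelBasis(hardA)
  sw <- sqrt(w)
  z <- if (ncol(N)) pinvSolve(sw * (M %*% N), sw * (meas$value - M %*% vp))
       else numeric(0)
  v <- as.numeric(vp + if (ncol(N)) N %*% z else 0)
  names(v) <- rids
  resid <- sqrt(sum(w * (as.numeric(M %*% v) - meas$value)^2))
  warnBoundViolations(v, constraints@bounds)
  new("AlgebraicSolution", fluxes = v, residualNorm = resid,
      method = if (weighted || !is.null(weights)) "weighted_least_squares"
               else "least_squares",
      consistent = resid < max(tol, tol * max(abs(meas$value))))
}
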