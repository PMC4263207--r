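#' @include constraints.R
NULL

#' Combined equation matrix of a constrained system
#'
#' Stacks (1) the mass-balance rows of the chosen scope, (2) the extra
#' equality rows of the constraint set (ratio rows and, in equation-row
#' mode, measurements) and (3) a unit-coefficient row `v_r = c` for every
#' reaction whose effective bounds are equal (measurements applied as bounds,
#' knockouts).  This is the matrix whose rank defines the exact degrees of
#' freedom and whose kernel is the admissible flux space.
#'
#' @param model A [MetabolicModel-class].
#' @param constraints An [EffectiveConstraints-class] (defaults to the bare
#'   model bounds).
#' @param scope Balance-row scope, `"full_system"` (default, all metabolites)
#'   or `"internal_only"`.
#' @return List with sparse `coefficients` (rows x reactions), `rhs`, and the
#'   raw row counts `n_balance`, `n_equality`, `n_fixed`.
#' @export
combinedEquationMatrix <- function(model, constraints = NULL,
                                   scope = c("full_system", "internal_only")) {
  scope <- match.arg(scope)
  constraints <- constraints %||% emptyConstraints(model)
  S <- stoichiometricMatrix(model, scope)
  b <- constraints@bounds
  fixed <- which(b[, 1] == b[, 2])
  n <- nReactions(model)
  rows <- list(S, constraints@equalityCoef)
  rhs <- c(rep(0, nrow(S)), constraints@equalityRhs)
  if (length(fixed)) {
    U <- sparseMatrix(i = seq_along(fixed), j = fixed, x = rep(1, length(fixed)),
                      dims = c(length(fixed), n),
                      dimnames = list(NULL, reactionIds(model)))
    rows <- c(rows, list(U))
    rhs <- c(rhs, unname(b[fixed, 1]))
  }
  C <- do.call(rbind, rows)
  list(coefficients = C, rhs = rhs,
       n_balance = nrow(S), n_equality = nrow(constraints@equalityCoef),
       n_fixed = length(fixed))
}

#' Degrees of freedom
#'
#' `countDegreesOfFreedomApproximate` is the cheap count: number of fluxes
#' minus the raw number of equations (balance rows + equality rows +
#' reactions fixed by equal bounds), ignoring linear dependency — it can go
#' negative, signalling overdetermination.  `countDegreesOfFreedomExact` is
#' the number of fluxes minus the numerical rank (singular values above
#' `max(m,n) * eps * sigma_max`) of the combined equation matrix.
#'
#' @param model A [MetabolicModel-class].
#' @param constraints An [EffectiveConstraints-class] or `NULL`.
#' @param scope Balance-row scope passed to [combinedEquationMatrix()].
#' @return Integer degrees of freedom.
#' @examples
#' m <- makeFixture("TOY-BR")
#' countDegreesOfFreedomApproximate(m)  # 5 fluxes - 3 balances = 2
#' @name degrees-of-freedom
NULL

#' @rdname degrees-of-freedom
#' @export
countDegreesOfFreedomApproximate <- function(model, constraints = NULL,
                                             scope = "full_system") {
  ce <- combinedEquationMatrix(model, constraints, scope)
  as.integer(nReactions(model) - (ce$n_balance + ce$n_equality + ce$n_fixed))
}

#' @rdname degrees-of-freedom
#' @export
countDegreesOfFreedomExact <- function(model, constraints = NULL,
                                       scope = "full_system") {
  ce <- combinedEquationMatrix(model, constraints, scope)
  as.integer(nReactions(model) - svdRank(ce$coefficients))
}

#' Classify a constrained system by determinacy
#'
#' Computes the approximate degrees of freedom always; when the
#' approximation is at or below `threshold` (genome-scale systems sit far
#' above it and stay classified as underdetermined without the costly rank
#' computation), also computes the exact value and derives the verdict from
#' it: positive exact DoF is underdetermined, zero is determined — unless the
#' right-hand side is inconsistent with the equation rows (augmented rank
#' exceeds coefficient rank), which marks redundant, conflicting
#' measurements: overdetermined.
#'
#' @param model A [MetabolicModel-class].
#' @param constraints An [EffectiveConstraints-class] or `NULL`.
#' @param threshold Approximate-DoF cutoff for running the exact computation
#'   (default 50).
#' @param scope Balance-row scope passed to [combinedEquationMatrix()].
#' @return A [SystemClassification-class].
#' @examples
#' m <- makeFixture("TOY-BR")
#' classifySystem(m)  # underdetermined, 2 degrees of freedom
#' @export
classifySystem <- function(model, constraints = NULL, threshold = 50L,
                           scope = "full_system") {
  stopifnot(threshold >= 0)
  ce <- combinedEquationMatrix(model, constraints, scope)
  n <- nReactions(model)
  raw <- ce$n_balance + ce$n_equality + ce$n_fixed
  approx <- as.integer(n - raw)
  if (approx > threshold) {
    return(new("SystemClassification", nUnknowns = as.integer(n),
               nEquationsRaw = as.integer(raw), dofApproximate = approx,
               dofExact = NA_integer_, verdict = "underdetermined",
               threshold = as.integer(threshold)))
  }
  r <- svdRank(ce$coefficients)
  dof <- as.integer(n - r)
  verdict <- if (dof > 0L) "underdetermined" else {
    r_aug <- svdRank(cbind(asDense(ce$coefficients), ce$rhs))
    if (r_aug > r) "overdetermined" else "determined"
  }
  new("SystemClassification", nUnknowns = as.integer(n),
      nEquationsRaw = as.integer(raw), dofApproximate = approx,
      dofExact = dof, verdict = verdict, threshold = as.integer(threshold))
}

#' Methods applicable under a classification
#'
#' The determinacy verdict gates the portfolio: underdetermined systems get
#' the optimization-based methods, determined systems the direct algebraic
#' solve (plus least squares), over-determined systems the (weighted) least
#' squares fit.  Null-space characterization and the variability analyses
#' are always available.
#'
#' @param classification A [SystemClassification-class].
#' @return Character vector of exported function names.
#' @export
availableMethods <- function(classification) {
  common <- c("nullSpaceBasis", "tightBounds")
  switch(classification@verdict,
    underdetermined = c("fba", "pfba", "qpFitMeasurements",
                        "fvaUnderOptimality", "robustnessAnalysis",
                        "knockoutAnalysis", common),
    determined = c("solveDetermined", "solveLeastSquares", common),
    overdetermined = c("solveLeastSquares", common))
}

#' Null-space basis of the constrained system
#'
#' Orthonormal basis of the kernel of the combined equation matrix.  For an
#' underdetermined system the basis spans the admissible steady-state flux
#' directions; for a determined system it is empty (dimension zero) and the
#' unique solution comes from [solveDetermined()].
#'
#' @param model A [MetabolicModel-class].
#' @param constraints An [EffectiveConstraints-class] or `NULL`.
#' @param scope Balance-row scope passed to [combinedEquationMatrix()].
#' @return A [NullSpaceBasis-class].
#' @examples
#' nullSpaceBasis(makeFixture("TOY-LIN"))  # one direction: (1, 1, 1)/sqrt(3)
#' @export
nullSpaceBasis <- function(model, constraints = NULL, scope = "full_system") {
  ce <- combinedEquationMatrix(model, constraints, scope)
  B <- kernelBasis(ce$coefficients)
  rownames(B) <- reactionIds(model)
  resid <- if (ncol(B)) max(abs(asDense(ce$coefficients) %*% B)) else 0
  new("NullSpaceBasis", basis = B, k = ncol(B), residualMax = resid)
}
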