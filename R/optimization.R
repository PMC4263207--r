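#' @include qp.R algebraic.R
NULL

## LP building blocks shared by the optimization methods -----------------------

lpData <- function(model, constraints) {
  S <- stoichiometricMatrix(model, "internal_only")
  Aeq <- rbind(S, constraints@equalityCoef)
  list(Aeq = asDense(Aeq),
       beq = c(rep(0, nrow(S)), constraints@equalityRhs),
       lower = constraints@bounds[, 1],
       upper = constraints@bounds[, 2],
       n_balance = nrow(S))
}

constraintSources <- function(constraints) {
  src <- c(
    sprintf("%d measurement(s) [%s]", nrow(constraints@measurements),
            constraints@measurementMode),
    sprintf("%d ratio row(s)", sum(constraints@equalityOrigin == "ratio")),
    sprintf("%d knockout(s)", length(constraints@silenced)),
    sprintf("%d bound override(s)", nrow(constraints@overridden)))
  paste(src, collapse = ", ")
}

objIndex <- function(model, objective) {
  objective <- objective %||% objectiveReaction(model)
  if (is.null(objective) || is.na(objective))
    fkStop("validationError", "no objective reaction given and none declared in the model")
  j <- match(objective, reactionIds(model))
  if (is.na(j))
    fkStop("validationError", "objective reaction '%s' not in model", objective)
  list(id = objective, j = j)
}

## wrap an LP solution into a FluxDistribution, asserting the type invariants
asDistribution <- function(model, constraints, v, obj_id, obj_value, method,
                           tol = FK_FEAS_TOL) {
  S <- stoichiometricMatrix(model, "internal_only")
  resid <- if (nrow(S)) max(abs(as.numeric(S %*% v))) else 0
  E <- constraints@equalityCoef
  if (nrow(E)) {
    eq_resid <- max(abs(as.numeric(E %*% v) - constraints@equalityRhs))
    if (eq_resid > tol)
      fkWarn("equality (ratio/measurement) rows violated by %g", eq_resid)
  }
  b <- constraints@bounds
  if (any(v < b[, 1] - tol | v > b[, 2] + tol))
    fkWarn("returned fluxes leave effective bounds by more than %g", tol)
  new("FluxDistribution", fluxes = v, objectiveReaction = obj_id,
      objectiveValue = obj_value, method = method,
      steadyStateResidual = resid, constraints = constraints)
}

#' Flux balance analysis
#'
#' Maximizes (or minimizes) the flux through an objective reaction subject
#' to internal mass balances, effective bounds and any ratio/measurement
#' equality rows.  Returns one optimal vertex; LP optima over genome-scale
#' networks are typically non-unique, so a message points to
#' [fvaUnderOptimality()] for characterizing the alternatives.
#'
#' @param model A [MetabolicModel-class].
#' @param constraints An [EffectiveConstraints-class] (`NULL` for the bare
#'   model bounds).
#' @param objective Objective reaction id (defaults to the model objective).
#' @param sense `"max"` or `"min"`.
#' @return A [FluxDistribution-class] with `method = "FBA"`.
#' @examples
#' m <- makeFixture("TOY-BR")
#' ec <- mergeConstraints(m, env = data.frame(reaction_id = "U",
#'                                            lower = 0, upper = 10))
#' fba(m, ec, objective = "E1")  # objective value 10
#' @export
fba <- function(model, constraints = NULL, objective = NULL,
                sense = c("max", "min")) {
  sense <- match.arg(sense)
  constraints <- constraints %||% emptyConstraints(model)
  ob <- objIndex(model, objective)
  lp <- lpData(model, constraints)
  cvec <- numeric(nReactions(model)); cvec[ob$j] <- 1
  res <- solveLP(cvec, lp$Aeq, lp$beq, lp$lower, lp$upper,
                 maximize = sense == "max")
  if (res$status == "infeasible")
    fkStop("infeasibleError", "FBA infeasible under: %s",
           constraintSources(constraints))
  if (res$status == "unbounded")
    fkStop("unboundedError", "FBA objective '%s' is unbounded", ob$id)
  v <- res$x; names(v) <- reactionIds(model)
  message("FBA optima may be non-unique; use fvaUnderOptimality() to characterize alternatives")
  asDistribution(model, constraints, v, ob$id, res$objective, "FBA")
}

#' Parsimonious FBA
#'
#' Two-stage method: (1) solve FBA; (2) holding the objective at its optimum
#' (equality, tolerance `opt_tol` relative), minimize the total sum of
#' absolute fluxes via reversible-flux splitting (v = v+ - v-, v+/- >= 0).
#' Used to discard futile cycles among the alternative FBA optima.
#'
#' @inheritParams fba
#' @param opt_tol Relative tolerance at which the primary objective is fixed.
#' @return A [FluxDistribution-class] with `method = "pFBA"`; the objective
#'   value equals the FBA optimum and the L1 norm is minimal among optima.
#' @examples
#' m <- makeFixture("TOY-CYC")
#' ec <- mergeConstraints(m, measurements = data.frame(
#'   reaction_id = "U", value = 10, stddev = NA))
#' sol <- suppressMessages(pfba(m, ec, objective = "E"))
#' sum(abs(fluxes(sol)))  # 30: the futile pair F, G carries no flux
#' @export
pfba <- function(model, constraints = NULL, objective = NULL,
                 sense = c("max", "min"), opt_tol = FK_OPT_TOL) {
  sense <- match.arg(sense)
  constraints <- constraints %||% emptyConstraints(model)
  ob <- objIndex(model, objective)
  stage1 <- suppressMessages(fba(model, constraints, ob$id, sense))
  opt <- stage1@objectiveValue

  lp <- lpData(model, constraints)
  n <- nReactions(model); m <- nrow(lp$Aeq)
  cap <- FK_BIG * 10
  ## columns: v (n), p (n), q (n); rows: Aeq v = beq; v - p + q = 0; c'v = opt
  A <- rbind(cbind(lp$Aeq, matrix(0, m, 2 * n)),
             cbind(diag(n), -diag(n), diag(n)),
             c(replace(numeric(n), ob$j, 1), numeric(2 * n)))
  b <- c(lp$beq, rep(0, n), opt)  # objective fixed at its optimum
  obj <- c(numeric(n), rep(1, 2 * n))
  res <- solveLP(obj, A, b,
                 lower = c(lp$lower, rep(0, 2 * n)),
                 upper = c(lp$upper, rep(cap, 2 * n)))
  if (res$status != "optimal")
    fkStop("numericalError",
           "pFBA stage 2 returned status '%s' with the objective fixed at %g (tolerance %g)",
           res$status, opt, opt_tol)
  v <- res$x[seq_len(n)]; names(v) <- reactionIds(model)
  asDistribution(model, constraints, v, ob$id, sum(v[ob$j]), "pFBA")
}

#' Quadratic-programming measurement fitting
#'
#' Minimizes the (inverse-variance weighted) squared difference between
#' measured and computed fluxes, subject to steady state, effective bounds,
#' ratio rows and knockouts — a convex QP of the same mathematical form as
#' the minimization of metabolic adjustment (MOMA), with the measured values
#' in place of a reference flux state.  The solution is unique in the
#' measured subspace.  Measurements must be supplied as soft targets, i.e.
#' the constraint set must not already fix them as hard bounds or rows
#' (merge with `measurement_mode = "as_fitting_targets"`).
#'
#' @param model A [MetabolicModel-class].
#' @param constraints An [EffectiveConstraints-class].
#' @param measurements `data.frame(reaction_id, value, stddev)`; defaults to
#'   the measurements recorded in `constraints`.
#' @return A [FluxDistribution-class] with `method = "QP_fit"`;
#'   `objectiveValue` is the attained weighted squared error.
#' @examples
#' m <- makeFixture("TOY-BR")
#' ec <- mergeConstraints(m,
#'   env = data.frame(reaction_id = "U", lower = 10, upper = 10),
#'   measurements = data.frame(reaction_id = c("E1", "E2"),
#'                             value = c(7, 2), stddev = NA),
#'   measurement_mode = "as_fitting_targets")
#' fluxes(qpFitMeasurements(m, ec))[c("E1", "E2")]  # 7.5, 2.5
#' @export
qpFitMeasurements <- function(model, constraints, measurements = NULL) {
  meas <- measurements %||% constraints@measurements
  if (is.null(meas) || nrow(meas) == 0L)
    fkStop("methodNotApplicableError", "QP fitting requires at least one measurement")
  if (is.null(measurements) &&
      constraints@measurementMode %in% c("as_equality_bounds", "as_equation_rows"))
    fkStop("methodNotApplicableError",
           "measurements are applied as hard constraints in this set; re-merge with measurement_mode = 'as_fitting_targets'")
  rids <- reactionIds(model)
  bad <- setdiff(meas$reaction_id, rids)
  if (length(bad))
    fkStop("validationError", "measurements reference unknown reaction(s): %s",
           paste(bad, collapse = ", "))
  n <- length(rids)
  w <- ifelse(!is.na(meas$stddev) & meas$stddev > 0, 1 / meas$stddev^2, 1)
  H <- matrix(0, n, n); g <- numeric(n); const <- 0
  for (k in seq_len(nrow(meas))) {
    j <- match(meas$reaction_id[k], rids)
    H[j, j] <- H[j, j] + 2 * w[k]
    g[j] <- g[j] - 2 * w[k] * meas$value[k]
    const <- const + w[k] * meas$value[k]^2
  }
  lp <- lpData(model, constraints)
  res <- solveBoxQP(H, g, lp$Aeq, lp$beq, lp$lower, lp$upper)
  if (!identical(res$status, "optimal"))
    fkStop("infeasibleError", "QP fit infeasible under: %s",
           constraintSources(constraints))
  v <- res$x; names(v) <- rids
  asDistribution(model, constraints, v, NA_character_,
                 res$objective + const, "QP_fit")
}

## min and max of one LP column under fixed constraint data
fluxExtrema <- function(cvec, Aeq, beq, lower, upper) {
  lo <- solveLP(cvec, Aeq, beq, lower, upper, maximize = FALSE)
  hi <- solveLP(cvec, Aeq, beq, lower, upper, maximize = TRUE)
  if (lo$status != "optimal" || hi$status != "optimal")
    fkStop("infeasibleError", "variability subproblem returned status %s/%s",
           lo$status, hi$status)
  c(lo$objective, hi$objective)
}

#' Tight flux bounds
#'
#' Computes, for every reaction that is neither measured nor knocked out,
#' the minimum and maximum flux admissible under the full constraint set —
#' flux variability analysis with no constraint on any objective.  Fixed
#' reactions (measurements applied as bounds, knockouts) are reported at
#' their fixed values.
#'
#' @param model A [MetabolicModel-class].
#' @param constraints An [EffectiveConstraints-class] or `NULL`.
#' @return A [FluxRangeSet-class] with `mode = "tight_bounds"`.
#' @examples
#' m <- makeFixture("TOY-BR")
#' ec <- mergeConstraints(m, measurements = data.frame(
#'   reaction_id = "U", value = 10, stddev = NA))
#' ranges(tightBounds(m, ec))["R1", ]  # 0 .. 10
#' @export
tightBounds <- function(model, constraints = NULL) {
  constraints <- constraints %||% emptyConstraints(model)
  lp <- lpData(model, constraints)
  rids <- reactionIds(model)
  n <- length(rids)
  out <- matrix(NA_real_, n, 2, dimnames = list(rids, c("min", "max")))
  feas <- solveLP(numeric(n), lp$Aeq, lp$beq, lp$lower, lp$upper)
  if (feas$status != "optimal")
    fkStop("infeasibleError", "constraint set infeasible under: %s",
           constraintSources(constraints))
  for (j in seq_len(n)) {
    if (lp$lower[j] == lp$upper[j]) {
      out[j, ] <- lp$lower[j]
    } else {
      cvec <- numeric(n); cvec[j] <- 1
      out[j, ] <- fluxExtrema(cvec, lp$Aeq, lp$beq, lp$lower, lp$upper)
    }
  }
  new("FluxRangeSet", ranges = out, mode = "tight_bounds",
      objectiveFixedAt = NA_real_)
}

#' Flux variability analysis under optimality
#'
#' Solves FBA for the objective, constrains the objective to at least
#' `fraction` times its optimum (at most, for minimization), and then
#' minimizes and maximizes every reaction flux under that additional
#' constraint — the standard characterization of alternative optima.
#'
#' @inheritParams fba
#' @param fraction Optimality fraction in (0, 1]; default 1 (exact optimum).
#' @return A [FluxRangeSet-class] with `mode = "under_optimality"` and the
#'   objective bound in `objectiveFixedAt`.
#' @examples
#' m <- makeFixture("TOY-BR")
#' ec <- mergeConstraints(m, measurements = data.frame(
#'   reaction_id = "U", value = 10, stddev = NA))
#' ranges(fvaUnderOptimality(m, ec, objective = "E1"))["E2", ]  # 0, 0
#' @export
fvaUnderOptimality <- function(model, constraints = NULL, objective = NULL,
                               sense = c("max", "min"), fraction = 1.0) {
  sense <- match.arg(sense)
  stopifnot(fraction > 0, fraction <= 1)
  constraints <- constraints %||% emptyConstraints(model)
  ob <- objIndex(model, objective)
  opt <- suppressMessages(fba(model, constraints, ob$id, sense))@objectiveValue
  target <- fraction * opt

  lp <- lpData(model, constraints)
  n <- nReactions(model)
  ## slack column turns the optimality inequality into an equality row:
  ## max: c'v - s = target (s >= 0); min: c'v + s = target
  sgn <- if (sense == "max") -1 else 1
  Aeq <- rbind(cbind(lp$Aeq, 0),
               c(replace(numeric(n), ob$j, 1), sgn))
  beq <- c(lp$beq, target)
  lower <- c(lp$lower, 0); upper <- c(lp$upper, FK_BIG * 10)
  rids <- reactionIds(model)
  out <- matrix(NA_real_, n, 2, dimnames = list(rids, c("min", "max")))
  for (j in seq_len(n)) {
    cvec <- numeric(n + 1); cvec[j] <- 1
    out[j, ] <- fluxExtrema(cvec, Aeq, beq, lower, upper)
  }
  new("FluxRangeSet", ranges = out, mode = "under_optimality",
      objectiveFixedAt = target)
}

#' Robustness analysis
#'
#' For each selected reaction, takes its flux value in a prior optimization
#' of the objective, then fixes the flux at each percentage of that value in
#' turn and re-optimizes, profiling the objective response.  Infeasible grid
#' points are marked, not fatal.  A reaction whose prior value is zero
#' yields a degenerate (flat) profile and a warning.
#'
#' @inheritParams fba
#' @param varied_reactions Character vector of reaction ids to vary.
#' @param percentages Increasing percentage grid (default 0, 10, ..., 100).
#' @return A list of [RobustnessProfile-class], one per varied reaction.
#' @examples
#' m <- makeFixture("TOY-BR")
#' ec <- mergeConstraints(m, env = data.frame(reaction_id = "U",
#'                                            lower = 0, upper = 10))
#' pr <- robustnessAnalysis(m, ec, objective = "E1", varied_reactions = "U",
#'                          percentages = c(0, 50, 100))
#' pr[[1]]@grid$objective  # 0, 5, 10
#' @export
robustnessAnalysis <- function(model, constraints = NULL, objective = NULL,
                               varied_reactions,
                               percentages = seq(0, 100, by = 10),
                               sense = c("max", "min")) {
  sense <- match.arg(sense)
  if (length(percentages) == 0L)
    fkStop("validationError", "percentage grid must be non-empty")
  percentages <- sort(unique(percentages))
  constraints <- constraints %||% emptyConstraints(model)
  ob <- objIndex(model, objective)
  prior <- suppressMessages(fba(model, constraints, ob$id, sense))
  rids <- reactionIds(model)
  bad <- setdiff(varied_reactions, rids)
  if (length(bad))
    fkStop("validationError", "unknown reaction(s) to vary: %s",
           paste(bad, collapse = ", "))
  lp <- lpData(model, constraints)
  cvec <- numeric(nReactions(model)); cvec[ob$j] <- 1

  lapply(varied_reactions, function(rid) {
    j <- match(rid, rids)
    ref <- unname(fluxes(prior)[j])
    if (abs(ref) < FK_FEAS_TOL)
      fkWarn("reaction %s has prior value 0; robustness profile is degenerate", rid)
    grid <- data.frame(percentage = percentages,
                       fixed_flux = percentages / 100 * ref,
                       objective = NA_real_, feasible = FALSE)
    for (k in seq_along(percentages)) {
      lo <- lp$lower; hi <- lp$upper
      lo[j] <- hi[j] <- grid$fixed_flux[k]
      res <- solveLP(cvec, lp$Aeq, lp$beq, lo, hi, maximize = sense == "max")
      if (res$status == "optimal") {
        grid$objective[k] <- res$objective
        grid$feasible[k] <- TRUE
      }
    }
    new("RobustnessProfile", variedReaction = rid, referenceValue = ref,
        grid = grid)
  })
}

## apply extra knockouts on top of an existing constraint set
applyKnockouts <- function(model, constraints, kos) {
  silenced <- expandGeneKnockouts(model, kos)
  b <- constraints@bounds
  overridden <- constraints@overridden
  for (rid in silenced) {
    if (b[rid, 1] != 0 || b[rid, 2] != 0) {
      src <- if (rid %in% constraints@measurements$reaction_id)
        "knockout overrode measurement" else "knockout fixed the flux to zero"
      overridden <- rbind(overridden, data.frame(
        reaction_id = rid, requested_lower = b[rid, 1],
        requested_upper = b[rid, 2], applied_lower = 0, applied_upper = 0,
        source = src, stringsAsFactors = FALSE))
    }
    b[rid, ] <- c(0, 0)
  }
  new("EffectiveConstraints", bounds = b,
      equalityCoef = constraints@equalityCoef,
      equalityRhs = constraints@equalityRhs,
      equalityOrigin = constraints@equalityOrigin,
      overridden = overridden, measurements = constraints@measurements,
      silenced = union(constraints@silenced, silenced),
      measurementMode = constraints@measurementMode)
}

#' Knockout phenotype analysis
#'
#' Expands gene knockouts through the GPR rules, forces the silenced
#' reactions to (0, 0) on top of the supplied constraint set, and runs the
#' chosen method — identical to calling the method with pre-merged
#' knockouts.
#'
#' @param model A [MetabolicModel-class].
#' @param constraints An [EffectiveConstraints-class] or `NULL`.
#' @param kos A [KnockoutSet-class].
#' @param method Name of the method to run: one of `"fba"`, `"pfba"`,
#'   `"qpFitMeasurements"`, `"tightBounds"`, `"fvaUnderOptimality"`,
#'   `"robustnessAnalysis"`, `"solveDetermined"`, `"solveLeastSquares"`.
#' @param ... Arguments passed to the method.
#' @return The chosen method's result.
#' @examples
#' m <- makeFixture("TOY-BR")
#' ec <- mergeConstraints(m, env = data.frame(reaction_id = "U",
#'                                            lower = 0, upper = 10))
#' sol <- suppressMessages(knockoutAnalysis(m, ec, knockoutSet("R1"),
#'                                          "fba", objective = "E1"))
#' sol@objectiveValue  # 0: the only route to B is gone
#' @export
knockoutAnalysis <- function(model, constraints = NULL, kos,
                             method = c("fba", "pfba", "qpFitMeasurements",
                                        "tightBounds", "fvaUnderOptimality",
                                        "robustnessAnalysis",
                                        "solveDetermined", "solveLeastSquares"),
                             ...) {
  method <- match.arg(method)
  constraints <- constraints %||% emptyConstraints(model)
  ec <- applyKnockouts(model, constraints, kos)
  fn <- match.fun(method)
  fn(model, ec, ...)
}
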