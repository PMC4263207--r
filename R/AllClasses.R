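#' @include AllGenerics.R
NULL

#' Constraint-based metabolic model
#'
#' Holds an ordered metabolite table, an ordered reaction table, the sparse
#' stoichiometric matrix connecting them, the gene universe referenced by the
#' gene-protein-reaction (GPR) rules, and an optional declared objective
#' reaction (typically biomass).  Row/column order of the matrix is the
#' declaration order of metabolites/reactions and is stable, so repeated
#' matrix construction is reproducible.
#'
#' @slot id Model identifier.
#' @slot metabolites `data.frame` with columns `id`, `name`, `compartment`,
#'   `external` (logical: boundary/drain-side species excluded from balancing).
#' @slot reactions `data.frame` with columns `id`, `name`, `lower`, `upper`
#'   (mmol/gDW/hr), `gpr` (boolean gene rule string or `NA`), `drain`
#'   (logical: exchanges matter with the environment).
#' @slot stoichiometry Sparse metabolite x reaction coefficient matrix;
#'   substrates negative, products positive.
#' @slot genes Character vector of gene identifiers.
#' @slot objective Reaction id of the declared objective, or `NA`.
#' @seealso [readSBML()], [readCSVModel()], [makeFixture()]
#' @export
setClass("MetabolicModel", representation(
  id = "character",
  metabolites = "data.frame",
  reactions = "data.frame",
  stoichiometry = "Matrix",
  genes = "character",
  objective = "character"
))

setValidity("MetabolicModel", function(object) {
  msg <- character()
  met <- object@metabolites
  rxn <- object@reactions
  need_m <- c("id", "name", "compartment", "external")
  need_r <- c("id", "name", "lower", "upper", "gpr", "drain")
  if (!all(need_m %in% names(met)))
    return(sprintf("metabolites must have columns %s", paste(need_m, collapse = ", ")))
  if (!all(need_r %in% names(rxn)))
    return(sprintf("reactions must have columns %s", paste(need_r, collapse = ", ")))
  if (anyDuplicated(met$id)) msg <- c(msg, "duplicate metabolite ids")
  if (anyDuplicated(rxn$id)) msg <- c(msg, "duplicate reaction ids")
  if (any(!nzchar(met$id)) || any(!nzchar(rxn$id)))
    msg <- c(msg, "empty identifiers are not allowed")
  if (any(rxn$lower > rxn$upper + 1e-12))
    msg <- c(msg, sprintf("lower_bound > upper_bound for reaction(s): %s",
                          paste(rxn$id[rxn$lower > rxn$upper + 1e-12], collapse = ", ")))
  S <- object@stoichiometry
  if (nrow(S) != nrow(met) || ncol(S) != nrow(rxn))
    msg <- c(msg, "stoichiometry dimensions do not match metabolite/reaction tables")
  else {
    if (!identical(rownames(S), met$id) || !identical(colnames(S), rxn$id))
      msg <- c(msg, "stoichiometry dimnames must equal metabolite/reaction ids in order")
    empty <- Matrix::colSums(abs(S)) == 0
    if (any(empty))
      msg <- c(msg, sprintf("reaction(s) with no nonzero coefficient: %s",
                            paste(rxn$id[empty], collapse = ", ")))
  }
  gpr_genes <- unique(unlist(lapply(rxn$gpr[!is.na(rxn$gpr)], gprGenes)))
  if (length(setdiff(gpr_genes, object@genes)))
    msg <- c(msg, sprintf("GPR references undeclared gene(s): %s",
                          paste(setdiff(gpr_genes, object@genes), collapse = ", ")))
  if (length(object@objective) != 1L)
    msg <- c(msg, "objective must be a single reaction id or NA")
  else if (!is.na(object@objective) && !(object@objective %in% rxn$id))
    msg <- c(msg, sprintf("objective reaction '%s' not in model", object@objective))
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Flux-ratio constraint
#'
#' An equality flux ratio (sum_i kappa_i v_i) / (sum_j kappa_j v_j) = tau,
#' the form in which fractional pathway contributions (e.g. from 13C
#' labelling studies) enter a constraint-based system.  It is enforced in
#' linearized form, see [linearizeRatio()].
#'
#' @slot numerator Named numeric vector: reaction id -> kappa_i.
#' @slot denominator Named numeric vector: reaction id -> kappa_j.
#' @slot tau The ratio value; must be nonzero.
#' @seealso [fluxRatio()], [parseRatioExpression()]
#' @export
setClass("FluxRatio", representation(
  numerator = "numeric",
  denominator = "numeric",
  tau = "numeric"
))

setValidity("FluxRatio", function(object) {
  msg <- character()
  if (length(object@numerator) == 0L || is.null(names(object@numerator)) ||
      any(!nzchar(names(object@numerator))))
    msg <- c(msg, "numerator must be a non-empty named numeric vector")
  if (length(object@denominator) == 0L || is.null(names(object@denominator)) ||
      any(!nzchar(names(object@denominator))))
    msg <- c(msg, "denominator must be a non-empty named numeric vector")
  if (length(object@tau) != 1L || !is.finite(object@tau) || object@tau == 0)
    msg <- c(msg, "tau must be a single nonzero finite number")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Knockout set
#'
#' Reactions and/or genes to silence.  Gene knockouts are propagated to
#' reactions through the model's GPR rules by [expandGeneKnockouts()].
#'
#' @slot reactions Character vector of reaction ids (may be empty).
#' @slot genes Character vector of gene ids (may be empty).
#' @seealso [knockoutSet()], [expandGeneKnockouts()], [knockoutAnalysis()]
#' @export
setClass("KnockoutSet", representation(
  reactions = "character",
  genes = "character"
))

#' Effective constraint set
#'
#' The merged result of model bounds, environmental conditions, measurements,
#' linearized flux ratios and knockouts: the per-reaction bounds actually
#' applied, the equality rows added on top of the mass balances, and an audit
#' trail of every requested bound that had to be narrowed or overridden.
#'
#' @slot bounds Numeric matrix (n_reactions x 2, columns `lower`, `upper`),
#'   rownames = reaction ids; the effective bounds.
#' @slot equalityCoef Sparse matrix (rows x reactions) of extra equality
#'   constraints (ratio rows and, in `as_equation_rows` mode, measurements).
#' @slot equalityRhs Right-hand sides of those rows.
#' @slot equalityOrigin `"ratio"` or `"measurement"` per row.
#' @slot overridden `data.frame` audit: reaction, requested and applied
#'   bounds, and the source that won.
#' @slot measurements `data.frame(reaction_id, value, stddev)` as supplied.
#' @slot silenced Reaction ids forced to (0, 0) by knockouts.
#' @slot measurementMode How measurements were applied:
#'   `"as_equality_bounds"`, `"as_equation_rows"` or `"as_fitting_targets"`.
#' @seealso [mergeConstraints()]
#' @export
setClass("EffectiveConstraints", representation(
  bounds = "matrix",
  equalityCoef = "Matrix",
  equalityRhs = "numeric",
  equalityOrigin = "character",
  overridden = "data.frame",
  measurements = "data.frame",
  silenced = "character",
  measurementMode = "character"
))

setValidity("EffectiveConstraints", function(object) {
  msg <- character()
  b <- object@bounds
  if (ncol(b) != 2L) return("bounds must have two columns (lower, upper)")
  if (any(b[, 1] > b[, 2] + 1e-12))
    msg <- c(msg, "empty effective bound interval (lower > upper)")
  if (length(object@silenced)) {
    ko <- b[object@silenced, , drop = FALSE]
    if (any(ko != 0)) msg <- c(msg, "knocked-out reaction without (0,0) bounds")
  }
  if (nrow(object@equalityCoef) != length(object@equalityRhs) ||
      nrow(object@equalityCoef) != length(object@equalityOrigin))
    msg <- c(msg, "equality rows, rhs and origins must align")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' System determinacy classification
#'
#' Degrees of freedom of the constrained system — the cheap approximation
#' (unknowns minus raw equation count, ignoring linear dependency) always,
#' and the exact value (unknowns minus numerical rank of the combined
#' equation matrix) when the approximation falls at or below the threshold —
#' together with the determinacy verdict that gates method availability.
#'
#' @slot nUnknowns Number of flux unknowns.
#' @slot nEquationsRaw Raw equation count: balance rows + equality rows +
#'   reactions fixed by equal bounds.
#' @slot dofApproximate `nUnknowns - nEquationsRaw`.
#' @slot dofExact `nUnknowns - rank(combined matrix)`, or `NA` when skipped.
#' @slot verdict `"underdetermined"`, `"determined"` or `"overdetermined"`.
#' @slot threshold The threshold used to decide whether the exact computation
#'   was performed.
#' @seealso [classifySystem()], [availableMethods()]
#' @export
setClass("SystemClassification", representation(
  nUnknowns = "integer",
  nEquationsRaw = "integer",
  dofApproximate = "integer",
  dofExact = "integer",
  verdict = "character",
  threshold = "integer"
))

#' Null-space basis of the constrained system
#'
#' Orthonormal basis of the kernel of the combined equation matrix (mass
#' balances + ratio rows + measurement/knockout equality rows).  Its
#' dimension equals the exact degrees of freedom; for a determined system it
#' is empty and the unique solution comes from the algebraic solvers.
#'
#' @slot basis Numeric matrix (n_reactions x k), rownames = reaction ids.
#' @slot k Kernel dimension.
#' @slot residualMax Largest |S_eff b| entry over all basis vectors.
#' @seealso [nullSpaceBasis()]
#' @export
setClass("NullSpaceBasis", representation(
  basis = "matrix",
  k = "integer",
  residualMax = "numeric"
))

#' Algebraic flux solution
#'
#' Result of the non-optimization solvers for determined and over-determined
#' systems: a complete flux assignment, the residual norm of the equation
#' system (weighted, for the weighted fit), and a consistency flag.
#'
#' @slot fluxes Named numeric vector over all reactions.
#' @slot residualNorm Euclidean (or weighted) residual norm, >= 0.
#' @slot method `"direct"`, `"least_squares"` or `"weighted_least_squares"`.
#' @slot consistent `residualNorm` below tolerance.
#' @seealso [solveDetermined()], [solveLeastSquares()]
#' @export
setClass("AlgebraicSolution", representation(
  fluxes = "numeric",
  residualNorm = "numeric",
  method = "character",
  consistent = "logical"
))

#' Optimized flux distribution
#'
#' A complete flux assignment from FBA, parsimonious FBA or the QP
#' measurement fit, with the objective value, the steady-state residual and
#' the constraint set under which it was computed.
#'
#' @slot fluxes Named numeric vector over all reactions.
#' @slot objectiveReaction Objective reaction id (`NA` for the QP fit).
#' @slot objectiveValue Optimal objective value (for the QP fit: the attained
#'   weighted squared error).
#' @slot method `"FBA"`, `"pFBA"` or `"QP_fit"`.
#' @slot steadyStateResidual max |S_internal v|.
#' @slot constraints The [EffectiveConstraints-class] used.
#' @seealso [fba()], [pfba()], [qpFitMeasurements()]
#' @export
setClass("FluxDistribution", representation(
  fluxes = "numeric",
  objectiveReaction = "character",
  objectiveValue = "numeric",
  method = "character",
  steadyStateResidual = "numeric",
  constraints = "EffectiveConstraints"
))

#' Per-reaction admissible flux ranges
#'
#' [min, max] interval per reaction from the tight-bounds analysis (no
#' objective constraint) or from flux variability analysis under optimality
#' (objective fixed at a fraction of its optimum).
#'
#' @slot ranges Numeric matrix (n_reactions x 2, columns `min`, `max`).
#' @slot mode `"tight_bounds"` or `"under_optimality"`.
#' @slot objectiveFixedAt The objective bound used in under-optimality mode,
#'   `NA` otherwise.
#' @seealso [tightBounds()], [fvaUnderOptimality()]
#' @export
setClass("FluxRangeSet", representation(
  ranges = "matrix",
  mode = "character",
  objectiveFixedAt = "numeric"
))

setValidity("FluxRangeSet", function(object) {
  if (any(object@ranges[, 1] > object@ranges[, 2] + 1e-6))
    return("range with min > max")
  if (identical(object@mode, "under_optimality") && is.na(object@objectiveFixedAt))
    return("under_optimality ranges must record objectiveFixedAt")
  TRUE
})

#' Robustness profile
#'
#' Objective response to fixing one flux at a grid of percentages of its
#' value in a prior optimization.
#'
#' @slot variedReaction Reaction whose flux is varied.
#' @slot referenceValue Its value in the prior optimization.
#' @slot grid `data.frame(percentage, fixed_flux, objective, feasible)`,
#'   percentages strictly increasing.
#' @seealso [robustnessAnalysis()]
#' @export
setClass("RobustnessProfile", representation(
  variedReaction = "character",
  referenceValue = "numeric",
  grid = "data.frame"
))

#' Structured simulation report
#'
#' Echoes the model summary, method and parameters, the supplied constraints,
#' the bounds that were actually used (overrides included), the objective
#' value, the net conversion rate of every boundary metabolite, and the full
#' flux table.  Render with [renderReport()].
#'
#' @slot modelSummary Named list: id and entity counts.
#' @slot method Named list: method name and parameters.
#' @slot constraintsEcho Named list describing the supplied constraints.
#' @slot overridden Bound-override audit table.
#' @slot objectiveValue Objective value or `NA`.
#' @slot netConversions Named numeric: boundary metabolite -> net rate.
#' @slot fluxTable `data.frame(reaction_id, ...)` with fluxes or ranges.
#' @seealso [buildReport()], [computeNetConversions()]
#' @export
setClass("SimulationReport", representation(
  modelSummary = "list",
  method = "list",
  constraintsEcho = "list",
  overridden = "data.frame",
  objectiveValue = "numeric",
  netConversions = "numeric",
  fluxTable = "data.frame"
))
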