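#' @include AllClasses.R
NULL

## ---- internal constructors -------------------------------------------------

## Build a MetabolicModel from a reaction list whose stoichiometries are
## named numeric vectors.  Metabolites may be given as a data.frame or be
## inferred (all internal) from the reactions.  Drain status, if NA, is
## derived from the rule: exactly one metabolite, or all metabolites external.
makeModel <- function(id, reactions, metabolites = NULL, genes = NULL,
                      objective = NA_character_) {
  stopifnot(length(reactions) > 0L)
  rid <- vapply(reactions, `[[`, "", "id")
  all_mets <- unique(unlist(lapply(reactions, function(r) names(r$stoich))))
  if (is.null(metabolites)) {
    metabolites <- data.frame(id = all_mets, name = all_mets,
                              compartment = "c", external = FALSE,
                              stringsAsFactors = FALSE)
  }
  metabolites$external <- as.logical(metabolites$external)
  missing_met <- setdiff(all_mets, metabolites$id)
  if (length(missing_met))
    fkStop("validationError", "stoichiometry references undeclared metabolite(s): %s",
           paste(missing_met, collapse = ", "))
  ext <- setNames(metabolites$external, metabolites$id)

  rxn <- data.frame(
    id = rid,
    name = vapply(reactions, function(r) r$name %||% r$id, ""),
    lower = vapply(reactions, function(r) as.numeric(r$lower), 0),
    upper = vapply(reactions, function(r) as.numeric(r$upper), 0),
    gpr = vapply(reactions, function(r) r$gpr %||% NA_character_, ""),
    drain = vapply(reactions, function(r) {
      d <- r$drain %||% NA
      if (is.na(d)) {
        mets <- names(r$stoich)
        length(mets) == 1L || all(ext[mets])
      } else as.logical(d)
    }, NA),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(rid))
    fkStop("validationError", "duplicate reaction id(s): %s",
           paste(unique(rid[duplicated(rid)]), collapse = ", "))
  if (anyDuplicated(metabolites$id))
    fkStop("validationError", "duplicate metabolite id(s): %s",
           paste(unique(metabolites$id[duplicated(metabolites$id)]), collapse = ", "))

  i <- integer(); j <- integer(); x <- numeric()
  midx <- setNames(seq_len(nrow(metabolites)), metabolites$id)
  for (k in seq_along(reactions)) {
    st <- reactions[[k]]$stoich
    st <- st[st != 0]
    if (length(st) == 0L)
      fkStop("validationError", "reaction '%s' has no nonzero coefficient", rid[k])
    i <- c(i, midx[names(st)]); j <- c(j, rep(k, length(st))); x <- c(x, unname(st))
  }
  S <- sparseMatrix(i = i, j = j, x = x,
                    dims = c(nrow(metabolites), nrow(rxn)),
                    dimnames = list(metabolites$id, rxn$id))
  genes <- genes %||% unique(unlist(lapply(rxn$gpr[!is.na(rxn$gpr)], gprGenes)))
  if (is.null(genes)) genes <- character()
  new("MetabolicModel", id = id, metabolites = metabolites, reactions = rxn,
      stoichiometry = S, genes = as.character(genes),
      objective = as.character(objective))
}

#' Construct a flux-ratio constraint
#'
#' @param numerator,denominator Named numeric vectors (reaction id ->
#'   coefficient); bare character vectors are accepted as coefficient-1
#'   shorthands.
#' @param tau The ratio value (nonzero).
#' @return A [FluxRatio-class].
#' @examples
#' fluxRatio(c(R1 = 1), c(U = 1), 0.6)
#' @export
fluxRatio <- function(numerator, denominator, tau) {
  coerce <- function(x) {
    if (is.character(x)) x <- setNames(rep(1, length(x)), x)
    x
  }
  new("FluxRatio", numerator = coerce(numerator),
      denominator = coerce(denominator), tau = as.numeric(tau))
}

#' Construct a knockout set
#'
#' @param reactions Reaction ids to silence.
#' @param genes Gene ids to silence (expanded through GPR rules).
#' @return A [KnockoutSet-class].
#' @examples
#' knockoutSet(reactions = "R1")
#' @export
knockoutSet <- function(reactions = character(), genes = character()) {
  new("KnockoutSet", reactions = as.character(reactions),
      genes = as.character(genes))
}

## ---- accessors -------------------------------------------------------------

#' @rdname fluxkit-accessors
#' @export
setMethod("reactionIds", "MetabolicModel", function(x) x@reactions$id)

#' @rdname fluxkit-accessors
#' @export
setMethod("metaboliteIds", "MetabolicModel", function(x) x@metabolites$id)

#' @rdname fluxkit-accessors
#' @export
setMethod("geneIds", "MetabolicModel", function(x) x@genes)

#' @rdname fluxkit-accessors
#' @export
setMethod("nReactions", "MetabolicModel", function(x) nrow(x@reactions))

#' @rdname fluxkit-accessors
#' @export
setMethod("nMetabolites", "MetabolicModel", function(x) nrow(x@metabolites))

#' @rdname fluxkit-accessors
#' @export
setMethod("reactionBounds", "MetabolicModel", function(x) {
  b <- cbind(lower = x@reactions$lower, upper = x@reactions$upper)
  rownames(b) <- x@reactions$id
  b
})

#' @rdname fluxkit-accessors
#' @export
setMethod("reactionBounds", "EffectiveConstraints", function(x) x@bounds)

#' @rdname fluxkit-accessors
#' @export
setMethod("objectiveReaction", "MetabolicModel", function(x) x@objective)

#' @rdname fluxkit-accessors
#' @export
setMethod("fluxes", "FluxDistribution", function(x) x@fluxes)

#' @rdname fluxkit-accessors
#' @export
setMethod("fluxes", "AlgebraicSolution", function(x) x@fluxes)

#' @rdname fluxkit-accessors
#' @export
setMethod("ranges", "FluxRangeSet", function(x) x@ranges)

#' @rdname fluxkit-accessors
#' @export
setMethod("verdict", "SystemClassification", function(x) x@verdict)

#' Reaction table of a model
#'
#' @param model A [MetabolicModel-class].
#' @return The reaction `data.frame` (id, name, lower, upper, gpr, drain).
#' @export
reactionTable <- function(model) model@reactions

#' Metabolite table of a model
#'
#' @param model A [MetabolicModel-class].
#' @return The metabolite `data.frame` (id, name, compartment, external).
#' @export
metaboliteTable <- function(model) model@metabolites

#' Degrees of freedom recorded in a classification
#'
#' @param x A [SystemClassification-class].
#' @param exact Return the exact value (`NA` when it was not computed)?
#' @return Integer degrees of freedom.
#' @export
degreesOfFreedom <- function(x, exact = TRUE) {
  if (exact) x@dofExact else x@dofApproximate
}

## ---- show methods ----------------------------------------------------------

setMethod("show", "MetabolicModel", function(object) {
  ext <- sum(object@metabolites$external)
  cat(sprintf("MetabolicModel '%s': %d reactions (%d drains), %d metabolites (%d internal, %d external), %d genes\n",
              object@id, nReactions(object), sum(object@reactions$drain),
              nMetabolites(object), nMetabolites(object) - ext, ext,
              length(object@genes)))
  if (!is.na(object@objective))
    cat(sprintf("  objective: %s\n", object@objective))
})

setMethod("show", "FluxRatio", function(object) {
  combo <- function(x) paste(sprintf("%g*%s", unname(x), names(x)), collapse = " + ")
  cat(sprintf("FluxRatio: (%s) / (%s) = %g\n",
              combo(object@numerator), combo(object@denominator), object@tau))
})

setMethod("show", "KnockoutSet", function(object) {
  cat(sprintf("KnockoutSet: %d reaction(s), %d gene(s)\n",
              length(object@reactions), length(object@genes)))
})

setMethod("show", "EffectiveConstraints", function(object) {
  fixed <- sum(object@bounds[, 1] == object@bounds[, 2])
  cat(sprintf("EffectiveConstraints: %d reactions (%d fixed), %d equality row(s), %d knockout(s), %d override(s); measurements %s\n",
              nrow(object@bounds), fixed, nrow(object@equalityCoef),
              length(object@silenced), nrow(object@overridden),
              object@measurementMode))
})

setMethod("show", "SystemClassification", function(object) {
  cat(sprintf("SystemClassification: %s\n", object@verdict))
  cat(sprintf("  unknowns: %d, raw equations: %d, DoF approx: %d, DoF exact: %s (threshold %d)\n",
              object@nUnknowns, object@nEquationsRaw, object@dofApproximate,
              ifelse(is.na(object@dofExact), "not computed", object@dofExact),
              object@threshold))
  cat(sprintf("  applicable methods: %s\n",
              paste(availableMethods(object), collapse = ", ")))
})

setMethod("show", "NullSpaceBasis", function(object) {
  cat(sprintf("NullSpaceBasis: dimension %d (%d reactions), max |S b| = %.3g\n",
              object@k, nrow(object@basis), object@residualMax))
})

setMethod("show", "AlgebraicSolution", function(object) {
  cat(sprintf("AlgebraicSolution (%s): %d fluxes, residual norm %.4g, %s\n",
              object@method, length(object@fluxes), object@residualNorm,
              if (object@consistent) "consistent" else "INCONSISTENT"))
})

setMethod("show", "FluxDistribution", function(object) {
  cat(sprintf("FluxDistribution (%s): objective %s = %.6g, steady-state residual %.3g\n",
              object@method,
              ifelse(is.na(object@objectiveReaction), "(fit error)",
                     object@objectiveReaction),
              object@objectiveValue, object@steadyStateResidual))
})

setMethod("show", "FluxRangeSet", function(object) {
  cat(sprintf("FluxRangeSet (%s): %d reactions%s\n", object@mode,
              nrow(object@ranges),
              ifelse(is.na(object@objectiveFixedAt), "",
                     sprintf(", objective fixed at %.6g", object@objectiveFixedAt))))
})

setMethod("show", "RobustnessProfile", function(object) {
  cat(sprintf("RobustnessProfile for %s (reference %.6g), %d grid points\n",
              object@variedReaction, object@referenceValue, nrow(object@grid)))
})

setMethod("show", "SimulationReport", function(object) {
  cat(renderReport(object, format = "text"))
})
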