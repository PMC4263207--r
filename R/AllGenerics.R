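#' @include utils.R
NULL

#' Accessor generics
#'
#' Small accessor generics shared by the model, constraint and result classes:
#' `reactionIds`, `metaboliteIds`, `geneIds`, `nReactions`, `nMetabolites`
#' interrogate a [MetabolicModel-class]; `reactionBounds` returns the declared
#' (model) or effective (constraint-set) bound matrix; `objectiveReaction`
#' returns the model's declared objective; `fluxes` extracts the named flux
#' vector from a solution object; `ranges` extracts the per-reaction interval
#' matrix from a [FluxRangeSet-class]; `verdict` extracts the determinacy
#' verdict from a [SystemClassification-class].
#'
#' @param x An object of the documented class.
#' @return See the method documentation for each class.
#' @name fluxkit-accessors
#' @aliases reactionIds metaboliteIds geneIds nReactions nMetabolites
#'   reactionBounds objectiveReaction fluxes ranges verdict
NULL

#' @rdname fluxkit-accessors
#' @export
setGeneric("reactionIds", function(x) standardGeneric("reactionIds"))

#' @rdname fluxkit-accessors
#' @export
setGeneric("metaboliteIds", function(x) standardGeneric("metaboliteIds"))

#' @rdname fluxkit-accessors
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname fluxkit-accessors
#' @export
setGeneric("nReactions", function(x) standardGeneric("nReactions"))

#' @rdname fluxkit-accessors
#' @export
setGeneric("nMetabolites", function(x) standardGeneric("nMetabolites"))

#' @rdname fluxkit-accessors
#' @export
setGeneric("reactionBounds", function(x) standardGeneric("reactionBounds"))

#' @rdname fluxkit-accessors
#' @export
setGeneric("objectiveReaction", function(x) standardGeneric("objectiveReaction"))

#' @rdname fluxkit-accessors
#' @export
setGeneric("fluxes", function(x) standardGeneric("fluxes"))

#' @rdname fluxkit-accessors
#' @export
setGeneric("ranges", function(x) standardGeneric("ranges"))

#' @rdname fluxkit-accessors
#' @export
setGeneric("verdict", function(x) standardGeneric("verdict"))

#' Stoichiometric matrix of a model
#'
#' Builds the sparse stoichiometric matrix S (metabolite rows x reaction
#' columns) of a model.  With `scope = "internal_only"` only balanced
#' (internal) metabolites contribute rows — the matrix of the quasi-steady
#' state system S v = 0; with `scope = "full_system"` every declared
#' metabolite, external ones included, gets a row.
#'
#' @param model A [MetabolicModel-class].
#' @param scope `"internal_only"` (default) or `"full_system"`.
#' @return A sparse `Matrix` with metabolite ids as rownames and reaction ids
#'   as colnames.  Column order always equals the model's reaction order.
#' @examples
#' m <- makeFixture("TOY-LIN")
#' stoichiometricMatrix(m)
#' @export
setGeneric("stoichiometricMatrix",
           function(model, scope = c("internal_only", "full_system"))
             standardGeneric("stoichiometricMatrix"))
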