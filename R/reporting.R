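#' @include optimization.R
NULL

#' Net conversions implied by a flux distribution
#'
#' Sums, for every metabolite, the stoichiometric contributions of the
#' non-drain reactions: `net[m] = sum_r S[m, r] * v_r`.  Metabolites balanced
#' by the internal network come out at (numerically) zero and are omitted;
#' what remains are the boundary metabolites and their net production
#' (positive) or consumption (negative) rates in mmol/gDW/hr.  Declared
#' external metabolites are always reported, even at zero.
#'
#' @param model A [MetabolicModel-class].
#' @param distribution A [FluxDistribution-class] or [AlgebraicSolution-class]
#'   (or a named flux vector).
#' @param tol Magnitude below which an internal metabolite counts as balanced.
#' @return Named numeric vector, metabolite id -> net rate.
#' @examples
#' m <- makeFixture("TOY-LIN")
#' v <- setNames(c(10, 10, 10), reactionIds(m))
#' computeNetConversions(m, v)  # A consumed at 10, B produced at 10
#' @export
computeNetConversions <- function(model, distribution, tol = FK_FEAS_TOL) {
  v <- if (is.numeric(distribution)) distribution else fluxes(distribution)
  v <- v[reactionIds(model)]
  S <- stoichiometricMatrix(model, "full_system")
  keep <- !model@reactions$drain
  net <- as.numeric(S[, keep, drop = FALSE] %*% v[keep])
  names(net) <- metaboliteIds(model)
  sel <- model@metabolites$external | abs(net) > tol
  net[sel]
}

#' Assemble a simulation report
#'
#' Bundles the model summary, the method and its parameters, an echo of the
#' supplied constraints, the bound-override audit, the objective value, the
#' net conversions and the flux (or range) table into a
#' [SimulationReport-class] ready for [renderReport()].
#'
#' @param model A [MetabolicModel-class].
#' @param constraints An [EffectiveConstraints-class] or `NULL`.
#' @param result A [FluxDistribution-class], [AlgebraicSolution-class] or
#'   [FluxRangeSet-class].
#' @param method Method name override (defaults to the result's own record).
#' @param parameters Named list of method parameters to echo.
#' @return A [SimulationReport-class].
#' @export
buildReport <- function(model, constraints = NULL, result,
                        method = NULL, parameters = list()) {
  constraints <- constraints %||% emptyConstraints(model)
  ext <- sum(model@metabolites$external)
  summary <- list(id = model@id,
                  n_reactions = nReactions(model),
                  n_drains = sum(model@reactions$drain),
                  n_internal_metabolites = nMetabolites(model) - ext,
                  n_external_metabolites = ext)
  echo <- list(
    measurement_mode = constraints@measurementMode,
    measurements = constraints@measurements,
    n_ratio_rows = sum(constraints@equalityOrigin == "ratio"),
    knockouts = constraints@silenced)

  if (is(result, "FluxRangeSet")) {
    method <- method %||% sprintf("variability (%s)", result@mode)
    objv <- result@objectiveFixedAt
    flux_table <- data.frame(reaction_id = rownames(ranges(result)),
                             min = ranges(result)[, 1],
                             max = ranges(result)[, 2],
                             row.names = NULL, stringsAsFactors = FALSE)
    net <- numeric(0)
  } else {
    method <- method %||% result@method
    objv <- if (is(result, "FluxDistribution")) result@objectiveValue else NA_real_
    v <- fluxes(result)
    flux_table <- data.frame(reaction_id = names(v), flux = unname(v),
                             stringsAsFactors = FALSE)
    net <- computeNetConversions(model, result)
  }
  new("SimulationReport", modelSummary = summary,
      method = c(list(name = method), parameters),
      constraintsEcho = echo, overridden = constraints@overridden,
      objectiveValue = as.numeric(objv), netConversions = net,
      fluxTable = flux_table)
}

#' Render or parse a simulation report
#'
#' `renderReport` serializes a report deterministically as human-readable
#' text (sections Model, Method, Constraints, Overrides, Objective, Net
#' conversions, Fluxes) or as JSON; `parseReportJSON` reads the JSON form
#' back into an equal [SimulationReport-class].
#'
#' @param report A [SimulationReport-class].
#' @param format `"text"` or `"json"`.
#' @return `renderReport`: a single string; `parseReportJSON`: a
#'   [SimulationReport-class].
#' @examples
#' m <- makeFixture("TOY-LIN")
#' ec <- mergeConstraints(m, measurements = data.frame(
#'   reaction_id = "U", value = 10, stddev = NA))
#' sol <- suppressMessages(fba(m, ec, objective = "E"))
#' cat(renderReport(buildReport(m, ec, sol), "text"))
#' @export
renderReport <- function(report, format = c("text", "json")) {
  format <- match.arg(format)
  if (format == "json") {
    payload <- list(
      model = report@modelSummary,
      method = report@method,
      constraints = list(
        measurement_mode = report@constraintsEcho$measurement_mode,
        measurements = report@constraintsEcho$measurements,
        n_ratio_rows = report@constraintsEcho$n_ratio_rows,
        knockouts = as.list(report@constraintsEcho$knockouts)),
      overridden = report@overridden,
      objective_value = report@objectiveValue,
      net_conversions = as.list(report@netConversions),
      fluxes = report@fluxTable)
    return(as.character(jsonlite::toJSON(payload, auto_unbox = TRUE,
                                         digits = NA, na = "null")))
  }
  s <- report@modelSummary
  lines <- c(
    "== Model ==",
    sprintf("%s: %d reactions (%d drains), %d internal + %d external metabolites",
            s$id, s$n_reactions, s$n_drains,
            s$n_internal_metabolites, s$n_external_metabolites),
    "", "== Method ==",
    paste(names(report@method), vapply(report@method, function(x)
      paste(format(x), collapse = " "), ""), sep = ": "),
    "", "== Constraints ==",
    sprintf("measurement mode: %s", report@constraintsEcho$measurement_mode),
    sprintf("measurements: %d", nrow(report@constraintsEcho$measurements)),
    if (nrow(report@constraintsEcho$measurements))
      sprintf("  %s = %g%s", report@constraintsEcho$measurements$reaction_id,
              report@constraintsEcho$measurements$value,
              ifelse(is.na(report@constraintsEcho$measurements$stddev), "",
                     sprintf(" (sd %g)", report@constraintsEcho$measurements$stddev))),
    sprintf("ratio rows: %d", report@constraintsEcho$n_ratio_rows),
    sprintf("knockouts: %s",
            if (length(report@constraintsEcho$knockouts))
              paste(report@constraintsEcho$knockouts, collapse = ", ") else "none"),
    "", "== Overrides ==",
    if (nrow(report@overridden))
      sprintf("%s: requested [%g, %g] -> applied [%g, %g] (%s)",
              report@overridden$reaction_id,
              report@overridden$requested_lower, report@overridden$requested_upper,
              report@overridden$applied_lower, report@overridden$applied_upper,
              report@overridden$source)
    else "none",
    "", "== Objective ==",
    if (is.na(report@objectiveValue)) "none" else
      sprintf("%.10g", report@objectiveValue),
    "", "== Net conversions ==",
    if (length(report@netConversions))
      sprintf("%s: %.10g", names(report@netConversions),
              unname(report@netConversions))
    else "none",
    "", "== Fluxes ==",
    paste(colnames(report@fluxTable), collapse = "\t"),
    do.call(sprintf, c(
      list(paste(c("%s", rep("%.10g", ncol(report@fluxTable) - 1L)),
                 collapse = "\t")),
      unname(as.list(report@fluxTable)))))
  paste0(paste(lines, collapse = "\n"), "\n")
}

#' @rdname renderReport
#' @param json JSON string produced by `renderReport(..., format = "json")`.
#' @export
parseReportJSON <- function(json) {
  p <- jsonlite::fromJSON(json, simplifyVector = TRUE)
  meas <- as.data.frame(p$constraints$measurements)
  if (nrow(meas) == 0L)
    meas <- data.frame(reaction_id = character(), value = numeric(),
                       stddev = numeric(), stringsAsFactors = FALSE)
  if (!"stddev" %in% names(meas)) meas$stddev <- NA_real_
  ovr <- as.data.frame(p$overridden)
  if (nrow(ovr) == 0L)
    ovr <- data.frame(reaction_id = character(),
                      requested_lower = numeric(), requested_upper = numeric(),
                      applied_lower = numeric(), applied_upper = numeric(),
                      source = character(), stringsAsFactors = FALSE)
  nc <- unlist(p$net_conversions) %||% numeric(0)
  if (is.null(nc)) nc <- numeric(0)
  new("SimulationReport",
      modelSummary = p$model,
      method = p$method,
      constraintsEcho = list(
        measurement_mode = p$constraints$measurement_mode,
        measurements = meas,
        n_ratio_rows = p$constraints$n_ratio_rows,
        knockouts = as.character(unlist(p$constraints$knockouts))),
      overridden = ovr,
      objectiveValue = as.numeric(p$objective_value %||% NA_real_),
      netConversions = nc,
      fluxTable = as.data.frame(p$fluxes))
}
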