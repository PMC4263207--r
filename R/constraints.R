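#' @include accessors.R gpr.R
NULL

#' Read constraint files
#'
#' Readers for the plain-text constraint formats:
#' * environmental conditions CSV with header `reaction_id,lower_bound,upper_bound`;
#' * flux measurements CSV with header `reaction_id,value,stddev`
#'   (stddev optional/empty);
#' * knockouts: one id per line, `gene:` prefix for gene knockouts;
#' * flux ratios: one expression per line, see [parseRatioExpression()].
#'
#' @param path File path.
#' @return `readEnvironmentalConditions`: `data.frame(reaction_id, lower,
#'   upper)`. `readFluxMeasurements`: `data.frame(reaction_id, value,
#'   stddev)`. `readKnockouts`: a [KnockoutSet-class]. `readFluxRatios`: a
#'   list of [FluxRatio-class].
#' @name constraint-readers
NULL

#' @rdname constraint-readers
#' @export
readEnvironmentalConditions <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("reaction_id", "lower_bound", "upper_bound") %in% names(df)))
    fkStop("formatError",
           "environmental conditions file needs header reaction_id,lower_bound,upper_bound")
  out <- data.frame(reaction_id = as.character(df$reaction_id),
                    lower = as.numeric(df$lower_bound),
                    upper = as.numeric(df$upper_bound),
                    stringsAsFactors = FALSE)
  bad <- out$lower > out$upper
  if (any(bad))
    fkStop("validationError", "lower > upper for reaction(s): %s",
           paste(out$reaction_id[bad], collapse = ", "))
  out
}

#' @rdname constraint-readers
#' @export
readFluxMeasurements <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("reaction_id", "value") %in% names(df)))
    fkStop("formatError",
           "measurements file needs header reaction_id,value[,stddev]")
  sd <- if ("stddev" %in% names(df)) suppressWarnings(as.numeric(df$stddev)) else NA_real_
  out <- data.frame(reaction_id = as.character(df$reaction_id),
                    value = as.numeric(df$value),
                    stddev = sd, stringsAsFactors = FALSE)
  if (any(!is.na(out$stddev) & out$stddev <= 0))
    fkStop("validationError", "measurement stddev must be positive when given")
  out
}

#' @rdname constraint-readers
#' @export
readKnockouts <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  is_gene <- startsWith(lines, "gene:")
  knockoutSet(reactions = lines[!is_gene],
              genes = trimws(sub("^gene:", "", lines[is_gene])))
}

#' @rdname constraint-readers
#' @export
readFluxRatios <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  lapply(lines, parseRatioExpression)
}

#' Parse a flux-ratio expression
#'
#' Grammar: `<linear-combo> / <linear-combo> = <real>` where a linear combo
#' is `[+-] [c*]ID [+- [c*]ID ...]` with coefficient default 1, e.g.
#' `"R_PPC / R_PPC + R_PCK = 0.4"`.
#'
#' @param x Expression string.
#' @return A [FluxRatio-class].
#' @examples
#' parseRatioExpression("R1 / U = 0.6")
#' parseRatioExpression("R2 + 0.5*R3 / U = 1")
#' @export
parseRatioExpression <- function(x) {
  m <- regmatches(x, regexec("^(.*?)/(.*)=\\s*([-+0-9.eE]+)\\s*$", x))[[1]]
  if (length(m) != 4L)
    fkStop("parseError", "ratio '%s': expected '<combo> / <combo> = <value>'", x)
  tau <- suppressWarnings(as.numeric(m[4]))
  if (is.na(tau))
    fkStop("parseError", "ratio '%s': value '%s' is not a number", x, m[4])
  combo <- function(s) {
    s <- trimws(s)
    if (!nzchar(s)) fkStop("parseError", "ratio '%s': empty linear combination", x)
    toks <- regmatches(s, gregexpr("[+-]|[^+[:space:]-][^+[:space:]]*", s))[[1]]
    out <- numeric(); sign <- 1; pending <- FALSE
    for (t in toks) {
      if (t == "+") { sign <- 1; pending <- TRUE; next }
      if (t == "-") { sign <- -1; pending <- TRUE; next }
      pending <- FALSE
      if (grepl("\\*", t)) {
        p <- strsplit(t, "\\*")[[1]]
        co <- suppressWarnings(as.numeric(p[1]))
        if (is.na(co) || length(p) != 2L || !nzchar(p[2]))
          fkStop("parseError", "ratio '%s': bad term '%s'", x, t)
        out[p[2]] <- (if (p[2] %in% names(out)) out[[p[2]]] else 0) + sign * co
      } else {
        co <- suppressWarnings(as.numeric(t))
        if (!is.na(co)) fkStop("parseError", "ratio '%s': dangling coefficient '%s'", x, t)
        out[t] <- (if (t %in% names(out)) out[[t]] else 0) + sign
      }
      sign <- 1
    }
    if (pending)
      fkStop("parseError", "ratio '%s': dangling sign in '%s'", x, s)
    if (length(out) == 0L)
      fkStop("parseError", "ratio '%s': empty linear combination", x)
    out
  }
  fluxRatio(combo(m[2]), combo(m[3]), tau)
}

#' Linearize a flux-ratio constraint
#'
#' Rewrites (sum_i kappa_i v_i) / (sum_j kappa_j v_j) = tau as the equality
#' row sum_i kappa_i v_i - tau * sum_j kappa_j v_j = 0.  Any flux vector with
#' a nonzero denominator satisfies the original ratio iff it satisfies this
#' row; vectors with zero denominator satisfy the row trivially (documented
#' behaviour — a nonzero-denominator guard would be nonlinear).
#'
#' @param ratio A [FluxRatio-class].
#' @return List with `coefficients` (named numeric; numerator minus
#'   tau-scaled denominator, shared ids merged), `rhs` (always 0) and
#'   `degenerate` (`TRUE` when all coefficients cancel, e.g. v/v = 1).
#' @examples
#' linearizeRatio(fluxRatio(c(R1 = 1), c(U = 1), 0.6))
#' @export
linearizeRatio <- function(ratio) {
  stopifnot(is(ratio, "FluxRatio"))
  validObject(ratio)
  co <- c(ratio@numerator, -ratio@tau * ratio@denominator)
  agg <- tapply(unname(co), names(co), sum)
  co <- setNames(as.numeric(agg), names(agg))
  degenerate <- all(abs(co) < 1e-12)
  list(coefficients = co, rhs = 0, degenerate = degenerate)
}

#' Expand gene knockouts to silenced reactions
#'
#' A reaction is silenced iff it is knocked out directly, or its GPR rule
#' evaluates to FALSE with every knocked-out gene FALSE and all other genes
#' TRUE.  Reactions without a GPR are unaffected by gene knockouts; a warning
#' is emitted when a knocked-out gene touches no reaction.
#'
#' @param model A [MetabolicModel-class].
#' @param kos A [KnockoutSet-class].
#' @return Character vector of reaction ids to silence.
#' @examples
#' m <- makeFixture("TOY-LIN")
#' expandGeneKnockouts(m, knockoutSet(reactions = "R"))
#' @export
expandGeneKnockouts <- function(model, kos) {
  stopifnot(is(kos, "KnockoutSet"))
  bad_r <- setdiff(kos@reactions, reactionIds(model))
  if (length(bad_r))
    fkStop("validationError", "unknown reaction id(s) in knockout set: %s",
           paste(bad_r, collapse = ", "))
  bad_g <- setdiff(kos@genes, geneIds(model))
  if (length(bad_g))
    fkStop("validationError", "unknown gene id(s) in knockout set: %s",
           paste(bad_g, collapse = ", "))
  silenced <- kos@reactions
  if (length(kos@genes)) {
    touched <- FALSE
    for (k in seq_len(nReactions(model))) {
      gpr <- model@reactions$gpr[k]
      if (is.na(gpr)) next
      if (length(intersect(gprGenes(gpr), kos@genes)) == 0L) next
      touched <- TRUE
      if (isFALSE(evalGPR(gpr, off = kos@genes)))
        silenced <- c(silenced, model@reactions$id[k])
    }
    if (!touched)
      fkWarn("gene knockout(s) %s reference no reaction GPR; no reaction silenced by them",
             paste(kos@genes, collapse = ", "))
  }
  unique(silenced)
}

#' Merge user constraints into an effective constraint set
#'
#' Applies, innermost last: model bounds intersected with environmental
#' bounds, then measurements (as `[value, value]` bounds in
#' `as_equality_bounds` mode, as unit-coefficient equality rows in
#' `as_equation_rows` mode, or merely recorded in `as_fitting_targets` mode
#' for the QP fit), then knockouts, which force `(0, 0)` and win over
#' measurements with a recorded override.  Every narrowing of a requested
#' bound is recorded in the `overridden` audit.  An empty bound intersection
#' is a conflict error naming the reaction and both sources — except
#' knockout-over-measurement, which is allowed and audited.
#'
#' @param model A [MetabolicModel-class].
#' @param env Environmental conditions `data.frame(reaction_id, lower,
#'   upper)` or `NULL`.
#' @param measurements `data.frame(reaction_id, value, stddev)` or `NULL`.
#' @param ratios List of [FluxRatio-class] (empty ok).
#' @param knockouts A [KnockoutSet-class] or `NULL`.
#' @param measurement_mode `"as_equality_bounds"` (default),
#'   `"as_equation_rows"` (for the algebraic solvers) or
#'   `"as_fitting_targets"`.
#' @return An [EffectiveConstraints-class].
#' @examples
#' m <- makeFixture("TOY-BR")
#' ec <- mergeConstraints(m,
#'   measurements = data.frame(reaction_id = "U", value = 10, stddev = NA),
#'   ratios = list(fluxRatio(c(R1 = 1), c(U = 1), 0.6)))
#' @export
mergeConstraints <- function(model, env = NULL, measurements = NULL,
                             ratios = list(), knockouts = NULL,
                             measurement_mode = c("as_equality_bounds",
                                                  "as_equation_rows",
                                                  "as_fitting_targets")) {
  measurement_mode <- match.arg(measurement_mode)
  rids <- reactionIds(model)
  bounds <- reactionBounds(model)
  overridden <- data.frame(reaction_id = character(),
                           requested_lower = numeric(), requested_upper = numeric(),
                           applied_lower = numeric(), applied_upper = numeric(),
                           source = character(), stringsAsFactors = FALSE)
  note_override <- function(rid, req_lo, req_hi, app_lo, app_hi, source) {
    overridden <<- rbind(overridden, data.frame(
      reaction_id = rid, requested_lower = req_lo, requested_upper = req_hi,
      applied_lower = app_lo, applied_upper = app_hi, source = source,
      stringsAsFactors = FALSE))
  }

  ## environmental conditions: intersect with model bounds
  if (!is.null(env) && nrow(env)) {
    bad <- setdiff(env$reaction_id, rids)
    if (length(bad))
      fkStop("validationError", "environmental conditions reference unknown reaction(s): %s",
             paste(bad, collapse = ", "))
    for (k in seq_len(nrow(env))) {
      rid <- env$reaction_id[k]
      lo <- max(bounds[rid, 1], env$lower[k])
      hi <- min(bounds[rid, 2], env$upper[k])
      if (lo > hi + 1e-12)
        fkStop("conflictError",
               "reaction %s: environmental bounds [%g, %g] do not intersect model bounds [%g, %g]",
               rid, env$lower[k], env$upper[k], bounds[rid, 1], bounds[rid, 2])
      if (lo != env$lower[k] || hi != env$upper[k])
        note_override(rid, env$lower[k], env$upper[k], lo, hi,
                      "model bounds clipped environmental condition")
      bounds[rid, ] <- c(lo, hi)
    }
  }

  eq_coef <- list(); eq_rhs <- numeric(); eq_origin <- character()

  ## measurements
  meas <- data.frame(reaction_id = character(), value = numeric(),
                     stddev = numeric(), stringsAsFactors = FALSE)
  if (!is.null(measurements) && nrow(measurements)) {
    if (!"stddev" %in% names(measurements)) measurements$stddev <- NA_real_
    bad <- setdiff(measurements$reaction_id, rids)
    if (length(bad))
      fkStop("validationError", "measurements reference unknown reaction(s): %s",
             paste(bad, collapse = ", "))
    meas <- measurements[, c("reaction_id", "value", "stddev")]
    if (measurement_mode == "as_equality_bounds") {
      for (k in seq_len(nrow(meas))) {
        rid <- meas$reaction_id[k]; val <- meas$value[k]
        if (val < bounds[rid, 1] - 1e-9 || val > bounds[rid, 2] + 1e-9)
          fkStop("conflictError",
                 "reaction %s: measurement %g conflicts with bounds [%g, %g] (environmental/model)",
                 rid, val, bounds[rid, 1], bounds[rid, 2])
        if (bounds[rid, 1] != val || bounds[rid, 2] != val)
          note_override(rid, bounds[rid, 1], bounds[rid, 2], val, val,
                        "measurement fixed the flux")
        bounds[rid, ] <- c(val, val)
      }
    } else if (measurement_mode == "as_equation_rows") {
      for (k in seq_len(nrow(meas))) {
        eq_coef[[length(eq_coef) + 1L]] <- setNames(1, meas$reaction_id[k])
        eq_rhs <- c(eq_rhs, meas$value[k])
        eq_origin <- c(eq_origin, "measurement")
      }
    } ## as_fitting_targets: recorded only
  }

  ## ratios
  for (ratio in ratios) {
    lin <- linearizeRatio(ratio)
    bad <- setdiff(names(lin$coefficients), rids)
    if (length(bad))
      fkStop("validationError", "flux ratio references unknown reaction(s): %s",
             paste(bad, collapse = ", "))
    if (lin$degenerate)
      fkWarn("degenerate flux ratio (all coefficients cancel); row is trivially satisfied")
    eq_coef[[length(eq_coef) + 1L]] <- lin$coefficients
    eq_rhs <- c(eq_rhs, lin$rhs)
    eq_origin <- c(eq_origin, "ratio")
  }

  ## knockouts: (0,0), winning over measurements with an audit record
  silenced <- character()
  if (!is.null(knockouts)) {
    silenced <- expandGeneKnockouts(model, knockouts)
    for (rid in silenced) {
      lo <- bounds[rid, 1]; hi <- bounds[rid, 2]
      if (lo > 0 + 1e-12 || hi < 0 - 1e-12) {
        src <- if (rid %in% meas$reaction_id)
          "knockout overrode measurement" else "knockout overrode bounds"
        note_override(rid, lo, hi, 0, 0, src)
      } else if (lo != 0 || hi != 0) {
        note_override(rid, lo, hi, 0, 0, "knockout fixed the flux to zero")
      }
      bounds[rid, ] <- c(0, 0)
    }
  }

  ## assemble sparse equality matrix
  n <- length(rids)
  if (length(eq_coef)) {
    i <- integer(); j <- integer(); x <- numeric()
    for (r in seq_along(eq_coef)) {
      co <- eq_coef[[r]]
      i <- c(i, rep(r, length(co)))
      j <- c(j, match(names(co), rids))
      x <- c(x, unname(co))
    }
    E <- sparseMatrix(i = i, j = j, x = x, dims = c(length(eq_coef), n),
                      dimnames = list(NULL, rids))
  } else {
    E <- sparseMatrix(i = integer(), j = integer(), x = numeric(),
                      dims = c(0L, n), dimnames = list(NULL, rids))
  }

  ec <- new("EffectiveConstraints", bounds = bounds, equalityCoef = E,
            equalityRhs = eq_rhs, equalityOrigin = eq_origin,
            overridden = overridden, measurements = meas,
            silenced = silenced, measurementMode = measurement_mode)
  validObject(ec)
  ec
}

## empty constraint set for a model (model bounds only)
emptyConstraints <- function(model) mergeConstraints(model)
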