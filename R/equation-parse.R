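#' @include utils.R
NULL

## Reaction-equation strings of the CSV model dialect:
##   "A + 2 B <-> C"   reversible
##   "A -> B"          irreversible
##   "A ->"            drain (no product side)
##   "-> A"            drain (no substrate side)
## Coefficients may be attached as "2 B" or "2*B"; default 1.

parseEquationSide <- function(side, sign, row = NA) {
  side <- trimws(side)
  if (!nzchar(side)) return(numeric())
  terms <- strsplit(side, "\\s*\\+\\s*")[[1]]
  ids <- character(); coefs <- numeric()
  for (tm in terms) {
    tm <- trimws(tm)
    if (!nzchar(tm)) next
    m <- regmatches(tm, regexec("^([0-9]*\\.?[0-9]+(?:[eE][+-]?[0-9]+)?)?\\s*\\*?\\s*([^\\s*]+)$", tm))[[1]]
    if (length(m) == 0L || !nzchar(m[3]))
      fkStop("parseError", "malformed equation term '%s'%s", tm,
             ifelse(is.na(row), "", sprintf(" (row %s)", row)))
    ids <- c(ids, m[3])
    coefs <- c(coefs, sign * (if (nzchar(m[2])) as.numeric(m[2]) else 1))
  }
  tapply_sum <- tapply(coefs, ids, sum)
  setNames(as.numeric(tapply_sum), names(tapply_sum))
}

#' Parse a reaction equation string
#'
#' Parses the CSV-dialect equation syntax (`"A + 2 B <-> C"`, `"A -> B"`,
#' one-sided drains `"A ->"` / `"-> A"`) into a signed stoichiometry vector.
#' Substrates get negative, products positive coefficients; `<->` marks the
#' reaction reversible.
#'
#' @param equation Equation string.
#' @param row Optional row number used in error messages.
#' @return List with `stoich` (named numeric) and `reversible` (logical).
#' @examples
#' parseReactionEquation("2 A <-> B + C")
#' @export
parseReactionEquation <- function(equation, row = NA) {
  equation <- trimws(equation)
  rev <- grepl("<->", equation, fixed = TRUE)
  parts <- if (rev) strsplit(equation, "<->", fixed = TRUE)[[1]]
           else strsplit(equation, "->", fixed = TRUE)[[1]]
  if (!grepl("->", equation, fixed = TRUE) || length(parts) > 2L)
    fkStop("parseError", "malformed equation '%s'%s: expected one '->' or '<->'",
           equation, ifelse(is.na(row), "", sprintf(" (row %s)", row)))
  lhs <- parseEquationSide(parts[1], -1, row)
  rhs <- if (length(parts) == 2L) parseEquationSide(parts[2], +1, row) else numeric()
  st <- c(lhs, rhs)
  if (length(st) == 0L)
    fkStop("parseError", "equation '%s' has no metabolites%s", equation,
           ifelse(is.na(row), "", sprintf(" (row %s)", row)))
  ## metabolites on both sides collapse to their net coefficient
  agg <- tapply(unname(st), names(st), sum)
  st <- setNames(as.numeric(agg), names(agg))
  st <- st[st != 0]
  list(stoich = st, reversible = rev)
}

## inverse of parseReactionEquation, used by writeCSVModel
deparseReactionEquation <- function(stoich, reversible) {
  fmt <- function(x) {
    paste(vapply(names(x), function(id) {
      co <- abs(x[[id]])
      if (co == 1) id else sprintf("%g %s", co, id)
    }, ""), collapse = " + ")
  }
  lhs <- fmt(stoich[stoich < 0])
  rhs <- fmt(stoich[stoich > 0])
  arrow <- if (reversible) "<->" else "->"
  trimws(paste(lhs, arrow, rhs))
}
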