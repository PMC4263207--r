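#' @include utils.R
NULL

## Gene-protein-reaction rules: boolean expressions over gene identifiers
## with AND / OR (case-insensitive) and parentheses, e.g.
## "g1 and (g2 or g3)".  Parsed by a small recursive-descent parser with the
## usual precedence (OR lowest, AND higher).

gprTokenize <- function(x) {
  toks <- regmatches(x, gregexpr("\\(|\\)|[^()[:space:]]+", x))[[1]]
  toks[nzchar(toks)]
}

parseGPR <- function(x) {
  toks <- gprTokenize(x)
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  take <- function() { t <- peek(); pos <<- pos + 1L; t }
  parseOr <- function() {
    left <- parseAnd()
    while (!is.na(peek()) && tolower(peek()) == "or") {
      take()
      left <- list(op = "or", args = list(left, parseAnd()))
    }
    left
  }
  parseAnd <- function() {
    left <- parseAtom()
    while (!is.na(peek()) && tolower(peek()) == "and") {
      take()
      left <- list(op = "and", args = list(left, parseAtom()))
    }
    left
  }
  parseAtom <- function() {
    t <- take()
    if (is.na(t)) fkStop("parseError", "GPR '%s': unexpected end of expression", x)
    if (t == "(") {
      e <- parseOr()
      if (!identical(take(), ")"))
        fkStop("parseError", "GPR '%s': missing closing parenthesis", x)
      return(e)
    }
    if (t == ")" || tolower(t) %in% c("and", "or"))
      fkStop("parseError", "GPR '%s': unexpected token '%s'", x, t)
    list(op = "gene", id = t)
  }
  out <- parseOr()
  if (!is.na(peek()))
    fkStop("parseError", "GPR '%s': trailing token '%s'", x, peek())
  out
}

## gene ids referenced by a GPR string
gprGenes <- function(x) {
  if (is.na(x) || !nzchar(trimws(x))) return(character())
  collect <- function(node) {
    if (node$op == "gene") node$id
    else unlist(lapply(node$args, collect))
  }
  unique(collect(parseGPR(x)))
}

#' Evaluate a gene-protein-reaction rule
#'
#' Evaluates a boolean GPR expression with the genes in `off` set to FALSE
#' and every other gene TRUE — the convention used to decide whether a gene
#' knockout silences a reaction.
#'
#' @param gpr GPR string (`"g1 and (g2 or g3)"`); `NA`/empty means no rule.
#' @param off Character vector of knocked-out genes.
#' @return `TRUE` if the reaction remains available, `FALSE` if silenced;
#'   `NA` when there is no rule.
#' @examples
#' evalGPR("g1 and (g2 or g3)", off = "g2")  # TRUE
#' evalGPR("g1 and (g2 or g3)", off = "g1")  # FALSE
#' @export
evalGPR <- function(gpr, off = character()) {
  if (is.na(gpr) || !nzchar(trimws(gpr))) return(NA)
  ev <- function(node) {
    switch(node$op,
           gene = !(node$id %in% off),
           and = ev(node$args[[1]]) && ev(node$args[[2]]),
           or = ev(node$args[[1]]) || ev(node$args[[2]]))
  }
  ev(parseGPR(gpr))
}
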