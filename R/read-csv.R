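#' @include equation-parse.R accessors.R
NULL

#' Read a metabolic model from the CSV dialect
#'
#' Reads a model from a reactions file with header
#' `id,equation,lower_bound,upper_bound,gpr` and an optional metabolites file
#' with header `id,name,compartment,external` (`external` in 0/1).  Equation
#' strings follow [parseReactionEquation()]: `"A + 2 B <-> C"` yields
#' coefficients (-1, -2, +1); `<->` marks reversibility.  Missing bounds
#' default to `[0, big_bound]` for irreversible and `[-big_bound, big_bound]`
#' for reversible reactions.  Without a metabolites file all metabolites are
#' internal and drains are detected structurally (single-metabolite
#' reactions).
#'
#' @param reactions_path Path to the reactions CSV.
#' @param metabolites_path Optional path to the metabolites CSV.
#' @param id Model id; defaults to the reactions file name.
#' @param big_bound Magnitude standing in for "unbounded".
#' @return A [MetabolicModel-class].
#' @seealso [writeCSVModel()], [readSBML()]
#' @export
readCSVModel <- function(reactions_path, metabolites_path = NULL,
                         id = NULL, big_bound = fluxkitDefaults()$big_bound) {
  if (!file.exists(reactions_path))
    fkStop("formatError", "reactions file not found: %s", reactions_path)
  df <- read.csv(reactions_path, stringsAsFactors = FALSE,
                 colClasses = "character")
  need <- c("id", "equation", "lower_bound", "upper_bound")
  if (!all(need %in% names(df)))
    fkStop("formatError",
           "reactions file must have header id,equation,lower_bound,upper_bound[,gpr]")
  if (!"gpr" %in% names(df)) df$gpr <- ""

  mets <- NULL
  if (!is.null(metabolites_path)) {
    md <- read.csv(metabolites_path, stringsAsFactors = FALSE)
    if (!all(c("id", "external") %in% names(md)))
      fkStop("formatError",
             "metabolites file must have header id,name,compartment,external")
    mets <- data.frame(id = as.character(md$id),
                       name = as.character(md$name %||% md$id),
                       compartment = as.character(md$compartment %||% "c"),
                       external = as.logical(as.integer(md$external)),
                       stringsAsFactors = FALSE)
  }

  reactions <- vector("list", nrow(df))
  for (k in seq_len(nrow(df))) {
    eq <- parseReactionEquation(df$equation[k], row = k + 1L)
    lo <- suppressWarnings(as.numeric(df$lower_bound[k]))
    hi <- suppressWarnings(as.numeric(df$upper_bound[k]))
    if (is.na(lo)) lo <- if (eq$reversible) -big_bound else 0
    if (is.na(hi)) hi <- big_bound
    gpr <- trimws(df$gpr[k])
    reactions[[k]] <- list(id = df$id[k], stoich = eq$stoich,
                           lower = lo, upper = hi,
                           gpr = if (nzchar(gpr)) gpr else NA_character_)
  }
  if (!is.null(mets)) {
    unknown <- setdiff(unique(unlist(lapply(reactions, function(r) names(r$stoich)))),
                       mets$id)
    if (length(unknown))
      fkStop("validationError",
             "equation metabolite(s) missing from metabolites file: %s",
             paste(unknown, collapse = ", "))
  }
  m <- makeModel(id %||% sub("\\.[^.]*$", "", basename(reactions_path)),
                 reactions, metabolites = mets)
  validObject(m)
  m
}

#' Write a metabolic model in the CSV dialect
#'
#' Inverse of [readCSVModel()]: writes the reactions file (and, when
#' `metabolites_path` is given, the metabolites file) such that re-reading
#' yields an identical model.
#'
#' @param model A [MetabolicModel-class].
#' @param reactions_path Output path for the reactions CSV.
#' @param metabolites_path Optional output path for the metabolites CSV.
#' @return Invisibly, `reactions_path`.
#' @export
writeCSVModel <- function(model, reactions_path, metabolites_path = NULL) {
  S <- model@stoichiometry
  rxn <- model@reactions
  eqs <- vapply(seq_len(nrow(rxn)), function(j) {
    col <- S[, j]
    deparseReactionEquation(col[col != 0], reversible = rxn$lower[j] < 0)
  }, "")
  out <- data.frame(id = rxn$id, equation = eqs,
                    lower_bound = rxn$lower, upper_bound = rxn$upper,
                    gpr = ifelse(is.na(rxn$gpr), "", rxn$gpr),
                    stringsAsFactors = FALSE)
  write.csv(out, reactions_path, row.names = FALSE, quote = TRUE)
  if (!is.null(metabolites_path)) {
    md <- model@metabolites
    write.csv(data.frame(id = md$id, name = md$name,
                         compartment = md$compartment,
                         external = as.integer(md$external)),
              metabolites_path, row.names = FALSE, quote = TRUE)
  }
  invisible(reactions_path)
}

#' @rdname stoichiometricMatrix
#' @export
setMethod("stoichiometricMatrix", "MetabolicModel",
  function(model, scope = c("internal_only", "full_system")) {
    scope <- match.arg(scope)
    S <- model@stoichiometry
    if (scope == "internal_only")
      S <- S[!model@metabolites$external, , drop = FALSE]
    S
  })
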