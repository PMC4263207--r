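#' @include accessors.R
NULL

## namespace-agnostic helpers: SBML documents mix core, fbc and html
## namespaces, so elements are matched on local-name() and attributes on
## their unprefixed name.
xAll <- function(node, local) {
  xml2::xml_find_all(node, sprintf(".//*[local-name()='%s']", local))
}
xAttr <- function(node, name) {
  at <- xml2::xml_attrs(node)
  hit <- match(name, sub("^.*:", "", names(at)))
  if (is.na(hit)) NA_character_ else unname(at[hit])
}

## fbc geneProductAssociation subtree -> GPR string
fbcGPRString <- function(node, label_of) {
  nm <- xml2::xml_name(node)
  kids <- xml2::xml_children(node)
  if (nm == "geneProductRef") {
    ref <- xAttr(node, "geneProduct")
    return(label_of[ref] %||% ref)
  }
  if (nm %in% c("and", "or")) {
    parts <- vapply(kids, fbcGPRString, "", label_of = label_of)
    return(paste0("(", paste(parts, collapse = sprintf(" %s ", nm)), ")"))
  }
  if (length(kids)) return(fbcGPRString(kids[[1]], label_of))
  NA_character_
}

#' Read a metabolic model from SBML
#'
#' Reads SBML Level 2 or Level 3 documents.  Flux bounds are taken from the
#' FBC package (`fbc:lowerFluxBound` / `fbc:upperFluxBound` parameter
#' references) when present, falling back to COBRA-style kinetic-law
#' parameters (`LOWER_BOUND` / `UPPER_BOUND`) and finally to defaults by
#' reversibility (`[0, big_bound]` irreversible, `[-big_bound, big_bound]`
#' reversible).  GPR rules come from `fbc:geneProductAssociation` or from
#' `GENE_ASSOCIATION:` notes.  Species are flagged external when
#' `boundaryCondition="true"` or when their compartment is listed in
#' `external_compartments`.  The FBC objective, when declared, becomes the
#' model objective.
#'
#' @param path Path to the SBML file.
#' @param external_compartments Compartment ids treated as external for
#'   Level 2 files without boundary-condition flags.
#' @param big_bound Magnitude standing in for "unbounded".
#' @return A [MetabolicModel-class].
#' @seealso [readCSVModel()]
#' @export
readSBML <- function(path,
                     external_compartments = c("e", "extracellular", "external"),
                     big_bound = fluxkitDefaults()$big_bound) {
  if (!file.exists(path)) fkStop("formatError", "SBML file not found: %s", path)
  doc <- tryCatch(xml2::read_xml(path), error = function(e)
    fkStop("formatError", "SBML parse failure in '%s': %s", path, conditionMessage(e)))
  root <- xml2::xml_find_first(doc, "/*[local-name()='sbml']")
  if (inherits(root, "xml_missing"))
    fkStop("formatError", "'%s' is not an SBML document (no <sbml> root)", path)
  level <- suppressWarnings(as.integer(xAttr(root, "level")))
  if (is.na(level) || !(level %in% c(2L, 3L)))
    fkWarn("SBML level %s is untested here (levels 2 and 3 are supported); attempting to read anyway",
           xAttr(root, "level") %||% "?")

  modelNode <- xml2::xml_find_first(doc, ".//*[local-name()='model']")
  model_id <- xAttr(modelNode, "id") %||% "sbml_model"
  if (is.na(model_id)) model_id <- "sbml_model"

  ## species ----------------------------------------------------------------
  spNodes <- xml2::xml_find_all(
    doc, ".//*[local-name()='listOfSpecies']/*[local-name()='species']")
  if (length(spNodes) == 0L)
    fkStop("formatError", "'%s': no species found", path)
  sp_id <- vapply(spNodes, xAttr, "", name = "id")
  if (anyDuplicated(sp_id))
    fkStop("validationError", "duplicate species id(s): %s",
           paste(unique(sp_id[duplicated(sp_id)]), collapse = ", "))
  sp_comp <- vapply(spNodes, xAttr, "", name = "compartment")
  sp_bc <- tolower(vapply(spNodes, xAttr, "", name = "boundaryCondition")) == "true"
  sp_bc[is.na(sp_bc)] <- FALSE
  mets <- data.frame(
    id = sp_id,
    name = ifelse(is.na(nm <- vapply(spNodes, xAttr, "", name = "name")), sp_id, nm),
    compartment = ifelse(is.na(sp_comp), "c", sp_comp),
    external = sp_bc | (sp_comp %in% external_compartments),
    stringsAsFactors = FALSE
  )

  ## global parameters (L3 fbc bound references) ----------------------------
  parNodes <- xml2::xml_find_all(
    doc, ".//*[local-name()='listOfParameters']/*[local-name()='parameter']")
  par_val <- suppressWarnings(as.numeric(vapply(parNodes, xAttr, "", name = "value")))
  names(par_val) <- vapply(parNodes, xAttr, "", name = "id")

  ## gene products (fbc) ----------------------------------------------------
  gpNodes <- xAll(doc, "geneProduct")
  label_of <- character()
  if (length(gpNodes)) {
    gp_id <- vapply(gpNodes, xAttr, "", name = "id")
    gp_lab <- vapply(gpNodes, xAttr, "", name = "label")
    label_of <- setNames(ifelse(is.na(gp_lab), gp_id, gp_lab), gp_id)
  }

  ## reactions ---------------------------------------------------------------
  rxNodes <- xml2::xml_find_all(
    doc, ".//*[local-name()='listOfReactions']/*[local-name()='reaction']")
  if (length(rxNodes) == 0L)
    fkStop("formatError", "'%s': no reactions found", path)
  rx_id <- vapply(rxNodes, xAttr, "", name = "id")
  if (anyDuplicated(rx_id))
    fkStop("validationError", "duplicate reaction id(s): %s",
           paste(unique(rx_id[duplicated(rx_id)]), collapse = ", "))

  reactions <- vector("list", length(rxNodes))
  for (k in seq_along(rxNodes)) {
    node <- rxNodes[[k]]
    rev <- tolower(xAttr(node, "reversible"))
    reversible <- is.na(rev) || rev == "true"   # SBML L2 default is true

    sref <- function(list_name, sign) {
      refs <- xml2::xml_find_all(node, sprintf(
        "./*[local-name()='%s']/*[local-name()='speciesReference']", list_name))
      if (length(refs) == 0L) return(numeric())
      ids <- vapply(refs, xAttr, "", name = "species")
      co <- suppressWarnings(as.numeric(vapply(refs, xAttr, "", name = "stoichiometry")))
      co[is.na(co)] <- 1
      agg <- tapply(sign * co, ids, sum)
      setNames(as.numeric(agg), names(agg))
    }
    lhs <- sref("listOfReactants", -1)
    rhs <- sref("listOfProducts", +1)
    st <- c(lhs, rhs)
    agg <- tapply(unname(st), names(st), sum)
    st <- setNames(as.numeric(agg), names(agg))
    st <- st[st != 0]
    if (length(st) == 0L)
      fkStop("validationError", "reaction '%s' has empty stoichiometry", rx_id[k])

    ## bounds: fbc refs > kinetic-law parameters > defaults
    lo <- hi <- NA_real_
    lo_ref <- xAttr(node, "lowerFluxBound"); hi_ref <- xAttr(node, "upperFluxBound")
    if (!is.na(lo_ref) && lo_ref %in% names(par_val)) lo <- par_val[[lo_ref]]
    if (!is.na(hi_ref) && hi_ref %in% names(par_val)) hi <- par_val[[hi_ref]]
    if (is.na(lo) || is.na(hi)) {
      klp <- xml2::xml_find_all(node, paste0(
        "./*[local-name()='kineticLaw']//*[local-name()='parameter']",
        " | ./*[local-name()='kineticLaw']//*[local-name()='localParameter']"))
      if (length(klp)) {
        kl_id <- toupper(vapply(klp, xAttr, "", name = "id"))
        kl_val <- suppressWarnings(as.numeric(vapply(klp, xAttr, "", name = "value")))
        if (is.na(lo) && "LOWER_BOUND" %in% kl_id)
          lo <- kl_val[match("LOWER_BOUND", kl_id)]
        if (is.na(hi) && "UPPER_BOUND" %in% kl_id)
          hi <- kl_val[match("UPPER_BOUND", kl_id)]
      }
    }
    if (is.na(lo)) lo <- if (reversible) -big_bound else 0
    if (is.na(hi)) hi <- big_bound
    lo <- max(lo, -big_bound); hi <- min(hi, big_bound)

    ## GPR: fbc association > COBRA notes
    gpr <- NA_character_
    gpa <- xml2::xml_find_first(node, ".//*[local-name()='geneProductAssociation']")
    if (!inherits(gpa, "xml_missing")) {
      kids <- xml2::xml_children(gpa)
      if (length(kids)) gpr <- fbcGPRString(kids[[1]], label_of)
    }
    if (is.na(gpr)) {
      notes <- xml2::xml_find_first(node, "./*[local-name()='notes']")
      if (!inherits(notes, "xml_missing")) {
        txt <- xml2::xml_text(notes)
        m <- regmatches(txt, regexec("GENE[ _]ASSOCIATION:\\s*([^\n<]*)", txt))[[1]]
        if (length(m) == 2L && nzchar(trimws(m[2]))) gpr <- trimws(m[2])
      }
    }

    reactions[[k]] <- list(id = rx_id[k],
                           name = xAttr(node, "name") %||% rx_id[k],
                           stoich = st, lower = lo, upper = hi, gpr = gpr)
  }
  for (k in seq_along(reactions))
    if (is.na(reactions[[k]]$name)) reactions[[k]]$name <- reactions[[k]]$id

  ## objective (fbc) ---------------------------------------------------------
  objective <- NA_character_
  fo <- xml2::xml_find_first(doc, ".//*[local-name()='fluxObjective']")
  if (!inherits(fo, "xml_missing")) {
    objective <- xAttr(fo, "reaction")
    if (!is.na(objective) && !(objective %in% rx_id)) objective <- NA_character_
  }

  m <- makeModel(model_id, reactions, metabolites = mets, objective = objective)
  validObject(m)
  m
}
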