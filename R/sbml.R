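#' Serialize a model definition to a structured config file
#'
#' Writes the species list, reaction set (id, kind, part, roles, parameter
#' keys), parameter names and HRE totals as JSON; `read_model_config()`
#' restores an equivalent `hif_model`.
#'
#' @param model A `hif_model`.
#' @param path Output JSON file.
#' @return `path`, invisibly.
#' @export
write_model_config <- function(model, path) {
  stopifnot(inherits(model, "hif_model"))
  cfg <- list(
    species = model$species,
    hre1_total = model$hre1_total,
    hre2_total = model$hre2_total,
    param_names = model$param_names,
    reactions = lapply(model$reactions, function(r)
      list(id = r$id, kind = r$kind, part = r$part,
           roles = as.list(r$roles), params = as.list(r$params))))
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_model_config
#' @export
read_model_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  need <- c("species", "hre1_total", "hre2_total", "reactions")
  miss <- setdiff(need, names(cfg))
  if (length(miss))
    stop("model config lacks field(s): ", paste(miss, collapse = ", "))
  model <- build_default_model(cfg$hre1_total, cfg$hre2_total)
  # validate that the stored network matches the canonical construction
  ids <- vapply(model$reactions, `[[`, character(1), "id")
  stored <- vapply(cfg$reactions, `[[`, character(1), "id")
  if (!setequal(ids, stored))
    stop("model config reaction set does not match the canonical network")
  model
}

## Minimal SBML Level 3 Version 1 export of the assembled network.
## Kinetic laws are written as MathML matching the package's flux
## definitions exactly; O2 is a constant boundary species.

.mathml <- function(expr) {
  ## expr: list-based prefix tree, e.g. list("times", "k", "X") with
  ## character leaves = <ci>, numeric leaves = <cn>
  render <- function(e) {
    if (is.character(e)) return(paste0("<ci> ", e, " </ci>"))
    if (is.numeric(e)) return(paste0("<cn> ", format(e, digits = 15),
                                     " </cn>"))
    op <- e[[1]]
    args <- vapply(e[-1], render, character(1))
    paste0("<apply><", op, "/>", paste(args, collapse = ""), "</apply>")
  }
  paste0('<math xmlns="http://www.w3.org/1998/Math/MathML">',
         render(expr), "</math>")
}

.kinetic_math <- function(r) {
  p <- r$params
  s <- r$roles
  switch(r$kind,
    constant_inflow = .mathml(p[["k"]]),
    first_order = .mathml(list("times", p[["k"]], s[["reactant"]])),
    catalytic_production = .mathml(list("times", p[["k"]], s[["modifier"]])),
    mm_hydroxylation = .mathml(
      list("times", p[["kcat"]], s[["enzyme"]],
           list("divide", s[["substrate"]],
                list("plus", p[["km_hif"]], s[["substrate"]])),
           list("divide", "O2", list("plus", p[["km_o2"]], "O2")))),
    reversible_binding = .mathml(
      list("minus",
           list("times", p[["k"]], s[["a"]], s[["b"]]),
           list("times", p[["k"]], p[["kd"]], s[["ab"]]))))
}

.sbml_reaction <- function(r) {
  reactants <- products <- modifiers <- character(0)
  sref <- function(sp) sprintf(
    '<speciesReference species="%s" stoichiometry="1" constant="true"/>', sp)
  mref <- function(sp) sprintf('<modifierSpeciesReference species="%s"/>', sp)
  switch(r$kind,
    constant_inflow = { products <- sref(r$roles[["product"]]) },
    first_order = { reactants <- sref(r$roles[["reactant"]]) },
    catalytic_production = {
      products <- sref(r$roles[["product"]])
      modifiers <- mref(r$roles[["modifier"]])
    },
    mm_hydroxylation = {
      reactants <- sref(r$roles[["substrate"]])
      modifiers <- c(mref(r$roles[["enzyme"]]), mref("O2"))
    },
    reversible_binding = {
      reactants <- c(sref(r$roles[["a"]]), sref(r$roles[["b"]]))
      products <- sref(r$roles[["ab"]])
    })
  reversible <- if (r$kind == "reversible_binding") "true" else "false"
  paste0(
    sprintf('<reaction id="%s" reversible="%s" fast="false">', r$id,
            reversible),
    if (length(reactants))
      paste0("<listOfReactants>", paste(reactants, collapse = ""),
             "</listOfReactants>"),
    if (length(products))
      paste0("<listOfProducts>", paste(products, collapse = ""),
             "</listOfProducts>"),
    if (length(modifiers))
      paste0("<listOfModifiers>", paste(modifiers, collapse = ""),
             "</listOfModifiers>"),
    "<kineticLaw>", .kinetic_math(r), "</kineticLaw>",
    "</reaction>")
}

#' Export the model as SBML Level 3
#'
#' Writes the assembled reaction network -- species with initial
#' concentrations, parameters, and reactions with MathML kinetic laws
#' matching the package's flux definitions -- as an SBML Level 3 Version 1
#' document for interchange with other simulators. O2 is exported as a
#' constant boundary species. Parameter ids replace the `.` separator with
#' `_` to stay SId-valid.
#'
#' @param model A `hif_model`.
#' @param params Named parameter vector.
#' @param init Initial state (default [initial_state()]).
#' @param path Output file.
#' @param o2 Boundary oxygen level.
#' @return `path`, invisibly; the document is validated as XML on write.
#' @export
export_sbml <- function(model, params, init = initial_state(model), path,
                        o2 = 1) {
  stopifnot(inherits(model, "hif_model"))
  p <- .check_params(model, params)
  names(p) <- model$param_names
  s0 <- .check_state(model, init)
  sid <- function(x) gsub(".", "_", x, fixed = TRUE)

  species <- c(
    vapply(model$species, function(sp) sprintf(
      paste0('<species id="%s" compartment="cell" ',
             'initialConcentration="%s" hasOnlySubstanceUnits="false" ',
             'boundaryCondition="false" constant="false"/>'),
      sp, format(s0[[sp]], digits = 15)), character(1)),
    sprintf(paste0('<species id="O2" compartment="cell" ',
                   'initialConcentration="%s" ',
                   'hasOnlySubstanceUnits="false" boundaryCondition="true" ',
                   'constant="true"/>'), format(o2, digits = 15)))
  parameters <- vapply(names(p), function(pn) sprintf(
    '<parameter id="%s" value="%s" constant="true"/>',
    sid(pn), format(p[[pn]], digits = 15)), character(1))

  reactions <- vapply(model$reactions, function(r) {
    r$params[] <- sid(r$params)
    .sbml_reaction(r)
  }, character(1))

  doc <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" ',
    'level="3" version="1">',
    '<model id="hifdyn_model" name="HIF-1/HIF-2 hypoxia gene activation">',
    '<listOfCompartments>',
    '<compartment id="cell" spatialDimensions="3" size="1" ',
    'constant="true"/>',
    '</listOfCompartments>',
    "<listOfSpecies>", paste(species, collapse = ""), "</listOfSpecies>",
    "<listOfParameters>", paste(parameters, collapse = ""),
    "</listOfParameters>",
    "<listOfReactions>", paste(reactions, collapse = ""),
    "</listOfReactions>",
    "</model></sbml>")
  parsed <- xml2::read_xml(doc)  # fails on malformed output
  xml2::write_xml(parsed, path)
  invisible(path)
}
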