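#' @useDynLib hifdyn, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

## Dynamic species, in canonical order. O2 is a boundary input, not a state.
.HIF_SPECIES <- c(
  "HIF1A_mrna", "HIF2A_mrna",
  "HIF1A_protein", "HIF2A_protein",
  "PHD_protein", "HIF1B",
  "HIF1AB", "HIF2AB",
  "HRE1", "HRE2",
  "HIF1AB_HRE1", "HIF2AB_HRE1",
  "HIF1AB_HRE2", "HIF2AB_HRE2",
  "Gene_mRNA"
)

.REACTION_KINDS <- c("constant_inflow", "first_order", "mm_hydroxylation",
                     "reversible_binding", "catalytic_production")

#' Names of the model's dynamic species
#'
#' The 15 dynamic species of the hypoxia gene-activation network, in the
#' canonical state-vector order used throughout the package. Oxygen is a
#' boundary input held constant between protocol steps and is not part of
#' the state vector.
#'
#' @return Character vector of length 15.
#' @export
hif_species <- function() .HIF_SPECIES

.new_reaction <- function(id, kind, part, roles, param_slots) {
  stopifnot(kind %in% .REACTION_KINDS)
  params <- stats::setNames(paste0(id, ".", param_slots), param_slots)
  structure(list(id = id, kind = kind, part = part,
                 roles = roles, params = params),
            class = "hif_reaction")
}

.role_slots <- function(kind) {
  switch(kind,
    constant_inflow      = "product",
    first_order          = "reactant",
    catalytic_production = c("modifier", "product"),
    mm_hydroxylation     = c("substrate", "enzyme"),
    reversible_binding   = c("a", "b", "ab"))
}

.param_slots <- function(kind) {
  switch(kind,
    constant_inflow      = "k",
    first_order          = "k",
    catalytic_production = "k",
    mm_hydroxylation     = c("kcat", "km_hif", "km_o2"),
    reversible_binding   = c("k", "kd"))
}

#' Build the default HIF-1/HIF-2 gene-activation network
#'
#' Assembles the full 15-species reaction network: production and decay of
#' *HIF1A*/*HIF2A* mRNA, translation (mRNA as template, not consumed),
#' first-order outflow of the free alpha subunits, oxygen- and
#' PHD-dependent hydroxylation of each alpha subunit (two-substrate
#' Michaelis-Menten, removing the subunit in one step), PHD production with
#' a basal term plus induction by each free alpha subunit, HIF1B inflow and
#' outflow, reversible dimerization of each alpha subunit with HIF1B,
#' reversible binding of either heterodimer to either HRE motif class, and
#' transcription of the target gene from each of the four HIF-HRE
#' complexes (complex as catalyst), plus basal Gene_mRNA turnover.
#'
#' HRE motif counts in promoter open chromatin are treated as the initial
#' concentrations of the free HRE species; HRE species take part only in
#' binding and unbinding, so free + bound HRE of each class is conserved.
#'
#' @param hre1_count Non-negative integer, number of HRE motifs annotated to
#'   HIF-1 in the target gene's promoter open chromatin (12 for *MIR210HG*).
#' @param hre2_count Non-negative integer, HRE motifs annotated to HIF-2
#'   (18 for *MIR210HG*).
#' @return An object of class `hif_model`: list with `species`, `reactions`,
#'   `hre1_total`, `hre2_total`, `param_names`.
#' @examples
#' m <- build_default_model(12, 18)
#' length(m$reactions)
#' @export
build_default_model <- function(hre1_count, hre2_count) {
  if (length(hre1_count) != 1L || length(hre2_count) != 1L ||
      is.na(hre1_count) || is.na(hre2_count) ||
      hre1_count < 0 || hre2_count < 0)
    stop("HRE counts must be single non-negative numbers")
  if (hre1_count != round(hre1_count) || hre2_count != round(hre2_count))
    stop("HRE counts must be integers")

  rx <- list()
  add <- function(id, kind, part, ...) {
    roles <- c(...)
    rx[[length(rx) + 1L]] <<- .new_reaction(id, kind, part, roles,
                                            .param_slots(kind))
  }

  ## cytoplasmic part: alpha-subunit production, degradation, PHD loop
  add("hif1a_mrna_in",  "constant_inflow", "cytoplasmic", product = "HIF1A_mrna")
  add("hif1a_mrna_out", "first_order",     "cytoplasmic", reactant = "HIF1A_mrna")
  add("hif2a_mrna_in",  "constant_inflow", "cytoplasmic", product = "HIF2A_mrna")
  add("hif2a_mrna_out", "first_order",     "cytoplasmic", reactant = "HIF2A_mrna")
  add("hif1a_mrna_to_protein", "catalytic_production", "cytoplasmic",
      modifier = "HIF1A_mrna", product = "HIF1A_protein")
  add("hif2a_mrna_to_protein", "catalytic_production", "cytoplasmic",
      modifier = "HIF2A_mrna", product = "HIF2A_protein")
  add("hif1a_protein_out", "first_order", "cytoplasmic", reactant = "HIF1A_protein")
  add("hif2a_protein_out", "first_order", "cytoplasmic", reactant = "HIF2A_protein")
  add("phd_to_hif1a_protein", "mm_hydroxylation", "cytoplasmic",
      substrate = "HIF1A_protein", enzyme = "PHD_protein")
  add("phd_to_hif2a_protein", "mm_hydroxylation", "cytoplasmic",
      substrate = "HIF2A_protein", enzyme = "PHD_protein")
  add("phd_in",  "constant_inflow", "cytoplasmic", product = "PHD_protein")
  add("phd_induction_by_hif1a", "catalytic_production", "cytoplasmic",
      modifier = "HIF1A_protein", product = "PHD_protein")
  add("phd_induction_by_hif2a", "catalytic_production", "cytoplasmic",
      modifier = "HIF2A_protein", product = "PHD_protein")
  add("phd_out", "first_order", "cytoplasmic", reactant = "PHD_protein")

  ## nuclear part: dimerization, HRE binding, transcription
  add("hif1b_in",  "constant_inflow", "nuclear", product = "HIF1B")
  add("hif1b_out", "first_order",     "nuclear", reactant = "HIF1B")
  add("hif1a_hif1b_binding", "reversible_binding", "nuclear",
      a = "HIF1A_protein", b = "HIF1B", ab = "HIF1AB")
  add("hif2a_hif1b_binding", "reversible_binding", "nuclear",
      a = "HIF2A_protein", b = "HIF1B", ab = "HIF2AB")
  add("hif1ab_hre1_binding", "reversible_binding", "nuclear",
      a = "HIF1AB", b = "HRE1", ab = "HIF1AB_HRE1")
  add("hif2ab_hre1_binding", "reversible_binding", "nuclear",
      a = "HIF2AB", b = "HRE1", ab = "HIF2AB_HRE1")
  add("hif1ab_hre2_binding", "reversible_binding", "nuclear",
      a = "HIF1AB", b = "HRE2", ab = "HIF1AB_HRE2")
  add("hif2ab_hre2_binding", "reversible_binding", "nuclear",
      a = "HIF2AB", b = "HRE2", ab = "HIF2AB_HRE2")
  add("transcription_hif1ab_hre1", "catalytic_production", "nuclear",
      modifier = "HIF1AB_HRE1", product = "Gene_mRNA")
  add("transcription_hif2ab_hre1", "catalytic_production", "nuclear",
      modifier = "HIF2AB_HRE1", product = "Gene_mRNA")
  add("transcription_hif1ab_hre2", "catalytic_production", "nuclear",
      modifier = "HIF1AB_HRE2", product = "Gene_mRNA")
  add("transcription_hif2ab_hre2", "catalytic_production", "nuclear",
      modifier = "HIF2AB_HRE2", product = "Gene_mRNA")
  add("gene_mrna_in",  "constant_inflow", "nuclear", product = "Gene_mRNA")
  add("gene_mrna_out", "first_order",     "nuclear", reactant = "Gene_mRNA")

  for (r in rx) {
    bad <- setdiff(r$roles, .HIF_SPECIES)
    if (length(bad)) stop("unknown species in reaction ", r$id, ": ", bad[1])
  }

  model <- structure(list(
    species = .HIF_SPECIES,
    reactions = rx,
    hre1_total = as.numeric(hre1_count),
    hre2_total = as.numeric(hre2_count),
    param_names = unlist(lapply(rx, function(r) unname(r$params)))
  ), class = "hif_model")
  model$compiled <- .compile_network(model)
  model
}

#' @export
print.hif_model <- function(x, ...) {
  cat("hif_model: ", length(x$species), " species, ",
      length(x$reactions), " reactions, ",
      length(x$param_names), " parameters\n", sep = "")
  cat("HRE totals: HRE1 =", x$hre1_total, " HRE2 =", x$hre2_total, "\n")
  invisible(x)
}

#' Restrict a model to its cytoplasmic part
#'
#' Keeps only the reactions of the cytoplasmic part (alpha-subunit mRNA and
#' protein turnover, hydroxylation, PHD loop). Nuclear species remain in the
#' state vector but are inert, so the first fitting step can run on the
#' same machinery.
#'
#' @param model A `hif_model`.
#' @return A `hif_model` containing only cytoplasmic reactions.
#' @export
cytoplasmic_model <- function(model) {
  stopifnot(inherits(model, "hif_model"))
  model$reactions <- Filter(function(r) r$part == "cytoplasmic", model$reactions)
  model$param_names <- unlist(lapply(model$reactions,
                                     function(r) unname(r$params)))
  model$compiled <- .compile_network(model)
  model
}

## Flatten the reaction list into integer arrays for the C++ kernels.
.KIND_CODE <- c(constant_inflow = 0L, first_order = 1L,
                catalytic_production = 2L, mm_hydroxylation = 3L,
                reversible_binding = 4L)

.compile_network <- function(model) {
  n_rx <- length(model$reactions)
  kind <- integer(n_rx)
  roles <- matrix(-1L, n_rx, 3L)
  pidx <- matrix(-1L, n_rx, 3L)
  pnames <- model$param_names
  for (j in seq_len(n_rx)) {
    r <- model$reactions[[j]]
    kind[j] <- .KIND_CODE[[r$kind]]
    sl <- .role_slots(r$kind)
    for (i in seq_along(sl))
      roles[j, i] <- match(r$roles[[sl[i]]], model$species) - 1L
    ps <- .param_slots(r$kind)
    for (i in seq_along(ps))
      pidx[j, i] <- match(r$params[[ps[i]]], pnames) - 1L
  }
  list(kind = kind, roles = roles, pidx = pidx, n_species = length(model$species))
}

#' Default parameter set
#'
#' Every rate/catalytic/Michaelis constant is initialised to 1 and every
#' dissociation constant (`*.kd`) to 1e-4 -- the starting point used for all
#' fits.
#'
#' @param model A `hif_model`.
#' @return Named numeric vector over `model$param_names`.
#' @export
default_params <- function(model) {
  stopifnot(inherits(model, "hif_model"))
  p <- stats::setNames(rep(1, length(model$param_names)), model$param_names)
  p[grepl("\\.kd$", names(p))] <- 1e-4
  p
}

.check_params <- function(model, params) {
  if (is.null(names(params))) stop("params must be a named vector")
  missing <- setdiff(model$param_names, names(params))
  if (length(missing))
    stop("missing parameter key(s): ", paste(missing, collapse = ", "))
  if (any(!is.finite(params[model$param_names])) ||
      any(params[model$param_names] < 0))
    stop("all parameters must be finite and non-negative")
  as.numeric(params[model$param_names])
}

.check_state <- function(model, state) {
  if (is.null(names(state))) stop("state must be a named vector")
  missing <- setdiff(model$species, names(state))
  if (length(missing))
    stop("missing species in state: ", paste(missing, collapse = ", "))
  s <- as.numeric(state[model$species])
  if (any(!is.finite(s)) || any(s < 0))
    stop("species concentrations must be finite and non-negative")
  names(s) <- model$species
  s
}

#' Initial conditions of the final model
#'
#' State at the onset of hypoxia: normoxic steady values are used directly
#' as initial conditions (no pre-equilibration). Free mRNAs, HIF1A protein,
#' PHD and Gene_mRNA start at their normoxic relative value 1; all
#' heterodimers and HIF-HRE complexes start at 0; the free HRE pools start
#' at the configured motif counts. `HIF2A_protein` defaults to 5.26, its
#' normoxic value on the HIF1A concentration scale (the ELISA scaling
#' constant m); set `hif2a_protein = 1` for unscaled (cytoplasmic-step)
#' work. The published initial-condition table also lists total-alpha
#' entries of 1; totals here are always derived from the state, never set.
#'
#' @param model A `hif_model`.
#' @param hif1b Initial free HIF1B concentration (default 60, the final
#'   model's value; 1 and 30 are the titration alternatives).
#' @param hif2a_protein Initial HIF2A_protein (default 5.26).
#' @param gene_mrna Initial target-gene mRNA (default 1).
#' @return Named numeric state vector over `hif_species()`.
#' @export
initial_state <- function(model, hif1b = 60, hif2a_protein = 5.26,
                          gene_mrna = 1) {
  stopifnot(inherits(model, "hif_model"))
  s <- stats::setNames(numeric(length(model$species)), model$species)
  s[c("HIF1A_mrna", "HIF2A_mrna", "HIF1A_protein", "PHD_protein")] <- 1
  s["HIF2A_protein"] <- hif2a_protein
  s["HIF1B"] <- hif1b
  s["Gene_mRNA"] <- gene_mrna
  s["HRE1"] <- model$hre1_total
  s["HRE2"] <- model$hre2_total
  .check_state(model, s)
}

#' Two-substrate Michaelis-Menten hydroxylation flux
#'
#' Rate of PHD-mediated, oxygen-dependent hydroxylation of a HIF alpha
#' subunit: `kcat * phd * hif/(km_hif + hif) * o2/(km_o2 + o2)`. The flux
#' consumes the alpha subunit only; PHD (enzyme) and O2 (boundary) are
#' unchanged. In the limit `km_o2 -> 0` with `o2 > 0` this reduces to
#' single-substrate Michaelis-Menten in the alpha subunit.
#'
#' @param hif_alpha,o2,phd Non-negative concentrations.
#' @param kcat Catalytic constant (per h).
#' @param km_hif,km_o2 Michaelis constants (> 0) for the two substrates.
#' @return Flux (concentration per h).
#' @export
mm_hydroxylation_flux <- function(hif_alpha, o2, phd, kcat, km_hif, km_o2) {
  if (any(c(hif_alpha, o2, phd, kcat) < 0)) stop("inputs must be non-negative")
  if (km_hif <= 0 || km_o2 <= 0) stop("Michaelis constants must be positive")
  kcat * phd * (hif_alpha / (km_hif + hif_alpha)) * (o2 / (km_o2 + o2))
}

#' Mass-action flux of a non-enzymatic reaction
#'
#' First-order decay: `k * [reactant]`; constant inflow: `k`; catalytic
#' production: `k * [modifier]`; reversible binding: forward
#' `k * [A] * [B]` and reverse `k * kd * [AB]`, so that at equilibrium
#' `[A][B]/[AB] = kd`.
#'
#' @param reaction A reaction from `build_default_model()$reactions`.
#' @param state Named state vector.
#' @param params Named parameter vector.
#' @return A single flux, or for reversible binding a named vector
#'   `c(forward=, reverse=)`.
#' @export
mass_action_flux <- function(reaction, state, params) {
  stopifnot(inherits(reaction, "hif_reaction"))
  if (reaction$kind == "mm_hydroxylation")
    stop("use mm_hydroxylation_flux() for hydroxylation reactions")
  need <- unname(reaction$params)
  miss <- setdiff(need, names(params))
  if (length(miss))
    stop("missing parameter key(s): ", paste(miss, collapse = ", "))
  k <- params[[reaction$params[["k"]]]]
  switch(reaction$kind,
    constant_inflow = k,
    first_order = k * state[[reaction$roles[["reactant"]]]],
    catalytic_production = k * state[[reaction$roles[["modifier"]]]],
    reversible_binding = {
      kd <- params[[reaction$params[["kd"]]]]
      c(forward = k * state[[reaction$roles[["a"]]]] *
                  state[[reaction$roles[["b"]]]],
        reverse = k * kd * state[[reaction$roles[["ab"]]]])
    })
}

#' Right-hand side of the ODE system
#'
#' Time-derivative of every dynamic species: the signed sum of
#' stoichiometry-weighted reaction fluxes. Free + bound HRE of each class
#' has exactly zero net derivative by construction.
#'
#' @param state Named state vector over `hif_species()`.
#' @param params Named parameter vector.
#' @param o2 Boundary oxygen level (relative units; 1 = 0.9\% O2 hypoxia).
#' @param model A `hif_model` (defaults to the *MIR210HG* network).
#' @return Named derivative vector.
#' @export
model_rhs <- function(state, params, o2, model = build_default_model(12, 18)) {
  s <- .check_state(model, state)
  p <- .check_params(model, params)
  if (length(o2) != 1L || !is.finite(o2) || o2 < 0)
    stop("o2 must be a single non-negative number")
  cm <- model$compiled
  d <- net_rhs_cpp(unname(s), p, o2, cm$kind, cm$roles, cm$pidx)
  stats::setNames(d, model$species)
}

#' Total alpha-subunit abundance
#'
#' Western blots cannot distinguish free alpha subunits from alpha bound in
#' heterodimers or on DNA, so observed protein is compared with the derived
#' totals: `hif1a_total = HIF1A_protein + HIF1AB + HIF1AB_HRE1 +
#' HIF1AB_HRE2`, and the HIF2A analogue.
#'
#' @param state Named state vector.
#' @return Named numeric `c(hif1a_total=, hif2a_total=)`.
#' @export
total_alpha <- function(state) {
  need <- c("HIF1A_protein", "HIF2A_protein", "HIF1AB", "HIF2AB",
            "HIF1AB_HRE1", "HIF2AB_HRE1", "HIF1AB_HRE2", "HIF2AB_HRE2")
  miss <- setdiff(need, names(state))
  if (length(miss)) stop("state lacks species: ", paste(miss, collapse = ", "))
  c(hif1a_total = unname(state[["HIF1A_protein"]] + state[["HIF1AB"]] +
                         state[["HIF1AB_HRE1"]] + state[["HIF1AB_HRE2"]]),
    hif2a_total = unname(state[["HIF2A_protein"]] + state[["HIF2AB"]] +
                         state[["HIF2AB_HRE1"]] + state[["HIF2AB_HRE2"]]))
}
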