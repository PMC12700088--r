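# Independent oracles used across the suite. These deliberately do not use
# the package's compiled kernels: the RHS oracle accumulates per-reaction
# fluxes in plain R from the reaction list, and the equilibrium oracle is
# the closed-form quadratic solution of an isolated binding reaction.

# Per-reaction accumulation of the time-derivative, in pure R.
oracle_rhs <- function(model, state, params, o2) {
  d <- stats::setNames(numeric(length(model$species)), model$species)
  for (r in model$reactions) {
    if (r$kind == "mm_hydroxylation") {
      hif <- state[[r$roles[["substrate"]]]]
      phd <- state[[r$roles[["enzyme"]]]]
      kcat <- params[[r$params[["kcat"]]]]
      km_h <- params[[r$params[["km_hif"]]]]
      km_o <- params[[r$params[["km_o2"]]]]
      f <- kcat * phd * (hif / (km_h + hif)) * (o2 / (km_o + o2))
      d[r$roles[["substrate"]]] <- d[r$roles[["substrate"]]] - f
    } else if (r$kind == "reversible_binding") {
      k <- params[[r$params[["k"]]]]
      kd <- params[[r$params[["kd"]]]]
      fwd <- k * state[[r$roles[["a"]]]] * state[[r$roles[["b"]]]]
      rev <- k * kd * state[[r$roles[["ab"]]]]
      net <- fwd - rev
      d[r$roles[["a"]]] <- d[r$roles[["a"]]] - net
      d[r$roles[["b"]]] <- d[r$roles[["b"]]] - net
      d[r$roles[["ab"]]] <- d[r$roles[["ab"]]] + net
    } else if (r$kind == "constant_inflow") {
      d[r$roles[["product"]]] <- d[r$roles[["product"]]] +
        params[[r$params[["k"]]]]
    } else if (r$kind == "first_order") {
      d[r$roles[["reactant"]]] <- d[r$roles[["reactant"]]] -
        params[[r$params[["k"]]]] * state[[r$roles[["reactant"]]]]
    } else if (r$kind == "catalytic_production") {
      d[r$roles[["product"]]] <- d[r$roles[["product"]]] +
        params[[r$params[["k"]]]] * state[[r$roles[["modifier"]]]]
    }
  }
  d
}

# Closed-form equilibrium complex concentration of A + B <-> AB given the
# conserved totals and the dissociation constant.
oracle_binding_equilibrium <- function(a_total, b_total, kd) {
  s <- a_total + b_total + kd
  (s - sqrt(s^2 - 4 * a_total * b_total)) / 2
}

# Random valid state on the model's species, positive.
random_state <- function(model, scale = 10) {
  s <- stats::runif(length(model$species), 0, scale)
  stats::setNames(s, model$species)
}

# Random positive parameter vector.
random_params <- function(model, scale = 2) {
  p <- stats::runif(length(model$param_names), 0.01, scale)
  stats::setNames(p, model$param_names)
}

# A tiny two-parameter world: a single isolated first-order decay, built by
# zeroing every other rate in the full network.
decay_only_params <- function(model, k) {
  p <- default_params(model)
  p[] <- 0
  p["hif1a_protein_out.k"] <- k
  p
}

table2 <- function() read_timeseries(hif_fixture("timeseries"))
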