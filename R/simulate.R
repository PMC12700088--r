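#' Observation time grid of the training data
#'
#' The 12 sampling times (hours) of the hypoxia time course used for model
#' fitting.
#'
#' @return Numeric vector `c(0, 2, 4, 6, 8, 10, 12, 16, 20, 24, 36, 48)`.
#' @export
obs_time_grid <- function() c(0, 2, 4, 6, 8, 10, 12, 16, 20, 24, 36, 48)

#' Oxygen protocol
#'
#' A piecewise-constant oxygen input: an ordered set of `(time, level)`
#' pairs, the level holding from each time until the next. Level 1 is the
#' 0.9\% O2 training hypoxia; `o2_level_from_percent()` maps other
#' percentages linearly onto that scale. The default protocol holds level 1
#' from t = 0 with normoxic initial conditions (the training experiment: no
#' pre-equilibration, normoxia enters only through the initial state).
#'
#' @param times Numeric, strictly increasing, first element <= 0.
#' @param levels Non-negative oxygen levels, same length as `times`.
#' @return Object of class `oxygen_protocol`.
#' @export
oxygen_protocol <- function(times = 0, levels = 1) {
  if (length(times) != length(levels) || length(times) < 1L)
    stop("times and levels must be equal-length, non-empty")
  if (any(diff(times) <= 0)) stop("protocol times must be strictly increasing")
  if (times[1] > 0) stop("first protocol time must be <= 0")
  if (any(levels < 0) || any(!is.finite(levels)))
    stop("oxygen levels must be finite and non-negative")
  structure(list(times = as.numeric(times), levels = as.numeric(levels)),
            class = "oxygen_protocol")
}

#' @rdname oxygen_protocol
#' @param percent Oxygen percentage (0.9 maps to level 1, 0.3 to 1/3).
#' @param ref_percent Percentage defining level 1 (default 0.9).
#' @export
o2_level_from_percent <- function(percent, ref_percent = 0.9) {
  if (any(percent < 0) || ref_percent <= 0) stop("invalid oxygen percentage")
  percent / ref_percent
}

#' Simulate the reaction network
#'
#' Integrates the ODE system under a piecewise-constant oxygen protocol and
#' returns the state at the requested times together with the derived
#' series: total HIF1A and HIF2A protein (free + heterodimer + DNA-bound),
#' free HRE pools, occupied HRE counts, and the target-gene fold change
#' over its 0 h value.
#'
#' Integration is adaptive with configurable relative/absolute tolerances
#' (defaults 1e-8/1e-10). `method = "auto"` (default) uses an explicit
#' Dormand-Prince 5(4) pair and falls back to an L-stable Rosenbrock 2(3)
#' when the problem is stiff; either method can be forced.
#'
#' @param model A `hif_model`.
#' @param params Named parameter vector (see [default_params()]).
#' @param init Named initial state (see [initial_state()]).
#' @param protocol An [oxygen_protocol()].
#' @param t_grid Output times in hours (default the training grid).
#' @param rtol,atol Integrator tolerances.
#' @param method `"auto"`, `"dp45"` or `"ros23"`.
#' @param max_steps Step budget per output interval.
#' @return A `hif_trajectory`: data.frame with column `time`, one column
#'   per species, and the derived columns `hif1a_total`, `hif2a_total`,
#'   `free_HRE1`, `free_HRE2`, `occupied_HRE1`, `occupied_HRE2`,
#'   `Gene_mRNA_fold`.
#' @export
simulate_model <- function(model, params, init = initial_state(model),
                           protocol = oxygen_protocol(),
                           t_grid = obs_time_grid(),
                           rtol = 1e-8, atol = 1e-10,
                           method = c("auto", "dp45", "ros23"),
                           max_steps = 5e6) {
  stopifnot(inherits(model, "hif_model"), inherits(protocol, "oxygen_protocol"))
  method <- match.arg(method)
  p <- .check_params(model, params)
  s0 <- .check_state(model, init)
  t_grid <- sort(unique(as.numeric(t_grid)))
  if (any(!is.finite(t_grid))) stop("t_grid must be finite")
  cm <- model$compiled
  res <- net_integrate_cpp(unname(s0), p, protocol$times, protocol$levels,
                           t_grid, cm$kind, cm$roles, cm$pidx,
                           rtol, atol, max_steps, method)
  if (res$status != 0) {
    last <- stats::setNames(res$last_state, model$species)
    stop("integration failed at t = ", signif(res$t_fail, 6),
         " h; last valid state: ",
         paste(sprintf("%s=%.3g", names(last), last), collapse = ", "))
  }
  y <- res$y
  colnames(y) <- model$species
  traj <- as.data.frame(y)
  traj <- cbind(time = t_grid, traj)
  traj$hif1a_total <- traj$HIF1A_protein + traj$HIF1AB +
    traj$HIF1AB_HRE1 + traj$HIF1AB_HRE2
  traj$hif2a_total <- traj$HIF2A_protein + traj$HIF2AB +
    traj$HIF2AB_HRE1 + traj$HIF2AB_HRE2
  traj$free_HRE1 <- traj$HRE1
  traj$free_HRE2 <- traj$HRE2
  traj$occupied_HRE1 <- model$hre1_total - traj$HRE1
  traj$occupied_HRE2 <- model$hre2_total - traj$HRE2
  g0 <- traj$Gene_mRNA[traj$time == min(traj$time)][1]
  traj$Gene_mRNA_fold <- if (g0 > 0) traj$Gene_mRNA / g0 else traj$Gene_mRNA
  structure(traj, class = c("hif_trajectory", "data.frame"),
            hre_totals = c(HRE1 = model$hre1_total, HRE2 = model$hre2_total))
}

#' HIF1B titration experiment
#'
#' Simulates the model for several initial free-HIF1B concentrations
#' (training values 1, 30, 60), returning one trajectory per level with
#' free-HRE and target-gene series for occupancy and induction comparison.
#' Parameters can be shared across levels (the per-gene prediction
#' protocol) or supplied per level (the per-level re-fit protocol).
#'
#' @param model A `hif_model`.
#' @param params_by_level Either a single named parameter vector shared by
#'   all levels, or a list of parameter vectors, one per level.
#' @param init Base initial state; its `HIF1B` entry is overwritten per
#'   level.
#' @param levels Positive initial HIF1B concentrations.
#' @param ... Passed to [simulate_model()].
#' @return Named list (one entry per level) of `hif_trajectory` objects;
#'   levels whose integration fails carry a `simpleError` instead.
#' @export
titrate_hif1b <- function(model, params_by_level, init = initial_state(model),
                          levels = c(1, 30, 60), ...) {
  if (any(levels < 0)) stop("HIF1B levels must be non-negative")
  per_level <- is.list(params_by_level) && !is.numeric(params_by_level)
  if (per_level && length(params_by_level) != length(levels))
    stop("need one parameter set per level")
  out <- vector("list", length(levels))
  names(out) <- as.character(levels)
  for (i in seq_along(levels)) {
    p <- if (per_level) params_by_level[[i]] else params_by_level
    s <- init
    s["HIF1B"] <- levels[i]
    out[[i]] <- tryCatch(simulate_model(model, p, init = s, ...),
                         error = function(e) e)
  }
  out
}

#' Predict target-gene induction from HRE motif counts
#'
#' Rebuilds the network with a gene's HRE1/HRE2 motif counts, re-simulates
#' under the fitted final-model parameters, and returns the predicted
#' Gene_mRNA fold change over 0 h at the observation times (default
#' 0/2/8/16 h, the microarray time points).
#'
#' @param model_params Fitted final-model parameter vector.
#' @param hre1,hre2 Non-negative integer motif counts for the gene.
#' @param hif1b_init Initial free HIF1B (1, 30 or 60 in the reported runs).
#' @param t_obs Observation times in hours.
#' @param ... Passed to [simulate_model()].
#' @return Named numeric vector of fold changes at `t_obs`.
#' @export
predict_gene <- function(model_params, hre1, hre2, hif1b_init = 60,
                         t_obs = c(0, 2, 8, 16), ...) {
  model <- build_default_model(hre1, hre2)
  init <- initial_state(model, hif1b = hif1b_init)
  grid <- sort(unique(c(0, t_obs)))
  traj <- simulate_model(model, model_params, init = init, t_grid = grid, ...)
  folds <- traj$Gene_mRNA_fold[match(t_obs, traj$time)]
  stats::setNames(folds, paste0(t_obs, "h"))
}
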