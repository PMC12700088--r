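#' Specification of a synthetic hypoxia time-course dataset
#'
#' Describes how to generate ground-truth-parameterized datasets with the
#' exact structure of the training table: the 12-point 0-48 h grid, the
#' eight columns, per-column normalization to the 0 h value, and the
#' blanked target-gene entries at the unmeasured times. Observation noise
#' is multiplicative log-normal (all observations are strictly positive
#' fold changes from densitometry/qPCR), default CV 0.10; ground-truth
#' parameters are the standard initial values (all rate constants 1, all
#' dissociation constants 1e-4) jittered by a log-normal factor.
#'
#' @param base_params Ground-truth base parameter vector (default
#'   [default_params()] of the *MIR210HG* model).
#' @param spread Geometric SD of the parameter jitter (>= 1; 1 = no
#'   jitter). Default 1.25: moderate (+/- ~25\%) rate-constant uncertainty.
#' @param grid Observation grid (must include 0 h).
#' @param cv Coefficient of variation of the multiplicative observation
#'   noise (>= 0).
#' @param seed Integer seed fixing all randomness (R's default
#'   Mersenne-Twister RNG).
#' @param columns Column names to emit (default: the eight training-table
#'   headers).
#' @param hif1b,hif2a_protein,hre1,hre2 World configuration: initial free
#'   HIF1B, initial scaled HIF2A, HRE motif counts.
#' @param blank_gene_times Times at which the target-gene column is
#'   blanked (NA), mirroring the unmeasured entries; set `numeric(0)` to
#'   keep all.
#' @return List of class `synthetic_spec`.
#' @export
synthetic_spec <- function(base_params = NULL, spread = 1.25,
                           grid = obs_time_grid(), cv = 0.10, seed = 1,
                           columns = NULL,
                           hif1b = 60, hif2a_protein = 5.26,
                           hre1 = 12, hre2 = 18,
                           blank_gene_times = c(4, 6, 10, 12, 20, 24, 36, 48)) {
  if (spread < 1) stop("spread must be >= 1")
  if (cv < 0) stop("cv must be >= 0")
  if (!0 %in% grid) stop("grid must include 0 h")
  model <- build_default_model(hre1, hre2)
  if (is.null(base_params)) base_params <- default_params(model)
  if (is.null(columns))
    columns <- c("HIF1A protein", "HIF2A protein", "HIF2A protein scaled",
                 "PHD protein", "HIF1A mRNA", "HIF2A mRNA", "MIR210HG mRNA")
  structure(list(base_params = base_params, spread = spread,
                 grid = sort(unique(grid)), cv = cv, seed = seed,
                 columns = columns, hif1b = hif1b,
                 hif2a_protein = hif2a_protein, hre1 = hre1, hre2 = hre2,
                 blank_gene_times = blank_gene_times, model = model),
            class = "synthetic_spec")
}

#' Draw a ground-truth parameter set
#'
#' Multiplies every base parameter by an independent log-normal factor with
#' geometric SD `spec$spread`; `spread = 1` returns the base set exactly.
#' Deterministic under `spec$seed`.
#'
#' @param spec A [synthetic_spec()].
#' @return Named parameter vector.
#' @export
sample_params <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  p <- spec$base_params
  if (spec$spread == 1) return(p)
  set.seed(spec$seed)
  p * exp(stats::rnorm(length(p), 0, log(spec$spread)))
}

#' Generate a synthetic training-table dataset
#'
#' Simulates the ground-truth model on the observation grid, applies
#' multiplicative log-normal noise to every post-normoxia measurement (the
#' 0 h entry defines the normalization and stays exact), renormalizes every
#' column to its 0 h value (so 0 h = 1 by construction; the scaled HIF2A
#' column is the renormalized relative series times the true scaling
#' constant m), and optionally blanks the target-gene column at the
#' unmeasured times. The noise-free truth is returned alongside.
#'
#' @param params Ground-truth parameter vector (e.g. from
#'   [sample_params()]).
#' @param spec A [synthetic_spec()].
#' @return List of class `synthetic_dataset`: `data` (noisy table in the
#'   training layout), `truth` (noise-free table), `trajectory` (full
#'   hidden `hif_trajectory`), `params`, `m` (true scaling constant),
#'   `spec`.
#' @export
generate_dataset <- function(params, spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  model <- spec$model
  init <- initial_state(model, hif1b = spec$hif1b,
                        hif2a_protein = spec$hif2a_protein)
  traj <- simulate_model(model, params, init = init, t_grid = spec$grid)
  m <- spec$hif2a_protein  # hif2a_total(0)/hif1a_total(0) in model units

  rel <- list(
    "HIF1A protein" = traj$hif1a_total / traj$hif1a_total[1],
    "HIF2A protein" = traj$hif2a_total / traj$hif2a_total[1],
    "PHD protein"   = traj$PHD_protein / traj$PHD_protein[1],
    "HIF1A mRNA"    = traj$HIF1A_mrna / traj$HIF1A_mrna[1],
    "HIF2A mRNA"    = traj$HIF2A_mrna / traj$HIF2A_mrna[1],
    "MIR210HG mRNA" = traj$Gene_mRNA_fold)

  noisy <- rel
  if (spec$cv > 0) {
    set.seed(spec$seed + 1L)
    sdlog <- sqrt(log(1 + spec$cv^2))
    post <- spec$grid > 0  # 0 h defines the normalization, left exact
    for (nm in names(noisy)) {
      v <- noisy[[nm]]
      v[post] <- v[post] * exp(stats::rnorm(sum(post), 0, sdlog))
      noisy[[nm]] <- v / v[1]  # renormalize to 0 h
    }
  }
  noisy[["HIF2A protein scaled"]] <- noisy[["HIF2A protein"]] * m
  rel[["HIF2A protein scaled"]] <- rel[["HIF2A protein"]] * m

  assemble <- function(series) {
    df <- data.frame(`time (hours)` = spec$grid, check.names = FALSE)
    for (cn in spec$columns) df[[cn]] <- series[[cn]]
    df
  }
  data <- assemble(noisy)
  truth <- assemble(rel)
  if ("MIR210HG mRNA" %in% names(data) && length(spec$blank_gene_times))
    data[["MIR210HG mRNA"]][data[["time (hours)"]] %in%
                              spec$blank_gene_times] <- NA_real_
  structure(list(data = data, truth = truth, trajectory = traj,
                 params = params, m = m, spec = spec),
            class = "synthetic_dataset")
}

#' Parameter-recovery experiment
#'
#' Generates synthetic data from jittered ground-truth parameters, runs the
#' two-step fit from the standard initial values, and reports the
#' proportional root-mean-square error between fitted and true
#' observation-grid trajectories plus per-parameter log2 ratios.
#'
#' @param spec A [synthetic_spec()].
#' @param cyto_config,nuclear_config Per-step [fit_config()]s.
#' @param replicates Number of independent replicates (seeds
#'   `spec$seed + 0:(replicates-1)`).
#' @return List of class `recovery_report`: per-replicate list with
#'   `seed`, `rmse` (proportional RMSE over all mapped full-model columns
#'   at the grid, fitted vs noise-free truth), `param_log2_ratio`, `fit`;
#'   plus `rmse` vector across replicates.
#' @export
recovery_experiment <- function(spec, cyto_config = fit_config(),
                                nuclear_config = fit_config(),
                                replicates = 1) {
  stopifnot(inherits(spec, "synthetic_spec"))
  reps <- vector("list", replicates)
  for (i in seq_len(replicates)) {
    sp <- spec
    sp$seed <- spec$seed + (i - 1L)
    truth_params <- sample_params(sp)
    ds <- generate_dataset(truth_params, sp)
    fit <- fit_two_step(ds$data, cyto_config = cyto_config,
                        nuclear_config = nuclear_config,
                        model = sp$model,
                        init = initial_state(sp$model, hif1b = sp$hif1b,
                                             hif2a_protein = sp$hif2a_protein))
    rmse <- trajectory_rmse(fit$params, ds$truth, sp)
    plr <- log2(fit$params / truth_params)
    reps[[i]] <- list(seed = sp$seed, rmse = rmse,
                      param_log2_ratio = plr, fit = fit)
  }
  structure(list(replicates = reps,
                 rmse = vapply(reps, `[[`, numeric(1), "rmse"),
                 spec = spec),
            class = "recovery_report")
}

#' Proportional RMSE of a fitted model against a truth table
#'
#' Simulates the full model under `params` on the truth table's grid and
#' returns the root mean square of `(predicted - truth)/truth` across all
#' full-model mapped columns and time points.
#'
#' @param params Fitted full-model parameter vector.
#' @param truth Noise-free truth table (training layout).
#' @param spec The [synthetic_spec()] that produced it.
#' @return Scalar RMSE (proportional units; 0.02 = 2\%).
#' @export
trajectory_rmse <- function(params, truth, spec) {
  model <- spec$model
  init <- initial_state(model, hif1b = spec$hif1b,
                        hif2a_protein = spec$hif2a_protein)
  r <- residuals_model(model, params, truth, observation_mapping("full"),
                       init = init, weighting = "proportional")
  sqrt(mean(r$residual^2))
}
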