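#' Observation-to-model mapping
#'
#' Maps the observed columns of a time-series table onto model output
#' series. For the full model the western-blot protein columns are compared
#' with the derived totals (free + bound alpha), HIF2A on the scaled
#' (common-concentration) scale; for the cytoplasmic first step there are
#' no heterodimers, so the free species are compared with the unscaled
#' columns.
#'
#' @param step `"full"` or `"cytoplasmic"`.
#' @return Named character vector: observed column -> trajectory column.
#' @export
observation_mapping <- function(step = c("full", "cytoplasmic")) {
  step <- match.arg(step)
  if (step == "full")
    c("HIF1A protein" = "hif1a_total",
      "HIF2A protein scaled" = "hif2a_total",
      "PHD protein" = "PHD_protein",
      "HIF1A mRNA" = "HIF1A_mrna",
      "HIF2A mRNA" = "HIF2A_mrna",
      "MIR210HG mRNA" = "Gene_mRNA")
  else
    c("HIF1A protein" = "HIF1A_protein",
      "HIF2A protein" = "HIF2A_protein",
      "PHD protein" = "PHD_protein",
      "HIF1A mRNA" = "HIF1A_mrna",
      "HIF2A mRNA" = "HIF2A_mrna")
}

#' Fitting configuration
#'
#' @param free Character vector of free parameter names, or NULL for the
#'   step's default free set.
#' @param lower,upper Box bounds on the natural (non-negative) scale.
#'   Optimization runs on log-parameters, so `lower` is clamped to 1e-12.
#' @param weighting `"proportional"` (residual `(pred-obs)/obs`; default --
#'   the observed species span ~0.1 to ~46 relative units, so unweighted
#'   residuals would be dominated by the protein columns) or `"absolute"`.
#' @param rtol,atol Integrator tolerances during fitting.
#' @param iter_max,eval_max Optimizer budgets (iterations; objective
#'   evaluations for the scalar fallback).
#' @param restarts Number of additional randomized starts (log-normal
#'   jitter, geometric SD `restart_spread`) beyond the deterministic
#'   default start.
#' @param restart_spread Geometric SD of restart jitter.
#' @param seed Integer seed for the restarts.
#' @param optimizer `"hybrid"` (default: bounded quasi-Newton on the
#'   scalar objective followed by a Levenberg-Marquardt polish on the
#'   residual vector -- the two stages escape different kinds of flat
#'   regions), `"lm"` (Levenberg-Marquardt only) or `"nlminb"`
#'   (quasi-Newton only).
#' @param method Integrator method during fitting.
#' @param max_steps Integrator step budget per output interval during
#'   fitting; pathological parameter sets fail fast and are penalized.
#' @return List of class `hif_fit_config`.
#' @export
fit_config <- function(free = NULL, lower = 0, upper = Inf,
                       weighting = c("proportional", "absolute"),
                       rtol = 1e-6, atol = 1e-9,
                       iter_max = 200, eval_max = 600,
                       restarts = 0, restart_spread = 1.5, seed = 1,
                       optimizer = c("hybrid", "lm", "nlminb"),
                       method = "auto", max_steps = 2e4) {
  structure(list(free = free, lower = lower, upper = upper,
                 weighting = match.arg(weighting), rtol = rtol, atol = atol,
                 iter_max = iter_max, eval_max = eval_max,
                 restarts = restarts, restart_spread = restart_spread,
                 seed = seed, optimizer = match.arg(optimizer),
                 method = method, max_steps = max_steps),
            class = "hif_fit_config")
}

## Levenberg-Marquardt with box projection on log-parameters.
## rfun(theta) returns the residual vector (finite everywhere; failures are
## mapped to a large constant by the caller).
.lm_least_squares <- function(rfun, theta0, lower, upper, iter_max = 100,
                              ftol = 1e-10, xtol = 1e-10) {
  clamp <- function(x) pmin(pmax(x, lower), upper)
  theta <- clamp(theta0)
  r <- rfun(theta)
  cost <- sum(r^2)
  lambda <- 1e-3
  npar <- length(theta)
  trace <- cost
  stall <- 0L
  for (it in seq_len(iter_max)) {
    ## forward-difference Jacobian of the residual vector
    J <- matrix(0, length(r), npar)
    ## absolute step on the log scale (~0.1% parameter change), well above
    ## the integrator's relative-tolerance noise floor
    hstep <- rep(1e-3, npar)
    for (j in seq_len(npar)) {
      tj <- theta
      tj[j] <- clamp_scalar(theta[j] + hstep[j], lower[j], upper[j])
      dj <- tj[j] - theta[j]
      if (dj == 0) { tj[j] <- theta[j] - hstep[j]; dj <- -hstep[j] }
      J[, j] <- (rfun(tj) - r) / dj
    }
    g <- crossprod(J, r)
    JtJ <- crossprod(J)
    improved <- FALSE
    for (k in 1:10) {
      A <- JtJ + lambda * diag(pmax(diag(JtJ), 1e-12), npar)
      step <- tryCatch(-solve(A, g), error = function(e) NULL)
      if (!is.null(step)) {
        cand <- clamp(theta + as.numeric(step))
        rc <- rfun(cand)
        cc <- sum(rc^2)
        if (is.finite(cc) && cc < cost) {
          rel <- (cost - cc) / max(cost, 1e-300)
          dx <- max(abs(cand - theta))
          theta <- cand; r <- rc; cost <- cc
          lambda <- max(lambda / 3, 1e-12)
          improved <- TRUE
          trace <- c(trace, cost)
          # convergence tests only count with a wide trust region: a tiny
          # step under heavy damping is caution, not arrival
          if ((rel < ftol || dx < xtol) && lambda <= 1e-3) {
            return(list(par = theta, objective = cost, convergence = 0L,
                        message = "converged (ftol/xtol)", trace = trace))
          }
          # three consecutive near-flat accepted steps with a wide trust
          # region (small lambda): treat as converged; large-lambda crawls
          # are not flat, just cautious
          stall <- if (rel < 1e-5 && lambda <= 1e-3) stall + 1L else 0L
          if (stall >= 3L)
            return(list(par = theta, objective = cost, convergence = 0L,
                        message = "converged (stalled)", trace = trace))
          break
        }
      }
      lambda <- lambda * 10
    }
    if (!improved)
      return(list(par = theta, objective = cost, convergence = 0L,
                  message = "converged (no descent direction)",
                  trace = trace))
  }
  list(par = theta, objective = cost, convergence = 1L,
       message = "iteration limit reached", trace = trace)
}

clamp_scalar <- function(x, lo, hi) min(max(x, lo), hi)

#' Residuals of a parameterized model against observed time series
#'
#' Simulates the model on the data's time grid and returns one residual per
#' (observed column, time point). Under the default proportional weighting
#' the residual is `(predicted - observed)/observed`; entries with observed
#' exactly 0 fall back to the absolute residual with a warning. Missing
#' observations (NA cells, e.g. the target-gene mRNA at unmeasured times)
#' are skipped.
#'
#' @param model A `hif_model`.
#' @param params Named parameter vector.
#' @param data Time-series data.frame (time column + observed columns).
#' @param mapping Named character vector, observed column -> trajectory
#'   column (see [observation_mapping()]).
#' @param init Initial state.
#' @param protocol Oxygen protocol.
#' @param weighting `"proportional"` or `"absolute"`.
#' @param ... Passed to [simulate_model()].
#' @return data.frame `column`, `time`, `observed`, `predicted`,
#'   `residual`.
#' @export
residuals_model <- function(model, params, data, mapping,
                            init = initial_state(model),
                            protocol = oxygen_protocol(),
                            weighting = c("proportional", "absolute"), ...) {
  weighting <- match.arg(weighting)
  tcol <- .time_column(data)
  times <- data[[tcol]]
  use <- names(mapping)[names(mapping) %in% names(data)]
  if (!length(use)) stop("no mapped column present in data")
  traj <- simulate_model(model, params, init = init, protocol = protocol,
                         t_grid = times, ...)
  idx <- match(times, traj$time)
  out <- list()
  for (col in use) {
    obs <- data[[col]]
    pred <- traj[[mapping[[col]]]][idx]
    keep <- !is.na(obs)
    obs <- obs[keep]; pred <- pred[keep]; tt <- times[keep]
    if (weighting == "proportional") {
      zero <- obs == 0
      if (any(zero))
        warning("observed value 0 in '", col,
                "': using absolute residual for those entries")
      r <- ifelse(zero, pred - obs, (pred - obs) / obs)
    } else {
      r <- pred - obs
    }
    out[[col]] <- data.frame(column = col, time = tt, observed = obs,
                             predicted = pred, residual = r)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

## Core bounded log-scale least-squares driver shared by both steps.
.fit_free <- function(model, data, mapping, init, protocol, params_full,
                      free, config) {
  stopifnot(all(free %in% names(params_full)))
  p_full <- params_full
  lower_nat <- max(config$lower, 1e-12)
  lo <- log(lower_nat)
  hi <- if (is.finite(config$upper)) log(config$upper) else Inf
  start <- log(pmax(p_full[free], lower_nat))

  n_res <- NULL
  resvec <- function(theta) {
    p <- p_full
    p[free] <- exp(theta)
    out <- tryCatch({
      r <- suppressWarnings(
        residuals_model(model, p, data, mapping, init = init,
                        protocol = protocol, weighting = config$weighting,
                        rtol = config$rtol, atol = config$atol,
                        method = config$method,
                        max_steps = config$max_steps))
      r$residual
    }, error = function(e) NULL)
    if (is.null(n_res) && !is.null(out)) n_res <<- length(out)
    if (is.null(out) || any(!is.finite(out)))
      out <- rep(1e5, if (is.null(n_res)) 1L else n_res)
    out
  }
  eval_log <- numeric(0)
  objective <- function(theta) {
    val <- sum(resvec(theta)^2)
    eval_log[length(eval_log) + 1L] <<- val
    val
  }

  starts <- list(start)
  if (config$restarts > 0) {
    set.seed(config$seed)
    for (i in seq_len(config$restarts))
      starts[[i + 1L]] <- start +
        stats::rnorm(length(start), 0, log(config$restart_spread))
  }
  best <- NULL
  provenance <- list()
  lo_v <- rep(lo, length(start))
  hi_v <- rep(hi, length(start))
  for (i in seq_along(starts)) {
    s <- pmin(pmax(starts[[i]], lo), if (is.finite(hi)) hi else starts[[i]])
    if (config$optimizer == "lm") {
      opt <- .lm_least_squares(resvec, s, lo_v, hi_v,
                               iter_max = config$iter_max)
      eval_log <- c(eval_log, opt$trace)
    } else if (config$optimizer == "nlminb") {
      opt <- stats::nlminb(s, objective, lower = lo, upper = hi,
                           control = list(iter.max = config$iter_max,
                                          eval.max = config$eval_max))
    } else {  # hybrid: quasi-Newton stage, then Levenberg-Marquardt polish
      st1 <- stats::nlminb(s, objective, lower = lo, upper = hi,
                           control = list(iter.max = config$iter_max,
                                          eval.max = config$eval_max))
      st2 <- .lm_least_squares(resvec, st1$par, lo_v, hi_v,
                               iter_max = max(20L, config$iter_max %/% 3L))
      eval_log <- c(eval_log, st2$trace)
      opt <- if (st2$objective <= st1$objective) st2 else st1
      opt$message <- paste0("nlminb ", signif(st1$objective, 6), " -> lm ",
                            signif(st2$objective, 6))
    }
    provenance[[i]] <- list(start_index = i, seed = config$seed,
                            start = stats::setNames(exp(s), free),
                            objective = opt$objective,
                            convergence = opt$convergence,
                            message = opt$message)
    if (is.null(best) || opt$objective < best$objective) best <- opt
  }

  p_fit <- p_full
  p_fit[free] <- exp(best$par)
  resid <- suppressWarnings(
    residuals_model(model, p_fit, data, mapping, init = init,
                    protocol = protocol, weighting = config$weighting,
                    rtol = config$rtol, atol = config$atol,
                    method = config$method, max_steps = config$max_steps))
  structure(list(
    params = p_fit,
    free = free,
    frozen = setdiff(names(p_full), free),
    loss = sum(resid$residual^2),
    residuals = resid,
    convergence = best$convergence == 0,
    message = best$message,
    objective_trace = cummin(eval_log),
    restarts = provenance,
    config = config
  ), class = "hif_fit")
}

#' @export
print.hif_fit <- function(x, ...) {
  cat("hif_fit: loss ", signif(x$loss, 6), ", ", length(x$free),
      " free / ", length(x$frozen), " frozen parameters, ",
      if (x$convergence) "converged" else "not converged", "\n", sep = "")
  invisible(x)
}

#' First fitting step: cytoplasmic sub-model
#'
#' Fits the cytoplasmic part of the model (mRNA inflow/outflow,
#' translation, free-protein outflow, oxygen/PHD hydroxylation, PHD
#' production and decay) to the unscaled relative time series, holding the
#' nuclear species out of the objective. All cytoplasmic rate constants
#' start at 1; there are no dissociation constants in this part.
#'
#' @param data Time-series data.frame containing at least the columns of
#'   `observation_mapping("cytoplasmic")`.
#' @param config A [fit_config()]; `config$free` defaults to all
#'   cytoplasmic parameters.
#' @param params0 Optional starting parameter vector (defaults to the
#'   standard initial values).
#' @param protocol Oxygen protocol (default: hypoxia level 1 from t = 0).
#' @return `hif_fit` result.
#' @export
fit_cytoplasmic <- function(data, config = fit_config(), params0 = NULL,
                            protocol = oxygen_protocol()) {
  model <- cytoplasmic_model(build_default_model(0, 0))
  mapping <- observation_mapping("cytoplasmic")
  need <- names(mapping)
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("data lacks column(s): ", paste(miss, collapse = ", "))
  params <- default_params(model)
  if (!is.null(params0)) params[names(params0)] <- params0
  free <- if (is.null(config$free)) model$param_names else config$free
  bad <- setdiff(free, model$param_names)
  if (length(bad))
    stop("not cytoplasmic parameter(s): ", paste(bad, collapse = ", "))
  init <- initial_state(model, hif1b = 0, hif2a_protein = 1)
  .fit_free(model, data, mapping, init, protocol, params, free, config)
}

#' Names of the parameters free in the second fitting step
#'
#' All nuclear-part reaction parameters (HIF1B inflow/outflow,
#' dimerization, HRE binding, transcription, target-gene basal turnover)
#' plus the three cytoplasmic reactions involving HIF2A:
#' `hif2a_mrna_to_protein`, `hif2a_protein_out`, `phd_to_hif2a_protein`.
#' The HIF2A cytoplasmic reactions are re-freed because the second step
#' works on the scaled HIF2A concentration axis.
#'
#' @param model A full `hif_model`.
#' @return Character vector of parameter names.
#' @export
nuclear_free_set <- function(model = build_default_model(12, 18)) {
  nuclear <- unlist(lapply(
    Filter(function(r) r$part == "nuclear", model$reactions),
    function(r) unname(r$params)))
  hif2a_cyto <- unlist(lapply(
    Filter(function(r) r$id %in% c("hif2a_mrna_to_protein",
                                   "hif2a_protein_out",
                                   "phd_to_hif2a_protein"),
           model$reactions),
    function(r) unname(r$params)))
  c(nuclear, hif2a_cyto)
}

#' Second fitting step: full model with frozen cytoplasmic parameters
#'
#' Fits the full model to the time series, using the scaled HIF2A column
#' and comparing the protein columns with the derived totals, starting
#' from the initial conditions of the final model. Only the nuclear-part
#' parameters and the three HIF2A-related cytoplasmic reactions are free;
#' every other cytoplasmic parameter is frozen bit-identically at its
#' first-step value.
#'
#' @param data Time-series data.frame with the full-model columns.
#' @param cyto_params Fitted parameter vector from [fit_cytoplasmic()] (or
#'   an `hif_fit`, whose `$params` is used).
#' @param config A [fit_config()]; `config$free` defaults to
#'   [nuclear_free_set()]. Attempting to free a frozen cytoplasmic
#'   parameter is a configuration error.
#' @param model Full model (default *MIR210HG*: HRE 12/18).
#' @param init Initial state (default [initial_state()] with HIF1B 60).
#' @param protocol Oxygen protocol.
#' @param params0 Optional start values for the free parameters (default:
#'   the standard initial values, rate constants 1 and kd 1e-4, as every
#'   reported fit used).
#' @return `hif_fit` result.
#' @export
fit_nuclear <- function(data, cyto_params, config = fit_config(),
                        model = build_default_model(12, 18),
                        init = initial_state(model),
                        protocol = oxygen_protocol(), params0 = NULL) {
  if (inherits(cyto_params, "hif_fit")) cyto_params <- cyto_params$params
  mapping <- observation_mapping("full")
  need <- c("HIF2A protein scaled", "MIR210HG mRNA")
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("data lacks column(s): ", paste(miss, collapse = ", "))
  allowed <- nuclear_free_set(model)
  free <- if (is.null(config$free)) allowed else config$free
  bad <- setdiff(free, allowed)
  if (length(bad))
    stop("attempt to free frozen cytoplasmic parameter(s): ",
         paste(bad, collapse = ", "))
  params <- default_params(model)
  keep <- intersect(names(cyto_params), names(params))
  params[keep] <- cyto_params[keep]
  ## free parameters restart from the standard initial values unless an
  ## explicit start is supplied
  params[free] <- default_params(model)[free]
  if (!is.null(params0)) {
    keep0 <- intersect(names(params0), free)
    params[keep0] <- params0[keep0]
  }
  .fit_free(model, data, mapping, init, protocol, params, free, config)
}

#' Two-step fit of the full model
#'
#' Runs [fit_cytoplasmic()] then [fit_nuclear()] and returns both results.
#'
#' @inheritParams fit_nuclear
#' @param cyto_config,nuclear_config Per-step [fit_config()]s.
#' @return List with `cytoplasmic` and `nuclear` `hif_fit` objects and the
#'   final `params`.
#' @export
fit_two_step <- function(data, cyto_config = fit_config(),
                         nuclear_config = fit_config(),
                         model = build_default_model(12, 18),
                         init = initial_state(model),
                         protocol = oxygen_protocol()) {
  cyto <- fit_cytoplasmic(data, config = cyto_config, protocol = protocol)
  nuc <- fit_nuclear(data, cyto, config = nuclear_config, model = model,
                     init = init, protocol = protocol)
  list(cytoplasmic = cyto, nuclear = nuc, params = nuc$params)
}
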