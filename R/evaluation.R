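#' Goodness-of-fit statistic for observed versus predicted induction
#'
#' `|log2(mean_t(observed_t / predicted_t))|`: the per-time-point ratio of
#' observed to predicted expression is averaged arithmetically over the
#' time points, then log2-transformed, then taken in absolute value --
#' exactly in that order. A value of 0 means the average ratio is 1; a
#' value of 1 means the observations are on average two-fold above (or
#' below) the predictions. When both series are normalized to 0 h, the
#' 0 h point contributes ratio 1 to the mean.
#'
#' The nesting is mean-of-ratios by default; `ratio_of_means = TRUE`
#' selects the alternative reading `|log2(mean(obs)/mean(pred))|`. The two
#' differ in general (the statistic is not symmetric in observed and
#' predicted for series of length > 1).
#'
#' @param observed,predicted Equal-length positive numeric vectors
#'   (predicted must be strictly positive).
#' @param ratio_of_means Use the ratio-of-means variant (default FALSE).
#' @return Non-negative scalar.
#' @examples
#' gof_metric(c(2, 2, 2, 2), c(1, 1, 1, 1))  # 1
#' @export
gof_metric <- function(observed, predicted, ratio_of_means = FALSE) {
  if (length(observed) != length(predicted) || length(observed) < 1L)
    stop("observed and predicted must be equal-length, non-empty")
  if (any(!is.finite(observed)) || any(!is.finite(predicted)))
    stop("series must be finite")
  if (any(predicted <= 0)) stop("predicted values must be > 0")
  if (any(observed < 0)) stop("observed values must be >= 0")
  r <- if (ratio_of_means) mean(observed) / mean(predicted)
       else mean(observed / predicted)
  abs(log2(r))
}

#' Combined scaled alpha-subunit concentration
#'
#' Element-wise sum of the HIF1A protein and scaled HIF2A protein columns
#' of a time-series table -- the total alpha-subunit pool competing for
#' HIF1B, on the common HIF1A concentration scale. In the training data it
#' reaches about 35 at 6 h and its maximum of about 41 at 10 h.
#'
#' @param data A time-series data.frame with a time column and the columns
#'   `HIF1A protein` and `HIF2A protein scaled`.
#' @return List with `time`, `combined` (numeric series), `t_max` (argmax
#'   time) and `max` (maximum combined value).
#' @export
combined_alpha_scaled <- function(data) {
  tcol <- .time_column(data)
  need <- c("HIF1A protein", "HIF2A protein scaled")
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("data lacks column(s): ", paste(miss, collapse = ", "))
  comb <- data[["HIF1A protein"]] + data[["HIF2A protein scaled"]]
  i <- which.max(comb)
  list(time = data[[tcol]], combined = comb,
       t_max = data[[tcol]][i], max = comb[i])
}

.time_column <- function(data) {
  cand <- intersect(c("time (hours)", "time"), names(data))
  if (!length(cand)) stop("no time column ('time (hours)' or 'time') found")
  cand[1]
}

#' Fold changes of a trajectory over its 0 h value
#'
#' `fold(t) = value(t) / value(0)` per species/series; series with a zero
#' 0 h value are reported as absolute values and flagged.
#'
#' @param traj A `hif_trajectory` (or any data.frame with a `time` column).
#' @param t_obs Times at which to report folds (must be in the grid).
#' @return data.frame: `time`, one column per series, plus an attribute
#'   `absolute_series` naming series reported unnormalized.
#' @export
fold_change_table <- function(traj, t_obs = NULL) {
  stopifnot(is.data.frame(traj), "time" %in% names(traj))
  if (!any(traj$time == 0)) stop("trajectory must include t = 0 h")
  if (is.null(t_obs)) t_obs <- traj$time
  idx <- match(t_obs, traj$time)
  if (any(is.na(idx)))
    stop("t_obs not in trajectory grid: ",
         paste(t_obs[is.na(idx)], collapse = ", "))
  cols <- setdiff(names(traj), "time")
  base <- as.numeric(traj[traj$time == 0, cols, drop = FALSE][1, ])
  absolute <- cols[base == 0]
  denom <- ifelse(base == 0, 1, base)
  out <- traj[idx, cols, drop = FALSE]
  out <- as.data.frame(Map(function(v, d) v / d, out, denom),
                       check.names = FALSE)
  out <- cbind(time = traj$time[idx], out)
  rownames(out) <- NULL
  attr(out, "absolute_series") <- absolute
  out
}

#' Observed-versus-predicted comparison records
#'
#' Builds the long-format comparison table and goodness-of-fit value for
#' one gene at one initial HIF1B concentration.
#'
#' @param gene Gene identifier.
#' @param hif1b_level Initial HIF1B concentration used in the simulation.
#' @param t_obs Observation times (h).
#' @param observed,predicted Fold-change series at `t_obs`.
#' @param ratio_of_means Passed to [gof_metric()].
#' @return List of class `gof_record` with fields `gene`, `hif1b_level`,
#'   `table` (long data.frame) and `gof`.
#' @export
gof_record <- function(gene, hif1b_level, t_obs, observed, predicted,
                       ratio_of_means = FALSE) {
  g <- gof_metric(observed, predicted, ratio_of_means = ratio_of_means)
  structure(list(
    gene = gene, hif1b_level = hif1b_level,
    table = data.frame(gene = gene, hif1b_level = hif1b_level,
                       time = t_obs, observed = observed,
                       predicted = predicted),
    gof = g), class = "gof_record")
}
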