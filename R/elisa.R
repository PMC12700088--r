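#' Absolute-to-relative concentration anchoring
#'
#' The western-blot time series are fold changes over normoxia; the ELISA
#' measurements are absolute (ng per mg total protein). One anchor time
#' point per alpha subunit links the two scales:
#' `k = absolute(anchor) / relative(anchor)`, in ng/mg per relative unit.
#' The training anchors are HIF1A at 2 h and HIF2A at 8 h, but any
#' (absolute, relative) pair may be supplied to examine robustness of the
#' scaling to anchor choice.
#'
#' @param absolute Absolute concentration at the anchor time (ng/mg).
#' @param relative Relative (fold over 0 h) concentration at the same time;
#'   must be > 0.
#' @return The anchor ratio k (ng/mg per relative unit).
#' @examples
#' compute_ratio_k(0.546, 4.6080)   # k1, HIF1A anchored at 2 h
#' compute_ratio_k(3.468, 5.5638)   # k2, HIF2A anchored at 8 h
#' @export
compute_ratio_k <- function(absolute, relative) {
  if (any(relative <= 0)) stop("relative concentration must be > 0")
  if (any(absolute < 0)) stop("absolute concentration must be >= 0")
  absolute / relative
}

#' Scaling constant m between the two alpha-subunit scales
#'
#' `m = k2 / k1`. Because relative values at 0 h are 1 by normalization,
#' m equals the ratio of the absolute normoxic HIF2A to the absolute
#' normoxic HIF1A concentration; the training data give m = 5.26.
#' Multiplying HIF2A's relative series by m puts it on the HIF1A
#' concentration scale, so the two subunits can compete realistically for
#' HIF1B and HREs in the model.
#'
#' @param k1 HIF1A anchor ratio (> 0).
#' @param k2 HIF2A anchor ratio.
#' @return m (dimensionless).
#' @export
compute_scaling_constant <- function(k1, k2) {
  if (any(k1 <= 0)) stop("k1 must be > 0")
  if (any(k2 < 0)) stop("k2 must be >= 0")
  k2 / k1
}

#' Scale a relative series by the constant m
#'
#' Element-wise product: `scaled(t) = relative(t) * m`.
#'
#' @param relative_series Numeric vector of fold changes.
#' @param m Positive scaling constant.
#' @return Scaled series.
#' @export
scale_series <- function(relative_series, m) {
  if (length(m) != 1L || m <= 0) stop("m must be a single positive number")
  relative_series * m
}

#' Back-infer an absolute concentration from a relative value
#'
#' `absolute = relative * k`; used e.g. to recover the credible normoxic
#' HIF2A concentration (0.62 ng/mg) from the 8 h anchor when the direct
#' normoxic ELISA reading is below the assay's reliable range.
#'
#' @param relative Fold change over 0 h.
#' @param k Anchor ratio (> 0).
#' @return Absolute concentration (ng/mg).
#' @export
back_infer_absolute <- function(relative, k) {
  if (any(k <= 0)) stop("k must be > 0")
  relative * k
}

#' Full scaling constants from anchor measurements
#'
#' Convenience wrapper computing k1, k2 and m in one call.
#'
#' @param hif1a_absolute,hif1a_relative HIF1A anchor pair (default: 2 h).
#' @param hif2a_absolute,hif2a_relative HIF2A anchor pair (default: 8 h).
#' @return List with `k1`, `k2`, `m`.
#' @export
scaling_constants <- function(hif1a_absolute, hif1a_relative,
                              hif2a_absolute, hif2a_relative) {
  k1 <- compute_ratio_k(hif1a_absolute, hif1a_relative)
  k2 <- compute_ratio_k(hif2a_absolute, hif2a_relative)
  list(k1 = k1, k2 = k2, m = compute_scaling_constant(k1, k2))
}
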