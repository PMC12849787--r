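clamp_p <- function(p) pmin(pmax(p, 1e-7), 1 - 1e-7)

#' Binary cross-entropy loss
#'
#' `-log(p)` for seizure samples (`y = 1`) and `-log(1 - p)` for non-seizure
#' samples (`y = 0`), with `p` clamped to `[1e-7, 1 - 1e-7]`. Vectorized.
#'
#' @param p predicted positive-class (seizure) probability.
#' @param y true label, 0 or 1.
#' @return per-sample loss (same length as `p`).
#' @export
cross_entropy <- function(p, y) {
  p <- clamp_p(p)
  ifelse(y == 1, -log(p), -log(1 - p))
}

#' Focal loss
#'
#' Cross-entropy reweighted so well-classified samples contribute less:
#' `-alpha * (1 - p)^gamma * log(p)` when `y = 1` and
#' `-(1 - alpha) * p^gamma * log(1 - p)` when `y = 0`. At `gamma = 0` and
#' `alpha = 0.5` this is exactly half the cross-entropy; `gamma > 0` shrinks
#' the loss of easy samples, and `alpha` balances the two classes.
#'
#' @param p predicted positive-class probability.
#' @param y true label, 0 or 1.
#' @param alpha class-balance weight in (0, 1) (default 0.25).
#' @param gamma focusing exponent >= 0 (default 2).
#' @return per-sample loss (same length as `p`); use `mean()` for batch loss.
#' @export
focal_loss <- function(p, y, alpha = 0.25, gamma = 2) {
  if (any(gamma < 0))
    gf_stop("gatformer_parameter_error", "gamma must be >= 0")
  if (any(alpha <= 0) || any(alpha >= 1))
    gf_stop("gatformer_parameter_error", "alpha must be in (0, 1)")
  p <- clamp_p(p)
  ifelse(y == 1,
         -alpha * (1 - p)^gamma * log(p),
         -(1 - alpha) * p^gamma * log(1 - p))
}
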