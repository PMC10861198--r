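# Axial (orientation, mod 180 degrees) circular statistics.
#
# A fiber or a nuclear long axis has no head or tail, so its angle lives on
# a circle of circumference 180 degrees. All statistics here use the
# standard doubled-angle embedding: theta -> 2*theta on the ordinary circle.

#' Wrap angles to the axial range (-90, 90] degrees
#'
#' @param angle numeric vector of angles in degrees.
#' @return angles wrapped modulo 180 into (-90, 90].
#' @export
#' @examples
#' wrap_axial(c(170, -95, 90, 180))
wrap_axial <- function(angle) {
  w <- angle %% 180
  w[w > 90] <- w[w > 90] - 180
  w
}

#' Axial angular difference between two orientations
#'
#' The distance on the axial circle: `min(|a - b|, 180 - |a - b|)`,
#' always in `[0, 90]` degrees.
#'
#' @param a,b angles in degrees (recycled).
#' @return difference in degrees in `[0, 90]`.
#' @export
#' @examples
#' axial_diff(10, 170) # 20: the axes are 20 degrees apart
axial_diff <- function(a, b) {
  d <- abs(a - b) %% 180
  pmin(d, 180 - d)
}

#' Axial circular mean and resultant length
#'
#' Weighted mean direction of axial angles via the doubled-angle transform.
#'
#' @param angle angles in degrees.
#' @param w optional non-negative weights.
#' @return list with `mean` (degrees in (-90, 90]) and `rbar` (mean
#'   resultant length of the doubled angles, in `[0, 1]`).
#' @export
axial_mean <- function(angle, w = NULL) {
  if (length(angle) == 0L) stop("no angles supplied")
  if (is.null(w)) w <- rep(1, length(angle))
  if (any(w < 0)) stop("weights must be non-negative")
  sw <- sum(w)
  if (sw <= 0) stop("weights sum to zero")
  th <- angle * pi / 90 # doubled angle in radians
  C <- sum(w * cos(th)) / sw
  S <- sum(w * sin(th)) / sw
  list(mean = wrap_axial(atan2(S, C) * 90 / pi),
       rbar = sqrt(C^2 + S^2))
}

#' Axial circular spread (histogram width) in degrees
#'
#' Circular standard deviation of axial angles,
#' `width = (90 / pi) * sqrt(-2 * log(Rbar))`, capped at the uniform-limit
#' maximum `(90 / pi) * sqrt(2) = 40.514` degrees so that uniformly
#' distributed axes report a finite, maximal width.
#'
#' @inheritParams axial_mean
#' @return width in degrees in `[0, 40.514]`.
#' @export
axial_width <- function(angle, w = NULL) {
  rbar <- axial_mean(angle, w)$rbar
  v <- if (rbar <= 0) 2 else min(-2 * log(rbar), 2)
  (90 / pi) * sqrt(v)
}

#' Mean pairwise axial angular difference
#'
#' Mean of [axial_diff()] over all unordered pairs; `NA` for fewer than two
#' angles. Under uniform axial orientations the expectation is 45 degrees.
#'
#' @param angle angles in degrees.
#' @return mean pairwise difference in degrees, in `[0, 90]`.
#' @export
mean_pairwise_axial_diff <- function(angle) {
  n <- length(angle)
  if (n < 2L) return(NA_real_)
  d <- outer(angle, angle, axial_diff)
  mean(d[upper.tri(d)])
}
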