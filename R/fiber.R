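# Structure-tensor fiber-orientation analysis for ECM channels.
#
# For every pixel, the structure tensor is the Gaussian-windowed outer
# product of the image gradient (Gaussian-derivative filters at 1 px):
# J_xx = <f_x^2>, J_xy = <f_x f_y>,
# J_yy = <f_y^2>. Its eigen-decomposition gives the dominant gradient
# direction phi = 0.5 * atan2(2 J_xy, J_xx - J_yy); the fiber (isophote)
# direction reported here is theta = phi + 90 wrapped to (-90, 90], so
# that hue maps encode fiber alignment, not gradient direction.
# Coherency = (l_max - l_min) / (l_max + l_min) in [0, 1] (0 where the
# tensor trace vanishes); energy = trace = J_xx + J_yy.

#' Compute a structure-tensor orientation field
#'
#' @param image 2-D intensity matrix, at least 8 x 8 pixels.
#' @param sigma Gaussian analysis-window scale in micrometres.
#' @param pixel_size um per pixel.
#' @return object of class `orientation_field`: list of matrices `theta`
#'   (fiber direction, degrees axial in (-90, 90], counterclockwise from
#'   +x with y up), `coherency` in `[0, 1]`, `energy` (tensor trace, >= 0),
#'   plus `sigma` and `pixel_size`. Borders use reflected padding.
#' @export
compute_orientation_field <- function(image, sigma = 2, pixel_size = 1) {
  stopifnot(is.matrix(image), nrow(image) >= 8L, ncol(image) >= 8L)
  assert_scalar_num(sigma, "sigma", min = 0, strict_min = TRUE)
  assert_scalar_num(pixel_size, "pixel_size", min = 0, strict_min = TRUE)
  # Gaussian-derivative gradients (scale 1 px): direction-unbiased, unlike
  # plain centered differences. y points up.
  gr <- gaussian_gradient(image, sigma_d = 1)
  fx <- gr$fx; fy <- gr$fy
  s_px <- sigma / pixel_size
  jxx <- gaussian_blur(fx * fx, s_px)
  jxy <- gaussian_blur(fx * fy, s_px)
  jyy <- gaussian_blur(fy * fy, s_px)
  energy <- jxx + jyy
  # numerically-zero gradients (constant image) clamp to exactly 0
  tol <- max(1e-30, (1e-10 * diff(range(image)))^2)
  energy[energy < tol] <- 0
  disc <- sqrt(pmax((jxx - jyy)^2 + 4 * jxy^2, 0))
  coherency <- ifelse(energy > .Machine$double.eps, disc / energy, 0)
  coherency <- pmin(pmax(coherency, 0), 1)
  phi <- 0.5 * atan2(2 * jxy, jxx - jyy) * 180 / pi
  theta <- wrap_axial(phi + 90)
  structure(list(theta = theta, coherency = coherency, energy = energy,
                 sigma = sigma, pixel_size = pixel_size),
            class = "orientation_field")
}

#' Axial orientation histogram of a fiber field
#'
#' Orientations are re-expressed relative to `reference_angle` (e.g. the
#' wound axis), wrapped axially, histogrammed over (-90, 90], and
#' summarized by the axial circular mean and width (circular SD via the
#' doubled-angle transform, capped at the 40.514-degree uniform limit).
#'
#' @param field an `orientation_field`, or a numeric vector of axial
#'   angles in degrees.
#' @param reference_angle reference axis in degrees (default 0: absolute
#'   angles).
#' @param n_bins number of histogram bins (>= 4).
#' @param weight per-pixel weighting: `"coherency*energy"` (default;
#'   suppresses isotropic background), `"energy"`, or `"none"`.
#' @param mask optional logical matrix restricting the analysis to an ROI.
#' @return object of class `orientation_histogram`: data.frame-like list
#'   with `bin_left`, `bin_right`, `weight` (per-bin totals), and scalars
#'   `mean` (degrees), `width` (degrees), `rbar`, `n`.
#' @export
orientation_histogram <- function(field, reference_angle = 0, n_bins = 36L,
                                  weight = c("coherency*energy", "energy",
                                             "none"),
                                  mask = NULL) {
  weight <- match.arg(weight)
  stopifnot(n_bins >= 4L)
  if (inherits(field, "orientation_field")) {
    th <- field$theta
    w <- switch(weight,
                "none" = rep(1, length(th)),
                "energy" = as.vector(field$energy),
                "coherency*energy" = as.vector(field$coherency *
                                               field$energy))
    th <- as.vector(th)
    if (!is.null(mask)) {
      stopifnot(is.logical(mask), length(mask) == length(th))
      if (!any(mask)) stop("empty mask")
      th <- th[as.vector(mask)]; w <- w[as.vector(mask)]
    }
  } else {
    th <- as.numeric(field)
    w <- rep(1, length(th))
    if (!is.null(mask)) {
      if (!any(mask)) stop("empty mask")
      th <- th[mask]; w <- w[mask]
    }
  }
  rel <- wrap_axial(th - reference_angle)
  edges <- seq(-90, 90, length.out = n_bins + 1L)
  # bins are (left, right]; -90 itself cannot occur after wrap_axial
  bin <- pmin(n_bins, pmax(1L, ceiling((rel + 90) / (180 / n_bins))))
  wt <- vapply(seq_len(n_bins), function(b) sum(w[bin == b]), 0)
  am <- axial_mean(rel, w)
  structure(list(bin_left = edges[-length(edges)], bin_right = edges[-1L],
                 weight = wt, mean = am$mean, rbar = am$rbar,
                 width = axial_width(rel, w), n = length(rel),
                 reference_angle = reference_angle),
            class = "orientation_histogram")
}

# Vectorized HSV -> RGB (h, s, v in [0, 1]); returns list(r, g, b).
hsv_to_rgb <- function(h, s, v) {
  h6 <- (h %% 1) * 6
  i <- floor(h6) %% 6
  f <- h6 - floor(h6)
  p <- v * (1 - s); q <- v * (1 - f * s); t <- v * (1 - (1 - f) * s)
  r <- ifelse(i == 0, v, ifelse(i == 1, q, ifelse(i == 2, p,
       ifelse(i == 3, p, ifelse(i == 4, t, v)))))
  g <- ifelse(i == 0, t, ifelse(i == 1, v, ifelse(i == 2, v,
       ifelse(i == 3, q, ifelse(i == 4, p, p)))))
  b <- ifelse(i == 0, p, ifelse(i == 1, p, ifelse(i == 2, t,
       ifelse(i == 3, v, ifelse(i == 4, v, q)))))
  list(r = r, g = g, b = b)
}

#' Render an HSB orientation map
#'
#' Hue encodes the local fiber orientation (`(theta + 90) / 180` of the
#' color wheel), saturation the coherency, and brightness the min-max
#' scaled input image; a corner orientation color wheel is inset as a
#' legend.
#'
#' @param field an `orientation_field`.
#' @param input_image the intensity image the field was computed from
#'   (same shape).
#' @param legend if `TRUE`, draw the orientation color wheel in the
#'   bottom-right corner.
#' @return an `nrow x ncol x 3` RGB array with values in `[0, 1]`.
#' @export
render_hsb_map <- function(field, input_image, legend = TRUE) {
  stopifnot(inherits(field, "orientation_field"),
            all(dim(input_image) == dim(field$theta)))
  h <- (field$theta + 90) / 180
  s <- field$coherency
  v <- matrix(minmax01(as.vector(input_image)), nrow(input_image))
  rgb <- hsv_to_rgb(h, s, v)
  out <- array(0, c(nrow(input_image), ncol(input_image), 3L))
  out[, , 1] <- rgb$r; out[, , 2] <- rgb$g; out[, , 3] <- rgb$b
  if (legend) {
    rad <- max(4L, round(min(dim(input_image)) / 10))
    cr <- nrow(out) - rad - 1L; cc <- ncol(out) - rad - 1L
    for (dr in -rad:rad) for (dc in -rad:rad) {
      rr <- dr^2 + dc^2
      if (rr > rad^2) next
      ang <- wrap_axial(atan2(-dr, dc) * 180 / pi) # y up
      px <- hsv_to_rgb((ang + 90) / 180, 1, 1)
      out[cr + dr, cc + dc, ] <- c(px$r, px$g, px$b)
    }
  }
  out
}

#' Write an RGB array as PNG (if the graphics device is available)
#'
#' @param rgb an `nr x nc x 3` array in `[0, 1]`.
#' @param path output path.
#' @return `path` invisibly, or `NULL` with a message when no PNG device
#'   is available in this R build.
#' @export
write_png_map <- function(rgb, path) {
  if (!capabilities("png")) {
    msg("PNG device unavailable; skipped %s", path)
    return(invisible(NULL))
  }
  grDevices::png(path, width = dim(rgb)[2], height = dim(rgb)[1])
  op <- graphics::par(mar = c(0, 0, 0, 0))
  on.exit({ graphics::par(op); grDevices::dev.off() })
  graphics::plot.new()
  graphics::rasterImage(rgb, 0, 0, 1, 1, interpolate = FALSE)
  invisible(path)
}

#' Write an orientation field as a 3-plane 32-bit float TIFF
#'
#' Planes: theta (degrees), coherency, energy.
#'
#' @param field an `orientation_field`.
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_orientation_field <- function(field, path) {
  stopifnot(inherits(field, "orientation_field"))
  write_tiff(list(field$theta, field$coherency, field$energy), path,
             bits = 32L)
  invisible(path)
}

#' Write an orientation histogram as CSV (bin_left, bin_right, weight)
#'
#' @param hist an `orientation_histogram`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_orientation_histogram <- function(hist, path) {
  stopifnot(inherits(hist, "orientation_histogram"))
  write.csv(data.frame(bin_left = hist$bin_left,
                       bin_right = hist$bin_right,
                       weight = hist$weight), path, row.names = FALSE)
  invisible(path)
}
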