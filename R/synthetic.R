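# Synthetic tissue scenes with known ground truth.
#
# Nuclei are textured ellipses: a base ellipse whose boundary radius is
# perturbed by a low-order Fourier series, filled with
# base * (1 + texture_contrast * band-passed noise at the chromatin blob
# scale), on a constant background with Gaussian read noise. Fiber images
# are additively superposed oriented line segments. Both expose their
# ground truth so downstream stages can be tested without external data.

#' Parameters of one synthetic nucleus population
#'
#' @param mean_area mean nuclear area, um^2.
#' @param area_cv coefficient of variation of area (lognormal).
#' @param mean_aspect_ratio mean major/minor axis ratio (>= 1).
#' @param texture_granularity chromatin blob length scale, um.
#' @param texture_contrast relative amplitude of the chromatin texture,
#'   in `[0, 1]`.
#' @param boundary_irregularity relative amplitude of the low-order Fourier
#'   boundary perturbation (>= 0; 0 gives a smooth ellipse).
#' @param orientation_concentration axial concentration of nuclear long
#'   axes: the reciprocal of the axial angular SD in radians (0 = uniform).
#' @param mean_intensity mean nuclear stain level, arbitrary units.
#' @return an object of class `population_params`.
#' @export
population_params <- function(mean_area = 60, area_cv = 0.2,
                              mean_aspect_ratio = 1.5,
                              texture_granularity = 1,
                              texture_contrast = 0.3,
                              boundary_irregularity = 0.05,
                              orientation_concentration = 0,
                              mean_intensity = 2000) {
  assert_scalar_num(mean_area, "mean_area", min = 0, strict_min = TRUE)
  assert_scalar_num(area_cv, "area_cv", min = 0)
  assert_scalar_num(mean_aspect_ratio, "mean_aspect_ratio", min = 1)
  assert_scalar_num(texture_granularity, "texture_granularity", min = 0,
                    strict_min = TRUE)
  assert_scalar_num(texture_contrast, "texture_contrast", min = 0, max = 1)
  assert_scalar_num(boundary_irregularity, "boundary_irregularity", min = 0)
  assert_scalar_num(orientation_concentration, "orientation_concentration",
                    min = 0)
  assert_scalar_num(mean_intensity, "mean_intensity", min = 0,
                    strict_min = TRUE)
  structure(list(mean_area = mean_area, area_cv = area_cv,
                 mean_aspect_ratio = mean_aspect_ratio,
                 texture_granularity = texture_granularity,
                 texture_contrast = texture_contrast,
                 boundary_irregularity = boundary_irregularity,
                 orientation_concentration = orientation_concentration,
                 mean_intensity = mean_intensity),
            class = "population_params")
}

# Sample axial angles (degrees) with a wrapped-normal doubled-angle model:
# concentration = 1 / (axial SD in radians); 0 means uniform.
sample_axial <- function(n, mean_angle, concentration) {
  if (concentration <= 0) return(wrap_axial(runif(n, -90, 90)))
  sd_deg <- (1 / concentration) * 180 / pi
  wrap_axial(mean_angle + rnorm(n, 0, sd_deg))
}

#' Generate an isotropic Gaussian point pattern
#'
#' Points are drawn from an isotropic bivariate normal with standard
#' deviation `dispersion` about the origin; the pattern is used as a
#' stand-in for implanted-cell centroid clouds.
#'
#' @param n number of points (>= 2).
#' @param dispersion per-axis SD in micrometres (>= 0).
#' @param seed integer seed.
#' @return data.frame with columns `id`, `x_um`, `y_um`.
#' @export
generate_point_pattern <- function(n, dispersion, seed) {
  stopifnot(n >= 2)
  assert_scalar_num(dispersion, "dispersion", min = 0)
  with_seed(seed, {
    z <- matrix(rnorm(2 * n), ncol = 2)
    data.frame(id = seq_len(n),
               x_um = dispersion * z[, 1],
               y_um = dispersion * z[, 2])
  })
}

#' Generate a synthetic fiber-texture image
#'
#' Renders additively superposed straight line segments whose axial angles
#' follow a wrapped-normal distribution with the stated mean and
#' concentration (`concentration = 0` gives uniform axial angles). Used as
#' a stand-in for collagen-fiber immunofluorescence.
#'
#' @param mean_angle axial mean fiber direction, degrees in (-90, 90],
#'   counterclockwise from +x.
#' @param concentration reciprocal axial angular SD in radians (>= 0).
#' @param image_size image side length, pixels.
#' @param seed integer seed.
#' @param n_segments number of segments; default scales with image area.
#' @param segment_length mean segment length, pixels.
#' @param noise_sd SD of additive Gaussian background noise (image units).
#' @return list of class `fiber_field_sim` with elements `image`
#'   (image_size x image_size matrix), `angles` (ground-truth segment
#'   angles, degrees axial), `mean_angle`, `concentration`, `seed`.
#' @export
generate_fiber_field <- function(mean_angle, concentration, image_size,
                                 seed, n_segments = NULL,
                                 segment_length = image_size / 8,
                                 noise_sd = 0) {
  if (!(mean_angle > -90 && mean_angle <= 90))
    stop("mean_angle must lie in (-90, 90]")
  assert_scalar_num(concentration, "concentration", min = 0)
  stopifnot(image_size >= 16)
  if (is.null(n_segments)) n_segments <- max(50L, round(image_size^2 / 800))
  with_seed(seed, {
    angles <- sample_axial(n_segments, mean_angle, concentration)
    cx <- runif(n_segments, 1, image_size)
    cy <- runif(n_segments, 1, image_size)
    len <- runif(n_segments, 0.5, 1) * segment_length
    amp <- runif(n_segments, 0.5, 1)
    img <- matrix(0, image_size, image_size)
    for (i in seq_len(n_segments)) {
      # y-up convention: moving along +angle decreases the row index
      npts <- max(2L, ceiling(len[i] * 2))
      t <- seq(-len[i] / 2, len[i] / 2, length.out = npts)
      px <- cx[i] + t * cos(angles[i] * pi / 180)
      py <- cy[i] + t * sin(angles[i] * pi / 180)
      col <- round(px); row <- round(image_size - py + 1)
      ok <- col >= 1 & col <= image_size & row >= 1 & row <= image_size
      if (!any(ok)) next
      idx <- cbind(row[ok], col[ok])
      img[idx] <- img[idx] + amp[i] / 2
    }
    img <- gaussian_blur(img, 1)
    if (noise_sd > 0) img <- img + rnorm(length(img), 0, noise_sd)
    structure(list(image = img, angles = angles, mean_angle = mean_angle,
                   concentration = concentration, seed = seed),
              class = "fiber_field_sim")
  })
}

# Band-passed texture field for one nucleus bounding box: unit-SD smooth
# noise at the requested granularity (pixels).
texture_field <- function(nr, nc, granularity_px) {
  noise <- matrix(rnorm(nr * nc), nr, nc)
  t <- gaussian_blur(noise, max(granularity_px, 0.5))
  s <- sd(t)
  if (s > 0) t / s else t
}

#' Generate a two-population synthetic nuclei scene
#'
#' Places `2 * n_per_pop` non-overlapping textured-ellipse nuclei (one half
#' per population) at positions drawn from an isotropic Gaussian of SD
#' `dispersion` about the image centre, renders a 16-bit-range nuclear
#' stain image with constant background and Gaussian read noise, and
#' returns the ground truth needed to validate every downstream stage.
#'
#' @param params_a,params_b [population_params()] for populations "A"/"B".
#' @param n_per_pop nuclei per population (>= 1).
#' @param dispersion placement SD about the image centre, um.
#' @param image_size image side, pixels.
#' @param pixel_size um per pixel.
#' @param seed integer seed; identical inputs and seed give identical scenes.
#' @param background constant background level, arbitrary units.
#' @param snr (foreground - background) / read-noise SD; `Inf` for noiseless.
#' @return object of class `synthetic_scene`: list with `image`, `labels`
#'   (integer ground-truth label matrix), `truth` (data.frame: id, pop,
#'   x_um, y_um, area_um2, aspect_ratio, orientation_deg), `pixel_size`,
#'   `params`, `seed`.
#' @export
generate_nuclei_scene <- function(params_a, params_b, n_per_pop, dispersion,
                                  image_size = 512, pixel_size = 0.5, seed = 1,
                                  background = 200, snr = 10) {
  stopifnot(inherits(params_a, "population_params"),
            inherits(params_b, "population_params"), n_per_pop >= 1)
  assert_scalar_num(dispersion, "dispersion", min = 0)
  n <- 2L * as.integer(n_per_pop)
  pops <- rep(c("A", "B"), each = n_per_pop)
  par_of <- function(p) if (p == "A") params_a else params_b
  with_seed(seed, {
    # Per-nucleus shape draws (independent of placement stream order).
    area <- ar <- ori <- numeric(n)
    for (i in seq_len(n)) {
      pp <- par_of(pops[i])
      sdl <- sqrt(log(1 + pp$area_cv^2))
      area[i] <- rlnorm(1, log(pp$mean_area) - sdl^2 / 2, sdl)
      ar[i] <- 1 + pmax(0, (pp$mean_aspect_ratio - 1) *
                          rlnorm(1, -0.045, 0.3))
      ori[i] <- sample_axial(1, 0, pp$orientation_concentration)
    }
    a_px <- sqrt(area * ar / pi) / pixel_size   # semi-major, px
    b_px <- sqrt(area / (ar * pi)) / pixel_size # semi-minor, px

    # Placement: candidate centres are centre + dispersion * z_k with a
    # fixed unit-normal stream, so rescaling `dispersion` rescales every
    # accepted centre (and all pairwise distances) exactly when the same
    # candidates are accepted.
    budget <- 100L * n
    zx <- rnorm(budget); zy <- rnorm(budget)
    half <- image_size * pixel_size / 2
    margin_px <- 2
    cx <- cy <- numeric(n)
    placed <- 0L
    for (k in seq_len(budget)) {
      i <- placed + 1L
      x <- half + dispersion * zx[k]
      y <- half + dispersion * zy[k]
      rmax_um <- (a_px[i] * (1 + 3 * par_of(pops[i])$boundary_irregularity) +
                    margin_px) * pixel_size
      if (x - rmax_um < 0 || x + rmax_um > 2 * half ||
          y - rmax_um < 0 || y + rmax_um > 2 * half) next
      if (placed > 0L) {
        rj <- (a_px[seq_len(placed)] * 1.3 + margin_px) * pixel_size
        if (any(sqrt((cx[seq_len(placed)] - x)^2 +
                     (cy[seq_len(placed)] - y)^2) <
                rmax_um + rj)) next
      }
      cx[i] <- x; cy[i] <- y
      placed <- i
      if (placed == n) break
    }
    if (placed < n)
      stop(sprintf(paste0("scene too crowded: placed %d of %d nuclei within ",
                          "the retry budget (achievable density ~%.3f ",
                          "nuclei per 1000 um^2 at this dispersion)"),
                   placed, n,
                   1000 * placed / (image_size * pixel_size)^2),
           call. = FALSE)

    # Render.
    img <- matrix(background, image_size, image_size)
    labels <- matrix(0L, image_size, image_size)
    truth <- data.frame(id = seq_len(n), pop = pops, x_um = cx, y_um = cy,
                        area_um2 = NA_real_, aspect_ratio = ar,
                        orientation_deg = ori)
    for (i in seq_len(n)) {
      pp <- par_of(pops[i])
      # Fourier boundary perturbation, orders 2..5
      amps <- pp$boundary_irregularity * rnorm(4) / (2:5)
      phs <- runif(4, 0, 2 * pi)
      rmax_px <- a_px[i] * (1 + 3 * pp$boundary_irregularity) + margin_px
      col0 <- floor(cx[i] / pixel_size + 0.5 - rmax_px)
      col1 <- ceiling(cx[i] / pixel_size + 0.5 + rmax_px)
      row0 <- floor(image_size - cy[i] / pixel_size + 0.5 - rmax_px)
      row1 <- ceiling(image_size - cy[i] / pixel_size + 0.5 + rmax_px)
      cols <- max(1L, col0):min(image_size, col1)
      rows <- max(1L, row0):min(image_size, row1)
      xs <- px_to_um_x(cols, pixel_size) - cx[i]
      ys <- px_to_um_y(rows, image_size, pixel_size) - cy[i]
      dx <- matrix(rep(xs, each = length(rows)), length(rows))
      dy <- matrix(rep(ys, times = length(cols)), length(rows))
      th <- ori[i] * pi / 180
      u <- (cos(th) * dx + sin(th) * dy) / (a_px[i] * pixel_size)
      v <- (-sin(th) * dx + cos(th) * dy) / (b_px[i] * pixel_size)
      phi <- atan2(v, u)
      pert <- 1 + amps[1] * cos(2 * phi + phs[1]) +
        amps[2] * cos(3 * phi + phs[2]) +
        amps[3] * cos(4 * phi + phs[3]) +
        amps[4] * cos(5 * phi + phs[4])
      inside <- sqrt(u^2 + v^2) <= pert
      if (!any(inside)) next
      tex <- texture_field(length(rows), length(cols),
                           pp$texture_granularity / pixel_size)
      val <- pp$mean_intensity *
        pmax(0.05, 1 + pp$texture_contrast * pmax(pmin(tex, 2.5), -2.5))
      sub_lab <- labels[rows, cols, drop = FALSE]
      sub_img <- img[rows, cols, drop = FALSE]
      put <- inside & sub_lab == 0L
      sub_lab[put] <- i
      sub_img[put] <- val[put]
      labels[rows, cols] <- sub_lab
      img[rows, cols] <- sub_img
    }
    if (is.finite(snr) && snr > 0) {
      noise_sd <- (mean(c(params_a$mean_intensity,
                          params_b$mean_intensity)) - background) / snr
      img <- img + rnorm(length(img), 0, noise_sd)
    }
    img <- pmin(pmax(img, 0), 65535)
    truth$area_um2 <- as.vector(tabulate(labels[labels > 0], nbins = n)) *
      pixel_size^2
    structure(list(image = img, labels = labels, truth = truth,
                   pixel_size = pixel_size,
                   params = list(a = params_a, b = params_b,
                                 n_per_pop = n_per_pop,
                                 dispersion = dispersion,
                                 background = background, snr = snr),
                   seed = seed),
              class = "synthetic_scene")
  })
}

#' Write a synthetic scene to disk
#'
#' Writes the rendered image and ground-truth label image as 16-bit TIFF
#' and the ground-truth table as CSV.
#'
#' @param scene a `synthetic_scene`.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return invisibly, the paths written.
#' @export
write_scene <- function(scene, dir, prefix = "scene") {
  stopifnot(inherits(scene, "synthetic_scene"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p_img <- file.path(dir, paste0(prefix, "_image.tif"))
  p_lab <- file.path(dir, paste0(prefix, "_labels.tif"))
  p_csv <- file.path(dir, paste0(prefix, "_truth.csv"))
  write_tiff(scene$image, p_img, bits = 16L)
  write_tiff(scene$labels, p_lab, bits = 16L)
  write.csv(scene$truth, p_csv, row.names = FALSE)
  invisible(c(image = p_img, labels = p_lab, truth = p_csv))
}
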