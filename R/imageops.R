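# Low-level image operations on plain R matrices (img[row, col], row 1 top).

# Reflect-pad a matrix by `r` pixels on every side (edge mirrored without
# repeating the border pixel when possible).
reflect_pad <- function(img, r) {
  nr <- nrow(img); nc <- ncol(img)
  ridx <- c(rev(seq_len(min(r, nr))), seq_len(nr),
            nr - seq_len(min(r, nr)) + 1L)
  # if r > nr the mirror recycles; fine for the small kernels used here
  while (length(ridx) < nr + 2L * r) ridx <- c(ridx[1L], ridx, ridx[length(ridx)])
  cidx <- c(rev(seq_len(min(r, nc))), seq_len(nc),
            nc - seq_len(min(r, nc)) + 1L)
  while (length(cidx) < nc + 2L * r) cidx <- c(cidx[1L], cidx, cidx[length(cidx)])
  img[ridx, cidx, drop = FALSE]
}

gaussian_kernel1d <- function(sigma_px) {
  r <- max(1L, ceiling(3 * sigma_px))
  k <- exp(-((-r):r)^2 / (2 * sigma_px^2))
  k / sum(k)
}

# Separable Gaussian blur with reflected boundaries; sigma in pixels.
gaussian_blur <- function(img, sigma_px) {
  if (sigma_px <= 0) return(img)
  k <- gaussian_kernel1d(sigma_px)
  r <- (length(k) - 1L) %/% 2L
  nr <- nrow(img); nc <- ncol(img)
  p <- reflect_pad(img, r)
  # rows (vertical pass)
  out <- matrix(0, nr, nc + 2L * r)
  for (i in seq_along(k))
    out <- out + k[i] * p[i:(i + nr - 1L), , drop = FALSE]
  # columns (horizontal pass)
  res <- matrix(0, nr, nc)
  for (i in seq_along(k))
    res <- res + k[i] * out[, i:(i + nc - 1L), drop = FALSE]
  res
}

# 1-D convolution of a matrix along rows or columns, reflected boundaries.
conv1d <- function(img, k, along = c("col", "row")) {
  along <- match.arg(along)
  r <- (length(k) - 1L) %/% 2L
  nr <- nrow(img); nc <- ncol(img)
  p <- reflect_pad(img, r)
  out <- matrix(0, nr, nc)
  if (along == "col") { # kernel slides horizontally
    pp <- p[(r + 1):(r + nr), , drop = FALSE]
    for (i in seq_along(k)) out <- out + k[i] * pp[, i:(i + nc - 1L)]
  } else {
    pp <- p[, (r + 1):(r + nc), drop = FALSE]
    for (i in seq_along(k)) out <- out + k[i] * pp[i:(i + nr - 1L), ]
  }
  out
}

# Image gradient by Gaussian-derivative filters (separable, scale sigma_d
# pixels). Far less direction-biased than plain centered differences,
# which matters for structure-tensor orientation estimates.
# Returns fx (rightward) and fy (upward: y-up convention).
gaussian_gradient <- function(img, sigma_d = 1) {
  r <- ceiling(4 * sigma_d)
  xs <- (-r):r
  g <- exp(-xs^2 / (2 * sigma_d^2)); g <- g / sum(g)
  dg <- -xs / sigma_d^2 * exp(-xs^2 / (2 * sigma_d^2))
  dg <- dg / sum(-xs * dg) # unit response to a unit ramp
  fx <- conv1d(conv1d(img, dg, "col"), g, "row")
  fy_down <- conv1d(conv1d(img, dg, "row"), g, "col")
  list(fx = fx, fy = -fy_down)
}

# Otsu's threshold on a numeric vector; returns NA for (near-)constant input.
otsu_threshold <- function(x, n_bins = 256L) {
  x <- x[is.finite(x)]
  rng <- range(x)
  if (diff(rng) <= .Machine$double.eps * max(1, abs(rng[2]))) return(NA_real_)
  h <- tabulate(pmin(n_bins, 1L + floor((x - rng[1]) / diff(rng) * n_bins)),
                nbins = n_bins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mids <- rng[1] + (seq_len(n_bins) - 0.5) / n_bins * diff(rng)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  denom <- omega * (1 - omega)
  sigma_b <- (mu_t * omega - mu)^2 / ifelse(denom > 0, denom, NA)
  k <- which.max(sigma_b)
  if (length(k) == 0L) return(NA_real_)
  mids[k]
}

# Label connected foreground components (logical matrix) 1..k.
label_components <- function(mask, connectivity = 8L) {
  stopifnot(is.matrix(mask))
  storage.mode(mask) <- "logical"
  .cc_label(mask, as.integer(connectivity))
}

# Fill holes: background regions not connected to the image border become
# foreground. 4-connectivity for the background, the complement of the
# 8-connected foreground.
fill_holes <- function(mask) {
  bg <- label_components(!mask, connectivity = 4L)
  border_ids <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
  border_ids <- border_ids[border_ids > 0]
  mask | (bg > 0 & !(bg %in% border_ids))
}

# Offsets (drow, dcol) of a disk structuring element of radius r (pixels).
disk_offsets <- function(r) {
  r <- max(1L, round(r))
  g <- expand.grid(dr = -r:r, dc = -r:r)
  g[g$dr^2 + g$dc^2 <= r^2 + 0.5, , drop = FALSE]
}

# Grayscale erosion/dilation by shifting over structuring-element offsets.
gray_morph <- function(img, offsets, op = c("erode", "dilate")) {
  op <- match.arg(op)
  nr <- nrow(img); nc <- ncol(img)
  r <- max(abs(offsets$dr), abs(offsets$dc))
  p <- reflect_pad(img, r)
  acc <- matrix(if (op == "erode") Inf else -Inf, nr, nc)
  f <- if (op == "erode") pmin else pmax
  for (i in seq_len(nrow(offsets))) {
    dr <- offsets$dr[i]; dc <- offsets$dc[i]
    acc <- f(acc, p[(r + 1 + dr):(r + nr + dr),
                    (r + 1 + dc):(r + nc + dc), drop = FALSE])
  }
  acc
}

# White top-hat: image minus its grayscale opening at radius r.
white_tophat <- function(img, r) {
  off <- disk_offsets(r)
  img - gray_morph(gray_morph(img, off, "erode"), off, "dilate")
}
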