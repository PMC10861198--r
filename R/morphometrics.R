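# Per-nucleus feature catalog in four groups: nuclear morphology, boundary
# characteristics, global intensity profile, chromatin texture.
#
# The catalog is a fixed, testable stand-in for published chromatin-feature
# repositories: 7 morphology + 3 boundary + 7 intensity + 7 texture = 24
# named features. Texture features are computed on per-nucleus min-max
# quantized intensities (64 gray levels) so they compare across staining
# depth; the gray-level co-occurrence matrix is averaged over 1-px offsets
# at 0/45/90/135 degrees.

FEATURE_GROUPS <- c(
  area = "morphology", perimeter = "morphology", aspect_ratio = "morphology",
  eccentricity = "morphology", solidity = "morphology", extent = "morphology",
  equiv_diameter = "morphology",
  circularity = "boundary", radial_cv = "boundary", concave_count = "boundary",
  int_mean = "intensity", int_sd = "intensity", int_skewness = "intensity",
  int_kurtosis = "intensity", int_entropy = "intensity",
  int_p10_p90 = "intensity", int_high_fraction = "intensity",
  glcm_contrast = "texture", glcm_correlation = "texture",
  glcm_homogeneity = "texture", glcm_energy = "texture",
  glcm_entropy = "texture", foci_count = "texture", foci_fraction = "texture")

#' The nuclear feature catalog
#'
#' @return named character vector mapping each feature to its group
#'   (`morphology`, `boundary`, `intensity`, `texture`).
#' @export
feature_catalog <- function() FEATURE_GROUPS

# ---- boundary tracing -------------------------------------------------

# Moore-neighbour boundary tracing of the largest-id component in a logical
# mask (assumed a single filled component). Returns an n x 2 matrix of
# (row, col) boundary pixels in order.
trace_boundary <- function(mask) {
  idx <- which(mask)
  if (length(idx) == 0L) return(NULL)
  nr <- nrow(mask)
  start_r <- ((idx[1] - 1L) %% nr) + 1L
  start_c <- ((idx[1] - 1L) %/% nr) + 1L
  if (length(idx) == 1L) return(cbind(start_r, start_c))
  # clockwise neighbour order (image coords, row down)
  dr <- c(0L, 1L, 1L, 1L, 0L, -1L, -1L, -1L)
  dc <- c(1L, 1L, 0L, -1L, -1L, -1L, 0L, 1L)
  inb <- function(r, c) r >= 1L && r <= nr && c >= 1L && c <= ncol(mask)
  fg <- function(r, c) inb(r, c) && mask[r, c]
  b <- c(start_r, start_c)
  back <- 5L # backtrack = W neighbour (background by column-major scan)
  path <- matrix(0L, length(idx) * 4L + 8L, 2L)
  path[1L, ] <- b
  np <- 1L
  first_move <- NA_integer_
  repeat {
    found <- FALSE
    for (k in 0:7) {
      d <- ((back - 1L + k) %% 8L) + 1L
      r2 <- b[1] + dr[d]; c2 <- b[2] + dc[d]
      if (fg(r2, c2)) {
        # new backtrack: the neighbour just before d, relative to new pixel
        prev_d <- ((back - 1L + k - 1L) %% 8L) + 1L
        pr <- b[1] + dr[prev_d]; pc <- b[2] + dc[prev_d]
        b <- c(r2, c2)
        # direction from new b back to (pr, pc)
        ddr <- pr - r2; ddc <- pc - c2
        back <- which(dr == ddr & dc == ddc)
        found <- TRUE
        break
      }
    }
    if (!found) break # isolated pixel cluster fallback
    np <- np + 1L
    if (np > nrow(path)) break
    path[np, ] <- b
    if (is.na(first_move)) first_move <- np
    if (b[1] == start_r && b[2] == start_c) break
  }
  path[seq_len(np - 1L), , drop = FALSE] # closed: drop repeated start
}

# Vossepoel-Smeulders perimeter estimate from a traced boundary (pixels).
chain_perimeter <- function(path) {
  n <- nrow(path)
  if (n < 2L) return(4) # single pixel: its own outline
  nxt <- rbind(path[-1L, , drop = FALSE], path[1L, , drop = FALSE])
  st <- nxt - path
  diag_step <- abs(st[, 1]) == 1L & abs(st[, 2]) == 1L
  ne <- sum(!diag_step); no <- sum(diag_step)
  code <- st[, 1] * 3L + st[, 2] # unique per direction
  ncorner <- sum(code != c(code[n], code[-n]))
  max(0.980 * ne + 1.406 * no - 0.091 * ncorner, 1)
}

# Count concave boundary segments: maximal runs of negative turning whose
# accumulated turn exceeds 5 degrees, on a smoothed closed boundary.
concave_segments <- function(path) {
  n <- nrow(path)
  if (n < 8L) return(0L)
  # to Cartesian (x = col, y = -row), circularly smoothed
  x <- path[, 2]; y <- -path[, 1]
  w <- 5L
  sm <- function(v) {
    vv <- c(v[(n - w + 1):n], v, v[1:w])
    stats::filter(vv, rep(1 / (2 * w + 1), 2 * w + 1))[(w + 1):(w + n)]
  }
  xs <- as.numeric(sm(x)); ys <- as.numeric(sm(y))
  vx <- diff(c(xs, xs[1])); vy <- diff(c(ys, ys[1]))
  ang <- atan2(vy, vx)
  turn <- diff(c(ang, ang[1]))
  turn <- ((turn + pi) %% (2 * pi)) - pi
  # boundary is traced clockwise in image coords = CCW in Cartesian:
  # convex turns are positive
  neg <- turn < 0
  runs <- rle(neg)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  count <- 0L
  for (k in which(runs$values)) {
    if (abs(sum(turn[starts[k]:ends[k]])) * 180 / pi > 5) count <- count + 1L
  }
  count
}

# ---- texture ----------------------------------------------------------

# GLCM features on a quantized sub-image (integers 1..levels, NA outside
# the nucleus), averaged over 1-px offsets at 0/45/90/135 degrees (y-up).
glcm_features <- function(q, levels = 64L) {
  offsets <- list(c(0L, 1L), c(-1L, 1L), c(-1L, 0L), c(-1L, -1L))
  nr <- nrow(q); nc <- ncol(q)
  acc <- c(contrast = 0, correlation = 0, homogeneity = 0, energy = 0,
           entropy = 0)
  n_used <- 0L
  for (off in offsets) {
    drr <- off[1]; dcc <- off[2]
    r1 <- max(1L, 1L - drr):min(nr, nr - drr)
    c1 <- max(1L, 1L - dcc):min(nc, nc - dcc)
    a <- q[r1, c1, drop = FALSE]
    b <- q[r1 + drr, c1 + dcc, drop = FALSE]
    ok <- !is.na(a) & !is.na(b)
    if (!any(ok)) next
    i <- a[ok]; j <- b[ok]
    P <- matrix(0, levels, levels)
    tab <- table(factor(i, levels = 1:levels), factor(j, levels = 1:levels))
    P <- unclass(tab) + t(unclass(tab)) # symmetric
    P <- P / sum(P)
    lev <- seq_len(levels)
    pi_m <- rowSums(P)
    mu <- sum(lev * pi_m)
    sg2 <- sum((lev - mu)^2 * pi_m)
    dif <- outer(lev, lev, "-")
    contrast <- sum(P * dif^2)
    homog <- sum(P / (1 + dif^2))
    energy <- sum(P^2)
    entrop <- -sum(P[P > 0] * log2(P[P > 0]))
    corr <- if (sg2 > 0)
      sum(P * outer(lev - mu, lev - mu)) / sg2 else 0
    acc <- acc + c(contrast, corr, homog, energy, entrop)
    n_used <- n_used + 1L
  }
  if (n_used == 0L) return(c(contrast = 0, correlation = 0, homogeneity = 1,
                             energy = 1, entropy = 0))
  acc / n_used
}

moments23 <- function(x) {
  s <- sd(x)
  if (!is.finite(s) || s == 0) return(c(skew = 0, kurt = 0))
  z <- (x - mean(x)) / s
  c(skew = mean(z^3), kurt = mean(z^4) - 3)
}

# ---- main entry -------------------------------------------------------

#' Compute the four-group nuclear feature table
#'
#' @param image intensity matrix the nuclei were segmented from.
#' @param seg a `nucleus_records` object ([segment_nuclei()]), or any list
#'   with elements `labels` (integer label matrix) and `pixel_size`.
#' @param condition condition label stored per row (e.g. `"old"`, `"PR"`).
#' @param image_id provenance tag stored per row.
#' @param texture_scale_um chromatin-focus scale for the white top-hat, um.
#' @param min_px nuclei with fewer pixels are flagged `degenerate` (their
#'   shape statistics are unreliable) and are excluded from classifier
#'   training downstream.
#' @return a `feature_table`: data.frame with columns `id`, `condition`,
#'   `image_id`, `degenerate` and the 24 features of [feature_catalog()];
#'   the group map is attached as attribute `groups`.
#' @export
compute_features <- function(image, seg, condition = NA_character_,
                             image_id = NA_character_,
                             texture_scale_um = 1, min_px = 16L) {
  labels <- seg$labels
  pixel_size <- seg$pixel_size
  stopifnot(is.matrix(image), is.matrix(labels),
            all(dim(image) == dim(labels)))
  ids <- sort(unique(labels[labels > 0L]))
  out <- vector("list", length(ids))
  nr <- nrow(labels)
  for (k in seq_along(ids)) {
    id <- ids[k]
    px <- which(labels == id)
    rows <- ((px - 1L) %% nr) + 1L
    cols <- ((px - 1L) %/% nr) + 1L
    r0 <- min(rows); r1 <- max(rows); c0 <- min(cols); c1 <- max(cols)
    sub_mask <- labels[r0:r1, c0:c1, drop = FALSE] == id
    sub_img <- image[r0:r1, c0:c1, drop = FALSE]
    out[[k]] <- c(id = id,
                  nucleus_features(sub_mask, sub_img, pixel_size,
                                   texture_scale_um))
  }
  df <- as.data.frame(do.call(rbind, out))
  if (nrow(df) == 0L) {
    df <- as.data.frame(matrix(numeric(), 0, length(FEATURE_GROUPS) + 2,
      dimnames = list(NULL, c("id", "n_px", names(FEATURE_GROUPS)))))
  }
  df$degenerate <- df$n_px < min_px
  df$condition <- condition
  df$image_id <- image_id
  df <- df[, c("id", "condition", "image_id", "degenerate", "n_px",
               names(FEATURE_GROUPS))]
  structure(df, groups = FEATURE_GROUPS, class = c("feature_table",
                                                   "data.frame"))
}

#' Feature-to-group map of a feature table
#' @param x a `feature_table`.
#' @return named character vector (feature -> group).
#' @export
feature_groups <- function(x) attr(x, "groups", exact = TRUE)

# All 24 features for one nucleus (mask + intensities in its bounding box).
nucleus_features <- function(mask, img, pixel_size, texture_scale_um) {
  n_px <- sum(mask)
  vals <- img[mask]
  area <- n_px * pixel_size^2

  # morphology from second central moments (pixel-extent corrected)
  rows <- row(mask)[mask]; cols <- col(mask)[mask]
  x <- px_to_um_x(cols, pixel_size)
  y <- px_to_um_y(rows, nrow(mask), pixel_size)
  mx <- x - mean(x); my <- y - mean(y)
  cxx <- mean(mx^2) + pixel_size^2 / 12
  cyy <- mean(my^2) + pixel_size^2 / 12
  cxy <- mean(mx * my)
  tr <- cxx + cyy
  det_ <- sqrt(max((cxx - cyy)^2 / 4 + cxy^2, 0))
  l1 <- tr / 2 + det_; l2 <- max(tr / 2 - det_, 1e-12)
  aspect_ratio <- sqrt(l1 / l2)
  eccentricity <- sqrt(max(1 - l2 / l1, 0))

  bbox_area <- prod(dim(mask)) * pixel_size^2
  extent <- area / bbox_area
  equiv_diameter <- 2 * sqrt(area / pi)

  hull_area <- {
    if (n_px >= 3L) {
      h <- grDevices::chull(x, y)
      hx <- x[h]; hy <- y[h]
      a <- abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2
      # pixel squares extend beyond their centres; add half-perimeter band
      a + 0.5 * pixel_size * sum(sqrt(diff(c(hx, hx[1]))^2 +
                                      diff(c(hy, hy[1]))^2)) + pixel_size^2
    } else area
  }
  solidity <- min(1, area / max(hull_area, area))

  path <- trace_boundary(mask)
  perim <- chain_perimeter(path) * pixel_size
  circularity <- min(1, 4 * pi * area / perim^2)
  bx <- px_to_um_x(path[, 2], pixel_size)
  by <- px_to_um_y(path[, 1], nrow(mask), pixel_size)
  rad <- sqrt((bx - mean(x))^2 + (by - mean(y))^2)
  radial_cv <- if (mean(rad) > 0) sd(rad) / mean(rad) else 0
  if (!is.finite(radial_cv)) radial_cv <- 0
  concave_count <- concave_segments(path)

  # intensity profile
  s <- sd(vals); if (!is.finite(s)) s <- 0
  m23 <- moments23(vals)
  if (s > 0) {
    sc <- minmax01(vals)
    h <- tabulate(pmin(64L, 1L + floor(sc * 64)), nbins = 64L)
    p <- h / sum(h)
    int_entropy <- -sum(p[p > 0] * log2(p[p > 0]))
    q <- quantile(vals, c(0.1, 0.9), names = FALSE)
    int_p10_p90 <- if (q[2] > 0) q[1] / q[2] else 0
    int_high_fraction <- mean(vals > mean(vals) + s)
  } else {
    int_entropy <- 0
    int_p10_p90 <- 1
    int_high_fraction <- 0
  }

  # texture: GLCM on per-nucleus min-max 64-level quantization
  if (s > 0) {
    qimg <- matrix(NA_integer_, nrow(mask), ncol(mask))
    qimg[mask] <- pmin(64L, 1L + floor(minmax01(vals) * 64))
    g <- glcm_features(qimg)
  } else {
    g <- c(contrast = 0, correlation = 0, homogeneity = 1, energy = 1,
           entropy = 0)
  }

  # chromatin foci: white top-hat at the texture scale, Otsu inside nucleus
  th_r <- max(1L, round(texture_scale_um / pixel_size))
  if (s > 0 && n_px >= 16L) {
    th <- white_tophat(img, th_r)
    thr <- otsu_threshold(th[mask])
    if (!is.na(thr)) {
      foci <- mask & th > thr
      lab <- label_components(foci, 8L)
      foci_count <- max(lab)
      foci_fraction <- sum(foci) / n_px
    } else {
      foci_count <- 0; foci_fraction <- 0
    }
  } else {
    foci_count <- 0; foci_fraction <- 0
  }

  c(n_px = n_px,
    area = area, perimeter = perim, aspect_ratio = aspect_ratio,
    eccentricity = eccentricity, solidity = solidity, extent = extent,
    equiv_diameter = equiv_diameter,
    circularity = circularity, radial_cv = radial_cv,
    concave_count = as.numeric(concave_count),
    int_mean = mean(vals), int_sd = s, int_skewness = m23[["skew"]],
    int_kurtosis = m23[["kurt"]], int_entropy = int_entropy,
    int_p10_p90 = int_p10_p90, int_high_fraction = int_high_fraction,
    glcm_contrast = g[["contrast"]], glcm_correlation = g[["correlation"]],
    glcm_homogeneity = g[["homogeneity"]], glcm_energy = g[["energy"]],
    glcm_entropy = g[["entropy"]],
    foci_count = as.numeric(foci_count), foci_fraction = foci_fraction)
}

#' Write a feature table as CSV with a two-row header (group, feature)
#'
#' @param features a `feature_table`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(features, path) {
  groups <- feature_groups(features)
  cols <- colnames(features)
  grow <- ifelse(cols %in% names(groups), groups[cols], "meta")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(grow, collapse = ","), con)
  writeLines(paste(cols, collapse = ","), con)
  write.table(features, con, sep = ",", col.names = FALSE,
              row.names = FALSE)
  invisible(path)
}
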