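# Nuclear segmentation from the nuclear-stain channel.
#
# Foreground = pixels above BOTH the global Otsu threshold and a local Otsu
# threshold computed in blocks; connected components (8-connectivity) are
# filled, measured, and filtered by area and mean intensity to remove
# large, dim autofluorescent regions. Touching nuclei merge: no watershed
# splitting is attempted (documented limitation).

# Block-wise local Otsu threshold map. Blocks whose histogram is
# (near-)constant fall back to the global threshold.
local_otsu_map <- function(img, block, global_thr) {
  nr <- nrow(img); nc <- ncol(img)
  thr <- matrix(global_thr, nr, nc)
  row_starts <- seq(1L, nr, by = block)
  col_starts <- seq(1L, nc, by = block)
  for (r0 in row_starts) {
    rows <- r0:min(nr, r0 + block - 1L)
    for (c0 in col_starts) {
      cols <- c0:min(nc, c0 + block - 1L)
      t <- otsu_threshold(img[rows, cols])
      if (!is.na(t)) thr[rows, cols] <- t
    }
  }
  thr
}

#' Segment nuclei by combined local and global Otsu thresholding
#'
#' @param image single-channel, non-negative intensity matrix.
#' @param pixel_size um per pixel.
#' @param min_area,max_area component area filter, um^2.
#' @param min_mean_intensity minimum component mean intensity (image units).
#' @param local_block side of the local-Otsu blocks, pixels; `Inf` disables
#'   the local threshold (global Otsu only).
#' @return object of class `nucleus_records`: list with
#'   `records` (data.frame: id, x_um, y_um, area_um2, mean_intensity,
#'   orientation_deg, n_px), `labels` (integer label matrix; ids match
#'   `records$id`), `pixel_size`. A constant image yields zero records with
#'   a warning rather than an error.
#' @export
segment_nuclei <- function(image, pixel_size, min_area = 10,
                           max_area = 400, min_mean_intensity = 0,
                           local_block = 64) {
  stopifnot(is.matrix(image), min_area < max_area, pixel_size > 0)
  if (any(image < 0)) stop("image must be non-negative")
  global_thr <- otsu_threshold(image)
  if (is.na(global_thr)) {
    warning("constant image: Otsu threshold undefined, returning no nuclei")
    return(structure(list(records = empty_records(),
                          labels = matrix(0L, nrow(image), ncol(image)),
                          pixel_size = pixel_size),
                     class = "nucleus_records"))
  }
  fg <- image > global_thr
  if (is.finite(local_block)) {
    fg <- fg & (image > local_otsu_map(image, as.integer(local_block),
                                       global_thr))
  }
  fg <- fill_holes(fg)
  lab <- label_components(fg, connectivity = 8L)
  recs <- measure_components(image, lab, pixel_size)
  keep <- recs$area_um2 >= min_area & recs$area_um2 <= max_area &
    recs$mean_intensity >= min_mean_intensity
  recs <- recs[keep, , drop = FALSE]
  # relabel surviving components 1..k, sorted by id
  new_lab <- matrix(0L, nrow(lab), ncol(lab))
  if (nrow(recs) > 0) {
    map <- integer(max(lab))
    map[recs$id] <- seq_len(nrow(recs))
    nz <- lab > 0L
    mapped <- map[lab[nz]]
    mapped[is.na(mapped)] <- 0L
    new_lab[nz] <- mapped
    recs$id <- seq_len(nrow(recs))
  }
  rownames(recs) <- NULL
  structure(list(records = recs, labels = new_lab, pixel_size = pixel_size),
            class = "nucleus_records")
}

empty_records <- function() {
  data.frame(id = integer(), x_um = numeric(), y_um = numeric(),
             area_um2 = numeric(), mean_intensity = numeric(),
             orientation_deg = numeric(), n_px = integer())
}

# Centroid, area, mean intensity and long-axis orientation per label.
measure_components <- function(image, lab, pixel_size) {
  ids <- sort(unique(lab[lab > 0L]))
  if (length(ids) == 0L) return(empty_records())
  nz <- which(lab > 0L)
  l <- lab[nz]
  rows <- ((nz - 1L) %% nrow(lab)) + 1L
  cols <- ((nz - 1L) %/% nrow(lab)) + 1L
  x <- px_to_um_x(cols, pixel_size)
  y <- px_to_um_y(rows, nrow(lab), pixel_size)
  inten <- image[nz]
  f <- factor(l, levels = ids)
  npx <- as.integer(table(f))
  cx <- tapply(x, f, mean)
  cy <- tapply(y, f, mean)
  mi <- tapply(inten, f, mean)
  ori <- vapply(seq_along(ids), function(k) {
    sel <- l == ids[k]
    mask_orientation(x[sel], y[sel])
  }, 0)
  data.frame(id = ids, x_um = as.vector(cx), y_um = as.vector(cy),
             area_um2 = npx * pixel_size^2, mean_intensity = as.vector(mi),
             orientation_deg = ori, n_px = npx)
}

# Long-axis direction from second central moments (degrees, CCW from +x,
# axial). Includes the 1/12 px^2 term implicitly omitted: not needed for
# direction.
mask_orientation <- function(x, y) {
  if (length(x) < 2L) return(0)
  mx <- x - mean(x); my <- y - mean(y)
  mxx <- mean(mx^2); myy <- mean(my^2); mxy <- mean(mx * my)
  if (abs(mxy) < 1e-12 && abs(mxx - myy) < 1e-12) return(0)
  wrap_axial(0.5 * atan2(2 * mxy, mxx - myy) * 180 / pi)
}

#' Write segmentation results
#'
#' Writes the label image as 16-bit TIFF and the records as CSV.
#'
#' @param seg a `nucleus_records` object.
#' @param dir output directory.
#' @param prefix file-name prefix.
#' @return invisibly, the paths written.
#' @export
write_segmentation <- function(seg, dir, prefix = "nuclei") {
  stopifnot(inherits(seg, "nucleus_records"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p_lab <- file.path(dir, paste0(prefix, "_labels.tif"))
  p_csv <- file.path(dir, paste0(prefix, "_records.csv"))
  write_tiff(seg$labels, p_lab, bits = 16L)
  write.csv(seg$records[, c("id", "x_um", "y_um", "area_um2",
                            "mean_intensity", "orientation_deg")],
            p_csv, row.names = FALSE)
  invisible(c(labels = p_lab, records = p_csv))
}
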