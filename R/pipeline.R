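# End-to-end orchestration: synthetic or file-based inputs through
# segmentation, features, LDA scoring, IPD, clustering (rejuvenation
# readout) or orientation analysis and fold changes (wound readout).
# Every run serializes its configuration verbatim into the output
# directory and stamps outputs with the config hash.

#' Default run configuration
#'
#' All under-specified analysis parameters live here so each run leaves a
#' complete audit trail. Conditions may specify synthetic generator
#' parameters (the default) or `image`/`labels` TIFF paths.
#'
#' @param out_dir output directory.
#' @return nested configuration list (class `run_config`).
#' @export
default_config <- function(out_dir = "tissuemorph_out") {
  structure(list(
    out_dir = out_dir,
    pixel_size = 0.5,
    seed = 1L,
    conditions = list(
      old = list(mean_area = 55, texture_contrast = 0.25,
                 dispersion = 40, n_per_pop = 60),
      PR = list(mean_area = 65, texture_contrast = 0.45,
                dispersion = 60, n_per_pop = 60)),
    image_size = 640,
    snr = 10,
    segmentation = list(min_area = 10, max_area = 400,
                        min_mean_intensity = 0, local_block = 64),
    lda = list(train_fraction = 0.75, balance = TRUE, shrinkage = "auto"),
    clustering = list(feature_set = "xy+score", min_cluster_size = 5),
    fibers = list(sigma = 2, n_bins = 36, reference_angle = NA,
                  weight = "coherency*energy", image_size = 512,
                  conditions = list(old = list(mean_angle = 0,
                                               concentration = 0),
                                    PR = list(mean_angle = 30,
                                              concentration = 10)))),
    class = "run_config")
}

load_config <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  stopifnot(is.list(config))
  cfg <- modifyList(default_config(), config)
  # condition lists are replaced wholesale, not merged with the defaults
  if (!is.null(config$conditions)) cfg$conditions <- config$conditions
  if (!is.null(config$fibers$conditions))
    cfg$fibers$conditions <- config$fibers$conditions
  cfg
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tmp))
}

write_config <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(config, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
}

condition_scene <- function(cond_cfg, cfg, seed) {
  if (!is.null(cond_cfg$image)) {
    img <- read_tiff(cond_cfg$image)
    return(list(image = img, labels = NULL, truth = NULL,
                pixel_size = cfg$pixel_size))
  }
  par_fields <- intersect(names(cond_cfg), names(formals(population_params)))
  pp <- do.call(population_params, cond_cfg[par_fields])
  n_half <- max(1L, floor(cond_cfg$n_per_pop / 2))
  generate_nuclei_scene(pp, pp, n_per_pop = n_half,
                        dispersion = cond_cfg$dispersion,
                        image_size = cfg$image_size,
                        pixel_size = cfg$pixel_size,
                        seed = seed, snr = cfg$snr)
}

#' Run the rejuvenation readout end-to-end
#'
#' segment -> features -> LDA score -> IPD matrix and dispersion per
#' condition -> density-based cluster statistics, writing one
#' machine-readable summary JSON plus per-stage CSVs.
#'
#' @param config a `run_config` list, or path to a JSON config; see
#'   [default_config()]. Must define exactly two conditions.
#' @return the summary list, invisibly; outputs under `config$out_dir`.
#' @export
run_rejuvenation_analysis <- function(config = default_config()) {
  cfg <- load_config(config)
  if (length(cfg$conditions) != 2L || is.null(names(cfg$conditions)) ||
      any(!nzchar(names(cfg$conditions))))
    stop("config must define exactly 2 named conditions")
  hash <- config_hash(cfg)
  out <- file.path(cfg$out_dir, "rejuvenation")
  write_config(cfg, out)
  conds <- names(cfg$conditions)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage `%s` failed: %s (partial outputs kept in %s)",
                   name, conditionMessage(e), out), call. = FALSE))
  }
  feats <- list(); segs <- list()
  summary <- list(config_hash = hash, conditions = conds)
  for (i in seq_along(conds)) {
    cname <- conds[i]
    scene <- stage(paste0("simulate:", cname),
                   condition_scene(cfg$conditions[[i]], cfg,
                                   seed = child_seed(cfg$seed, i)))
    seg <- stage(paste0("segment:", cname), do.call(segment_nuclei,
      c(list(image = scene$image, pixel_size = cfg$pixel_size),
        cfg$segmentation)))
    msg("%s: %d nuclei segmented", cname, nrow(seg$records))
    write_segmentation(seg, out, prefix = paste0(cname, "_nuclei"))
    ft <- stage(paste0("features:", cname),
                compute_features(scene$image, seg, condition = cname,
                                 image_id = cname))
    write_feature_table(ft, file.path(out, paste0(cname, "_features.csv")))
    segs[[cname]] <- seg
    feats[[cname]] <- ft
  }
  all_ft <- do.call(rbind, lapply(feats, as.data.frame))
  attr(all_ft, "groups") <- feature_groups(feats[[1]])
  class(all_ft) <- c("feature_table", "data.frame")
  ss <- stage("lda", do.call(train_score_lda,
    c(list(features = all_ft, seed = child_seed(cfg$seed, 10)),
      cfg$lda)))
  write_score_set(ss, out)
  summary$lda <- list(test_accuracy = ss$test_accuracy,
                      n_scored = nrow(ss$scores),
                      top_features = rank_feature_groups(ss, 5L))
  for (cname in conds) {
    seg <- segs[[cname]]
    rec <- seg$records
    if (nrow(rec) >= 2L) {
      ipd <- stage(paste0("ipd:", cname), compute_ipd_matrix(rec))
      write_ipd_matrix(ipd, file.path(out, paste0(cname, "_ipd.csv")))
      summary$ipd_dispersion[[cname]] <- ipd_dispersion(ipd)
    }
    sc <- ss$scores[ss$scores$label == cname, c("id", "score")]
    rec2 <- merge(rec, sc, by = "id")
    ca <- stage(paste0("clusters:", cname), do.call(cluster_nuclei,
      c(list(records = rec2), cfg$clustering)))
    ca <- cluster_angular_difference(ca, rec)
    write.csv(ca$clusters, file.path(out, paste0(cname, "_clusters.csv")),
              row.names = FALSE)
    msg("%s: %d clusters, noise fraction %.2f", cname,
        nrow(ca$clusters), mean(ca$labels == -1L))
    summary$clusters[[cname]] <-
      list(n_clusters = nrow(ca$clusters),
           noise_fraction = mean(ca$labels == -1L),
           mean_score = mean(ca$clusters$mean_score),
           mean_angular_diff_deg =
             mean(ca$clusters$mean_angular_diff_deg, na.rm = TRUE))
  }
  jsonlite::write_json(summary, file.path(out, "summary.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       dataframe = "rows")
  invisible(summary)
}

#' Run the wound (fiber-alignment) readout end-to-end
#'
#' orientation field -> axial histogram and width per condition -> HSB
#' maps, plus optional ROI intensity fold changes, writing a summary JSON.
#'
#' @param config a `run_config` list or JSON path; `config$fibers` defines
#'   the conditions (generator parameters or `image` paths),
#'   `reference_angle` (if `NA`, absolute angles are used with a logged
#'   notice) and the histogram settings.
#' @param roi_measurements optional data.frame for
#'   [intensity_fold_change()]; the first condition is the reference.
#' @return the summary list, invisibly; outputs under `config$out_dir`.
#' @export
run_wound_analysis <- function(config = default_config(),
                               roi_measurements = NULL) {
  cfg <- load_config(config)
  fc <- cfg$fibers
  hash <- config_hash(cfg)
  out <- file.path(cfg$out_dir, "wound")
  write_config(cfg, out)
  ref_angle <- fc$reference_angle
  if (is.null(ref_angle) || is.na(ref_angle)) {
    msg("no wound reference angle supplied: histogram uses absolute angles")
    ref_angle <- 0
  }
  summary <- list(config_hash = hash)
  for (i in seq_along(fc$conditions)) {
    cname <- names(fc$conditions)[i]
    cc <- fc$conditions[[i]]
    img <- if (!is.null(cc$image)) read_tiff(cc$image)
      else generate_fiber_field(cc$mean_angle, cc$concentration,
                                image_size = fc$image_size,
                                seed = child_seed(cfg$seed, 100 + i))$image
    field <- compute_orientation_field(img, sigma = fc$sigma,
                                       pixel_size = cfg$pixel_size)
    write_orientation_field(field,
                            file.path(out, paste0(cname, "_field.tif")))
    oh <- orientation_histogram(field, reference_angle = ref_angle,
                                n_bins = fc$n_bins, weight = fc$weight)
    write_orientation_histogram(oh,
      file.path(out, paste0(cname, "_orientation_hist.csv")))
    write_png_map(render_hsb_map(field, img),
                  file.path(out, paste0(cname, "_hsb.png")))
    msg("%s: orientation width %.1f deg (mean %.1f deg)", cname,
        oh$width, oh$mean)
    summary$orientation[[cname]] <- list(width_deg = oh$width,
                                         mean_deg = oh$mean,
                                         rbar = oh$rbar)
  }
  if (!is.null(roi_measurements)) {
    ref_cond <- names(fc$conditions)[1]
    fcres <- intensity_fold_change(roi_measurements, ref_cond)
    write.csv(fcres, file.path(out, "roi_fold_change.csv"),
              row.names = FALSE)
    summary$fold_change <- attr(fcres, "summary")
  }
  jsonlite::write_json(summary, file.path(out, "summary.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       dataframe = "rows")
  invisible(summary)
}
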