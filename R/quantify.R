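# ROI intensity fold changes, delta-delta-Ct relative expression, and the
# group-comparison statistics used for such readouts.

#' Per-channel ROI intensity fold change relative to a reference condition
#'
#' Each measurement's mean intensity is background-subtracted, then every
#' value in a channel is divided by that channel's reference-condition
#' mean, so the reference condition's mean fold change is 1 by
#' construction.
#'
#' @param measurements data.frame with columns `channel`, `condition`,
#'   `mean_intensity`, optionally `background` (default 0) and any
#'   provenance columns (`image_id`, `roi`).
#' @param reference_condition the condition that defines fold change 1.
#' @return data.frame: one row per measurement with `fold_change` added,
#'   plus attribute `summary` (per channel x condition mean fold change).
#' @export
intensity_fold_change <- function(measurements, reference_condition) {
  m <- as.data.frame(measurements)
  stopifnot(all(c("channel", "condition", "mean_intensity") %in% names(m)))
  if (!"background" %in% names(m)) m$background <- 0
  if (any(m$mean_intensity < 0)) stop("mean intensities must be >= 0")
  if (!reference_condition %in% m$condition)
    stop("no measurements for reference condition `",
         reference_condition, "`")
  m$net <- m$mean_intensity - m$background
  m$fold_change <- NA_real_
  for (ch in unique(m$channel)) {
    sel <- m$channel == ch
    ref <- sel & m$condition == reference_condition
    if (!any(ref))
      stop("channel `", ch, "` has no reference-condition measurements")
    if (!any(sel & m$condition != reference_condition))
      stop("channel `", ch, "` has no non-reference measurements")
    ref_mean <- mean(m$net[ref])
    if (ref_mean <= 0)
      stop("channel `", ch,
           "`: reference mean <= 0 after background subtraction")
    m$fold_change[sel] <- m$net[sel] / ref_mean
  }
  sum_df <- stats::aggregate(fold_change ~ channel + condition, data = m,
                             FUN = mean)
  names(sum_df)[3] <- "mean_fold_change"
  structure(m[, setdiff(names(m), "net")], summary = sum_df)
}

#' Relative expression by the 2^-ddCt method
#'
#' Per sample, `dCt = Ct_target - Ct_housekeeping`; `ddCt` is the sample's
#' dCt minus the mean dCt of the reference condition; the fold change is
#' `2^-ddCt` (amplification efficiency fixed at 2).
#'
#' @param records data.frame with columns `sample`, `condition`,
#'   `ct_target`, `ct_housekeeping` (and optionally `gene`, processed
#'   separately).
#' @param reference_condition condition defining the baseline (default
#'   `"reference"`).
#' @return the records with `dct`, `ddct` and `fold_change` columns added;
#'   rows with a missing housekeeping Ct are dropped with a warning.
#' @export
ddct_fold_change <- function(records, reference_condition = "reference") {
  r <- as.data.frame(records)
  stopifnot(all(c("sample", "condition", "ct_target", "ct_housekeeping")
                %in% names(r)))
  bad <- !is.finite(r$ct_housekeeping) | !is.finite(r$ct_target)
  if (any(bad)) {
    warning(sum(bad), " record(s) skipped: missing Ct value")
    r <- r[!bad, , drop = FALSE]
  }
  if (any(r$ct_target <= 0 | r$ct_target >= 45 |
          r$ct_housekeeping <= 0 | r$ct_housekeeping >= 45))
    stop("Ct values must lie in (0, 45) cycles")
  if (!"gene" %in% names(r)) r$gene <- "gene"
  out <- do.call(rbind, lapply(split(r, r$gene), function(g) {
    g$dct <- g$ct_target - g$ct_housekeeping
    ref <- g$condition == reference_condition
    if (!any(ref))
      stop("no reference-condition records for gene `", g$gene[1], "`")
    g$ddct <- g$dct - mean(g$dct[ref])
    g$fold_change <- 2^(-g$ddct)
    g
  }))
  rownames(out) <- NULL
  out
}

p_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**",
    ifelse(p < 0.05, "*", "ns")))
}

#' Group-comparison statistics with the figure star convention
#'
#' Thin wrapper over the standard R tests, reporting the statistic, the
#' p-value, per-group n, the `*`/`**`/`***` convention (p < 0.05 / 0.01 /
#' 0.001), and a reliability flag for groups with n < 3. A paired t test
#' on identical groups (all differences zero) is reported as statistic 0,
#' p = 1 by convention.
#'
#' @param values_by_group named list of numeric vectors, one per group.
#' @param test `"mann_whitney"`, `"tukey_hsd"`, `"paired_t"` or `"anova"`.
#' @return data.frame with columns `comparison`, `statistic`, `p_value`,
#'   `n`, `stars`, `reliable`.
#' @export
compare_groups <- function(values_by_group,
                           test = c("mann_whitney", "tukey_hsd",
                                    "paired_t", "anova")) {
  test <- match.arg(test)
  g <- values_by_group
  stopifnot(is.list(g), length(g) >= 2L)
  if (is.null(names(g)) || any(names(g) == ""))
    names(g) <- paste0("group", seq_along(g))
  ns <- vapply(g, length, 0L)
  reliable <- all(ns >= 3L)
  if (!reliable)
    msg("group(s) with n < 3: results flagged unreliable")
  n_str <- paste(ns, collapse = "/")
  if (test %in% c("mann_whitney", "paired_t") && length(g) != 2L)
    stop(test, " requires exactly 2 groups")
  res <- switch(test,
    mann_whitney = {
      h <- suppressWarnings(wilcox.test(g[[1]], g[[2]]))
      data.frame(comparison = paste(names(g)[1], "vs", names(g)[2]),
                 statistic = unname(h$statistic), p_value = h$p.value)
    },
    paired_t = {
      if (length(g[[1]]) != length(g[[2]]))
        stop("paired_t requires equal-length groups")
      d <- g[[1]] - g[[2]]
      if (all(d == 0)) {
        data.frame(comparison = paste(names(g)[1], "vs", names(g)[2]),
                   statistic = 0, p_value = 1)
      } else {
        h <- t.test(g[[1]], g[[2]], paired = TRUE)
        data.frame(comparison = paste(names(g)[1], "vs", names(g)[2]),
                   statistic = unname(h$statistic), p_value = h$p.value)
      }
    },
    anova = {
      df <- data.frame(y = unlist(g),
                       grp = factor(rep(names(g), ns)))
      a <- summary(aov(y ~ grp, data = df))[[1]]
      data.frame(comparison = paste(names(g), collapse = " vs "),
                 statistic = a[["F value"]][1], p_value = a[["Pr(>F)"]][1])
    },
    tukey_hsd = {
      df <- data.frame(y = unlist(g),
                       grp = factor(rep(names(g), ns)))
      tk <- TukeyHSD(aov(y ~ grp, data = df))$grp
      data.frame(comparison = sub("-", " vs ", rownames(tk)),
                 statistic = tk[, "diff"], p_value = tk[, "p adj"])
    })
  res$n <- n_str
  res$stars <- p_stars(res$p_value)
  res$reliable <- reliable
  rownames(res) <- NULL
  res
}
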