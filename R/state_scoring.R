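# Two-class linear-discriminant cell-state scoring.
#
# The classifier is the closed-form two-class LDA on standardized features
# with the pooled covariance shrunk toward its diagonal (features are few
# but correlated; shrinkage keeps the solve stable without an external
# dependency). Every nucleus - train and test - receives a raw LDA1
# projection; the normalized score is the min-max of the raw projection
# over all scored nuclei, giving a per-nucleus cell-state readout in [0, 1].

#' Train a two-class LDA and score every nucleus
#'
#' @param features a `feature_table` ([compute_features()]) or data.frame
#'   containing the feature columns, a label column and optionally a
#'   `degenerate` flag column (flagged rows are excluded).
#' @param label_column name of the two-level condition column.
#' @param train_fraction fraction of nuclei used for training (default 0.75,
#'   stratified by class); the rest form the held-out test set.
#' @param balance if `TRUE`, the majority class is randomly downsampled
#'   (seeded) to the minority count before splitting.
#' @param shrinkage shrinkage intensity toward the diagonal of the pooled
#'   covariance in `[0, 1]`, or `"auto"` for `p / (p + n_train)`.
#' @param seed integer seed controlling balancing and the split.
#' @return object of class `score_set`: list with
#'   \describe{
#'     \item{scores}{data.frame: id, image_id, label, raw (LDA1 projection),
#'       score (min-max normalized to `[0, 1]`), split ("train"/"test"),
#'       predicted.}
#'     \item{coefficients}{named vector on the standardized feature scale.}
#'     \item{center, scale}{train-set standardization constants.}
#'     \item{intercept}{projection offset: `raw = z %*% coefficients -
#'       intercept` for standardized features `z`.}
#'     \item{test_accuracy}{held-out accuracy at the raw > 0 threshold.}
#'     \item{class_levels}{the two labels; raw > 0 predicts the second.}
#'     \item{groups, seed, shrinkage}{provenance.}
#'   }
#' @export
train_score_lda <- function(features, label_column = "condition",
                            train_fraction = 0.75, balance = TRUE,
                            shrinkage = "auto", seed = 1) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  groups <- attr(features, "groups", exact = TRUE)
  df <- as.data.frame(features)
  if (!label_column %in% names(df))
    stop("label column `", label_column, "` not found")
  feat_names <- if (!is.null(groups)) intersect(names(groups), names(df))
    else setdiff(names(df)[vapply(df, is.numeric, TRUE)],
                 c("id", "n_px", label_column))
  if ("degenerate" %in% names(df)) df <- df[!df$degenerate, , drop = FALSE]
  df <- df[stats::complete.cases(df[, feat_names, drop = FALSE]), ,
           drop = FALSE]
  lab <- as.character(df[[label_column]])
  levels_ <- sort(unique(lab))
  if (length(levels_) < 2L)
    stop("need exactly 2 condition labels, got ", length(levels_))
  if (length(levels_) > 2L)
    stop("more than 2 condition labels: ", paste(levels_, collapse = ", "))
  if (min(table(lab)) < 20L)
    stop("need at least 20 non-degenerate nuclei per label")

  with_seed(seed, {
    idx <- seq_len(nrow(df))
    if (balance) {
      n_min <- min(table(lab))
      idx <- unlist(lapply(levels_, function(l) {
        cand <- which(lab == l)
        if (length(cand) > n_min) sort(sample(cand, n_min)) else cand
      }))
    }
    lab_b <- lab[idx]
    # stratified split
    train_sel <- unlist(lapply(levels_, function(l) {
      cand <- which(lab_b == l)
      sample(cand, round(train_fraction * length(cand)))
    }))
    split <- rep("test", length(idx))
    split[train_sel] <- "train"

    X <- as.matrix(df[idx, feat_names, drop = FALSE])
    tr <- split == "train"
    ctr <- colMeans(X[tr, , drop = FALSE])
    scl <- apply(X[tr, , drop = FALSE], 2, sd)
    zero_var <- !is.finite(scl) | scl <= 0
    if (any(zero_var)) {
      msg("dropping %d zero-variance feature(s): %s", sum(zero_var),
          paste(feat_names[zero_var], collapse = ", "))
      feat_names <- feat_names[!zero_var]
      X <- X[, !zero_var, drop = FALSE]
      ctr <- ctr[!zero_var]; scl <- scl[!zero_var]
    }
    Z <- sweep(sweep(X, 2, ctr), 2, scl, "/")
    y <- lab_b == levels_[2]
    p <- ncol(Z)
    n_train <- sum(tr)
    gamma <- if (identical(shrinkage, "auto")) p / (p + n_train)
      else assert_scalar_num(shrinkage, "shrinkage", min = 0, max = 1)

    mu0 <- colMeans(Z[tr & !y, , drop = FALSE])
    mu1 <- colMeans(Z[tr & y, , drop = FALSE])
    c0 <- stats::cov(Z[tr & !y, , drop = FALSE])
    c1 <- stats::cov(Z[tr & y, , drop = FALSE])
    n0 <- sum(tr & !y); n1 <- sum(tr & y)
    S <- ((n0 - 1) * c0 + (n1 - 1) * c1) / (n0 + n1 - 2)
    S <- (1 - gamma) * S + gamma * diag(diag(S), p)
    diag(S) <- diag(S) + 1e-8 * mean(diag(S))
    w <- solve(S, mu1 - mu0)
    names(w) <- feat_names
    intercept <- sum((mu0 + mu1) / 2 * w)

    raw <- as.vector(Z %*% w) - intercept
    predicted <- ifelse(raw > 0, levels_[2], levels_[1])
    test_accuracy <- mean(predicted[!tr] == lab_b[!tr])
    score <- minmax01(raw)

    scores <- data.frame(
      id = if ("id" %in% names(df)) df$id[idx] else idx,
      image_id = if ("image_id" %in% names(df)) df$image_id[idx]
        else NA_character_,
      label = lab_b, raw = raw, score = score, split = split,
      predicted = predicted)
    structure(list(scores = scores, coefficients = w, center = ctr,
                   scale = scl, intercept = intercept,
                   test_accuracy = test_accuracy, class_levels = levels_,
                   groups = if (!is.null(groups))
                     groups[feat_names] else setNames(
                       rep(NA_character_, length(feat_names)), feat_names),
                   seed = seed, shrinkage = gamma),
              class = "score_set")
  })
}

#' Rank features by their LDA coefficient magnitude
#'
#' Features are sorted by `|coefficient|` on the standardized inputs,
#' descending, ties broken lexicographically by feature name.
#'
#' @param score_set a `score_set` from [train_score_lda()].
#' @param top_k number of features to return; values larger than the
#'   number of features return all (with a message).
#' @return data.frame with columns `feature`, `group`, `coefficient`.
#' @export
rank_feature_groups <- function(score_set, top_k = 10L) {
  stopifnot(inherits(score_set, "score_set"), top_k >= 0)
  w <- score_set$coefficients
  if (top_k > length(w)) {
    msg("top_k = %d exceeds %d features; returning all", top_k, length(w))
    top_k <- length(w)
  }
  ord <- order(-abs(w), names(w))
  sel <- head(ord, top_k)
  data.frame(feature = names(w)[sel],
             group = unname(score_set$groups[names(w)[sel]]),
             coefficient = unname(w[sel]))
}

#' @export
print.score_set <- function(x, ...) {
  cat(sprintf(paste0("<score_set> %d nuclei (%s), test accuracy %.3f, ",
                     "shrinkage %.3f, seed %d\n"),
              nrow(x$scores), paste(x$class_levels, collapse = " vs "),
              x$test_accuracy, x$shrinkage, x$seed))
  invisible(x)
}

#' Write scores as CSV and the model as JSON
#'
#' @param score_set a `score_set`.
#' @param dir output directory.
#' @param prefix file-name prefix.
#' @return invisibly, the paths written.
#' @export
write_score_set <- function(score_set, dir, prefix = "lda") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p_csv <- file.path(dir, paste0(prefix, "_scores.csv"))
  p_json <- file.path(dir, paste0(prefix, "_model.json"))
  write.csv(score_set$scores, p_csv, row.names = FALSE)
  model <- list(features = names(score_set$coefficients),
                coefficients = unname(score_set$coefficients),
                center = unname(score_set$center),
                scale = unname(score_set$scale),
                intercept = score_set$intercept,
                class_levels = score_set$class_levels,
                test_accuracy = score_set$test_accuracy,
                shrinkage = score_set$shrinkage,
                seed = score_set$seed)
  jsonlite::write_json(model, p_json, auto_unbox = TRUE, digits = NA)
  invisible(c(scores = p_csv, model = p_json))
}
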