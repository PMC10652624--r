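#' Random-forest configuration for FOG classification
#'
#' The detector is an ensemble of cost-sensitive classification trees,
#' chosen over margin-based learners because tree traversal is cheap enough
#' for per-sample use on an embedded processor. FOG detection is highly
#' imbalanced (walking dominates), so the misclassification cost of a false
#' negative (missed FOG) is set 10 times that of a false positive.
#'
#' @param n_trees number of trees (default 25).
#' @param max_size maximum tree depth (default 15).
#' @param prune_alpha cost-complexity pruning parameter (rpart `cp`); small
#'   positive default keeps pruning enabled.
#' @param false_negative_cost_ratio cost of a missed FOG window relative to a
#'   false alarm (default 10).
#' @param decision_threshold probability (fraction of trees voting FOG) above
#'   which a window is labeled FOG.
#' @param mtry number of candidate features per tree (random subspace);
#'   default `floor(sqrt(p))` at fit time.
#' @param min_split minimum node size to attempt a split.
#' @param seed integer; fixed seed gives identical forests.
#' @return A list of class `forest_config`.
#' @export
forest_config <- function(n_trees = 25L, max_size = 15L, prune_alpha = 0.001,
                          false_negative_cost_ratio = 10,
                          decision_threshold = 0.5, mtry = NULL,
                          min_split = 20L, seed = 1L) {
  stopifnot(n_trees >= 1, false_negative_cost_ratio > 0,
            decision_threshold >= 0, decision_threshold <= 1,
            max_size >= 1, prune_alpha >= 0)
  structure(list(n_trees = as.integer(n_trees), max_size = as.integer(max_size),
                 prune_alpha = prune_alpha,
                 false_negative_cost_ratio = false_negative_cost_ratio,
                 decision_threshold = decision_threshold, mtry = mtry,
                 min_split = as.integer(min_split), seed = as.integer(seed)),
            class = "forest_config")
}

#' Train the FOG random forest
#'
#' Fits `n_trees` cost-sensitive trees, each on a bootstrap resample of the
#' labeled windows using a random feature subspace of size `mtry`. Each tree
#' is depth-capped, cost-complexity pruned, and carries the asymmetric loss
#' matrix (false negatives `false_negative_cost_ratio` times costlier than
#' false positives), so individual tree votes already reflect the detection
#' objective. Windows labeled `unannotated` are excluded.
#'
#' @param features a `window_features` data frame (see [extract_features()])
#'   with a `label` column containing both `fog` and `no_fog`.
#' @param config a [forest_config()].
#' @return An object of class `fog_forest`.
#' @export
fog_train <- function(features, config = forest_config()) {
  fcols <- feature_columns(features)
  if (!length(fcols)) stop("no feature columns found", call. = FALSE)
  keep <- features$label %in% c("fog", "no_fog")
  df <- features[keep, c(fcols, "label")]
  df$label <- factor(df$label, levels = c("no_fog", "fog"))
  if (length(unique(df$label)) < 2) {
    stop("degenerate labels: training data must contain both fog and no_fog windows",
         call. = FALSE)
  }
  p <- length(fcols)
  mtry <- config$mtry %||% max(1L, floor(sqrt(p)))
  # loss[i, j]: cost of classifying a row of true class i (row) as j (col);
  # levels are (no_fog, fog), so [2, 1] is the missed-FOG cell.
  loss <- matrix(c(0, config$false_negative_cost_ratio, 1, 0), 2, 2)
  ctl <- rpart::rpart.control(maxdepth = config$max_size, cp = config$prune_alpha,
                              minsplit = config$min_split, xval = 0)
  n <- nrow(df)
  trees <- with_seed(config$seed, lapply(seq_len(config$n_trees), function(b) {
    rows <- sample.int(n, n, replace = TRUE)
    feats <- sort(sample.int(p, mtry))
    fit <- rpart::rpart(label ~ ., data = df[rows, c(fcols[feats], "label")],
                        method = "class", parms = list(loss = loss),
                        control = ctl)
    list(fit = fit, features = fcols[feats])
  }))
  structure(list(trees = trees, feature_names = fcols, config = config,
                 classes = c("no_fog", "fog")),
            class = "fog_forest")
}

#' Predict FOG probabilities for feature windows
#'
#' The per-window FOG probability is the fraction of trees whose
#' (cost-aware) class vote is FOG; the label applies the configured decision
#' threshold.
#'
#' @param model a [fog_train()] forest.
#' @param features a `window_features` data frame with the training feature
#'   columns.
#' @param threshold decision threshold override.
#' @return A data frame of class `fog_track`: `window_end_time`,
#'   `probability`, `label_pred`, and `label_true` where available.
#' @export
fog_predict <- function(model, features, threshold = NULL) {
  threshold <- threshold %||% model$config$decision_threshold
  missing_cols <- setdiff(model$feature_names, names(features))
  if (length(missing_cols)) {
    stop("feature columns missing from input: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  votes <- vapply(model$trees, function(tr) {
    cls <- predict(tr$fit, newdata = features, type = "class")
    as.numeric(cls == "fog")
  }, numeric(nrow(features)))
  if (nrow(features) == 1L) votes <- matrix(votes, nrow = 1L)
  prob <- rowMeans(votes)
  out <- data.frame(
    window_end_time = if ("window_end_time" %in% names(features))
      features$window_end_time else seq_len(nrow(features)),
    probability = prob,
    label_pred = ifelse(prob >= threshold, "fog", "no_fog"),
    stringsAsFactors = FALSE)
  if ("label" %in% names(features)) out$label_true <- features$label
  class(out) <- c("fog_track", "data.frame")
  out
}
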