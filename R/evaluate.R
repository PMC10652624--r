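#' ROC curve and AUC by threshold sweep
#'
#' Sweeps the decision threshold over the unique predicted probabilities and
#' reports one operating point per threshold, plus the (0,0) and (1,1)
#' anchors. AUC is computed by the trapezoid rule over the curve sorted by
#' false-positive rate.
#'
#' @param probabilities numeric vector of FOG probabilities in `[0, 1]`.
#' @param truth labels, `"fog"`/`"no_fog"` (or logical, `TRUE` = fog).
#'   Both classes must be present.
#' @return List with `points` (data frame `threshold`, `fpr` = 1-specificity,
#'   `tpr` = sensitivity) and `auc`.
#' @export
roc_curve <- function(probabilities, truth) {
  if (is.logical(truth)) truth <- ifelse(truth, "fog", "no_fog")
  pos <- truth == "fog"
  if (!any(pos) || all(pos)) {
    stop("ROC undefined: truth contains a single class", call. = FALSE)
  }
  np <- sum(pos); nn <- sum(!pos)
  th <- sort(unique(probabilities), decreasing = TRUE)
  tpr <- vapply(th, function(t) sum(probabilities >= t & pos) / np, numeric(1))
  fpr <- vapply(th, function(t) sum(probabilities >= t & !pos) / nn, numeric(1))
  pts <- data.frame(threshold = c(Inf, th, -Inf),
                    fpr = c(0, fpr, 1), tpr = c(0, tpr, 1))
  pts <- pts[order(pts$fpr, pts$tpr), ]
  auc <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) + utils::tail(pts$tpr, -1)) / 2)
  list(points = pts, auc = auc)
}

confusion_rates <- function(pred_fog, true_fog) {
  tp <- sum(pred_fog & true_fog); fn <- sum(!pred_fog & true_fog)
  tn <- sum(!pred_fog & !true_fog); fp <- sum(pred_fog & !true_fog)
  list(tp = tp, fn = fn, tn = tn, fp = fp,
       sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
}

#' Leave-one-subject-out evaluation of the FOG detector
#'
#' For each subject, trains the forest on all other subjects' annotated
#' windows and evaluates on the held-out subject, preventing within-subject
#' leakage between neighbouring windows. Reports window-level sensitivity
#' (`TP/(TP+FN)`) and specificity (`TN/(TN+FP)`) per subject and their means
#' across subjects; a subject lacking one class has that metric flagged
#' `NA` (undefined) and excluded from the mean. The ROC is computed over the
#' pooled held-out predictions.
#'
#' @param features a `window_features` data frame covering >= 2 subjects
#'   (`subject_id` column), labels `fog`/`no_fog` (unannotated excluded).
#' @param config a [forest_config()].
#' @return A list of class `loso_report`: `per_subject` data frame
#'   (`subject_id`, `sensitivity`, `specificity`, `n_fog_windows`,
#'   `n_nofog_windows`), `mean_sensitivity`, `mean_specificity`, `roc`
#'   (points + `auc`), and `pooled` predictions.
#' @export
leave_one_subject_out <- function(features, config = forest_config()) {
  keep <- features$label %in% c("fog", "no_fog")
  df <- features[keep, , drop = FALSE]
  subjects <- unique(df$subject_id)
  if (length(subjects) < 2) {
    stop("leave-one-subject-out needs >= 2 subjects", call. = FALSE)
  }
  per <- vector("list", length(subjects))
  pooled_prob <- numeric(0); pooled_true <- character(0)
  pooled_subj <- character(0)
  for (i in seq_along(subjects)) {
    s <- subjects[i]
    train <- df[df$subject_id != s, , drop = FALSE]
    # canonical row order: bootstrap draws must not depend on how the other
    # subjects' windows happened to be concatenated
    train <- train[order(train$subject_id, train$window_end_time), , drop = FALSE]
    test <- df[df$subject_id == s, , drop = FALSE]
    model <- fog_train(train, config)
    track <- fog_predict(model, test)
    cr <- confusion_rates(track$label_pred == "fog", test$label == "fog")
    per[[i]] <- data.frame(subject_id = s,
                           sensitivity = cr$sensitivity,
                           specificity = cr$specificity,
                           n_fog_windows = sum(test$label == "fog"),
                           n_nofog_windows = sum(test$label == "no_fog"),
                           stringsAsFactors = FALSE)
    pooled_prob <- c(pooled_prob, track$probability)
    pooled_true <- c(pooled_true, test$label)
    pooled_subj <- c(pooled_subj, test$subject_id)
  }
  per <- do.call(rbind, per)
  roc <- if (length(unique(pooled_true)) > 1) roc_curve(pooled_prob, pooled_true)
         else NULL
  structure(list(per_subject = per,
                 mean_sensitivity = mean(per$sensitivity, na.rm = TRUE),
                 mean_specificity = mean(per$specificity, na.rm = TRUE),
                 roc = roc,
                 pooled = data.frame(subject_id = pooled_subj,
                                     probability = pooled_prob,
                                     label_true = pooled_true,
                                     stringsAsFactors = FALSE)),
            class = "loso_report")
}

#' @export
print.loso_report <- function(x, ...) {
  cat("<loso_report>\n")
  print(x$per_subject, row.names = FALSE)
  cat(sprintf("mean sensitivity %.1f%%, mean specificity %.1f%%",
              100 * x$mean_sensitivity, 100 * x$mean_specificity))
  if (!is.null(x$roc)) cat(sprintf(", pooled AUC %.3f", x$roc$auc))
  cat("\n")
  invisible(x)
}
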