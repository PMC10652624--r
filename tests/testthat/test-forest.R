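test_that("training demands both classes and excludes unannotated windows", {
  feats <- small_cohort_features()
  expect_error(fog_train(feats[feats$label == "no_fog", ]), "degenerate labels")
  # flipping some labels to unannotated must not smuggle them into training
  f2 <- feats
  f2$label[f2$label == "fog"] <- "unannotated"
  expect_error(fog_train(f2), "degenerate labels")
})

test_that("the forest separates synthetic trembling from walking on resubstitution", {
  feats <- small_cohort_features()
  model <- small_model()
  track <- fog_predict(model, feats)
  keep <- feats$label %in% c("fog", "no_fog")
  acc <- mean(track$label_pred[keep] == feats$label[keep])
  expect_gte(acc, 0.98)
})

test_that("training is deterministic under a fixed seed", {
  feats <- small_cohort_features()
  probe <- feats[seq(1, nrow(feats), by = 7), ]
  m1 <- fog_train(feats, forest_config(seed = 42))
  m2 <- fog_train(feats, forest_config(seed = 42))
  expect_identical(fog_predict(m1, probe)$probability,
                   fog_predict(m2, probe)$probability)
})

test_that("prediction is pointwise and thresholds behave at the boundaries", {
  model <- small_model()
  feats <- small_cohort_features()
  probe <- feats[5, ]
  dup <- probe[rep(1, 4), ]
  p <- fog_predict(model, dup)$probability
  expect_true(all(p == p[1]))
  expect_true(all(fog_predict(model, feats, threshold = 0)$label_pred == "fog"))
  expect_true(all(fog_predict(model, feats, threshold = 1.01)$label_pred == "no_fog"))
  expect_error(fog_predict(model, feats[, 1:3]), "missing")
})

test_that("an all-walking stream stays below 5% false alarms", {
  model <- small_model()
  sim <- generate_recording(synthetic_config(duration = 120, fog_episode_rate = 0,
                                             seed = 31))
  f <- extract_features(sim$recording, hop = 32)
  track <- fog_predict(model, f)
  expect_lte(mean(track$label_pred == "fog"), 0.05)
})

test_that("raising the miss cost does not lower held-out sensitivity", {
  # imbalanced cohorts: rare, short FOG episodes
  sens_at <- function(ratio) {
    mean(vapply(1:3, function(s) {
      feats <- do.call(rbind, lapply(1:3, function(subj) {
        cfg <- synthetic_config(duration = 120, fog_episode_rate = 1.5,
                                fog_duration_mean = 3, fog_duration_sd = 1,
                                noise_sd = 0.8, freeze_tremble_amplitude = 0.8,
                                seed = 10 * s + subj)
        extract_features(generate_recording(cfg)$recording, hop = 32)
      }))
      rep <- leave_one_subject_out(feats,
        forest_config(false_negative_cost_ratio = ratio, seed = s))
      rep$mean_sensitivity
    }, numeric(1)))
  }
  expect_gte(sens_at(10) + 0.02, sens_at(1))  # small slack for tree tie-breaks
})

test_that("ROC sweep matches hand enumeration and an independent library", {
  r <- roc_curve(c(0.9, 0.8, 0.3, 0.1), c("fog", "fog", "no_fog", "no_fog"))
  expect_equal(r$auc, 1)
  expect_equal(roc_curve(c(1, 1, 0, 0), c("fog", "fog", "no_fog", "no_fog"))$auc, 1)
  expect_equal(roc_curve(rep(0.4, 6), rep(c("fog", "no_fog"), 3))$auc, 0.5)
  expect_error(roc_curve(c(0.1, 0.9), c("fog", "fog")), "single class")
  skip_if_not_installed("pROC")
  set.seed(5)
  prob <- runif(200)
  truth <- ifelse(runif(200) < plogis(4 * (prob - 0.5)), "fog", "no_fog")
  ours <- roc_curve(prob, truth)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = truth, predictor = prob, levels = c("no_fog", "fog"),
    direction = "<", quiet = TRUE)))
  expect_equal(ours, ref, tolerance = 1e-9)
})

test_that("LOSO reports per-subject metrics and survives a FOG-free subject", {
  feats <- small_cohort_features()
  expect_error(leave_one_subject_out(feats[feats$subject_id == "synth1", ]),
               ">= 2 subjects")
  nofog <- extract_features(
    generate_recording(synthetic_config(duration = 120, fog_episode_rate = 0,
                                        seed = 77))$recording, hop = 32)
  rep <- leave_one_subject_out(rbind(feats, nofog))
  row <- rep$per_subject[rep$per_subject$subject_id == "synth77", ]
  expect_true(is.na(row$sensitivity))   # undefined, not zero-filled
  expect_false(is.na(row$specificity))
  expect_false(is.na(rep$mean_sensitivity))
  # confusion recount from the pooled predictions at threshold 0.5
  pool <- rep$pooled
  for (s in unique(pool$subject_id)) {
    sub <- pool[pool$subject_id == s, ]
    pred <- sub$probability >= 0.5
    truth <- sub$label_true == "fog"
    want <- if (any(truth)) sum(pred & truth) / sum(truth) else NA_real_
    expect_equal(rep$per_subject$sensitivity[rep$per_subject$subject_id == s],
                 want)
  }
})

test_that("held-out predictions ignore the ordering of other subjects' data", {
  feats <- small_cohort_features()
  set.seed(1)
  shuffled <- feats[sample(nrow(feats)), ]
  r1 <- leave_one_subject_out(feats, forest_config(seed = 3))
  r2 <- leave_one_subject_out(shuffled, forest_config(seed = 3))
  p1 <- r1$pooled[order(r1$pooled$subject_id, r1$pooled$probability), ]
  p2 <- r2$pooled[order(r2$pooled$subject_id, r2$pooled$probability), ]
  expect_equal(p1$probability, p2$probability)
  s1 <- r1$per_subject[order(r1$per_subject$subject_id), ]
  s2 <- r2$per_subject[order(r2$per_subject$subject_id), ]
  expect_equal(s1$sensitivity, s2$sensitivity)
  expect_equal(s1$specificity, s2$specificity)
})
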