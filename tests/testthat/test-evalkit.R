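test_that("confusion counts match a brute-force tally", {
  labels <- c("malignant", "malignant", "benign", "benign")
  expect_equal(unclass(confusion(labels, labels))[c("TP", "FN", "TN", "FP")],
               list(TP = 2, FN = 0, TN = 2, FP = 0))
  flipped <- ifelse(labels == "benign", "malignant", "benign")
  cmf <- confusion(labels, flipped)
  expect_equal(cmf$TP + cmf$TN, 0)
  set.seed(12)
  lab <- sample(c("benign", "malignant"), 200, replace = TRUE)
  pred <- sample(c("benign", "malignant"), 200, replace = TRUE)
  cm <- confusion(lab, pred)
  expect_equal(cm$TP, sum(lab == "malignant" & pred == "malignant"))
  expect_equal(cm$FN + cm$TP, sum(lab == "malignant"))
  expect_equal(cm$TN + cm$FP, sum(lab == "benign"))
  expect_error(confusion(lab, pred[-1]), class = "phb_input_error")
  expect_error(confusion(c("tumor"), c("benign")), class = "phb_input_error")
})

test_that("scalar metrics reproduce their defining formulas on random fixtures", {
  perfect <- metrics(confusion(rep(c("benign", "malignant"), 5),
                               rep(c("benign", "malignant"), 5)))
  expect_true(all(perfect$value == 1))
  # total disagreement on a balanced fixture: MCC = -1
  m_flip <- metrics(structure(list(TP = 0, FN = 10, TN = 0, FP = 10),
                              class = "confusion_matrix"))
  expect_equal(m_flip$value[m_flip$metric == "mcc"], -1)
  # worked example
  m <- metrics(structure(list(TP = 50, FN = 10, TN = 80, FP = 20),
                         class = "confusion_matrix"))
  o <- oracle_metrics(50, 10, 80, 20)
  expect_equal(setNames(m$value, m$metric), o)
  # random sweep against the formula oracle
  set.seed(31)
  for (i in 1:250) {
    cts <- rpois(4, 20)
    if (cts[1] + cts[2] == 0 || cts[3] + cts[4] == 0) next
    cm <- structure(list(TP = cts[1], FN = cts[2], TN = cts[3], FP = cts[4]),
                    class = "confusion_matrix")
    got <- metrics(cm)
    want <- oracle_metrics(cts[1], cts[2], cts[3], cts[4])
    expect_equal(setNames(got$value, got$metric), want, tolerance = 1e-12)
  }
})

test_that("MCC conventions: zero denominator flags 0; symmetric under class swap", {
  all_ben_pred <- metrics(confusion(c("benign", "malignant"),
                                    c("benign", "benign")))
  expect_equal(all_ben_pred$value[all_ben_pred$metric == "mcc"], 0)
  expect_true(attr(all_ben_pred, "mcc_undefined"))
  set.seed(8)
  lab <- sample(c("benign", "malignant"), 60, replace = TRUE)
  pred <- sample(c("benign", "malignant"), 60, replace = TRUE)
  swap <- function(v) ifelse(v == "benign", "malignant", "benign")
  m1 <- metrics(confusion(lab, pred))
  m2 <- metrics(confusion(swap(lab), swap(pred)))
  expect_equal(m1$value[m1$metric == "mcc"], m2$value[m2$metric == "mcc"],
               tolerance = 1e-12)
})

test_that("ROC/AUC equals the pair-counting oracle, with tie handling", {
  lab <- c(rep("malignant", 5), rep("benign", 5))
  expect_equal(roc_auc(lab, c(6:10, 1:5))$auc, 1)
  expect_equal(roc_auc(lab, rep(1, 10))$auc, 0.5)
  set.seed(17)
  for (i in 1:100) {
    n <- 30
    lab <- sample(c("benign", "malignant"), n, replace = TRUE,
                  prob = c(0.6, 0.4))
    if (length(unique(lab)) < 2) next
    scores <- round(rnorm(n, ifelse(lab == "malignant", 0.5, 0), 1), 1)
    rc <- roc_auc(lab, scores)
    expect_equal(rc$auc, oracle_auc_pairs(lab, scores), tolerance = 1e-12)
    expect_true(all(diff(rc$curve$fpr) >= 0))
    expect_true(all(diff(rc$curve$tpr) >= 0))
  }
  expect_error(roc_auc(rep("benign", 5), 1:5), class = "phb_input_error")
})

test_that("AUC is invariant under the monotone score-to-probability map", {
  tab <- gaussian_table(100, seed = 23)
  m <- train_adaboost(tab, hyperparameters(0.5, 20, 2))
  a1 <- roc_auc(tab$label, predict_score(m, tab))$auc
  a2 <- roc_auc(tab$label, predict_proba(m, tab))$auc
  expect_equal(a1, a2, tolerance = 1e-12)
})

test_that("vertical ROC averaging interpolates on the common FPR grid", {
  rc <- roc_auc(c(rep("malignant", 3), rep("benign", 3)),
                c(3, 2.5, 1, 2, 0.5, 0.2))
  avg_same <- average_roc(list(rc, rc))
  f <- function(x) avg_same$tpr_mean[avg_same$fpr == x]
  expect_true(all(avg_same$tpr_sd == 0))
  expect_true(all(diff(avg_same$tpr_mean) >= 0))
  # two hand-built step curves average pointwise
  c1 <- structure(list(curve = tibble::tibble(threshold = c(Inf, 1, 0),
                                              tpr = c(0, 1, 1),
                                              fpr = c(0, 0, 1)),
                       auc = 1), class = "roc_curve")
  c2 <- structure(list(curve = tibble::tibble(threshold = c(Inf, 1, 0),
                                              tpr = c(0, 0, 1),
                                              fpr = c(0, 1, 1)),
                       auc = 0), class = "roc_curve")
  avg <- average_roc(list(c1, c2))
  expect_equal(avg$tpr_mean[avg$fpr == 0.5], 0.5)
  expect_equal(avg$tpr_mean[avg$fpr == 1], 1)
})

test_that("repeated cross-validated evaluation aggregates reproducibly", {
  tab <- gaussian_table(80, seed = 41)
  ev1 <- repeat_evaluate(tab, hyperparameters(0.5, 15, 1), n_repeats = 3,
                         k = 4, seed = 6)
  ev2 <- repeat_evaluate(tab, hyperparameters(0.5, 15, 1), n_repeats = 3,
                         k = 4, seed = 6)
  expect_identical(ev1$metrics, ev2$metrics)
  expect_identical(ev1$confusion, ev2$confusion)
  expect_equal(sum(ev1$confusion_mean), nrow(tab))
  expect_true(all(c("sensitivity", "specificity", "accuracy", "ppv", "npv",
                    "mcc", "auc") %in% ev1$metrics$metric))
  # separable data: all repeats identical, SD 0
  sep <- tibble::tibble(f1 = c(1:10, 101:110),
                        label = rep(c("benign", "malignant"), each = 10))
  evs <- repeat_evaluate(sep, hyperparameters(1, 5, 1), n_repeats = 3, k = 5,
                         seed = 1)
  expect_true(all(evs$metrics$sd == 0))
  expect_true(all(evs$metrics$mean == 1))
  # emitted metrics satisfy the confusion identities
  cm <- ev1$confusion_mean
  met <- setNames(ev1$metrics$mean, ev1$metrics$metric)
  expect_equal(met[["accuracy"]], (cm[["TP"]] + cm[["TN"]]) / sum(cm),
               tolerance = 1e-12)
  expect_equal(met[["sensitivity"]], cm[["TP"]] / (cm[["TP"]] + cm[["FN"]]),
               tolerance = 1e-12)
})

test_that("predictor importance localizes on the features actually used", {
  tab2 <- tibble::tibble(f1 = c(1, 2, 9, 10), f2 = c(5, 5, 5, 5),
                         label = c("benign", "benign",
                                   "malignant", "malignant"))
  m <- train_adaboost(tab2, hyperparameters(1, 3, 1))
  imp <- predictor_importance(m)
  expect_equal(imp$importance[imp$feature == "f1"], 1)
  expect_equal(imp$importance[imp$feature == "f2"], 0)
  expect_equal(sum(imp$importance), 1)
})

test_that("channel aggregation ranks the channels carrying the class signal", {
  # cohort whose classes differ in the CH1/CH5 lifetimes only
  tab <- memo("cohort_lifetime_only",
              simulate_cohort(60, lifetime_only_config(), seed = 303L,
                              points_per_roi = 5L))
  m <- train_adaboost(tab, hyperparameters(0.3, 60, 3))
  agg <- aggregate_by_channel(predictor_importance(m))
  expect_setequal(agg$channel, c("CH1", "CH2", "CH3", "CH4", "CH5", "RR"))
  get <- function(ch) agg$importance[agg$channel == ch]
  expect_gt(max(get("CH1"), get("CH5")), max(get("CH2"), get("CH3")))
})

test_that("the feature-pool ablation reports one row per pool with correct sizes", {
  cfg <- lifetime_only_config()
  tr <- simulate_cohort(40, cfg, seed = 61, points_per_roi = 3,
                        cohort = "train")
  te <- simulate_cohort(24, cfg, seed = 62, points_per_roi = 3,
                        cohort = "test")
  rep <- run_ablation(tr, te, pools = c("all", "intensity_only",
                                        "lifetime_only"),
                      n_cycles = 4, k = 4, n_repeats = 2, n_test_models = 2,
                      seed = 3)
  expect_equal(nrow(rep), 3)
  expect_equal(rep$n_features, c(26L, 6L, 20L))
  expect_true(all(c("cv_accuracy_mean", "cv_auc_sd", "test_mcc")
                  %in% names(rep)))
  # classes differ only in lifetimes here: intensity-only must do worse
  expect_lt(rep$test_auc[rep$pool == "intensity_only"],
            rep$test_auc[rep$pool == "lifetime_only"])
  expect_error(run_ablation(tr, te, pools = "bogus"),
               class = "phb_input_error")
})
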