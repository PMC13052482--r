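# Binary-classification evaluation: confusion counts (malignant = positive),
# scalar metrics incl. MCC, ROC/AUC by threshold sweep, repeated
# cross-validation aggregation, predictor importance and the feature-pool
# ablation.

#' Confusion matrix with malignant as the positive class
#'
#' @param labels,predictions Vectors of `"benign"`/`"malignant"`.
#' @return A `confusion_matrix`: named list TP, FN, TN, FP.
#' @export
confusion <- function(labels, predictions) {
  if (length(labels) != length(predictions)) {
    abort("labels and predictions differ in length.",
          class = "phb_input_error")
  }
  ok <- c("benign", "malignant")
  if (!all(labels %in% ok) || !all(predictions %in% ok)) {
    abort("labels must be 'benign' or 'malignant'.",
          class = "phb_input_error")
  }
  structure(
    list(TP = sum(labels == "malignant" & predictions == "malignant"),
         FN = sum(labels == "malignant" & predictions == "benign"),
         TN = sum(labels == "benign" & predictions == "benign"),
         FP = sum(labels == "benign" & predictions == "malignant")),
    class = "confusion_matrix"
  )
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion_matrix> TP=%g FN=%g TN=%g FP=%g\n",
              x$TP, x$FN, x$TN, x$FP))
  invisible(x)
}

#' Scalar metrics from a confusion matrix
#'
#' Sensitivity TP/(TP+FN), specificity TN/(TN+FP), accuracy (TP+TN)/N,
#' PPV TP/(TP+FP), NPV TN/(TN+FN) and the Matthews correlation coefficient
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`. A zero MCC
#' denominator yields MCC 0 with an `mcc_undefined` attribute flag.
#'
#' @param cm A [confusion()] result.
#' @return Tibble with columns `metric`, `value`.
#' @export
metrics <- function(cm) {
  n <- cm$TP + cm$FN + cm$TN + cm$FP
  if (n == 0) abort("empty confusion matrix.", class = "phb_input_error")
  safe_div <- function(a, b) if (b > 0) a / b else NA_real_
  denom <- sqrt(prod(c(cm$TP + cm$FP, cm$TP + cm$FN,
                       cm$TN + cm$FP, cm$TN + cm$FN)))
  mcc_undef <- denom == 0
  mcc <- if (mcc_undef) 0 else (cm$TP * cm$TN - cm$FP * cm$FN) / denom
  out <- tibble::tibble(
    metric = c("sensitivity", "specificity", "accuracy", "ppv", "npv", "mcc"),
    value = c(safe_div(cm$TP, cm$TP + cm$FN),
              safe_div(cm$TN, cm$TN + cm$FP),
              (cm$TP + cm$TN) / n,
              safe_div(cm$TP, cm$TP + cm$FP),
              safe_div(cm$TN, cm$TN + cm$FN),
              mcc)
  )
  attr(out, "mcc_undefined") <- mcc_undef
  out
}

#' ROC curve and AUC by threshold sweep
#'
#' Sweeps the unique scores as thresholds (predict malignant when
#' `score >= threshold`); tied scores cross simultaneously, producing
#' diagonal segments, and the AUC is the trapezoidal area (equal to the
#' tie-corrected Mann-Whitney statistic).
#'
#' @param labels `"benign"`/`"malignant"` vector; both classes must occur.
#' @param scores Numeric classifier scores (higher = more malignant).
#' @return A `roc_curve`: list with `curve` (tibble `threshold, fpr, tpr`)
#'   and `auc`.
#' @export
roc_auc <- function(labels, scores) {
  pos <- labels == "malignant"
  if (!any(pos) || all(pos)) {
    abort("both classes must be present for a ROC curve.",
          class = "phb_input_error")
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  p <- pos[ord]
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(p)
  fp <- cumsum(!p)
  last <- !duplicated(grp, fromLast = TRUE)
  curve <- tibble::tibble(
    threshold = c(Inf, s[last]),
    tpr = c(0, tp[last] / sum(pos)),
    fpr = c(0, fp[last] / sum(!pos))
  )
  auc <- sum(diff(curve$fpr) * (head(curve$tpr, -1) + tail(curve$tpr, -1)) / 2)
  structure(list(curve = curve, auc = auc), class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> %d points, AUC %.4f\n", nrow(x$curve), x$auc))
  invisible(x)
}

#' Vertical averaging of ROC curves
#'
#' Evaluates each step curve's TPR on a common FPR grid and averages
#' vertically, with a per-iteration SD band.
#'
#' @param curves List of [roc_auc()] results.
#' @param grid FPR grid (default 0..1 by 0.01).
#' @return Tibble `fpr, tpr_mean, tpr_sd`.
#' @export
average_roc <- function(curves, grid = seq(0, 1, by = 0.01)) {
  if (length(curves) == 0L) abort("no curves to average.")
  tprs <- vapply(curves, function(rc) {
    # collapse vertical segments: max TPR attained at each distinct FPR
    agg <- rc$curve |>
      dplyr::group_by(.data$fpr) |>
      dplyr::summarise(tpr = max(.data$tpr)) |>
      dplyr::arrange(.data$fpr)
    if (nrow(agg) == 1L) return(rep(agg$tpr, length(grid)))
    f <- stats::stepfun(agg$fpr[-1], agg$tpr, right = FALSE)
    f(grid)
  }, numeric(length(grid)))
  tprs <- matrix(tprs, nrow = length(grid))
  tibble::tibble(
    fpr = grid,
    tpr_mean = rowMeans(tprs),
    tpr_sd = apply(tprs, 1, sd)
  )
}

#' Repeated cross-validated evaluation
#'
#' Runs stratified k-fold cross-validation `n_repeats` times with fresh fold
#' shuffles; per repeat, held-out predictions are pooled into one confusion
#' matrix, scalar metrics and a ROC curve. Metrics are aggregated as mean and
#' SD across repeats; the displayed pooled confusion matrix holds mean counts
#' rounded to the closest integer while percentages/metrics use the unrounded
#' values.
#'
#' @inheritParams cross_validate
#' @param n_repeats Number of repeated CV passes (default 20).
#' @return A `repeat_eval`: `metrics` (tibble `metric, mean, sd`),
#'   `confusion` (rounded mean counts), `confusion_mean` (unrounded),
#'   `curves`, `mean_curve`.
#' @export
repeat_evaluate <- function(table, hp, n_repeats = 20L, k = 5L, seed = 1L) {
  if (n_repeats < 1L) abort("n_repeats must be >= 1.",
                            class = "phb_config_error")
  per_rep <- purrr::map(seq_len(n_repeats), function(r) {
    res <- cv_run(table, hp, k, seed = derive_seed(seed, r))
    pred <- ifelse(res$prob >= 0.5, "malignant", "benign")
    cm <- confusion(res$label, pred)
    rc <- roc_auc(res$label, res$prob)
    met <- dplyr::bind_rows(metrics(cm),
                            tibble::tibble(metric = "auc", value = rc$auc))
    list(cm = cm, roc = rc, metrics = met)
  })
  met <- purrr::map_dfr(per_rep, "metrics") |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(mean = mean(.data$value),
                     sd = if (dplyr::n() > 1) sd(.data$value) else 0) |>
    dplyr::arrange(match(.data$metric, c("sensitivity", "specificity",
                                         "accuracy", "ppv", "npv", "mcc",
                                         "auc")))
  cms <- purrr::map(per_rep, "cm")
  mean_cm <- vapply(c("TP", "FN", "TN", "FP"),
                    function(f) mean(vapply(cms, `[[`, numeric(1), f)),
                    numeric(1))
  structure(
    list(metrics = met,
         confusion = round(mean_cm),
         confusion_mean = mean_cm,
         curves = purrr::map(per_rep, "roc"),
         mean_curve = average_roc(purrr::map(per_rep, "roc"))),
    class = "repeat_eval"
  )
}

#' @export
print.repeat_eval <- function(x, ...) {
  cat(sprintf("<repeat_eval> %d repeats\n", length(x$curves)))
  m <- x$metrics
  for (i in seq_len(nrow(m))) {
    cat(sprintf("  %-12s %.3f ± %.3f\n", m$metric[i], m$mean[i], m$sd[i]))
  }
  invisible(x)
}

#' Predictor importance of an ensemble
#'
#' Per feature, the sum of weighted Gini impurity decreases over every split
#' using that feature across all weak learners, normalized to sum 1.
#'
#' @param model An `ensemble_model`.
#' @return Tibble `feature, importance`, sorted decreasing.
#' @export
predictor_importance <- function(model) {
  imp <- setNames(numeric(length(model$features)), model$features)
  for (tr in model$trees) {
    splits <- which(tr$feature >= 0L)
    for (k in splits) {
      f <- model$features[tr$feature[k] + 1L]
      imp[f] <- imp[f] + tr$gain[k]
    }
  }
  if (sum(imp) > 0) imp <- imp / sum(imp)
  tibble::tibble(feature = names(imp), importance = unname(imp)) |>
    dplyr::arrange(dplyr::desc(.data$importance))
}

#' Aggregate feature importance by detection channel
#'
#' Mean importance over each channel's five features; the redox ratio is
#' reported on its own.
#'
#' @param scores Output of [predictor_importance()].
#' @return Tibble `channel, importance`.
#' @export
aggregate_by_channel <- function(scores) {
  scores |>
    dplyr::mutate(channel = dplyr::if_else(
      .data$feature == "rr", "RR",
      paste0("CH", sub(".*_ch", "", .data$feature)))) |>
    dplyr::group_by(.data$channel) |>
    dplyr::summarise(importance = mean(.data$importance)) |>
    dplyr::arrange(.data$channel)
}

#' Feature-pool ablation
#'
#' For each pool, re-tunes the ensemble on the training table, estimates
#' cross-validated mean +/- SD accuracy/AUC/MCC, trains `n_test_models`
#' seed-tagged models on the full training table, and averages their metrics
#' on the test table.
#'
#' @param train_table,test_table Observation tables.
#' @param pools Pool names from [feature_pools()].
#' @param n_cycles Hyperparameter search cycles per pool.
#' @param k CV folds.
#' @param n_repeats Repeated CV passes for the training metrics.
#' @param n_test_models Models averaged for the test metrics.
#' @param seed Master seed.
#' @return Tibble with one row per pool (Nfeatures, CV and test metrics).
#' @export
run_ablation <- function(train_table, test_table,
                         pools = names(feature_pools()),
                         n_cycles = 60L, k = 5L, n_repeats = 20L,
                         n_test_models = 20L, seed = 1L) {
  registry <- feature_pools()
  bad <- setdiff(pools, names(registry))
  if (length(bad)) {
    abort(paste0("unknown pools: ", paste(bad, collapse = ", ")),
          class = "phb_input_error")
  }
  purrr::map_dfr(pools, function(pool) {
    tr <- select_pool(train_table, pool)
    te <- select_pool(test_table, pool)
    tuned <- tune_hyperparameters(tr, n_cycles = n_cycles, k = k,
                                  seed = derive_seed(seed, match(pool, pools)))
    ev <- repeat_evaluate(tr, tuned$best, n_repeats = n_repeats, k = k,
                          seed = derive_seed(seed, match(pool, pools), 2L))
    test_met <- purrr::map_dfr(seq_len(n_test_models), function(r) {
      fit <- train_adaboost(tr, tuned$best, seed = derive_seed(seed, r))
      prob <- predict_proba(fit, te)
      pred <- ifelse(prob >= 0.5, "malignant", "benign")
      dplyr::bind_rows(
        metrics(confusion(te$label, pred)),
        tibble::tibble(metric = "auc", value = roc_auc(te$label, prob)$auc)
      )
    }) |>
      dplyr::group_by(.data$metric) |>
      dplyr::summarise(mean = mean(.data$value))
    g <- function(tbl, m, col = "mean") tbl[[col]][tbl$metric == m]
    tibble::tibble(
      pool = pool,
      n_features = length(registry[[pool]]),
      learning_rate = tuned$best$learning_rate,
      n_learners = tuned$best$n_learners,
      max_nodes = tuned$best$max_nodes,
      cv_accuracy_mean = g(ev$metrics, "accuracy"),
      cv_accuracy_sd = g(ev$metrics, "accuracy", "sd"),
      cv_auc_mean = g(ev$metrics, "auc"),
      cv_auc_sd = g(ev$metrics, "auc", "sd"),
      cv_mcc_mean = g(ev$metrics, "mcc"),
      cv_mcc_sd = g(ev$metrics, "mcc", "sd"),
      test_accuracy = g(test_met, "accuracy"),
      test_auc = g(test_met, "auc"),
      test_mcc = g(test_met, "mcc")
    )
  })
}
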