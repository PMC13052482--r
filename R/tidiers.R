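# broom-style tidiers for the fitted objects.

#' @export
tidy.ensemble_model <- function(x, ...) {
  tibble::tibble(
    iteration = seq_along(x$trees),
    alpha = x$alphas,
    error = x$epsilons,
    n_splits = vapply(x$trees, function(tr) sum(tr$feature >= 0L), integer(1))
  )
}

#' @export
glance.ensemble_model <- function(x, ...) {
  tibble::tibble(
    n_learners = length(x$trees),
    learning_rate = x$hp$learning_rate,
    max_nodes = x$hp$max_nodes,
    degenerate = x$degenerate,
    total_alpha = sum(x$alphas)
  )
}

#' @export
tidy.repeat_eval <- function(x, ...) x$metrics

#' @export
glance.repeat_eval <- function(x, ...) {
  tibble::tibble(
    n_repeats = length(x$curves),
    accuracy = x$metrics$mean[x$metrics$metric == "accuracy"],
    auc = x$metrics$mean[x$metrics$metric == "auc"],
    mcc = x$metrics$mean[x$metrics$metric == "mcc"]
  )
}

#' @export
tidy.tune_result <- function(x, ...) x$log

#' @export
glance.tune_result <- function(x, ...) {
  tibble::tibble(
    best_loss = x$best_loss,
    learning_rate = x$best$learning_rate,
    n_learners = x$best$n_learners,
    max_nodes = x$best$max_nodes,
    n_cycles = nrow(x$log)
  )
}

#' @export
tidy.confusion_matrix <- function(x, ...) {
  tibble::tibble(cell = c("TP", "FN", "TN", "FP"),
                 count = c(x$TP, x$FN, x$TN, x$FP))
}

#' @export
tidy.roc_curve <- function(x, ...) x$curve

#' @export
glance.roc_curve <- function(x, ...) tibble::tibble(auc = x$auc)
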