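# AdaBoost.M1 over depth-limited weighted CART trees (binary, benign = -1,
# malignant = +1). The weak learner is grown best-first to at most
# `max_nodes` branch nodes with weighted Gini impurity and deterministic
# tie-breaks (lowest feature index, then lowest threshold), so training is
# fully reproducible.

#' Ensemble hyperparameters
#'
#' @param learning_rate Shrinkage nu in (0, 1] multiplying each learner
#'   weight.
#' @param n_learners Maximum number of boosting rounds (early stop allowed).
#' @param max_nodes Maximum branch (split) nodes per weak learner; 1 gives
#'   decision stumps.
#' @return A `hyperparameters` object.
#' @export
hyperparameters <- function(learning_rate = 0.1, n_learners = 100L,
                            max_nodes = 3L) {
  if (learning_rate <= 0 || learning_rate > 1) {
    abort("learning_rate must be in (0, 1].", class = "phb_config_error")
  }
  if (n_learners < 1L || max_nodes < 1L) {
    abort("n_learners and max_nodes must be positive.",
          class = "phb_config_error")
  }
  structure(list(learning_rate = learning_rate,
                 n_learners = as.integer(n_learners),
                 max_nodes = as.integer(max_nodes)),
            class = "hyperparameters")
}

# split an observation table into X (feature matrix) and y (+1/-1)
design_matrix <- function(table, features = NULL) {
  meta <- c("label", "sample_id", "patient_id", "cohort")
  if (is.null(features)) features <- setdiff(names(table), meta)
  missing <- setdiff(features, names(table))
  if (length(missing)) {
    abort(paste0("missing feature columns: ", paste(missing, collapse = ", ")),
          class = "phb_input_error")
  }
  X <- as.matrix(table[features])
  storage.mode(X) <- "double"
  y <- NULL
  if ("label" %in% names(table)) {
    lab <- as.character(table$label)
    bad <- setdiff(unique(lab), c("benign", "malignant"))
    if (length(bad)) {
      abort("labels must be 'benign' or 'malignant'.",
            class = "phb_input_error")
    }
    y <- ifelse(lab == "malignant", 1L, -1L)
  }
  list(X = X, y = y, features = features)
}

#' Train an AdaBoost.M1 ensemble
#'
#' Boosting loop: observation weights start uniform; each round fits a
#' weighted tree, computes its weighted error `eps_t`, stops if
#' `eps_t >= 0.5`, sets `alpha_t = nu * 0.5 * log((1 - eps_t) / eps_t)` (with
#' `eps_t` clipped to `[1e-10, 1 - 1e-10]` so perfect learners do not produce
#' infinite weights), reweights misclassified observations up and correct
#' ones down, and renormalizes. A perfect first-round learner ends training;
#' a first-round error >= 0.5 yields a flagged degenerate (empty) model that
#' predicts 0.5 everywhere.
#'
#' @param table Observation table: feature columns plus a `label` column with
#'   values `"benign"`/`"malignant"` (identifier columns are ignored).
#' @param hp A [hyperparameters()] object.
#' @param seed Stored in the model metadata (training itself is
#'   deterministic).
#' @param keep_history If TRUE, per-round observation weights are retained
#'   (for diagnostics and oracle comparisons).
#' @return An `ensemble_model`.
#' @export
train_adaboost <- function(table, hp = hyperparameters(), seed = NULL,
                           keep_history = FALSE) {
  d <- design_matrix(table)
  if (is.null(d$y)) abort("`table` needs a `label` column.",
                          class = "phb_input_error")
  if (length(unique(d$y)) < 2L) {
    abort("need observations of both classes to train.",
          class = "phb_input_error")
  }
  n <- nrow(d$X)
  y01 <- as.integer(d$y == 1L)
  w <- rep(1 / n, n)
  trees <- list()
  alphas <- numeric(0)
  epsilons <- numeric(0)
  history <- if (keep_history) list(w) else NULL
  degenerate <- FALSE

  for (t in seq_len(hp$n_learners)) {
    tree <- fit_tree_cpp(d$X, y01, w, hp$max_nodes)
    h <- predict_tree_cpp(tree$feature, tree$threshold, tree$left,
                          tree$right, tree$vote, d$X)
    miss <- h != d$y
    eps <- sum(w[miss])
    if (eps >= 0.5) {
      if (t == 1L) degenerate <- TRUE
      break
    }
    eps_c <- min(max(eps, 1e-10), 1 - 1e-10)
    alpha <- hp$learning_rate * 0.5 * log((1 - eps_c) / eps_c)
    trees[[t]] <- tree
    alphas[t] <- alpha
    epsilons[t] <- eps
    w <- w * exp(-alpha * d$y * h)
    w <- w / sum(w)
    if (keep_history) history[[t + 1L]] <- w
    if (eps <= 1e-12) break  # perfect learner: nothing left to reweight
  }

  structure(
    list(trees = trees, alphas = alphas, epsilons = epsilons,
         features = d$features, hp = hp, seed = seed,
         degenerate = degenerate,
         history = history),
    class = "ensemble_model"
  )
}

#' @export
print.ensemble_model <- function(x, ...) {
  cat(sprintf(
    "<ensemble_model> %d learners (nu=%g, max_nodes=%d)%s, %d features\n",
    length(x$trees), x$hp$learning_rate, x$hp$max_nodes,
    if (x$degenerate) " [degenerate]" else "", length(x$features)))
  invisible(x)
}

#' Ensemble margin score
#'
#' `score(x) = sum_t alpha_t h_t(x)` with votes `h_t in {-1, +1}`; positive
#' scores favor malignancy.
#'
#' @param model An `ensemble_model`.
#' @param table Observation table carrying the model's feature columns.
#' @return Numeric score per row.
#' @export
predict_score <- function(model, table) {
  d <- design_matrix(table, model$features)
  score <- numeric(nrow(d$X))
  for (t in seq_along(model$trees)) {
    tr <- model$trees[[t]]
    h <- predict_tree_cpp(tr$feature, tr$threshold, tr$left, tr$right,
                          tr$vote, d$X)
    score <- score + model$alphas[t] * h
  }
  score
}

#' Probability of malignancy
#'
#' Logistic mapping of the boosting margin, `p = 1 / (1 + exp(-2 score))`
#' (the standard calibration for the exponential loss); an empty ensemble
#' returns 0.5.
#'
#' @inheritParams predict_score
#' @return Probability per row.
#' @export
predict_proba <- function(model, table) {
  1 / (1 + exp(-2 * predict_score(model, table)))
}

#' @param object An `ensemble_model`.
#' @param newdata Observation table.
#' @param type `"prob"`, `"score"` or `"label"` (label = probability >= 0.5).
#' @param ... Unused.
#' @rdname predict_score
#' @export
predict.ensemble_model <- function(object, newdata,
                                   type = c("prob", "score", "label"), ...) {
  type <- match.arg(type)
  switch(type,
    score = predict_score(object, newdata),
    prob = predict_proba(object, newdata),
    label = ifelse(predict_proba(object, newdata) >= 0.5,
                   "malignant", "benign")
  )
}

# stratified fold assignment; same seed -> same folds
make_folds <- function(y, k, seed) {
  folds <- integer(length(y))
  with_seed(derive_seed(seed, 31L), {
    for (cls in unique(y)) {
      idx <- which(y == cls)
      folds[idx] <- rep_len(seq_len(k), length(idx))[sample.int(length(idx))]
    }
  })
  folds
}

# one full k-fold CV pass; returns held-out label/probability per row
cv_run <- function(table, hp, k = 5L, seed = 1L) {
  d <- design_matrix(table)
  if (k < 2L) abort("k must be >= 2.", class = "phb_config_error")
  if (k > min(table(d$y))) {
    abort("k exceeds the smaller class count.", class = "phb_config_error")
  }
  folds <- make_folds(d$y, k, seed)
  purrr::map_dfr(seq_len(k), function(f) {
    fit <- train_adaboost(table[folds != f, , drop = FALSE], hp)
    tibble::tibble(
      row = which(folds == f),
      fold = f,
      label = ifelse(d$y[folds == f] == 1L, "malignant", "benign"),
      prob = predict_proba(fit, table[folds == f, , drop = FALSE])
    )
  })
}

#' Stratified k-fold cross-validation loss
#'
#' Misclassification rate of held-out predictions, averaged over folds.
#' Folds are stratified by class and reproducible under `seed`.
#'
#' @inheritParams train_adaboost
#' @param k Number of folds (default 5).
#' @param seed Fold-shuffle seed.
#' @return Mean misclassification loss (scalar).
#' @export
cross_validate <- function(table, hp, k = 5L, seed = 1L) {
  res <- cv_run(table, hp, k, seed)
  res |>
    dplyr::mutate(pred = ifelse(.data$prob >= 0.5, "malignant", "benign")) |>
    dplyr::group_by(.data$fold) |>
    dplyr::summarise(loss = mean(.data$pred != .data$label)) |>
    dplyr::pull(.data$loss) |>
    mean()
}

#' Default hyperparameter search space
#'
#' Ranges wide enough to span under- and overfitting: learning rate
#' `[0.01, 1]` sampled log-uniformly, `n_learners` `[10, 500]`,
#' `max_nodes` `[1, 20]`.
#' @return Named list of `c(lo, hi)` ranges.
#' @export
hp_space <- function() {
  list(learning_rate = c(0.01, 1), n_learners = c(10L, 500L),
       max_nodes = c(1L, 20L))
}

#' Seeded hyperparameter search
#'
#' Evaluates `n_cycles` configurations drawn from the search space (learning
#' rate log-uniform, integer ranges uniform) against the stratified k-fold
#' cross-validation loss, on folds held fixed across configurations, and
#' returns the argmin together with the full evaluation log (the objective
#' trace).
#'
#' @inheritParams cross_validate
#' @param space Search space as in [hp_space()]; a degenerate range
#'   (`lo == hi`) pins that hyperparameter.
#' @param n_cycles Number of evaluated configurations (default 60).
#' @return A `tune_result`: `best` ([hyperparameters()]), `best_loss`, and
#'   `log` (tibble with one row per cycle).
#' @export
tune_hyperparameters <- function(table, space = hp_space(), n_cycles = 60L,
                                 k = 5L, seed = 1L) {
  if (length(space) == 0L) {
    abort("empty search space.", class = "phb_config_error")
  }
  needed <- c("learning_rate", "n_learners", "max_nodes")
  if (!all(needed %in% names(space))) {
    abort("space must define learning_rate, n_learners and max_nodes.",
          class = "phb_config_error")
  }
  configs <- with_seed(derive_seed(seed, 47L), {
    tibble::tibble(
      cycle = seq_len(n_cycles),
      learning_rate = exp(runif(n_cycles, log(space$learning_rate[1]),
                                log(space$learning_rate[2]))),
      n_learners = as.integer(round(runif(n_cycles, space$n_learners[1],
                                          space$n_learners[2]))),
      max_nodes = as.integer(round(runif(n_cycles, space$max_nodes[1],
                                         space$max_nodes[2])))
    )
  })
  configs$loss <- vapply(seq_len(n_cycles), function(i) {
    cross_validate(table,
                   hyperparameters(configs$learning_rate[i],
                                   configs$n_learners[i],
                                   configs$max_nodes[i]),
                   k = k, seed = seed)
  }, numeric(1))
  best_i <- which.min(configs$loss)
  structure(
    list(best = hyperparameters(configs$learning_rate[best_i],
                                configs$n_learners[best_i],
                                configs$max_nodes[best_i]),
         best_loss = configs$loss[best_i],
         log = configs),
    class = "tune_result"
  )
}

#' @export
print.tune_result <- function(x, ...) {
  cat(sprintf(
    "<tune_result> %d cycles; best CV loss %.4f at nu=%.4g, %d learners, %d nodes\n",
    nrow(x$log), x$best_loss, x$best$learning_rate, x$best$n_learners,
    x$best$max_nodes))
  invisible(x)
}
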