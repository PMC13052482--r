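test_that("a separable 1-D problem is solved by a single stump", {
  tab <- tibble::tibble(xf = c(1, 2, 3, 4),
                        label = c("malignant", "malignant",
                                  "benign", "benign"))
  m <- train_adaboost(tab, hyperparameters(1, 10, 1))
  expect_length(m$trees, 1)
  expect_false(m$degenerate)
  expect_equal(predict(m, tab, type = "label"), tab$label)
  expect_equal(m$epsilons, 0)
})

test_that("boosting weight trajectories match the exhaustive stump oracle", {
  # 4-point non-separable 1-D fixture with a tie among best stumps
  X4 <- matrix(c(1, 2, 3, 4), ncol = 1)
  y4 <- c(1L, -1L, 1L, -1L)
  # 5-point fixture with a unique best stump per round
  X5 <- matrix(c(1, 2, 3, 4, 5, 0.5, 2.5, 1.5, 3.5, 2.0), ncol = 2)
  y5 <- c(1L, 1L, -1L, 1L, -1L)
  for (fix in list(list(X = X4, y = y4), list(X = X5, y = y5))) {
    tab <- tibble::as_tibble(as.data.frame(fix$X))
    names(tab) <- paste0("f", seq_len(ncol(fix$X)))
    tab$label <- ifelse(fix$y == 1, "malignant", "benign")
    m <- train_adaboost(tab, hyperparameters(1, 3, 1), keep_history = TRUE)
    o <- oracle_adaboost_stumps(fix$X, fix$y, rounds = 3)
    expect_equal(length(m$alphas), length(o$alphas))
    expect_equal(m$alphas, o$alphas, tolerance = 1e-12)
    expect_equal(m$epsilons, o$epsilons, tolerance = 1e-12)
    for (t in seq_along(m$history)) {
      expect_equal(m$history[[t]], o$weights[[t]], tolerance = 1e-12)
    }
  }
})

test_that("a first-round error of one half yields a flagged degenerate model", {
  # XOR corners: every axis-aligned stump has weighted error exactly 0.5
  tab <- tibble::tibble(f1 = c(0, 1, 0, 1), f2 = c(0, 0, 1, 1),
                        label = c("malignant", "benign",
                                  "benign", "malignant"))
  m <- train_adaboost(tab, hyperparameters(1, 10, 1))
  expect_true(m$degenerate)
  expect_length(m$trees, 0)
  expect_equal(predict(m, tab, type = "prob"), rep(0.5, 4))
})

test_that("observation weights stay normalized through every round", {
  tab <- gaussian_table(80, seed = 5)
  m <- train_adaboost(tab, hyperparameters(1, 15, 2), keep_history = TRUE)
  for (w in m$history) expect_equal(sum(w), 1, tolerance = 1e-12)
})

test_that("training error respects the boosting bound on random fixtures", {
  for (i in 1:25) {
    tab <- gaussian_table(40, p = 3, seed = 100 + i, noise = 1.5)
    if (length(unique(tab$label)) < 2) next
    m <- train_adaboost(tab, hyperparameters(1, 8, 1))
    if (length(m$trees) == 0) next
    err <- mean(predict(m, tab, type = "label") != tab$label)
    bound <- prod(2 * sqrt(m$epsilons * (1 - m$epsilons)))
    expect_lte(err, bound + 1e-12)
  }
})

test_that("predictions agree with the reference binary AdaBoost at nu = 1", {
  tab <- gaussian_table(200, p = 4, seed = 7)
  m <- train_adaboost(tab, hyperparameters(1, 50, 1))
  X <- as.matrix(tab[paste0("f", 1:4)])
  ref <- sklearn_adaboost_predict(X, as.integer(tab$label == "malignant"), 50)
  expect_false(is.null(ref))
  pred <- predict(m, tab, type = "label")
  agreement <- mean(pred == ifelse(ref == 1, "malignant", "benign"))
  expect_gte(agreement, 0.99)
})

test_that("training error is non-increasing in ensemble size at nu = 1", {
  tab <- gaussian_table(120, p = 3, seed = 11)
  m <- train_adaboost(tab, hyperparameters(1, 30, 1))
  y <- ifelse(tab$label == "malignant", 1, -1)
  d <- tab[paste0("f", 1:3)]
  score <- numeric(nrow(tab))
  errs <- vapply(seq_along(m$trees), function(t) {
    tr <- m$trees[[t]]
    h <- phasorboost:::predict_tree_cpp(tr$feature, tr$threshold, tr$left,
                                        tr$right, tr$vote, as.matrix(d))
    score <<- score + m$alphas[t] * h
    mean(sign(score) != y & score != 0 | (score == 0 & y == -1))
  }, numeric(1))
  checkpoints <- errs[unique(pmin(c(1, 5, 10, 20, length(errs)),
                                  length(errs)))]
  expect_true(all(diff(checkpoints) <= 1e-12))
})

test_that("margin scores map to probabilities by the logistic calibration", {
  empty <- structure(list(trees = list(), alphas = numeric(0),
                          epsilons = numeric(0), features = "f1",
                          hp = hyperparameters(), seed = NULL,
                          degenerate = TRUE, history = NULL),
                     class = "ensemble_model")
  tab <- tibble::tibble(f1 = c(-1, 0, 1))
  expect_equal(predict_proba(empty, tab), rep(0.5, 3))
  # single stump with alpha = 0.5 voting malignant
  tab2 <- tibble::tibble(f1 = c(1, 2, 9, 10),
                         label = c("benign", "benign",
                                   "malignant", "malignant"))
  m <- train_adaboost(tab2, hyperparameters(1, 1, 1))
  m$alphas <- 0.5
  p <- predict_proba(m, tibble::tibble(f1 = 100))
  expect_equal(p, 1 / (1 + exp(-1)), tolerance = 1e-12)
  # probabilities are monotone in score
  tab3 <- gaussian_table(60, seed = 3)
  m3 <- train_adaboost(tab3, hyperparameters(0.5, 20, 2))
  sc <- predict_score(m3, tab3)
  pr <- predict_proba(m3, tab3)
  expect_equal(order(sc), order(pr))
  expect_error(predict_score(m3, tibble::tibble(bad = 1)), "missing feature",
               class = "phb_input_error")
})

test_that("training rejects degenerate inputs", {
  one_class <- tibble::tibble(f1 = 1:4, label = rep("benign", 4))
  expect_error(train_adaboost(one_class, hyperparameters()),
               class = "phb_input_error")
  expect_error(hyperparameters(learning_rate = 0), class = "phb_config_error")
  expect_error(hyperparameters(learning_rate = 1.5),
               class = "phb_config_error")
  expect_error(hyperparameters(n_learners = 0), class = "phb_config_error")
})

test_that("cross-validation is stratified, seeded and correct at the extremes", {
  sep <- tibble::tibble(f1 = c(1:10, 101:110),
                        label = rep(c("benign", "malignant"), each = 10))
  expect_equal(cross_validate(sep, hyperparameters(1, 5, 1), k = 5, seed = 1),
               0)
  # permutation null: balanced random labels give ~0.5 loss
  set.seed(99)
  null_tab <- tibble::tibble(f1 = rnorm(120), f2 = rnorm(120),
                             label = sample(rep(c("benign", "malignant"), 60)))
  loss <- cross_validate(null_tab, hyperparameters(1, 20, 1), k = 5, seed = 2)
  expect_gt(loss, 0.3)
  expect_lt(loss, 0.7)
  # determinism
  tab <- gaussian_table(60, seed = 8)
  l1 <- cross_validate(tab, hyperparameters(0.5, 10, 2), k = 5, seed = 3)
  l2 <- cross_validate(tab, hyperparameters(0.5, 10, 2), k = 5, seed = 3)
  expect_identical(l1, l2)
  expect_error(cross_validate(tab, hyperparameters(), k = 1),
               class = "phb_config_error")
})

test_that("hyperparameter search returns the argmin over its evaluation log", {
  tab <- gaussian_table(80, seed = 13)
  # degenerate space pins the configuration
  space1 <- list(learning_rate = c(0.5, 0.5), n_learners = c(7L, 7L),
                 max_nodes = c(2L, 2L))
  res1 <- tune_hyperparameters(tab, space1, n_cycles = 3, k = 5, seed = 1)
  expect_equal(res1$best$learning_rate, 0.5)
  expect_equal(res1$best$n_learners, 7L)
  expect_equal(res1$best$max_nodes, 2L)
  # separable data: some configuration reaches loss 0 and is returned
  sep <- tibble::tibble(f1 = c(1:10, 101:110),
                        label = rep(c("benign", "malignant"), each = 10))
  res0 <- tune_hyperparameters(sep, n_cycles = 5, k = 5, seed = 1)
  expect_equal(res0$best_loss, 0)
  # argmin property and determinism
  res <- tune_hyperparameters(tab, n_cycles = 8, k = 4, seed = 4)
  expect_equal(res$best_loss, min(res$log$loss))
  expect_lte(res$best_loss, stats::median(res$log$loss))
  res_again <- tune_hyperparameters(tab, n_cycles = 8, k = 4, seed = 4)
  expect_identical(res$log, res_again$log)
  expect_error(tune_hyperparameters(tab, space = list()),
               class = "phb_config_error")
})

test_that("JSON serialization round-trips the model exactly", {
  tab <- gaussian_table(80, seed = 21)
  m <- train_adaboost(tab, hyperparameters(0.7, 12, 3), seed = 99)
  path <- tempfile(fileext = ".json")
  write_model_json(m, path)
  m2 <- read_model_json(path)
  expect_identical(m$features, m2$features)
  expect_equal(m$alphas, m2$alphas, tolerance = 0)
  expect_identical(predict_score(m, tab), predict_score(m2, tab))
  expect_identical(predictor_importance(m), predictor_importance(m2))
})
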