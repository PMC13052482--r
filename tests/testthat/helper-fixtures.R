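# Shared fixtures, generated in code and memoised across test files.

phb_fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = phb_fixtures)) {
    assign(key, force(expr), envir = phb_fixtures)
  }
  get(key, envir = phb_fixtures)
}

# low-resolution config for fast tests (the physics is resolution-independent);
# scene large enough that benign ROIs fit well clear of the lesion
fast_config <- function(...) {
  sim_config(n_bins = 256L, photon_budget = 3000, scene_size = 24L,
             lesion_radius = c(5, 6), roi_size = 4L, ...)
}

# config whose classes differ only in CH1/CH5 lifetimes (no intensity
# signal, no dispersion signal): known signal placement for importance tests
lifetime_only_config <- function(n_bins = 256L, photon_budget = 3000, ...) {
  cm <- default_class_models()
  for (ch in 1:5) {
    cm$malignant[[ch]]$intensity <- cm$benign[[ch]]$intensity
    cm$malignant[[ch]]$tau_sd <- cm$benign[[ch]]$tau_sd
  }
  for (ch in c(2, 3, 4)) {
    cm$malignant[[ch]]$components <- cm$benign[[ch]]$components
  }
  sim_config(n_bins = n_bins, photon_budget = photon_budget,
             class_models = cm, ...)
}

# a mono-exponential config (both classes identical, single component,
# all lifetime dispersion off)
mono_config <- function(tau, ...) {
  cm <- default_class_models()
  for (cls in c("benign", "malignant")) {
    for (ch in 1:5) {
      cm[[cls]][[ch]]$components <- data.frame(tau = tau, frac = 1)
      cm[[cls]][[ch]]$tau_sd <- 0
    }
  }
  sim_config(class_models = cm, tau_meas_sd = 0, intensity_bio_cv = 0, ...)
}

fixture_cohort <- function() {
  memo("cohort60", simulate_cohort(60, fast_config(), seed = 101L,
                                   points_per_roi = 5L))
}

fixture_scan <- function() {
  memo("scan16", {
    cfg <- fast_config()
    scene <- sample_scene(cfg, seed = 202L)
    simulate_scan(scene, cfg, seed = 202L)
  })
}

# random continuous tabular fixture with a linear signal
gaussian_table <- function(n, p = 4, seed = 1, noise = 0.8) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  lab <- ifelse(X[, 1] + 0.5 * X[, 2] + rnorm(n, 0, noise) > 0,
                "malignant", "benign")
  tab <- tibble::as_tibble(as.data.frame(X))
  names(tab) <- paste0("f", seq_len(p))
  tab$label <- lab
  tab
}

# run sklearn's binary AdaBoost (SAMME) as an external reference
sklearn_adaboost_predict <- function(X, y01, n_estimators) {
  fixture <- tempfile(fileext = ".csv")
  out <- tempfile(fileext = ".csv")
  script <- tempfile(fileext = ".py")
  utils::write.csv(cbind(X, y = y01), fixture, row.names = FALSE)
  writeLines(c(
    "import sys, pandas as pd",
    "from sklearn.ensemble import AdaBoostClassifier",
    "from sklearn.tree import DecisionTreeClassifier",
    sprintf("d = pd.read_csv('%s')", fixture),
    "X, y = d.iloc[:, :-1].values, d['y'].values",
    "clf = AdaBoostClassifier(estimator=DecisionTreeClassifier(max_depth=1),",
    sprintf("  n_estimators=%d, learning_rate=1.0).fit(X, y)", n_estimators),
    sprintf("pd.DataFrame({'pred': clf.predict(X)}).to_csv('%s', index=False)",
            out)
  ), script)
  status <- system2("python", script, stdout = FALSE, stderr = FALSE)
  if (status != 0L) return(NULL)
  utils::read.csv(out)$pred
}
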