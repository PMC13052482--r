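# Independent oracles used to cross-check the implementation. These are
# deliberately written as brute-force enumerations / direct formulas, sharing
# no code with the package internals.

# Exhaustive weighted stump search: every (feature, midpoint threshold)
# split, Gini gain computed by direct formula, leaf votes by weighted
# majority (ties -> benign). Tie-breaks mirror the stated determinism
# contract: lowest feature index, then lowest threshold.
oracle_best_stump <- function(X, y, w) {
  gini <- function(w0, w1) if (w0 + w1 > 0) 2 * w0 * w1 / (w0 + w1) else 0
  parent <- gini(sum(w[y == -1]), sum(w[y == 1]))
  best <- list(gain = 0, feature = NA, threshold = NA)
  for (j in seq_len(ncol(X))) {
    vals <- sort(unique(X[, j]))
    if (length(vals) < 2) next
    thresholds <- head(vals, -1) + diff(vals) / 2
    for (th in thresholds) {
      L <- X[, j] <= th
      g <- parent - gini(sum(w[L & y == -1]), sum(w[L & y == 1])) -
        gini(sum(w[!L & y == -1]), sum(w[!L & y == 1]))
      if (g > best$gain + 1e-15) best <- list(gain = g, feature = j,
                                              threshold = th)
    }
  }
  if (is.na(best$feature)) return(NULL)
  L <- X[, best$feature] <= best$threshold
  vote_of <- function(m) if (sum(w[m & y == 1]) > sum(w[m & y == -1])) 1 else -1
  best$predict <- function(Xn) {
    ifelse(Xn[, best$feature] <= best$threshold, vote_of(L), vote_of(!L))
  }
  best
}

# Textbook AdaBoost.M1 with the exhaustive stump learner; returns the weight
# trajectory, errors and alphas over `rounds` rounds.
oracle_adaboost_stumps <- function(X, y, rounds, nu = 1) {
  n <- nrow(X)
  w <- rep(1 / n, n)
  traj <- list(w)
  alphas <- numeric(0)
  eps <- numeric(0)
  for (t in seq_len(rounds)) {
    st <- oracle_best_stump(X, y, w)
    if (is.null(st)) break
    h <- st$predict(X)
    e <- sum(w[h != y])
    if (e >= 0.5) break
    ec <- min(max(e, 1e-10), 1 - 1e-10)
    a <- nu * 0.5 * log((1 - ec) / ec)
    w <- w * exp(-a * y * h)
    w <- w / sum(w)
    traj[[t + 1]] <- w
    alphas[t] <- a
    eps[t] <- e
    if (e <= 1e-12) break
  }
  list(weights = traj, alphas = alphas, epsilons = eps)
}

# AUC as the tie-corrected Mann-Whitney statistic by explicit pair counting
oracle_auc_pairs <- function(labels, scores) {
  sp <- scores[labels == "malignant"]
  sn <- scores[labels == "benign"]
  cmp <- outer(sp, sn, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# scalar metrics straight from the definitions
oracle_metrics <- function(TP, FN, TN, FP) {
  mcc_den <- sqrt((TP + FP) * (TP + FN) * (TN + FP) * (TN + FN))
  c(sensitivity = TP / (TP + FN),
    specificity = TN / (TN + FP),
    accuracy = (TP + TN) / (TP + FN + TN + FP),
    ppv = TP / (TP + FP),
    npv = TN / (TN + FN),
    mcc = if (mcc_den == 0) 0 else (TP * TN - FP * FN) / mcc_den)
}

# first-harmonic phasor by direct elementwise summation (no shared code)
oracle_phasor_dft <- function(counts, T) {
  n <- length(counts)
  g <- 0; s <- 0; tot <- 0
  for (i in seq_len(n)) {
    t <- (i - 0.5) * T / n
    g <- g + counts[i] * cos(2 * pi * t / T)
    s <- s + counts[i] * sin(2 * pi * t / T)
    tot <- tot + counts[i]
  }
  c(g = g / tot, s = s / tot)
}
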