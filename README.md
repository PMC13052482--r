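# phasorboost

Fit-free autofluorescence-lifetime feature extraction and ensemble
classification of benign versus malignant tissue, with a synthetic
multichannel TCSPC scan generator so the whole pipeline runs and is tested
without any external data.

## The problem

Label-free optical spectroscopy can flag malignant colorectal tissue during
endoscopy or on fresh surgical specimens. A fiber probe delivers two
multiplexed picosecond excitations (375 and 445 nm) and collects
time-correlated single photon counting (TCSPC) decay histograms in five
spectral detection channels chosen to isolate collagen, NAD(P)H and FAD
autofluorescence. Each measurement point yields five decays `I(t)` over one
laser period (`T = 50` ns at 20 MHz repetition).

`phasorboost` implements the full analysis chain for such data:

1. **Phasor transform.** Each background-corrected decay maps to
   first-harmonic Fourier coordinates

   ```
   g = ∫ I(t) cos(2πt/T) dt / ∫ I(t) dt
   s = ∫ I(t) sin(2πt/T) dt / ∫ I(t) dt
   ```

   calibrated against the measured instrument response function (IRF, a
   τ = 0 reference) by complex division. Phase and modulation lifetimes
   follow as `τp = (T/2π)(s/g)` and `τm = (T/2π)·sqrt(1/(g²+s²) − 1)`.
   Decays with fewer than 50 photons or fewer than 10 peak counts are
   excluded.

2. **Features.** Per channel: `g, s, τp, τm` and the fractional intensity
   `F` (channel intensity over the summed intensity of its excitation
   group). Plus the optical redox ratio
   `RR = I2 / (I2 + I5) ≡ NAD(P)H / (NAD(P)H + FAD)` — 26 features per
   measurement. Point measurements are rasterized into parameter maps and
   averaged within labeled regions of interest (ROIs) to form observations.

3. **Classification.** AdaBoost.M1 over depth-limited decision trees
   (weighted Gini, deterministic tie-breaks), with stratified 5-fold
   cross-validation, a seeded 60-cycle hyperparameter search (learning rate,
   number of weak learners, maximum nodes per learner), repeated-run metric
   aggregation (sensitivity, specificity, accuracy, PPV, NPV, MCC, ROC-AUC),
   predictor importance, and a feature-pool ablation over named channel
   subsets.

4. **Maps.** Per-point malignancy probabilities in acquisition order, and
   Gaussian-kernel-smoothed probability / lifetime maps of the scanned
   specimen.

5. **Simulator.** A synthetic scan generator with known ground truth:
   class-conditional multi-exponential decays (shorter malignant lifetimes in
   channels 1 and 5, wider malignant dispersion in channels 2–3), Poisson
   photon noise, Gaussian IRF convolution with periodic wrap (integrated
   analytically per TCSPC bin), uniform background, lesion geometry and a
   serpentine scan path.

## Worked example

```r
library(phasorboost)

cfg   <- sim_config(n_bins = 256)
train <- simulate_cohort(120, cfg, seed = 11, cohort = "train")
test  <- simulate_cohort(60,  cfg, seed = 12, cohort = "test")

tuned <- tune_hyperparameters(train, n_cycles = 10, k = 5, seed = 13)
fit   <- train_adaboost(train, tuned$best)
prob  <- predict_proba(fit, test)

roc_auc(test$label, prob)
metrics(confusion(test$label, ifelse(prob >= 0.5, "malignant", "benign")))
head(predictor_importance(fit), 5)
```

prints

```
<roc_curve> 46 points, AUC 0.9918
# A tibble: 6 × 2
  metric      value
  <chr>       <dbl>
1 sensitivity 0.957
2 specificity 0.919
3 accuracy    0.933
4 ppv         0.88
5 npv         0.971
6 mcc         0.863
# A tibble: 5 × 2
  feature   importance
  <chr>          <dbl>
1 g_ch1         0.199
2 s_ch5         0.152
3 tau_m_ch4     0.0927
4 s_ch2         0.0837
5 rr            0.0807
```

The tuned ensemble (170 stumps-to-shallow trees here) separates the held-out
synthetic cohort with AUC 0.99; the most important predictors are the phasor
coordinates of channels 1 and 5 — the channels the generator endows with the
benign/malignant lifetime contrast — with the redox ratio contributing as
well. `autoplot()` methods render probability maps, averaged ROC curves and
phasor plots; `tidy()`/`glance()` expose fitted objects as tibbles.

A thin CLI over the same functions lives in `inst/cli/phasorboost.R`
(subcommands `simulate`, `extract`, `train`, `evaluate`, `ablate`, `map`).

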