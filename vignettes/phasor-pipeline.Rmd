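---
title: "Phasor-based lifetime features and ensemble tissue classification: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phasor-based lifetime features and ensemble tissue classification: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of its models, numerical choices
and limitations. It states no empirical result beyond what the test suite
and `scripts/acceptance.R` compute.

## The measurement model

A fiber-probe system excites tissue autofluorescence with two multiplexed
picosecond lasers (375 nm feeding detection channels 1–3, 445 nm feeding
channels 4–5) at a 20 MHz repetition rate, and records a TCSPC histogram per
channel per probe position. Because the emission persists across pulse
periods, the steady-state decay observed on one period $[0, T)$,
$T = 50$ ns, is the *wrapped* response

$$ f(t) = \sum_{k \ge 0} h(t + kT), $$

where $h$ is the multi-exponential emission convolved with the instrument
response function (IRF). `phasorboost` models the IRF as a Gaussian and
evaluates each TCSPC bin's expected count *analytically*: the convolution of
a one-sided exponential with a Gaussian has the exponentially-modified
Gaussian CDF

$$ F(x) = \Phi(z) - \exp\!\left(\tfrac{\sigma^2}{2\tau^2} -
   \tfrac{x - t_0}{\tau}\right)\,\Phi\!\left(z - \tfrac{\sigma}{\tau}\right),
   \qquad z = \tfrac{x - t_0}{\sigma}, $$

so a bin $[a, b)$ of pulse copy $k$ contributes $F(b + kT) - F(a + kT)$. The
second term is evaluated in log space (`pnorm(log.p = TRUE)`), which keeps
the pre-rise region numerically exact; the pulse sum is truncated when the
geometric tail $e^{-kT/\tau}$ falls below double precision
($k \le \lceil 37\,\tau/T \rceil$). This makes the continuum closed forms
below hold to machine precision up to binning, which is what the closed-form
tests exploit.

## Phasor transform and calibration

The phasor coordinates are the first-harmonic Fourier moments of the decay
normalized by its intensity. Discretely, with bin centers $t_i$:

$$ g = \frac{\sum_i c_i \cos(2\pi t_i / T)}{\sum_i c_i}, \qquad
   s = \frac{\sum_i c_i \sin(2\pi t_i / T)}{\sum_i c_i}. $$

The bin-center Riemann rendering is standard phasor practice; its error is
$O(1/n_\text{bins}^2)$ at harmonic 1 (about $10^{-6}$ relative at the
default 1024 bins). The harmonic is fixed at 1.

Calibration divides the raw phasor by the IRF phasor in the complex plane —
the IRF is a zero-lifetime reference, so an IRF measurement maps to
$(1, 0)$, and because the transform of a convolution is the product of
transforms, referencing removes the IRF *and* the half-bin discretization
phase in one step. Time-domain deconvolution is deliberately avoided (the
phasor approach is fit-free). For a mono-exponential, the calibrated phasor
sits on the universal semicircle at

$$ g = \frac{1}{1 + (\omega\tau)^2}, \qquad
   s = \frac{\omega\tau}{1 + (\omega\tau)^2}, \qquad \omega = 2\pi/T, $$

and both the phase lifetime $\tau_p = (T/2\pi)(s/g)$ and modulation lifetime
$\tau_m = (T/2\pi)\sqrt{1/(g^2+s^2) - 1}$ equal $\tau$. The acceptance
script verifies this for the two validation standards commonly used on such
instruments (POPOP at 1.36 ns for the 375 nm arm, Coumarin 6 at 2.72 ns for
the 445 nm arm).

Numerical conventions: $g \le 0$ makes $\tau_p$ undefined (`NA`, point
flagged and excluded downstream); a modulus $g^2 + s^2 > 1$ (shot noise
outside the universal circle) is clamped to 1, giving $\tau_m = 0$.

## Background correction and quality control

A constant background is estimated as the mean count over a pre-rise window
(the leading 5% of bins by default; the default IRF offset of 5 ns leaves
that window clear of the rising edge) and subtracted from every bin, with
negatives clamped to zero so the counts stay physical for count-based QC.
The clamp introduces a small, analytically computable positive bias on
near-empty bins — the test suite bounds it with
$E[\max(\mathrm{Pois}(b) - b, 0)]$ per bin rather than pretending the
correction is noiseless. Uniform background contributes exactly $(0,0)$ at
harmonic 1, so it mainly corrupts the modulus ($\tau_m$), which is what the
correction demonstrably improves.

A corrected decay is kept iff it holds at least 50 photons *and* 10 peak
counts; boundary values pass (a literal reading of "fewer than"). QC is
monotone: adding photons never turns a passing decay into a failing one.

Fractional intensities normalize within excitation groups (channels 1–3 and
4–5), and the redox ratio is $RR = I_2/(I_2 + I_5)$ on background-corrected
absolute intensities. F and RR are computed only for points whose five
channels all pass QC; per-channel phasor quantities are reported for any
passing channel. Whether these measurement-level quantities should be
computed before or after QC exclusion is genuinely open; computing them only
on fully-passing points is the conservative choice.

## From points to observations

Point measurements are rasterized onto the scan grid (coincident points
averaged, unobserved pixels missing) and each labeled ROI becomes one
observation by averaging every parameter over its non-missing pixels. Each
of the 26 parameters is averaged independently in its own space —
recomputing $\tau_p$ from ROI-mean $(g, s)$ would be an equally defensible
convention; the independent average was chosen because it treats all 26
features uniformly. ROIs intersecting no measured pixel are dropped with a
warning rather than imputed.

The ablation sub-pools are registered explicitly (intensity-only 6,
lifetime-only 20, single-excitation 15 and 10, three-fluorophore pools 16
and 11 in two channel variants, full 26) rather than generated from
wildcards, so the pool table is bit-reproducible.

## The ensemble

AdaBoost.M1 with depth-limited CART weak learners, authored in the package
(the tree in C++ for speed):

* trees grow best-first to at most `max_nodes` branch nodes on weighted Gini
  impurity; split-gain ties keep the lowest feature index, then the lowest
  threshold; leaf-vote ties go to benign — training is fully deterministic;
* round $t$: weighted error $\varepsilon_t$; stop if
  $\varepsilon_t \ge 0.5$ (a first-round stop yields a flagged degenerate
  model predicting 0.5); $\alpha_t = \nu \cdot \tfrac12
  \ln((1-\varepsilon_t)/\varepsilon_t)$ with $\varepsilon_t$ clipped to
  $[10^{-10}, 1 - 10^{-10}]$ so a perfect learner does not produce infinite
  weights; weights are reweighted by $e^{\mp\alpha_t}$ and renormalized;
* scores are $\sum_t \alpha_t h_t(x)$, mapped to a malignancy probability by
  the exponential-loss calibration $p = 1/(1 + e^{-2\,\text{score}})$.

Cross-validation folds are stratified by class (protecting the smaller
malignant class) and reproducible under a seed. Hyperparameters are tuned by
a seeded random search — learning rate log-uniform on $[0.01, 1]$,
`n_learners` on $[10, 500]$, `max_nodes` on $[1, 20]$, 60 evaluated
configurations against the CV loss on folds held fixed across
configurations — returning the argmin and the full objective trace. A
surrogate-model search would explore the same space more cleverly, but the
contract here is only the argmin over a fixed evaluation budget, and a
quasi-random search keeps the result exactly reproducible.

Because training is deterministic given the data, repeated evaluation
varies only the fold shuffles; "20 models trained on the full training
table with different seeds" therefore coincide, and their test-metric SD is
zero by construction. This is reported honestly rather than disguised with
artificial jitter.

Predictor importance sums each feature's weighted impurity decreases over
all splits in all learners, normalized to sum 1; channel aggregates average
the five features of a channel, with RR reported alone.

## The synthetic-data generator

The generator emulates, with known ground truth: five detection channels
over two excitation arms; class-conditional two-component decays; Poisson
photon statistics at a realistic point-measurement budget (5000 expected
counts per decay, log-normal 15% per-measurement variation); uniform
background (0.2 counts/bin); a 0.2 ns FWHM Gaussian IRF at 5 ns offset;
disk-shaped lesions on a square scene scanned serpentine-fashion; and small
square ROIs drawn fully inside (malignant) or well clear of (benign) the
lesion, at most three per tissue type.

No numeric per-class lifetime distributions are published for this kind of
cohort, so the class models are the package's own choices, fixed once to
reproduce the qualitative phenomenology of colorectal tissue:

* shorter malignant lifetimes in channels 1 (collagen) and 5 (FAD):
  dominant-component means 5.2 → 4.0 ns and 4.4 → 3.5 ns;
* equal class means but wider malignant dispersion in the NAD(P)H channels
  2–3 (SD 0.3 vs 0.7 ns) — metabolic heterogeneity;
* a subtle channel-4 shift (3.6 → 3.5 ns);
* a modest redox-ratio shift via relative channel intensities
  (RR ≈ 0.55 benign vs 0.61 malignant).

Dispersion is split into a tissue-level draw (per ROI/spot; the class
models' `tau_sd`, plus log-normal 20% channel-intensity variation) and a
measurement-level jitter (0.1 ns; 15% budget CV). The split matters: with
purely per-measurement dispersion, ROI averaging shrinks the spread by
$1/\sqrt{n_\text{points}}$ and the classes become nearly separable — a
single tree then classifies perfectly and predictor importance collapses
onto one feature, which contradicts the overlapping class distributions and
distributed importance the method is meant to exhibit. With the split, a
synthetic 300/150-ROI cohort yields a strong but imperfect classifier, and
in a cohort whose signal is placed only in the CH1/CH5 lifetimes the
recovered importance ranking localizes on those channels — the end-to-end
property the acceptance suite checks.

What the generator does **not** emulate: probe-distance and scanning-speed
artifacts, detector afterpulsing, spectral bleed-through between channels,
patient-level correlation beyond the ROI grouping, and any claim about the
*true* lifetime distributions of colorectal tissue. Passing tests therefore
demonstrate the correctness of the pipeline's mathematics and its behavior
under a plausible data-generating process — not clinical performance.

## Problem sizes and reproducibility

The test suite runs its physics checks at 128–256 bins (the transform's
accuracy is resolution-independent; closed-form checks use the full 1024)
and its end-to-end check on a 300-train / 150-test ROI cohort at 1024 bins
with a 60-cycle hyperparameter search — the cohort scale at which the
class-recovery properties are stable. All randomness flows through explicit
seeds; per-(position, channel) RNG streams are derived from the master seed
by an integer hash, so any subset of a scan re-simulates bit-identically.

## Known limitations

* The flat-CSV archive is the interchange format; HDF5 containers used by
  some acquisition software are not read directly.
* Background is modeled and corrected as uniform; structured backgrounds
  (room-light modulation, afterpulsing tails) would bias the modulus.
* The probability map's Gaussian smoothing (σ = 2 px default) is a display
  convention, not an inference; masked pixels simply lack measurement
  support.
* MCC is defined as 0 (flagged) when a confusion margin is empty; the
  alternative convention (undefined) would drop such repeats from averages.
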