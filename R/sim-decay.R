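# Analytic decay model: a periodically excited multi-exponential convolved
# with a Gaussian IRF, integrated exactly over each TCSPC bin via the
# exponentially-modified-Gaussian CDF, with the periodic wrap summed as
# explicit pulse terms until the geometric tail is below double precision.

# CDF of exp(-(x-t0)/tau)/tau (x > t0) convolved with N(0, sigma^2).
# Evaluated in log space on the second term so it is stable far into the
# pre-rise region.
emg_cdf <- function(x, t0, sigma, tau) {
  u <- x - t0
  if (sigma <= 0) {
    return(ifelse(u > 0, 1 - exp(-u / tau), 0))
  }
  z <- u / sigma
  term <- exp(pnorm(z - sigma / tau, log.p = TRUE) +
                sigma^2 / (2 * tau^2) - u / tau)
  pmax(pnorm(z) - term, 0)
}

# Expected per-bin probabilities of the wrapped model (sums to ~1).
# taus/fracs: multi-exponential components; t0/sigma: IRF center and SD.
decay_model_bins <- function(taus, fracs, t0, sigma, n_bins, T) {
  edges <- seq(0, T, length.out = n_bins + 1L)
  out <- numeric(n_bins)
  for (j in seq_along(taus)) {
    tau <- taus[j]
    K <- max(3L, ceiling(37 * tau / T))
    shifted <- outer(edges, (0:K) * T, "+")
    cdf <- emg_cdf(as.vector(shifted), t0, sigma, tau)
    cdf <- matrix(cdf, nrow = n_bins + 1L)
    out <- out + fracs[j] * rowSums(diff(cdf))
  }
  pmax(out, 0)
}

fwhm_to_sd <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

#' Synthesize an instrument response function histogram
#'
#' Discretizes a Gaussian pulse of the configured FWHM and offset onto the
#' decay binning (bin-integrated, wrapped over the period). A width of zero
#' produces a single-bin delta. The IRF carries the zero-lifetime reference
#' (tau_ref = 0 ns) used for phasor calibration.
#'
#' @param config A [sim_config()].
#' @param channel Channel id 1..5 (the synthetic IRF is channel-independent in
#'   shape; the id is recorded for bookkeeping).
#' @param counts Total counts in the histogram (default 1e6; the IRF is used
#'   ratiometrically so the scale is immaterial).
#' @return One-row tibble with list-column `counts`.
#' @export
make_irf <- function(config, channel, counts = 1e6) {
  stopifnot(channel %in% 1:5)
  n <- config$n_bins
  edges <- seq(0, config$T, length.out = n + 1L)
  sigma <- fwhm_to_sd(config$irf_fwhm)
  if (sigma <= 0) {
    p <- numeric(n)
    idx <- min(n, max(1L, findInterval(config$irf_offset, edges,
                                       rightmost.closed = TRUE)))
    p[idx] <- 1
  } else {
    p <- numeric(n)
    for (k in -1:1) {
      cdf <- pnorm(edges + k * config$T, mean = config$irf_offset, sd = sigma)
      p <- p + diff(cdf)
    }
  }
  tibble::tibble(
    channel = as.integer(channel),
    counts = list(p / sum(p) * counts),
    n_bins = n, bin_width = config$T / n, T = config$T
  )
}

#' Simulate one TCSPC decay
#'
#' Draws a single decay histogram for one tissue class and detection channel:
#' the class/channel multi-exponential (dominant lifetime perturbed by a
#' truncated-normal inter-measurement draw) is convolved with the Gaussian
#' IRF, wrapped over the period, scaled to a log-normally varying photon
#' budget, summed with uniform background, and Poisson-sampled.
#'
#' @param tissue_class `"benign"` or `"malignant"`.
#' @param channel Channel id 1..5.
#' @param config A [sim_config()].
#' @param seed Optional integer; when given, the decay is drawn under its own
#'   RNG stream and the caller's RNG state is untouched.
#' @param noise If `FALSE`, returns the noise-free expected histogram (class
#'   mean lifetime, mean budget, no Poisson draw) — useful for closed-form
#'   checks.
#' @param tau_center Optional tissue-spot lifetime for the dominant
#'   component, ns. When given, the biological draw is skipped and only the
#'   measurement-level jitter (`tau_meas_sd`) is applied — this is how a
#'   cohort simulation ties repeat measurements of one ROI to one piece of
#'   tissue.
#' @param intensity_mult Optional tissue-spot relative-intensity multiplier;
#'   when given it replaces the per-decay biological intensity draw
#'   (`intensity_bio_cv`), analogous to `tau_center`.
#' @return One-row tibble (a decay record): `channel`, `tissue_class`,
#'   list-column `counts`, `n_bins`, `bin_width`, `T`, `total`, `peak`.
#' @export
sample_decay <- function(tissue_class, channel, config, seed = NULL,
                         noise = TRUE, tau_center = NULL,
                         intensity_mult = NULL) {
  stopifnot(tissue_class %in% c("benign", "malignant"), channel %in% 1:5)
  model <- config$class_models[[tissue_class]][[channel]]
  draw <- function() {
    taus <- model$components$tau
    fracs <- model$components$frac
    budget <- config$photon_budget * model$intensity
    if (noise) {
      i_main <- which.max(fracs)
      center <- if (is.null(tau_center)) {
        rtruncnorm1(taus[i_main], model$tau_sd, lower = 0.1)
      } else {
        tau_center
      }
      taus[i_main] <- rtruncnorm1(center, config$tau_meas_sd %||% 0.1,
                                  lower = 0.1)
      bio_cv <- config$intensity_bio_cv %||% 0.2
      mult <- if (is.null(intensity_mult)) {
        if (bio_cv > 0) exp(rnorm(1, -bio_cv^2 / 2, bio_cv)) else 1
      } else {
        intensity_mult
      }
      budget <- budget * mult
      cv <- config$budget_cv %||% 0.15
      if (cv > 0) budget <- budget * exp(rnorm(1, -cv^2 / 2, cv))
    }
    p <- decay_model_bins(taus, fracs, config$irf_offset,
                          fwhm_to_sd(config$irf_fwhm),
                          config$n_bins, config$T)
    lam <- p / sum(p) * budget + config$background_rate
    cts <- if (noise) rpois(config$n_bins, lam) else lam
    tibble::tibble(
      channel = as.integer(channel), tissue_class = tissue_class,
      counts = list(cts),
      n_bins = config$n_bins, bin_width = config$T / config$n_bins,
      T = config$T, total = sum(cts), peak = max(cts)
    )
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

# one truncated-normal draw by inverse-CDF (deterministic given the stream)
rtruncnorm1 <- function(mean, sd, lower) {
  if (sd <= 0) return(max(mean, lower))
  plo <- pnorm((lower - mean) / sd)
  mean + sd * qnorm(runif(1, plo, 1))
}
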