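#' Simulator configuration
#'
#' Builds the configuration object for the synthetic multichannel fiber-probe
#' TCSPC scan generator. The defaults emulate the acquisition geometry of a
#' five-channel autofluorescence lifetime macro-imaging system: two multiplexed
#' excitation wavelengths (375 nm feeding detection channels 1--3 and 445 nm
#' feeding channels 4--5), a 20 MHz laser repetition rate (period `T = 50` ns),
#' and TCSPC histograms of `n_bins` bins spanning one period.
#'
#' Class-conditional decay models follow the qualitative contrast reported for
#' benign versus malignant colorectal tissue: malignant decays are shorter in
#' channels 1 (collagen band) and 5 (FAD band), while channels 2--3 (NAD(P)H
#' bands) show equal class means but a wider malignant dispersion. Each channel
#' model is a two-component multi-exponential; the dominant component lifetime
#' is drawn per measurement from a truncated normal around the class mean with
#' the stated dispersion SD.
#'
#' @param T Laser repetition period in ns.
#' @param n_bins Number of TCSPC histogram bins over one period (>= 64).
#' @param photon_budget Mean total photon count per decay for a channel of
#'   relative intensity 1.
#' @param budget_cv Log-normal coefficient of variation of the per-decay
#'   photon budget (default 0.15; 0 fixes the budget at its mean).
#' @param tau_meas_sd Measurement-level SD of the dominant component lifetime
#'   in ns (probe repositioning and shot-noise jitter between repeat
#'   measurements of the same tissue spot; default 0.1). The class models'
#'   `tau_sd` is the tissue-level (biological) dispersion on top of this.
#' @param intensity_bio_cv Tissue-level log-normal CV of each channel's
#'   relative intensity (default 0.2): fluorophore abundance varies from spot
#'   to spot, so fractional intensities and the redox ratio overlap between
#'   classes rather than separating them cleanly.
#' @param background_rate Uniform background, counts per bin.
#' @param irf_fwhm Gaussian IRF full width at half maximum, ns. 0 gives a
#'   single-bin delta.
#' @param irf_offset IRF peak position, ns. The pre-rise region before the
#'   offset is what the background-estimation window samples.
#' @param bg_window_frac Fraction of leading bins used as the background
#'   window (must lie before the IRF rise).
#' @param scene_size Scan grid side, pixels (square scene).
#' @param n_lesions Number of malignant lesions in a scene.
#' @param lesion_radius Range (min, max) of lesion disk radius, pixels.
#' @param roi_size Side of square ROIs drawn by the scan simulator, pixels.
#' @param max_rois_per_type Maximum ROIs per tissue type per scene.
#' @param class_models Optional replacement for the default per-class,
#'   per-channel decay models; see [default_class_models()].
#'
#' @return A `sim_config` object (a list).
#' @export
#' @examples
#' cfg <- sim_config(n_bins = 256)
#' cfg$channels
sim_config <- function(T = 50, n_bins = 1024L,
                       photon_budget = 5000, budget_cv = 0.15,
                       tau_meas_sd = 0.1, intensity_bio_cv = 0.2,
                       background_rate = 0.2,
                       irf_fwhm = 0.2, irf_offset = 5,
                       bg_window_frac = 0.05,
                       scene_size = 64L, n_lesions = 1L,
                       lesion_radius = c(12, 18),
                       roi_size = 10L, max_rois_per_type = 3L,
                       class_models = default_class_models()) {
  n_bins <- as.integer(n_bins)
  if (n_bins < 64L) abort("`n_bins` must be >= 64.", class = "phb_config_error")
  if (T <= 0) abort("`T` must be positive.", class = "phb_config_error")
  if (photon_budget < 0) {
    abort("`photon_budget` must be >= 0.", class = "phb_config_error")
  }
  if (irf_fwhm < 0) abort("`irf_fwhm` must be >= 0.", class = "phb_config_error")

  channels <- tibble::tibble(
    channel = 1:5,
    excitation = c(375, 375, 375, 445, 445),
    band = c("380/40", "472/28", "525/50", "472/28", "525/50"),
    fluorophore = c("collagen", "NAD(P)H", "NAD(P)H/FAD", "NAD(P)H", "FAD")
  )
  check_class_models(class_models, T)

  structure(
    list(
      T = T, n_bins = n_bins, channels = channels,
      class_models = class_models,
      photon_budget = photon_budget, budget_cv = budget_cv,
      tau_meas_sd = tau_meas_sd, intensity_bio_cv = intensity_bio_cv,
      background_rate = background_rate,
      irf_fwhm = irf_fwhm, irf_offset = irf_offset,
      bg_window_frac = bg_window_frac,
      scene_size = as.integer(scene_size), n_lesions = as.integer(n_lesions),
      lesion_radius = lesion_radius, roi_size = as.integer(roi_size),
      max_rois_per_type = as.integer(max_rois_per_type)
    ),
    class = "sim_config"
  )
}

#' Default class-conditional decay models
#'
#' One entry per class (`benign`, `malignant`), each a list of five channel
#' models. A channel model has `components` (a data frame of component
#' lifetimes `tau` in ns and intensity fractions `frac` summing to 1),
#' `tau_sd` (the inter-measurement SD of the dominant component lifetime, ns)
#' and `intensity` (relative mean channel intensity used for the photon
#' budget, fractional intensities and the redox ratio).
#'
#' @return Named list of class models.
#' @export
default_class_models <- function() {
  ch <- function(tau_main, tau_sd, intensity) {
    list(
      components = data.frame(tau = c(0.5, tau_main), frac = c(0.2, 0.8)),
      tau_sd = tau_sd,
      intensity = intensity
    )
  }
  # class means overlap substantially (tissue-level heterogeneity dominates),
  # with the contrast carried by shorter malignant lifetimes in CH1 and CH5
  # and a wider malignant spread in the NAD(P)H channels 2-3
  list(
    benign = list(
      ch(5.2, 0.50, 1.00), ch(2.8, 0.30, 0.90), ch(3.2, 0.30, 0.80),
      ch(3.6, 0.40, 0.70), ch(4.4, 0.45, 0.75)
    ),
    malignant = list(
      ch(4.0, 0.60, 0.90), ch(2.8, 0.70, 1.00), ch(3.2, 0.70, 0.80),
      ch(3.5, 0.45, 0.70), ch(3.5, 0.50, 0.65)
    )
  )
}

check_class_models <- function(cm, T) {
  if (!setequal(names(cm), c("benign", "malignant"))) {
    abort("class_models must have entries 'benign' and 'malignant'.",
          class = "phb_config_error")
  }
  for (cls in names(cm)) {
    if (length(cm[[cls]]) != 5L) {
      abort("each class model needs 5 channel entries.",
            class = "phb_config_error")
    }
    for (m in cm[[cls]]) {
      if (abs(sum(m$components$frac) - 1) > 1e-8) {
        abort("component intensity fractions must sum to 1.",
              class = "phb_config_error")
      }
      if (any(m$components$tau <= 0)) {
        abort("component lifetimes must be positive.",
              class = "phb_config_error")
      }
    }
  }
  invisible(cm)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  period T: %g ns, %d bins (%.4g ns/bin)\n",
              x$T, x$n_bins, x$T / x$n_bins))
  cat(sprintf("  IRF: Gaussian FWHM %g ns at %g ns; background %g counts/bin\n",
              x$irf_fwhm, x$irf_offset, x$background_rate))
  cat(sprintf("  photon budget: %g counts/decay; scene %dx%d px\n",
              x$photon_budget, x$scene_size, x$scene_size))
  invisible(x)
}
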