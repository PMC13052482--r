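# Phasor transform of TCSPC decays and derived lifetime features.
#
# A decay I(t) over one excitation period T is mapped to first-harmonic
# Fourier coordinates
#   g = sum_i c_i cos(2 pi h t_i / T) / sum_i c_i
#   s = sum_i c_i sin(2 pi h t_i / T) / sum_i c_i
# with t_i the bin centers (bin-center Riemann rendering of the continuous
# integrals; error O(1/n_bins^2) at harmonic 1). Calibration against a
# measured IRF (a zero-lifetime reference) is a complex division in phasor
# space. Phase and modulation lifetimes follow from the calibrated angle and
# modulus.

as_counts <- function(decay) {
  if (is.numeric(decay)) return(decay)
  if (is.data.frame(decay) && "counts" %in% names(decay)) {
    return(decay$counts[[1]])
  }
  abort("expected a numeric histogram or a decay record with a `counts` column.")
}

#' Background correction of a decay histogram
#'
#' Estimates a constant background as the mean count over a pre-rise bin
#' window and subtracts it from every bin, clamping negatives to zero (keeps
#' counts physical for the count-based QC). Total and peak metadata are
#' recomputed on the corrected histogram.
#'
#' @param decay A decay record (one-row tibble with a `counts` list-column)
#'   or a bare numeric histogram.
#' @param window Integer bin indices of a contiguous pre-rise window.
#' @return Same shape as the input, background-corrected.
#' @export
subtract_background <- function(decay, window) {
  if (length(window) == 0L) {
    abort("background window is empty.", class = "phb_input_error")
  }
  counts <- as_counts(decay)
  if (any(window < 1L | window > length(counts))) {
    abort("background window outside the histogram.", class = "phb_input_error")
  }
  corrected <- pmax(counts - mean(counts[window]), 0)
  if (is.numeric(decay)) return(corrected)
  decay$counts <- list(corrected)
  decay$total <- sum(corrected)
  decay$peak <- max(corrected)
  decay
}

#' Count-based decay quality control
#'
#' A background-corrected decay is retained iff it holds at least `min_total`
#' photons in total and at least `min_peak` counts in its maximum bin;
#' decays with fewer than 50 photons or fewer than 10 peak counts are
#' excluded by default (boundary values pass).
#'
#' @param decay Decay record(s) (tibble with `total`/`peak` columns) or a
#'   numeric histogram.
#' @param min_total,min_peak QC thresholds.
#' @return Logical vector, one element per decay.
#' @export
qc_pass <- function(decay, min_total = 50, min_peak = 10) {
  if (is.numeric(decay)) {
    return(sum(decay) >= min_total && max(decay) >= min_peak)
  }
  decay$total >= min_total & decay$peak >= min_peak
}

#' Phasor transform
#'
#' @param decay Decay record or numeric histogram.
#' @param T Period in ns (taken from the record when present).
#' @param harmonic Harmonic order (default 1).
#' @return A `phasor_point`: list with `g`, `s`, `harmonic`, `T`.
#' @export
phasor_transform <- function(decay, T = NULL, harmonic = 1L) {
  counts <- as_counts(decay)
  if (is.null(T)) {
    if (is.data.frame(decay) && "T" %in% names(decay)) T <- decay$T[[1]]
    else abort("`T` must be supplied for a bare histogram.")
  }
  tot <- sum(counts)
  if (tot <= 0) {
    abort("zero total intensity: phasor undefined.", class = "phb_phasor_error")
  }
  n <- length(counts)
  tc <- (seq_len(n) - 0.5) * T / n
  w <- 2 * pi * harmonic * tc / T
  phasor_point(sum(counts * cos(w)) / tot, sum(counts * sin(w)) / tot,
               harmonic, T)
}

#' Construct a phasor point
#'
#' @param g,s Phasor coordinates.
#' @param harmonic Harmonic order.
#' @param T Period in ns.
#' @return A `phasor_point`.
#' @export
phasor_point <- function(g, s, harmonic = 1L, T = 50) {
  structure(list(g = g, s = s, harmonic = as.integer(harmonic), T = T),
            class = "phasor_point")
}

#' @export
print.phasor_point <- function(x, ...) {
  cat(sprintf("<phasor_point> g=%.5f s=%.5f (harmonic %d, T=%g ns)\n",
              x$g, x$s, x$harmonic, x$T))
  invisible(x)
}

# vectorized transform of a counts matrix (rows = decays); internal fast path
phasor_transform_matrix <- function(M, T, harmonic = 1L) {
  n <- ncol(M)
  tc <- (seq_len(n) - 0.5) * T / n
  w <- 2 * pi * harmonic * tc / T
  tot <- rowSums(M)
  tibble::tibble(g = as.vector(M %*% cos(w)) / tot,
                 s = as.vector(M %*% sin(w)) / tot,
                 total = tot)
}

#' Calibrate a raw phasor against an IRF reference
#'
#' The IRF is a zero-lifetime reference (tau_ref = 0 ns), so calibration is
#' the complex division (g + i s) / (g_irf + i s_irf): modulation ratios are
#' divided and phases subtracted, mapping an IRF measurement to (1, 0).
#'
#' @param raw,irf_raw `phasor_point`s of the decay and of the IRF measured in
#'   the same channel.
#' @return Calibrated `phasor_point`.
#' @export
reference_phasor <- function(raw, irf_raw) {
  m2 <- irf_raw$g^2 + irf_raw$s^2
  if (m2 <= 0) {
    abort("IRF phasor at the origin: cannot reference.",
          class = "phb_phasor_error")
  }
  z <- complex(real = raw$g, imaginary = raw$s) /
    complex(real = irf_raw$g, imaginary = irf_raw$s)
  phasor_point(Re(z), Im(z), raw$harmonic, raw$T)
}

#' Phase lifetime from a phasor
#'
#' `tau_p = (T / 2 pi h) * s / g`. Undefined (NA) for g <= 0; such points are
#' flagged and excluded downstream.
#'
#' @param p A `phasor_point`.
#' @return Lifetime in ns, or NA.
#' @export
phase_lifetime <- function(p) {
  if (!is.finite(p$g) || p$g <= 0) return(NA_real_)
  (p$T / (2 * pi * p$harmonic)) * p$s / p$g
}

#' Modulation lifetime from a phasor
#'
#' `tau_m = (T / 2 pi h) * sqrt(1 / (g^2 + s^2) - 1)`. A modulus above 1
#' (noise outside the universal circle) is clamped to 1, giving 0 ns; a
#' modulus of 0 is undefined (NA).
#'
#' @param p A `phasor_point`.
#' @return Lifetime in ns, or NA.
#' @export
modulation_lifetime <- function(p) {
  m2 <- p$g^2 + p$s^2
  if (!is.finite(m2) || m2 <= 0) return(NA_real_)
  m2 <- min(m2, 1)
  (p$T / (2 * pi * p$harmonic)) * sqrt(1 / m2 - 1)
}

#' Fractional intensities per excitation group
#'
#' Channel intensity divided by the summed intensity of all channels sharing
#' the same excitation wavelength: channels 1--3 form the 375 nm group and
#' channels 4--5 the 445 nm group. A group with zero total yields NA for its
#' channels (the measurement is dropped downstream).
#'
#' @param intensities Numeric length-5 vector of background-corrected channel
#'   totals (channels 1..5).
#' @return Numeric length-5 vector of fractions; each group sums to 1.
#' @export
fractional_intensities <- function(intensities) {
  stopifnot(length(intensities) == 5L)
  out <- rep(NA_real_, 5)
  for (grp in list(1:3, 4:5)) {
    tot <- sum(intensities[grp])
    if (tot > 0) out[grp] <- intensities[grp] / tot
  }
  out
}

#' Optical redox ratio
#'
#' `RR = I2 / (I2 + I5)`, the NAD(P)H-channel intensity over the summed
#' NAD(P)H and FAD channel intensities (background-corrected absolute
#' intensities of detection channels 2 and 5). A label-free metabolic index
#' in `[0, 1]`.
#'
#' @param I2,I5 Background-corrected total intensities of channels 2 and 5.
#' @return RR in `[0, 1]`, or NA when `I2 + I5` is 0.
#' @export
redox_ratio <- function(I2, I5) {
  ifelse(I2 + I5 > 0, I2 / (I2 + I5), NA_real_)
}

#' The 26 decay-derived feature names
#'
#' `{g, s, tau_p, tau_m, F} x channels 1..5` plus the redox ratio `rr`.
#' @return Character vector of length 26.
#' @export
feature_names <- function() {
  c(as.vector(vapply(1:5, function(ch) {
    paste0(c("g", "s", "tau_p", "tau_m", "F"), "_ch", ch)
  }, character(5))), "rr")
}

#' Per-point phasor feature extraction
#'
#' Runs the full preprocessing pipeline on a decay archive: per-decay
#' background correction over a pre-rise window, count QC (fewer than
#' `min_total` photons or `min_peak` peak counts excludes a decay), phasor
#' transform, IRF referencing per channel, phase/modulation lifetimes,
#' per-excitation-group fractional intensities and the redox ratio.
#' Measurement-level quantities (F, RR) are computed only for points whose
#' five channels all pass QC.
#'
#' @param archive A `phasor_archive` (from [simulate_scan()] or
#'   [read_archive_csv()]).
#' @param bg_window Integer bin indices of the background window; default the
#'   leading `bg_window_frac` of bins from the archive config.
#' @param min_total,min_peak QC thresholds (photons; peak counts).
#' @return Tibble: `point_id, x, y`, QC flags, then
#'   `g_ch1 ... F_ch5, rr` (see [feature_names()]); lifetime/phasor columns
#'   are NA for QC-failing channels.
#' @export
phasor_features <- function(archive, bg_window = NULL,
                            min_total = 50, min_peak = 10) {
  cfg <- archive$config
  n <- cfg$n_bins
  if (is.null(bg_window)) {
    bg_window <- seq_len(max(1L, floor(cfg$bg_window_frac * n)))
  }
  decays <- archive$decays
  M <- do.call(rbind, decays$counts)
  M <- pmax(M - rowMeans(M[, bg_window, drop = FALSE]), 0)
  totals <- rowSums(M)
  peaks <- apply(M, 1, max)
  qc <- totals >= min_total & peaks >= min_peak

  # raw phasors, then per-channel IRF referencing (complex division)
  ph <- phasor_transform_matrix(M, cfg$T)
  z <- complex(real = ph$g, imaginary = ph$s)
  z[totals <= 0] <- NA_complex_
  irf_z <- vapply(1:5, function(ch) {
    row <- which(archive$irf$channel == ch)
    p <- phasor_transform(archive$irf$counts[[row]], T = cfg$T)
    complex(real = p$g, imaginary = p$s)
  }, complex(1))
  zc <- z / irf_z[decays$channel]

  g <- Re(zc)
  s <- Im(zc)
  w0 <- 2 * pi / cfg$T
  tau_p <- ifelse(g > 0, (1 / w0) * s / g, NA_real_)
  m2 <- pmin(g^2 + s^2, 1)
  tau_m <- ifelse(m2 > 0, (1 / w0) * sqrt(1 / m2 - 1), NA_real_)

  pt <- tibble::tibble(
    point_id = decays$point_id, x = decays$x, y = decays$y,
    channel = decays$channel,
    g = ifelse(qc, g, NA_real_), s = ifelse(qc, s, NA_real_),
    tau_p = ifelse(qc, tau_p, NA_real_), tau_m = ifelse(qc, tau_m, NA_real_),
    total = totals, qc = qc
  )

  per_point <- pt |>
    dplyr::group_by(.data$point_id, .data$x, .data$y) |>
    dplyr::arrange(.data$channel, .by_group = TRUE) |>
    dplyr::summarise(
      qc_all = all(.data$qc),
      feats = list({
        f_vals <- if (all(.data$qc)) fractional_intensities(.data$total)
                  else rep(NA_real_, 5)
        rr <- if (all(.data$qc)) redox_ratio(.data$total[2], .data$total[5])
              else NA_real_
        v <- c(rbind(.data$g, .data$s, .data$tau_p, .data$tau_m, f_vals), rr)
        setNames(v, feature_names())
      }),
      .groups = "drop"
    )

  qc_flags <- pt |>
    dplyr::select("point_id", "channel", "qc") |>
    tidyr::pivot_wider(names_from = "channel", values_from = "qc",
                       names_prefix = "qc_ch")

  per_point |>
    tidyr::unnest_wider("feats") |>
    dplyr::left_join(qc_flags, by = "point_id") |>
    dplyr::relocate(dplyr::starts_with("qc_ch"), .after = "qc_all")
}
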