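#' Sample a synthetic specimen scene
#'
#' Draws a class map for a square scan grid: disk-shaped malignant lesions on
#' a benign background, plus a serpentine scan path visiting every pixel (the
#' synthetic analogue of hand-scanning a specimen with a fiber probe).
#'
#' @param config A [sim_config()]; `scene_size` must be >= 16.
#' @param seed Integer seed; the same seed reproduces the scene exactly.
#' @return A `scene` object: `class_map` (character matrix, `[y, x]`),
#'   `lesion_mask` (logical matrix), `path` (tibble `order`, `x`, `y`).
#' @export
sample_scene <- function(config, seed) {
  sz <- config$scene_size
  if (sz < 16L) abort("scene_size must be >= 16.", class = "phb_config_error")
  if (any(config$lesion_radius <= 0) ||
      config$lesion_radius[1] > config$lesion_radius[2]) {
    abort("invalid lesion_radius range.", class = "phb_config_error")
  }
  lesion <- matrix(FALSE, sz, sz)
  with_seed(derive_seed(seed, 101L), {
    if (config$n_lesions > 0L) {
      for (i in seq_len(config$n_lesions)) {
        r <- runif(1, config$lesion_radius[1], config$lesion_radius[2])
        lo <- ceiling(r) + 1
        hi <- sz - ceiling(r)
        cx <- if (lo <= hi) runif(1, lo, hi) else (sz + 1) / 2
        cy <- if (lo <= hi) runif(1, lo, hi) else (sz + 1) / 2
        xs <- matrix(rep(seq_len(sz), each = sz), sz, sz)   # [y, x] -> x
        ys <- matrix(rep(seq_len(sz), times = sz), sz, sz)  # [y, x] -> y
        lesion <- lesion | ((xs - cx)^2 + (ys - cy)^2 <= r^2)
      }
    }
  })
  class_map <- matrix("benign", sz, sz)
  class_map[lesion] <- "malignant"
  xs <- unlist(lapply(seq_len(sz), function(row) {
    if (row %% 2L == 1L) seq_len(sz) else rev(seq_len(sz))
  }))
  path <- tibble::tibble(
    order = seq_len(sz * sz),
    x = xs,
    y = rep(seq_len(sz), each = sz)
  )
  structure(list(class_map = class_map, lesion_mask = lesion, path = path),
            class = "scene")
}

#' @export
print.scene <- function(x, ...) {
  cat(sprintf("<scene> %dx%d px, %d malignant px, %d scan positions\n",
              nrow(x$class_map), ncol(x$class_map), sum(x$lesion_mask),
              nrow(x$path)))
  invisible(x)
}

#' Simulate a full probe scan of a scene
#'
#' Produces one decay per detection channel per scan position (each under its
#' own RNG stream derived from the master seed, so any subset re-simulates
#' identically) together with labeled ground-truth ROIs: small squares drawn
#' fully inside the lesion (malignant) or remote from it (benign), at most
#' `max_rois_per_type` each.
#'
#' @param scene A [sample_scene()] result.
#' @param config The [sim_config()] used for the scene.
#' @param seed Integer master seed.
#' @param sample_id,patient_id Identifiers copied onto the ROIs.
#' @return List with `archive` (a `phasor_archive`) and `rois` (tibble
#'   `roi_id, x0, y0, x1, y1, label, sample_id, patient_id`).
#' @export
simulate_scan <- function(scene, config, seed, sample_id = "S1",
                          patient_id = "P1") {
  if (nrow(scene$path) == 0L) {
    abort("scan path is empty.", class = "phb_config_error")
  }
  irf <- purrr::map_dfr(1:5, function(ch) make_irf(config, ch))
  decays <- purrr::pmap_dfr(scene$path, function(order, x, y) {
    cls <- scene$class_map[y, x]
    purrr::map_dfr(1:5, function(ch) {
      d <- sample_decay(cls, ch, config,
                        seed = derive_seed(seed, order, ch))
      d$point_id <- order
      d$x <- x
      d$y <- y
      d
    })
  })
  archive <- new_phasor_archive(decays, irf, config)
  rois <- draw_rois(scene, config, derive_seed(seed, 999L),
                    sample_id, patient_id)
  list(archive = archive, rois = rois)
}

# sample up to max_rois_per_type non-overlapping square ROIs per class:
# malignant squares fully inside the lesion mask, benign squares with no
# lesion pixel within one ROI side (drawn "remotely" from the lesion)
draw_rois <- function(scene, config, seed, sample_id, patient_id) {
  sz <- nrow(scene$class_map)
  k <- config$roi_size
  candidates <- function(ok_px) {
    pos <- expand.grid(x0 = seq_len(sz - k + 1L), y0 = seq_len(sz - k + 1L))
    keep <- vapply(seq_len(nrow(pos)), function(i) {
      all(ok_px[pos$y0[i]:(pos$y0[i] + k - 1L),
                pos$x0[i]:(pos$x0[i] + k - 1L)])
    }, logical(1))
    pos[keep, , drop = FALSE]
  }
  dilate <- function(mask, r) {
    out <- mask
    idx <- which(mask, arr.ind = TRUE)
    if (nrow(idx) == 0L) return(out)
    for (dy in -r:r) for (dx in -r:r) {
      yy <- pmin(pmax(idx[, 1] + dy, 1L), sz)
      xx <- pmin(pmax(idx[, 2] + dx, 1L), sz)
      out[cbind(yy, xx)] <- TRUE
    }
    out
  }
  pick <- function(cand, n_max) {
    chosen <- list()
    with_seed(seed + length(chosen), {
      cand <- cand[sample.int(nrow(cand)), , drop = FALSE]
    })
    for (i in seq_len(nrow(cand))) {
      if (length(chosen) >= n_max) break
      ok <- all(vapply(chosen, function(c0) {
        abs(c0$x0 - cand$x0[i]) >= k || abs(c0$y0 - cand$y0[i]) >= k
      }, logical(1)))
      if (ok) chosen[[length(chosen) + 1L]] <- cand[i, ]
    }
    dplyr::bind_rows(chosen)
  }
  mal_cand <- candidates(scene$lesion_mask)
  ben_cand <- candidates(!dilate(scene$lesion_mask, k))
  mal <- if (nrow(mal_cand)) pick(mal_cand, config$max_rois_per_type) else NULL
  ben <- if (nrow(ben_cand)) pick(ben_cand, config$max_rois_per_type) else NULL
  rois <- dplyr::bind_rows(
    if (!is.null(ben) && nrow(ben)) dplyr::mutate(ben, label = "benign"),
    if (!is.null(mal) && nrow(mal)) dplyr::mutate(mal, label = "malignant")
  )
  if (is.null(rois) || nrow(rois) == 0L) {
    return(tibble::tibble(roi_id = integer(), x0 = integer(), y0 = integer(),
                          x1 = integer(), y1 = integer(), label = character(),
                          sample_id = character(), patient_id = character()))
  }
  tibble::tibble(
    roi_id = seq_len(nrow(rois)),
    x0 = as.integer(rois$x0), y0 = as.integer(rois$y0),
    x1 = as.integer(rois$x0 + k - 1L), y1 = as.integer(rois$y0 + k - 1L),
    label = rois$label, sample_id = sample_id, patient_id = patient_id
  )
}

new_phasor_archive <- function(decays, irf, config) {
  structure(list(decays = decays, irf = irf, config = config),
            class = "phasor_archive")
}

#' @export
print.phasor_archive <- function(x, ...) {
  cat(sprintf("<phasor_archive> %d decays, %d IRF channels, %d bins over %g ns\n",
              nrow(x$decays), nrow(x$irf), x$config$n_bins, x$config$T))
  invisible(x)
}

#' Simulate a labeled ROI cohort
#'
#' Generates an observation table directly: each ROI is assigned a tissue
#' class, `points_per_roi` probe measurements (5 channels each) are drawn
#' from the class decay model, pushed through the full phasor feature
#' pipeline, and averaged over QC-passing points into one 26-feature
#' observation. Sample/patient identifiers group consecutive ROIs in threes,
#' mirroring the at-most-three-ROIs-per-sample acquisition convention.
#'
#' @param n_rois Number of observations to generate.
#' @param config A [sim_config()].
#' @param seed Integer master seed.
#' @param malignant_frac Fraction of ROIs labeled malignant (default 0.39,
#'   the class balance of a typical surgical cohort).
#' @param points_per_roi Probe measurements averaged per ROI.
#' @param cohort Cohort tag copied onto every row (also prefixes ids so two
#'   cohorts never share patients).
#' @return Tibble: 26 feature columns, `label`, `sample_id`, `patient_id`,
#'   `cohort`.
#' @export
simulate_cohort <- function(n_rois, config = sim_config(), seed = 1L,
                            malignant_frac = 0.39, points_per_roi = 9L,
                            cohort = "train") {
  n_mal <- round(n_rois * malignant_frac)
  labels <- with_seed(derive_seed(seed, 7L), {
    sample(c(rep("malignant", n_mal), rep("benign", n_rois - n_mal)))
  })
  irf <- purrr::map_dfr(1:5, function(ch) make_irf(config, ch))
  rows <- purrr::map_dfr(seq_len(n_rois), function(i) {
    # one biological lifetime draw per ROI per channel: repeat measurements
    # sample the same piece of tissue, so only measurement jitter varies
    centers <- vapply(1:5, function(ch) {
      model <- config$class_models[[labels[i]]][[ch]]
      i_main <- which.max(model$components$frac)
      with_seed(derive_seed(seed, i, 600L + ch), {
        rtruncnorm1(model$components$tau[i_main], model$tau_sd, lower = 0.1)
      })
    }, numeric(1))
    bio_cv <- config$intensity_bio_cv %||% 0.2
    mults <- vapply(1:5, function(ch) {
      with_seed(derive_seed(seed, i, 700L + ch), {
        if (bio_cv > 0) exp(rnorm(1, -bio_cv^2 / 2, bio_cv)) else 1
      })
    }, numeric(1))
    decays <- purrr::map_dfr(seq_len(points_per_roi), function(j) {
      purrr::map_dfr(1:5, function(ch) {
        d <- sample_decay(labels[i], ch, config,
                          seed = derive_seed(seed, i, j, ch),
                          tau_center = centers[ch],
                          intensity_mult = mults[ch])
        d$point_id <- j
        d$x <- j
        d$y <- 1L
        d
      })
    })
    feats <- phasor_features(new_phasor_archive(decays, irf, config))
    feats <- dplyr::filter(feats, .data$qc_all)
    if (nrow(feats) == 0L) return(NULL)
    out <- dplyr::summarise(feats, dplyr::across(dplyr::all_of(feature_names()),
                                                 ~ mean(.x, na.rm = TRUE)))
    out$label <- labels[i]
    out$sample_id <- paste0(cohort, "_S", ceiling(i / 3))
    out$patient_id <- paste0(cohort, "_P", ceiling(i / 3))
    out$cohort <- cohort
    out
  })
  tibble::as_tibble(rows)
}
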