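#' Rasterize per-point features into parameter maps
#'
#' Places QC-passing point measurements on the scan grid, one 2D map per
#' parameter; multiple points falling on a pixel are averaged and pixels
#' without measurement support are NA.
#'
#' @param points Per-point feature table from [phasor_features()].
#' @param params Parameters to rasterize (default all 26).
#' @param dims Grid dims `c(ny, nx)`; default the bounding box of the points.
#' @return Named list of `ny x nx` matrices (`[y, x]`).
#' @export
rasterize <- function(points, params = feature_names(), dims = NULL) {
  pts <- dplyr::filter(points, .data$qc_all)
  if (nrow(pts) == 0L) {
    abort("no QC-passing points to rasterize.", class = "phb_input_error")
  }
  if (is.null(dims)) dims <- c(max(pts$y), max(pts$x))
  agg <- pts |>
    dplyr::group_by(.data$x, .data$y) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(params), ~ mean(.x)),
                     .groups = "drop")
  maps <- lapply(params, function(p) {
    m <- matrix(NA_real_, dims[1], dims[2])
    m[cbind(agg$y, agg$x)] <- agg[[p]]
    m
  })
  names(maps) <- params
  maps
}

#' Average parameter maps within a labeled ROI
#'
#' Each feature of the observation is the mean of the corresponding map over
#' the non-missing pixels inside the ROI rectangle; the class label and
#' identifiers are copied from the ROI definition. An ROI intersecting no
#' measured pixel is dropped with a warning.
#'
#' @param maps Named list of matrices from [rasterize()].
#' @param roi One-row tibble: `x0, y0, x1, y1, label, sample_id, patient_id`.
#' @return One-row observation tibble, or NULL when the ROI is empty.
#' @export
average_roi <- function(maps, roi) {
  ys <- max(1L, roi$y0):min(nrow(maps[[1]]), roi$y1)
  xs <- max(1L, roi$x0):min(ncol(maps[[1]]), roi$x1)
  vals <- vapply(maps, function(m) {
    v <- m[ys, xs]
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }, numeric(1))
  if (all(is.na(vals))) {
    warn(sprintf("ROI %s intersects no measured pixel; dropped.",
                 if ("roi_id" %in% names(roi)) roi$roi_id else "?"))
    return(NULL)
  }
  out <- tibble::as_tibble(as.list(vals))
  out$label <- roi$label
  out$sample_id <- if ("sample_id" %in% names(roi)) roi$sample_id else NA
  out$patient_id <- if ("patient_id" %in% names(roi)) roi$patient_id else NA
  out
}

#' Assemble the observation table from an archive and ROI definitions
#'
#' Convenience pipeline: per-point features, rasterized maps, then one
#' pixel-averaged observation per ROI.
#'
#' @param archive A `phasor_archive`.
#' @param rois ROI tibble (`x0, y0, x1, y1, label, sample_id, patient_id`).
#' @param ... Passed to [phasor_features()].
#' @return Observation tibble: 26 features + `label`, `sample_id`,
#'   `patient_id`.
#' @export
extract_features <- function(archive, rois, ...) {
  points <- phasor_features(archive, ...)
  maps <- rasterize(points)
  purrr::map_dfr(seq_len(nrow(rois)), function(i) {
    average_roi(maps, rois[i, ]) %||% tibble::tibble()
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Feature-pool registry
#'
#' Named sub-pools of the 26 features used for the ablation of detection
#' channels and excitation arms. Pool sizes: intensity_only 6,
#' lifetime_only 20, ex375 15, ex445 10, ch1_ch2_ch5_rr 16, ch2_ch5_rr 11,
#' ch1_ch3_ch5_rr 16, ch3_ch5_rr 11, all 26.
#'
#' @return Named list of character vectors of feature names.
#' @export
feature_pools <- function() {
  by_ch <- function(chs, params = c("g", "s", "tau_p", "tau_m", "F")) {
    as.vector(vapply(chs, function(ch) paste0(params, "_ch", ch),
                     character(length(params))))
  }
  list(
    intensity_only = c(by_ch(1:5, "F"), "rr"),
    lifetime_only = by_ch(1:5, c("g", "s", "tau_p", "tau_m")),
    ex375 = by_ch(1:3),
    ex445 = by_ch(4:5),
    ch1_ch2_ch5_rr = c(by_ch(c(1, 2, 5)), "rr"),
    ch2_ch5_rr = c(by_ch(c(2, 5)), "rr"),
    ch1_ch3_ch5_rr = c(by_ch(c(1, 3, 5)), "rr"),
    ch3_ch5_rr = c(by_ch(c(3, 5)), "rr"),
    all = feature_names()
  )
}

#' Restrict an observation table to a feature pool
#'
#' @param table Observation table (features + metadata columns).
#' @param pool_name One of `names(feature_pools())`.
#' @return Table with feature columns restricted to the pool; `label` and
#'   identifier columns kept.
#' @export
select_pool <- function(table, pool_name) {
  pools <- feature_pools()
  if (!pool_name %in% names(pools)) {
    abort(sprintf("unknown pool '%s'; available: %s", pool_name,
                  paste(names(pools), collapse = ", ")),
          class = "phb_input_error")
  }
  meta <- intersect(c("label", "sample_id", "patient_id", "cohort"),
                    names(table))
  dplyr::select(table, dplyr::all_of(c(pools[[pool_name]], meta)))
}
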