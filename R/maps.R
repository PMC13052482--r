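# Probability-of-malignancy and lifetime maps from sequential single-point
# fiber measurements: Gaussian-kernel distance weighting of nearby point
# values, with pixels beyond kernel support masked as missing.

#' Per-point malignancy probabilities in acquisition order
#'
#' Applies a trained ensemble to each QC-passing point measurement of a
#' per-point feature table, preserving acquisition order.
#'
#' @param points Per-point feature table from [phasor_features()].
#' @param model An `ensemble_model`.
#' @return Tibble `point_id, x, y, prob` ordered by `point_id`.
#' @export
point_probabilities <- function(points, model) {
  pts <- points |>
    dplyr::filter(.data$qc_all) |>
    dplyr::arrange(.data$point_id)
  pts |>
    dplyr::transmute(.data$point_id, .data$x, .data$y,
                     prob = predict_proba(model, pts))
}

# kernel-weighted rasterization shared by probability and lifetime maps
smooth_to_grid <- function(x, y, values, dims, sigma, radius) {
  grid_x <- rep(seq_len(dims[2]), each = dims[1])
  grid_y <- rep(seq_len(dims[1]), times = dims[2])
  m <- matrix(NA_real_, dims[1], dims[2])
  if (sigma <= 0 || radius <= 0) {
    # limit: plain per-pixel rasterization (mean of coincident points)
    agg <- tibble::tibble(x = x, y = y, v = values) |>
      dplyr::group_by(.data$x, .data$y) |>
      dplyr::summarise(v = mean(.data$v), .groups = "drop")
    m[cbind(agg$y, agg$x)] <- agg$v
    return(m)
  }
  d2 <- outer(grid_x, x, "-")^2 + outer(grid_y, y, "-")^2
  w <- exp(-d2 / (2 * sigma^2))
  w[d2 > radius^2] <- 0
  tot <- rowSums(w)
  vals <- as.vector(w %*% values) / tot
  vals[tot <= 0] <- NA_real_
  m[cbind(grid_y, grid_x)] <- vals
  m
}

new_map <- function(m, kind, sigma, radius, provenance = NULL) {
  structure(list(map = m, kind = kind, sigma = sigma, radius = radius,
                 provenance = provenance),
            class = c(paste0(kind, "_map"), "phb_map"))
}

#' Probability-of-malignancy map
#'
#' Rasterizes per-point ensemble probabilities: each pixel is the
#' Gaussian-kernel distance-weighted average of nearby point probabilities
#' (the averaging of sequential single-point measurements that smooths out
#' isolated misclassifications); pixels beyond kernel support are missing.
#'
#' @inheritParams point_probabilities
#' @param sigma Kernel SD in pixels (default 2); 0 gives plain nearest-point
#'   rasterization.
#' @param radius Kernel support cutoff in pixels (default `3 * sigma`).
#' @param dims Grid dims `c(ny, nx)`; default the points' bounding box.
#' @return A `probability_map` (values in `[0, 1]` where supported).
#' @export
probability_map <- function(points, model, sigma = 2, radius = 3 * sigma,
                            dims = NULL) {
  pp <- point_probabilities(points, model)
  if (nrow(pp) == 0L) {
    abort("no QC-passing points.", class = "phb_input_error")
  }
  if (is.null(dims)) dims <- c(max(pp$y), max(pp$x))
  m <- smooth_to_grid(pp$x, pp$y, pp$prob, dims, sigma, radius)
  new_map(m, "probability", sigma, radius,
          provenance = list(n_learners = length(model$trees),
                            hp = unclass(model$hp)))
}

#' Lifetime / phasor parameter map
#'
#' Same smoothing contract as [probability_map()] applied to one decay
#' parameter of one detection channel.
#'
#' @inheritParams probability_map
#' @param channel Channel id 1..5.
#' @param parameter One of `"g"`, `"s"`, `"tau_p"`, `"tau_m"`, `"F"`.
#' @return A `lifetime_map`.
#' @export
lifetime_map <- function(points, channel, parameter, sigma = 2,
                         radius = 3 * sigma, dims = NULL) {
  if (!parameter %in% c("g", "s", "tau_p", "tau_m", "F")) {
    abort("parameter must be one of g, s, tau_p, tau_m, F.",
          class = "phb_input_error")
  }
  col <- paste0(parameter, "_ch", channel)
  pts <- points |>
    dplyr::filter(.data$qc_all, is.finite(.data[[col]]))
  if (nrow(pts) == 0L) abort("no usable points.", class = "phb_input_error")
  if (is.null(dims)) dims <- c(max(pts$y), max(pts$x))
  m <- smooth_to_grid(pts$x, pts$y, pts[[col]], dims, sigma, radius)
  new_map(m, "lifetime", sigma, radius,
          provenance = list(channel = channel, parameter = parameter))
}

#' @export
print.phb_map <- function(x, ...) {
  cat(sprintf("<%s_map> %dx%d px, sigma=%g px, %d missing\n", x$kind,
              nrow(x$map), ncol(x$map), x$sigma, sum(is.na(x$map))))
  invisible(x)
}

#' Export a map as CSV (long form: x, y, value)
#'
#' @param map A `phb_map`.
#' @param path CSV path.
#' @export
write_map_csv <- function(map, path) {
  df <- tibble::tibble(
    x = rep(seq_len(ncol(map$map)), each = nrow(map$map)),
    y = rep(seq_len(nrow(map$map)), times = ncol(map$map)),
    value = as.vector(map$map)
  )
  readr::write_csv(df, path)
  invisible(path)
}
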