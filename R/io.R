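# Plain-text interchange formats: flat CSV decay archive (one row per decay:
# kind, point_id, channel, x, y, T, then bin counts), JSON ROI files, and CSV
# observation tables.

#' Write / read a decay archive as flat CSV
#'
#' One row per decay with columns `kind` (`"decay"` or `"irf"`), `point_id`,
#' `channel`, `x`, `y`, `T`, then `bin_1 ... bin_n`. The IRF histograms are
#' stored as `kind = "irf"` rows.
#'
#' @param archive A `phasor_archive`.
#' @param path CSV file path.
#' @return `write_archive_csv` returns `path` invisibly; `read_archive_csv`
#'   the reconstructed `phasor_archive`.
#' @export
write_archive_csv <- function(archive, path) {
  n <- archive$config$n_bins
  bin_cols <- paste0("bin_", seq_len(n))
  flat <- function(tbl, kind) {
    M <- do.call(rbind, tbl$counts)
    colnames(M) <- bin_cols
    dplyr::bind_cols(
      tibble::tibble(
        kind = kind,
        point_id = if ("point_id" %in% names(tbl)) tbl$point_id else NA_integer_,
        channel = tbl$channel,
        x = if ("x" %in% names(tbl)) tbl$x else NA_integer_,
        y = if ("y" %in% names(tbl)) tbl$y else NA_integer_,
        T = archive$config$T
      ),
      tibble::as_tibble(M)
    )
  }
  out <- dplyr::bind_rows(flat(archive$irf, "irf"),
                          flat(archive$decays, "decay"))
  readr::write_csv(out, path)
  invisible(path)
}

#' @param config Optional [sim_config()] to attach; defaults to one rebuilt
#'   from the stored `T` and bin count.
#' @rdname write_archive_csv
#' @export
read_archive_csv <- function(path, config = NULL) {
  flat <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  bin_cols <- grep("^bin_", names(flat), value = TRUE)
  n <- length(bin_cols)
  if (is.null(config)) config <- sim_config(T = flat$T[1], n_bins = n)
  unflat <- function(rows) {
    M <- as.matrix(rows[bin_cols])
    tibble::tibble(
      point_id = rows$point_id, channel = as.integer(rows$channel),
      x = rows$x, y = rows$y,
      counts = lapply(seq_len(nrow(M)), function(i) unname(M[i, ])),
      n_bins = n, bin_width = config$T / n, T = config$T,
      total = rowSums(M), peak = apply(M, 1, max)
    )
  }
  new_phasor_archive(unflat(flat[flat$kind == "decay", ]),
                     unflat(flat[flat$kind == "irf", ]), config)
}

#' Write / read ROI definitions as JSON
#'
#' Rectangles in pixel coordinates with a binary label and sample/patient
#' identifiers.
#'
#' @param rois ROI tibble (`roi_id, x0, y0, x1, y1, label, sample_id,
#'   patient_id`).
#' @param path JSON file path.
#' @export
write_rois_json <- function(rois, path) {
  jsonlite::write_json(rois, path, auto_unbox = FALSE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_rois_json
#' @export
read_rois_json <- function(path) {
  tibble::as_tibble(jsonlite::read_json(path, simplifyVector = TRUE))
}
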