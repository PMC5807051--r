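# Even-odd rule point-in-polygon test, vectorised over points.
# Vertices need not repeat the first point; edges wrap around.
point_in_polygon <- function(px, py, poly) {
  vx <- poly[, 1]; vy <- poly[, 2]
  n <- length(vx)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Mean intensity inside a polygonal ROI, normalized to Hoechst
#'
#' Averages each channel over pixels whose centers fall inside the
#' polygon (even-odd rule), and divides by the Hoechst mean over the
#' identical pixels — the standard way section measurements are made
#' comparable across sections and embryos. Because both numerator and
#' denominator use the same pixels, multiplying the whole image by any
#' constant leaves the normalized value unchanged.
#'
#' @param section A one-plane [voxel_grid()] (a 2D section image).
#' @param polygon Two-column matrix of ROI vertices (x, y in um).
#' @param channels Channels to quantify (default: all but Hoechst).
#' @param hoechst_channel Nuclear-stain channel name.
#' @param roi_id,group Labels recorded in the output.
#' @return A tibble, one row per channel: `roi_id`, `group`, `channel`,
#'   `mean_intensity`, `hoechst_normalized`, `n_pixels`.
#' @export
roi_mean <- function(section, polygon, channels = NULL,
                     hoechst_channel = "hoechst", roi_id = "roi",
                     group = NA_character_) {
  d <- grid_dim(section)
  if (d[3] != 1L) {
    cp_abort("`section` must be a single-plane grid.", "cp_error_spec")
  }
  if (!hoechst_channel %in% channel_names(section)) {
    cp_abort("Hoechst channel missing from section.", "cp_error_spec")
  }
  channels <- channels %||%
    setdiff(channel_names(section), hoechst_channel)
  coords <- grid_coords(section)
  px <- rep(coords$x, each = d[1]); py <- rep(coords$y, times = d[2])
  inside <- point_in_polygon(px, py, polygon)
  if (!any(inside)) {
    cp_abort("ROI polygon covers no pixel centers.", "cp_error_empty")
  }
  sel <- matrix(inside, d[1], d[2])
  ho <- mean(grid_channel(section, hoechst_channel)[, , 1][sel])
  if (ho <= 0) {
    cp_abort("Zero Hoechst mean inside ROI.", "cp_error_degenerate")
  }
  purrr::map_dfr(channels, function(ch) {
    m <- mean(grid_channel(section, ch)[, , 1][sel])
    tibble::tibble(roi_id = roi_id, group = group, channel = ch,
                   mean_intensity = m, hoechst_normalized = m / ho,
                   n_pixels = sum(sel))
  })
}

#' Per-cell disc quantification of a 2D section
#'
#' Quantifies a small disc (default radius 5 um, about one nucleus)
#' around each manually selected cell position as in [roi_mean()], then
#' summarises each group of cells as mean +/- SD (sample SD, n - 1
#' denominator) of the Hoechst-normalized values.
#'
#' @param section A one-plane [voxel_grid()].
#' @param points Tibble with columns `x_um`, `y_um` and optionally
#'   `group` (cell-type label).
#' @param radius_um Disc radius in um (default 5).
#' @param channels,hoechst_channel As in [roi_mean()].
#' @return A `point_quant` list: `cells` (per-point per-channel tibble)
#'   and `groups` (per group x channel: `mean_normalized`,
#'   `sd_normalized`, `n_cells`).
#' @export
point_cell_quant <- function(section, points, radius_um = 5,
                             channels = NULL,
                             hoechst_channel = "hoechst") {
  check_positive_scalar(radius_um, "radius_um")
  group <- if ("group" %in% names(points)) points$group else
    rep(NA_character_, nrow(points))
  theta <- seq(0, 2 * pi, length.out = 33L)[-33L]
  cells <- purrr::map_dfr(seq_len(nrow(points)), function(i) {
    poly <- cbind(points$x_um[i] + radius_um * cos(theta),
                  points$y_um[i] + radius_um * sin(theta))
    roi_mean(section, poly, channels = channels,
             hoechst_channel = hoechst_channel,
             roi_id = paste0("cell_", i), group = group[i])
  })
  groups <- cells |>
    dplyr::group_by(.data$group, .data$channel) |>
    dplyr::summarise(
      mean_normalized = mean(.data$hoechst_normalized),
      sd_normalized = stats::sd(.data$hoechst_normalized),
      n_cells = dplyr::n(), .groups = "drop")
  structure(list(cells = cells, groups = groups), class = "point_quant")
}

#' @export
print.point_quant <- function(x, ...) {
  cat(sprintf("<point_quant> %d cells, %d group x channel summaries\n",
              length(unique(x$cells$roi_id)), nrow(x$groups)))
  print(x$groups)
  invisible(x)
}

#' Read regions of interest from JSON
#'
#' Schema: an array of objects
#' `{roi_id, group, type: "polygon"|"point", coordinates_um}`, where
#' `coordinates_um` is an array of `[x, y]` vertices for polygons or a
#' single `[x, y]` for points. Keeps manual selections reproducible:
#' recorded once, the downstream arithmetic reruns exactly.
#'
#' @param path JSON file path.
#' @return A list of ROI lists with elements `roi_id`, `group`, `type`
#'   and `coordinates_um` (matrix).
#' @export
read_roi_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(raw, function(r) {
    co <- r$coordinates_um
    m <- if (is.list(co[[1]])) {
      do.call(rbind, lapply(co, function(v) unlist(v)))
    } else matrix(unlist(co), ncol = 2)
    if (!r$type %in% c("polygon", "point")) {
      cp_abort("ROI type must be 'polygon' or 'point'.", "cp_error_io")
    }
    list(roi_id = r$roi_id, group = r$group %||% NA_character_,
         type = r$type, coordinates_um = m)
  })
}

#' @rdname read_roi_json
#' @param rois List of ROI lists as returned by [read_roi_json()].
#' @export
write_roi_json <- function(rois, path) {
  jsonlite::write_json(
    lapply(rois, function(r) list(
      roi_id = r$roi_id, group = r$group, type = r$type,
      coordinates_um = apply(r$coordinates_um, 1, as.numeric,
                             simplify = FALSE))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
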