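#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a radial profile into a plain tibble
#'
#' @param x A `radial_profile`.
#' @param ... Unused.
#' @return A tibble of per-bin rows without the profile class.
#' @method tidy radial_profile
#' @export
tidy.radial_profile <- function(x, ...) {
  out <- tibble::as_tibble(x)
  class(out) <- class(tibble::tibble())
  out
}

#' @rdname tidy.radial_profile
#' @method glance radial_profile
#' @export
glance.radial_profile <- function(x, ...) {
  geom <- attr(x, "geometry")
  tibble::tibble(
    colony_id = paste(unique(x$colony_id), collapse = ","),
    n_channels = length(unique(x$channel)),
    n_bins = length(unique(x$bin_start_um)),
    bin_width_um = stats::median(x$bin_end_um - x$bin_start_um),
    total_voxels = sum(x$n_voxels[x$channel == x$channel[1]]),
    normalization = unique(x$normalization),
    fitted_radius_um = if (!is.null(geom)) geom$fitted_radius_um
    else NA_real_)
}

#' Tidy a coexpression gate result
#'
#' @param x A `gate_result`.
#' @param ... Unused.
#' @return Quadrant tibble with channel and threshold columns.
#' @method tidy gate_result
#' @export
tidy.gate_result <- function(x, ...) {
  dplyr::mutate(x$quadrants,
                channel_a = x$channels[["a"]],
                channel_b = x$channels[["b"]],
                threshold_a = x$thresholds[["a"]],
                threshold_b = x$thresholds[["b"]])
}

#' @rdname tidy.gate_result
#' @method glance gate_result
#' @export
glance.gate_result <- function(x, ...) {
  q <- x$quadrants
  tibble::tibble(
    channel_a = x$channels[["a"]], channel_b = x$channels[["b"]],
    threshold_a = x$thresholds[["a"]],
    threshold_b = x$thresholds[["b"]],
    n_voxels = x$n_voxels,
    pct_double_positive = q$percent[q$quadrant == "++"],
    pct_double_negative = q$percent[q$quadrant == "--"])
}

#' Tidy a nuclear density measurement
#'
#' @param x A `density_measurement`.
#' @param ... Unused.
#' @return The per-segment tibble.
#' @method tidy density_measurement
#' @export
tidy.density_measurement <- function(x, ...) x$per_segment

#' @rdname tidy.density_measurement
#' @method glance density_measurement
#' @export
glance.density_measurement <- function(x, ...) {
  tibble::tibble(nuclei_per_100um = x$nuclei_per_100um,
                 positions_sampled = x$positions_sampled,
                 sd_per_100um = stats::sd(x$per_segment$per_100um),
                 context = x$context)
}
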