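new_radial_profile <- function(df, bin_edges = NULL, geometry = NULL) {
  out <- tibble::as_tibble(df)
  class(out) <- c("radial_profile", class(tibble::tibble()))
  attr(out, "bin_edges_um") <- bin_edges
  attr(out, "geometry") <- geometry
  out
}

#' Estimate colony center and radius from a nuclear mask
#'
#' The colony center is the probability-weighted centroid of the
#' thresholded mask projected to xy (a definition that works on cropped
#' single-colony stacks and reduces to the disc center for a symmetric
#' colony); the fitted radius is the xy radius enclosing 99% of mask
#' voxels, which resists stray bright voxels outside the colony.
#'
#' @param mask A [nuclear_mask()].
#' @param nominal_radius_um Optional known micropattern radius
#'   (diameter/2), carried along for reporting.
#' @return A `colony_geometry` list: `center_um` (x, y),
#'   `fitted_radius_um`, `nominal_radius_um`.
#' @export
estimate_center <- function(mask, nominal_radius_um = NA_real_) {
  bin <- mask_binary(mask)
  if (!any(bin)) {
    cp_abort("Mask is empty after thresholding.", "cp_error_empty")
  }
  w <- mask$probability * bin
  d <- dim(w)
  w_xy <- rowSums(w, dims = 2)                     # (y, x)
  xs <- vox_centers(d[2], mask$spacing_um[1])
  ys <- vox_centers(d[1], mask$spacing_um[2])
  tot <- sum(w_xy)
  cx <- sum(w_xy %*% xs) / tot
  cy <- sum(ys %*% w_xy) / tot
  cnt_xy <- rowSums(bin, dims = 2)
  nz_xy <- which(cnt_xy > 0, arr.ind = TRUE)
  r <- sqrt((xs[nz_xy[, 2]] - cx)^2 + (ys[nz_xy[, 1]] - cy)^2)
  fitted <- as.numeric(quantile(rep(r, times = cnt_xy[nz_xy]),
                                0.99, names = FALSE))
  structure(
    list(center_um = c(x = cx, y = cy), fitted_radius_um = fitted,
         nominal_radius_um = nominal_radius_um),
    class = "colony_geometry"
  )
}

#' @export
print.colony_geometry <- function(x, ...) {
  cat(sprintf(
    "<colony_geometry> center (%.1f, %.1f) um, fitted radius %.1f um\n",
    x$center_um["x"], x$center_um["y"], x$fitted_radius_um))
  invisible(x)
}

#' Radial fluorescence profile of a colony
#'
#' The core quantification: every in-colony voxel (mask probability at
#' or above the mask threshold) is assigned its xy distance from the
#' colony center, distances are binned into discrete radial bands of
#' width `bin_width_um` running from 0 to the fitted colony radius, and
#' the arithmetic mean intensity of the voxels in each band is computed
#' per channel. All z-planes contribute at their xy radius; voxels
#' beyond the fitted radius are excluded. Bins are half-open
#' `[a, b)` with the final bin closed, so every selected voxel is
#' counted exactly once.
#'
#' @param grid A [voxel_grid()].
#' @param mask A [nuclear_mask()] congruent with `grid`.
#' @param geometry Optional [estimate_center()] result; computed from
#'   the mask when omitted.
#' @param bin_width_um Radial bin width in micrometres (default 10).
#' @param channels Channels to profile (default all).
#' @param colony_id Identifier recorded in the output.
#' @return A `radial_profile` tibble with columns `colony_id`,
#'   `channel`, `bin_start_um`, `bin_end_um`, `mean_intensity`
#'   (`NA` for empty bins), `n_voxels` and `normalization` (`"raw"`).
#' @export
radial_profile <- function(grid, mask, geometry = NULL,
                           bin_width_um = 10, channels = NULL,
                           colony_id = "colony") {
  check_mask_grid(mask, grid)
  check_positive_scalar(bin_width_um, "bin_width_um")
  geometry <- geometry %||% estimate_center(mask)
  channels <- channels %||% channel_names(grid)
  d <- grid_dim(grid)
  cx <- geometry$center_um["x"]; cy <- geometry$center_um["y"]
  xs <- vox_centers(d[2], grid$spacing_um[1])
  ys <- vox_centers(d[1], grid$spacing_um[2])
  if (cx < 0 || cx > max(xs) + grid$spacing_um[1] / 2 ||
      cy < 0 || cy > max(ys) + grid$spacing_um[2] / 2) {
    cp_abort("Geometry center lies outside the grid.",
             "cp_error_geometry")
  }
  R <- geometry$fitted_radius_um
  if (bin_width_um > R) {
    cp_abort("`bin_width_um` exceeds the colony radius.",
             "cp_error_spec")
  }
  edges <- seq(0, R, by = bin_width_um)
  if (tail(edges, 1) < R) edges <- c(edges, R)
  nb <- length(edges) - 1L

  rmat <- sqrt(outer((ys - cy)^2, (xs - cx)^2, "+"))   # (y, x)
  bin <- mask_binary(mask)
  rfull <- array(rmat, dim = d)                        # constant in z
  sel <- bin & rfull <= R
  idx <- findInterval(rfull[sel], edges, rightmost.closed = TRUE)
  n_vox <- tabulate(idx, nbins = nb)

  rows <- purrr::map_dfr(channels, function(ch) {
    v <- grid_channel(grid, ch)[sel]
    s <- numeric(nb)
    if (length(v)) {
      agg <- rowsum(v, idx)
      s[as.integer(rownames(agg))] <- agg[, 1]
    }
    tibble::tibble(
      colony_id = colony_id, channel = ch,
      bin_start_um = edges[-length(edges)], bin_end_um = edges[-1],
      mean_intensity = ifelse(n_vox > 0, s / n_vox, NA_real_),
      n_voxels = n_vox, normalization = "raw")
  })
  new_radial_profile(rows, bin_edges = edges, geometry = geometry)
}

#' Average radial profiles across colonies
#'
#' Per-bin unweighted mean of per-colony bin means: each colony
#' contributes equally regardless of voxel count, matching how results
#' are averaged across colonies for display. Bins that are empty in
#' some colonies average only the colonies with data; `n_colonies`
#' records how many contributed. `n_voxels` is summed for bookkeeping.
#'
#' @param profiles List of `radial_profile` tibbles with identical bin
#'   edges, channels and normalization.
#' @return A `radial_profile` tibble with `colony_id = "average"` and an
#'   extra `n_colonies` column.
#' @export
average_profiles <- function(profiles) {
  if (!length(profiles)) {
    cp_abort("Need at least one profile.", "cp_error_spec")
  }
  key <- function(p) list(
    bins = paste(p$channel, p$bin_start_um, p$bin_end_um, collapse = ";"),
    norm = unique(p$normalization))
  k1 <- key(profiles[[1]])
  for (p in profiles[-1]) {
    if (!identical(key(p), k1)) {
      cp_abort("Profiles have mismatched binning, channels or normalization.",
               "cp_error_spec")
    }
  }
  bound <- dplyr::bind_rows(profiles, .id = ".colony")
  out <- bound |>
    dplyr::group_by(.data$channel, .data$bin_start_um, .data$bin_end_um,
                    .data$normalization) |>
    dplyr::summarise(
      mean_intensity = if (any(.data$n_voxels > 0))
        mean(.data$mean_intensity[.data$n_voxels > 0]) else NA_real_,
      n_colonies = sum(.data$n_voxels > 0),
      n_voxels = sum(.data$n_voxels),
      .groups = "drop") |>
    dplyr::mutate(colony_id = "average") |>
    dplyr::arrange(.data$channel, .data$bin_start_um) |>
    dplyr::select("colony_id", "channel", "bin_start_um", "bin_end_um",
                  "mean_intensity", "n_voxels", "n_colonies",
                  "normalization")
  new_radial_profile(out, bin_edges = attr(profiles[[1]], "bin_edges_um"),
                     geometry = attr(profiles[[1]], "geometry"))
}

#' Normalize a radial profile for display
#'
#' Three modes mirror standard presentation of radial profiles:
#' `"max100_per_timepoint"` scales each channel so its highest bin mean
#' becomes 100; `"max100_across_timecourse"` scales by the channel
#' maximum over a supplied set of profiles (so relative levels remain
#' comparable across timepoints); `"hoechst_relative"` divides each
#' channel's bin means by the nuclear-stain bin means, bin by bin.
#'
#' @param profile A `radial_profile`.
#' @param mode One of `"max100_per_timepoint"`,
#'   `"max100_across_timecourse"`, `"hoechst_relative"`.
#' @param reference For the across-timecourse mode, a list of profiles
#'   over which the per-channel maximum is taken (include `profile`
#'   itself for the usual convention).
#' @param hoechst_channel Name of the nuclear-stain channel.
#' @return A `radial_profile` with rescaled means and updated
#'   `normalization` column.
#' @export
normalize_profile <- function(profile,
                              mode = c("max100_per_timepoint",
                                       "max100_across_timecourse",
                                       "hoechst_relative"),
                              reference = NULL,
                              hoechst_channel = "hoechst") {
  mode <- match.arg(mode)
  df <- tibble::as_tibble(profile)
  if (mode == "hoechst_relative") {
    if (!hoechst_channel %in% df$channel) {
      cp_abort("Hoechst channel missing from profile.", "cp_error_spec")
    }
    ho <- df[df$channel == hoechst_channel,
             c("bin_start_um", "mean_intensity")]
    names(ho)[2] <- ".hoechst"
    out <- dplyr::left_join(df, ho, by = "bin_start_um") |>
      dplyr::mutate(
        mean_intensity = ifelse(.data$.hoechst > 0,
                                .data$mean_intensity / .data$.hoechst,
                                NA_real_)) |>
      dplyr::select(-".hoechst")
  } else {
    ref_profiles <- if (mode == "max100_across_timecourse") {
      if (is.null(reference)) {
        cp_abort("Across-timecourse mode needs `reference` profiles.",
                 "cp_error_spec")
      }
      reference
    } else list(profile)
    ref_df <- dplyr::bind_rows(lapply(ref_profiles, tibble::as_tibble))
    maxima <- ref_df |>
      dplyr::group_by(.data$channel) |>
      dplyr::summarise(.max = suppressWarnings(
        max(.data$mean_intensity, na.rm = TRUE)), .groups = "drop")
    if (any(!is.finite(maxima$.max)) || any(maxima$.max <= 0)) {
      bad <- maxima$channel[!is.finite(maxima$.max) | maxima$.max <= 0]
      cp_abort(paste("Zero or undefined maximum for channel(s):",
                     paste(bad, collapse = ", ")), "cp_error_zero_max")
    }
    out <- dplyr::left_join(df, maxima, by = "channel") |>
      dplyr::mutate(mean_intensity = .data$mean_intensity /
                      .data$.max * 100) |>
      dplyr::select(-".max")
  }
  out$normalization <- mode
  new_radial_profile(out, bin_edges = attr(profile, "bin_edges_um"),
                     geometry = attr(profile, "geometry"))
}

#' Annotate cell records with radial position
#'
#' Adds each detected cell's distance from the colony center and polar
#' angle, producing the table behind average-colony dot plots where each
#' segmented cell is one dot coloured by its fluorescence. Pool cells
#' from multiple colonies by row-binding per-colony results.
#'
#' @param cells Cell-record tibble from [detect_cell_centroids()].
#' @param geometry A `colony_geometry`.
#' @return The input tibble with `radius_um` and `angle_rad` columns.
#' @export
dot_summary <- function(cells, geometry) {
  cx <- unname(geometry$center_um["x"])
  cy <- unname(geometry$center_um["y"])
  cells |>
    dplyr::mutate(
      radius_um = sqrt((.data$x_um - cx)^2 + (.data$y_um - cy)^2),
      angle_rad = atan2(.data$y_um - cy, .data$x_um - cx))
}

#' Recover a domain boundary from a radial profile
#'
#' For a channel whose profile has one dominant rise or fall, returns
#' the radius at which the profile crosses halfway between its minimum
#' and maximum bin means, by linear interpolation between bin centers.
#' This operationalises reading a domain boundary off a radial profile.
#'
#' @param profile A `radial_profile`.
#' @param channel Channel name.
#' @return Boundary radius in micrometres.
#' @export
recover_boundary <- function(profile, channel) {
  df <- tibble::as_tibble(profile)
  df <- df[df$channel == channel & !is.na(df$mean_intensity), ]
  if (nrow(df) < 2L) {
    cp_abort("Not enough populated bins.", "cp_error_spec")
  }
  centers <- (df$bin_start_um + df$bin_end_um) / 2
  m <- df$mean_intensity
  hi <- max(m); lo <- min(m)
  if (hi - lo <= 1e-9 * max(hi, 1)) {
    cp_abort("Profile is flat: no half-maximum crossing.",
             "cp_error_no_crossing")
  }
  half <- (hi + lo) / 2
  i_ext <- range(which.max(m), which.min(m))
  seg <- seq(i_ext[1], i_ext[2])
  for (k in head(seg, -1)) {
    a <- m[k] - half; b <- m[k + 1] - half
    if (a == 0) return(centers[k])
    if (a * b < 0) {
      return(centers[k] + (centers[k + 1] - centers[k]) * a / (a - b))
    }
    if (b == 0) return(centers[k + 1])
  }
  cp_abort("No half-maximum crossing found.", "cp_error_no_crossing")
}
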