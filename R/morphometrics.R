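#' Colony height versus radial position
#'
#' For each radial bin, the colony height is the z-extent of the
#' binarized nuclear mask over that annulus, measured as a robust extent
#' (2.5th to 97.5th percentile of contributing z indices, inclusive,
#' times the z-spacing) so single stray voxels cannot set the height.
#' Empty bins report height 0.
#'
#' @param mask A [nuclear_mask()].
#' @param geometry Optional `colony_geometry`; estimated from the mask
#'   when omitted (required for an empty mask).
#' @param bin_width_um Radial bin width (default 25 um).
#' @param z_quantiles Robust-extent percentiles (default 0.025/0.975).
#' @param colony_id Identifier recorded in the output.
#' @return A `height_profile` tibble: `colony_id`, `bin_start_um`,
#'   `bin_end_um`, `height_um`, `n_voxels`.
#' @export
height_profile <- function(mask, geometry = NULL, bin_width_um = 25,
                           z_quantiles = c(0.025, 0.975),
                           colony_id = "colony") {
  check_positive_scalar(bin_width_um, "bin_width_um")
  bin <- mask_binary(mask)
  if (!any(bin)) {
    if (is.null(geometry)) {
      cp_abort("Empty mask and no geometry supplied.", "cp_error_empty")
    }
    edges <- height_edges(geometry$fitted_radius_um, bin_width_um)
    return(structure(tibble::tibble(
      colony_id = colony_id,
      bin_start_um = edges[-length(edges)], bin_end_um = edges[-1],
      height_um = 0, n_voxels = 0L),
      class = c("height_profile", class(tibble::tibble()))))
  }
  geometry <- geometry %||% estimate_center(mask)
  d <- dim(bin)
  dz <- mask$spacing_um[3]
  xs <- vox_centers(d[2], mask$spacing_um[1])
  ys <- vox_centers(d[1], mask$spacing_um[2])
  cx <- geometry$center_um["x"]; cy <- geometry$center_um["y"]
  R <- geometry$fitted_radius_um
  edges <- height_edges(R, bin_width_um)
  nb <- length(edges) - 1L
  rmat <- sqrt(outer((ys - cy)^2, (xs - cx)^2, "+"))
  rfull <- array(rmat, dim = d)
  zfull <- array(rep(seq_len(d[3]), each = d[1] * d[2]), dim = d)
  sel <- bin & rfull <= R
  ridx <- findInterval(rfull[sel], edges, rightmost.closed = TRUE)
  zidx <- zfull[sel]
  height <- numeric(nb); n_vox <- tabulate(ridx, nbins = nb)
  for (b in which(n_vox > 0)) {
    zq <- quantile(zidx[ridx == b], z_quantiles, names = FALSE, type = 1)
    height[b] <- (zq[2] - zq[1] + 1) * dz
  }
  structure(tibble::tibble(
    colony_id = colony_id,
    bin_start_um = edges[-length(edges)], bin_end_um = edges[-1],
    height_um = height, n_voxels = n_vox),
    class = c("height_profile", class(tibble::tibble())))
}

height_edges <- function(R, w) {
  if (!is.finite(R) || R <= 0) R <- w
  edges <- seq(0, R, by = w)
  if (tail(edges, 1) < R) edges <- c(edges, R)
  edges
}

#' Nuclei per 100 micrometres along line segments
#'
#' Counts detected nuclei inside a strip around each line segment and
#' reports the average linear density scaled to nuclei per 100 um —
#' the side-view counting protocol, where one counts the single row of
#' nuclei visible along a line across the colony. By default the strip
#' width adapts to the packing: it equals the median nearest-neighbour
#' distance of the supplied cells, i.e. the thickness of one nuclear
#' row, so the linear count scales with the square root of areal
#' density exactly as a manual row count does. Pass an explicit
#' `strip_width_um` to count within a fixed-thickness optical section
#' instead.
#'
#' @param cells Cell-record tibble (columns `x_um`, `y_um`).
#' @param segments Tibble/data frame with one row per segment:
#'   `x0, y0, x1, y1` (um).
#' @param strip_width_um Full strip width in um, or `NULL` (default)
#'   for the adaptive one-row width.
#' @param context Label recorded on the measurement
#'   (e.g. `"colony_sideview"`, `"epiblast_section"`).
#' @return A `density_measurement`: list with `per_segment` tibble
#'   (`segment`, `length_um`, `n_nuclei`, `per_100um`),
#'   `nuclei_per_100um` (mean across segments), `positions_sampled`,
#'   `strip_width_um`, `context`.
#' @export
nuclei_per_100um <- function(cells, segments, strip_width_um = NULL,
                             context = "colony_sideview") {
  if (!nrow(segments)) {
    cp_abort("Need at least one segment.", "cp_error_spec")
  }
  if (is.null(strip_width_um)) {
    strip_width_um <- if (nrow(cells) >= 2) {
      stats::median(internuclear_distances(cells)$distance_um)
    } else 9
  }
  per <- purrr::map_dfr(seq_len(nrow(segments)), function(i) {
    sx <- segments$x0[i]; sy <- segments$y0[i]
    ex <- segments$x1[i]; ey <- segments$y1[i]
    L <- sqrt((ex - sx)^2 + (ey - sy)^2)
    if (L <= 0) {
      cp_abort("Zero-length segment.", "cp_error_spec")
    }
    ux <- (ex - sx) / L; uy <- (ey - sy) / L
    tx <- (cells$x_um - sx) * ux + (cells$y_um - sy) * uy
    perp <- abs(-(cells$x_um - sx) * uy + (cells$y_um - sy) * ux)
    n <- sum(tx >= 0 & tx <= L & perp <= strip_width_um / 2)
    tibble::tibble(segment = i, length_um = L, n_nuclei = n,
                   per_100um = n / L * 100)
  })
  structure(
    list(per_segment = per,
         nuclei_per_100um = mean(per$per_100um),
         positions_sampled = nrow(per),
         strip_width_um = strip_width_um,
         context = context),
    class = "density_measurement"
  )
}

#' @export
print.density_measurement <- function(x, ...) {
  cat(sprintf(
    "<density_measurement> %.2f nuclei / 100 um (%d positions, %s)\n",
    x$nuclei_per_100um, x$positions_sampled, x$context))
  invisible(x)
}

#' Inter-nuclear distances
#'
#' Center-to-center distances between nuclei, in 3D micrometres.
#' `mode = "nearest_neighbor"` returns each cell's distance to its
#' nearest other centroid; `mode = "sampled_pairs"` returns distances
#' for supplied adjacent pairs, emulating manual line measurements
#' between neighbouring nuclei.
#'
#' @param cells Cell-record tibble (columns `x_um`, `y_um`, and
#'   optionally `z_um`).
#' @param mode `"nearest_neighbor"` or `"sampled_pairs"`.
#' @param pairs For `sampled_pairs`: tibble with columns `i`, `j`
#'   (row indices into `cells`).
#' @return A tibble: for nearest-neighbor, `cell`, `neighbor`,
#'   `distance_um`; for sampled pairs, `i`, `j`, `distance_um`.
#' @export
internuclear_distances <- function(cells,
                                   mode = c("nearest_neighbor",
                                            "sampled_pairs"),
                                   pairs = NULL) {
  mode <- match.arg(mode)
  if (nrow(cells) < 2L) {
    cp_abort("Need at least two cells.", "cp_error_spec")
  }
  z <- if ("z_um" %in% names(cells)) cells$z_um else rep(0, nrow(cells))
  if (mode == "sampled_pairs") {
    if (is.null(pairs) || !all(c("i", "j") %in% names(pairs))) {
      cp_abort("`pairs` with columns i, j required for sampled_pairs.",
               "cp_error_spec")
    }
    d <- sqrt((cells$x_um[pairs$i] - cells$x_um[pairs$j])^2 +
                (cells$y_um[pairs$i] - cells$y_um[pairs$j])^2 +
                (z[pairs$i] - z[pairs$j])^2)
    return(tibble::tibble(i = pairs$i, j = pairs$j, distance_um = d))
  }
  dm <- as.matrix(stats::dist(cbind(cells$x_um, cells$y_um, z)))
  diag(dm) <- Inf
  nb <- apply(dm, 1L, which.min)
  tibble::tibble(cell = seq_len(nrow(cells)), neighbor = as.integer(nb),
                 distance_um = dm[cbind(seq_len(nrow(cells)), nb)])
}
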