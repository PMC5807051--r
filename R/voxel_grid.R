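#' Multi-channel voxel grid
#'
#' The unit of all quantification: a set of co-registered 3D fluorescence
#' channels sharing one voxel geometry. Channels are stored as numeric
#' arrays indexed `[y, x, z]`; physical coordinates are voxel-center
#' positions in micrometres, so column `i` is centred at `(i - 0.5) * dx`.
#' A 2D section is simply a grid with a single z-plane.
#'
#' @param channels Named list of numeric 3D arrays (or 2D matrices, which
#'   are promoted to a single z-plane), all with identical dimensions and
#'   non-negative intensities.
#' @param spacing_um Numeric length-3 vector `(dx, dy, dz)` of voxel
#'   spacing in micrometres; all entries must be positive.
#' @param nuclear_channel Name of the channel holding the DNA stain
#'   (Hoechst). Defaults to `"hoechst"` when such a channel exists.
#'
#' @return An object of class `voxel_grid`: a list with elements
#'   `channels`, `spacing_um` and `nuclear_channel`.
#' @export
voxel_grid <- function(channels, spacing_um, nuclear_channel = NULL) {
  if (!is.list(channels) || length(channels) == 0L ||
      is.null(names(channels)) || any(names(channels) == "")) {
    cp_abort("`channels` must be a non-empty named list of arrays.",
             "cp_error_spec")
  }
  if (anyDuplicated(names(channels))) {
    cp_abort("Channel names must be unique.", "cp_error_spec")
  }
  channels <- lapply(channels, function(ch) {
    if (is.matrix(ch)) ch <- array(ch, dim = c(dim(ch), 1L))
    if (!is.array(ch) || length(dim(ch)) != 3L) {
      cp_abort("Each channel must be a 2D matrix or 3D array.",
               "cp_error_spec")
    }
    ch
  })
  dims <- lapply(channels, dim)
  if (!all(vapply(dims, identical, logical(1), dims[[1]]))) {
    cp_abort("All channels must share one geometry.", "cp_error_geometry")
  }
  if (any(vapply(channels, function(ch) any(ch < 0), logical(1)))) {
    cp_abort("Intensities must be non-negative.", "cp_error_spec")
  }
  if (!is.numeric(spacing_um) || length(spacing_um) != 3L ||
      any(!is.finite(spacing_um)) || any(spacing_um <= 0)) {
    cp_abort("`spacing_um` must be three positive numbers (dx, dy, dz).",
             "cp_error_spec")
  }
  spacing_um <- unname(as.numeric(spacing_um))
  if (is.null(nuclear_channel) && "hoechst" %in% names(channels)) {
    nuclear_channel <- "hoechst"
  }
  if (!is.null(nuclear_channel) &&
      !nuclear_channel %in% names(channels)) {
    cp_abort(sprintf("Nuclear channel '%s' not present.", nuclear_channel),
             "cp_error_spec")
  }
  structure(
    list(channels = channels, spacing_um = spacing_um,
         nuclear_channel = nuclear_channel),
    class = "voxel_grid"
  )
}

#' @export
print.voxel_grid <- function(x, ...) {
  d <- grid_dim(x)
  cat(sprintf(
    "<voxel_grid> %d x %d x %d voxels (y, x, z), %d channel(s)\n",
    d[1], d[2], d[3], length(x$channels)))
  cat(sprintf("  spacing (um): dx=%g dy=%g dz=%g\n",
              x$spacing_um[1], x$spacing_um[2], x$spacing_um[3]))
  cat("  channels:", paste(names(x$channels), collapse = ", "), "\n")
  if (!is.null(x$nuclear_channel)) {
    cat("  nuclear channel:", x$nuclear_channel, "\n")
  }
  invisible(x)
}

#' @rdname voxel_grid
#' @param grid A `voxel_grid`.
#' @export
grid_dim <- function(grid) dim(grid$channels[[1]])

#' Extract one channel as a 3D array
#'
#' @param grid A [voxel_grid()].
#' @param name Channel name.
#' @return Numeric 3D array `[y, x, z]`.
#' @export
grid_channel <- function(grid, name) {
  if (!name %in% names(grid$channels)) {
    cp_abort(sprintf("Channel '%s' not present.", name), "cp_error_spec")
  }
  grid$channels[[name]]
}

#' @rdname voxel_grid
#' @export
channel_names <- function(grid) names(grid$channels)

# Voxel-center coordinate vectors in um, matching array axes [y, x, z].
grid_coords <- function(grid) {
  d <- grid_dim(grid)
  list(y = vox_centers(d[1], grid$spacing_um[2]),
       x = vox_centers(d[2], grid$spacing_um[1]),
       z = vox_centers(d[3], grid$spacing_um[3]))
}

nuclear_channel_of <- function(grid, nuclear_channel = NULL) {
  ch <- nuclear_channel %||% grid$nuclear_channel
  if (is.null(ch)) {
    cp_abort("No nuclear channel designated; pass `nuclear_channel`.",
             "cp_error_spec")
  }
  ch
}
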