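#' Write a voxel grid to disk as per-channel TIFF stacks
#'
#' Each channel is saved as one multi-page TIFF (z as pages) in `dir`,
#' alongside a `stack.json` sidecar recording channel names, voxel
#' spacing and the nuclear channel, so [read_stack()] can reassemble the
#' grid without further arguments. 16-bit output quantises to integers
#' (exact round-trip for integer-valued data); 32-bit output stores
#' floats.
#'
#' @param grid A [voxel_grid()].
#' @param dir Output directory (created if needed).
#' @param bits 16 (integer, default) or 32 (float).
#' @return Invisibly, the sidecar path.
#' @export
write_stack <- function(grid, dir, bits = 16L) {
  if (!bits %in% c(16L, 32L)) {
    cp_abort("`bits` must be 16 or 32.", "cp_error_io")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (ch in channel_names(grid)) {
    arr <- grid_channel(grid, ch)
    pages <- lapply(seq_len(dim(arr)[3]), function(k) {
      pg <- arr[, , k]
      if (bits == 16L) pg / INTENSITY_MAX else pg
    })
    f <- file.path(dir, paste0(ch, ".tif"))
    tiff::writeTIFF(pages, f, bits.per.sample = bits,
                    compression = "none")
    files <- c(files, basename(f))
  }
  sidecar <- file.path(dir, "stack.json")
  jsonlite::write_json(
    list(channel_names = channel_names(grid), files = files,
         voxel_spacing_um = grid$spacing_um,
         nuclear_channel = grid$nuclear_channel, bits = bits),
    sidecar, auto_unbox = TRUE, digits = NA)
  invisible(sidecar)
}

#' Read a multi-channel z-stack from per-channel TIFF files
#'
#' Accepts either a directory written by [write_stack()] (the
#' `stack.json` sidecar supplies spacing and channel names) or an
#' explicit vector of single-channel TIFF paths, in which case
#' `channel_names` and `spacing_um` are required — unknown spacing is an
#' error, never guessed. Page counts and frame shapes must agree across
#' channels; inconsistent geometry is rejected rather than coerced.
#'
#' @param path Directory containing `stack.json`, or character vector of
#'   TIFF files (one per channel).
#' @param spacing_um Voxel spacing `(dx, dy, dz)` in um; required unless
#'   a sidecar provides it.
#' @param channel_names Channel names matching `path`; required for the
#'   explicit-files form.
#' @param nuclear_channel Optional nuclear channel name.
#' @return A [voxel_grid()].
#' @export
read_stack <- function(path, spacing_um = NULL, channel_names = NULL,
                       nuclear_channel = NULL) {
  bits <- 16L
  if (length(path) == 1L && dir.exists(path)) {
    sidecar <- file.path(path, "stack.json")
    if (!file.exists(sidecar)) {
      cp_abort("Directory has no stack.json sidecar.", "cp_error_io")
    }
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    files <- file.path(path, meta$files)
    channel_names <- channel_names %||% meta$channel_names
    spacing_um <- spacing_um %||% meta$voxel_spacing_um
    nuclear_channel <- nuclear_channel %||% meta$nuclear_channel
    bits <- meta$bits %||% 16L
  } else {
    files <- path
  }
  if (is.null(spacing_um)) {
    cp_abort("Unknown voxel spacing: pass `spacing_um`.", "cp_error_io")
  }
  if (is.null(channel_names) || length(channel_names) != length(files)) {
    cp_abort("Need one channel name per file.", "cp_error_io")
  }
  missing <- files[!file.exists(files)]
  if (length(missing)) {
    cp_abort(paste("Missing file(s):", paste(missing, collapse = ", ")),
             "cp_error_io")
  }
  stacks <- lapply(files, function(f) {
    pages <- tiff::readTIFF(f, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    pages
  })
  shapes <- lapply(stacks, function(p) c(dim(p[[1]]), length(p)))
  if (!all(vapply(shapes, identical, logical(1), shapes[[1]]))) {
    cp_abort("Channel page counts or frame shapes differ.",
             "cp_error_geometry")
  }
  channels <- lapply(stacks, function(pages) {
    arr <- array(unlist(pages), dim = c(dim(pages[[1]]), length(pages)))
    if (bits == 16L) round(arr * INTENSITY_MAX) else arr
  })
  names(channels) <- channel_names
  voxel_grid(channels, spacing_um, nuclear_channel = nuclear_channel)
}

#' Persist and load nuclear probability masks
#'
#' Masks are stored as multi-page 32-bit float TIFFs (z as pages) with
#' probabilities in `[0, 1]`. On read, values outside `[0, 1]` beyond
#' float-precision slack are rejected; tiny float32 round-off is clamped.
#'
#' @param mask A [nuclear_mask()].
#' @param path Output/input TIFF path.
#' @return `write_mask()` returns `path` invisibly; `read_mask()`
#'   returns a [nuclear_mask()] with `source = "external"`.
#' @export
write_mask <- function(mask, path) {
  pages <- lapply(seq_len(dim(mask$probability)[3]),
                  function(k) mask$probability[, , k])
  tiff::writeTIFF(pages, path, bits.per.sample = 32L,
                  compression = "none")
  invisible(path)
}

#' @rdname write_mask
#' @param spacing_um Voxel spacing of the mask's grid.
#' @param threshold Probability cutoff to store on the mask.
#' @export
read_mask <- function(path, spacing_um, threshold = 0.5) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- array(unlist(pages), dim = c(dim(pages[[1]]), length(pages)))
  tol <- 1e-5
  if (any(arr < -tol) || any(arr > 1 + tol)) {
    cp_abort("Mask probabilities outside [0, 1].", "cp_error_mask_range")
  }
  arr <- pmin(pmax(arr, 0), 1)
  nuclear_mask(arr, spacing_um, threshold = threshold,
               source = "external")
}

#' Write and read radial profiles as CSV
#'
#' Column schema: `colony_id, channel, bin_start_um, bin_end_um,
#' mean_intensity, n_voxels` plus `normalization` and, for averaged
#' profiles, `n_colonies`. An empty profile writes a header-only file.
#'
#' @param profile A `radial_profile` tibble (see [radial_profile()]).
#' @param path CSV path.
#' @return `write_profile()` returns `path` invisibly; `read_profile()`
#'   returns the profile tibble.
#' @export
write_profile <- function(profile, path) {
  readr::write_csv(as.data.frame(profile), path)
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE,
                        progress = FALSE)
  new_radial_profile(df)
}

#' Write any tabular result as CSV
#'
#' Thin wrapper over [readr::write_csv()] so every persisted table in
#' the pipeline goes through one point.
#'
#' @param rows A data frame.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_table <- function(rows, path) {
  readr::write_csv(as.data.frame(rows), path)
  invisible(path)
}

#' Persist colony ground truth as JSON
#'
#' Stores the cell table, true boundaries, center and colony radius of a
#' synthetic colony (not the voxel-level nuclear region, which is
#' re-derivable from the spec).
#'
#' @param truth A `ground_truth` from [generate_colony()].
#' @param path JSON path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(
    list(cells = truth$cells,
         center_um = as.list(truth$center_um),
         colony_radius_um = truth$colony_radius_um,
         boundary_radii_um = truth$boundary_radii_um),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
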