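#' Per-voxel nuclear probability mask
#'
#' Holds the probability, for every voxel of a companion [voxel_grid()],
#' that the voxel lies inside a nucleus, together with the probability
#' cutoff that defines the binary "in-colony" region used by all
#' downstream voxel selections.
#'
#' @param probability Numeric 3D array (or 2D matrix) of probabilities in
#'   `[0, 1]`, spatially congruent with its grid.
#' @param spacing_um Voxel spacing `(dx, dy, dz)` in micrometres.
#' @param threshold Probability cutoff defining in-colony voxels
#'   (default 0.5).
#' @param source `"builtin"` for masks produced by [classify_nuclei()],
#'   `"external"` for masks produced by other classifiers and read from
#'   disk.
#'
#' @return An object of class `nuclear_mask`.
#' @export
nuclear_mask <- function(probability, spacing_um, threshold = 0.5,
                         source = c("builtin", "external")) {
  source <- match.arg(source)
  if (is.matrix(probability)) {
    probability <- array(probability, dim = c(dim(probability), 1L))
  }
  if (!is.array(probability) || length(dim(probability)) != 3L) {
    cp_abort("`probability` must be a 2D matrix or 3D array.",
             "cp_error_spec")
  }
  if (any(!is.finite(probability)) ||
      any(probability < 0) || any(probability > 1)) {
    cp_abort("Mask probabilities must lie in [0, 1].",
             "cp_error_mask_range")
  }
  if (!is_scalar_number(threshold) || threshold < 0 || threshold > 1) {
    cp_abort("`threshold` must be a probability.", "cp_error_spec")
  }
  if (!is.numeric(spacing_um) || length(spacing_um) != 3L ||
      any(spacing_um <= 0)) {
    cp_abort("`spacing_um` must be three positive numbers.",
             "cp_error_spec")
  }
  structure(
    list(probability = probability,
         spacing_um = unname(as.numeric(spacing_um)),
         threshold = threshold, source = source),
    class = "nuclear_mask"
  )
}

#' @export
print.nuclear_mask <- function(x, ...) {
  d <- dim(x$probability)
  cat(sprintf(
    "<nuclear_mask> %d x %d x %d voxels, threshold %.2f, source '%s'\n",
    d[1], d[2], d[3], x$threshold, x$source))
  cat(sprintf("  in-colony voxels at threshold: %d\n",
              sum(x$probability >= x$threshold)))
  invisible(x)
}

#' Binarize a nuclear mask
#'
#' Voxels with probability greater than or equal to the threshold are
#' in-colony. Raising the threshold can only shrink the region
#' (monotonicity), which downstream code relies on.
#'
#' @param mask A [nuclear_mask()].
#' @param threshold Optional override of the mask's stored threshold.
#' @return Logical 3D array.
#' @export
mask_binary <- function(mask, threshold = NULL) {
  thr <- threshold %||% mask$threshold
  mask$probability >= thr
}

# Geometry congruence check used by every grid+mask entry point.
check_mask_grid <- function(mask, grid) {
  if (!identical(dim(mask$probability), grid_dim(grid))) {
    cp_abort("Mask and grid geometries differ.", "cp_error_geometry")
  }
  invisible(TRUE)
}
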