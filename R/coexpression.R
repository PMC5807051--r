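#' Paired voxel intensities for two markers
#'
#' Coexpression is analysed at the voxel level: for every in-colony
#' voxel, the fluorescence of both markers in that voxel forms one
#' (a, b) pair. A 2D histogram density (128 x 128 bins on log1p-scaled
#' axes) is attached per pair for density-coloured scatter plots.
#'
#' @param grid A [voxel_grid()].
#' @param mask A [nuclear_mask()] congruent with `grid`.
#' @param channel_a,channel_b Marker channel names.
#' @param density_bins Number of histogram bins per axis.
#' @return A tibble with one row per masked voxel: columns `a`, `b`
#'   (intensities, a.u.) and `density` (count of pairs in the same 2D
#'   histogram cell). Attributes `channels` and `density_grid` (tibble
#'   of cell midpoints and counts) support plotting.
#' @export
voxel_pairs <- function(grid, mask, channel_a, channel_b,
                        density_bins = 128L) {
  check_mask_grid(mask, grid)
  for (ch in c(channel_a, channel_b)) {
    if (!ch %in% channel_names(grid)) {
      cp_abort(sprintf("Channel '%s' not present.", ch), "cp_error_spec")
    }
  }
  sel <- mask_binary(mask)
  a <- grid_channel(grid, channel_a)[sel]
  b <- grid_channel(grid, channel_b)[sel]
  out <- tibble::tibble(a = a, b = b)
  if (nrow(out)) {
    la <- log1p(a); lb <- log1p(b)
    brk <- function(v) {
      r <- range(v)
      if (r[1] == r[2]) r <- r + c(-0.5, 0.5)
      seq(r[1], r[2], length.out = density_bins + 1L)
    }
    ba <- brk(la); bb <- brk(lb)
    ia <- findInterval(la, ba, rightmost.closed = TRUE)
    ib <- findInterval(lb, bb, rightmost.closed = TRUE)
    cell <- (ia - 1L) * density_bins + ib
    counts <- tabulate(cell, nbins = density_bins^2)
    out$density <- counts[cell]
    grid_tb <- tibble::tibble(
      cell = which(counts > 0),
      a_mid = expm1((ba[-1] + ba[-length(ba)]) / 2)[
        ((which(counts > 0) - 1L) %/% density_bins) + 1L],
      b_mid = expm1((bb[-1] + bb[-length(bb)]) / 2)[
        ((which(counts > 0) - 1L) %% density_bins) + 1L],
      count = counts[counts > 0])
    attr(out, "density_grid") <- grid_tb
  }
  attr(out, "channels") <- c(a = channel_a, b = channel_b)
  out
}

#' Derive an intensity gate from a 0 hr reference
#'
#' For markers absent (or lowly expressed) at the start of
#' differentiation, the positivity threshold is drawn from the 0 hr
#' reference: the given quantile of that channel's masked voxel
#' intensities in the reference colony. The default quantile of 0.99
#' tolerates the rare spontaneously differentiated cells present even
#' at 0 hr.
#'
#' @param reference_grid 0 hr reference [voxel_grid()].
#' @param reference_mask Its [nuclear_mask()].
#' @param channel Channel to gate.
#' @param quantile Reference quantile in (0, 1); default 0.99.
#' @return Threshold intensity (a.u.).
#' @export
gate_from_reference <- function(reference_grid, reference_mask, channel,
                                quantile = 0.99) {
  if (!is_scalar_number(quantile) || quantile <= 0 || quantile >= 1) {
    cp_abort("`quantile` must lie strictly between 0 and 1.",
             "cp_error_spec")
  }
  check_mask_grid(reference_mask, reference_grid)
  sel <- mask_binary(reference_mask)
  if (!any(sel)) {
    cp_abort("Reference mask is empty.", "cp_error_empty")
  }
  v <- grid_channel(reference_grid, channel)[sel]
  stats::quantile(v, quantile, names = FALSE, type = 7)
}

#' Quadrant percentages of gated voxel pairs
#'
#' Classifies every voxel pair into the four quadrants defined by the
#' two thresholds — positivity means strictly greater than the
#' threshold (ties count as negative, a conservative call) — and
#' reports the percentage of total masked voxels in each quadrant.
#' The four percentages sum to 100 exactly.
#'
#' @param pairs Tibble from [voxel_pairs()] (columns `a`, `b`).
#' @param threshold_a,threshold_b Gate thresholds (a.u.).
#' @param reference Optional description of how the gates were derived,
#'   recorded in the result.
#' @return A `gate_result`: list with `channels`, `thresholds`,
#'   `quadrants` tibble (`quadrant` in `--`, `+-`, `-+`, `++`; `n`;
#'   `percent`), `n_voxels` and `reference`.
#' @export
quadrant_percentages <- function(pairs, threshold_a, threshold_b,
                                 reference = NULL) {
  if (!nrow(pairs)) {
    cp_abort("Empty pair list.", "cp_error_empty")
  }
  if (!is.finite(threshold_a) || !is.finite(threshold_b)) {
    cp_abort("Thresholds must be finite.", "cp_error_spec")
  }
  ap <- pairs$a > threshold_a
  bp <- pairs$b > threshold_b
  n <- nrow(pairs)
  counts <- c(`--` = sum(!ap & !bp), `+-` = sum(ap & !bp),
              `-+` = sum(!ap & bp), `++` = sum(ap & bp))
  percent <- 100 * as.numeric(counts) / n
  structure(
    list(channels = attr(pairs, "channels"),
         thresholds = c(a = threshold_a, b = threshold_b),
         quadrants = tibble::tibble(
           quadrant = names(counts), n = as.integer(counts),
           percent = percent),
         n_voxels = n,
         reference = reference),
    class = "gate_result"
  )
}

#' @export
print.gate_result <- function(x, ...) {
  ch <- x$channels
  cat(sprintf("<gate_result> %s vs %s, n = %d voxels\n",
              ch[["a"]], ch[["b"]], x$n_voxels))
  cat(sprintf("  thresholds: %s > %.1f, %s > %.1f\n",
              ch[["a"]], x$thresholds["a"], ch[["b"]], x$thresholds["b"]))
  q <- x$quadrants
  for (i in seq_len(nrow(q))) {
    cat(sprintf("  %s : %6.2f%% (%d)\n", q$quadrant[i], q$percent[i],
                q$n[i]))
  }
  invisible(x)
}
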