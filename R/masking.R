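#' Rolling-ball style background subtraction
#'
#' Estimates the background of each z-slice of each channel by grayscale
#' morphological opening with a disc structuring element whose radius
#' exceeds a nucleus, then subtracts it. A flat background maps to ~0 and
#' the output is clamped non-negative. This is the classical
#' rolling-ball operator familiar from ImageJ, implemented as
#' erosion-then-dilation per slice.
#'
#' @param grid A [voxel_grid()].
#' @param ball_radius_um Structuring-element radius in micrometres; must
#'   be positive and should exceed the nuclear diameter (~6 um) so
#'   nuclei are not flattened.
#' @param channels Channels to process (default all).
#' @return A new [voxel_grid()] with background-subtracted intensities.
#' @export
subtract_background <- function(grid, ball_radius_um,
                                channels = NULL) {
  if (!is_scalar_number(ball_radius_um) || ball_radius_um <= 0) {
    cp_abort("`ball_radius_um` must be positive.", "cp_error_spec")
  }
  channels <- channels %||% channel_names(grid)
  r_px <- max(1L, round(ball_radius_um / grid$spacing_um[1]))
  brush <- EBImage::makeBrush(2L * r_px + 1L, shape = "disc")
  out <- grid$channels
  for (ch in channels) {
    arr <- out[[ch]]
    for (k in seq_len(dim(arr)[3])) {
      mx <- max(arr[, , k])
      if (mx <= 0) next
      # EBImage grayscale morphology clamps to [0, 1]; rescale around it.
      bg <- EBImage::opening(arr[, , k] / mx, brush) * mx
      arr[, , k] <- pmax(arr[, , k] - bg, 0)
    }
    out[[ch]] <- arr
  }
  voxel_grid(out, grid$spacing_um, nuclear_channel = grid$nuclear_channel)
}

# Separable Gaussian smoothing of a 3D array with per-axis sigma in
# voxels. Dense per-axis smoothing matrices (rows renormalised at the
# borders) keep results exact and fast via BLAS.
gauss_smooth3 <- function(arr, sigma_vox) {
  smooth_mat <- function(n, s) {
    if (s <= 0) return(NULL)
    h <- max(1L, ceiling(3 * s))
    idx <- seq_len(n)
    S <- matrix(0, n, n)
    for (i in idx) {
      j <- max(1L, i - h):min(n, i + h)
      w <- exp(-((j - i)^2) / (2 * s^2))
      S[i, j] <- w / sum(w)
    }
    S
  }
  d <- dim(arr)
  Sy <- smooth_mat(d[1], sigma_vox[2])
  Sx <- smooth_mat(d[2], sigma_vox[1])
  Sz <- smooth_mat(d[3], sigma_vox[3])
  if (!is.null(Sy)) {
    arr <- array(Sy %*% matrix(arr, d[1], d[2] * d[3]), dim = d)
  }
  if (!is.null(Sx)) {
    tmp <- aperm(arr, c(2, 1, 3))
    tmp <- array(Sx %*% matrix(tmp, d[2], d[1] * d[3]),
                 dim = c(d[2], d[1], d[3]))
    arr <- aperm(tmp, c(2, 1, 3))
  }
  if (!is.null(Sz) && d[3] > 1L) {
    arr <- array(matrix(arr, d[1] * d[2], d[3]) %*% t(Sz), dim = d)
  }
  arr
}

#' Classify nuclei into a 3D probability mask
#'
#' Deterministic stand-in for a trained pixel classifier with the same
#' output contract: the nuclear channel is smoothed with an anisotropic
#' Gaussian (sigma scaled per axis by voxel spacing, so physical
#' smoothing is isotropic), an intensity threshold is chosen
#' automatically by Otsu's
#' method on the smoothed channel, and smoothed intensities are mapped
#' through a logistic centred on that threshold to per-voxel nuclear
#' probabilities. Because the threshold and the logistic width both
#' scale with the data, rescaling the channel by any k > 0 leaves the
#' binarized mask unchanged.
#'
#' @param grid A [voxel_grid()]; background should already be
#'   subtracted, or pass `subtract_bg_um` to do it here.
#' @param nuclear_channel Channel to classify (defaults to the grid's
#'   designated nuclear channel).
#' @param sigma_um Smoothing sigma in micrometres (default 1.2, about
#'   0.4 x the nuclear radius — wide enough to suppress shot noise,
#'   narrow enough not to blur the nuclear boundary at ~2 um voxels).
#' @param threshold Probability cutoff stored on the mask (default 0.5).
#' @param subtract_bg_um Optional rolling-ball radius to apply first.
#' @return A [nuclear_mask()] with `source = "builtin"`.
#' @export
classify_nuclei <- function(grid, nuclear_channel = NULL,
                            sigma_um = 1.2, threshold = 0.5,
                            subtract_bg_um = NULL) {
  ch <- nuclear_channel_of(grid, nuclear_channel)
  if (!is.null(subtract_bg_um)) {
    grid <- subtract_background(grid, subtract_bg_um, channels = ch)
  }
  arr <- grid_channel(grid, ch)
  if (max(arr) <= 0) {
    cp_abort("Nuclear channel is all zero; no threshold definable.",
             "cp_error_degenerate")
  }
  if (max(arr) == min(arr)) {
    cp_abort("Nuclear channel is uniform; threshold is degenerate.",
             "cp_error_degenerate")
  }
  sm <- gauss_smooth3(arr, sigma_um / grid$spacing_um)
  mx <- max(sm)
  thr <- as.numeric(EBImage::otsu(matrix(sm / mx, nrow = dim(sm)[1]),
                                  range = c(0, 1))) * mx
  if (!is.finite(thr) || thr <= 0) {
    cp_abort("Degenerate Otsu threshold.", "cp_error_degenerate")
  }
  p <- stats::plogis((sm - thr) / (0.25 * thr))
  nuclear_mask(p, grid$spacing_um, threshold = threshold,
               source = "builtin")
}

# Separable box maximum filter (window half-width per axis, in voxels)
# via shifted pmax passes; used for local-maximum detection.
box_max3 <- function(arr, half) {
  d <- dim(arr)
  shift_axis <- function(a, s, axis) {
    out <- array(-Inf, dim = d)
    if (axis == 1L) {
      src <- seq_len(d[1]); dst <- src + s
      ok <- dst >= 1L & dst <= d[1]
      out[dst[ok], , ] <- a[src[ok], , ]
    } else if (axis == 2L) {
      src <- seq_len(d[2]); dst <- src + s
      ok <- dst >= 1L & dst <= d[2]
      out[, dst[ok], ] <- a[, src[ok], ]
    } else {
      src <- seq_len(d[3]); dst <- src + s
      ok <- dst >= 1L & dst <= d[3]
      out[, , dst[ok]] <- a[, , src[ok]]
    }
    out
  }
  for (axis in 1:3) {
    h <- half[axis]
    if (h < 1L || d[axis] == 1L) next
    acc <- arr
    for (s in seq_len(h)) {
      acc <- pmax(acc, shift_axis(arr, s, axis), shift_axis(arr, -s, axis))
    }
    arr <- acc
  }
  arr
}

#' Detect per-cell centroids from the nuclear channel
#'
#' Finds 3D local maxima of the smoothed nuclear channel inside the
#' binarized mask, merges maxima closer than a minimum separation
#' (0.8 x the expected inter-nuclear spacing, keeping the brighter
#' peak), and measures per-channel mean intensity in a fixed-radius
#' spherical neighbourhood around each centroid. Detection feeds dot
#' plots and morphometrics only — voxel-level quantification never
#' depends on it, so segmentation artefacts cannot contaminate radial
#' profiles or gating.
#'
#' @param mask A [nuclear_mask()].
#' @param grid The companion [voxel_grid()].
#' @param expected_spacing_um Expected inter-nuclear distance (um);
#'   default 12, matching epithelial packing at the default density of
#'   5 cells per 1000 square um.
#' @param measure_radius_um Radius of the intensity-measurement
#'   neighbourhood (um).
#' @param sigma_um Smoothing sigma used for peak detection.
#' @param nuclear_channel Optional override of the nuclear channel.
#' @return A tibble of cell records: `cell`, `x_um`, `y_um`, `z_um` and
#'   one mean-intensity column per channel. Empty tibble when the mask
#'   selects nothing.
#' @export
detect_cell_centroids <- function(mask, grid, expected_spacing_um = 12,
                                  measure_radius_um = 3, sigma_um = 1.5,
                                  nuclear_channel = NULL) {
  check_mask_grid(mask, grid)
  ch <- nuclear_channel_of(grid, nuclear_channel)
  bin <- mask_binary(mask)
  empty <- tibble::tibble(cell = integer(), x_um = numeric(),
                          y_um = numeric(), z_um = numeric())
  if (!any(bin)) return(empty)
  sm <- gauss_smooth3(grid_channel(grid, ch), sigma_um / grid$spacing_um)
  min_sep <- 0.8 * expected_spacing_um
  half <- pmax(1L, floor(min_sep / 2 / grid$spacing_um[c(2, 1, 3)]))
  mx <- box_max3(sm, half)
  is_peak <- bin & (sm >= mx) & (sm > 0)
  idx <- which(is_peak)
  if (!length(idx)) return(empty)
  d <- dim(sm)
  iy <- ((idx - 1L) %% d[1]) + 1L
  ix <- (((idx - 1L) %/% d[1]) %% d[2]) + 1L
  iz <- ((idx - 1L) %/% (d[1] * d[2])) + 1L
  px <- (ix - 0.5) * grid$spacing_um[1]
  py <- (iy - 0.5) * grid$spacing_um[2]
  pz <- (iz - 0.5) * grid$spacing_um[3]
  ord <- order(sm[idx], decreasing = TRUE)
  keep_x <- numeric(0); keep_y <- numeric(0); keep_z <- numeric(0)
  for (k in ord) {
    if (length(keep_x)) {
      d2 <- (keep_x - px[k])^2 + (keep_y - py[k])^2 + (keep_z - pz[k])^2
      if (min(d2) < min_sep^2) next
    }
    keep_x <- c(keep_x, px[k]); keep_y <- c(keep_y, py[k])
    keep_z <- c(keep_z, pz[k])
  }
  n <- length(keep_x)
  coords <- grid_coords(grid)
  means <- matrix(NA_real_, n, length(channel_names(grid)),
                  dimnames = list(NULL, channel_names(grid)))
  r <- measure_radius_um
  for (i in seq_len(n)) {
    sel_x <- which(abs(coords$x - keep_x[i]) <= r)
    sel_y <- which(abs(coords$y - keep_y[i]) <= r)
    sel_z <- which(abs(coords$z - keep_z[i]) <= r)
    dx2 <- (coords$x[sel_x] - keep_x[i])^2
    dy2 <- (coords$y[sel_y] - keep_y[i])^2
    dz2 <- (coords$z[sel_z] - keep_z[i])^2
    d2 <- outer(outer(dy2, dx2, "+"), dz2, "+")
    inside <- d2 <= r^2
    for (ch_i in channel_names(grid)) {
      blk <- grid$channels[[ch_i]][sel_y, sel_x, sel_z, drop = FALSE]
      means[i, ch_i] <- mean(blk[inside])
    }
  }
  dplyr::bind_cols(
    tibble::tibble(cell = seq_len(n), x_um = keep_x, y_um = keep_y,
                   z_um = keep_z),
    tibble::as_tibble(means))
}
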