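#' Generate a synthetic colony z-stack with ground truth
#'
#' Renders a circular micropatterned colony as a multi-channel confocal
#' z-stack: nuclei are anisotropic Gaussian blobs placed by Poisson-disc
#' sampling inside the colony disc, each cell carries one true level per
#' marker drawn from its domain model evaluated at the cell's radius,
#' markers are painted as constant nuclear-localised intensity over each
#' cell's blob (nearest cell wins where blobs overlap), and acquisition
#' noise is applied last. The ground truth records everything before
#' noise.
#'
#' @param spec A [colony_spec()].
#' @return A list with elements `grid` (a [voxel_grid()] holding
#'   `hoechst` plus one channel per marker) and `truth` (a
#'   `ground_truth` list: `cells` tibble with centroids, radii and true
#'   per-channel levels; `center_um`; `colony_radius_um`;
#'   `boundary_radii_um`; `nuclear_voxels` logical array of the true
#'   nuclear-core region; `height_um` tibble of expected height vs
#'   radius).
#' @export
generate_colony <- function(spec) {
  if (!inherits(spec, "colony_spec")) {
    cp_abort("`spec` must be a colony_spec().", "cp_error_spec")
  }
  withr::with_seed(spec$seed, generate_colony_impl(spec))
}

generate_colony_impl <- function(spec) {
  dx <- spec$voxel_spacing_um[1]; dy <- spec$voxel_spacing_um[2]
  dz <- spec$voxel_spacing_um[3]
  R <- spec$diameter_um / 2
  field <- spec$diameter_um + 2 * spec$pad_um
  nx <- ceiling(field / dx); ny <- ceiling(field / dy)
  nz <- spec$n_z_layers
  center <- c(x = nx * dx / 2, y = ny * dy / 2)

  cells <- place_cells(spec, R, center)
  n_cells <- nrow(cells)

  # True marker level per cell; salt-type misexpression swaps levels.
  levels <- list()
  for (mm in spec$marker_models) {
    lev <- marker_level(mm, cells$radius_um)
    if (mm$positive_fraction_noise > 0) {
      flip <- runif(n_cells) < mm$positive_fraction_noise
      lev[flip] <- mm$level_inside + mm$level_outside - lev[flip]
    }
    levels[[mm$channel_name]] <- lev
  }

  painted <- paint_cells(cells, levels, nx, ny, nz, dx, dy, dz)

  truth <- structure(
    list(
      cells = {
        base <- dplyr::bind_cols(tibble::tibble(cell = seq_len(n_cells)),
                                 cells)
        if (length(levels)) dplyr::bind_cols(base,
                                             tibble::as_tibble(levels))
        else base
      },
      center_um = center,
      colony_radius_um = R,
      boundary_radii_um = stats::setNames(
        lapply(spec$marker_models, `[[`, "boundary_radii_um"),
        vapply(spec$marker_models, `[[`, character(1), "channel_name")),
      nuclear_voxels = painted$core,
      height_um = layer_height_table(spec, R),
      spec = spec
    ),
    class = "ground_truth"
  )

  grid_channels <- c(list(hoechst = painted$nuclear), painted$markers)
  grid_channels <- lapply(grid_channels, apply_noise, spec = spec,
                          nx = nx, dx = dx)
  grid <- voxel_grid(grid_channels, spec$voxel_spacing_um,
                     nuclear_channel = "hoechst")
  list(grid = grid, truth = truth)
}

# Poisson-disc (dart-throwing) placement of cell centroids in the colony
# disc; minimum xy spacing derived from the requested areal density so
# packing resembles an epithelium. Multilayer regions duplicate cells in z.
place_cells <- function(spec, R, center) {
  rho <- spec$cell_density / 1000          # cells per um^2
  n_target <- max(1L, round(rho * pi * R^2))
  # Density-derived spacing with a physical floor: nuclei (~6 um short
  # axis) cannot overlap, so requested densities that would force
  # centers closer than 5.5 um become geometrically infeasible.
  r_min <- max(0.7 / sqrt(rho), 5.5)
  margin <- min(1, R * 0.02)
  xs <- numeric(n_target); ys <- numeric(n_target)
  placed <- 0L
  attempts <- 0L; max_attempts <- 200L * n_target
  while (placed < n_target && attempts < max_attempts) {
    attempts <- attempts + 1L
    rr <- sqrt(runif(1)) * (R - margin)
    th <- runif(1, 0, 2 * pi)
    px <- center["x"] + rr * cos(th); py <- center["y"] + rr * sin(th)
    if (placed > 0L) {
      d2 <- (xs[seq_len(placed)] - px)^2 + (ys[seq_len(placed)] - py)^2
      if (min(d2) < r_min^2) next
    }
    placed <- placed + 1L
    xs[placed] <- px; ys[placed] <- py
  }
  if (placed < n_target) {
    cp_abort(sprintf(
      "Infeasible spec: placed %d of %d cells at density %g/1000um^2.",
      placed, n_target, spec$cell_density), "cp_error_infeasible")
  }
  r_um <- sqrt((xs - center["x"])^2 + (ys - center["y"])^2)

  dzf <- spec$voxel_spacing_um[3]
  z_mid <- spec$n_z_layers * dzf / 2
  n_layers <- rep(spec$n_cell_layers, n_target)
  if (!is.null(spec$ridge)) {
    in_ridge <- r_um >= spec$ridge$r_min_um & r_um <= spec$ridge$r_max_um
    n_layers[in_ridge] <- pmax(n_layers[in_ridge], spec$ridge$n_layers)
  }
  # Base layer cell plus stacked copies (small xy jitter) where n_layers > 1.
  out_x <- xs; out_y <- ys
  out_z <- z_mid + (1 - (n_layers + 1) / 2) * LAYER_PITCH +
    runif(n_target, -0.5, 0.5)
  extra_x <- c(); extra_y <- c(); extra_z <- c()
  multi <- which(n_layers > 1L)
  for (i in multi) {
    for (l in 2:n_layers[i]) {
      extra_x <- c(extra_x, xs[i] + runif(1, -1, 1))
      extra_y <- c(extra_y, ys[i] + runif(1, -1, 1))
      extra_z <- c(extra_z, z_mid + (l - (n_layers[i] + 1) / 2) *
                     LAYER_PITCH + runif(1, -0.5, 0.5))
    }
  }
  x_all <- c(out_x, extra_x); y_all <- c(out_y, extra_y)
  z_all <- c(out_z, extra_z)
  tibble::tibble(
    x_um = x_all, y_um = y_all, z_um = z_all,
    radius_um = sqrt((x_all - center["x"])^2 + (y_all - center["y"])^2)
  )
}

# Render nuclei (additive Gaussian blobs) and markers (constant per-cell
# level over the blob support; nearest cell owns contested voxels).
paint_cells <- function(cells, levels, nx, ny, nz, dx, dy, dz) {
  xs_c <- vox_centers(nx, dx); ys_c <- vox_centers(ny, dy)
  zs_c <- vox_centers(nz, dz)
  nuclear <- array(0, dim = c(ny, nx, nz))
  best_d2 <- array(Inf, dim = c(ny, nx, nz))
  markers <- lapply(levels, function(...) array(0, dim = c(ny, nx, nz)))
  rx <- BLOB_TRUNC * BLOB_SIGMA_XY; rz <- BLOB_TRUNC * BLOB_SIGMA_Z
  lev_mat <- if (length(levels)) do.call(cbind, levels) else NULL

  for (i in seq_len(nrow(cells))) {
    xi <- cells$x_um[i]; yi <- cells$y_um[i]; zi <- cells$z_um[i]
    ix <- which(xs_c >= xi - rx & xs_c <= xi + rx)
    iy <- which(ys_c >= yi - rx & ys_c <= yi + rx)
    iz <- which(zs_c >= zi - rz & zs_c <= zi + rz)
    if (!length(ix) || !length(iy) || !length(iz)) next
    ax <- ((xs_c[ix] - xi) / BLOB_SIGMA_XY)^2
    ay <- ((ys_c[iy] - yi) / BLOB_SIGMA_XY)^2
    az <- ((zs_c[iz] - zi) / BLOB_SIGMA_Z)^2
    d2 <- outer(outer(ay, ax, "+"), az, "+")   # dims (y, x, z)
    sel <- d2 <= BLOB_TRUNC^2
    if (!any(sel)) next
    blk <- nuclear[iy, ix, iz, drop = FALSE]
    blk[sel] <- blk[sel] + NUC_AMP * exp(-d2[sel] / 2)
    nuclear[iy, ix, iz] <- blk

    bd <- best_d2[iy, ix, iz, drop = FALSE]
    upd <- sel & d2 < bd
    if (any(upd)) {
      bd[upd] <- d2[upd]
      best_d2[iy, ix, iz] <- bd
      for (m in seq_along(markers)) {
        mb <- markers[[m]][iy, ix, iz, drop = FALSE]
        mb[upd] <- lev_mat[i, m]
        markers[[m]][iy, ix, iz] <- mb
      }
    }
  }
  list(nuclear = nuclear, markers = markers,
       core = nuclear >= CORE_FRACTION * NUC_AMP)
}

# Acquisition noise: planar background, shot-like variance ~ mean, read
# noise; clipped to the 16-bit range and quantised to integers. With the
# noise model off the quantised image equals the painted image exactly
# (levels are integers on the 16-bit scale).
apply_noise <- function(img, spec, nx, dx) {
  noise <- spec$noise
  if (noise_is_off(noise)) {
    return(round(pmin(pmax(img, 0), INTENSITY_MAX)))
  }
  d <- dim(img)
  if (noise$background_level > 0 || noise$background_gradient > 0) {
    bg_row <- noise$background_level +
      noise$background_gradient * vox_centers(nx, dx)
    img <- img + array(rep(bg_row, each = d[1]), dim = d)
  }
  n <- length(img)
  if (noise$shot_scale > 0) {
    img <- img + rnorm(n, 0, sqrt(noise$shot_scale * pmax(img, 0)))
  }
  if (noise$read_sigma > 0) {
    img <- img + rnorm(n, 0, noise$read_sigma)
  }
  round(pmin(pmax(img, 0), INTENSITY_MAX))
}

layer_height_table <- function(spec, R) {
  r <- seq(0, R, by = 5)
  n_layers <- rep(spec$n_cell_layers, length(r))
  if (!is.null(spec$ridge)) {
    in_ridge <- r >= spec$ridge$r_min_um & r <= spec$ridge$r_max_um
    n_layers[in_ridge] <- pmax(n_layers[in_ridge], spec$ridge$n_layers)
  }
  tibble::tibble(
    radius_um = r,
    expected_height_um = 2 * sqrt(CORE_D2) * BLOB_SIGMA_Z +
      (n_layers - 1) * LAYER_PITCH
  )
}

#' Generate a synthetic differentiation time course
#'
#' Produces one colony per timepoint from a shared 0 hr spec and a set of
#' per-channel transitions. All timepoints share the same placement seed,
#' so cells sit at identical positions and only marker levels and domain
#' boundaries change — mimicking fixed-endpoint imaging of sister
#' colonies along a differentiation time course.
#'
#' @param spec_0hr A [colony_spec()] describing the 0 hr colony.
#' @param transitions Named list, one entry per marker channel, each a
#'   list with numeric vectors `level_multiplier` and
#'   `boundary_shift_um`, one value per timepoint (the 0 hr entry is
#'   conventionally 1 and 0). Channels without an entry are left
#'   unchanged.
#' @param timepoints_hr Strictly increasing numeric vector of timepoints
#'   in hours (the first is the reference).
#' @return A list with one element per timepoint:
#'   `list(time_hr, grid, truth)`; each `truth` additionally records the
#'   applied `level_multiplier` and `boundary_shift_um`.
#' @export
generate_timecourse <- function(spec_0hr, transitions, timepoints_hr) {
  if (is.unsorted(timepoints_hr, strictly = TRUE)) {
    cp_abort("`timepoints_hr` must be strictly increasing.",
             "cp_error_spec")
  }
  nt <- length(timepoints_hr)
  for (tr in transitions) {
    if (length(tr$level_multiplier %||% rep(1, nt)) != nt ||
        length(tr$boundary_shift_um %||% rep(0, nt)) != nt) {
      cp_abort("Each transition needs one value per timepoint.",
               "cp_error_spec")
    }
  }
  R <- spec_0hr$diameter_um / 2
  purrr::map(seq_len(nt), function(k) {
    spec_k <- spec_0hr
    spec_k$marker_models <- lapply(spec_0hr$marker_models, function(mm) {
      tr <- transitions[[mm$channel_name]]
      if (is.null(tr)) return(mm)
      mult <- (tr$level_multiplier %||% rep(1, nt))[k]
      shift <- (tr$boundary_shift_um %||% rep(0, nt))[k]
      mm$level_inside <- mm$level_inside * mult
      mm$level_outside <- mm$level_outside * mult
      if (length(mm$boundary_radii_um)) {
        mm$boundary_radii_um <- pmin(pmax(mm$boundary_radii_um + shift,
                                          1e-6), R)
      }
      mm
    })
    res <- generate_colony(spec_k)
    res$truth$applied_transitions <- purrr::map(
      transitions, function(tr) list(
        level_multiplier = (tr$level_multiplier %||% rep(1, nt))[k],
        boundary_shift_um = (tr$boundary_shift_um %||% rep(0, nt))[k]))
    list(time_hr = timepoints_hr[k], grid = res$grid, truth = res$truth)
  })
}

#' Generate a 2D section fixture with polygonal regions
#'
#' Emulates a confocal image of a transverse cryosection: non-overlapping
#' polygonal regions (e.g. anterior vs posterior epiblast), each with
#' known per-channel mean levels plus a nuclear (Hoechst) channel, with
#' optional Gaussian noise. Used to validate ROI- and point-based
#' quantification against known ratios.
#'
#' @param regions List of regions, each a list with `region_id`,
#'   `polygon` (two-column matrix of x,y vertices in um) and `means`
#'   (named numeric vector of channel means, including `hoechst`).
#' @param seed Integer seed.
#' @param spacing_um Pixel spacing in um (isotropic).
#' @param noise_sigma Gaussian noise SD (a.u.); 0 for exact levels.
#' @param pad_um Empty margin around the union of regions.
#' @return `list(grid, truth)`: a one-plane [voxel_grid()] and a
#'   `truth` list with the per-region true means tibble and polygons.
#'   Overlapping regions raise an invalid-fixture error.
#' @export
generate_section_fixture <- function(regions, seed = 1, spacing_um = 1,
                                     noise_sigma = 0, pad_um = 5) {
  if (!length(regions)) {
    cp_abort("Need at least one region.", "cp_error_spec")
  }
  ch_names <- unique(unlist(lapply(regions, function(r) names(r$means))))
  if (!"hoechst" %in% ch_names) {
    cp_abort("Regions must include a 'hoechst' mean.", "cp_error_spec")
  }
  all_xy <- do.call(rbind, lapply(regions, `[[`, "polygon"))
  if (any(all_xy < 0)) {
    cp_abort("Region coordinates must be non-negative um.",
             "cp_error_spec")
  }
  # Canvas shares the grid's coordinate frame: origin at (0, 0), so ROI
  # polygons quantify in the same um coordinates they were defined in.
  nx <- ceiling((max(all_xy[, 1]) + pad_um) / spacing_um)
  ny <- ceiling((max(all_xy[, 2]) + pad_um) / spacing_um)
  xs <- vox_centers(nx, spacing_um)
  ys <- vox_centers(ny, spacing_um)
  px <- rep(xs, each = ny); py <- rep(ys, times = nx)

  withr::with_seed(seed, {
    imgs <- lapply(stats::setNames(ch_names, ch_names),
                   function(ch) matrix(0, ny, nx))
    claimed <- matrix(0L, ny, nx)
    for (rg in regions) {
      inside <- matrix(point_in_polygon(px, py, rg$polygon), ny, nx)
      if (any(claimed[inside] > 0L)) {
        cp_abort("Regions overlap: invalid section fixture.",
                 "cp_error_overlap")
      }
      claimed[inside] <- 1L
      for (ch in names(rg$means)) {
        imgs[[ch]][inside] <- rg$means[[ch]]
      }
    }
    if (noise_sigma > 0) {
      imgs <- lapply(imgs, function(m)
        pmax(m + rnorm(length(m), 0, noise_sigma), 0))
    }
    grid <- voxel_grid(imgs, c(spacing_um, spacing_um, 1),
                       nuclear_channel = "hoechst")
    truth <- list(
      regions = purrr::map_dfr(regions, function(rg)
        tibble::tibble(region_id = rg$region_id,
                       channel = names(rg$means),
                       true_mean = unname(unlist(rg$means)))),
      polygons = stats::setNames(lapply(regions, `[[`, "polygon"),
                                 vapply(regions, `[[`, character(1),
                                        "region_id"))
    )
    list(grid = grid, truth = truth)
  })
}
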