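# Rendering constants for the synthetic colonies. Nuclei are drawn as
# anisotropic Gaussian blobs truncated at 3 sigma. The ground-truth
# nuclear region is the 18% isophote of the noise-free nuclear channel:
# the steep flank of the blob profile, fixed once as the definition of
# "inside a nucleus" at this voxel resolution (~ Mahalanobis 1.85 sigma
# for an isolated blob).
BLOB_SIGMA_XY <- 3    # um
BLOB_SIGMA_Z  <- 2    # um
BLOB_TRUNC    <- 3    # sigma
NUC_AMP       <- 10000  # a.u., single-blob peak on the 16-bit scale
CORE_FRACTION <- 0.18   # isophote (fraction of blob peak) defining truth
CORE_D2       <- -2 * log(CORE_FRACTION)  # isolated-blob equivalent
LAYER_PITCH   <- 5    # um between stacked cell layers
INTENSITY_MAX <- 65535

#' Marker domain model
#'
#' Describes how one immunostained marker varies with radial position in
#' a synthetic colony: a radially organised expression domain with smooth
#' (logistic) boundaries. `profile_kind` selects the geometry:
#' `"uniform"` (everywhere at `level_inside`), `"center_high"` (high
#' inside one boundary radius), `"edge_high"` (high outside it) or
#' `"annulus"` (high between two radii).
#'
#' @param channel_name Channel label, e.g. `"sox2"`.
#' @param profile_kind One of `"uniform"`, `"center_high"`,
#'   `"edge_high"`, `"annulus"`.
#' @param boundary_radii_um Domain boundary radii in micrometres: none
#'   for `uniform`, one for `center_high`/`edge_high`, two (strictly
#'   increasing) for `annulus`.
#' @param boundary_sharpness_um Logistic transition width in
#'   micrometres; `0` gives a hard step.
#' @param level_inside,level_outside Expression level (a.u., 16-bit
#'   scale) inside and outside the domain; both must be non-negative.
#' @param positive_fraction_noise Probability that a cell misexpresses,
#'   i.e. swaps its inside/outside level (salt-type noise).
#'
#' @return A `marker_model` list.
#' @export
marker_model <- function(channel_name,
                         profile_kind = c("uniform", "center_high",
                                          "edge_high", "annulus"),
                         boundary_radii_um = numeric(),
                         boundary_sharpness_um = 10,
                         level_inside = 8000, level_outside = 200,
                         positive_fraction_noise = 0) {
  profile_kind <- match.arg(profile_kind)
  n_expected <- switch(profile_kind, uniform = 0L, center_high = 1L,
                       edge_high = 1L, annulus = 2L)
  if (length(boundary_radii_um) != n_expected) {
    cp_abort(sprintf("Profile '%s' needs %d boundary radius(ii).",
                     profile_kind, n_expected), "cp_error_spec")
  }
  if (n_expected > 0 &&
      (any(boundary_radii_um <= 0) || is.unsorted(boundary_radii_um,
                                                  strictly = TRUE))) {
    cp_abort("Boundary radii must be positive and strictly increasing.",
             "cp_error_spec")
  }
  if (level_inside < 0 || level_outside < 0) {
    cp_abort("Intensity levels must be >= 0.", "cp_error_spec")
  }
  if (boundary_sharpness_um < 0) {
    cp_abort("`boundary_sharpness_um` must be >= 0.", "cp_error_spec")
  }
  if (positive_fraction_noise < 0 || positive_fraction_noise > 1) {
    cp_abort("`positive_fraction_noise` must be a probability.",
             "cp_error_spec")
  }
  structure(
    list(channel_name = channel_name, profile_kind = profile_kind,
         boundary_radii_um = as.numeric(boundary_radii_um),
         boundary_sharpness_um = boundary_sharpness_um,
         level_inside = level_inside, level_outside = level_outside,
         positive_fraction_noise = positive_fraction_noise),
    class = "marker_model"
  )
}

#' Acquisition noise model
#'
#' Additive background (optionally with a planar tilt along x), shot-like
#' signal-dependent noise with a given variance-to-mean ratio, and
#' Gaussian read noise. All parameters in a.u. on the 16-bit scale;
#' [noise_off()] disables every term, in which case rendered intensities
#' equal the model-assigned levels exactly.
#'
#' @param background_level Constant background offset (a.u.).
#' @param background_gradient Background slope along x (a.u. per um).
#' @param shot_scale Variance-to-mean ratio of signal-dependent noise.
#' @param read_sigma Standard deviation of signal-independent noise.
#' @return A `noise_model` list.
#' @export
noise_model <- function(background_level = 200, background_gradient = 0,
                        shot_scale = 2, read_sigma = 30) {
  vals <- c(background_level, background_gradient, shot_scale, read_sigma)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    cp_abort("Noise parameters must be finite and >= 0.", "cp_error_spec")
  }
  structure(
    list(background_level = background_level,
         background_gradient = background_gradient,
         shot_scale = shot_scale, read_sigma = read_sigma),
    class = "noise_model"
  )
}

#' @rdname noise_model
#' @export
noise_off <- function() noise_model(0, 0, 0, 0)

noise_is_off <- function(noise) {
  noise$background_level == 0 && noise$background_gradient == 0 &&
    noise$shot_scale == 0 && noise$read_sigma == 0
}

#' Synthetic colony specification
#'
#' A complete generative description of one micropatterned colony image:
#' disc diameter, areal cell density, marker domain models, noise model,
#' voxel spacing and the random seed. The same spec with the same seed
#' always produces a bit-identical image and ground truth.
#'
#' Colonies are monolayers by default; colonies of diameter
#' <= 140 um default to two stacked cell layers, mimicking the taller
#' aggregates small micropatterns form. An optional `ridge` raises the
#' local number of cell layers inside a radial annulus (used to emulate
#' volcano-like height profiles).
#'
#' @param diameter_um Colony diameter in micrometres (the study used 80,
#'   140, 225, 500 and 1000 um discs).
#' @param cell_density Cells per 1000 square micrometres (default 5,
#'   a pre-gastrulation epiblast-like monolayer regime).
#' @param n_z_layers Number of z-planes in the stack; default is chosen
#'   to contain the tallest rendered structure.
#' @param marker_models List of [marker_model()]s; may be empty, in
#'   which case the stack holds only the nuclear channel.
#' @param noise A [noise_model()].
#' @param voxel_spacing_um Voxel spacing `(dx, dy, dz)` in micrometres.
#' @param seed Integer seed; mandatory for reproducibility.
#' @param n_cell_layers Baseline number of stacked cell layers
#'   (default 1; 2 when `diameter_um <= 140`).
#' @param ridge Optional `list(r_min_um, r_max_um, n_layers)` describing
#'   a multilayer annulus.
#' @param pad_um Margin of empty field around the colony disc.
#'
#' @return A `colony_spec` list.
#' @export
colony_spec <- function(diameter_um, cell_density = 5, n_z_layers = NULL,
                        marker_models = list(), noise = noise_model(),
                        voxel_spacing_um = c(2, 2, 1), seed = 1,
                        n_cell_layers = NULL, ridge = NULL, pad_um = 10) {
  check_positive_scalar(diameter_um, "diameter_um")
  check_positive_scalar(cell_density, "cell_density")
  if (!is.numeric(voxel_spacing_um) || length(voxel_spacing_um) != 3L ||
      any(voxel_spacing_um <= 0)) {
    cp_abort("`voxel_spacing_um` must be three positive numbers.",
             "cp_error_spec")
  }
  if (!is_scalar_number(seed)) {
    cp_abort("`seed` must be a single integer.", "cp_error_spec")
  }
  if (!inherits(noise, "noise_model")) {
    cp_abort("`noise` must be a noise_model().", "cp_error_spec")
  }
  radius <- diameter_um / 2
  for (mm in marker_models) {
    if (!inherits(mm, "marker_model")) {
      cp_abort("`marker_models` must contain marker_model() objects.",
               "cp_error_spec")
    }
    if (length(mm$boundary_radii_um) &&
        any(mm$boundary_radii_um > radius)) {
      cp_abort("Marker boundary radii must not exceed the colony radius.",
               "cp_error_spec")
    }
  }
  nm <- vapply(marker_models, `[[`, character(1), "channel_name")
  if (anyDuplicated(c("hoechst", nm))) {
    cp_abort("Marker channel names must be unique and not 'hoechst'.",
             "cp_error_spec")
  }
  n_cell_layers <- n_cell_layers %||% if (diameter_um <= 140) 2L else 1L
  if (!is.null(ridge)) {
    if (!all(c("r_min_um", "r_max_um", "n_layers") %in% names(ridge)) ||
        ridge$r_min_um >= ridge$r_max_um || ridge$n_layers < 1) {
      cp_abort("`ridge` needs r_min_um < r_max_um and n_layers >= 1.",
               "cp_error_spec")
    }
  }
  max_layers <- max(n_cell_layers, if (is.null(ridge)) 1 else ridge$n_layers)
  dz <- voxel_spacing_um[3]
  if (is.null(n_z_layers)) {
    depth <- 2 * BLOB_TRUNC * BLOB_SIGMA_Z + (max_layers - 1) * LAYER_PITCH
    n_z_layers <- ceiling(depth / dz) + 2L
  }
  check_positive_scalar(n_z_layers, "n_z_layers")
  structure(
    list(diameter_um = diameter_um, cell_density = cell_density,
         n_z_layers = as.integer(n_z_layers),
         marker_models = marker_models, noise = noise,
         voxel_spacing_um = unname(as.numeric(voxel_spacing_um)),
         seed = as.integer(seed), n_cell_layers = as.integer(n_cell_layers),
         ridge = ridge, pad_um = pad_um),
    class = "colony_spec"
  )
}

# Domain weight w(r) in [0, 1]; the cell-level marker level is
# level_outside + (level_inside - level_outside) * w(r).
domain_weight <- function(model, r) {
  b <- model$boundary_radii_um
  s <- model$boundary_sharpness_um
  step_lo <- function(r, b) if (s > 0) stats::plogis((b - r) / s) else
    as.numeric(r <= b)
  step_hi <- function(r, b) if (s > 0) stats::plogis((r - b) / s) else
    as.numeric(r > b)
  switch(model$profile_kind,
         uniform     = rep(1, length(r)),
         center_high = step_lo(r, b[1]),
         edge_high   = step_hi(r, b[1]),
         annulus     = step_hi(r, b[1]) * step_lo(r, b[2]))
}

marker_level <- function(model, r) {
  model$level_outside +
    (model$level_inside - model$level_outside) * domain_weight(model, r)
}
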