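test_that("a spec without marker models yields a nuclear-only stack with the requested cell count", {
  spec <- colony_spec(80, cell_density = 2, n_cell_layers = 1,
                      noise = noise_off(), seed = 5)
  sim <- generate_colony(spec)
  expect_identical(channel_names(sim$grid), "hoechst")
  n_expected <- round(2 / 1000 * pi * 40^2)
  expect_equal(nrow(sim$truth$cells), n_expected)
})

test_that("uniform marker with equal levels and noise off paints a constant field inside cells", {
  lvl <- 4321
  spec <- colony_spec(
    140, n_cell_layers = 1,
    marker_models = list(marker_model("mk", "uniform",
                                      level_inside = lvl,
                                      level_outside = lvl)),
    noise = noise_off(), seed = 7)
  sim <- generate_colony(spec)
  mk <- grid_channel(sim$grid, "mk")
  expect_setequal(unique(as.vector(mk)), c(0, lvl))
  expect_true(all(mk[sim$truth$nuclear_voxels] == lvl))
})

test_that("zero-sharpness center_high domain assigns step-function levels by cell radius", {
  spec <- colony_spec(
    140, n_cell_layers = 1,
    marker_models = list(marker_model("mk", "center_high", 35,
                                      boundary_sharpness_um = 0,
                                      level_inside = 9000,
                                      level_outside = 500)),
    noise = noise_off(), seed = 9)
  tc <- generate_colony(spec)$truth$cells
  expect_true(all(tc$mk[tc$radius_um <= 35] == 9000))
  expect_true(all(tc$mk[tc$radius_um > 35] == 500))
})

test_that("the same spec and seed produce byte-identical TIFF output", {
  spec <- colony_spec(80, seed = 1)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_stack(generate_colony(spec)$grid, d1)
  write_stack(generate_colony(spec)$grid, d2)
  f1 <- file.path(d1, "hoechst.tif"); f2 <- file.path(d2, "hoechst.tif")
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("generated centroids respect the colony disc and stack depth", {
  sim <- fixture_small_colony()$sim
  truth <- sim$truth
  expect_true(all(truth$cells$radius_um <= truth$colony_radius_um))
  dz <- sim$grid$spacing_um[3]
  nz <- grid_dim(sim$grid)[3]
  expect_true(all(truth$cells$z_um >= 0 & truth$cells$z_um <= nz * dz))
})

test_that("realized cell density matches the request within 5% for large colonies", {
  spec <- colony_spec(500, voxel_spacing_um = c(4, 4, 1), seed = 2)
  truth <- generate_colony(spec)$truth
  realized <- nrow(truth$cells) / (pi * 250^2) * 1000
  expect_lt(abs(realized - spec$cell_density) / spec$cell_density, 0.05)
})

test_that("densities that force nuclear overlap raise an infeasible-spec error", {
  spec <- colony_spec(80, cell_density = 45, seed = 1)
  expect_error(generate_colony(spec), class = "cp_error_infeasible")
})

test_that("minimum spacing between placed nuclei is honoured", {
  truth <- fixture_small_colony()$sim$truth
  xy <- as.matrix(truth$cells[, c("x_um", "y_um")])
  dmin <- min(stats::dist(xy))
  rho <- fixture_small_colony()$spec$cell_density / 1000
  expect_gte(dmin, max(0.7 / sqrt(rho), 5.5) - 1e-9)
})

test_that("timecourse multipliers scale true levels exactly and identity transitions reproduce the colony", {
  spec <- colony_spec(
    140,
    marker_models = list(marker_model("mk", "center_high", 35, 8)),
    noise = noise_off(), seed = 3)
  tc <- generate_timecourse(
    spec,
    transitions = list(mk = list(level_multiplier = c(1, 0.5),
                                 boundary_shift_um = c(0, 0))),
    timepoints_hr = c(0, 24))
  lev0 <- tc[[1]]$truth$cells$mk
  lev24 <- tc[[2]]$truth$cells$mk
  expect_equal(lev24 / lev0, rep(0.5, length(lev0)))
  central0 <- mean(lev0[tc[[1]]$truth$cells$radius_um < 35])
  central24 <- mean(lev24[tc[[2]]$truth$cells$radius_um < 35])
  expect_identical(central24 / central0, 0.5)

  ident <- generate_timecourse(
    spec,
    transitions = list(mk = list(level_multiplier = c(1, 1),
                                 boundary_shift_um = c(0, 0))),
    timepoints_hr = c(0, 24))
  expect_identical(ident[[1]]$grid, ident[[2]]$grid)

  shifted <- generate_timecourse(
    spec,
    transitions = list(mk = list(level_multiplier = c(1, 1),
                                 boundary_shift_um = c(0, -15))),
    timepoints_hr = c(0, 24))
  expect_equal(shifted[[2]]$truth$boundary_radii_um$mk, 20)
  expect_error(
    generate_timecourse(spec, list(), timepoints_hr = c(24, 24)),
    class = "cp_error_spec")
})

test_that("section fixtures hold exact region means and reject overlaps", {
  regions <- list(
    list(region_id = "A",
         polygon = rbind(c(0, 0), c(20, 0), c(20, 20), c(0, 20)),
         means = c(mk = 10, hoechst = 20)),
    list(region_id = "B",
         polygon = rbind(c(30, 0), c(50, 0), c(50, 20), c(30, 20)),
         means = c(mk = 30, hoechst = 20)))
  fx <- generate_section_fixture(regions, seed = 1)
  rA <- roi_mean(fx$grid, regions[[1]]$polygon, roi_id = "A")
  rB <- roi_mean(fx$grid, regions[[2]]$polygon, roi_id = "B")
  expect_equal(rA$hoechst_normalized, 0.5)
  expect_equal(rB$hoechst_normalized, 1.5)

  single <- generate_section_fixture(regions[1], seed = 1)
  expect_equal(unique(single$truth$regions$region_id), "A")

  overlapping <- list(regions[[1]], modifyList(regions[[2]], list(
    polygon = rbind(c(10, 0), c(30, 0), c(30, 20), c(10, 20)))))
  expect_error(generate_section_fixture(overlapping, seed = 1),
               class = "cp_error_overlap")
})

test_that("noisy section sample means stay within three standard errors of truth", {
  regions <- list(list(
    region_id = "A",
    polygon = rbind(c(0, 0), c(40, 0), c(40, 40), c(0, 40)),
    means = c(mk = 500, hoechst = 400)))
  sigma <- 25
  fx <- generate_section_fixture(regions, seed = 4, noise_sigma = sigma)
  r <- roi_mean(fx$grid, regions[[1]]$polygon)
  se <- sigma / sqrt(r$n_pixels)
  expect_lt(abs(r$mean_intensity - 500), 3 * se)
})
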