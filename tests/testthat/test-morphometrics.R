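test_that("a flat monolayer has a near-constant height profile bounded by the stack depth", {
  clean <- fixture_clean_colony()
  mask <- nuclear_mask(clean$sim$truth$nuclear_voxels * 1,
                       clean$sim$grid$spacing_um)
  hp <- height_profile(mask, bin_width_um = 25)
  pop <- hp$height_um[hp$n_voxels > 100]
  expect_gt(length(pop), 2)
  expect_lt((max(pop) - min(pop)) / mean(pop), 0.2)
  nz <- grid_dim(clean$sim$grid)[3]
  expect_true(all(hp$height_um <= nz * clean$sim$grid$spacing_um[3]))
})

test_that("an empty mask yields an all-zero height profile", {
  mask <- nuclear_mask(array(0, c(10, 10, 4)), c(2, 2, 1))
  hp <- height_profile(mask, geometry = manual_geometry(10, 10, 10),
                       bin_width_um = 5)
  expect_true(all(hp$height_um == 0))
  expect_error(height_profile(mask), class = "cp_error_empty")
})

test_that("a multilayer ridge produces a height peak at the ridge radius", {
  spec <- colony_spec(
    225, ridge = list(r_min_um = 60, r_max_um = 85, n_layers = 3),
    noise = noise_off(), seed = 31)
  sim <- generate_colony(spec)
  mask <- classify_nuclei(sim$grid)
  hp <- height_profile(mask, bin_width_um = 15)
  peak <- hp[which.max(hp$height_um), ]
  peak_center <- (peak$bin_start_um + peak$bin_end_um) / 2
  expect_lt(abs(peak_center - 72.5), 15 + 1e-9)
})

test_that("nuclei counts along segments recover exact and Poisson densities", {
  cells <- tibble::tibble(x_um = seq(5, 95, by = 10), y_um = rep(0, 10))
  seg <- tibble::tibble(x0 = 0, y0 = 0, x1 = 100, y1 = 0)
  dm <- nuclei_per_100um(cells, seg, strip_width_um = 4)
  expect_equal(dm$nuclei_per_100um, 10)
  expect_identical(dm$positions_sampled, 1L)

  none <- nuclei_per_100um(tibble::tibble(x_um = numeric(),
                                          y_um = numeric()),
                           seg, strip_width_um = 4)
  expect_equal(none$nuclei_per_100um, 0)

  expect_error(
    nuclei_per_100um(cells, tibble::tibble(x0 = 1, y0 = 1,
                                           x1 = 1, y1 = 1)),
    class = "cp_error_spec")

  # Poisson field at known linear density within the strip
  set.seed(12)
  lambda_area <- 0.02                      # nuclei per um^2
  w <- 10; L <- 400; n_seg <- 10
  n_pts <- rpois(1, lambda_area * (L + 20) * n_seg * 50)
  pts <- tibble::tibble(
    x_um = runif(n_pts, -10, L + 10),
    y_um = runif(n_pts, 0, n_seg * 50) )
  segs <- tibble::tibble(x0 = 0, y0 = seq(25, by = 50,
                                          length.out = n_seg),
                         x1 = L, y1 = seq(25, by = 50,
                                          length.out = n_seg))
  # strips y in [25 - 5, 25 + 5] etc; expected per-100um = lambda*w*100
  dm2 <- nuclei_per_100um(pts, segs, strip_width_um = w)
  expected <- lambda_area * w * 100
  se <- sqrt(lambda_area * w * L * n_seg) / (L * n_seg) * 100
  expect_lt(abs(dm2$nuclei_per_100um - expected), 3 * se)
  gl <- glance(dm2)
  expect_identical(gl$positions_sampled, 10L)
})

test_that("inter-nuclear distances cover the 3-4-5 triangle, lattices and generator guarantees", {
  two <- tibble::tibble(x_um = c(0, 3), y_um = c(0, 4),
                        z_um = c(0, 0))
  expect_equal(internuclear_distances(two)$distance_um, c(5, 5))

  lat <- expand.grid(x_um = seq(0, 40, 10), y_um = seq(0, 40, 10))
  nn <- internuclear_distances(tibble::as_tibble(lat))
  expect_true(all(nn$distance_um == 10))

  pairs <- tibble::tibble(i = 1, j = 2)
  sp <- internuclear_distances(two, mode = "sampled_pairs",
                               pairs = pairs)
  expect_equal(sp$distance_um, 5)

  expect_error(internuclear_distances(two[1, ]), class = "cp_error_spec")

  truth <- fixture_small_colony()$sim$truth
  nn2 <- internuclear_distances(truth$cells)
  rho <- fixture_small_colony()$spec$cell_density / 1000
  expect_gte(min(nn2$distance_um), max(0.7 / sqrt(rho), 5.5) - 1e-9)
})

test_that("quadrupling areal density roughly doubles the linear nuclear count", {
  mk_cells <- function(density, seed) {
    spec <- colony_spec(225, cell_density = density, seed = seed)
    generate_colony(spec)$truth$cells
  }
  segs <- tibble::tibble(
    x0 = 122.5 - 100 * cos(seq(0, pi - 0.3, length.out = 8)),
    y0 = 122.5 - 100 * sin(seq(0, pi - 0.3, length.out = 8)),
    x1 = 122.5 + 100 * cos(seq(0, pi - 0.3, length.out = 8)),
    y1 = 122.5 + 100 * sin(seq(0, pi - 0.3, length.out = 8)))
  d1 <- purrr::map_dbl(1:3, function(s)
    nuclei_per_100um(mk_cells(5, s), segs)$nuclei_per_100um)
  d4 <- purrr::map_dbl(1:3, function(s)
    nuclei_per_100um(mk_cells(20, s + 10), segs)$nuclei_per_100um)
  ratio <- mean(d4) / mean(d1)
  expect_lt(abs(ratio - 2) / 2, 0.1)
})
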