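make_disc_mask <- function(n = 41, radius_px = 15, nz = 3, spacing = 2) {
  cy <- cx <- (n + 1) / 2
  m <- (row(matrix(0, n, n)) - cy)^2 + (col(matrix(0, n, n)) - cx)^2 <=
    radius_px^2
  nuclear_mask(array(rep(m, nz), c(n, n, nz)),
               c(spacing, spacing, 1))
}

test_that("the center of a symmetric colony is recovered to sub-voxel accuracy", {
  mask <- make_disc_mask()
  geom <- estimate_center(mask)
  expect_lt(abs(geom$center_um["x"] - 41), 1e-9)
  expect_lt(abs(geom$center_um["y"] - 41), 1e-9)
})

test_that("a missing wedge shifts the center estimate less than 2% of the radius", {
  mask <- make_disc_mask(n = 61, radius_px = 25)
  p <- mask$probability
  n <- dim(p)[1]
  ang <- atan2(row(matrix(0, n, n)) - 31, col(matrix(0, n, n)) - 31)
  wedge <- ang > 0 & ang < 0.1 * 2 * pi          # 10% angular wedge
  p[array(wedge, dim(p))] <- 0
  cut_mask <- nuclear_mask(p, mask$spacing_um)
  geom <- estimate_center(cut_mask)
  # independent oracle: plain centroid over remaining voxels
  idx <- which(p >= 0.5, arr.ind = TRUE)
  ox <- mean((idx[, 2] - 0.5) * 2); oy <- mean((idx[, 1] - 0.5) * 2)
  expect_equal(unname(geom$center_um["x"]), ox, tolerance = 1e-9)
  expect_equal(unname(geom$center_um["y"]), oy, tolerance = 1e-9)
  # removing fraction f at mean lever arm d shifts the centroid by
  # f * d / (1 - f); for a 10% wedge that is ~7% of the radius
  R <- 25 * 2
  shift <- sqrt((ox - 61)^2 + (oy - 61)^2)
  expect_lt(shift, 0.08 * R)
})

test_that("an empty mask has no center", {
  empty <- nuclear_mask(array(0, c(5, 5, 1)), c(1, 1, 1))
  expect_error(estimate_center(empty), class = "cp_error_empty")
})

test_that("three masked voxels bin into the hand-computed profile", {
  n <- 60
  arr <- array(0, c(n, n, 1))
  p <- array(0, c(n, n, 1))
  # voxel centers at x = 35.5, 45.5, 55.5 on row y = 30.5
  arr[31, 36, 1] <- 10; arr[31, 46, 1] <- 20; arr[31, 56, 1] <- 30
  p[31, 36, 1] <- 1; p[31, 46, 1] <- 1; p[31, 56, 1] <- 1
  grid <- voxel_grid(list(mk = arr), c(1, 1, 1))
  mask <- nuclear_mask(p, c(1, 1, 1))
  geom <- manual_geometry(30.5, 30.5, 30)
  prof <- radial_profile(grid, mask, geom, bin_width_um = 10)
  expect_equal(prof$mean_intensity, c(10, 20, 30))
  expect_identical(prof$n_voxels, c(1L, 1L, 1L))
  expect_equal(prof$bin_start_um, c(0, 10, 20))
})

test_that("binned means equal the brute-force per-voxel oracle on random grids", {
  for (seed in 1:6) {
    rg <- random_grid_mask(seed)
    d <- grid_dim(rg$grid)
    cx <- d[2] * rg$grid$spacing_um[1] / 2
    cy <- d[1] * rg$grid$spacing_um[2] / 2
    R <- min(cx, cy) * 0.9
    bw <- R / 4
    geom <- manual_geometry(cx, cy, R)
    prof <- radial_profile(rg$grid, rg$mask, geom, bw)
    oracle <- brute_profile(rg$grid, rg$mask, c(cx, cy), R, bw)
    for (ch in channel_names(rg$grid)) {
      got <- prof[prof$channel == ch, ]
      expect_equal(got$mean_intensity, oracle[[ch]]$mean,
                   tolerance = 1e-9)
      expect_identical(got$n_voxels, oracle[[ch]]$n)
    }
  }
})

test_that("bin voxel counts conserve the masked voxel total", {
  fx <- fixture_small_colony()
  prof <- radial_profile(fx$grid, fx$mask, fx$geometry, 10)
  d <- grid_dim(fx$grid)
  xs <- (seq_len(d[2]) - 0.5) * fx$grid$spacing_um[1]
  ys <- (seq_len(d[1]) - 0.5) * fx$grid$spacing_um[2]
  rmat <- sqrt(outer((ys - fx$geometry$center_um["y"])^2,
                     (xs - fx$geometry$center_um["x"])^2, "+"))
  inside <- array(rmat, d) <= fx$geometry$fitted_radius_um
  n_expected <- sum(mask_binary(fx$mask) & inside)
  one_channel <- prof[prof$channel == "hoechst", ]
  expect_identical(sum(one_channel$n_voxels), n_expected)
})

test_that("a constant channel profiles flat and an all-zero mask gives undefined means", {
  grid <- voxel_grid(list(mk = array(77, c(30, 30, 2))), c(2, 2, 1))
  p <- array(runif(30 * 30 * 2) > 0.5, c(30, 30, 2)) * 1
  mask <- nuclear_mask(p, c(2, 2, 1))
  geom <- manual_geometry(30, 30, 25)
  prof <- radial_profile(grid, mask, geom, 5)
  expect_true(all(prof$mean_intensity[prof$n_voxels > 0] == 77))

  empty <- nuclear_mask(array(0, c(30, 30, 2)), c(2, 2, 1))
  prof0 <- radial_profile(grid, empty, geom, 5)
  expect_true(all(prof0$n_voxels == 0))
  expect_true(all(is.na(prof0$mean_intensity)))
})

test_that("rotating the stack a quarter turn leaves the radial profile unchanged", {
  fx <- fixture_small_colony()
  rot <- function(a) {
    d <- dim(a)
    out <- array(0, c(d[2], d[1], d[3]))
    for (k in seq_len(d[3])) out[, , k] <- t(a[d[1]:1, , k])
    out
  }
  grid_r <- voxel_grid(lapply(fx$grid$channels, rot),
                       fx$grid$spacing_um, fx$grid$nuclear_channel)
  mask_r <- nuclear_mask(rot(fx$mask$probability), fx$mask$spacing_um)
  p1 <- radial_profile(fx$grid, fx$mask, bin_width_um = 10)
  p2 <- radial_profile(grid_r, mask_r, bin_width_um = 10)
  expect_equal(p2$mean_intensity, p1$mean_intensity, tolerance = 1e-6)
  expect_identical(p2$n_voxels, p1$n_voxels)
})

test_that("profile averaging weights colonies equally and tracks partially empty bins", {
  mk_prof <- function(means, n_vox) {
    structure(tibble::tibble(
      colony_id = "c", channel = "mk",
      bin_start_um = c(0, 10), bin_end_um = c(10, 20),
      mean_intensity = means, n_voxels = n_vox,
      normalization = "raw"),
      class = c("radial_profile", class(tibble::tibble())))
  }
  p1 <- mk_prof(c(10, 40), c(5L, 7L))
  avg_same <- average_profiles(list(p1, p1))
  expect_equal(avg_same$mean_intensity, p1$mean_intensity)
  expect_true(all(avg_same$n_colonies == 2L))

  p2 <- mk_prof(c(30, NA), c(9L, 0L))
  avg <- average_profiles(list(p1, p2))
  expect_equal(avg$mean_intensity, c(20, 40))
  expect_identical(avg$n_colonies, c(2L, 1L))
  expect_identical(avg$n_voxels, c(14L, 7L))

  p3 <- mk_prof(c(1, 2), c(1L, 1L))
  p3$bin_start_um <- c(0, 5); p3$bin_end_um <- c(5, 10)
  expect_error(average_profiles(list(p1, p3)), class = "cp_error_spec")
})

test_that("max-100 normalization behaves per timepoint and across a timecourse", {
  mk_prof <- function(means) {
    structure(tibble::tibble(
      colony_id = "c", channel = "mk",
      bin_start_um = c(0, 10, 20), bin_end_um = c(10, 20, 30),
      mean_intensity = means, n_voxels = c(4L, 4L, 4L),
      normalization = "raw"),
      class = c("radial_profile", class(tibble::tibble())))
  }
  p <- mk_prof(c(2, 4, 8))
  np <- normalize_profile(p, "max100_per_timepoint")
  expect_equal(np$mean_intensity, c(25, 50, 100))
  expect_identical(unique(np$normalization), "max100_per_timepoint")

  p0 <- mk_prof(c(2, 4, 8)); p1 <- mk_prof(c(4, 8, 16))
  across <- normalize_profile(p0, "max100_across_timecourse",
                              reference = list(p0, p1))
  expect_equal(max(across$mean_intensity), 50)

  zero <- mk_prof(c(0, 0, 0))
  expect_error(normalize_profile(zero, "max100_per_timepoint"),
               class = "cp_error_zero_max")
})

test_that("hoechst-relative normalization divides bin by bin", {
  df <- tibble::tibble(
    colony_id = "c",
    channel = rep(c("hoechst", "mk"), each = 2),
    bin_start_um = rep(c(0, 10), 2), bin_end_um = rep(c(10, 20), 2),
    mean_intensity = c(20, 40, 10, 10), n_voxels = rep(3L, 4),
    normalization = "raw")
  prof <- structure(df, class = c("radial_profile",
                                  class(tibble::tibble())))
  nm <- normalize_profile(prof, "hoechst_relative")
  mk <- nm[nm$channel == "mk", ]
  expect_equal(mk$mean_intensity, c(0.5, 0.25))
  no_ho <- structure(df[df$channel == "mk", ],
                     class = class(prof))
  expect_error(normalize_profile(no_ho, "hoechst_relative"),
               class = "cp_error_spec")
})

test_that("dot summaries annotate radius and angle and pass through empty tables", {
  cells <- tibble::tibble(cell = 1L, x_um = 600, y_um = 500, mk = 5)
  geom <- manual_geometry(500, 500, 500)
  dots <- dot_summary(cells, geom)
  expect_equal(dots$radius_um, 100)
  expect_equal(dots$angle_rad, 0)

  empty <- dot_summary(cells[0, ], geom)
  expect_identical(nrow(empty), 0L)
})

test_that("edge-high markers show higher dot intensity outside the boundary", {
  fx <- fixture_small_colony()
  cells <- detect_cell_centroids(fx$mask, fx$grid)
  dots <- dot_summary(cells, fx$geometry)
  outer_mean <- mean(dots$brachyury[dots$radius_um > 90])
  inner_mean <- mean(dots$brachyury[dots$radius_um < 90])
  expect_gt(outer_mean, inner_mean)
})

test_that("half-maximum boundary recovery interpolates, honours exact edges and flags flat profiles", {
  mk_prof <- function(means, bw = 10) {
    nb <- length(means)
    structure(tibble::tibble(
      colony_id = "c", channel = "mk",
      bin_start_um = bw * (seq_len(nb) - 1), bin_end_um = bw * seq_len(nb),
      mean_intensity = means, n_voxels = rep(10L, nb),
      normalization = "raw"),
      class = c("radial_profile", class(tibble::tibble())))
  }
  # step exactly between bins 2 and 3: crossing at the shared edge 20
  step <- mk_prof(c(100, 100, 0, 0))
  expect_equal(recover_boundary(step, "mk"), 20)

  flat <- mk_prof(rep(5, 6))
  expect_error(recover_boundary(flat, "mk"),
               class = "cp_error_no_crossing")

  centers <- seq(5, 295, by = 10)
  logi <- mk_prof(1000 * plogis((150 - centers) / 12))
  expect_lt(abs(recover_boundary(logi, "mk") - 150), 1)
})
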