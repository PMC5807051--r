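test_that("background subtraction removes a flat background and is idempotent on zeros", {
  flat <- voxel_grid(list(a = array(300, c(30, 30, 2))), c(2, 2, 1))
  out <- subtract_background(flat, 10)
  expect_equal(range(grid_channel(out, "a")), c(0, 0))

  zero <- voxel_grid(list(a = array(0, c(20, 20, 1))), c(2, 2, 1))
  expect_equal(range(grid_channel(subtract_background(zero, 10), "a")),
               c(0, 0))
  expect_error(subtract_background(flat, -1), class = "cp_error_spec")
})

test_that("background subtraction matches a brute-force opening oracle on a blob", {
  n <- 41
  bgl <- 500
  img <- matrix(bgl, n, n)
  yy <- row(img); xx <- col(img)
  img <- img + 4000 * exp(-((yy - 21)^2 + (xx - 21)^2) / (2 * 2.5^2))
  grid <- voxel_grid(list(a = array(img, c(n, n, 1))), c(2, 2, 1))
  out <- grid_channel(subtract_background(grid, 12), "a")[, , 1]

  # Oracle: erosion then dilation with the same disc, naive loops.
  brush <- EBImage::makeBrush(13, "disc")
  offs <- which(brush > 0, arr.ind = TRUE) - 7L
  shift <- function(m, dy, dx) {
    res <- matrix(NA_real_, n, n)
    ys <- (1:n) + dy; xs <- (1:n) + dx
    oky <- ys >= 1 & ys <= n; okx <- xs >= 1 & xs <= n
    res[oky, okx] <- m[ys[oky], xs[okx]]
    res
  }
  ero <- matrix(Inf, n, n)
  for (i in seq_len(nrow(offs))) {
    s <- shift(img, offs[i, 1], offs[i, 2]); w <- !is.na(s)
    ero[w] <- pmin(ero[w], s[w])
  }
  dil <- matrix(-Inf, n, n)
  for (i in seq_len(nrow(offs))) {
    s <- shift(ero, offs[i, 1], offs[i, 2]); w <- !is.na(s)
    dil[w] <- pmax(dil[w], s[w])
  }
  oracle <- pmax(img - dil, 0)
  expect_equal(out, oracle, tolerance = 1e-6)
  # blob peak reduced by about the background level, shape preserved
  expect_equal(max(out), max(img) - bgl, tolerance = 0.02 * bgl)
})

test_that("nuclear classification is scale invariant and rejects degenerate channels", {
  clean <- fixture_clean_colony()
  grid <- clean$sim$grid
  m1 <- mask_binary(classify_nuclei(grid))
  scaled <- voxel_grid(lapply(grid$channels, function(a) a * 3.7),
                       grid$spacing_um, grid$nuclear_channel)
  m2 <- mask_binary(classify_nuclei(scaled))
  expect_identical(m1, m2)

  uniform <- voxel_grid(list(hoechst = array(100, c(10, 10, 2))),
                        c(2, 2, 1))
  expect_error(classify_nuclei(uniform), class = "cp_error_degenerate")
  zero <- voxel_grid(list(hoechst = array(0, c(10, 10, 2))),
                     c(2, 2, 1))
  expect_error(classify_nuclei(zero), class = "cp_error_degenerate")
})

test_that("on noise-free colonies the mask covers the true nuclear region and excludes empty field", {
  clean <- fixture_clean_colony()
  p <- clean$mask$probability
  gt <- clean$sim$truth$nuclear_voxels
  expect_gte(mean(p[gt] > 0.5), 0.95)
  # Voxels outside every blob support render as exactly zero here.
  outside <- grid_channel(clean$sim$grid, "hoechst") == 0
  expect_true(all(p[outside] < 0.5))
})

test_that("binarized masks are monotone in the probability threshold", {
  fx <- fixture_small_colony()
  hi <- mask_binary(fx$mask, 0.8)
  lo <- mask_binary(fx$mask, 0.3)
  expect_true(all(lo[hi]))
})

test_that("two well-separated synthetic nuclei are each detected within one voxel", {
  d <- c(40, 40, 9)
  spacing <- c(2, 2, 1)
  nuc <- array(0, dim = d)
  centers <- rbind(c(25, 25, 4.5), c(60, 55, 4.5))   # um
  ys <- (seq_len(d[1]) - 0.5) * spacing[2]
  xs <- (seq_len(d[2]) - 0.5) * spacing[1]
  zs <- (seq_len(d[3]) - 0.5) * spacing[3]
  for (i in 1:2) {
    dy2 <- ((ys - centers[i, 2]) / 3)^2
    dx2 <- ((xs - centers[i, 1]) / 3)^2
    dz2 <- ((zs - centers[i, 3]) / 2)^2
    nuc <- nuc + 10000 * exp(-outer(outer(dy2, dx2, "+"), dz2, "+") / 2)
  }
  grid <- voxel_grid(list(hoechst = nuc), spacing)
  mask <- classify_nuclei(grid)
  cells <- detect_cell_centroids(mask, grid)
  expect_identical(nrow(cells), 2L)
  ord <- order(cells$x_um)
  expect_lt(max(abs(cells$x_um[ord] - centers[, 1])), 2)
  expect_lt(max(abs(cells$y_um[ord] - centers[, 2])), 2)
})

test_that("an empty mask yields an empty cell table", {
  grid <- voxel_grid(list(hoechst = array(1, c(8, 8, 2))), c(2, 2, 1))
  mask <- nuclear_mask(array(0, c(8, 8, 2)), c(2, 2, 1))
  cells <- detect_cell_centroids(mask, grid)
  expect_identical(nrow(cells), 0L)
})

test_that("detected cell count tracks ground truth within 10% at study density", {
  fx <- fixture_small_colony()
  cells <- detect_cell_centroids(fx$mask, fx$grid)
  n_true <- nrow(fx$sim$truth$cells)
  expect_lt(abs(nrow(cells) - n_true) / n_true, 0.1)
})
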