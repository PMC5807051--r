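# Shared fixtures. Expensive synthetic colonies are built once per test
# run and memoised here; everything is generated in code, nothing on disk.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# A small three-domain colony (225 um) with default noise.
fixture_small_colony <- function() {
  cached("small_colony", function() {
    spec <- colony_spec(
      225,
      marker_models = list(
        marker_model("sox2", "center_high", 60, 10),
        marker_model("brachyury", "edge_high", 90, 10,
                     level_outside = 0)),
      seed = 11)
    sim <- generate_colony(spec)
    bg <- subtract_background(sim$grid, 20)
    mask <- classify_nuclei(bg)
    list(spec = spec, sim = sim, grid = bg, mask = mask,
         geometry = estimate_center(mask))
  })
}

# Same layout, noise off, for exactness checks.
fixture_clean_colony <- function() {
  cached("clean_colony", function() {
    spec <- colony_spec(
      225,
      marker_models = list(
        marker_model("sox2", "center_high", 60, 10),
        marker_model("brachyury", "edge_high", 90, 10,
                     level_outside = 0)),
      noise = noise_off(), seed = 11)
    sim <- generate_colony(spec)
    mask <- classify_nuclei(sim$grid)
    list(spec = spec, sim = sim, mask = mask)
  })
}

# Brute-force radial-profile oracle: per-voxel loop, no vectorisation.
brute_profile <- function(grid, mask, center, R, bin_width) {
  edges <- seq(0, R, by = bin_width)
  if (edges[length(edges)] < R) edges <- c(edges, R)
  nb <- length(edges) - 1L
  bin <- mask_binary(mask)
  d <- grid_dim(grid)
  res <- list()
  for (ch in channel_names(grid)) {
    s <- numeric(nb); n <- integer(nb)
    arr <- grid_channel(grid, ch)
    for (k in seq_len(d[3])) for (j in seq_len(d[2])) {
      x <- (j - 0.5) * grid$spacing_um[1]
      for (i in seq_len(d[1])) {
        if (!bin[i, j, k]) next
        y <- (i - 0.5) * grid$spacing_um[2]
        r <- sqrt((x - center[1])^2 + (y - center[2])^2)
        if (r > R) next
        b <- findInterval(r, edges, rightmost.closed = TRUE)
        s[b] <- s[b] + arr[i, j, k]
        n[b] <- n[b] + 1L
      }
    }
    res[[ch]] <- list(mean = ifelse(n > 0, s / n, NA_real_), n = n)
  }
  res
}

# Geometry object without estimating from a mask.
manual_geometry <- function(cx, cy, R) {
  structure(list(center_um = c(x = cx, y = cy), fitted_radius_um = R,
                 nominal_radius_um = R), class = "colony_geometry")
}

# Random small grid + mask pair for property checks.
random_grid_mask <- function(seed, n_channels = 2) {
  withr::with_seed(seed, {
    d <- c(sample(10:24, 1), sample(10:24, 1), sample(2:5, 1))
    chs <- lapply(seq_len(n_channels), function(i)
      array(runif(prod(d), 0, 1000), dim = d))
    names(chs) <- paste0("ch", seq_len(n_channels))
    spacing <- c(runif(1, 1, 3), 0, 0)
    spacing[2] <- spacing[1]            # square xy pixels
    spacing[3] <- runif(1, 0.5, 2)
    grid <- voxel_grid(chs, spacing)
    p <- array(runif(prod(d)), dim = d)
    mask <- nuclear_mask(p, spacing, threshold = 0.5)
    list(grid = grid, mask = mask)
  })
}

match_centroids <- function(detected, truth, tol_um = 5) {
  if (!nrow(detected)) return(list(precision = 0, recall = 0))
  dm <- sqrt(outer(detected$x_um, truth$x_um, "-")^2 +
               outer(detected$y_um, truth$y_um, "-")^2)
  list(precision = mean(apply(dm, 1, min) < tol_um),
       recall = mean(apply(dm, 2, min) < tol_um))
}
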