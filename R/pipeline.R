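#' Run the full analysis pipeline from a single configuration
#'
#' Orchestrates generate-or-ingest, background subtraction, nuclear
#' masking, centroid detection, radial profiling (per colony and
#' averaged), optional coexpression gating, and morphometrics, writing
#' every output file plus a JSON manifest listing parameters and MD5
#' checksums. Rerunning with an identical config and seed reproduces
#' bit-identical outputs.
#'
#' Config structure (YAML/JSON file or list): `mode` (`"synthetic"` or
#' `"stacks"`); `output_dir`; for synthetic mode a mandatory `seed`,
#' `n_colonies` and a `colony` block (passed to [colony_spec()], with
#' `markers` a list of [marker_model()] argument lists); for stacks mode
#' a `stacks` list of directories readable by [read_stack()] and
#' optionally `masks` (external mask TIFFs). Optional stage blocks:
#' `background` (`ball_radius_um`), `masking` (`sigma_um`), `profile`
#' (`bin_width_um`, `normalization`), `coexpress` (`channel_a`,
#' `channel_b`, `quantile`), `height` (`bin_width_um`), `density`
#' (`n_segments`, `strip_width_um`).
#'
#' @param config Path to a YAML/JSON config, or an equivalent list.
#' @param output_dir Optional override of `config$output_dir`.
#' @return The manifest list, invisibly; also written as
#'   `manifest.json` in the output directory.
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  if (is.character(config)) {
    config <- if (grepl("\\.json$", config)) {
      jsonlite::read_json(config, simplifyVector = TRUE,
                          simplifyDataFrame = FALSE)
    } else yaml::read_yaml(config)
  }
  cfg <- validate_config(config)
  out_dir <- output_dir %||% cfg$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  manifest <- list(package = "colonyprofiler",
                   config_used = cfg, files = list(),
                   stages = list())
  add_file <- function(name, path) {
    manifest$files[[name]] <<- list(
      path = path, md5 = unname(tools::md5sum(path)))
  }
  run_stage <- function(name, fn) {
    res <- tryCatch(fn(), error = function(e) {
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(e))
      write_manifest(manifest, out_dir)
      cp_abort(sprintf("Stage '%s' failed: %s", name,
                       conditionMessage(e)), "cp_error_stage")
    })
    manifest$stages[[name]] <<- list(status = "ok")
    res
  }

  colonies <- run_stage("acquire", function() acquire_colonies(cfg,
                                                               out_dir,
                                                               add_file))

  if (!is.null(cfg$background)) {
    colonies <- run_stage("background", function() {
      lapply(colonies, function(co) {
        co$grid <- subtract_background(co$grid,
                                       cfg$background$ball_radius_um)
        co
      })
    })
  }

  colonies <- run_stage("mask", function() {
    lapply(colonies, function(co) {
      if (is.null(co$mask)) {
        co$mask <- classify_nuclei(
          co$grid, sigma_um = cfg$masking$sigma_um %||% 1.5)
      }
      f <- file.path(out_dir, paste0(co$id, "_mask.tif"))
      write_mask(co$mask, f)
      add_file(paste0(co$id, "_mask"), f)
      co$geometry <- estimate_center(co$mask)
      co
    })
  })

  colonies <- run_stage("centroids", function() {
    lapply(colonies, function(co) {
      co$cells <- detect_cell_centroids(co$mask, co$grid)
      dots <- dot_summary(co$cells, co$geometry)
      f <- file.path(out_dir, paste0(co$id, "_cells.csv"))
      write_table(dots, f)
      add_file(paste0(co$id, "_cells"), f)
      co
    })
  })

  profiles <- run_stage("profile", function() {
    bw <- cfg$profile$bin_width_um %||% 10
    # Shared binning across colonies so profiles can be averaged:
    # truncate every colony at the smallest fitted radius.
    shared_R <- min(vapply(colonies,
                           function(co) co$geometry$fitted_radius_um,
                           numeric(1)))
    ps <- lapply(colonies, function(co) {
      geom <- co$geometry
      geom$fitted_radius_um <- shared_R
      p <- radial_profile(co$grid, co$mask, geom,
                          bin_width_um = bw, colony_id = co$id)
      f <- file.path(out_dir, paste0(co$id, "_profile.csv"))
      write_profile(p, f)
      add_file(paste0(co$id, "_profile"), f)
      p
    })
    avg <- average_profiles(ps)
    norm <- cfg$profile$normalization %||% "none"
    if (norm != "none") {
      avg <- normalize_profile(avg, norm)
    }
    f <- file.path(out_dir, "average_profile.csv")
    write_profile(avg, f)
    add_file("average_profile", f)
    ps
  })

  if (!is.null(cfg$coexpress)) {
    run_stage("coexpress", function() {
      cc <- cfg$coexpress
      ref <- colonies[[cc$reference_colony %||% 1L]]
      for (co in colonies) {
        pr <- voxel_pairs(co$grid, co$mask, cc$channel_a, cc$channel_b)
        ta <- gate_from_reference(ref$grid, ref$mask, cc$channel_a,
                                  cc$quantile %||% 0.99)
        tb <- gate_from_reference(ref$grid, ref$mask, cc$channel_b,
                                  cc$quantile %||% 0.99)
        gr <- quadrant_percentages(pr, ta, tb,
                                   reference = paste0("colony ",
                                                      ref$id))
        f <- file.path(out_dir, paste0(co$id, "_gate.json"))
        jsonlite::write_json(
          list(channels = as.list(gr$channels),
               thresholds = as.list(gr$thresholds),
               quadrants = gr$quadrants, n_voxels = gr$n_voxels,
               reference = gr$reference),
          f, auto_unbox = TRUE, digits = NA)
        add_file(paste0(co$id, "_gate"), f)
      }
      invisible(NULL)
    })
  }

  run_stage("morphometrics", function() {
    hw <- cfg$height$bin_width_um %||% 25
    for (co in colonies) {
      hp <- height_profile(co$mask, co$geometry, bin_width_um = hw,
                           colony_id = co$id)
      f <- file.path(out_dir, paste0(co$id, "_height.csv"))
      write_table(hp, f)
      add_file(paste0(co$id, "_height"), f)
      if (nrow(co$cells) >= 2L) {
        segs <- chord_segments(co$geometry,
                               cfg$density$n_segments %||% 10L)
        dens <- nuclei_per_100um(
          co$cells, segs,
          strip_width_um = cfg$density$strip_width_um %||% 9)
        f <- file.path(out_dir, paste0(co$id, "_density.csv"))
        write_table(dens$per_segment, f)
        add_file(paste0(co$id, "_density"), f)
        nn <- internuclear_distances(co$cells)
        f <- file.path(out_dir, paste0(co$id, "_nndist.csv"))
        write_table(nn, f)
        add_file(paste0(co$id, "_nndist"), f)
      }
    }
    invisible(NULL)
  })

  write_manifest(manifest, out_dir)
  invisible(manifest)
}

write_manifest <- function(manifest, out_dir) {
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
}

# Chords through the colony center at evenly spaced angles: the
# "entire width of the colony at N distinct positions" counting design.
chord_segments <- function(geometry, n) {
  th <- seq(0, pi, length.out = n + 1L)[seq_len(n)]
  R <- geometry$fitted_radius_um
  cx <- geometry$center_um["x"]; cy <- geometry$center_um["y"]
  tibble::tibble(
    x0 = cx - R * cos(th), y0 = cy - R * sin(th),
    x1 = cx + R * cos(th), y1 = cy + R * sin(th))
}

validate_config <- function(cfg) {
  mode <- cfg$mode %||% "synthetic"
  if (!mode %in% c("synthetic", "stacks")) {
    cp_abort("`mode` must be 'synthetic' or 'stacks'.",
             "cp_error_config")
  }
  if (is.null(cfg$output_dir)) {
    cp_abort("`output_dir` is required.", "cp_error_config")
  }
  if (mode == "synthetic") {
    if (is.null(cfg$seed)) {
      cp_abort("Synthetic mode requires a `seed`.", "cp_error_config")
    }
    if (is.null(cfg$colony)) {
      cp_abort("Synthetic mode requires a `colony` block.",
               "cp_error_config")
    }
  } else {
    if (is.null(cfg$stacks) || !length(cfg$stacks)) {
      cp_abort("Stacks mode requires a `stacks` list.",
               "cp_error_config")
    }
    missing <- unlist(cfg$stacks)[!file.exists(unlist(cfg$stacks))]
    if (length(missing)) {
      cp_abort(paste("Configured stack path(s) missing:",
                     paste(missing, collapse = ", ")),
               "cp_error_config")
    }
    if (!is.null(cfg$masks)) {
      mm <- unlist(cfg$masks)[!file.exists(unlist(cfg$masks))]
      if (length(mm)) {
        cp_abort(paste("Configured mask path(s) missing:",
                       paste(mm, collapse = ", ")), "cp_error_config")
      }
    }
  }
  cfg$mode <- mode
  cfg
}

spec_from_config <- function(colony_cfg, seed) {
  markers <- lapply(colony_cfg$markers %||% list(), function(m) {
    do.call(marker_model, m)
  })
  noise <- if (!is.null(colony_cfg$noise)) {
    do.call(noise_model, colony_cfg$noise)
  } else noise_model()
  colony_spec(
    diameter_um = colony_cfg$diameter_um,
    cell_density = colony_cfg$cell_density %||% 5,
    n_z_layers = colony_cfg$n_z_layers,
    marker_models = markers, noise = noise,
    voxel_spacing_um = colony_cfg$voxel_spacing_um %||% c(2, 2, 1),
    seed = seed,
    ridge = colony_cfg$ridge)
}

acquire_colonies <- function(cfg, out_dir, add_file) {
  if (cfg$mode == "synthetic") {
    n <- cfg$n_colonies %||% 1L
    lapply(seq_len(n), function(i) {
      spec <- spec_from_config(cfg$colony, seed = cfg$seed + i - 1L)
      sim <- generate_colony(spec)
      id <- sprintf("colony_%02d", i)
      sd <- file.path(out_dir, "stacks", id)
      write_stack(sim$grid, sd)
      add_file(paste0(id, "_stack"), file.path(sd, "stack.json"))
      gt <- file.path(out_dir, "stacks", paste0(id, "_truth.json"))
      write_ground_truth(sim$truth, gt)
      add_file(paste0(id, "_truth"), gt)
      list(id = id, grid = sim$grid, truth = sim$truth, mask = NULL)
    })
  } else {
    masks <- cfg$masks %||% vector("list", length(cfg$stacks))
    if (is.null(cfg$masks) && is.null(cfg$masking)) {
      cp_abort(
        "Stacks mode without masks needs a `masking` block (or external masks).",
        "cp_error_config")
    }
    purrr::map2(cfg$stacks, seq_along(cfg$stacks), function(p, i) {
      grid <- read_stack(p)
      mask <- if (!is.null(masks[[i]])) {
        read_mask(masks[[i]], grid$spacing_um)
      } else NULL
      list(id = sprintf("colony_%02d", i), grid = grid, truth = NULL,
           mask = mask)
    })
  }
}

#' Write a battery of synthetic fixtures mirroring the study designs
#'
#' Presets: `"diameter_series"` (80, 140, 225, 500 and 1000 um
#' colonies sharing one marker layout), `"timecourse"` (0/24/48/72 hr
#' colonies with a central marker halving at 24 hr and a
#' posterior marker invading from the edge), `"posterior_bmp"`
#' (three concentric domains: central, mid annulus, outer) and
#' `"anterior_nobmp"` (central domain only, no outer induction).
#'
#' @param preset Preset name.
#' @param dir Output directory.
#' @param seed Base seed.
#' @param spacing_um xy/z voxel spacing used for the fixtures
#'   (default 4/1 um, an economical fixture resolution).
#' @return Tibble of written files, invisibly.
#' @export
make_fixtures <- function(preset, dir, seed = 1,
                          spacing_um = c(4, 4, 1)) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  emit <- function(name, sim) {
    sd <- file.path(dir, name)
    write_stack(sim$grid, sd)
    write_ground_truth(sim$truth, file.path(dir,
                                            paste0(name, "_truth.json")))
    files <<- c(files, sd)
  }
  three_domains <- function(R) list(
    marker_model("sox2", "center_high", R * 0.5, 15),
    marker_model("nanog", "annulus", c(R * 0.5, R * 0.8), 15),
    marker_model("brachyury", "edge_high", R * 0.8, 15))
  if (preset == "diameter_series") {
    for (dia in c(80, 140, 225, 500, 1000)) {
      spec <- colony_spec(dia, marker_models = three_domains(dia / 2),
                          voxel_spacing_um = spacing_um, seed = seed)
      emit(sprintf("colony_d%04d", dia), generate_colony(spec))
    }
  } else if (preset == "timecourse") {
    spec0 <- colony_spec(
      1000,
      marker_models = list(
        marker_model("sox2", "center_high", 250, 15),
        marker_model("brachyury", "edge_high", 400, 15,
                     level_outside = 0)),
      voxel_spacing_um = spacing_um, seed = seed)
    tc <- generate_timecourse(
      spec0,
      transitions = list(
        sox2 = list(level_multiplier = c(1, 0.5, 0.5, 0.5),
                    boundary_shift_um = c(0, 0, 0, 0)),
        brachyury = list(level_multiplier = c(0, 1, 1, 1),
                         boundary_shift_um = c(0, 0, -50, -100))),
      timepoints_hr = c(0, 24, 48, 72))
    for (tp in tc) {
      emit(sprintf("colony_t%02dh", tp$time_hr),
           list(grid = tp$grid, truth = tp$truth))
    }
  } else if (preset == "posterior_bmp") {
    spec <- colony_spec(500, marker_models = three_domains(250),
                        voxel_spacing_um = spacing_um, seed = seed)
    emit("colony_posterior", generate_colony(spec))
  } else if (preset == "anterior_nobmp") {
    spec <- colony_spec(
      500,
      marker_models = list(
        marker_model("sox2", "center_high", 200, 15),
        marker_model("brachyury", "edge_high", 200, 15,
                     level_inside = 0, level_outside = 0)),
      voxel_spacing_um = spacing_um, seed = seed)
    emit("colony_anterior", generate_colony(spec))
  } else {
    cp_abort(sprintf("Unknown preset '%s'.", preset),
             "cp_error_config")
  }
  invisible(tibble::tibble(preset = preset, path = files))
}
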