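#' Pipeline configuration
#'
#' One nested list holds every tunable of the processing chain, with
#' the rig constants and the defaults used throughout the package.
#' `read_pipeline_config()` loads a YAML file and merges it over the
#' defaults, rejecting unknown keys.
#'
#' @param ... Named overrides of the default sections (partial lists
#'   are merged).
#' @return A named list of class `pipeline_config` with sections `rig`
#'   (plane_distance, intrinsics path), `fusion` (window, aggregator,
#'   kernel size/sigma), `grid` (edge/Hough parameters, cell pitch),
#'   `segmentation`, `occlusion`, `mesh`, `biomass`, `evaluation`, and
#'   `seed`.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    rig = list(plane_distance = 505, intrinsics = NULL),
    fusion = list(window = 4L, aggregator = "median",
                  kernel_size = 11L, kernel_sigma = 1.3),
    grid = list(canny_low = 0.1, canny_high = 0.3, hough_threshold = 0.5,
                band_deg = 5, cell_pitch = 30),
    segmentation = list(backend = "threshold", green_margin = 20,
                        min_pixels = 40, size_split = 600),
    occlusion = list(kappa = 0.5, w_threshold = 0.3, k = 12L,
                     extend = FALSE),
    mesh = list(kind = "quad", quad_size = 2, relax_iters = 500L,
                tol = 1e-3, min_points = 30L, max_points = 4000L),
    biomass = list(model_kind = "density", samples = NULL),
    evaluation = list(manual_csv = NULL),
    seed = 1L
  )
  over <- list(...)
  bad <- setdiff(names(over), names(defaults))
  if (length(bad)) {
    stop("unknown config sections: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  for (sec in names(over)) {
    if (sec == "seed") { defaults$seed <- over$seed; next }
    badk <- setdiff(names(over[[sec]]), names(defaults[[sec]]))
    if (length(badk)) {
      stop(sprintf("unknown keys in config section '%s': %s", sec,
                   paste(badk, collapse = ", ")), call. = FALSE)
    }
    defaults[[sec]][names(over[[sec]])] <- over[[sec]]
  }
  structure(defaults, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file path.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}

#' Run the phenotyping pipeline
#'
#' Orchestrates the stages over a frame manifest: depth fusion and
#' height statistics (`"height"`), leaf segmentation, meshing and area
#' (`"leaves"`), weight prediction (`"biomass"`), and comparison with
#' manual measurements (`"evaluate"`); `"all"` runs everything. Stage
#' outputs are written as CSV under `out_dir` along with a
#' machine-readable run log (config hash, seed, package version);
#' outputs are pure functions of (inputs, config, seed).
#'
#' @param manifest Frame manifest: a tibble (see
#'   [read_frame_manifest()]) or a YAML path.
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @param stages Character vector of stages, or `"all"`.
#' @param intrinsics A [camera_intrinsics()]; if `NULL`, read from
#'   `config$rig$intrinsics`.
#' @param frames_root Directory frame paths are relative to.
#' @return Invisibly, a list of stage outputs (`grid`, `heights`,
#'   `cells`, `leaf_areas`, `weights`, `comparisons`, paths).
#' @export
run_pipeline <- function(manifest, config = pipeline_config(),
                         out_dir = "phenotray_run", stages = "all",
                         intrinsics = NULL, frames_root = ".") {
  stopifnot(inherits(config, "pipeline_config"))
  if (identical(stages, "all")) {
    stages <- c("height", "leaves", "biomass", "evaluate")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  if (is.character(manifest)) manifest <- read_frame_manifest(manifest)
  if (is.null(intrinsics)) {
    if (is.null(config$rig$intrinsics)) {
      stop("no intrinsics: supply `intrinsics` or config$rig$intrinsics",
           call. = FALSE)
    }
    intrinsics <- read_intrinsics(config$rig$intrinsics)
  }
  out <- list()

  groups <- manifest |>
    dplyr::group_by(.data$rack_id, .data$das) |>
    dplyr::group_split()
  merged_by_group <- purrr::map(groups, function(g) {
    frames <- load_frames(g, root = frames_root)
    window <- min(config$fusion$window, length(frames))
    list(rack_id = g$rack_id[1], das = g$das[1],
         density_class = g$density_class[1],
         merged = merge_depth_frames(lapply(frames[seq_len(window)],
                                            `[[`, "depth"),
                                     aggregator = config$fusion$aggregator),
         color = frames[[1]]$color)
  })

  # grid per rack, detected at the earliest day and reused
  racks <- unique(vapply(merged_by_group, `[[`, character(1), "rack_id"))
  grids <- list()
  for (rk in racks) {
    sel <- purrr::keep(merged_by_group, \(m) m$rack_id == rk)
    first <- sel[[which.min(vapply(sel, `[[`, numeric(1), "das"))]]
    grids[[rk]] <- build_tray_grid(
      first$color,
      canny_low = config$grid$canny_low,
      canny_high = config$grid$canny_high,
      hough_threshold = config$grid$hough_threshold,
      band_deg = config$grid$band_deg,
      cell_pitch = config$grid$cell_pitch)
    write_tray_grid(grids[[rk]],
                    file.path(out_dir, paste0("grid_", rk, ".json")))
  }
  out$grid <- grids

  if ("height" %in% stages) {
    res <- purrr::map(merged_by_group, function(m) {
      grid <- grids[[m$rack_id]]
      Ml <- apply_line_mask(m$merged, grid$line_mask)
      Ms <- smooth_depth(Ml, size = config$fusion$kernel_size,
                         sigma = config$fusion$kernel_sigma)
      hs <- suppressWarnings(
        compute_height_surface(Ms, config$rig$plane_distance,
                               das = m$das, rack_id = m$rack_id))
      summ <- suppressWarnings(rack_height_summary(hs, grid))
      list(surface = hs, cells = summ$cells, pooled = summ$summary)
    })
    out$heights <- res
    out$cells <- dplyr::bind_rows(purrr::map(res, "cells"))
    utils::write.csv(out$cells, file.path(out_dir, "height_cells.csv"),
                     row.names = FALSE)
  }

  if ("leaves" %in% stages) {
    leaf_tab <- purrr::map_dfr(merged_by_group, function(m) {
      Ms <- smooth_depth(m$merged, size = config$fusion$kernel_size,
                         sigma = config$fusion$kernel_sigma)
      masks <- segment_leaves(
        m$color, backend = config$segmentation$backend,
        green_margin = config$segmentation$green_margin,
        min_pixels = config$segmentation$min_pixels,
        size_split = config$segmentation$size_split)
      if (!length(masks)) return(tibble::tibble())
      lab <- project_masks_to_cloud(masks, Ms, m$color, intrinsics)
      if (isTRUE(config$occlusion$extend)) {
        nf <- estimate_normals(lab, k = config$occlusion$k)
        for (j in seq_along(masks)) {
          lab <- extend_occluded_leaf(lab, nf, j,
                                      kappa = config$occlusion$kappa,
                                      w_threshold =
                                        config$occlusion$w_threshold)
        }
      }
      purrr::map_dfr(seq_along(masks), function(j) {
        pts <- lab[!is.na(lab$leaf_id) & lab$leaf_id == j, ]
        if (nrow(pts) < config$mesh$min_points) return(tibble::tibble())
        mesh <- if (config$mesh$kind == "quad") {
          fit_quad_mesh(pts, quad_size = config$mesh$quad_size,
                        relax_iters = config$mesh$relax_iters,
                        tol = config$mesh$tol,
                        max_points = config$mesh$max_points)
        } else {
          triangulate_leaf(pts, max_points = config$mesh$max_points)
        }
        tibble::tibble(rack_id = m$rack_id, das = m$das,
                       leaf_id = j, mesh_kind = mesh$mesh_kind,
                       size_class = masks[[j]]$size_class,
                       area_mm2 = mesh$total_area, n_points = nrow(pts))
      })
    })
    out$leaf_areas <- leaf_tab
    utils::write.csv(leaf_tab, file.path(out_dir, "leaf_areas.csv"),
                     row.names = FALSE)
  }

  manual <- NULL
  if (!is.null(config$evaluation$manual_csv)) {
    manual <- read_manual_measurements(config$evaluation$manual_csv)
  }

  if ("biomass" %in% stages) {
    if (is.null(config$biomass$samples)) {
      stop("biomass stage needs config$biomass$samples (CSV path)",
           call. = FALSE)
    }
    samples <- if (is.character(config$biomass$samples)) {
      read_leaf_samples(config$biomass$samples)
    } else config$biomass$samples
    model <- fit_weight_area_model(samples,
                                   kind = config$biomass$model_kind)
    out$model <- model
    if (!is.null(out$leaf_areas) && nrow(out$leaf_areas)) {
      # median over segmented leaves: robust to partially occluded
      # fragments and occasional merged masks
      avm <- out$leaf_areas |>
        dplyr::group_by(.data$rack_id, .data$das) |>
        dplyr::summarise(area_mm2 = stats::median(.data$area_mm2),
                         n_leaves_seen = dplyr::n(), .groups = "drop")
      avm$leaf_weight_g <- weight_from_area(model, avm$area_mm2)
      out$weights <- avm
      if (!is.null(manual)) {
        # per-plug predictions: the leaf count is an input (it is not
        # predicted from vision), taken from each harvested plug
        out$plug_weights <- manual |>
          dplyr::select("rack_id", "das", "plug_id", "n_leaves") |>
          dplyr::inner_join(avm, by = c("rack_id", "das")) |>
          dplyr::mutate(plug_weight_g = .data$leaf_weight_g *
                          .data$n_leaves)
        utils::write.csv(out$plug_weights,
                         file.path(out_dir, "plug_weights.csv"),
                         row.names = FALSE)
      }
      utils::write.csv(avm, file.path(out_dir, "leaf_weights.csv"),
                       row.names = FALSE)
    }
  }

  if ("evaluate" %in% stages && !is.null(manual)) {
    comps <- list()
    if (!is.null(out$cells)) {
      pred_h <- out$cells |>
        dplyr::filter(.data$n_pixels > 0) |>
        dplyr::transmute(.data$rack_id, .data$das,
                         height_mm = .data$h_mean_mm)
      comps$height <- compare_to_ground_truth(pred_h, manual, "height_mm")
      write_comparison_csv(comps$height,
                           file.path(out_dir, "comparison_height.csv"))
    }
    if (!is.null(out$plug_weights)) {
      pred_w <- out$plug_weights |>
        dplyr::transmute(.data$rack_id, .data$das,
                         leaves_weight_g = .data$plug_weight_g)
      comps$weight <- compare_to_ground_truth(pred_w, manual,
                                              "leaves_weight_g")
      write_comparison_csv(comps$weight,
                           file.path(out_dir, "comparison_weight.csv"))
    }
    out$comparisons <- comps
  }

  log <- list(
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    seed = config$seed,
    config_hash = rlang::hash(unclass(config)),
    package_version = as.character(utils::packageVersion("phenotray")),
    r_version = R.version.string,
    stages = stages
  )
  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE)
  invisible(out)
}

#' Write a synthetic rack to disk as a pipeline input
#'
#' Renders scenes for the requested days, writes the frames as
#' PNG pairs plus the YAML manifest, the camera intrinsics, a manual
#' ground-truth CSV sampled from the scene truth, and a reference
#' leaf-sample CSV — everything [run_pipeline()] consumes.
#'
#' @param config A [scene_config()].
#' @param das_values Days to render.
#' @param out_dir Output directory.
#' @param n_plugs Manual plugs sampled per day, default 40 (capped at
#'   the cell count).
#' @return List with `manifest` (tibble), `truths` (per day), and the
#'   file paths (`manifest`, `intrinsics`, `manual_csv`, `samples_csv`).
#' @export
simulate_rack <- function(config, das_values, out_dir,
                          n_plugs = 40L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list(); truths <- list(); manual <- list()
  for (das in das_values) {
    sc <- generate_scene(config, das)
    truths[[as.character(das)]] <- sc$truth
    for (f in seq_along(sc$frames)) {
      dp <- sprintf("depth_das%02d_f%d.png", das, f)
      cp <- sprintf("color_das%02d_f%d.png", das, f)
      write_depth_png(sc$frames[[f]]$depth, file.path(out_dir, dp))
      write_color_png(sc$frames[[f]]$color, file.path(out_dir, cp))
      rows[[length(rows) + 1L]] <- tibble::tibble(
        color = cp, depth = dp, das = das,
        rack_id = paste0("sim_", config$density_class),
        density_class = config$density_class, frame_index = f)
    }
    manual[[as.character(das)]] <- with_scene_rng(
      config$seed + 7L, das,
      generate_manual_measurements(sc$truth,
                                   n_plugs = min(n_plugs,
                                                 config$rows * config$cols)))
  }
  manifest <- dplyr::bind_rows(rows)
  write_frame_manifest(manifest, file.path(out_dir, "manifest.yaml"))
  write_intrinsics(scene_intrinsics(config),
                   file.path(out_dir, "intrinsics.yaml"))
  manual_df <- dplyr::bind_rows(manual)
  utils::write.csv(manual_df, file.path(out_dir, "manual.csv"),
                   row.names = FALSE)
  samples <- with_scene_rng(config$seed + 13L, 0L,
                            generate_leaf_samples(config))
  utils::write.csv(samples, file.path(out_dir, "leaf_samples.csv"),
                   row.names = FALSE)
  list(manifest = manifest, truths = truths,
       paths = list(manifest = file.path(out_dir, "manifest.yaml"),
                    intrinsics = file.path(out_dir, "intrinsics.yaml"),
                    manual_csv = file.path(out_dir, "manual.csv"),
                    samples_csv = file.path(out_dir, "leaf_samples.csv")))
}
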