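#' Synthetic tray scene configuration
#'
#' Describes a simulated rack layer: a planar tray at the rig's
#' camera-to-tray distance, a regular cell grid, and per-cell plant
#' canopies made of elliptical leaves. The generator renders aligned
#' RGBD frames geometrically consistent with the package's camera
#' model (every depth pixel deprojects onto the true 3D leaf plane), so
#' every pipeline stage can be tested against exact ground truth.
#'
#' Defaults emulate the rig: 30 mm cell pitch, 505 mm plane distance,
#' 720 x 1280 images, four frames per day with 1 px inter-frame jitter,
#' depth noise of 2 mm and a 10% hole fraction. The high-density layout
#' is a 12 x 12 cell tray (144 plugs), the low-density one 8 x 13
#' (104 plugs) with slightly wider per-cell height spread — denser
#' planting stabilizes growth at similar heights. Canopy height follows
#' a logistic curve over days after sowing; leaf size scales with the
#' same curve, so cells are sparsely covered early (grid lines visible)
#' and a closed leaf carpet later.
#'
#' @param density_class `"high"` or `"low"`.
#' @param rows,cols Cell grid size; defaults depend on `density_class`.
#' @param cell_pitch Cell spacing, mm; default 30.
#' @param plane_distance Camera-to-tray distance, mm; default 505.
#' @param image_size `c(H, W)` pixels; default `c(720, 1280)`.
#' @param focal_px Focal length in pixels (`f * mx`); default 650
#'   (about 1.3 px/mm on the tray plane, leaving the full tray in
#'   frame at canopy height).
#' @param leaves_per_plug Leaves rendered per cell; default 4
#'   (0 renders a bare tray).
#' @param canopy_max Asymptotic canopy height, mm; defaults 140 (high)
#'   / 120 (low).
#' @param growth_rate,growth_midpoint Logistic growth parameters over
#'   days; defaults 0.45 and day 14.
#' @param cell_height_sd Between-cell height spread, mm; defaults 4
#'   (high) / 6 (low).
#' @param leaf_a_range,leaf_b_range Full-size leaf semi-axis ranges, mm.
#' @param leaf_tilt_max Maximum leaf tilt from horizontal, degrees;
#'   default 20.
#' @param rho_bl Leaf density (weight / area), g/mm2; default 2e-4.
#' @param depth_noise_sd Additive depth noise, mm; default 2.
#' @param hole_fraction Fraction of depth pixels knocked out per frame;
#'   default 0.1.
#' @param frames_per_day Frames captured per day; default 4.
#' @param jitter_px Maximum integer inter-frame shift, px; default 1.
#' @param line_width_px Rendered grid-line width, px; default 2.
#' @param seed RNG seed; all randomness flows from it.
#' @return An object of class `scene_config`.
#' @export
scene_config <- function(density_class = c("high", "low"),
                         rows = NULL, cols = NULL,
                         cell_pitch = 30, plane_distance = 505,
                         image_size = c(720, 1280), focal_px = 650,
                         leaves_per_plug = 4,
                         canopy_max = NULL,
                         growth_rate = 0.45, growth_midpoint = 14,
                         cell_height_sd = NULL,
                         leaf_a_range = c(6.5, 8.5),
                         leaf_b_range = c(5, 6.5),
                         leaf_tilt_max = 20,
                         rho_bl = 2e-4,
                         depth_noise_sd = 2, hole_fraction = 0.1,
                         frames_per_day = 4, jitter_px = 1,
                         line_width_px = 2, seed = 1L) {
  density_class <- match.arg(density_class)
  if (is.null(rows)) rows <- if (density_class == "high") 12L else 8L
  if (is.null(cols)) cols <- if (density_class == "high") 12L else 13L
  if (is.null(canopy_max)) {
    canopy_max <- if (density_class == "high") 140 else 120
  }
  if (is.null(cell_height_sd)) {
    cell_height_sd <- if (density_class == "high") 4 else 6
  }
  stopifnot(rows >= 1, cols >= 1, cell_pitch > 0, plane_distance > 0,
            all(image_size > 0), focal_px > 0, leaves_per_plug >= 0,
            hole_fraction >= 0, hole_fraction < 1, frames_per_day >= 1,
            depth_noise_sd >= 0, rho_bl > 0)
  structure(list(
    density_class = density_class, rows = as.integer(rows),
    cols = as.integer(cols), cell_pitch = cell_pitch,
    plane_distance = plane_distance,
    image_size = as.integer(image_size), focal_px = focal_px,
    leaves_per_plug = as.integer(leaves_per_plug),
    canopy_max = canopy_max, growth_rate = growth_rate,
    growth_midpoint = growth_midpoint, cell_height_sd = cell_height_sd,
    leaf_a_range = leaf_a_range, leaf_b_range = leaf_b_range,
    leaf_tilt_max = leaf_tilt_max, rho_bl = rho_bl,
    depth_noise_sd = depth_noise_sd, hole_fraction = hole_fraction,
    frames_per_day = as.integer(frames_per_day),
    jitter_px = as.integer(jitter_px),
    line_width_px = as.integer(line_width_px), seed = as.integer(seed)
  ), class = "scene_config")
}

#' @export
print.scene_config <- function(x, ...) {
  cat(sprintf(paste0("<scene_config> %s density, %d x %d cells ",
                     "(%g mm pitch), %d x %d px, D = %g mm, seed %d\n"),
              x$density_class, x$rows, x$cols, x$cell_pitch,
              x$image_size[1], x$image_size[2], x$plane_distance, x$seed))
  invisible(x)
}

#' Camera intrinsics of a synthetic scene
#'
#' @param config A [scene_config()].
#' @return A [camera_intrinsics()] with the principal point at the
#'   image center and no distortion.
#' @export
scene_intrinsics <- function(config) {
  H <- config$image_size[1]; W <- config$image_size[2]
  camera_intrinsics(f = 1, mx = config$focal_px, my = config$focal_px,
                    px = (W / 2) / config$focal_px,
                    py = (H / 2) / config$focal_px,
                    height = H, width = W)
}

# Logistic canopy growth curve, mm, and the leaf-size scale factor.
canopy_height_at <- function(config, das) {
  config$canopy_max /
    (1 + exp(-config$growth_rate * (das - config$growth_midpoint)))
}

leaf_scale_at <- function(config, das) {
  min(1, max(0.25, canopy_height_at(config, das) / config$canopy_max))
}

# Shift a matrix by (dy, dx) pixels, filling vacated entries.
shift_matrix <- function(M, dy, dx, fill) {
  H <- nrow(M); W <- ncol(M)
  out <- matrix(fill, H, W)
  ys <- seq_len(H) - dy; xs <- seq_len(W) - dx
  ok_y <- ys >= 1 & ys <= H; ok_x <- xs >= 1 & xs <= W
  out[ok_y, ok_x] <- M[ys[ok_y], xs[ok_x]]
  out
}

# Evaluate RNG-dependent code under the scene seed (offset per day),
# restoring the caller's RNG state afterwards.
with_scene_rng <- function(seed, das, code) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed((seed * 131L + das) %% .Machine$integer.max)
  force(code)
}

#' Render a synthetic tray scene for one day
#'
#' Renders the tray plane at the rig distance with dark grid lines at
#' the cell pitch, and per-cell plant canopies of planar elliptical
#' leaves at the cell's canopy height (Lambertian-like green shading
#' with a darker rim). Depth is the per-pixel nearest surface, in
#' integer mm; each of the day's frames gets independent Gaussian depth
#' noise, missing-data holes at the configured fraction, and a small
#' integer pixel jitter (the first frame is unjittered). Rendering is
#' exact ray casting against the leaf planes, so depth pixels deproject
#' onto the true leaf surfaces. Deterministic under the config seed.
#'
#' @param config A [scene_config()].
#' @param das Day after sowing.
#' @return List with `frames` (list of [rgbd_frame()]), `truth` (see
#'   Details) and `intrinsics`.
#'
#' @details `truth` is a list with: `cells` — tibble of per-cell truth
#'   (nominal canopy height, and mean/max/sd of the noiseless rendered
#'   height surface over the cell interior); `leaves` — tibble of
#'   per-leaf truth (3D center, semi-axes mm, pose, analytic area
#'   `pi a b`, weight = `rho_bl * area`, occlusion fraction);
#'   `grid` — line positions in pixels and the vertex lattice;
#'   `depth_clean`, `color_clean` — the noiseless render; `das`,
#'   `config`.
#' @export
generate_scene <- function(config, das) {
  stopifnot(inherits(config, "scene_config"))
  with_scene_rng(config$seed, das, {
    H <- config$image_size[1]; W <- config$image_size[2]
    D <- config$plane_distance
    fpx <- config$focal_px
    cx <- W / 2; cy <- H / 2
    intr <- scene_intrinsics(config)

    # --- tray and grid geometry (world mm, camera at origin) ---------
    gx0 <- -config$cols * config$cell_pitch / 2
    gy0 <- -config$rows * config$cell_pitch / 2
    vline_x <- gx0 + (0:config$cols) * config$cell_pitch   # world mm
    hline_y <- gy0 + (0:config$rows) * config$cell_pitch
    px_of_x <- function(x, z) fpx * x / z + cx             # 0-based px
    px_of_y <- function(y, z) fpx * y / z + cy
    vline_px <- px_of_x(vline_x, D)
    hline_px <- px_of_y(hline_y, D)
    if (min(vline_px) < 2 || max(vline_px) > W - 3 ||
        min(hline_px) < 2 || max(hline_px) > H - 3) {
      warning("tray exceeds the image bounds: clipped", call. = FALSE)
    }

    # --- per-cell canopy heights ------------------------------------
    h_nom <- canopy_height_at(config, das)
    n_cells <- config$rows * config$cols
    cell_h <- pmax(1, h_nom + stats::rnorm(n_cells, 0,
                                           config$cell_height_sd))
    cells <- tibble::tibble(
      cell_row = rep(seq_len(config$rows), times = config$cols),
      cell_col = rep(seq_len(config$cols), each = config$rows),
      canopy_height_mm = cell_h
    )
    cells$center_x <- gx0 + (cells$cell_col - 0.5) * config$cell_pitch
    cells$center_y <- gy0 + (cells$cell_row - 0.5) * config$cell_pitch

    # --- surface leaves ------------------------------------------------
    s <- leaf_scale_at(config, das)
    npp <- config$leaves_per_plug
    # sub-grid anchor offsets within a cell (up to 4 anchors, recycled)
    anchors <- matrix(c(-1, -1, 1, 1, -1, 1, -1, 1), ncol = 2) *
      config$cell_pitch / 4
    leaves <- if (npp == 0L) {
      tibble::tibble(cell_row = integer(0), cell_col = integer(0),
                     cx_mm = numeric(0), cy_mm = numeric(0),
                     a_mm = numeric(0), b_mm = numeric(0),
                     height_mm = numeric(0), phi = numeric(0),
                     tilt = numeric(0), tilt_azimuth = numeric(0))
    } else purrr::pmap_dfr(cells, function(cell_row, cell_col,
                                              canopy_height_mm,
                                              center_x, center_y) {
      a0 <- stats::runif(1, config$leaf_a_range[1], config$leaf_a_range[2])
      b0 <- stats::runif(1, config$leaf_b_range[1], config$leaf_b_range[2])
      idx <- ((seq_len(npp) - 1L) %% 4L) + 1L
      tibble::tibble(
        cell_row = cell_row, cell_col = cell_col,
        cx_mm = center_x + anchors[idx, 1] + stats::runif(npp, -1.5, 1.5),
        cy_mm = center_y + anchors[idx, 2] + stats::runif(npp, -1.5, 1.5),
        a_mm = s * a0 * stats::runif(npp, 0.92, 1.08),
        b_mm = s * b0 * stats::runif(npp, 0.92, 1.08),
        height_mm = pmax(1, canopy_height_mm + stats::runif(npp, -3, 3)),
        phi = stats::runif(npp, 0, pi),
        tilt = stats::runif(npp, 0, config$leaf_tilt_max) * pi / 180,
        tilt_azimuth = stats::runif(npp, 0, 2 * pi)
      )
    })
    leaves$leaf_id <- seq_len(nrow(leaves))
    leaves$area_mm2 <- pi * leaves$a_mm * leaves$b_mm
    leaves$weight_g <- config$rho_bl * leaves$area_mm2

    # --- understory: once the canopy closes (leaf scale >= 0.6), the
    # shaded lower foliage fills each cell below the surface leaves.
    # Rendered as a squarish superellipse pad at the cell footprint,
    # darker and less green-dominant than sunlit surface leaves.
    has_understory <- s >= 0.6 && npp > 0L
    pads <- if (has_understory) {
      dplyr::mutate(cells,
                    pad_height = pmax(1, .data$canopy_height_mm - 8))
    } else NULL

    # --- noiseless render --------------------------------------------
    depth <- matrix(D, H, W)
    owner <- matrix(0L, H, W)               # leaf_id per pixel, 0 = tray
    rim <- matrix(FALSE, H, W)
    if (has_understory) {
      # pads extend a margin beyond their cell: lower foliage interleaves
      # across cell borders, and the margin also closes the parallax
      # wedges between neighbouring pads of different heights
      pm <- config$cell_pitch * 0.2
      for (ci in seq_len(nrow(pads))) {
        zpad <- D - pads$pad_height[ci]
        r <- pads$cell_row[ci]; cc <- pads$cell_col[ci]
        x0p <- max(0, floor(px_of_x(vline_x[cc] - pm, zpad)))
        x1p <- min(W - 1, ceiling(px_of_x(vline_x[cc + 1L] + pm, zpad)))
        y0p <- max(0, floor(px_of_y(hline_y[r] - pm, zpad)))
        y1p <- min(H - 1, ceiling(px_of_y(hline_y[r + 1L] + pm, zpad)))
        if (x1p < x0p || y1p < y0p) next
        xs_p <- x0p:x1p; ys_p <- y0p:y1p
        blk <- depth[ys_p + 1L, xs_p + 1L]
        blk[blk > zpad] <- zpad
        depth[ys_p + 1L, xs_p + 1L] <- blk
      }
    }
    pad_depth <- depth                      # tray + understory only
    for (li in seq_len(nrow(leaves))) {
      lf <- leaves[li, ]
      zc <- D - lf$height_mm
      ctr <- c(lf$cx_mm, lf$cy_mm, zc)
      # leaf frame: major/minor axes rotated by phi, then tilted
      u0 <- c(cos(lf$phi), sin(lf$phi), 0)
      v0 <- c(-sin(lf$phi), cos(lf$phi), 0)
      taz <- c(cos(lf$tilt_azimuth), sin(lf$tilt_azimuth), 0)
      # tilt rotates about the axis perpendicular to taz in the plane
      ct <- cos(lf$tilt); st <- sin(lf$tilt)
      tilt_vec <- function(w) {
        par <- sum(w * taz)
        w + (ct - 1) * par * taz + c(0, 0, st * par)
      }
      u <- tilt_vec(u0); v <- tilt_vec(v0)
      nrm <- c(u[2] * v[3] - u[3] * v[2],
               u[3] * v[1] - u[1] * v[3],
               u[1] * v[2] - u[2] * v[1])
      nrm <- nrm / sqrt(sum(nrm^2))
      ext <- max(lf$a_mm, lf$b_mm) * 1.2
      xr <- range(px_of_x(lf$cx_mm + c(-ext, ext), zc - ext))
      yr <- range(px_of_y(lf$cy_mm + c(-ext, ext), zc - ext))
      xs <- max(0, floor(xr[1])):min(W - 1, ceiling(xr[2]))
      ys <- max(0, floor(yr[1])):min(H - 1, ceiling(yr[2]))
      if (!length(xs) || !length(ys)) next
      # rays through the pixel block: dir = K^-1 (x, y, 1)
      dx <- (rep(xs, each = length(ys)) - cx) / fpx
      dy <- (rep(ys, times = length(xs)) - cy) / fpx
      denom <- dx * nrm[1] + dy * nrm[2] + nrm[3]
      tstar <- sum(ctr * nrm) / denom
      PX <- tstar * dx - ctr[1]
      PY <- tstar * dy - ctr[2]
      PZ <- tstar - ctr[3]
      au <- (PX * u[1] + PY * u[2] + PZ * u[3]) / lf$a_mm
      bv <- (PX * v[1] + PY * v[2] + PZ * v[3]) / lf$b_mm
      r2 <- au^2 + bv^2
      inside <- r2 <= 1 & tstar > 0
      if (!any(inside)) next
      rows_i <- rep(ys, times = length(xs)) + 1L
      cols_i <- rep(xs, each = length(ys)) + 1L
      lin <- (cols_i - 1L) * H + rows_i
      lin_in <- lin[inside]
      closer <- tstar[inside] < depth[lin_in]
      upd <- lin_in[closer]
      depth[upd] <- tstar[inside][closer]
      owner[upd] <- lf$leaf_id
      rim[upd] <- r2[inside][closer] > 0.80
    }

    # occlusion fraction per leaf: visible pixels vs unoccluded footprint
    vis <- tabulate(owner[owner > 0L], nbins = nrow(leaves))
    px_area <- (fpx / (D - leaves$height_mm))^2   # px per mm^2 at leaf depth
    foot <- pmax(1, leaves$area_mm2 * px_area * cos(leaves$tilt))
    leaves$occlusion <- pmin(1, pmax(0, 1 - vis / foot))

    # --- colour image -------------------------------------------------
    col_r <- matrix(132, H, W); col_g <- matrix(120, H, W)
    col_b <- matrix(104, H, W)                      # tray substrate
    on_leaf <- owner > 0L
    on_pad <- pad_depth < D & !on_leaf              # shaded understory
    col_r[on_pad] <- 70; col_g[on_pad] <- 85; col_b[on_pad] <- 52
    shade <- matrix(0, H, W)
    shade[on_leaf] <- cos(leaves$tilt[owner[on_leaf]])  # Lambertian-ish
    col_r[on_leaf] <- 30 + 25 * shade[on_leaf]
    col_g[on_leaf] <- 110 + 80 * shade[on_leaf]
    col_b[on_leaf] <- 28 + 20 * shade[on_leaf]
    drim <- rim & on_leaf                           # darker leaf margin
    col_r[drim] <- 25; col_g[drim] <- 62; col_b[drim] <- 18
    # grid lines drawn where the tray is visible
    lw <- config$line_width_px
    line_mask_true <- matrix(FALSE, H, W)
    for (xp in vline_px) {
      cols_l <- round(xp - (lw - 1) / 2) + seq_len(lw) - 1L
      cols_l <- cols_l[cols_l >= 0 & cols_l < W] + 1L
      ys_l <- (max(0, floor(min(hline_px))):min(H - 1,
                                                ceiling(max(hline_px)))) + 1L
      line_mask_true[ys_l, cols_l] <- TRUE
    }
    for (yp in hline_px) {
      rows_l <- round(yp - (lw - 1) / 2) + seq_len(lw) - 1L
      rows_l <- rows_l[rows_l >= 0 & rows_l < H] + 1L
      xs_l <- (max(0, floor(min(vline_px))):min(W - 1,
                                                ceiling(max(vline_px)))) + 1L
      line_mask_true[rows_l, xs_l] <- TRUE
    }
    on_line <- line_mask_true & !on_leaf & !on_pad
    col_r[on_line] <- 25; col_g[on_line] <- 25; col_b[on_line] <- 25
    color <- array(c(col_r, col_g, col_b), dim = c(H, W, 3))

    # --- per-cell truth from the noiseless render ---------------------
    hmap <- D - depth
    margin <- lw + 1L
    cell_truth <- purrr::pmap_dfr(
      cells, function(cell_row, cell_col, canopy_height_mm, ...) {
        x0c <- max(0, floor(vline_px[cell_col] + margin))
        x1c <- min(W - 1, ceiling(vline_px[cell_col + 1L] - margin))
        y0c <- max(0, floor(hline_px[cell_row] + margin))
        y1c <- min(H - 1, ceiling(hline_px[cell_row + 1L] - margin))
        if (x1c < x0c || y1c < y0c) {
          return(tibble::tibble(
            cell_row = cell_row, cell_col = cell_col,
            canopy_height_mm = canopy_height_mm,
            h_mean_mm = NA_real_, h_max_mm = NA_real_, h_sd_mm = NA_real_,
            n_pixels = 0L, coverage = 0))
        }
        xs_c <- (x0c:x1c) + 1L
        ys_c <- (y0c:y1c) + 1L
        z <- hmap[ys_c, xs_c]
        z <- z[z > 0]
        tibble::tibble(
          cell_row = cell_row, cell_col = cell_col,
          canopy_height_mm = canopy_height_mm,
          h_mean_mm = if (length(z)) mean(z) else NA_real_,
          h_max_mm = if (length(z)) max(z) else NA_real_,
          h_sd_mm = if (length(z) > 1) stats::sd(z) else 0,
          n_pixels = length(z),
          coverage = length(z) / length(ys_c) / length(xs_c)
        )
      })

    grid_truth <- list(
      vline_px = vline_px, hline_px = hline_px,
      vertices = tibble::tibble(
        x = rep(vline_px, times = length(hline_px)),
        y = rep(hline_px, each = length(vline_px))
      ),
      cell_pitch_mm = config$cell_pitch
    )

    # --- frames: jitter + noise + holes -------------------------------
    frames <- purrr::map(seq_len(config$frames_per_day), function(f) {
      if (f == 1L || config$jitter_px == 0L) {
        dzx <- 0L; dzy <- 0L
      } else {
        dzx <- sample(-config$jitter_px:config$jitter_px, 1)
        dzy <- sample(-config$jitter_px:config$jitter_px, 1)
      }
      dmat <- shift_matrix(depth, dzy, dzx, fill = D)
      if (config$depth_noise_sd > 0) {
        dmat <- dmat + matrix(stats::rnorm(H * W, 0,
                                           config$depth_noise_sd), H, W)
      }
      dmat <- round(pmax(dmat, 1))
      if (config$hole_fraction > 0) {
        holes <- matrix(stats::runif(H * W) < config$hole_fraction, H, W)
        dmat[holes] <- 0
      }
      cmat <- color
      if (dzx != 0L || dzy != 0L) {
        for (ch in 1:3) {
          cmat[, , ch] <- shift_matrix(color[, , ch], dzy, dzx,
                                       fill = color[1, 1, ch])
        }
      }
      rgbd_frame(cmat, dmat, das = das,
                 rack_id = paste0("sim_", config$density_class),
                 density_class = config$density_class, frame_index = f)
    })

    list(
      frames = frames,
      truth = list(cells = cell_truth, leaves = leaves,
                   grid = grid_truth, depth_clean = depth,
                   color_clean = color, owner = owner,
                   line_mask_true = line_mask_true,
                   das = das, config = config),
      intrinsics = intr
    )
  })
}

#' Simulated manual (destructive) measurements
#'
#' Emulates the manual protocol: on harvest days a sample of plugs is
#' cut and, per plug, the plant height, the total leaf weight, the leaf
#' count and the plug weight are recorded. Values derive from the scene
#' truth with configurable measurement noise.
#'
#' @param truth The `truth` element of [generate_scene()].
#' @param n_plugs Plugs sampled for the day (default 40, the typical
#'   manual sample); must not exceed the available cells.
#' @param height_noise_sd Ruler noise on height, mm; default 2.
#' @param weight_noise_cv Multiplicative scale noise on weights;
#'   default 0.03.
#' @return Tibble in the manual-measurement schema: `rack_id`, `das`,
#'   `plug_id`, `height_mm`, `leaves_weight_g`, `n_leaves`,
#'   `plug_weight_g`.
#' @export
generate_manual_measurements <- function(truth, n_plugs = 40L,
                                         height_noise_sd = 2,
                                         weight_noise_cv = 0.03) {
  cells <- truth$cells
  if (n_plugs > nrow(cells)) {
    stop("sampling plan exceeds the available plugs", call. = FALSE)
  }
  take <- sort(sample.int(nrow(cells), n_plugs))
  picked <- cells[take, ]
  per_plug <- truth$leaves |>
    dplyr::group_by(.data$cell_row, .data$cell_col) |>
    dplyr::summarise(leaves_weight_g = sum(.data$weight_g),
                     n_leaves = dplyr::n(), .groups = "drop")
  out <- picked |>
    dplyr::left_join(per_plug, by = c("cell_row", "cell_col")) |>
    dplyr::transmute(
      rack_id = paste0("sim_", truth$config$density_class),
      das = truth$das,
      plug_id = sprintf("r%02dc%02d", .data$cell_row, .data$cell_col),
      height_mm = .data$h_mean_mm +
        stats::rnorm(dplyr::n(), 0, height_noise_sd),
      leaves_weight_g = .data$leaves_weight_g *
        exp(stats::rnorm(dplyr::n(), 0, weight_noise_cv)),
      n_leaves = .data$n_leaves,
      plug_weight_g = .data$leaves_weight_g * 1.35
    )
  tibble::as_tibble(out)
}

#' Synthetic reference leaf samples for the weight-area model
#'
#' Draws single leaves at the configured leaf density with
#' multiplicative measurement noise on the weight, mimicking the
#' reference sample of destructively measured leaves.
#'
#' @param config A [scene_config()] (for `rho_bl` and axis ranges).
#' @param n Number of reference leaves, default 50.
#' @param noise_cv Multiplicative weight noise, default 0.05.
#' @return Tibble with `species`, `weight_g`, `area_mm2`.
#' @export
generate_leaf_samples <- function(config, n = 50L, noise_cv = 0.05) {
  a <- stats::runif(n, config$leaf_a_range[1], config$leaf_a_range[2])
  b <- stats::runif(n, config$leaf_b_range[1], config$leaf_b_range[2])
  area <- pi * a * b
  tibble::tibble(
    species = sample(c("Ya", "Yb", "Yc"), n, replace = TRUE),
    weight_g = config$rho_bl * area * exp(stats::rnorm(n, 0, noise_cv)),
    area_mm2 = area
  )
}
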