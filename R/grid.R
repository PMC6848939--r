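#' Tray grid: detected cell lines, vertices and cells
#'
#' The tray is a regular grid of 30 mm cells, each seating one plug.
#' The grid is detected once per rack, from an early-day image where
#' the lines between cells are still visible, and reused unchanged for
#' all later days. A `tray_grid` holds the binary line mask `L` (0 at
#' line pixels, 1 elsewhere), the detected crossing vertices (pixels,
#' 0-based), and the cells as vertex-index triples `(i, j, k)` — two
#' consecutive corner edges of the cell parallelogram; the fourth
#' corner is implied.
#'
#' @name tray_grid
NULL

# Luminance of an 8-bit RGB array, in [0, 1].
luminance <- function(img) {
  (0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]) / 255
}

# Canny-style edge map: Sobel gradient magnitude + two-threshold
# hysteresis (weak components are kept only if they touch a strong
# pixel). Returns a logical H x W matrix.
canny_edges <- function(gray, low = 0.1, high = 0.3) {
  sx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)
  gx <- EBImage::filter2(gray, sx, boundary = "replicate")
  gy <- EBImage::filter2(gray, t(sx), boundary = "replicate")
  mag <- sqrt(gx^2 + gy^2)
  if (max(mag) <= .Machine$double.eps) {
    return(matrix(FALSE, nrow(gray), ncol(gray)))
  }
  mag <- mag / max(mag)
  weak <- mag > low
  strong <- mag > high
  if (!any(strong)) return(matrix(FALSE, nrow(gray), ncol(gray)))
  lab <- EBImage::bwlabel(weak)
  keep <- sort(unique(lab[strong]))
  keep <- keep[keep > 0]
  matrix(lab %in% keep, nrow(gray), ncol(gray))
}

# Hough voting restricted to two orientation bands. theta is the angle
# of the line normal: near 0 (vertical lines) and near pi/2 (horizontal
# lines); the rig tilt is bounded, so +-band_deg around each suffices.
# One physical line appears in several (rho, theta) bins (thick edge
# clusters, neighbouring orientations), so candidates are clustered by
# a theta-invariant position (where the line crosses the image
# mid-axis) and each cluster's rho is refined as the vote-weighted
# centroid at the winning theta.
hough_lines <- function(edges, threshold = 0.5, band_deg = 5,
                        step_deg = 0.5, min_sep = 12) {
  empty <- tibble::tibble(rho = numeric(0), theta = numeric(0),
                          votes = numeric(0), orientation = character(0))
  ys <- which(edges, arr.ind = TRUE)
  if (nrow(ys) == 0L) return(empty)
  x <- ys[, 2] - 1; y <- ys[, 1] - 1            # 0-based (col, row)
  H <- nrow(edges); W <- ncol(edges)
  out <- list()
  for (ori in c("vertical", "horizontal")) {
    th0 <- if (ori == "vertical") 0 else 90
    thetas <- (th0 + seq(-band_deg, band_deg, by = step_deg)) * pi / 180
    extent <- if (ori == "vertical") H else W    # pixels a full line spans
    rho_max <- ceiling(sqrt(H^2 + W^2))
    acc <- matrix(0L, 2L * rho_max + 1L, length(thetas))
    for (ti in seq_along(thetas)) {
      rho <- round(x * cos(thetas[ti]) + y * sin(thetas[ti]))
      acc[, ti] <- tabulate(rho + rho_max + 1L, nbins = 2L * rho_max + 1L)
    }
    # votes relative to the strongest line of this orientation (the
    # tray need not span the full frame), with an absolute floor
    vmin <- max(threshold * max(acc), 0.15 * extent)
    peaks <- which(acc >= vmin, arr.ind = TRUE)
    if (nrow(peaks) == 0L) { out[[ori]] <- empty; next }
    cand <- tibble::tibble(
      rho = peaks[, 1] - rho_max - 1,
      theta = thetas[peaks[, 2]],
      votes = as.numeric(acc[peaks])
    )
    # theta-invariant position: intercept with the image mid-axis
    mid <- if (ori == "vertical") {
      (cand$rho - (H / 2) * sin(cand$theta)) / cos(cand$theta)
    } else {
      (cand$rho - (W / 2) * cos(cand$theta)) / sin(cand$theta)
    }
    cand$mid <- mid
    cand <- cand[order(-cand$votes), ]
    kept <- list()
    taken_mid <- numeric(0)
    for (i in seq_len(nrow(cand))) {
      if (length(taken_mid) &&
          any(abs(taken_mid - cand$mid[i]) < min_sep)) next
      # refine: the true orientation has the sharpest peak (a tilted
      # reading of a straight line smears votes across rho); take the
      # theta with the highest single-bin vote near this position, then
      # the vote-weighted centroid of the contiguous run around the
      # peak (the thick edge cluster of the line's two transitions).
      best <- NULL
      for (ti in seq_along(thetas)) {
        rc <- if (ori == "vertical") {
          cand$mid[i] * cos(thetas[ti]) + (H / 2) * sin(thetas[ti])
        } else {
          cand$mid[i] * sin(thetas[ti]) + (W / 2) * cos(thetas[ti])
        }
        rr <- round(rc - min_sep):round(rc + min_sep)
        idx <- rr + rho_max + 1L
        ok <- idx >= 1L & idx <= 2L * rho_max + 1L
        rr <- rr[ok]; idx <- idx[ok]
        wts <- acc[idx, ti]
        pk <- which.max(wts)
        # prefer the band center unless a tilt is decisively sharper
        # (a genuine rig tilt costs half the peak at 0.5 deg off)
        score <- wts[pk] -
          10 * abs(thetas[ti] - th0 * pi / 180) * 180 / pi
        if (wts[pk] < vmin) next
        if (is.null(best) || score > best$score) {
          # contiguous cluster of bins >= 30% of the peak
          hot <- wts >= 0.3 * wts[pk]
          lo <- pk; while (lo > 1L && hot[lo - 1L]) lo <- lo - 1L
          hi <- pk; while (hi < length(wts) && hot[hi + 1L]) hi <- hi + 1L
          sel <- lo:hi
          best <- list(rho = sum(rr[sel] * wts[sel]) / sum(wts[sel]),
                       theta = thetas[ti], score = score,
                       votes = wts[pk])
        }
      }
      if (is.null(best)) next
      kept[[length(kept) + 1L]] <- tibble::tibble(
        rho = round(best$rho, 6),       # decimal-exact for serialization
        theta = best$theta,
        votes = as.numeric(best$votes), orientation = ori
      )
      taken_mid <- c(taken_mid, cand$mid[i])
    }
    out[[ori]] <- dplyr::bind_rows(kept)
  }
  dplyr::arrange(dplyr::bind_rows(out), .data$orientation, .data$rho)
}

# Rasterize a (rho, theta) line 1 px wide into an H x W logical matrix.
rasterize_line <- function(rho, theta, H, W) {
  m <- matrix(FALSE, H, W)
  if (abs(cos(theta)) >= abs(sin(theta))) {     # near-vertical: x per y
    yy <- 0:(H - 1)
    xx <- round((rho - yy * sin(theta)) / cos(theta))
    ok <- xx >= 0 & xx < W
    m[cbind(yy[ok] + 1L, xx[ok] + 1L)] <- TRUE
  } else {                                      # near-horizontal: y per x
    xx <- 0:(W - 1)
    yy <- round((rho - xx * cos(theta)) / sin(theta))
    ok <- yy >= 0 & yy < H
    m[cbind(yy[ok] + 1L, xx[ok] + 1L)] <- TRUE
  }
  m
}

#' Detect tray grid lines in an early-day image
#'
#' Runs gradient-magnitude hysteresis edge detection (Canny) followed by
#' a Hough transform restricted to near-vertical and near-horizontal
#' orientation bands (the tray is axis-aligned up to a small rig tilt),
#' and rasterizes the detected lines, 1 px wide, into a binary line
#' mask with 0 exactly on line pixels and 1 elsewhere.
#'
#' @param img `H x W x 3` colour array in `[0, 255]`, from a day early
#'   enough that the cell lines are visible.
#' @param canny_low,canny_high Hysteresis thresholds on normalized
#'   gradient magnitude, defaults 0.1 / 0.3.
#' @param hough_threshold Minimum Hough votes for a line, as a fraction
#'   of the image extent along the line's direction; default 0.5.
#' @param band_deg Half-width of each orientation band, degrees;
#'   default 5.
#' @return A list with `line_mask` (`H x W`, 0 on lines), and `lines`
#'   (tibble: `rho`, `theta`, `votes`, `orientation`).
#' @export
detect_grid_lines <- function(img, canny_low = 0.1, canny_high = 0.3,
                              hough_threshold = 0.5, band_deg = 5) {
  gray <- luminance(img)
  edges <- canny_edges(gray, canny_low, canny_high)
  lines <- hough_lines(edges, threshold = hough_threshold,
                       band_deg = band_deg)
  nv <- sum(lines$orientation == "vertical")
  nh <- sum(lines$orientation == "horizontal")
  if (nv < 2L || nh < 2L) {
    stop(sprintf(paste0("grid not found: %d vertical and %d horizontal ",
                        "lines detected (need >= 2 of each)"), nv, nh),
         call. = FALSE)
  }
  H <- nrow(gray); W <- ncol(gray)
  mask <- matrix(1, H, W)
  for (i in seq_len(nrow(lines))) {
    mask[rasterize_line(lines$rho[i], lines$theta[i], H, W)] <- 0
  }
  list(line_mask = mask, lines = lines)
}

#' Zero the grid-line pixels of a depth map
#'
#' Pointwise (Hadamard) product of the depth map with the binary line
#' mask: depth becomes 0 exactly on line pixels, turning them into
#' missing data so they never contribute height samples.
#'
#' @param M `H x W` depth matrix.
#' @param L `H x W` binary line mask (0 on lines).
#' @return `M * L`, elementwise.
#' @export
apply_line_mask <- function(M, L) {
  if (!all(dim(M) == dim(L))) {
    stop("depth map and line mask shapes differ", call. = FALSE)
  }
  M * L
}

#' Find grid vertices in a line mask
#'
#' A pixel is a vertex of the tray grid when all four of its
#' 4-connected neighbours (up, down, left, right) are line pixels
#' (value 0) — the signature of two crossing 1-px lines. Detections
#' within 3 px of each other are merged to their centroid.
#'
#' @param L Binary line mask (0 on lines).
#' @param merge_radius Radius (px) within which detections merge;
#'   default 3.
#' @return Tibble of vertex coordinates `x`, `y` (0-based pixels),
#'   ordered by `y` then `x`; possibly empty.
#' @export
find_vertices <- function(L, merge_radius = 3) {
  stopifnot(is.matrix(L))
  H <- nrow(L); W <- ncol(L)
  if (H < 3L || W < 3L) return(tibble::tibble(x = numeric(0), y = numeric(0)))
  up    <- L[1:(H - 2), 2:(W - 1)]
  down  <- L[3:H,       2:(W - 1)]
  left  <- L[2:(H - 1), 1:(W - 2)]
  right <- L[2:(H - 1), 3:W]
  hit <- (up == 0) & (down == 0) & (left == 0) & (right == 0)
  idx <- which(hit, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(tibble::tibble(x = numeric(0), y = numeric(0)))
  pts <- cbind(x = idx[, 2], y = idx[, 1])      # interior offset: +1 -1 = 0
  # greedy merge of detections within merge_radius
  centers <- matrix(numeric(0), 0, 2)
  counts <- integer(0)
  for (i in seq_len(nrow(pts))) {
    if (nrow(centers)) {
      d2 <- (centers[, 1] - pts[i, 1])^2 + (centers[, 2] - pts[i, 2])^2
      j <- which.min(d2)
      if (d2[j] <= merge_radius^2) {
        centers[j, ] <- (centers[j, ] * counts[j] + pts[i, ]) /
          (counts[j] + 1)
        counts[j] <- counts[j] + 1L
        next
      }
    }
    centers <- rbind(centers, pts[i, , drop = FALSE])
    counts <- c(counts, 1L)
  }
  out <- tibble::tibble(x = centers[, 1], y = centers[, 2])
  dplyr::arrange(out, .data$y, .data$x)
}

#' Refine vertices to subpixel line intersections
#'
#' A vertex found on the rasterized 1-px line mask sits on integer
#' pixels; this replaces each one by the analytic intersection of its
#' nearest detected vertical and horizontal lines, when that
#' intersection lies within `snap` pixels.
#'
#' @param vertices Tibble `x`, `y` from [find_vertices()].
#' @param lines Detected lines tibble (`rho`, `theta`, `orientation`).
#' @param snap Maximum refinement displacement, px; default 3.
#' @return The refined vertices tibble.
#' @export
refine_vertices <- function(vertices, lines, snap = 3) {
  lv <- lines[lines$orientation == "vertical", ]
  lh <- lines[lines$orientation == "horizontal", ]
  if (nrow(lv) == 0L || nrow(lh) == 0L || nrow(vertices) == 0L) {
    return(vertices)
  }
  for (i in seq_len(nrow(vertices))) {
    x <- vertices$x[i]; y <- vertices$y[i]
    dv <- abs(x * cos(lv$theta) + y * sin(lv$theta) - lv$rho)
    dh <- abs(x * cos(lh$theta) + y * sin(lh$theta) - lh$rho)
    v <- lv[which.min(dv), ]; h <- lh[which.min(dh), ]
    A <- rbind(c(cos(v$theta), sin(v$theta)),
               c(cos(h$theta), sin(h$theta)))
    if (abs(det(A)) < 1e-6) next
    p <- solve(A, c(v$rho, h$rho))
    if (sqrt((p[1] - x)^2 + (p[2] - y)^2) <= snap) {
      vertices$x[i] <- p[1]; vertices$y[i] <- p[2]
    }
  }
  vertices
}

#' Assemble cells from grid vertices
#'
#' Organizes the detected vertices into grid rows and columns (by
#' clustering their y and x coordinates) and emits one cell per
#' adjacent vertex square, encoded by the vertex triple
#' `(i, j, k)` = (top-left, top-right, bottom-right); the bottom-left
#' corner of the parallelogram is implied.
#'
#' @param vertices Tibble with `x`, `y` (0-based pixels).
#' @param tol Clustering tolerance (px) for assigning vertices to a
#'   common grid row/column; default 5.
#' @return Tibble of cells: `cell_row`, `cell_col`, vertex indices
#'   `i`, `j`, `k` into `vertices`.
#' @export
assemble_cells <- function(vertices, tol = 5) {
  if (nrow(vertices) < 4L) {
    stop("need at least 4 vertices to form a cell", call. = FALSE)
  }
  cluster_1d <- function(v) {
    o <- order(v)
    g <- integer(length(v))
    gid <- 1L
    g[o[1]] <- gid
    ref <- v[o[1]]
    for (i in seq_along(o)[-1]) {
      if (v[o[i]] - ref > tol) { gid <- gid + 1L; ref <- v[o[i]] }
      g[o[i]] <- gid
    }
    g
  }
  rowg <- cluster_1d(vertices$y)
  colg <- cluster_1d(vertices$x)
  key <- matrix(NA_integer_, max(rowg), max(colg))
  key[cbind(rowg, colg)] <- seq_len(nrow(vertices))
  cells <- list()
  for (r in seq_len(nrow(key) - 1L)) {
    for (cc in seq_len(ncol(key) - 1L)) {
      i <- key[r, cc]; j <- key[r, cc + 1L]; k <- key[r + 1L, cc + 1L]
      if (!is.na(i) && !is.na(j) && !is.na(k)) {
        cells[[length(cells) + 1L]] <-
          tibble::tibble(cell_row = r, cell_col = cc, i = i, j = j, k = k)
      }
    }
  }
  if (!length(cells)) stop("no complete cells found", call. = FALSE)
  dplyr::bind_rows(cells)
}

#' Build the full tray grid from an early-day image
#'
#' Convenience wrapper: [detect_grid_lines()], [find_vertices()] and
#' [assemble_cells()] in sequence.
#'
#' @inheritParams detect_grid_lines
#' @param cell_pitch Physical cell spacing, mm; default 30.
#' @return An object of class `tray_grid`: `line_mask`, `lines`,
#'   `vertices`, `cells`, `cell_pitch`.
#' @export
build_tray_grid <- function(img, canny_low = 0.1, canny_high = 0.3,
                            hough_threshold = 0.5, band_deg = 5,
                            cell_pitch = 30) {
  det <- detect_grid_lines(img, canny_low, canny_high, hough_threshold,
                           band_deg)
  vertices <- find_vertices(det$line_mask)
  vertices <- refine_vertices(vertices, det$lines)
  cells <- assemble_cells(vertices)
  structure(list(line_mask = det$line_mask, lines = det$lines,
                 vertices = vertices, cells = cells,
                 cell_pitch = cell_pitch),
            class = "tray_grid")
}

#' @export
print.tray_grid <- function(x, ...) {
  cat(sprintf("<tray_grid> %d lines, %d vertices, %d cells (pitch %g mm)\n",
              nrow(x$lines), nrow(x$vertices), nrow(x$cells),
              x$cell_pitch))
  invisible(x)
}

#' Strict parallelogram membership test for a cell
#'
#' Tests whether projected points lie strictly inside a cell bounded by
#' the vertex triple `(Vi, Vj, Vk)`: the projection of `(Vi - p)` onto
#' the edge `(Vi - Vj)` and of `(Vj - p)` onto the edge `(Vj - Vk)`
#' must both lie strictly between 0 and the squared edge length. The
#' strict inequalities exclude the boundary, so no point belongs to two
#' adjacent cells; boundary pixels coincide with the zeroed line mask,
#' so no height sample is lost ambiguously.
#'
#' @param px,py Point coordinates (vectors allowed), 0-based pixels.
#' @param cell One row of `grid$cells` (or a list with `i`, `j`, `k`).
#' @param grid A `tray_grid` (or any list with a `vertices` tibble).
#' @return Logical vector, `TRUE` for points strictly inside.
#' @export
point_in_cell <- function(px, py, cell, grid) {
  V <- grid$vertices
  vi <- c(V$x[cell$i], V$y[cell$i])
  vj <- c(V$x[cell$j], V$y[cell$j])
  vk <- c(V$x[cell$k], V$y[cell$k])
  e1 <- vi - vj
  e2 <- vj - vk
  l1 <- sum(e1^2); l2 <- sum(e2^2)
  if (l1 <= 0 || l2 <= 0) {
    stop("degenerate cell: zero-length edge", call. = FALSE)
  }
  t1 <- e1[1] * (vi[1] - px) + e1[2] * (vi[2] - py)
  t2 <- e2[1] * (vj[1] - px) + e2[2] * (vj[2] - py)
  (t1 > 0) & (t1 < l1) & (t2 > 0) & (t2 < l2)
}

#' Serialize a tray grid to JSON
#'
#' @param grid A `tray_grid`.
#' @param path Output JSON path.
#' @return `read_tray_grid()` returns a `tray_grid` (without the pixel
#'   mask, which is re-rasterized from the stored line equations);
#'   `write_tray_grid()` returns `path` invisibly.
#' @export
write_tray_grid <- function(grid, path) {
  stopifnot(inherits(grid, "tray_grid"))
  lines <- grid$lines
  # theta is a multiple of the angular step: degrees are decimal-exact,
  # so the mask re-rasterizes identically after a round trip
  lines$theta_deg <- round(lines$theta * 180 / pi, 4)
  lines$theta <- NULL
  obj <- list(
    lines = lines,
    vertices = grid$vertices,
    cells = grid$cells,
    cell_pitch_mm = grid$cell_pitch,
    image_size = dim(grid$line_mask)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_tray_grid
#' @export
read_tray_grid <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  H <- obj$image_size[1]; W <- obj$image_size[2]
  mask <- matrix(1, H, W)
  lines <- tibble::as_tibble(obj$lines)
  lines$theta <- lines$theta_deg * pi / 180
  lines$theta_deg <- NULL
  lines <- lines[c("rho", "theta", "votes", "orientation")]
  for (i in seq_len(nrow(lines))) {
    mask[rasterize_line(lines$rho[i], lines$theta[i], H, W)] <- 0
  }
  structure(list(line_mask = mask, lines = lines,
                 vertices = tibble::as_tibble(obj$vertices),
                 cells = tibble::as_tibble(obj$cells),
                 cell_pitch = obj$cell_pitch_mm),
            class = "tray_grid")
}
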