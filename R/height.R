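#' Gaussian summary of a trait sample
#'
#' Mean, standard deviation and sample size of one trait distribution
#' (heights in mm, weights in g, areas in mm2). This is the unit the
#' evaluation layer compares with the Bhattacharyya distance: predicted
#' and manual samples have very different sizes, so distributions are
#' compared instead of paired values.
#'
#' @param mu Mean.
#' @param sigma Standard deviation (>= 0).
#' @param n Sample count.
#' @return An object of class `gaussian_summary`.
#' @export
gaussian_summary <- function(mu, sigma, n = NA_integer_) {
  stopifnot(is.finite(mu), is.finite(sigma), sigma >= 0)
  structure(list(mu = mu, sigma = sigma, n = n), class = "gaussian_summary")
}

#' @export
print.gaussian_summary <- function(x, ...) {
  cat(sprintf("<gaussian_summary> mu = %.3f, sigma = %.3f, n = %s\n",
              x$mu, x$sigma, format(x$n)))
  invisible(x)
}

# Summarize a numeric vector; sd uses the N-1 denominator (0 when n = 1).
summarize_gaussian <- function(z) {
  gaussian_summary(mean(z), if (length(z) > 1) stats::sd(z) else 0,
                   length(z))
}

#' Plant height surface from a line-masked depth map
#'
#' Converts a (merged, line-masked, smoothed) depth map into per-pixel
#' plant height above the tray plane: `Hp = D - Ml` at non-zero pixels,
#' where `D` is the rig's camera-to-tray-plane distance (505 mm by
#' default). Zero pixels (sensor holes and grid-line pixels) are
#' excluded, not treated as height `D`. Small negative heights — depth
#' noise around the bare tray — are clamped to 0 and counted.
#'
#' @param Ml `H x W` line-masked depth matrix, mm; `0` = excluded.
#'   Should already be smoothed (see [smooth_depth()]).
#' @param plane_distance Camera-to-tray-plane distance `D`, mm; default
#'   505 (a required rig constant — it must match the physical setup).
#' @param das,rack_id Optional capture metadata carried through.
#' @return Object of class `height_surface`: `heights` (`H x W`, mm),
#'   `included` (logical mask), `plane_distance`, `n_clamped`, `das`,
#'   `rack_id`.
#' @export
compute_height_surface <- function(Ml, plane_distance = 505,
                                   das = NA_integer_,
                                   rack_id = NA_character_) {
  stopifnot(is.matrix(Ml))
  if (plane_distance <= 0) {
    stop("`plane_distance` must be > 0", call. = FALSE)
  }
  included <- Ml != 0
  Hp <- matrix(0, nrow(Ml), ncol(Ml))
  Hp[included] <- plane_distance - Ml[included]
  neg <- included & Hp < 0
  n_clamped <- sum(neg)
  if (n_clamped > 0) {
    Hp[neg] <- 0
    warning(sprintf("%d negative heights clamped to 0 (residual noise)",
                    n_clamped), call. = FALSE)
  }
  structure(list(heights = Hp, included = included,
                 plane_distance = plane_distance, n_clamped = n_clamped,
                 das = das, rack_id = rack_id),
            class = "height_surface")
}

#' @export
print.height_surface <- function(x, ...) {
  z <- x$heights[x$included & x$heights > 0]
  cat(sprintf("<height_surface> %d x %d px, D = %g mm, DAS %s, rack %s\n",
              nrow(x$heights), ncol(x$heights), x$plane_distance,
              format(x$das), format(x$rack_id)))
  if (length(z)) {
    cat(sprintf("  canopy: %.1f-%.1f mm (mean %.1f) over %d px\n",
                min(z), max(z), mean(z), length(z)))
  } else cat("  bare tray (no positive heights)\n")
  invisible(x)
}

# Included height pixels of one cell: pixels strictly inside the cell
# parallelogram with positive height.
cell_height_pixels <- function(height, grid, cell) {
  V <- grid$vertices
  xs <- c(V$x[cell$i], V$x[cell$j], V$x[cell$k])
  ys <- c(V$y[cell$i], V$y[cell$j], V$y[cell$k])
  # implied fourth corner of the parallelogram
  xs <- c(xs, xs[1] + xs[3] - xs[2]); ys <- c(ys, ys[1] + ys[3] - ys[2])
  Hn <- nrow(height$heights); Wn <- ncol(height$heights)
  x0 <- max(0, floor(min(xs))); x1 <- min(Wn - 1, ceiling(max(xs)))
  y0 <- max(0, floor(min(ys))); y1 <- min(Hn - 1, ceiling(max(ys)))
  if (x1 < x0 || y1 < y0) return(numeric(0))
  gx <- rep(x0:x1, each = y1 - y0 + 1)
  gy <- rep(y0:y1, times = x1 - x0 + 1)
  inside <- point_in_cell(gx, gy, cell, grid)
  lin <- (gx[inside]) * Hn + gy[inside] + 1L      # column-major, 0-based px
  z <- height$heights[lin]
  keep <- height$included[lin] & z > 0
  z[keep]
}

#' Per-cell height statistics
#'
#' For every tray cell, collects the height pixels strictly inside the
#' cell (positive height, not excluded) and reports the maximum, the
#' mean, and the sample standard deviation (`N - 1` denominator), plus
#' the pixel count. Cells with no included pixel are reported with `NA`
#' statistics and `n_pixels = 0` rather than aborting the pipeline.
#'
#' @param height A [compute_height_surface()] result.
#' @param grid A `tray_grid`.
#' @return Tibble: `cell_row`, `cell_col`, `h_max_mm`, `h_mean_mm`,
#'   `h_sd_mm`, `n_pixels` (plus `rack_id`, `das` carried from the
#'   surface).
#' @export
cell_stats <- function(height, grid) {
  stopifnot(inherits(height, "height_surface"), inherits(grid, "tray_grid"))
  res <- purrr::pmap_dfr(grid$cells, function(cell_row, cell_col, i, j, k) {
    z <- cell_height_pixels(height, grid,
                            list(i = i, j = j, k = k))
    if (length(z) == 0L) {
      tibble::tibble(cell_row = cell_row, cell_col = cell_col,
                     h_max_mm = NA_real_, h_mean_mm = NA_real_,
                     h_sd_mm = NA_real_, n_pixels = 0L)
    } else {
      tibble::tibble(cell_row = cell_row, cell_col = cell_col,
                     h_max_mm = max(z), h_mean_mm = mean(z),
                     h_sd_mm = if (length(z) > 1) stats::sd(z) else 0,
                     n_pixels = length(z))
    }
  })
  n_empty <- sum(res$n_pixels == 0L)
  if (n_empty > 0) {
    warning(sprintf("%d empty cells (no positive-height pixels)", n_empty),
            call. = FALSE)
  }
  res$rack_id <- height$rack_id
  res$das <- height$das
  res
}

#' Pooled rack height summary
#'
#' Pools all included height pixels of every cell into one Gaussian
#' summary for the rack, and returns the per-cell table alongside.
#' Optionally the per-cell table is aggregated into 2 x 2 cell
#' neighbourhoods, a coarser view useful for visualisation.
#'
#' @param height A [compute_height_surface()] result.
#' @param grid A `tray_grid`.
#' @param neighbourhood If `TRUE`, also return per-2x2-block means.
#' @return List with `summary` (a [gaussian_summary()] over all pooled
#'   pixels), `cells` (the [cell_stats()] tibble) and, when requested,
#'   `neighbourhoods`.
#' @export
rack_height_summary <- function(height, grid, neighbourhood = FALSE) {
  cells <- cell_stats(height, grid)
  filled <- cells[cells$n_pixels > 0L, ]
  if (nrow(filled) == 0L) {
    stop("all cells empty: no height samples in any cell", call. = FALSE)
  }
  z <- unlist(purrr::pmap(grid$cells, function(cell_row, cell_col, i, j, k) {
    cell_height_pixels(height, grid, list(i = i, j = j, k = k))
  }))
  out <- list(summary = summarize_gaussian(z), cells = cells)
  if (neighbourhood) {
    out$neighbourhoods <- cells |>
      dplyr::mutate(block_row = (.data$cell_row - 1L) %/% 2L + 1L,
                    block_col = (.data$cell_col - 1L) %/% 2L + 1L) |>
      dplyr::group_by(.data$block_row, .data$block_col) |>
      dplyr::summarise(
        h_mean_mm = stats::weighted.mean(.data$h_mean_mm, .data$n_pixels,
                                         na.rm = TRUE),
        h_max_mm = suppressWarnings(max(.data$h_max_mm, na.rm = TRUE)),
        n_pixels = sum(.data$n_pixels),
        .groups = "drop"
      )
  }
  out
}
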