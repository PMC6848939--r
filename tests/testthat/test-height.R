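test_that("height surface is the plane distance minus masked depth", {
  Ml <- matrix(505, 10, 10)
  hs <- compute_height_surface(Ml, 505)
  expect_true(all(hs$heights == 0))

  hs2 <- compute_height_surface(matrix(480, 10, 10), 505)
  expect_true(all(hs2$heights == 25))

  # zeros are missing data, not height 505
  Ml3 <- matrix(480, 10, 10); Ml3[3, ] <- 0
  hs3 <- compute_height_surface(Ml3, 505)
  expect_false(any(hs3$included[3, ]))
  expect_true(all(hs3$heights[3, ] == 0))

  # residual noise below the tray plane is clamped, with a count
  Ml4 <- matrix(c(510, 480), 10, 10)
  expect_warning(hs4 <- compute_height_surface(Ml4, 505), "clamped")
  expect_equal(hs4$n_clamped, 50)
  expect_true(all(hs4$heights >= 0))

  expect_error(compute_height_surface(Ml, 0), "plane_distance")
})

test_that("per-cell statistics use the sample (N-1) standard deviation", {
  # three-pixel cell fixture: {10, 20, 30} -> max 30, mean 20, sd 10
  verts <- tibble::tibble(x = c(0, 4, 0, 4), y = c(0, 0, 4, 4))
  grid <- structure(list(
    line_mask = matrix(1, 6, 6),
    vertices = verts,
    cells = tibble::tibble(cell_row = 1L, cell_col = 1L,
                           i = 1L, j = 2L, k = 4L),
    cell_pitch = 30), class = "tray_grid")
  H <- matrix(0, 6, 6)
  H[cbind(c(1, 2, 3) + 1L, c(1, 2, 3) + 1L)] <- c(10, 20, 30)
  hs <- structure(list(heights = H, included = H > 0,
                       plane_distance = 505, n_clamped = 0,
                       das = 21L, rack_id = "r"),
                  class = "height_surface")
  cs <- cell_stats(hs, grid)
  expect_equal(cs$h_max_mm, 30)
  expect_equal(cs$h_mean_mm, 20)
  expect_equal(cs$h_sd_mm, 10)
  expect_equal(cs$n_pixels, 3L)

  # constant cell: zero spread
  H2 <- H; H2[H2 > 0] <- 30
  hs2 <- hs; hs2$heights <- H2; hs2$included <- H2 > 0
  cs2 <- cell_stats(hs2, grid)
  expect_equal(cs2$h_max_mm, 30)
  expect_equal(cs2$h_mean_mm, 30)
  expect_equal(cs2$h_sd_mm, 0)
})

test_that("cell statistics equal a brute-force pixel loop", {
  hs <- cached_height(24)
  g <- cached_grid()
  cs <- suppressWarnings(cell_stats(hs, g))
  px <- rep(0:(ncol(hs$heights) - 1), each = nrow(hs$heights))
  py <- rep(0:(nrow(hs$heights) - 1), times = ncol(hs$heights))
  for (ci in c(1, 5, 12)) {
    cell <- g$cells[ci, ]
    ins <- point_in_cell(px, py, cell, g)
    lin <- cbind(py[ins] + 1L, px[ins] + 1L)
    z <- hs$heights[lin]
    z <- z[hs$included[lin] & z > 0]
    row <- cs[cs$cell_row == cell$cell_row & cs$cell_col == cell$cell_col, ]
    expect_equal(row$h_max_mm, max(z))
    expect_equal(row$h_mean_mm, mean(z))
    expect_equal(row$h_sd_mm, sd(z))
    expect_equal(row$n_pixels, length(z))
  }
})

test_that("rack summary pools cells with conservation of counts", {
  hs <- cached_height(24)
  g <- cached_grid()
  rs <- suppressWarnings(rack_height_summary(hs, g, neighbourhood = TRUE))
  cs <- rs$cells
  expect_equal(rs$summary$n, sum(cs$n_pixels))
  # pooled mean equals the count-weighted mean of cell means
  expect_equal(rs$summary$mu,
               weighted.mean(cs$h_mean_mm, cs$n_pixels, na.rm = TRUE),
               tolerance = 1e-9)
  # pooled mean lies within the cell-mean range
  expect_gte(rs$summary$mu, min(cs$h_mean_mm, na.rm = TRUE))
  expect_lte(rs$summary$mu, max(cs$h_mean_mm, na.rm = TRUE))
  expect_true(all(c("block_row", "block_col") %in% names(rs$neighbourhoods)))
})

test_that("per-cell canopy heights are recovered within a millimetre", {
  sc <- cached_scene(24)
  hs <- cached_height(24)
  g <- cached_grid()
  cs <- suppressWarnings(cell_stats(hs, g))
  cmp <- dplyr::inner_join(cs, sc$truth$cells,
                           by = c("cell_row", "cell_col"),
                           suffix = c("", "_true"))
  expect_equal(nrow(cmp), nrow(sc$truth$cells))
  expect_lt(max(abs(cmp$h_mean_mm - cmp$h_mean_mm_true)), 1)

  # pooled prediction vs pooled truth: Bhattacharyya distance < 0.05
  pool <- suppressWarnings(rack_height_summary(hs, g))$summary
  hm <- sc$truth$config$plane_distance - sc$truth$depth_clean
  z <- hm[hm > 0 & !sc$truth$line_mask_true]
  expect_lt(bhattacharyya_distance(pool$mu, mean(z),
                                   sigma_p = pool$sigma, sigma_m = sd(z)),
            0.05)
})

test_that("denser planting shows the tighter height spread", {
  # the generator encodes the competition effect: high density grows
  # taller with smaller between-cell spread; the pipeline sees it
  hi <- generate_scene(scene_config("high", rows = 4, cols = 5,
                                    image_size = c(300, 380),
                                    focal_px = 700, seed = 21), 24)
  lo <- generate_scene(scene_config("low", rows = 4, cols = 5,
                                    image_size = c(300, 380),
                                    focal_px = 700, seed = 21), 24)
  sd_of <- function(sc) sd(sc$truth$cells$h_mean_mm)
  expect_lt(sd_of(hi), sd_of(lo))
})
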