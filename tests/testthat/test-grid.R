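test_that("grid lines are recovered within a pixel of the rendered lines", {
  sc <- cached_scene(7)
  det <- detect_grid_lines(sc$frames[[1]]$color)
  tg <- sc$truth$grid

  lv <- sort(det$lines$rho[det$lines$orientation == "vertical"])
  lh <- sort(det$lines$rho[det$lines$orientation == "horizontal"])
  expect_length(lv, length(tg$vline_px))
  expect_length(lh, length(tg$hline_px))
  expect_lt(max(abs(lv - sort(tg$vline_px))), 1)
  expect_lt(max(abs(lh - sort(tg$hline_px))), 1)

  # the mask is zero exactly on the rasterized line footprint
  n_zero <- sum(det$line_mask == 0)
  foot <- matrix(FALSE, nrow(det$line_mask), ncol(det$line_mask))
  for (i in seq_len(nrow(det$lines))) {
    foot <- foot | phenotray:::rasterize_line(det$lines$rho[i],
                                              det$lines$theta[i],
                                              nrow(foot), ncol(foot))
  }
  expect_equal(n_zero, sum(foot))
})

test_that("a featureless image raises grid-not-found", {
  blank <- array(120, dim = c(60, 80, 3))
  expect_error(detect_grid_lines(blank), "grid not found")
})

test_that("line masking is a pointwise product", {
  M <- matrix(runif(20, 400, 500), 4, 5)
  ones <- matrix(1, 4, 5)
  expect_identical(apply_line_mask(M, ones), M)
  expect_true(all(apply_line_mask(M, ones * 0) == 0))
  L <- ones; L[2, ] <- 0
  Ml <- apply_line_mask(M, L)
  expect_true(all(Ml[2, ] == 0))
  expect_identical(Ml[-2, ], M[-2, ])
  expect_error(apply_line_mask(M, ones[, 1:3]), "shape")
})

test_that("vertices are pixels whose four neighbours are line pixels", {
  # perfect '+' crossing of two 1-px lines in a 5x5 patch
  L <- matrix(1, 5, 5)
  L[3, ] <- 0; L[, 3] <- 0
  v <- find_vertices(L)
  expect_equal(nrow(v), 1)
  expect_equal(c(v$x, v$y), c(2, 2))      # 0-based center

  # a straight line has no 4-connected zero neighbourhood
  L2 <- matrix(1, 5, 5); L2[3, ] <- 0
  expect_equal(nrow(find_vertices(L2)), 0)

  # full synthetic grid: rows x cols of crossings within 1 px each
  sc <- cached_scene(7)
  g <- cached_grid()
  tv <- sc$truth$grid$vertices
  expect_equal(nrow(g$vertices), nrow(tv))
  d <- RANN::nn2(as.matrix(tv), as.matrix(g$vertices[, c("x", "y")]),
                 k = 1)$nn.dists
  expect_lt(max(d), 1)
})

test_that("cell membership matches a point-in-parallelogram oracle", {
  g <- cached_grid()
  cell <- g$cells[7, ]
  V <- g$vertices
  vi <- c(V$x[cell$i], V$y[cell$i])
  vj <- c(V$x[cell$j], V$y[cell$j])
  vk <- c(V$x[cell$k], V$y[cell$k])
  v4 <- vi + vk - vj                      # implied fourth corner

  set.seed(12)
  px <- runif(1e4, min(V$x) - 10, max(V$x) + 10)
  py <- runif(1e4, min(V$y) - 10, max(V$y) + 10)
  got <- point_in_cell(px, py, cell, g)

  # generic oracle: barycentric coordinates in the parallelogram frame
  e1 <- vj - vi; e2 <- vk - vj
  den <- e1[1] * e2[2] - e1[2] * e2[1]
  aa <- ((px - vi[1]) * e2[2] - (py - vi[2]) * e2[1]) / den
  bb <- (e1[1] * (py - vi[2]) - e1[2] * (px - vi[1])) / den
  oracle <- aa > 0 & aa < 1 & bb > 0 & bb < 1
  expect_identical(got, oracle)

  # the cell's own vertices are excluded (strict inequalities)
  expect_false(any(point_in_cell(c(vi[1], vj[1], vk[1], v4[1]),
                                 c(vi[2], vj[2], vk[2], v4[2]), cell, g)))
  # the centroid is inside
  ctr <- (vi + vk) / 2
  expect_true(point_in_cell(ctr[1], ctr[2], cell, g))
})

test_that("cells are pairwise disjoint under strict membership", {
  g <- cached_grid()
  set.seed(13)
  px <- runif(3000, min(g$vertices$x), max(g$vertices$x))
  py <- runif(3000, min(g$vertices$y), max(g$vertices$y))
  hits <- rowSums(vapply(seq_len(nrow(g$cells)), function(ci) {
    point_in_cell(px, py, g$cells[ci, ], g)
  }, logical(3000)))
  expect_lte(max(hits), 1)
})

test_that("tray grids survive a JSON round trip", {
  g <- cached_grid()
  f <- withr::local_tempfile(fileext = ".json")
  write_tray_grid(g, f)
  back <- read_tray_grid(f)
  expect_equal(back$vertices, g$vertices, tolerance = 1e-9)
  expect_equal(back$cells, g$cells)
  expect_equal(back$cell_pitch, g$cell_pitch)
  expect_identical(back$line_mask, g$line_mask)
})

test_that("degenerate cells are rejected", {
  g <- cached_grid()
  gg <- g
  gg$vertices$x[g$cells$j[1]] <- gg$vertices$x[g$cells$i[1]]
  gg$vertices$y[g$cells$j[1]] <- gg$vertices$y[g$cells$i[1]]
  expect_error(point_in_cell(1, 1, gg$cells[1, ], gg), "degenerate")
})
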