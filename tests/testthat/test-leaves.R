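test_that("the classical backend finds disjoint leaves with high IoU", {
  # bare image -> no masks
  blank <- array(120, dim = c(60, 80, 3))
  expect_length(segment_leaves(blank), 0)

  # one plug per cell on a 1x5 tray: five disjoint ellipse leaves
  cfg <- scene_config("high", rows = 1, cols = 5,
                      image_size = c(160, 320), focal_px = 600,
                      leaves_per_plug = 1, seed = 5)
  sc <- generate_scene(cfg, 28)
  expect_equal(nrow(sc$truth$leaves), 5)
  masks <- segment_leaves(sc$frames[[1]]$color)
  expect_equal(length(masks), 5)
  own <- sc$truth$owner
  ious <- vapply(masks, function(m) {
    ids <- own[m$mask]; ids <- ids[ids > 0]
    id <- as.integer(names(sort(table(ids), decreasing = TRUE))[1])
    tr <- own == id
    sum(m$mask & tr) / sum(m$mask | tr)
  }, 1)
  expect_true(all(ious >= 0.9))
  # colour keys are unique
  keys <- vapply(masks, function(m) paste(m$mask_color, collapse = ","), "")
  expect_equal(anyDuplicated(keys), 0L)
})

test_that("mask projection labels exactly the valid-depth mask pixels", {
  intr <- unit_intrinsics()
  M <- matrix(10, 20, 20)
  M[1:3, 1:3] <- 0
  mk <- matrix(FALSE, 20, 20); mk[1:10, 1:10] <- TRUE
  masks <- list(leaf_mask(mk, c(10, 200, 30)))
  lab <- project_masks_to_cloud(masks, M, intr = intr)
  expect_equal(sum(!is.na(lab$leaf_id)), sum(mk) - 9)
  expect_equal(attr(lab, "skipped_mask_pixels"), 9)
  # labelled points carry the mask colour (the indicator key)
  on <- !is.na(lab$leaf_id)
  expect_true(all(lab$G[on] == 200))

  # no masks -> nothing labelled
  lab0 <- project_masks_to_cloud(list(), M, intr = intr)
  expect_true(all(is.na(lab0$leaf_id)))

  # full-frame mask labels every valid-depth point
  full <- list(leaf_mask(matrix(TRUE, 20, 20), c(1, 2, 3)))
  lab1 <- project_masks_to_cloud(full, M, intr = intr)
  expect_true(all(!is.na(lab1$leaf_id)))
})

test_that("k-NN normals recover planar and spherical geometry", {
  set.seed(14)
  cl <- tibble::tibble(X = runif(400, 0, 50), Y = runif(400, 0, 50),
                       Z = 10, R = 0, G = 0, B = 0)
  nf <- estimate_normals(cl, 12)
  expect_lt(max(abs(abs(nf$normals[, 3]) - 1)), 1e-6)
  # oriented toward the camera (-Z hemisphere)
  expect_true(all(nf$normals[, 3] <= 0))
  expect_equal(unname(sqrt(rowSums(nf$normals^2))), rep(1, 400),
               tolerance = 1e-9)

  # sphere: normal at p is parallel to p
  u <- matrix(rnorm(3 * 3000), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  sph <- tibble::tibble(X = 50 * u[, 1], Y = 50 * u[, 2], Z = 50 * u[, 3],
                        R = 0, G = 0, B = 0)
  nfs <- estimate_normals(sph, 12)
  cosang <- abs(rowSums(nfs$normals * u))
  expect_gt(min(cosang), cos(5 * pi / 180))

  expect_error(estimate_normals(cl[1:5, ], 12), "fewer points than k")
})

test_that("occluded-leaf extension grows across a disoccluded plane", {
  # planar leaf on a pixel-like grid; right half lost its mask
  g <- expand.grid(X = seq(0, 60, 0.6), Y = seq(0, 30, 0.6))
  lab <- tibble::tibble(X = g$X, Y = g$Y, Z = 100, R = 0, G = 0, B = 0,
                        leaf_id = ifelse(g$X < 30, 1L, NA_integer_))
  nf <- estimate_normals(lab, 12)
  ext <- extend_occluded_leaf(lab, nf, 1L)
  expect_gte(mean(!is.na(ext$leaf_id[g$X >= 30])), 0.9)
  # labels are grown, never removed
  expect_true(all(which(!is.na(lab$leaf_id)) %in%
                    which(!is.na(ext$leaf_id))))

  # closed boundary: nothing to absorb, cloud unchanged
  closed <- lab
  closed$leaf_id <- 1L
  ext2 <- extend_occluded_leaf(closed, estimate_normals(closed, 12), 1L)
  expect_identical(ext2$leaf_id, closed$leaf_id)

  expect_error(extend_occluded_leaf(lab, nf, 99L), "unknown leaf_id")
})

test_that("perpendicular surfaces are never absorbed", {
  leaf <- expand.grid(X = seq(0, 30, 0.6), Y = seq(0, 30, 0.6))
  wall <- expand.grid(Z = seq(100, 80, -0.6), Y = seq(0, 30, 0.6))
  cl <- tibble::tibble(X = c(leaf$X, rep(30, nrow(wall))),
                       Y = c(leaf$Y, wall$Y),
                       Z = c(rep(100, nrow(leaf)), wall$Z),
                       R = 0, G = 0, B = 0,
                       leaf_id = c(rep(1L, nrow(leaf)),
                                   rep(NA_integer_, nrow(wall))))
  # exact normals isolate the cost rule from normal-estimation error
  N <- rbind(matrix(c(0, 0, -1), nrow(leaf), 3, byrow = TRUE),
             matrix(c(-1, 0, 0), nrow(wall), 3, byrow = TRUE))
  nf <- structure(list(normals = N, k = 12L, mean_knn_radius = 1.2),
                  class = "normal_field")
  ext <- extend_occluded_leaf(cl, nf, 1L)
  expect_equal(sum(!is.na(ext$leaf_id)) , nrow(leaf))

  # the printed cost form (raw dot product) is available behind a flag
  # and, under argmin, favours misaligned normals instead
  ext_printed <- extend_occluded_leaf(cl, nf, 1L, as_printed = TRUE)
  expect_gt(sum(!is.na(ext_printed$leaf_id)), nrow(leaf))
})

test_that("extension never steals labels from other leaves", {
  g <- expand.grid(X = seq(0, 60, 0.6), Y = seq(0, 30, 0.6))
  lab <- tibble::tibble(X = g$X, Y = g$Y, Z = 100, R = 0, G = 0, B = 0,
                        leaf_id = dplyr::case_when(g$X < 20 ~ 1L,
                                                   g$X > 40 ~ 2L,
                                                   TRUE ~ NA_integer_))
  nf <- estimate_normals(lab, 12)
  ext <- extend_occluded_leaf(lab, nf, 1L)
  expect_identical(ext$leaf_id[lab$leaf_id == 2L & !is.na(lab$leaf_id)],
                   rep(2L, sum(lab$leaf_id == 2L, na.rm = TRUE)))
})

test_that("leaf masks round-trip through indexed PNG + JSON", {
  mk1 <- matrix(FALSE, 20, 30); mk1[2:6, 3:9] <- TRUE
  mk2 <- matrix(FALSE, 20, 30); mk2[10:18, 12:25] <- TRUE
  masks <- list(leaf_mask(mk1, c(10, 20, 30), "small", 0.8),
                leaf_mask(mk2, c(40, 50, 60), "large", 1))
  fp <- withr::local_tempfile(fileext = ".png")
  fj <- withr::local_tempfile(fileext = ".json")
  write_leaf_masks(masks, fp, fj)
  back <- read_leaf_masks(fp, fj)
  expect_length(back, 2)
  expect_identical(back[[1]]$mask, mk1)
  expect_identical(back[[2]]$mask, mk2)
  expect_equal(back[[2]]$mask_color, c(40L, 50L, 60L))
  expect_equal(back[[1]]$size_class, "small")
})
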