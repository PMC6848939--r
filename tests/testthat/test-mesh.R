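test_that("triangulation reproduces analytic areas", {
  # single triangle
  t1 <- triangulate_leaf(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                         trim = FALSE, smooth_k = 0)
  expect_equal(t1$total_area, 0.5)
  expect_equal(sum(t1$face_areas), t1$total_area, tolerance = 1e-12)

  # dense planar disk of radius 10 mm: within 2% of 100*pi
  disk <- disk_points()
  tm <- triangulate_leaf(disk, max_points = 25000)
  expect_lt(abs(tm$total_area / (100 * pi) - 1), 0.02)

  # rigid motion leaves area unchanged within 0.5%
  set.seed(15)
  sub <- disk[sample(nrow(disk), 4000), ]
  a0 <- triangulate_leaf(sub)$total_area
  moved <- sweep(sub %*% t(rot_x(0.35) %*% rot_z(0.8)), 2, c(5, -3, 480), "+")
  a1 <- triangulate_leaf(moved)$total_area
  expect_lt(abs(a1 - a0) / a0, 0.005)

  expect_error(triangulate_leaf(rbind(c(0, 0, 0), c(1, 1, 1), c(2, 2, 2)),
                                trim = FALSE), "collinear")
  expect_error(triangulate_leaf(rbind(c(0, 0, 0), c(1, 0, 0))), "at least 3")
})

test_that("spring-relaxed quad mesh fits planar fixtures", {
  # exact rectangle with the pitch dividing both sides
  gr <- as.matrix(expand.grid(X = seq(0, 20, 0.4), Y = seq(0, 12, 0.4)))
  gr <- cbind(gr, Z = 0); colnames(gr) <- c("X", "Y", "Z")
  qr <- fit_quad_mesh(gr, quad_size = 2)
  expect_lt(abs(qr$total_area / 240 - 1), 0.01)
  expect_true(all(qr$face_areas > 0))
  expect_equal(sum(qr$face_areas), qr$total_area, tolerance = 1e-9)

  # single planar quad of side s has area s^2
  sq <- as.matrix(expand.grid(X = seq(0, 3, 0.25), Y = seq(0, 3, 0.25)))
  sq <- cbind(sq, Z = 0); colnames(sq) <- c("X", "Y", "Z")
  q1 <- fit_quad_mesh(sq, quad_size = 3)
  expect_equal(nrow(q1$faces), 1)
  expect_lt(abs(q1$total_area - 9) / 9, 0.02)

  expect_error(fit_quad_mesh(gr, quad_size = 0), "quad_size")
  expect_error(fit_quad_mesh(gr[1:3, ]), "at least 4")
})

test_that("disk area error shrinks (or holds) as the pitch halves", {
  disk <- disk_points()
  truth <- 100 * pi
  e2 <- abs(fit_quad_mesh(disk, quad_size = 2,
                          max_points = 25000)$total_area / truth - 1)
  e1 <- abs(fit_quad_mesh(disk, quad_size = 1,
                          max_points = 25000)$total_area / truth - 1)
  expect_lt(e2, 0.02)
  expect_lte(e1, e2 + 1e-9)

  # cross-method agreement on the same fixture
  tm <- triangulate_leaf(disk, max_points = 25000)
  qm <- fit_quad_mesh(disk, quad_size = 2, max_points = 25000)
  expect_lt(abs(tm$total_area - qm$total_area) / tm$total_area, 0.03)
})

test_that("pruning removes only empty boundary quads", {
  # fully occupied grid: identity
  gr <- as.matrix(expand.grid(X = seq(0, 10, 0.25), Y = seq(0, 10, 0.25)))
  gr <- cbind(gr, Z = 0); colnames(gr) <- c("X", "Y", "Z")
  full <- fit_quad_mesh(gr, quad_size = 2, prune = FALSE)
  pruned <- prune_boundary_quads(full, gr)
  expect_equal(nrow(pruned$faces), nrow(full$faces))
  expect_equal(pruned$face_areas, full$face_areas)

  # data confined to the middle: the empty outer ring is removed ...
  mid <- gr[gr[, 1] > 2 & gr[, 1] < 8 & gr[, 2] > 2 & gr[, 2] < 8, ]
  m2 <- fit_quad_mesh(gr, quad_size = 2, prune = FALSE)
  p2 <- prune_boundary_quads(m2, mid)
  expect_equal(nrow(p2$faces), nrow(m2$faces) - (25 - 9))

  # ... but an empty interior face (an occlusion hole) is retained
  hole <- gr[!(gr[, 1] >= 4 & gr[, 1] <= 6 & gr[, 2] >= 4 & gr[, 2] <= 6), ]
  m3 <- fit_quad_mesh(gr, quad_size = 2, prune = FALSE)
  p3 <- prune_boundary_quads(m3, hole)
  expect_equal(nrow(p3$faces), nrow(m3$faces))
})

test_that("mesh area is positive and errors on empty meshes", {
  gr <- as.matrix(expand.grid(X = seq(0, 6, 0.3), Y = seq(0, 6, 0.3)))
  gr <- cbind(gr, Z = 0); colnames(gr) <- c("X", "Y", "Z")
  m <- fit_quad_mesh(gr, quad_size = 2)
  expect_gt(mesh_area(m), 0)
  expect_equal(mesh_area(m), m$total_area)
  m$faces <- m$faces[0, , drop = FALSE]
  expect_error(mesh_area(m), "empty mesh")
})

test_that("meshes are written as OBJ (quads) and PLY (triangles)", {
  gr <- as.matrix(expand.grid(X = seq(0, 6, 0.3), Y = seq(0, 6, 0.3)))
  gr <- cbind(gr, Z = 0); colnames(gr) <- c("X", "Y", "Z")
  m <- fit_quad_mesh(gr, quad_size = 2)
  fo <- withr::local_tempfile(fileext = ".obj")
  write_mesh_obj(m, fo)
  obj <- readLines(fo)
  expect_equal(sum(grepl("^v ", obj)), nrow(m$vertices))
  f_lines <- grep("^f ", obj, value = TRUE)
  expect_equal(length(f_lines), nrow(m$faces))
  expect_true(all(lengths(strsplit(f_lines, " ")) == 5))  # quads kept

  fp <- withr::local_tempfile(fileext = ".ply")
  write_mesh_ply(m, fp)
  ply <- readLines(fp)
  expect_equal(sum(grepl("^3 ", ply)), 2 * nrow(m$faces))  # triangulated
})
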