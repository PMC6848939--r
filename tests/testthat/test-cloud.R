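test_that("depth maps deproject to one point per non-zero pixel", {
  intr <- unit_intrinsics()
  M <- matrix(0, 5, 6)
  expect_warning(cl <- depth_to_cloud(M, intr = intr), "empty")
  expect_equal(nrow(cl), 0)

  M[2, 3] <- 10; M[4, 5] <- 20
  C <- array(100, dim = c(5, 6, 3))
  cl <- depth_to_cloud(M, C, intr)
  expect_equal(nrow(cl), sum(M != 0))
  # pixel (x=2, y=1) 0-based at depth 10 with K = I
  expect_equal(cl$X[1], 2 * 10)
  expect_equal(cl$Y[1], 1 * 10)
  expect_equal(cl$Z[1], 10)
  expect_true(all(cl$R == 100))

  # constant-depth plane lies at Z = d
  Mc <- matrix(505, 8, 8)
  clc <- depth_to_cloud(Mc, intr = intr)
  expect_true(all(clc$Z == 505))
})

test_that("consensus plane fit recovers the tray plane", {
  set.seed(2)
  n <- 600
  cl <- tibble::tibble(X = runif(n, -100, 100), Y = runif(n, -100, 100),
                       Z = 505, R = 0, G = 0, B = 0)
  p <- fit_tray_plane(cl)
  expect_equal(abs(p$normal[3]), 1, tolerance = 1e-9)
  expect_equal(p$c, 505, tolerance = 1e-9)

  # 20% gross outliers do not move the consensus fit
  out <- cl
  idx <- sample(n, n / 5)
  out$Z[idx] <- runif(length(idx), 100, 400)
  out$Z[-idx] <- out$Z[-idx] + rnorm(n - length(idx), 0, 0.5)
  p2 <- fit_tray_plane(out)
  ang <- acos(min(1, abs(p2$normal[3]))) * 180 / pi
  expect_lt(ang, 1)
  expect_lt(abs(p2$c - 505), 1)

  expect_error(fit_tray_plane(cl[1:2, ]), "at least 3")
})

test_that("clipping beyond the plane keeps exactly the camera side", {
  set.seed(4)
  cl <- tibble::tibble(X = runif(300, -50, 50), Y = runif(300, -50, 50),
                       Z = runif(300, 100, 900), R = 0, G = 0, B = 0)
  plane <- structure(list(normal = c(0, 0, 1), c = 505), class = "plane")
  kept <- clip_beyond_plane(cl, plane, margin = 0)
  expect_setequal(which(cl$Z < 505), which(cl$Z %in% kept$Z))

  # identity when everything is already on the camera side
  near <- cl[cl$Z < 400, ]
  expect_equal(clip_beyond_plane(near, plane), near)

  # monotone in margin; infinite margin clears the cloud
  n_kept <- vapply(c(0, 50, 100, Inf),
                   function(m) nrow(clip_beyond_plane(cl, plane, m)), 1)
  expect_true(all(diff(n_kept) <= 0))
  expect_equal(n_kept[4], 0)

  # idempotent at fixed margin
  once <- clip_beyond_plane(cl, plane, 20)
  expect_equal(clip_beyond_plane(once, plane, 20), once)
})

test_that("ICP recovers a known rigid motion and cleans outliers", {
  set.seed(6)
  A <- tibble::tibble(X = runif(700, 0, 100), Y = runif(700, 0, 100),
                      Z = runif(700, 0, 30), R = 0, G = 0, B = 0)
  # B = Rz' (A - t): aligning B onto A must recover (Rz, t)
  th <- 2 * pi / 180
  P <- sweep(as.matrix(A[, 1:3]), 2, c(3, 0, 0)) %*% rot_z(th)
  B <- A; B$X <- P[, 1]; B$Y <- P[, 2]; B$Z <- P[, 3]
  r <- icp_clean(A, B, corr_threshold = 5)
  ang <- acos(pmin(1, (sum(diag(r$transform$R)) - 1) / 2)) * 180 / pi
  expect_lt(abs(ang - 2), 0.1)
  expect_lt(max(abs(r$transform$t - c(3, 0, 0))), 0.1)
  expect_true(all(diff(r$rms) <= 1e-9))
  expect_equal(r$removed, 0)

  # identical clouds: identity transform, nothing removed
  r2 <- icp_clean(A, A)
  expect_lt(max(abs(r2$transform$R - diag(3))), 1e-9)
  expect_lt(max(abs(r2$transform$t)), 1e-9)
  expect_equal(r2$removed, 0)

  # isolated far-away points in A have no support in B and are removed
  out <- A
  out[1:50, 1:3] <- out[1:50, 1:3] + 500
  r3 <- icp_clean(out, A, corr_threshold = 5)
  expect_equal(r3$removed, 50)
  expect_equal(nrow(r3$cloud), nrow(A) - 50)

  expect_error(icp_clean(A[0, ], A), "non-empty")
})

test_that("rigid transforms preserve pairwise distances", {
  set.seed(8)
  cl <- tibble::tibble(X = rnorm(50), Y = rnorm(50), Z = rnorm(50),
                       R = 0, G = 0, B = 0)
  tf <- rigid_transform(rot_x(0.7) %*% rot_z(-1.1), c(5, -2, 9))
  moved <- transform_cloud(cl, tf)
  expect_lt(max(abs(dist(as.matrix(cl[, 1:3])) -
                      dist(as.matrix(moved[, 1:3])))), 1e-9)
})

test_that("metric rescale recovers similarity and affine maps", {
  sq <- rbind(c(0, 0, 505), c(30, 0, 505), c(30, 30, 505), c(0, 30, 505))

  r_id <- estimate_rescale(sq, sq)
  expect_equal(r_id$T, diag(4), tolerance = 1e-9)

  # halved measurements: isotropic scale 2 recovered in closed form
  r_half <- estimate_rescale(sq / 2, sq)
  expect_equal(r_half$scale, 2, tolerance = 1e-9)
  expect_equal(apply_rescale(sq / 2, r_half), sq, tolerance = 1e-9)

  # a mis-scaled, rotated cell snaps back to the 30 mm pitch
  VM <- sq %*% t(rot_z(0.03)) * 0.97
  rs <- estimate_rescale(VM, sq)
  after <- apply_rescale(VM, rs)
  edge <- sqrt(sum((after[2, ] - after[1, ])^2))
  expect_lt(abs(edge - 30), 0.1)

  # full affine model reproduces an anisotropic stretch
  An <- sq %*% diag(c(1.1, 0.9, 1))
  ra <- estimate_rescale(sq, An, model = "affine")
  expect_equal(apply_rescale(sq, ra), An, tolerance = 1e-9)

  coll <- rbind(c(0, 0, 0), c(1, 1, 1), c(2, 2, 2), c(3, 3, 3))
  expect_error(estimate_rescale(coll, coll), "collinear")
})

test_that("point clouds survive PLY round trips in both formats", {
  set.seed(10)
  cl <- as_point_cloud(tibble::tibble(
    X = round(runif(40, -100, 100), 3), Y = round(runif(40, -100, 100), 3),
    Z = round(runif(40, 300, 600), 3),
    R = sample(0:255, 40, TRUE), G = sample(0:255, 40, TRUE),
    B = sample(0:255, 40, TRUE)))
  fa <- withr::local_tempfile(fileext = ".ply")
  write_ply(cl, fa, format = "ascii")
  expect_equal(read_ply(fa), cl, tolerance = 1e-5)

  fb <- withr::local_tempfile(fileext = ".ply")
  write_ply(cl, fb, format = "binary_little_endian")
  expect_equal(read_ply(fb), cl, tolerance = 1e-5)

  # empty cloud is a valid PLY
  f0 <- withr::local_tempfile(fileext = ".ply")
  write_ply(cl[0, ], f0)
  expect_equal(nrow(read_ply(f0)), 0)
})
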