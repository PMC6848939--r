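#' Point clouds as tibbles
#'
#' A point cloud is an `N x 6` tibble with metric coordinates `X, Y, Z`
#' (mm) and 8-bit colours `R, G, B`, one row per deprojected depth
#' pixel. `as_point_cloud()` validates any data frame into this shape.
#'
#' @param df Data frame with columns `X, Y, Z` (and optionally
#'   `R, G, B`, filled with 0 when absent).
#' @return A tibble with columns `X, Y, Z, R, G, B`.
#' @export
as_point_cloud <- function(df) {
  stopifnot(all(c("X", "Y", "Z") %in% names(df)))
  df <- tibble::as_tibble(df)
  for (ch in c("R", "G", "B")) if (!ch %in% names(df)) df[[ch]] <- 0
  if (nrow(df) > 0) {
    if (!all(is.finite(df$X) & is.finite(df$Y) & is.finite(df$Z))) {
      stop("point coordinates must be finite", call. = FALSE)
    }
    rng <- range(df$R, df$G, df$B)
    if (rng[1] < 0 || rng[2] > 255) {
      stop("colours must lie in [0, 255]", call. = FALSE)
    }
  }
  df[c("X", "Y", "Z", "R", "G", "B")]
}

#' Deproject a depth map to a coloured point cloud
#'
#' Creates one point per non-zero depth pixel: pixel coordinates are
#' radially undistorted (if the intrinsics carry distortion
#' coefficients) and deprojected with [deproject()]; colours are copied
#' from the aligned colour image.
#'
#' @param M `H x W` depth matrix, mm; `0` = missing (skipped).
#' @param C Optional aligned `H x W x 3` colour array in `[0, 255]`.
#' @param intr A [camera_intrinsics()].
#' @param ext A [rigid_transform()]; default identity.
#' @return A point-cloud tibble (see [as_point_cloud()]) with extra
#'   columns `px_x`, `px_y` recording the source pixel.
#' @export
depth_to_cloud <- function(M, C = NULL, intr, ext = rigid_transform()) {
  stopifnot(is.matrix(M))
  if (!is.null(C) && !all(dim(C)[1:2] == dim(M))) {
    stop("colour image and depth map must be aligned (same H x W)",
         call. = FALSE)
  }
  idx <- which(M != 0)
  if (length(idx) == 0L) {
    warning("all-zero depth map: empty point cloud", call. = FALSE)
    out <- as_point_cloud(tibble::tibble(X = numeric(0), Y = numeric(0),
                                         Z = numeric(0)))
    out$px_x <- integer(0); out$px_y <- integer(0)
    return(out)
  }
  row <- ((idx - 1L) %% nrow(M))        # 0-based row = y
  col <- ((idx - 1L) %/% nrow(M))       # 0-based col = x
  uv <- undistort_pixel(col, row, intr)
  P <- deproject(uv[, "x"], uv[, "y"], M[idx], intr, ext)
  out <- tibble::tibble(X = P[, 1], Y = P[, 2], Z = P[, 3])
  if (!is.null(C)) {
    n <- nrow(M) * ncol(M)
    out$R <- C[idx]; out$G <- C[idx + n]; out$B <- C[idx + 2L * n]
  }
  out <- as_point_cloud(out)
  out$px_x <- col; out$px_y <- row
  out
}

#' Robust plane fit to a point cloud (random consensus)
#'
#' Fits the dominant plane of a cloud by repeated sampling of point
#' triples and inlier counting, then refines on the inliers by total
#' least squares. Intended for the tray plane, which is the flat
#' background behind the canopy: the consensus step makes the fit
#' immune to the leaf points that dominate the cloud at later growth
#' stages. The returned unit normal is oriented so that the camera
#' origin lies on the non-positive side (`c >= 0`).
#'
#' @param cloud Point-cloud tibble (needs `X, Y, Z`).
#' @param inlier_threshold Distance (mm) within which a point counts as
#'   on the plane; default 3 mm, the depth-noise scale.
#' @param max_iter Number of random triples; default 200.
#' @return A list of class `plane` with unit `normal` (length 3),
#'   offset `c` (mm; plane is `{p : n . p = c}`) and `inlier_fraction`.
#' @export
fit_tray_plane <- function(cloud, inlier_threshold = 3, max_iter = 200L) {
  P <- as.matrix(cloud[, c("X", "Y", "Z")])
  n <- nrow(P)
  if (n < 3L) stop("plane fit needs at least 3 points", call. = FALSE)
  best_inl <- NULL
  for (i in seq_len(max_iter)) {
    tri <- P[sample.int(n, 3L), , drop = FALSE]
    v1 <- tri[2, ] - tri[1, ]; v2 <- tri[3, ] - tri[1, ]
    nv <- c(v1[2] * v2[3] - v1[3] * v2[2],
            v1[3] * v2[1] - v1[1] * v2[3],
            v1[1] * v2[2] - v1[2] * v2[1])
    nn <- sqrt(sum(nv^2))
    if (nn < 1e-12) next                       # collinear triple
    nv <- nv / nn
    d <- abs(P %*% nv - sum(nv * tri[1, ]))
    inl <- d < inlier_threshold
    if (is.null(best_inl) || sum(inl) > sum(best_inl)) best_inl <- inl
  }
  if (is.null(best_inl) || sum(best_inl) < 3L) {
    stop("degenerate geometry: no plane consensus found", call. = FALSE)
  }
  Q <- P[best_inl, , drop = FALSE]
  ctr <- colMeans(Q)
  sv <- svd(sweep(Q, 2, ctr), nu = 0, nv = 3)
  normal <- sv$v[, 3]
  if (sv$d[2] < 1e-9) {
    stop("degenerate geometry: inliers are collinear", call. = FALSE)
  }
  offset <- sum(normal * ctr)
  if (offset < 0) { normal <- -normal; offset <- -offset }
  structure(list(normal = normal, c = offset,
                 inlier_fraction = mean(best_inl)),
            class = "plane")
}

#' @export
print.plane <- function(x, ...) {
  cat(sprintf("<plane> n = (%.4f, %.4f, %.4f), c = %.2f mm (%.0f%% inliers)\n",
              x$normal[1], x$normal[2], x$normal[3], x$c,
              100 * (x$inlier_fraction %||% NA)))
  invisible(x)
}

#' Signed distance of points to a plane
#'
#' Positive beyond the plane (away from the camera), negative on the
#' camera side, given the plane orientation of [fit_tray_plane()].
#'
#' @param cloud Point-cloud tibble.
#' @param plane A `plane` object.
#' @return Numeric vector, mm.
#' @export
plane_distance <- function(cloud, plane) {
  as.numeric(as.matrix(cloud[, c("X", "Y", "Z")]) %*% plane$normal - plane$c)
}

#' Drop points beyond the tray plane
#'
#' Retains only points strictly on the camera side of the plane shifted
#' toward the camera by `margin`; everything at or beyond it (sensor
#' returns through or under the tray) is removed.
#'
#' @param cloud Point-cloud tibble.
#' @param plane A `plane` object.
#' @param margin Extra clearance, mm (default 0). Larger margins keep
#'   fewer points.
#' @return The filtered cloud.
#' @export
clip_beyond_plane <- function(cloud, plane, margin = 0) {
  stopifnot(inherits(plane, "plane"))
  keep <- plane_distance(cloud, plane) < -margin
  cloud[keep, , drop = FALSE]
}

#' Apply a rigid transform to a point cloud
#'
#' @param cloud Point-cloud tibble.
#' @param tf A [rigid_transform()].
#' @return The transformed cloud (colours untouched).
#' @export
transform_cloud <- function(cloud, tf) {
  stopifnot(inherits(tf, "rigid_transform"))
  P <- as.matrix(cloud[, c("X", "Y", "Z")]) %*% t(tf$R)
  P <- sweep(P, 2, tf$t, "+")
  cloud$X <- P[, 1]; cloud$Y <- P[, 2]; cloud$Z <- P[, 3]
  cloud
}

# Kabsch: rigid motion (R, t) minimizing ||A - (B R' + t)|| over rows,
# i.e. mapping B onto A.
kabsch <- function(B, A) {
  ca <- colMeans(A); cb <- colMeans(B)
  S <- crossprod(sweep(A, 2, ca), sweep(B, 2, cb)) / nrow(A)  # t(Ac) Bc
  sv <- svd(t(S))
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t <- ca - as.numeric(R %*% cb)
  rigid_transform(R, t)
}

#' Align two clouds with ICP and remove loose correspondences
#'
#' Point-to-point iterative closest point: alternates nearest-neighbour
#' correspondence (from `cloud_b`, moved by the current estimate, into
#' `cloud_a`) with the least-squares rigid motion, until the RMS
#' residual improves by less than `tol` or `max_iter` is reached. The
#' estimated transform maps `cloud_b` onto `cloud_a`. Points of
#' `cloud_a` whose nearest neighbour in the aligned `cloud_b` is
#' farther than `corr_threshold` have no support in the second capture
#' and are removed, cleaning isolated noise returns.
#'
#' @param cloud_a,cloud_b Point-cloud tibbles, both non-empty.
#' @param max_iter Maximum ICP iterations, default 50.
#' @param tol RMS improvement (mm) below which iteration stops, default
#'   1e-6.
#' @param corr_threshold Residual (mm) above which an `cloud_a` point is
#'   dropped, default 5.
#' @param subsample Optional cap on correspondence points per iteration
#'   (speeds up large clouds); sampling is deterministic given the R
#'   RNG state.
#' @return List with `transform` ([rigid_transform()] mapping b to a),
#'   `cloud` (cleaned `cloud_a`), `removed` (row count), `rms` (residual
#'   trace, non-increasing), `converged` (logical).
#' @export
icp_clean <- function(cloud_a, cloud_b, max_iter = 50L, tol = 1e-6,
                      corr_threshold = 5, subsample = NULL) {
  A <- as.matrix(cloud_a[, c("X", "Y", "Z")])
  B <- as.matrix(cloud_b[, c("X", "Y", "Z")])
  if (nrow(A) == 0L || nrow(B) == 0L) {
    stop("both clouds must be non-empty", call. = FALSE)
  }
  Bs <- if (!is.null(subsample) && nrow(B) > subsample) {
    B[sample.int(nrow(B), subsample), , drop = FALSE]
  } else B
  R <- diag(3); tt <- c(0, 0, 0)
  rms <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    Bt <- sweep(Bs %*% t(R), 2, tt, "+")
    nn <- RANN::nn2(A, Bt, k = 1)
    r <- sqrt(mean(nn$nn.dists^2))
    if (length(rms) && r > rms[length(rms)] - tol) {
      rms <- c(rms, min(r, rms[length(rms)]))
      converged <- TRUE
      break
    }
    rms <- c(rms, r)
    tf <- kabsch(Bs, A[nn$nn.idx[, 1], , drop = FALSE])
    R <- tf$R; tt <- tf$t
  }
  tf <- rigid_transform(R, tt)
  Bt <- sweep(B %*% t(R), 2, tt, "+")
  res_a <- RANN::nn2(Bt, A, k = 1)$nn.dists[, 1]
  keep <- res_a <= corr_threshold
  list(transform = tf,
       cloud = cloud_a[keep, , drop = FALSE],
       removed = sum(!keep),
       rms = rms,
       converged = converged || length(rms) < max_iter)
}

#' Metric rescaling from known cell geometry
#'
#' The deprojected cloud is only approximately metric: the fixed camera
#' is not perfectly aligned with the tray and the factory intrinsics
#' are imprecise. Given the four vertices of one visible tray cell as
#' measured on the cloud (`VM`) and their expected real-world positions
#' (`VE`, a square of the known 30 mm cell pitch), this estimates the
#' transform `T` with `VE = T VM` in the least-squares sense. The
#' default model is a similarity (rotation + translation + isotropic
#' scale, closed form); `model = "affine"` fits a full affine map.
#'
#' @param VM `n x 3` matrix of measured points (n >= 3, non-collinear).
#' @param VE `n x 3` matrix of expected points, same order.
#' @param model `"similarity"` (default) or `"affine"`.
#' @return An object of class `affine_rescale` with the homogeneous
#'   `4 x 4` matrix `T`, plus `scale` for the similarity model.
#' @export
estimate_rescale <- function(VM, VE, model = c("similarity", "affine")) {
  model <- match.arg(model)
  VM <- as.matrix(VM); VE <- as.matrix(VE)
  stopifnot(ncol(VM) == 3L, ncol(VE) == 3L, nrow(VM) == nrow(VE),
            nrow(VM) >= 3L)
  cm <- colMeans(VM)
  if (svd(sweep(VM, 2, cm))$d[2] < 1e-9) {
    stop("measured points are collinear: rescale is under-determined",
         call. = FALSE)
  }
  T4 <- diag(4); s <- NA_real_
  if (model == "similarity") {
    # Umeyama closed form: VE ~ s R VM + t
    ce <- colMeans(VE)
    X <- sweep(VM, 2, cm); Y <- sweep(VE, 2, ce)
    S <- crossprod(Y, X) / nrow(VM)          # cross-covariance (E, M)
    sv <- svd(S)
    D <- diag(c(1, 1, sign(det(sv$u) * det(sv$v))))
    R <- sv$u %*% D %*% t(sv$v)
    var_m <- mean(rowSums(X^2))
    s <- sum(sv$d * diag(D)) / var_m
    if (s <= 0) stop("non-positive scale estimated", call. = FALSE)
    t <- ce - s * as.numeric(R %*% cm)
    T4[1:3, 1:3] <- s * R
    T4[1:3, 4] <- t
  } else {
    VMa <- VM; VEa <- VE
    # coplanar points (the usual case: four cell corners on the tray
    # plane) under-determine a 3D affine map; complete the system by
    # constraining the plane normal to map to the target plane normal
    if (svd(sweep(VM, 2, cm))$d[3] < 1e-9 * max(abs(VM))) {
      nrm_of <- function(P) {
        sv <- svd(sweep(P, 2, colMeans(P)))
        sv$v[, 3]
      }
      VMa <- rbind(VM, cm + nrm_of(VM))
      VEa <- rbind(VE, colMeans(VE) + nrm_of(VE))
    }
    cf <- qr.solve(cbind(VMa, 1), VEa)       # 4 x 3
    T4[1:3, ] <- t(cf)
    if (abs(det(T4[1:3, 1:3])) < 1e-12) {
      stop("degenerate affine fit", call. = FALSE)
    }
  }
  structure(list(T = T4, model = model, scale = s,
                 rms = sqrt(mean((apply_rescale_mat(VM, T4) - VE)^2))),
            class = "affine_rescale")
}

apply_rescale_mat <- function(P, T4) {
  H <- cbind(P, 1) %*% t(T4)
  H[, 1:3, drop = FALSE]
}

#' Apply a metric rescale to a cloud or point matrix
#'
#' @param cloud Point-cloud tibble or `n x 3` matrix.
#' @param rescale An [estimate_rescale()] result.
#' @return Same container as the input, coordinates transformed.
#' @export
apply_rescale <- function(cloud, rescale) {
  stopifnot(inherits(rescale, "affine_rescale"))
  if (is.matrix(cloud)) return(apply_rescale_mat(cloud, rescale$T))
  P <- apply_rescale_mat(as.matrix(cloud[, c("X", "Y", "Z")]), rescale$T)
  cloud$X <- P[, 1]; cloud$Y <- P[, 2]; cloud$Z <- P[, 3]
  cloud
}

#' @export
print.affine_rescale <- function(x, ...) {
  cat(sprintf("<affine_rescale> model = %s%s, fit RMS = %.3g mm\n",
              x$model,
              if (!is.na(x$scale)) sprintf(", scale = %.6g", x$scale) else "",
              x$rms))
  invisible(x)
}

#' Point cloud I/O in PLY format
#'
#' Reads and writes point clouds as PLY with vertex properties
#' `x, y, z` (float) and `red, green, blue` (uchar). Both ASCII and
#' binary little-endian files are supported.
#'
#' @param cloud Point-cloud tibble.
#' @param path File path.
#' @param format `"ascii"` (default) or `"binary_little_endian"`.
#' @return `read_ply()` returns a point-cloud tibble; `write_ply()`
#'   returns `path` invisibly.
#' @export
write_ply <- function(cloud, path,
                      format = c("ascii", "binary_little_endian")) {
  format <- match.arg(format)
  cloud <- as_point_cloud(cloud)
  n <- nrow(cloud)
  hdr <- c("ply",
           sprintf("format %s 1.0", format),
           sprintf("element vertex %d", n),
           "property float x", "property float y", "property float z",
           "property uchar red", "property uchar green",
           "property uchar blue",
           "end_header")
  if (format == "ascii") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(hdr, con)
    if (n > 0) {
      writeLines(sprintf("%.6g %.6g %.6g %d %d %d",
                         cloud$X, cloud$Y, cloud$Z,
                         as.integer(round(cloud$R)),
                         as.integer(round(cloud$G)),
                         as.integer(round(cloud$B))), con)
    }
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(hdr, con)
    if (n > 0) {
      xyz <- t(as.matrix(cloud[, c("X", "Y", "Z")]))
      rgb <- t(as.matrix(cloud[, c("R", "G", "B")]))
      for (i in seq_len(n)) {
        writeBin(as.numeric(xyz[, i]), con, size = 4, endian = "little")
        writeBin(as.raw(round(rgb[, i])), con)
      }
    }
  }
  invisible(path)
}

#' @rdname write_ply
#' @export
read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- character(0)
  repeat {
    ln <- readLines(con, n = 1L)
    hdr <- c(hdr, ln)
    if (identical(ln, "end_header")) break
    if (length(hdr) > 100) stop("malformed PLY header", call. = FALSE)
  }
  fmt <- sub("^format (\\S+).*$", "\\1", grep("^format", hdr, value = TRUE))
  n <- as.integer(sub("^element vertex (\\d+).*$", "\\1",
                      grep("^element vertex", hdr, value = TRUE)))
  if (fmt == "ascii") {
    if (n == 0) {
      return(as_point_cloud(tibble::tibble(X = numeric(0), Y = numeric(0),
                                           Z = numeric(0))))
    }
    dat <- utils::read.table(path, skip = length(hdr), nrows = n)
    return(as_point_cloud(tibble::tibble(X = dat[[1]], Y = dat[[2]],
                                         Z = dat[[3]], R = dat[[4]],
                                         G = dat[[5]], B = dat[[6]])))
  }
  if (fmt != "binary_little_endian") {
    stop("unsupported PLY format: ", fmt, call. = FALSE)
  }
  X <- Y <- Z <- numeric(n); R <- G <- B <- numeric(n)
  for (i in seq_len(n)) {
    v <- readBin(con, "numeric", n = 3, size = 4, endian = "little")
    cch <- as.integer(readBin(con, "raw", n = 3))
    X[i] <- v[1]; Y[i] <- v[2]; Z[i] <- v[3]
    R[i] <- cch[1]; G[i] <- cch[2]; B[i] <- cch[3]
  }
  as_point_cloud(tibble::tibble(X = X, Y = Y, Z = Z, R = R, G = G, B = B))
}
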