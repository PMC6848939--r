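#' Camera intrinsics for the overhead RGBD sensor
#'
#' Bundles the pinhole parameters of the fixed overhead RGBD camera:
#' focal length `f` (mm), pixel densities `mx`, `my` (pixels per mm),
#' skew `s` (pixels), principal point `(px, py)` expressed in normalized
#' image units so that the calibration matrix carries `px * mx` and
#' `py * my` in its third column, radial distortion coefficients
#' `kappas`, the distortion center `(xc, yc)` in pixels, and the image
#' size.
#'
#' Pixel coordinates throughout the package are 0-based with `x` the
#' column index and `y` the row index; pixel centers sit at integer
#' coordinates.
#'
#' @param f Focal length, mm. Must be positive.
#' @param mx,my Pixels per mm along x and y. Must be positive.
#' @param s Skew, pixels. Default 0.
#' @param px,py Principal point in normalized image units (the
#'   calibration matrix holds `px * mx`, `py * my`).
#' @param kappas Numeric vector of radial distortion coefficients
#'   (kappa1, kappa2, ...). Default none (no distortion).
#' @param xc,yc Distortion center, pixels. Default 0.
#' @param height,width Image size in pixels.
#' @return An object of class `camera_intrinsics`.
#' @seealso [build_K()], [undistort_pixel()], [deproject()]
#' @export
#' @examples
#' intr <- camera_intrinsics(f = 1, mx = 925, my = 925,
#'                           px = 640, py = 360,
#'                           height = 720, width = 1280)
#' build_K(intr)
camera_intrinsics <- function(f, mx, my, s = 0, px = 0, py = 0,
                              kappas = numeric(0), xc = 0, yc = 0,
                              height, width) {
  stopifnot(is.numeric(f), length(f) == 1L, is.finite(f),
            is.numeric(mx), length(mx) == 1L, is.finite(mx),
            is.numeric(my), length(my) == 1L, is.finite(my),
            is.numeric(s), length(s) == 1L, is.finite(s),
            is.numeric(px), length(px) == 1L, is.finite(px),
            is.numeric(py), length(py) == 1L, is.finite(py),
            is.numeric(kappas), all(is.finite(kappas)),
            is.numeric(height), is.numeric(width))
  if (f <= 0) stop("focal length `f` must be > 0", call. = FALSE)
  if (mx <= 0 || my <= 0) stop("`mx` and `my` must be > 0", call. = FALSE)
  if (height <= 0 || width <= 0) {
    stop("`height` and `width` must be positive", call. = FALSE)
  }
  structure(
    list(f = f, mx = mx, my = my, s = s, px = px, py = py,
         kappas = as.numeric(kappas), xc = xc, yc = yc,
         height = as.integer(height), width = as.integer(width)),
    class = "camera_intrinsics"
  )
}

#' @export
print.camera_intrinsics <- function(x, ...) {
  cat("<camera_intrinsics>\n")
  cat(sprintf("  f = %g mm; mx = %g, my = %g px/mm; s = %g\n",
              x$f, x$mx, x$my, x$s))
  cat(sprintf("  principal point (normalized): (%g, %g)\n", x$px, x$py))
  if (length(x$kappas)) {
    cat(sprintf("  radial kappas: %s; center (%g, %g) px\n",
                paste(signif(x$kappas, 4), collapse = ", "), x$xc, x$yc))
  }
  cat(sprintf("  image: %d x %d px (H x W)\n", x$height, x$width))
  invisible(x)
}

#' Calibration matrix of the pinhole model
#'
#' Assembles the 3x3 calibration matrix
#' \deqn{K = \begin{pmatrix} f m_x & s & p_x m_x \\ 0 & f m_y & p_y m_y
#' \\ 0 & 0 & 1 \end{pmatrix}}
#' mapping metric camera coordinates to pixels. Note the principal
#' point enters scaled by the pixel densities, matching the normalized
#' convention of [camera_intrinsics()].
#'
#' @param intr A [camera_intrinsics()] object.
#' @return A 3x3 numeric matrix; always invertible for valid intrinsics.
#' @export
build_K <- function(intr) {
  stopifnot(inherits(intr, "camera_intrinsics"))
  K <- matrix(c(intr$f * intr$mx, intr$s,          intr$px * intr$mx,
                0,                intr$f * intr$my, intr$py * intr$my,
                0,                0,                1),
              nrow = 3, byrow = TRUE)
  if (abs(K[1, 1] * K[2, 2]) < .Machine$double.eps) {
    stop("invalid intrinsics: singular calibration matrix", call. = FALSE)
  }
  K
}

#' Rigid transform (rotation + translation)
#'
#' @param R 3x3 rotation matrix (orthonormal, det +1).
#' @param t Length-3 translation, mm.
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(R = diag(3), t = c(0, 0, 0)) {
  R <- as.matrix(R); t <- as.numeric(t)
  stopifnot(all(dim(R) == c(3L, 3L)), length(t) == 3L,
            all(is.finite(R)), all(is.finite(t)))
  if (max(abs(crossprod(R) - diag(3))) > 1e-9) {
    stop("R is not orthonormal (R'R != I within 1e-9)", call. = FALSE)
  }
  if (abs(det(R) - 1) > 1e-9) {
    stop("R must be a proper rotation (det = +1)", call. = FALSE)
  }
  structure(list(R = R, t = t), class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("<rigid_transform>\nR =\n")
  print(signif(x$R, 6))
  cat("t =", paste(signif(x$t, 6), collapse = ", "), "mm\n")
  invisible(x)
}

# Radial magnification L(r). The sensor documentation style gives the
# series with each coefficient multiplying r linearly
# (L = 1 + k1 r + k2 r + ...); the conventional photogrammetric series
# uses even powers (L = 1 + k1 r^2 + k2 r^4 + ...). Both are available;
# "printed" is the default.
radial_L <- function(r, kappas, series = c("printed", "even")) {
  series <- match.arg(series)
  if (!length(kappas)) return(rep(1, length(r)))
  L <- rep(1, length(r))
  for (i in seq_along(kappas)) {
    L <- L + if (series == "printed") kappas[i] * r else kappas[i] * r^(2 * i)
  }
  L
}

#' Radial undistortion of pixel coordinates
#'
#' Corrects raw pixel coordinates for radial lens distortion about the
#' distortion center: `x_hat = xc + L(r) (x - xc)` (same for y), with
#' `r^2 = (x - xc)^2 + (y - yc)^2`. By default `L(r) = 1 + sum_i
#' kappa_i r` (each coefficient enters linearly in `r`); set
#' `series = "even"` for the conventional even-power series
#' `1 + kappa_1 r^2 + kappa_2 r^4 + ...`.
#'
#' @param x,y Raw pixel coordinates (vectors allowed).
#' @param intr A [camera_intrinsics()] object.
#' @param series `"printed"` (default, linear in r per coefficient) or
#'   `"even"` (even powers of r).
#' @return A two-column matrix with columns `x`, `y` of corrected
#'   coordinates.
#' @export
undistort_pixel <- function(x, y, intr, series = c("printed", "even")) {
  stopifnot(inherits(intr, "camera_intrinsics"),
            length(x) == length(y), all(is.finite(x)), all(is.finite(y)))
  series <- match.arg(series)
  dx <- x - intr$xc
  dy <- y - intr$yc
  L <- radial_L(sqrt(dx^2 + dy^2), intr$kappas, series)
  cbind(x = intr$xc + L * dx, y = intr$yc + L * dy)
}

#' Deproject pixels with depth to 3D camera coordinates
#'
#' Maps corrected pixel coordinates and their depth to metric scene
#' coordinates: `(X, Y, Z)' = d * K^-1 R (x_hat, y_hat, 1)' + t`. With
#' the defaults `R = I`, `t = 0` the fixed camera is the world
#' reference. Depth `d` is the per-pixel range in integer millimetres;
#' `d = 0` encodes missing data and should be excluded upstream.
#'
#' @param x,y Corrected pixel coordinates (vectors allowed).
#' @param d Depth values, mm (same length); must be >= 0.
#' @param intr A [camera_intrinsics()] object.
#' @param ext A [rigid_transform()]; default identity.
#' @return An `n x 3` matrix of (X, Y, Z) in mm.
#' @export
deproject <- function(x, y, d, intr, ext = rigid_transform()) {
  stopifnot(inherits(intr, "camera_intrinsics"),
            inherits(ext, "rigid_transform"),
            length(x) == length(y), length(x) == length(d))
  if (any(d < 0)) stop("depth must be >= 0", call. = FALSE)
  K <- build_K(intr)
  A <- solve(K) %*% ext$R                     # 3x3
  hom <- rbind(x, y, 1)                       # 3xn
  P <- t(A %*% hom) * d                       # nx3, rows d * K^-1 R (x,y,1)'
  P <- sweep(P, 2, ext$t, "+")
  colnames(P) <- c("X", "Y", "Z")
  P
}

#' Project 3D points back to pixels and depth
#'
#' Exact algebraic inverse of [deproject()]: recovers the corrected
#' pixel coordinates and depth that map to a given scene point. Points
#' at or behind the camera center (non-positive depth after removing
#' the extrinsics) are out of view.
#'
#' @param P An `n x 3` matrix (or length-3 vector) of (X, Y, Z), mm.
#' @param intr A [camera_intrinsics()] object.
#' @param ext A [rigid_transform()]; default identity.
#' @return An `n x 3` matrix with columns `x`, `y`, `d`.
#' @export
project <- function(P, intr, ext = rigid_transform()) {
  if (is.null(dim(P))) P <- matrix(P, nrow = 1)
  stopifnot(ncol(P) == 3L, inherits(intr, "camera_intrinsics"))
  K <- build_K(intr)
  # invert P = d K^-1 R (x,y,1)' + t:  R'K(P - t) = d (x,y,1)'
  M <- t(ext$R) %*% K
  Q <- sweep(P, 2, ext$t, "-")
  H <- Q %*% t(M)
  d <- H[, 3]
  if (any(d <= 0)) {
    stop("point at or behind the camera: out of view", call. = FALSE)
  }
  out <- cbind(x = H[, 1] / d, y = H[, 2] / d, d = d)
  out
}

#' Read or write camera intrinsics as YAML
#'
#' Intrinsics are stored as a flat YAML block with keys `f, mx, my, s,
#' px, py, kappas, xc, yc, height, width`; the loader validates the
#' [camera_intrinsics()] invariants.
#'
#' @param path File path.
#' @param intr A [camera_intrinsics()] object (for writing).
#' @return `read_intrinsics()` returns a [camera_intrinsics()];
#'   `write_intrinsics()` returns `path` invisibly.
#' @export
read_intrinsics <- function(path) {
  y <- yaml::read_yaml(path)
  need <- c("f", "mx", "my", "height", "width")
  miss <- setdiff(need, names(y))
  if (length(miss)) {
    stop("intrinsics file missing fields: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  camera_intrinsics(
    f = y$f, mx = y$mx, my = y$my,
    s = y$s %||% 0, px = y$px %||% 0, py = y$py %||% 0,
    kappas = as.numeric(unlist(y$kappas %||% numeric(0))),
    xc = y$xc %||% 0, yc = y$yc %||% 0,
    height = y$height, width = y$width
  )
}

#' @rdname read_intrinsics
#' @export
write_intrinsics <- function(intr, path) {
  stopifnot(inherits(intr, "camera_intrinsics"))
  yaml::write_yaml(unclass(intr), path)
  invisible(path)
}
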