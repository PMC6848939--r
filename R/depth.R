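#' RGBD frame container
#'
#' One aligned colour image + depth map from the overhead camera, with
#' capture metadata. Colour is an `H x W x 3` array with 8-bit channel
#' values in `[0, 255]`; depth is an `H x W` numeric matrix in integer
#' millimetres with `0` encoding missing data (sensor holes and, after
#' line masking, tray-grid pixels).
#'
#' @param color `H x W x 3` array, channel values in `[0, 255]`.
#' @param depth `H x W` matrix, mm; `0` = missing.
#' @param das Day-after-sowing index of the capture.
#' @param rack_id Rack identifier.
#' @param density_class `"high"` or `"low"` planting density.
#' @param frame_index Capture ordinal within the day.
#' @return An object of class `rgbd_frame`.
#' @export
rgbd_frame <- function(color, depth, das = NA_integer_,
                       rack_id = NA_character_,
                       density_class = NA_character_,
                       frame_index = 1L) {
  stopifnot(length(dim(color)) == 3L, dim(color)[3] == 3L,
            is.matrix(depth))
  if (!all(dim(color)[1:2] == dim(depth))) {
    stop("color and depth must share the same H x W", call. = FALSE)
  }
  if (any(depth < 0) || any(!is.finite(depth))) {
    stop("depth values must be finite and >= 0", call. = FALSE)
  }
  if (min(color) < 0 || max(color) > 255) {
    stop("color channels must lie in [0, 255]", call. = FALSE)
  }
  structure(list(color = color, depth = depth, das = das,
                 rack_id = rack_id, density_class = density_class,
                 frame_index = frame_index),
            class = "rgbd_frame")
}

#' @export
print.rgbd_frame <- function(x, ...) {
  cat(sprintf("<rgbd_frame> %d x %d px, DAS %s, rack %s (%s density)\n",
              nrow(x$depth), ncol(x$depth), x$das, x$rack_id,
              x$density_class))
  cat(sprintf("  depth: %.0f-%.0f mm, %.1f%% missing\n",
              suppressWarnings(min(x$depth[x$depth > 0])), max(x$depth),
              100 * mean(x$depth == 0)))
  invisible(x)
}

#' Merge consecutive depth frames
#'
#' The camera is fixed, but flickering illumination and ventilation move
#' the leaves between captures, so single depth maps are sparse and
#' noisy. Merging the non-zero samples of consecutive frames per pixel
#' fills holes (a pixel stays missing only if it is missing in every
#' frame) and suppresses noise. The default aggregator is the median,
#' robust to inter-frame jitter; the mean is available.
#'
#' @param frames List of `H x W` depth matrices (or `rgbd_frame`s, whose
#'   depth is taken), all the same shape; mm, `0` = missing.
#' @param aggregator `"median"` (default) or `"mean"`, applied per pixel
#'   over the non-zero samples.
#' @return A merged `H x W` depth matrix.
#' @export
merge_depth_frames <- function(frames, aggregator = c("median", "mean")) {
  aggregator <- match.arg(aggregator)
  if (!is.list(frames) || length(frames) == 0L) {
    stop("`frames` must be a non-empty list of depth maps", call. = FALSE)
  }
  mats <- lapply(frames, function(f) {
    if (inherits(f, "rgbd_frame")) f$depth else f
  })
  dims <- vapply(mats, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("all depth maps must share the same shape", call. = FALSE)
  }
  if (length(mats) == 1L) return(mats[[1]])
  V <- vapply(mats, as.numeric, numeric(prod(dims[, 1])))  # pixels x frames
  V[V == 0] <- NA_real_
  agg <- if (aggregator == "median") {
    matrixStats::rowMedians(V, na.rm = TRUE)
  } else {
    rowMeans(V, na.rm = TRUE)
  }
  agg[is.nan(agg) | is.na(agg)] <- 0
  matrix(agg, dims[1, 1], dims[2, 1])
}

# Normalized 2D Gaussian kernel, odd size.
gaussian_kernel <- function(size, sigma) {
  stopifnot(size %% 2 == 1, sigma > 0)
  h <- (size - 1) / 2
  g <- exp(-(-h:h)^2 / (2 * sigma^2))
  k <- outer(g, g)
  k / sum(k)
}

#' Smooth a depth map with a masked Gaussian kernel
#'
#' Convolves the depth map with a normalized Gaussian kernel (default
#' 11 x 11, sigma 1.3). Zero pixels are semantic missing data (sensor
#' holes, grid-line pixels): they are excluded from the weighted
#' average and remain zero in the output, so smoothing never leaks the
#' missing-data code into heights nor biases heights downward.
#'
#' @param M `H x W` depth matrix, mm; `0` = missing.
#' @param size Odd kernel size in pixels, default 11.
#' @param sigma Gaussian standard deviation in pixels, default 1.3.
#' @return Smoothed depth matrix, zeros preserved.
#' @export
smooth_depth <- function(M, size = 11L, sigma = 1.3) {
  stopifnot(is.matrix(M))
  if (size %% 2 == 0) stop("kernel `size` must be odd", call. = FALSE)
  k <- gaussian_kernel(size, sigma)
  valid <- (M != 0) * 1
  num <- EBImage::filter2(M, k, boundary = 0)
  den <- EBImage::filter2(valid, k, boundary = 0)
  out <- matrix(0, nrow(M), ncol(M))
  ok <- valid == 1 & den > 0
  out[ok] <- num[ok] / den[ok]
  out
}

#' Read and write depth maps and colour images as PNG
#'
#' Depth maps are stored as 16-bit single-channel PNG with the pixel
#' value equal to the range in mm; colour images as ordinary 8-bit PNG.
#'
#' @param path PNG file path.
#' @param M Depth matrix, mm (values must fit in 16 bits).
#' @param img Colour array `H x W x 3` in `[0, 255]`.
#' @return Readers return the matrix/array; writers return `path`
#'   invisibly.
#' @export
read_depth_png <- function(path) {
  v <- png::readPNG(path)
  if (length(dim(v)) == 3L) v <- v[, , 1]
  round(v * 65535)
}

# Table-driven CRC-32 (ISO 3309, as used by PNG chunks), computed in
# unsigned-double arithmetic (values < 2^32; XOR on 16-bit halves).
xor32 <- function(a, b) {
  bitwXor(as.integer(a %/% 65536), as.integer(b %/% 65536)) * 65536 +
    bitwXor(as.integer(a %% 65536), as.integer(b %% 65536))
}

crc32_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      t <- numeric(256)
      for (n in 0:255) {
        cc <- n
        for (k in 1:8) {
          cc <- if (cc %% 2 == 1) xor32(3988292384, cc %/% 2) else cc %/% 2
        }
        t[n + 1L] <- cc
      }
      tab <<- t
    }
    tab
  }
})

crc32_raw <- function(r) {
  tab <- crc32_table()
  cc <- 4294967295
  for (b in as.integer(r)) {
    idx <- bitwXor(as.integer(cc %% 256), b)
    cc <- xor32(tab[idx + 1L], cc %/% 256)
  }
  u <- xor32(cc, 4294967295)
  as.raw(c(u %/% 16777216, (u %/% 65536) %% 256, (u %/% 256) %% 256,
           u %% 256))
}

uint32_be <- function(v) {
  as.raw(c(v %/% 16777216, (v %/% 65536) %% 256, (v %/% 256) %% 256,
           v %% 256))
}

png_chunk <- function(type, data) {
  body <- c(charToRaw(type), data)
  c(uint32_be(length(data)), body, crc32_raw(body))
}

#' @rdname read_depth_png
#' @export
write_depth_png <- function(M, path) {
  stopifnot(is.matrix(M), all(M >= 0), all(M <= 65535))
  # 16-bit grayscale PNG, written directly (the installed PNG writers
  # quantize to 8 bits, which would truncate depths to 257 mm steps)
  H <- nrow(M); W <- ncol(M)
  v <- as.integer(round(t(M)))                    # row-major scan order
  hi <- as.raw(v %/% 256L); lo <- as.raw(v %% 256L)
  sl <- matrix(raw(1), nrow = 2L * W + 1L, ncol = H)  # filter byte 0 + data
  sl[2L * (1:W), ] <- matrix(hi, nrow = W, byrow = FALSE)
  sl[2L * (1:W) + 1L, ] <- matrix(lo, nrow = W, byrow = FALSE)
  scan <- as.vector(sl)
  idat <- memCompress(scan, type = "gzip")        # zlib stream (RFC 1950)
  ihdr <- c(uint32_be(W), uint32_be(H),
            as.raw(c(16L, 0L, 0L, 0L, 0L)))      # 16-bit, grayscale
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x89, 0x50, 0x4e, 0x47, 0x0d, 0x0a, 0x1a, 0x0a)), con)
  writeBin(png_chunk("IHDR", ihdr), con)
  writeBin(png_chunk("IDAT", idat), con)
  writeBin(png_chunk("IEND", raw(0)), con)
  invisible(path)
}

#' @rdname read_depth_png
#' @export
read_color_png <- function(path) {
  v <- png::readPNG(path)
  if (length(dim(v)) == 2L) v <- array(rep(v, 3), dim = c(dim(v), 3))
  round(v[, , 1:3] * 255)
}

#' @rdname read_depth_png
#' @export
write_color_png <- function(img, path) {
  stopifnot(length(dim(img)) == 3L)
  png::writePNG(img[, , 1:3] / 255, path)
  invisible(path)
}

#' Frame-sequence manifests
#'
#' A manifest is a YAML list of frames: each entry carries the colour
#' and depth PNG paths plus `das`, `rack_id`, `density_class` and
#' `frame_index`. `read_frame_manifest()` returns a tibble (one row per
#' frame) suitable for dplyr grouping by day; `load_frames()` reads the
#' referenced PNGs into `rgbd_frame`s.
#'
#' @param path Manifest YAML path.
#' @param manifest Tibble as returned by `read_frame_manifest()`.
#' @param root Directory against which relative paths resolve.
#' @return `read_frame_manifest()`: a tibble with columns `color`,
#'   `depth`, `das`, `rack_id`, `density_class`, `frame_index`.
#'   `load_frames()`: a list of [rgbd_frame()].
#' @export
read_frame_manifest <- function(path) {
  y <- yaml::read_yaml(path)
  frames <- y$frames %||% y
  purrr::map_dfr(frames, function(f) {
    tibble::tibble(
      color = f$color, depth = f$depth,
      das = as.integer(f$das %||% NA),
      rack_id = as.character(f$rack_id %||% NA),
      density_class = as.character(f$density_class %||% NA),
      frame_index = as.integer(f$frame_index %||% 1L)
    )
  })
}

#' @rdname read_frame_manifest
#' @export
write_frame_manifest <- function(manifest, path) {
  frames <- purrr::pmap(manifest, function(...) list(...))
  yaml::write_yaml(list(frames = frames), path)
  invisible(path)
}

#' @rdname read_frame_manifest
#' @export
load_frames <- function(manifest, root = ".") {
  purrr::pmap(manifest, function(color, depth, das, rack_id,
                                 density_class, frame_index, ...) {
    rgbd_frame(read_color_png(file.path(root, color)),
               read_depth_png(file.path(root, depth)),
               das = das, rack_id = rack_id,
               density_class = density_class,
               frame_index = frame_index)
  })
}
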