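#' Segment surface leaves in a colour image
#'
#' Produces per-leaf instance masks, each tagged with a unique colour
#' id. Segmentation is a pluggable backend: any function taking the
#' colour array and returning an integer label matrix (0 = background)
#' can be supplied, so a deep instance-segmentation model can attach
#' through the same interface. The bundled classical fallback
#' (`backend = "threshold"`) marks green-dominant pixels and splits
#' touching blobs with a distance-transform watershed.
#'
#' Leaves occluded by more than about 60% of their area are outside the
#' measurement contract: no backend promises to recover them.
#'
#' @param img `H x W x 3` colour array in `[0, 255]`.
#' @param backend `"threshold"` (default) or a function
#'   `function(img) -> integer label matrix`.
#' @param green_margin Fallback: minimum excess of the green channel
#'   over the other channels, default 20.
#' @param min_pixels Fallback: blobs smaller than this are dropped,
#'   default 40.
#' @param watershed_tolerance Fallback: watershed merge tolerance on the
#'   distance transform, default 1.
#' @param size_split Leaf pixel count separating `"small"` from
#'   `"large"` size classes, default 600.
#' @return List of `leaf_mask` objects: `mask` (logical `H x W`),
#'   `mask_color` (unique RGB triple), `size_class`, `confidence`.
#'   Empty list when no leaf pixels are present.
#' @export
segment_leaves <- function(img, backend = "threshold", green_margin = 20,
                           min_pixels = 40, watershed_tolerance = 1,
                           size_split = 600) {
  stopifnot(length(dim(img)) == 3L)
  labels <- if (is.function(backend)) {
    backend(img)
  } else if (identical(backend, "threshold")) {
    green <- img[, , 2] - pmax(img[, , 1], img[, , 3])
    fg <- green > green_margin
    if (!any(fg)) {
      matrix(0L, dim(img)[1], dim(img)[2])
    } else {
      # bright leaf cores as seeds: the darker leaf margins separate
      # touching leaves, so each sunlit blade interior is one seed;
      # propagate the seeds over the full green support. Without
      # usable cores, fall back to a distance-transform watershed.
      core <- fg & img[, , 2] > 120
      seeds <- if (any(core)) EBImage::bwlabel(core) else NULL
      if (!is.null(seeds) && max(seeds) >= 1L) {
        counts <- tabulate(seeds[seeds > 0L])
        drop <- which(counts < 10L)
        if (length(drop)) seeds[seeds %in% drop] <- 0L
      }
      if (!is.null(seeds) && max(seeds) >= 1L) {
        lb <- EBImage::propagate(EBImage::distmap(fg * 1), seeds,
                                 mask = fg)
        matrix(as.integer(lb), dim(img)[1], dim(img)[2])
      } else {
        dm <- EBImage::distmap(fg * 1)
        EBImage::watershed(dm, tolerance = watershed_tolerance)
      }
    }
  } else {
    stop("unknown segmentation backend", call. = FALSE)
  }
  ids <- sort(unique(as.integer(labels)))
  ids <- ids[ids > 0L]
  counts <- tabulate(labels[labels > 0L])
  ids <- ids[counts[ids] >= min_pixels]
  purrr::imap(ids, function(id, ord) {
    npx <- counts[id]
    leaf_mask(mask = labels == id,
              mask_color = leaf_color(ord),
              size_class = if (npx >= size_split) "large" else "small",
              confidence = 1)
  })
}

# Distinct 8-bit colour key for leaf j (avoids 0,0,0 = background).
leaf_color <- function(j) {
  c(R = (37 * j) %% 256, G = (101 * j + 64) %% 256, B = (197 * j + 128) %% 256)
}

#' Leaf instance mask
#'
#' @param mask Logical `H x W` matrix, `TRUE` on the leaf.
#' @param mask_color Length-3 RGB colour id, unique within an image.
#' @param size_class `"large"` or `"small"`.
#' @param confidence Backend confidence in `[0, 1]`.
#' @return Object of class `leaf_mask`.
#' @export
leaf_mask <- function(mask, mask_color, size_class = "large",
                      confidence = 1) {
  stopifnot(is.matrix(mask), any(mask), length(mask_color) == 3L,
            size_class %in% c("large", "small"),
            confidence >= 0, confidence <= 1)
  structure(list(mask = mask, mask_color = as.integer(mask_color),
                 size_class = size_class, confidence = confidence),
            class = "leaf_mask")
}

#' @export
print.leaf_mask <- function(x, ...) {
  cat(sprintf("<leaf_mask> %d px, %s, colour (%d,%d,%d), conf %.2f\n",
              sum(x$mask), x$size_class, x$mask_color[1], x$mask_color[2],
              x$mask_color[3], x$confidence))
  invisible(x)
}

#' Project leaf masks onto the point cloud
#'
#' Deprojects the depth map and labels every 3D point whose source
#' pixel lies inside a mask with that mask's leaf id — the mask colours
#' act as an indicator function on the cloud, so a leaf can later be
#' pulled out of the cloud by selecting its colour. Mask pixels with
#' zero depth produce no point and are counted.
#'
#' @param masks List of [leaf_mask()] objects.
#' @param M `H x W` depth matrix, mm.
#' @param C Optional aligned colour image.
#' @param intr A [camera_intrinsics()].
#' @param ext A [rigid_transform()].
#' @return A labelled cloud: point-cloud tibble with columns `leaf_id`
#'   (integer, `NA` off-leaf), `px_x`, `px_y`; attribute
#'   `skipped_mask_pixels` counts mask pixels lost to missing depth.
#' @export
project_masks_to_cloud <- function(masks, M, C = NULL, intr,
                                   ext = rigid_transform()) {
  cloud <- depth_to_cloud(M, C, intr, ext)
  lab <- matrix(NA_integer_, nrow(M), ncol(M))
  skipped <- 0L
  for (j in seq_along(masks)) {
    mk <- masks[[j]]$mask
    if (!all(dim(mk) == dim(M))) {
      stop("mask and depth map are not aligned", call. = FALSE)
    }
    lab[mk] <- j
    skipped <- skipped + sum(mk & M == 0)
  }
  cloud$leaf_id <- lab[cbind(cloud$px_y + 1L, cloud$px_x + 1L)]
  if (length(masks)) {
    cols <- t(vapply(masks, `[[`, integer(3), "mask_color"))
    on_leaf <- !is.na(cloud$leaf_id)
    cloud$R[on_leaf] <- cols[cloud$leaf_id[on_leaf], 1]
    cloud$G[on_leaf] <- cols[cloud$leaf_id[on_leaf], 2]
    cloud$B[on_leaf] <- cols[cloud$leaf_id[on_leaf], 3]
  }
  attr(cloud, "skipped_mask_pixels") <- skipped
  cloud
}

#' Per-point surface normals from k-nearest neighbours
#'
#' Estimates the unit normal at each point as the smallest-eigenvalue
#' eigenvector of the covariance of its `k` nearest neighbours (a local
#' plane fit). Normals are oriented toward the camera (negative-Z
#' hemisphere; the camera looks down +Z).
#'
#' @param cloud Point-cloud tibble.
#' @param k Neighbourhood size, default 12 (>= 3).
#' @return List of class `normal_field`: `normals` (`N x 3`, unit
#'   rows), `k`, `mean_knn_radius` (mm; mean distance to the k-th
#'   neighbour, the local length scale).
#' @export
estimate_normals <- function(cloud, k = 12L) {
  P <- as.matrix(cloud[, c("X", "Y", "Z")])
  n <- nrow(P)
  if (k < 3L) stop("k must be >= 3", call. = FALSE)
  if (n < k) stop("cloud has fewer points than k", call. = FALSE)
  nn <- RANN::nn2(P, P, k = k)
  N <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    Q <- P[nn$nn.idx[i, ], , drop = FALSE]
    Qc <- sweep(Q, 2, colMeans(Q))
    ev <- eigen(crossprod(Qc), symmetric = TRUE)
    v <- ev$vectors[, 3]
    if (v[3] > 0) v <- -v
    N[i, ] <- v / sqrt(sum(v^2))
  }
  structure(list(normals = N, k = as.integer(k),
                 mean_knn_radius = mean(nn$nn.dists[, k])),
            class = "normal_field")
}

#' Grow a leaf label across a disocclusion boundary
#'
#' A leaf occluded in the RGB image may be partly visible in 3D, but
#' the instance mask does not extend over the disoccluded part. This
#' operation grows the leaf label outward from its boundary: an
#' unlabelled point `P'` near a boundary point `P` is absorbed when its
#' best cost
#' \deqn{w_n(P, P') = \kappa D(P, P') + (1 - \kappa)(1 - n_P \cdot n_{P'})}
#' over the boundary falls below `w_threshold`. `D` is the Euclidean
#' distance normalized by the cloud's mean k-NN radius, so both terms
#' are dimensionless: nearby points on a surface with matching normals
#' are absorbed, while points on perpendicular surfaces are not.
#' Growth iterates until no candidate qualifies; points already
#' labelled by another leaf are never taken.
#'
#' The cosine term uses `1 - n . n'` so that aligned normals are cheap;
#' `as_printed = TRUE` switches to the raw dot product `n . n'` form.
#'
#' @param lab Labelled cloud from [project_masks_to_cloud()].
#' @param normals A [estimate_normals()] result for the same cloud.
#' @param leaf_id Leaf label to grow.
#' @param kappa Distance/normal trade-off in `[0, 1]`, default 0.5.
#' @param w_threshold Absorption threshold, default 0.3 (empirical).
#' @param as_printed Use the raw dot-product cosine term.
#' @param max_iter Safety cap on growth sweeps, default 100.
#' @return The labelled cloud with the leaf label grown; attribute
#'   `n_absorbed` counts the points added.
#' @export
extend_occluded_leaf <- function(lab, normals, leaf_id, kappa = 0.5,
                                 w_threshold = 0.3, as_printed = FALSE,
                                 max_iter = 100L) {
  stopifnot(inherits(normals, "normal_field"))
  if (!leaf_id %in% lab$leaf_id) {
    stop("unknown leaf_id: ", leaf_id, call. = FALSE)
  }
  P <- as.matrix(lab[, c("X", "Y", "Z")])
  N <- normals$normals
  scale <- normals$mean_knn_radius
  k <- normals$k
  nn <- RANN::nn2(P, P, k = k)
  labels <- lab$leaf_id
  n_absorbed <- 0L
  for (it in seq_len(max_iter)) {
    on_leaf <- which(!is.na(labels) & labels == leaf_id)
    # boundary: leaf points with an unlabelled neighbour
    nb_lab <- matrix(labels[nn$nn.idx[on_leaf, , drop = FALSE]],
                     nrow = length(on_leaf))
    is_b <- rowSums(is.na(nb_lab)) > 0
    b <- on_leaf[is_b]
    if (!length(b)) break
    # candidates: unlabelled neighbours of boundary points
    cand <- unique(as.vector(nn$nn.idx[b, , drop = FALSE]))
    cand <- cand[is.na(labels[cand])]
    if (!length(cand)) break
    # cost: per candidate, minimum over boundary points
    D <- sqrt(outer(rowSums(P[cand, , drop = FALSE]^2),
                    rowSums(P[b, , drop = FALSE]^2), "+") -
                2 * P[cand, , drop = FALSE] %*% t(P[b, , drop = FALSE]))
    D <- pmax(D, 0) / scale
    dot <- N[cand, , drop = FALSE] %*% t(N[b, , drop = FALSE])
    cosv <- if (as_printed) dot else 1 - dot
    w <- kappa * D + (1 - kappa) * cosv
    wstar <- apply(w, 1, min)
    take <- cand[wstar < w_threshold]
    if (!length(take)) break
    labels[take] <- leaf_id
    n_absorbed <- n_absorbed + length(take)
  }
  lab$leaf_id <- labels
  attr(lab, "n_absorbed") <- n_absorbed
  lab
}

#' Leaf masks I/O: indexed label PNG + JSON sidecar
#'
#' The label image stores leaf index / 255 in a grayscale PNG
#' (0 = background); the sidecar records each leaf's colour id, size
#' class and confidence.
#'
#' @param masks List of [leaf_mask()] objects.
#' @param png_path,json_path Output paths.
#' @return `read_leaf_masks()` returns the list of masks;
#'   `write_leaf_masks()` returns `png_path` invisibly.
#' @export
write_leaf_masks <- function(masks, png_path, json_path) {
  if (length(masks) > 255L) stop("more than 255 leaves", call. = FALSE)
  dm <- dim(masks[[1]]$mask)
  lab <- matrix(0L, dm[1], dm[2])
  for (j in seq_along(masks)) lab[masks[[j]]$mask] <- j
  png::writePNG(lab / 255, png_path)
  side <- purrr::imap(masks, function(m, j) {
    list(leaf_id = j, mask_color = as.integer(m$mask_color),
         size_class = m$size_class, confidence = m$confidence)
  })
  jsonlite::write_json(side, json_path, auto_unbox = TRUE, digits = NA)
  invisible(png_path)
}

#' @rdname write_leaf_masks
#' @export
read_leaf_masks <- function(png_path, json_path) {
  lab <- round(png::readPNG(png_path) * 255)
  if (length(dim(lab)) == 3L) lab <- lab[, , 1]
  side <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  purrr::map(seq_len(nrow(side)), function(j) {
    leaf_mask(mask = lab == side$leaf_id[j],
              mask_color = unlist(side$mask_color[j]),
              size_class = side$size_class[j],
              confidence = side$confidence[j])
  })
}
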