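#' Leaf surface meshes
#'
#' A leaf's labelled 3D points are near-planar at the imaged growth
#' stages, so surfaces are parameterized over the leaf's principal
#' plane (covariance eigenvectors) and reconstructed either as a 2.5D
#' Delaunay triangulation or as a regular quadrilateral grid relaxed
#' onto the points with a spring energy. The leaf area is the sum of
#' the per-face areas.
#'
#' @name leaf_surface
NULL

# Principal-plane frame: center, two in-plane axes, normal.
principal_plane <- function(P) {
  ctr <- colMeans(P)
  Q <- sweep(P, 2, ctr)
  ev <- eigen(crossprod(Q) / nrow(P), symmetric = TRUE)
  list(center = ctr, e1 = ev$vectors[, 1], e2 = ev$vectors[, 2],
       e3 = ev$vectors[, 3], lambda = ev$values)
}

# Parameterize points in the plane frame: columns u, v, w.
plane_coords <- function(P, frame) {
  Q <- sweep(P, 2, frame$center)
  cbind(u = Q %*% frame$e1, v = Q %*% frame$e2, w = Q %*% frame$e3)
}

# Robustly trim points far from the leaf's dominant plane: mask
# boundaries pick up pixels of the understory or of lower leaves
# several mm off-plane, which would corrupt the fitted surface. Two
# passes of a median/MAD filter on the normal displacement.
trim_points_to_plane <- function(P, nsig = 4, floor_mm = 1.5) {
  for (pass in 1:2) {
    if (nrow(P) < 4L) return(P)
    fr <- principal_plane(P)
    w <- plane_coords(P, fr)[, 3]
    med <- stats::median(w)
    lim <- max(nsig * stats::mad(w), floor_mm)
    keep <- abs(w - med) <= lim
    if (all(keep)) return(P)
    P <- P[keep, , drop = FALSE]
  }
  P
}

leaf_surface_mesh <- function(vertices, faces, mesh_kind,
                              quad_size = NA_real_, grid_dim = NULL,
                              frame = NULL, origin = NULL,
                              converged = TRUE) {
  areas <- face_areas(vertices, faces)
  structure(list(vertices = vertices, faces = faces,
                 face_areas = areas, total_area = sum(areas),
                 mesh_kind = mesh_kind, quad_size = quad_size,
                 grid_dim = grid_dim, frame = frame, origin = origin,
                 converged = converged),
            class = "leaf_surface_mesh")
}

#' @export
print.leaf_surface_mesh <- function(x, ...) {
  cat(sprintf("<leaf_surface_mesh> %s: %d vertices, %d faces, area %.2f mm^2\n",
              x$mesh_kind, nrow(x$vertices), nrow(x$faces), x$total_area))
  if (!x$converged) cat("  (relaxation did not converge)\n")
  invisible(x)
}

# Triangle area by cross product; quads split along (1,3).
face_areas <- function(V, F) {
  tri_area <- function(a, b, c) {
    u <- V[b, , drop = FALSE] - V[a, , drop = FALSE]
    w <- V[c, , drop = FALSE] - V[a, , drop = FALSE]
    cx <- u[, 2] * w[, 3] - u[, 3] * w[, 2]
    cy <- u[, 3] * w[, 1] - u[, 1] * w[, 3]
    cz <- u[, 1] * w[, 2] - u[, 2] * w[, 1]
    0.5 * sqrt(cx^2 + cy^2 + cz^2)
  }
  if (ncol(F) == 3L) {
    tri_area(F[, 1], F[, 2], F[, 3])
  } else {
    tri_area(F[, 1], F[, 2], F[, 3]) + tri_area(F[, 1], F[, 3], F[, 4])
  }
}

#' Triangulate a leaf point set
#'
#' Projects the points onto their principal plane, builds a Delaunay
#' triangulation there, and lifts the triangles back to 3D; the area is
#' the sum of 3D triangle areas. Dense clouds are subsampled to
#' `max_points` first (area converges well before that).
#'
#' @param points `n x 3` matrix or point-cloud tibble of leaf points,
#'   mm; n >= 3, non-collinear.
#' @param max_points Subsampling cap, default 4000.
#' @param trim Robustly drop points far off the leaf's dominant plane
#'   (stray understory/neighbour pixels at mask borders); default
#'   `TRUE`.
#' @param smooth_k Neighbourhood size for smoothing the normal
#'   displacement before lifting the triangles (depth quantization and
#'   residual noise otherwise inflate the area of small triangles);
#'   default 8, `0` disables.
#' @return A `leaf_surface_mesh` with `mesh_kind = "tri"`.
#' @export
triangulate_leaf <- function(points, max_points = 4000L, trim = TRUE,
                             smooth_k = 8L) {
  P <- if (is.matrix(points)) points else
    as.matrix(points[, c("X", "Y", "Z")])
  if (nrow(P) < 3L) stop("need at least 3 points", call. = FALSE)
  if (trim && nrow(P) >= 8L) P <- trim_points_to_plane(P)
  if (nrow(P) > max_points) {
    P <- P[sort(sample.int(nrow(P), max_points)), , drop = FALSE]
  }
  fr <- principal_plane(P)
  if (fr$lambda[2] < 1e-12 * max(fr$lambda[1], 1)) {
    stop("degenerate leaf: points are collinear", call. = FALSE)
  }
  uv <- plane_coords(P, fr)
  if (smooth_k >= 3L && nrow(P) > smooth_k + 1L) {
    nn <- RANN::nn2(uv[, 1:2], uv[, 1:2], k = smooth_k)
    w_s <- rowMeans(matrix(uv[nn$nn.idx, 3], nrow = nrow(uv)))
    P <- matrix(rep(fr$center, each = nrow(uv)), ncol = 3) +
      outer(uv[, 1], fr$e1) + outer(uv[, 2], fr$e2) + outer(w_s, fr$e3)
  }
  # deldir drops exact duplicates; ind.orig maps retained points back
  dd <- deldir::deldir(uv[, 1], uv[, 2], suppressMsge = TRUE)
  tl <- deldir::triang.list(dd)
  if (!length(tl)) stop("degenerate leaf: no triangulation", call. = FALSE)
  F <- t(vapply(tl, function(tr) as.integer(tr$ptNum), integer(3)))
  V <- P[dd$ind.orig, , drop = FALSE]
  leaf_surface_mesh(V, F, mesh_kind = "tri", frame = fr)
}

# Grid topology helpers for the quad mesh: faces indexed (fi, fj) over
# an (nu x nv) cell grid; vertices (nu+1) x (nv+1).
quad_vertex_index <- function(i, j, nvert_u) (j - 1L) * nvert_u + i

#' Fit a spring-relaxed quadrilateral mesh to leaf points
#'
#' Initializes a regular quad grid at pitch `quad_size` on the leaf's
#' principal-plane bounding box, then relaxes the grid vertices with
#' damped Gauss-Seidel sweeps minimizing a data-fidelity term (squared
#' distance of each vertex to the mean of its nearest data points) plus
#' a spring term (squared deviation of every edge length from
#' `quad_size`). The energy is kept non-increasing by step halving;
#' iteration stops when the largest vertex motion drops below `tol`.
#'
#' `quad_size` controls the smoothness/fit trade-off: smaller quads
#' follow the leaf boundary and curvature more closely at higher cost.
#'
#' @param points `n x 3` matrix or point-cloud tibble, n >= 4.
#' @param quad_size Grid pitch, mm; default 2 (leaf scale is 20-60 mm).
#' @param relax_iters Maximum relaxation sweeps, default 500.
#' @param tol Vertex-motion convergence threshold, mm; default 1e-3.
#' @param damping Step damping in (0, 1], default 0.5.
#' @param spring_weight Weight of the spring term, default 1.
#' @param prune If `TRUE` (default) remove empty boundary quads after
#'   relaxation (see [prune_boundary_quads()]).
#' @param max_points Subsampling cap for the fidelity search,
#'   default 4000.
#' @param trim Robustly drop points far off the leaf's dominant plane;
#'   default `TRUE`.
#' @return A `leaf_surface_mesh` with `mesh_kind = "quad"`.
#' @export
fit_quad_mesh <- function(points, quad_size = 2, relax_iters = 500L,
                          tol = 1e-3, damping = 0.5, spring_weight = 1,
                          prune = TRUE, max_points = 4000L, trim = TRUE) {
  P <- if (is.matrix(points)) points else
    as.matrix(points[, c("X", "Y", "Z")])
  if (nrow(P) < 4L) stop("need at least 4 points", call. = FALSE)
  if (quad_size <= 0) stop("`quad_size` must be > 0", call. = FALSE)
  if (trim && nrow(P) >= 8L) P <- trim_points_to_plane(P)
  P_full <- P
  if (nrow(P) > max_points) {
    P <- P[sort(sample.int(nrow(P), max_points)), , drop = FALSE]
  }
  fr <- principal_plane(P)
  uvw <- plane_coords(P, fr)
  ur <- range(uvw[, 1]); vr <- range(uvw[, 2])
  nu <- max(1L, ceiling((ur[2] - ur[1]) / quad_size))
  nv <- max(1L, ceiling((vr[2] - vr[1]) / quad_size))
  us <- ur[1] + (0:nu) * quad_size
  vs <- vr[1] + (0:nv) * quad_size
  nvert_u <- nu + 1L
  gu <- rep(us, times = nv + 1L)
  gv <- rep(vs, each = nu + 1L)
  # vertices in 3D, initialized on the principal plane
  V <- matrix(rep(fr$center, each = length(gu)), ncol = 3) +
    outer(gu, fr$e1) + outer(gv, fr$e2)
  # data fidelity, two zones by distance to the nearest data point:
  # vertices inside the data support (near a point) are pulled onto the
  # local tangent plane only — normal displacement, so the in-plane
  # grid pitch is preserved; vertices overhanging the support (the rim
  # of the grid bounding box outside the leaf) are pulled toward the
  # data boundary, so boundary quads contract to the true outline.
  m_loc <- min(8L, nrow(P))
  nnv <- RANN::nn2(P, V, k = m_loc)
  has_data <- nnv$nn.dists[, 1] <= 1.5 * quad_size
  has_plane <- has_pull <- logical(nrow(V))
  Ctr <- matrix(0, nrow(V), 3)
  Nrm <- matrix(0, nrow(V), 3)
  for (i in which(has_data)) {
    Q <- P[nnv$nn.idx[i, ], , drop = FALSE]
    cc <- colMeans(Q)
    n_i <- if (m_loc >= 3L) {
      ev <- eigen(crossprod(sweep(Q, 2, cc)), symmetric = TRUE)
      ev$vectors[, 3]
    } else fr$e3
    # interior vertices have data all around (in-plane centroid offset
    # small): glue them to the local tangent plane; rim vertices see
    # one-sided data: pull them onto the data boundary
    dlt <- cc - V[i, ]
    inplane <- dlt - sum(dlt * n_i) * n_i
    if (sqrt(sum(inplane^2)) <= 0.35 * quad_size) {
      has_plane[i] <- TRUE
      Ctr[i, ] <- cc
      Nrm[i, ] <- n_i
    } else {
      has_pull[i] <- TRUE
      Ctr[i, ] <- Q[1, ]              # snap to the nearest data point
    }
  }
  # edges of the grid
  ii <- rep(seq_len(nvert_u - 1L), times = nv + 1L)
  jj <- rep(seq_len(nv + 1L), each = nvert_u - 1L)
  e_h <- cbind(quad_vertex_index(ii, jj, nvert_u),
               quad_vertex_index(ii + 1L, jj, nvert_u))
  ii <- rep(seq_len(nvert_u), times = nv)
  jj <- rep(seq_len(nv), each = nvert_u)
  e_v <- cbind(quad_vertex_index(ii, jj, nvert_u),
               quad_vertex_index(ii, jj + 1L, nvert_u))
  E <- rbind(e_h, e_v)
  # edges touching a rim-snapped vertex are excluded from the spring
  # term: otherwise the boundary contraction would compress the whole
  # in-plane lattice below the nominal pitch
  E <- E[!has_pull[E[, 1]] & !has_pull[E[, 2]], , drop = FALSE]
  fid_dev <- function(V) {
    rowSums((V - Ctr) * Nrm)          # signed normal distance; 0 off-data
  }
  energy <- function(V) {
    d <- V[E[, 1], ] - V[E[, 2], ]
    el <- sqrt(rowSums(d^2))
    sum(fid_dev(V)[has_plane]^2) +
      sum((V[has_pull, , drop = FALSE] - Ctr[has_pull, , drop = FALSE])^2) +
      spring_weight * sum((el - quad_size)^2)
  }
  acc <- function(vals, idx, n) {
    out <- numeric(n)
    s <- rowsum(vals, idx)
    out[as.integer(rownames(s))] <- s
    out
  }
  grad <- function(V) {
    G <- 2 * fid_dev(V) * Nrm
    G[!has_plane, ] <- 0
    G[has_pull, ] <- 2 * (V[has_pull, , drop = FALSE] -
                            Ctr[has_pull, , drop = FALSE])
    d <- V[E[, 1], , drop = FALSE] - V[E[, 2], , drop = FALSE]
    el <- pmax(sqrt(rowSums(d^2)), 1e-12)
    f <- 2 * spring_weight * (el - quad_size) / el
    for (c3 in 1:3) {
      G[, c3] <- G[, c3] + acc(d[, c3] * f, E[, 1], nrow(V)) -
        acc(d[, c3] * f, E[, 2], nrow(V))
    }
    G
  }
  en <- energy(V)
  converged <- FALSE
  step <- damping * 0.25          # scaled: gradient has weight ~2-4
  for (it in seq_len(relax_iters)) {
    G <- grad(V)
    repeat {
      Vn <- V - step * G
      en_new <- energy(Vn)
      if (en_new <= en || step < 1e-8) break
      step <- step / 2
    }
    if (en_new > en) { converged <- TRUE; break }   # stuck: keep best
    motion <- max(abs(Vn - V))
    plateau <- (en - en_new) < 1e-9 * max(en, 1)
    V <- Vn; en <- en_new
    if (motion < tol || plateau) { converged <- TRUE; break }
    step <- min(step * 1.3, damping)  # grow while descent succeeds
  }
  if (!converged) {
    warning("quad-mesh relaxation did not converge; returning best iterate",
            call. = FALSE)
  }
  fi <- rep(seq_len(nu), times = nv)
  fj <- rep(seq_len(nv), each = nu)
  F <- cbind(quad_vertex_index(fi, fj, nvert_u),
             quad_vertex_index(fi + 1L, fj, nvert_u),
             quad_vertex_index(fi + 1L, fj + 1L, nvert_u),
             quad_vertex_index(fi, fj + 1L, nvert_u))
  mesh <- leaf_surface_mesh(V, F, mesh_kind = "quad",
                            quad_size = quad_size,
                            grid_dim = c(nu = nu, nv = nv), frame = fr,
                            origin = c(u0 = ur[1], v0 = vr[1]),
                            converged = converged)
  if (prune) prune_boundary_quads(mesh, P_full) else mesh
}

# Occupancy of quad faces: data points binned into the parameter-space
# grid cells the faces were initialized on.
quad_occupancy <- function(mesh, P) {
  fr <- mesh$frame
  uvw <- plane_coords(P, fr)
  nu <- mesh$grid_dim["nu"]; nv <- mesh$grid_dim["nv"]
  u0 <- mesh$origin["u0"]; v0 <- mesh$origin["v0"]
  ci <- pmin(pmax(floor((uvw[, 1] - u0) / mesh$quad_size) + 1L, 1L), nu)
  cj <- pmin(pmax(floor((uvw[, 2] - v0) / mesh$quad_size) + 1L, 1L), nv)
  occ <- matrix(FALSE, nu, nv)
  occ[cbind(ci, cj)] <- TRUE
  occ
}

#' Remove empty boundary quads
#'
#' Iteratively deletes faces that contain no data point, but only while
#' they sit on the current mesh boundary (a face with a missing
#' neighbour). Interior empty faces — holes left by occlusion — are
#' retained so the surface is not punctured. Terminates when every
#' boundary face is occupied.
#'
#' @param mesh A quad `leaf_surface_mesh` (from [fit_quad_mesh()]).
#' @param points The leaf data points used for occupancy.
#' @return The pruned mesh (per-face areas of retained faces are
#'   unchanged).
#' @export
prune_boundary_quads <- function(mesh, points) {
  stopifnot(inherits(mesh, "leaf_surface_mesh"),
            mesh$mesh_kind == "quad")
  P <- if (is.matrix(points)) points else
    as.matrix(points[, c("X", "Y", "Z")])
  nu <- mesh$grid_dim["nu"]; nv <- mesh$grid_dim["nv"]
  occ <- quad_occupancy(mesh, P)
  alive <- matrix(TRUE, nu, nv)
  pad <- function(m) {                    # FALSE border
    out <- matrix(FALSE, nrow(m) + 2L, ncol(m) + 2L)
    out[2:(nrow(m) + 1L), 2:(ncol(m) + 1L)] <- m
    out
  }
  repeat {
    a <- pad(alive)
    nbr_missing <- !(a[1:nu, 2:(nv + 1L)] & a[3:(nu + 2L), 2:(nv + 1L)] &
                       a[2:(nu + 1L), 1:nv] & a[2:(nu + 1L), 3:(nv + 2L)])
    kill <- alive & nbr_missing & !occ
    if (!any(kill)) break
    alive[kill] <- FALSE
  }
  keep <- as.vector(alive)                # faces were built column-major
  F <- mesh$faces[keep, , drop = FALSE]
  if (nrow(F) == 0L) {
    stop("pruning removed every face: no occupied quad", call. = FALSE)
  }
  leaf_surface_mesh(mesh$vertices, F, mesh_kind = "quad",
                    quad_size = mesh$quad_size,
                    grid_dim = mesh$grid_dim, frame = mesh$frame,
                    converged = mesh$converged)
}

#' Total mesh area
#'
#' Sum of per-face areas; quads are split into two triangles.
#'
#' @param mesh A `leaf_surface_mesh`.
#' @return Area in mm2.
#' @export
mesh_area <- function(mesh) {
  stopifnot(inherits(mesh, "leaf_surface_mesh"))
  if (nrow(mesh$faces) == 0L) stop("empty mesh", call. = FALSE)
  sum(face_areas(mesh$vertices, mesh$faces))
}

#' Write a mesh as OBJ (quads preserved) or PLY (triangulated)
#'
#' @param mesh A `leaf_surface_mesh`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mesh_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("v %.6f %.6f %.6f", mesh$vertices[, 1],
                     mesh$vertices[, 2], mesh$vertices[, 3]), con)
  writeLines(paste("f", apply(mesh$faces, 1, paste, collapse = " ")), con)
  invisible(path)
}

#' @rdname write_mesh_obj
#' @export
write_mesh_ply <- function(mesh, path) {
  F <- mesh$faces
  if (ncol(F) == 4L) {
    F <- rbind(F[, c(1, 2, 3)], F[, c(1, 3, 4)])
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(mesh$vertices)),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", nrow(F)),
               "property list uchar int vertex_indices",
               "end_header"), con)
  writeLines(sprintf("%.6f %.6f %.6f", mesh$vertices[, 1],
                     mesh$vertices[, 2], mesh$vertices[, 3]), con)
  writeLines(sprintf("3 %d %d %d", F[, 1] - 1L, F[, 2] - 1L, F[, 3] - 1L),
             con)
  invisible(path)
}
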