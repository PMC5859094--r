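#' Corner angles of every face from edge lengths
#'
#' Law-of-cosines angles for each face corner given a metric (per-edge
#' lengths). The default metric is the Euclidean 3D one.
#'
#' @param mesh a `TriMesh`.
#' @param edge_lengths numeric vector over [mesh_edges()] rows; default 3D.
#' @param et optional precomputed [mesh_edges()] result.
#' @return M x 3 matrix of angles (radians), column k = angle at face
#'   vertex k.
#' @export
corner_angles <- function(mesh, edge_lengths = NULL, et = NULL) {
  if (is.null(et)) et <- mesh_edges(mesh)
  if (is.null(edge_lengths)) edge_lengths <- edge_lengths_3d(mesh, et$edges)
  check_triangle_inequality(et, edge_lengths)
  # length of edge opposite corner k
  l1 <- edge_lengths[et$face_edges[, 1]]
  l2 <- edge_lengths[et$face_edges[, 2]]
  l3 <- edge_lengths[et$face_edges[, 3]]
  ang <- function(a, b, c) acos(pmin(1, pmax(-1, (b^2 + c^2 - a^2) / (2 * b * c))))
  cbind(ang(l1, l2, l3), ang(l2, l3, l1), ang(l3, l1, l2))
}

check_triangle_inequality <- function(et, edge_lengths) {
  l1 <- edge_lengths[et$face_edges[, 1]]
  l2 <- edge_lengths[et$face_edges[, 2]]
  l3 <- edge_lengths[et$face_edges[, 3]]
  bad <- l1 >= l2 + l3 | l2 >= l1 + l3 | l3 >= l1 + l2 |
    l1 <= 0 | l2 <= 0 | l3 <= 0
  if (any(bad))
    stop("metric error: triangle inequality violated on face(s) ",
         paste(utils::head(which(bad), 5), collapse = ", "))
  invisible(TRUE)
}

# TRUE when lengths are a valid metric, no error
metric_is_valid <- function(et, edge_lengths) {
  l1 <- edge_lengths[et$face_edges[, 1]]
  l2 <- edge_lengths[et$face_edges[, 2]]
  l3 <- edge_lengths[et$face_edges[, 3]]
  !any(l1 >= l2 + l3 | l2 >= l1 + l3 | l3 >= l1 + l2 |
         !is.finite(l1) | !is.finite(l2) | !is.finite(l3) |
         l1 <= 0 | l2 <= 0 | l3 <= 0)
}

#' Discrete Gaussian curvature (angle deficit)
#'
#' Interior vertices carry 2*pi minus the sum of incident corner angles;
#' boundary vertices carry the geodesic-curvature convention pi minus the
#' angle sum, so that the total over all vertices satisfies the discrete
#' Gauss-Bonnet identity sum(K) = 2*pi*chi exactly.
#'
#' @param mesh a `TriMesh`.
#' @param edge_lengths optional metric; default Euclidean 3D lengths.
#' @return numeric vector of per-vertex curvature (radians), attribute
#'   `boundary` flags boundary vertices.
#' @export
discrete_gaussian_curvature <- function(mesh, edge_lengths = NULL) {
  et <- mesh_edges(mesh)
  ang <- corner_angles(mesh, edge_lengths, et)
  n <- nrow(mesh$vertices)
  angle_sum <- numeric(n)
  grp <- sort(unique(c(mesh$faces)))
  angle_sum[grp] <- rowsum(c(ang), group = c(mesh$faces))[, 1]
  bnd <- is_boundary_vertex(mesh)
  k <- ifelse(bnd, pi, 2 * pi) - angle_sum
  attr(k, "boundary") <- bnd
  k
}

#' Mesh quality report
#'
#' Per-face aspect ratio under the longest-edge over smallest-altitude
#' convention, aspect = l_max^2 / (2 * area), which equals 2/sqrt(3)
#' (about 1.1547) for an equilateral triangle. Also counts degenerate
#' faces, duplicated faces and non-manifold edges.
#'
#' @param mesh a `TriMesh`.
#' @param threshold flag faces with aspect ratio above this (default 20).
#' @return object of class `MeshQualityReport`: list with
#'   `aspect_ratio` (per face), `max_aspect_ratio`, `min_angle_deg`,
#'   `n_degenerate`, `n_duplicate_faces`, `n_nonmanifold_edges`,
#'   `flagged_faces`.
#' @export
mesh_quality <- function(mesh, threshold = 20) {
  f <- mesh$faces
  v <- mesh$vertices
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e3 <- v[f[, 3], , drop = FALSE] - v[f[, 2], , drop = FALSE]
  l <- cbind(sqrt(rowSums(e3^2)), sqrt(rowSums(e2^2)), sqrt(rowSums(e1^2)))
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  area <- 0.5 * sqrt(rowSums(cr^2))
  lmax <- pmax(l[, 1], l[, 2], l[, 3])
  aspect <- ifelse(area > 0, lmax^2 / (2 * area), Inf)
  degen <- f[, 1] == f[, 2] | f[, 2] == f[, 3] | f[, 1] == f[, 3] | area == 0
  fk <- apply(f, 1, function(r) paste(sort(r), collapse = "-"))
  ndup <- sum(duplicated(fk))
  et <- mesh_edges(mesh)
  ang <- tryCatch(corner_angles(mesh, et = et), error = function(e) NULL)
  min_angle <- if (is.null(ang)) 0 else min(ang) * 180 / pi
  structure(list(
    aspect_ratio = aspect,
    max_aspect_ratio = max(aspect),
    min_angle_deg = min_angle,
    n_degenerate = sum(degen),
    n_duplicate_faces = ndup,
    n_nonmanifold_edges = sum(et$n_incident > 2),
    flagged_faces = which(aspect > threshold),
    threshold = threshold
  ), class = "MeshQualityReport")
}

#' @export
print.MeshQualityReport <- function(x, ...) {
  cat(sprintf("MeshQualityReport: max aspect %.3f (threshold %g, %d flagged)\n",
              x$max_aspect_ratio, x$threshold, length(x$flagged_faces)))
  cat(sprintf("  min angle %.2f deg; degenerate %d, duplicates %d, non-manifold edges %d\n",
              x$min_angle_deg, x$n_degenerate, x$n_duplicate_faces,
              x$n_nonmanifold_edges))
  invisible(x)
}

#' Shortest distance from points to a triangulated surface
#'
#' Exact point-to-triangle minimum over all faces, pruned by per-face
#' bounding boxes against a running upper bound seeded from nearest-vertex
#' distances; the result is identical to the brute-force minimum.
#'
#' @param points K x 3 numeric matrix (mm).
#' @param surface a `TriMesh`.
#' @param brute_force if TRUE skip pruning (reference path for tests).
#' @return numeric vector of K distances (mm).
#' @export
point_to_surface_distance <- function(points, surface, brute_force = FALSE) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  points <- as.matrix(points)
  if (ncol(points) != 3) stop("`points` must be K x 3")
  if (n_faces(surface) == 0) stop("argument error: empty surface")
  v <- surface$vertices
  f <- surface$faces
  k <- nrow(points)
  best <- rep(Inf, k)
  # pruning bound: distance to the nearest surface vertex (slightly
  # inflated so the owning faces are always evaluated exactly)
  ub <- rep(Inf, k)
  if (!brute_force) {
    step <- max(1L, floor(2e6 / nrow(v)))
    for (s in seq(1, k, by = step)) {
      idx <- s:min(k, s + step - 1)
      d2 <- outer(rowSums(points[idx, , drop = FALSE]^2), rowSums(v^2), "+") -
        2 * points[idx, , drop = FALSE] %*% t(v)
      ub[idx] <- sqrt(pmax(0, apply(d2, 1, min))) * (1 + 1e-9) + 1e-300
    }
  }
  # per-face bounding boxes
  bb_lo <- pmin(v[f[, 1], , drop = FALSE], v[f[, 2], , drop = FALSE],
                v[f[, 3], , drop = FALSE])
  bb_hi <- pmax(v[f[, 1], , drop = FALSE], v[f[, 2], , drop = FALSE],
                v[f[, 3], , drop = FALSE])
  for (fi in seq_len(nrow(f))) {
    if (!brute_force) {
      dx <- pmax(0, bb_lo[fi, 1] - points[, 1], points[, 1] - bb_hi[fi, 1])
      dy <- pmax(0, bb_lo[fi, 2] - points[, 2], points[, 2] - bb_hi[fi, 2])
      dz <- pmax(0, bb_lo[fi, 3] - points[, 3], points[, 3] - bb_hi[fi, 3])
      lb2 <- dx^2 + dy^2 + dz^2
      act <- which(lb2 <= pmin(ub, best * (1 + 1e-9) + 1e-300)^2)
    } else {
      act <- seq_len(k)
    }
    if (!length(act)) next
    d <- dist_point_triangle(points[act, , drop = FALSE],
                             v[f[fi, 1], ], v[f[fi, 2], ], v[f[fi, 3], ])
    best[act] <- pmin(best[act], d)
  }
  best
}

# exact distance from each row of P to triangle (a,b,c); Ericson-style
# projection onto the triangle's Voronoi regions, vectorised over points
dist_point_triangle <- function(P, a, b, c) {
  # elementwise dot products (batch-size independent, unlike BLAS %*%)
  dot3 <- function(M, w) M[, 1] * w[1] + M[, 2] * w[2] + M[, 3] * w[3]
  ab <- b - a; ac <- c - a
  ap <- sweep(P, 2, a)
  d1 <- dot3(ap, ab); d2 <- dot3(ap, ac)
  bp <- sweep(P, 2, b)
  d3 <- dot3(bp, ab); d4 <- dot3(bp, ac)
  cp <- sweep(P, 2, c)
  d5 <- dot3(cp, ab); d6 <- dot3(cp, ac)
  n <- nrow(P)
  q <- matrix(NA_real_, n, 3)
  done <- rep(FALSE, n)
  set_q <- function(idx, pts) {
    q[idx, ] <<- pts
    done[idx] <<- TRUE
  }
  # vertex regions
  r <- which(!done & d1 <= 0 & d2 <= 0)
  if (length(r)) set_q(r, matrix(a, length(r), 3, byrow = TRUE))
  r <- which(!done & d3 >= 0 & d4 <= d3)
  if (length(r)) set_q(r, matrix(b, length(r), 3, byrow = TRUE))
  r <- which(!done & d6 >= 0 & d5 <= d6)
  if (length(r)) set_q(r, matrix(c, length(r), 3, byrow = TRUE))
  # edge ab
  vc <- d1 * d4 - d3 * d2
  r <- which(!done & vc <= 0 & d1 >= 0 & d3 <= 0)
  if (length(r)) {
    t <- d1[r] / (d1[r] - d3[r])
    set_q(r, matrix(a, length(r), 3, byrow = TRUE) + outer(t, ab))
  }
  # edge ac
  vb <- d5 * d2 - d1 * d6
  r <- which(!done & vb <= 0 & d2 >= 0 & d6 <= 0)
  if (length(r)) {
    t <- d2[r] / (d2[r] - d6[r])
    set_q(r, matrix(a, length(r), 3, byrow = TRUE) + outer(t, ac))
  }
  # edge bc
  va <- d3 * d6 - d5 * d4
  r <- which(!done & va <= 0 & (d4 - d3) >= 0 & (d5 - d6) >= 0)
  if (length(r)) {
    t <- (d4[r] - d3[r]) / ((d4[r] - d3[r]) + (d5[r] - d6[r]))
    set_q(r, matrix(b, length(r), 3, byrow = TRUE) + outer(t, c - b))
  }
  # interior
  r <- which(!done)
  if (length(r)) {
    denom <- va[r] + vb[r] + vc[r]
    vv <- vb[r] / denom
    ww <- vc[r] / denom
    set_q(r, matrix(a, length(r), 3, byrow = TRUE) + outer(vv, ab) + outer(ww, ac))
  }
  sqrt(rowSums((P - q)^2))
}
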