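#' Discrete Ricci flow to a flat metric
#'
#' Computes per-vertex log conformal factors `u` so that the deformed metric
#' `l_ij = l0_ij * exp((u_i + u_j)/2)` (discrete conformal vertex scaling)
#' attains a prescribed discrete Gaussian curvature. Two boundary conditions
#' are supported:
#'
#' * `disk_free_boundary` — for a surface with chi = 1 (genus 0, one
#'   boundary): target curvature 0 at every interior vertex, boundary metric
#'   left unchanged (u fixed at 0 on the boundary). The result is a flat
#'   metric developable onto a planar disk-like domain.
#' * `annulus_zero` — for a surface with chi = 0 (genus 0, two boundaries):
#'   target curvature 0 at every vertex including both boundaries, giving a
#'   flat cylinder metric whose development is a straight strip.
#'
#' Newton's method on `u` is used; the Jacobian of the curvature map is the
#' cotangent-weighted Laplacian of the current metric, and a step-halving
#' line search guards both the triangle inequalities and monotone decrease
#' of the curvature residual.
#'
#' @param mesh a `TriMesh`.
#' @param mode "disk_free_boundary" or "annulus_zero".
#' @param tolerance convergence tolerance on max |K - Kbar| (radians).
#' @param max_iter maximum Newton iterations.
#' @return an object of class `RicciMetric`: list with `u`, `edge_lengths`
#'   (deformed, over `edges` rows), `edges`, `target_curvature`,
#'   `achieved_curvature`, `converged`, `residual`, `residual_history`,
#'   `iterations`, `mode`, `free` (logical per vertex).
#' @export
ricci_flow_metric <- function(mesh,
                              mode = c("disk_free_boundary", "annulus_zero"),
                              tolerance = 1e-8, max_iter = 50) {
  mode <- match.arg(mode)
  top <- mesh_topology(mesh)
  if (mode == "disk_free_boundary" && !(top$chi == 1 && top$n_boundary == 1))
    stop("topology error: disk_free_boundary requires chi=1, b=1 (got chi=",
         top$chi, ", b=", top$n_boundary, ")")
  if (mode == "annulus_zero" && !(top$chi == 0 && top$n_boundary == 2))
    stop("topology error: annulus_zero requires chi=0, b=2 (got chi=",
         top$chi, ", b=", top$n_boundary, ")")
  et <- mesh_edges(mesh)
  l0 <- edge_lengths_3d(mesh, et$edges)
  n <- nrow(mesh$vertices)
  bnd <- is_boundary_vertex(mesh)
  free <- if (mode == "disk_free_boundary") !bnd else {
    fr <- rep(TRUE, n)
    fr[1] <- FALSE  # pin the additive gauge; K there follows by Gauss-Bonnet
    fr
  }
  kbar <- numeric(n)
  u <- numeric(n)
  ea <- et$edges[, 1]; eb <- et$edges[, 2]
  fe <- et$face_edges
  faces <- mesh$faces
  lengths_of <- function(u) l0 * exp((u[ea] + u[eb]) / 2)
  curv <- function(l) {
    ang <- corner_angles(mesh, l, et)
    angle_sum <- numeric(n)
    grp <- sort(unique(c(faces)))
    angle_sum[grp] <- rowsum(c(ang), group = c(faces))[, 1]
    list(K = ifelse(bnd, pi, 2 * pi) - angle_sum, ang = ang)
  }
  l <- lengths_of(u)
  cv <- curv(l)
  resid <- max(abs(cv$K - kbar)[free])
  history <- resid
  it <- 0L
  while (resid > tolerance && it < max_iter) {
    it <- it + 1L
    # cotangent weights: w_e = 0.5 * sum of cot of angles opposite edge e
    cot <- 1 / tan(cv$ang)
    w <- numeric(nrow(et$edges))
    acc <- rowsum(c(cot), group = c(fe))
    w[as.integer(rownames(acc))] <- 0.5 * acc[, 1]
    L <- Matrix::sparseMatrix(
      i = c(ea, eb, ea, eb), j = c(eb, ea, ea, eb),
      x = c(-w, -w, w, w), dims = c(n, n))
    rhs <- (kbar - cv$K)[free]
    Lff <- L[free, free, drop = FALSE]
    delta <- tryCatch(
      as.numeric(Matrix::solve(Lff, rhs)),
      error = function(e) as.numeric(Matrix::solve(
        Lff + Matrix::Diagonal(sum(free), 1e-10 * mean(abs(w))), rhs)))
    step <- 1
    repeat {
      u_try <- u
      u_try[free] <- u[free] + step * delta
      l_try <- lengths_of(u_try)
      if (metric_is_valid(et, l_try)) {
        cv_try <- curv(l_try)
        r_try <- max(abs(cv_try$K - kbar)[free])
        if (r_try < resid) break
      }
      step <- step / 2
      if (step < 1e-12)
        stop("convergence error: Ricci flow line search stalled at residual ",
             signif(resid, 4), " (iteration ", it, "); residual history: ",
             paste(signif(history, 3), collapse = ", "))
      }
    u <- u_try
    l <- l_try
    cv <- cv_try
    resid <- r_try
    history <- c(history, resid)
  }
  converged <- resid <= tolerance
  if (!converged)
    stop("convergence error: Ricci flow did not reach tolerance ", tolerance,
         " in ", max_iter, " iterations; residual history: ",
         paste(signif(history, 3), collapse = ", "))
  structure(list(u = u, edge_lengths = l, edges = et$edges,
                 target_curvature = kbar, achieved_curvature = cv$K,
                 converged = converged, residual = resid,
                 residual_history = history, iterations = it,
                 mode = mode, free = free),
            class = "RicciMetric")
}

#' @export
print.RicciMetric <- function(x, ...) {
  cat(sprintf("RicciMetric (%s): %d Newton iterations, residual %.3g (%s)\n",
              x$mode, x$iterations, x$residual,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Planar embedding constructor (internal representation)
#'
#' @param points complex vector of per-vertex planar coordinates.
#' @param faces face matrix of the embedded mesh.
#' @param domain "disk", "strip" or "annulus".
#' @param conformal_factor per-vertex conformal factor field (higher where
#'   the flattening compresses the surface, i.e. at protruding features).
#' @param orig_vertex integer map from embedded vertices to vertices of the
#'   original (unslit) surface; NA for vertices inserted by face splitting.
#' @param extra named list of additional bookkeeping.
#' @return object of class `PlanarEmbedding`.
#' @export
planar_embedding <- function(points, faces, domain, conformal_factor = NULL,
                             orig_vertex = seq_along(points), extra = list()) {
  structure(list(points = points, faces = faces, domain = domain,
                 conformal_factor = conformal_factor,
                 orig_vertex = orig_vertex, extra = extra),
            class = "PlanarEmbedding")
}

#' @export
print.PlanarEmbedding <- function(x, ...) {
  cat(sprintf("PlanarEmbedding (%s): %d vertices, %d faces\n",
              x$domain, length(x$points), nrow(x$faces)))
  invisible(x)
}

# signed areas of embedded faces (positive = counterclockwise)
embedding_signed_areas <- function(points, faces) {
  p1 <- points[faces[, 1]]; p2 <- points[faces[, 2]]; p3 <- points[faces[, 3]]
  0.5 * (Re(p2 - p1) * Im(p3 - p1) - Im(p2 - p1) * Re(p3 - p1))
}

# develop a flat metric into the plane by breadth-first face propagation
layout_flat_metric <- function(mesh, metric, seed_face = 1L) {
  faces <- mesh$faces
  m <- nrow(faces)
  n <- nrow(mesh$vertices)
  et <- mesh_edges(mesh)
  len <- metric$edge_lengths
  fe <- et$face_edges
  # l(face corner pair): edge opposite corner k
  # face adjacency via shared edges
  ef <- split(rep(seq_len(m), 3), c(fe))
  nbrs <- vector("list", m)
  for (fs in ef[lengths(ef) == 2]) {
    nbrs[[fs[1]]] <- c(nbrs[[fs[1]]], fs[2])
    nbrs[[fs[2]]] <- c(nbrs[[fs[2]]], fs[1])
  }
  pos <- complex(n)
  placed <- rep(FALSE, n)
  face_len <- function(fi) {
    # lengths of edges (v1v2, v2v3, v3v1) of face fi
    len[fe[fi, c(3, 1, 2)]]
  }
  f <- faces[seed_face, ]
  l <- face_len(seed_face)   # l12, l23, l31
  pos[f[1]] <- 0 + 0i
  pos[f[2]] <- l[1] + 0i
  # angle at v1 from law of cosines
  ca <- (l[1]^2 + l[3]^2 - l[2]^2) / (2 * l[1] * l[3])
  ca <- min(1, max(-1, ca))
  pos[f[3]] <- complex(real = l[3] * ca,
                       imaginary = l[3] * sqrt(max(0, 1 - ca^2)))
  placed[f] <- TRUE
  visited <- rep(FALSE, m)
  visited[seed_face] <- TRUE
  queue <- nbrs[[seed_face]]
  inq <- rep(FALSE, m)
  inq[queue] <- TRUE
  head <- 1L
  queue <- as.integer(queue)
  n_pop <- 0L
  while (head <= length(queue)) {
    n_pop <- n_pop + 1L
    if (n_pop > 10L * m + 100L)
      stop("layout error: propagation did not terminate")
    fi <- queue[head]
    head <- head + 1L
    if (visited[fi]) next
    f <- faces[fi, ]
    np <- !placed[f]
    if (sum(np) >= 2) {           # not ready yet; requeue at the back
      if (head > length(queue)) {
        stop("layout error: mesh disconnected or propagation stalled at face ", fi)
      }
      queue <- c(queue, fi)
      next
    }
    visited[fi] <- TRUE
    if (sum(np) == 1) {
      k <- which(np)              # unplaced corner index in face row
      rot <- switch(k, c(2, 3, 1), c(3, 1, 2), c(1, 2, 3))
      a <- f[rot[1]]; b <- f[rot[2]]; cidx <- f[rot[3]]
      l <- face_len(fi)           # l12,l23,l31 in original row order
      lab <- switch(k, l[2], l[3], l[1])   # |a-b|
      lac <- switch(k, l[1], l[2], l[3])   # wait: see below
      # edge (rot1,rot2) etc: for k=1 rot=(2,3,1): ab=(v2,v3)=l23=l[2];
      # ac=(v2,v1)=l12=l[1]; bc=(v3,v1)=l31=l[3]
      lac <- switch(k, l[1], l[2], l[3])
      lbc <- switch(k, l[3], l[1], l[2])
      pa <- pos[a]; pb <- pos[b]
      d <- abs(pb - pa)
      x <- (lac^2 - lbc^2 + d^2) / (2 * d)
      y2 <- lac^2 - x^2
      y <- sqrt(max(0, y2))
      e1 <- (pb - pa) / d
      pos[cidx] <- pa + (x + 1i * y) * e1
      placed[cidx] <- TRUE
    }
    for (nb in nbrs[[fi]]) {
      if (!visited[nb] && !inq[nb]) {
        queue <- c(queue, nb)
        inq[nb] <- TRUE
      }
    }
    inq[fi] <- FALSE
  }
  if (!all(visited)) stop("layout error: mesh is not edge-connected")
  sa <- embedding_signed_areas(pos, faces)
  if (any(sa <= 0))
    stop("layout error: flipped face(s) during layout: ",
         paste(utils::head(which(sa <= 0), 5), collapse = ", "))
  pos
}

#' Embed a disk-type flat metric in the plane
#'
#' Develops the flat metric produced by [ricci_flow_metric()] in
#' `disk_free_boundary` mode into the plane by breadth-first face
#' propagation from a seed face, and attaches the conformal factor field
#' (-u: larger where the map compresses the surface, so protruding
#' features appear as peaks).
#'
#' @param mesh the `TriMesh` the metric was computed on.
#' @param metric a converged `RicciMetric` in disk mode.
#' @param seed_face face index at which the layout is seeded (default 1,
#'   the lowest-index face, for reproducibility).
#' @return a `PlanarEmbedding` with `domain = "disk"`.
#' @export
embed_disk <- function(mesh, metric, seed_face = 1L) {
  if (!inherits(metric, "RicciMetric") || metric$mode != "disk_free_boundary")
    stop("embed_disk needs a converged disk_free_boundary RicciMetric")
  pos <- layout_flat_metric(mesh, metric, seed_face)
  planar_embedding(pos, mesh$faces, "disk",
                   conformal_factor = -metric$u,
                   extra = list(u = metric$u))
}

# max relative deviation between embedded edge lengths and metric lengths
layout_length_error <- function(embedding, metric) {
  e <- metric$edges
  emb <- abs(embedding$points[e[, 1]] - embedding$points[e[, 2]])
  max(abs(emb - metric$edge_lengths) / metric$edge_lengths)
}
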