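#' Shortest cut graph from a vertex to a boundary loop
#'
#' Dijkstra shortest path over the mesh edge graph weighted by 3D edge
#' length, from `from_vertex` to the nearest vertex of the target boundary
#' loop. Intermediate vertices avoid all boundary loops, so the path can be
#' used to slit the surface open without touching existing boundaries except
#' at its endpoints.
#'
#' @param mesh a `TriMesh`.
#' @param from_vertex source vertex id (must not lie on the target loop).
#' @param to_boundary index of the target boundary loop (in
#'   [mesh_topology()] order), default 1.
#' @return integer vector of vertex ids from `from_vertex` to the boundary.
#' @export
cut_graph <- function(mesh, from_vertex, to_boundary = 1L) {
  top <- mesh_topology(mesh)
  if (to_boundary > top$n_boundary) stop("no boundary loop ", to_boundary)
  target <- top$loops[[to_boundary]]
  if (from_vertex %in% target)
    stop("from_vertex lies on the target boundary loop")
  other_bnd <- setdiff(unlist(top$loops[-to_boundary]), from_vertex)
  e <- top$edges
  w <- edge_lengths_3d(mesh, e)
  # drop edges into forbidden (other-boundary) vertices
  keep <- !(e[, 1] %in% other_bnd) & !(e[, 2] %in% other_bnd)
  g <- igraph::graph_from_edgelist(e[keep, , drop = FALSE], directed = FALSE)
  if (igraph::vcount(g) < nrow(mesh$vertices))
    g <- igraph::add_vertices(g, nrow(mesh$vertices) - igraph::vcount(g))
  d <- igraph::distances(g, v = from_vertex, to = target,
                         weights = w[keep])[1, ]
  if (all(!is.finite(d))) stop("no-path error: mesh disconnected from target boundary")
  best <- target[which.min(d)]
  p <- igraph::shortest_paths(g, from = from_vertex, to = best,
                              weights = w[keep])$vpath[[1]]
  as.integer(p)
}

#' Slit a mesh open along a path
#'
#' Inserts a boundary by duplicating vertices along a path. In `edge_path`
#' mode the path is a simple chain of existing mesh edges; interior path
#' vertices are always duplicated, and a path endpoint is duplicated when it
#' lies on an existing boundary (so slitting an annulus along a
#' boundary-to-boundary path yields a disk, while slitting an interior path
#' in a disk yields an annulus). In `planar_line` mode the path is the
#' straight planar segment between two vertices of a disk embedding; the
#' walk snaps to vertices within tolerance and splits faces where the
#' segment crosses edges before slitting.
#'
#' @param mesh a `TriMesh`.
#' @param path integer vertex path (edge_path), or a segment as returned by
#'   [inter_feature_segment()] (planar_line).
#' @param mode "edge_path" or "planar_line".
#' @param embedding disk `PlanarEmbedding` (required for planar_line).
#' @param snap_tol vertex snapping tolerance, relative to segment length.
#' @return list with `mesh` (slit `TriMesh`), `orig_vertex` (provenance:
#'   new-vertex id -> source-vertex id on the input mesh, NA for vertices
#'   inserted by face splitting), `side_a`, `side_b` (the two copies of the
#'   slit path, as vertex chains on the new mesh), and for planar_line mode
#'   `embedding` (updated input embedding including split vertices).
#' @export
slit_mesh <- function(mesh, path, mode = c("edge_path", "planar_line"),
                      embedding = NULL, snap_tol = 1e-6) {
  mode <- match.arg(mode)
  if (mode == "planar_line") {
    if (is.null(embedding)) stop("planar_line mode needs a disk embedding")
    tr <- trace_planar_segment(mesh, embedding, path$from_vertex,
                               path$to_vertex, snap_tol = snap_tol)
    res <- slit_edge_path(tr$mesh, tr$path)
    res$embedding <- tr$embedding
    res$orig_vertex <- ifelse(is.na(res$orig_vertex), NA_integer_,
                              tr$orig_vertex[res$orig_vertex])
    res
  } else {
    res <- slit_edge_path(mesh, path)
    res
  }
}

# duplicate vertices along a simple edge path; faces strictly right of the
# oriented path are reassigned to the duplicates
slit_edge_path <- function(mesh, path) {
  path <- as.integer(path)
  p <- length(path)
  if (p < 2) stop("path must contain at least two vertices")
  if (anyDuplicated(path)) stop("path must be simple")
  n <- nrow(mesh$vertices)
  faces <- mesh$faces
  bnd <- is_boundary_vertex(mesh)
  if (any(bnd[path[-c(1, p)]]))
    stop("unsupported-slit error: path touches an existing boundary ",
         "at an interior position")
  vf <- vertex_faces(mesh)
  # directed-edge -> face lookup
  K <- as.double(n) + 1
  de <- directed_edges(mesh)
  dekey <- de[, 1] * K + de[, 2]
  deface <- rep(seq_len(nrow(faces)), times = 3)
  face_of_directed <- function(a, b) {
    hit <- match(a * K + b, dekey)
    if (is.na(hit)) NA_integer_ else deface[hit]
  }
  # verify path edges exist and are interior
  for (i in seq_len(p - 1)) {
    fw <- face_of_directed(path[i], path[i + 1])
    bw <- face_of_directed(path[i + 1], path[i])
    if (is.na(fw) || is.na(bw))
      stop("unsupported-slit error: path edge ", path[i], "-", path[i + 1],
           " is not an interior mesh edge")
  }
  dup <- rep(FALSE, p)
  dup[-c(1, p)] <- TRUE
  dup[1] <- bnd[path[1]]
  dup[p] <- bnd[path[p]]
  if (!any(dup))
    stop("unsupported-slit error: nothing to slit (path too short ",
         "with interior endpoints)")
  verts <- mesh$vertices
  fields <- mesh$fields
  orig <- seq_len(n)
  new_id <- rep(NA_integer_, p)
  out_faces <- faces
  for (i in seq_len(p)) {
    if (!dup[i]) { new_id[i] <- path[i]; next }
    v <- path[i]
    inc <- vf[[v]]
    # fan adjacency among incident faces via shared non-path edges at v
    path_nb <- c(if (i > 1) path[i - 1], if (i < p) path[i + 1])
    comp <- fan_components(out_faces, inc, v, path_nb)
    # right side: faces containing directed edge (next -> v) or (v -> prev)
    right_faces <- integer(0)
    if (i < p) {
      fb <- face_of_directed(path[i + 1], v)
      if (!is.na(fb)) right_faces <- c(right_faces, fb)
    }
    if (i > 1) {
      fb <- face_of_directed(v, path[i - 1])
      if (!is.na(fb)) right_faces <- c(right_faces, fb)
    }
    right_faces <- intersect(right_faces, inc)
    if (!length(right_faces))
      stop("unsupported-slit error: cannot identify slit side at vertex ", v)
    right_comp <- unique(comp[match(right_faces, inc)])
    if (length(right_comp) != 1 || length(unique(comp)) < 2)
      stop("unsupported-slit error: fan at vertex ", v,
           " does not split into two sides")
    vid_new <- nrow(verts) + 1L
    verts <- rbind(verts, verts[v, , drop = FALSE])
    for (nm in names(fields)) fields[[nm]] <- c(fields[[nm]], fields[[nm]][v])
    orig <- c(orig, v)
    new_id[i] <- vid_new
    move <- inc[comp == right_comp]
    for (fi in move) out_faces[fi, ][out_faces[fi, ] == v] <- vid_new
  }
  side_a <- path
  side_b <- ifelse(is.na(new_id), path, new_id)
  new_mesh <- trimesh(verts, out_faces, fields = fields)
  list(mesh = new_mesh, orig_vertex = orig, side_a = side_a, side_b = side_b)
}

# connected components of the face fan around vertex v, where two incident
# faces are adjacent iff they share an edge at v that is not a path edge
fan_components <- function(faces, inc, v, path_nb) {
  k <- length(inc)
  other <- lapply(inc, function(fi) setdiff(faces[fi, ], v))
  comp <- seq_len(k)
  for (a in seq_len(k - 1)) {
    for (b in (a + 1):k) {
      shared <- intersect(other[[a]], other[[b]])
      shared <- setdiff(shared, path_nb)
      if (length(shared)) {
        ca <- comp[a]; cb <- comp[b]
        if (ca != cb) comp[comp == cb] <- ca
      }
    }
  }
  comp
}

# walk the straight segment between two embedded vertices, snapping to
# vertices and splitting crossed edges; returns updated mesh/embedding and
# the resulting vertex path
trace_planar_segment <- function(mesh, embedding, from_vertex, to_vertex,
                                 snap_tol = 1e-6, max_steps = NULL) {
  verts <- mesh$vertices
  fields <- mesh$fields
  faces <- mesh$faces
  pts <- embedding$points
  cfac <- embedding$conformal_factor
  orig <- seq_len(nrow(verts))
  seg_len <- abs(pts[to_vertex] - pts[from_vertex])
  tol <- snap_tol * seg_len
  if (is.null(max_steps)) max_steps <- 4L * nrow(faces) + 100L
  cur <- from_vertex
  path <- cur
  steps <- 0L
  vf_stale <- TRUE
  vf <- NULL
  while (cur != to_vertex) {
    steps <- steps + 1L
    if (steps > max_steps) stop("geometry error: segment walk did not terminate")
    if (vf_stale) {
      vf <- split(rep(seq_len(nrow(faces)), 3), c(faces))
      vf_stale <- FALSE
    }
    pcur <- pts[cur]
    d <- pts[to_vertex] - pcur
    inc <- vf[[as.character(cur)]]
    ring <- setdiff(unique(c(faces[inc, ])), cur)
    # snap: neighbour nearly on the segment direction and not past the target
    vec <- pts[ring] - pcur
    crossv <- abs(Im(Conj(d) * vec)) / abs(d)
    dotv <- Re(Conj(d) * vec)
    ok <- which(crossv < tol & dotv > 0 & abs(vec) <= abs(d) + tol)
    if (length(ok)) {
      w <- ring[ok[which.min(crossv[ok])]]
      path <- c(path, w)
      cur <- w
      next
    }
    # otherwise find the incident face whose wedge contains the direction
    best <- NULL
    best_score <- -Inf
    for (fi in inc) {
      f <- faces[fi, ]
      r <- which(f == cur)
      x <- f[r %% 3 + 1]
      y <- f[(r + 1) %% 3 + 1]
      ex <- pts[x] - pcur
      ey <- pts[y] - pcur
      c1 <- Im(Conj(ex) * d) / (abs(ex) * abs(d))
      c2 <- Im(Conj(d) * ey) / (abs(ey) * abs(d))
      score <- min(c1, c2)
      if (score > best_score) {
        best_score <- score
        best <- c(fi, x, y)
      }
    }
    if (best_score < -1e-9)
      stop("geometry error: segment leaves the embedded domain at vertex ", cur)
    fi <- best[1]; x <- best[2]; y <- best[3]
    # intersect segment (pcur -> target) with edge (x, y)
    px <- pts[x]; py <- pts[y]
    den <- Im(Conj(d) * (py - px))
    if (abs(den) < 1e-300)
      stop("geometry error: degenerate crossing in segment walk")
    t_edge <- Im(Conj(d) * (pcur - px)) / den
    t_edge <- min(1, max(0, t_edge))
    q <- px + t_edge * (py - px)
    if (abs(q - px) < tol) { path <- c(path, x); cur <- x; next }
    if (abs(q - py) < tol) { path <- c(path, y); cur <- y; next }
    # split edge (x, y) at q
    vid_new <- nrow(verts) + 1L
    verts <- rbind(verts, (1 - t_edge) * verts[x, ] + t_edge * verts[y, ])
    for (nm in names(fields))
      fields[[nm]] <- c(fields[[nm]], (1 - t_edge) * fields[[nm]][x] +
                          t_edge * fields[[nm]][y])
    if (!is.null(cfac)) cfac <- c(cfac, (1 - t_edge) * cfac[x] + t_edge * cfac[y])
    pts <- c(pts, q)
    orig <- c(orig, NA_integer_)
    adj_faces <- which(rowSums(matrix(faces %in% c(x, y), nrow(faces))) == 2)
    adj_faces <- adj_faces[vapply(adj_faces, function(ff)
      all(c(x, y) %in% faces[ff, ]), TRUE)]
    for (ff in adj_faces) {
      f <- faces[ff, ]
      # replace y by new vertex in this face, append copy with x replaced
      f1 <- f; f1[f1 == y] <- vid_new
      f2 <- f; f2[f2 == x] <- vid_new
      faces[ff, ] <- f1
      faces <- rbind(faces, f2)
    }
    vf_stale <- TRUE
    path <- c(path, vid_new)
    cur <- vid_new
  }
  new_mesh <- trimesh(verts, faces, fields = fields)
  new_emb <- planar_embedding(pts, faces, embedding$domain,
                              conformal_factor = cfac,
                              orig_vertex = ifelse(is.na(orig), NA_integer_,
                                                   embedding$orig_vertex[orig]))
  list(mesh = new_mesh, embedding = new_emb, path = path, orig_vertex = orig)
}
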