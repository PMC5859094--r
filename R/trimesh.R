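#' Triangulated surface mesh
#'
#' `trimesh()` builds an indexed triangle surface from a vertex coordinate
#' matrix and a face index matrix. Vertices are in millimetres; faces are
#' stored counterclockwise when viewed from outside the surface. Optional
#' per-vertex scalar fields (named numeric vectors of length `N`) ride along
#' with the mesh and are preserved by operations that resample or slit it.
#'
#' Validation enforces the invariants every downstream algorithm relies on:
#' all face indices in range, no degenerate faces (three distinct vertices),
#' edge-manifoldness (each undirected edge borders one or two faces) and
#' consistent orientation. Readers reorient inconsistently oriented but
#' orientable input (see [read_mesh()]).
#'
#' @param vertices numeric matrix, N x 3 (mm).
#' @param faces integer matrix, M x 3 of 1-based vertex indices.
#' @param fields optional named list of numeric length-N vectors.
#' @param validate logical; check invariants (default TRUE).
#' @return an object of class `TriMesh`: a list with elements `vertices`,
#'   `faces`, `fields`.
#' @export
trimesh <- function(vertices, faces, fields = list(), validate = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("`vertices` must be an N x 3 matrix")
  if (ncol(faces) != 3L) stop("`faces` must be an M x 3 matrix")
  dimnames(vertices) <- NULL
  dimnames(faces) <- NULL
  mesh <- structure(list(vertices = vertices, faces = faces,
                         fields = as.list(fields)),
                    class = "TriMesh")
  if (validate) validate_trimesh(mesh)
  mesh
}

#' @export
print.TriMesh <- function(x, ...) {
  top <- mesh_topology(x)
  cat(sprintf("TriMesh: %d vertices, %d faces, %d edges\n",
              nrow(x$vertices), nrow(x$faces), nrow(top$edges)))
  cat(sprintf("  chi = %d, genus = %d, boundary loops = %d\n",
              top$chi, top$genus, top$n_boundary))
  if (length(x$fields))
    cat("  fields:", paste(names(x$fields), collapse = ", "), "\n")
  invisible(x)
}

n_vertices <- function(mesh) nrow(mesh$vertices)
n_faces <- function(mesh) nrow(mesh$faces)

#' Validate TriMesh invariants
#'
#' Checks index ranges, face degeneracy, edge-manifoldness and orientation
#' consistency. Errors name the offending elements.
#'
#' @param mesh a `TriMesh`.
#' @return invisibly TRUE; errors on violation.
#' @export
validate_trimesh <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  if (anyNA(v)) stop("vertex coordinates contain NA")
  if (nrow(f) > 0) {
    if (min(f) < 1L || max(f) > nrow(v))
      stop("face indices out of range [1, ", nrow(v), "]")
    degen <- f[, 1] == f[, 2] | f[, 2] == f[, 3] | f[, 1] == f[, 3]
    if (any(degen))
      stop("degenerate faces (repeated vertex): ",
           paste(utils::head(which(degen), 5), collapse = ", "))
  }
  for (nm in names(mesh$fields)) {
    if (length(mesh$fields[[nm]]) != nrow(v))
      stop("field '", nm, "' length != number of vertices")
  }
  ec <- directed_edges(mesh)
  key <- edge_key(pmin(ec[, 1], ec[, 2]), pmax(ec[, 1], ec[, 2]), nrow(v))
  cnt <- table(key)
  if (any(cnt > 2)) {
    bad <- names(cnt)[cnt > 2][1]
    stop("non-manifold edge (", paste(key_edge(as.numeric(bad), nrow(v)),
                                      collapse = "-"),
         ") borders more than two faces")
  }
  # orientation: an interior edge must appear once per direction
  dkey <- ec[, 1] + (ec[, 2] - 1) * as.double(nrow(v))
  if (anyDuplicated(dkey)) {
    stop("inconsistently oriented faces: directed edge repeated; ",
         "use read_mesh() which reorients orientable input")
  }
  invisible(TRUE)
}

# directed half-edges (3M x 2), in face orientation order
directed_edges <- function(mesh) {
  f <- mesh$faces
  cbind(c(f[, 1], f[, 2], f[, 3]), c(f[, 2], f[, 3], f[, 1]))
}

edge_key <- function(a, b, n) a + (b - 1) * as.double(n)
key_edge <- function(k, n) {
  b <- floor((k - 1) / n) + 1
  c(k - (b - 1) * n, b)
}

#' Edge table of a mesh
#'
#' Unique undirected edges with incident-face counts.
#'
#' @param mesh a `TriMesh`.
#' @return list with `edges` (E x 2, each row sorted), `n_incident`
#'   (faces per edge), `face_edges` (M x 3 edge ids, edge k opposite
#'   face vertex k), `boundary` (logical per edge).
#' @export
mesh_edges <- function(mesh) {
  f <- mesh$faces
  n <- nrow(mesh$vertices)
  # edge opposite vertex 1 is (v2,v3), etc.
  ea <- cbind(c(f[, 2], f[, 1], f[, 1]), c(f[, 3], f[, 3], f[, 2]))
  a <- pmin(ea[, 1], ea[, 2]); b <- pmax(ea[, 1], ea[, 2])
  key <- edge_key(a, b, n)
  uk <- unique(key)
  id <- match(key, uk)
  edges <- cbind(a, b)[match(uk, key), , drop = FALSE]
  cnt <- tabulate(id, nbins = length(uk))
  m <- nrow(f)
  list(edges = edges,
       n_incident = cnt,
       face_edges = matrix(id, ncol = 3, dimnames = NULL),
       boundary = cnt == 1L)
}

#' Boundary loops of a mesh
#'
#' Traces the closed simple cycles formed by boundary edges.
#'
#' @param mesh a `TriMesh`.
#' @return list of integer vectors, each a cyclic vertex sequence.
#' @export
boundary_loops <- function(mesh) {
  et <- mesh_edges(mesh)
  be <- et$edges[et$boundary, , drop = FALSE]
  if (nrow(be) == 0) return(list())
  # each boundary vertex must have exactly two boundary edges
  deg <- tabulate(c(be[, 1], be[, 2]), nbins = nrow(mesh$vertices))
  if (any(deg != 0 & deg != 2))
    stop("boundary is not a union of simple loops (vertex ",
         which(deg != 0 & deg != 2)[1], ")")
  nbr <- vector("list", nrow(mesh$vertices))
  for (i in seq_len(nrow(be))) {
    nbr[[be[i, 1]]] <- c(nbr[[be[i, 1]]], be[i, 2])
    nbr[[be[i, 2]]] <- c(nbr[[be[i, 2]]], be[i, 1])
  }
  seen <- rep(FALSE, nrow(mesh$vertices))
  loops <- list()
  for (s in sort(unique(c(be)))) {
    if (seen[s]) next
    loop <- s
    seen[s] <- TRUE
    prev <- 0L
    cur <- s
    repeat {
      nxt <- setdiff(nbr[[cur]], prev)[1]
      if (is.na(nxt) || nxt == s) break
      loop <- c(loop, nxt)
      seen[nxt] <- TRUE
      prev <- cur
      cur <- nxt
    }
    loops[[length(loops) + 1L]] <- loop
  }
  loops
}

#' Topology summary (Euler characteristic, genus, boundary count)
#'
#' Computes chi = V - E + F, the number of boundary loops b, and the genus
#' solved from chi = 2 - 2g - b for an orientable surface.
#'
#' @param mesh a `TriMesh`.
#' @return list with `chi`, `genus`, `n_boundary`, `loops`, `edges`.
#' @export
mesh_topology <- function(mesh) {
  et <- mesh_edges(mesh)
  loops <- boundary_loops(mesh)
  chi <- nrow(mesh$vertices) - nrow(et$edges) + nrow(mesh$faces)
  b <- length(loops)
  g <- (2 - b - chi) / 2
  if (g != round(g) || g < 0)
    stop("topology inconsistent: chi=", chi, ", b=", b,
         " gives non-integer or negative genus")
  list(chi = as.integer(chi), genus = as.integer(g),
       n_boundary = as.integer(b), loops = loops, edges = et$edges)
}

#' Euler characteristic
#'
#' @param mesh a `TriMesh`.
#' @return integer chi = V - E + F, with attributes `genus` and
#'   `n_boundary`.
#' @export
euler_characteristic <- function(mesh) {
  top <- mesh_topology(mesh)
  structure(top$chi, genus = top$genus, n_boundary = top$n_boundary)
}

#' Per-vertex boundary flag
#' @param mesh a `TriMesh`.
#' @return logical vector of length N.
#' @export
is_boundary_vertex <- function(mesh) {
  et <- mesh_edges(mesh)
  be <- et$edges[et$boundary, , drop = FALSE]
  out <- rep(FALSE, nrow(mesh$vertices))
  out[c(be)] <- TRUE
  out
}

# vertex -> incident faces (list of integer vectors)
vertex_faces <- function(mesh) {
  f <- mesh$faces
  m <- nrow(f)
  split(rep(seq_len(m), 3), c(f))
}

# 1-ring vertex adjacency as list
vertex_rings <- function(mesh) {
  et <- mesh_edges(mesh)
  e <- et$edges
  n <- nrow(mesh$vertices)
  adj <- vector("list", n)
  sp1 <- split(e[, 2], e[, 1])
  sp2 <- split(e[, 1], e[, 2])
  for (k in names(sp1)) adj[[as.integer(k)]] <- sp1[[k]]
  for (k in names(sp2)) {
    i <- as.integer(k)
    adj[[i]] <- c(adj[[i]], sp2[[k]])
  }
  adj
}

#' Euclidean edge lengths of a mesh
#'
#' @param mesh a `TriMesh`.
#' @param edges optional E x 2 edge matrix (defaults to [mesh_edges()]).
#' @return numeric vector of lengths (mm).
#' @export
edge_lengths_3d <- function(mesh, edges = NULL) {
  if (is.null(edges)) edges <- mesh_edges(mesh)$edges
  d <- mesh$vertices[edges[, 1], , drop = FALSE] -
    mesh$vertices[edges[, 2], , drop = FALSE]
  sqrt(rowSums(d^2))
}
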