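# shared fixtures, memoised across test files (helpers persist for the run)

.fix <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fix[[key]])) .fix[[key]] <- force(expr)
  .fix[[key]]
}

fix_femur <- function() memo("femur", make_femur(femur_spec()))

fix_param <- function() memo("param", {
  parametrise_femur(fix_femur()$outer, tolerance = 1e-10)
})

# the same femur after a rigid motion plus uniform scale
rigid_scale_transform <- function() {
  th <- c(0.7, -0.4, 1.2)
  rx <- rbind(c(1, 0, 0), c(0, cos(th[1]), -sin(th[1])),
              c(0, sin(th[1]), cos(th[1])))
  ry <- rbind(c(cos(th[2]), 0, sin(th[2])), c(0, 1, 0),
              c(-sin(th[2]), 0, cos(th[2])))
  rz <- rbind(c(cos(th[3]), -sin(th[3]), 0),
              c(sin(th[3]), cos(th[3]), 0), c(0, 0, 1))
  list(R = rx %*% ry %*% rz, s = 1.7, t = c(31, -12, 5))
}

apply_rigid_scale <- function(mesh, tr = rigid_scale_transform()) {
  trimesh(sweep(tr$s * mesh$vertices %*% t(tr$R), 2, tr$t, "+"),
          mesh$faces, fields = mesh$fields)
}

fix_param_moved <- function() memo("param_moved", {
  parametrise_femur(apply_rigid_scale(fix_femur()$outer), tolerance = 1e-10)
})

fix_template <- function() memo("template", make_template(fix_param()))

# small canonical meshes ----------------------------------------------------

single_triangle <- function() {
  trimesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)), rbind(c(1, 2, 3)))
}

tetra_mesh <- function() {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  f <- rbind(c(1, 3, 2), c(1, 2, 4), c(2, 3, 4), c(1, 4, 3))
  trimesh(v, f)
}

# flat rectangular grid in the z = 0 plane, one boundary (chi = 1)
grid_mesh <- function(nx = 8, ny = 8, dx = 1) {
  vid <- function(i, j) (i - 1L) * ny + j
  v <- cbind(rep((seq_len(nx) - 1) * dx, each = ny),
             rep((seq_len(ny) - 1) * dx, nx), 0)
  f <- list()
  for (i in seq_len(nx - 1)) for (j in seq_len(ny - 1)) {
    f[[length(f) + 1L]] <- c(vid(i, j), vid(i + 1, j), vid(i + 1, j + 1))
    f[[length(f) + 1L]] <- c(vid(i, j), vid(i + 1, j + 1), vid(i, j + 1))
  }
  trimesh(v, do.call(rbind, f))
}

# open cylinder, two boundaries (chi = 0)
cylinder_mesh <- function(nt = 16, nz = 9, r = 5, h = 20) {
  vid <- function(i, j) (i - 1L) * nt + ((j - 1L) %% nt) + 1L
  v <- NULL
  for (i in seq_len(nz)) {
    th <- 2 * pi * (seq_len(nt) - 1) / nt
    v <- rbind(v, cbind(r * cos(th), r * sin(th), h * (i - 1) / (nz - 1)))
  }
  f <- list()
  for (i in seq_len(nz - 1)) for (j in seq_len(nt)) {
    a <- vid(i, j); b <- vid(i, j + 1)
    d <- vid(i + 1, j); cc <- vid(i + 1, j + 1)
    f[[length(f) + 1L]] <- c(a, cc, d)
    f[[length(f) + 1L]] <- c(a, b, cc)
  }
  trimesh(v, do.call(rbind, f))
}

# closed UV sphere (chi = 2)
uv_sphere <- function(r = 1, nt = 16, np = 12) {
  v <- rbind(c(0, 0, r))
  for (i in seq_len(np - 1)) {
    phi <- pi * i / np
    th <- 2 * pi * (seq_len(nt) - 1) / nt
    v <- rbind(v, cbind(r * sin(phi) * cos(th), r * sin(phi) * sin(th),
                        r * cos(phi)))
  }
  v <- rbind(v, c(0, 0, -r))
  south <- nrow(v)
  vid <- function(i, j) 1L + (i - 1L) * nt + ((j - 1L) %% nt) + 1L
  f <- list()
  for (j in seq_len(nt)) f[[length(f) + 1L]] <- c(1L, vid(1, j), vid(1, j + 1))
  for (i in seq_len(np - 2)) for (j in seq_len(nt)) {
    a <- vid(i, j); b <- vid(i, j + 1)
    d <- vid(i + 1, j); cc <- vid(i + 1, j + 1)
    f[[length(f) + 1L]] <- c(a, d, cc)
    f[[length(f) + 1L]] <- c(a, cc, b)
  }
  for (j in seq_len(nt))
    f[[length(f) + 1L]] <- c(south, vid(np - 1, j + 1), vid(np - 1, j))
  trimesh(v, do.call(rbind, f))
}

# O(V^2) Dijkstra, independent of igraph, for cut-graph oracles
dijkstra_oracle <- function(mesh, from, forbidden = integer(0)) {
  et <- mesh_edges(mesh)
  w <- edge_lengths_3d(mesh, et$edges)
  n <- nrow(mesh$vertices)
  adj <- vector("list", n)
  for (k in seq_len(nrow(et$edges))) {
    a <- et$edges[k, 1]; b <- et$edges[k, 2]
    adj[[a]] <- rbind(adj[[a]], c(b, w[k]))
    adj[[b]] <- rbind(adj[[b]], c(a, w[k]))
  }
  dist <- rep(Inf, n)
  dist[from] <- 0
  done <- rep(FALSE, n)
  done[forbidden] <- TRUE
  repeat {
    cand <- which(!done & is.finite(dist))
    if (!length(cand)) break
    u <- cand[which.min(dist[cand])]
    done[u] <- TRUE
    if (!is.null(adj[[u]])) {
      for (r in seq_len(nrow(adj[[u]]))) {
        v <- adj[[u]][r, 1]
        if (!done[v]) {
          nd <- dist[u] + adj[[u]][r, 2]
          if (nd < dist[v]) dist[v] <- nd
        }
      }
    }
  }
  dist
}

dice_overlap <- function(a, b) {
  2 * length(intersect(a, b)) / (length(a) + length(b))
}

# identity planar embedding of a flat mesh lying in z = 0
flat_embedding <- function(mesh, conformal_factor = NULL) {
  planar_embedding(complex(real = mesh$vertices[, 1],
                           imaginary = mesh$vertices[, 2]),
                   mesh$faces, "disk", conformal_factor = conformal_factor)
}
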