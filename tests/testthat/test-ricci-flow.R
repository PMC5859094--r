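test_that("flow is a no-op on already-flat input and enforces topology preconditions", {
  g <- grid_mesh(7, 7)
  met <- ricci_flow_metric(g, "disk_free_boundary")
  expect_true(met$converged)
  expect_identical(met$iterations, 0L)
  expect_equal(max(abs(met$u)), 0)

  expect_error(ricci_flow_metric(fix_femur()$outer, "annulus_zero"),
               "topology error")
  expect_error(ricci_flow_metric(cylinder_mesh(), "disk_free_boundary"),
               "topology error")
})

test_that("disk flow on the femur converges with free boundary and monotone residuals", {
  met <- fix_param()$metrics$disk
  expect_true(met$converged)
  expect_lte(met$residual, 1e-8)
  bnd <- is_boundary_vertex(fix_femur()$outer)
  expect_equal(max(abs(met$u[bnd])), 0)         # boundary metric unchanged
  expect_lt(max(abs(met$achieved_curvature[!bnd])), 1e-8)
  expect_true(all(diff(met$residual_history) < 0))
  # Gauss-Bonnet with the flowed metric (chi = 1)
  expect_lt(abs(sum(met$achieved_curvature) - 2 * pi), 1e-8)
})

test_that("annulus flow flattens every vertex including both boundaries", {
  cyl <- cylinder_mesh()
  met <- ricci_flow_metric(cyl, "annulus_zero", tolerance = 1e-10)
  expect_true(met$converged)
  expect_lt(max(abs(met$achieved_curvature)), 1e-9)
  # total curvature 0 = 2 pi chi: each boundary develops straight
  expect_lt(abs(sum(met$achieved_curvature)), 1e-9)

  met2 <- fix_param()$metrics$annulus
  expect_lt(max(abs(met2$achieved_curvature)), 1e-8)
})

test_that("layout realises the flat metric exactly and never flips faces", {
  par <- fix_param()
  expect_lt(layout_length_error(par$disk, par$metrics$disk), 1e-6)
  expect_gt(min(embedding_signed_areas(par$disk$points, par$disk$faces)), 0)
  expect_gt(min(embedding_signed_areas(par$strip$points, par$strip$faces)), 0)
  expect_gt(min(embedding_signed_areas(par$annulus$points,
                                       par$annulus$faces)), 0)
  # flat input is reproduced up to rigid motion: pairwise distances match
  g <- grid_mesh(6, 5)
  met <- ricci_flow_metric(g, "disk_free_boundary")
  emb <- embed_disk(g, met)
  d_in <- dist(g$vertices[, 1:2])
  d_out <- dist(cbind(Re(emb$points), Im(emb$points)))
  expect_lt(max(abs(d_in - d_out)), 1e-9)
})

test_that("angle distortion decreases under mesh refinement", {
  distortion <- vapply(list(c(16, 20), c(24, 32), c(36, 48)), function(rs) {
    spec <- femur_spec(n_theta = rs[1], n_rings = rs[2])
    mesh <- make_femur(spec)$outer
    met <- ricci_flow_metric(mesh, "disk_free_boundary", tolerance = 1e-10)
    a3 <- corner_angles(mesh)
    a2 <- corner_angles(mesh, met$edge_lengths)
    mean(abs(a3 - a2))
  }, 0)
  expect_true(all(diff(distortion) < 0))
})

test_that("cut graph is the shortest boundary-avoiding path (Dijkstra oracle)", {
  fem <- make_femur(femur_spec(n_theta = 16, n_rings = 20))
  mesh <- fem$outer
  top <- mesh_topology(mesh)
  from <- fem$ground_truth$apex$GT
  path <- cut_graph(mesh, from, 1)
  expect_false(anyDuplicated(path) > 0)
  expect_true(path[length(path)] %in% top$loops[[1]])
  expect_true(all(!path[-length(path)] %in% top$loops[[1]]))
  # length equals the exhaustive-Dijkstra optimum
  seg <- mesh$vertices[path[-1], , drop = FALSE] -
    mesh$vertices[path[-length(path)], , drop = FALSE]
  plen <- sum(sqrt(rowSums(seg^2)))
  dist <- dijkstra_oracle(mesh, from)
  expect_equal(plen, min(dist[top$loops[[1]]]), tolerance = 1e-12)

  # vertex adjacent to the boundary: single-edge path
  ring <- vertex_rings(mesh)
  bnd_v <- top$loops[[1]][1]
  inner_nb <- setdiff(ring[[bnd_v]], top$loops[[1]])[1]
  p2 <- cut_graph(mesh, inner_nb, 1)
  expect_identical(length(p2), 2L)
})

test_that("slitting changes topology as predicted and duplicates the right vertices", {
  # interior edge path in a grid: chi 1 -> 0, b 1 -> 2, N + k vertices
  g <- grid_mesh(7, 7)
  path <- c(17, 24, 31)        # interior column
  expect_true(all(!is_boundary_vertex(g)[path]))
  s <- slit_mesh(g, path, mode = "edge_path")
  chi <- euler_characteristic(s$mesh)
  expect_identical(as.integer(chi), 0L)
  expect_identical(attr(chi, "n_boundary"), 2L)
  expect_identical(nrow(s$mesh$vertices), nrow(g$vertices) + 1L)  # k = 1

  # cutting the annulus along a boundary-to-boundary path gives a disk
  cyl <- cylinder_mesh(nt = 12, nz = 6)
  p <- c(1, 13, 25, 37, 49, 61)
  s2 <- slit_mesh(cyl, p, mode = "edge_path")
  chi2 <- euler_characteristic(s2$mesh)
  expect_identical(as.integer(chi2), 1L)
  expect_identical(attr(chi2, "n_boundary"), 1L)
  expect_identical(nrow(s2$mesh$vertices), nrow(cyl$vertices) + length(p))

  # a path with an interior vertex on the boundary is unsupported
  expect_error(slit_mesh(g, c(10, 3, 11), mode = "edge_path"),
               "unsupported-slit")
  # provenance maps duplicates to their originals
  expect_identical(s$orig_vertex[nrow(s$mesh$vertices)], 24L)
})

test_that("planar-line slitting splits crossed faces and reaches the target topology", {
  g <- grid_mesh(9, 9)
  emb <- flat_embedding(g)
  # diagonal-ish segment between two interior vertices not joined by edges
  from <- 21; to <- 60   # (2,2) to (6,5): crosses edges away from vertices
  seg <- list(from = emb$points[from], to = emb$points[to],
              from_vertex = from, to_vertex = to)
  s <- slit_mesh(g, seg, mode = "planar_line", embedding = emb)
  chi <- euler_characteristic(s$mesh)
  expect_identical(as.integer(chi), 0L)
  expect_identical(attr(chi, "n_boundary"), 2L)
  # inserted vertices carry NA provenance, duplicated ones their original
  expect_true(any(is.na(s$orig_vertex)))
  expect_gt(min(embedding_signed_areas(s$embedding$points,
                                       s$embedding$faces)), 0)
})

test_that("strip normalisation pins the slit to [0, 2*pi] on the imaginary axis", {
  par <- fix_param()
  st <- par$strip
  ch <- st$extra$slit_chain
  expect_lt(max(abs(Re(st$points[ch]))), 1e-9)
  expect_equal(min(Im(st$points[ch])), 0, tolerance = 1e-12)
  expect_equal(max(Im(st$points[ch])), 2 * pi, tolerance = 1e-12)
  expect_lte(max(Re(st$points)), 1e-9)

  # already-normalised input: identity up to 1e-12
  st2 <- normalise_strip(st, ch)
  expect_lt(max(abs(st2$points - st$points)), 1e-12)

  # axis-aligned unit-square fundamental domain scales by exactly 2*pi
  g <- grid_mesh(5, 5, dx = 0.25)
  emb0 <- flat_embedding(g)
  chain_ids <- which(abs(Re(emb0$points) - 1) < 1e-12)
  chain_ids <- chain_ids[order(Im(emb0$points[chain_ids]))]
  ns <- normalise_strip(emb0, chain_ids)
  expect_equal(abs(ns$points[chain_ids[2]] - ns$points[chain_ids[1]]) /
                 abs(emb0$points[chain_ids[2]] - emb0$points[chain_ids[1]]),
               2 * pi, tolerance = 1e-12)
  expect_equal(sort(Im(ns$points[chain_ids]))[1], 0)
  expect_equal(max(Im(ns$points[chain_ids])), 2 * pi)
  expect_lte(max(Re(ns$points)), 1e-12)
})

test_that("the exponential map sends the strip to the annulus", {
  par <- fix_param()
  ann <- par$annulus
  st <- par$strip
  expect_equal(ann$points, exp(st$points))
  ch <- st$extra$slit_chain
  expect_lt(max(abs(Mod(ann$points[ch]) - 1)), 1e-9)
  expect_true(all(Mod(ann$points) <= 1 + 1e-9))
  expect_equal(min(Mod(ann$points)), exp(min(Re(st$points))))
  # endpoints of a 2*pi span map to the same point
  expect_lt(abs(exp(0 + 0i) - exp(0 + 2i * pi)), 1e-15)
  expect_equal(exp(complex(real = -2, imaginary = 0)), exp(-2) + 0i)
})
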