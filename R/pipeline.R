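#' Fully automatic two-step conformal parametrisation of a proximal femur
#'
#' Runs the whole chain with no user input: free-boundary Ricci flow and
#' disk embedding; femoral head (FH) and greater trochanter (GT) detection
#' from conformal-factor peaks; slit along the straight inter-feature
#' segment in the disk (giving a chi = 0 annulus-type surface); zero-target
#' Ricci flow; cut graph from GT to the distal boundary; development of the
#' fundamental domain; normalisation so the inter-feature boundary spans
#' `[0, 2*pi]` on the imaginary axis; lesser trochanter (LT) detection and
#' Gaussian region fits in the strip frame; exponential map to the annulus.
#'
#' @param mesh outer surface `TriMesh` with chi = 1 (genus 0, one boundary).
#' @param tolerance Ricci-flow curvature tolerance (radians).
#' @param max_iter Newton iteration cap per flow.
#' @param min_prominence prominence threshold for the disk FH/GT peaks.
#' @param lt_min_prominence prominence threshold for the LT peak on the
#'   strip (the annulus-metric conformal factor varies on a smaller scale).
#' @return object of class `FemurParametrisation`: list with
#'   `mesh`, `disk`, `strip`, `annulus` (`PlanarEmbedding`s),
#'   `features` (FH/GT on the disk, FH/LT as strip-frame `FeatureRegion`s,
#'   GT strip positions), `slit` (the twice-slit mesh and provenance),
#'   `metrics` (both `RicciMetric`s) and `log` (iterations, residuals).
#' @export
parametrise_femur <- function(mesh, tolerance = 1e-8, max_iter = 50,
                              min_prominence = 0.1,
                              lt_min_prominence = 0.02) {
  t_start <- Sys.time()
  disk_metric <- ricci_flow_metric(mesh, "disk_free_boundary",
                                   tolerance = tolerance, max_iter = max_iter)
  disk <- embed_disk(mesh, disk_metric)
  det <- detect_disk_features(disk, min_prominence = min_prominence)
  fh_region_disk <- fit_feature_region(disk, det$FH)
  gt_region_disk <- fit_feature_region(disk, det$GT)
  seg <- inter_feature_segment(disk, det$FH, det$GT)
  s1 <- slit_mesh(mesh, seg, mode = "planar_line", embedding = disk)
  annulus_metric <- ricci_flow_metric(s1$mesh, "annulus_zero",
                                      tolerance = tolerance,
                                      max_iter = max_iter)
  # GT id is preserved by the first slit (interior endpoints not duplicated)
  gt2 <- seg$to_vertex
  fh2 <- seg$from_vertex
  top2 <- mesh_topology(s1$mesh)
  # distal loop = the boundary loop not containing FH
  distal_loop <- which(!vapply(top2$loops, function(l) fh2 %in% l, TRUE))[1]
  cut <- cut_graph(s1$mesh, gt2, to_boundary = distal_loop)
  s2 <- slit_mesh(s1$mesh, cut, mode = "edge_path")
  mesh3 <- s2$mesh
  # flat metric on the cut mesh: u carried over to duplicated vertices
  u3 <- annulus_metric$u[s2$orig_vertex]
  et3 <- mesh_edges(mesh3)
  l3 <- edge_lengths_3d(mesh3, et3$edges) *
    exp((u3[et3$edges[, 1]] + u3[et3$edges[, 2]]) / 2)
  metric3 <- list(edge_lengths = l3, edges = et3$edges, u = u3)
  # provenance of mesh3 vertices back to the input mesh
  orig2 <- ifelse(is.na(s1$orig_vertex), NA_integer_, s1$orig_vertex)
  orig3 <- orig2[s2$orig_vertex]
  # the inter-feature (slit) chain on mesh3: the boundary arc between the
  # two GT copies that contains FH
  gt_a <- s2$side_a[1]
  gt_b <- s2$side_b[1]
  loop3 <- boundary_loops(mesh3)
  if (length(loop3) != 1) stop("internal error: cut surface should have one boundary")
  loop3 <- loop3[[1]]
  ia <- match(gt_a, loop3); ib <- match(gt_b, loop3)
  if (is.na(ia) || is.na(ib)) stop("internal error: GT copies not on boundary")
  if (ia > ib) { tmp <- ia; ia <- ib; ib <- tmp }
  arc1 <- loop3[ia:ib]
  arc2 <- c(loop3[ib:length(loop3)], loop3[1:ia])
  chain <- if (fh2 %in% arc1) arc1 else arc2
  if (!fh2 %in% chain) stop("internal error: FH not on slit boundary arc")
  seed_face <- min(which(apply(
    matrix(mesh3$faces %in% chain, nrow(mesh3$faces)), 1, any)))
  pos3 <- layout_flat_metric(mesh3, metric3, seed_face = seed_face)
  dev3 <- planar_embedding(pos3, mesh3$faces, "disk",
                           conformal_factor = -u3, orig_vertex = orig3)
  strip <- normalise_strip(dev3, chain)
  fh3 <- which(orig3 == orig2[fh2])[1]
  lt <- tryCatch(
    detect_lt(strip, exclusion = list(fh_region_disk, gt_region_disk),
              min_prominence = lt_min_prominence),
    error = function(e) NULL)
  lt_region <- if (!is.null(lt)) fit_feature_region(strip, lt) else NULL
  # the FH process peak of the strip conformal factor may sit a few rings
  # from the FH vertex (the annulus metric is a different flat structure):
  # ascend to the local maximum before fitting the region
  adj3 <- embedding_adjacency(strip)
  fh_peak3 <- ascend_to_peak(strip$conformal_factor, adj3, fh3)
  fh_strip_pt <- feature_point(fh_peak3, strip$points[fh_peak3], "FH",
                               strip$conformal_factor[fh_peak3])
  fh_region_strip <- fit_feature_region(strip, fh_strip_pt)
  annulus <- exponential_map(strip)
  out <- list(
    mesh = mesh,
    disk = disk,
    strip = strip,
    annulus = annulus,
    features = list(FH_disk = det$FH, GT_disk = det$GT,
                    FH_strip = fh_strip_pt, LT_strip = lt,
                    gt_strip_ids = c(gt_a, gt_b), fh_strip_id = fh3),
    regions = list(FH_disk = fh_region_disk, GT_disk = gt_region_disk,
                   FH_strip = fh_region_strip, LT_strip = lt_region),
    slit = list(first = s1, cut_path = cut, second = s2, mesh3 = mesh3,
                chain = chain, orig_vertex = orig3),
    metrics = list(disk = disk_metric, annulus = annulus_metric),
    log = list(
      disk_iterations = disk_metric$iterations,
      disk_residual = disk_metric$residual,
      annulus_iterations = annulus_metric$iterations,
      annulus_residual = annulus_metric$residual,
      lt_detected = !is.null(lt),
      seconds = as.numeric(Sys.time() - t_start, units = "secs"))
  )
  class(out) <- "FemurParametrisation"
  out
}

#' @export
print.FemurParametrisation <- function(x, ...) {
  cat(sprintf(
    "FemurParametrisation: %d vertices; disk flow %d it (res %.2g), annulus flow %d it (res %.2g)\n",
    nrow(x$mesh$vertices), x$log$disk_iterations, x$log$disk_residual,
    x$log$annulus_iterations, x$log$annulus_residual))
  cat(sprintf("  FH at strip (%.4g, %.4g); LT %s; %.1f s\n",
              Re(x$features$FH_strip$position),
              Im(x$features$FH_strip$position),
              if (x$log$lt_detected) "detected" else "not detected",
              x$log$seconds))
  invisible(x)
}
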