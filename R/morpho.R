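#' Cortical thickness at outer-surface nodes
#'
#' Thickness at each node of the outer (periosteal) surface is the shortest
#' distance to the inner (endosteal) surface.
#'
#' @param outer outer `TriMesh` (or an n x 3 matrix of node positions).
#' @param inner inner `TriMesh`.
#' @return numeric vector of thickness (mm), one per outer node.
#' @export
cortical_thickness <- function(outer, inner) {
  pts <- if (inherits(outer, "TriMesh")) outer$vertices else as.matrix(outer)
  point_to_surface_distance(pts, inner)
}

# optimal rotation (no reflection) aligning X onto Y, both centred
kabsch_rotation <- function(X, Y) {
  s <- svd(crossprod(X, Y))
  d <- sign(det(s$u %*% t(s$v)))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

#' Generalised Procrustes alignment of an isotopological set
#'
#' Iterative removal of translation, rotation and (optionally) scale about
#' the evolving mean shape, to convergence of the mean-shape change below
#' `tol`. Rotations are proper (no reflections - anatomy is chiral). The
#' per-subject scale factor is the Procrustes scale of the mean-to-subject
#' similarity fit, so it measures subject size relative to the canonical
#' (mean) shape.
#'
#' @param shapes an `IsotopologicalSet`, or a list of n x 3 matrices with
#'   identical n.
#' @param scale_normalise remove size before averaging (default TRUE).
#' @param tol convergence tolerance on mean-shape RMS change.
#' @param max_iter iteration cap.
#' @return object of class `ShapeModel`: list with `mean` (n x 3),
#'   `aligned` (list of n x 3), `scale` (per subject), `rss` (Procrustes
#'   sum of squares history), `scale_normalise`.
#' @export
generalized_procrustes <- function(shapes, scale_normalise = TRUE,
                                   tol = 1e-10, max_iter = 100) {
  if (inherits(shapes, "IsotopologicalSet")) shapes <- shapes$coords
  shapes <- lapply(shapes, as.matrix)
  s <- length(shapes)
  if (s < 2) stop("need at least two shapes")
  n <- nrow(shapes[[1]])
  if (any(vapply(shapes, nrow, 0L) != n))
    stop("shapes must share the node count")
  centred <- lapply(shapes, function(x) sweep(x, 2, colMeans(x)))
  cs <- vapply(centred, function(x) sqrt(sum(x^2)), 0)
  if (any(cs == 0)) stop("alignment error: degenerate (all-coincident) shape")
  aligned <- if (scale_normalise) {
    Map(function(x, k) x / k, centred, cs)
  } else centred
  mean_shape <- aligned[[1]]
  rss <- numeric(0)
  for (it in seq_len(max_iter)) {
    aligned <- lapply(aligned, function(x) x %*% kabsch_rotation(x, mean_shape))
    new_mean <- Reduce(`+`, aligned) / s
    if (scale_normalise) new_mean <- new_mean / sqrt(sum(new_mean^2))
    rss <- c(rss, sum(vapply(aligned,
                             function(x) sum((x - new_mean)^2), 0)))
    delta <- sqrt(mean((new_mean - mean_shape)^2))
    mean_shape <- new_mean
    if (delta < tol && it > 1) break
  }
  # scale of the Procrustes fit of the mean onto each original shape,
  # reported relative to the cohort (geometric mean 1)
  scale <- vapply(centred, function(x) {
    r <- kabsch_rotation(mean_shape, x)
    sum((mean_shape %*% r) * x) / sum(mean_shape^2)
  }, 0)
  scale <- scale / exp(mean(log(scale)))
  structure(list(mean = mean_shape, aligned = aligned, scale = scale,
                 rss = rss, scale_normalise = scale_normalise,
                 n_iter = length(rss)),
            class = "ShapeModel")
}

#' @export
print.ShapeModel <- function(x, ...) {
  cat(sprintf("ShapeModel: %d subjects x %d nodes, GPA %d iterations\n",
              length(x$aligned), nrow(x$mean), x$n_iter))
  if (!is.null(x$explained))
    cat("  modes:", length(x$explained), "; explained:",
        paste(sprintf("%.1f%%", 100 * x$explained), collapse = ", "), "\n")
  invisible(x)
}

#' Shape modes (principal components of aligned vertex displacements)
#'
#' PCA of the mean-centred aligned coordinate vectors from a generalised
#' Procrustes alignment. Mode loadings are orthonormal 3n-vectors, scores
#' are per-subject projections, and explained-variance fractions are
#' non-increasing.
#'
#' @param model a `ShapeModel` from [generalized_procrustes()].
#' @param n_modes number of modes to keep (default 5).
#' @return the `ShapeModel` with `loadings` (3n x n_modes), `scores`
#'   (subjects x n_modes), `explained` (variance fractions) added.
#' @export
shape_modes <- function(model, n_modes = 5) {
  stopifnot(inherits(model, "ShapeModel"))
  s <- length(model$aligned)
  if (n_modes > s - 1)
    stop("argument error: n_modes must be <= n_subjects - 1")
  X <- t(vapply(model$aligned, as.numeric, numeric(3 * nrow(model$mean))))
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  tot <- sum(pc$sdev^2)
  model$loadings <- pc$rotation[, seq_len(n_modes), drop = FALSE]
  model$scores <- pc$x[, seq_len(n_modes), drop = FALSE]
  model$explained <- pc$sdev[seq_len(n_modes)]^2 / tot
  model$center <- pc$center
  model
}

#' Generalised Procrustes alignment of sparse landmark sets
#'
#' Utility for annotation-style validation: mutually aligns K-point
#' landmark sets (K >= 3) and returns the aligned sets and their mean.
#' Reflections are not allowed; a mirror-image set keeps a nonzero
#' residual rather than being flipped.
#'
#' @param annotation_sets list of K x 3 matrices with equal K.
#' @param scale_normalise remove size (default TRUE).
#' @return list with `aligned` (list of K x 3), `mean` (K x 3),
#'   `residual` (per-set RMS distance to the mean).
#' @export
align_point_sets <- function(annotation_sets, scale_normalise = TRUE) {
  k <- vapply(annotation_sets, nrow, 0L)
  if (length(unique(k)) != 1) stop("argument error: point counts differ")
  if (k[1] < 3) stop("argument error: need at least 3 points per set")
  gpa <- generalized_procrustes(annotation_sets,
                                scale_normalise = scale_normalise)
  resid <- vapply(gpa$aligned, function(x) sqrt(mean((x - gpa$mean)^2)), 0)
  list(aligned = gpa$aligned, mean = gpa$mean, residual = resid,
       scale = gpa$scale)
}
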