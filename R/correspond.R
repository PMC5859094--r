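#' Canonical 2D template from a reference parametrisation
#'
#' The template is the normalised strip mesh of a designated reference
#' subject, cropped at a distal limit so it never extends past the shorter
#' subjects in the cohort. Its FH and LT feature regions drive the
#' per-subject RBF correction.
#'
#' @param param a `FemurParametrisation` (the reference subject).
#' @param distal_limit positive depth (strip units): template keeps
#'   vertices with real coordinate >= -distal_limit. Use
#'   [cohort_distal_limit()] for the usual 95%-of-minimum rule.
#' @return object of class `Template2D`: list with `points` (complex),
#'   `faces`, `regions` (FH, LT `FeatureRegion`s), `distal_limit`,
#'   `keep` (ids of kept vertices on the source strip).
#' @export
make_template <- function(param, distal_limit = NULL) {
  stopifnot(inherits(param, "FemurParametrisation"))
  strip <- param$strip
  if (is.null(param$regions$LT_strip))
    stop("reference subject has no detected LT region")
  if (is.null(distal_limit)) distal_limit <- -min(Re(strip$points))
  keep <- which(Re(strip$points) >= -distal_limit)
  idx <- match(seq_along(strip$points), keep)
  fk <- matrix(idx[strip$faces], ncol = 3)
  fk <- fk[stats::complete.cases(fk), , drop = FALSE]
  used <- sort(unique(c(fk)))
  if (length(used) < length(keep)) {       # drop isolated vertices
    keep <- keep[used]
    idx <- match(seq_along(strip$points), keep)
    fk <- matrix(idx[strip$faces], ncol = 3)
    fk <- fk[stats::complete.cases(fk), , drop = FALSE]
  }
  structure(list(points = strip$points[keep], faces = fk,
                 regions = list(FH = param$regions$FH_strip,
                                LT = param$regions$LT_strip),
                 distal_limit = distal_limit, keep = keep),
            class = "Template2D")
}

#' Common distal limit for a cohort
#'
#' 95% (by default) of the minimum distal extent of the normalised strips,
#' so the template stays inside every subject's parametrised domain.
#'
#' @param params list of `FemurParametrisation`s.
#' @param fraction fraction of the minimum extent to keep.
#' @return positive depth in strip units.
#' @export
cohort_distal_limit <- function(params, fraction = 0.95) {
  fraction * min(vapply(params, function(p) -min(Re(p$strip$points)), 0))
}

# Wendland C2 kernel, compact support rho
wendland_c2 <- function(r, rho) {
  x <- r / rho
  ifelse(x < 1, (1 - x)^4 * (4 * x + 1), 0)
}

#' Wendland RBF deformation matching feature regions
#'
#' Control points are the region centre plus `n_ring` points on the
#' 1-sigma ellipse of each template region; their prescribed displacements
#' send the template centre to the target centre and the template ellipse
#' onto the target ellipse by translation plus symmetric (rotation-free)
#' principal-axis scaling `Sigma_target^(1/2) Sigma_template^(-1/2)`. The
#' compactly supported Wendland C2 kernel interpolates these displacements
#' exactly and vanishes identically beyond distance `rho` from every
#' control point.
#'
#' @param template_regions list of `FeatureRegion`s (usually FH and LT).
#' @param target_regions matching list for the target subject.
#' @param rho support radius (strip units); default 2x the largest
#'   1-sigma extent among the template regions.
#' @param n_ring ellipse control points per region.
#' @return object of class `RBFDeformation`.
#' @export
build_rbf <- function(template_regions, target_regions, rho = NULL,
                      n_ring = 8) {
  stopifnot(length(template_regions) == length(target_regions))
  sym_sqrt <- function(S) {
    e <- eigen(S, symmetric = TRUE)
    if (any(e$values <= 0)) stop("degenerate region covariance")
    e$vectors %*% diag(sqrt(e$values)) %*% t(e$vectors)
  }
  ctrl <- NULL; disp <- NULL
  sig_max <- 0
  for (k in seq_along(template_regions)) {
    rT <- template_regions[[k]]; rt <- target_regions[[k]]
    ST <- sym_sqrt(rT$covariance); St <- sym_sqrt(rt$covariance)
    sig_max <- max(sig_max, sqrt(max(eigen(rT$covariance,
                                           symmetric = TRUE)$values)))
    ang <- 2 * pi * (seq_len(n_ring) - 1) / n_ring
    circ <- rbind(cos(ang), sin(ang))
    muT <- c(Re(rT$centre), Im(rT$centre))
    mut <- c(Re(rt$centre), Im(rt$centre))
    pT <- cbind(muT[1] + t(ST %*% circ)[, 1], muT[2] + t(ST %*% circ)[, 2])
    pt <- cbind(mut[1] + t(St %*% circ)[, 1], mut[2] + t(St %*% circ)[, 2])
    ctrl <- rbind(ctrl, matrix(muT, 1), pT)
    disp <- rbind(disp, matrix(mut - muT, 1), pt - pT)
  }
  if (is.null(rho)) rho <- 2 * sig_max
  d2 <- outer(ctrl[, 1], ctrl[, 1], "-")^2 + outer(ctrl[, 2], ctrl[, 2], "-")^2
  phi <- wendland_c2(sqrt(d2), rho)
  coef <- tryCatch(solve(phi, disp), error = function(e)
    stop("solver error: ill-conditioned RBF kernel matrix; ",
         "try a larger support radius rho"))
  structure(list(control = ctrl, displacement = disp, coef = coef,
                 rho = rho), class = "RBFDeformation")
}

#' Apply an RBF deformation to planar points
#'
#' @param def an `RBFDeformation`.
#' @param points complex vector of planar positions.
#' @return complex vector of displaced positions.
#' @export
rbf_deform <- function(def, points) {
  x <- Re(points); y <- Im(points)
  dx <- outer(x, def$control[, 1], "-")
  dy <- outer(y, def$control[, 2], "-")
  phi <- wendland_c2(sqrt(dx^2 + dy^2), def$rho)
  d <- phi %*% def$coef
  complex(real = x + d[, 1], imaginary = y + d[, 2])
}

#' Natural representation of template nodes on a target embedding
#'
#' Locates each template node in a face of the target planar mesh and
#' records barycentric weights. A node exactly on a shared edge or vertex is
#' assigned to the lowest-index containing face. Nodes outside the target
#' domain are clamped to the nearest point on the target boundary and
#' flagged.
#'
#' @param points complex template-node positions (already RBF-corrected).
#' @param target a `PlanarEmbedding` (the target strip).
#' @param tol barycentric containment tolerance.
#' @return object of class `CorrespondenceMap`: list with `face`,
#'   `weights` (n x 3), `clamped` (logical).
#' @export
natural_representation <- function(points, target, tol = 1e-9) {
  sa <- embedding_signed_areas(target$points, target$faces)
  if (any(sa <= 0))
    stop("geometry error: target embedding has flipped faces")
  f <- target$faces
  tp <- target$points
  ax <- Re(tp[f[, 1]]); ay <- Im(tp[f[, 1]])
  bx <- Re(tp[f[, 2]]); by <- Im(tp[f[, 2]])
  cx <- Re(tp[f[, 3]]); cy <- Im(tp[f[, 3]])
  # grid binning of face bounding boxes
  ng <- max(8L, floor(sqrt(nrow(f) / 2)))
  xr <- range(ax, bx, cx); yr <- range(ay, by, cy)
  gx <- function(x) pmin(ng, pmax(1, floor((x - xr[1]) / diff(xr) * ng) + 1))
  gy <- function(y) pmin(ng, pmax(1, floor((y - yr[1]) / diff(yr) * ng) + 1))
  cell <- vector("list", ng * ng)
  flo_x <- gx(pmin(ax, bx, cx)); fhi_x <- gx(pmax(ax, bx, cx))
  flo_y <- gy(pmin(ay, by, cy)); fhi_y <- gy(pmax(ay, by, cy))
  for (i in seq_len(nrow(f))) {
    for (ix in flo_x[i]:fhi_x[i]) for (iy in flo_y[i]:fhi_y[i]) {
      k <- (iy - 1) * ng + ix
      cell[[k]] <- c(cell[[k]], i)
    }
  }
  denom <- (bx - ax) * (cy - ay) - (by - ay) * (cx - ax)
  n <- length(points)
  face_id <- integer(n)
  wts <- matrix(0, n, 3)
  clamped <- rep(FALSE, n)
  bd_cache <- NULL
  px_all <- Re(points); py_all <- Im(points)
  for (i in seq_len(n)) {
    px <- px_all[i]; py <- py_all[i]
    cand <- cell[[(gy(py) - 1) * ng + gx(px)]]
    hit <- 0L
    if (length(cand)) {
      wb <- ((px - ax[cand]) * (cy[cand] - ay[cand]) -
               (py - ay[cand]) * (cx[cand] - ax[cand])) / denom[cand]
      wc <- ((bx[cand] - ax[cand]) * (py - ay[cand]) -
               (by[cand] - ay[cand]) * (px - ax[cand])) / denom[cand]
      wa <- 1 - wb - wc
      ok <- which(wa >= -tol & wb >= -tol & wc >= -tol)
      if (length(ok)) {
        j <- ok[which.min(cand[ok])]
        hit <- cand[j]
        w <- pmax(c(wa[j], wb[j], wc[j]), 0)
        wts[i, ] <- w / sum(w)
      }
    }
    if (hit == 0L) {
      clamped[i] <- TRUE
      if (is.null(bd_cache)) bd_cache <- boundary_cache(target)
      cl <- clamp_to_boundary(px, py, target, bd_cache)
      hit <- cl$face
      wts[i, ] <- cl$weights
    }
    face_id[i] <- hit
  }
  structure(list(face = face_id, weights = wts, clamped = clamped),
            class = "CorrespondenceMap")
}

boundary_cache <- function(target) {
  m2 <- trimesh(cbind(Re(target$points), Im(target$points), 0),
                target$faces, validate = FALSE)
  et <- mesh_edges(m2)
  be <- et$edges[et$boundary, , drop = FALSE]
  # face adjacent to each boundary edge
  K <- as.double(length(target$points)) + 1
  fc <- target$faces
  a <- c(fc[, 1], fc[, 2], fc[, 3]); b <- c(fc[, 2], fc[, 3], fc[, 1])
  allk <- pmin(a, b) * K + pmax(a, b)
  fid <- rep(seq_len(nrow(fc)), times = 3)
  bk <- pmin(be[, 1], be[, 2]) * K + pmax(be[, 1], be[, 2])
  list(edges = be, face = fid[match(bk, allk)])
}

# nearest point on the boundary of the embedded mesh, as barycentric
# weights in the face adjacent to the winning boundary edge
clamp_to_boundary <- function(px, py, target, bd) {
  ax <- Re(target$points[bd$edges[, 1]]); ay <- Im(target$points[bd$edges[, 1]])
  bx <- Re(target$points[bd$edges[, 2]]); by <- Im(target$points[bd$edges[, 2]])
  ex <- bx - ax; ey <- by - ay
  t <- ((px - ax) * ex + (py - ay) * ey) / (ex^2 + ey^2)
  t <- pmin(1, pmax(0, t))
  qx <- ax + t * ex; qy <- ay + t * ey
  d2 <- (px - qx)^2 + (py - qy)^2
  j <- which.min(d2)
  fi <- bd$face[j]
  fc <- target$faces[fi, ]
  w <- numeric(3)
  w[match(bd$edges[j, 1], fc)] <- 1 - t[j]
  w[match(bd$edges[j, 2], fc)] <- t[j]
  list(face = fi, weights = w)
}

#' Resample target coordinates and fields at template nodes
#'
#' Barycentric interpolation of the target's 3D vertex coordinates and of
#' every per-vertex scalar field. Has linear precision: any field that is an
#' affine function of the planar coordinates is reproduced exactly.
#'
#' @param map a `CorrespondenceMap` for the target.
#' @param target the target `TriMesh` whose vertices correspond to the
#'   embedding the map was built against (for a parametrised femur this is
#'   the twice-slit mesh carrying interpolated fields).
#' @return list with `coords` (n x 3) and `fields` (named list of numeric
#'   vectors).
#' @export
resample <- function(map, target) {
  f <- target$faces[map$face, , drop = FALSE]
  w <- map$weights
  interp <- function(vals) {
    w[, 1] * vals[f[, 1]] + w[, 2] * vals[f[, 2]] + w[, 3] * vals[f[, 3]]
  }
  coords <- cbind(interp(target$vertices[, 1]),
                  interp(target$vertices[, 2]),
                  interp(target$vertices[, 3]))
  fields <- lapply(target$fields, interp)
  list(coords = coords, fields = fields)
}

#' Build an isotopological surface set by registering a template to a cohort
#'
#' For every parametrised subject: fit the RBF correction from the FH and LT
#' feature regions, deform the template, locate its nodes on the subject's
#' strip (natural representation), and resample 3D coordinates and fields.
#' The output surfaces all share the template connectivity.
#'
#' @param template a `Template2D`.
#' @param params list of `FemurParametrisation`s (the targets).
#' @param rho RBF support radius; default 2x the largest template region
#'   sigma (see [build_rbf()]).
#' @param subject_ids optional character ids.
#' @return object of class `IsotopologicalSet`: list with `faces`,
#'   `points2d` (template), `coords` (list of n x 3 per subject), `fields`
#'   (field name -> n x S matrix), `clamped` (n x S logical), `subject_ids`,
#'   `n_clamped` (per subject), `errors` (named list of per-subject
#'   failures, empty when all succeeded).
#' @export
build_isotopological_set <- function(template, params, rho = NULL,
                                     subject_ids = NULL) {
  stopifnot(inherits(template, "Template2D"))
  s <- length(params)
  if (is.null(subject_ids)) subject_ids <- sprintf("subj%03d", seq_len(s))
  coords <- vector("list", s)
  clamped <- NULL
  fields <- NULL
  errors <- list()
  for (k in seq_len(s)) {
    res <- tryCatch({
      p <- params[[k]]
      if (is.null(p$regions$LT_strip))
        stop("subject has no detected LT region")
      def <- build_rbf(template$regions,
                       list(FH = p$regions$FH_strip, LT = p$regions$LT_strip),
                       rho = rho)
      pts <- rbf_deform(def, template$points)
      map <- natural_representation(pts, p$strip)
      rs <- resample(map, p$slit$mesh3)
      list(map = map, rs = rs)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors[[subject_ids[k]]] <- conditionMessage(res)
      next
    }
    coords[[k]] <- res$rs$coords
    if (is.null(clamped))
      clamped <- matrix(FALSE, length(template$points), s)
    clamped[, k] <- res$map$clamped
    for (nm in names(res$rs$fields)) {
      if (is.null(fields[[nm]]))
        fields[[nm]] <- matrix(NA_real_, length(template$points), s)
      fields[[nm]][, k] <- res$rs$fields[[nm]]
    }
  }
  structure(list(faces = template$faces, points2d = template$points,
                 coords = coords, fields = fields, clamped = clamped,
                 subject_ids = subject_ids,
                 n_clamped = if (is.null(clamped)) rep(NA_integer_, s)
                             else colSums(clamped),
                 errors = errors),
            class = "IsotopologicalSet")
}

#' @export
print.IsotopologicalSet <- function(x, ...) {
  ok <- sum(!vapply(x$coords, is.null, TRUE))
  cat(sprintf(
    "IsotopologicalSet: %d/%d subjects registered on %d nodes / %d faces\n",
    ok, length(x$coords), length(x$points2d), nrow(x$faces)))
  if (length(x$errors))
    cat("  failures:", paste(names(x$errors), collapse = ", "), "\n")
  invisible(x)
}
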