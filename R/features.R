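#' Feature points and regions from conformal-factor fields
#'
#' Protruding processes of the surface (femoral head, trochanters) are
#' compressed by the flattening, so they appear as peaks of the conformal
#' factor over the planar mesh. Peaks are ranked by topographic prominence
#' computed by watershed flooding: vertices are processed from high to low
#' conformal factor, merging basins across 1-ring edges; when a peak's basin
#' first touches a basin with a higher peak, its prominence is fixed as peak
#' height minus the merge level.
#'
#' @name feature-detection
NULL

# watershed prominence of interior local maxima of a vertex field.
# Returns data.frame(vertex, height, prominence) sorted by prominence.
peak_prominence <- function(field, adj, eligible = rep(TRUE, length(field))) {
  n <- length(field)
  ord <- order(field, decreasing = TRUE)
  comp <- rep(0L, n)          # basin id per processed vertex
  parent <- integer(0)        # union-find over basins
  peak_of <- integer(0)       # basin id -> peak vertex
  prom <- numeric(0)          # per basin (NA until fixed)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (v in ord) {
    nb <- adj[[v]]
    nb <- nb[comp[nb] != 0L]
    if (!length(nb)) {
      parent[length(parent) + 1L] <- length(parent) + 1L
      peak_of[length(peak_of) + 1L] <- v
      prom[length(prom) + 1L] <- NA_real_
      comp[v] <- length(parent)
      next
    }
    roots <- unique(vapply(comp[nb], find, 1L))
    # attach v to the basin with the highest peak
    hts <- field[peak_of[roots]]
    main <- roots[which.max(hts)]
    comp[v] <- main
    for (r in roots) {
      if (r == main) next
      # lower peak dies here: prominence = its height - current level
      if (is.na(prom[r])) prom[r] <- field[peak_of[r]] - field[v]
      parent[r] <- main
    }
  }
  live <- which(parent == seq_along(parent))
  prom[live] <- field[peak_of[live]] - min(field)
  keep <- eligible[peak_of]
  out <- data.frame(vertex = peak_of[keep], height = field[peak_of[keep]],
                    prominence = prom[keep])
  out[order(-out$prominence), , drop = FALSE]
}

embedding_adjacency <- function(embedding) {
  mesh <- trimesh(cbind(Re(embedding$points), Im(embedding$points), 0),
                  embedding$faces, validate = FALSE)
  vertex_rings(mesh)
}

embedding_boundary <- function(embedding) {
  mesh <- trimesh(cbind(Re(embedding$points), Im(embedding$points), 0),
                  embedding$faces, validate = FALSE)
  is_boundary_vertex(mesh)
}

feature_point <- function(vertex, position, label, value) {
  structure(list(vertex = vertex, position = position, label = label,
                 value = value), class = "FeaturePoint")
}

#' @export
print.FeaturePoint <- function(x, ...) {
  cat(sprintf("FeaturePoint %s: vertex %d at (%.4g, %.4g), value %.4g\n",
              x$label, x$vertex, Re(x$position), Im(x$position), x$value))
  invisible(x)
}

#' Detect femoral head and greater trochanter on the disk parametrisation
#'
#' Finds the two most prominent interior local maxima of the conformal
#' factor over the embedded mesh graph. The femoral head (FH) is
#' disambiguated from the greater trochanter (GT) as the peak with the
#' higher conformal-factor value: the head is the largest and most
#' protruding process, so the flattening compresses it the most. (The
#' planar footprint of the fitted regions is not a reliable discriminator:
#' stronger compression shrinks the planar image of the larger feature.)
#'
#' @param disk a `PlanarEmbedding` with `domain == "disk"` and a conformal
#'   factor field.
#' @param min_prominence minimum prominence (in conformal-factor units) for
#'   a peak to count as a feature.
#' @return list with `FH` and `GT` (`FeaturePoint`s), and `peaks`
#'   (the full prominence table).
#' @export
detect_disk_features <- function(disk, min_prominence = 0.1) {
  stopifnot(inherits(disk, "PlanarEmbedding"), disk$domain == "disk")
  cf <- disk$conformal_factor
  if (is.null(cf)) stop("disk embedding has no conformal factor")
  adj <- embedding_adjacency(disk)
  bnd <- embedding_boundary(disk)
  pk <- peak_prominence(cf, adj, eligible = !bnd)
  pk <- pk[pk$prominence >= min_prominence, , drop = FALSE]
  if (nrow(pk) < 2)
    stop("detection error: found ", nrow(pk),
         " prominent interior conformal-factor peak(s), need 2 ",
         "(prominences: ",
         paste(signif(utils::head(pk$prominence, 5), 3), collapse = ", "), ")")
  cand <- pk$vertex[1:2]
  fh_i <- if (cf[cand[1]] >= cf[cand[2]]) 1L else 2L
  gt_i <- 3L - fh_i
  list(FH = feature_point(cand[fh_i], disk$points[cand[fh_i]], "FH",
                          cf[cand[fh_i]]),
       GT = feature_point(cand[gt_i], disk$points[cand[gt_i]], "GT",
                          cf[cand[gt_i]]),
       peaks = pk)
}

region_area <- function(region) {
  pi * sqrt(max(det(region$covariance), 0))
}

#' Detect the lesser trochanter on the annulus/strip parametrisation
#'
#' The lesser trochanter does not separate well from the head and greater
#' trochanter in the disk parametrisation; it is identified from the second
#' (annulus) parametrisation as the most prominent conformal-factor local
#' maximum outside the exclusion regions around FH and GT.
#'
#' @param embedding a `PlanarEmbedding` (strip or annulus) with conformal
#'   factor.
#' @param exclusion list of `FeatureRegion`s (or vertex-id vectors) whose
#'   support (dilated by one ring) is excluded; ids refer to vertices of
#'   the original surface and are matched through `orig_vertex` provenance.
#' @param min_prominence minimum prominence for a valid peak.
#' @param exclusion_sigma Mahalanobis radius (in fitted-Gaussian standard
#'   deviations) of the excluded neighbourhood around FH and GT; the
#'   feature processes extend well past their 1-sigma support, so the
#'   default excludes 3 sigma.
#' @return a `FeaturePoint` labelled "LT".
#' @export
detect_lt <- function(embedding, exclusion = list(), min_prominence = 0.02,
                      exclusion_sigma = 3) {
  stopifnot(inherits(embedding, "PlanarEmbedding"))
  cf <- embedding$conformal_factor
  if (is.null(cf)) stop("embedding has no conformal factor")
  adj <- embedding_adjacency(embedding)
  bnd <- embedding_boundary(embedding)
  excl_orig <- unique(unlist(lapply(exclusion, function(r) {
    if (inherits(r, "FeatureRegion")) {
      if (!is.null(r$mahal2)) {
        stats::na.omit(r$orig_map[r$mahal2 <= exclusion_sigma^2])
      } else r$support_orig %||% r$support
    } else r
  })))
  elig <- !bnd
  if (length(excl_orig)) {
    hit <- which(embedding$orig_vertex %in% excl_orig)
    hit <- unique(c(hit, unlist(adj[hit])))   # dilate one ring
    elig[hit] <- FALSE
  }
  pk <- peak_prominence(cf, adj, eligible = elig)
  pk <- pk[pk$prominence >= min_prominence, , drop = FALSE]
  if (nrow(pk) < 1)
    stop("detection error: no prominent conformal-factor peak outside ",
         "the exclusion regions")
  feature_point(pk$vertex[1], embedding$points[pk$vertex[1]], "LT",
                cf[pk$vertex[1]])
}

#' Fit a 2D Gaussian feature region around a peak
#'
#' Least-squares fit of `amplitude * exp(-0.5 (x-mu)' Sigma^-1 (x-mu)) +
#' offset` to the conformal factor over the watershed basin of the peak
#' (grown by one ring), with moment-based initialisation and
#' Levenberg-Marquardt refinement. The support set is every vertex of the
#' embedding whose planar position lies within Mahalanobis distance 1 of
#' the fitted centre.
#'
#' @param embedding a `PlanarEmbedding` with conformal factor.
#' @param peak a `FeaturePoint` on this embedding (a local maximum).
#' @return object of class `FeatureRegion`: list with `peak`, `centre`
#'   (complex), `covariance` (2x2), `amplitude`, `offset`, `support`
#'   (vertex ids on the embedding), `support_orig` (original-surface ids).
#' @export
fit_feature_region <- function(embedding, peak) {
  cf <- embedding$conformal_factor
  adj <- embedding_adjacency(embedding)
  basin <- watershed_basin(cf, adj, peak$vertex)
  # cap the basin at its highest exit level so the fit sees only the local
  # dome of this peak, not everything draining to it
  rim <- basin[vapply(basin, function(v) any(!(adj[[v]] %in% basin)), TRUE)]
  if (length(rim)) basin <- basin[cf[basin] >= max(cf[rim])]
  basin <- unique(c(basin, unlist(adj[basin])))
  if (length(basin) < 6)
    stop("fit error: basin of vertex ", peak$vertex, " too small to fit")
  x <- Re(embedding$points[basin]); y <- Im(embedding$points[basin])
  z <- cf[basin]
  # the offset is pinned at the basin minimum (the conformal-factor level
  # the feature process sits on): a free offset trades off against
  # amplitude and width and leaves the least-squares problem unidentified
  off0 <- min(z)
  wts <- pmax(z - off0, 0)
  if (sum(wts) <= 0) stop("fit error: degenerate (flat) field around peak")
  mx <- sum(wts * x) / sum(wts); my <- sum(wts * y) / sum(wts)
  sxx <- sum(wts * (x - mx)^2) / sum(wts)
  syy <- sum(wts * (y - my)^2) / sum(wts)
  sxy <- sum(wts * (x - mx) * (y - my)) / sum(wts)
  amp0 <- max(z) - off0
  if (amp0 <= 0) stop("fit error: zero-amplitude field around peak")
  # parametrise Sigma^-1 = U'U, U upper triangular: guarantees PD
  s0 <- solve(matrix(c(sxx, sxy, sxy, syy), 2) + diag(1e-12, 2))
  u0 <- chol(s0)
  par0 <- c(mx, my, log(u0[1, 1]), u0[1, 2], log(u0[2, 2]), log(amp0))
  model <- function(p) {
    u11 <- exp(p[3]); u12 <- p[4]; u22 <- exp(p[5])
    dx <- x - p[1]; dy <- y - p[2]
    q <- (u11 * dx + u12 * dy)^2 + (u22 * dy)^2
    exp(p[6]) * exp(-0.5 * q) + off0
  }
  fit <- minpack.lm::nls.lm(par0, fn = function(p) model(p) - z,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 1000, maxfev = 50000,
                              ftol = 1e-15, ptol = 1e-15))
  p <- c(fit$par, off0)
  u11 <- exp(p[3]); u12 <- p[4]; u22 <- exp(p[5])
  U <- matrix(c(u11, 0, u12, u22), 2)   # [u11 u12; 0 u22]
  sigma_inv <- crossprod(U)             # U'U = Sigma^-1
  covar <- solve(sigma_inv)
  if (!all(is.finite(covar)))
    stop("fit error: singular covariance in feature-region fit")
  centre <- complex(real = p[1], imaginary = p[2])
  dxa <- Re(embedding$points) - p[1]
  dya <- Im(embedding$points) - p[2]
  mahal2 <- sigma_inv[1, 1] * dxa^2 + 2 * sigma_inv[1, 2] * dxa * dya +
    sigma_inv[2, 2] * dya^2
  support <- which(mahal2 <= 1)
  structure(list(peak = peak, centre = centre, covariance = covar,
                 amplitude = exp(p[6]), offset = p[7],
                 support = support,
                 support_orig = unique(stats::na.omit(
                   embedding$orig_vertex[support])),
                 mahal2 = mahal2,
                 orig_map = embedding$orig_vertex),
            class = "FeatureRegion")
}

#' @export
print.FeatureRegion <- function(x, ...) {
  cat(sprintf(
    "FeatureRegion %s: centre (%.4g, %.4g), amp %.3g, support %d vertices\n",
    x$peak$label, Re(x$centre), Im(x$centre), x$amplitude, length(x$support)))
  invisible(x)
}

# steepest-ascent walk from `start` to its local maximum
ascend_to_peak <- function(field, adj, start) {
  cur <- start
  repeat {
    nb <- adj[[cur]]
    hi <- nb[field[nb] > field[cur]]
    if (!length(hi)) return(cur)
    cur <- hi[which.max(field[hi])]
  }
}

# vertices whose steepest-ascent path leads to `peak`
watershed_basin <- function(field, adj, peak) {
  n <- length(field)
  ord <- order(field, decreasing = TRUE)
  lab <- integer(n)
  for (v in ord) {
    nb <- adj[[v]]
    hi <- nb[field[nb] > field[v]]
    if (!length(hi)) {
      lab[v] <- v
    } else {
      lab[v] <- lab[hi[which.max(field[hi])]]
    }
  }
  which(lab == peak)
}

#' Straight inter-feature segment in the disk
#'
#' The straight planar segment between the FH and GT feature positions,
#' used to introduce the second boundary by slitting.
#'
#' @param disk a disk `PlanarEmbedding`.
#' @param fh,gt `FeaturePoint`s from [detect_disk_features()].
#' @return list with `from`, `to` (complex endpoints), `from_vertex`,
#'   `to_vertex`.
#' @export
inter_feature_segment <- function(disk, fh, gt) {
  bnd <- embedding_boundary(disk)
  if (bnd[fh$vertex] || bnd[gt$vertex])
    stop("geometry error: feature points must be interior to the disk")
  list(from = disk$points[fh$vertex], to = disk$points[gt$vertex],
       from_vertex = fh$vertex, to_vertex = gt$vertex)
}
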