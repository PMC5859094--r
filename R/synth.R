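#' Specification of a synthetic femur-like surface
#'
#' The generator emulates a proximal femur as a surface of revolution — a
#' flattened dome (epiphysis) continued by a shaft tube with one open
#' distal boundary — plus Gaussian protrusions for the femoral head (FH),
#' greater trochanter (GT) and lesser trochanter (LT). Units are mm.
#' Positions along the surface use a normalised generatrix coordinate `s`
#' (0 = apex, 1 = distal boundary) and an azimuth `theta`.
#'
#' With the default bump azimuths (FH and LT at 0, GT at pi) the mesh is
#' exactly mirror symmetric about the FH-GT plane: trigonometric tables are
#' constructed so mirrored vertices have bitwise-identical coordinates up
#' to the sign of y, and the triangulation diagonals flip across the plane.
#'
#' @param cap_radius dome radius (mm).
#' @param shaft_radius shaft tube radius (mm).
#' @param shaft_length shaft length below the dome (mm).
#' @param cap_flatten vertical scaling of the dome (1 = hemisphere).
#' @param cap_fraction fraction of the generatrix inside the dome.
#' @param bumps named list (FH, GT, LT) of lists with `theta`, `s`, `amp`
#'   (mm), `sigma_s`, `sigma_theta`; set `amp = 0` to remove a feature.
#' @param thickness cortical shell offset t0 (mm); a constant or a
#'   function(s, theta) returning per-vertex thickness.
#' @param n_theta vertices per ring (even).
#' @param n_rings rings below the apex.
#' @param size global scale multiplier.
#' @param jitter sd of seeded vertex jitter (mm; 0 keeps exact symmetry).
#' @param seed integer seed (used when jitter > 0).
#' @return object of class `FemurSpec`.
#' @export
femur_spec <- function(cap_radius = 22, shaft_radius = 15, shaft_length = 60,
                       cap_flatten = 0.45, cap_fraction = 0.35,
                       bumps = list(
                         FH = list(theta = 0, s = 0.16, amp = 13,
                                   sigma_s = 0.085, sigma_theta = 0.80),
                         GT = list(theta = pi, s = 0.30, amp = 9,
                                   sigma_s = 0.075, sigma_theta = 0.65),
                         LT = list(theta = 0, s = 0.55, amp = 4.5,
                                   sigma_s = 0.05, sigma_theta = 0.45)),
                       thickness = 2, n_theta = 28, n_rings = 40,
                       size = 1, jitter = 0, seed = 1L) {
  if (n_theta %% 2 != 0) stop("n_theta must be even")
  if (n_theta < 8 || n_rings < 8) stop("resolution too low")
  for (b in bumps) {
    if (b$amp < 0) stop("bump amplitudes must be >= 0")
  }
  if (is.numeric(thickness) && any(thickness <= 0))
    stop("thickness must be positive")
  structure(as.list(environment()), class = "FemurSpec")
}

# mirror-exact azimuth tables: cos/sin per column, plus index-based wrapped
# angular distance to an azimuth that is a multiple of pi
azimuth_tables <- function(n_theta) {
  idx <- 0:(n_theta - 1)
  jj <- pmin(idx, n_theta - idx)
  ang <- 2 * pi * jj / n_theta
  cosv <- cos(ang)
  sinv <- ifelse(idx <= n_theta / 2, sin(ang), -sin(ang))
  sinv[idx == 0 | idx == n_theta / 2] <- 0
  list(idx = idx, cosv = cosv, sinv = sinv)
}

wrapped_dtheta <- function(idx, theta_b, n_theta) {
  k2 <- theta_b * n_theta / (2 * pi)
  if (abs(k2 - round(k2)) < 1e-12) {           # on-grid azimuth: exact
    d <- abs(idx - round(k2))
    2 * pi * pmin(d, n_theta - d) / n_theta
  } else {
    th <- 2 * pi * idx / n_theta
    d <- abs(th - theta_b) %% (2 * pi)
    pmin(d, 2 * pi - d)
  }
}

#' Generate a synthetic femur-like surface pair
#'
#' Builds the outer (periosteal) surface described by a [femur_spec()] —
#' genus 0 with exactly one open distal boundary — and a concentric inner
#' (endosteal) surface offset inward along vertex normals by the thickness
#' field, with a curvature-limited step to avoid self-intersection.
#' Generation is a pure function of the spec (and its seed).
#'
#' @param spec a `FemurSpec`.
#' @return list with `outer` and `inner` (`TriMesh`es; the outer carries a
#'   `thickness` field with the applied offsets) and `ground_truth`: apex
#'   vertex ids (`FH`, `GT`, `LT`, NA when the bump amplitude is 0),
#'   requested thickness, and the spec.
#' @export
make_femur <- function(spec = femur_spec()) {
  stopifnot(inherits(spec, "FemurSpec"))
  nt <- spec$n_theta
  nr <- spec$n_rings
  az <- azimuth_tables(nt)
  s_grid <- seq_len(nr) / nr
  # generatrix (r0, z0)(s): dome for s <= cap_fraction, then tube
  gen <- function(s) {
    r0 <- numeric(length(s)); z0 <- numeric(length(s))
    cap <- s <= spec$cap_fraction
    phi <- (s[cap] / spec$cap_fraction) * (pi / 2)
    r0[cap] <- spec$cap_radius * sin(phi)
    z0[cap] <- spec$cap_flatten * spec$cap_radius * cos(phi)
    v <- (s[!cap] - spec$cap_fraction) / (1 - spec$cap_fraction)
    g <- pmin(1, v / 0.5)
    g <- 3 * g^2 - 2 * g^3
    r0[!cap] <- spec$cap_radius + (spec$shaft_radius - spec$cap_radius) * g
    z0[!cap] <- -v * spec$shaft_length
    cbind(r0, z0)
  }
  g <- gen(s_grid)
  # outward normal of the base surface of revolution, from generatrix slope
  h <- 1e-5
  gp <- (gen(pmin(1, s_grid + h)) - gen(pmax(0, s_grid - h))) /
    (pmin(1, s_grid + h) - pmax(0, s_grid - h))
  nrm2 <- cbind(-gp[, 2], gp[, 1])
  nrm2 <- nrm2 / sqrt(rowSums(nrm2^2))
  # bump amplitude field on the (s, theta) grid
  bump_amp <- function(s, dtheta_list) {
    a <- 0
    for (bi in seq_along(spec$bumps)) {
      b <- spec$bumps[[bi]]
      if (b$amp == 0) next
      a <- a + b$amp * exp(-((s - b$s)^2) / (2 * b$sigma_s^2) -
                             (dtheta_list[[bi]]^2) / (2 * b$sigma_theta^2))
    }
    a
  }
  dthetas <- lapply(spec$bumps, function(b) wrapped_dtheta(az$idx, b$theta, nt))
  n <- 1L + nr * nt
  verts <- matrix(0, n, 3)
  # apex: the pole has no azimuth, so each bump contributes its azimuthal
  # mean there (the smooth limit of the field; a zero-distance convention
  # would put a spike at the pole)
  a_apex <- 0
  for (bi in seq_along(spec$bumps)) {
    b <- spec$bumps[[bi]]
    if (b$amp == 0) next
    a_apex <- a_apex + b$amp * exp(-(b$s^2) / (2 * b$sigma_s^2)) *
      mean(exp(-dthetas[[bi]]^2 / (2 * b$sigma_theta^2)))
  }
  verts[1, ] <- c(0, 0, spec$cap_flatten * spec$cap_radius + a_apex)
  for (i in seq_len(nr)) {
    amp <- bump_amp(s_grid[i], dthetas)
    r <- g[i, 1] + amp * nrm2[i, 1]
    z <- g[i, 2] + amp * nrm2[i, 2]
    rows <- 1L + (i - 1L) * nt + seq_len(nt)
    verts[rows, ] <- cbind(r * az$cosv, r * az$sinv, z)
  }
  verts <- verts * spec$size
  if (spec$jitter > 0) {
    set.seed(spec$seed)
    verts <- verts + matrix(stats::rnorm(3 * n, sd = spec$jitter), n, 3)
  }
  # faces: apex fan + quad bands with mirror-symmetric diagonals
  vid <- function(i, j) 1L + (i - 1L) * nt + ((j - 1L) %% nt) + 1L
  faces <- matrix(0L, nt + 2L * nt * (nr - 1L), 3)
  fi <- 0L
  for (j in seq_len(nt)) {
    fi <- fi + 1L
    faces[fi, ] <- c(1L, vid(1, j), vid(1, j + 1))
  }
  for (i in seq_len(nr - 1L)) {
    for (j in seq_len(nt)) {
      A <- vid(i, j); B <- vid(i, j + 1)
      D <- vid(i + 1, j); C <- vid(i + 1, j + 1)
      if (j <= nt / 2) {
        faces[fi + 1L, ] <- c(A, D, C)
        faces[fi + 2L, ] <- c(A, C, B)
      } else {
        faces[fi + 1L, ] <- c(A, D, B)
        faces[fi + 2L, ] <- c(B, D, C)
      }
      fi <- fi + 2L
    }
  }
  # thickness field: constant, per-vertex vector, or function(s, theta)
  thick <- if (is.function(spec$thickness)) {
    s_of <- c(0, rep(s_grid, each = nt))
    th_of <- c(0, rep(2 * pi * az$idx / nt, nr))
    spec$thickness(s_of, th_of)
  } else if (length(spec$thickness) == n) {
    as.numeric(spec$thickness)
  } else if (length(spec$thickness) == 1L) {
    rep(spec$thickness, n)
  } else stop("thickness must be scalar, length-N vector, or function")
  outer_mesh <- trimesh(verts, faces, fields = list(thickness = thick))
  inner_mesh <- offset_inner_surface(outer_mesh, thick)
  gt_ids <- lapply(seq_along(spec$bumps), function(bi) {
    b <- spec$bumps[[bi]]
    if (b$amp == 0) return(NA_integer_)
    i <- which.min(abs(s_grid - b$s))
    j <- round(b$theta * nt / (2 * pi)) %% nt + 1L
    vid(i, j)
  })
  names(gt_ids) <- names(spec$bumps)
  list(outer = outer_mesh, inner = inner_mesh,
       ground_truth = list(apex = gt_ids,
                           thickness = outer_mesh$fields$thickness,
                           spec = spec))
}

# inner surface: inward vertex-normal offset with a curvature-limited step
offset_inner_surface <- function(mesh, thickness) {
  v <- mesh$vertices
  f <- mesh$faces
  e1 <- v[f[, 2], ] - v[f[, 1], ]
  e2 <- v[f[, 3], ] - v[f[, 1], ]
  fn <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  n <- nrow(v)
  vn <- matrix(0, n, 3)
  for (k in 1:3) {
    for (c3 in 1:3) {
      acc <- rowsum(fn[, c3], group = f[, k])
      vn[as.integer(rownames(acc)), c3] <- vn[as.integer(rownames(acc)), c3] + acc[, 1]
    }
  }
  vn <- vn / pmax(sqrt(rowSums(vn^2)), 1e-300)
  # curvature-limited offset: stay below the local radius of curvature,
  # estimated from the mean-curvature normal (cotangent Laplacian)
  et <- mesh_edges(mesh)
  ang <- corner_angles(mesh, et = et)
  cot <- 1 / tan(ang)
  w <- numeric(nrow(et$edges))
  acc <- rowsum(c(cot), group = c(et$face_edges))
  w[as.integer(rownames(acc))] <- 0.5 * acc[, 1]
  lap <- matrix(0, n, 3)
  wsum <- numeric(n)
  for (c3 in 1:3) {
    d <- v[et$edges[, 1], c3] - v[et$edges[, 2], c3]
    acc1 <- rowsum(w * d, group = et$edges[, 1])
    lap[as.integer(rownames(acc1)), c3] <-
      lap[as.integer(rownames(acc1)), c3] + acc1[, 1]
    acc2 <- rowsum(-w * d, group = et$edges[, 2])
    lap[as.integer(rownames(acc2)), c3] <-
      lap[as.integer(rownames(acc2)), c3] + acc2[, 1]
  }
  # mixed area per vertex ~ 1/3 of incident face areas
  fa <- 0.5 * sqrt(rowSums(cbind(
    e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
    e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
    e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])^2))
  va <- numeric(n)
  accA <- rowsum(rep(fa / 3, 3), group = c(f))
  va[as.integer(rownames(accA))] <- accA[, 1]
  hmag <- sqrt(rowSums(lap^2)) / (2 * pmax(va, 1e-300))  # |mean curvature|
  t_eff <- pmin(thickness, 0.8 / pmax(hmag, 1e-6))
  # one smoothing pass over the clamped offsets: abrupt clamp transitions
  # otherwise pinch the inner shell into slivers
  adj <- vertex_rings(mesh)
  t_eff <- vapply(seq_len(n), function(i)
    mean(c(t_eff[i], t_eff[adj[[i]]])), 0)
  t_eff <- pmin(thickness, t_eff)
  trimesh(v - vn * t_eff, f, validate = FALSE)
}

#' Vertices within a graph-ring radius of a centre vertex
#'
#' @param mesh a `TriMesh` (or face matrix via `faces =`).
#' @param center centre vertex id.
#' @param rings number of 1-ring dilations.
#' @return integer vertex ids (including the centre).
#' @export
region_around <- function(mesh, center, rings = 3) {
  adj <- if (inherits(mesh, "TriMesh")) vertex_rings(mesh) else
    vertex_rings(trimesh(matrix(0, max(mesh), 3), mesh, validate = FALSE))
  cur <- center
  for (k in seq_len(rings)) cur <- unique(c(cur, unlist(adj[cur])))
  sort(cur)
}

#' Specification of a synthetic cohort
#'
#' Describes a control group plus loading groups with planted effects on
#' per-vertex fields, subject-level shape variation (shaft length, global
#' size, bump positions along the generatrix; azimuths stay fixed), and
#' covariates (body weight in kg, sideways-fall impact force in N).
#'
#' @param base a `FemurSpec` shared by all subjects before perturbation.
#' @param n_control control-group size.
#' @param groups named list; each entry a list with `n` and optionally
#'   `effect` = list(`region` (vertex ids on the base outer mesh, e.g. from
#'   [region_around()]), `pct` (percent thickness change), `field`
#'   ("thickness")).
#' @param noise_sd_pct per-vertex multiplicative thickness noise, percent.
#' @param between_sd_pct between-subject global thickness variation,
#'   percent.
#' @param smooth_steps neighbour-averaging steps applied to the log noise
#'   field (makes the noise spatially correlated, as biological variation
#'   is).
#' @param shaft_sd,size_sd,bump_s_sd log-normal / normal perturbation
#'   scales for shaft length, global size and bump generatrix positions.
#' @param weight_mean,weight_sd,impact_mean,impact_sd covariate
#'   distributions (kg, N).
#' @param seed integer seed.
#' @return object of class `CohortSpec`.
#' @export
cohort_spec <- function(base = femur_spec(), n_control = 20,
                        groups = list(HI = list(n = 20, effect = list(
                          region = NULL, pct = 30, field = "thickness"))),
                        noise_sd_pct = 10, between_sd_pct = 5,
                        smooth_steps = 2,
                        shaft_sd = 0.08, size_sd = 0.05, bump_s_sd = 0.01,
                        weight_mean = 65, weight_sd = 8,
                        impact_mean = 2600, impact_sd = 350, seed = 1L) {
  if (n_control < 2 || any(vapply(groups, function(g) g$n, 0) < 2))
    stop("config error: need n >= 2 per group")
  structure(as.list(environment()), class = "CohortSpec")
}

#' Generate a synthetic cohort of femur surface pairs
#'
#' Draws per-subject shape perturbations and thickness fields with the
#' planted group effects of a [cohort_spec()], and generates the outer and
#' inner meshes. A group's effect multiplies thickness by `1 + pct/100`
#' over its region (default: the region around the planted LT apex).
#'
#' @param spec a `CohortSpec`.
#' @param generate_meshes build the meshes (default TRUE); otherwise only
#'   specs and the cohort table are returned.
#' @return list with `subjects` (per subject: `id`, `group`, `spec`, and
#'   when generated `outer`, `inner`, `ground_truth`), `cohort`
#'   (data.frame: subject_id, group, weight_kg, impact_force_N, size_mult,
#'   shaft_mult), `effects` (per group: region and pct), `spec`.
#' @export
make_cohort <- function(spec, generate_meshes = TRUE) {
  stopifnot(inherits(spec, "CohortSpec"))
  set.seed(spec$seed)
  base_fem <- make_femur(spec$base)
  n_vert <- nrow(base_fem$outer$vertices)
  adj <- vertex_rings(base_fem$outer)
  groups <- c(list(control = list(n = spec$n_control)), spec$groups)
  effects <- list()
  for (g in names(spec$groups)) {
    ef <- spec$groups[[g]]$effect
    if (is.null(ef)) next
    if (is.null(ef$region))
      ef$region <- region_around(base_fem$outer,
                                 base_fem$ground_truth$apex$LT, rings = 4)
    if (is.null(ef$field)) ef$field <- "thickness"
    effects[[g]] <- ef
  }
  subjects <- list()
  rows <- list()
  k <- 0L
  for (g in names(groups)) {
    for (i in seq_len(groups[[g]]$n)) {
      k <- k + 1L
      id <- sprintf("%s_%02d", g, i)
      size_mult <- exp(stats::rnorm(1, 0, spec$size_sd))
      shaft_mult <- exp(stats::rnorm(1, 0, spec$shaft_sd))
      bumps <- spec$base$bumps
      for (b in seq_along(bumps)) {
        bumps[[b]]$s <- min(0.95, max(0.05,
          bumps[[b]]$s + stats::rnorm(1, 0, spec$bump_s_sd)))
      }
      # thickness: base level x subject level x smooth vertex noise x effect
      subj_mult <- exp(stats::rnorm(1, 0, spec$between_sd_pct / 100))
      lognoise <- stats::rnorm(n_vert, 0, spec$noise_sd_pct / 100)
      for (st in seq_len(spec$smooth_steps)) {
        lognoise <- vapply(seq_len(n_vert), function(v)
          mean(c(lognoise[v], lognoise[adj[[v]]])), 0)
      }
      tfield <- spec$base$thickness * subj_mult * exp(lognoise)
      if (!is.null(effects[[g]]) && effects[[g]]$field == "thickness") {
        tfield[effects[[g]]$region] <-
          tfield[effects[[g]]$region] * (1 + effects[[g]]$pct / 100)
      }
      fs <- spec$base
      fs$bumps <- bumps
      fs$size <- spec$base$size * size_mult
      fs$shaft_length <- spec$base$shaft_length * shaft_mult
      fs$thickness <- tfield * size_mult   # thickness scales with the bone
      subj <- list(id = id, group = g, spec = fs)
      if (generate_meshes) {
        fem <- make_femur(fs)
        subj$outer <- fem$outer
        subj$inner <- fem$inner
        subj$ground_truth <- fem$ground_truth
      }
      subjects[[k]] <- subj
      rows[[k]] <- data.frame(
        subject_id = id, group = g,
        weight_kg = stats::rnorm(1, spec$weight_mean, spec$weight_sd),
        impact_force_N = stats::rnorm(1, spec$impact_mean, spec$impact_sd),
        size_mult = size_mult, shaft_mult = shaft_mult)
    }
  }
  list(subjects = subjects, cohort = do.call(rbind, rows),
       effects = effects, spec = spec)
}

#' Simulate per-node feature cohorts on a fixed template
#'
#' Desk-scale generator for the statistical machinery: per-subject feature
#' fields (e.g. cortical thickness) on a shared template, with optional
#' planted group effects, spatially smoothed multiplicative noise and
#' subject-level variation - no meshes involved.
#'
#' @param faces template connectivity (defines the smoothing/cluster
#'   graph).
#' @param n_nodes number of template nodes.
#' @param n_control,n_group group sizes.
#' @param base per-node baseline (scalar or length-n vector), mm.
#' @param effect_nodes vertex ids carrying the effect (empty = null
#'   cohort).
#' @param effect_pct percent increase in the effect group.
#' @param noise_sd_pct per-node multiplicative noise, percent.
#' @param between_sd_pct subject-level variation, percent.
#' @param smooth_steps neighbour-averaging steps for the noise field.
#' @param seed integer seed.
#' @return list with `features` (n_nodes x S), `group` (factor:
#'   control/loaded), `effect_nodes`.
#' @export
simulate_thickness_cohort <- function(faces, n_nodes, n_control = 20,
                                      n_group = 20, base = 2,
                                      effect_nodes = integer(0),
                                      effect_pct = 30, noise_sd_pct = 10,
                                      between_sd_pct = 5, smooth_steps = 2,
                                      seed = 1L) {
  set.seed(seed)
  edges <- template_edges(faces)
  adj <- vector("list", n_nodes)
  sp1 <- split(edges[, 2], edges[, 1])
  sp2 <- split(edges[, 1], edges[, 2])
  for (nm in names(sp1)) adj[[as.integer(nm)]] <- sp1[[nm]]
  for (nm in names(sp2)) {
    i <- as.integer(nm); adj[[i]] <- c(adj[[i]], sp2[[nm]])
  }
  s <- n_control + n_group
  base <- rep(base, length.out = n_nodes)
  feat <- matrix(0, n_nodes, s)
  grp <- factor(rep(c("control", "loaded"), c(n_control, n_group)),
                levels = c("control", "loaded"))
  for (j in seq_len(s)) {
    lognoise <- stats::rnorm(n_nodes, 0, noise_sd_pct / 100)
    for (st in seq_len(smooth_steps)) {
      lognoise <- vapply(seq_len(n_nodes), function(v)
        mean(c(lognoise[v], lognoise[adj[[v]]])), 0)
    }
    f <- base * exp(stats::rnorm(1, 0, between_sd_pct / 100)) * exp(lognoise)
    if (grp[j] == "loaded" && length(effect_nodes))
      f[effect_nodes] <- f[effect_nodes] * (1 + effect_pct / 100)
    feat[, j] <- f
  }
  list(features = feat, group = grp, effect_nodes = effect_nodes)
}
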