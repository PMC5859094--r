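fix_cohort3 <- function() memo("cohort3", {
  co <- make_cohort(cohort_spec(
    n_control = 3, groups = list(), seed = 21,
    shaft_sd = 0.12, size_sd = 0.05, bump_s_sd = 0.015),
    generate_meshes = TRUE)
  params <- lapply(co$subjects, function(s)
    parametrise_femur(s$outer, tolerance = 1e-10))
  list(co = co, params = params)
})

test_that("self-registration is the identity to 1e-9", {
  par <- fix_param()
  tmpl <- make_template(par)             # uncropped template from itself
  iso <- build_isotopological_set(tmpl, list(par))
  expect_length(iso$errors, 0)
  truth <- par$slit$mesh3$vertices[tmpl$keep, , drop = FALSE]
  expect_lt(max(abs(iso$coords[[1]] - truth)), 1e-9)
  th_truth <- par$slit$mesh3$fields$thickness[tmpl$keep]
  expect_lt(max(abs(iso$fields$thickness[, 1] - th_truth)), 1e-9)
})

test_that("Wendland RBF interpolates exactly and has exact compact support", {
  par1 <- fix_cohort3()$params[[1]]
  par2 <- fix_cohort3()$params[[2]]
  tmpl <- make_template(par1, cohort_distal_limit(fix_cohort3()$params))
  def <- build_rbf(tmpl$regions, list(FH = par2$regions$FH_strip,
                                      LT = par2$regions$LT_strip))
  ctrl <- complex(real = def$control[, 1], imaginary = def$control[, 2])
  target <- ctrl + complex(real = def$displacement[, 1],
                           imaginary = def$displacement[, 2])
  expect_lt(max(abs(rbf_deform(def, ctrl) - target)), 1e-9)
  # displacement is identically zero beyond rho from all control points
  set.seed(3)
  far <- complex(real = runif(50, -50, 50), imaginary = runif(50, -50, 50))
  dmin <- vapply(far, function(z) min(abs(z - ctrl)), 0)
  far <- far[dmin > def$rho]
  expect_identical(rbf_deform(def, far), far)
  # feature centres coincide after deformation
  moved_fh <- rbf_deform(def, tmpl$regions$FH$centre)
  expect_lt(abs(moved_fh - par2$regions$FH_strip$centre), 1e-6)
  moved_lt <- rbf_deform(def, tmpl$regions$LT$centre)
  expect_lt(abs(moved_lt - par2$regions$LT_strip$centre), 1e-6)

  # identical template and target regions: zero displacement field
  def0 <- build_rbf(tmpl$regions, tmpl$regions)
  set.seed(4)
  pts <- complex(real = runif(100, -10, 0), imaginary = runif(100, 0, 2 * pi))
  expect_lt(max(abs(rbf_deform(def0, pts) - pts)), 1e-9)

  # pure translation: displacement parallel to the shift, exact at centres,
  # never overshooting, and zero beyond the support
  tr <- 0.3 - 0.2i
  shifted <- lapply(tmpl$regions, function(r) {
    r$centre <- r$centre + tr
    r
  })
  deft <- build_rbf(tmpl$regions, shifted)
  samp <- tmpl$regions$FH$centre +
    complex(real = runif(30, -0.2, 0.2), imaginary = runif(30, -0.2, 0.2))
  disp <- rbf_deform(deft, samp) - samp
  expect_lt(max(abs(Arg(disp / tr))[abs(disp) > 1e-12]), 1e-9)
  # interpolation between controls can overshoot the translation slightly
  expect_lte(max(abs(disp)), abs(tr) * 1.05)
  expect_equal(rbf_deform(deft, tmpl$regions$FH$centre),
               tmpl$regions$FH$centre + tr)
})

test_that("natural representation locates nodes with valid barycentric weights", {
  par <- fix_param()
  st <- par$strip
  # nodes at target vertices get weight 1 on that vertex
  map <- natural_representation(st$points[1:50], st)
  expect_true(all(abs(rowSums(map$weights) - 1) < 1e-12))
  expect_true(all(map$weights >= 0))
  for (i in 1:50) {
    f <- st$faces[map$face[i], ]
    w <- map$weights[i, ]
    expect_equal(sum(w * st$points[f]), st$points[i], tolerance = 1e-9)
  }
  # a node beyond the distal extent is clamped and flagged
  outside <- min(Re(st$points)) - 1 + 1i * pi
  map2 <- natural_representation(outside, st)
  expect_true(map2$clamped[1])
  expect_true(all(map2$weights >= 0))
})

test_that("resampling has linear precision and reproduces constants", {
  par <- fix_param()
  st <- par$strip
  m3 <- par$slit$mesh3
  lin <- 2.5 * Re(st$points) - 1.25 * Im(st$points) + 0.5
  tgt <- m3
  tgt$fields <- list(const = rep(3.14, length(st$points)), lin = lin)
  set.seed(6)
  q <- complex(real = runif(200, quantile(Re(st$points), 0.2),
                            quantile(Re(st$points), 0.8)),
               imaginary = runif(200, 1, 5))
  map <- natural_representation(q, st)
  rs <- resample(map, tgt)
  expect_lt(max(abs(rs$fields$const - 3.14)), 1e-12)
  keep <- !map$clamped
  expect_lt(max(abs(rs$fields$lin[keep] -
                      (2.5 * Re(q[keep]) - 1.25 * Im(q[keep]) + 0.5))), 1e-9)
})

test_that("a shape-varying cohort registers into one isotopological set", {
  cc <- fix_cohort3()
  tmpl <- make_template(cc$params[[1]], cohort_distal_limit(cc$params))
  iso <- build_isotopological_set(tmpl, cc$params,
                                  subject_ids = cc$co$cohort$subject_id)
  expect_length(iso$errors, 0)
  expect_identical(dim(iso$fields$thickness),
                   c(length(tmpl$points), 3L))
  # same connectivity, different geometry
  expect_gt(max(abs(iso$coords[[1]] - iso$coords[[2]])), 1)
  # clamped nodes (if any) hug the template domain boundary - RBF-corrected
  # nodes can only leave the target domain near its edges
  cl <- which(rowSums(iso$clamped) > 0)
  if (length(cl) > 0) {
    tm <- trimesh(cbind(Re(tmpl$points), Im(tmpl$points), 0), tmpl$faces,
                  validate = FALSE)
    near_bnd <- region_around(tm, which(is_boundary_vertex(tm)), rings = 3)
    expect_true(all(cl %in% near_bnd))
  }
})

test_that("a subject shorter than the template distal limit clamps only distal rows", {
  par <- fix_param()
  short <- make_femur(femur_spec(shaft_length = 45))
  par2 <- parametrise_femur(short$outer, tolerance = 1e-10)
  tmpl <- make_template(par)   # full extent of the longer subject
  iso <- build_isotopological_set(tmpl, list(par2))
  expect_length(iso$errors, 0)
  cl <- which(iso$clamped[, 1])
  expect_gt(length(cl), 0)
  # every template node deeper than the short subject's domain is clamped
  deeper <- which(Re(tmpl$points) < min(Re(par2$strip$points)))
  expect_true(all(deeper %in% cl))
  # and the clamped set is dominated by the distal rows
  expect_gt(mean(Re(tmpl$points[cl]) <
                   stats::quantile(Re(tmpl$points), 0.25)), 0.85)
})

test_that("rigid 3D motion of a subject moves resampled coordinates rigidly and leaves fields unchanged", {
  par1 <- fix_param()
  par2 <- fix_param_moved()
  tr <- rigid_scale_transform()
  tmpl <- make_template(par1, distal_limit = 0.9 * -min(Re(par1$strip$points)))
  iso <- build_isotopological_set(tmpl, list(par1, par2))
  expect_length(iso$errors, 0)
  moved <- sweep(tr$s * iso$coords[[1]] %*% t(tr$R), 2, tr$t, "+")
  # the strip coordinates themselves agree to ~1e-13 (conformal invariance);
  # the residual here is amplified through the feature-region fits
  expect_lt(max(abs(iso$coords[[2]] - moved)), 5e-6)
  expect_lt(max(abs(iso$fields$thickness[, 2] -
                      iso$fields$thickness[, 1])), 1e-9)
})
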