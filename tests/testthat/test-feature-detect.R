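test_that("FH and GT are found at the planted apices and disambiguated by region size", {
  fem <- fix_femur()
  par <- fix_param()
  det <- detect_disk_features(par$disk)
  adj <- vertex_rings(fem$outer)
  within_ring <- function(v, truth)
    v == truth || v %in% adj[[truth]]
  expect_true(within_ring(det$FH$vertex, fem$ground_truth$apex$FH))
  expect_true(within_ring(det$GT$vertex, fem$ground_truth$apex$GT))
  # FH is the more compressed (higher conformal factor) process, and its
  # fitted support region stays clear of the GT peak
  expect_gt(det$FH$value, det$GT$value)
  expect_false(det$GT$vertex %in% par$regions$FH_disk$support)
})

test_that("detection is invariant under rigid motion plus uniform scale", {
  det1 <- detect_disk_features(fix_param()$disk)
  det2 <- detect_disk_features(fix_param_moved()$disk)
  expect_identical(det1$FH$vertex, det2$FH$vertex)
  expect_identical(det1$GT$vertex, det2$GT$vertex)
})

test_that("detection is invariant under vertex-order permutation", {
  fem <- make_femur(femur_spec(n_theta = 20, n_rings = 28))
  set.seed(5)
  perm <- sample.int(nrow(fem$outer$vertices))
  inv <- integer(length(perm))
  inv[perm] <- seq_along(perm)
  shuffled <- trimesh(fem$outer$vertices[perm, ],
                      matrix(inv[fem$outer$faces], ncol = 3),
                      fields = lapply(fem$outer$fields, function(x) x[perm]))
  m1 <- ricci_flow_metric(fem$outer, "disk_free_boundary", tolerance = 1e-10)
  m2 <- ricci_flow_metric(shuffled, "disk_free_boundary", tolerance = 1e-10)
  d1 <- detect_disk_features(embed_disk(fem$outer, m1))
  d2 <- detect_disk_features(embed_disk(shuffled, m2))
  expect_identical(d1$FH$vertex, perm[d2$FH$vertex])
  expect_identical(d1$GT$vertex, perm[d2$GT$vertex])
})

test_that("a single-peak surface is a detection error, as is a missing LT", {
  spec <- femur_spec(bumps = list(
    FH = list(theta = 0, s = 0.16, amp = 13, sigma_s = 0.085,
              sigma_theta = 0.80),
    GT = list(theta = pi, s = 0.30, amp = 0, sigma_s = 0.075,
              sigma_theta = 0.65),
    LT = list(theta = 0, s = 0.55, amp = 0, sigma_s = 0.05,
              sigma_theta = 0.45)))
  fem <- make_femur(spec)
  met <- ricci_flow_metric(fem$outer, "disk_free_boundary")
  expect_error(detect_disk_features(embed_disk(fem$outer, met)),
               "detection error")

  # LT bump removed: the strip has no prominent peak left
  spec2 <- femur_spec(bumps = list(
    FH = list(theta = 0, s = 0.16, amp = 13, sigma_s = 0.085,
              sigma_theta = 0.80),
    GT = list(theta = pi, s = 0.30, amp = 9, sigma_s = 0.075,
              sigma_theta = 0.65),
    LT = list(theta = 0, s = 0.55, amp = 0, sigma_s = 0.05,
              sigma_theta = 0.45)))
  fem2 <- make_femur(spec2)
  par2 <- parametrise_femur(fem2$outer)
  expect_false(par2$log$lt_detected)
  expect_error(detect_lt(par2$strip,
                         exclusion = list(par2$regions$FH_disk,
                                          par2$regions$GT_disk)),
               "detection error")
})

test_that("LT is detected near its apex and is stable under shaft-length changes", {
  fem <- fix_femur()
  par <- fix_param()
  expect_true(par$log$lt_detected)
  lt_orig <- par$slit$orig_vertex[par$features$LT_strip$vertex]
  adj <- vertex_rings(fem$outer)
  expect_true(lt_orig == fem$ground_truth$apex$LT ||
                lt_orig %in% adj[[fem$ground_truth$apex$LT]])
  # LT sits on the mirror plane: strip imaginary coordinate pi
  expect_equal(Im(par$features$LT_strip$position), pi, tolerance = 1e-6)

  # longer shaft (same grid): same source vertex up to one ring
  fem2 <- make_femur(femur_spec(shaft_length = 80))
  par2 <- parametrise_femur(fem2$outer, tolerance = 1e-10)
  lt2 <- par2$slit$orig_vertex[par2$features$LT_strip$vertex]
  expect_true(lt2 == lt_orig || lt2 %in% adj[[lt_orig]])
})

test_that("feature detection hits planted apices across a perturbed cohort", {
  co <- make_cohort(cohort_spec(
    n_control = 10,
    groups = list(g = list(n = 10, effect = NULL)),
    seed = 42), generate_meshes = TRUE)
  hits <- 0L
  total <- 0L
  for (s in co$subjects) {
    par <- parametrise_femur(s$outer)
    adj <- vertex_rings(s$outer)
    near <- function(v, truth) v == truth || v %in% adj[[truth]]
    gt <- s$ground_truth$apex
    total <- total + 3L
    hits <- hits +
      near(par$features$FH_disk$vertex, gt$FH) +
      near(par$features$GT_disk$vertex, gt$GT) +
      (par$log$lt_detected &&
         near(par$slit$orig_vertex[par$features$LT_strip$vertex], gt$LT))
  }
  expect_gte(hits / total, 0.95)
})

test_that("the Gaussian region fit recovers an exact isotropic Gaussian field", {
  g <- grid_mesh(21, 21, dx = 0.15)   # [0,3]^2: the far corners carry
  ctr <- c(1.5, 1.5)                  # a negligible Gaussian tail
  s <- 0.3
  r2 <- (g$vertices[, 1] - ctr[1])^2 + (g$vertices[, 2] - ctr[2])^2
  field <- 2.5 * exp(-r2 / (2 * s^2)) + 0.7
  emb <- flat_embedding(g, conformal_factor = field)
  peak_v <- which.min(r2)
  region <- fit_feature_region(emb, feature_point(peak_v, emb$points[peak_v],
                                                  "FH", field[peak_v]))
  expect_lt(max(abs(region$covariance - diag(s^2, 2))), 1e-6)
  expect_equal(region$amplitude, 2.5, tolerance = 1e-6)
  expect_equal(region$offset, 0.7, tolerance = 1e-6)
  # support = vertices within one (fitted) standard deviation; vertices
  # exactly on the rim may flip with the fit's 1e-7-level covariance error
  expect_true(all(which(r2 <= s^2 * (1 - 1e-4)) %in% region$support))
  expect_true(all(region$support %in% which(r2 <= s^2 * (1 + 1e-4))))

  # flat (zero-amplitude) field cannot be fitted
  emb0 <- flat_embedding(g, conformal_factor = rep(1, nrow(g$vertices)))
  expect_error(fit_feature_region(emb0, feature_point(peak_v,
                                                      emb$points[peak_v],
                                                      "FH", 1)),
               "fit error")
})

test_that("the inter-feature segment is interior and FH normalises to pi", {
  par <- fix_param()
  seg <- inter_feature_segment(par$disk, par$features$FH_disk,
                               par$features$GT_disk)
  expect_equal(seg$from, par$disk$points[par$features$FH_disk$vertex])
  # FH at imaginary coordinate pi on the strip; GT copies at 0 and 2*pi
  fh_strip <- par$strip$points[par$features$fh_strip_id]
  expect_equal(Im(fh_strip), pi, tolerance = 1e-6)
  expect_equal(Re(fh_strip), 0, tolerance = 1e-9)
  gt_imag <- sort(Im(par$strip$points[par$features$gt_strip_ids]))
  expect_equal(gt_imag, c(0, 2 * pi), tolerance = 1e-9)
})
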