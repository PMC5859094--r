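fix_spm_template <- function() memo("spm_template", {
  tmpl <- fix_template()
  list(faces = tmpl$faces, n = length(tmpl$points))
})

test_that("node-wise OLS recovers noiseless coefficients and the pooled t", {
  tp <- fix_spm_template()
  set.seed(20)
  s <- 24
  grp <- factor(rep(c("control", "loaded"), each = s / 2),
                levels = c("control", "loaded"))
  w <- rnorm(s, 65, 8)
  des <- spm_design(grp, "loaded", covariates = data.frame(w = w))
  beta_true <- rbind(2, 0.4, 0.01)   # intercept, group, weight
  Y <- des$X %*% beta_true %*% matrix(1, 1, 50)
  fit <- fit_node_models(t(Y), des)
  expect_lt(max(abs(fit$beta - as.numeric(beta_true))), 1e-9)

  # two-group design without covariates equals the closed-form pooled t
  sim <- simulate_thickness_cohort(tp$faces, tp$n, 10, 10, seed = 20)
  des2 <- spm_design(sim$group, "loaded")
  fit2 <- fit_node_models(sim$features, des2)
  x <- sim$features[, sim$group == "loaded"]
  y <- sim$features[, sim$group == "control"]
  pooled <- function(i) {
    nx <- ncol(x); ny <- ncol(y)
    sp <- sqrt(((nx - 1) * var(x[i, ]) + (ny - 1) * var(y[i, ])) /
                 (nx + ny - 2))
    (mean(x[i, ]) - mean(y[i, ])) / (sp * sqrt(1 / nx + 1 / ny))
  }
  oracle <- vapply(seq_len(tp$n), pooled, 0)
  expect_lt(max(abs(fit2$t - oracle)), 1e-9)

  # consistent row permutation leaves the t-map unchanged
  set.seed(21)
  pm <- sample(ncol(sim$features))
  des3 <- spm_design(sim$group[pm], "loaded")
  fit3 <- fit_node_models(sim$features[, pm], des3)
  expect_equal(fit3$t, fit2$t, tolerance = 1e-12)

  # collinear designs are rejected with the offending column named
  expect_error(spm_design(sim$group, "loaded",
                          covariates = data.frame(
                            a = as.numeric(sim$group == "loaded"))),
               "design error.*a")
})

test_that("an orthogonal confound changes t only through residual df", {
  tp <- fix_spm_template()
  sim <- simulate_thickness_cohort(tp$faces, tp$n, 10, 10, seed = 22)
  feat <- sim$features[1:10, , drop = FALSE]  # rank room for an orthogonal column
  des <- spm_design(sim$group, "loaded")
  fit1 <- fit_node_models(feat, des)
  # a column orthogonal to the design and to every node's data
  q <- qr.Q(qr(cbind(des$X, t(feat))), complete = TRUE)
  extra <- q[, ncol(q)]
  expect_lt(max(abs(crossprod(extra, cbind(des$X, t(feat))))), 1e-9)
  des2 <- des
  des2$X <- cbind(des$X, extra)
  des2$contrast <- c(des$contrast, 0)
  fit2 <- fit_node_models(feat, des2)
  expect_equal(fit2$t * sqrt(fit1$df / fit2$df), fit1$t, tolerance = 1e-9)
  expect_equal(fit2$contrast_estimate, fit1$contrast_estimate,
               tolerance = 1e-9)
})

test_that("the thickness mask excludes exactly the thin patch", {
  tp <- fix_spm_template()
  thin <- region_around(trimesh(matrix(0, tp$n, 3), tp$faces,
                                validate = FALSE), 400, rings = 3)
  base <- rep(2, tp$n)
  base[thin] <- 0.6
  sim <- simulate_thickness_cohort(tp$faces, tp$n, 10, 10, base = base,
                                   noise_sd_pct = 2, seed = 23)
  mask <- build_mask(sim$features, threshold = 1,
                     control = sim$group == "control")
  expect_setequal(which(!mask), thin)
  expect_true(all(build_mask(sim$features, threshold = 0)))
})

test_that("supra-threshold clustering splits planted patches into components", {
  tp <- fix_spm_template()
  g <- trimesh(matrix(0, tp$n, 3), tp$faces, validate = FALSE)
  p1 <- region_around(g, 300, rings = 3)
  p2 <- region_around(g, 900, rings = 3)
  expect_length(intersect(p1, p2), 0)
  df <- 38
  mask <- rep(TRUE, tp$n)
  t0 <- rep(0, tp$n)
  expect_length(supra_threshold_clusters(t0, df, mask, tp$faces), 0)
  t1 <- t0; t1[p1] <- 10
  cl1 <- supra_threshold_clusters(t1, df, mask, tp$faces)
  expect_length(cl1, 1)
  expect_setequal(cl1[[1]], p1)
  t2 <- t1; t2[p2] <- 8
  cl2 <- supra_threshold_clusters(t2, df, mask, tp$faces)
  expect_length(cl2, 2)
  # one-sided direction: negative effects need direction = "less"
  expect_length(supra_threshold_clusters(-t1, df, mask, tp$faces), 0)
  expect_length(supra_threshold_clusters(-t1, df, mask, tp$faces,
                                         direction = "less"), 1)
})

test_that("permutation inference is seeded, deterministic and finds planted effects", {
  tp <- fix_spm_template()
  g <- trimesh(matrix(0, tp$n, 3), tp$faces, validate = FALSE)
  eff <- region_around(g, 500, rings = 4)
  sim <- simulate_thickness_cohort(tp$faces, tp$n, 20, 20,
                                   effect_nodes = eff, effect_pct = 30,
                                   seed = 24)
  des <- spm_design(sim$group, "loaded")
  mask <- rep(TRUE, tp$n)
  r1 <- cluster_inference(sim$features, des, mask, tp$faces,
                          n_perm = 300, seed = 7)
  r2 <- cluster_inference(sim$features, des, mask, tp$faces,
                          n_perm = 300, seed = 7)
  expect_identical(r1$clusters$p, r2$clusters$p)
  expect_identical(r1$null_max_extent, r2$null_max_extent)
  expect_true(any(r1$clusters$significant))
  best <- r1$cluster_nodes[[which.min(r1$clusters$p)]]
  expect_gte(dice_overlap(best, eff), 0.5)
  expect_error(cluster_inference(sim$features, des, mask, tp$faces,
                                 n_perm = 300), "seed")
  expect_warning(cluster_inference(sim$features, des, mask, tp$faces,
                                   n_perm = 50, seed = 1), "n_perm")
})

test_that("rft inference approximates cluster significance", {
  tp <- fix_spm_template()
  g <- trimesh(matrix(0, tp$n, 3), tp$faces, validate = FALSE)
  eff <- region_around(g, 500, rings = 4)
  sim <- simulate_thickness_cohort(tp$faces, tp$n, 20, 20,
                                   effect_nodes = eff, effect_pct = 40,
                                   seed = 25)
  des <- spm_design(sim$group, "loaded")
  r <- cluster_inference(sim$features, des, rep(TRUE, tp$n), tp$faces,
                         method = "rft")
  expect_true(all(r$clusters$p >= 0 & r$clusters$p <= 1))
  expect_lt(r$clusters$p[which.max(r$clusters$extent)], 0.05)
  # warning on small meshes
  small <- make_femur(femur_spec(n_theta = 10, n_rings = 12))
  sm <- simulate_thickness_cohort(small$outer$faces,
                                  nrow(small$outer$vertices), 8, 8,
                                  seed = 26)
  expect_warning(cluster_inference(sm$features,
                                   spm_design(sm$group, "loaded"),
                                   rep(TRUE, nrow(small$outer$vertices)),
                                   small$outer$faces, method = "rft"),
                 "rft|unreliable")
})

test_that("node-wise parametric p-values are uniform under the null", {
  tp <- fix_spm_template()
  ps <- c()
  for (k in 1:50) {
    sim <- simulate_thickness_cohort(tp$faces, tp$n, 10, 10,
                                     smooth_steps = 0, between_sd_pct = 0,
                                     seed = 400 + k)
    des <- spm_design(sim$group, "loaded")
    fit <- fit_node_models(sim$features, des)
    ps <- c(ps, stats::pt(fit$t, fit$df, lower.tail = FALSE))
  }
  ks <- stats::ks.test(ps, "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("percent differences summarise clusters and respect rescaling", {
  tp <- fix_spm_template()
  g <- trimesh(matrix(0, tp$n, 3), tp$faces, validate = FALSE)
  eff <- region_around(g, 500, rings = 4)
  grp <- factor(rep(c("control", "loaded"), each = 10),
                levels = c("control", "loaded"))
  feat <- matrix(2, tp$n, 20)
  feat[, grp == "loaded"] <- 2 * 1.3
  res <- structure(list(
    clusters = data.frame(id = 1L, extent = length(eff), p = 0.001,
                          significant = TRUE),
    cluster_nodes = list(eff)), class = "SpmResult")
  pd <- percent_difference_summary(res, feat, grp == "loaded",
                                   grp == "control")
  expect_equal(pd$mean_pct_diff, 30, tolerance = 1e-12)
  pd2 <- percent_difference_summary(res, feat * 7.3, grp == "loaded",
                                    grp == "control")
  expect_equal(pd2$mean_pct_diff, pd$mean_pct_diff, tolerance = 1e-12)
  # equal groups: zero percent difference
  pd0 <- percent_difference_summary(res, matrix(2, tp$n, 20),
                                    grp == "loaded", grp == "control")
  expect_equal(pd0$mean_pct_diff, 0)
  # recovered magnitude on a simulated 40%-patch cohort
  sim <- simulate_thickness_cohort(tp$faces, tp$n, 20, 20,
                                   effect_nodes = eff, effect_pct = 40,
                                   seed = 30)
  des <- spm_design(sim$group, "loaded")
  r <- cluster_inference(sim$features, des, rep(TRUE, tp$n), tp$faces,
                         n_perm = 300, seed = 3)
  pd3 <- percent_difference_summary(r, sim$features,
                                    sim$group == "loaded",
                                    sim$group == "control")
  expect_true(any(pd3$mean_pct_diff > 35 & pd3$mean_pct_diff < 45))
})

test_that("composite maps label nodes by the responsible group set", {
  tp <- fix_spm_template()
  g <- trimesh(matrix(0, tp$n, 3), tp$faces, validate = FALSE)
  pa <- region_around(g, 300, rings = 4)
  nb <- setdiff(pa, 300)[1]
  pb <- region_around(g, nb, rings = 2)    # overlaps pa, shifted centre
  mk <- function(nodes, sig = TRUE) structure(list(
    t = rep(0, tp$n),
    clusters = data.frame(id = 1L, extent = length(nodes), p = 0.01,
                          significant = sig),
    cluster_nodes = list(nodes)), class = "SpmResult")
  lab <- composite_map(list(A = mk(seq_len(tp$n))), tp$n)
  expect_true(all(lab == "A"))
  lab2 <- composite_map(list(A = mk(pa), B = mk(pb)), tp$n)
  both <- intersect(pa, pb)
  expect_true(length(both) > 0)
  expect_true(all(lab2[both] == "A+B"))
  expect_true(all(lab2[setdiff(pa, pb)] == "A"))
  expect_true(all(lab2[-union(pa, pb)] == "n/s"))
  lab3 <- composite_map(list(A = mk(pa, sig = FALSE)), tp$n)
  expect_true(all(lab3 == "n/s"))
  expect_error(composite_map(list(A = mk(pa)), tp$n + 5), "argument error")
})
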